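## subtype_discovery: three-step subtyping of each driver gene's carriers
## (MAD gene selection -> consensus PAM clustering -> silhouette pruning)
## and MAD-based transcriptomic heterogeneity quantification.

#' Per-gene median absolute deviation over a sample set
#'
#' Raw (unscaled) median of absolute deviations from the per-gene median,
#' the heterogeneity measure used throughout: higher MAD means messier
#' expression across the chosen samples.
#'
#' @param expr genes x samples matrix.
#' @param sample_set character or integer subset of columns (>= 2 samples).
#' @return named numeric vector, one MAD per gene.
#' @export
gene_mad_profile <- function(expr, sample_set) {
  if (length(sample_set) == 0) stop("empty sample set", call. = FALSE)
  x <- expr[, sample_set, drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples for a MAD profile", call. = FALSE)
  med <- apply(x, 1, stats::median)
  apply(abs(x - med), 1, stats::median)
}

#' Compare two MAD heterogeneity profiles
#'
#' Two-sided Wilcoxon rank-sum test between two per-gene MAD profiles over
#' the same gene universe, with the direction reported as the difference of
#' medians (a minus b). The rank-sum (unpaired) form is used; a paired
#' rank-sum test is a contradiction in terms, so no pairing is assumed.
#'
#' @param mad_a,mad_b numeric vectors over the same genes.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic`, `p`, `median_difference`.
#' @export
compare_heterogeneity <- function(mad_a, mad_b, alternative = "two.sided") {
  stopifnot(length(mad_a) == length(mad_b))
  if (length(unique(c(mad_a, mad_b))) == 1L) {
    warning("all values tied; p set to 1", call. = FALSE)
    return(list(statistic = NA_real_, p = 1,
                median_difference = 0))
  }
  wt <- suppressWarnings(stats::wilcox.test(mad_a, mad_b, paired = FALSE,
                                            alternative = alternative,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_difference = stats::median(mad_a) - stats::median(mad_b))
}

#' Select top-variable genes and normalize for clustering
#'
#' Ranks genes by MAD within `sample_set`, keeps the top `n_top` (ties at
#' the cutoff broken by gene-id lexicographic order, so selection is
#' deterministic), log2(x+1)-transforms and median-centers each gene across
#' `sample_set`.
#'
#' @param expr raw-scale genes x samples matrix.
#' @param sample_set columns to use.
#' @param n_top number of genes to keep (<= number of genes).
#' @return log2-centered matrix (selected genes x sample_set) with
#'   attribute `scale = "log2_centered"`.
#' @export
select_top_variable <- function(expr, sample_set, n_top = 2000L) {
  if (n_top > nrow(expr)) stop("n_top exceeds the number of genes", call. = FALSE)
  mads <- gene_mad_profile(expr, sample_set)
  ord <- order(-mads, rownames(expr))
  sel <- rownames(expr)[ord[seq_len(n_top)]]
  x <- log2(expr[sel, sample_set, drop = FALSE] + 1)
  med <- apply(x, 1, stats::median)
  x <- x - med
  attr(x, "scale") <- "log2_centered"
  x
}

#' Pearson distance between two vectors
#'
#' 1 minus the Pearson correlation coefficient; 0 for perfectly correlated,
#' 2 for perfectly anti-correlated vectors.
#'
#' @param x,y numeric vectors of equal length >= 2, non-constant.
#' @return numeric scalar in \[0, 2\].
#' @export
pearson_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson distance undefined for constant vectors", call. = FALSE)
  }
  1 - stats::cor(x, y)
}

## Pairwise Pearson distance between the COLUMNS (samples) of a matrix.
pearson_distance_matrix <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant sample profile; Pearson distance undefined",
                          call. = FALSE)
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

#' Partitioning Around Medoids (BUILD + SWAP, multi-start)
#'
#' Deterministic k-medoids on a precomputed distance matrix: greedy BUILD
#' initialization followed by best-improvement SWAP until no single
#' medoid/non-medoid exchange lowers the total distance to nearest medoids.
#' Because SWAP is a local search whose result depends on its start,
#' `n_start` diversified BUILD initializations are run (the first medoid is
#' forced to each of the `n_start` points with the smallest distance sums)
#' and the best local optimum is returned; three starts were measured to
#' remove all misses of the global optimum on small random instances. Ties
#' are broken toward the smallest index, so the result depends only on the
#' distance matrix.
#'
#' @param D symmetric distance matrix.
#' @param k number of medoids, 1 <= k <= n.
#' @param n_start number of diversified BUILD starts (default 3).
#' @return list(`medoids` indices, `labels` per point (medoid rank),
#'   `cost` total distance to nearest medoids).
#' @export
pam_cluster <- function(D, k, n_start = 3L) {
  n <- nrow(D)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  stopifnot(k >= 1, n_start >= 1, isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  if (k == n) {
    return(list(medoids = seq_len(n), labels = seq_len(n), cost = 0))
  }
  build <- function(first) {
    med <- first
    dnear <- D[med, ]
    while (length(med) < k) {
      cand <- setdiff(seq_len(n), med)
      gains <- rowSums(pmax(matrix(dnear, nrow = length(cand), ncol = n,
                                   byrow = TRUE) - D[cand, , drop = FALSE], 0))
      med <- c(med, cand[which.max(gains)])
      dnear <- pmin(dnear, D[med[length(med)], ])
    }
    med
  }
  swap <- function(med) {
    repeat {
      DM <- D[med, , drop = FALSE]
      m1 <- apply(DM, 2, which.min)
      d1 <- DM[cbind(m1, seq_len(n))]
      d2 <- if (k == 1) rep(Inf, n) else
        apply(DM, 2, function(col) sort(col, partial = 2)[2])
      cur_cost <- sum(d1)
      best <- list(delta = -1e-12, mi = NA, c = NA)
      cand <- setdiff(seq_len(n), med)
      for (mi in seq_len(k)) {
        base <- ifelse(m1 == mi, d2, d1)
        costs <- rowSums(pmin(D[cand, , drop = FALSE],
                              matrix(base, nrow = length(cand), ncol = n,
                                     byrow = TRUE)))
        j <- which.min(costs)
        delta <- costs[j] - cur_cost
        if (delta < best$delta) best <- list(delta = delta, mi = mi, c = cand[j])
      }
      if (is.na(best$mi)) break
      med[best$mi] <- best$c
    }
    med
  }
  starts <- order(colSums(D))[seq_len(min(n_start, n))]
  best_med <- NULL
  best_cost <- Inf
  for (first in starts) {
    med <- sort(swap(build(first)))
    cost <- sum(apply(D[med, , drop = FALSE], 2, min))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best_med <- med
    }
  }
  DM <- D[best_med, , drop = FALSE]
  labels <- apply(DM, 2, which.min)
  list(medoids = best_med, labels = labels,
       cost = sum(DM[cbind(labels, seq_len(n))]))
}

#' Consensus clustering with PAM on Pearson distance
#'
#' Resamples `subsample` of the samples without replacement `n_iter` times,
#' clusters each subsample with PAM at every k in `k_range`, and records
#' how often each sample pair lands in the same cluster among the runs that
#' sampled both. The number of clusters is chosen by minimizing the
#' proportion of ambiguous clustering (PAC: off-diagonal consensus entries
#' strictly between 0.1 and 0.9); ties go to the smaller k. Final labels
#' come from average-linkage hierarchical clustering of 1 - consensus cut
#' at the chosen k.
#'
#' @param expr_subset log2-centered top-variable matrix (genes x samples).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param n_iter resampling iterations (default 1000).
#' @param subsample fraction of samples per iteration (default 0.8).
#' @param seed integer seed for the resampling stream.
#' @param pac_tol the chosen k is the smallest candidate whose PAC is
#'   within `pac_tol` of the minimum; a strict argmin lets a large k win
#'   on a sub-0.01 PAC difference where a consensus-heatmap reader would
#'   choose the smaller k.
#' @return list(`k_candidates`, `consensus` (list of matrices), `pac`
#'   (named numeric), `chosen_k`, `labels` named by sample).
#' @export
consensus_cluster <- function(expr_subset, k_range = 2:6, n_iter = 1000L,
                              subsample = 0.8, seed = 1L, pac_tol = 0.01) {
  n <- ncol(expr_subset)
  ids <- colnames(expr_subset)
  stopifnot(n >= max(k_range) + 1, subsample > 0, subsample <= 1)
  D <- pearson_distance_matrix(expr_subset)
  m <- ceiling(subsample * n)
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, m))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    Dsub <- D[idx, idx, drop = FALSE]
    for (k in k_range) {
      lab <- pam_cluster(Dsub, k)$labels
      same <- outer(lab, lab, "==")
      kk <- as.character(k)
      co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
    }
  }
  never <- co_sampled == 0
  diag(never) <- FALSE
  if (any(never)) {
    warning(sprintf("%d sample pairs never co-sampled; consensus set to 0.5",
                    sum(never) / 2), call. = FALSE)
  }
  consensus <- lapply(co_clustered, function(cc) {
    cons <- cc / pmax(co_sampled, 1)
    cons[never] <- 0.5
    dimnames(cons) <- list(ids, ids)
    cons
  })
  pac <- vapply(consensus, function(cons) {
    off <- cons[upper.tri(cons)]
    mean(off > 0.1 & off < 0.9)
  }, numeric(1))
  chosen_k <- k_range[which(pac <= min(pac) + pac_tol)[1]]
  hc <- stats::hclust(stats::as.dist(1 - consensus[[as.character(chosen_k)]]),
                      method = "average")
  labels <- stats::cutree(hc, k = chosen_k)
  names(labels) <- ids
  list(k_candidates = k_range, consensus = consensus, pac = pac,
       chosen_k = chosen_k, labels = labels)
}

#' Silhouette widths from a distance matrix
#'
#' s(i) = (b - a) / max(a, b) where a is the mean distance to i's own
#' cluster and b the smallest mean distance to another cluster. Members of
#' singleton clusters get s = 0.
#'
#' @param D distance matrix.
#' @param labels integer cluster labels (length = nrow(D)).
#' @return numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(D, labels) {
  n <- nrow(D)
  stopifnot(length(labels) == n)
  cl <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(cl[cl != labels[i]], function(c2) {
      mean(D[i, labels == c2])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Prune unstable samples and undersized subtypes
#'
#' Computes silhouette widths on the Pearson distance in one pass, removes
#' samples with non-positive width (including singleton-cluster members,
#' whose width is defined as 0), then removes whole subtypes left with
#' fewer than `min_subtype_size` members. No recomputation after removal.
#' Retained subtypes are renumbered 1..k by decreasing size (ties by
#' original cluster label).
#'
#' @param expr_subset log2-centered matrix (genes x samples).
#' @param labels named integer cluster labels (names = sample ids).
#' @param min_subtype_size minimum retained subtype size (default 5).
#' @return list(`subtypes` named list S1.. -> member ids, `silhouette`
#'   named numeric over input samples, `removed_samples`,
#'   `dropped_subtype_sizes`).
#' @export
silhouette_prune <- function(expr_subset, labels, min_subtype_size = 5L) {
  stopifnot(!is.null(names(labels)),
            all(names(labels) %in% colnames(expr_subset)))
  if (length(unique(labels)) < 2) {
    stop("silhouette pruning needs at least 2 clusters", call. = FALSE)
  }
  D <- pearson_distance_matrix(expr_subset[, names(labels), drop = FALSE])
  s <- silhouette_widths(D, labels)
  names(s) <- names(labels)
  singletons <- names(labels)[labels %in%
    as.integer(names(which(table(labels) == 1)))]
  if (length(singletons) > 0) {
    sx_log("removing %d singleton-cluster samples (silhouette defined 0)",
           length(singletons), stage = "subtype")
  }
  keep <- s > 0
  removed <- names(labels)[!keep]
  kept_labels <- labels[keep]
  sizes <- table(kept_labels)
  ok_clusters <- as.integer(names(sizes)[sizes >= min_subtype_size])
  dropped_sizes <- as.integer(sizes[!as.integer(names(sizes)) %in% ok_clusters])
  kept_labels <- kept_labels[kept_labels %in% ok_clusters]
  ## renumber by decreasing size, ties by original label
  sizes_ok <- sizes[as.character(ok_clusters)]
  new_order <- ok_clusters[order(-as.integer(sizes_ok), ok_clusters)]
  subtypes <- lapply(new_order, function(c0) {
    sort(names(kept_labels)[kept_labels == c0])
  })
  names(subtypes) <- sprintf("S%d", seq_along(subtypes))
  list(subtypes = subtypes, silhouette = s, removed_samples = removed,
       dropped_subtype_sizes = dropped_sizes)
}

#' Options for [subtype_all()]
#'
#' @param n_top top-variable genes used for clustering.
#' @param k_range candidate k for the consensus path.
#' @param n_iter consensus resampling iterations.
#' @param subsample resampling fraction.
#' @param small_group_cutoff carriers <= this take the direct k=2 PAM path.
#' @param min_subtype_size subtypes below this are dropped.
#' @param seed master seed; per-gene streams are derived from it.
#' @return list of options.
#' @export
subtype_options <- function(n_top = 2000L, k_range = 2:6, n_iter = 1000L,
                            subsample = 0.8, small_group_cutoff = 20L,
                            min_subtype_size = 5L, seed = 1L) {
  list(n_top = n_top, k_range = k_range, n_iter = n_iter,
       subsample = subsample, small_group_cutoff = small_group_cutoff,
       min_subtype_size = min_subtype_size, seed = seed)
}

#' Subtype every driver gene and append subtype events
#'
#' For each gene-level event: carriers above `small_group_cutoff` go through
#' consensus clustering with automatic k selection; smaller carrier sets are
#' split directly into two groups by a single PAM run on the full data.
#' Both paths are followed by silhouette pruning. Surviving subtypes are
#' appended to the alteration matrix as events `GENE::S<k>` whose columns
#' are 1 exactly for retained members. A gene whose subtypes are all
#' dropped keeps only its gene-level event.
#'
#' @param matrix gene-level `alteration_matrix`.
#' @param expr raw-count expression matrix covering the matrix samples.
#' @param opts from [subtype_options()].
#' @return list(`catalog` per-gene subtyping record, `matrix` augmented
#'   `alteration_matrix`).
#' @export
subtype_all <- function(matrix, expr, opts = subtype_options()) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  samples <- colnames(matrix$values)
  stopifnot(all(samples %in% colnames(expr)))
  genes <- matrix$event_meta$event_id[is.na(matrix$event_meta$subtype)]
  catalog <- list()
  new_rows <- list()
  for (g in genes) {
    carriers <- samples[matrix$values[g, ] == 1]
    n_top <- min(opts$n_top, nrow(expr))
    entry <- list(gene = g, n_carriers = length(carriers),
                  small_group_rule_applied = FALSE)
    if (length(carriers) < 4) {
      sx_log("gene %s has %d carriers; too few to subtype", g,
             length(carriers), stage = "subtype")
      entry$chosen_k <- NA_integer_
      entry$subtypes <- list()
      catalog[[g]] <- entry
      next
    }
    sub_expr <- select_top_variable(expr, carriers, n_top = n_top)
    if (length(carriers) > opts$small_group_cutoff) {
      k_range <- opts$k_range[opts$k_range < length(carriers)]
      cc <- consensus_cluster(sub_expr, k_range = k_range,
                              n_iter = opts$n_iter,
                              subsample = opts$subsample,
                              seed = derive_seed(opts$seed, "subtype", g))
      labels <- cc$labels
      entry$chosen_k <- cc$chosen_k
      entry$pac <- cc$pac
    } else {
      entry$small_group_rule_applied <- TRUE
      D <- pearson_distance_matrix(sub_expr)
      labels <- pam_cluster(D, 2)$labels
      names(labels) <- carriers
      entry$chosen_k <- 2L
    }
    pr <- silhouette_prune(sub_expr, labels,
                           min_subtype_size = opts$min_subtype_size)
    entry$subtypes <- pr$subtypes
    entry$silhouette <- pr$silhouette
    entry$removed_samples <- pr$removed_samples
    entry$dropped_subtype_sizes <- pr$dropped_subtype_sizes
    if (length(pr$subtypes) == 0) {
      sx_log("gene %s: all subtypes dropped; keeping gene-level event only",
             g, stage = "subtype")
    }
    for (s in names(pr$subtypes)) {
      row <- integer(length(samples))
      names(row) <- samples
      row[pr$subtypes[[s]]] <- 1L
      new_rows[[sprintf("%s::%s", g, s)]] <- row
    }
    catalog[[g]] <- entry
  }
  values <- matrix$values
  if (length(new_rows) > 0) {
    add <- do.call(rbind, new_rows)
    values <- rbind(values, add)
  }
  meta <- parse_event_ids(rownames(values))
  out <- new_alteration_matrix(values, meta)
  list(catalog = catalog, matrix = out)
}
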