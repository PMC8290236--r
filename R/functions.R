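## functions_mapping: expression filter, subtype-vs-wild-type differential
## expression with a negative-binomial Wald test, hypergeometric gene-set
## enrichment, and function assignment to exclusive pairs/triples by
## enrichment-set intersection.

#' Wild-type samples for a set of genes
#'
#' A sample is wild-type for `genes` if it carries no non-silent mutation
#' in any of them, judged from the gene-level rows of the alteration
#' matrix. This single definition is shared by the differential-expression
#' and survival modules.
#'
#' @param matrix `alteration_matrix` containing gene-level rows.
#' @param genes character vector of gene symbols.
#' @return character vector of wild-type sample ids.
#' @export
wildtype_samples <- function(matrix, genes) {
  stopifnot(inherits(matrix, "alteration_matrix"),
            all(genes %in% rownames(matrix$values)))
  block <- matrix$values[genes, , drop = FALSE]
  colnames(matrix$values)[colSums(block) == 0]
}

#' Filter to detectably expressed genes
#'
#' Keeps genes whose count exceeds `min_count` (strictly) in at least
#' `min_frac` of the samples.
#'
#' @param expr_counts raw count matrix, genes x samples.
#' @param min_count count threshold (strict, default 1).
#' @param min_frac minimum fraction of samples (default 0.30).
#' @return filtered count matrix.
#' @export
filter_expressed <- function(expr_counts, min_count = 1, min_frac = 0.30) {
  frac <- rowMeans(expr_counts > min_count)
  expr_counts[frac >= min_frac, , drop = FALSE]
}

## median-of-ratios size factors; genes with any zero are excluded from the
## geometric-mean reference
size_factors <- function(counts) {
  all_pos <- rowSums(counts == 0) == 0
  if (sum(all_pos) < 10) {
    ## fall back to library-size factors on sparse data
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
}

#' Differential expression: subtype vs wild-type
#'
#' Per-gene negative-binomial model with median-of-ratios size factors and
#' a method-of-moments dispersion (pooled across the two groups, floored at
#' 1e-8), fitted by IRLS with a log link and the size factor as offset; the
#' group coefficient is tested with a two-sided Wald test and BH-adjusted.
#' A gene is called differentially expressed when |log2 fold change| >=
#' `lfc_threshold` and q < `q_threshold`.
#'
#' @param expr raw counts (already through [filter_expressed()]).
#' @param subtype_samples,wildtype_samples disjoint sample id vectors
#'   (each of size >= 2).
#' @param lfc_threshold DEG |log2FC| cutoff (default 1).
#' @param q_threshold DEG FDR cutoff (default 0.05).
#' @return data.frame per gene: `log2_fc` (subtype over wild-type), `p`,
#'   `q`, `mean_subtype`, `mean_wildtype`, `dispersion`, `deg`.
#' @export
de_test <- function(expr, subtype_samples, wildtype_samples,
                    lfc_threshold = 1, q_threshold = 0.05) {
  if (length(subtype_samples) < 2 || length(wildtype_samples) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (length(intersect(subtype_samples, wildtype_samples)) > 0) {
    stop("subtype and wild-type groups overlap", call. = FALSE)
  }
  use <- c(wildtype_samples, subtype_samples)
  stopifnot(all(use %in% colnames(expr)))
  counts <- expr[, use, drop = FALSE]
  sf <- size_factors(counts)
  x <- c(rep(0, length(wildtype_samples)), rep(1, length(subtype_samples)))
  norm <- sweep(counts, 2, sf, "/")
  ## pooled method-of-moments dispersion per gene:
  ## Var(K/s) ~ mu * E(1/s) + alpha * mu^2 within each group
  disp <- vapply(seq_len(nrow(counts)), function(g) {
    alphas <- vapply(c(0, 1), function(grp) {
      v <- norm[g, x == grp]
      s <- sf[x == grp]
      mu_g <- mean(v)
      if (mu_g <= 0) return(NA_real_)
      (stats::var(v) - mu_g * mean(1 / s)) / mu_g^2
    }, numeric(1))
    a <- mean(alphas, na.rm = TRUE)
    if (is.nan(a)) a <- 0
    max(a, 1e-8)
  }, numeric(1))
  off <- log(sf)
  res <- t(vapply(seq_len(nrow(counts)), function(g) {
    nb_wald_two_group(counts[g, ], x, off, disp[g])
  }, numeric(3)))
  log2_fc <- res[, 1] / log(2)
  p <- res[, 2]
  out <- data.frame(
    gene = rownames(counts),
    log2_fc = log2_fc,
    p = p,
    q = NA_real_,
    mean_subtype = rowMeans(norm[, x == 1, drop = FALSE]),
    mean_wildtype = rowMeans(norm[, x == 0, drop = FALSE]),
    dispersion = disp,
    stringsAsFactors = FALSE
  )
  out$q <- bh_fdr(out$p)
  out$deg <- abs(out$log2_fc) >= lfc_threshold & out$q < q_threshold
  rownames(out) <- NULL
  out
}

## NB GLM with log link, offset, fixed dispersion alpha, design ~ group.
## Returns c(beta1, p, se). IRLS/Newton on (beta0, beta1).
nb_wald_two_group <- function(y, x, off, alpha) {
  if (all(y == y[1])) {
    ## identical counts everywhere: no group difference by construction
    return(c(0, 1, NA_real_))
  }
  m0 <- sum(y[x == 0]) / sum(exp(off[x == 0]))
  m1 <- sum(y[x == 1]) / sum(exp(off[x == 1]))
  eps <- 0.5 / length(y)
  beta <- c(log(max(m0, eps)), log(max(m1, eps)) - log(max(m0, eps)))
  for (it in 1:50) {
    eta <- beta[1] + beta[2] * x + off
    mu <- exp(pmin(eta, 30))
    w <- mu / (1 + alpha * mu)
    z <- (y - mu) / mu
    ## score and Fisher information for (beta0, beta1)
    u <- c(sum(w * z), sum(w * z * x))
    I11 <- sum(w); I12 <- sum(w * x); I22 <- sum(w * x * x)
    det <- I11 * I22 - I12^2
    if (det <= 1e-12) break
    step <- c(I22 * u[1] - I12 * u[2], I11 * u[2] - I12 * u[1]) / det
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- beta[1] + beta[2] * x + off
  mu <- exp(pmin(eta, 30))
  w <- mu / (1 + alpha * mu)
  I11 <- sum(w); I12 <- sum(w * x); I22 <- sum(w * x * x)
  det <- I11 * I22 - I12^2
  se <- sqrt(I11 / det)
  zstat <- beta[2] / se
  p <- 2 * stats::pnorm(-abs(zstat))
  c(beta[2], max(p, .Machine$double.xmin), se)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test of each term against the query
#' gene set, BH-corrected across terms. Terms are first intersected with
#' the universe and kept only if their effective size lies inside
#' `size_bounds`.
#'
#' @param query_genes character vector (must be a subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of testable genes.
#' @param size_bounds keep terms with effective size in this range.
#' @param q_threshold significance threshold.
#' @return data.frame per tested term: `term`, `term_size`, `query_size`,
#'   `overlap`, `p`, `q`, `significant`.
#' @export
enrich <- function(query_genes, gene_sets, universe,
                   size_bounds = c(5L, 2000L), q_threshold = 0.05) {
  empty <- data.frame(term = character(0), term_size = integer(0),
                      query_size = integer(0), overlap = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(query_genes) == 0) return(empty)
  stopifnot(all(query_genes %in% universe))
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  sets <- lapply(gene_sets, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= size_bounds[1] & sizes <= size_bounds[2]
  sets <- sets[keep]
  if (length(sets) == 0) return(empty)
  N <- length(universe); K <- length(query_genes)
  rows <- lapply(names(sets), function(term) {
    ts <- length(sets[[term]])
    ov <- length(intersect(sets[[term]], query_genes))
    p <- stats::phyper(ov - 1, ts, N - ts, K, lower.tail = FALSE)
    data.frame(term = term, term_size = ts, query_size = K, overlap = ov,
               p = max(p, .Machine$double.xmin), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Functions of a mutually exclusive pair
#'
#' The function set of a pair is the intersection of the two member
#' subtypes' significant enrichment terms: what both transcriptomic
#' contexts converge on, under the functional-redundancy reading of mutual
#' exclusivity.
#'
#' @param pair character vector of the two subtype event ids.
#' @param enrichment_tables named list (event id -> [enrich()] table).
#' @return character vector of shared significant term ids.
#' @export
pair_functions <- function(pair, enrichment_tables) {
  stopifnot(length(pair) == 2)
  for (ev in pair) {
    if (is.null(enrichment_tables[[ev]])) {
      stop("no enrichment table for event ", ev, call. = FALSE)
    }
  }
  sig <- lapply(pair, function(ev) {
    tab <- enrichment_tables[[ev]]
    tab$term[tab$significant]
  })
  sort(intersect(sig[[1]], sig[[2]]))
}

#' Functions of a mutually exclusive triple
#'
#' Terms appearing in at least two of the triple's three pair function
#' sets.
#'
#' @param pair_function_sets list of 3 character vectors.
#' @return character vector of term ids.
#' @export
triple_functions <- function(pair_function_sets) {
  stopifnot(length(pair_function_sets) == 3)
  terms <- unlist(lapply(pair_function_sets, unique))
  counts <- table(terms)
  sort(names(counts)[counts >= 2])
}
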