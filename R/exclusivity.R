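## exclusivity: margin-constrained maximum-entropy background model for
## binary alteration matrices and the exact Poisson-binomial test for
## mutual exclusivity / co-occurrence, at gene level, subtype level, and
## for triples.

#' Fit the maximum-entropy background model
#'
#' Models P(event i altered in sample j) as logistic(mu_i + lambda_j) and
#' fits mu (per-event effect) and lambda (per-sample mutation load) so that
#' every expected row and column margin matches the observed margin. This
#' is the maximum-entropy distribution over independent Bernoulli entries
#' subject to the margin constraints; it lets frequently mutated samples
#' carry higher background probabilities, which is what makes the
#' exclusivity test robust to mutation-load heterogeneity.
#'
#' Fitting alternates vectorized Newton sweeps on rows and columns.
#' All-zero / all-one rows and columns are degenerate: their probabilities
#' are pinned to 0 or 1 and excluded from fitting (applied repeatedly until
#' stable).
#'
#' @param matrix an `alteration_matrix` or plain 0/1 matrix.
#' @param tol maximum allowed |expected - observed| margin residual.
#' @param max_iter maximum number of row+column sweeps.
#' @return object of class `background_model`: `p` (probability matrix),
#'   `mu`, `lambda`, `max_margin_residual`, `degenerate_rows/cols`.
#' @export
fit_background <- function(matrix, tol = 1e-6, max_iter = 5000L) {
  X <- if (inherits(matrix, "alteration_matrix")) matrix$values else matrix
  stopifnot(all(X %in% c(0L, 1L)))
  n_r <- nrow(X); n_c <- ncol(X)
  p <- matrix(NA_real_, n_r, n_c, dimnames = dimnames(X))
  ## peel degenerate rows/columns iteratively
  active_r <- rep(TRUE, n_r); active_c <- rep(TRUE, n_c)
  repeat {
    changed <- FALSE
    rs <- rowSums(X[, active_c, drop = FALSE])
    nz <- sum(active_c)
    for (i in which(active_r)) {
      if (rs[i] %in% c(0L, nz) || nz == 0) {
        p[i, active_c] <- if (nz > 0 && rs[i] == nz) 1 else 0
        active_r[i] <- FALSE
        changed <- TRUE
      }
    }
    cs <- colSums(X[active_r, , drop = FALSE])
    nzr <- sum(active_r)
    for (j in which(active_c)) {
      if (cs[j] %in% c(0L, nzr) || nzr == 0) {
        p[active_r, j] <- if (nzr > 0 && cs[j] == nzr) 1 else 0
        active_c[j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mu <- stats::setNames(rep(NA_real_, n_r), rownames(X))
  lam <- stats::setNames(rep(NA_real_, n_c), colnames(X))
  max_res <- 0
  if (any(active_r) && any(active_c)) {
    A <- X[active_r, active_c, drop = FALSE]
    r_obs <- rowSums(A); c_obs <- colSums(A)
    m <- sx_logit(mean(A))
    mu_a <- sx_logit(r_obs / ncol(A)) - m / 2
    lam_a <- sx_logit(c_obs / nrow(A)) - m / 2
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ## Newton step on every row effect simultaneously
      for (rep_i in 1:2) {
        Pa <- sx_logistic(outer(mu_a, lam_a, "+"))
        g <- rowSums(Pa) - r_obs
        h <- rowSums(Pa * (1 - Pa))
        mu_a <- mu_a - g / pmax(h, 1e-12)
      }
      for (rep_j in 1:2) {
        Pa <- sx_logistic(outer(mu_a, lam_a, "+"))
        g <- colSums(Pa) - c_obs
        h <- colSums(Pa * (1 - Pa))
        lam_a <- lam_a - g / pmax(h, 1e-12)
      }
      Pa <- sx_logistic(outer(mu_a, lam_a, "+"))
      max_res <- max(abs(rowSums(Pa) - r_obs), abs(colSums(Pa) - c_obs))
      if (max_res <= tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf("background model did not converge: max margin residual %.3g > tol %.3g",
                   max_res, tol), call. = FALSE)
    }
    p[active_r, active_c] <- Pa
    mu[active_r] <- mu_a
    lam[active_c] <- lam_a
  }
  structure(list(p = p, mu = mu, lambda = lam,
                 max_margin_residual = max_res,
                 degenerate_rows = rownames(X)[!active_r],
                 degenerate_cols = colnames(X)[!active_c]),
            class = "background_model")
}

#' Extend a gene-level background model to subtype events
#'
#' Per-sample load effects lambda are a property of samples, so they are
#' fitted once on the gene-level matrix and frozen; each subtype row then
#' gets its own mu fitted by Newton so that its expected row sum matches
#' the observed subtype carrier count. This prevents the disjoint subtype
#' rows of one gene from distorting the sample loads.
#'
#' @param model gene-level `background_model`.
#' @param matrix augmented `alteration_matrix` containing subtype events.
#' @param tol margin tolerance for the per-row fits.
#' @return `background_model` whose `p` covers all events in `matrix`.
#' @export
extend_background <- function(model, matrix, tol = 1e-6) {
  stopifnot(inherits(model, "background_model"),
            inherits(matrix, "alteration_matrix"))
  X <- matrix$values
  samples <- colnames(X)
  stopifnot(all(samples %in% colnames(model$p)))
  lam <- model$lambda[samples]
  active_c <- !is.na(lam)
  p <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  mu <- stats::setNames(rep(NA_real_, nrow(X)), rownames(X))
  gene_rows <- rownames(X)[rownames(X) %in% rownames(model$p)]
  p[gene_rows, ] <- model$p[gene_rows, samples]
  mu[gene_rows] <- model$mu[gene_rows]
  new_rows <- setdiff(rownames(X), gene_rows)
  for (ev in new_rows) {
    ## degenerate columns are pinned to the observed value; the row target
    ## counts only the active columns, so the full expected row sum still
    ## equals the observed carrier count
    x <- X[ev, ]
    p[ev, !active_c] <- x[!active_c]
    target <- sum(x[active_c])
    if (target == 0 || target == sum(active_c)) {
      p[ev, active_c] <- if (target == 0) 0 else 1
      next
    }
    m <- sx_logit(target / sum(active_c))
    for (it in 1:200) {
      pe <- sx_logistic(m + lam[active_c])
      g <- sum(pe) - target
      if (abs(g) <= tol) break
      m <- m - g / max(sum(pe * (1 - pe)), 1e-12)
    }
    p[ev, active_c] <- sx_logistic(m + lam[active_c])
    mu[ev] <- m
  }
  structure(list(p = p, mu = mu, lambda = lam,
                 max_margin_residual = model$max_margin_residual,
                 degenerate_rows = model$degenerate_rows,
                 degenerate_cols = model$degenerate_cols),
            class = "background_model")
}

#' Exact Poisson-binomial CDF
#'
#' P(X <= x) for X the sum of independent Bernoulli variables with success
#' probabilities `probs`, by exact dynamic-programming convolution. Only
#' the first x+1 states are tracked, so the cost is O(n * x) and the
#' computation is numerically stable for n up to 10^4.
#'
#' @param probs numeric vector in \[0, 1\].
#' @param x integer threshold.
#' @return P(X <= x) in \[0, 1\].
#' @export
poisson_binomial_cdf <- function(probs, x) {
  stopifnot(all(probs >= 0), all(probs <= 1))
  n <- length(probs)
  if (x < 0) return(0)
  if (x >= n) return(1)
  x <- as.integer(x)
  f <- c(1, numeric(x))  # f[k+1] = P(X = k) over processed entries
  for (p in probs) {
    shifted <- c(0, f[seq_len(x)])
    f <- f * (1 - p) + shifted * p
  }
  min(1, sum(f))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with enforced monotonicity; the output is in the
#' input order.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  stopifnot(all(p > 0), all(p <= 1))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Test one event pair for mutual exclusivity or co-occurrence
#'
#' The observed overlap o (samples altered in both events) is compared to
#' its distribution under the background model, where sample j contributes
#' an independent Bernoulli with probability p_aj * p_bj. The mutual
#' exclusivity p-value is P(X <= o), the co-occurrence p-value P(X >= o).
#' Subtype events of the same gene are structurally exclusive and are
#' refused.
#'
#' @param model `background_model` covering both events.
#' @param matrix `alteration_matrix` containing both events.
#' @param event_a,event_b event ids.
#' @param direction "mutual_exclusivity" or "co_occurrence".
#' @return list(`event_a`, `event_b`, `overlap`, `expected_overlap`,
#'   `direction`, `p_value`).
#' @export
test_pair <- function(model, matrix, event_a, event_b,
                      direction = c("mutual_exclusivity", "co_occurrence")) {
  direction <- match.arg(direction)
  meta <- matrix$event_meta
  ga <- meta$gene[meta$event_id == event_a]
  gb <- meta$gene[meta$event_id == event_b]
  if (length(ga) != 1 || length(gb) != 1) {
    stop("event not present in the alteration matrix", call. = FALSE)
  }
  sa <- meta$subtype[meta$event_id == event_a]
  sb <- meta$subtype[meta$event_id == event_b]
  if (ga == gb && (!is.na(sa) || !is.na(sb)) && event_a != event_b) {
    stop(sprintf("%s and %s belong to the same gene: structural exclusivity, refusing to test",
                 event_a, event_b), call. = FALSE)
  }
  xa <- matrix$values[event_a, ]
  xb <- matrix$values[event_b, ]
  o <- sum(xa == 1L & xb == 1L)
  pp <- model$p[event_a, colnames(matrix$values)] *
    model$p[event_b, colnames(matrix$values)]
  p_val <- if (direction == "mutual_exclusivity") {
    poisson_binomial_cdf(pp, o)
  } else {
    1 - poisson_binomial_cdf(pp, o - 1)
  }
  list(event_a = event_a, event_b = event_b, overlap = o,
       expected_overlap = sum(pp), direction = direction,
       p_value = max(p_val, .Machine$double.xmin))
}

#' Screen all admissible event pairs for ME and CO
#'
#' Tests every unordered pair of events at the requested level (gene-level
#' events or subtype events), in both directions. Same-gene subtype pairs
#' are structurally exclusive and skipped. Benjamini-Hochberg correction is
#' applied within each direction family separately. Pairs are emitted in
#' lexicographic event order.
#'
#' @param matrix `alteration_matrix` (with subtype events for
#'   `level = "subtype"`).
#' @param model `background_model` covering the tested events.
#' @param level "gene" or "subtype".
#' @param q_threshold significance threshold on the BH q-value.
#' @return data.frame with columns event_a, event_b, gene_a, gene_b,
#'   overlap, expected, direction, p, q, significant.
#' @export
screen_pairs <- function(matrix, model, level = c("gene", "subtype"),
                         q_threshold = 0.05) {
  level <- match.arg(level)
  meta <- matrix$event_meta
  ids <- if (level == "gene") meta$event_id[is.na(meta$subtype)]
         else meta$event_id[!is.na(meta$subtype)]
  ids <- sort(ids)
  if (length(ids) < 2) {
    return(data.frame(event_a = character(0), event_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      overlap = integer(0), expected = numeric(0),
                      direction = character(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  gene_of <- stats::setNames(meta$gene, meta$event_id)
  pairs <- utils::combn(ids, 2)
  keep <- gene_of[pairs[1, ]] != gene_of[pairs[2, ]]
  pairs <- pairs[, keep, drop = FALSE]
  rows <- list()
  for (dir in c("mutual_exclusivity", "co_occurrence")) {
    res <- lapply(seq_len(ncol(pairs)), function(i) {
      test_pair(model, matrix, pairs[1, i], pairs[2, i], direction = dir)
    })
    df <- data.frame(
      event_a = vapply(res, `[[`, character(1), "event_a"),
      event_b = vapply(res, `[[`, character(1), "event_b"),
      overlap = vapply(res, `[[`, numeric(1), "overlap"),
      expected = vapply(res, `[[`, numeric(1), "expected_overlap"),
      direction = dir,
      p = vapply(res, `[[`, numeric(1), "p_value"),
      stringsAsFactors = FALSE
    )
    df$q <- bh_fdr(df$p)
    rows[[dir]] <- df
  }
  out <- rbind(rows$mutual_exclusivity, rows$co_occurrence)
  out$gene_a <- unname(gene_of[out$event_a])
  out$gene_b <- unname(gene_of[out$event_b])
  out$significant <- out$q < q_threshold
  out <- out[, c("event_a", "event_b", "gene_a", "gene_b", "overlap",
                 "expected", "direction", "p", "q", "significant")]
  rownames(out) <- NULL
  out
}

#' Enumerate mutually exclusive triples
#'
#' Builds the graph whose edges are significant mutually exclusive pairs
#' and enumerates its triangles; a triangle is kept only if its three
#' events come from three distinct genes. Every pair inside a reported
#' triple is therefore itself significantly mutually exclusive.
#'
#' @param exclusivity_table output of [screen_pairs()] at subtype level.
#' @param q_threshold significance threshold.
#' @return data.frame with events, genes and the three pair q-values, one
#'   row per triple, events sorted lexicographically within each triple.
#' @export
find_triples <- function(exclusivity_table, q_threshold = 0.05) {
  et <- exclusivity_table
  edges <- et[et$direction == "mutual_exclusivity" & et$q < q_threshold, ,
              drop = FALSE]
  empty <- data.frame(event_1 = character(0), event_2 = character(0),
                      event_3 = character(0), gene_1 = character(0),
                      gene_2 = character(0), gene_3 = character(0),
                      q_12 = numeric(0), q_13 = numeric(0),
                      q_23 = numeric(0), stringsAsFactors = FALSE)
  if (nrow(edges) < 3) return(empty)
  nodes <- sort(unique(c(edges$event_a, edges$event_b)))
  qmap <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (i in seq_len(nrow(edges))) {
    assign(ekey(edges$event_a[i], edges$event_b[i]), edges$q[i], envir = qmap)
  }
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(unique(c(edges$event_b[edges$event_a == v],
                  edges$event_a[edges$event_b == v])))
  })
  gene_of <- stats::setNames(c(edges$gene_a, edges$gene_b),
                             c(edges$event_a, edges$event_b))
  out <- list()
  for (a in nodes) {
    nb <- adj[[a]][adj[[a]] > a]
    for (b in nb) {
      common <- intersect(adj[[a]], adj[[b]])
      for (c3 in common[common > b]) {
        genes <- unname(gene_of[c(a, b, c3)])
        if (length(unique(genes)) == 3) {
          out[[length(out) + 1L]] <- data.frame(
            event_1 = a, event_2 = b, event_3 = c3,
            gene_1 = genes[1], gene_2 = genes[2], gene_3 = genes[3],
            q_12 = get(ekey(a, b), envir = qmap),
            q_13 = get(ekey(a, c3), envir = qmap),
            q_23 = get(ekey(b, c3), envir = qmap),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
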