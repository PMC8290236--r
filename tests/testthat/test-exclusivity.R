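test_that("fit_background handles degenerate matrices", {
  ones <- matrix(1L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  m <- fit_background(ones)
  expect_true(all(m$p == 1))
  ident <- diag(2); storage.mode(ident) <- "integer"
  dimnames(ident) <- list(c("a", "b"), c("x", "y"))
  m <- fit_background(ident)
  expect_equal(unname(m$p), matrix(0.5, 2, 2))  # symmetry forces equal margins
  zero_row <- rbind(a = c(0L, 0L, 0L), b = c(1L, 0L, 1L))
  colnames(zero_row) <- paste0("s", 1:3)
  m <- fit_background(zero_row)
  expect_true(all(m$p["a", ] == 0))
  expect_true("a" %in% m$degenerate_rows)
})

test_that("fit_background matches observed margins and an independent optimizer", {
  set.seed(14)
  for (r in 1:5) {
    nr <- sample(5:10, 1); nc <- sample(15:40, 1)
    X <- matrix(rbinom(nr * nc, 1L, runif(1, 0.2, 0.6)), nr, nc,
                dimnames = list(paste0("g", 1:nr), paste0("s", 1:nc)))
    m <- fit_background(X, tol = 1e-8)
    act_r <- !rownames(X) %in% m$degenerate_rows
    act_c <- !colnames(X) %in% m$degenerate_cols
    expect_lt(max(abs(rowSums(m$p[act_r, , drop = FALSE]) -
                        rowSums(X[act_r, , drop = FALSE]))), 1e-6)
    expect_lt(max(abs(colSums(m$p[, act_c, drop = FALSE]) -
                        colSums(X[, act_c, drop = FALSE]))), 1e-6)

    ## independent constrained maximum-entropy solve: BFGS on the full
    ## Bernoulli log-likelihood of the logistic row+column model
    A <- X[act_r, act_c, drop = FALSE]
    if (nrow(A) < 2) next
    nr2 <- nrow(A); nc2 <- ncol(A)
    nll <- function(par) {
      eta <- outer(par[1:nr2], par[nr2 + 1:nc2], "+")
      -sum(A * eta - log1p(exp(eta)))
    }
    gr <- function(par) {
      P <- 1 / (1 + exp(-outer(par[1:nr2], par[nr2 + 1:nc2], "+")))
      R <- P - A
      c(rowSums(R), colSums(R))
    }
    o <- optim(rep(0, nr2 + nc2), nll, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
    P_oracle <- 1 / (1 + exp(-outer(o$par[1:nr2], o$par[nr2 + 1:nc2], "+")))
    expect_lt(max(abs(P_oracle - m$p[act_r, act_c])), 1e-4)
  }
})

test_that("extend_background freezes sample loads and matches subtype carrier counts", {
  b <- default_bundle()
  gm <- bundle_gene_matrix(b)
  model <- fit_background(gm)
  ev <- truth_event_matrix(b, gm)
  em <- extend_background(model, ev)
  expect_identical(em$lambda, model$lambda[colnames(ev$values)])
  sub_rows <- ev$event_meta$event_id[!is.na(ev$event_meta$subtype)]
  expect_lt(max(abs(rowSums(em$p[sub_rows, ]) -
                      rowSums(ev$values[sub_rows, ]))), 1e-5)
})

test_that("poisson_binomial_cdf is exact against enumeration and closed forms", {
  expect_equal(poisson_binomial_cdf(numeric(0), 0), 1)
  expect_equal(poisson_binomial_cdf(c(0.3, 0.7), -1), 0)
  expect_equal(poisson_binomial_cdf(c(0.3, 0.7), 5), 1)
  ## equal probabilities reduce to the binomial CDF
  expect_equal(poisson_binomial_cdf(rep(0.3, 20), 7), pbinom(7, 20, 0.3),
               tolerance = 1e-12)
  set.seed(10)
  for (r in 1:20) {
    n <- sample(1:10, 1)
    probs <- runif(n)
    x <- sample(0:n, 1)
    expect_equal(poisson_binomial_cdf(probs, x), pb_enumerate(probs, x),
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr reproduces the step-up example and its properties", {
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(12)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_equal(q, p.adjust(p, "BH"))   # reference implementation
  ## input order preserved
  expect_equal(bh_fdr(rev(p)), rev(q))
})

test_that("test_pair matches the binomial closed form and its identities", {
  vals <- rbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 0L, 1L, 1L))
  colnames(vals) <- paste0("s", 1:4)
  m <- new_alteration_matrix(vals, parse_event_ids(rownames(vals)))
  model <- structure(list(
    p = matrix(0.5, 2, 4, dimnames = dimnames(vals)),
    mu = c(A = 0, B = 0), lambda = setNames(rep(0, 4), colnames(vals)),
    max_margin_residual = 0, degenerate_rows = character(0),
    degenerate_cols = character(0)), class = "background_model")
  res <- test_pair(model, m, "A", "B", "mutual_exclusivity")
  expect_equal(res$p_value, (1 - 0.25)^4)   # Bin(4, 0.25) at 0 = 0.31640625
  expect_equal(res$overlap, 0)
  expect_equal(res$expected_overlap, 1)

  ## full support: ME p = 1
  vals2 <- rbind(A = rep(1L, 4), B = rep(1L, 4))
  colnames(vals2) <- paste0("s", 1:4)
  m2 <- new_alteration_matrix(vals2, parse_event_ids(rownames(vals2)))
  model2 <- model; model2$p <- matrix(1, 2, 4, dimnames = dimnames(vals2))
  expect_equal(test_pair(model2, m2, "A", "B", "mutual_exclusivity")$p_value, 1)

  ## P(X<=o) + P(X>=o) - P(X=o) = 1, and symmetry in the two events
  set.seed(20)
  vals3 <- matrix(rbinom(2 * 30, 1L, 0.4), 2, 30,
                  dimnames = list(c("A", "B"), sprintf("t%02d", 1:30)))
  m3 <- new_alteration_matrix(vals3, parse_event_ids(rownames(vals3)))
  model3 <- fit_background(m3)
  me <- test_pair(model3, m3, "A", "B", "mutual_exclusivity")
  co <- test_pair(model3, m3, "A", "B", "co_occurrence")
  pp <- model3$p["A", ] * model3$p["B", ]
  pmf_o <- poisson_binomial_cdf(pp, me$overlap) -
    poisson_binomial_cdf(pp, me$overlap - 1)
  expect_equal(me$p_value + co$p_value - pmf_o, 1, tolerance = 1e-10)
  me_sym <- test_pair(model3, m3, "B", "A", "mutual_exclusivity")
  expect_equal(me_sym$p_value, me$p_value)
})

test_that("test_pair refuses same-gene subtype pairs", {
  vals <- rbind("G" = c(1L, 1L, 1L, 0L), "G::S1" = c(1L, 0L, 0L, 0L),
                "G::S2" = c(0L, 1L, 0L, 0L), "H" = c(0L, 1L, 0L, 1L))
  colnames(vals) <- paste0("s", 1:4)
  m <- new_alteration_matrix(vals, parse_event_ids(rownames(vals)))
  model <- fit_background(m)
  expect_error(test_pair(model, m, "G::S1", "G::S2"), "structural")
})

test_that("test_pair p-values are exchangeable under column permutation", {
  set.seed(33)
  vals <- matrix(rbinom(2 * 40, 1L, 0.35), 2, 40,
                 dimnames = list(c("A", "B"), sprintf("s%02d", 1:40)))
  m <- new_alteration_matrix(vals, parse_event_ids(rownames(vals)))
  model <- fit_background(m)
  p0 <- test_pair(model, m, "A", "B", "mutual_exclusivity")$p_value
  perm <- sample(40)
  vals_p <- vals[, perm]
  mp <- new_alteration_matrix(vals_p, parse_event_ids(rownames(vals_p)))
  model_p <- fit_background(mp)
  expect_equal(test_pair(model_p, mp, "A", "B", "mutual_exclusivity")$p_value,
               p0, tolerance = 1e-8)
})

test_that("screen_pairs handles edge cases and recovers planted pairs", {
  ## single event: empty table
  vals <- matrix(c(1L, 0L, 1L), 1, 3, dimnames = list("A", paste0("s", 1:3)))
  m1 <- new_alteration_matrix(vals, parse_event_ids("A"))
  expect_equal(nrow(screen_pairs(m1, fit_background(m1), "gene")), 0L)

  ## planted recovery with truth-label subtype events (clustering bypassed)
  b <- default_bundle()
  gm <- bundle_gene_matrix(b)
  ev <- truth_event_matrix(b, gm)
  model <- bundle_background(b, gm)
  em <- extend_background(model, ev)
  ps <- screen_pairs(ev, em, level = "subtype")
  sig <- ps[ps$significant & ps$direction == "mutual_exclusivity", ]
  for (i in seq_len(nrow(b$truth$me_pairs))) {
    A <- b$truth$me_pairs$gene_a[i]; B <- b$truth$me_pairs$gene_b[i]
    expect_true(any((sig$gene_a == A & sig$gene_b == B) |
                      (sig$gene_a == B & sig$gene_b == A)),
                label = sprintf("planted pair %s-%s detected", A, B))
  }
  ## the diluted gene-level planted pairs stay non-significant
  pg <- screen_pairs(gm, model, level = "gene")
  for (i in seq_len(nrow(b$truth$me_pairs))) {
    A <- b$truth$me_pairs$gene_a[i]; B <- b$truth$me_pairs$gene_b[i]
    qv <- pg$q[pg$direction == "mutual_exclusivity" &
                 ((pg$gene_a == A & pg$gene_b == B) |
                    (pg$gene_a == B & pg$gene_b == A))]
    expect_gte(min(qv), 0.05)
  }
  ## same-gene subtype pairs never tested
  expect_false(any(ps$gene_a == ps$gene_b))
  ## co-occurrence planted pair visible in the CO family (raw p)
  co <- ps[ps$direction == "co_occurrence", ]
  co_p <- co$p[(co$gene_a == "DRV05" & co$gene_b == "DRV06") |
                 (co$gene_a == "DRV06" & co$gene_b == "DRV05")]
  expect_lt(min(co_p), 0.05)
})

test_that("planted-pair detection increases as the suppression deepens", {
  ## power property over 20 replicates at epsilon 0, 0.25, 0.5, using
  ## truth labels so only the exclusivity stage is exercised
  detect <- sapply(c(0, 0.25, 0.5), function(eps) {
    hits <- vapply(1:20, function(r) {
      b <- simulate_cohort(fast_config(
        seed = 7000 + r,
        me_pairs = data.frame(gene_a = "DRV01", subtype_a = 1L,
                              gene_b = "DRV02", epsilon = eps),
        co_pairs = data.frame(gene_a = character(0), subtype_a = integer(0),
                              gene_b = character(0), rho = numeric(0)),
        triple = list()))
      gm <- bundle_gene_matrix(b)
      ev <- truth_event_matrix(b, gm)
      em <- extend_background(bundle_background(b, gm), ev)
      ps <- screen_pairs(ev, em, level = "subtype")
      ## the informative cell is the same-program subtype pair; the
      ## cross-program pair is exclusive through label correlation alone
      row <- ps[ps$direction == "mutual_exclusivity" &
                  ((ps$event_a == "DRV01::S1" & ps$event_b == "DRV02::S1") |
                     (ps$event_a == "DRV02::S1" & ps$event_b == "DRV01::S1")), ]
      nrow(row) == 1 && row$q < 0.05
    }, logical(1))
    mean(hits)
  })
  expect_true(detect[1] >= detect[2])
  expect_true(detect[2] >= detect[3])
  expect_gt(detect[1], detect[3])
  expect_gte(detect[1], 0.8)
})

test_that("find_triples enumerates triangles with the distinct-gene rule", {
  expect_equal(nrow(find_triples(data.frame(
    event_a = character(0), event_b = character(0), gene_a = character(0),
    gene_b = character(0), direction = character(0), p = numeric(0),
    q = numeric(0)))), 0L)

  ## hand-built 5-node graph with exactly one admissible triangle
  et <- data.frame(
    event_a = c("A::S1", "A::S1", "B::S1", "B::S1", "D::S1"),
    event_b = c("B::S1", "C::S1", "C::S1", "E::S1", "E::S1"),
    gene_a = c("A", "A", "B", "B", "D"),
    gene_b = c("B", "C", "C", "E", "E"),
    direction = "mutual_exclusivity",
    p = 1e-5, q = c(0.001, 0.002, 0.003, 0.004, 0.005),
    stringsAsFactors = FALSE)
  tr <- find_triples(et)
  expect_equal(nrow(tr), 1L)
  expect_setequal(unlist(tr[1, c("event_1", "event_2", "event_3")]),
                  c("A::S1", "B::S1", "C::S1"))
  expect_equal(sort(unlist(tr[1, c("q_12", "q_13", "q_23")])),
               c(0.001, 0.002, 0.003), ignore_attr = TRUE)

  ## triangle touching two subtypes of one gene is excluded
  et2 <- data.frame(
    event_a = c("A::S1", "A::S1", "A::S2"),
    event_b = c("A::S2", "B::S1", "B::S1"),
    gene_a = c("A", "A", "A"), gene_b = c("A", "B", "B"),
    direction = "mutual_exclusivity", p = 1e-5, q = 0.01,
    stringsAsFactors = FALSE)
  expect_equal(nrow(find_triples(et2)), 0L)

  ## exhaustive triangle oracle on a random significance graph
  set.seed(44)
  genes <- LETTERS[1:8]
  evs <- paste0(genes, "::S1")
  pairs <- utils::combn(evs, 2)
  keep <- runif(ncol(pairs)) < 0.4
  et3 <- data.frame(event_a = pairs[1, keep], event_b = pairs[2, keep],
                    gene_a = substr(pairs[1, keep], 1, 1),
                    gene_b = substr(pairs[2, keep], 1, 1),
                    direction = "mutual_exclusivity", p = 1e-6, q = 0.01,
                    stringsAsFactors = FALSE)
  tr3 <- find_triples(et3)
  ## oracle: test all C(8,3) combinations directly
  edge_set <- paste(pmin(et3$event_a, et3$event_b),
                    pmax(et3$event_a, et3$event_b))
  combos <- utils::combn(sort(evs), 3)
  n_expected <- sum(apply(combos, 2, function(tri) {
    all(c(paste(tri[1], tri[2]), paste(tri[1], tri[3]),
          paste(tri[2], tri[3])) %in% edge_set)
  }))
  expect_equal(nrow(tr3), n_expected)
})
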