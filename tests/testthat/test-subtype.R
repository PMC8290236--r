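test_that("gene_mad_profile matches direct enumeration and is permutation invariant", {
  expr <- rbind(const = rep(5, 5), g2 = c(1, 2, 3, 4, 100))
  colnames(expr) <- paste0("s", 1:5)
  mads <- gene_mad_profile(expr, colnames(expr))
  expect_equal(unname(mads["const"]), 0)
  expect_equal(unname(mads["g2"]), 1)  # median 3, |dev| {2,1,0,1,97}, median 1
  perm <- c("s3", "s1", "s5", "s2", "s4")
  expect_equal(gene_mad_profile(expr, perm), mads)
  expect_error(gene_mad_profile(expr, character(0)), "empty")
})

test_that("compare_heterogeneity behaves at the boundaries and detects shifts", {
  x <- runif(200)
  expect_warning(res <- compare_heterogeneity(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res$p, 1)
  res <- compare_heterogeneity(x + 10, x)
  expect_lt(res$p, 0.001)
  expect_gt(res$median_difference, 0)
  ## antisymmetry
  res_ab <- compare_heterogeneity(x + 0.3, x)
  res_ba <- compare_heterogeneity(x, x + 0.3)
  expect_equal(res_ab$p, res_ba$p, tolerance = 1e-12)
  expect_equal(res_ab$median_difference, -res_ba$median_difference)
})

test_that("select_top_variable ranks by MAD, centers rows, and is deterministic", {
  set.seed(2)
  expr <- matrix(rpois(10 * 12, 30), 10, 12,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
  expr[3, ] <- expr[3, ] * c(1, 40)        # make g03 highly variable
  sel <- select_top_variable(expr, colnames(expr), n_top = 4)
  mads <- gene_mad_profile(expr, colnames(expr))
  hand <- rownames(expr)[order(-mads, rownames(expr))][1:4]
  expect_equal(rownames(sel), hand)
  expect_true(all(abs(apply(sel, 1, median)) < 1e-9))
  expect_identical(sel, select_top_variable(expr, colnames(expr), n_top = 4))

  full <- select_top_variable(expr, colnames(expr), n_top = 10)
  expect_setequal(rownames(full), rownames(expr))
  expect_error(select_top_variable(expr, colnames(expr), n_top = 11), "n_top")
})

test_that("pearson_distance matches hand computation", {
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearson_distance(c(1, 2, 3), c(-1, -2, -3)), 2)
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)  # r = 0.5
  expect_error(pearson_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("pam_cluster solves degenerate cases and matches exhaustive search", {
  set.seed(11)
  D <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  res <- pam_cluster(D, 6)
  expect_equal(res$cost, 0)
  res1 <- pam_cluster(D, 1)
  expect_equal(res1$medoids, unname(which.min(colSums(D))))

  for (r in 1:25) {
    n <- sample(4:8, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    res <- pam_cluster(D, 2)
    expect_equal(res$cost, pam_exhaustive_cost2(D), tolerance = 1e-10)
  }
  expect_error(pam_cluster(D, 100), "exceeds")
})

test_that("pam_cluster is at least as good as the reference implementation", {
  skip_if_not_installed("cluster")
  ## multi-start SWAP can land in a better local optimum than single-start
  ## cluster::pam, never a worse one
  set.seed(4)
  for (r in 1:10) {
    n <- sample(10:25, 1); k <- sample(2:4, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    mine <- pam_cluster(D, k)
    ref <- cluster::pam(as.dist(D), k)
    ref_cost <- sum(apply(D[ref$id.med, , drop = FALSE], 2, min))
    expect_lte(mine$cost, ref_cost + 1e-8)
  }
})

test_that("pam_cluster is invariant under sample permutation", {
  set.seed(8)
  n <- 15
  D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
  perm <- sample(n)
  res <- pam_cluster(D, 3)
  res_p <- pam_cluster(D[perm, perm], 3)
  expect_equal(res_p$cost, res$cost, tolerance = 1e-10)
  ## partitions agree up to label names
  expect_equal(adjusted_rand_index(res$labels[perm], res_p$labels), 1)
})

test_that("consensus_cluster separates planted blobs and selects k = 2", {
  set.seed(21)
  n_half <- 15
  ## the two groups must differ in per-gene PATTERN (Pearson distance is
  ## blind to constant shifts): genes 1:20 high in group 1, 21:40 in group 2
  pattern <- rbind(cbind(matrix(10, 20, n_half), matrix(0, 20, n_half)),
                   cbind(matrix(0, 20, n_half), matrix(10, 20, n_half)))
  x <- pattern + matrix(rnorm(40 * 2 * n_half), 40)
  colnames(x) <- sprintf("s%02d", seq_len(2 * n_half))
  cc <- consensus_cluster(x, k_range = 2:4, n_iter = 50, seed = 99)
  expect_equal(cc$chosen_k, 2)
  truth <- rep(1:2, each = n_half)
  expect_equal(adjusted_rand_index(cc$labels, truth), 1)
  cons <- cc$consensus[["2"]]
  within <- cons[1:n_half, 1:n_half][upper.tri(diag(n_half))]
  across <- cons[1:n_half, (n_half + 1):(2 * n_half)]
  expect_true(all(within >= 0.95))
  expect_true(all(across <= 0.05))
  ## perfect block consensus has PAC 0
  expect_equal(unname(cc$pac["2"]), 0)
})

test_that("single full-sample iteration reduces to plain PAM co-membership", {
  set.seed(3)
  x <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("s", 1:10)))
  cc <- consensus_cluster(x, k_range = 2, n_iter = 1, subsample = 1.0, seed = 1)
  lab <- pam_cluster(pearson_distance_matrix(x), 2)$labels
  expect_identical(cc$consensus[["2"]], outer(lab, lab, function(a, b) (a == b) * 1)
                   |> `dimnames<-`(list(paste0("s", 1:10), paste0("s", 1:10))))
})

test_that("silhouette widths match the hand formula and stay in [-1, 1]", {
  ## 4 points, two pairs: within-pair distance 1, across 4
  D <- matrix(4, 4, 4); diag(D) <- 0; D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  s <- silhouette_widths(D, c(1, 1, 2, 2))
  expect_equal(s, rep(0.75, 4))  # (4-1)/4
  ## singleton cluster gets width 0
  s <- silhouette_widths(D, c(1, 1, 2, 3))
  expect_equal(s[4], 0)
  set.seed(5)
  D <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  s <- silhouette_widths(D, rep(1:4, each = 5))
  expect_true(all(s >= -1 & s <= 1))
})

test_that("silhouette_prune removes unstable samples and small subtypes", {
  set.seed(6)
  ## two tight clusters with opposite gene patterns: nothing removed,
  ## widths near 1 (patterned, not shifted: Pearson distance)
  pattern <- rbind(cbind(matrix(8, 25, 8), matrix(0, 25, 8)),
                   cbind(matrix(0, 25, 8), matrix(8, 25, 8)))
  x <- pattern + matrix(rnorm(50 * 16, 0, 0.3), 50)
  colnames(x) <- sprintf("s%02d", 1:16)
  labels <- setNames(rep(1:2, each = 8), colnames(x))
  pr <- silhouette_prune(x, labels)
  expect_equal(lengths(pr$subtypes), c(S1 = 8L, S2 = 8L))
  expect_length(pr$removed_samples, 0)
  expect_true(all(pr$silhouette > 0.8))

  ## a subtype that drops below 5 members disappears entirely
  labels2 <- setNames(c(rep(1, 12), rep(2, 4)), colnames(x))
  pr2 <- silhouette_prune(x, labels2)
  expect_equal(names(pr2$subtypes), "S1")
  expect_equal(pr2$dropped_subtype_sizes, 4L)
})

test_that("subtype_all takes the direct k=2 path for small carrier sets and appends valid events", {
  ## low-rate null cohort: every gene has <= 20 carriers, so the direct
  ## k=2 path is guaranteed; one gene is inflated to force the consensus
  ## path alongside it
  b <- simulate_cohort(fast_config(seed = 19, plant_structure = FALSE,
                                   carrier_rate_range = c(0.045, 0.06)))
  gm <- bundle_gene_matrix(b)
  carriers <- rowSums(gm$values)
  small <- names(carriers)[carriers <= 20 & carriers >= 8][1]
  big <- names(carriers)[which.max(carriers)]
  vals <- gm$values[c(big, small), , drop = FALSE]
  set.seed(19)
  vals[big, sample(which(vals[big, ] == 0), 40)] <- 1L  # force > 20 carriers
  sub <- new_alteration_matrix(vals, parse_event_ids(rownames(vals)))
  st <- subtype_all(sub, b$expression,
                    subtype_options(k_range = 2:3, n_iter = 30, seed = 1))
  expect_true(st$catalog[[small]]$small_group_rule_applied)
  expect_false(st$catalog[[big]]$small_group_rule_applied)
  expect_equal(st$catalog[[small]]$chosen_k, 2L)

  ## structural invariants of appended events
  meta <- st$matrix$event_meta
  for (g in c(big, small)) {
    rows <- meta$event_id[meta$gene == g & !is.na(meta$subtype)]
    if (length(rows) == 0) next
    block <- st$matrix$values[rows, , drop = FALSE]
    expect_true(all(colSums(block) <= 1))                      # disjoint
    expect_true(all(block <= rep(st$matrix$values[g, ],
                                 each = nrow(block))))         # subset of parent
    expect_true(all(rowSums(block) >= 5))                      # min size rule
  }
})

test_that("planted subtypes have lower MAD than the full carrier set", {
  ## the subtype-homogeneity claim, tested where it is testable: planted
  ## labels, default effect, rank test on top-variable MAD profiles
  b <- default_bundle()
  g <- "DRV07"
  lab <- unlist(b$truth$subtype_labels[[g]])
  carriers <- names(lab)
  sub <- select_top_variable(b$expression, carriers, n_top = 500)
  mad_all <- gene_mad_profile(sub, carriers)
  members <- names(lab)[lab == 1]
  mad_sub <- gene_mad_profile(sub, members)
  res <- compare_heterogeneity(mad_sub, mad_all, alternative = "less")
  expect_lt(res$p, 0.05)
})
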