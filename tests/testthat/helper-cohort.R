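## Shared fixtures: all synthetic, built in code, memoized per session.

.sx_cache <- new.env(parent = emptyenv())

## Default-world cohort (the stated simulation world); expensive pieces are
## cached so several test files can share one realization.
default_bundle <- function(seed = 5) {
  key <- paste0("bundle_", seed)
  if (is.null(.sx_cache[[key]])) {
    .sx_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  }
  .sx_cache[[key]]
}

## Small fast cohort for replicate-heavy property tests: full structure,
## scaled-down expression layer.
fast_config <- function(seed, ...) {
  sim_config(n_genes_expr = 200L, de_block_size = 40L, n_decoy_terms = 5L,
             seed = seed, ...)
}

## Mutation records of a bundle in the io module's internal shape.
bundle_records <- function(bundle, nonsilent_only = TRUE) {
  m <- bundle$mutations
  keep <- if (nonsilent_only) m$Variant_Classification != "Silent" else TRUE
  data.frame(sample = m$Tumor_Sample_Barcode[keep],
             gene = m$Hugo_Symbol[keep],
             variant_class = "missense",   # class is irrelevant downstream
             stringsAsFactors = FALSE)
}

## Driver-gene alteration matrix of a bundle (no carrier filter).
bundle_gene_matrix <- function(bundle) {
  recs <- bundle_records(bundle)
  build_gene_matrix(recs[grepl("^DRV", recs$gene), , drop = FALSE],
                    bundle$driver_genes, colnames(bundle$expression))
}

## Background model the way the pipeline builds it: lambda from the full
## mutation profile, per-event mu refit on the driver matrix.
bundle_background <- function(bundle, gm = bundle_gene_matrix(bundle)) {
  recs <- bundle_records(bundle)
  full <- build_gene_matrix(recs, sort(unique(recs$gene)),
                            colnames(gm$values))
  extend_background(fit_background(full), gm)
}

## Alteration matrix with subtype events taken from the planted truth
## labels (bypasses clustering; isolates the exclusivity stage).
truth_event_matrix <- function(bundle, gm = bundle_gene_matrix(bundle)) {
  samples <- colnames(gm$values)
  rows <- list()
  for (g in rownames(gm$values)) {
    lab <- unlist(bundle$truth$subtype_labels[[g]])
    for (s in sort(unique(lab))) {
      row <- integer(length(samples))
      names(row) <- samples
      row[intersect(names(lab)[lab == s], samples)] <- 1L
      rows[[sprintf("%s::S%d", g, s)]] <- row
    }
  }
  values <- rbind(gm$values, do.call(rbind, rows))
  new_alteration_matrix(values, parse_event_ids(rownames(values)))
}

## Brute-force Poisson-binomial CDF by full enumeration (oracle, n <= ~14).
pb_enumerate <- function(probs, x) {
  n <- length(probs)
  total <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(bits) <= x) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

## Exhaustive PAM cost oracle for k = 2 (all medoid pairs).
pam_exhaustive_cost2 <- function(D) {
  n <- nrow(D)
  min(apply(utils::combn(n, 2), 2, function(m) {
    sum(apply(D[m, , drop = FALSE], 2, min))
  }))
}

## Map a planted (gene, subtype-index) to the discovered subtype event id
## whose retained members are majority-planted with that index.
match_truth_event <- function(bundle, ev_matrix, gene, subtype_index) {
  tl <- unlist(bundle$truth$subtype_labels[[gene]])
  meta <- ev_matrix$event_meta
  cands <- meta$event_id[meta$gene == gene & !is.na(meta$subtype)]
  best <- NULL
  best_frac <- -1
  for (ev in cands) {
    mem <- colnames(ev_matrix$values)[ev_matrix$values[ev, ] == 1]
    mem <- intersect(mem, names(tl))
    if (length(mem) == 0) next
    frac <- mean(tl[mem] == subtype_index)
    if (frac > best_frac) { best_frac <- frac; best <- ev }
  }
  best
}

## Recovered-vs-planted adjusted Rand index for one gene of a subtype
## catalog (restricted to retained members).
catalog_ari <- function(bundle, catalog, gene) {
  e <- catalog[[gene]]
  if (length(e$subtypes) == 0) return(NA_real_)
  kept <- unlist(e$subtypes)
  lab <- rep(seq_along(e$subtypes), lengths(e$subtypes))
  names(lab) <- kept
  tl <- unlist(bundle$truth$subtype_labels[[gene]])
  common <- intersect(names(lab), names(tl))
  if (length(common) < 2) return(NA_real_)
  adjusted_rand_index(lab[common], tl[common])
}
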