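## cli_pipeline: orchestrate the stages end-to-end with a single config,
## deterministic seeding, structured logging and a run manifest.

#' Pipeline configuration
#'
#' Bundles input paths, the analysis thresholds (defaults are the standard
#' choices: >15 carriers, top 2000 variable genes, direct k=2 split at <=20
#' carriers, minimum subtype size 5, q < 0.05 for exclusivity, |log2FC| >=
#' 1 and FDR < 0.05 for differential expression, expression detectable at
#' counts > 1 in >= 30% of samples), the consensus-clustering settings, and
#' the switches (endpoint, tie method).
#'
#' @param mutations,expression,clinical,drivers,gene_sets input paths.
#' @param out_dir output directory (must differ from input directories).
#' @param min_carriers strict carrier-count threshold for driver events.
#' @param top_n top-variable genes for clustering.
#' @param small_group_cutoff direct k=2 path at or below this many carriers.
#' @param min_subtype_size subtypes below this are dropped.
#' @param q exclusivity significance threshold.
#' @param de_lfc,de_q DEG thresholds.
#' @param expr_min_count,expr_min_frac expression-filter thresholds.
#' @param k_range,n_iter,subsample consensus-clustering settings.
#' @param seed master seed; all stochastic stages derive child streams.
#' @param endpoint "os" or "dss".
#' @param ties Cox tie handling.
#' @param maf_cols column mapping from [maf_columns()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mutations, expression, clinical, drivers,
                            gene_sets, out_dir,
                            min_carriers = 15L, top_n = 2000L,
                            small_group_cutoff = 20L, min_subtype_size = 5L,
                            q = 0.05, de_lfc = 1, de_q = 0.05,
                            expr_min_count = 1, expr_min_frac = 0.30,
                            k_range = 2:6, n_iter = 1000L, subsample = 0.8,
                            seed = 1L, endpoint = "os", ties = "breslow",
                            maf_cols = maf_columns()) {
  stopifnot(min_carriers > 0, top_n > 0, q > 0, de_lfc > 0, de_q > 0,
            expr_min_frac > 0, min_subtype_size > 0)
  in_dirs <- unique(dirname(normalizePath(c(mutations, expression, clinical,
                                            drivers, gene_sets),
                                          mustWork = FALSE)))
  if (normalizePath(out_dir, mustWork = FALSE) %in% in_dirs) {
    ## allowed but flagged: outputs have fixed names distinct from inputs
    sx_log("out_dir coincides with an input directory", stage = "config")
  }
  structure(list(mutations = mutations, expression = expression,
                 clinical = clinical, drivers = drivers,
                 gene_sets = gene_sets, out_dir = out_dir,
                 min_carriers = as.integer(min_carriers),
                 top_n = as.integer(top_n),
                 small_group_cutoff = as.integer(small_group_cutoff),
                 min_subtype_size = as.integer(min_subtype_size),
                 q = q, de_lfc = de_lfc, de_q = de_q,
                 expr_min_count = expr_min_count,
                 expr_min_frac = expr_min_frac,
                 k_range = k_range, n_iter = as.integer(n_iter),
                 subsample = subsample, seed = as.integer(seed),
                 endpoint = endpoint, ties = ties, maf_cols = maf_cols),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stage order: io (read + filters + gene matrix) -> subtype discovery ->
#' gene-level exclusivity -> subtype-level exclusivity -> triples ->
#' functions (DE + enrichment + intersections) -> survival. Each stage's
#' outputs are written to `out_dir` before the next stage starts; any
#' stage error aborts with the stage name. Re-running with the same config
#' and inputs reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (also written to `manifest.json`): config echo,
#'   per-stage counts, md5 checksums of inputs and outputs.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  outputs <- character(0)
  stage <- function(name, fn) {
    sx_log("starting", stage = name)
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    sx_log("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs"),
           stage = name)
    res
  }

  ## --- io ---
  io <- stage("io", function() {
    raw <- read_maf(config$mutations, config$maf_cols)
    expr <- read_expression(config$expression)
    clinical <- read_clinical(config$clinical)
    drivers <- read_gene_list(config$drivers)
    gene_sets <- read_gmt(config$gene_sets)
    ## universe: samples with mutation data (any class) AND expression data
    samples <- common_samples(raw, expr)
    records <- filter_nonsilent(raw)
    gm <- filter_min_carriers(
      build_gene_matrix(records, drivers, samples),
      min_carriers = config$min_carriers)
    path <- file.path(out, "gene_matrix.tsv")
    write_alteration_matrix(gm, path)
    list(records = records, expr = expr[, samples, drop = FALSE],
         clinical = clinical, gene_sets = gene_sets, matrix = gm,
         path = path)
  })
  counts$genes_kept <- nrow(io$matrix$values)
  counts$samples <- ncol(io$matrix$values)
  outputs <- c(outputs, io$path)

  ## --- subtype discovery ---
  st <- stage("subtype", function() {
    opts <- subtype_options(n_top = min(config$top_n, nrow(io$expr)),
                            k_range = config$k_range,
                            n_iter = config$n_iter,
                            subsample = config$subsample,
                            small_group_cutoff = config$small_group_cutoff,
                            min_subtype_size = config$min_subtype_size,
                            seed = config$seed)
    res <- subtype_all(io$matrix, io$expr, opts)
    mpath <- file.path(out, "events_matrix.tsv")
    write_alteration_matrix(res$matrix, mpath)
    cpath <- file.path(out, "catalog.json")
    jsonlite::write_json(res$catalog, cpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    c(res, list(paths = c(mpath, cpath)))
  })
  counts$subtype_events <- sum(!is.na(st$matrix$event_meta$subtype))
  outputs <- c(outputs, st$paths)

  ## --- exclusivity ---
  ## per-sample load effects are estimated from the full mutation profile
  ## (all mutated genes, not only drivers), as load estimation from a
  ## handful of driver events is far too noisy; per-event effects are then
  ## fitted with the loads frozen
  model <- stage("exclusivity_gene", function() {
    all_genes <- sort(unique(io$records$gene))
    full <- build_gene_matrix(io$records, all_genes,
                              colnames(io$matrix$values))
    full_fit <- fit_background(full)
    extend_background(full_fit, io$matrix)
  })
  pairs_gene <- stage("exclusivity_gene", function() {
    pg <- screen_pairs(io$matrix, model, level = "gene",
                       q_threshold = config$q)
    sx_write_tsv(pg, file.path(out, "pairs_gene.tsv"))
    pg
  })
  counts$gene_me_significant <-
    sum(pairs_gene$significant & pairs_gene$direction == "mutual_exclusivity")
  outputs <- c(outputs, file.path(out, "pairs_gene.tsv"))

  pairs_sub <- stage("exclusivity_subtype", function() {
    em <- extend_background(model, st$matrix)
    ps <- screen_pairs(st$matrix, em, level = "subtype",
                       q_threshold = config$q)
    sx_write_tsv(ps, file.path(out, "pairs_subtype.tsv"))
    ps
  })
  counts$subtype_me_significant <-
    sum(pairs_sub$significant & pairs_sub$direction == "mutual_exclusivity")
  counts$subtype_co_significant <-
    sum(pairs_sub$significant & pairs_sub$direction == "co_occurrence")
  outputs <- c(outputs, file.path(out, "pairs_subtype.tsv"))

  triples <- stage("triples", function() {
    tr <- find_triples(pairs_sub, q_threshold = config$q)
    sx_write_tsv(tr, file.path(out, "triples.tsv"))
    tr
  })
  counts$triples <- nrow(triples)
  outputs <- c(outputs, file.path(out, "triples.tsv"))

  ## --- functions ---
  fx <- stage("functions", function() {
    expr_f <- filter_expressed(io$expr, min_count = config$expr_min_count,
                               min_frac = config$expr_min_frac)
    universe <- rownames(expr_f)
    sig_me <- pairs_sub[pairs_sub$significant &
                          pairs_sub$direction == "mutual_exclusivity", ]
    events <- sort(unique(c(sig_me$event_a, sig_me$event_b)))
    tables <- list()
    de_summary <- list()
    for (ev in events) {
      members <- colnames(st$matrix$values)[st$matrix$values[ev, ] == 1]
      gene <- st$matrix$event_meta$gene[st$matrix$event_meta$event_id == ev]
      wt <- wildtype_samples(io$matrix, gene)
      de <- de_test(expr_f, members, wt, lfc_threshold = config$de_lfc,
                    q_threshold = config$de_q)
      tables[[ev]] <- enrich(de$gene[de$deg], io$gene_sets, universe,
                             q_threshold = 0.05)
      de_summary[[ev]] <- data.frame(event = ev, n_deg = sum(de$deg),
                                     stringsAsFactors = FALSE)
    }
    pf <- lapply(seq_len(nrow(sig_me)), function(i) {
      terms <- pair_functions(c(sig_me$event_a[i], sig_me$event_b[i]), tables)
      if (length(terms) == 0) return(NULL)
      data.frame(event_a = sig_me$event_a[i], event_b = sig_me$event_b[i],
                 term = terms, stringsAsFactors = FALSE)
    })
    pf_df <- do.call(rbind, pf)
    if (is.null(pf_df)) {
      pf_df <- data.frame(event_a = character(0), event_b = character(0),
                          term = character(0), stringsAsFactors = FALSE)
    }
    tf <- lapply(seq_len(nrow(triples)), function(i) {
      evs <- unlist(triples[i, c("event_1", "event_2", "event_3")])
      key <- function(a, b) pf_df$term[(pf_df$event_a == a & pf_df$event_b == b) |
                                         (pf_df$event_a == b & pf_df$event_b == a)]
      sets <- list(key(evs[1], evs[2]), key(evs[1], evs[3]), key(evs[2], evs[3]))
      terms <- triple_functions(sets)
      if (length(terms) == 0) return(NULL)
      data.frame(triple = paste(evs, collapse = "+"), term = terms,
                 stringsAsFactors = FALSE)
    })
    tf_df <- do.call(rbind, tf)
    if (is.null(tf_df)) {
      tf_df <- data.frame(triple = character(0), term = character(0),
                          stringsAsFactors = FALSE)
    }
    sx_write_tsv(do.call(rbind, c(de_summary, list(
      data.frame(event = character(0), n_deg = integer(0))))),
      file.path(out, "de_summary.tsv"))
    sx_write_tsv(pf_df, file.path(out, "pair_functions.tsv"))
    sx_write_tsv(tf_df, file.path(out, "triple_functions.tsv"))
    list(tables = tables, pair_functions = pf_df, triple_functions = tf_df)
  })
  counts$pairs_with_functions <- length(unique(paste(
    fx$pair_functions$event_a, fx$pair_functions$event_b)))
  outputs <- c(outputs, file.path(out, c("de_summary.tsv",
                                         "pair_functions.tsv",
                                         "triple_functions.tsv")))

  ## --- survival ---
  surv <- stage("survival", function() {
    if (nrow(triples) == 0) {
      sv <- data.frame()
    } else {
      sv <- evaluate_triples(triples, st$matrix, io$clinical,
                             endpoint = config$endpoint, ties = config$ties)
    }
    sx_write_tsv(sv, file.path(out, "survival.tsv"))
    sv
  })
  counts$prognostic_triples <- if (nrow(surv) > 0)
    sum(surv$logrank_p < 0.05) else 0L
  outputs <- c(outputs, file.path(out, "survival.tsv"))

  manifest <- list(
    tool = "subtypex",
    version = as.character(utils::packageVersion("subtypex")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)), "maf_cols")],
    counts = counts,
    input_checksums = as.list(tools::md5sum(c(config$mutations,
                                              config$expression,
                                              config$clinical,
                                              config$drivers,
                                              config$gene_sets))),
    output_checksums = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
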