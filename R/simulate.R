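## synthetic_data: cohorts with the statistical structure the analysis
## assumes, plus planted ground truth for recovery tests.

#' Simulation configuration
#'
#' Describes a synthetic tumor cohort: heterogeneous per-gene mutation rates
#' and per-sample mutation loads, latent expression subtypes inside each
#' driver's carrier set, mutual exclusivity planted at the subtype (not
#' gene) level, negative-binomial expression with subtype-specific
#' differential blocks, and exponential survival with an elevated hazard
#' for carriers of the planted triple.
#'
#' Defaults give a 300-sample, 2,000-gene, 12-driver cohort that runs in
#' minutes on one CPU. Planted structure defaults: two fully suppressed
#' (`epsilon = 0`) mutual-exclusivity pairs, one co-occurrence pair
#' (3x enrichment), and one pairwise-exclusive triple whose carriers have
#' hazard ratio 1.8.
#'
#' @param n_samples number of tumor samples.
#' @param n_genes_expr number of expression genes.
#' @param n_driver_genes number of driver genes (symbols `DRV01`...).
#' @param carrier_rate_range carrier probability range (uniform) for
#'   driver genes without planted structure.
#' @param planted_rate_range carrier probability range for genes involved
#'   in planted pairs or the triple; defaults mirror high-frequency driver
#'   genes, whose subtype events are large enough for an exclusivity signal
#'   to be detectable at all.
#' @param load_sigma SD of the per-sample log mutation-load multiplier.
#' @param label_fidelity probability that a gene's subtype label copies the
#'   sample's global transcriptomic program rather than being redrawn
#'   uniformly; subtype programs of co-carried driver genes are correlated
#'   in real tumors, and without this correlation no clustering can
#'   disentangle twelve independent subtype structures.
#' @param k_subtypes latent subtypes per driver gene.
#' @param subtype_proportions mixing proportions (length `k_subtypes`).
#' @param de_block_size number of differentially expressed genes per subtype.
#' @param log2_effect log2 mean shift of a subtype's DE block.
#' @param me_pairs data.frame (`gene_a`, `subtype_a`, `gene_b`, `epsilon`):
#'   inside subtype `subtype_a` of `gene_a`, `gene_b`'s mutation probability
#'   is multiplied by `epsilon` in \[0, 1\].
#' @param compensate_me if TRUE (default) carriers of `gene_b` removed from
#'   the designated subtype are redistributed uniformly over the remaining
#'   samples, preserving the gene-level marginal so the exclusivity is
#'   visible only at the subtype level (as in the real-data examples where
#'   a gene pair is exclusive between subtypes but independent overall).
#' @param co_pairs data.frame (`gene_a`, `subtype_a`, `gene_b`, `rho`):
#'   enrichment factor `rho` >= 1 for `gene_b` inside the subtype.
#' @param triple list(`genes` = 3 symbols, `subtypes` = 3 indices,
#'   `epsilon`): all three pairs suppressed pairwise, or NULL.
#' @param baseline_hazard exponential event hazard per day.
#' @param hr_triple hazard ratio for triple carriers.
#' @param censor_rate target censoring fraction.
#' @param nb_dispersion_range per-gene NB dispersion, log-uniform.
#' @param n_decoy_terms random gene-set terms added beside the true ones.
#' @param plant_structure FALSE gives a null cohort: heterogeneous rates
#'   and loads and expression subtypes, but no planted exclusivity,
#'   co-occurrence, triple or survival effect.
#' @param seed master seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L,
                       n_genes_expr = 2000L,
                       n_driver_genes = 12L,
                       carrier_rate_range = c(0.08, 0.18),
                       planted_rate_range = c(0.35, 0.45),
                       load_sigma = 0.5,
                       label_fidelity = 0.98,
                       k_subtypes = 2L,
                       subtype_proportions = NULL,
                       de_block_size = 83L,
                       log2_effect = 2.0,
                       me_pairs = NULL,
                       co_pairs = NULL,
                       triple = NULL,
                       compensate_me = TRUE,
                       baseline_hazard = 1 / 1500,
                       hr_triple = 1.8,
                       censor_rate = 0.3,
                       nb_dispersion_range = c(0.02, 0.15),
                       n_decoy_terms = 30L,
                       plant_structure = TRUE,
                       seed) {
  if (missing(seed)) stop("seed is mandatory in sim_config()", call. = FALSE)
  if (is.null(subtype_proportions)) {
    subtype_proportions <- rep(1 / k_subtypes, k_subtypes)
  }
  stopifnot(abs(sum(subtype_proportions) - 1) < 1e-8,
            length(subtype_proportions) == k_subtypes,
            hr_triple > 0, load_sigma >= 0,
            label_fidelity >= 0, label_fidelity <= 1,
            carrier_rate_range[1] > 0, carrier_rate_range[2] < 1,
            planted_rate_range[1] > 0, planted_rate_range[2] < 1)
  genes <- sprintf("DRV%02d", seq_len(n_driver_genes))
  if (!plant_structure) {
    me_pairs <- data.frame(gene_a = character(0), subtype_a = integer(0),
                           gene_b = character(0), epsilon = numeric(0))
    co_pairs <- data.frame(gene_a = character(0), subtype_a = integer(0),
                           gene_b = character(0), rho = numeric(0))
    triple <- list()
  }
  if (is.null(me_pairs)) {
    me_pairs <- data.frame(gene_a = c("DRV01", "DRV03"), subtype_a = c(1L, 1L),
                           gene_b = c("DRV02", "DRV04"), epsilon = c(0, 0),
                           stringsAsFactors = FALSE)
  }
  if (is.null(co_pairs)) {
    co_pairs <- data.frame(gene_a = "DRV05", subtype_a = 1L,
                           gene_b = "DRV06", rho = 3,
                           stringsAsFactors = FALSE)
  }
  if (is.null(triple)) {
    triple <- list(genes = c("DRV07", "DRV08", "DRV09"),
                   subtypes = c(1L, 2L, 1L), epsilon = 0)
  }
  if (nrow(me_pairs) > 0) {
    stopifnot(all(me_pairs$epsilon >= 0), all(me_pairs$epsilon <= 1))
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes_expr = as.integer(n_genes_expr),
              driver_genes = genes,
              carrier_rate_range = carrier_rate_range,
              planted_rate_range = planted_rate_range,
              load_sigma = load_sigma,
              label_fidelity = label_fidelity,
              k_subtypes = as.integer(k_subtypes),
              subtype_proportions = subtype_proportions,
              de_block_size = as.integer(de_block_size),
              log2_effect = log2_effect,
              me_pairs = me_pairs, co_pairs = co_pairs, triple = triple,
              compensate_me = compensate_me,
              baseline_hazard = baseline_hazard, hr_triple = hr_triple,
              censor_rate = censor_rate,
              nb_dispersion_range = nb_dispersion_range,
              n_decoy_terms = as.integer(n_decoy_terms),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## Validate that planted structure is feasible before any sampling:
## expected subtype sizes must allow the >=5-member rule to be meaningful,
## and suppression sources must precede their targets in planting order.
check_sim_feasibility <- function(cfg) {
  min_rate <- cfg$carrier_rate_range[1]
  exp_min_subtype <- min(cfg$subtype_proportions) * min_rate * cfg$n_samples
  if (exp_min_subtype < 5) {
    stop(sprintf("infeasible sim_config: expected minimum subtype size %.1f < 5",
                 exp_min_subtype), call. = FALSE)
  }
  directives <- plant_directives(cfg)
  ord <- match(c(directives$source, directives$target), cfg$driver_genes)
  if (any(is.na(ord))) stop("planted pair names a gene outside the driver list",
                            call. = FALSE)
  bad <- match(directives$source, cfg$driver_genes) >=
    match(directives$target, cfg$driver_genes)
  if (any(bad)) {
    stop("planted pairs must point from an earlier to a later driver gene",
         call. = FALSE)
  }
  if (cfg$k_subtypes * cfg$de_block_size > cfg$n_genes_expr) {
    stop("DE blocks do not fit in the expression gene pool; reduce de_block_size",
         call. = FALSE)
  }
  invisible(TRUE)
}

## Flatten planted ME pairs, CO pairs and the triple into a uniform list of
## directives: inside subtype `subtype` of `source`, multiply `target`'s
## mutation probability by `epsilon` (< 1 suppresses) or enrich by `rho`.
plant_directives <- function(cfg) {
  d <- data.frame(source = character(0), subtype = integer(0),
                  target = character(0), epsilon = numeric(0),
                  rho = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cfg$me_pairs) > 0) {
    d <- rbind(d, data.frame(source = cfg$me_pairs$gene_a,
                             subtype = cfg$me_pairs$subtype_a,
                             target = cfg$me_pairs$gene_b,
                             epsilon = cfg$me_pairs$epsilon, rho = NA_real_,
                             stringsAsFactors = FALSE))
  }
  if (nrow(cfg$co_pairs) > 0) {
    d <- rbind(d, data.frame(source = cfg$co_pairs$gene_a,
                             subtype = cfg$co_pairs$subtype_a,
                             target = cfg$co_pairs$gene_b,
                             epsilon = NA_real_, rho = cfg$co_pairs$rho,
                             stringsAsFactors = FALSE))
  }
  if (length(cfg$triple) > 0) {
    ## explicit suppression is only needed for edges whose two subtype
    ## indices coincide (same global program); edges across programs are
    ## exclusive through the label correlation itself
    tg <- cfg$triple$genes; ts <- cfg$triple$subtypes; eps <- cfg$triple$epsilon
    edges <- list(c(1, 2), c(1, 3), c(2, 3))
    for (e in edges) {
      if (ts[e[1]] == ts[e[2]]) {
        d <- rbind(d, data.frame(
          source = tg[e[1]], subtype = ts[e[1]], target = tg[e[2]],
          epsilon = eps, rho = NA_real_, stringsAsFactors = FALSE))
      }
    }
  }
  d
}

#' Simulate a synthetic tumor cohort with planted ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with elements `mutations` (MAF-like record data.frame),
#'   `expression` (integer count matrix, genes x samples), `clinical`
#'   (data.frame), `gene_sets` (named list), `driver_genes` (character),
#'   and `truth` (planted subtype labels, pairs, triple, DE blocks, true
#'   term per subtype, hazard ratio).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_sim_feasibility(cfg)
  n <- cfg$n_samples
  genes <- cfg$driver_genes
  samples <- sprintf("S%04d", seq_len(n))

  ## --- mutation layer: logistic(a_i + b_j) with calibrated gene effects ---
  set.seed(derive_seed(cfg$seed, "mutations"))
  directives <- plant_directives(cfg)
  ## only exclusivity-planted genes get the high-frequency rates: a
  ## suppression signal needs large subtype events to be detectable, while
  ## a co-occurrence boost does not (and a boost factor rho only fits a
  ## moderate baseline rate)
  planted_genes <- unique(c(cfg$me_pairs$gene_a, cfg$me_pairs$gene_b,
                            if (!is.null(cfg$triple)) cfg$triple$genes))
  rates <- ifelse(genes %in% planted_genes,
                  stats::runif(length(genes), cfg$planted_rate_range[1],
                               cfg$planted_rate_range[2]),
                  stats::runif(length(genes), cfg$carrier_rate_range[1],
                               cfg$carrier_rate_range[2]))
  names(rates) <- genes
  b <- stats::rnorm(n, 0, cfg$load_sigma)
  ## calibrate a_i so that mean_j logistic(a_i + b_j) = rate_i exactly,
  ## mirroring the background model's margin matching
  a <- vapply(rates, function(r) {
    mu <- sx_logit(r)
    for (it in 1:50) {
      p <- sx_logistic(mu + b)
      g <- mean(p) - r
      if (abs(g) < 1e-12) break
      mu <- mu - g / mean(p * (1 - p))
    }
    mu
  }, numeric(1))
  P <- sx_logistic(outer(a, b, "+"))
  M <- matrix(stats::rbinom(length(P), 1L, P), nrow = length(genes),
              dimnames = list(genes, samples))

  ## --- planted structure: global program, subtype labels, directives ---
  ## Each sample carries a latent global transcriptomic program; a gene's
  ## subtype label copies the program with probability label_fidelity and
  ## is redrawn uniformly otherwise, so subtype structures of co-carried
  ## genes are correlated (as in real tumors) but not identical.
  labels <- vector("list", length(genes))
  names(labels) <- genes
  set.seed(derive_seed(cfg$seed, "subtypes"))
  program <- sample.int(cfg$k_subtypes, n, replace = TRUE,
                        prob = cfg$subtype_proportions)
  names(program) <- samples
  draw_labels <- function(carriers) {
    lab <- program[carriers]
    flip <- stats::runif(length(carriers)) > cfg$label_fidelity
    lab[flip] <- sample.int(cfg$k_subtypes, sum(flip), replace = TRUE,
                            prob = cfg$subtype_proportions)
    lab
  }
  for (g in genes) {
    ## apply directives targeting g (sources already labeled)
    hit <- directives[directives$target == g, , drop = FALSE]
    for (i in seq_len(nrow(hit))) {
      src_lab <- labels[[hit$source[i]]]
      src_members <- names(src_lab)[src_lab == hit$subtype[i]]
      if (!is.na(hit$epsilon[i])) {
        drop_set <- src_members[M[g, src_members] == 1]
        keep <- stats::rbinom(length(drop_set), 1L, hit$epsilon[i])
        removed <- drop_set[keep == 0]
        M[g, removed] <- 0L
        if (cfg$compensate_me && length(removed) > 0) {
          ## redistribute the removed carriers, mostly (80%) into the
          ## source gene's other subtypes: the removals came specifically
          ## from the source/target joint, so only a within-source return
          ## keeps the gene-level pair near independence, while the 15%
          ## leak avoids an extreme carrier pile-up in the other subtype
          other <- setdiff(samples, src_members)
          cand <- other[M[g, other] == 0]
          if (length(cand) > 0) {
            in_src <- cand %in% names(src_lab)
            wt <- rep(1, length(cand))
            if (any(in_src) && any(!in_src)) {
              wt[in_src] <- 0.85 / sum(in_src)
              wt[!in_src] <- 0.15 / sum(!in_src)
            }
            add <- sample(cand, min(length(removed), length(cand)),
                          prob = wt)
            M[g, add] <- 1L
          }
        }
      } else {
        add_set <- src_members[M[g, src_members] == 0]
        p_add <- min(1, (hit$rho[i] - 1) * rates[g] / (1 - rates[g]))
        add <- stats::rbinom(length(add_set), 1L, p_add)
        M[g, add_set[add == 1]] <- 1L
      }
    }
    carriers <- samples[M[g, ] == 1]
    labels[[g]] <- draw_labels(carriers)
  }

  ## --- expression layer: NB counts with subtype DE blocks ---
  set.seed(derive_seed(cfg$seed, "expression"))
  expr_genes <- sprintf("EXP%04d", seq_len(cfg$n_genes_expr))
  mu0 <- exp(stats::runif(cfg$n_genes_expr, log(20), log(200)))
  disp <- exp(stats::runif(cfg$n_genes_expr,
                           log(cfg$nb_dispersion_range[1]),
                           log(cfg$nb_dispersion_range[2])))
  libsize <- exp(stats::rnorm(n, 0, 0.15))
  ## consecutive DE block per (driver gene, subtype); blocks are laid out
  ## end to end and wrap around the gene pool when it is exhausted (only
  ## blocks of different driver genes ever share genes)
  de_blocks <- list()
  offset <- 0L
  for (g in genes) for (s in seq_len(cfg$k_subtypes)) {
    idx <- (offset + seq_len(cfg$de_block_size) - 1L) %% cfg$n_genes_expr + 1L
    de_blocks[[sprintf("%s::S%d", g, s)]] <- expr_genes[idx]
    offset <- offset + cfg$de_block_size
  }
  log2mu <- matrix(log2(mu0), nrow = cfg$n_genes_expr, ncol = n,
                   dimnames = list(expr_genes, samples))
  for (ev in names(de_blocks)) {
    meta <- parse_event_ids(ev)
    members <- names(labels[[meta$gene]])[labels[[meta$gene]] == meta$subtype]
    if (length(members) > 0) {
      log2mu[de_blocks[[ev]], members] <-
        log2mu[de_blocks[[ev]], members] + cfg$log2_effect
    }
  }
  mu <- 2^log2mu * rep(libsize, each = cfg$n_genes_expr)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / disp, n)),
                   nrow = cfg$n_genes_expr,
                   dimnames = list(expr_genes, samples))
  storage.mode(counts) <- "integer"

  ## --- gene sets: one true term per subtype block + random decoys ---
  set.seed(derive_seed(cfg$seed, "genesets"))
  gene_sets <- list()
  true_terms <- character(0)
  for (ev in names(de_blocks)) {
    term <- sprintf("TRUE_%s", gsub("::", "_", ev))
    gene_sets[[term]] <- de_blocks[[ev]]
    true_terms[ev] <- term
  }
  for (i in seq_len(cfg$n_decoy_terms)) {
    gene_sets[[sprintf("DECOY_%03d", i)]] <-
      sort(sample(expr_genes, cfg$de_block_size))
  }

  ## --- clinical layer: exponential survival, triple carriers at risk ---
  set.seed(derive_seed(cfg$seed, "clinical"))
  triple_carriers <- character(0)
  if (length(cfg$triple) > 0) {
    triple_carriers <- unique(unlist(lapply(seq_len(3), function(i) {
      g <- cfg$triple$genes[i]; s <- cfg$triple$subtypes[i]
      names(labels[[g]])[labels[[g]] == s]
    })))
  }
  hz <- cfg$baseline_hazard * ifelse(samples %in% triple_carriers,
                                     cfg$hr_triple, 1)
  t_event <- stats::rexp(n, hz)
  censor_ratio <- cfg$censor_rate / (1 - cfg$censor_rate)
  t_cens <- stats::rexp(n, cfg$baseline_hazard * censor_ratio)
  os_time <- round(pmin(t_event, t_cens), 1)
  os_event <- as.integer(t_event <= t_cens)
  dss_event <- os_event * stats::rbinom(n, 1L, 0.85)
  clinical <- data.frame(
    sample = samples,
    os_time = os_time, os_event = os_event,
    dss_time = os_time, dss_event = dss_event,
    age = round(pmin(pmax(stats::rnorm(n, 65, 10), 30), 90)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    ajcc_stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                        prob = c(0.50, 0.25, 0.18, 0.07)),
    t_stage = sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                     prob = c(0.30, 0.50, 0.13, 0.07)),
    n_stage = sample(c("N0", "N1", "N2", "N3"), n, replace = TRUE,
                     prob = c(0.60, 0.22, 0.15, 0.03)),
    stringsAsFactors = FALSE
  )

  ## --- mutation records (one row per gene-sample hit, plus silent noise) ---
  set.seed(derive_seed(cfg$seed, "records"))
  hits <- which(M == 1L, arr.ind = TRUE)
  class_probs <- c(missense = 0.826, nonsense = 0.087,
                   splice_site = 0.035, translation_start_site = 0.001,
                   nonstop = 0.001, frameshift_del = 0.022,
                   frameshift_ins = 0.021, in_frame_del = 0.004,
                   in_frame_ins = 0.003)
  rev_map <- stats::setNames(names(.maf_class_map), .maf_class_map)
  records <- data.frame(
    Tumor_Sample_Barcode = samples[hits[, 2]],
    Hugo_Symbol = genes[hits[, 1]],
    Variant_Classification = rev_map[sample(names(class_probs), nrow(hits),
                                            replace = TRUE, prob = class_probs)],
    stringsAsFactors = FALSE
  )
  ## silent mutations in driver genes (removed by the non-silent filter)
  n_silent <- round(nrow(hits) * 0.15)
  silent <- data.frame(
    Tumor_Sample_Barcode = sample(samples, n_silent, replace = TRUE),
    Hugo_Symbol = sample(genes, n_silent, replace = TRUE),
    Variant_Classification = "Silent", stringsAsFactors = FALSE
  )
  ## passenger mutations outside the driver list: every sequenced tumor
  ## has at least one somatic call, so no sample drops out of the MAF
  ## universe; passenger counts scale with the sample's mutation-load
  ## multiplier, as the background model assumes
  n_pass <- 1L + stats::rpois(n, 2.5 * exp(b))
  passenger <- data.frame(
    Tumor_Sample_Barcode = rep(samples, n_pass),
    Hugo_Symbol = sample(sprintf("PSG%02d", 1:40), sum(n_pass), replace = TRUE),
    Variant_Classification = sample(c("Missense_Mutation", "Silent"),
                                    sum(n_pass), replace = TRUE,
                                    prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  )
  records <- rbind(records, silent, passenger)
  records <- records[order(records$Tumor_Sample_Barcode, records$Hugo_Symbol,
                           records$Variant_Classification), , drop = FALSE]
  rownames(records) <- NULL

  truth <- list(
    subtype_labels = labels,
    me_pairs = cfg$me_pairs,
    co_pairs = cfg$co_pairs,
    triple = cfg$triple,
    triple_carriers = sort(triple_carriers),
    de_blocks = de_blocks,
    true_terms = as.list(true_terms),
    carrier_rates = rates,
    hr_triple = cfg$hr_triple,
    baseline_hazard = cfg$baseline_hazard
  )
  list(mutations = records, expression = counts, clinical = clinical,
       gene_sets = gene_sets, driver_genes = genes, truth = truth,
       config = cfg)
}

#' Write a simulated cohort bundle to disk
#'
#' Emits `mutations.tsv` (GDC MAF columns), `expression.tsv`,
#' `clinical.tsv`, `gene_sets.gmt`, `drivers.txt` and `truth.json` in
#' formats readable by the io module, so a written bundle round-trips.
#'
#' @param bundle result of [simulate_cohort()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of paths.
#' @export
write_cohort <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  paths <- c(
    mutations = file.path(out_dir, "mutations.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    gene_sets = file.path(out_dir, "gene_sets.gmt"),
    drivers = file.path(out_dir, "drivers.txt"),
    truth = file.path(out_dir, "truth.json")
  )
  sx_write_tsv(bundle$mutations, paths["mutations"])
  write_expression(bundle$expression, paths["expression"])
  sx_write_tsv(bundle$clinical, paths["clinical"])
  write_gmt(bundle$gene_sets, paths["gene_sets"])
  writeLines(bundle$driver_genes, paths["drivers"])
  truth <- bundle$truth
  truth$subtype_labels <- lapply(truth$subtype_labels, as.list)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}
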