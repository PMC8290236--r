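## survival: Kaplan-Meier curves, two-group log-rank test, and
## univariate/multivariate Cox models for mutually exclusive triples.

#' Kaplan-Meier curves and two-group log-rank test
#'
#' The log-rank statistic accumulates observed-minus-expected events for
#' the first group over the distinct event times, with the hypergeometric
#' variance, and is referred to chi-squared on 1 degree of freedom.
#' Kaplan-Meier estimates handle right censoring.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group_labels two-level grouping vector.
#' @return list(`chi_sq`, `p`, `observed`, `expected` (first group),
#'   `variance`, `km_curves` data.frame with columns group, time, n_risk,
#'   n_event, surv).
#' @export
km_logrank <- function(times, events, group_labels) {
  stopifnot(length(times) == length(events),
            length(times) == length(group_labels),
            all(events %in% c(0, 1)), all(times >= 0))
  groups <- sort(unique(as.character(group_labels)))
  if (length(groups) != 2) stop("log-rank test needs exactly two groups", call. = FALSE)
  if (any(table(group_labels) == 0)) stop("empty group", call. = FALSE)
  if (sum(events) == 0) stop("no events observed", call. = FALSE)
  g1 <- as.character(group_labels) == groups[1]
  event_times <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in event_times) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1
  km <- do.call(rbind, lapply(groups, function(g) {
    idx <- as.character(group_labels) == g
    tt <- sort(unique(times[idx & events == 1]))
    surv <- 1
    rows <- lapply(tt, function(t) {
      n_risk <- sum(times[idx] >= t)
      n_event <- sum(times[idx] == t & events[idx] == 1)
      surv <<- surv * (1 - n_event / n_risk)
      data.frame(group = g, time = t, n_risk = n_risk, n_event = n_event,
                 surv = surv, stringsAsFactors = FALSE)
    })
    if (length(rows) == 0) {
      data.frame(group = character(0), time = numeric(0), n_risk = integer(0),
                 n_event = integer(0), surv = numeric(0))
    } else do.call(rbind, rows)
  }))
  list(chi_sq = chi, p = p, observed = O, expected = E, variance = V,
       km_curves = km)
}

#' Cox proportional-hazards fit with flags
#'
#' Partial-likelihood Newton fit via [survival::coxph()] with Breslow (or
#' Efron) tie handling, returning per-covariate hazard ratios, Wald 95%
#' confidence intervals and p-values. Non-convergence or monotone
#' likelihood (separation, detected as an extreme coefficient or standard
#' error) is reported through the `flag` column instead of silently
#' returning numbers.
#'
#' @param design numeric design matrix (no constant column).
#' @param times,events survival outcome.
#' @param ties "breslow" (default) or "efron".
#' @return list(`coefficients` data.frame (term, hr, ci_lo, ci_hi, p,
#'   flag), `loglik`, `n`, `n_events`, `score_chi_sq`).
#' @export
cox_fit <- function(design, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  stopifnot(nrow(design) == length(times), length(times) == length(events))
  const <- apply(design, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(design)[const], collapse = ", "),
         call. = FALSE)
  }
  if (sum(events) < ncol(design)) {
    stop("fewer events than covariates", call. = FALSE)
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ design, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ design, ties = ties))
      attr(f, "sx_flag") <- conditionMessage(w)
      f
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  flag <- rep(NA_character_, length(beta))
  warn <- attr(fit, "sx_flag")
  sep <- abs(beta) > 15 | se > 100
  flag[sep] <- "possible separation / monotone likelihood"
  if (!is.null(warn)) flag[is.na(flag)] <- warn
  coefs <- data.frame(
    term = colnames(design),
    hr = exp(beta),
    ci_lo = exp(beta - 1.959964 * se),
    ci_hi = exp(beta + 1.959964 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    flag = flag,
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  list(coefficients = coefs, loglik = fit$loglik[2], n = fit$n,
       n_events = fit$nevent, score_chi_sq = unname(fit$score))
}

## Build dummy columns against baseline I / T1 / N0; levels absent from the
## data are dropped with a warning.
stage_dummies <- function(df) {
  spec <- list(ajcc_stage = list(base = "I", levels = c("II", "III", "IV")),
               t_stage = list(base = "T1", levels = c("T2", "T3", "T4")),
               n_stage = list(base = "N0", levels = c("N1", "N2", "N3")))
  cols <- list()
  for (var in names(spec)) {
    present <- unique(stats::na.omit(df[[var]]))
    for (lev in spec[[var]]$levels) {
      if (!lev %in% present) {
        warning(sprintf("level %s of %s absent; dummy dropped", lev, var),
                call. = FALSE)
        next
      }
      cols[[sprintf("%s_%s", var, lev)]] <- as.numeric(df[[var]] == lev)
    }
  }
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

#' Prognostic evaluation of mutually exclusive triples
#'
#' For each triple: carriers are the union of its three subtype member
#' sets; the comparator is wild-type for all three genes (samples mutated
#' in a triple gene but pruned from its subtype belong to neither group
#' unless `include_pruned`). Per triple the function runs a carrier vs
#' comparator log-rank test, a univariate Cox model on the carrier
#' indicator, and a multivariate Cox model adding age, gender and AJCC/T/N
#' stage dummies (baselines I, T1, N0). Models use complete cases, with n
#' reported; the independent-predictor flag is multivariate p < 0.05.
#'
#' @param triples data.frame from [find_triples()].
#' @param matrix augmented `alteration_matrix` (gene + subtype rows).
#' @param clinical clinical table with a `sample` column.
#' @param endpoint "os" or "dss".
#' @param ties tie method for [cox_fit()].
#' @param include_pruned count carriers pruned from their subtype as triple
#'   carriers (default FALSE).
#' @return data.frame, one row per triple.
#' @export
evaluate_triples <- function(triples, matrix, clinical,
                             endpoint = c("os", "dss"),
                             ties = "breslow", include_pruned = FALSE) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  stopifnot(all(c("sample", tcol, ecol) %in% names(clinical)))
  if (all(is.na(clinical[[ecol]])) || sum(clinical[[ecol]], na.rm = TRUE) == 0) {
    stop("no observed events for endpoint ", endpoint, call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(triples))) {
    evs <- unlist(triples[i, c("event_1", "event_2", "event_3")])
    genes <- unlist(triples[i, c("gene_1", "gene_2", "gene_3")])
    id <- paste(evs, collapse = "+")
    carrier_rows <- if (include_pruned) genes else evs
    block <- matrix$values[carrier_rows, , drop = FALSE]
    carriers <- colnames(matrix$values)[colSums(block) > 0]
    comparator <- wildtype_samples(matrix, genes)
    if (length(comparator) == 0) {
      stop("comparator group empty for triple ", id, call. = FALSE)
    }
    df <- clinical[clinical$sample %in% c(carriers, comparator), , drop = FALSE]
    df$carrier <- as.numeric(df$sample %in% carriers)
    df <- df[!is.na(df[[tcol]]) & !is.na(df[[ecol]]), , drop = FALSE]
    lr <- km_logrank(df[[tcol]], df[[ecol]], df$carrier)
    uni <- cox_fit(cbind(carrier = df$carrier), df[[tcol]], df[[ecol]],
                   ties = ties)
    dummies <- stage_dummies(df)
    design <- cbind(carrier = df$carrier,
                    age = df$age,
                    gender_male = as.numeric(df$gender == "male"),
                    dummies)
    cc <- stats::complete.cases(design)
    multi <- cox_fit(design[cc, , drop = FALSE], df[[tcol]][cc],
                     df[[ecol]][cc], ties = ties)
    mrow <- multi$coefficients[multi$coefficients$term == "carrier", ]
    urow <- uni$coefficients[1, ]
    rows[[i]] <- data.frame(
      triple = id,
      n_carrier = length(carriers), n_comparator = length(comparator),
      logrank_chi_sq = lr$chi_sq, logrank_p = lr$p,
      uni_hr = urow$hr, uni_ci_lo = urow$ci_lo, uni_ci_hi = urow$ci_hi,
      uni_p = urow$p,
      multi_hr = mrow$hr, multi_ci_lo = mrow$ci_lo, multi_ci_hi = mrow$ci_hi,
      multi_p = mrow$p, multi_n = multi$n,
      independent_predictor = mrow$p < 0.05,
      flag = ifelse(is.na(mrow$flag), "", mrow$flag),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
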