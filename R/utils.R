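#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: logging, seed derivation,
## small numeric utilities.

sx_log <- function(..., stage = NULL) {
  tag <- if (is.null(stage)) "" else sprintf("[%s] ", stage)
  message(tag, sprintf(...))
}

#' Derive a child random seed from a master seed and a label
#'
#' Stochastic stages derive independent streams from `(seed, label)` so that
#' adding or removing one driver gene does not perturb the stream used for
#' another. The hash is a plain 32-bit polynomial rolling hash of the label
#' characters folded into the master seed; the result is always a
#' non-negative integer below 2^31.
#'
#' @param master integer master seed.
#' @param ... character labels (stage name, gene symbol, replicate index ...).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (cp in utf8ToInt(label)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

## Adjusted Rand index between two label vectors (same length).
## Used by recovery tests; exported because pipeline reports use it too.

#' Adjusted Rand index
#'
#' Agreement between two partitions of the same objects, corrected for
#' chance. 1 means identical partitions (up to label permutation), 0 is the
#' expected value under independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## logistic and logit with clamping, shared by the background model and the
## mutation simulator
sx_logistic <- function(x) 1 / (1 + exp(-x))

sx_logit <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

## write a data.frame as TSV with fixed conventions so that reruns produce
## byte-identical files (determinism contract of the pipeline)
sx_write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
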