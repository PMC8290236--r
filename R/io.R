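## io_and_filters: read the standard formats, apply the mutation and gene
## filters, and build the binary alteration matrix.

#' Closed set of variant classifications
#'
#' The nine protein-altering (non-silent) classes retained for analysis,
#' plus `silent` and the `other` fallback.
#' @export
VARIANT_CLASSES <- c("missense", "nonsense", "translation_start_site",
                     "in_frame_del", "in_frame_ins",
                     "frameshift_del", "frameshift_ins",
                     "splice_site", "nonstop", "silent", "other")

#' The nine non-silent classes kept by [filter_nonsilent()]
#' @export
NONSILENT_CLASSES <- setdiff(VARIANT_CLASSES, c("silent", "other"))

## GDC MAF spellings -> internal enum
.maf_class_map <- c(
  "Missense_Mutation"      = "missense",
  "Nonsense_Mutation"      = "nonsense",
  "Translation_Start_Site" = "translation_start_site",
  "In_Frame_Del"           = "in_frame_del",
  "In_Frame_Ins"           = "in_frame_ins",
  "Frame_Shift_Del"        = "frameshift_del",
  "Frame_Shift_Ins"        = "frameshift_ins",
  "Splice_Site"            = "splice_site",
  "Nonstop_Mutation"       = "nonstop",
  "Silent"                 = "silent"
)

#' Column-name configuration for MAF dialects
#'
#' Defaults follow the GDC MAF dialect. `barcode_trim` optionally truncates
#' sample barcodes to their first `barcode_trim` characters (e.g. 12 for
#' TCGA patient-level barcodes); it is off (`NA`) by default because
#' synthetic data needs no normalization.
#'
#' @param sample,gene,variant_class column names in the MAF-like TSV.
#' @param barcode_trim integer or NA.
#' @return a named list used by [read_maf()].
#' @export
maf_columns <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        variant_class = "Variant_Classification",
                        barcode_trim = NA_integer_) {
  list(sample = sample, gene = gene, variant_class = variant_class,
       barcode_trim = barcode_trim)
}

#' Read a MAF-like mutation table
#'
#' Reads a tab-separated somatic mutation table and maps each row to a
#' mutation record (sample, gene, variant class). Classification strings not
#' in the known dialect map to `other` with a warning.
#'
#' @param path TSV file with a header.
#' @param columns column-name mapping from [maf_columns()].
#' @return a data.frame with columns `sample`, `gene`, `variant_class`.
#' @export
read_maf <- function(path, columns = maf_columns()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  for (col in c("sample", "gene", "variant_class")) {
    if (!columns[[col]] %in% names(df)) {
      stop(sprintf("MAF file %s is missing required column '%s'",
                   path, columns[[col]]), call. = FALSE)
    }
  }
  out <- data.frame(
    sample = as.character(df[[columns$sample]]),
    gene = as.character(df[[columns$gene]]),
    variant_class = unname(.maf_class_map[as.character(df[[columns$variant_class]])]),
    stringsAsFactors = FALSE
  )
  unknown <- is.na(out$variant_class)
  if (any(unknown)) {
    warning(sprintf("%d mutation records with unknown classification (%s) mapped to 'other'",
                    sum(unknown),
                    paste(unique(df[[columns$variant_class]][unknown]), collapse = ", ")),
            call. = FALSE)
    out$variant_class[unknown] <- "other"
  }
  if (!is.na(columns$barcode_trim)) {
    out$sample <- substr(out$sample, 1L, columns$barcode_trim)
  }
  if (nrow(out) > 0 && any(!nzchar(out$sample) | !nzchar(out$gene))) {
    stop("MAF contains empty sample or gene identifiers", call. = FALSE)
  }
  out
}

#' Keep only non-silent mutation records
#'
#' Retains exactly the nine protein-altering classes (missense, nonsense,
#' translation start site, in-frame del/ins, frameshift del/ins, splice
#' site, nonstop); silent and `other` records are dropped.
#'
#' @param records data.frame from [read_maf()].
#' @return filtered data.frame.
#' @export
filter_nonsilent <- function(records) {
  records[records$variant_class %in% NONSILENT_CLASSES, , drop = FALSE]
}

#' Build the gene-level binary alteration matrix
#'
#' Entry `(g, s)` is 1 iff at least one record maps gene `g` to sample `s`;
#' multiple mutations of one gene in one sample collapse to 1. Rows are
#' restricted to the driver list, columns to the supplied sample universe.
#'
#' @param records non-silent-filtered mutation records.
#' @param driver_genes character vector of gene symbols (the event universe).
#' @param samples character vector: the sample universe (column order).
#' @return a `BinaryAlterationMatrix`.
#' @export
build_gene_matrix <- function(records, driver_genes, samples) {
  if (length(driver_genes) == 0) {
    stop("driver gene list is empty", call. = FALSE)
  }
  driver_genes <- unique(driver_genes)
  samples <- unique(samples)
  values <- matrix(0L, nrow = length(driver_genes), ncol = length(samples),
                   dimnames = list(driver_genes, samples))
  keep <- records$gene %in% driver_genes & records$sample %in% samples
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) > 0) {
    values[cbind(match(rec$gene, driver_genes), match(rec$sample, samples))] <- 1L
  }
  new_alteration_matrix(values,
                        event_meta = data.frame(event_id = driver_genes,
                                                gene = driver_genes,
                                                subtype = NA_integer_,
                                                stringsAsFactors = FALSE))
}

#' Binary alteration matrix constructor
#'
#' Events (gene or gene-subtype, ids `GENE` or `GENE::S<k>`) by samples,
#' values 0/1. Validates: no duplicate event ids; for subtype events of one
#' gene, carrier sets pairwise disjoint and each a subset of the parent
#' gene row (when the parent row is present).
#'
#' @param values integer 0/1 matrix with dimnames (event ids, sample ids).
#' @param event_meta data.frame with columns `event_id`, `gene`, `subtype`.
#' @return object of class `alteration_matrix`.
#' @export
new_alteration_matrix <- function(values, event_meta) {
  stopifnot(is.matrix(values), all(values %in% c(0L, 1L)),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate event ids in alteration matrix", call. = FALSE)
  }
  stopifnot(identical(event_meta$event_id, rownames(values)))
  storage.mode(values) <- "integer"
  x <- structure(list(values = values, event_meta = event_meta),
                 class = "alteration_matrix")
  validate_alteration_matrix(x)
  x
}

validate_alteration_matrix <- function(x) {
  meta <- x$event_meta
  sub <- meta[!is.na(meta$subtype), , drop = FALSE]
  for (g in unique(sub$gene)) {
    rows <- sub$event_id[sub$gene == g]
    block <- x$values[rows, , drop = FALSE]
    if (any(colSums(block) > 1)) {
      stop(sprintf("subtype events of gene %s are not disjoint", g), call. = FALSE)
    }
    if (g %in% meta$event_id[is.na(meta$subtype)]) {
      parent <- x$values[g, ]
      if (any(block > rep(parent, each = nrow(block)))) {
        stop(sprintf("subtype event of gene %s is not a subset of its gene row", g),
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.alteration_matrix <- function(x, ...) {
  n_sub <- sum(!is.na(x$event_meta$subtype))
  cat(sprintf("alteration_matrix: %d events (%d subtype-level) x %d samples\n",
              nrow(x$values), n_sub, ncol(x$values)))
  invisible(x)
}

#' @export
dim.alteration_matrix <- function(x) dim(x$values)

#' Drop events with too few carriers
#'
#' Keeps rows whose carrier count is strictly greater than `min_carriers`
#' (the "> 15 patients" rule); row order is preserved.
#'
#' @param matrix a `alteration_matrix`.
#' @param min_carriers integer >= 1, default 15.
#' @return filtered `alteration_matrix`.
#' @export
filter_min_carriers <- function(matrix, min_carriers = 15L) {
  stopifnot(inherits(matrix, "alteration_matrix"), min_carriers >= 1)
  keep <- rowSums(matrix$values) > min_carriers
  new_alteration_matrix(matrix$values[keep, , drop = FALSE],
                        matrix$event_meta[keep, , drop = FALSE])
}

#' Write / read an alteration matrix as TSV
#'
#' Events in rows, samples in columns, 0/1 values; the first column holds
#' the event id. Subtype structure is recovered from the `GENE::S<k>`
#' event-id convention on read, so the round trip is bit-exact.
#'
#' @param matrix a `alteration_matrix`.
#' @param path output TSV path.
#' @return the path (write) or an `alteration_matrix` (read).
#' @export
write_alteration_matrix <- function(matrix, path) {
  df <- data.frame(event_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sx_write_tsv(df, path)
}

#' @rdname write_alteration_matrix
#' @export
read_alteration_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$event_id
  storage.mode(values) <- "integer"
  new_alteration_matrix(values, event_meta = parse_event_ids(df$event_id))
}

#' Parse event ids into gene / subtype metadata
#'
#' `GENE::S<k>` -> (gene, subtype k); plain `GENE` -> (gene, NA).
#' @param ids character vector of event ids.
#' @return data.frame with columns `event_id`, `gene`, `subtype`.
#' @export
parse_event_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)::S([0-9]+)$", ids))
  gene <- ids
  subtype <- rep(NA_integer_, length(ids))
  hit <- lengths(m) == 3
  gene[hit] <- vapply(m[hit], `[`, character(1), 2)
  subtype[hit] <- as.integer(vapply(m[hit], `[`, character(1), 3))
  data.frame(event_id = ids, gene = gene, subtype = subtype,
             stringsAsFactors = FALSE)
}

#' Read an expression matrix TSV (genes in rows, first column gene id)
#' @param path TSV path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("expression matrix contains negative values", call. = FALSE)
  m
}

#' Write an expression matrix TSV
#' @param expr genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sx_write_tsv(df, path)
}

#' Read a clinical table TSV
#'
#' Expected columns (any may contain NA): `sample`, `os_time`, `os_event`,
#' `dss_time`, `dss_event`, `age`, `gender`, `ajcc_stage`, `t_stage`,
#' `n_stage`. Times must be non-negative, events 0/1.
#' @param path TSV path.
#' @return data.frame keyed by `sample`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("clinical table lacks 'sample' column", call. = FALSE)
  for (col in c("os_time", "dss_time")) {
    if (col %in% names(df) && any(df[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative survival times in column %s", col), call. = FALSE)
    }
  }
  for (col in c("os_event", "dss_event")) {
    if (col %in% names(df) && !all(df[[col]] %in% c(0, 1, NA))) {
      stop(sprintf("event indicator %s outside {0,1}", col), call. = FALSE)
    }
  }
  df
}

#' Read a driver gene list (one symbol per line)
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read / write a GMT gene-set collection
#'
#' GMT lines are `term<TAB>description<TAB>gene1<TAB>gene2...`.
#' @param path GMT file.
#' @return named list of character vectors (term -> member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                        character(1))
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @param descriptions optional character vector parallel to `gene_sets`.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersect mutation and expression sample universes
#'
#' The analysis universe is the set of samples present in both the mutation
#' records and the expression matrix; samples outside it are dropped with a
#' logged count.
#'
#' @param records mutation records.
#' @param expr expression matrix (columns = samples).
#' @return character vector of retained sample ids (expression column order).
#' @export
common_samples <- function(records, expr) {
  mut_samples <- unique(records$sample)
  keep <- colnames(expr)[colnames(expr) %in% mut_samples]
  dropped <- length(mut_samples) + ncol(expr) - 2 * length(keep)
  if (dropped > 0) {
    sx_log("dropped %d samples absent from mutation or expression data",
           dropped, stage = "io")
  }
  keep
}
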