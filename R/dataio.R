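#' Read a peptide-level quantification report
#'
#' Parses one of three tab-separated report layouts into the canonical long
#' table of peptide observations. Intensities are kept on the linear scale;
#' zero, negative or absent intensities are treated as missing (MaxQuant
#' writes 0 for peptides not quantified in a sample). A `detected` flag is
#' derived from the report's confidence q-value: `qvalue <= qvalue_threshold`.
#' Rows whose q-value is absent count as detected when their intensity is
#' present (only the generic dialect carries optional q-values).
#'
#' Supported dialects:
#' \describe{
#'   \item{`generic_long`}{columns `sample_id`, `protein_id`, `peptide_id`,
#'     `intensity`, optional `qvalue`.}
#'   \item{`maxquant_wide`}{simplified MaxQuant peptides.txt: `Sequence`,
#'     `Leading razor protein`, one `Intensity <sample>` column per sample.}
#'   \item{`diann_long`}{simplified DIA-NN report: `Run`, `Protein.Group`,
#'     `Modified.Sequence`, `Precursor.Quantity`, `Q.Value`. Several
#'     precursors of one modified sequence in one run are aggregated by
#'     summing intensities and keeping the smallest q-value.}
#' }
#'
#' @param path path to a TSV file.
#' @param dialect one of `"generic_long"`, `"maxquant_wide"`, `"diann_long"`.
#' @param qvalue_threshold detection threshold on the q-value, default 0.01.
#' @return a `peptide_table`: data.frame with columns `sample_id`,
#'   `protein_id`, `peptide_id`, `intensity`, `qvalue`, `detected`. The
#'   number of malformed rows dropped is attached as attribute
#'   `n_malformed`.
#' @export
read_peptide_table <- function(path,
                               dialect = c("generic_long", "maxquant_wide",
                                           "diann_long"),
                               qvalue_threshold = 0.01) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(qvalue_threshold > 0, qvalue_threshold <= 1)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty peptide table: ", path, call. = FALSE)

  tab <- switch(dialect,
    generic_long = parse_generic_long(raw),
    maxquant_wide = parse_maxquant_wide(raw),
    diann_long = parse_diann_long(raw))

  n0 <- nrow(tab)
  ok <- !is.na(tab$sample_id) & !is.na(tab$peptide_id) &
    !is.na(tab$protein_id) & nzchar(tab$peptide_id)
  tab <- tab[ok, , drop = FALSE]
  # non-positive / absent intensity => missing observation: drop the row
  tab$intensity[!is.na(tab$intensity) & tab$intensity <= 0] <- NA_real_
  tab <- tab[!is.na(tab$intensity), , drop = FALSE]
  if (nrow(tab) == 0) stop("no usable observations in ", path, call. = FALSE)

  dup <- duplicated(tab[c("peptide_id", "sample_id")])
  if (any(dup))
    stop("duplicate (peptide_id, sample_id) rows in ", path, call. = FALSE)
  multi <- tapply(tab$protein_id, tab$peptide_id,
                  function(p) length(unique(p)))
  if (any(multi > 1))
    stop("peptide(s) mapped to more than one protein: ",
         paste(utils::head(names(multi)[multi > 1], 5), collapse = ", "),
         call. = FALSE)

  tab$detected <- ifelse(is.na(tab$qvalue), TRUE,
                         tab$qvalue <= qvalue_threshold)
  rownames(tab) <- NULL
  attr(tab, "n_malformed") <- n0 - nrow(tab)
  attr(tab, "qvalue_threshold") <- qvalue_threshold
  class(tab) <- c("peptide_table", "data.frame")
  tab
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

parse_generic_long <- function(raw) {
  require_columns(raw, c("sample_id", "protein_id", "peptide_id",
                         "intensity"), "generic_long")
  data.frame(
    sample_id = as.character(raw$sample_id),
    protein_id = as.character(raw$protein_id),
    peptide_id = as.character(raw$peptide_id),
    intensity = suppressWarnings(as.numeric(raw$intensity)),
    qvalue = if ("qvalue" %in% names(raw))
      suppressWarnings(as.numeric(raw$qvalue)) else NA_real_,
    stringsAsFactors = FALSE)
}

parse_maxquant_wide <- function(raw) {
  require_columns(raw, c("Sequence", "Leading razor protein"),
                  "maxquant_wide")
  icols <- grep("^Intensity ", names(raw), value = TRUE)
  if (!length(icols))
    stop("maxquant_wide: missing mandatory column(s): 'Intensity <sample>'",
         call. = FALSE)
  samples <- sub("^Intensity ", "", icols)
  long <- lapply(seq_along(icols), function(j) {
    data.frame(
      sample_id = samples[j],
      protein_id = as.character(raw[["Leading razor protein"]]),
      peptide_id = as.character(raw[["Sequence"]]),
      intensity = suppressWarnings(as.numeric(raw[[icols[j]]])),
      qvalue = NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, long)
}

parse_diann_long <- function(raw) {
  require_columns(raw, c("Run", "Protein.Group", "Modified.Sequence",
                         "Precursor.Quantity", "Q.Value"), "diann_long")
  df <- data.frame(
    sample_id = as.character(raw$Run),
    protein_id = as.character(raw$Protein.Group),
    peptide_id = as.character(raw$Modified.Sequence),
    intensity = suppressWarnings(as.numeric(raw$Precursor.Quantity)),
    qvalue = suppressWarnings(as.numeric(raw$Q.Value)),
    stringsAsFactors = FALSE)
  # aggregate precursor rows (e.g. charge states) of the same peptide+run
  key <- paste(df$peptide_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    agg_int <- tapply(df$intensity, key, function(v)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    agg_q <- tapply(df$qvalue, key, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$intensity <- as.numeric(agg_int[key[first]])
    df$qvalue <- as.numeric(agg_q[key[first]])
  }
  df
}

#' Read a sample metadata table
#'
#' @param path TSV with mandatory columns `sample_id` and `group`, an
#'   optional logical `exclude` column (samples kept for QC but never entering
#'   filtering, normalization or differential testing) and arbitrary extra
#'   covariate columns which are carried along untouched.
#' @return a `sample_metadata` data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, check.names = FALSE)
  require_columns(raw, c("sample_id", "group"), "sample metadata")
  raw$sample_id <- as.character(raw$sample_id)
  raw$group <- as.character(raw$group)
  raw$exclude <- if ("exclude" %in% names(raw))
    parse_flag(raw$exclude) else FALSE
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  class(raw) <- c("sample_metadata", "data.frame")
  raw
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "y")
}

#' Build the log2 abundance matrix from a peptide table
#'
#' Converts linear intensities to log2 (exactly once, here), lays peptides
#' out as rows ordered by (protein_id, peptide_id) and samples as metadata
#' columns. Excluded samples are dropped unless `include_excluded = TRUE`
#' (QC paths want them; the statistical path never does).
#'
#' @param table a `peptide_table` from [read_peptide_table()].
#' @param metadata a `sample_metadata` table covering every sample in
#'   `table`.
#' @param include_excluded keep samples flagged `exclude`?
#' @return an [abundance_matrix()] with the `detected` mask attached.
#' @export
build_matrix <- function(table, metadata, include_excluded = FALSE) {
  unknown <- setdiff(unique(table$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("sample(s) present in peptide table but not in metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  meta <- metadata
  if (!include_excluded) meta <- meta[!meta$exclude, , drop = FALSE]
  if (nrow(meta) == 0) stop("no samples left after exclusion", call. = FALSE)

  tab <- table[table$sample_id %in% meta$sample_id, , drop = FALSE]
  pep2prot <- tapply(tab$protein_id, tab$peptide_id, `[`, 1)
  feat <- data.frame(peptide_id = names(pep2prot),
                     protein_id = as.character(pep2prot))
  feat <- feat[order(feat$protein_id, feat$peptide_id), , drop = FALSE]

  ri <- match(tab$peptide_id, feat$peptide_id)
  ci <- match(tab$sample_id, meta$sample_id)
  vals <- matrix(NA_real_, nrow(feat), nrow(meta),
                 dimnames = list(feat$peptide_id, meta$sample_id))
  det <- matrix(FALSE, nrow(feat), nrow(meta),
                dimnames = dimnames(vals))
  vals[cbind(ri, ci)] <- log2(tab$intensity)
  det[cbind(ri, ci)] <- tab$detected

  abundance_matrix(vals, stats::setNames(meta$group, meta$sample_id),
                   stats::setNames(feat$protein_id, feat$peptide_id),
                   detected = det)
}

#' Write result tables as TSV files
#'
#' Every table is written tab-separated, UTF-8, `.` decimal separator and
#' missing values as empty strings, so that [read_results_table()] restores
#' numeric values to within 1e-9 and missing cells to `NA`. Matrices are
#' written with their row names in a leading `id` column.
#'
#' @param tables named list of data.frames or matrices.
#' @param out_dir output directory, created if needed.
#' @param run_log optional list echoed to `run_log.json` together with per
#'   table row counts.
#' @return invisible character vector of file paths written.
#' @export
write_results <- function(tables, out_dir, run_log = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.matrix(x))
      x <- data.frame(id = rownames(x), as.data.frame(x),
                      check.names = FALSE)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    data.table::fwrite(x, p, sep = "\t", na = "", quote = FALSE,
                       scipen = 999)
    paths <- c(paths, p)
  }
  log <- c(list(written = basename(paths),
                rows = vapply(tables, NROW, integer(1))),
           if (!is.null(run_log)) list(config = run_log))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a TSV result table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame with empty strings restored to `NA`.
#' @export
read_results_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = "", check.names = FALSE)
}
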