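#' Construct a log2 peptide abundance matrix object
#'
#' The central container of the pipeline: a log2-intensity matrix with
#' features (peptides or proteins) as rows and samples as columns, a group
#' label per column, and a feature-to-protein map. Missing cells are `NA` and
#' stay `NA` through every downstream step — no imputation anywhere.
#'
#' @param values numeric matrix, log2 scale, rows = features, cols = samples;
#'   dimnames required.
#' @param groups character vector of group labels, one per column.
#' @param feature_to_protein named character vector mapping every row name to
#'   a protein id.
#' @param detected optional logical matrix aligned with `values` marking
#'   confidently identified cells (q-value at or below the detection
#'   threshold).
#' @return an `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, groups, feature_to_protein,
                             detected = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("`values` must have row names (feature ids)", call. = FALSE)
    rownames(values) <- character(0)   # empty survivor sets are legal
  }
  if (length(groups) != ncol(values))
    stop("`groups` must have one label per column", call. = FALSE)
  groups <- stats::setNames(as.character(groups), colnames(values))
  miss <- setdiff(rownames(values), names(feature_to_protein))
  if (length(miss))
    stop("feature_to_protein lacks entries for: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  if (!is.null(detected)) {
    stopifnot(is.logical(detected), all(dim(detected) == dim(values)))
    dimnames(detected) <- dimnames(values)
  }
  structure(
    list(values = values, groups = groups,
         feature_to_protein = feature_to_protein[rownames(values)],
         detected = detected),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "abundance_matrix: %d features x %d samples (%d proteins, %d groups)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$feature_to_protein)), length(unique(x$groups))))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by features and/or samples
#'
#' @param x an `abundance_matrix`.
#' @param features,samples row/column selectors (names, indices or logical).
#' @return an `abundance_matrix` restricted to the selection.
#' @export
subset_matrix <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (is.null(features)) features <- seq_len(nrow(x$values))
  if (is.null(samples)) samples <- seq_len(ncol(x$values))
  v <- x$values[features, samples, drop = FALSE]
  d <- if (!is.null(x$detected))
    x$detected[features, samples, drop = FALSE]
  abundance_matrix(v, x$groups[samples][colnames(v)],
                   x$feature_to_protein, d)
}

#' Construct a protein-level abundance matrix
#'
#' @param values numeric log2 matrix (proteins x samples).
#' @param groups group label per column.
#' @param n_peptides integer vector, per protein, of peptides that
#'   contributed at least one observed cell.
#' @param method rollup method label.
#' @return a `protein_matrix` object.
#' @export
protein_matrix <- function(values, groups, n_peptides, method) {
  stopifnot(is.matrix(values), length(n_peptides) == nrow(values))
  groups <- stats::setNames(as.character(groups), colnames(values))
  structure(list(values = values, groups = groups,
                 n_peptides = stats::setNames(as.integer(n_peptides),
                                              rownames(values)),
                 method = method),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix (%s): %d proteins x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a per-sample normalization offset record
#'
#' Normalized data are always `input + offset`, one additive log2 constant
#' per sample column.
#'
#' @param offsets named numeric vector, one offset per sample (log2 units).
#' @param method method label.
#' @param converged logical, did the solver converge.
#' @param iterations iterations used.
#' @return a `norm_offsets` object.
#' @export
norm_offsets <- function(offsets, method, converged = TRUE, iterations = 0L) {
  structure(list(per_sample_offset = offsets, method = method,
                 converged = converged, iterations = as.integer(iterations)),
            class = "norm_offsets")
}

#' @export
print.norm_offsets <- function(x, ...) {
  cat(sprintf("norm_offsets [%s]: range %.4g .. %.4g (converged: %s)\n",
              x$method, min(x$per_sample_offset), max(x$per_sample_offset),
              x$converged))
  invisible(x)
}

#' Define a two-group contrast
#'
#' @param group_a,group_b group labels to compare; foldchanges are reported
#'   as `group_b - group_a` on the log2 scale.
#' @param name optional contrast name; defaults to "A_vs_B" style.
#' @return a `contrast` object.
#' @export
contrast <- function(group_a, group_b, name = NULL) {
  if (identical(group_a, group_b))
    stop("contrast groups must differ", call. = FALSE)
  if (is.null(name)) name <- paste0(group_b, "_vs_", group_a)
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "contrast")
}

# internal: check contrast groups exist in a metadata table / group vector
check_contrast_groups <- function(ctr, groups) {
  missing <- setdiff(c(ctr$group_a, ctr$group_b), groups)
  if (length(missing))
    stop("contrast '", ctr$name, "': group(s) not present: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
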