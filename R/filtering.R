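#' Feature-selection parameters
#'
#' Controls which peptides enter the statistical comparison. A peptide is
#' retained only when it is detected often enough in every sample group in
#' scope; proteins then need a minimum number of surviving peptides, and
#' optionally only the top-N most reliable peptides per protein are kept.
#'
#' @param min_detect absolute detection count required per group (0 = off).
#' @param min_detect_fraction fraction of a group's replicates in which the
#'   peptide must be detected; converted per group as
#'   `ceiling(fraction * group size)` ("at least" semantics). Mutually
#'   exclusive with `min_detect`.
#' @param min_peptides_per_protein proteins with fewer surviving peptides
#'   are dropped entirely. Default 1.
#' @param topn_peptides keep at most this many peptides per protein,
#'   ranked by detection count, then mean log2 intensity, then peptide id;
#'   `Inf` keeps all.
#' @param by_contrast apply the rules within each contrast's two groups
#'   rather than across the whole dataset.
#' @return a `filter_params` object.
#' @export
filter_params <- function(min_detect = 0, min_detect_fraction = NULL,
                          min_peptides_per_protein = 1,
                          topn_peptides = Inf, by_contrast = FALSE) {
  if (!is.null(min_detect_fraction)) {
    stopifnot(min_detect_fraction >= 0, min_detect_fraction <= 1)
    if (min_detect > 0)
      stop("use min_detect or min_detect_fraction, not both", call. = FALSE)
  }
  stopifnot(min_detect >= 0, min_peptides_per_protein >= 1,
            topn_peptides >= 1)
  if (is.finite(topn_peptides) &&
      topn_peptides < min_peptides_per_protein)
    stop("topn_peptides must be >= min_peptides_per_protein", call. = FALSE)
  structure(list(min_detect = min_detect,
                 min_detect_fraction = min_detect_fraction,
                 min_peptides_per_protein = min_peptides_per_protein,
                 topn_peptides = topn_peptides,
                 by_contrast = by_contrast),
            class = "filter_params")
}

#' Filter peptides by detection consistency and protein support
#'
#' Applies, in order: (1) the per-group detection rule — a peptide survives
#' iff its detected count (or fraction) meets the threshold in EVERY group
#' in scope; (2) the minimum-peptides-per-protein rule; (3) the top-N
#' peptides per protein rule. Row order of the input is preserved.
#'
#' @param matrix an [abundance_matrix()] carrying a `detected` mask.
#' @param params a [filter_params()] object.
#' @param groups_in_scope group labels the detection rule applies to;
#'   defaults to all groups of the matrix.
#' @return a filtered `abundance_matrix`.
#' @export
filter_peptides <- function(matrix, params,
                            groups_in_scope = unique(matrix$groups)) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(params, "filter_params"))
  if (is.null(matrix$detected))
    stop("matrix carries no `detected` mask", call. = FALSE)
  bad <- setdiff(groups_in_scope, matrix$groups)
  if (length(bad))
    stop("group(s) without samples in matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)

  det <- matrix$detected & !is.na(matrix$values)
  in_scope_cols <- matrix$groups %in% groups_in_scope

  keep <- rep(TRUE, nrow(matrix$values))
  for (g in groups_in_scope) {
    cols <- matrix$groups == g
    if (!any(cols))
      stop("group with zero samples in scope: ", g, call. = FALSE)
    counts <- rowSums(det[, cols, drop = FALSE])
    thr <- if (!is.null(params$min_detect_fraction))
      ceiling(params$min_detect_fraction * sum(cols))
    else params$min_detect
    keep <- keep & counts >= thr
  }

  prot <- matrix$feature_to_protein
  keep <- apply_protein_rules(keep, prot, det, matrix$values,
                              in_scope_cols, params)
  subset_matrix(matrix, features = keep)
}

# min-peptides-per-protein rule followed by the top-N ranking rule
apply_protein_rules <- function(keep, prot, det, values, in_scope_cols,
                                params) {
  if (params$min_peptides_per_protein > 1) {
    n_per_prot <- tapply(keep, prot, sum)
    keep <- keep & (n_per_prot[prot] >= params$min_peptides_per_protein)
  }
  if (is.finite(params$topn_peptides)) {
    idx <- which(keep)
    det_count <- rowSums(det[idx, in_scope_cols, drop = FALSE])
    mean_int <- rowMeans(values[idx, in_scope_cols, drop = FALSE],
                         na.rm = TRUE)
    mean_int[is.nan(mean_int)] <- -Inf
    for (p in unique(prot[idx])) {
      rows <- idx[prot[idx] == p]
      if (length(rows) <= params$topn_peptides) next
      loc <- match(rows, idx)
      ord <- order(-det_count[loc], -mean_int[loc], rownames(values)[rows])
      keep[rows[ord[-seq_len(params$topn_peptides)]]] <- FALSE
    }
  }
  keep
}

#' Filter a matrix for one contrast
#'
#' By-contrast feature selection: samples outside the contrast's two groups
#' are dropped, then [filter_peptides()] runs with exactly those two groups
#' in scope. This keeps peptides reliably observed in the compared groups
#' even when absent elsewhere.
#'
#' @param matrix an [abundance_matrix()].
#' @param params a [filter_params()]; `by_contrast` must be `TRUE`.
#' @param ctr a [contrast()].
#' @return a filtered `abundance_matrix` containing only the contrast's
#'   samples.
#' @export
filter_for_contrast <- function(matrix, params, ctr) {
  stopifnot(inherits(ctr, "contrast"))
  if (!isTRUE(params$by_contrast))
    stop("filter_for_contrast requires by_contrast = TRUE", call. = FALSE)
  check_contrast_groups(ctr, matrix$groups)
  keep_cols <- matrix$groups %in% c(ctr$group_a, ctr$group_b)
  sub <- subset_matrix(matrix, samples = keep_cols)
  filter_peptides(sub, params,
                  groups_in_scope = c(ctr$group_a, ctr$group_b))
}
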