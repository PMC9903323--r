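#' Quality-control metrics for a peptide dataset
#'
#' Computes the sample-level diagnostics used to spot outlier samples and
#' batch structure before any statistics are run:
#' \itemize{
#'   \item per-sample detected peptide counts;
#'   \item per-group coefficient-of-variation summaries (CV of linear
#'     intensities per peptide across a group's replicates);
#'   \item leave-one-out impact: how much the group's median CV changes
#'     when each sample is dropped (negative = the sample inflates
#'     within-group variation);
#'   \item PCA sample coordinates (standard PCA on complete-case rows,
#'     feature-centered) with all metadata columns attached for
#'     color-coding;
#'   \item per-contrast foldchange-distribution summaries (median and KDE
#'     mode of the peptide-level group-mean foldchanges).
#' }
#' Metrics undefined for singleton groups are reported as `NA`. Excluded
#' samples may be included here (build the matrix with
#' `include_excluded = TRUE`): QC is exactly where they should be visible.
#'
#' @param matrix an [abundance_matrix()] with `detected` mask.
#' @param metadata a `sample_metadata` table covering the matrix columns.
#' @param contrasts optional list of [contrast()]s for foldchange
#'   summaries.
#' @return named list of data.frames: `sample_counts`, `group_cv`,
#'   `leave_one_out`, `pca`, `contrast_fc`.
#' @export
qc_metrics <- function(matrix, metadata = NULL, contrasts = NULL) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  x <- matrix$values
  groups <- matrix$groups
  det <- if (!is.null(matrix$detected)) matrix$detected & !is.na(x)
         else !is.na(x)

  sample_counts <- data.frame(sample_id = colnames(x),
                              group = unname(groups),
                              n_detected = colSums(det),
                              n_quantified = colSums(!is.na(x)))

  cv_of <- function(cols) {
    if (length(cols) < 2) return(NULL)
    lin <- 2^x[, cols, drop = FALSE]
    n <- rowSums(!is.na(lin))
    m <- rowMeans(lin, na.rm = TRUE)
    s <- apply(lin, 1, stats::sd, na.rm = TRUE)
    cv <- ifelse(n >= 2, s / m, NA_real_)
    cv[is.finite(cv)]
  }

  glev <- unique(groups)
  group_cv <- do.call(rbind, lapply(glev, function(g) {
    cv <- cv_of(which(groups == g))
    if (is.null(cv) || !length(cv))
      return(data.frame(group = g, n_samples = sum(groups == g),
                        median_cv = NA_real_, q25_cv = NA_real_,
                        q75_cv = NA_real_))
    qs <- stats::quantile(cv, c(0.25, 0.5, 0.75))
    data.frame(group = g, n_samples = sum(groups == g),
               median_cv = qs[[2]], q25_cv = qs[[1]], q75_cv = qs[[3]])
  }))

  loo <- do.call(rbind, lapply(colnames(x), function(s) {
    g <- groups[s]
    cols <- which(groups == g)
    if (length(cols) < 3)
      return(data.frame(sample_id = s, group = unname(g),
                        delta_median_cv = NA_real_))
    full <- stats::median(cv_of(cols))
    without <- stats::median(cv_of(setdiff(cols, which(colnames(x) == s))))
    data.frame(sample_id = s, group = unname(g),
               delta_median_cv = without - full)
  }))

  pca <- qc_pca(x, groups, metadata)

  contrast_fc <- NULL
  if (!is.null(contrasts)) {
    if (inherits(contrasts, "contrast")) contrasts <- list(contrasts)
    contrast_fc <- do.call(rbind, lapply(contrasts, function(ctr) {
      check_contrast_groups(ctr, groups)
      fc <- rowMeans(x[, groups == ctr$group_b, drop = FALSE],
                     na.rm = TRUE) -
        rowMeans(x[, groups == ctr$group_a, drop = FALSE], na.rm = TRUE)
      fc <- fc[is.finite(fc)]
      data.frame(contrast = ctr$name, n_features = length(fc),
                 fc_median = stats::median(fc),
                 fc_mode = estimate_mode(fc))
    }))
  }

  list(sample_counts = sample_counts, group_cv = group_cv,
       leave_one_out = loo, pca = pca, contrast_fc = contrast_fc)
}

qc_pca <- function(x, groups, metadata) {
  complete <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(complete) < 3)
    return(data.frame(sample_id = colnames(x), group = unname(groups),
                      PC1 = NA_real_, PC2 = NA_real_))
  # samples as observations, features centered
  pc <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
  out <- data.frame(sample_id = colnames(x), group = unname(groups),
                    PC1 = pc$x[, 1],
                    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else NA_real_,
                    row.names = NULL)
  if (!is.null(metadata)) {
    extra <- metadata[match(out$sample_id, metadata$sample_id),
                      setdiff(names(metadata), c("sample_id", "group")),
                      drop = FALSE]
    out <- cbind(out, extra)
  }
  out
}
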