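#' ROC curve and partial AUC at fixed specificity
#'
#' Threshold sweep over the ranking scores (smaller = more significant,
#' i.e. p-values), with tied scores collapsed into a single threshold step
#' so the curve is deterministic. The partial AUC integrates TPR over
#' FPR in \[0, 1 - specificity_floor\] by the trapezoid rule, interpolating
#' at the right edge; with the default floor of 0.95 the maximum
#' attainable value is 0.05 and the chance level is 0.05^2 / 2 = 0.00125.
#'
#' @param scores numeric ranking values; `NA` scores rank last (least
#'   significant).
#' @param labels logical truth (TRUE = positive/regulated).
#' @param specificity_floor default 0.95.
#' @return a `roc_result` list: `fpr`, `tpr`, `pauc95`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_pauc <- function(scores, labels, specificity_floor = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  scores[is.na(scores)] <- Inf
  o <- order(scores)
  s <- scores[o]; l <- labels[o]
  # cumulative counts at the end of each tie block
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l)[block_end]
  fp <- cumsum(!l)[block_end]
  fpr <- c(0, fp / n_neg)
  tpr <- c(0, tp / n_pos)
  fmax <- 1 - specificity_floor
  pauc <- trapezoid_partial(fpr, tpr, fmax)
  auc <- trapezoid_partial(fpr, tpr, 1)
  structure(list(fpr = fpr, tpr = tpr, pauc95 = pauc, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

# trapezoid integral of tpr over fpr on [0, fmax], interpolating at fmax
trapezoid_partial <- function(fpr, tpr, fmax) {
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    if (x0 >= fmax) break
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x1 > fmax) {
      y1 <- if (x1 > x0) y0 + (y1 - y0) * (fmax - x0) / (x1 - x0) else y0
      x1 <- fmax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  min(area, fmax)   # guard accumulated floating-point overshoot
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d pos / %d neg, pAUC@95%% = %.5f, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$pauc95, x$auc))
  invisible(x)
}

#' Distance to the best normalization within each (contrast, DEA) cell
#'
#' For every combination of contrast and DEA algorithm, the best partial
#' AUC over the compared normalization chains is located and each row's
#' distance to it recorded; the best chain scores 0 and larger distances
#' mean worse ranking performance.
#'
#' @param grid data.frame with at least columns `normalization`, `dea`,
#'   `contrast`, `pauc95`.
#' @return the grid with a `distance_to_best` column.
#' @export
distance_to_best <- function(grid) {
  stopifnot(all(c("normalization", "dea", "contrast", "pauc95") %in%
                names(grid)))
  key <- paste(grid$contrast, grid$dea, sep = "\r")
  best <- tapply(grid$pauc95, key, max)
  grid$distance_to_best <- as.numeric(best[key] - grid$pauc95)
  grid
}

#' Median log2 foldchange of background proteins
#'
#' Centering diagnostic for spike-in data: background (unregulated)
#' proteins should have log2 foldchange 0 after normalization; the median
#' of their foldchange distribution measures residual mis-centering.
#'
#' @param dea_results result data.frame (one algorithm's rows).
#' @param background_set protein ids of the background class.
#' @return scalar median log2 foldchange.
#' @export
background_fc_median <- function(dea_results, background_set) {
  sel <- dea_results$protein_id %in% background_set
  if (!any(sel))
    stop("no background proteins among results", call. = FALSE)
  stats::median(dea_results$log2fc[sel], na.rm = TRUE)
}

#' Confusion counts at q-value cutoffs
#'
#' True/false positive and negative counts against ground truth, at each
#' q-value cutoff, optionally restricted to proteins with at least
#' `min_peptides` peptides and requiring `|log2fc| >= fc_threshold` for a
#' call.
#'
#' @param dea_results result data.frame (one algorithm's rows).
#' @param truth_positive protein ids that are truly regulated.
#' @param q_cutoffs numeric vector of FDR cutoffs, default `c(0.01, 0.05)`.
#' @param fc_threshold optional absolute log2 foldchange requirement.
#' @param min_peptides optional minimum peptide count.
#' @return data.frame with one row per cutoff: `q_cutoff`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(dea_results, truth_positive,
                             q_cutoffs = c(0.01, 0.05),
                             fc_threshold = NULL, min_peptides = NULL) {
  res <- dea_results
  if (!is.null(min_peptides))
    res <- res[res$n_peptides >= min_peptides, , drop = FALSE]
  scored <- res[!is.na(res$qvalue), , drop = FALSE]
  pos <- scored$protein_id %in% truth_positive
  out <- lapply(q_cutoffs, function(qc) {
    call <- scored$qvalue <= qc
    if (!is.null(fc_threshold))
      call <- call & !is.na(scored$log2fc) &
        abs(scored$log2fc) >= fc_threshold
    data.frame(q_cutoff = qc,
               tp = sum(call & pos), fp = sum(call & !pos),
               tn = sum(!call & !pos), fn = sum(!call & pos))
  })
  do.call(rbind, out)
}

#' Benchmark a grid of normalization chains and DEA algorithms
#'
#' Runs the full pipeline for every supplied normalization chain and every
#' DEA algorithm against ground truth and scores each combination:
#' partial AUC at 95% specificity of the p-value ranking, the background
#' foldchange median, and confusion counts at the requested cutoffs.
#'
#' @param matrix an [abundance_matrix()] (non-excluded samples).
#' @param ctr a [contrast()].
#' @param truth_positive regulated protein ids.
#' @param chains named list of normalization chains (character vectors);
#'   names label the grid rows.
#' @param algorithms DEA algorithms to compare.
#' @param rollup_method rollup strategy, default `"maxlfq"`.
#' @param q_cutoffs cutoffs for [confusion_counts()].
#' @return a data.frame grid with `distance_to_best` filled in.
#' @export
benchmark_grid <- function(matrix, ctr, truth_positive, chains,
                           algorithms = c("ebayes", "deqms"),
                           rollup_method = "maxlfq",
                           q_cutoffs = c(0.01, 0.05)) {
  stopifnot(is.list(chains), !is.null(names(chains)))
  rows <- list()
  for (nm in names(chains)) {
    normed <- normalize_matrix(matrix, chains[[nm]],
                               rollup_method = rollup_method)
    pmat <- rollup(normed$matrix, method = rollup_method)
    for (alg in algorithms) {
      fn <- get(alg, envir = .dea_registry)
      res <- fn(normed$matrix, pmat, ctr, 0.01, NULL)
      res$algorithm <- alg
      background <- setdiff(res$protein_id, truth_positive)
      scored <- !is.na(res$pvalue)
      roc <- roc_pauc(res$pvalue[scored],
                      res$protein_id[scored] %in% truth_positive)
      cc <- confusion_counts(res, truth_positive, q_cutoffs)
      row <- data.frame(normalization = nm, dea = alg,
                        contrast = ctr$name,
                        pauc95 = roc$pauc95,
                        background_fc_median =
                          background_fc_median(res, background),
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(cc))) {
        row[[paste0("tp_q", cc$q_cutoff[i])]] <- cc$tp[i]
        row[[paste0("fp_q", cc$q_cutoff[i])]] <- cc$fp[i]
      }
      rows[[paste(nm, alg)]] <- row
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  distance_to_best(grid)
}
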