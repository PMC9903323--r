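#' Collapse a peptide matrix to protein level
#'
#' Dispatches to one of the rollup strategies. All operate on each
#' protein's peptide x sample log2 submatrix; proteins whose cells are all
#' missing are dropped, and `n_peptides` records, per protein, the number
#' of peptides with at least one observed cell.
#'
#' @param matrix an [abundance_matrix()].
#' @param method `"sum"` (log2 of summed linear intensities), `"tmp"`
#'   (Tukey median polish) or `"maxlfq"` (pairwise-ratio least squares).
#' @return a [protein_matrix()].
#' @export
rollup <- function(matrix, method = c("maxlfq", "tmp", "sum")) {
  method <- match.arg(method)
  switch(method,
         sum = rollup_sum(matrix),
         tmp = rollup_tmp(matrix),
         maxlfq = rollup_maxlfq(matrix))
}

split_by_protein <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  prot <- matrix$feature_to_protein
  idx <- split(seq_len(nrow(matrix$values)), prot)
  idx[order(names(idx))]
}

assemble_protein_matrix <- function(rows, idx, matrix, method) {
  values <- do.call(rbind, rows)
  rownames(values) <- names(idx)
  n_pep <- vapply(idx, function(i)
    sum(rowSums(!is.na(matrix$values[i, , drop = FALSE])) > 0),
    integer(1))
  keep <- rowSums(!is.na(values)) > 0
  protein_matrix(values[keep, , drop = FALSE], matrix$groups,
                 n_pep[keep], method)
}

#' Sum rollup
#'
#' Protein abundance per sample = log2 of the sum of linear peptide
#' intensities over observed cells; missing when no peptide was observed.
#' The traditional baseline; dominated by the most intense peptides.
#'
#' @param matrix an [abundance_matrix()].
#' @return a [protein_matrix()].
#' @export
rollup_sum <- function(matrix) {
  idx <- split_by_protein(matrix)
  rows <- lapply(idx, function(i) {
    sub <- 2^matrix$values[i, , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0] <- NA_real_
    log2(s)
  })
  assemble_protein_matrix(rows, idx, matrix, "sum")
}

#' Tukey median polish rollup
#'
#' Per protein, the peptide x sample log2 submatrix is decomposed into
#' overall + row (peptide) + column (sample) effects by alternating
#' row/column median sweeps (row sweep first, midpoint median, missing
#' cells ignored) until the largest sweep change drops below `tol` or
#' `max_sweeps` is reached. The protein profile is overall + column
#' effects; samples without any observed peptide stay missing.
#'
#' @param matrix an [abundance_matrix()].
#' @param tol sweep convergence tolerance, default 1e-6.
#' @param max_sweeps sweep cap, default 20.
#' @return a [protein_matrix()].
#' @export
rollup_tmp <- function(matrix, tol = 1e-6, max_sweeps = 20) {
  idx <- split_by_protein(matrix)
  rows <- lapply(idx, function(i) {
    sub <- matrix$values[i, , drop = FALSE]
    prof <- median_polish_profile(sub, tol, max_sweeps)
    prof[colSums(!is.na(sub)) == 0] <- NA_real_
    prof
  })
  assemble_protein_matrix(rows, idx, matrix, "tmp")
}

# overall + column effects of a median polish; single-row shortcut keeps
# a 1-peptide protein identical to its peptide
median_polish_profile <- function(sub, tol, max_sweeps) {
  if (nrow(sub) == 1) return(drop(sub))
  r <- sub
  overall <- 0
  row_eff <- numeric(nrow(sub))
  col_eff <- numeric(ncol(sub))
  for (s in seq_len(max_sweeps)) {
    rd <- cpp_row_medians(r)
    rd[is.na(rd)] <- 0
    row_eff <- row_eff + rd
    r <- r - rd                      # recycles down columns: per-row sweep
    cd <- cpp_col_medians(r)
    cd[is.na(cd)] <- 0
    col_eff <- col_eff + cd
    r <- sweep(r, 2, cd, `-`)
    # move the medians of the effect vectors into the overall term
    rm_med <- stats::median(row_eff)
    row_eff <- row_eff - rm_med
    cm_med <- stats::median(col_eff)
    col_eff <- col_eff - cm_med
    overall <- overall + rm_med + cm_med
    if (max(abs(rd), abs(cd)) < tol) break
  }
  overall + col_eff
}

#' MaxLFQ-style rollup
#'
#' Per protein: (1) for every pair of samples the median peptide log2
#' ratio over peptides observed in both; (2) least-squares reconstruction
#' of a per-sample profile whose pairwise differences match those medians
#' (pairs with at least one shared peptide enter the system); (3) the
#' profile is anchored so its mean equals the mean of the protein's
#' observed peptide cells. Samples in no valid pair are missing; proteins
#' with no valid pair at all fall back to per-sample means of their
#' observed cells.
#'
#' @param matrix an [abundance_matrix()].
#' @return a [protein_matrix()].
#' @export
rollup_maxlfq <- function(matrix) {
  idx <- split_by_protein(matrix)
  rows <- lapply(idx, function(i)
    maxlfq_profile(matrix$values[i, , drop = FALSE]))
  assemble_protein_matrix(rows, idx, matrix, "maxlfq")
}

maxlfq_profile <- function(sub) {
  n <- ncol(sub)
  if (nrow(sub) == 1) return(drop(sub))
  pr <- cpp_pairwise_ratio_medians(sub)
  ratio <- pr$ratio; count <- pr$count
  valid <- count > 0
  in_pair <- apply(valid, 1, any)
  prof <- rep(NA_real_, n)
  names(prof) <- colnames(sub)
  if (!any(in_pair)) {
    cm <- colMeans(sub, na.rm = TRUE)
    cm[is.nan(cm)] <- NA_real_
    return(cm)
  }
  # connected components of the valid-pair graph; each anchored on its own
  # observed-cell mean (the global anchor when the graph is connected)
  pairs <- which(upper.tri(valid) & valid, arr.ind = TRUE)
  comp <- pair_components(n, pairs)
  for (cc in unique(comp[in_pair])) {
    cols <- which(comp == cc & in_pair)
    if (length(cols) < 2) next
    sub_pairs <- pairs[pairs[, 1] %in% cols & pairs[, 2] %in% cols, ,
                       drop = FALSE]
    k <- length(cols)
    L <- matrix(0, k, k)
    b <- numeric(k)
    loc <- match(seq_len(n), cols)
    for (r in seq_len(nrow(sub_pairs))) {
      j <- loc[sub_pairs[r, 1]]; h <- loc[sub_pairs[r, 2]]
      rr <- ratio[sub_pairs[r, 1], sub_pairs[r, 2]]
      L[j, j] <- L[j, j] + 1; L[h, h] <- L[h, h] + 1
      L[j, h] <- L[j, h] - 1; L[h, j] <- L[h, j] - 1
      b[h] <- b[h] + rr; b[j] <- b[j] - rr
    }
    anchor <- mean(sub[, cols], na.rm = TRUE)
    p <- solve(L + matrix(1 / k, k, k), b + anchor)
    prof[cols] <- p
  }
  prof
}
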