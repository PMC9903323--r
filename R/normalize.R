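#' Estimate the mode of a distribution by kernel density
#'
#' Argmax of a Gaussian kernel density (Silverman's rule-of-thumb
#' bandwidth) evaluated on a 512-point grid spanning the data range padded
#' by 3 bandwidths. Deterministic for fixed input. Used throughout the
#' mode-based normalizations: the most frequent log-foldchange of a
#' (mostly unregulated) feature population is a robust estimate of the
#' systematic shift between two samples or groups, insensitive to an
#' asymmetric regulated minority where mean or even median are not.
#'
#' @param values numeric vector; non-finite entries are ignored.
#' @param min_n below this many finite values the estimator falls back to
#'   the median with a warning (default 10).
#' @return scalar mode estimate.
#' @export
estimate_mode <- function(values, min_n = 10) {
  x <- values[is.finite(values)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) < min_n) {
    warning("estimate_mode: fewer than ", min_n,
            " finite values, falling back to median", call. = FALSE)
    return(stats::median(x))
  }
  if (diff(range(x)) < .Machine$double.eps^0.5) return(x[1])
  d <- stats::density(x, bw = "nrd0", kernel = "gaussian", n = 512, cut = 3)
  d$x[which.max(d$y)]
}

#' Within-group variation-minimizing sample scaling (VW)
#'
#' Within each sample group independently, per-sample additive log2 offsets
#' are chosen so that the spread of each peptide across replicates shrinks:
#' coordinate descent repeatedly re-centers every column on the median of
#' its deviations from the within-group row means, until offsets change by
#' less than `tol`. Groups with a single sample get offset 0 (a singleton
#' has no within-group variation to minimize).
#'
#' @param matrix an [abundance_matrix()] or plain log2 matrix.
#' @param groups group label per column (taken from the matrix if absent).
#' @param tol convergence tolerance on the offset update, default 1e-6.
#' @param max_iter iteration cap, default 100.
#' @return a [norm_offsets()] record.
#' @export
vw_offsets <- function(matrix, groups = NULL, tol = 1e-6, max_iter = 100) {
  x <- as_values(matrix); groups <- resolve_groups(matrix, groups, x)
  off <- stats::setNames(numeric(ncol(x)), colnames(x))
  converged <- TRUE; iters <- 0L
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    sub <- x[, cols, drop = FALSE]
    o <- numeric(length(cols))
    for (it in seq_len(max_iter)) {
      shifted <- sweep(sub, 2, o, `+`)
      rm <- rowMeans(shifted, na.rm = TRUE)
      delta <- cpp_col_medians(rm - shifted)
      delta[is.na(delta)] <- 0
      o <- o + delta
      iters <- max(iters, it)
      if (max(abs(delta)) < tol) break
    }
    if (max(abs(delta)) >= tol) converged <- FALSE
    off[cols] <- o - mean(o)   # keep each group's overall level unchanged
  }
  norm_offsets(off, "vw", converged, iters)
}

#' Within-group pairwise-mode sample scaling (MW)
#'
#' Mode-foldchange variant of the within-group step: for every pair of
#' samples in a group, the mode of their per-peptide log2 differences
#' (shared non-missing rows) is computed, and per-sample offsets are solved
#' so all pairwise modes become zero. More robust than [vw_offsets()] when
#' unmodelled cofactors shift many peptides within a group.
#'
#' @inheritParams vw_offsets
#' @param min_shared minimum shared features for a pair to enter the
#'   objective (default 10).
#' @return a [norm_offsets()] record.
#' @export
mw_offsets <- function(matrix, groups = NULL, min_shared = 10) {
  x <- as_values(matrix); groups <- resolve_groups(matrix, groups, x)
  off <- stats::setNames(numeric(ncol(x)), colnames(x))
  converged <- TRUE; iters <- 0L
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    sub <- x[, cols, drop = FALSE]
    pm <- pairwise_mode_matrix(sub, seq_along(cols), min_shared)
    sol <- solve_offsets_from_pairwise_modes(pm)
    # negate: applying the offsets must cancel the observed modes
    off[cols] <- -sol$offsets
    converged <- converged && sol$converged
    iters <- max(iters, sol$iterations)
  }
  norm_offsets(off, "mw", converged, iters)
}

#' Between-group mode scaling (MB)
#'
#' Per-feature group means are computed over non-missing cells; for every
#' pair of groups the mode of the between-group log2 foldchanges is
#' estimated; per-group offsets are then solved to minimize the sum of
#' absolute residual modes (zero-sum anchored) and broadcast to every
#' sample of the group. After application, the most frequent between-group
#' foldchange is (near) zero, which is the null-hypothesis geometry the
#' downstream tests assume. Within-group foldchanges are untouched because
#' offsets are constant per group.
#'
#' @inheritParams mw_offsets
#' @param min_shared minimum features shared by a group pair; pairs below
#'   it are dropped from the objective with a warning, and an error is
#'   raised if the pair graph disconnects.
#' @return a [norm_offsets()] record with the `pairwise_modes` matrix
#'   attached as an attribute.
#' @export
mb_offsets <- function(matrix, groups = NULL, min_shared = 10) {
  x <- as_values(matrix); groups <- resolve_groups(matrix, groups, x)
  glev <- unique(groups)
  if (length(glev) < 2)
    stop("mb_offsets needs at least two sample groups", call. = FALSE)
  gm <- group_means(x, groups, glev)
  pm <- pairwise_mode_matrix(gm, seq_along(glev), min_shared,
                             labels = glev)
  sol <- solve_offsets_from_pairwise_modes(pm)
  off <- stats::setNames(-sol$offsets[match(groups, glev)], colnames(x))
  out <- norm_offsets(off, "mb", sol$converged, sol$iterations)
  attr(out, "pairwise_modes") <- pm
  out
}

# per-feature means per group over non-missing cells
group_means <- function(x, groups, glev = unique(groups)) {
  out <- vapply(glev, function(g)
    rowMeans(x[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(x)))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- glev
  out
}

# mode of column k minus column j for all pairs; drops sparse pairs
pairwise_mode_matrix <- function(cols_mat, idx, min_shared,
                                 labels = colnames(cols_mat)) {
  n <- length(idx)
  if (is.null(labels)) labels <- paste0("c", idx)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(m) <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      d <- cols_mat[, idx[k]] - cols_mat[, idx[j]]
      d <- d[is.finite(d)]
      if (length(d) < min_shared) {
        warning("pair (", labels[j], ", ", labels[k], ") shares only ",
                length(d), " features; dropped from mode objective",
                call. = FALSE)
        next
      }
      md <- estimate_mode(d, min_n = min_shared)
      m[j, k] <- md
      m[k, j] <- -md
    }
  }
  structure(list(groups = labels, m = m), class = "pairwise_mode_matrix")
}

#' Solve per-group levels from a pairwise mode matrix
#'
#' Finds zero-sum levels `o` minimizing
#' `sum over pairs g<h of |m[g,h] - (o_h - o_g)|`
#' by iteratively reweighted least squares on the pair-difference design
#' (weights `1/max(|residual|, 1e-6)`), initialized at the ordinary
#' least-squares solution. With consistent modes the solution reproduces
#' them exactly; with two groups it is the closed form `(-m/2, +m/2)`.
#'
#' Note the returned levels REPRODUCE the observed modes; callers that
#' normalize data apply their negation (see [mb_offsets()]).
#'
#' @param pm a `pairwise_mode_matrix` (list with `groups` and antisymmetric
#'   matrix `m`; `NA` entries mark dropped pairs).
#' @param tol convergence tolerance on the level update, default 1e-8.
#' @param max_iter iteration cap, default 200.
#' @return list with `offsets` (named, zero-sum), `objective`, `converged`,
#'   `iterations`.
#' @export
solve_offsets_from_pairwise_modes <- function(pm, tol = 1e-8,
                                              max_iter = 200) {
  m <- pm$m; G <- length(pm$groups)
  pairs <- which(upper.tri(m) & !is.na(m), arr.ind = TRUE)
  if (nrow(pairs) == 0)
    stop("no usable group pairs in mode matrix", call. = FALSE)
  comp <- pair_components(G, pairs)
  if (length(unique(comp)) > 1)
    stop("group pair graph is disconnected; components: ",
         paste(tapply(pm$groups, comp, paste, collapse = "+"),
               collapse = " | "), call. = FALSE)
  y <- m[pairs]
  X <- matrix(0, nrow(pairs), G)
  X[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- -1
  X[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
  Z <- rbind(diag(G - 1), -1)          # zero-sum parameterization
  XZ <- X %*% Z
  a <- qr.solve(crossprod(XZ), crossprod(XZ, y))
  o <- drop(Z %*% a)
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% o)
    w <- 1 / pmax(abs(r), 1e-6)
    a <- qr.solve(crossprod(XZ, w * XZ), crossprod(XZ, w * y))
    o_new <- drop(Z %*% a)
    step <- max(abs(o_new - o))
    o <- o_new
    if (step < tol) { converged <- TRUE; break }
  }
  o <- o - mean(o)
  list(offsets = stats::setNames(o, pm$groups),
       objective = sum(abs(y - drop(X %*% o))),
       converged = converged, iterations = it)
}

pair_components <- function(G, pairs) {
  comp <- seq_len(G)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (comp[a] != comp[b]) {
        comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Protein-level mode-between scaling applied to peptide data (MBprot)
#'
#' Rolls the peptide matrix up to protein level (default MaxLFQ-style),
#' computes between-group mode offsets on the PROTEIN matrix, and applies
#' those per-group offsets back to the PEPTIDE matrix. This corrects the
#' failure mode of peptide-level centering: a few regulated proteins with
#' very many peptides can dominate the peptide foldchange distribution
#' (peptides-per-protein is power-law distributed), so a centered peptide
#' distribution need not give a centered protein foldchange distribution.
#' Chain it after any peptide-level normalization.
#'
#' @inheritParams mb_offsets
#' @param rollup_method rollup used internally, default `"maxlfq"`.
#' @return a [norm_offsets()] record (per peptide-matrix sample).
#' @export
modebetween_protein <- function(matrix, groups = NULL,
                                rollup_method = "maxlfq",
                                min_shared = 10) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  groups <- resolve_groups(matrix, groups, matrix$values)
  prot <- rollup(matrix, method = rollup_method)
  mb <- mb_offsets(prot$values, groups = prot$groups,
                   min_shared = min_shared)
  off <- mb$per_sample_offset[colnames(matrix$values)]
  out <- norm_offsets(off, "modebetween_protein", mb$converged,
                      mb$iterations)
  attr(out, "pairwise_modes") <- attr(mb, "pairwise_modes")
  out
}

# --- method registry ------------------------------------------------------

.norm_registry <- new.env(parent = emptyenv())

#' Register a normalization plugin
#'
#' A plugin is a function `(matrix, groups, ...)` returning a
#' [norm_offsets()] record (or a bare named offset vector) for the samples
#' of `matrix`.
#'
#' @param name method name used in normalization chains.
#' @param fn the plugin function.
#' @export
register_normalization <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .norm_registry)
  invisible(name)
}

#' @export
#' @rdname register_normalization
normalization_methods <- function() sort(ls(.norm_registry))

norm_median <- function(matrix, groups = NULL, ...) {
  x <- as_values(matrix)
  cm <- cpp_col_medians(x)
  norm_offsets(stats::setNames(stats::median(x, na.rm = TRUE) - cm,
                               colnames(x)), "median")
}

register_default_normalizations <- function() {
  register_normalization("median", norm_median)
  register_normalization("var_overall", function(matrix, groups = NULL, ...) {
    # VW under the assumption all samples form one group
    x <- as_values(matrix)
    out <- vw_offsets(x, groups = rep("all", ncol(x)))
    out$method <- "var_overall"
    out
  })
  register_normalization("vw", function(matrix, groups = NULL, ...)
    vw_offsets(matrix, groups))
  register_normalization("mw", function(matrix, groups = NULL, ...)
    mw_offsets(matrix, groups))
  register_normalization("modebetween", function(matrix, groups = NULL, ...)
    mb_offsets(matrix, groups))
  register_normalization("vwmb", function(matrix, groups = NULL, ...)
    compose_offsets(matrix, groups, vw_offsets, mb_offsets, "vwmb"))
  register_normalization("mwmb", function(matrix, groups = NULL, ...)
    compose_offsets(matrix, groups, mw_offsets, mb_offsets, "mwmb"))
  register_normalization("modebetween_protein",
    function(matrix, groups = NULL, ...)
      modebetween_protein(matrix, groups, ...))
}

compose_offsets <- function(matrix, groups, step1, step2, label, ...) {
  x <- as_values(matrix); groups <- resolve_groups(matrix, groups, x)
  o1 <- step1(x, groups)
  x2 <- sweep(x, 2, o1$per_sample_offset, `+`)
  o2 <- step2(x2, groups)
  norm_offsets(o1$per_sample_offset + o2$per_sample_offset, label,
               o1$converged && o2$converged,
               max(o1$iterations, o2$iterations))
}

#' Apply a chain of normalizations
#'
#' Methods are applied left to right, each on the previous output; e.g.
#' `c("vwmb", "modebetween_protein")` first does within-group variance
#' scaling plus peptide-level between-group mode scaling, then re-balances
#' between-group levels on the protein rollup. Missing cells are untouched;
#' every method contributes a single additive log2 constant per sample.
#'
#' @param matrix an [abundance_matrix()].
#' @param chain character vector of registered method names (see
#'   [normalization_methods()]).
#' @param ... passed to each method (e.g. `rollup_method` for
#'   `modebetween_protein`).
#' @return list with `matrix` (normalized `abundance_matrix`) and
#'   `offsets` (list of [norm_offsets()], one per chain element).
#' @export
normalize_matrix <- function(matrix, chain, ...) {
  stopifnot(inherits(matrix, "abundance_matrix"), length(chain) >= 1)
  unknown <- setdiff(chain, normalization_methods())
  if (length(unknown))
    stop("unknown normalization method(s): ",
         paste(unknown, collapse = ", "), "; registered: ",
         paste(normalization_methods(), collapse = ", "), call. = FALSE)
  out <- matrix
  offs <- list()
  for (nm in chain) {
    fn <- get(nm, envir = .norm_registry)
    o <- fn(out, groups = out$groups, ...)
    if (!inherits(o, "norm_offsets"))
      o <- norm_offsets(o, nm)
    out$values <- sweep(out$values, 2,
                        o$per_sample_offset[colnames(out$values)], `+`)
    offs[[nm]] <- o
  }
  list(matrix = out, offsets = offs)
}

# --- small shared helpers -------------------------------------------------

as_values <- function(matrix) {
  if (inherits(matrix, "abundance_matrix")) matrix$values
  else if (inherits(matrix, "protein_matrix")) matrix$values
  else { stopifnot(is.matrix(matrix)); matrix }
}

resolve_groups <- function(matrix, groups, x) {
  if (is.null(groups)) {
    if (inherits(matrix, "abundance_matrix") ||
        inherits(matrix, "protein_matrix")) groups <- matrix$groups
    else stop("`groups` required for plain matrices", call. = FALSE)
  }
  if (length(groups) != ncol(x))
    stop("`groups` must have one label per sample column", call. = FALSE)
  as.character(groups)
}
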