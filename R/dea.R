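#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of min(1, m * p_(j) / j)
#' for p-values sorted ascending.
#'
#' @param pvalues numeric vector in \[0, 1\]; `NA`s are passed through.
#' @return q-values in the input order.
#' @export
adjust_bh <- function(pvalues) {
  q <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  p <- pvalues[ok]
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(q)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  q[ok[o]] <- adj
  q
}

# Newton solver for trigamma(x) = y (monotone decreasing), after Smyth
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of the scaled-F prior for residual variances:
# log s^2 matched to the log-chi-square moments via digamma/trigamma.
# Returns prior df d0 (possibly Inf, capped at 1e6) and either a scalar
# prior variance s0sq or, when `covariate` is supplied, a per-protein
# trend fitted by natural cubic spline on the covariate.
fit_variance_prior <- function(s2, df, covariate = NULL, spline_df = 3) {
  ok <- is.finite(s2) & df > 0
  s2f <- pmax(s2[ok], 1e-10)
  dff <- df[ok]
  z <- log(s2f)
  e <- z - digamma(dff / 2) + log(dff / 2)
  n <- length(e)
  if (n < 2) stop("cannot estimate variance prior from fewer than 2 ",
                  "proteins; use an unmoderated t-test", call. = FALSE)
  if (is.null(covariate)) {
    ehat <- rep(mean(e), n)
  } else {
    cv <- covariate[ok]
    u <- length(unique(cv))
    if (u < 2)
      stop("variance-prior covariate is constant", call. = FALSE)
    dfs <- min(spline_df, u - 1)
    # heavy ties in the covariate (most proteins have 1 peptide) can push
    # all spline knots onto a boundary; degrade gracefully to a polynomial
    basis <- NULL
    if (dfs >= 2)
      basis <- tryCatch(suppressWarnings(splines::ns(cv, df = dfs)),
                        error = function(e) NULL)
    if (is.null(basis))
      basis <- if (u >= 3) cbind(cv, cv^2) else cbind(cv)
    fit <- stats::lm(e ~ basis)
    ehat <- stats::fitted(fit)
  }
  resid <- e - ehat
  evar <- sum(resid^2) / (n - 1) - mean(trigamma(dff / 2))
  s0sq_fit <- if (is.finite(evar) && evar > 0) {
    d0 <- min(2 * trigamma_inverse(evar), 1e6)
    exp(ehat + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: infinite prior
    # df, and the prior level is the plain average of the variances
    d0 <- Inf
    if (is.null(covariate)) rep(mean(s2f), n) else exp(ehat)
  }
  s0sq_all <- rep(NA_real_, length(s2))
  s0sq_all[ok] <- s0sq_fit
  # proteins excluded from the fit inherit the overall prior level
  s0sq_all[!ok] <- mean(s0sq_fit)
  list(d0 = d0, s0sq = s0sq_all)
}

two_group_stats <- function(pmat, ctr) {
  check_contrast_groups(ctr, pmat$groups)
  x <- pmat$values
  a_cols <- pmat$groups == ctr$group_a
  b_cols <- pmat$groups == ctr$group_b
  na <- rowSums(!is.na(x[, a_cols, drop = FALSE]))
  nb <- rowSums(!is.na(x[, b_cols, drop = FALSE]))
  ma <- rowMeans(x[, a_cols, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(x[, b_cols, drop = FALSE], na.rm = TRUE)
  ssa <- rowSums((x[, a_cols, drop = FALSE] - ma)^2, na.rm = TRUE)
  ssb <- rowSums((x[, b_cols, drop = FALSE] - mb)^2, na.rm = TRUE)
  df <- na + nb - 2
  s2 <- ifelse(df > 0, (ssa + ssb) / df, NA_real_)
  list(log2fc = mb - ma, na = na, nb = nb, s2 = s2, df = df,
       testable = na >= 2 & nb >= 2)
}

moderated_fit <- function(pmat, ctr, algorithm, alpha, fc_threshold,
                          covariate_trend) {
  st <- two_group_stats(pmat, ctr)
  res <- data.frame(
    protein_id = rownames(pmat$values),
    contrast = ctr$name,
    log2fc = st$log2fc,
    se = NA_real_, t = NA_real_, df = NA_real_,
    pvalue = NA_real_, qvalue = NA_real_,
    n_peptides = as.integer(pmat$n_peptides),
    algorithm = algorithm,
    signif = NA, reason = NA_character_,
    stringsAsFactors = FALSE)
  res$log2fc[!is.finite(res$log2fc)] <- NA_real_
  res$reason[!st$testable] <- "fewer than 2 observed values in a group"
  tst <- st$testable
  if (sum(tst) < 2)
    stop("fewer than 2 testable proteins; cannot estimate the variance ",
         "prior", call. = FALSE)
  covariate <- if (covariate_trend)
    log(pmax(res$n_peptides[tst], 1L)) else NULL
  prior <- fit_variance_prior(st$s2[tst], st$df[tst], covariate)
  d0 <- prior$d0
  post <- if (is.finite(d0))
    (d0 * prior$s0sq + st$df[tst] * st$s2[tst]) / (d0 + st$df[tst])
  else prior$s0sq
  se <- sqrt(post * (1 / st$na[tst] + 1 / st$nb[tst]))
  tt <- st$log2fc[tst] / se
  df_tot <- pmin(d0 + st$df[tst], 1e6)
  res$se[tst] <- se
  res$t[tst] <- tt
  res$df[tst] <- df_tot
  res$pvalue[tst] <- 2 * stats::pt(-abs(tt), df_tot)
  res$qvalue <- adjust_bh(res$pvalue)
  res$signif <- res$qvalue <= alpha &
    (is.null(fc_threshold) | abs(res$log2fc) >= (fc_threshold %||% 0))
  attr(res, "prior") <- list(d0 = d0,
                             s0sq = prior$s0sq,
                             trend = covariate_trend)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moderated t-test on protein abundances (empirical Bayes)
#'
#' Two-group moderated t-statistics: per-protein pooled residual variances
#' are shrunk toward a common prior estimated across all proteins by
#' matching the moments of log s^2 to the scaled chi-square model
#' (digamma/trigamma method of moments); t-statistics use the posterior
#' variance and gain the prior degrees of freedom. Proteins with fewer
#' than two observed values in either group are reported with a reason
#' code instead of being dropped.
#'
#' @param pmat a [protein_matrix()].
#' @param ctr a [contrast()]; foldchange is `group_b - group_a`.
#' @param alpha q-value cutoff used for the `signif` flag, default 0.01.
#' @param fc_threshold optional absolute log2 foldchange required for
#'   `signif`.
#' @param moderate set `FALSE` to force the prior df to zero (plain pooled
#'   two-sample t-test; diagnostic).
#' @return a data.frame of per-protein results with the fitted prior
#'   attached as attribute `prior`.
#' @export
fit_ebayes <- function(pmat, ctr, alpha = 0.01, fc_threshold = NULL,
                       moderate = TRUE) {
  if (!moderate) return(plain_t_fit(pmat, ctr, alpha, fc_threshold))
  moderated_fit(pmat, ctr, "ebayes", alpha, fc_threshold,
                covariate_trend = FALSE)
}

plain_t_fit <- function(pmat, ctr, alpha, fc_threshold) {
  st <- two_group_stats(pmat, ctr)
  res <- moderated_fit(pmat, ctr, "t", alpha, fc_threshold, FALSE)
  tst <- st$testable
  se <- sqrt(st$s2[tst] * (1 / st$na[tst] + 1 / st$nb[tst]))
  res$se[tst] <- se
  res$t[tst] <- st$log2fc[tst] / se
  res$df[tst] <- st$df[tst]
  res$pvalue[tst] <- 2 * stats::pt(-abs(res$t[tst]), st$df[tst])
  res$qvalue <- adjust_bh(res$pvalue)
  res$signif <- res$qvalue <= alpha &
    (is.null(fc_threshold) | abs(res$log2fc) >= (fc_threshold %||% 0))
  attr(res, "prior") <- list(d0 = 0, s0sq = NA_real_, trend = FALSE)
  res
}

#' Peptide-count-aware moderated t-test (DEqMS-style)
#'
#' Like [fit_ebayes()] but the variance prior is a function of how many
#' peptides quantified each protein: log s^2 is regressed on
#' log(n_peptides) with a natural cubic spline (3 df), the prior variance
#' per protein is the exponentiated fitted trend, and the prior degrees of
#' freedom are re-estimated from the spread around the trend. Proteins
#' quantified by many peptides typically have smaller variance; exploiting
#' this gives better-calibrated shrinkage and more power than a single
#' common prior. Falls back to [fit_ebayes()] (with a warning) when all
#' proteins share one peptide count.
#'
#' @inheritParams fit_ebayes
#' @return a data.frame of per-protein results.
#' @export
fit_deqms <- function(pmat, ctr, alpha = 0.01, fc_threshold = NULL) {
  if (length(unique(pmat$n_peptides)) < 2) {
    warning("all proteins have the same peptide count; ",
            "falling back to fit_ebayes", call. = FALSE)
    res <- fit_ebayes(pmat, ctr, alpha, fc_threshold)
    res$algorithm <- "deqms"
    return(res)
  }
  moderated_fit(pmat, ctr, "deqms", alpha, fc_threshold,
                covariate_trend = TRUE)
}

#' Permutation-based foldchange threshold
#'
#' Estimates the magnitude of log2 foldchanges arising by chance: group
#' labels of the contrast's samples are permuted (distinct reassignments
#' of the group-A set), per-protein |log2fc| is recomputed for each
#' permutation, and the requested quantile of the pooled null values is
#' returned. Used as an additional cutoff on top of the q-value to define
#' significant hits.
#'
#' @param pmat a [protein_matrix()].
#' @param ctr a [contrast()].
#' @param n_permutations maximum distinct permutations, default 1000. When
#'   fewer distinct reassignments exist they are enumerated exhaustively
#'   with a warning.
#' @param probs quantile of the pooled null |log2fc|, default 0.95.
#' @param seed integer seed making the sampled permutation set
#'   reproducible.
#' @return scalar threshold (log2 units).
#' @export
estimate_fc_threshold <- function(pmat, ctr, n_permutations = 1000,
                                  probs = 0.95, seed = 1L) {
  check_contrast_groups(ctr, pmat$groups)
  cols <- which(pmat$groups %in% c(ctr$group_a, ctr$group_b))
  x <- pmat$values[, cols, drop = FALSE]
  na_ <- sum(pmat$groups[cols] == ctr$group_a)
  n <- length(cols)
  if (na_ < 3 || (n - na_) < 3)
    stop("permutation threshold needs at least 3 samples per group",
         call. = FALSE)
  n_distinct <- choose(n, na_)
  perms <- if (n_distinct <= n_permutations) {
    warning("only ", n_distinct, " distinct permutations exist; ",
            "using all of them", call. = FALSE)
    utils::combn(n, na_, simplify = FALSE)
  } else {
    with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- vector("list", n_permutations)
      got <- 0L
      while (got < n_permutations) {
        cand <- sort(sample.int(n, na_))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- cand
        }
      }
      out
    })
  }
  null_fc <- unlist(lapply(perms, function(ia) {
    ma <- rowMeans(x[, ia, drop = FALSE], na.rm = TRUE)
    mb <- rowMeans(x[, -ia, drop = FALSE], na.rm = TRUE)
    d <- abs(mb - ma)
    d[is.finite(d)]
  }))
  unname(stats::quantile(null_fc, probs = probs, type = 7))
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- DEA plugin registry --------------------------------------------------

.dea_registry <- new.env(parent = emptyenv())

#' Register a differential-expression plugin
#'
#' A plugin is a function `(peptide_matrix, protein_matrix, contrast, alpha,
#' fc_threshold)` returning a result data.frame shaped like [fit_ebayes()]
#' output. The built-in protein-level algorithms are registered under
#' `"ebayes"` and `"deqms"`.
#'
#' @param name algorithm name used in configs.
#' @param fn plugin function.
#' @export
register_dea <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .dea_registry)
  invisible(name)
}

#' @export
#' @rdname register_dea
dea_methods <- function() sort(ls(.dea_registry))

register_default_dea <- function() {
  register_dea("ebayes", function(pepmat, pmat, ctr, alpha, fc_threshold)
    fit_ebayes(pmat, ctr, alpha, fc_threshold))
  register_dea("deqms", function(pepmat, pmat, ctr, alpha, fc_threshold)
    fit_deqms(pmat, ctr, alpha, fc_threshold))
}

#' Pipeline configuration for differential expression analysis
#'
#' @param filter a [filter_params()].
#' @param normalization character chain of normalization method names.
#' @param rollup_method rollup strategy, default `"maxlfq"`.
#' @param algorithms DEA algorithm names (see [dea_methods()]).
#' @param alpha q-value cutoff for `signif`, default 0.01.
#' @param fc_threshold `NULL`, a fixed absolute log2 foldchange, or
#'   `"permute"` to estimate one per contrast by permutation.
#' @param n_permutations permutations when `fc_threshold = "permute"`.
#' @param seed run-level seed; stochastic steps derive child seeds from it.
#' @return a `dea_config` list.
#' @export
dea_config <- function(filter = filter_params(),
                       normalization = c("vwmb", "modebetween_protein"),
                       rollup_method = "maxlfq",
                       algorithms = c("ebayes", "deqms"),
                       alpha = 0.01, fc_threshold = NULL,
                       n_permutations = 1000, seed = 1L) {
  unknown <- setdiff(algorithms, dea_methods())
  if (length(unknown))
    stop("unknown DEA algorithm(s): ", paste(unknown, collapse = ", "),
         "; registered: ", paste(dea_methods(), collapse = ", "),
         call. = FALSE)
  structure(list(filter = filter, normalization = normalization,
                 rollup_method = rollup_method, algorithms = algorithms,
                 alpha = alpha, fc_threshold = fc_threshold,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "dea_config")
}

#' Run the full differential-expression pipeline
#'
#' Per contrast: feature selection (per contrast when
#' `filter$by_contrast`, else dataset-wide), the normalization chain,
#' peptide-to-protein rollup, then every configured algorithm. Samples
#' flagged `exclude` in the metadata never enter this path (drop them when
#' building the matrix).
#'
#' @param matrix an [abundance_matrix()] of non-excluded samples, with the
#'   `detected` mask (from [build_matrix()]).
#' @param contrasts a [contrast()] or list of contrasts.
#' @param config a [dea_config()].
#' @return data.frame of results over all contrasts and algorithms, with
#'   per-contrast foldchange thresholds attached as attribute
#'   `fc_thresholds`.
#' @export
run_dea <- function(matrix, contrasts, config = dea_config()) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(config, "dea_config"))
  if (inherits(contrasts, "contrast")) contrasts <- list(contrasts)
  out <- list()
  thresholds <- list()
  for (ci in seq_along(contrasts)) {
    ctr <- contrasts[[ci]]
    check_contrast_groups(ctr, matrix$groups)
    filtered <- if (isTRUE(config$filter$by_contrast))
      filter_for_contrast(matrix, config$filter, ctr)
    else {
      f <- filter_peptides(matrix, config$filter)
      subset_matrix(f, samples = f$groups %in% c(ctr$group_a, ctr$group_b))
    }
    normed <- normalize_matrix(filtered, config$normalization,
                               rollup_method = config$rollup_method)
    pmat <- rollup(normed$matrix, method = config$rollup_method)
    fc_thr <- config$fc_threshold
    if (identical(fc_thr, "permute"))
      fc_thr <- estimate_fc_threshold(
        pmat, ctr, n_permutations = config$n_permutations,
        seed = config$seed + 7919L * ci)
    thresholds[[ctr$name]] <- fc_thr %||% NA_real_
    for (alg in config$algorithms) {
      fn <- get(alg, envir = .dea_registry)
      res <- fn(normed$matrix, pmat, ctr, config$alpha, fc_thr)
      res$algorithm <- alg
      out[[paste(ctr$name, alg)]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fc_thresholds") <- unlist(thresholds)
  res
}
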