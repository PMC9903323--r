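make_pmat <- function(x, groups, n_peptides = NULL) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  if (is.null(n_peptides)) n_peptides <- rep(1L, nrow(x))
  protein_matrix(x, groups, n_peptides, "test")
}

sim_pmat <- function(n = 300, nA = 4, nB = 4, delta = 0, sd = 0.3,
                     seed = 1, n_peptides = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * (nA + nB), 20, 1), n, nA + nB) +
    matrix(rnorm(n * (nA + nB), 0, sd), n, nA + nB)
  x[, (nA + 1):(nA + nB)] <- x[, (nA + 1):(nA + nB)] + delta
  make_pmat(x, rep(c("A", "B"), c(nA, nB)), n_peptides = n_peptides)
}

test_that("adjust_bh matches hand computation and the brute-force oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(5)
  p <- runif(50)
  expect_equal(adjust_bh(p), oracle_bh(p))
  pna <- c(0.01, NA, 0.5)
  q <- adjust_bh(pna)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(pna[c(1, 3)]))
})

test_that("fit_ebayes agrees with the limma oracle on complete data", {
  skip_if_not_installed("limma")
  pm <- sim_pmat(n = 200, seed = 11)
  ctr <- contrast("A", "B")
  res <- fit_ebayes(pm, ctr)
  design <- cbind(1, pm$groups == "B")
  fit <- limma::eBayes(limma::lmFit(pm$values, design))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 1e-4)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$pvalue, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("exactly equal per-protein variances give a degenerate prior", {
  set.seed(21)
  n <- 100; v <- 0.09
  x <- matrix(rnorm(n * 8), n, 8)
  # rescale each protein's residuals so the pooled variance is exactly v
  for (i in seq_len(n)) {
    xa <- x[i, 1:4]; xb <- x[i, 5:8]
    r <- c(xa - mean(xa), xb - mean(xb))
    s <- sqrt(sum(r^2) / 6)
    x[i, ] <- c(mean(xa) + (xa - mean(xa)) * sqrt(v) / s,
                mean(xb) + (xb - mean(xb)) * sqrt(v) / s)
  }
  pm <- make_pmat(x, rep(c("A", "B"), each = 4))
  res <- fit_ebayes(pm, contrast("A", "B"))
  prior <- attr(res, "prior")
  expect_false(is.finite(prior$d0))            # no spread: infinite prior df
  expect_equal(unique(round(prior$s0sq, 10)), v, tolerance = 1e-9)
  # posterior variance is v everywhere: ordinary t with common variance
  t_plain <- (rowMeans(x[, 5:8]) - rowMeans(x[, 1:4])) / sqrt(v * (1/4 + 1/4))
  expect_equal(res$t, unname(t_plain), tolerance = 1e-6)
  # and limma's estimator lands on the same prior for this input
  skip_if_not_installed("limma")
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, rep(0:1, each = 4))))
  expect_equal(unique(round(prior$s0sq, 10)), fit$s2.prior,
               tolerance = 1e-6)
})

test_that("moderate = FALSE reproduces the pooled two-sample t exactly", {
  pm <- sim_pmat(n = 50, seed = 31)
  res <- fit_ebayes(pm, contrast("A", "B"), moderate = FALSE)
  i <- 7
  tt <- t.test(pm$values[i, 5:8], pm$values[i, 1:4], var.equal = TRUE)
  expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$pvalue[i], tt$p.value, tolerance = 1e-10)
  expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))),
               tolerance = 1e-10)
})

test_that("posterior variance lies between observed and prior variance", {
  pm <- sim_pmat(n = 150, seed = 41, sd = 0.5)
  res <- fit_ebayes(pm, contrast("A", "B"))
  prior <- attr(res, "prior")
  st <- lfqpipe:::two_group_stats(pm, contrast("A", "B"))
  post <- res$se^2 / (1 / st$na + 1 / st$nb)
  lo <- pmin(st$s2, prior$s0sq)
  hi <- pmax(st$s2, prior$s0sq)
  ok <- !is.na(post)
  expect_true(all(post[ok] >= lo[ok] - 1e-12 & post[ok] <= hi[ok] + 1e-12))
})

test_that("deqms trend tracks a peptide-count variance law", {
  set.seed(51)
  n <- 600
  k <- sample(1:10, n, replace = TRUE)
  true_var <- 0.5 / k
  x <- matrix(rnorm(n * 10, 20, sqrt(rep(true_var, 10))), n, 10)
  pm <- make_pmat(x, rep(c("A", "B"), each = 5), n_peptides = k)
  res <- fit_deqms(pm, contrast("A", "B"))
  prior <- attr(res, "prior")
  expect_true(prior$trend)
  trend_by_k <- tapply(prior$s0sq, k, mean)
  expect_true(all(diff(trend_by_k) < 0))   # monotone decreasing in k
  # per-protein trend beats the constant prior in MSE against truth
  res_const <- fit_ebayes(pm, contrast("A", "B"))
  mse_trend <- mean((prior$s0sq - true_var)^2)
  mse_const <- mean((attr(res_const, "prior")$s0sq - true_var)^2)
  expect_lt(mse_trend, mse_const)
})

test_that("deqms with constant peptide counts falls back to ebayes", {
  pm <- sim_pmat(n = 80, seed = 61, n_peptides = rep(3L, 80))
  expect_warning(res <- fit_deqms(pm, contrast("A", "B")), "falling back")
  ref <- fit_ebayes(pm, contrast("A", "B"))
  expect_equal(res$pvalue, ref$pvalue)
  expect_equal(res$algorithm, rep("deqms", 80))
})

test_that("swapping contrast groups negates effects, keeps p-values", {
  pm <- sim_pmat(n = 120, seed = 71, delta = 0.3)
  r1 <- fit_ebayes(pm, contrast("A", "B"))
  r2 <- fit_ebayes(pm, contrast("B", "A"))
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$pvalue, r2$pvalue)
})

test_that("proteins with too few observations get reason codes", {
  x <- rand_matrix(5, 6, seed = 81)
  x[1, 1:2] <- NA   # only 1 value left in group A
  pm <- make_pmat(x, rep(c("A", "B"), each = 3))
  pm$values[1, 1:2] <- NA
  res <- fit_ebayes(pm, contrast("A", "B"))
  expect_true(is.na(res$pvalue[1]))
  expect_match(res$reason[1], "fewer than 2")
  expect_true(all(!is.na(res$pvalue[-1])))
})

test_that("permutation threshold matches exhaustive enumeration at 4v4", {
  pm <- sim_pmat(n = 60, seed = 91)
  ctr <- contrast("A", "B")
  expect_warning(
    thr <- estimate_fc_threshold(pm, ctr, n_permutations = 1000),
    "distinct permutations")
  # independent exhaustive enumeration
  combos <- combn(8, 4, simplify = FALSE)
  null_fc <- unlist(lapply(combos, function(ia) {
    abs(rowMeans(pm$values[, -ia, drop = FALSE]) -
          rowMeans(pm$values[, ia, drop = FALSE]))
  }))
  expect_equal(thr, unname(quantile(null_fc, 0.95)), tolerance = 1e-12)
})

test_that("permutation threshold shrinks with vanishing variance and is seeded", {
  pm_small <- sim_pmat(n = 40, nA = 5, nB = 5, sd = 1e-4, seed = 93)
  pm_small$values <- 20 + (pm_small$values - 20) * 1e-3
  expect_warning(thr0 <- estimate_fc_threshold(pm_small, contrast("A", "B"),
                                               n_permutations = 300))
  expect_lt(thr0, 0.01)
  pm <- sim_pmat(n = 40, nA = 8, nB = 8, seed = 94)
  t1 <- estimate_fc_threshold(pm, contrast("A", "B"),
                              n_permutations = 200, seed = 5)
  t2 <- estimate_fc_threshold(pm, contrast("A", "B"),
                              n_permutations = 200, seed = 5)
  expect_identical(t1, t2)
  expect_error(estimate_fc_threshold(sim_pmat(n = 10, nA = 2, nB = 2),
                                     contrast("A", "B")), "at least 3")
})

test_that("run_dea orchestrates filtering, normalization, rollup and DEA", {
  sim <- simulate_dataset(sim_config(n_proteins = 120, seed = 3,
                                     frac_regulated = 0.1, fc = 2))
  mat <- build_matrix(sim$table, sim$metadata)
  cfg <- dea_config(filter = filter_params(min_detect = 4,
                                           by_contrast = TRUE),
                    normalization = c("median", "modebetween_protein"),
                    algorithms = c("ebayes", "deqms"),
                    alpha = 0.05, seed = 2)
  res <- run_dea(mat, contrast("A", "B"), cfg)
  expect_setequal(unique(res$algorithm), c("ebayes", "deqms"))
  counts <- table(res$protein_id)
  expect_true(all(counts == 2))   # once per algorithm
  # signif recount
  scored <- res[!is.na(res$qvalue), ]
  expect_equal(scored$signif, scored$qvalue <= 0.05)
  expect_error(dea_config(algorithms = "msqrob"), "registered")
})

test_that("excluded samples never influence the results", {
  sim <- simulate_dataset(sim_config(n_proteins = 80, seed = 5))
  meta2 <- sim$metadata
  extra <- sim$table[sim$table$sample_id == "s01", ]
  extra$sample_id <- "s99"
  extra$intensity <- extra$intensity * 7    # wild outlier sample
  tab2 <- rbind(sim$table, extra)
  meta2 <- rbind(meta2, data.frame(sample_id = "s99", group = "B",
                                   exclude = TRUE))
  cfg <- dea_config(normalization = "median", algorithms = "ebayes",
                    alpha = 0.05)
  r_with <- run_dea(build_matrix(tab2, meta2), contrast("A", "B"), cfg)
  r_without <- run_dea(build_matrix(sim$table, sim$metadata),
                       contrast("A", "B"), cfg)
  expect_equal(r_with$log2fc, r_without$log2fc)
  expect_equal(r_with$pvalue, r_without$pvalue)
})

test_that("permutation-based significance gating is applied and recountable", {
  sim <- simulate_dataset(sim_config(n_proteins = 150, seed = 7,
                                     frac_regulated = 0.2, fc = 1.8))
  mat <- build_matrix(sim$table, sim$metadata)
  cfg <- dea_config(normalization = "median", algorithms = "ebayes",
                    alpha = 0.05, fc_threshold = "permute",
                    n_permutations = 100, seed = 11)
  res <- run_dea(mat, contrast("A", "B"), cfg)
  thr <- attr(res, "fc_thresholds")[["B_vs_A"]]
  expect_gt(thr, 0)
  scored <- res[!is.na(res$qvalue), ]
  expect_equal(scored$signif,
               scored$qvalue <= 0.05 & abs(scored$log2fc) >= thr)
})

test_that("DEA plugins join the registry and run inside run_dea", {
  register_dea("naive_t", function(pepmat, pmat, ctr, alpha, fc_threshold)
    fit_ebayes(pmat, ctr, alpha, fc_threshold, moderate = FALSE))
  sim <- simulate_dataset(sim_config(n_proteins = 60, seed = 9))
  mat <- build_matrix(sim$table, sim$metadata)
  cfg <- dea_config(normalization = "median",
                    algorithms = c("ebayes", "naive_t"), alpha = 0.05)
  res <- run_dea(mat, contrast("A", "B"), cfg)
  expect_true("naive_t" %in% res$algorithm)
})
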