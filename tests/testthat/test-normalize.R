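test_that("estimate_mode handles degenerate and symmetric inputs", {
  expect_equal(estimate_mode(rep(1.7, 50)), 1.7)
  set.seed(1)
  half <- abs(rnorm(500))
  a <- c(-half, half)            # exactly symmetric, peaked at zero
  expect_lt(abs(estimate_mode(a)), 0.05)
  expect_warning(md <- estimate_mode(c(1, 2, 30)), "median")
  expect_equal(md, 2)
})

test_that("estimate_mode matches a fine-grid KDE oracle on a 90:10 mixture", {
  set.seed(99)
  x <- c(rnorm(9000, 0, 0.1), rnorm(1000, 2, 0.1))
  m <- estimate_mode(x)
  expect_lt(abs(m), 0.02)                      # mode sits at the majority
  expect_lt(abs(m - oracle_mode(x)), 0.01)     # grid-resolution agreement
})

test_that("vw removes exact per-column offsets within a group", {
  base <- rand_matrix(100, 1, seed = 2)[, 1]
  shifts <- c(0, 0.5, -1.2, 2)
  x <- outer(base, rep(1, 4)) + outer(rep(1, 100), shifts)
  dimnames(x) <- list(sprintf("p%03d", 1:100), sprintf("s%d", 1:4))
  o <- vw_offsets(x, groups = rep("G", 4))
  norm <- sweep(x, 2, o$per_sample_offset, `+`)
  expect_lt(max(apply(norm, 1, var)), 1e-12)   # rows constant
  expect_true(o$converged)
})

test_that("vw gives zero offsets to singleton groups", {
  x <- rand_matrix(50, 3, seed = 3)
  o <- vw_offsets(x, groups = c("A", "B", "C"))
  expect_equal(unname(o$per_sample_offset), c(0, 0, 0))
})

test_that("vw reduces median within-group row variance, near a grid oracle", {
  x <- rand_matrix(200, 3, seed = 4, sd = 0.5)
  x <- sweep(x, 2, c(0, 0.4, -0.3), `+`)
  o <- vw_offsets(x, groups = rep("G", 3))
  med_var <- function(off) median(apply(sweep(x, 2, off, `+`), 1, var))
  before <- med_var(c(0, 0, 0))
  after <- med_var(o$per_sample_offset)
  expect_lt(after, before)
  # grid search over zero-anchored offsets on a 50-row subset; the
  # coordinate-descent scheme targets the same objective but is not an
  # exact global minimizer, so allow a 25% slack on the optimum
  sub <- x[1:50, ]
  mv_sub <- function(off) median(apply(sweep(sub, 2, off, `+`), 1, var))
  grid <- seq(-0.6, 0.6, by = 0.02)
  best <- Inf
  for (o2 in grid) for (o3 in grid) {
    v <- mv_sub(c(0, o2, o3))
    if (v < best) best <- v
  }
  o_sub <- vw_offsets(sub, groups = rep("G", 3))$per_sample_offset
  expect_lt(mv_sub(o_sub - o_sub[1]), mv_sub(c(0, 0, 0)))
  expect_lte(mv_sub(o_sub - o_sub[1]), best * 1.25 + 1e-6)
})

test_that("mw cancels an exact shift between two samples", {
  base <- rand_matrix(300, 1, seed = 6)[, 1]
  x <- cbind(s1 = base, s2 = base + 0.8)
  rownames(x) <- sprintf("p%03d", 1:300)
  o <- mw_offsets(x, groups = c("G", "G"))
  expect_equal(unname(diff(o$per_sample_offset)), -0.8, tolerance = 0.02)
  norm <- sweep(x, 2, o$per_sample_offset, `+`)
  expect_lt(abs(estimate_mode(norm[, 2] - norm[, 1])), 0.02)
  # identical columns: zero offsets
  xx <- cbind(s1 = base, s2 = base)
  o0 <- mw_offsets(xx, groups = c("G", "G"))
  expect_equal(max(abs(o0$per_sample_offset)), 0, tolerance = 0.02)
})

test_that("mw ignores an asymmetric regulated minority", {
  set.seed(61)
  base <- rnorm(2000, 20, 2)
  s2 <- base + 0.5                      # true loading shift
  idx <- sample(2000, 200)
  s2[idx] <- s2[idx] + 2                # 10% of rows regulated up
  x <- cbind(s1 = base + rnorm(2000, 0, 0.1),
             s2 = s2 + rnorm(2000, 0, 0.1))
  rownames(x) <- sprintf("p%04d", 1:2000)
  o <- mw_offsets(x, groups = c("G", "G"))
  norm <- sweep(x, 2, o$per_sample_offset, `+`)
  # oracle KDE recount of the residual pairwise mode
  expect_lt(abs(oracle_mode(norm[, 2] - norm[, 1])), 0.02)
})

test_that("mb two-group closed form cancels an injected group shift", {
  set.seed(71)
  base <- rnorm(500, 20, 2)
  x <- cbind(a1 = base + rnorm(500, 0, 0.05),
             a2 = base + rnorm(500, 0, 0.05),
             b1 = base + 0.7 + rnorm(500, 0, 0.05),
             b2 = base + 0.7 + rnorm(500, 0, 0.05))
  rownames(x) <- sprintf("p%03d", 1:500)
  groups <- c("A", "A", "B", "B")
  o <- mb_offsets(x, groups = groups)
  delta <- o$per_sample_offset["b1"] - o$per_sample_offset["a1"]
  expect_equal(unname(delta), -0.7, tolerance = 0.02)
  norm <- sweep(x, 2, o$per_sample_offset, `+`)
  gm <- rowMeans(norm[, 3:4]) - rowMeans(norm[, 1:2])
  expect_lt(abs(estimate_mode(gm)), 0.02)
})

test_that("solver reproduces consistent systems and the 2-group closed form", {
  m2 <- matrix(c(0, -0.6, 0.6, 0), 2, 2,   # m[A,B] = +0.6
               dimnames = list(c("A", "B"), c("A", "B")))
  sol2 <- solve_offsets_from_pairwise_modes(
    structure(list(groups = c("A", "B"), m = m2),
              class = "pairwise_mode_matrix"))
  expect_equal(unname(sol2$offsets), c(-0.3, 0.3), tolerance = 1e-8)
  m3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  m3["A", "B"] <- 1; m3["B", "A"] <- -1
  m3["B", "C"] <- 1; m3["C", "B"] <- -1
  m3["A", "C"] <- 2; m3["C", "A"] <- -2
  sol3 <- solve_offsets_from_pairwise_modes(
    structure(list(groups = LETTERS[1:3], m = m3),
              class = "pairwise_mode_matrix"))
  expect_equal(unname(sol3$offsets), c(-1, 0, 1), tolerance = 1e-6)
  expect_lt(sol3$objective, 1e-8)
})

test_that("solver beats a 0.005-resolution grid on inconsistent 3-group modes", {
  m3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  m3["A", "B"] <- 0.9;  m3["B", "A"] <- -0.9
  m3["B", "C"] <- 0.35; m3["C", "B"] <- -0.35
  m3["A", "C"] <- 1.6;  m3["C", "A"] <- -1.6
  sol <- solve_offsets_from_pairwise_modes(
    structure(list(groups = LETTERS[1:3], m = m3),
              class = "pairwise_mode_matrix"))
  grid <- seq(-1.8, 1.8, by = 0.005)
  best <- Inf
  for (ob in grid) for (oc in grid) {
    v <- mb_objective(m3, c(-(ob + oc), ob, oc) + (ob + oc) / 3 * 0)
    if (v < best) best <- v
  }
  expect_lte(sol$objective, best + 1e-3)
})

test_that("solver rejects disconnected pair graphs", {
  m4 <- matrix(NA_real_, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(m4) <- 0
  m4["A", "B"] <- 0.2; m4["B", "A"] <- -0.2
  m4["C", "D"] <- 0.1; m4["D", "C"] <- -0.1
  expect_error(solve_offsets_from_pairwise_modes(
    structure(list(groups = LETTERS[1:4], m = m4),
              class = "pairwise_mode_matrix")), "disconnected")
})

test_that("normalization chains behave: median baseline, MB idempotence", {
  m <- make_abmat(sweep(rand_matrix(120, 6, seed = 81, miss = 0.1), 2,
                        c(0, 1, -1, 0.5, 2, -0.5), `+`),
                  rep(c("A", "B"), each = 3))
  out <- normalize_matrix(m, "median")
  cm <- apply(out$matrix$values, 2, median, na.rm = TRUE)
  expect_lt(diff(range(cm)), 1e-9)
  # vwmb followed by another MB changes (almost) nothing
  o1 <- normalize_matrix(m, "vwmb")
  o2 <- normalize_matrix(m, c("vwmb", "modebetween"))
  expect_equal(o1$matrix$values, o2$matrix$values, tolerance = 0.05)
  expect_lt(max(abs(o2$offsets$modebetween$per_sample_offset)), 0.05)
  expect_error(normalize_matrix(m, "vsn"), "registered")
})

test_that("every method is additive per column and preserves missingness", {
  m <- make_abmat(rand_matrix(150, 6, seed = 91, miss = 0.15),
                  rep(c("A", "B"), each = 3))
  for (chain in list("median", "var_overall", "vwmb", "mwmb",
                     "modebetween", "modebetween_protein")) {
    out <- normalize_matrix(m, chain)
    expect_identical(is.na(out$matrix$values), is.na(m$values))
    diffmat <- out$matrix$values - m$values
    col_dev <- apply(diffmat, 2, function(v)
      diff(range(v[is.finite(v)])))
    expect_lt(max(col_dev), 1e-9)
  }
})

test_that("group-constant offsets leave within-group foldchanges invariant", {
  m <- make_abmat(rand_matrix(80, 6, seed = 95, miss = 0.1),
                  rep(c("A", "B"), each = 3))
  o <- mb_offsets(m$values, groups = m$groups, min_shared = 5)
  norm <- sweep(m$values, 2, o$per_sample_offset, `+`)
  expect_equal(norm[, 1] - norm[, 2], m$values[, 1] - m$values[, 2])
  # and a second MB pass finds nothing left to do
  o2 <- mb_offsets(norm, groups = m$groups, min_shared = 5)
  expect_lt(max(abs(o2$per_sample_offset)), 0.03)
})

test_that("MBprot re-centers what peptide-level MB cannot", {
  # one regulated protein with 50 peptides vs 99 unregulated 1-peptide
  # proteins: the peptide foldchange distribution is dominated by the
  # regulated protein, the protein-level one is not
  set.seed(101)
  n_bg <- 99
  # background proteins have heterogeneous replicate noise (real data);
  # the regulated protein's 50 peptides are tightly reproducible, so the
  # peptide foldchange MODE sits on the regulated block
  bg_sd <- runif(n_bg, 0.3, 1.2)
  bg <- matrix(rnorm(n_bg * 6, 20, rep(bg_sd, 6)), n_bg, 6)
  reg <- matrix(rnorm(50 * 6, 18, 0.05), 50, 6)
  reg[, 4:6] <- reg[, 4:6] + 1.5
  x <- rbind(bg, reg)
  rownames(x) <- sprintf("p%03d", 1:(n_bg + 50))
  colnames(x) <- sprintf("s%d", 1:6)
  prots <- setNames(c(sprintf("BG%02d", 1:n_bg), rep("REG", 50)),
                    rownames(x))
  m <- make_abmat(x, rep(c("A", "B"), each = 3), proteins = prots)
  # peptide-level MB is pulled toward the 50-peptide regulated block
  pep_mb <- normalize_matrix(m, "modebetween")
  prot_pep <- rollup(pep_mb$matrix, "maxlfq")
  fc_pep <- rowMeans(prot_pep$values[, 4:6]) - rowMeans(prot_pep$values[, 1:3])
  bg_ids <- sprintf("BG%02d", 1:n_bg)
  mis <- abs(estimate_mode(fc_pep[bg_ids]))
  expect_gt(mis, 0.2)
  # protein-level MB recovers the background center
  prot_mb <- normalize_matrix(m, "modebetween_protein")
  prot_prot <- rollup(prot_mb$matrix, "maxlfq")
  fc_prot <- rowMeans(prot_prot$values[, 4:6]) -
    rowMeans(prot_prot$values[, 1:3])
  expect_lt(abs(estimate_mode(fc_prot[bg_ids])), 0.05)
})

test_that("var_overall treats the dataset as one group", {
  x <- sweep(rand_matrix(100, 4, seed = 105, sd = 0.1), 2,
             c(0, 1, 2, 3), `+`)
  m <- make_abmat(x, c("A", "A", "B", "B"))
  out <- normalize_matrix(m, "var_overall")
  # offsets cancel the injected constants irrespective of group labels,
  # up to one common additive constant
  o <- out$offsets$var_overall$per_sample_offset
  expect_lt(diff(range(o + c(0, 1, 2, 3))), 0.05)
})

test_that("normalization plugins can be registered and used", {
  register_normalization("testshift", function(matrix, groups = NULL, ...) {
    x <- if (inherits(matrix, "abundance_matrix")) matrix$values else matrix
    setNames(rep(1, ncol(x)), colnames(x))
  })
  m <- make_abmat(rand_matrix(10, 3, seed = 1), rep("A", 3))
  out <- normalize_matrix(m, "testshift")
  expect_equal(out$matrix$values, m$values + 1)
  expect_true("testshift" %in% normalization_methods())
})
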