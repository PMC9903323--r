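# Shared fixture builders and independent oracles. Oracles deliberately use
# a different computational route than the package code they check.

make_abmat <- function(values, groups, proteins = NULL, detected = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("pep%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(proteins))
    proteins <- stats::setNames(rownames(values), rownames(values))
  if (is.null(names(proteins))) names(proteins) <- rownames(values)
  if (is.null(detected)) detected <- !is.na(values)
  abundance_matrix(values, groups, proteins, detected = detected)
}

rand_matrix <- function(nr, nc, miss = 0, seed = 1, sd = 1, mean = 20) {
  set.seed(seed)
  x <- matrix(rnorm(nr * nc, mean, sd), nr, nc)
  if (miss > 0) x[runif(nr * nc) < miss] <- NA
  rownames(x) <- sprintf("pep%03d", seq_len(nr))
  colnames(x) <- sprintf("s%02d", seq_len(nc))
  x
}

write_generic_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# fine-grid Gaussian-KDE argmax, independent of stats::density internals
oracle_mode <- function(x, n_grid = 20001) {
  x <- x[is.finite(x)]
  bw <- stats::bw.nrd0(x)
  grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(g) sum(dnorm((g - x) / bw)), numeric(1))
  grid[which.max(dens)]
}

# brute-force BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  q
}

# exhaustive-threshold trapezoid pAUC; every unique score is a cutoff
oracle_pauc <- function(scores, labels, fmax = 0.05) {
  thr <- sort(unique(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  fpr <- c(0, vapply(thr, function(t) sum(scores <= t & !labels) / n_neg,
                     numeric(1)))
  tpr <- c(0, vapply(thr, function(t) sum(scores <= t & labels) / n_pos,
                     numeric(1)))
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]; y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= fmax) break
    if (x1 > fmax) {
      y1 <- y0 + (y1 - y0) * (fmax - x0) / (x1 - x0)
      x1 <- fmax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

# dense normal-equations MaxLFQ oracle: assemble the full pairwise system
# with explicit loops, solve with a pseudoinverse, re-anchor on the mean
oracle_maxlfq <- function(sub) {
  n <- ncol(sub)
  rows <- list(); rhs <- c()
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      shared <- which(is.finite(sub[, j]) & is.finite(sub[, k]))
      if (!length(shared)) next
      r <- median(sub[shared, k] - sub[shared, j])
      v <- numeric(n); v[j] <- -1; v[k] <- 1
      rows[[length(rows) + 1]] <- v
      rhs <- c(rhs, r)
    }
  }
  if (!length(rows)) return(colMeans(sub, na.rm = TRUE))
  A <- do.call(rbind, rows)
  in_pair <- colSums(abs(A)) > 0
  p <- rep(NA_real_, n)
  Ai <- A[, in_pair, drop = FALSE]
  sol <- MASS_ginv(crossprod(Ai)) %*% crossprod(Ai, rhs)
  anchor <- mean(sub[, in_pair], na.rm = TRUE)
  p[in_pair] <- sol - mean(sol) + anchor
  p
}

# minimal Moore-Penrose pseudoinverse (avoids a MASS dependency)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# L1 objective of the between-group mode matching problem
mb_objective <- function(m, o) {
  tot <- 0
  G <- length(o)
  for (g in seq_len(G - 1))
    for (h in (g + 1):G)
      if (is.finite(m[g, h])) tot <- tot + abs(m[g, h] - (o[h] - o[g]))
  tot
}
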