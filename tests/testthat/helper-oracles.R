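# Independent oracles used across the test files. Each one takes the
# slow-but-transparent route (dense matrices, generic optimizers, full
# enumeration) so agreement with the package is a genuine cross-check.

# Dense-matrix REML oracle for the crossed random-intercept model:
# maximizes the restricted likelihood over all three log-variances with a
# generic optimizer and solves for BLUPs directly from V.
oracle_crossed_reml <- function(y, X, f1, f2) {
  f1 <- factor(f1)
  f2 <- factor(f2)
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  Z1 <- outer(f1, levels(f1), "==") * 1
  Z2 <- outer(f2, levels(f2), "==") * 1
  neg2_relik <- function(ls) {
    s2 <- exp(ls)
    V <- s2[3] * diag(n) + s2[1] * tcrossprod(Z1) + s2[2] * tcrossprod(Z2)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    as.numeric(
      determinant(V)$modulus + determinant(XtViX)$modulus +
        t(r) %*% Vi %*% r + (n - p) * log(2 * pi)
    )
  }
  o <- optim(c(-1, -1, -1), neg2_relik, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 3000))
  o <- optim(o$par, neg2_relik, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 200))
  s2 <- exp(o$par)
  V <- s2[3] * diag(n) + s2[1] * tcrossprod(Z1) + s2[2] * tcrossprod(Z2)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u1 <- s2[1] * t(Z1) %*% Vi %*% r
  u2 <- s2[2] * t(Z2) %*% Vi %*% r
  list(loglik = -o$value / 2, fixef = as.numeric(beta),
       u1 = stats::setNames(as.numeric(u1), levels(f1)),
       u2 = stats::setNames(as.numeric(u2), levels(f2)),
       sigma2 = s2)
}

# Grid-search oracle for the restricted likelihood of the k-study
# random-effects meta-analysis model.
oracle_meta_grid <- function(yi, vi, grid_max = NULL, grid_n = 40001L) {
  nll <- function(t2) {
    w <- 1 / (vi + t2)
    mu <- sum(w * yi) / sum(w)
    sum(log(vi + t2)) + log(sum(w)) + sum(w * (yi - mu)^2)
  }
  if (is.null(grid_max)) grid_max <- 10 * max(max(vi), stats::var(yi))
  grid <- seq(0, grid_max, length.out = grid_n)
  vals <- vapply(grid, nll, numeric(1))
  best <- which.min(vals)
  # refine around the coarse minimum
  lo <- grid[max(1L, best - 2L)]
  hi <- grid[min(grid_n, best + 2L)]
  grid2 <- seq(lo, hi, length.out = 4001L)
  vals2 <- vapply(grid2, nll, numeric(1))
  t2 <- grid2[which.min(vals2)]
  w <- 1 / (vi + t2)
  list(tau2 = t2, estimate = sum(w * yi) / sum(w), se = 1 / sqrt(sum(w)))
}

# Stepwise-enumeration oracle for the KS enrichment statistic: walks the
# ranked list position by position, tracking the running tag ECDF.
oracle_ks <- function(tags, n) {
  t <- length(tags)
  best_a <- -Inf
  best_b <- -Inf
  for (j in seq_len(t)) {
    count_before <- sum(tags < tags[j])
    best_a <- max(best_a, (count_before + 1) / t - tags[j] / n)
    best_b <- max(best_b, tags[j] / n - count_before / t)
  }
  if (best_a > best_b) best_a else -best_b
}

oracle_score <- function(pos_up, pos_down, n, variant) {
  ku <- oracle_ks(sort(pos_up), n)
  kd <- oracle_ks(sort(pos_down), n)
  if (variant == "new") return(ku - kd)
  if (sign(ku) == sign(kd)) 0 else ku - kd
}

# Full 2^n enumeration of the signed-rank statistic distribution.
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  lower <- mean(vs <= v_obs + 1e-9)
  upper <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Direct Benjamini-Hochberg step-up implementation.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# Classical two-sample linear-model estimate and standard error.
oracle_two_group <- function(y, grp) {
  n1 <- sum(grp == 0)
  n2 <- sum(grp == 1)
  est <- mean(y[grp == 1]) - mean(y[grp == 0])
  sp2 <- (sum((y[grp == 0] - mean(y[grp == 0]))^2) +
            sum((y[grp == 1] - mean(y[grp == 1]))^2)) / (n1 + n2 - 2)
  list(est = est, se = sqrt(sp2 * (1 / n1 + 1 / n2)))
}

# Rank-then-Pearson Spearman oracle with t-approximation p-value.
oracle_spearman <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}
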