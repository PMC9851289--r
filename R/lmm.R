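#' Crossed random-intercept linear mixed models by profiled REML
#'
#' Fits \code{y = X beta + Z1 u1 + Z2 u2 + e} where \code{u1}, \code{u2} are
#' independent random intercepts for two crossed grouping factors and
#' \code{e} is i.i.d. Gaussian noise. The restricted likelihood is profiled
#' over the residual variance and maximized over the two variance ratios
#' \code{lambda_k = sigma_k^2 / sigma_e^2} on the log scale, so the
#' non-negativity constraint holds by parameterization and boundary fits
#' (a variance component estimated as zero) are reached smoothly.
#'
#' All quantities are computed from sufficient statistics
#' (\code{X'X}, \code{X'Z}, \code{Z'Z}, \code{X'y}, \code{Z'y}, \code{y'y}),
#' which makes refitting many response vectors over one design cheap
#' (see \code{\link{lmm_crossed_multi}}).
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param f1,f2 grouping factors (coerced with \code{factor()}), each with
#'   at least 2 levels unless the factor is confounded with the intercept.
#' @param reltol relative convergence tolerance on the REML criterion.
#' @param maxit maximum optimizer iterations.
#' @return an object of class \code{tsr_lmm}: list with elements
#'   \code{fixef}, \code{se_fixef}, \code{vcov_fixef}, \code{ranef}
#'   (list of the two named BLUP vectors), \code{varcomp} (named vector
#'   \code{sigma2_f1}, \code{sigma2_f2}, \code{sigma2_resid}),
#'   \code{loglik_restricted}, \code{converged}, \code{n}, \code{p}.
#' @export
lmm_crossed <- function(y, X, f1, f2, reltol = 1e-12, maxit = 500L) {
  ss <- lmm_suffstats(X, f1, f2)
  sy <- lmm_response_stats(ss, X, y)
  fit <- lmm_fit_from_stats(ss, sy$Xty, sy$Zty, sy$yty, reltol, maxit)
  lmm_as_fit_object(ss, fit)
}

#' Sufficient statistics for a crossed two-factor mixed design
#'
#' @inheritParams lmm_crossed
#' @return list of cross-products and factor metadata, reusable across
#'   many response vectors sharing the design.
#' @export
lmm_suffstats <- function(X, f1, f2) {
  X <- as.matrix(X)
  f1 <- droplevels(factor(f1))
  f2 <- droplevels(factor(f2))
  n <- nrow(X)
  if (length(f1) != n || length(f2) != n)
    stop("grouping factors must have one entry per row of X")
  q1 <- nlevels(f1)
  q2 <- nlevels(f2)
  N <- unclass(table(f1, f2))
  ZtZ <- rbind(
    cbind(diag(as.numeric(table(f1)), q1), N),
    cbind(t(N), diag(as.numeric(table(f2)), q2))
  )
  XtZ <- cbind(t(rowsum(X, f1)), t(rowsum(X, f2)))
  list(
    XtX = crossprod(X), XtZ = XtZ, ZtZ = ZtZ,
    n = n, p = ncol(X), q1 = q1, q2 = q2,
    levels1 = levels(f1), levels2 = levels(f2),
    f1 = f1, f2 = f2
  )
}

lmm_response_stats <- function(ss, X, y) {
  y <- as.numeric(y)
  list(
    Xty = as.numeric(crossprod(X, y)),
    Zty = c(rowsum(cbind(y), ss$f1)[, 1L], rowsum(cbind(y), ss$f2)[, 1L]),
    yty = sum(y * y)
  )
}

# Profiled -2 * restricted log-likelihood and, on request, the full set of
# estimates at the given log variance ratios. Floor on the residual variance
# (1e-12) keeps degenerate zero-variance responses finite.
lmm_eval <- function(theta, ss, Xty, Zty, yty, details = FALSE) {
  theta <- pmin(pmax(theta, -30), 30)
  lam <- exp(theta)
  lamvec <- c(rep(lam[1L], ss$q1), rep(lam[2L], ss$q2))
  s <- sqrt(lamvec)
  q <- ss$q1 + ss$q2
  A <- diag(q) + (s %o% s) * ss$ZtZ
  R <- chol(A)
  logdetA <- 2 * sum(log(diag(R)))
  Ms <- ss$XtZ * rep(s, each = ss$p) # p x q
  sZty <- s * Zty
  AinvMt <- backsolve(R, forwardsolve(t(R), t(Ms)))
  Ainvz <- backsolve(R, forwardsolve(t(R), sZty))
  XtHX <- ss$XtX - Ms %*% AinvMt
  XtHX <- (XtHX + t(XtHX)) / 2
  XtHy <- Xty - as.numeric(Ms %*% Ainvz)
  ytHy <- yty - sum(sZty * Ainvz)
  Rx <- chol(XtHX)
  beta <- backsolve(Rx, forwardsolve(t(Rx), XtHy))
  rss <- max(ytHy - sum(beta * XtHy), 0)
  np <- ss$n - ss$p
  sigma2 <- max(rss / np, 1e-12)
  crit <- np * log(2 * pi * sigma2) + rss / sigma2 +
    logdetA + 2 * sum(log(diag(Rx)))
  if (!details) return(crit)
  Ztr <- Zty - as.numeric(crossprod(ss$XtZ, beta))
  u <- lamvec * (Ztr - as.numeric(ss$ZtZ %*% (s * backsolve(
    R, forwardsolve(t(R), s * Ztr)
  ))))
  vcov_beta <- sigma2 * chol2inv(Rx)
  list(
    crit = crit, beta = beta, vcov_beta = vcov_beta, u = u,
    sigma2 = sigma2, lam = lam, theta = theta
  )
}

lmm_fit_from_stats <- function(ss, Xty, Zty, yty, reltol = 1e-12,
                               maxit = 500L, polish = TRUE) {
  obj <- function(th) lmm_eval(th, ss, Xty, Zty, yty)
  o <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                    control = list(reltol = reltol, maxit = maxit))
  if (polish) {
    # quasi-Newton polish sharpens the optimum for oracle-level agreement
    o2 <- suppressWarnings(try(
      stats::optim(o$par, obj, method = "BFGS",
                   control = list(reltol = reltol, maxit = 100L)),
      silent = TRUE
    ))
    if (!inherits(o2, "try-error") && is.finite(o2$value) &&
        o2$value <= o$value) o <- o2
  }
  det <- lmm_eval(o$par, ss, Xty, Zty, yty, details = TRUE)
  det$converged <- is.finite(o$value)
  det
}

lmm_as_fit_object <- function(ss, fit) {
  lam <- fit$lam
  lam[fit$theta <= -29.9] <- 0 # snap boundary fits to an exact zero
  u1 <- fit$u[seq_len(ss$q1)]
  u2 <- fit$u[ss$q1 + seq_len(ss$q2)]
  names(u1) <- ss$levels1
  names(u2) <- ss$levels2
  structure(list(
    fixef = as.numeric(fit$beta),
    se_fixef = sqrt(diag(as.matrix(fit$vcov_beta))),
    vcov_fixef = fit$vcov_beta,
    ranef = list(f1 = u1, f2 = u2),
    varcomp = c(sigma2_f1 = lam[1L] * fit$sigma2,
                sigma2_f2 = lam[2L] * fit$sigma2,
                sigma2_resid = fit$sigma2),
    loglik_restricted = -fit$crit / 2,
    converged = fit$converged,
    n = ss$n, p = ss$p
  ), class = "tsr_lmm")
}

#' Fit one crossed mixed design to many response vectors
#'
#' Shares the design cross-products across responses; each column of
#' \code{Y} gets its own REML variance estimates, fixed effects and BLUPs.
#'
#' @param Y numeric matrix, one response per column.
#' @param polish run the quasi-Newton polish after Nelder-Mead (off by
#'   default here: the per-gene fits trade the last decimals of the
#'   optimum for speed).
#' @inheritParams lmm_crossed
#' @return list of \code{tsr_lmm} objects, one per column of \code{Y}.
#' @export
lmm_crossed_multi <- function(Y, X, f1, f2, reltol = 1e-10, maxit = 500L,
                              polish = FALSE) {
  Y <- as.matrix(Y)
  ss <- lmm_suffstats(X, f1, f2)
  XtY <- crossprod(X, Y)
  ZtY <- rbind(rowsum(Y, ss$f1), rowsum(Y, ss$f2))
  ytY <- colSums(Y * Y)
  out <- vector("list", ncol(Y))
  for (g in seq_len(ncol(Y))) {
    fit <- lmm_fit_from_stats(ss, XtY[, g], ZtY[, g], ytY[g], reltol,
                              maxit, polish)
    out[[g]] <- lmm_as_fit_object(ss, fit)
  }
  names(out) <- colnames(Y)
  out
}

#' @export
print.tsr_lmm <- function(x, ...) {
  cat("Crossed random-intercept model (REML)\n")
  cat(sprintf("  n = %d, p = %d, restricted logLik = %.4f\n",
              x$n, x$p, x$loglik_restricted))
  cat(sprintf("  variance components: %s = %.6g, %s = %.6g, resid = %.6g\n",
              "f1", x$varcomp[["sigma2_f1"]],
              "f2", x$varcomp[["sigma2_f2"]],
              x$varcomp[["sigma2_resid"]]))
  invisible(x)
}
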