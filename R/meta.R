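#' Random-effects inverse-variance meta-analysis (REML)
#'
#' Combines k estimates with known sampling variances under the standard
#' additive heterogeneity model \code{y_i ~ N(mu, v_i + tau2)}. \code{tau2}
#' maximizes the restricted likelihood on \code{[0, Inf)}; the zero
#' boundary is accepted silently (the usual behavior for k as small as 2).
#'
#' @param yi numeric vector of estimates.
#' @param vi sampling variances (same length, strictly positive).
#' @return list with \code{estimate}, \code{se}, \code{tau2}, \code{k}.
#' @export
meta_reml <- function(yi, vi) {
  if (length(yi) != length(vi)) stop("yi and vi must have equal length")
  if (any(!is.finite(vi) | vi <= 0)) stop("all sampling variances must be > 0")
  k <- length(yi)
  if (k == 0L) stop("no estimates to combine")
  if (k == 1L)
    return(list(estimate = yi[1L], se = sqrt(vi[1L]), tau2 = 0, k = 1L))
  if (k == 2L) {
    # closed form: the restricted likelihood reduces to log(s) + D^2/s
    # with s = v1 + v2 + 2 tau2, minimized at s = D^2
    tau2 <- max(0, ((yi[1L] - yi[2L])^2 - vi[1L] - vi[2L]) / 2)
    w <- 1 / (vi + tau2)
    return(list(estimate = sum(w * yi) / sum(w), se = 1 / sqrt(sum(w)),
                tau2 = tau2, k = 2L))
  }
  nll <- function(t2) {
    w <- 1 / (vi + t2)
    mu <- sum(w * yi) / sum(w)
    sum(log(vi + t2)) + log(sum(w)) + sum(w * (yi - mu)^2)
  }
  upper <- 10 * max(max(vi), stats::var(yi), 1e-8)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-12)
  tau2 <- if (nll(0) <= opt$objective + 1e-12) 0 else opt$minimum
  w <- 1 / (vi + tau2)
  list(estimate = sum(w * yi) / sum(w), se = 1 / sqrt(sum(w)),
       tau2 = tau2, k = k)
}

#' Combine 6 h and 24 h drug signatures by meta-analysis
#'
#' For every (drug, gene) present at both timepoints the two
#' log2-fold-change estimates are combined by random-effects REML
#' meta-analysis (\code{\link{meta_reml}}, k = 2); a (drug, gene) present
#' at a single timepoint passes through unchanged. The combined p-value is
#' the two-sided normal (Wald) p of estimate/se.
#'
#' @param sig signature data frame with columns \code{drug_id},
#'   \code{gene_id}, \code{timepoint} (values "6h"/"24h"), \code{log2fc},
#'   \code{se}, and optionally \code{corrected}.
#' @return data frame of combined entries (\code{timepoint = "combined"})
#'   with an extra \code{tau2} column.
#' @export
combine_signature_timepoints <- function(sig) {
  sig <- as.data.frame(sig)
  sig <- sig[sig$timepoint %in% c("6h", "24h"), , drop = FALSE]
  if (nrow(sig) == 0L) stop("no 6h/24h entries to combine")
  if (any(!is.finite(sig$se) | sig$se <= 0))
    stop("all standard errors must be > 0")
  corrected <- if ("corrected" %in% names(sig)) any(sig$corrected) else FALSE
  # vectorized over (drug, gene): pivot the two timepoints side by side
  # and apply the closed-form k = 2 REML combination
  s6 <- sig[sig$timepoint == "6h", ]
  s24 <- sig[sig$timepoint == "24h", ]
  key6 <- paste(s6$drug_id, s6$gene_id, sep = "\r")
  key24 <- paste(s24$drug_id, s24$gene_id, sep = "\r")
  if (anyDuplicated(key6) || anyDuplicated(key24))
    stop("duplicate (drug, gene) entries within a timepoint")
  keys <- union(key6, key24)
  i6 <- match(keys, key6)
  i24 <- match(keys, key24)
  y1 <- s6$log2fc[i6]
  v1 <- s6$se[i6]^2
  y2 <- s24$log2fc[i24]
  v2 <- s24$se[i24]^2
  both <- !is.na(i6) & !is.na(i24)
  tau2 <- est <- se2 <- numeric(length(keys))
  tau2[both] <- pmax(0, ((y1[both] - y2[both])^2 -
                           v1[both] - v2[both]) / 2)
  w1 <- 1 / (v1[both] + tau2[both])
  w2 <- 1 / (v2[both] + tau2[both])
  est[both] <- (w1 * y1[both] + w2 * y2[both]) / (w1 + w2)
  se2[both] <- 1 / (w1 + w2)
  only6 <- !is.na(i6) & is.na(i24)
  est[only6] <- y1[only6]
  se2[only6] <- v1[only6]
  only24 <- is.na(i6) & !is.na(i24)
  est[only24] <- y2[only24]
  se2[only24] <- v2[only24]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    drug_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    timepoint = "combined", log2fc = est, se = sqrt(se2),
    p = 2 * stats::pnorm(-abs(est / sqrt(se2))),
    corrected = corrected, tau2 = tau2, stringsAsFactors = FALSE
  )
  out[order(out$drug_id, out$gene_id), , drop = FALSE]
}

#' Meta-analysis mean tumor signature
#'
#' Per-gene random-effects REML meta-analysis of the tumor-versus-normal
#' log2 fold changes across tumor types. Genes observed in a single tumor
#' type pass through unchanged.
#'
#' @param stats tumor DE statistics with columns \code{tumor_type},
#'   \code{gene_id}, \code{log2fc}, \code{se}.
#' @return data frame \code{gene_id}, \code{log2fc}, \code{se},
#'   \code{tau2}, \code{k}.
#' @export
meta_tumor_signature <- function(stats) {
  stats <- as.data.frame(stats)
  idx <- split(seq_len(nrow(stats)), stats$gene_id)
  out <- lapply(names(idx), function(g) {
    rows <- stats[idx[[g]], ]
    m <- meta_reml(rows$log2fc, rows$se^2)
    data.frame(gene_id = g, log2fc = m$estimate, se = m$se,
               tau2 = m$tau2, k = m$k, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
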