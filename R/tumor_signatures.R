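#' Expression-level gene filter for count matrices
#'
#' Keeps genes whose mean over samples of \code{log2(count + 1)} is at
#' least \code{threshold} (default 6), restricting the analysis to
#' well-expressed genes.
#'
#' @param counts non-negative genes-by-samples count matrix.
#' @param threshold minimum mean log2(count + 1).
#' @return the filtered matrix.
#' @export
filter_genes <- function(counts, threshold = 6) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts[rowMeans(log2(counts + 1)) >= threshold, , drop = FALSE]
}

#' Upper-quartile normalization factors
#'
#' Per-sample scaling factor: the 75th percentile (linear-interpolation
#' quantile) of the sample's nonzero counts divided by its library size,
#' rescaled so the factors have geometric mean 1. Proportional library
#' scalings cancel out exactly.
#'
#' @param counts non-negative genes-by-samples count matrix; every sample
#'   needs at least one nonzero count.
#' @param p quantile used (default 0.75).
#' @return named numeric vector of factors, geometric mean 1.
#' @export
upperquartile_factors <- function(counts, p = 0.75) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    if (length(x) == 0L)
      stop("sample has all-zero counts: ",
           colnames(counts)[j] %||% as.character(j))
    stats::quantile(x, p, names = FALSE, type = 7) / lib[j]
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision-weighted tumor-versus-normal differential expression
#'
#' The mean-variance modeled (voom-style) pipeline: counts are converted
#' to log2 counts-per-million with a 0.5 count offset against the
#' normalized library sizes, a gene-wise two-group linear model supplies
#' residual standard deviations, a lowess trend (span 0.5) of sqrt(sd)
#' against mean log-count is inverted into observation-level
#' inverse-variance weights, the tumor-versus-normal contrast is
#' re-estimated by weighted least squares, residual variances are
#' moderated by empirical Bayes (moderated t with estimated prior df) and
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param counts filtered genes-by-samples count matrix.
#' @param factors per-sample normalization factors
#'   (\code{\link{upperquartile_factors}}).
#' @param tumor_indicator logical/0-1 vector, TRUE (1) for tumor samples.
#' @param span lowess span of the mean-variance trend.
#' @return data frame with columns \code{gene_id}, \code{log2fc},
#'   \code{se}, \code{t_stat}, \code{p}, \code{p_adj},
#'   \code{mean_logcpm}.
#' @export
precision_weighted_de <- function(counts, factors, tumor_indicator,
                                  span = 0.5) {
  tumor_indicator <- as.numeric(tumor_indicator)
  if (length(tumor_indicator) != ncol(counts))
    stop("tumor_indicator must have one entry per sample")
  if (sum(tumor_indicator == 1) < 2 || sum(tumor_indicator == 0) < 2)
    stop("need at least 2 samples in each arm")
  elib <- colSums(counts) * factors
  y <- t(log2(t(counts + 0.5) / (elib + 1) * 1e6))
  design <- cbind(Intercept = 1, tumor = tumor_indicator)
  n <- ncol(y)
  p <- 2L
  fit0 <- stats::lm.fit(design, t(y))
  res0 <- t(fit0$residuals)
  sigma0 <- sqrt(rowSums(res0^2) / (n - p))
  amean <- rowMeans(y)
  sx <- amean + mean(log2(elib + 1)) - log2(1e6)
  sy <- sqrt(sigma0)
  l <- stats::lowess(sx, sy, f = span)
  trend <- stats::approxfun(l, rule = 2, ties = list("ordered", mean))
  fitted_logcpm <- t(design %*% fit0$coefficients)
  fitted_count <- t(t(2^fitted_logcpm) * (elib + 1)) * 1e-6
  sqrt_sd <- trend(log2(fitted_count))
  sqrt_sd <- pmax(sqrt_sd, 1e-4) # guards degenerate zero-variance input
  w <- matrix(1 / sqrt_sd^4, nrow(y), ncol(y))
  # gene-wise weighted least squares for the two-group contrast
  sw <- w
  s1 <- rowSums(sw)
  sxw <- rowSums(sw * rep(tumor_indicator, each = nrow(y)))
  sxxw <- sxw # indicator is 0/1 so x^2 = x
  syw <- rowSums(sw * y)
  sxyw <- rowSums(sw * y * rep(tumor_indicator, each = nrow(y)))
  det <- s1 * sxxw - sxw^2
  beta1 <- (s1 * sxyw - sxw * syw) / det
  beta0 <- (syw - sxw * beta1) / s1
  fitted <- outer(beta0, rep(1, n)) + outer(beta1, tumor_indicator)
  rss <- rowSums(w * (y - fitted)^2)
  df_resid <- n - p
  s2 <- rss / df_resid
  stdev_unscaled <- sqrt(s1 / det)
  if (all(s2 < 1e-14)) {
    s2_post <- s2
    df_prior <- 0
  } else {
    sq <- limma::squeezeVar(s2, df_resid)
    s2_post <- sq$var.post
    df_prior <- sq$df.prior
  }
  df_total <- min(df_resid + df_prior, df_resid * nrow(y))
  t_stat <- beta1 / (stdev_unscaled * sqrt(s2_post))
  pval <- 2 * stats::pt(-abs(t_stat), df_total)
  data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2fc = beta1, se = stdev_unscaled * sqrt(s2_post), t_stat = t_stat,
    p = pval, p_adj = stats::p.adjust(pval, "BH"), mean_logcpm = amean,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Select a tumor signature's up/down gene sets
#'
#' Restricts the DE table to the landmark genes shared with the drug
#' perturbation panel, then selects genes by scenario: \code{topK}
#' scenarios take the K smallest p-values (ties broken by larger
#' |log2FC|, then gene id); \code{fc_adjp} takes genes with
#' |log2FC| > 1.5 and adjusted p < 0.001. Selected genes split into up-
#' and downregulated sets by the sign of the fold change.
#'
#' @param stats DE statistics for one tumor type
#'   (\code{\link{precision_weighted_de}} output, plus optionally a
#'   \code{tumor_type} column).
#' @param scenario one of \code{"top50"}, \code{"top100"},
#'   \code{"top150"}, \code{"fc_adjp"}.
#' @param landmark_genes character vector of genes measured in the drug
#'   perturbation data.
#' @param fc_cutoff,padj_cutoff thresholds of the \code{fc_adjp} rule.
#' @return list of class \code{tumor_signature}: \code{tumor_type},
#'   \code{scenario}, \code{up_genes}, \code{down_genes}, \code{empty}.
#' @export
select_signature <- function(stats, scenario, landmark_genes,
                             fc_cutoff = 1.5, padj_cutoff = 0.001) {
  scenario <- match.arg(scenario, c("top50", "top100", "top150", "fc_adjp"))
  stats <- as.data.frame(stats)
  stats <- stats[stats$gene_id %in% landmark_genes, , drop = FALSE]
  if (scenario == "fc_adjp") {
    sel <- stats[abs(stats$log2fc) > fc_cutoff &
                   stats$p_adj < padj_cutoff, , drop = FALSE]
    sel <- sel[order(sel$p, -abs(sel$log2fc), sel$gene_id), , drop = FALSE]
  } else {
    k <- as.integer(sub("top", "", scenario))
    ord <- order(stats$p, -abs(stats$log2fc), stats$gene_id)
    sel <- stats[ord[seq_len(min(k, nrow(stats)))], , drop = FALSE]
  }
  structure(list(
    tumor_type = if ("tumor_type" %in% names(stats) && nrow(stats) > 0)
      stats$tumor_type[1L] else NA_character_,
    scenario = scenario,
    up_genes = sel$gene_id[sel$log2fc > 0],
    down_genes = sel$gene_id[sel$log2fc < 0],
    empty = nrow(sel) == 0L
  ), class = "tumor_signature")
}

#' DE statistics and signatures for every tumor type
#'
#' @param counts genes-by-samples count matrix over all tumor types.
#' @param samples sample metadata (\code{sample_id}, \code{tumor_type},
#'   \code{arm}).
#' @param filter_threshold mean log2(count+1) filter threshold.
#' @return data frame of per-type DE statistics (filter and
#'   normalization applied within type).
#' @export
tumor_de_all_types <- function(counts, samples, filter_threshold = 6) {
  out <- list()
  for (tt in sort(unique(samples$tumor_type))) {
    ids <- samples$sample_id[samples$tumor_type == tt]
    sub <- counts[, ids, drop = FALSE]
    sub <- filter_genes(sub, filter_threshold)
    fac <- upperquartile_factors(sub)
    arm <- samples$arm[match(ids, samples$sample_id)]
    de <- precision_weighted_de(sub, fac, arm == "tumor")
    de$tumor_type <- tt
    out[[tt]] <- de
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
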