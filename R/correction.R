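#' Gene-level association between drug response and drug potency
#'
#' For every gene and timepoint, correlates the drug-signature log2 fold
#' changes with the drugs' mean normalized AUC across drugs (Spearman,
#' average ranks, two-sided t-approximation p), and stores the ordinary
#' least-squares fit of log2FC on log(mnAUC) used by the correction. A
#' negative rho marks a gene upregulated by potency-reducing drugs
#' (stress-response-like); a positive rho marks one downregulated
#' (replication-machinery-like).
#'
#' @param signatures drug-signature data frame (\code{drug_id},
#'   \code{gene_id}, \code{timepoint}, \code{log2fc}).
#' @param mnauc mnAUC table from \code{\link{compute_mnauc}}; only the
#'   \code{subset_label == "all"} rows are used.
#' @param min_drugs minimum shared drugs per gene (default 3).
#' @return data frame with columns \code{gene_id}, \code{timepoint},
#'   \code{spearman_rho}, \code{p}, \code{n_drugs}, \code{ols_intercept},
#'   \code{ols_slope}.
#' @export
gene_mnauc_correlation <- function(signatures, mnauc, min_drugs = 3L) {
  signatures <- as.data.frame(signatures)
  mn <- mnauc[mnauc$subset_label == "all", c("drug_id", "mnauc")]
  sig <- merge(signatures, mn, by = "drug_id")
  idx <- split(seq_len(nrow(sig)),
               list(gene = sig$gene_id, tp = sig$timepoint), drop = TRUE)
  out <- list()
  skipped <- 0L
  for (key in names(idx)) {
    rows <- sig[idx[[key]], ]
    x <- log(rows$mnauc)
    y <- rows$log2fc
    if (nrow(rows) < min_drugs || stats::sd(y) == 0 || stats::sd(x) == 0) {
      skipped <- skipped + 1L
      next
    }
    ct <- spearman_cor(y, rows$mnauc)
    fit <- stats::lm.fit(cbind(1, x), y)
    out[[key]] <- data.frame(
      gene_id = rows$gene_id[1L], timepoint = rows$timepoint[1L],
      spearman_rho = ct$rho, p = ct$p, n_drugs = nrow(rows),
      ols_intercept = fit$coefficients[1L],
      ols_slope = fit$coefficients[2L], stringsAsFactors = FALSE
    )
  }
  if (skipped > 0L)
    warning(sprintf(
      "%d gene/timepoint group(s) skipped (fewer than %d drugs or constant values)",
      skipped, min_drugs))
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$timepoint, res$gene_id), , drop = FALSE]
}

#' Remove the viability-driven component from drug signatures
#'
#' Per gene and per duration subset (6 h and 24 h separately), the log2
#' fold changes are regressed on log(mnAUC) by ordinary least squares
#' (intercept included) and replaced by the residuals: the part of the
#' differential expression not explained by the drug's anti-proliferative
#' potency. Standard errors are carried over unchanged so downstream
#' meta-analysis weighting is preserved. Genes whose regression is not
#' computable pass through uncorrected (flag stays FALSE).
#'
#' @inheritParams gene_mnauc_correlation
#' @return signature data frame (6h/24h rows) with corrected log2fc and
#'   \code{corrected = TRUE} where the regression was applied.
#' @export
correct_signatures <- function(signatures, mnauc, min_drugs = 3L) {
  sig <- as.data.frame(signatures)
  sig <- sig[sig$timepoint %in% c("6h", "24h"), , drop = FALSE]
  mn <- mnauc[mnauc$subset_label == "all", c("drug_id", "mnauc")]
  lmn <- log(mn$mnauc)[match(sig$drug_id, mn$drug_id)]
  sig$corrected <- FALSE
  idx <- split(seq_len(nrow(sig)),
               list(gene = sig$gene_id, tp = sig$timepoint), drop = TRUE)
  passed <- 0L
  for (key in names(idx)) {
    rows <- idx[[key]]
    x <- lmn[rows]
    y <- sig$log2fc[rows]
    usable <- is.finite(x)
    if (sum(usable) < min_drugs || stats::sd(x[usable]) == 0 ||
        stats::sd(y[usable]) == 0) {
      passed <- passed + 1L
      next
    }
    fit <- stats::lm.fit(cbind(1, x[usable]), y[usable])
    sig$log2fc[rows[usable]] <- fit$residuals
    # drugs without an mnAUC keep their centered-only value
    if (any(!usable))
      sig$log2fc[rows[!usable]] <- y[!usable] - mean(y[usable])
    sig$corrected[rows] <- TRUE
  }
  if (passed > 0L)
    message(sprintf(
      "%d gene/timepoint group(s) passed through uncorrected", passed))
  sig
}
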