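#' Filter perturbation experiments to the analyzable design
#'
#' Keeps drug experiments at 10 uM only, drops drugs tested in fewer than
#' \code{min_cell_lines} distinct cell lines (applied within each
#' duration subset separately), always retains DMSO controls, and splits
#' the data into independent 6 h and 24 h subsets.
#'
#' @param dataset a \code{perturbation_dataset}.
#' @param dose required drug concentration in uM (default 10).
#' @param min_cell_lines minimum distinct cell lines per drug (default 5).
#' @return named list with elements \code{"6h"} and \code{"24h"}; a
#'   subset with no remaining drug experiments is \code{NULL} (with a
#'   warning).
#' @export
filter_experiments <- function(dataset, dose = 10, min_cell_lines = 5L) {
  stopifnot(inherits(dataset, "perturbation_dataset"))
  meta <- dataset$meta
  out <- list()
  for (dur in c(6L, 24L)) {
    in_dur <- meta$duration_h == dur
    is_dmso <- meta$treatment == "DMSO"
    keep_drug <- in_dur & !is_dmso & meta$dose_uM == dose
    sub <- meta[keep_drug, , drop = FALSE]
    n_cl <- tapply(sub$cell_line_id, sub$treatment,
                   function(x) length(unique(x)))
    ok_drugs <- names(n_cl)[n_cl >= min_cell_lines]
    keep <- (in_dur & is_dmso) |
      (keep_drug & meta$treatment %in% ok_drugs)
    lab <- paste0(dur, "h")
    if (!any(keep & !is_dmso)) {
      warning(sprintf("no drug experiments left in the %s subset", lab))
      out[[lab]] <- NULL
    } else {
      out[[lab]] <- new_perturbation_dataset(
        meta[keep, , drop = FALSE],
        dataset$values[keep, , drop = FALSE])
    }
  }
  out
}

#' Per-gene drug signatures from one duration subset
#'
#' For every landmark gene, fits a linear mixed model of expression on
#' treatment (categorical, DMSO reference) with crossed random intercepts
#' for cell line and plate, sharing the variance estimates across all
#' drugs of the subset. The reported log2 fold change is the drug-vs-DMSO
#' fixed-effect contrast, its standard error comes from the fixed-effect
#' covariance at the REML estimates, and the p-value is two-sided Wald
#' (normal).
#'
#' @param subset a \code{perturbation_dataset} (one duration) containing
#'   DMSO experiments.
#' @param timepoint label stored in the output ("6h" or "24h").
#' @return data frame with columns \code{drug_id}, \code{gene_id},
#'   \code{timepoint}, \code{log2fc}, \code{se}, \code{p},
#'   \code{corrected} (FALSE).
#' @export
fit_gene_signature <- function(subset, timepoint = NULL) {
  stopifnot(inherits(subset, "perturbation_dataset"))
  meta <- subset$meta
  if (!any(meta$treatment == "DMSO"))
    stop("subset contains no DMSO control experiments")
  if (is.null(timepoint))
    timepoint <- paste0(unique(meta$duration_h)[1L], "h")
  drugs <- sort(setdiff(unique(meta$treatment), "DMSO"))
  trt <- factor(meta$treatment, levels = c("DMSO", drugs))
  X <- stats::model.matrix(~trt)
  fits <- lmm_crossed_multi(subset$values, X, meta$cell_line_id,
                            meta$plate_id)
  zero_var <- vapply(fits, function(f)
    f$varcomp[["sigma2_resid"]] <= 1e-12, logical(1L))
  if (any(zero_var))
    message(sprintf(
      "%d gene(s) hit the residual variance floor (zero-variance fit)",
      sum(zero_var)))
  coef_idx <- 1L + seq_along(drugs) # treatment contrasts follow intercept
  out <- lapply(seq_along(fits), function(g) {
    f <- fits[[g]]
    fc <- f$fixef[coef_idx]
    se <- f$se_fixef[coef_idx]
    data.frame(
      drug_id = drugs, gene_id = subset$genes[g], timepoint = timepoint,
      log2fc = fc, se = se, p = 2 * stats::pnorm(-abs(fc / se)),
      corrected = FALSE, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$drug_id, res$gene_id), , drop = FALSE]
}

#' Estimate 6 h, 24 h and combined drug signatures
#'
#' Convenience wrapper: filters the dataset, fits each duration subset,
#' and meta-combines the timepoints.
#'
#' @param dataset a \code{perturbation_dataset}.
#' @inheritParams filter_experiments
#' @return signature data frame stacking the 6h, 24h and combined entries.
#' @export
estimate_drug_signatures <- function(dataset, dose = 10,
                                     min_cell_lines = 5L) {
  subsets <- filter_experiments(dataset, dose, min_cell_lines)
  parts <- list()
  for (lab in names(subsets)) {
    if (!is.null(subsets[[lab]]))
      parts[[lab]] <- fit_gene_signature(subsets[[lab]], lab)
  }
  if (length(parts) == 0L) stop("no drug experiments survive filtering")
  sig <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  comb <- combine_signature_timepoints(sig)
  comb$tau2 <- NULL
  rbind(sig, comb, make.row.names = FALSE)
}
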