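#' Fit the crossed drug/cell-line model to a viability table
#'
#' Models \code{log(auc)} with a global intercept and crossed random
#' intercepts for drug and cell line, estimated by REML. The intercept is
#' the log mean normalized AUC of the average drug in the average cell
#' line; the drug BLUPs are the posterior drug effects that enter the
#' mnAUC.
#'
#' @param records data frame with columns \code{drug_id},
#'   \code{cell_line_id}, \code{auc} (strictly positive); replicated
#'   (drug, cell line) pairs are allowed and enter as independent
#'   residuals.
#' @return a \code{tsr_viability_fit}: the \code{tsr_lmm} fit plus the
#'   per-drug observation counts.
#' @export
fit_crossed_intercepts <- function(records) {
  records <- as.data.frame(records)
  need <- c("drug_id", "cell_line_id", "auc")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("viability table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$auc) | records$auc <= 0))
    stop("all auc values must be positive and finite")
  if (length(unique(records$drug_id)) < 2)
    stop("degenerate design: fewer than 2 distinct drugs")
  if (length(unique(records$cell_line_id)) < 2)
    stop("degenerate design: fewer than 2 distinct cell lines")
  y <- log(records$auc)
  X <- matrix(1, length(y), 1L)
  fit <- lmm_crossed(y, X, records$drug_id, records$cell_line_id)
  fit$n_obs_drug <- table(factor(records$drug_id))
  class(fit) <- c("tsr_viability_fit", class(fit))
  fit
}

#' Mean normalized AUC per drug
#'
#' \code{mnauc = exp(intercept + drug_ranef)}: the model intercept plus the
#' drug's posterior (BLUP) effect, exponentiated back to the AUC scale.
#' A value of 1 means no effect versus control in the average cell line;
#' values below 1 indicate anti-proliferative potency.
#'
#' @param fit a \code{tsr_viability_fit} from
#'   \code{\link{fit_crossed_intercepts}}.
#' @param subset_label label describing the cell-line subset the fit used
#'   ("all", a tumor type, or "excl:<tumor type>").
#' @return data frame with columns \code{drug_id}, \code{subset_label},
#'   \code{intercept}, \code{drug_ranef}, \code{mnauc}, \code{n_obs}.
#' @export
compute_mnauc <- function(fit, subset_label = "all") {
  if (!isTRUE(fit$converged)) stop("viability model fit did not converge")
  d <- fit$ranef$f1
  data.frame(
    drug_id = names(d),
    subset_label = subset_label,
    intercept = fit$fixef[1L],
    drug_ranef = as.numeric(d),
    mnauc = exp(fit$fixef[1L] + as.numeric(d)),
    n_obs = as.integer(fit$n_obs_drug[names(d)]),
    stringsAsFactors = FALSE
  )
}

#' Per-tumor-type and leave-one-tumor-type-out mnAUC estimates
#'
#' Refits the crossed model independently on the records of each tumor
#' type's cell lines, and (optionally) on each complement: all records
#' whose cell line is not mapped to the tumor type. Subsets with fewer
#' than \code{min_cell_lines} cell lines are skipped with a warning,
#' mirroring a minimum-panel inclusion rule.
#'
#' @param records viability table; must carry a \code{tumor_type} column
#'   unless \code{tumor_map} is given.
#' @param tumor_map optional data frame (\code{cell_line_id},
#'   \code{tumor_type}) assigning each cell line to at most one type.
#' @param min_cell_lines minimum distinct cell lines per subset (default 4).
#' @param include_excl also fit the "excl:<type>" complements.
#' @param include_all also fit the all-cell-lines model.
#' @return data frame of mnAUC estimates stacked over subsets.
#' @export
mnauc_by_tumor_type <- function(records, tumor_map = NULL,
                                min_cell_lines = 4L, include_excl = TRUE,
                                include_all = TRUE) {
  records <- as.data.frame(records)
  if (is.null(tumor_map)) {
    if (!"tumor_type" %in% names(records))
      stop("records carry no tumor_type column and no tumor_map was given")
    tumor_map <- unique(records[!is.na(records$tumor_type),
                                c("cell_line_id", "tumor_type")])
  }
  if (anyDuplicated(tumor_map$cell_line_id))
    stop("tumor_map assigns some cell line to more than one tumor type")
  records$tumor_type <- tumor_map$tumor_type[
    match(records$cell_line_id, tumor_map$cell_line_id)]
  out <- list()
  if (include_all)
    out[["all"]] <- compute_mnauc(fit_crossed_intercepts(records), "all")
  for (tt in sort(unique(stats::na.omit(records$tumor_type)))) {
    sub <- records[!is.na(records$tumor_type) & records$tumor_type == tt, ]
    if (length(unique(sub$cell_line_id)) < min_cell_lines) {
      warning(sprintf(
        "tumor type %s skipped: %d cell line(s) < minimum %d",
        tt, length(unique(sub$cell_line_id)), min_cell_lines))
      next
    }
    out[[tt]] <- compute_mnauc(fit_crossed_intercepts(sub), tt)
    if (include_excl) {
      comp <- records[is.na(records$tumor_type) | records$tumor_type != tt, ]
      if (length(unique(comp$cell_line_id)) >= max(2L, min_cell_lines)) {
        lab <- paste0("excl:", tt)
        out[[lab]] <- compute_mnauc(fit_crossed_intercepts(comp), lab)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
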