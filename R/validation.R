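# Spearman correlation with average-rank ties and the two-sided
# t-approximation p-value (the behavior of cor.test with exact = FALSE).
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Spearman correlation of connectivity scores with in-tumor potency
#'
#' Per tumor type x scenario x corrected-state x variant: Spearman
#' correlation (average-rank ties, two-sided t-approximation p) between
#' the drugs' connectivity scores and their mnAUC estimated in the cell
#' lines of the same tumor type. A positive rho means drugs scored as
#' stronger reverters (more negative scores) are the more potent (lower
#' mnAUC) drugs.
#'
#' @param scores connectivity score table (\code{\link{score_all}}).
#' @param mnauc_by_tumor mnAUC table whose \code{subset_label} carries
#'   the tumor types.
#' @param min_drugs minimum drugs per cell (default 3).
#' @return data frame of correlation cells (\code{tumor_type},
#'   \code{scenario}, \code{corrected}, \code{variant}, \code{rho},
#'   \code{p}, \code{n_drugs}).
#' @export
spearman_score_vs_mnauc <- function(scores, mnauc_by_tumor,
                                    min_drugs = 3L) {
  scores <- as.data.frame(scores)
  mn <- mnauc_by_tumor[c("drug_id", "subset_label", "mnauc")]
  names(mn)[2L] <- "tumor_type"
  df <- merge(scores, mn, by = c("drug_id", "tumor_type"))
  idx <- split(seq_len(nrow(df)),
               list(df$tumor_type, df$scenario, df$corrected, df$variant),
               drop = TRUE)
  out <- list()
  for (key in names(idx)) {
    rows <- df[idx[[key]], ]
    rows <- rows[is.finite(rows$score), , drop = FALSE]
    if (nrow(rows) < min_drugs) next
    ct <- spearman_cor(rows$score, rows$mnauc)
    if (!is.finite(ct$rho)) {
      warning("degenerate score or mnAUC vector in cell ", key)
      next
    }
    out[[key]] <- data.frame(
      tumor_type = rows$tumor_type[1L], scenario = rows$scenario[1L],
      corrected = rows$corrected[1L], variant = rows$variant[1L],
      rho = ct$rho, p = ct$p, n_drugs = ct$n, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$variant, res$corrected, res$scenario, res$tumor_type), ,
      drop = FALSE]
}

#' Exact Wilcoxon signed-rank test of median zero
#'
#' Zeros are dropped; absolute values are ranked with average ranks. For
#' n of at most \code{exact_max} the two-sided p-value is exact, from
#' full enumeration of the 2^n sign assignments (computed by dynamic
#' programming over the doubled ranks, so ties are handled exactly);
#' above that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x numeric vector.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with \code{p}, \code{statistic} (V, sum of positive
#'   ranks), \code{n} (nonzero values), \code{method}.
#' @export
wilcoxon_rho_vs_zero <- function(x, exact_max = 25L) {
  x <- x[is.finite(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) {
    warning("all values are zero; p = 1")
    return(list(p = 1, statistic = 0, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r)) # doubled ranks are integers, ties incl.
    # counts[w + 1] = number of sign assignments with doubled statistic w
    counts <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * v))
    lower <- sum(counts[seq_len(w2 + 1L)]) / total
    upper <- sum(counts[seq.int(w2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(p = p, statistic = v, n = n, method = method)
}

#' Correlation between tumor fold changes and the viability program
#'
#' Per tumor type and timepoint: Spearman correlation between each
#' gene's tumor-versus-normal log2FC and the gene's correlation with
#' drug potency (\code{\link{gene_mnauc_correlation}}). A positive value
#' reproduces the signature-reversion premise: genes downregulated by
#' potency-reducing drugs tend to be upregulated in tumors.
#'
#' @param tumor_stats per-type DE table (\code{tumor_type},
#'   \code{gene_id}, \code{log2fc}).
#' @param gene_assocs \code{\link{gene_mnauc_correlation}} output.
#' @param min_genes minimum shared genes (default 10).
#' @return data frame (\code{tumor_type}, \code{timepoint}, \code{rho},
#'   \code{p}, \code{n_genes}).
#' @export
tumor_program_correlation <- function(tumor_stats, gene_assocs,
                                      min_genes = 10L) {
  out <- list()
  for (tt in sort(unique(tumor_stats$tumor_type))) {
    ts <- tumor_stats[tumor_stats$tumor_type == tt,
                      c("gene_id", "log2fc")]
    for (tp in sort(unique(gene_assocs$timepoint))) {
      ga <- gene_assocs[gene_assocs$timepoint == tp,
                        c("gene_id", "spearman_rho")]
      m <- merge(ts, ga, by = "gene_id")
      if (nrow(m) < min_genes) next
      ct <- spearman_cor(m$log2fc, m$spearman_rho)
      if (!is.finite(ct$rho)) next
      out[[paste(tt, tp)]] <- data.frame(
        tumor_type = tt, timepoint = tp, rho = ct$rho, p = ct$p,
        n_genes = ct$n, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Nested linear models for explained potency variation
#'
#' Outcome: log mnAUC of each drug in the tumor type's own cell lines.
#' Model 1 regresses on the connectivity score, model 2 on the log mnAUC
#' estimated in all other cell lines, model 3 on both. Reports R2 of
#' models 1 and 2 (F test against the null model) and the R2 increase of
#' model 3 over model 2 (F test of the added term). Where the score's
#' coefficient is negative (opposite the expected direction) the
#' corresponding p-value is replaced with 1.
#'
#' @param mnauc_tumor log mnAUC in the tumor's cell lines (per drug).
#' @param score connectivity score (same drugs, same order).
#' @param mnauc_excl log mnAUC excluding the tumor's cell lines.
#' @param tumor_type label carried into the output.
#' @return one-row data frame (\code{tumor_type}, \code{r2_model1},
#'   \code{p_model1}, \code{r2_model2}, \code{p_model2},
#'   \code{delta_r2_model3}, \code{p_model3}, \code{n_drugs}).
#' @export
nested_r2 <- function(mnauc_tumor, score, mnauc_excl,
                      tumor_type = NA_character_) {
  ok <- is.finite(mnauc_tumor) & is.finite(score) & is.finite(mnauc_excl)
  yv <- mnauc_tumor[ok]
  s <- score[ok]
  x <- mnauc_excl[ok]
  if (length(yv) < 5L) stop("need at least 5 drugs with all quantities")
  if (stats::sd(s) == 0 || stats::sd(x) == 0)
    stop("rank-deficient design: constant covariate (",
         if (stats::sd(s) == 0) "score" else "mnauc_excl", ")")
  m1 <- stats::lm(yv ~ s)
  m2 <- stats::lm(yv ~ x)
  m3 <- stats::lm(yv ~ x + s)
  r2 <- function(m) summary(m)$r.squared
  fp <- function(m) {
    f <- summary(m)$fstatistic
    unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
  }
  p1 <- if (stats::coef(m1)[["s"]] < 0) 1 else fp(m1)
  p3 <- stats::anova(m2, m3)[["Pr(>F)"]][2L]
  if (stats::coef(m3)[["s"]] < 0) p3 <- 1
  data.frame(
    tumor_type = tumor_type,
    r2_model1 = r2(m1), p_model1 = p1,
    r2_model2 = r2(m2), p_model2 = fp(m2),
    delta_r2_model3 = r2(m3) - r2(m2), p_model3 = p3,
    n_drugs = length(yv), stringsAsFactors = FALSE
  )
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of tests in the family.
#' @return \code{alpha / m}; reports format it to 3 decimals.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

# Significance stars: * < 0.05, ** < 0.01, *** < 0.001.
annotate_stars <- function(p) {
  ifelse(!is.finite(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

format_cell <- function(rho, p) {
  ifelse(!is.finite(rho), "-",
         sprintf("%+.2f (P = %.2g)%s", rho, p,
                 ifelse(annotate_stars(p) == "", "",
                        paste0(" ", annotate_stars(p)))))
}

#' Assemble the validation report
#'
#' Builds the correlation tables (uncorrected and corrected signatures),
#' the nested-model table, a per-condition summary of the rho
#' distributions (median, exact signed-rank p against median zero, star
#' annotation) and the tumor-program correlation table.
#'
#' @param cells \code{\link{spearman_score_vs_mnauc}} output.
#' @param nested data frame of stacked \code{\link{nested_r2}} rows.
#' @param program \code{\link{tumor_program_correlation}} output
#'   (optional).
#' @param variant which score variant the tables report.
#' @return list of class \code{tsr_report} with elements
#'   \code{table_uncorrected}, \code{table_corrected},
#'   \code{table_nested}, \code{rho_summary}, \code{program},
#'   \code{cells}.
#' @export
build_report <- function(cells, nested = NULL, program = NULL,
                         variant = "new") {
  cells_v <- cells[cells$variant == variant, , drop = FALSE]
  wide <- function(corrected) {
    sub <- cells_v[cells_v$corrected == corrected, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    types <- sort(unique(sub$tumor_type))
    scen <- sort(unique(sub$scenario))
    out <- data.frame(tumor_type = types, stringsAsFactors = FALSE)
    for (sc in scen) {
      m <- sub[sub$scenario == sc, ]
      idx <- match(types, m$tumor_type)
      out[[sc]] <- format_cell(m$rho[idx], m$p[idx])
    }
    out
  }
  rho_summary <- NULL
  if (nrow(cells_v) > 0L) {
    conds <- unique(cells_v[c("scenario", "corrected")])
    rows <- lapply(seq_len(nrow(conds)), function(i) {
      sub <- cells_v[cells_v$scenario == conds$scenario[i] &
                       cells_v$corrected == conds$corrected[i], ]
      w <- wilcoxon_rho_vs_zero(sub$rho)
      data.frame(
        scenario = conds$scenario[i], corrected = conds$corrected[i],
        n = nrow(sub), median_rho = stats::median(sub$rho),
        signed_rank_p = w$p, stars = annotate_stars(w$p),
        stringsAsFactors = FALSE)
    })
    rho_summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  table_nested <- NULL
  if (!is.null(nested) && nrow(nested) > 0L) {
    table_nested <- data.frame(
      tumor_type = nested$tumor_type,
      model1 = sprintf("%.3g%% (P = %.2g)%s", 100 * nested$r2_model1,
                       nested$p_model1,
                       ifelse(annotate_stars(nested$p_model1) == "", "",
                              paste0(" ", annotate_stars(nested$p_model1)))),
      model2 = sprintf("%.3g%% (P = %.2g)%s", 100 * nested$r2_model2,
                       nested$p_model2,
                       ifelse(annotate_stars(nested$p_model2) == "", "",
                              paste0(" ", annotate_stars(nested$p_model2)))),
      model3 = sprintf("%.3g%% (P = %.2g)%s",
                       100 * nested$delta_r2_model3, nested$p_model3,
                       ifelse(annotate_stars(nested$p_model3) == "", "",
                              paste0(" ", annotate_stars(nested$p_model3)))),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    table_uncorrected = wide(FALSE), table_corrected = wide(TRUE),
    table_nested = table_nested, rho_summary = rho_summary,
    program = program, cells = cells, nested = nested
  ), class = "tsr_report")
}

#' @export
print.tsr_report <- function(x, ...) {
  cat("Signature-reversion validation report\n")
  if (!is.null(x$rho_summary)) {
    cat("\nScore-vs-potency rho distributions (signed-rank test of median 0):\n")
    print(x$rho_summary, row.names = FALSE)
  }
  if (!is.null(x$nested)) {
    cat(sprintf(
      "\nMedian R2: model 1 (score) %.2f%%, model 2 (other cell lines) %.2f%%, model 3 increment %.4f%%\n",
      100 * stats::median(x$nested$r2_model1),
      100 * stats::median(x$nested$r2_model2),
      100 * stats::median(x$nested$delta_r2_model3)))
  }
  invisible(x)
}
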