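#' Rank a drug signature's genes
#'
#' Orders genes by descending log2 fold change (rank 1 = most
#' upregulated by the drug); ties break lexicographically by gene id so
#' rankings are deterministic.
#'
#' @param signature signature entries of one drug / timepoint /
#'   corrected-state (columns \code{drug_id}, \code{gene_id},
#'   \code{log2fc}, optionally \code{timepoint}, \code{corrected}).
#' @return list of class \code{ranked_signature}: \code{drug_id},
#'   \code{corrected}, \code{timepoint}, \code{genes} (ordered character
#'   vector).
#' @export
rank_genes <- function(signature) {
  signature <- as.data.frame(signature)
  if (nrow(signature) < 2L) stop("need at least 2 genes to rank")
  if (any(!is.finite(signature$log2fc)))
    stop("all log2fc values must be finite")
  if (length(unique(signature$drug_id)) != 1L)
    stop("rank_genes expects entries of a single drug")
  degenerate <- stats::sd(signature$log2fc) == 0
  if (degenerate)
    warning("all log2fc equal: ranking is purely lexicographic")
  ord <- order(-signature$log2fc, signature$gene_id)
  structure(list(
    drug_id = signature$drug_id[1L],
    corrected = if ("corrected" %in% names(signature))
      signature$corrected[1L] else NA,
    timepoint = if ("timepoint" %in% names(signature))
      signature$timepoint[1L] else NA_character_,
    genes = as.character(signature$gene_id[ord]),
    degenerate = degenerate
  ), class = "ranked_signature")
}

#' Kolmogorov-Smirnov enrichment statistic of a tag set in a ranked list
#'
#' For ascending tag positions \code{V(1..t)} among \code{n} ranked
#' genes, computes \code{a = max_j(j/t - V(j)/n)} and
#' \code{b = max_j(V(j)/n - (j-1)/t)} and returns \code{a} if
#' \code{a > b}, else \code{-b}. Positive values mean the tags
#' concentrate at the top of the ranking, negative at the bottom.
#'
#' @param tag_positions strictly increasing integer positions in 1..n.
#' @param n total number of ranked genes.
#' @return KS statistic in [-1, 1].
#' @export
ks_enrichment <- function(tag_positions, n) {
  t <- length(tag_positions)
  if (t == 0L) stop("empty tag set")
  if (any(diff(tag_positions) <= 0))
    stop("tag positions must be strictly increasing")
  if (tag_positions[1L] < 1 || tag_positions[t] > n)
    stop("tag positions must lie in 1..n")
  j <- seq_len(t)
  a <- max(j / t - tag_positions / n)
  b <- max(tag_positions / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity (reversal) score of a drug against a tumor signature
#'
#' KS enrichment of the tumor's up- and downregulated gene sets in the
#' drug's ranked signature. The \code{"new"} variant always reports
#' \code{ks_up - ks_down}; the \code{"original"} variant reports 0
#' whenever the two components share a sign. Negative scores indicate
#' reversal of the tumor signature (tumor-up genes pushed down by the
#' drug and vice versa).
#'
#' @param ranked a \code{\link{rank_genes}} result.
#' @param sig a \code{\link{select_signature}} result.
#' @param variant \code{"new"} or \code{"original"}.
#' @return one-row data frame (\code{drug_id}, \code{tumor_type},
#'   \code{scenario}, \code{corrected}, \code{variant}, \code{ks_up},
#'   \code{ks_down}, \code{score}); the score is \code{NA} when either
#'   gene set is empty.
#' @export
connectivity_score <- function(ranked, sig, variant = c("new", "original")) {
  variant <- match.arg(variant)
  base <- data.frame(
    drug_id = ranked$drug_id, tumor_type = sig$tumor_type,
    scenario = sig$scenario, corrected = ranked$corrected,
    variant = variant, ks_up = NA_real_, ks_down = NA_real_,
    score = NA_real_, stringsAsFactors = FALSE
  )
  if (length(sig$up_genes) == 0L || length(sig$down_genes) == 0L)
    return(base)
  pos_up <- sort(match(sig$up_genes, ranked$genes))
  pos_down <- sort(match(sig$down_genes, ranked$genes))
  if (anyNA(pos_up) || anyNA(pos_down))
    stop("signature genes missing from the ranked list")
  n <- length(ranked$genes)
  ks_up <- ks_enrichment(pos_up, n)
  ks_down <- ks_enrichment(pos_down, n)
  score <- if (variant == "new") {
    ks_up - ks_down
  } else if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
  base$ks_up <- ks_up
  base$ks_down <- ks_down
  base$score <- score
  base
}

#' Score every drug against every tumor signature
#'
#' @param ranked_list list of \code{\link{rank_genes}} results (one per
#'   drug).
#' @param tumor_sigs list of \code{\link{select_signature}} results.
#' @param variant score variant(s) to compute.
#' @return data frame of connectivity scores, one row per drug x tumor
#'   signature x variant; empty signatures propagate \code{NA} scores.
#' @export
score_all <- function(ranked_list, tumor_sigs,
                      variant = c("new", "original")) {
  variant <- match.arg(variant, several.ok = TRUE)
  rows <- list()
  k <- 0L
  for (rk in ranked_list) for (sg in tumor_sigs) for (v in variant) {
    k <- k + 1L
    rows[[k]] <- connectivity_score(rk, sg, v)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$tumor_type, out$scenario, out$variant, out$drug_id), ,
      drop = FALSE]
}
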