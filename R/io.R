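#' Lossless CSV writer
#'
#' Plain UTF-8 CSV with a header row and "." decimal separator; numeric
#' columns are printed with 17 significant digits so a write/read
#' round-trip reproduces every double bit-exactly.
#'
#' @param df data frame to write.
#' @param path output file.
#' @export
tsr_write_csv <- function(df, path) {
  out <- df
  chr_cols <- which(vapply(out, function(x)
    is.character(x) || is.factor(x), logical(1L)))
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE,
                   quote = if (length(chr_cols) > 0) chr_cols else FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname tsr_write_csv
#' @export
tsr_read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

tsr_write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genes-by-samples counts matrix (TSV)
#'
#' @param path TSV with a \code{gene_id} column followed by one integer
#'   column per sample.
#' @return integer matrix with gene rownames.
#' @export
read_counts_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("counts table is missing column: gene_id")
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  if (any(!is.finite(m)) || any(m < 0))
    stop("counts must be finite and non-negative")
  rownames(m) <- df$gene_id
  m
}

#' Read the drug-by-cell-line viability table
#'
#' @param path CSV with columns \code{drug_id}, \code{cell_line_id},
#'   \code{tumor_type}, \code{auc}; extra dose-response columns
#'   (\code{slope}, \code{ec50}, \code{ic50}) are tolerated and ignored.
#' @return data frame of viability records, one per row of the file.
#' @export
read_auc_table <- function(path) {
  df <- tsr_read_csv(path)
  need <- c("drug_id", "cell_line_id", "tumor_type", "auc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("auc table is missing column(s): ", paste(miss, collapse = ", "))
  auc <- suppressWarnings(as.numeric(df$auc))
  bad <- which(is.na(auc) | auc <= 0)
  if (length(bad) > 0)
    stop(sprintf("invalid auc (non-numeric or <= 0) in row(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  df$auc <- auc
  df$tumor_type[df$tumor_type %in% c("", "NA")] <- NA_character_
  df[c(need, intersect(c("slope", "ec50", "ic50"), names(df)))]
}

new_perturbation_dataset <- function(meta, values) {
  stopifnot(nrow(meta) == nrow(values))
  structure(list(meta = meta, values = values,
                 genes = colnames(values)),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat(sprintf(
    "Perturbation dataset: %d experiments x %d genes (%d drugs, %d cell lines)\n",
    nrow(x$meta), length(x$genes),
    length(setdiff(unique(x$meta$treatment), "DMSO")),
    length(unique(x$meta$cell_line_id))))
  invisible(x)
}

#' Read long-format perturbation experiments
#'
#' @param path CSV with columns \code{experiment_id}, \code{treatment}
#'   (drug id or literal "DMSO"), \code{cell_line_id}, \code{plate_id},
#'   \code{duration_h} (6 or 24), \code{dose_uM}, \code{gene_id},
#'   \code{value}.
#' @return a \code{perturbation_dataset}: per-experiment metadata plus an
#'   experiments-by-genes expression matrix. Metadata must be consistent
#'   within each experiment and every experiment must report the same
#'   gene panel.
#' @export
read_expression_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(experiment_id = "character",
                                       treatment = "character",
                                       cell_line_id = "character",
                                       plate_id = "character",
                                       duration_h = "integer",
                                       dose_uM = "numeric",
                                       gene_id = "character",
                                       value = "numeric"))
  need <- c("experiment_id", "treatment", "cell_line_id", "plate_id",
            "duration_h", "dose_uM", "gene_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("expression table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    return(new_perturbation_dataset(
      data.frame(experiment_id = character(), treatment = character(),
                 cell_line_id = character(), plate_id = character(),
                 duration_h = integer(), dose_uM = numeric(),
                 stringsAsFactors = FALSE),
      matrix(numeric(), 0L, 0L)))
  }
  if (!all(df$duration_h %in% c(6L, 24L)))
    stop("unknown duration_h (must be 6 or 24)")
  meta <- unique(df[c("experiment_id", "treatment", "cell_line_id",
                      "plate_id", "duration_h", "dose_uM")])
  dup <- meta$experiment_id[duplicated(meta$experiment_id)]
  if (length(dup) > 0)
    stop("inconsistent metadata within experiment_id(s): ",
         paste(unique(dup), collapse = ", "))
  genes <- sort(unique(df$gene_id))
  exps <- meta$experiment_id
  values <- matrix(NA_real_, length(exps), length(genes),
                   dimnames = list(exps, genes))
  values[cbind(match(df$experiment_id, exps), match(df$gene_id, genes))] <-
    df$value
  if (anyNA(values))
    stop("experiments do not share a common gene panel")
  new_perturbation_dataset(meta, values)
}

write_expression_long <- function(dataset, path) {
  meta <- dataset$meta
  n_g <- length(dataset$genes)
  long <- data.frame(
    experiment_id = rep(meta$experiment_id, each = n_g),
    treatment = rep(meta$treatment, each = n_g),
    cell_line_id = rep(meta$cell_line_id, each = n_g),
    plate_id = rep(meta$plate_id, each = n_g),
    duration_h = rep(meta$duration_h, each = n_g),
    dose_uM = rep(meta$dose_uM, each = n_g),
    gene_id = rep(dataset$genes, times = nrow(meta)),
    value = as.numeric(t(dataset$values)),
    stringsAsFactors = FALSE
  )
  tsr_write_csv(long, path)
}

#' Read sample metadata for the tumor counts
#'
#' @param path CSV with columns \code{sample_id}, \code{tumor_type},
#'   \code{arm} (values "tumor"/"normal").
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- tsr_read_csv(path)
  need <- c("sample_id", "tumor_type", "arm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("sample metadata is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$arm %in% c("tumor", "normal")))
    stop("arm must be 'tumor' or 'normal'")
  df
}
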