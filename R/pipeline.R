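#' Build a run configuration
#'
#' @param auc_table,expression_table,counts_table,sample_metadata input
#'   file paths (pipeline CSV/TSV schemas).
#' @param output_dir directory receiving every intermediate table.
#' @param seed master seed (only the simulate stage draws random
#'   numbers).
#' @param scenarios signature-selection scenarios to score.
#' @param score_variant \code{"new"} (non-zeroing) or \code{"original"};
#'   both are computed, this one drives the report.
#' @param timepoints which drug-signature timepoint the connectivity
#'   stage ranks (\code{"combined"}, \code{"6h"} or \code{"24h"}).
#' @param alpha significance level for the Bonferroni family.
#' @param n_tumor_types_for_bonferroni family size; defaults to the
#'   number of tumor types actually analyzed.
#' @param primary_scenario scenario used for the nested-model table.
#' @param min_cell_lines_subset minimum cell lines per tumor-type subset.
#' @param simulate if TRUE, generate the input bundle first.
#' @param sim list of \code{\link{sim_params}} overrides.
#' @return list of class \code{tsr_config}.
#' @export
tsr_config <- function(auc_table = NULL, expression_table = NULL,
                       counts_table = NULL, sample_metadata = NULL,
                       output_dir = "tsr_output", seed = 1L,
                       scenarios = c("top50", "top100", "top150",
                                     "fc_adjp"),
                       score_variant = "new", timepoints = "combined",
                       alpha = 0.05, n_tumor_types_for_bonferroni = NULL,
                       primary_scenario = "top100",
                       min_cell_lines_subset = 4L, simulate = FALSE,
                       sim = list()) {
  cfg <- structure(list(
    paths = list(auc_table = auc_table,
                 expression_table = expression_table,
                 counts_table = counts_table,
                 sample_metadata = sample_metadata,
                 output_dir = output_dir),
    seed = as.integer(seed), scenarios = scenarios,
    score_variant = score_variant, timepoints = timepoints,
    alpha = alpha,
    n_tumor_types_for_bonferroni = n_tumor_types_for_bonferroni,
    primary_scenario = primary_scenario,
    min_cell_lines_subset = as.integer(min_cell_lines_subset),
    simulate = isTRUE(simulate), sim = sim
  ), class = "tsr_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$scenarios) == 0L)
    stop("config error: scenarios must be non-empty")
  bad <- setdiff(cfg$scenarios, c("top50", "top100", "top150", "fc_adjp"))
  if (length(bad) > 0)
    stop("config error: unknown scenario(s): ", paste(bad, collapse = ", "))
  if (!cfg$score_variant %in% c("new", "original"))
    stop("config error: score_variant must be 'new' or 'original'")
  if (!cfg$timepoints %in% c("combined", "6h", "24h"))
    stop("config error: timepoints must be 'combined', '6h' or '24h'")
  if (is.na(cfg$seed) || cfg$seed < 0L)
    stop("config error: seed must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must be in (0, 1)")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Simple key: value (YAML) dialect; keys mirror the arguments of
#' \code{\link{tsr_config}} with input paths at the top level.
#'
#' @param path config file.
#' @return a \code{tsr_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(tsr_config)))]
  do.call(tsr_config, args)
}

out_path <- function(cfg, name) file.path(cfg$paths$output_dir, name)

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

require_input <- function(cfg, key) {
  p <- cfg$paths[[key]]
  if (is.null(p) || !file.exists(p))
    stop(sprintf("stage input missing: %s (%s)", key,
                 if (is.null(p)) "unset" else p))
  p
}

stage_simulate <- function(cfg) {
  params <- do.call(sim_params, c(cfg$sim, list(seed = cfg$seed)))
  bundle <- simulate_all(params, out_path(cfg, "sim"))
  stage_log("simulate",
            "%d drugs, %d viability cell lines, %d genes, %d tumor types",
            params$n_drugs, params$n_cell_lines_viability,
            params$n_genes, params$n_tumor_types)
  cfg$paths[c("auc_table", "expression_table", "counts_table",
              "sample_metadata")] <-
    bundle$paths[c("auc_table", "expression_table", "counts_table",
                   "sample_metadata")]
  list(cfg = cfg, files = unlist(bundle$paths, use.names = FALSE))
}

stage_mnauc <- function(cfg) {
  records <- read_auc_table(require_input(cfg, "auc_table"))
  mn <- mnauc_by_tumor_type(records,
                            min_cell_lines = cfg$min_cell_lines_subset)
  f <- out_path(cfg, "mnauc.csv")
  tsr_write_csv(mn, f)
  stage_log("mnauc", "%d records in -> %d drugs x %d subsets out",
            nrow(records), length(unique(mn$drug_id)),
            length(unique(mn$subset_label)))
  list(files = f)
}

stage_drug_sig <- function(cfg) {
  pd <- read_expression_long(require_input(cfg, "expression_table"))
  sig <- estimate_drug_signatures(pd)
  f <- out_path(cfg, "drug_signatures.csv")
  tsr_write_csv(sig, f)
  stage_log("drug-sig", "%d experiments in -> %d drugs x %d genes out",
            nrow(pd$meta), length(unique(sig$drug_id)),
            length(unique(sig$gene_id)))
  list(files = f)
}

stage_correct <- function(cfg) {
  sig <- tsr_read_csv(out_path(cfg, "drug_signatures.csv"))
  mn <- tsr_read_csv(out_path(cfg, "mnauc.csv"))
  assoc <- gene_mnauc_correlation(sig, mn)
  corr <- correct_signatures(sig, mn)
  corr_comb <- combine_signature_timepoints(corr)
  corr_comb$tau2 <- NULL
  corr_all <- rbind(corr, corr_comb, make.row.names = FALSE)
  f1 <- out_path(cfg, "gene_viability_assoc.csv")
  f2 <- out_path(cfg, "drug_signatures_corrected.csv")
  tsr_write_csv(assoc, f1)
  tsr_write_csv(corr_all, f2)
  stage_log("correct", "%d gene/timepoint associations, %d entries corrected",
            nrow(assoc), sum(corr_all$corrected))
  list(files = c(f1, f2))
}

stage_tumor_sig <- function(cfg) {
  counts <- read_counts_matrix(require_input(cfg, "counts_table"))
  samples <- read_sample_metadata(require_input(cfg, "sample_metadata"))
  stats <- tumor_de_all_types(counts, samples)
  sig <- tsr_read_csv(out_path(cfg, "drug_signatures.csv"))
  landmark <- intersect(unique(sig$gene_id), unique(stats$gene_id))
  rows <- list()
  for (tt in sort(unique(stats$tumor_type))) {
    st <- stats[stats$tumor_type == tt, ]
    for (sc in cfg$scenarios) {
      ts <- select_signature(st, sc, landmark)
      if (length(ts$up_genes) + length(ts$down_genes) > 0)
        rows[[paste(tt, sc)]] <- data.frame(
          tumor_type = tt, scenario = sc,
          direction = c(rep("up", length(ts$up_genes)),
                        rep("down", length(ts$down_genes))),
          gene_id = c(ts$up_genes, ts$down_genes),
          stringsAsFactors = FALSE)
    }
  }
  sig_long <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  f1 <- out_path(cfg, "tumor_stats.csv")
  f2 <- out_path(cfg, "tumor_signatures.csv")
  f3 <- out_path(cfg, "tumor_meta_signature.csv")
  tsr_write_csv(stats, f1)
  tsr_write_csv(sig_long, f2)
  tsr_write_csv(meta_tumor_signature(stats), f3)
  stage_log("tumor-sig", "%d tumor types, %d genes kept, %d signature rows",
            length(unique(stats$tumor_type)),
            length(unique(stats$gene_id)), nrow(sig_long))
  list(files = c(f1, f2, f3))
}

signatures_from_long <- function(sig_long) {
  out <- list()
  for (tt in unique(sig_long$tumor_type)) {
    for (sc in unique(sig_long$scenario[sig_long$tumor_type == tt])) {
      sub <- sig_long[sig_long$tumor_type == tt &
                        sig_long$scenario == sc, ]
      out[[paste(tt, sc)]] <- structure(list(
        tumor_type = tt, scenario = sc,
        up_genes = sub$gene_id[sub$direction == "up"],
        down_genes = sub$gene_id[sub$direction == "down"],
        empty = nrow(sub) == 0L
      ), class = "tumor_signature")
    }
  }
  out
}

stage_connectivity <- function(cfg) {
  sig_u <- tsr_read_csv(out_path(cfg, "drug_signatures.csv"))
  sig_c <- tsr_read_csv(out_path(cfg, "drug_signatures_corrected.csv"))
  sig_long <- tsr_read_csv(out_path(cfg, "tumor_signatures.csv"))
  tumor_sigs <- signatures_from_long(sig_long)
  landmark <- unique(sig_long$gene_id)
  score_one_state <- function(sig, corrected) {
    sub <- sig[sig$timepoint == cfg$timepoints, ]
    ranked <- lapply(split(sub, sub$drug_id), function(d) {
      d$corrected <- corrected
      rank_genes(d)
    })
    score_all(ranked, tumor_sigs, c("new", "original"))
  }
  scores <- rbind(score_one_state(sig_u, FALSE),
                  score_one_state(sig_c, TRUE),
                  make.row.names = FALSE)
  f <- out_path(cfg, "connectivity_scores.csv")
  tsr_write_csv(scores, f)
  stage_log("connectivity", "%d scores (%d drugs x %d signatures x 2 states x 2 variants)",
            nrow(scores), length(unique(scores$drug_id)),
            length(tumor_sigs))
  list(files = f)
}

stage_validate <- function(cfg) {
  scores <- tsr_read_csv(out_path(cfg, "connectivity_scores.csv"))
  mn <- tsr_read_csv(out_path(cfg, "mnauc.csv"))
  stats <- tsr_read_csv(out_path(cfg, "tumor_stats.csv"))
  assoc <- tsr_read_csv(out_path(cfg, "gene_viability_assoc.csv"))
  cells <- spearman_score_vs_mnauc(scores, mn)
  types <- sort(unique(cells$tumor_type))
  sc_primary <- if (cfg$primary_scenario %in% cfg$scenarios)
    cfg$primary_scenario else cfg$scenarios[1L]
  nested <- list()
  for (tt in types) {
    mt <- mn[mn$subset_label == tt, c("drug_id", "mnauc")]
    me <- mn[mn$subset_label == paste0("excl:", tt),
             c("drug_id", "mnauc")]
    sc <- scores[scores$tumor_type == tt &
                   scores$scenario == sc_primary &
                   scores$corrected == FALSE &
                   scores$variant == cfg$score_variant,
                 c("drug_id", "score")]
    df <- merge(merge(mt, me, by = "drug_id",
                      suffixes = c("_tumor", "_excl")), sc,
                by = "drug_id")
    df <- df[is.finite(df$score), ]
    if (nrow(df) < 5L) next
    nested[[tt]] <- nested_r2(log(df$mnauc_tumor), df$score,
                              log(df$mnauc_excl), tt)
  }
  nested <- do.call(rbind, c(nested, list(make.row.names = FALSE)))
  program <- tumor_program_correlation(stats, assoc)
  report <- build_report(cells, nested, program, cfg$score_variant)
  m <- if (is.null(cfg$n_tumor_types_for_bonferroni))
    max(1L, length(types)) else cfg$n_tumor_types_for_bonferroni
  report$bonferroni <- data.frame(
    alpha = cfg$alpha, m = m,
    threshold = bonferroni_threshold(cfg$alpha, m),
    formatted = sprintf("%.3f", bonferroni_threshold(cfg$alpha, m)),
    stringsAsFactors = FALSE)
  files <- character()
  wr <- function(obj, name) {
    if (is.null(obj)) return(invisible(NULL))
    f <- out_path(cfg, name)
    tsr_write_csv(obj, f)
    files <<- c(files, f)
  }
  wr(report$table_uncorrected, "validation_table1.csv")
  wr(report$table_corrected, "validation_table2.csv")
  wr(report$table_nested, "validation_table3.csv")
  wr(report$rho_summary, "validation_fig4.csv")
  wr(report$cells, "validation_cells.csv")
  wr(report$nested, "validation_nested.csv")
  wr(report$program, "validation_program.csv")
  wr(report$bonferroni, "validation_bonferroni.csv")
  stage_log("validate", "%d correlation cells, %d nested-model rows",
            nrow(cells), if (is.null(nested)) 0L else nrow(nested))
  list(files = files, report = report)
}

#' Run the validation pipeline end to end
#'
#' Executes the stages in order (simulate if requested, then viability
#' summarization, drug signatures, viability correction, tumor
#' signatures, connectivity scoring, validation), writing every
#' intermediate table plus a run manifest to the output directory.
#' Identical configuration and seed yield byte-identical outputs.
#'
#' @param config a \code{\link{tsr_config}}.
#' @param stages character vector of stage names to run (default all).
#' @return the validation report (a \code{tsr_report}), invisibly for
#'   partial runs; the manifest is attached as attribute
#'   \code{"manifest"}.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "mnauc", "drug-sig",
                                    "correct", "tumor-sig",
                                    "connectivity", "validate")) {
  validate_config(config)
  if (!config$simulate) stages <- setdiff(stages, "simulate")
  dir.create(config$paths$output_dir, recursive = TRUE,
             showWarnings = FALSE)
  runners <- list(
    "simulate" = stage_simulate, "mnauc" = stage_mnauc,
    "drug-sig" = stage_drug_sig, "correct" = stage_correct,
    "tumor-sig" = stage_tumor_sig, "connectivity" = stage_connectivity,
    "validate" = stage_validate
  )
  unknown <- setdiff(stages, names(runners))
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  # parameter snapshot: the exact configuration of this run
  snap <- out_path(config, "run_config.yaml")
  yaml::write_yaml(unclass(config), snap)
  manifest <- list(config = data.frame(stage = "config", file = snap,
                                       stringsAsFactors = FALSE))
  report <- NULL
  for (st in intersect(names(runners), stages)) {
    res <- tryCatch(runners[[st]](config),
                    error = function(e)
                      stop(sprintf("stage '%s' failed: %s", st,
                                   conditionMessage(e)), call. = FALSE))
    if (!is.null(res$cfg)) config <- res$cfg
    if (!is.null(res$report)) report <- res$report
    if (length(res$files) > 0)
      manifest[[st]] <- data.frame(stage = st, file = res$files,
                                   stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  if (!is.null(manifest) && nrow(manifest) > 0) {
    manifest$md5 <- as.character(tools::md5sum(manifest$file))
    manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    tsr_write_csv(manifest, out_path(config, "manifest.csv"))
  }
  if (is.null(report)) {
    return(invisible(structure(list(), manifest = manifest)))
  }
  attr(report, "manifest") <- manifest
  report
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{mnauc}, \code{drug-sig},
#' \code{correct}, \code{tumor-sig}, \code{connectivity},
#' \code{validate}, \code{all}. Flags: \code{--config <file>},
#' \code{--seed <int>}, \code{--stage <name>}, \code{--out <dir>}.
#'
#' @param args character vector (defaults to the command line).
#' @return the stage result, invisibly.
#' @export
tsr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages_all <- c("simulate", "mnauc", "drug-sig", "correct",
                  "tumor-sig", "connectivity", "validate")
  flag <- function(name) {
    hit <- which(args == paste0("--", name))
    if (length(hit) == 1L && hit < length(args)) args[hit + 1L]
    else {
      pre <- grep(paste0("^--", name, "="), args, value = TRUE)
      if (length(pre) == 1L) sub(paste0("^--", name, "="), "", pre)
      else NULL
    }
  }
  stage <- if (length(args) > 0 && !startsWith(args[1L], "--")) args[1L]
  else flag("stage") %||% "all"
  cfg <- if (!is.null(flag("config"))) read_config(flag("config"))
  else tsr_config(simulate = TRUE)
  if (!is.null(flag("seed"))) cfg$seed <- as.integer(flag("seed"))
  if (!is.null(flag("out"))) cfg$paths$output_dir <- flag("out")
  validate_config(cfg)
  stages <- if (stage == "all") stages_all else stage
  if (identical(stages, "simulate")) cfg$simulate <- TRUE
  invisible(run_pipeline(cfg, stages))
}
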