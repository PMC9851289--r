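#' Simulation parameters for the synthetic study
#'
#' Builds the parameter set that defines the synthetic study conditions:
#' a drug-by-cell-line viability screen with a minority of potent drugs,
#' long-format drug/DMSO perturbation experiments carrying a planted
#' viability-response gene program, and tumor/normal count matrices in
#' which the program's drug-downregulated genes are upregulated in tumors.
#'
#' Viability is generated on the natural-log AUC scale as
#' \code{log(auc) = d_drug + c_cellline + e}; inactive drugs center at
#' \code{auc = 1}, a fraction \code{frac_active_drugs} is shifted by
#' \code{mu_active} (negative: potent). Expression responds to potency
#' through the hinge \code{max(0, -log(mnAUC))}, so the program is silent
#' for drugs with mnAUC above 1.
#'
#' @param n_drugs number of drugs screened.
#' @param n_cell_lines_viability cell lines in the viability screen; must
#'   be at least \code{n_tumor_types * cell_lines_per_tumor_type}.
#' @param n_tumor_types,cell_lines_per_tumor_type tumor-type panel layout.
#' @param n_cell_lines_expr,n_plates,n_replicates perturbation design.
#' @param n_genes,n_program_genes,n_mechanism_genes_per_drug gene panel:
#'   total genes, viability-program genes, and per-drug mechanism genes.
#' @param frac_active_drugs fraction of drugs with a potency shift.
#' @param mu_active mean log-AUC shift of active drugs (negative).
#' @param sigma_drug,sigma_cellline,sigma_resid log-AUC standard deviations.
#' @param gamma_scale scale of the program-gene response slopes
#'   (log2 expression per unit of \code{-log(mnAUC)}).
#' @param sigma_expr_cellline,sigma_expr_plate,sigma_expr_resid log2
#'   expression standard deviations.
#' @param tumor_effect_size planted |log2FC| of program genes in tumors.
#' @param n_tumor_samples_per_arm samples per arm per tumor type.
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param missing_frac fraction of viability records masked out.
#' @param seed master seed; each stage draws from its own named substream
#'   so adding a stage never perturbs earlier stages' draws.
#' @return a validated list of class \code{sim_params}.
#' @export
sim_params <- function(n_drugs = 120L, n_cell_lines_viability = 80L,
                       n_tumor_types = 10L, cell_lines_per_tumor_type = 8L,
                       n_cell_lines_expr = 6L, n_plates = 2L,
                       n_genes = 900L, n_program_genes = 8L,
                       n_mechanism_genes_per_drug = 5L,
                       frac_active_drugs = 0.05, mu_active = -0.5,
                       sigma_drug = 0.35, sigma_cellline = 0.1,
                       sigma_resid = 0.25, gamma_scale = 0.5,
                       sigma_expr_cellline = 0.15, sigma_expr_plate = 0.1,
                       sigma_expr_resid = 1.0, n_replicates = 2L,
                       tumor_effect_size = 2, n_tumor_samples_per_arm = 8L,
                       nb_dispersion = 0.05, missing_frac = 0, seed = 1L) {
  p <- list(
    n_drugs = as.integer(n_drugs),
    n_cell_lines_viability = as.integer(n_cell_lines_viability),
    n_tumor_types = as.integer(n_tumor_types),
    cell_lines_per_tumor_type = as.integer(cell_lines_per_tumor_type),
    n_cell_lines_expr = as.integer(n_cell_lines_expr),
    n_plates = as.integer(n_plates), n_genes = as.integer(n_genes),
    n_program_genes = as.integer(n_program_genes),
    n_mechanism_genes_per_drug = as.integer(n_mechanism_genes_per_drug),
    frac_active_drugs = frac_active_drugs, mu_active = mu_active,
    sigma_drug = sigma_drug, sigma_cellline = sigma_cellline,
    sigma_resid = sigma_resid, gamma_scale = gamma_scale,
    sigma_expr_cellline = sigma_expr_cellline,
    sigma_expr_plate = sigma_expr_plate,
    sigma_expr_resid = sigma_expr_resid,
    n_replicates = as.integer(n_replicates),
    tumor_effect_size = tumor_effect_size,
    n_tumor_samples_per_arm = as.integer(n_tumor_samples_per_arm),
    nb_dispersion = nb_dispersion, missing_frac = missing_frac,
    seed = as.integer(seed)
  )
  counts <- c("n_drugs", "n_cell_lines_viability", "n_tumor_types",
              "cell_lines_per_tumor_type", "n_cell_lines_expr", "n_plates",
              "n_genes", "n_program_genes", "n_replicates",
              "n_tumor_samples_per_arm")
  for (nm in counts) if (p[[nm]] < 1L) stop(nm, " must be >= 1")
  sigmas <- c("sigma_drug", "sigma_cellline", "sigma_resid", "gamma_scale",
              "sigma_expr_cellline", "sigma_expr_plate", "sigma_expr_resid")
  for (nm in sigmas) if (p[[nm]] < 0) stop(nm, " must be >= 0")
  if (p$frac_active_drugs < 0 || p$frac_active_drugs > 1)
    stop("frac_active_drugs must be in [0, 1]")
  if (p$missing_frac < 0 || p$missing_frac >= 1)
    stop("missing_frac must be in [0, 1)")
  if (p$n_program_genes > p$n_genes)
    stop("n_program_genes must not exceed n_genes")
  if (p$n_mechanism_genes_per_drug > p$n_genes)
    stop("n_mechanism_genes_per_drug must not exceed n_genes")
  if (p$n_tumor_types * p$cell_lines_per_tumor_type >
      p$n_cell_lines_viability)
    stop("n_cell_lines_viability is too small for the tumor-type panel")
  if (p$seed < 0L) stop("seed must be >= 0")
  structure(p, class = "sim_params")
}

# Deterministic per-stage substream: hashing the stage name into the seed
# means adding a new stage never shifts the draws of existing stages.
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1013904223
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

sim_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Simulate the drug-by-cell-line viability screen
#'
#' @param params a \code{\link{sim_params}} object.
#' @return list with \code{records} (columns \code{drug_id},
#'   \code{cell_line_id}, \code{tumor_type}, \code{auc}) and \code{truth}
#'   (per-drug effects \code{d}, activity flags, true mnAUC, per-cell-line
#'   effects, tumor map).
#' @export
simulate_viability <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "viability"))
  drugs <- sim_ids("drug", params$n_drugs)
  cls <- sim_ids("cl", params$n_cell_lines_viability)
  n_active <- floor(params$frac_active_drugs * params$n_drugs)
  active <- rep(FALSE, params$n_drugs)
  if (n_active > 0) active[sample.int(params$n_drugs, n_active)] <- TRUE
  d <- stats::rnorm(params$n_drugs, 0, params$sigma_drug) +
    ifelse(active, params$mu_active, 0)
  cl_eff <- stats::rnorm(params$n_cell_lines_viability, 0,
                         params$sigma_cellline)
  types <- rep(NA_character_, params$n_cell_lines_viability)
  mapped <- params$n_tumor_types * params$cell_lines_per_tumor_type
  types[seq_len(mapped)] <- rep(sprintf("TT%02d", seq_len(params$n_tumor_types)),
                                each = params$cell_lines_per_tumor_type)
  grid <- expand.grid(drug_idx = seq_len(params$n_drugs),
                      cl_idx = seq_len(params$n_cell_lines_viability))
  if (params$missing_frac > 0)
    grid <- grid[stats::runif(nrow(grid)) >= params$missing_frac, ,
                 drop = FALSE]
  log_auc <- d[grid$drug_idx] + cl_eff[grid$cl_idx] +
    stats::rnorm(nrow(grid), 0, params$sigma_resid)
  records <- data.frame(
    drug_id = drugs[grid$drug_idx],
    cell_line_id = cls[grid$cl_idx],
    tumor_type = types[grid$cl_idx],
    auc = exp(log_auc),
    stringsAsFactors = FALSE
  )
  truth <- list(
    drug = data.frame(drug_id = drugs, d = d, active = active,
                      mnauc_true = exp(d), stringsAsFactors = FALSE),
    cell_line = data.frame(cell_line_id = cls, c = cl_eff,
                           tumor_type = types, stringsAsFactors = FALSE)
  )
  list(records = records, truth = truth)
}

#' Simulate long-format drug perturbation experiments
#'
#' Emits DMSO control and 10 uM drug experiments at 6 h and 24 h across
#' cell lines, plates and replicates. Expression of gene g is
#' \code{baseline_g + u_cellline + v_plate +
#' treated * (delta_g,drug + gamma_g * hinge_drug) + e} with
#' \code{hinge = max(0, -log(true mnAUC))}: program genes respond only to
#' drugs that actually reduce viability, with slopes of both signs
#' (stress-response genes rise, replication genes fall).
#'
#' @param params a \code{\link{sim_params}} object.
#' @param truth the truth component returned by
#'   \code{\link{simulate_viability}} on the same params.
#' @return list with \code{dataset} (a \code{perturbation_dataset}) and
#'   \code{truth} (program slopes \code{gamma} and per-drug mechanism
#'   effects \code{delta}).
#' @export
simulate_perturbation <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "perturbation"))
  genes <- sim_ids("g", params$n_genes)
  program_idx <- sample.int(params$n_genes, params$n_program_genes)
  gamma <- numeric(params$n_genes)
  signs <- rep(c(1, -1), length.out = params$n_program_genes)
  gamma[program_idx] <- signs * params$gamma_scale *
    stats::runif(params$n_program_genes, 0.5, 1.5)
  baseline <- stats::runif(params$n_genes, 4, 12)
  drugs <- truth$drug$drug_id
  hinge <- pmax(0, -log(truth$drug$mnauc_true))
  delta <- matrix(0, params$n_genes, length(drugs),
                  dimnames = list(genes, drugs))
  for (j in seq_along(drugs)) {
    idx <- sample.int(params$n_genes, params$n_mechanism_genes_per_drug)
    delta[idx, j] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      stats::runif(length(idx), 0.5, 2)
  }
  ecl <- sim_ids("ecl", params$n_cell_lines_expr)
  meta <- list()
  for (dur in c(6L, 24L)) {
    plates <- sprintf("p%02d_%02d", dur, seq_len(params$n_plates))
    dmso <- expand.grid(cl = ecl, plate = plates,
                        rep = seq_len(params$n_replicates),
                        stringsAsFactors = FALSE)
    dmso$treatment <- "DMSO"
    dmso$dose_uM <- 0
    drg <- expand.grid(treatment = drugs, cl = ecl,
                       rep = seq_len(params$n_replicates),
                       stringsAsFactors = FALSE)
    drg$plate <- plates[1L + (match(drg$cl, ecl) + drg$rep) %%
                          params$n_plates]
    drg$dose_uM <- 10
    blk <- rbind(dmso[c("treatment", "cl", "plate", "rep", "dose_uM")],
                 drg[c("treatment", "cl", "plate", "rep", "dose_uM")])
    blk$duration_h <- dur
    meta[[as.character(dur)]] <- blk
  }
  meta <- do.call(rbind, meta)
  meta$experiment_id <- sprintf("exp%05d", seq_len(nrow(meta)))
  u_cl <- stats::rnorm(length(ecl), 0, params$sigma_expr_cellline)
  names(u_cl) <- ecl
  plates_all <- unique(meta$plate)
  v_pl <- stats::rnorm(length(plates_all), 0, params$sigma_expr_plate)
  names(v_pl) <- plates_all
  treated <- meta$treatment != "DMSO"
  drug_col <- match(meta$treatment, drugs) # NA for DMSO
  mean_mat <- matrix(baseline, nrow(meta), params$n_genes, byrow = TRUE)
  resp <- t(delta) * 1 + hinge * t(matrix(gamma, params$n_genes,
                                          length(drugs))) # drug x gene
  rows_t <- which(treated)
  mean_mat[rows_t, ] <- mean_mat[rows_t, ] + resp[drug_col[rows_t], ]
  mean_mat <- mean_mat + u_cl[meta$cl] + v_pl[meta$plate]
  values <- mean_mat + matrix(
    stats::rnorm(nrow(meta) * params$n_genes, 0, params$sigma_expr_resid),
    nrow(meta), params$n_genes)
  colnames(values) <- genes
  rownames(values) <- meta$experiment_id
  dataset <- new_perturbation_dataset(data.frame(
    experiment_id = meta$experiment_id, treatment = meta$treatment,
    cell_line_id = meta$cl, plate_id = meta$plate,
    duration_h = meta$duration_h, dose_uM = meta$dose_uM,
    stringsAsFactors = FALSE
  ), values)
  sim_truth <- list(
    gene = data.frame(gene_id = genes, gamma = gamma, baseline = baseline,
                      program = seq_len(params$n_genes) %in% program_idx,
                      stringsAsFactors = FALSE),
    delta = delta
  )
  list(dataset = dataset, truth = sim_truth)
}

#' Simulate tumor/normal count matrices
#'
#' Negative-binomial (Poisson-gamma) counts per tumor type, two arms.
#' Program genes carry a planted tumor log2FC of
#' \code{tumor_effect_size * sign(-gamma_g)}: genes the viability program
#' downregulates under potent drugs are upregulated in tumors. A sparse
#' set of non-program genes gets tumor-type-specific DE.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param truth combined truth (needs the \code{gene} table from
#'   \code{\link{simulate_perturbation}}).
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{samples} (sample metadata: \code{sample_id},
#'   \code{tumor_type}, \code{arm}) and \code{truth} (per-gene planted
#'   tumor log2FC per tumor type).
#' @export
simulate_tumor_counts <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "tumor"))
  genes <- truth$gene$gene_id
  gamma <- truth$gene$gamma
  n_genes <- length(genes)
  types <- sprintf("TT%02d", seq_len(params$n_tumor_types))
  base_log2 <- stats::runif(n_genes, 5.5, 12)
  n_arm <- params$n_tumor_samples_per_arm
  nonprog <- which(gamma == 0)
  # type-specific DE lives on disjoint gene blocks: each tumor type has
  # its own biology on top of the shared proliferation program
  n_sparse <- max(0L, min(round(0.1 * length(nonprog)),
                          floor(length(nonprog) / length(types))))
  sparse_pool <- sample(nonprog)
  fc_mat <- matrix(0, n_genes, length(types),
                   dimnames = list(genes, types))
  counts <- NULL
  samples <- list()
  for (t_idx in seq_along(types)) {
    fc <- ifelse(gamma != 0,
                 params$tumor_effect_size * sign(-gamma), 0)
    if (n_sparse > 0) {
      idx <- sparse_pool[(t_idx - 1L) * n_sparse + seq_len(n_sparse)]
      fc[idx] <- sample(c(-1, 1), n_sparse, TRUE) *
        stats::runif(n_sparse, 1, 3)
    }
    fc_mat[, t_idx] <- fc
    arm <- rep(c("normal", "tumor"), each = n_arm)
    libfac <- exp(stats::rnorm(2 * n_arm, 0, 0.15))
    mu <- 2^(base_log2 + outer(fc, as.numeric(arm == "tumor"))) *
      rep(libfac, each = n_genes)
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / params$nb_dispersion),
                  n_genes, 2 * n_arm)
    ids <- sprintf("%s_%s%02d", types[t_idx],
                   ifelse(arm == "tumor", "t", "n"),
                   c(seq_len(n_arm), seq_len(n_arm)))
    colnames(cnt) <- ids
    counts <- if (is.null(counts)) cnt else cbind(counts, cnt)
    samples[[t_idx]] <- data.frame(sample_id = ids,
                                   tumor_type = types[t_idx], arm = arm,
                                   stringsAsFactors = FALSE)
  }
  rownames(counts) <- genes
  storage.mode(counts) <- "integer"
  list(counts = counts,
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
       truth = list(tumor_fc = fc_mat, base_log2 = base_log2))
}

#' Simulate the full study bundle and write it to disk
#'
#' Runs the three simulators off one master seed and writes the
#' pipeline-schema files \code{auc.csv}, \code{expression.csv} (long
#' format), \code{counts.tsv}, \code{samples.csv} and the ground-truth
#' long table \code{truth.csv}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param dir output directory (created if absent).
#' @return (invisibly) list with the in-memory objects, the combined
#'   truth, and the file paths.
#' @export
simulate_all <- function(params, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("output directory is not writable: ", dir)
  via <- simulate_viability(params)
  pert <- simulate_perturbation(params, via$truth)
  tum <- simulate_tumor_counts(params, pert$truth)
  truth <- c(via$truth, pert$truth, tum$truth)
  paths <- list(
    auc_table = file.path(dir, "auc.csv"),
    expression_table = file.path(dir, "expression.csv"),
    counts_table = file.path(dir, "counts.tsv"),
    sample_metadata = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.csv")
  )
  tsr_write_csv(via$records, paths$auc_table)
  write_expression_long(pert$dataset, paths$expression_table)
  tsr_write_counts(tum$counts, paths$counts_table)
  tsr_write_csv(tum$samples, paths$sample_metadata)
  tsr_write_csv(truth_long_table(truth), paths$truth)
  invisible(list(viability = via$records, perturbation = pert$dataset,
                 counts = tum$counts, samples = tum$samples,
                 truth = truth, paths = paths))
}

# Ground truth in long (entity, parameter, value) form: sufficient to
# recompute every planted quantity without re-reading the simulator.
truth_long_table <- function(truth) {
  rows <- list(
    data.frame(entity = truth$drug$drug_id, parameter = "d",
               value = truth$drug$d, stringsAsFactors = FALSE),
    data.frame(entity = truth$drug$drug_id, parameter = "active",
               value = as.numeric(truth$drug$active),
               stringsAsFactors = FALSE),
    data.frame(entity = truth$cell_line$cell_line_id, parameter = "c",
               value = truth$cell_line$c, stringsAsFactors = FALSE),
    data.frame(entity = truth$gene$gene_id, parameter = "gamma",
               value = truth$gene$gamma, stringsAsFactors = FALSE)
  )
  dl <- which(truth$delta != 0, arr.ind = TRUE)
  if (nrow(dl) > 0)
    rows <- c(rows, list(data.frame(
      entity = paste(colnames(truth$delta)[dl[, 2L]],
                     rownames(truth$delta)[dl[, 1L]], sep = ":"),
      parameter = "delta", value = truth$delta[dl],
      stringsAsFactors = FALSE
    )))
  fc <- truth$tumor_fc
  idx <- which(fc != 0, arr.ind = TRUE)
  if (nrow(idx) > 0)
    rows <- c(rows, list(data.frame(
      entity = paste(colnames(fc)[idx[, 2L]], rownames(fc)[idx[, 1L]],
                     sep = ":"),
      parameter = "tumor_fc", value = fc[idx], stringsAsFactors = FALSE
    )))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
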