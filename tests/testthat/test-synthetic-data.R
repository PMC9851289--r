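test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(n_drugs = 0), "n_drugs")
  expect_error(sim_params(frac_active_drugs = 1.2), "frac_active")
  expect_error(sim_params(n_program_genes = 50, n_genes = 40),
               "n_program_genes")
  expect_error(sim_params(n_tumor_types = 10, cell_lines_per_tumor_type = 10,
                          n_cell_lines_viability = 50), "too small")
  expect_error(sim_params(sigma_drug = -1), "sigma_drug")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("noiseless inactive viability is exactly auc = 1", {
  p <- sim_params(n_drugs = 6, n_cell_lines_viability = 8,
                  n_tumor_types = 2, cell_lines_per_tumor_type = 4,
                  sigma_drug = 0, sigma_cellline = 0, sigma_resid = 0,
                  frac_active_drugs = 0, seed = 5)
  via <- simulate_viability(p)
  expect_equal(via$records$auc, rep(1, nrow(via$records)))
  expect_equal(via$truth$drug$d, rep(0, 6))
})

test_that("active drugs have lower mean log AUC than inactive drugs", {
  p <- sim_params(n_drugs = 80, n_cell_lines_viability = 30,
                  n_tumor_types = 3, cell_lines_per_tumor_type = 10,
                  frac_active_drugs = 0.3, mu_active = -0.5, seed = 23)
  via <- simulate_viability(p)
  mean_log <- tapply(log(via$records$auc), via$records$drug_id, mean)
  act <- via$truth$drug$active[match(names(mean_log),
                                     via$truth$drug$drug_id)]
  expect_lt(mean(mean_log[act]), mean(mean_log[!act]))
})

test_that("a single-drug table is valid and the missingness mask thins rows", {
  p <- sim_params(n_drugs = 1, n_cell_lines_viability = 6,
                  n_tumor_types = 1, cell_lines_per_tumor_type = 6,
                  seed = 2)
  via <- simulate_viability(p)
  expect_equal(nrow(via$records), 6L)
  pm <- sim_params(n_drugs = 20, n_cell_lines_viability = 20,
                   n_tumor_types = 2, cell_lines_per_tumor_type = 10,
                   missing_frac = 0.4, seed = 3)
  vm <- simulate_viability(pm)
  expect_lt(nrow(vm$records), 400L)
  expect_gt(nrow(vm$records), 150L)
})

test_that("the simulated AUC distribution is centered near 1 at the default mixture", {
  # the record median is dominated by the finite drug draw, so the
  # distributional property is asserted at a drug count where the
  # median's sampling noise is small relative to the band
  p <- sim_params(n_drugs = 2000, n_cell_lines_viability = 30,
                  n_tumor_types = 1, cell_lines_per_tumor_type = 1,
                  seed = 404)
  via <- simulate_viability(p)
  expect_gt(median(via$records$auc), 0.95)
  expect_lt(median(via$records$auc), 1.05)
  # the potent minority skews the log-AUC distribution to the left
  expect_lt(mean(log(via$records$auc)), median(log(via$records$auc)))
})

test_that("the perturbation response follows the hinge in the noiseless limit", {
  p <- sim_params(n_drugs = 10, n_cell_lines_viability = 8,
                  n_tumor_types = 2, cell_lines_per_tumor_type = 4,
                  n_cell_lines_expr = 2, n_genes = 30, n_program_genes = 10,
                  n_mechanism_genes_per_drug = 0,
                  sigma_expr_cellline = 0, sigma_expr_plate = 0,
                  sigma_expr_resid = 0, n_replicates = 1, seed = 77)
  via <- simulate_viability(p)
  pert <- simulate_perturbation(p, via$truth)
  ds <- pert$dataset
  gamma <- pert$truth$gene$gamma
  baseline <- pert$truth$gene$baseline
  hinge <- pmax(0, -log(via$truth$drug$mnauc_true))
  for (i in c(1, 4, 9)) {
    drug <- via$truth$drug$drug_id[i]
    rows <- which(ds$meta$treatment == drug & ds$meta$duration_h == 6)
    dmso <- which(ds$meta$treatment == "DMSO" & ds$meta$duration_h == 6 &
                    ds$meta$cell_line_id %in%
                      ds$meta$cell_line_id[rows])
    diff <- colMeans(ds$values[rows, , drop = FALSE]) -
      colMeans(ds$values[dmso, , drop = FALSE])
    expect_equal(unname(diff), gamma * hinge[i], tolerance = 1e-10)
  }
  # a drug with mnauc >= 1 leaves every non-mechanism gene untouched
  quiet <- which(via$truth$drug$mnauc_true >= 1)[1]
  expect_false(is.na(quiet))
  drug <- via$truth$drug$drug_id[quiet]
  rows <- which(ds$meta$treatment == drug & ds$meta$duration_h == 24)
  dmso <- which(ds$meta$treatment == "DMSO" & ds$meta$duration_h == 24)
  diff <- colMeans(ds$values[rows, , drop = FALSE]) -
    colMeans(ds$values[dmso, , drop = FALSE])
  expect_equal(unname(diff), rep(0, p$n_genes), tolerance = 1e-10)
})

test_that("program slopes carry both signs and are zero off the program", {
  p <- sim_params(n_genes = 50, n_program_genes = 12, seed = 31)
  via <- simulate_viability(p)
  pert <- simulate_perturbation(p, via$truth)
  g <- pert$truth$gene
  expect_equal(sum(g$gamma != 0), 12L)
  expect_true(any(g$gamma > 0) && any(g$gamma < 0))
  expect_true(all(g$gamma[!g$program] == 0))
})

test_that("simulated fold changes track potency with the program sign", {
  p <- sim_params(n_drugs = 60, n_cell_lines_viability = 24,
                  n_tumor_types = 3, cell_lines_per_tumor_type = 8,
                  n_genes = 40, n_program_genes = 10,
                  n_mechanism_genes_per_drug = 0, gamma_scale = 1,
                  sigma_expr_resid = 0.3, seed = 41)
  via <- simulate_viability(p)
  pert <- simulate_perturbation(p, via$truth)
  sig <- fit_gene_signature(filter_experiments(pert$dataset)[["24h"]],
                            "24h")
  mn <- compute_mnauc(fit_crossed_intercepts(via$records))
  assoc <- gene_mnauc_correlation(sig, mn)
  g <- pert$truth$gene
  for (gid in g$gene_id[g$program][1:5]) {
    rho <- assoc$spearman_rho[assoc$gene_id == gid]
    # positive slope genes rise under potent (low mnAUC) drugs: rho < 0
    expect_equal(sign(rho), -sign(g$gamma[g$gene_id == gid]))
  }
})

test_that("tumor counts have the planted shape and sign structure", {
  p <- sim_params(n_drugs = 10, n_cell_lines_viability = 9,
                  n_tumor_types = 3, cell_lines_per_tumor_type = 3,
                  n_genes = 60, n_program_genes = 10,
                  n_tumor_samples_per_arm = 3, seed = 13)
  via <- simulate_viability(p)
  pert <- simulate_perturbation(p, via$truth)
  tum <- simulate_tumor_counts(p, pert$truth)
  expect_equal(dim(tum$counts), c(60L, 3L * 6L))
  expect_equal(nrow(tum$samples), 18L)
  expect_equal(unname(table(tum$samples$tumor_type)), rep(6L, 3L) ,
               ignore_attr = TRUE)
  gamma <- pert$truth$gene$gamma
  fc <- tum$truth$tumor_fc
  for (tt in colnames(fc)) {
    prog <- gamma != 0
    expect_equal(unname(fc[prog, tt]),
                 unname(p$tumor_effect_size * sign(-gamma[prog])))
  }
  # zero effect size removes the program from the tumors
  p0 <- sim_params(n_drugs = 10, n_cell_lines_viability = 9,
                   n_tumor_types = 3, cell_lines_per_tumor_type = 3,
                   n_genes = 60, n_program_genes = 10,
                   tumor_effect_size = 0, n_tumor_samples_per_arm = 3,
                   seed = 13)
  tum0 <- simulate_tumor_counts(p0, pert$truth)
  expect_true(all(tum0$truth$tumor_fc[gamma != 0, ] == 0))
})

test_that("the written bundle round-trips through the pipeline readers", {
  p <- sim_params(n_drugs = 6, n_cell_lines_viability = 8,
                  n_tumor_types = 2, cell_lines_per_tumor_type = 4,
                  n_cell_lines_expr = 5, n_genes = 12, n_program_genes = 4,
                  n_tumor_samples_per_arm = 3, seed = 9)
  dir <- withr::local_tempdir()
  bundle <- simulate_all(p, dir)
  rec <- read_auc_table(bundle$paths$auc_table)
  expect_equal(nrow(rec), nrow(bundle$viability))
  expect_equal(rec$auc, bundle$viability$auc, tolerance = 1e-15)
  ds <- read_expression_long(bundle$paths$expression_table)
  expect_equal(dim(ds$values), dim(bundle$perturbation$values))
  expect_equal(ds$values[bundle$perturbation$meta$experiment_id, ],
               bundle$perturbation$values, tolerance = 1e-15)
  cm <- read_counts_matrix(bundle$paths$counts_table)
  expect_identical(unname(cm), unname(bundle$counts))
  truth <- tsr_read_csv(bundle$paths$truth)
  # the truth file suffices to recompute the planted quantities
  d <- truth$value[truth$parameter == "d"]
  expect_equal(d, bundle$truth$drug$d, tolerance = 1e-15)
  gam <- truth$value[truth$parameter == "gamma"]
  expect_equal(gam[gam != 0], bundle$truth$gene$gamma[
    bundle$truth$gene$gamma != 0], tolerance = 1e-15)
})

test_that("stage substreams are stable when later stages change", {
  p1 <- sim_params(n_drugs = 8, n_cell_lines_viability = 8,
                   n_tumor_types = 2, cell_lines_per_tumor_type = 4,
                   n_genes = 10, n_program_genes = 4, seed = 55)
  p2 <- sim_params(n_drugs = 8, n_cell_lines_viability = 8,
                   n_tumor_types = 2, cell_lines_per_tumor_type = 4,
                   n_genes = 20, n_program_genes = 4, seed = 55)
  v1 <- simulate_viability(p1)
  v2 <- simulate_viability(p2)
  # viability draws do not depend on the expression-stage gene count
  expect_equal(v1$records$auc, v2$records$auc)
})
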