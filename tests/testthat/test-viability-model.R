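test_that("constant viability gives the boundary fit: zero effects and variances", {
  records <- expand.grid(drug_id = paste0("d", 1:4),
                         cell_line_id = paste0("c", 1:3),
                         stringsAsFactors = FALSE)
  records$auc <- 1
  fit <- fit_crossed_intercepts(records)
  expect_equal(fit$fixef, 0, tolerance = 1e-10)
  expect_equal(unname(fit$ranef$f1), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(fit$ranef$f2), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(fit$varcomp[["sigma2_f1"]]), 0)
  expect_equal(unname(fit$varcomp[["sigma2_f2"]]), 0)
  mn <- compute_mnauc(fit)
  expect_equal(mn$mnauc, rep(1, 4), tolerance = 1e-8)
})

test_that("noiseless balanced additive data reproduce the planted effects", {
  d <- c(-0.4, -0.1, 0, 0.2, 0.3)
  cl <- c(-0.15, -0.05, 0.05, 0.15)
  grid <- expand.grid(i = seq_along(d), j = seq_along(cl))
  records <- data.frame(
    drug_id = paste0("d", grid$i), cell_line_id = paste0("c", grid$j),
    auc = exp(0.1 + d[grid$i] + cl[grid$j]), stringsAsFactors = FALSE
  )
  fit <- fit_crossed_intercepts(records)
  # effects recovered up to the identifiability constant in the intercept
  # (residual variance sits on the zero boundary, so shrinkage vanishes)
  est_d <- fit$ranef$f1[paste0("d", seq_along(d))]
  expect_equal(unname(est_d - mean(est_d)), d - mean(d), tolerance = 1e-4)
  est_c <- fit$ranef$f2[paste0("c", seq_along(cl))]
  expect_equal(unname(est_c - mean(est_c)), cl - mean(cl), tolerance = 1e-4)
  # residual variance collapses to the boundary
  expect_lt(fit$varcomp[["sigma2_resid"]], 1e-8)
  # mnauc equals each drug's geometric-mean auc (balanced design)
  mn <- compute_mnauc(fit)
  geo <- tapply(log(records$auc), records$drug_id, mean)
  expect_equal(mn$mnauc, as.numeric(exp(geo[mn$drug_id])),
               tolerance = 1e-4)
})

test_that("REML and BLUPs match the dense brute-force oracle on an unbalanced design", {
  set.seed(42)
  nd <- 30L
  nc <- 20L
  d <- rnorm(nd, 0, 0.3)
  cl <- rnorm(nc, 0, 0.15)
  grid <- expand.grid(i = seq_len(nd), j = seq_len(nc))
  grid <- grid[runif(nrow(grid)) > 0.15, ]
  y <- 0.05 + d[grid$i] + cl[grid$j] + rnorm(nrow(grid), 0, 0.2)
  f1 <- paste0("d", sprintf("%02d", grid$i))
  f2 <- paste0("c", sprintf("%02d", grid$j))
  X <- matrix(1, length(y), 1)
  fit <- lmm_crossed(y, X, f1, f2)
  orc <- oracle_crossed_reml(y, X, f1, f2)
  expect_equal(fit$loglik_restricted, orc$loglik, tolerance = 1e-6)
  expect_equal(fit$fixef, orc$fixef, tolerance = 1e-6)
  expect_equal(unname(fit$ranef$f1[names(orc$u1)]), unname(orc$u1),
               tolerance = 1e-6)
  expect_equal(unname(fit$ranef$f2[names(orc$u2)]), unname(orc$u2),
               tolerance = 1e-6)
})

test_that("REML agrees with lme4 on a random crossed design", {
  skip_if_not_installed("lme4")
  set.seed(7)
  grid <- expand.grid(i = 1:15, j = 1:10)
  grid <- grid[runif(nrow(grid)) > 0.2, ]
  df <- data.frame(
    drug = paste0("d", grid$i), cell = paste0("c", grid$j),
    y = rnorm(15)[grid$i] * 0.5 + rnorm(10)[grid$j] * 0.2 +
      rnorm(nrow(grid), 0, 0.3))
  fit <- lmm_crossed(df$y, matrix(1, nrow(df), 1), df$drug, df$cell)
  m <- lme4::lmer(y ~ 1 + (1 | drug) + (1 | cell), df, REML = TRUE)
  expect_equal(-2 * fit$loglik_restricted, lme4::REMLcrit(m),
               tolerance = 1e-5)
  expect_equal(fit$fixef, unname(lme4::fixef(m)[1]), tolerance = 1e-4)
  re <- lme4::ranef(m)
  expect_equal(unname(fit$ranef$f1[rownames(re$drug)]), re$drug[[1]],
               tolerance = 1e-4)
})

test_that("BLUPs shrink towards zero relative to raw drug means", {
  set.seed(11)
  grid <- expand.grid(i = 1:12, j = 1:8)
  y <- rnorm(12, 0, 0.4)[grid$i] + rnorm(nrow(grid), 0, 0.3)
  f1 <- paste0("d", grid$i)
  fit <- lmm_crossed(y, matrix(1, length(y), 1), f1, paste0("c", grid$j))
  raw <- tapply(y, f1, mean) - fit$fixef
  blup <- fit$ranef$f1[names(raw)]
  expect_true(all(abs(blup) <= abs(raw) + 1e-8))
})

test_that("mnAUC is invariant to row order and cell-line relabeling", {
  set.seed(3)
  grid <- expand.grid(i = 1:8, j = 1:6)
  records <- data.frame(
    drug_id = paste0("d", grid$i),
    cell_line_id = paste0("c", grid$j),
    auc = exp(rnorm(nrow(grid), 0, 0.3)), stringsAsFactors = FALSE)
  mn1 <- compute_mnauc(fit_crossed_intercepts(records))
  shuffled <- records[sample(nrow(records)), ]
  shuffled$cell_line_id <- paste0("zz_", shuffled$cell_line_id)
  mn2 <- compute_mnauc(fit_crossed_intercepts(shuffled))
  expect_equal(mn1$mnauc, mn2$mnauc[match(mn1$drug_id, mn2$drug_id)],
               tolerance = 1e-7)
})

test_that("mnauc identity and degenerate designs are enforced", {
  records <- data.frame(drug_id = c("a", "a"), cell_line_id = c("x", "y"),
                        auc = c(0.5, 0.7))
  expect_error(fit_crossed_intercepts(records), "degenerate")
  records2 <- data.frame(drug_id = c("a", "b"), cell_line_id = c("x", "x"),
                         auc = c(0.5, 0.7))
  expect_error(fit_crossed_intercepts(records2), "degenerate")
  records3 <- data.frame(drug_id = c("a", "b"), cell_line_id = c("x", "y"),
                         auc = c(0.5, -0.1))
  expect_error(fit_crossed_intercepts(records3), "positive")
})

test_that("mnauc equals exp(intercept + drug effect) to machine precision", {
  set.seed(8)
  grid <- expand.grid(i = 1:6, j = 1:5)
  records <- data.frame(
    drug_id = paste0("d", grid$i), cell_line_id = paste0("c", grid$j),
    auc = exp(rnorm(nrow(grid), -0.1, 0.25)), stringsAsFactors = FALSE)
  fit <- fit_crossed_intercepts(records)
  mn <- compute_mnauc(fit)
  expect_identical(mn$mnauc, exp(mn$intercept + mn$drug_ranef))
  expect_true(all(mn$mnauc > 0))
})

test_that("tumor-type subsets partition records and skip small panels", {
  set.seed(12)
  grid <- expand.grid(i = 1:10, j = 1:12)
  records <- data.frame(
    drug_id = paste0("d", grid$i), cell_line_id = paste0("c", grid$j),
    tumor_type = c(rep("TT1", 6), rep("TT2", 4), NA, NA)[grid$j],
    auc = exp(rnorm(nrow(grid), 0, 0.2)), stringsAsFactors = FALSE)
  mn <- mnauc_by_tumor_type(records, min_cell_lines = 4L)
  expect_setequal(unique(mn$subset_label),
                  c("all", "TT1", "TT2", "excl:TT1", "excl:TT2"))
  # one tumor type holding all cell lines reproduces the full fit
  rec_one <- records
  rec_one$tumor_type <- "TT1"
  mn_one <- mnauc_by_tumor_type(rec_one, min_cell_lines = 4L,
                                include_excl = FALSE)
  all_fit <- mn_one[mn_one$subset_label == "all", ]
  tt_fit <- mn_one[mn_one$subset_label == "TT1", ]
  expect_equal(all_fit$mnauc,
               tt_fit$mnauc[match(all_fit$drug_id, tt_fit$drug_id)],
               tolerance = 1e-9)
  # small panels are skipped with a warning
  rec_small <- records
  rec_small$tumor_type[rec_small$cell_line_id == "c7"] <- "TT3"
  w <- capture_warnings(mnauc_by_tumor_type(rec_small,
                                            min_cell_lines = 4L))
  expect_true(any(grepl("TT3", w)))
})
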