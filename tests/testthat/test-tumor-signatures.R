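test_that("expression filter keeps genes at the boundary and drops below", {
  counts <- rbind(a = rep(63, 4), b = rep(62, 4),
                  c = c(1000, 1200, 900, 1100), d = rep(2, 4),
                  e = rep(100, 4))
  kept <- filter_genes(counts)
  expect_setequal(rownames(kept), c("a", "c", "e"))
  expect_equal(nrow(filter_genes(counts[c("c", "e", "a", "b", "d"), ])), 3L)
})

test_that("upper-quartile factors are scale-invariant and match a hand oracle", {
  m <- matrix(c(10, 20, 30, 40,
                20, 40, 60, 80,
                5, 100, 10, 1), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  f <- upperquartile_factors(m)
  # proportional samples (s2 = 2 * s1) share a factor
  expect_equal(unname(f["s1"]), unname(f["s2"]), tolerance = 1e-12)
  # hand computation: q75 of nonzero counts (type-7 quantile) / libsize,
  # rescaled to geometric mean 1
  q <- apply(m, 2, function(x) quantile(x[x > 0], 0.75, names = FALSE))
  raw <- q / colSums(m)
  expect_equal(unname(f), unname(raw / exp(mean(log(raw)))),
               tolerance = 1e-12)
  # permuting genes leaves the factors unchanged
  expect_equal(upperquartile_factors(m[c(3, 1, 4, 2), ]), f)
  bad <- cbind(m, s4 = c(0, 0, 0, 0))
  expect_error(upperquartile_factors(bad), "s4")
})

test_that("upper-quartile factors agree with edgeR on zero-free matrices", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  m <- matrix(rpois(200 * 6, lambda = 150), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  f <- upperquartile_factors(m)
  fe <- edgeR::calcNormFactors(m, method = "upperquartile")
  expect_equal(unname(f), unname(fe), tolerance = 1e-10)
})

test_that("noiseless balanced counts give log2fc equal to logCPM group difference", {
  n <- 8
  arm <- rep(c(0, 1), each = n / 2)
  counts <- rbind(g1 = c(rep(400, 4), rep(1600, 4)),
                  g2 = rep(800, 8),
                  g3 = c(rep(1000, 4), rep(250, 4)),
                  g4 = rep(640, 8))
  fac <- rep(1, 8)
  # near-zero sample variances trigger an expected moderation warning
  de <- suppressWarnings(precision_weighted_de(counts, fac, arm))
  elib <- colSums(counts)
  logcpm <- t(log2(t(counts + 0.5) / (elib + 1) * 1e6))
  manual <- rowMeans(logcpm[, arm == 1]) - rowMeans(logcpm[, arm == 0])
  expect_equal(de$log2fc, unname(manual), tolerance = 1e-10)
})

test_that("precision-weighted DE matches the limma voom pipeline on noisy data", {
  skip_if_not_installed("edgeR")
  set.seed(77)
  G <- 120
  n <- 12
  arm <- rep(c(0, 1), each = n / 2)
  mu <- 2^runif(G, 6, 11)
  fc <- ifelse(runif(G) < 0.2, sample(c(-1.5, 1.5), G, TRUE), 0)
  m <- t(vapply(seq_len(G), function(g)
    rnbinom(n, mu = mu[g] * 2^(fc[g] * arm), size = 20), numeric(n)))
  rownames(m) <- paste0("g", seq_len(G))
  fac <- upperquartile_factors(m)
  mine <- precision_weighted_de(m, fac, arm)
  design <- cbind(1, arm)
  v <- limma::voom(m, design, lib.size = colSums(m) * fac)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  expect_equal(mine$log2fc, tab$logFC, tolerance = 1e-8)
  expect_equal(mine$t_stat, tab$t, tolerance = 1e-6)
  expect_equal(mine$p, tab$P.Value, tolerance = 1e-6)
  expect_equal(mine$p_adj, tab$adj.P.Val, tolerance = 1e-6)
})

test_that("type-I error is calibrated on null count data", {
  set.seed(202)
  reps <- 40
  G <- 25
  pvals <- numeric(0)
  for (r in seq_len(reps)) {
    mu <- 2^runif(G, 6.5, 10)
    m <- t(vapply(seq_len(G), function(g)
      rnbinom(10, mu = mu[g], size = 20), numeric(10)))
    rownames(m) <- paste0("g", seq_len(G))
    de <- precision_weighted_de(m, upperquartile_factors(m),
                                rep(c(0, 1), each = 5))
    pvals <- c(pvals, de$p)
  }
  rate <- mean(pvals < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / length(pvals))
  expect_gt(rate, 0.05 - band - 0.01)
  expect_lt(rate, 0.05 + band + 0.01)
})

test_that("planted fold changes are recovered with the right sign", {
  set.seed(303)
  G <- 100
  n <- 20
  arm <- rep(c(0, 1), each = 10)
  planted <- sample(G, 10)
  fc <- numeric(G)
  fc[planted] <- 2 * sample(c(-1, 1), 10, TRUE)
  mu <- 2^runif(G, 7, 10)
  m <- t(vapply(seq_len(G), function(g)
    rnbinom(n, mu = mu[g] * 2^(fc[g] * arm), size = 20), numeric(n)))
  rownames(m) <- paste0("g", seq_len(G))
  de <- precision_weighted_de(m, upperquartile_factors(m), arm)
  agree <- sign(de$log2fc[planted]) == sign(fc[planted])
  expect_gt(mean(agree), 0.95)
})

test_that("BH adjustment matches a direct step-up implementation", {
  set.seed(13)
  for (r in 1:20) {
    p <- runif(sample(5:60, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # the DE output's p_adj is BH of its own p-values
  m <- matrix(rpois(50 * 8, 500), 50, 8,
              dimnames = list(paste0("g", 1:50), NULL))
  de <- precision_weighted_de(m, rep(1, 8), rep(c(0, 1), each = 4))
  expect_equal(de$p_adj, oracle_bh(de$p), tolerance = 1e-12)
  expect_true(all(de$p_adj >= de$p - 1e-15))
})

test_that("signature selection applies the scenario rules", {
  stats <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(2.0, -1.6, 1.4, 1.7, -2.2, 0.3),
    p = c(1e-5, 5e-5, 1e-6, 2e-4, 1e-7, 0.8),
    p_adj = c(1e-4, 5e-4, 1e-5, 2e-3, 1e-6, 0.9),
    stringsAsFactors = FALSE)
  lm_genes <- stats$gene_id
  sel <- select_signature(stats, "fc_adjp", lm_genes)
  expect_setequal(sel$up_genes, "g1")
  expect_setequal(sel$down_genes, c("g2", "g5"))
  # topK exhausts the available genes when K exceeds them
  sel50 <- select_signature(stats, "top50", lm_genes)
  expect_equal(length(sel50$up_genes) + length(sel50$down_genes), 6L)
  # landmark restriction applies before selection
  sel_lm <- select_signature(stats, "top50", c("g1", "g2"))
  expect_setequal(c(sel_lm$up_genes, sel_lm$down_genes), c("g1", "g2"))
  # empty fc_adjp selection is flagged, not an error
  weak <- stats
  weak$p_adj <- 0.5
  expect_true(select_signature(weak, "fc_adjp", lm_genes)$empty)
})

test_that("topK signatures are nested and p-ties break by |log2fc| then gene id", {
  set.seed(5)
  stats <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    log2fc = rnorm(200, 0, 2),
    p = signif(runif(200), 2), stringsAsFactors = FALSE)
  stats$p_adj <- p.adjust(stats$p, "BH")
  lm_genes <- stats$gene_id
  gs <- function(s) c(s$up_genes, s$down_genes)
  s50 <- gs(select_signature(stats, "top50", lm_genes))
  s100 <- gs(select_signature(stats, "top100", lm_genes))
  s150 <- gs(select_signature(stats, "top150", lm_genes))
  expect_true(all(s50 %in% s100))
  expect_true(all(s100 %in% s150))
  # tie rule: equal p resolved by larger |log2fc|, then lexicographic id
  tie <- data.frame(gene_id = c("gB", "gA", "gC"),
                    log2fc = c(1, -2, 1), p = c(0.01, 0.01, 0.01),
                    p_adj = c(0.01, 0.01, 0.01), stringsAsFactors = FALSE)
  # K = 1 via top50 on a 1-slot problem is not expressible; check ordering
  # through the selected composition at the boundary instead
  sel <- select_signature(tie, "top50", tie$gene_id)
  expect_setequal(gs(sel), c("gA", "gB", "gC"))
  expect_identical(sel$down_genes, "gA")
})
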