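test_that("size factors reproduce the median-of-ratios hand computation", {
  m <- matrix(c(10L, 30L, 50L, 20L, 60L, 100L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  # every gene's counts are (c, 2c): geometric mean c*sqrt(2), so the ratio
  # columns are 1/sqrt(2) and sqrt(2) for every gene
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  # identical samples -> all factors 1
  m2 <- cbind(s1 = c(5L, 8L), s2 = c(5L, 8L), s3 = c(5L, 8L))
  rownames(m2) <- c("g1", "g2")
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # scale equivariance: multiplying one column by 10 multiplies its factor
  # tenfold relative to the others (the factors are defined up to the
  # geometric-mean reference, so the invariant lives in the ratios)
  m3 <- m2; m3[, 2] <- m3[, 2] * 10L
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3 / sf3[1]), c(1, 10, 1), tolerance = 1e-12)
  # no all-nonzero gene -> actionable error, pseudo-reference fallback works
  m4 <- cbind(s1 = c(0L, 8L), s2 = c(5L, 0L), s3 = c(5L, 8L))
  rownames(m4) <- c("g1", "g2")
  expect_error(size_factors(m4), "pseudo_reference")
  expect_length(size_factors(m4, pseudo_reference = TRUE), 3)
})

test_that("dispersion estimation recovers truth and handles limit cases", {
  set.seed(21)
  n <- 400; reps <- 50
  mu <- exp(runif(n, log(50), log(500)))
  counts <- matrix(rnbinom(n * reps, mu = rep(mu, reps), size = 1 / 0.1),
                   n, reps, dimnames = list(paste0("g", 1:n),
                                            paste0("s", 1:reps)))
  meta <- validate_metadata(data.frame(
    sample_id = colnames(counts), genotype = "col0", treatment = "none",
    time_hpi = 0, experiment = 1, replicate = seq_len(reps)))
  sf <- size_factors(counts)
  a <- estimate_dispersion(counts, meta, sf, shrink_weight = 0)
  expect_gt(median(a), 0.08)
  expect_lt(median(a), 0.12)
  # Poisson data -> dispersion near zero; constant gene -> exactly zero raw
  pois <- matrix(rpois(n * reps, rep(mu, reps)), n, reps,
                 dimnames = dimnames(counts))
  pois[1, ] <- 100L  # constant gene
  ap <- estimate_dispersion(pois, meta, size_factors(pois),
                            shrink_weight = 0)
  expect_lt(median(ap), 0.01)
  # single-replicate design carries no dispersion information
  m1 <- counts[, 1:2]
  meta1 <- validate_metadata(data.frame(
    sample_id = colnames(m1), genotype = "col0",
    treatment = c("none", "EV"), time_hpi = c(0, 4),
    experiment = 1, replicate = 1))
  expect_error(estimate_dispersion(m1, meta1, size_factors(m1)),
               "dispersion cannot be estimated")
})

test_that("Wald p-value agrees with an independent Poisson GLM fit", {
  # 2 vs 2 toy at dispersion zero; the oracle is a GLM fitted by IRLS. The
  # closed-form Wald statistic is checked against the GLM's own Wald test;
  # the GLM's likelihood-ratio test (which is genuinely sharper than Wald at
  # counts this small) must agree on direction and significance.
  counts <- matrix(c(10L, 12L, 40L, 44L), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:4)))
  meta <- validate_metadata(data.frame(
    sample_id = colnames(counts), genotype = "col0",
    treatment = rep(c("EV", "AvrRps4"), each = 2), time_hpi = 4,
    experiment = 1, replicate = rep(1:2, 2)))
  sf <- setNames(rep(1, 4), colnames(counts))
  tab <- nb_wald_test(counts, meta, sf, setNames(0, "g1"),
                      contrast_spec("col0", 4, "AvrRps4", "EV_same_time"))
  fit1 <- glm(c(10, 12, 40, 44) ~ rep(c(0, 1), each = 2), family = poisson())
  wald <- summary(fit1)$coefficients[2, ]
  p_wald <- 2 * pnorm(-abs(wald[["z value"]]))
  expect_lt(abs(log10(tab$p_value) - log10(p_wald)), 0.3)
  p_lrt <- anova(fit1, test = "Chisq")[["Pr(>Chi)"]][2]
  expect_lt(p_lrt, 0.05)
  expect_lt(tab$p_value, 0.05)
  expect_equal(tab$log2_fc, log2(42.5 / 11.5), tolerance = 1e-10)
})

test_that("the Wald test is calibrated under the null", {
  nd <- null_counts(n = 3000, dispersion = 0.05, seed = 19)
  sf <- size_factors(nd$counts)
  disp <- estimate_dispersion(nd$counts, nd$meta, sf)
  tab <- nb_wald_test(nd$counts, nd$meta, sf, disp,
                      contrast_spec("col0", 4, "AvrRps4", "EV_same_time"))
  frac <- mean(tab$p_value[tab$tested] < 0.05)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
  # null log2 fold changes are centred on zero
  expect_lt(abs(median(tab$log2_fc[tab$tested])), 0.05)
})

test_that("power rises with effect size and with replication", {
  power_at <- function(lfc, reps, seed = 31) {
    set.seed(seed)
    n <- 400
    mu <- rep(100, n)
    g1 <- matrix(rnbinom(n * reps, mu = mu, size = 1 / 0.05), n, reps)
    g2 <- matrix(rnbinom(n * reps, mu = mu * 2^lfc, size = 1 / 0.05), n, reps)
    counts <- cbind(g1, g2)
    dimnames(counts) <- list(paste0("g", 1:n),
                             paste0("s", seq_len(2 * reps)))
    meta <- validate_metadata(data.frame(
      sample_id = colnames(counts), genotype = "col0",
      treatment = rep(c("EV", "AvrRps4"), each = reps), time_hpi = 4,
      experiment = 1, replicate = rep(seq_len(reps), 2)))
    sf <- setNames(rep(1, ncol(counts)), colnames(counts))
    disp <- estimate_dispersion(counts, meta, sf)
    tab <- nb_wald_test(counts, meta, sf, disp,
                        contrast_spec("col0", 4, "AvrRps4", "EV_same_time"))
    degs <- call_degs(tab)
    length(degs$up) / n
  }
  p_small <- power_at(1.2, 4)
  p_mid <- power_at(2, 4)
  p_big <- power_at(3, 4)
  expect_true(p_small <= p_mid && p_mid <= p_big)
  expect_gt(p_big, 0.9)
  expect_lte(power_at(1.5, 3), power_at(1.5, 6))
})

test_that("BH adjustment matches an exhaustive step-up oracle", {
  bh_oracle <- function(p) {
    # independent step-up: sort, scale by m/i, enforce monotonicity, cap
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling uses strict thresholds and is threshold-monotone", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    base_mean = 50, log2_fc = c(1.1, 1.0, 5, -1.2),
                    se_log2_fc = 0.1, stat = 1,
                    p_value = c(0.001, 0.001, 0.05, 0.001),
                    p_adjusted = c(0.04, 0.04, 0.05, 0.01),
                    dispersion = 0.05, tested = TRUE)
  class(tab) <- c("de_table", class(tab))
  degs <- call_degs(tab, run_config())
  expect_equal(degs$up, "a")     # b: fold change not > 2; c: p_adj not < 0.05
  expect_equal(degs$down, "d")
  looser <- call_degs(tab, run_config(alpha_fdr = 0.2))
  expect_true(all(degs$up %in% looser$up))
  expect_true(length(looser$up) >= length(degs$up))
})

test_that("z-score matrix is standardized, rank-preserving and zero-safe", {
  set.seed(4)
  counts <- matrix(rpois(200, 50), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  counts[1, ] <- 7L  # constant gene (constant after unit-factor scaling)
  sf <- setNames(rep(1, 10), colnames(counts))
  z <- vst_zscore(counts, sf)
  expect_equal(unname(rowMeans(z)), rep(0, 20), tolerance = 1e-9)
  expect_equal(unname(apply(z[-1, ], 1, sd)), rep(1, 19), tolerance = 1e-9)
  expect_true(all(z[1, ] == 0))
  # and with genuine size factors the standardization still holds
  sf2 <- size_factors(counts)
  z2 <- vst_zscore(counts, sf2)
  expect_equal(unname(rowMeans(z2)), rep(0, 20), tolerance = 1e-9)
  norm <- normalize_counts(counts, sf2)
  for (g in 2:5)
    expect_equal(order(z2[g, ]), order(norm[g, ]))
})

test_that("fold-change estimates agree with an established NB DE package", {
  # independent cross-check of the bespoke test against DESeq2 on planted
  # effects (the packages differ in shrinkage, so agreement is directional
  # and correlational, not numeric identity)
  set.seed(77)
  n <- 300; reps <- 6
  lfc <- c(rep(0, 250), runif(50, 1.5, 3) * sample(c(-1, 1), 50, TRUE))
  mu <- exp(runif(n, log(50), log(500)))
  g1 <- matrix(rnbinom(n * reps, mu = mu, size = 1 / 0.05), n, reps)
  g2 <- matrix(rnbinom(n * reps, mu = mu * 2^lfc, size = 1 / 0.05), n, reps)
  counts <- cbind(g1, g2)
  dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:12))
  meta <- validate_metadata(data.frame(
    sample_id = colnames(counts), genotype = "col0",
    treatment = rep(c("EV", "AvrRps4"), each = reps), time_hpi = 4,
    experiment = rep(1:3, 4), replicate = rep(1:2, 6)))
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, meta, sf)
  tab <- nb_wald_test(counts, meta, sf, disp,
                      contrast_spec("col0", 4, "AvrRps4", "EV_same_time"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, data.frame(group = factor(rep(c("EV", "eff"), each = reps),
                                        levels = c("EV", "eff"))),
      ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  expect_gt(cor(tab$log2_fc, res$log2FoldChange, use = "complete.obs"), 0.95)
  ours <- call_degs(tab, run_config())
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                            abs(res$log2FoldChange) > 1]
  both <- union(ours$up, ours$down)
  jac <- length(intersect(both, theirs)) / length(union(both, theirs))
  expect_gt(jac, 0.8)
})
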