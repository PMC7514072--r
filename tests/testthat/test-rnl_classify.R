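test_that("the decision table maps all 16 flag combinations exhaustively", {
  # brute force over every DE-flag outcome with the wild type DE
  seen <- character()
  for (a in c(TRUE, FALSE)) for (n in c(TRUE, FALSE))
    for (h in c(TRUE, FALSE)) {
      flags <- c(col0 = TRUE, adr1_triple = a, nrg1_double = n,
                 helperless = h)
      cat <- classify_gene(flags)
      expect_true(cat %in% RNL_CATEGORIES)
      if (h) expect_equal(cat, "RNL_INDEPENDENT")
      seen <- c(seen, cat)
      # and with col0 = FALSE the gene is never ETI
      flags[["col0"]] <- FALSE
      expect_equal(classify_gene(flags), "NOT_ETI")
    }
  expect_setequal(seen, RNL_CATEGORIES)
  # the worked examples of the category definitions
  expect_equal(classify_gene(c(col0 = TRUE, adr1_triple = TRUE,
                               nrg1_double = TRUE, helperless = TRUE)),
               "RNL_INDEPENDENT")
  expect_equal(classify_gene(c(col0 = TRUE, adr1_triple = FALSE,
                               nrg1_double = FALSE, helperless = FALSE)),
               "SYNERGISTIC")
  expect_equal(classify_gene(c(col0 = TRUE, adr1_triple = TRUE,
                               nrg1_double = TRUE, helperless = FALSE)),
               "REDUNDANT")
  expect_equal(classify_gene(c(col0 = TRUE, adr1_triple = FALSE,
                               nrg1_double = TRUE, helperless = FALSE)),
               "ADR1_SPECIFIC")
  expect_equal(classify_gene(c(col0 = TRUE, adr1_triple = TRUE,
                               nrg1_double = FALSE, helperless = FALSE)),
               "NRG1_SPECIFIC")
  expect_error(classify_gene(c(col0 = TRUE)), "complete")
})

test_that("fraction reports reproduce the printed worked example", {
  r <- report_from_counts(table1_counts$AvrRps4_4, "AvrRps4", 4)
  expect_equal(r$n_eti, 560)
  expect_equal(r$n_rnl_dependent, 486)
  expect_equal(r$rnl_dependent_pct, 86.8)
  expect_equal(r$synergistic_pct, 63.6)
  expect_equal(r$redundant_pct, 3.5)
  expect_equal(r$shared_pct, 67.1)
  expect_equal(r$specific_pct, 32.9)
  expect_equal(r$adr1_of_specific_pct, 74.4)
  expect_equal(r$nrg1_of_specific_pct, 25.6)
  # conservation and complementarity invariants
  expect_equal(r$n_rnl_dependent,
               r$n_synergistic + r$n_redundant + r$n_adr1_specific +
                 r$n_nrg1_specific)
  expect_equal(r$n_eti, r$n_rnl_dependent + r$n_rnl_independent)
  expect_equal(r$shared_pct + r$specific_pct, 100, tolerance = 0.1)
  # empty input: zero counts, undefined (not zero) percentages
  e <- fraction_report(character(0), "AvrRps4", 4, "up")
  expect_equal(e$n_eti, 0)
  expect_true(is.na(e$rnl_dependent_pct))
  expect_true(is.na(e$synergistic_pct))
})

test_that("percentages round half-up to one decimal", {
  expect_equal(round_half_up(74.375, 1), 74.4)
  expect_equal(round_half_up(86.785, 1), 86.8)
  expect_equal(round_half_up(0.05, 1), 0.1)   # base round() gives 0 here
  expect_equal(round_half_up(2.25, 1), 2.3)   # base round() gives 2.2
  expect_equal(round_half_up(-2.25, 1), -2.3)
})

test_that("venn region counts match a brute-force membership oracle", {
  expect_equal(unname(venn_counts(list(A = letters[1:3], B = letters[4:7]))),
               c(3, 4, 0))
  same <- venn_counts(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(unname(same), c(0, 0, 5))
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:3, 1)
    sets <- lapply(seq_len(k), function(j)
      sample(letters[1:20], sample(0:12, 1)))
    names(sets) <- LETTERS[seq_len(k)]
    got <- venn_counts(sets)
    u <- unique(unlist(sets))
    for (nm in names(got)) {
      inside <- strsplit(nm, "&", fixed = TRUE)[[1]]
      outside <- setdiff(names(sets), inside)
      expected <- sum(vapply(u, function(el) {
        all(vapply(inside, function(s) el %in% sets[[s]], TRUE)) &&
          !any(vapply(outside, function(s) el %in% sets[[s]], TRUE))
      }, TRUE))
      expect_equal(unname(got[nm]), expected)
    }
    # region sums reconstruct set cardinalities
    for (s in names(sets)) {
      regions <- got[vapply(names(got), function(nm)
        s %in% strsplit(nm, "&", fixed = TRUE)[[1]], TRUE)]
      expect_equal(sum(regions), length(unique(sets[[s]])))
    }
  }
  expect_error(venn_counts(list(a = "x")), "2 or 3")
})

test_that("ETI set selectors enforce their domain", {
  sim <- sim_default()
  expect_error(eti_regulated(sim$contrasts$degs, "col0", "AvrRps4", 0.5),
               "4 and 8 hpi")
  expect_error(eti_regulated(sim$contrasts$degs, "col0", "EV", 4),
               "effector")
  s <- eti_regulated(sim$contrasts$degs, "col0", "AvrRps4", 8)
  expect_length(intersect(s$up, s$down), 0)
})

test_that("PTI induction is shared across genotypes", {
  sim <- sim_default()
  sets <- pti_sets(sim$contrasts$degs)
  up05 <- lapply(GENOTYPES, function(g) sets[[g]][["0.5"]]$up)
  # planted PTI genes respond in every genotype from 0.5 hpi, so pairwise
  # overlap of the 0.5-hpi EV-induced sets is high
  for (i in 1:3) for (j in (i + 1):4) {
    jac <- length(intersect(up05[[i]], up05[[j]])) /
      length(union(up05[[i]], up05[[j]]))
    expect_gt(jac, 0.5)
  }
  # strong planted PTI effects are recovered with high sensitivity at 4 hpi
  pti_up <- sim$truth$gene_id[sim$truth$klass == "PTI_induced" &
                                sim$truth$direction == "up"]
  for (g in GENOTYPES) {
    sens <- mean(pti_up %in% sets[[g]][["4"]]$up)
    expect_gt(sens, 0.9)
  }
})

test_that("ETI set size scales with the planted gene count", {
  # plant ETI genes responsive to one effector so that the wild-type
  # effector-vs-EV set at 8 hpi should recover about 1,449 genes
  n_eti <- 1449
  p <- sim_params(n_genes = round(n_eti / 0.1), p_shared_scope = 1,
                  seed = 23)
  design <- full_design(genotypes = "col0", treatments = c("EV", "AvrRps4"),
                        times = 8)
  sim <- simulate_dataset(p, design)
  res <- run_contrasts(sim$counts, sim$design, run_config(),
                       times_pti = numeric(0))
  s <- eti_regulated(res$degs, "col0", "AvrRps4", 8)
  planted <- nrow(planted_eti(sim$truth, "AvrRps4", 8))
  expect_equal(planted, n_eti, tolerance = 0.01)
  expect_equal(length(s$up) + length(s$down), planted, tolerance = 0.1)
})

test_that("no planted signal yields an FDR-controlled empty ETI set", {
  p <- sim_params(n_genes = 2000,
                  class_proportions = c(background = 1, PTI_induced = 0,
                                        ETI = 0), seed = 29)
  design <- full_design(genotypes = "col0", treatments = c("EV", "AvrRps4"),
                        times = 8)
  sim <- simulate_dataset(p, design)
  res <- run_contrasts(sim$counts, sim$design, run_config(),
                       times_pti = numeric(0))
  s <- eti_regulated(res$degs, "col0", "AvrRps4", 8)
  expect_lte(length(s$up) + length(s$down), 2)
})

test_that("planted categories are recovered on the default fixture", {
  sim <- sim_default()
  acc <- category_recovery(sim, "AvrRps4", 8)
  expect_gt(acc, 0.85)
  # binary RNL-dependent vs independent accuracy, among recovered ETI genes
  hits <- 0L; tot <- 0L
  for (dir in c("up", "down")) {
    a <- classify_eti_genes(sim$contrasts$degs, "AvrRps4", 8, dir)
    tru <- planted_eti(sim$truth, "AvrRps4", 8, dir)
    m <- merge(a, tru[, c("gene_id", "rnl_category")], by = "gene_id")
    hits <- hits + sum((m$category == "RNL_INDEPENDENT") ==
                         (m$rnl_category == "RNL_INDEPENDENT"))
    tot <- tot + nrow(m)
  }
  expect_gt(hits / tot, 0.95)
})

test_that("recovery degrades monotonically with weaker effects", {
  acc_full <- category_recovery(sim_default(), "AvrRps4", 8)
  acc_half <- category_recovery(sim_half_effect(), "AvrRps4", 8)
  expect_lte(acc_half, acc_full)
})
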