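# Shared fixtures, built once per test run. All randomness is seeded through
# sim_params() so the suite is deterministic.

options(rnleti.quiet = TRUE)

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# desk-scale dataset at the default study conditions (2,000 genes, 2 samples
# x 3 experiments = 6 replicates per condition) plus all design contrasts
sim_default <- function() {
  memo("sim_default", function() {
    params <- sim_params(seed = 42)
    sim <- simulate_dataset(params, full_design())
    sim$contrasts <- run_contrasts(sim$counts, sim$design, run_config())
    sim
  })
}

# same conditions with halved planted effect sizes (degradation checks)
sim_half_effect <- function() {
  memo("sim_half_effect", function() {
    params <- sim_params(effect_range = c(1, 2), seed = 42)
    sim <- simulate_dataset(params, full_design())
    sim$contrasts <- run_contrasts(sim$counts, sim$design, run_config())
    sim
  })
}

# truth rows planted as ETI genes responsive to an effector at a time/direction
planted_eti <- function(truth, effector, time_hpi, direction = NULL) {
  rows <- truth$klass == "ETI" &
    vapply(strsplit(truth$effectors, ","), function(s) effector %in% s, TRUE) &
    truth$onset_hpi <= time_hpi
  if (!is.null(direction)) rows <- rows & truth$direction == direction
  truth[rows, , drop = FALSE]
}

# fraction of planted ETI genes assigned their planted category
category_recovery <- function(sim, effector = "AvrRps4", time_hpi = 8) {
  hits <- 0L
  planted <- 0L
  for (dir in c("up", "down")) {
    a <- classify_eti_genes(sim$contrasts$degs, effector, time_hpi, dir)
    tru <- planted_eti(sim$truth, effector, time_hpi, dir)
    planted <- planted + nrow(tru)
    m <- merge(a, tru[, c("gene_id", "rnl_category")], by = "gene_id")
    hits <- hits + sum(m$category == m$rnl_category)
  }
  hits / planted
}

# simple null count matrix: n genes, two 6-sample groups, equal means
null_counts <- function(n = 5000, dispersion = 0.05, seed = 11) {
  set.seed(seed)
  mu <- exp(runif(n, log(20), log(500)))
  counts <- matrix(rnbinom(n * 12, mu = rep(mu, 12), size = 1 / dispersion),
                   n, 12, dimnames = list(paste0("g", seq_len(n)),
                                          paste0("s", 1:12)))
  meta <- validate_metadata(data.frame(
    sample_id = colnames(counts), genotype = "col0",
    treatment = rep(c("EV", "AvrRps4"), each = 6), time_hpi = 4,
    experiment = rep(1:3, 4), replicate = rep(1:2, 6)))
  list(counts = counts, meta = meta)
}

# counts printed in the study's fraction-accounting table, one column per
# (effector, time): total ETI-regulated genes and the four dependent
# category counts (RNL-independent is the remainder)
table1_counts <- list(
  AvrRps4_4 = c(eti = 560,  syn = 309, red = 17,  adr1 = 119, nrg1 = 41),
  AvrRps4_8 = c(eti = 1449, syn = 512, red = 330, adr1 = 407, nrg1 = 155),
  AvrRpt2_4 = c(eti = 883,  syn = 192, red = 56,  adr1 = 132, nrg1 = 37),
  AvrRpt2_8 = c(eti = 1831, syn = 164, red = 129, adr1 = 103, nrg1 = 67),
  AvrRpm1_4 = c(eti = 1712, syn = 349, red = 98,  adr1 = 137, nrg1 = 83),
  AvrRpm1_8 = c(eti = 2725, syn = 203, red = 96,  adr1 = 79,  nrg1 = 80))

report_from_counts <- function(cnt, effector = NA, time_hpi = NA) {
  dep <- cnt[["syn"]] + cnt[["red"]] + cnt[["adr1"]] + cnt[["nrg1"]]
  fraction_report(rep(c("SYNERGISTIC", "REDUNDANT", "ADR1_SPECIFIC",
                        "NRG1_SPECIFIC", "RNL_INDEPENDENT"),
                      c(cnt[["syn"]], cnt[["red"]], cnt[["adr1"]],
                        cnt[["nrg1"]], cnt[["eti"]] - dep)),
                  effector, time_hpi, "up")
}
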