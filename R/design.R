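# Controlled vocabulary for the factorial design and the single shared
# definition of which genotypes express an ETI effect in each RNL-dependency
# category. Both the simulator and the classifier use this map, so the two
# can never drift apart.

#' Design vocabulary
#'
#' Constant vectors naming the genotypes, treatments, sampling times,
#' effectors and RNL-dependency categories of the four-genotype ETI design.
#'
#' @format Character (or numeric, for times) vectors.
#' @name design-vocabulary
NULL

#' @rdname design-vocabulary
#' @export
GENOTYPES <- c("col0", "adr1_triple", "nrg1_double", "helperless")

#' @rdname design-vocabulary
#' @export
TREATMENTS <- c("none", "EV", "AvrRps4", "AvrRpt2", "AvrRpm1")

#' @rdname design-vocabulary
#' @export
EFFECTORS <- c("AvrRps4", "AvrRpt2", "AvrRpm1")

#' @rdname design-vocabulary
#' @export
TIMES_HPI <- c(0, 0.5, 4, 8)

#' @rdname design-vocabulary
#' @export
RNL_CATEGORIES <- c("RNL_INDEPENDENT", "SYNERGISTIC", "REDUNDANT",
                    "ADR1_SPECIFIC", "NRG1_SPECIFIC")

# token -> canonical genotype; keys are lowercased with [ ._-] stripped
.genotype_aliases <- c(
  "col0"            = "col0",
  "columbia0"       = "col0",
  "wt"              = "col0",
  "adr1triple"      = "adr1_triple",
  "adr1adr1l1adr1l2" = "adr1_triple",
  "nrg1double"      = "nrg1_double",
  "nrg11nrg12"      = "nrg1_double",
  "helperless"      = "helperless"
)

.squash <- function(x) gsub("[ ._-]", "", tolower(x))

#' Normalize genotype and treatment tokens
#'
#' Maps common spellings (`"Col-0"`, `"col0"`, `"adr1 triple"`,
#' `"nrg1.1 nrg1.2"`, `"Pf0-EV"`, ...) onto the canonical tokens in
#' [GENOTYPES] and [TREATMENTS].
#'
#' @param x Character vector of tokens.
#' @return Character vector of canonical tokens.
#' @examples
#' normalize_genotype(c("Col-0", "col0", "nrg1.1 nrg1.2"))
#' normalize_treatment(c("Pf0-EV", "avrrps4", "none"))
#' @export
normalize_genotype <- function(x) {
  key <- .squash(x)
  out <- unname(.genotype_aliases[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown genotype token(s): ", paste(unique(x[bad]), collapse = ", "),
         "; allowed: ", paste(GENOTYPES, collapse = ", "),
         " (plus common spellings such as 'Col-0', 'adr1 triple', 'nrg1.1 nrg1.2')",
         call. = FALSE)
  }
  out
}

#' @rdname normalize_genotype
#' @export
normalize_treatment <- function(x) {
  key <- sub("^pf0", "", .squash(x))
  key[key == ""] <- "none"
  lut <- c(none = "none", mock = "none", ev = "EV",
           avrrps4 = "AvrRps4", avrrpt2 = "AvrRpt2", avrrpm1 = "AvrRpm1")
  out <- unname(lut[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown treatment token(s): ", paste(unique(x[bad]), collapse = ", "),
         "; allowed: ", paste(TREATMENTS, collapse = ", "), call. = FALSE)
  }
  out
}

#' Genotypes expressing an ETI effect for each RNL-dependency category
#'
#' The behavioural signature of each category: in which genotypes an
#' ETI-regulated gene of that category is differentially expressed in the
#' effector-vs-EV contrast. This single map drives both the count simulator
#' (where the planted effect is applied) and defines the decision table the
#' classifier must invert.
#'
#' * `RNL_INDEPENDENT`: effect in all four genotypes (survives loss of all RNLs);
#' * `SYNERGISTIC`: effect only in Col-0 (lost in either family's mutant);
#' * `REDUNDANT`: effect in Col-0 and both single-family mutants, lost only in
#'   `helperless` (either family suffices);
#' * `ADR1_SPECIFIC`: effect lost in `adr1_triple` (and `helperless`), kept in
#'   `nrg1_double`;
#' * `NRG1_SPECIFIC`: the mirror image.
#'
#' @param category One of [RNL_CATEGORIES].
#' @return Character vector of genotype tokens.
#' @examples
#' category_genotypes("ADR1_SPECIFIC")
#' @export
category_genotypes <- function(category) {
  category <- match.arg(category, RNL_CATEGORIES)
  switch(category,
    RNL_INDEPENDENT = GENOTYPES,
    SYNERGISTIC     = "col0",
    REDUNDANT       = c("col0", "adr1_triple", "nrg1_double"),
    ADR1_SPECIFIC   = c("col0", "nrg1_double"),
    NRG1_SPECIFIC   = c("col0", "adr1_triple"))
}

#' Build the full factorial sample design
#'
#' Enumerates the study design: per genotype one untreated time-0 condition
#' plus each bacterial treatment at 0.5, 4 and 8 hpi, sampled in
#' `n_replicates` samples within each of `n_experiments` independent
#' experiments (the study design is 2 samples x 3 experiments).
#'
#' @param genotypes,treatments Subsets of [GENOTYPES] / [TREATMENTS]
#'   (`"none"` is implied and must not be listed).
#' @param times Post-infiltration times in hours; subset of `c(0.5, 4, 8)`.
#' @param n_experiments,n_replicates Integers >= 1.
#' @return A data frame of sample metadata with columns `sample_id`,
#'   `genotype`, `treatment`, `time_hpi`, `experiment`, `replicate`.
#' @examples
#' nrow(full_design())  # 4 * (1 + 3*4) * 3 * 2 = 312
#' @export
full_design <- function(genotypes = GENOTYPES,
                        treatments = c("EV", EFFECTORS),
                        times = c(0.5, 4, 8),
                        n_experiments = 3, n_replicates = 2) {
  genotypes <- normalize_genotype(genotypes)
  treatments <- normalize_treatment(treatments)
  stopifnot(!"none" %in% treatments, all(times %in% c(0.5, 4, 8)),
            n_experiments >= 1, n_replicates >= 1)
  cond <- rbind(
    data.frame(treatment = "none", time_hpi = 0),
    expand.grid(treatment = treatments, time_hpi = times,
                stringsAsFactors = FALSE))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      experiment = seq_len(n_experiments),
                      ci = seq_len(nrow(cond)),
                      genotype = genotypes,
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    genotype   = grid$genotype,
    treatment  = cond$treatment[grid$ci],
    time_hpi   = cond$time_hpi[grid$ci],
    experiment = grid$experiment,
    replicate  = grid$replicate,
    stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_t%s_e%d_r%d", meta$genotype,
                            meta$treatment, meta$time_hpi,
                            meta$experiment, meta$replicate)
  validate_metadata(meta[, c("sample_id", "genotype", "treatment",
                             "time_hpi", "experiment", "replicate")])
}
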