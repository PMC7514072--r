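# Five-way RNL-dependency classification of ETI-regulated genes from their
# DEG status across the four genotypes, plus PTI/ETI set derivation, the
# fraction-accounting report mirroring the study's headline table, and Venn
# region counts.

.deg_key <- function(genotype, treatment, time_hpi, denominator) {
  sprintf("%s_%s_t%s_vs_%s", genotype, treatment, time_hpi,
          if (denominator == "EV_same_time") "EV" else "t0")
}

.get_degs <- function(deg_calls, key) {
  if (is.null(deg_calls[[key]]))
    stop("missing DEG calls for contrast '", key, "'", call. = FALSE)
  deg_calls[[key]]
}

#' PTI-induced gene sets per genotype and time
#'
#' Returns, for every genotype/time combination, the genes induced (and
#' repressed) by the empty-vector infiltration relative to the genotype's
#' untreated time-0 samples.
#'
#' @param deg_calls Named list of [call_degs()] results keyed by contrast
#'   label (as produced by [run_contrasts()]).
#' @param genotypes,times The combinations to collect.
#' @return Nested list: `[[genotype]][[as.character(time)]]` is a `deg_sets`
#'   object.
#' @export
pti_sets <- function(deg_calls, genotypes = GENOTYPES,
                     times = c(0.5, 4, 8)) {
  out <- lapply(stats::setNames(genotypes, genotypes), function(g) {
    lapply(stats::setNames(as.character(times), as.character(times)),
           function(t) .get_degs(deg_calls,
                                 .deg_key(g, "EV", as.numeric(t),
                                          "time_zero")))
  })
  out
}

#' ETI-regulated gene set for a genotype, effector and time
#'
#' The DEG set of the effector-vs-EV contrast at the matched time; the
#' study's "ETI-regulated" set is this set for Col-0. With
#' `mode = "set_difference"`, the set is instead the effector-vs-time0 DEG
#' set minus the EV-vs-time0 DEG set (same direction). ETI sets are defined
#' at 4 and 8 hpi only: NLR activation effects on expression only become
#' visible from 4 hpi.
#'
#' @param deg_calls Named list of [call_degs()] results.
#' @param genotype,effector,time_hpi Condition selectors.
#' @param mode `"contrast"` (default) or `"set_difference"`.
#' @return List with character vectors `up` and `down`.
#' @export
eti_regulated <- function(deg_calls, genotype, effector, time_hpi,
                          mode = c("contrast", "set_difference")) {
  mode <- match.arg(mode)
  genotype <- normalize_genotype(genotype)
  effector <- normalize_treatment(effector)
  if (!effector %in% EFFECTORS)
    stop("effector must be one of ", paste(EFFECTORS, collapse = ", "),
         call. = FALSE)
  if (!time_hpi %in% c(4, 8))
    stop("ETI-regulated sets are defined at 4 and 8 hpi only", call. = FALSE)
  if (mode == "contrast") {
    d <- .get_degs(deg_calls, .deg_key(genotype, effector, time_hpi,
                                       "EV_same_time"))
    list(up = d$up, down = d$down)
  } else {
    eff <- .get_degs(deg_calls, .deg_key(genotype, effector, time_hpi,
                                         "time_zero"))
    ev <- .get_degs(deg_calls, .deg_key(genotype, "EV", time_hpi,
                                        "time_zero"))
    list(up = setdiff(eff$up, ev$up), down = setdiff(eff$down, ev$down))
  }
}

#' Classify one gene's RNL dependency from its DE flags
#'
#' Decision table over the gene's DE status (same direction, same
#' effector-vs-EV contrast) in the four genotypes:
#' not DE in Col-0 -> `NOT_ETI`; DE in `helperless` -> `RNL_INDEPENDENT`;
#' otherwise DE in neither single-family mutant -> `SYNERGISTIC` (both
#' families required), in both -> `REDUNDANT` (either suffices), DE only in
#' `nrg1_double` -> `ADR1_SPECIFIC`, DE only in `adr1_triple` ->
#' `NRG1_SPECIFIC`.
#'
#' @param de_flags Named logical vector with exactly the names in
#'   [GENOTYPES].
#' @return One of `"NOT_ETI"` or [RNL_CATEGORIES].
#' @examples
#' classify_gene(c(col0 = TRUE, adr1_triple = FALSE,
#'                 nrg1_double = TRUE, helperless = FALSE))  # ADR1_SPECIFIC
#' @export
classify_gene <- function(de_flags) {
  if (!setequal(names(de_flags), GENOTYPES) || anyNA(de_flags))
    stop("de_flags must be a complete named logical over: ",
         paste(GENOTYPES, collapse = ", "), call. = FALSE)
  f <- de_flags[GENOTYPES]
  if (!f[["col0"]]) return("NOT_ETI")
  if (f[["helperless"]]) return("RNL_INDEPENDENT")
  adr1_ok <- f[["adr1_triple"]]  # DE despite loss of ADR1s
  nrg1_ok <- f[["nrg1_double"]]
  if (!adr1_ok && !nrg1_ok) return("SYNERGISTIC")
  if (adr1_ok && nrg1_ok) return("REDUNDANT")
  if (!adr1_ok) return("ADR1_SPECIFIC")
  "NRG1_SPECIFIC"
}

#' Classify all ETI-regulated genes for one effector/time/direction
#'
#' Builds each gene's DE-status vector across the four genotypes from the
#' directional effector-vs-EV DEG sets and applies [classify_gene()]. Genes
#' DE in a mutant with the opposite sign to Col-0 are treated as not DE for
#' this direction (and counted in the `opposite_sign` attribute).
#'
#' @param deg_calls Named list of [call_degs()] results.
#' @param effector,time_hpi,direction Condition selectors; `direction` is
#'   `"up"` or `"down"`.
#' @param mode Passed to [eti_regulated()].
#' @return Data frame `gene_id`, `effector`, `time_hpi`, `direction`,
#'   `category` over the Col-0 ETI-regulated genes of that direction.
#' @export
classify_eti_genes <- function(deg_calls, effector, time_hpi,
                               direction = c("up", "down"),
                               mode = c("contrast", "set_difference")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  opp <- if (direction == "up") "down" else "up"
  sets <- lapply(stats::setNames(GENOTYPES, GENOTYPES), function(g)
    eti_regulated(deg_calls, g, effector, time_hpi, mode))
  genes <- sets$col0[[direction]]
  n_opp <- 0L
  cat <- vapply(genes, function(gene) {
    flags <- vapply(GENOTYPES, function(g) {
      if (gene %in% sets[[g]][[opp]]) n_opp <<- n_opp + 1L
      gene %in% sets[[g]][[direction]]
    }, TRUE)
    classify_gene(flags)
  }, "")
  if (n_opp > 0)
    .log(sprintf(
      "%s %s hpi %s: %d mutant DE call(s) with opposite sign treated as not DE",
      effector, time_hpi, direction, n_opp))
  out <- data.frame(gene_id = genes, effector = effector,
                    time_hpi = time_hpi, direction = direction,
                    category = unname(cat), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "opposite_sign") <- n_opp
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), matching how the
#' study's percentages are printed, unlike base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fraction-accounting report for one effector, time and direction
#'
#' Counts per RNL category and the derived percentages: the RNL-dependent
#' fraction is relative to all ETI-regulated genes; shared (synergistic +
#' redundant), specific, synergistic and redundant percentages are relative
#' to the RNL-dependent count; the ADR1s/NRG1s split is relative to the
#' specific count. Percentages are rounded half-up to one decimal and are
#' `NA` (undefined, not 0) when their denominator is zero.
#'
#' @param assignments Character vector of categories (values in
#'   [RNL_CATEGORIES]; `NOT_ETI` entries are dropped), or a
#'   [classify_eti_genes()] data frame.
#' @param effector,time_hpi,direction Labels carried into the report.
#' @return List with class `"fraction_report"`: all counts (`n_eti`,
#'   `n_rnl_dependent`, `n_synergistic`, `n_redundant`, `n_adr1_specific`,
#'   `n_nrg1_specific`, `n_shared`, `n_specific`) and percentages
#'   (`rnl_dependent_pct`, `shared_pct`, `specific_pct`, `synergistic_pct`,
#'   `redundant_pct`, `adr1_of_specific_pct`, `nrg1_of_specific_pct`).
#' @examples
#' r <- fraction_report(rep(c("SYNERGISTIC", "REDUNDANT", "ADR1_SPECIFIC",
#'                            "NRG1_SPECIFIC", "RNL_INDEPENDENT"),
#'                          c(309, 17, 119, 41, 74)),
#'                      "AvrRps4", 4, "up")
#' r$rnl_dependent_pct  # 86.8
#' @export
fraction_report <- function(assignments, effector = NA, time_hpi = NA,
                            direction = NA) {
  if (is.data.frame(assignments)) {
    if (!is.na(assignments$effector[1])) effector <- assignments$effector[1]
    if (!is.na(assignments$time_hpi[1])) time_hpi <- assignments$time_hpi[1]
    if (!is.na(assignments$direction[1])) direction <- assignments$direction[1]
    assignments <- assignments$category
  }
  assignments <- assignments[assignments != "NOT_ETI"]
  bad <- setdiff(unique(assignments), RNL_CATEGORIES)
  if (length(bad))
    stop("unknown category value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- vapply(RNL_CATEGORIES, function(k) sum(assignments == k), 0L)
  n_eti <- length(assignments)
  n_dep <- n_eti - n[["RNL_INDEPENDENT"]]
  n_shared <- n[["SYNERGISTIC"]] + n[["REDUNDANT"]]
  n_spec <- n[["ADR1_SPECIFIC"]] + n[["NRG1_SPECIFIC"]]
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  structure(list(
    effector = effector, time_hpi = time_hpi, direction = direction,
    n_eti = n_eti, n_rnl_dependent = n_dep,
    n_rnl_independent = n[["RNL_INDEPENDENT"]],
    n_synergistic = n[["SYNERGISTIC"]], n_redundant = n[["REDUNDANT"]],
    n_adr1_specific = n[["ADR1_SPECIFIC"]],
    n_nrg1_specific = n[["NRG1_SPECIFIC"]],
    n_shared = n_shared, n_specific = n_spec,
    rnl_dependent_pct = pct(n_dep, n_eti),
    shared_pct = pct(n_shared, n_dep),
    specific_pct = pct(n_spec, n_dep),
    synergistic_pct = pct(n[["SYNERGISTIC"]], n_dep),
    redundant_pct = pct(n[["REDUNDANT"]], n_dep),
    adr1_of_specific_pct = pct(n[["ADR1_SPECIFIC"]], n_spec),
    nrg1_of_specific_pct = pct(n[["NRG1_SPECIFIC"]], n_spec)),
    class = "fraction_report")
}

#' Venn region counts for two or three gene sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector over the `2^k - 1` exclusive regions; names
#'   join member set names with `&` and exclusion is relative to the listed
#'   sets (e.g. `"A"` counts elements in A only).
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2, 3)) stop("venn_counts needs 2 or 3 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  out <- integer(0)
  for (size in seq_len(k)) {
    combos <- utils::combn(names(sets), size, simplify = FALSE)
    for (cmb in combos) {
      inside <- rowSums(member[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(member[, setdiff(names(sets), cmb), drop = FALSE]) == 0
      out[paste(cmb, collapse = "&")] <- sum(inside)
    }
  }
  out
}
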