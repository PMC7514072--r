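# Factorial RNA-seq count simulator with planted PTI/ETI effects. Every
# downstream stage is benchmarked against this generator's ground truth, so
# the planted effect -> genotype mapping is taken from category_genotypes()
# and is therefore identical, by construction, to the map the classifier
# inverts.

#' Simulation parameters
#'
#' Defaults encode the study conditions: the full design is 27,206
#' protein-coding genes over 4 genotypes x (time 0 + 3 times x 4 treatments)
#' x 2 samples x 3 experiments; the desk-scale default used throughout the
#' tests is 2,000 genes. Planted RNL-category proportions echo the observed
#' 8-hpi fraction accounting for the fully RNL-dependent ETI (96.9%
#' RNL-dependent, of which 36.5% synergistic, 23.5% redundant and the
#' specific remainder split roughly 72/28 towards ADR1s).
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric over `background`, `PTI_induced`,
#'   `ETI`; must sum to 1.
#' @param rnl_proportions Named numeric over [RNL_CATEGORIES] (conditional on
#'   class ETI); must sum to 1.
#' @param effect_range Interval of |log2 fold change| for planted effects;
#'   lower bound >= 1 keeps every planted gene above the fold-change-2 calling
#'   threshold.
#' @param baseline_range Interval of baseline mean counts for signal genes
#'   (log-uniform draw); background genes use `background_range`.
#' @param background_range Baseline interval for background genes.
#' @param dispersion_model `c(asymptote, scale)` of the mean-dispersion trend
#'   alpha(mu) = asymptote + scale/mu.
#' @param library_size_range Interval of per-sample relative library-size
#'   factors (uniform draw).
#' @param batch_sd Standard deviation (log scale) of the per-experiment
#'   log-normal batch factor.
#' @param p_up Probability a planted effect is an induction (vs repression).
#' @param p_shared_scope Probability an ETI gene responds to all three
#'   effectors rather than a single one (ETI responses overlap extensively).
#' @param p_onset4 Probability an ETI gene's effect starts at 4 hpi (else 8).
#' @param pti_boost Extra log2 over-induction of PTI genes during effector
#'   infections (RNL-dependent for AvrRps4, RNL-independent otherwise); set
#'   to 0 to disable.
#' @param seed Integer seed.
#' @return List with class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 2000,
                       class_proportions = c(background = 0.80,
                                             PTI_induced = 0.10,
                                             ETI = 0.10),
                       rnl_proportions = c(RNL_INDEPENDENT = 0.031,
                                           SYNERGISTIC = 0.354,
                                           REDUNDANT = 0.228,
                                           ADR1_SPECIFIC = 0.281,
                                           NRG1_SPECIFIC = 0.106),
                       effect_range = c(2, 4),
                       baseline_range = c(50, 500),
                       background_range = c(0.5, 1000),
                       dispersion_model = c(asymptote = 0.01, scale = 1),
                       library_size_range = c(0.7, 1.3),
                       batch_sd = 0.1,
                       p_up = 0.6, p_shared_scope = 0.5, p_onset4 = 0.5,
                       pti_boost = 0.5, seed = 1) {
  p <- as.list(environment())
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (abs(sum(rnl_proportions) - 1) > 1e-9)
    stop("rnl_proportions must sum to 1", call. = FALSE)
  if (!setequal(names(class_proportions),
                c("background", "PTI_induced", "ETI")))
    stop("class_proportions must name background, PTI_induced, ETI",
         call. = FALSE)
  if (!setequal(names(rnl_proportions), RNL_CATEGORIES))
    stop("rnl_proportions must name all five RNL categories", call. = FALSE)
  if (effect_range[1] < 0 || diff(effect_range) < 0)
    stop("effect_range must be a non-negative increasing interval",
         call. = FALSE)
  if (batch_sd < 0) stop("batch_sd must be >= 0", call. = FALSE)
  class(p) <- "sim_params"
  p
}

# split n into integer counts proportional to p, summing exactly to n
.apportion <- function(n, p) {
  cum <- round(cumsum(p) / sum(p) * n)
  counts <- diff(c(0L, cum))
  stats::setNames(as.integer(counts), names(p))
}

.loguni <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Plant ground-truth gene classes
#'
#' Deterministically (under the seed) assigns each gene a class
#' (`background`, `PTI_induced`, `ETI`), and for ETI genes an effector scope,
#' an RNL-dependency category, a direction, an effect size and an onset time.
#' Category counts are within rounding of `n_genes * proportion`.
#'
#' @param params A [sim_params()] object.
#' @return Data frame (one row per gene) with columns `gene_id`, `klass`,
#'   `effectors` (comma-separated; empty unless ETI), `rnl_category`,
#'   `direction`, `log2_effect`, `baseline_mean`, `dispersion`, `onset_hpi`.
#' @export
plant_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  ncls <- .apportion(n, params$class_proportions[
    c("background", "PTI_induced", "ETI")])
  klass <- rep(names(ncls), ncls)
  truth <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    klass = klass,
    effectors = "",
    rnl_category = NA_character_,
    direction = ifelse(runif(n) < params$p_up, "up", "down"),
    log2_effect = runif(n, params$effect_range[1], params$effect_range[2]),
    baseline_mean = .loguni(n, params$baseline_range),
    dispersion = NA_real_,
    onset_hpi = 4,
    stringsAsFactors = FALSE)
  bg <- truth$klass == "background"
  truth$baseline_mean[bg] <- .loguni(sum(bg), params$background_range)
  truth$log2_effect[bg] <- 0
  truth$direction[bg] <- "up"
  pti <- truth$klass == "PTI_induced"
  truth$onset_hpi[pti] <- 0.5
  eti <- which(truth$klass == "ETI")
  if (length(eti)) {
    ncat <- .apportion(length(eti), params$rnl_proportions[RNL_CATEGORIES])
    truth$rnl_category[eti] <- sample(rep(names(ncat), ncat))
    shared <- runif(length(eti)) < params$p_shared_scope
    single <- sample(EFFECTORS, length(eti), replace = TRUE)
    truth$effectors[eti] <- ifelse(shared, paste(EFFECTORS, collapse = ","),
                                   single)
    truth$onset_hpi[eti] <- ifelse(runif(length(eti)) < params$p_onset4, 4, 8)
  }
  dm <- params$dispersion_model
  truth$dispersion <- dm[["asymptote"]] + dm[["scale"]] / truth$baseline_mean
  truth
}

# log2 effect of gene g in a sample with the given condition
.effect_matrix <- function(truth, design, params) {
  e <- matrix(0, nrow(truth), nrow(design),
              dimnames = list(truth$gene_id, design$sample_id))
  sgn <- ifelse(truth$direction == "up", 1, -1)
  scope <- strsplit(truth$effectors, ",", fixed = TRUE)
  cat_geno <- lapply(stats::setNames(RNL_CATEGORIES, RNL_CATEGORIES),
                     category_genotypes)
  for (j in seq_len(nrow(design))) {
    trt <- design$treatment[j]
    t <- design$time_hpi[j]
    g <- design$genotype[j]
    if (trt == "none") next
    active <- t >= truth$onset_hpi
    is_pti <- truth$klass == "PTI_induced" & active
    e[is_pti, j] <- e[is_pti, j] + sgn[is_pti] * truth$log2_effect[is_pti]
    if (trt %in% EFFECTORS) {
      # over-induction of PTI genes during ETI (lost in helperless when the
      # triggering ETI is fully RNL-dependent, i.e. AvrRps4)
      if (params$pti_boost > 0 &&
          !(trt == "AvrRps4" && g == "helperless")) {
        e[is_pti, j] <- e[is_pti, j] + sgn[is_pti] * params$pti_boost
      }
      is_eti <- truth$klass == "ETI" & active &
        vapply(scope, function(s) trt %in% s, TRUE)
      if (any(is_eti)) {
        in_geno <- vapply(truth$rnl_category, function(cc)
          !is.na(cc) && g %in% cat_geno[[cc]], TRUE)
        k <- is_eti & in_geno
        e[k, j] <- e[k, j] + sgn[k] * truth$log2_effect[k]
      }
    }
  }
  e
}

#' Simulate negative-binomial counts for a design
#'
#' Count of gene g in sample j is drawn from NB with mean
#' `baseline_mean_g * libfactor_j * batchfactor_exp(j) * 2^e(g, j)` and
#' dispersion `alpha_g` (variance `mu + alpha * mu^2`). The log2 effect
#' `e(g, j)` applies the planted PTI effect in every genotype for every
#' bacterial treatment from the gene's onset time, and the ETI effect on top
#' for the gene's effectors in the genotype set implied by its RNL category
#' (see [category_genotypes()]).
#'
#' @param truth Output of [plant_truth()].
#' @param design Sample metadata (see [full_design()]).
#' @param params The [sim_params()] object (seeds the draw).
#' @return Integer count matrix, genes x samples. Attributes `lib_factors`
#'   and `batch_factors` record the sampled nuisance factors.
#' @export
simulate_counts <- function(truth, design, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!nrow(design)) stop("design is empty", call. = FALSE)
  if (anyDuplicated(truth$gene_id))
    stop("truth gene ids must be unique", call. = FALSE)
  design <- validate_metadata(design)
  set.seed(params$seed + 1L)
  nlib <- runif(nrow(design), params$library_size_range[1],
                params$library_size_range[2])
  exps <- sort(unique(design$experiment))
  batch <- stats::setNames(rlnorm(length(exps), 0, params$batch_sd),
                           as.character(exps))
  e <- .effect_matrix(truth, design, params)
  mu <- truth$baseline_mean * 2^e
  mu <- sweep(mu, 2, nlib * batch[as.character(design$experiment)], `*`)
  size <- 1 / truth$dispersion
  counts <- matrix(0L, nrow(truth), nrow(design),
                   dimnames = dimnames(mu))
  for (j in seq_len(ncol(mu))) {
    pois <- !is.finite(size)
    col <- integer(nrow(mu))
    if (any(pois)) col[pois] <- rpois(sum(pois), mu[pois, j])
    if (any(!pois)) col[!pois] <- rnbinom(sum(!pois), mu = mu[!pois, j],
                                          size = size[!pois])
    counts[, j] <- col
  }
  attr(counts, "lib_factors") <- stats::setNames(nlib, design$sample_id)
  attr(counts, "batch_factors") <- batch
  counts
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [plant_truth()] then [simulate_counts()].
#'
#' @inheritParams simulate_counts
#' @return List with `truth`, `counts`, `design`, `params`.
#' @export
simulate_dataset <- function(params = sim_params(), design = full_design()) {
  truth <- plant_truth(params)
  counts <- simulate_counts(truth, design, params)
  list(truth = truth, counts = counts, design = design, params = params)
}

#' Write a fixture bundle
#'
#' Emits `counts.tsv`, `metadata.tsv`, `truth.tsv` and `params.json` into a
#' directory; the first two round-trip through [read_counts()] and
#' [read_metadata()].
#'
#' @param truth,counts,design As produced by [simulate_dataset()].
#' @param out_dir Output directory (created if absent).
#' @param params Optional [sim_params()] snapshot written as `params.json`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(truth, counts, design, out_dir, params = NULL) {
  if (!nrow(truth)) stop("empty truth table", call. = FALSE)
  if (!identical(rownames(counts), truth$gene_id))
    stop("counts rows and truth gene ids disagree", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             params = file.path(out_dir, "params.json"))
  write_counts(counts, paths[["counts"]])
  write_metadata(design, paths[["metadata"]])
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), paths[["params"]],
                         auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[names(paths) != "params"]
  }
  invisible(paths)
}
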