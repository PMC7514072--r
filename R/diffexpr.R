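# Negative-binomial differential expression: median-of-ratios size factors,
# pooled method-of-moments dispersion with mean-trend shrinkage, two-group NB
# Wald tests with BH correction, DEG calling at the FDR/fold-change
# thresholds, and the log-stabilized z-score matrix used for QC views.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of the gene's count to its across-sample geometric mean. Reference
#' genes are those with nonzero counts in every sample; with
#' `pseudo_reference = TRUE` genes nonzero in at least half the samples are
#' used instead (geometric means over their nonzero entries), for sparse
#' inputs without any all-nonzero gene.
#'
#' @param counts Integer count matrix, genes x samples (>= 2 samples).
#' @param pseudo_reference Fall back to the relaxed reference set.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    if (!pseudo_reference)
      stop("no gene has nonzero counts in every sample; ",
           "re-run with pseudo_reference = TRUE", call. = FALSE)
    ref <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(ref)) stop("counts too sparse even for the pseudo-reference",
                        call. = FALSE)
  }
  x <- counts[ref, , drop = FALSE]
  loggeo <- rowSums(ifelse(x > 0, log(x), 0)) / rowSums(x > 0)
  sf <- apply(x, 2, function(col) {
    r <- log(col[col > 0]) - loggeo[col > 0]
    exp(median(r))
  })
  stats::setNames(sf, colnames(counts))
}

#' Normalized counts
#'
#' @param counts Count matrix.
#' @param factors Size factors from [size_factors()].
#' @return Matrix of counts divided column-wise by the factors.
#' @export
normalize_counts <- function(counts, factors) {
  sweep(counts, 2, factors[colnames(counts)], `/`)
}

#' Per-gene dispersion by pooled method of moments
#'
#' Within each condition (genotype x treatment x time) with >= 2 replicates,
#' the moment estimate `(s^2 - mu) / mu^2` is computed on normalized counts;
#' estimates are pooled across conditions with weights `n_c - 1` and floored
#' at zero. A mean-dispersion trend `alpha(mu) = a0 + a1/mu` is then fitted
#' across genes and the raw estimates are shrunk towards it:
#' `alpha = (1 - w) * raw + w * trend`.
#'
#' @param counts Count matrix.
#' @param meta Sample metadata (validated as in [validate_metadata()]).
#' @param factors Size factors.
#' @param shrink_weight Trend shrinkage weight `w` in \[0, 1\]; 0 returns the
#'   raw pooled moment estimates.
#' @return Named non-negative numeric vector, one dispersion per gene, with
#'   attributes `trend` (the fitted `c(a0, a1)`) and `mean` (per-gene mean
#'   normalized count).
#' @export
estimate_dispersion <- function(counts, meta, factors, shrink_weight = 0.5) {
  stopifnot(shrink_weight >= 0, shrink_weight <= 1)
  norm <- normalize_counts(counts, factors)
  cond <- interaction(meta$genotype, meta$treatment, meta$time_hpi,
                      drop = TRUE)
  groups <- split(seq_len(nrow(meta)), cond)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups))
    stop("no condition has >= 2 replicates; dispersion cannot be estimated",
         call. = FALSE)
  num <- matrix(0, nrow(counts), 1)
  den <- 0
  mu_acc <- rep(0, nrow(counts))
  ns <- 0
  raw <- rep(0, nrow(counts))
  wsum <- 0
  for (idx in groups) {
    x <- norm[, idx, drop = FALSE]
    mu <- rowMeans(x)
    s2 <- rowSums((x - mu)^2) / (length(idx) - 1)
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    w <- length(idx) - 1
    raw <- raw + w * a
    wsum <- wsum + w
    mu_acc <- mu_acc + length(idx) * mu
    ns <- ns + length(idx)
  }
  raw <- pmax(0, raw / wsum)
  mu_bar <- mu_acc / ns
  ok <- mu_bar > 0
  fit <- lm(raw[ok] ~ I(1 / mu_bar[ok]))
  a0 <- max(coef(fit)[1], 1e-8)
  a1 <- max(coef(fit)[2], 0)
  trend <- a0 + a1 / pmax(mu_bar, 1e-8)
  alpha <- pmax((1 - shrink_weight) * raw + shrink_weight * trend, 1e-8)
  alpha[!ok] <- 0
  structure(stats::setNames(alpha, rownames(counts)),
            trend = c(a0 = a0, a1 = a1),
            mean = stats::setNames(mu_bar, rownames(counts)))
}

#' Specify a two-condition contrast
#'
#' Numerator is a treatment at a time within one genotype; denominator is
#' either the empty-vector control at the same time (`"EV_same_time"`) or the
#' genotype's untreated time-0 condition (`"time_zero"`).
#'
#' @param genotype One of [GENOTYPES].
#' @param time_hpi Time of the numerator condition (0.5, 4 or 8).
#' @param numerator Treatment of the numerator condition.
#' @param denominator `"EV_same_time"` or `"time_zero"`.
#' @param label Optional label; a canonical one is derived if absent.
#' @return List with class `"contrast_spec"`.
#' @export
contrast_spec <- function(genotype, time_hpi,
                          numerator,
                          denominator = c("EV_same_time", "time_zero"),
                          label = NULL) {
  genotype <- normalize_genotype(genotype)
  numerator <- normalize_treatment(numerator)
  denominator <- match.arg(denominator)
  if (!time_hpi %in% c(0.5, 4, 8))
    stop("contrast time must be 0.5, 4 or 8 hpi", call. = FALSE)
  if (numerator == "none")
    stop("numerator treatment cannot be 'none'", call. = FALSE)
  if (denominator == "EV_same_time" && numerator == "EV")
    stop("numerator and denominator conditions coincide", call. = FALSE)
  if (is.null(label)) {
    label <- sprintf("%s_%s_t%s_vs_%s", genotype, numerator, time_hpi,
                     if (denominator == "EV_same_time") "EV" else "t0")
  }
  structure(list(label = label, genotype = genotype, time_hpi = time_hpi,
                 numerator = numerator, denominator = denominator),
            class = "contrast_spec")
}

.contrast_samples <- function(meta, contrast) {
  num <- meta$genotype == contrast$genotype &
    meta$treatment == contrast$numerator &
    meta$time_hpi == contrast$time_hpi
  if (contrast$denominator == "EV_same_time") {
    den <- meta$genotype == contrast$genotype &
      meta$treatment == "EV" & meta$time_hpi == contrast$time_hpi
    den_desc <- sprintf("%s EV at %s hpi", contrast$genotype,
                        contrast$time_hpi)
  } else {
    den <- meta$genotype == contrast$genotype & meta$treatment == "none" &
      meta$time_hpi == 0
    den_desc <- sprintf("%s untreated at 0 hpi", contrast$genotype)
  }
  if (sum(num) < 2)
    stop("contrast '", contrast$label, "': numerator condition (",
         contrast$genotype, " ", contrast$numerator, " at ",
         contrast$time_hpi, " hpi) has fewer than 2 samples", call. = FALSE)
  if (sum(den) < 2)
    stop("contrast '", contrast$label, "': denominator condition (", den_desc,
         ") has fewer than 2 samples", call. = FALSE)
  list(num = which(num), den = which(den))
}

#' Negative-binomial Wald test for one contrast
#'
#' Per gene, group means are estimated on size-factor-normalized counts with
#' a moderation of +0.5 normalized counts per group (avoiding infinite fold
#' changes); `log2_fc = log2(m_num / m_den)`. The standard error follows the
#' NB variance `mu + alpha mu^2` propagated through the log ratio of group
#' means, the Wald statistic is `log2_fc / se`, and two-sided p-values come
#' from the normal reference. Genes whose mean normalized count across the
#' contrast's samples falls below `min_count_filter` are flagged
#' `tested = FALSE`, carry no p-values, and are excluded from the BH family.
#'
#' @param counts Count matrix.
#' @param meta Sample metadata.
#' @param factors Size factors.
#' @param dispersions Per-gene dispersion vector (see
#'   [estimate_dispersion()]).
#' @param contrast A [contrast_spec()].
#' @param min_count_filter Independent-filtering threshold on the base mean.
#' @return Data frame (class `"de_table"`) with columns `gene_id`,
#'   `base_mean`, `log2_fc`, `se_log2_fc`, `stat`, `p_value`, `p_adjusted`,
#'   `dispersion`, `tested`; the contrast is attached as attribute
#'   `"contrast"`.
#' @export
nb_wald_test <- function(counts, meta, factors, dispersions, contrast,
                         min_count_filter = 5) {
  idx <- .contrast_samples(meta, contrast)
  norm <- normalize_counts(counts, factors)
  alpha <- dispersions[rownames(counts)]
  grp_stats <- function(cols) {
    x <- norm[, cols, drop = FALSE]
    m <- rowMeans(x) + 0.5
    s <- factors[colnames(counts)[cols]]
    # Var(mean of k_i/s_i) for NB k_i with mean mu*s_i, dispersion alpha
    v <- (m %o% (1 / s) + alpha * m^2) %*% rep(1 / length(cols)^2,
                                               length(cols))
    list(m = m, v = drop(v))
  }
  g1 <- grp_stats(idx$num)
  g0 <- grp_stats(idx$den)
  log2_fc <- log2(g1$m / g0$m)
  se <- sqrt(g1$v / g1$m^2 + g0$v / g0$m^2) / log(2)
  stat <- log2_fc / se
  p <- 2 * pnorm(-abs(stat))
  base_mean <- rowMeans(norm[, c(idx$num, idx$den), drop = FALSE])
  tested <- base_mean >= min_count_filter
  p[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  if (any(tested)) padj[tested] <- bh_adjust(p[tested])
  out <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2_fc = log2_fc, se_log2_fc = se, stat = stat,
                    p_value = p, p_adjusted = padj,
                    dispersion = unname(alpha), tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_table", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "BH")`: step-up adjusted
#' values, monotone and capped at 1.
#'
#' @param p_values Numeric vector in \[0, 1\] (NA not allowed).
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated when `p_adjusted < alpha_fdr` and
#' `log2_fc > log2(fc_threshold)` (both strict); down-regulation is the
#' mirror image. Untested genes are never called.
#'
#' @param table A [nb_wald_test()] result.
#' @param config A [run_config()] (supplies `alpha_fdr`, `fc_threshold`).
#' @return List with character vectors `up` and `down` (disjoint), plus the
#'   thresholds used, class `"deg_sets"`.
#' @export
call_degs <- function(table, config = run_config()) {
  lfc <- log2(config$fc_threshold)
  ok <- table$tested & !is.na(table$p_adjusted) &
    table$p_adjusted < config$alpha_fdr
  up <- table$gene_id[ok & table$log2_fc > lfc]
  down <- table$gene_id[ok & table$log2_fc < -lfc]
  structure(list(up = up, down = down,
                 alpha_fdr = config$alpha_fdr,
                 fc_threshold = config$fc_threshold,
                 contrast = attr(table, "contrast")),
            class = "deg_sets")
}

#' Log-stabilized z-score matrix
#'
#' `log2(count / size_factor + 1)` per cell, then each gene standardized to
#' mean 0 and unit standard deviation along the samples; constant genes map
#' to all-zero rows.
#'
#' @param counts Count matrix (>= 2 samples).
#' @param factors Size factors.
#' @return Numeric matrix of the same shape.
#' @export
vst_zscore <- function(counts, factors) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  t <- log2(normalize_counts(counts, factors) + 1)
  mu <- rowMeans(t)
  s <- apply(t, 1, sd)
  z <- (t - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}
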