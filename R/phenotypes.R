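# Infection-phenotype statistics: disease index over 6 symptom categories,
# sporangiophore binning, cfu surface densities, total ROS by trapezoidal
# integration, and one-way ANOVA with Tukey HSD compact letter displays.

#' Disease index from a symptom tally
#'
#' Leaves are scored into six symptom categories (1 = no symptoms ...
#' 6 = fungal sporulation); with `n_i` the percentage of leaves in category
#' `i`, the disease index is `DI = sum(i * n_i)`, ranging from 100 (all
#' asymptomatic) to 600. With `scale = "fraction"`, `n_i` is a fraction and
#' DI ranges 1-6.
#'
#' @param tally Non-negative integer vector of length 6 (counts per
#'   category, in category order), with at least one leaf.
#' @param scale `"percent"` (the index's defining scale) or `"fraction"`.
#' @return The disease index.
#' @examples
#' disease_index(c(0, 5, 0, 5, 0, 0))  # 300
#' @export
disease_index <- function(tally, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  if (length(tally) != 6 || any(tally < 0) || any(tally != round(tally)))
    stop("tally must be 6 non-negative integer counts (categories 1-6)",
         call. = FALSE)
  total <- sum(tally)
  if (total == 0) stop("tally contains no leaves", call. = FALSE)
  n_i <- tally / total * if (scale == "percent") 100 else 1
  sum(seq_len(6) * n_i)
}

.spor_bins <- c("0", "1-5", "6-10", "11-15", ">15")

#' Bin sporangiophore counts per cotyledon
#'
#' Cotyledons are classified as supporting no sporulation (0 per cotyledon),
#' light sporulation (1-5 and 6-10), medium sporulation (11-15), or heavy
#' sporulation (>15); bounds are inclusive integers, so a count of 15 is
#' medium and 16 is heavy.
#'
#' @param counts Non-negative integer vector, one count per cotyledon.
#' @return List with `fractions` (named over the five bins, summing to 1)
#'   and `mean` (sporangiophores per cotyledon, rounded to two decimals).
#' @export
bin_sporangiophores <- function(counts) {
  if (!length(counts)) stop("need at least one cotyledon", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("sporangiophore counts must be non-negative integers",
         call. = FALSE)
  bin <- cut(counts, breaks = c(-0.5, 0.5, 5.5, 10.5, 15.5, Inf),
             labels = .spor_bins)
  list(fractions = stats::setNames(as.numeric(table(bin) / length(counts)),
                                   .spor_bins),
       mean = round_half_up(mean(counts), 2))
}

#' Colony-forming units per leaf area
#'
#' Converts a plate count back to the bacterial surface density of the
#' sampled leaf discs: `cfu/cm^2 = colonies * 10^(-dilution_exponent) *
#' (extract_volume / plated_volume) / disc_area`. The conversion constants
#' are explicit arguments because they vary between assays.
#'
#' @param colonies Non-negative integer colony count.
#' @param dilution_exponent Integer <= 0 (e.g. -3 for a 10^-3 dilution).
#' @param plated_volume,extract_volume Volumes in the same unit (> 0).
#' @param disc_area Total sampled leaf area in cm^2 (> 0).
#' @return cfu per cm^2.
#' @examples
#' cfu_per_cm2(30, -3, plated_volume = 10, extract_volume = 200,
#'             disc_area = 0.196)  # about 3.06e6
#' @export
cfu_per_cm2 <- function(colonies, dilution_exponent, plated_volume,
                        extract_volume, disc_area) {
  if (colonies < 0 || colonies != round(colonies))
    stop("colonies must be a non-negative integer", call. = FALSE)
  if (dilution_exponent > 0)
    stop("dilution_exponent must be <= 0", call. = FALSE)
  if (plated_volume <= 0 || extract_volume <= 0 || disc_area <= 0)
    stop("volumes and disc_area must be positive", call. = FALSE)
  colonies * 10^(-dilution_exponent) * (extract_volume / plated_volume) /
    disc_area
}

#' Total ROS production over a luminescence time course
#'
#' Trapezoidal integral of the recorded signal over the measurement window
#' (e.g. total photon counts over the 34 minutes following elicitor
#' treatment).
#'
#' @param time Strictly increasing numeric vector (>= 2 points).
#' @param luminescence Signal values matching `time`.
#' @return The integral, in signal units x time units.
#' @export
total_ros <- function(time, luminescence) {
  if (length(time) < 2 || length(time) != length(luminescence))
    stop("need >= 2 matched (time, luminescence) points", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time points must be strictly increasing", call. = FALSE)
  pracma::trapz(time, luminescence)
}

# compact letter display by insert-and-absorb on the significant-pair list
.letter_display <- function(group_names, sig_pairs) {
  cols <- list(stats::setNames(rep(TRUE, length(group_names)), group_names))
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
      hit <- vapply(cols, function(col) col[[i]] && col[[j]], TRUE)
      for (h in which(hit)) {
        a <- cols[[h]]; a[[i]] <- FALSE
        b <- cols[[h]]; b[[j]] <- FALSE
        cols[[h]] <- a
        cols[[length(cols) + 1]] <- b
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (u in seq_along(cols)) {
        for (v in seq_along(cols)) {
          if (u != v && keep[u] && keep[v] &&
              all(cols[[u]] <= cols[[v]]) && any(cols[[u]] < cols[[v]]))
            keep[u] <- FALSE
          if (u != v && keep[u] && keep[v] && u > v &&
              identical(cols[[u]], cols[[v]]))
            keep[u] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  ord <- order(vapply(cols, function(col) which(col)[1], 0))
  cols <- cols[ord]
  letters_used <- letters[seq_along(cols)]
  vapply(group_names, function(g) {
    paste(letters_used[vapply(cols, `[[`, TRUE, g)], collapse = "")
  }, "")
}

#' One-way ANOVA with Tukey HSD letter display
#'
#' Classic equal-variance one-way ANOVA followed by Tukey's honestly
#' significant difference test on all pairwise group differences; groups
#' sharing a letter in the compact letter display are not significantly
#' different at `alpha`.
#'
#' @param groups Named list of numeric vectors, >= 2 groups with >= 2
#'   observations each.
#' @param alpha Family-wise significance level (the study uses 0.05).
#' @return List with `f_value`, `p_value` (the ANOVA F test), `tukey` (data
#'   frame of pairwise comparisons: `pair`, `diff`, `lwr`, `upr`, `p_adj`),
#'   and `letters` (named character vector).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  small <- names(groups)[lengths(groups) < 2]
  if (length(small))
    stop("group(s) with < 2 observations: ", paste(small, collapse = ", "),
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(grepl("-", names(groups), fixed = TRUE)))
    stop("group names must not contain '-'", call. = FALSE)
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- aov(y ~ g, data = dat)
  tab <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(hsd), "-", fixed = TRUE))
  sig <- hsd[, "p adj"] < alpha
  list(f_value = tab[["F value"]][1],
       p_value = tab[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                          lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                          p_adj = hsd[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE),
       letters = .letter_display(names(groups),
                                 pairs[sig, , drop = FALSE]))
}
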