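# Orchestration: run every contrast of the factorial design, classify, build
# the fraction-accounting table and Venn counts, QC by PCA, and write a
# provenance manifest. Stage outputs are plain TSV/JSON files so any stage
# can be re-run standalone.

#' Run all design contrasts and call DEGs
#'
#' Computes size factors and dispersions once, then fits the PTI contrasts
#' (EV vs time 0 per genotype and time) and the ETI contrasts (effector vs
#' same-time EV per genotype, effector and time in \{4, 8\}). With
#' `eti_mode = "set_difference"` in the config, effector-vs-time0 contrasts
#' are fitted as well.
#'
#' @param counts Count matrix.
#' @param meta Sample metadata.
#' @param config A [run_config()].
#' @param times_pti,times_eti Times at which to fit PTI / ETI contrasts.
#' @return List with `factors`, `dispersions`, `tables` (named list of
#'   [nb_wald_test()] results) and `degs` (named list of [call_degs()]
#'   results, keyed like the tables).
#' @export
run_contrasts <- function(counts, meta, config = run_config(),
                          times_pti = c(0.5, 4, 8), times_eti = c(4, 8)) {
  meta <- validate_metadata(meta)
  factors <- size_factors(counts)
  dispersions <- estimate_dispersion(counts, meta, factors)
  specs <- list()
  genotypes <- intersect(GENOTYPES, unique(meta$genotype))
  for (g in genotypes) {
    for (t in intersect(times_pti, unique(meta$time_hpi))) {
      if (any(meta$genotype == g & meta$treatment == "EV" &
              meta$time_hpi == t))
        specs <- c(specs, list(contrast_spec(g, t, "EV", "time_zero")))
    }
    for (eff in intersect(EFFECTORS, unique(meta$treatment))) {
      for (t in intersect(times_eti, unique(meta$time_hpi))) {
        has <- any(meta$genotype == g & meta$treatment == eff &
                   meta$time_hpi == t)
        if (!has) next
        specs <- c(specs, list(contrast_spec(g, t, eff, "EV_same_time")))
        if (config$eti_mode == "set_difference")
          specs <- c(specs, list(contrast_spec(g, t, eff, "time_zero")))
      }
    }
  }
  tables <- lapply(specs, function(cs)
    nb_wald_test(counts, meta, factors, dispersions, cs,
                 min_count_filter = config$min_count_filter))
  names(tables) <- vapply(specs, `[[`, "", "label")
  degs <- lapply(tables, call_degs, config = config)
  list(factors = factors, dispersions = dispersions, tables = tables,
       degs = degs)
}

#' PCA quality-control coordinates
#'
#' Principal components of the samples computed on the per-gene standardized
#' log-normalized expression of the most variable genes (variance taken on
#' the log-normalized scale, before standardization).
#'
#' @param counts Count matrix (>= 3 samples).
#' @param factors Size factors.
#' @param meta Sample metadata (labels the coordinates).
#' @param n_top Number of most-variable genes to use.
#' @return Data frame with `sample_id`, `genotype`, `treatment`, `time_hpi`,
#'   `PC1`, `PC2`; attribute `"variance_explained"` holds the per-component
#'   variance fractions.
#' @export
pca_qc <- function(counts, factors, meta, n_top = 2000) {
  if (ncol(counts) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  t <- log2(normalize_counts(counts, factors) + 1)
  v <- apply(t, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(t)))]
  z <- vst_zscore(counts[keep, , drop = FALSE], factors)
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  out <- data.frame(sample_id = colnames(counts), genotype = meta$genotype,
                    treatment = meta$treatment, time_hpi = meta$time_hpi,
                    PC1 = pc$x[, 1], PC2 = pc$x[, 2], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "variance_explained") <- ve
  out
}

.fmt_cell <- function(pctval, num, den) {
  if (is.na(pctval) || den == 0) return("—")
  sprintf("%.1f%%(%s/%s)", pctval, format(num, big.mark = ",", trim = TRUE),
          format(den, big.mark = ",", trim = TRUE))
}

#' Format fraction reports as the headline table
#'
#' One column per (effector, time) report, rows: RNL dependent, shared
#' regulation, synergistic, redundant, specific regulation, ADR1s specific,
#' NRG1s specific. Cells are `"pct%(num/den)"` with one-decimal percentages;
#' undefined fractions print as an em dash.
#'
#' @param reports List of [fraction_report()] objects.
#' @return Character matrix with row and column names.
#' @export
table1_report <- function(reports) {
  if (!length(reports)) stop("need >= 1 fraction report", call. = FALSE)
  if (inherits(reports, "fraction_report")) reports <- list(reports)
  cols <- lapply(reports, function(r) {
    c("RNL dependent" = .fmt_cell(r$rnl_dependent_pct, r$n_rnl_dependent,
                                  r$n_eti),
      "Shared regulation" = .fmt_cell(r$shared_pct, r$n_shared,
                                      r$n_rnl_dependent),
      "Synergistic" = .fmt_cell(r$synergistic_pct, r$n_synergistic,
                                r$n_rnl_dependent),
      "Redundant" = .fmt_cell(r$redundant_pct, r$n_redundant,
                              r$n_rnl_dependent),
      "Specific regulation" = .fmt_cell(r$specific_pct, r$n_specific,
                                        r$n_rnl_dependent),
      "ADR1s specific" = .fmt_cell(r$adr1_of_specific_pct, r$n_adr1_specific,
                                   r$n_specific),
      "NRG1s specific" = .fmt_cell(r$nrg1_of_specific_pct, r$n_nrg1_specific,
                                   r$n_specific))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(reports, function(r)
    sprintf("%s %s hpi", r$effector, r$time_hpi), "")
  m
}

#' Run the full pipeline
#'
#' Simulate (or read) counts, normalize, test every design contrast,
#' classify ETI-regulated genes per effector x time x direction, and write
#' fraction reports, per-gene assignments, Venn counts, PCA coordinates, the
#' formatted summary table, optional term enrichment of each classified
#' up-set, and a JSON run manifest with file digests and stage timings.
#'
#' @param config A [run_config()]; recognized extra keys: `counts_path`,
#'   `metadata_path` (read instead of simulating), `annotation_path`
#'   (enables enrichment).
#' @param out_dir Output directory.
#' @param params [sim_params()] for the simulation stage (ignored when counts
#'   are read); its seed is overridden by `config$seed`.
#' @param design Design to simulate (defaults to a desk-scale
#'   [full_design()]).
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         params = sim_params(),
                         design = full_design()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = list(), outputs = list())
  t0 <- Sys.time()
  tick <- function(stage) {
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[stage]] <<- round(dt, 3)
    t0 <<- Sys.time()
  }
  stage_error <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$counts_path)) {
    counts <- stage_error("read", read_counts(config$counts_path))
    meta <- stage_error("read", read_metadata(config$metadata_path))
    truth <- NULL
    tick("read")
  } else {
    params$seed <- config$seed
    sim <- stage_error("simulate", simulate_dataset(params, design))
    counts <- sim$counts; meta <- sim$design; truth <- sim$truth
    write_fixture(truth, counts, meta, out_dir, params = params)
    tick("simulate")
  }

  res <- stage_error("diffexpr", run_contrasts(counts, meta, config))
  tick("diffexpr")

  times_eti <- intersect(c(4, 8), unique(meta$time_hpi))
  effectors <- intersect(EFFECTORS, unique(meta$treatment))
  assignments <- list(); reports <- list(); venns <- list()
  for (eff in effectors) {
    for (t in times_eti) {
      for (dir in c("up", "down")) {
        a <- stage_error("classify",
                         classify_eti_genes(res$degs, eff, t, dir,
                                            mode = config$eti_mode))
        key <- sprintf("%s_t%s_%s", eff, t, dir)
        assignments[[key]] <- a
        reports[[key]] <- fraction_report(a)
      }
      col0 <- eti_regulated(res$degs, "col0", eff, t, config$eti_mode)
      hl <- eti_regulated(res$degs, "helperless", eff, t, config$eti_mode)
      venns[[sprintf("%s_t%s_col0_vs_helperless_up", eff, t)]] <-
        venn_counts(list(col0 = col0$up, helperless = hl$up))
    }
  }
  for (t in times_eti) {
    if (length(effectors) == 3) {
      sets <- lapply(stats::setNames(effectors, effectors), function(eff)
        eti_regulated(res$degs, "col0", eff, t, config$eti_mode)$up)
      venns[[sprintf("effector_overlap_t%s_up", t)]] <- venn_counts(sets)
    }
  }
  tick("classify")

  outs <- character()
  asg <- do.call(rbind, assignments)
  outs["assignments"] <- file.path(out_dir, "rnl_assignments.tsv")
  write.table(asg, outs["assignments"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  rep_tab <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)))
  outs["fractions"] <- file.path(out_dir, "fraction_reports.tsv")
  write.table(rep_tab, outs["fractions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  up_reports <- reports[grepl("_up$", names(reports))]
  if (length(up_reports)) {
    outs["table1"] <- file.path(out_dir, "fraction_table.tsv")
    tbl <- table1_report(up_reports)
    write.table(data.frame(row = rownames(tbl), tbl, check.names = FALSE),
                outs["table1"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  outs["venn"] <- file.path(out_dir, "venn_counts.json")
  jsonlite::write_json(lapply(venns, as.list), outs["venn"],
                       auto_unbox = TRUE, digits = NA)
  pca <- stage_error("pca", pca_qc(counts, res$factors, meta))
  outs["pca"] <- file.path(out_dir, "pca_coordinates.tsv")
  write.table(pca, outs["pca"], sep = "\t", quote = FALSE, row.names = FALSE)
  tick("report")

  if (!is.null(config$annotation_path)) {
    annot <- stage_error("enrich",
                         read_annotation(config$annotation_path,
                                         universe = rownames(counts)))
    enr <- list()
    for (key in names(assignments)) {
      if (!grepl("_up$", key)) next
      q <- assignments[[key]]$gene_id
      if (length(q))
        enr[[key]] <- top_terms(hypergeom_enrich(q, annot),
                                config$top_k_terms)
    }
    if (length(enr)) {
      etab <- do.call(rbind, Map(function(nm, d)
        cbind(set = nm, d, stringsAsFactors = FALSE), names(enr), enr))
      outs["enrichment"] <- file.path(out_dir, "enrichment.tsv")
      write.table(etab, outs["enrichment"], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    tick("enrich")
  }

  manifest$outputs <- as.list(tools::md5sum(unname(outs)))
  manifest$n_genes <- nrow(counts)
  manifest$n_samples <- ncol(counts)
  outm <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, outm, auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(assignments = assignments, reports = reports,
                             venns = venns, truth = truth,
                             contrasts = res)))
}
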