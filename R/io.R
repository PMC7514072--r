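# Readers, writers and validators for the plain-text interchange formats:
# counts (TSV genes x samples, or MatrixMarket triplet), sample metadata TSV,
# term->gene annotation TSV, GMT gene sets, and the flat key:value run
# configuration. Validation is total: malformed input raises an error naming
# the offending entity, never a partial object.

.log <- function(..., level = "INFO") {
  if (isTRUE(getOption("rnleti.quiet", FALSE))) return(invisible())
  message(sprintf("[rnleti %s] %s", level, paste0(...)))
}

#' Validate a sample metadata table
#'
#' Checks the factorial-design invariants: canonical genotype/treatment
#' tokens, times in \{0, 0.5, 4, 8\}, treatment `"none"` if and only if
#' `time_hpi == 0` (samples at time 0 are collected before treatment), and
#' uniqueness of (genotype, treatment, time, experiment, replicate).
#'
#' @param meta Data frame with columns `sample_id`, `genotype`, `treatment`,
#'   `time_hpi`; missing `experiment`/`replicate` columns default to 1 with a
#'   warning so minimal toy inputs remain usable.
#' @return The validated, token-normalized data frame.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "genotype", "treatment", "time_hpi")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("experiment", "replicate")) {
    if (is.null(meta[[col]])) {
      warning("metadata has no '", col, "' column; defaulting to 1",
              call. = FALSE)
      meta[[col]] <- 1L
    }
  }
  meta$genotype <- normalize_genotype(meta$genotype)
  meta$treatment <- normalize_treatment(meta$treatment)
  meta$time_hpi <- as.numeric(meta$time_hpi)
  meta$experiment <- as.integer(meta$experiment)
  meta$replicate <- as.integer(meta$replicate)
  if (!all(meta$time_hpi %in% TIMES_HPI))
    stop("time_hpi must be one of ", paste(TIMES_HPI, collapse = ", "),
         call. = FALSE)
  if (any(meta$experiment < 1L) || any(meta$replicate < 1L))
    stop("experiment and replicate must be integers >= 1", call. = FALSE)
  bad0 <- xor(meta$time_hpi == 0, meta$treatment == "none")
  if (any(bad0))
    stop("samples must have treatment 'none' exactly when time_hpi is 0; ",
         "violated by: ", paste(meta$sample_id[bad0], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  key <- interaction(meta$genotype, meta$treatment, meta$time_hpi,
                     meta$experiment, meta$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (genotype, treatment, time, experiment, replicate) ",
         "combination in metadata", call. = FALSE)
  rownames(meta) <- meta$sample_id
  meta
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with a header row and the columns
#'   documented in [validate_metadata()].
#' @return Validated metadata data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  validate_metadata(read.delim(path, stringsAsFactors = FALSE,
                               check.names = FALSE))
}

#' @rdname read_metadata
#' @param meta Validated metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_counts <- function(counts, what = "counts") {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must carry gene ids as row names and sample ids as column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id(s) in ", what, call. = FALSE)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at gene '",
         rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a gene x sample count matrix
#'
#' Two plain-text dialects are supported: `"tsv"`, a tab-separated table with
#' a leading `gene_id` header cell and one column per sample; and
#' `"mtx_triplet"`, a MatrixMarket coordinate file with companion
#' `<stem>.genes.txt` and `<stem>.samples.txt` index files (one id per line).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"mtx_triplet"`.
#' @return Validated integer matrix with gene row names and sample column
#'   names.
#' @export
read_counts <- function(path, format = c("tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(tab) < 2)
      stop("counts TSV needs a gene_id column plus >= 1 sample column",
           call. = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
  } else {
    stem <- sub("\\.mtx$", "", path)
    gfile <- paste0(stem, ".genes.txt")
    sfile <- paste0(stem, ".samples.txt")
    if (!file.exists(gfile) || !file.exists(sfile))
      stop("mtx_triplet counts need companion index files ", gfile, " and ",
           sfile, call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gfile)
    colnames(m) <- readLines(sfile)
    counts <- m
  }
  counts <- .validate_counts(counts)
  .log(sprintf("read %d genes x %d samples from %s",
               nrow(counts), ncol(counts), path))
  counts
}

#' @rdname read_counts
#' @param counts Integer count matrix with dimnames.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx_triplet")) {
  format <- match.arg(format)
  counts <- .validate_counts(counts)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(counts), counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  }
  invisible(path)
}

#' Run configuration
#'
#' `run_config()` builds a validated configuration list; `load_config()`
#' reads one from a flat `key: value` text file (YAML subset) and applies
#' defaults for absent keys. The defaults encode the study's DEG thresholds:
#' FDR-adjusted p < 0.05, fold change > 2, and top-25 term reporting.
#'
#' @param alpha_fdr FDR threshold in (0, 1).
#' @param fc_threshold Fold-change threshold (> 1); DEGs need
#'   |log2 FC| > log2(fc_threshold), strictly.
#' @param min_count_filter Genes with mean normalized count below this are
#'   excluded from testing and from the FDR family.
#' @param top_k_terms Number of enrichment terms to report per gene set.
#' @param seed Integer seed for all stochastic stages.
#' @param eti_mode `"contrast"` (effector-vs-EV DEG set, default) or
#'   `"set_difference"` (effector-vs-time0 minus EV-vs-time0).
#' @param ... Further keys (e.g. paths) carried through verbatim.
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(alpha_fdr = 0.05, fc_threshold = 2,
                       min_count_filter = 5, top_k_terms = 25, seed = 1,
                       eti_mode = c("contrast", "set_difference"), ...) {
  cfg <- list(alpha_fdr = as.numeric(alpha_fdr),
              fc_threshold = as.numeric(fc_threshold),
              min_count_filter = as.numeric(min_count_filter),
              top_k_terms = as.integer(top_k_terms),
              seed = as.integer(seed),
              eti_mode = match.arg(eti_mode), ...)
  if (!is.finite(cfg$alpha_fdr) || cfg$alpha_fdr <= 0 || cfg$alpha_fdr >= 1)
    stop("alpha_fdr must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(cfg$fc_threshold) || cfg$fc_threshold <= 1)
    stop("fc_threshold must be > 1", call. = FALSE)
  if (cfg$top_k_terms <= 0) stop("top_k_terms must be positive", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path Path to a flat key:value text file; an empty file yields the
#'   defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  cfg <- do.call(run_config, vals)
  .log("effective config: ",
       paste(names(cfg), vapply(cfg, function(x) paste(x, collapse = ","),
                                ""), sep = "=", collapse = " "))
  cfg
}

#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character vectors (the `description` attribute of
#'   each element holds the GMT description field).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", l, call. = FALSE)
    genes <- f[-(1:2)]
    attr(genes, "description") <- f[2]
    genes
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a term-to-gene annotation table
#'
#' @param path Two-column TSV (`term_id`, `gene_id`), with or without header.
#' @param universe Optional character vector of gene ids defining the
#'   enrichment universe; defaults to all annotated genes.
#' @return List with elements `terms` (named list term -> gene ids) and
#'   `universe`.
#' @export
read_annotation <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (identical(tolower(tab[1, 1]), "term_id")) tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("annotation must have two columns", call. = FALSE)
  terms <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  terms <- lapply(terms, unique)
  annotation(terms, universe = universe)
}

#' @rdname read_annotation
#' @param terms Named list term -> character vector of gene ids.
#' @export
annotation <- function(terms, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty annotation universe", call. = FALSE)
  outside <- setdiff(unique(unlist(terms, use.names = FALSE)), universe)
  if (length(outside))
    stop("annotated gene(s) missing from universe: ",
         paste(head(outside, 5), collapse = ", "), call. = FALSE)
  structure(list(terms = terms, universe = universe), class = "annotation")
}
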