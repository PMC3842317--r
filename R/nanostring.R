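#' Construct a NanoString nCounter dataset
#'
#' Bundles a probe-by-sample count matrix with probe classes and a sample
#' sheet. Probe classes partition the rows into negative controls
#' (background), positive controls (spike-in ladder, QC only), reference
#' candidates (normalization) and targets.
#'
#' @param counts numeric matrix, rows = probes (rownames required),
#'   columns = samples (colnames required), non-negative.
#' @param probe_class character vector (or named vector over probes) with
#'   values `"negative"`, `"positive"`, `"reference"`, `"target"`.
#' @param samples data.frame with columns `name`, `condition` (e.g. "GA",
#'   "DMSO"), `replicate`; `name` must match `colnames(counts)`.
#' @return object of class `nanostring_dataset` (list: `counts`,
#'   `probe_class`, `samples`).
#' @export
nanostring_dataset <- function(counts, probe_class, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0 | !is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (is.null(names(probe_class))) names(probe_class) <- rownames(counts)
  probe_class <- probe_class[rownames(counts)]
  if (any(is.na(probe_class))) stop("every probe needs a class")
  bad <- setdiff(unique(probe_class),
                 c("negative", "positive", "reference", "target"))
  if (length(bad) > 0) stop("unknown probe class: ", paste(bad, collapse = ", "))
  stopifnot(all(c("name", "condition", "replicate") %in% names(samples)))
  if (!identical(sort(samples$name), sort(colnames(counts)))) {
    stop("sample sheet does not match count matrix columns")
  }
  if (sum(probe_class == "negative") < 2 || sum(probe_class == "positive") < 2) {
    stop("need at least 2 negative and 2 positive control probes")
  }
  structure(list(counts = counts, probe_class = probe_class,
                 samples = samples[match(colnames(counts), samples$name), ]),
            class = "nanostring_dataset")
}

ns_rows <- function(ds, classes) names(ds$probe_class[ds$probe_class %in% classes])

geomean <- function(x) exp(mean(log(x)))

#' Subtract the negative-control background from each sample
#'
#' Per sample the background threshold is mean + 2 sd (sample sd, n - 1
#' denominator) of the negative-control counts; reference and target
#' counts become count - threshold, and values below 1 are fixed to 1.
#' Control probes are left untouched so that QC still sees raw values.
#'
#' @param ds a [nanostring_dataset()].
#' @return the dataset with corrected counts; per-sample thresholds in
#'   attribute `"background_threshold"`.
#' @export
background_correct <- function(ds) {
  stopifnot(inherits(ds, "nanostring_dataset"))
  neg <- ds$counts[ns_rows(ds, "negative"), , drop = FALSE]
  if (nrow(neg) < 2) stop("need >= 2 negative controls for background sd")
  thr <- apply(neg, 2, function(x) mean(x) + 2 * stats::sd(x))
  fix <- ns_rows(ds, c("reference", "target"))
  corrected <- sweep(ds$counts[fix, , drop = FALSE], 2, thr, "-")
  corrected[corrected < 1] <- 1
  ds$counts[fix, ] <- corrected
  attr(ds, "background_threshold") <- thr
  ds
}

#' Positive-control quality gate
#'
#' Computes each sample's mean positive-control count and the max/min
#' ratio of these means across samples; the run passes when the ratio is
#' below 3. This is an assay-performance gate only -- positive controls
#' play no part in normalization.
#'
#' @param ds a [nanostring_dataset()].
#' @return list: `pass`, `ratio`, `sample_means`.
#' @export
qc_positive_controls <- function(ds) {
  stopifnot(inherits(ds, "nanostring_dataset"))
  if (ncol(ds$counts) < 2) stop("QC needs at least 2 samples")
  means <- colMeans(ds$counts[ns_rows(ds, "positive"), , drop = FALSE])
  if (any(means == 0)) {
    return(list(pass = FALSE, ratio = Inf, sample_means = means))
  }
  ratio <- max(means) / min(means)
  list(pass = ratio < 3, ratio = ratio, sample_means = means)
}

# average pairwise-variation stability for each column of a log2 matrix
genorm_m_values <- function(l2) {
  g <- ncol(l2)
  vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j),
                function(k) stats::sd(l2[, j] - l2[, k]), 0))
  }, 0)
}

#' Select stable reference genes by the geNorm procedure
#'
#' For each candidate gene j the stability measure M_j is the mean, over
#' all other candidates k, of the standard deviation across samples of
#' log2(x_j / x_k) (low M = expression constant relative to the others).
#' The least stable candidate is removed and M recomputed, iterating until
#' `k` genes remain.
#'
#' @param ds a [nanostring_dataset()], normally background-corrected;
#'   candidate counts must be positive.
#' @param k size of the selected reference set (default 12).
#' @param candidates probe names to rank (default: all `"reference"`
#'   probes).
#' @return object of class `genorm_result`: data.frame `ranking` (gene,
#'   initial M, elimination step or NA if selected), `selected` (character
#'   vector), `M_selected` (final M values of the selected set).
#' @export
genorm_select <- function(ds, k = 12, candidates = NULL) {
  stopifnot(inherits(ds, "nanostring_dataset"))
  if (is.null(candidates)) candidates <- ns_rows(ds, "reference")
  if (length(candidates) < 3) stop("geNorm needs at least 3 candidates")
  x <- ds$counts[candidates, , drop = FALSE]
  if (any(x <= 0)) stop("geNorm requires positive counts")
  if (length(candidates) < k) {
    warning("no more candidates than requested references; keeping all")
  }
  l2 <- t(log2(x))                       # samples x genes
  m0 <- genorm_m_values(l2)
  elim <- rep(NA_integer_, length(candidates))
  names(elim) <- candidates
  alive <- candidates
  step <- 0L
  while (length(alive) > max(k, 2)) {
    m <- genorm_m_values(l2[, alive, drop = FALSE])
    step <- step + 1L
    # ties resolve to the later-listed candidate so input order is stable
    worst <- alive[max(which(m >= max(m) - 1e-12))]
    elim[worst] <- step
    alive <- setdiff(alive, worst)
  }
  ranking <- data.frame(gene = candidates, M = m0,
                        eliminated_step = elim[candidates],
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(!is.na(ranking$eliminated_step),
                           -replace(ranking$eliminated_step,
                                    is.na(ranking$eliminated_step), 0),
                           ranking$M), ]
  structure(list(ranking = ranking, selected = alive,
                 M_selected = genorm_m_values(l2[, alive, drop = FALSE])),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm reference selection:", length(x$selected), "genes kept\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize counts by the geometric mean of reference genes
#'
#' Each sample's scaling factor is the geometric mean of its reference
#' counts; reference and target counts are multiplied by (grand geometric
#' mean of the factors) / (sample factor), which equalizes reference
#' geomeans across samples while keeping output on a count-like scale.
#' The choice of anchor cancels in any cross-sample ratio.
#'
#' @param ds a [nanostring_dataset()] (background-corrected).
#' @param reference_set probe names used for scaling (e.g.
#'   `genorm_select(ds)$selected`).
#' @return the dataset with normalized reference/target counts;
#'   per-sample factors in attribute `"size_factor"`.
#' @export
normalize_counts <- function(ds, reference_set) {
  stopifnot(inherits(ds, "nanostring_dataset"),
            all(reference_set %in% rownames(ds$counts)))
  refs <- ds$counts[reference_set, , drop = FALSE]
  if (any(refs <= 0)) stop("reference counts must be positive")
  factors <- apply(refs, 2, geomean)
  anchor <- geomean(factors)
  fix <- ns_rows(ds, c("reference", "target"))
  ds$counts[fix, ] <- sweep(ds$counts[fix, , drop = FALSE], 2,
                            anchor / factors, "*")
  attr(ds, "size_factor") <- factors
  ds
}

#' Per-gene log2 fold-changes between conditions
#'
#' log2 of the ratio of geometric-mean counts in the numerator condition
#' over the denominator condition. When `average_technical` is set,
#' samples sharing a (condition, replicate) pair -- technical repeats of
#' one biological sample -- are first averaged on the log scale.
#'
#' @param ds a normalized [nanostring_dataset()].
#' @param numerator,denominator condition labels (default "GA" over
#'   "DMSO").
#' @param genes probe names (default: all targets).
#' @param average_technical average technical repeats first (default TRUE).
#' @return named numeric vector of log2 fold-changes.
#' @export
fold_changes <- function(ds, numerator = "GA", denominator = "DMSO",
                         genes = NULL, average_technical = TRUE) {
  stopifnot(inherits(ds, "nanostring_dataset"))
  if (is.null(genes)) genes <- ns_rows(ds, "target")
  sm <- ds$samples
  stopifnot(any(sm$condition == numerator), any(sm$condition == denominator))
  l2 <- log2(ds$counts[genes, , drop = FALSE])
  if (average_technical) {
    key <- paste(sm$condition, sm$replicate, sep = "::")
    groups <- split(seq_len(ncol(l2)), key)
    l2 <- vapply(groups, function(ix) rowMeans(l2[, ix, drop = FALSE]),
                 numeric(length(genes)))
    if (length(genes) == 1) l2 <- matrix(l2, nrow = 1,
                                         dimnames = list(genes, names(groups)))
    cond <- vapply(strsplit(colnames(l2), "::", fixed = TRUE), `[`, "", 1)
  } else {
    cond <- sm$condition
  }
  num <- rowMeans(l2[, cond == numerator, drop = FALSE])
  den <- rowMeans(l2[, cond == denominator, drop = FALSE])
  num - den
}

#' Run the full nCounter processing chain
#'
#' Background correction, positive-control QC (a warning, not an error,
#' on failure), geNorm reference selection, geometric-mean normalization
#' and per-target log2 fold-changes.
#'
#' @param ds raw [nanostring_dataset()].
#' @param k_ref reference-set size for geNorm (default 12).
#' @param numerator,denominator condition labels for fold-changes.
#' @return list: `qc`, `genorm`, `dataset` (normalized), `fold_changes`
#'   (data.frame gene / log2_fc).
#' @export
process_nanostring <- function(ds, k_ref = 12, numerator = "GA",
                               denominator = "DMSO") {
  ds <- background_correct(ds)
  qc <- qc_positive_controls(ds)
  if (!qc$pass) {
    warning(sprintf("positive-control QC failed (max/min ratio %.2f >= 3)",
                    qc$ratio))
  }
  gn <- genorm_select(ds, k = k_ref)
  ds <- normalize_counts(ds, gn$selected)
  fc <- fold_changes(ds, numerator = numerator, denominator = denominator)
  list(qc = qc, genorm = gn, dataset = ds,
       fold_changes = data.frame(gene = names(fc), log2_fc = unname(fc),
                                 stringsAsFactors = FALSE))
}

#' Read an nCounter dataset from CSV files
#'
#' @param counts_path CSV with columns `probe`, `class`, then one column
#'   per sample.
#' @param samples_path CSV with columns `name`, `condition`, `replicate`.
#' @return a [nanostring_dataset()].
#' @export
read_nanostring <- function(counts_path, samples_path) {
  raw <- utils::read.csv(counts_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  stopifnot(all(c("probe", "class") %in% names(raw)))
  scols <- setdiff(names(raw), c("probe", "class"))
  counts <- as.matrix(raw[scols])
  rownames(counts) <- raw$probe
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  nanostring_dataset(counts, stats::setNames(raw$class, raw$probe), samples)
}

#' Write an nCounter dataset to CSV files
#'
#' @param ds a [nanostring_dataset()].
#' @param counts_path,samples_path output CSV paths.
#' @export
write_nanostring <- function(ds, counts_path, samples_path) {
  df <- data.frame(probe = rownames(ds$counts),
                   class = unname(ds$probe_class[rownames(ds$counts)]),
                   ds$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, counts_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}
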