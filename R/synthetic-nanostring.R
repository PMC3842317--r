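#' Configuration for the synthetic nCounter count generator
#'
#' Emulates a two-condition nCounter run: negative controls drawn around a
#' low background, a positive-control spike-in ladder (nearly identical
#' across samples unless a QC failure is planted), near-constant reference
#' candidates, and target genes whose counts carry planted log2
#' fold-changes in the treated condition plus multiplicative lognormal
#' noise.
#'
#' @param n_targets number of target probes (default 88).
#' @param n_reference number of reference candidates (default 12).
#' @param n_negative,n_positive numbers of control probes (default 6 each).
#' @param samples_per_condition samples per condition (default 2; each is
#'   its own biological replicate).
#' @param fold_change_map named numeric vector of true log2 fold-changes
#'   (treated over control) keyed by target name `T001`...; unnamed
#'   targets change 0. `NULL` plants no changes.
#' @param count_noise_logsd sd, in log2 units, of multiplicative count
#'   noise (default 0.1, i.e. "10% log-noise"; fold-change analyses are
#'   reported in log2, so the noise scale matches the readout scale).
#' @param baseline_count_range 2-vector, low < high, from which target and
#'   reference baselines are drawn log-uniformly (default 50..5000).
#' @param conditions condition labels, denominator (control) first
#'   (default DMSO, GA).
#' @param qc_failure plant a positive-control failure (one sample's
#'   positives scaled 4x) for QC tests.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return validated object of class `nano_sim_config`.
#' @export
nano_sim_config <- function(n_targets = 88, n_reference = 12,
                            n_negative = 6, n_positive = 6,
                            samples_per_condition = 2,
                            fold_change_map = NULL,
                            count_noise_logsd = 0.1,
                            baseline_count_range = c(50, 5000),
                            conditions = c("DMSO", "GA"),
                            qc_failure = FALSE, seed = NULL) {
  stopifnot(n_targets >= 1, n_reference >= 3, n_negative >= 2,
            n_positive >= 2, samples_per_condition >= 1,
            count_noise_logsd >= 0, length(baseline_count_range) == 2,
            baseline_count_range[1] > 0,
            baseline_count_range[1] < baseline_count_range[2],
            length(conditions) == 2)
  cfg <- list(n_targets = n_targets, n_reference = n_reference,
              n_negative = n_negative, n_positive = n_positive,
              samples_per_condition = samples_per_condition,
              fold_change_map = fold_change_map,
              count_noise_logsd = count_noise_logsd,
              baseline_count_range = baseline_count_range,
              conditions = conditions, qc_failure = qc_failure, seed = seed)
  class(cfg) <- "nano_sim_config"
  cfg
}

#' Generate a synthetic nCounter dataset with known fold-changes
#'
#' @param cfg a [nano_sim_config()].
#' @return list with `dataset` (a [nanostring_dataset()]) and `truth`
#'   (named vector of true log2 fold-changes for every target).
#' @export
generate_nanostring_counts <- function(cfg) {
  stopifnot(inherits(cfg, "nano_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  spc <- cfg$samples_per_condition
  samples <- data.frame(
    name = sprintf("S%d", seq_len(2 * spc)),
    condition = rep(cfg$conditions, each = spc),
    replicate = rep(seq_len(spc), 2),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  sdl <- cfg$count_noise_logsd
  noise <- function(n) if (sdl > 0) 2^stats::rnorm(n, 0, sdl) else rep(1, n)

  probes <- c(sprintf("NEG%d", seq_len(cfg$n_negative)),
              sprintf("POS%d", seq_len(cfg$n_positive)),
              sprintf("REF%03d", seq_len(cfg$n_reference)),
              sprintf("T%03d", seq_len(cfg$n_targets)))
  cls <- c(rep("negative", cfg$n_negative), rep("positive", cfg$n_positive),
           rep("reference", cfg$n_reference), rep("target", cfg$n_targets))
  names(cls) <- probes
  counts <- matrix(0, length(probes), ns,
                   dimnames = list(probes, samples$name))

  # additive non-specific background, the quantity negative controls
  # measure; at zero noise every background draw equals bg_mean so the
  # mean + 2 sd threshold cancels it exactly
  bg_mean <- 12
  bg <- function(n) bg_mean * noise(n)
  counts[cls == "negative", ] <-
    matrix(bg(cfg$n_negative * ns), cfg$n_negative, ns)
  ladder <- 32000 / 4^(seq_len(cfg$n_positive) - 1)
  counts[cls == "positive", ] <- ladder *
    matrix(if (sdl > 0) stats::rlnorm(cfg$n_positive * ns, 0, 0.02)
           else 1, cfg$n_positive, ns)
  if (cfg$qc_failure) counts[cls == "positive", 1] <-
    counts[cls == "positive", 1] * 4

  lo <- log(cfg$baseline_count_range[1])
  hi <- log(cfg$baseline_count_range[2])
  base_ref <- exp(stats::runif(cfg$n_reference, lo, hi))
  counts[cls == "reference", ] <- base_ref *
    matrix(noise(cfg$n_reference * ns), cfg$n_reference, ns) +
    matrix(bg(cfg$n_reference * ns), cfg$n_reference, ns)

  fc <- stats::setNames(rep(0, cfg$n_targets),
                        sprintf("T%03d", seq_len(cfg$n_targets)))
  if (!is.null(cfg$fold_change_map)) {
    known <- intersect(names(cfg$fold_change_map), names(fc))
    fc[known] <- cfg$fold_change_map[known]
  }
  base_tgt <- exp(stats::runif(cfg$n_targets, lo, hi))
  treated <- samples$condition == cfg$conditions[2]
  tgt <- matrix(base_tgt, cfg$n_targets, ns) *
    2^(fc %o% as.numeric(treated))
  tgt <- tgt * matrix(noise(cfg$n_targets * ns), cfg$n_targets, ns) +
    matrix(bg(cfg$n_targets * ns), cfg$n_targets, ns)
  counts[cls == "target", ] <- tgt

  list(dataset = nanostring_dataset(counts, cls, samples), truth = fc)
}
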