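#' Configuration for the synthetic SILAC protein-group generator
#'
#' Describes a two-time-point SILAC experiment with replicate structure, a
#' planted mixture of temporal patterns, and controlled contamination so the
#' whole downstream filter/test/cluster chain can be validated against known
#' ground truth.
#'
#' `cluster_mix` is a named vector of fractions keyed by pattern label: `"1"`
#' to `"12"` plant the corresponding change template (see
#' [cluster_patterns()]), `"14"` plants proteins quantified at only one time
#' point. Whatever fraction remains is generated flat (true log2 ratio 0 at
#' both time points, pattern label 13). The default mixture mirrors a
#' chaperone-inhibition experiment: about 17% of proteins change, dominated
#' by the monotone up/down and late-only patterns.
#'
#' @param n_proteins number of genuine protein groups.
#' @param replicates number of biological replicates (default 3).
#' @param swapped_replicates replicate indices emitted with inverted H/L
#'   orientation (label swap; default 3).
#' @param timepoints_h sampling times in hours (default 6 and 20).
#' @param cluster_mix named fractions per planted pattern label (see above).
#' @param effect_size_log2 log2-ratio magnitude of one template unit.
#' @param noise_sd_log2 SD of Gaussian noise added to each replicate's log2
#'   ratio.
#' @param contaminant_fraction,reverse_fraction fractions (of `n_proteins`)
#'   of extra planted contaminant / reverse-hit rows.
#' @param single_evidence_fraction fraction of ratio cells backed by a
#'   single evidence (these should be blanked by quality filtering).
#' @param outlier_fraction fraction of genuine proteins planted with one
#'   replicate violating the fold-spread (x1.41) rule.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return validated config object of class `silac_sim_config`.
#' @export
silac_sim_config <- function(n_proteins = 200,
                             replicates = 3,
                             swapped_replicates = 3,
                             timepoints_h = c(6, 20),
                             cluster_mix = NULL,
                             effect_size_log2 = 0.5,
                             noise_sd_log2 = 0.15,
                             contaminant_fraction = 0.02,
                             reverse_fraction = 0.02,
                             single_evidence_fraction = 0.05,
                             outlier_fraction = 0.02,
                             seed = NULL) {
  if (is.null(cluster_mix)) {
    cluster_mix <- c("2" = 0.05, "6" = 0.04, "7" = 0.04, "11" = 0.03,
                     "1" = 0.002, "3" = 0.002, "4" = 0.002, "5" = 0.002,
                     "8" = 0.002, "9" = 0.002, "10" = 0.002, "12" = 0.002,
                     "14" = 0.01)
  }
  stopifnot(n_proteins >= 1, replicates >= 1, length(timepoints_h) == 2,
            effect_size_log2 > 0, noise_sd_log2 >= 0)
  fr <- c(contaminant_fraction, reverse_fraction, single_evidence_fraction,
          outlier_fraction, cluster_mix)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (is.null(names(cluster_mix)) ||
      !all(names(cluster_mix) %in% as.character(c(1:12, 14)))) {
    stop("cluster_mix must be named with pattern labels 1..12 or 14")
  }
  if (sum(cluster_mix) > 1 + 1e-12) {
    stop("cluster_mix fractions sum to more than 1")
  }
  if (!all(swapped_replicates %in% seq_len(replicates))) {
    stop("swapped_replicates out of range")
  }
  cfg <- list(n_proteins = n_proteins, replicates = replicates,
              swapped_replicates = as.integer(swapped_replicates),
              timepoints_h = timepoints_h, cluster_mix = cluster_mix,
              effect_size_log2 = effect_size_log2,
              noise_sd_log2 = noise_sd_log2,
              contaminant_fraction = contaminant_fraction,
              reverse_fraction = reverse_fraction,
              single_evidence_fraction = single_evidence_fraction,
              outlier_fraction = outlier_fraction, seed = seed)
  class(cfg) <- "silac_sim_config"
  cfg
}

#' Generate a synthetic SILAC protein-group table with ground truth
#'
#' Each genuine protein is assigned a temporal pattern; its true log2 ratio
#' at the two time points is the pattern template times `effect_size_log2`.
#' Every replicate measurement adds independent Gaussian noise on the log2
#' scale. Label-swapped replicates are emitted with inverted H/L ratios, as
#' they come off the instrument; pass the table through [orient_ratios()]
#' (or write it and use [read_protein_groups()]) before analysis. Planted
#' contaminant and reverse rows carry `"+"` flags; planted outliers have one
#' replicate forced beyond the fold-spread rule; a fraction of ratio cells
#' is marked as backed by a single evidence.
#'
#' @param cfg a [silac_sim_config()].
#' @return list with `table` (as-emitted [protein_group_table]), `truth`
#'   (data.frame: `group_ids`, `pattern`, `true_log2_t1`, `true_log2_t2`,
#'   `planted_outlier`), and `config`.
#' @export
generate_stsilac_table <- function(cfg) {
  stopifnot(inherits(cfg, "silac_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_proteins
  R <- cfg$replicates
  tps <- cfg$timepoints_h
  templ <- cluster_patterns(include_null = TRUE)

  # pattern assignment: deterministic counts, shuffled positions
  counts <- floor(cfg$cluster_mix * n)
  labels <- rep("13", n)
  pool <- sample.int(n)
  at <- 1
  for (lab in names(counts)) {
    k <- counts[[lab]]
    if (k > 0) {
      labels[pool[at:(at + k - 1)]] <- lab
      at <- at + k
    }
  }

  ids <- sprintf("P%04d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(n))
  true_l2 <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "14") {
      # quantified at one time point only; the seen value is a one-unit step
      true_l2[i, ] <- c(cfg$effect_size_log2, NA_real_)
    } else {
      true_l2[i, ] <- templ[lab, c("t1", "t2")] * cfg$effect_size_log2
    }
  }

  meas <- array(NA_real_, c(n, R, 2))  # oriented log2 ratios
  for (tp in 1:2) {
    for (r in seq_len(R)) {
      meas[, r, tp] <- true_l2[, tp] +
        stats::rnorm(n, 0, cfg$noise_sd_log2)
    }
  }

  # planted outliers: one replicate forced above 1.41x the largest other
  n_out <- floor(cfg$outlier_fraction * n)
  out_idx <- if (n_out > 0) sample(which(labels != "14"), n_out) else integer()
  for (i in out_idx) {
    tp <- sample(1:2, 1)
    r <- sample(seq_len(R), 1)
    others <- meas[i, -r, tp]
    meas[i, r, tp] <- max(others, na.rm = TRUE) + log2(1.6)
  }

  evid <- array(2L, c(n, R, 2))
  evid[] <- 2L + stats::rpois(n * R * 2, 3)
  n_single <- floor(cfg$single_evidence_fraction * n * R * 2)
  single_cells <- sample(seq_len(n * R * 2), n_single)
  evid[single_cells] <- 1L
  # keep planted outlier cells multi-evidence so they survive to the
  # outlier test rather than being blanked first
  for (i in out_idx) evid[i, , ] <- pmax(evid[i, , ], 2L)

  df <- data.frame(group_ids = ids, gene_name = genes,
                   stringsAsFactors = FALSE)
  for (r in seq_len(R)) {
    for (tp in 1:2) {
      l2 <- meas[, r, tp]
      ratio <- 2^l2
      if (r %in% cfg$swapped_replicates) ratio <- 1 / ratio  # as-measured
      df[[sprintf("ratio_r%d_t%d", r, tps[tp])]] <- ratio
      df[[sprintf("evidence_r%d_t%d", r, tps[tp])]] <- evid[, r, tp]
    }
  }
  df$contaminant <- ""
  df$reverse <- ""

  extra <- function(k, prefix, flag) {
    if (k == 0) return(NULL)
    e <- data.frame(group_ids = sprintf("%s%03d", prefix, seq_len(k)),
                    gene_name = "", stringsAsFactors = FALSE)
    for (r in seq_len(R)) {
      for (tp in 1:2) {
        e[[sprintf("ratio_r%d_t%d", r, tps[tp])]] <-
          2^stats::rnorm(k, 0, 0.5)
        e[[sprintf("evidence_r%d_t%d", r, tps[tp])]] <-
          2L + stats::rpois(k, 3)
      }
    }
    e$contaminant <- if (flag == "contaminant") "+" else ""
    e$reverse <- if (flag == "reverse") "+" else ""
    e
  }
  con <- extra(round(cfg$contaminant_fraction * n), "CON__", "contaminant")
  rev <- extra(round(cfg$reverse_fraction * n), "REV__", "reverse")
  df <- rbind(df, con, rev)

  truth <- data.frame(group_ids = ids,
                      pattern = as.integer(labels),
                      true_log2_t1 = true_l2[, 1],
                      true_log2_t2 = true_l2[, 2],
                      planted_outlier = seq_len(n) %in% out_idx,
                      stringsAsFactors = FALSE)

  list(table = protein_group_table(df), truth = truth, config = cfg)
}
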