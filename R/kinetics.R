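#' Preset for the pulse-chase turnover simulator
#'
#' Describes a two-condition (control vs drug-treated) pulse-chase
#' metabolic-labelling experiment under the first-order turnover model
#' dP_old/dt = -k_d P_old, dP_new/dt = V_s - k_d P_new. Per-protein
#' parameters are drawn lognormally around the preset medians; defaults are
#' calibrated to a global proteome response to Hsp90 inhibition: control
#' half-life median 55.9 h, treated/control decay-rate factor median 1.73
#' and synthesis-rate factor median 0.57 (implying a treated half-life
#' median near 32 h).
#'
#' `category_overrides` plants named protein categories whose half-lives
#' are drawn lognormally (log-sd `category_logsd`) so that the arithmetic
#' MEAN half-life matches the stated per-condition value; see
#' [pcsilac_categories()] for calibrated examples. Override proteins are
#' appended to `n_proteins`.
#'
#' @param n_proteins number of background proteins (default 911).
#' @param ctrl_halflife_median_h median control half-life, hours.
#' @param ctrl_halflife_logsd log-sd of the control half-life distribution.
#' @param kd_factor_median,kd_factor_logsd lognormal treated/control
#'   decay-rate factor.
#' @param vs_ctrl_median,vs_ctrl_logsd lognormal control synthesis rate
#'   (arbitrary signal units per hour).
#' @param vs_factor_median,vs_factor_logsd lognormal treated/control
#'   synthesis-rate factor.
#' @param sample_times_h sampling grid in hours; must start at 0, sorted.
#' @param n_replicates independent replicate measurements per time point
#'   (default 2, the usual pulse-chase design).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   measurement noise per signal (default 0.10).
#' @param category_overrides named list of
#'   `list(ctrl_halflife_mean_h, treated_halflife_mean_h, n)`.
#' @param category_logsd log-sd of override half-life draws (default 0.2).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return validated object of class `pcsilac_preset`.
#' @export
pcsilac_preset <- function(n_proteins = 911,
                           ctrl_halflife_median_h = 55.9,
                           ctrl_halflife_logsd = 0.8,
                           kd_factor_median = 1.73,
                           kd_factor_logsd = 0.35,
                           vs_ctrl_median = 10,
                           vs_ctrl_logsd = 0.5,
                           vs_factor_median = 0.57,
                           vs_factor_logsd = 0.35,
                           sample_times_h = c(0, 6, 20),
                           n_replicates = 2,
                           noise_cv = 0.10,
                           category_overrides = NULL,
                           category_logsd = 0.2,
                           seed = NULL) {
  stopifnot(n_proteins >= 1, ctrl_halflife_median_h > 0,
            kd_factor_median > 0, vs_ctrl_median > 0, vs_factor_median > 0,
            ctrl_halflife_logsd > 0, kd_factor_logsd > 0,
            vs_ctrl_logsd > 0, vs_factor_logsd > 0,
            n_replicates >= 1, noise_cv >= 0, category_logsd > 0)
  if (is.unsorted(sample_times_h) || sample_times_h[1] != 0) {
    stop("sample_times_h must be sorted and start at 0")
  }
  if (!is.null(category_overrides)) {
    stopifnot(is.list(category_overrides),
              !is.null(names(category_overrides)))
    for (ov in category_overrides) {
      stopifnot(ov$ctrl_halflife_mean_h > 0, ov$treated_halflife_mean_h > 0,
                ov$n >= 1)
    }
  }
  p <- list(n_proteins = n_proteins,
            ctrl_halflife_median_h = ctrl_halflife_median_h,
            ctrl_halflife_logsd = ctrl_halflife_logsd,
            kd_factor_median = kd_factor_median,
            kd_factor_logsd = kd_factor_logsd,
            vs_ctrl_median = vs_ctrl_median, vs_ctrl_logsd = vs_ctrl_logsd,
            vs_factor_median = vs_factor_median,
            vs_factor_logsd = vs_factor_logsd,
            sample_times_h = sample_times_h, n_replicates = n_replicates,
            noise_cv = noise_cv, category_overrides = category_overrides,
            category_logsd = category_logsd, seed = seed)
  class(p) <- "pcsilac_preset"
  p
}

#' Calibrated category overrides for the chaperone-inhibition preset
#'
#' Two protein categories with distinctive turnover responses to Hsp90
#' inhibition: the chaperone machinery itself (very stable at baseline,
#' strongly destabilised: mean half-life 321 h -> 43.5 h) and protein
#' kinases (39.9 h -> 22.5 h; 16 quantified proteins). The chaperone
#' category size is set to 20, a typical size for this family plus
#' cofactors in such datasets.
#'
#' @return named list suitable for `category_overrides` in
#'   [pcsilac_preset()].
#' @export
pcsilac_categories <- function() {
  list(
    hsp90_cofactors = list(ctrl_halflife_mean_h = 321,
                           treated_halflife_mean_h = 43.5, n = 20),
    kinases = list(ctrl_halflife_mean_h = 39.9,
                   treated_halflife_mean_h = 22.5, n = 16)
  )
}

# lognormal draw with a target arithmetic mean
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate pulse-chase time courses with known kinetic ground truth
#'
#' Per protein: control decay rate k_d = ln2 / half-life with the half-life
#' drawn lognormally; treated k_d multiplied by a lognormal factor;
#' synthesis rates likewise. Both conditions start from the same
#' pre-treatment steady-state old pool H0 = V_s,ctrl / k_d,ctrl. Signals
#' follow the first-order model -- old pool H(t) = H0 exp(-k_d t), new pool
#' N(t) = (V_s / k_d)(1 - exp(-k_d t)), with N(0) = 0 exactly -- and each
#' measured signal (t > 0, and the old pool at t = 0) is multiplied by
#' lognormal noise with coefficient of variation `noise_cv` and median 1,
#' independently per replicate.
#'
#' @param preset a [pcsilac_preset()].
#' @return list with `series` (long data.frame: `protein`, `condition`
#'   ("control"/"treated"), `replicate`, `time_h`, `old_signal`,
#'   `new_signal`) and `truth` (per protein: `category`, true `kd_ctrl`,
#'   `kd_treated`, `vs_ctrl`, `vs_treated`, `thalf_ctrl`, `thalf_treated`).
#' @export
generate_pcsilac_series <- function(preset) {
  stopifnot(inherits(preset, "pcsilac_preset"))
  if (!is.null(preset$seed)) set.seed(preset$seed)
  ln2 <- log(2)

  n0 <- preset$n_proteins
  thalf_c <- stats::rlnorm(n0, log(preset$ctrl_halflife_median_h),
                           preset$ctrl_halflife_logsd)
  kd_c <- ln2 / thalf_c
  kd_t <- kd_c * stats::rlnorm(n0, log(preset$kd_factor_median),
                               preset$kd_factor_logsd)
  vs_c <- stats::rlnorm(n0, log(preset$vs_ctrl_median), preset$vs_ctrl_logsd)
  vs_t <- vs_c * stats::rlnorm(n0, log(preset$vs_factor_median),
                               preset$vs_factor_logsd)
  category <- rep("background", n0)

  for (nm in names(preset$category_overrides)) {
    ov <- preset$category_overrides[[nm]]
    tc <- rlnorm_mean(ov$n, ov$ctrl_halflife_mean_h, preset$category_logsd)
    tt <- rlnorm_mean(ov$n, ov$treated_halflife_mean_h, preset$category_logsd)
    vc <- stats::rlnorm(ov$n, log(preset$vs_ctrl_median), preset$vs_ctrl_logsd)
    vt <- vc * stats::rlnorm(ov$n, log(preset$vs_factor_median),
                             preset$vs_factor_logsd)
    kd_c <- c(kd_c, ln2 / tc)
    kd_t <- c(kd_t, ln2 / tt)
    vs_c <- c(vs_c, vc)
    vs_t <- c(vs_t, vt)
    category <- c(category, rep(nm, ov$n))
  }

  n <- length(kd_c)
  ids <- sprintf("P%04d", seq_len(n))
  times <- preset$sample_times_h
  sdlog <- if (preset$noise_cv > 0) sqrt(log(1 + preset$noise_cv^2)) else 0
  h0 <- vs_c / kd_c  # shared pre-treatment steady state

  grid <- expand.grid(time_h = times,
                      replicate = seq_len(preset$n_replicates),
                      condition = c("control", "treated"),
                      protein = ids, stringsAsFactors = FALSE)
  kd <- ifelse(grid$condition == "control", kd_c[match(grid$protein, ids)],
               kd_t[match(grid$protein, ids)])
  vs <- ifelse(grid$condition == "control", vs_c[match(grid$protein, ids)],
               vs_t[match(grid$protein, ids)])
  H0 <- h0[match(grid$protein, ids)]
  old <- H0 * exp(-kd * grid$time_h)
  new <- (vs / kd) * (1 - exp(-kd * grid$time_h))
  if (sdlog > 0) {
    old <- old * stats::rlnorm(nrow(grid), 0, sdlog)
    pos <- grid$time_h > 0
    new[pos] <- new[pos] * stats::rlnorm(sum(pos), 0, sdlog)
  }
  new[grid$time_h == 0] <- 0

  series <- data.frame(protein = grid$protein, condition = grid$condition,
                       replicate = grid$replicate, time_h = grid$time_h,
                       old_signal = old, new_signal = new,
                       stringsAsFactors = FALSE)
  truth <- data.frame(protein = ids, category = category,
                      kd_ctrl = kd_c, kd_treated = kd_t,
                      vs_ctrl = vs_c, vs_treated = vs_t,
                      thalf_ctrl = ln2 / kd_c, thalf_treated = ln2 / kd_t,
                      stringsAsFactors = FALSE)
  list(series = series, truth = truth, preset = preset)
}

#' Fit a first-order decay rate constant from chase signals
#'
#' Ordinary least-squares regression of ln(old pool signal) on time; the
#' decay rate constant is minus the slope, clamped at 0 when the fitted
#' slope is positive (a constant or rising chase signal means no measurable
#' decay).
#'
#' @param times_h sampling times, hours.
#' @param old_signal chase (pre-existing pool) signals; non-positive or
#'   missing values are dropped.
#' @return k_d in 1/h, or `NA` with fewer than 2 usable points.
#' @export
fit_decay <- function(times_h, old_signal) {
  ok <- is.finite(old_signal) & old_signal > 0 & is.finite(times_h)
  t <- times_h[ok]
  y <- log(old_signal[ok])
  if (length(t) < 2 || length(unique(t)) < 2) return(NA_real_)
  slope <- stats::cov(t, y) / stats::var(t)
  max(-slope, 0)
}

#' Fit a synthesis rate from pulse signals given the decay constant
#'
#' Under the first-order model the new pool is N(t) = (V_s / k_d)
#' (1 - exp(-k_d t)), linear in V_s, so the least-squares estimate has the
#' closed form V_s = sum(g N) / sum(g^2) with g(t) = (1 - exp(-k_d t)) /
#' k_d (g(t) = t in the k_d -> 0 limit). Only t > 0 points carry
#' information.
#'
#' @param times_h sampling times, hours.
#' @param new_signal pulse (newly synthesized pool) signals.
#' @param kd decay rate constant from [fit_decay()].
#' @return V_s in signal units per hour, or `NA`.
#' @export
fit_synthesis <- function(times_h, new_signal, kd) {
  if (is.na(kd)) return(NA_real_)
  ok <- is.finite(new_signal) & is.finite(times_h) & times_h > 0
  t <- times_h[ok]
  N <- new_signal[ok]
  if (length(t) < 1) return(NA_real_)
  g <- if (kd > 0) (1 - exp(-kd * t)) / kd else t
  sum(g * N) / sum(g^2)
}

#' Half-life from a decay rate constant
#'
#' @param kd decay rate constant(s), 1/h; must be non-negative.
#' @return ln2 / k_d in hours; `Inf` where k_d = 0; NAs propagate.
#' @export
half_life <- function(kd) {
  if (any(kd < 0, na.rm = TRUE)) stop("decay rate constants must be >= 0")
  ifelse(kd > 0, log(2) / kd, Inf)
}

#' Centre log2 ratios on the dataset-wide median
#'
#' Adjusts per-protein log2 ratios for global proteome shifts by
#' subtracting the median over all finite values, so that the adjusted
#' dataset has median 0 and category averages read as deviations from the
#' global response.
#'
#' @param log2_ratios numeric vector (NA/Inf tolerated, returned shifted).
#' @return adjusted values.
#' @export
adjust_by_global_median <- function(log2_ratios) {
  fin <- log2_ratios[is.finite(log2_ratios)]
  if (length(fin) == 0) stop("no finite values to centre")
  log2_ratios - stats::median(fin)
}

#' Fit turnover kinetics for every protein and condition
#'
#' Runs [fit_decay()] and [fit_synthesis()] per protein per condition on a
#' long-format pulse-chase table, derives half-lives and treated/control
#' ratios, and (optionally) centres the log2 ratios on their global
#' medians. Steady-state abundance per condition is V_s / k_d, so the
#' abundance ratio is (V_s ratio) / (k_d ratio).
#'
#' @param series long data.frame as produced by
#'   [generate_pcsilac_series()] (columns `protein`, `condition`, `time_h`,
#'   `old_signal`, `new_signal`; `condition` values "control"/"treated").
#' @param adjust_global_median subtract dataset-median log2 ratios
#'   (default TRUE).
#' @return data.frame, one row per protein: fitted `kd_*`, `vs_*`,
#'   `thalf_*` per condition, `kd_ratio`, `vs_ratio`, `thalf_ratio`,
#'   `abundance_ratio`, their `log2_*` transforms, and `adj_log2_*`
#'   median-centred versions.
#' @export
fit_kinetics <- function(series, adjust_global_median = TRUE) {
  need <- c("protein", "condition", "time_h", "old_signal", "new_signal")
  stopifnot(all(need %in% names(series)))
  fit_one <- function(d) {
    kd <- fit_decay(d$time_h, d$old_signal)
    vs <- fit_synthesis(d$time_h, d$new_signal, kd)
    c(kd = kd, vs = vs)
  }
  sp <- split(series, list(series$protein, series$condition), drop = TRUE)
  fits <- vapply(sp, fit_one, c(kd = 0, vs = 0))
  key <- strsplit(names(sp), ".", fixed = TRUE)
  prot <- vapply(key, `[`, "", 1)
  cond <- vapply(key, `[`, "", 2)
  ids <- unique(series$protein)
  pick <- function(what, cnd) {
    v <- fits[what, cond == cnd]
    v[match(ids, prot[cond == cnd])]
  }
  out <- data.frame(protein = ids,
                    kd_control = pick("kd", "control"),
                    kd_treated = pick("kd", "treated"),
                    vs_control = pick("vs", "control"),
                    vs_treated = pick("vs", "treated"),
                    stringsAsFactors = FALSE)
  out$thalf_control <- half_life(out$kd_control)
  out$thalf_treated <- half_life(out$kd_treated)
  out$kd_ratio <- out$kd_treated / out$kd_control
  out$vs_ratio <- out$vs_treated / out$vs_control
  out$thalf_ratio <- out$thalf_treated / out$thalf_control
  out$abundance_ratio <- out$vs_ratio / out$kd_ratio
  for (q in c("kd_ratio", "vs_ratio", "thalf_ratio", "abundance_ratio")) {
    out[[paste0("log2_", q)]] <- log2(out[[q]])
  }
  if (adjust_global_median) {
    for (q in c("kd_ratio", "vs_ratio", "thalf_ratio", "abundance_ratio")) {
      out[[paste0("adj_log2_", q)]] <-
        adjust_by_global_median(out[[paste0("log2_", q)]])
    }
  }
  rownames(out) <- NULL
  out
}

#' Average kinetic changes for protein categories
#'
#' Arithmetic means per category of the median-centred log2 ratios
#' (synthesis, decay, abundance, half-life) plus the raw (uncentred) mean
#' half-life per condition. Means are taken over finite values; proteins
#' with no measurable decay (infinite half-life) do not contribute to the
#' half-life means.
#'
#' @param fits output of [fit_kinetics()] with `adj_log2_*` columns.
#' @param categories named list of protein-id vectors, or a data.frame
#'   with columns `protein`, `category`.
#' @return data.frame, one row per category: `category`, `n`,
#'   `mean_adj_log2_vs_ratio`, `mean_adj_log2_kd_ratio`,
#'   `mean_adj_log2_abundance_ratio`, `mean_adj_log2_thalf_ratio`,
#'   `mean_thalf_control`, `mean_thalf_treated`.
#' @export
summarize_category <- function(fits, categories) {
  if (is.data.frame(categories)) {
    stopifnot(all(c("protein", "category") %in% names(categories)))
    categories <- split(categories$protein, categories$category)
  }
  fmean <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  rows <- lapply(names(categories), function(nm) {
    sub <- fits[fits$protein %in% categories[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(category = nm, n = nrow(sub),
               mean_adj_log2_vs_ratio = fmean(sub$adj_log2_vs_ratio),
               mean_adj_log2_kd_ratio = fmean(sub$adj_log2_kd_ratio),
               mean_adj_log2_abundance_ratio =
                 fmean(sub$adj_log2_abundance_ratio),
               mean_adj_log2_thalf_ratio = fmean(sub$adj_log2_thalf_ratio),
               mean_thalf_control = fmean(sub$thalf_control),
               mean_thalf_treated = fmean(sub$thalf_treated),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
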