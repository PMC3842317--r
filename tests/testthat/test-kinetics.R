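test_that("decay fits invert the exponential model exactly", {
  t3 <- c(0, 6, 20)
  expect_equal(fit_decay(t3, 100 * exp(-0.1 * t3)), 0.1, tolerance = 1e-12)
  # two points with a half-life of 6 h
  expect_equal(fit_decay(c(0, 6), c(100, 50)), log(2) / 6, tolerance = 1e-12)
  expect_equal(fit_decay(t3, c(80, 80, 80)), 0)           # no decay
  expect_true(is.na(fit_decay(c(0, 6), c(100, NA))))      # one usable point
  # rising signal clamps at zero rather than going negative
  expect_equal(fit_decay(t3, c(50, 60, 80)), 0)
})

test_that("synthesis fits solve the accumulation model", {
  expect_equal(fit_synthesis(20, 86.46647, kd = 0.1), 10.0, tolerance = 1e-5)
  expect_equal(fit_synthesis(20, 40, kd = 0), 2.0)        # linear limit
  expect_true(is.na(fit_synthesis(0, 0, kd = 0.1)))       # nothing past t=0
  expect_true(is.na(fit_synthesis(20, 40, kd = NA_real_)))
})

test_that("half-life is the reciprocal law in ln2", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.0124), 55.9, tolerance = 1e-3)
  expect_equal(half_life(0.2) / half_life(0.4), 2)
  expect_equal(half_life(0), Inf)
  expect_error(half_life(-0.1), ">= 0")
})

test_that("global median centring leaves residuals with median zero", {
  expect_equal(adjust_by_global_median(c(3, 3, 3)), c(0, 0, 0))
  expect_equal(adjust_by_global_median(c(-1, 0, 3)), c(-1, 0, 3))
  x <- c(0.3, -1.2, 4.1, 0.9, 2.2)
  adj <- adjust_by_global_median(x)
  expect_equal(median(adj), 0)
  expect_equal(sum(adj == 0), 1)                 # odd length: a member is 0
  expect_equal(adjust_by_global_median(c(1, Inf))[2], Inf)  # Inf passes through
  expect_error(adjust_by_global_median(NA_real_), "finite")
})

test_that("noise-free series recover the generator's parameters to 1e-9", {
  preset <- pcsilac_preset(n_proteins = 40, noise_cv = 0, seed = 14)
  sim <- generate_pcsilac_series(preset)
  fits <- fit_kinetics(sim$series)
  ord <- match(sim$truth$protein, fits$protein)
  expect_equal(fits$kd_control[ord], sim$truth$kd_ctrl, tolerance = 1e-9)
  expect_equal(fits$kd_treated[ord], sim$truth$kd_treated, tolerance = 1e-9)
  expect_equal(fits$vs_control[ord], sim$truth$vs_ctrl, tolerance = 1e-9)
  expect_equal(fits$vs_treated[ord], sim$truth$vs_treated, tolerance = 1e-9)
})

test_that("half-life and decay ratios obey the reciprocal identity", {
  preset <- pcsilac_preset(n_proteins = 60, seed = 9)
  fits <- fit_kinetics(generate_pcsilac_series(preset)$series)
  ok <- is.finite(fits$kd_ratio) & fits$kd_ratio > 0
  expect_true(any(ok))
  expect_equal(fits$thalf_ratio[ok], 1 / fits$kd_ratio[ok], tolerance = 1e-12)
})

test_that("true parameter ratios centre on the preset medians", {
  preset <- pcsilac_preset(seed = 20)          # n = 911
  sim <- generate_pcsilac_series(preset)
  expect_equal(median(sim$truth$kd_treated / sim$truth$kd_ctrl), 1.73,
               tolerance = 0.1)
  expect_equal(median(sim$truth$vs_treated / sim$truth$vs_ctrl), 0.57,
               tolerance = 0.1)
  expect_equal(median(sim$truth$thalf_ctrl), 55.9, tolerance = 0.1)
})

test_that("series generation honours the stated signal model", {
  # spot values of the noiseless curves
  expect_equal(100 * exp(-0.1 * 6), 54.88116, tolerance = 1e-5)
  preset <- pcsilac_preset(n_proteins = 3, noise_cv = 0, seed = 2)
  sim <- generate_pcsilac_series(preset)
  s <- sim$series
  expect_true(all(s$new_signal[s$time_h == 0] == 0))
  expect_true(all(s$old_signal > 0))
  one <- s[s$protein == "P0001" & s$condition == "treated" &
             s$replicate == 1, ]
  tr <- sim$truth[1, ]
  h0 <- tr$vs_ctrl / tr$kd_ctrl
  expect_equal(one$old_signal, h0 * exp(-tr$kd_treated * one$time_h),
               tolerance = 1e-12)
  expect_equal(one$new_signal[one$time_h == 20],
               tr$vs_treated / tr$kd_treated *
                 (1 - exp(-tr$kd_treated * 20)), tolerance = 1e-12)
})

test_that("decay estimator bias stays below 5% under 10% CV noise", {
  set.seed(33)
  kd <- 0.05
  times <- rep(c(0, 6, 20), 2)
  sdl <- sqrt(log(1 + 0.1^2))
  est <- replicate(2000, {
    y <- 100 * exp(-kd * times) * rlnorm(length(times), 0, sdl)
    fit_decay(times, y)
  })
  expect_lt(abs(mean(est) - kd) / kd, 0.05)
})

test_that("category summaries average fits and report raw half-lives", {
  fits <- data.frame(protein = c("A", "B", "C"),
                     thalf_control = c(300, 342, 10),
                     thalf_treated = c(40, 47, Inf),
                     adj_log2_vs_ratio = c(-1, -0.5, 0),
                     adj_log2_kd_ratio = c(1, 0.5, 0),
                     adj_log2_abundance_ratio = c(-2, -1, 0),
                     adj_log2_thalf_ratio = c(-1, -0.5, 0),
                     stringsAsFactors = FALSE)
  s <- summarize_category(fits, list(pair = c("A", "B"), solo = "C"))
  pair <- s[s$category == "pair", ]
  expect_equal(pair$mean_thalf_control, 321)
  expect_equal(pair$mean_adj_log2_vs_ratio, -0.75)
  solo <- s[s$category == "solo", ]
  expect_equal(solo$n, 1)
  expect_equal(solo$mean_thalf_control, 10)
  expect_true(is.na(solo$mean_thalf_treated))   # Inf excluded from means
  expect_null(summarize_category(fits, list(none = "ZZZ")))
  # whole-dataset adjusted means vanish only if values are median-centred;
  # here centring a single category reproduces adjust_by_global_median
  expect_equal(median(adjust_by_global_median(fits$adj_log2_kd_ratio)), 0)
})
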