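simple_counts <- function(neg, targets, refs = c(REF1 = 400, REF2 = 900,
                                                 REF3 = 1600), ns = 2) {
  probes <- c(names(neg), "POS1", "POS2", names(refs), names(targets))
  counts <- matrix(rep(c(neg, c(POS1 = 20000, POS2 = 5000), refs, targets),
                       ns),
                   nrow = length(probes),
                   dimnames = list(probes, sprintf("S%d", seq_len(ns))))
  cls <- c(rep("negative", length(neg)), rep("positive", 2),
           rep("reference", length(refs)), rep("target", length(targets)))
  names(cls) <- probes
  list(counts = counts, cls = cls)
}

test_that("background threshold is mean plus two sample sds, floored at 1", {
  x <- simple_counts(neg = c(NEG1 = 2, NEG2 = 4, NEG3 = 6),
                     targets = c(T1 = 10, T2 = 5, T3 = 300))
  ds <- make_ns_dataset(x$counts, x$cls)
  bc <- background_correct(ds)
  thr <- attr(bc, "background_threshold")
  expect_equal(unname(thr), c(8, 8))          # 4 + 2 * sd(2,4,6) = 8
  expect_equal(unname(bc$counts["T1", ]), c(2, 2))
  expect_equal(unname(bc$counts["T2", ]), c(1, 1))   # 5 - 8 -> floored to 1
  expect_equal(unname(bc$counts["T3", ]), c(292, 292))
  expect_equal(bc$counts["NEG1", ], ds$counts["NEG1", ])  # controls untouched
  # all-zero negatives: threshold 0, zero counts floored to 1
  x0 <- simple_counts(neg = c(NEG1 = 0, NEG2 = 0),
                      targets = c(T1 = 0, T2 = 7))
  bc0 <- background_correct(make_ns_dataset(x0$counts, x0$cls))
  expect_equal(unname(bc0$counts["T1", ]), c(1, 1))
  expect_equal(unname(bc0$counts["T2", ]), c(7, 7))
})

test_that("positive-control QC gates on the max/min ratio of sample means", {
  mk <- function(means) {
    counts <- rbind(NEG1 = rep(1, length(means)), NEG2 = rep(2, length(means)),
                    POS1 = means * 2 - 100, POS2 = rep(100, length(means)),
                    REF1 = rep(500, length(means)),
                    T1 = rep(50, length(means)))
    colnames(counts) <- sprintf("S%d", seq_along(means))
    cls <- c(NEG1 = "negative", NEG2 = "negative", POS1 = "positive",
             POS2 = "positive", REF1 = "reference", T1 = "target")
    qc_positive_controls(make_ns_dataset(counts, cls))
  }
  q <- mk(c(100, 150, 250))
  expect_equal(q$ratio, 2.5)
  expect_true(q$pass)
  q2 <- mk(c(100, 350))
  expect_equal(q2$ratio, 3.5)
  expect_false(q2$pass)
  q3 <- mk(c(120, 120))
  expect_equal(q3$ratio, 1.0)
  expect_true(q3$pass)
})

test_that("planted QC failure is caught by the gate", {
  sim <- generate_nanostring_counts(nano_sim_config(qc_failure = TRUE,
                                                    seed = 6))
  expect_false(qc_positive_controls(sim$dataset)$pass)
  sim_ok <- generate_nanostring_counts(nano_sim_config(seed = 6))
  expect_true(qc_positive_controls(sim_ok$dataset)$pass)
})

test_that("geNorm M values match the brute-force oracle", {
  set.seed(7)
  counts <- matrix(exp(rnorm(5 * 6, log(500), 0.4)), nrow = 5,
                   dimnames = list(sprintf("REF%d", 1:5), sprintf("S%d", 1:6)))
  counts["REF4", ] <- counts["REF4", ] * exp(rnorm(6, 0, 1.5))  # unstable
  full <- rbind(counts,
                NEG1 = rep(1, 6), NEG2 = rep(2, 6),
                POS1 = rep(1e4, 6), POS2 = rep(100, 6),
                T1 = rep(50, 6))
  cls <- setNames(c(rep("reference", 5), "negative", "negative",
                    "positive", "positive", "target"), rownames(full))
  ds <- make_ns_dataset(full, cls, conditions = rep(c("DMSO", "GA"), 3))
  res <- genorm_select(ds, k = 3)
  expect_equal(sort(res$ranking$M[match(sprintf("REF%d", 1:5),
                                        res$ranking$gene)]),
               sort(genorm_oracle(counts)), tolerance = 1e-12)
  expect_false("REF4" %in% res$selected)   # the noisy gene goes first
  expect_length(res$selected, 3)
})

test_that("degenerate geNorm inputs behave deterministically", {
  # two perfectly proportional candidates have pairwise sd 0
  counts <- rbind(REF1 = c(100, 200, 400), REF2 = c(50, 100, 200),
                  REF3 = c(100, 150, 100),
                  NEG1 = rep(1, 3), NEG2 = rep(1, 3),
                  POS1 = rep(1e4, 3), POS2 = rep(100, 3), T1 = rep(50, 3))
  colnames(counts) <- sprintf("S%d", 1:3)
  cls <- setNames(c(rep("reference", 3), "negative", "negative",
                    "positive", "positive", "target"), rownames(counts))
  ds <- make_ns_dataset(counts, cls, conditions = c("DMSO", "GA", "GA"))
  res <- suppressWarnings(genorm_select(ds, k = 3))
  m <- res$ranking$M[match(c("REF1", "REF2"), res$ranking$gene)]
  oracle <- genorm_oracle(counts[1:3, ])
  expect_equal(m, oracle[1:2])
  # identical samples: all M = 0, input order kept
  const <- counts
  const[1:3, ] <- c(100, 300, 700)
  ds2 <- make_ns_dataset(const, cls, conditions = c("DMSO", "GA", "GA"))
  res2 <- suppressWarnings(genorm_select(ds2, k = 3))
  expect_equal(unname(res2$M_selected), rep(0, 3))
  expect_equal(res2$selected, c("REF1", "REF2", "REF3"))
  expect_error(genorm_select(ds, k = 2, candidates = c("REF1", "REF2")),
               "at least 3")
})

test_that("normalization scales by reference geomeans and is scale invariant", {
  counts <- rbind(NEG1 = c(1, 1), NEG2 = c(1, 1),
                  POS1 = c(1e4, 1e4), POS2 = c(100, 100),
                  REF1 = c(4, 8), REF2 = c(9, 18),
                  T1 = c(100, 300))
  colnames(counts) <- c("S1", "S2")
  cls <- setNames(c("negative", "negative", "positive", "positive",
                    "reference", "reference", "target"), rownames(counts))
  ds <- make_ns_dataset(counts, cls)
  nm <- normalize_counts(ds, c("REF1", "REF2"))
  expect_equal(unname(attr(nm, "size_factor")), c(6, 12))  # sqrt(4*9), sqrt(8*18)
  # reference geomeans equalized across samples
  g1 <- exp(mean(log(nm$counts[c("REF1", "REF2"), "S1"])))
  g2 <- exp(mean(log(nm$counts[c("REF1", "REF2"), "S2"])))
  expect_equal(g1, g2)
  # doubling every count of S2: the sample's scaling cancels, so all
  # cross-sample ratios (hence fold-changes) are unchanged; the global
  # anchor shifts every sample by the same 2^(1/ns) factor
  counts2 <- counts
  counts2[, "S2"] <- counts2[, "S2"] * 2
  nm2 <- normalize_counts(make_ns_dataset(counts2, cls), c("REF1", "REF2"))
  expect_equal(nm2$counts["T1", "S2"] / nm2$counts["T1", "S1"],
               nm$counts["T1", "S2"] / nm$counts["T1", "S1"])
  expect_equal(unname(nm2$counts["T1", ] / nm$counts["T1", ]),
               rep(sqrt(2), 2))
  expect_equal(fold_changes(nm2, genes = "T1"),
               fold_changes(nm, genes = "T1"))
})

test_that("fold-changes are geomean ratios, antisymmetric in the labels", {
  counts <- rbind(NEG1 = rep(1, 4), NEG2 = rep(1, 4),
                  POS1 = rep(1e4, 4), POS2 = rep(100, 4),
                  REF1 = rep(100, 4),
                  T1 = c(1, 4, 2, 8), T2 = rep(6, 4))
  colnames(counts) <- sprintf("S%d", 1:4)
  cls <- setNames(c("negative", "negative", "positive", "positive",
                    "reference", "target", "target"), rownames(counts))
  ds <- make_ns_dataset(counts, cls,
                        conditions = c("DMSO", "DMSO", "GA", "GA"))
  fc <- fold_changes(ds)
  expect_equal(unname(fc["T1"]), 1.0)     # geomean(2,8)/geomean(1,4) = 2
  expect_equal(unname(fc["T2"]), 0.0)
  rev <- fold_changes(ds, numerator = "DMSO", denominator = "GA")
  expect_equal(unname(rev), unname(-fc))
})

test_that("the pipeline recovers planted fold-changes exactly at zero noise", {
  fc_map <- c(T001 = 1.5, T002 = -2, T010 = 0.25)
  sim <- generate_nanostring_counts(
    nano_sim_config(n_targets = 12, fold_change_map = fc_map,
                    count_noise_logsd = 0, seed = 19))
  res <- process_nanostring(sim$dataset)
  got <- setNames(res$fold_changes$log2_fc, res$fold_changes$gene)
  expect_equal(got[names(sim$truth)], sim$truth, tolerance = 1e-9)
  # determinism of the generator
  sim2 <- generate_nanostring_counts(
    nano_sim_config(n_targets = 12, fold_change_map = fc_map,
                    count_noise_logsd = 0, seed = 19))
  expect_identical(sim$dataset$counts, sim2$dataset$counts)
})

test_that("10% log-noise keeps 95% of genes within 0.2 log2 units", {
  n <- 1000
  set.seed(27)
  fc_map <- setNames(round(runif(n, -2, 2), 2), sprintf("T%03d", 1:n))
  # baselines well above background isolate the stated noise condition
  sim <- generate_nanostring_counts(
    nano_sim_config(n_targets = n, fold_change_map = fc_map,
                    count_noise_logsd = 0.1,
                    baseline_count_range = c(500, 5000), seed = 27))
  res <- process_nanostring(sim$dataset)
  got <- setNames(res$fold_changes$log2_fc, res$fold_changes$gene)
  frac <- mean(abs(got[names(sim$truth)] - sim$truth) <= 0.2)
  # 0.95 minus two binomial standard errors: finite-sample allowance
  expect_gte(frac, 0.95 - 2 * sqrt(0.95 * 0.05 / n))
})
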