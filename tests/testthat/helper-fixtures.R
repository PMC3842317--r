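# Small in-code fixtures shared across test files.

# Build a protein-group table from per-replicate ratio vectors.
# ratios_t6 / ratios_t20: list per protein of length-R numeric (NA allowed).
make_pg_table <- function(ratios_t6, ratios_t20 = ratios_t6,
                          evidence = 3L, ids = NULL,
                          contaminant = NULL, reverse = NULL) {
  n <- length(ratios_t6)
  R <- length(ratios_t6[[1]])
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  df <- data.frame(group_ids = ids, gene_name = toupper(ids),
                   stringsAsFactors = FALSE)
  ev <- if (!is.list(evidence)) {
    lapply(seq_len(n), function(i) rep(evidence, R))
  } else evidence
  for (r in seq_len(R)) {
    df[[sprintf("ratio_r%d_t6", r)]] <-
      vapply(ratios_t6, `[`, numeric(1), r)
    df[[sprintf("evidence_r%d_t6", r)]] <-
      vapply(ev, `[`, numeric(1), r)
    df[[sprintf("ratio_r%d_t20", r)]] <-
      vapply(ratios_t20, `[`, numeric(1), r)
    df[[sprintf("evidence_r%d_t20", r)]] <-
      vapply(ev, `[`, numeric(1), r)
  }
  df$contaminant <- if (is.null(contaminant)) "" else contaminant
  df$reverse <- if (is.null(reverse)) "" else reverse
  protein_group_table(df)
}

# Noise-free two-point decay/synthesis series for one protein+condition.
make_series <- function(kd, vs, h0 = 100, times = c(0, 6, 20),
                        protein = "P1", condition = "control") {
  data.frame(protein = protein, condition = condition,
             replicate = 1L, time_h = times,
             old_signal = h0 * exp(-kd * times),
             new_signal = if (kd > 0) (vs / kd) * (1 - exp(-kd * times))
                          else vs * times,
             stringsAsFactors = FALSE)
}

# Minimal nCounter dataset built by hand.
make_ns_dataset <- function(counts, classes, conditions = NULL) {
  ns <- ncol(counts)
  if (is.null(conditions)) {
    conditions <- rep(c("DMSO", "GA"), length.out = ns)
  }
  samples <- data.frame(name = colnames(counts), condition = conditions,
                        replicate = seq_len(ns), stringsAsFactors = FALSE)
  nanostring_dataset(counts, classes, samples)
}
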