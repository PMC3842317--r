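#' Temporal model templates for correlation clustering
#'
#' The clustering scheme matches each protein trajectory (a log2-ratio time
#' course with a prepended (t = 0, 0) reference point) against a fixed set of
#' qualitative templates encoding all possible directions of change over two
#' time points (0 = no change, 1 = up, -1 = down), plus, where both changes
#' share a sign, a faster/slower distinction (2 vs 1). Twelve templates
#' describe change; the thirteenth, all-zero pattern stands for "no
#' significant change" and is assigned by the significance test, not by
#' correlation. Proteins quantified at only one time point fall into an
#' extra class, 14.
#'
#' @param include_null if `TRUE`, append the all-zero pattern (row `"13"`).
#' @return integer matrix with one template per row (rownames are cluster
#'   labels `"1"`..`"12"`, optionally `"13"`) and columns `t0`, `t1`, `t2`.
#' @export
cluster_patterns <- function(include_null = FALSE) {
  m <- rbind(
    c(0,  2,  1),
    c(0,  1,  2),
    c(0,  1,  1),
    c(0,  1,  0),
    c(0,  1, -1),
    c(0,  0,  1),
    c(0,  0, -1),
    c(0, -1,  1),
    c(0, -1,  0),
    c(0, -1, -1),
    c(0, -1, -2),
    c(0, -2, -1)
  )
  if (include_null) m <- rbind(m, c(0, 0, 0))
  dimnames(m) <- list(as.character(seq_len(nrow(m))), c("t0", "t1", "t2"))
  m
}

#' Number of the cluster reserved for non-significant proteins
#' @export
CLUSTER_NO_CHANGE <- 13L

#' Number of the cluster reserved for proteins seen at a single time point
#' @export
CLUSTER_ONE_TIMEPOINT <- 14L
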