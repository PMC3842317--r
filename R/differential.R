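#' One-sample t-test of log2 ratios against zero
#'
#' Tests the null hypothesis that the mean log2 ratio is 0 using the
#' one-sample Student t statistic `t = mean / (sd / sqrt(n))` with sample
#' standard deviation (n - 1 denominator), df = n - 1 and a two-tailed
#' p-value. Degenerate inputs with zero spread follow the convention
#' p = 1 when the mean is also 0 and p = 0 otherwise, so that noise-free
#' fixtures behave deterministically.
#'
#' @param values numeric vector of log2 ratios (NAs dropped).
#' @return list with `t`, `df`, `p` (all `NA` when fewer than 2 values).
#' @export
one_sample_ttest <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  m <- mean(x)
  s <- stats::sd(x)
  df <- n - 1
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(m) * Inf, df = df, p = 0))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up procedure: with order statistics p_(1) <= ... <=
#' p_(m), the adjusted value for p_(i) is min over j >= i of
#' min(m * p_(j) / j, 1), returned in the input order. NAs are preserved
#' and excluded from m.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- pvalues
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  if (m == 0) return(p)
  out <- p
  o <- order(p[ok], decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[ok][o]))[ro]
  out[ok] <- adj
  out
}

#' Per-time-point significance calling on a protein-group table
#'
#' For each protein and time point, runs [one_sample_ttest()] on the
#' replicate log2 ratios and applies [bh_adjust()] across proteins. The
#' adjustment is per time point by default; `adjust = "pooled"` corrects
#' across both time points jointly.
#'
#' @param table protein-group table (oriented), normally occurrence-filtered.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param adjust `"per_timepoint"` (default) or `"pooled"`.
#' @return data.frame with one row per protein: `group_ids`, `gene_name`,
#'   per time point `n_t*`, `mean_log2_t*`, `median_log2_t*`, `t_t*`,
#'   `df_t*`, `p_t*`, `q_t*`, `significant_t*`, plus `significant_any` and
#'   `n_detected_timepoints`.
#' @export
test_differential <- function(table, alpha = 0.05,
                              adjust = c("per_timepoint", "pooled")) {
  adjust <- match.arg(adjust)
  lay <- pg_layout(table)
  res <- data.frame(group_ids = table$group_ids,
                    gene_name = table$gene_name,
                    stringsAsFactors = FALSE)
  pcols <- character()
  for (tp in lay$timepoints) {
    l2 <- log2(pg_matrix(table, tp))
    tt <- apply(l2, 1, function(x) unlist(one_sample_ttest(x)))
    res[[sprintf("n_t%d", tp)]] <- rowSums(!is.na(l2))
    res[[sprintf("mean_log2_t%d", tp)]] <- rowMeans(l2, na.rm = TRUE)
    res[[sprintf("median_log2_t%d", tp)]] <- median_log2(table, tp)
    res[[sprintf("t_t%d", tp)]] <- tt["t", ]
    res[[sprintf("df_t%d", tp)]] <- tt["df", ]
    res[[sprintf("p_t%d", tp)]] <- tt["p", ]
    pcols <- c(pcols, sprintf("p_t%d", tp))
  }
  if (adjust == "per_timepoint") {
    for (pc in pcols) {
      res[[sub("^p_", "q_", pc)]] <- bh_adjust(res[[pc]])
    }
  } else {
    pooled <- bh_adjust(unlist(res[pcols], use.names = FALSE))
    k <- nrow(res)
    for (i in seq_along(pcols)) {
      res[[sub("^p_", "q_", pcols[i])]] <- pooled[((i - 1) * k + 1):(i * k)]
    }
  }
  sig_any <- rep(FALSE, nrow(res))
  for (tp in lay$timepoints) {
    s <- !is.na(res[[sprintf("q_t%d", tp)]]) &
      res[[sprintf("q_t%d", tp)]] < alpha
    res[[sprintf("significant_t%d", tp)]] <- s
    sig_any <- sig_any | s
  }
  res$significant_any <- sig_any
  det <- rep(0L, nrow(res))
  for (tp in lay$timepoints) det <- det + (res[[sprintf("n_t%d", tp)]] > 0)
  res$n_detected_timepoints <- det
  res
}

#' Assign one trajectory to a temporal pattern cluster
#'
#' Implements model-correlation clustering of a two-time-point log2-ratio
#' trajectory with a prepended (0, 0) reference: proteins quantified at
#' only one time point go to cluster 14; proteins with no significant time
#' point go to cluster 13; every other trajectory is assigned to the change
#' template (see [cluster_patterns()]) with which its Pearson correlation
#' is highest. Correlation ties (within 1e-9) resolve to the
#' lowest-numbered template; a flat trajectory flagged significant is
#' inconsistent and falls back to cluster 13 with a warning.
#'
#' @param trajectory numeric length-3 vector `(0, m_t1, m_t2)` of median
#'   log2 ratios with the reference time point prepended.
#' @param significant was the protein significant at >= 1 time point?
#' @param n_detected number of time points with quantitation (1 or 2).
#' @return list with `cluster` (1..14) and `correlation` (`NA` for 13/14).
#' @export
assign_cluster <- function(trajectory, significant, n_detected = 2) {
  if (n_detected < 2) {
    return(list(cluster = CLUSTER_ONE_TIMEPOINT, correlation = NA_real_))
  }
  if (!isTRUE(significant)) {
    return(list(cluster = CLUSTER_NO_CHANGE, correlation = NA_real_))
  }
  stopifnot(length(trajectory) == 3)
  if (trajectory[1] != 0) stop("trajectory must start with the 0 reference")
  if (stats::sd(trajectory) == 0) {
    warning("flat trajectory flagged significant; assigning no-change cluster")
    return(list(cluster = CLUSTER_NO_CHANGE, correlation = NA_real_))
  }
  templ <- cluster_patterns()
  cors <- apply(templ, 1, function(m) stats::cor(trajectory, m))
  best <- which(cors >= max(cors) - 1e-9)[1]
  list(cluster = as.integer(best), correlation = unname(cors[best]))
}

#' Cluster every significant protein in a test-result table
#'
#' @param tests output of [test_differential()].
#' @return data.frame `group_ids`, `cluster`, `best_correlation`.
#' @export
assign_clusters <- function(tests) {
  lay_tp <- as.integer(sub("^median_log2_t", "",
                           grep("^median_log2_t", names(tests), value = TRUE)))
  lay_tp <- sort(lay_tp)
  stopifnot(length(lay_tp) == 2)
  m1 <- tests[[sprintf("median_log2_t%d", lay_tp[1])]]
  m2 <- tests[[sprintf("median_log2_t%d", lay_tp[2])]]
  out <- data.frame(group_ids = tests$group_ids,
                    cluster = NA_integer_,
                    best_correlation = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tests))) {
    traj <- c(0, m1[i], m2[i])
    traj[is.na(traj)] <- 0  # unused when n_detected < 2
    a <- assign_cluster(traj, tests$significant_any[i],
                        tests$n_detected_timepoints[i])
    out$cluster[i] <- a$cluster
    out$best_correlation[i] <- a$correlation
  }
  out
}

#' Hypergeometric enrichment of annotation terms in a query set
#'
#' For each term, compares the number of query genes carrying the term with
#' the number expected from the background: enrichment = (k/n) / (K/N) and
#' an upper-tail hypergeometric p-value P(X >= k), BH-adjusted across
#' terms. A replacement for web enrichment tools when the background is
#' "all identified proteins".
#'
#' @param query_genes character vector (must be a subset of the background).
#' @param term_map data.frame with columns `gene`, `term`.
#' @param background_genes character vector defining the universe.
#' @return data.frame per term: `term`, `k`, `n`, `K`, `N`, `enrichment`,
#'   `p`, `q`, sorted by p.
#' @export
enrichment_hypergeometric <- function(query_genes, term_map,
                                      background_genes) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (!all(query_genes %in% background_genes)) {
    stop("query genes must be a subset of the background")
  }
  stopifnot(all(c("gene", "term") %in% names(term_map)))
  term_map <- unique(term_map[c("gene", "term")])
  n <- length(query_genes)
  N <- length(background_genes)
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    genes <- term_map$gene[term_map$term == tm]
    K <- sum(background_genes %in% genes)
    if (K == 0) {
      warning("term '", tm, "' absent from background; skipped")
      return(NULL)
    }
    k <- sum(query_genes %in% genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               enrichment = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), enrichment = numeric(),
                      p = numeric(), q = numeric()))
  }
  res$q <- bh_adjust(res$p)
  res[order(res$p), , drop = FALSE]
}
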