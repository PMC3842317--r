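#' Flag protein groups whose replicate ratios spread beyond a fold factor
#'
#' A protein group is an outlier when, at any single time point, the ratio
#' between the largest and the smallest available replicate H/L values
#' exceeds `factor` (default 1.41, i.e. a pairwise difference of about 0.5
#' on the log2 scale). A time point with fewer than two available
#' replicates contributes no pair and cannot flag the row.
#'
#' @param table protein-group table (oriented ratios).
#' @param factor maximum tolerated max/min replicate ratio (> 1).
#' @return character vector of flagged `group_ids`.
#' @export
detect_outliers <- function(table, factor = 1.41) {
  stopifnot(factor > 1)
  lay <- pg_layout(table)
  flagged <- rep(FALSE, nrow(table))
  for (tp in lay$timepoints) {
    m <- pg_matrix(table, tp)
    spread <- apply(m, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) return(1)
      max(x) / min(x)
    })
    flagged <- flagged | (spread > factor)
  }
  table$group_ids[flagged]
}

#' Quality-filter a protein-group table
#'
#' Applies, in order: removal of database contaminants and reverse hits;
#' removal of groups matching a lab contaminant list; blanking of ratio
#' cells backed by fewer than `min_evidence` evidences; per-time-point
#' blanking of proteins quantified in fewer than `min_replicates`
#' replicates at that time point; removal of fold-spread outliers
#' ([detect_outliers()]); and removal of rows left without any quantified
#' time point. The result is the "quality-filtered" dataset: every retained
#' protein is quantified in at least `min_replicates` replicates at one or
#' more time points.
#'
#' @param table protein-group table (oriented ratios).
#' @param lab_contaminant_ids accessions to drop regardless of flags; a
#'   group is dropped when any of its members matches.
#' @param outlier_factor fold-spread threshold passed to [detect_outliers()].
#' @param min_evidence minimum evidences behind a ratio cell (default 2;
#'   cells below are blanked as "single evidences").
#' @param min_replicates minimum replicates per retained time point.
#' @return list with `table` (filtered) and `report` (a `filter_report`:
#'   rows removed per rule plus retained; removed + retained = input).
#' @export
filter_quality <- function(table, lab_contaminant_ids = character(),
                           outlier_factor = 1.41, min_evidence = 2,
                           min_replicates = 2) {
  lay <- pg_layout(table)
  n_in <- nrow(table)
  report <- list(input = n_in)

  is_con <- table$contaminant == "+"
  is_rev <- table$reverse == "+" & !is_con
  members <- strsplit(table$group_ids, ";", fixed = TRUE)
  is_lab <- vapply(members, function(g) any(g %in% lab_contaminant_ids),
                   logical(1)) & !is_con & !is_rev
  report$contaminant <- sum(is_con)
  report$reverse <- sum(is_rev)
  report$lab_list <- sum(is_lab)
  table <- table[!(is_con | is_rev | is_lab), , drop = FALSE]

  # blank single-evidence ratio cells
  blanked <- 0L
  for (tp in lay$timepoints) {
    for (r in lay$replicates) {
      rc <- sprintf("ratio_r%d_t%d", r, tp)
      ec <- sprintf("evidence_r%d_t%d", r, tp)
      low <- !is.na(table[[rc]]) & table[[ec]] < min_evidence
      blanked <- blanked + sum(low)
      table[[rc]][low] <- NA_real_
    }
  }
  report$single_evidence_cells <- blanked

  # per time point: drop values present in fewer than min_replicates reps
  dropped_tp <- 0L
  for (tp in lay$timepoints) {
    m <- pg_matrix(table, tp)
    avail <- rowSums(!is.na(m))
    kill <- avail > 0 & avail < min_replicates
    dropped_tp <- dropped_tp + sum(kill)
    for (r in lay$replicates) {
      rc <- sprintf("ratio_r%d_t%d", r, tp)
      table[[rc]][kill] <- NA_real_
    }
  }
  report$under_replicated_timepoints <- dropped_tp

  out_ids <- detect_outliers(table, outlier_factor)
  report$outlier <- length(out_ids)
  table <- table[!table$group_ids %in% out_ids, , drop = FALSE]

  any_val <- rep(FALSE, nrow(table))
  for (tp in lay$timepoints) {
    any_val <- any_val | rowSums(!is.na(pg_matrix(table, tp))) > 0
  }
  report$empty <- sum(!any_val)
  table <- table[any_val, , drop = FALSE]

  report$retained <- nrow(table)
  list(table = table, report = structure(report, class = "filter_report"))
}

#' @export
print.filter_report <- function(x, ...) {
  cat("protein-group quality filter\n")
  cat(sprintf("  input rows:              %d\n", x$input))
  cat(sprintf("  contaminants removed:    %d\n", x$contaminant))
  cat(sprintf("  reverse hits removed:    %d\n", x$reverse))
  cat(sprintf("  lab-list removed:        %d\n", x$lab_list))
  cat(sprintf("  single-evidence cells:   %d (blanked)\n",
              x$single_evidence_cells))
  cat(sprintf("  under-replicated tps:    %d (blanked)\n",
              x$under_replicated_timepoints))
  cat(sprintf("  fold-spread outliers:    %d\n", x$outlier))
  cat(sprintf("  emptied rows removed:    %d\n", x$empty))
  cat(sprintf("  retained:                %d\n", x$retained))
  invisible(x)
}

#' Keep protein groups quantified in every replicate
#'
#' Occurrence filter preceding the significance analysis: a row is kept
#' when at least one time point has a ratio in every replicate. (Requiring
#' both time points would empty the single-time-point cluster.)
#'
#' @param table protein-group table.
#' @return filtered table.
#' @export
filter_occurrence <- function(table) {
  lay <- pg_layout(table)
  keep <- rep(FALSE, nrow(table))
  for (tp in lay$timepoints) {
    keep <- keep | rowSums(!is.na(pg_matrix(table, tp))) == length(lay$replicates)
  }
  table[keep, , drop = FALSE]
}
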