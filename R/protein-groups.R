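#' Protein-group quantitation tables
#'
#' A protein-group table is a plain `data.frame` with one row per protein
#' group and a regular column layout: `group_ids` (semicolon-joined
#' accessions), `gene_name`, one `ratio_r<r>_t<t>` and one
#' `evidence_r<r>_t<t>` column per replicate `r` and time point `t` (hours),
#' and `contaminant` / `reverse` flag columns holding `"+"` or `""`.
#' Ratios are heavy/light quantitation values oriented treated/control;
#' missing quantitation is `NA`, never 0.
#'
#' @param df data.frame with the column layout described above.
#' @return `df`, validated, with class `protein_group_table` prepended.
#' @export
protein_group_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("group_ids", "gene_name", "contaminant", "reverse")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("protein-group table lacks columns: ", paste(miss, collapse = ", "))
  }
  lay <- pg_layout(df)
  if (length(lay$replicates) < 1 || length(lay$timepoints) < 1) {
    stop("no ratio_r<r>_t<t> columns found")
  }
  for (cn in c(lay$ratio_cols, lay$evidence_cols)) {
    if (!is.numeric(df[[cn]])) stop("column ", cn, " is not numeric")
  }
  rat <- unlist(df[lay$ratio_cols], use.names = FALSE)
  if (any(rat <= 0, na.rm = TRUE)) stop("ratios must be strictly positive")
  if (anyDuplicated(df$group_ids)) stop("duplicated group_ids")
  class(df) <- unique(c("protein_group_table", class(df)))
  df
}

#' Column layout of a protein-group table
#'
#' Parses the `ratio_r<r>_t<t>` / `evidence_r<r>_t<t>` column names and
#' returns the replicate indices and time points they encode.
#'
#' @param table protein-group table (or bare data.frame with the layout).
#' @return list with `replicates`, `timepoints` (hours, sorted),
#'   `ratio_cols`, `evidence_cols`.
#' @export
pg_layout <- function(table) {
  nm <- names(table)
  rc <- grep("^ratio_r[0-9]+_t[0-9]+$", nm, value = TRUE)
  ec <- grep("^evidence_r[0-9]+_t[0-9]+$", nm, value = TRUE)
  reps <- sort(unique(as.integer(sub("^ratio_r([0-9]+)_t[0-9]+$", "\\1", rc))))
  tps <- sort(unique(as.integer(sub("^ratio_r[0-9]+_t([0-9]+)$", "\\1", rc))))
  list(replicates = reps, timepoints = tps, ratio_cols = rc, evidence_cols = ec)
}

#' Ratio matrix at one time point
#'
#' @param table protein-group table.
#' @param timepoint time point in hours (must match a `_t<t>` suffix).
#' @param what `"ratio"` or `"evidence"`.
#' @return numeric matrix, rows = protein groups, columns = replicates.
#' @export
pg_matrix <- function(table, timepoint, what = c("ratio", "evidence")) {
  what <- match.arg(what)
  lay <- pg_layout(table)
  if (!timepoint %in% lay$timepoints) {
    stop("no columns for time point ", timepoint, "h")
  }
  cols <- sprintf("%s_r%d_t%d", what, lay$replicates, timepoint)
  m <- as.matrix(table[cols])
  dimnames(m) <- list(table$group_ids, sprintf("r%d", lay$replicates))
  m
}

#' Per-protein median of log2 ratios at one time point
#'
#' The median over available replicates of log2(H/L), the summary used for
#' trajectory construction and model-correlation clustering.
#'
#' @inheritParams pg_matrix
#' @return named numeric vector (NA where no replicate has a value).
#' @export
median_log2 <- function(table, timepoint) {
  m <- log2(pg_matrix(table, timepoint))
  apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else stats::median(x)
  })
}

#' Read a protein-group table, reorienting label-swapped replicates
#'
#' In a label-swap design one replicate carries the light label on treated
#' cells; its measured H/L ratios are control/treated and must be inverted
#' (r -> 1/r) so that every stored ratio is treated/control.
#'
#' @param path tab-separated file with the protein-group column layout.
#' @param label_swap integer vector of replicate indices measured with
#'   swapped labels (default none).
#' @return a [protein_group_table].
#' @export
read_protein_groups <- function(path, label_swap = integer()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  lay <- pg_layout(raw)
  for (cn in c(lay$ratio_cols, lay$evidence_cols)) {
    v <- raw[[cn]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      stop("malformed numeric value in column ", cn, ", row ", bad[1],
           ": '", v[bad[1]], "'")
    }
    raw[[cn]] <- num
  }
  for (cn in c("contaminant", "reverse")) {
    if (!cn %in% names(raw)) raw[[cn]] <- ""
    raw[[cn]][is.na(raw[[cn]])] <- ""
  }
  tab <- protein_group_table(raw)
  orient_ratios(tab, label_swap)
}

#' Invert H/L ratios of label-swapped replicates
#'
#' @param table protein-group table in as-measured orientation.
#' @param label_swap replicate indices whose ratios are control/treated.
#' @return table with every ratio oriented treated/control.
#' @export
orient_ratios <- function(table, label_swap = integer()) {
  lay <- pg_layout(table)
  bad <- setdiff(label_swap, lay$replicates)
  if (length(bad) > 0) stop("unknown replicate index: ", paste(bad, collapse = ", "))
  for (r in label_swap) {
    for (tp in lay$timepoints) {
      cn <- sprintf("ratio_r%d_t%d", r, tp)
      table[[cn]] <- 1 / table[[cn]]
    }
  }
  table
}

#' Write a protein-group table as TSV
#'
#' @param table protein-group table.
#' @param path output file.
#' @export
write_protein_groups <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
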