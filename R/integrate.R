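#' Align two tables keyed by protein-group identifier lists
#'
#' Two protein groups are matched only when their identifier sets are
#' identical (order-insensitive): a group must contain exactly the same
#' accessions in both datasets. Unmatched rows from either side are
#' retained with the other side's fields absent, so the joint table has
#' |A| + |B| - |matched| rows.
#'
#' @param a,b data.frames each with a `group_ids` column (semicolon-joined
#'   accessions); id sets must be unique within each table.
#' @param suffixes column-name suffixes for overlapping columns.
#' @return joint data.frame with `group_ids` (canonical sorted form) and a
#'   logical `matched` column.
#' @export
align_datasets <- function(a, b, suffixes = c(".x", ".y")) {
  stopifnot("group_ids" %in% names(a), "group_ids" %in% names(b))
  canon <- function(ids) {
    vapply(strsplit(ids, ";", fixed = TRUE),
           function(g) paste(sort(g), collapse = ";"), "")
  }
  ka <- canon(a$group_ids)
  kb <- canon(b$group_ids)
  if (anyDuplicated(ka)) stop("duplicate id sets in first table")
  if (anyDuplicated(kb)) stop("duplicate id sets in second table")
  a2 <- a
  b2 <- b
  a2$group_ids <- ka
  b2$group_ids <- kb
  joint <- merge(a2, b2, by = "group_ids", all = TRUE, suffixes = suffixes,
                 sort = TRUE)
  joint$matched <- joint$group_ids %in% intersect(ka, kb)
  joint
}

#' Export node attributes for network visualisation
#'
#' Selects proteins by UNcorrected p-value (default p < 0.05 at at least
#' one time point -- network exploration privileges connectivity over
#' stringency) and writes a table loadable as node attributes: ids, gene
#' names, log2 ratios and a symmetric colour value per time point mapping
#' log2 ratios linearly onto [-1, 1] (red-to-blue thermogram; 0 = white),
#' clamped at +/- `clamp_log2`.
#'
#' @param tests output of [test_differential()].
#' @param path optional TSV output path.
#' @param alpha raw p-value threshold (default 0.05).
#' @param clamp_log2 |log2 ratio| mapped to full colour saturation
#'   (default 2).
#' @return the node table, invisibly if written to `path`.
#' @export
export_node_attributes <- function(tests, path = NULL, alpha = 0.05,
                                   clamp_log2 = 2) {
  tps <- sort(as.integer(sub("^p_t", "", grep("^p_t[0-9]+$", names(tests),
                                              value = TRUE))))
  sel <- rep(FALSE, nrow(tests))
  for (tp in tps) {
    p <- tests[[sprintf("p_t%d", tp)]]
    sel <- sel | (!is.na(p) & p < alpha)
  }
  out <- tests[sel, , drop = FALSE]
  for (tp in tps) {
    m <- out[[sprintf("median_log2_t%d", tp)]]
    out[[sprintf("color_t%d", tp)]] <- pmin(pmax(m / clamp_log2, -1), 1)
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Read a flat pipeline configuration file
#'
#' Plain-text `section.key = value` lines (`#` comments allowed). Values
#' are parsed as numeric, logical, or comma-separated vectors where
#' possible.
#'
#' @param path configuration file.
#' @return nested named list, one element per section.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("config keys must be section.key: '", key, "'")
    v <- strsplit(val, ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    num <- suppressWarnings(as.numeric(v))
    parsed <- if (!any(is.na(num))) num
      else if (all(v %in% c("TRUE", "FALSE", "true", "false")))
        as.logical(toupper(v))
      else v
    cfg[[parts[1]]][[parts[2]]] <- parsed
  }
  cfg
}

#' Run the simulation-to-report pipeline end to end
#'
#' Generates (or loads) the three datasets, then runs filtering,
#' significance testing and clustering, kinetic fitting with category
#' summaries, nCounter processing, protein-group alignment of the
#' abundance and kinetics tables, and node-attribute export. All tables
#' are written as TSV/CSV under `out_dir` together with a run log
#' recording seeds and filter bookkeeping.
#'
#' @param config nested list (see [read_pipeline_config()]) with optional
#'   sections `silac`, `pcsilac`, `nanostring` (arguments passed to the
#'   respective config constructors) and `analysis` (fields `alpha`,
#'   `k_ref`, `use_categories`).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds derive from it unless the
#'   stage config sets its own.
#' @return invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  analysis <- config$analysis
  alpha <- if (is.null(analysis$alpha)) 0.05 else analysis$alpha
  k_ref <- if (is.null(analysis$k_ref)) 12 else analysis$k_ref
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("hsp90flux pipeline, master seed %d", seed)

  sil_args <- config$silac
  sil_args$seed <- if (is.null(sil_args$seed)) seed else sil_args$seed
  sil_cfg <- do.call(silac_sim_config, sil_args)
  sim <- generate_stsilac_table(sil_cfg)
  tab <- orient_ratios(sim$table, sil_cfg$swapped_replicates)
  fq <- filter_quality(tab)
  occ <- filter_occurrence(fq$table)
  tests <- test_differential(occ, alpha = alpha)
  clusters <- assign_clusters(tests)
  silac_out <- merge(tests, clusters, by = "group_ids", sort = FALSE)
  write_protein_groups(fq$table, file.path(out_dir, "silac_filtered.tsv"))
  utils::write.table(silac_out, file.path(out_dir, "silac_tests_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("silac: %d rows in, %d quality-filtered, %d occurrence-filtered, %d significant",
       fq$report$input, fq$report$retained, nrow(occ),
       sum(tests$significant_any))

  pc_args <- config$pcsilac
  pc_args$seed <- if (is.null(pc_args$seed)) seed + 1 else pc_args$seed
  use_cat <- is.null(analysis$use_categories) || isTRUE(analysis$use_categories)
  if (use_cat && is.null(pc_args$category_overrides)) {
    pc_args$category_overrides <- pcsilac_categories()
  }
  preset <- do.call(pcsilac_preset, pc_args)
  pc <- generate_pcsilac_series(preset)
  fits <- fit_kinetics(pc$series)
  cats <- split(pc$truth$protein, pc$truth$category)
  cat_summary <- summarize_category(fits, cats)
  utils::write.table(fits, file.path(out_dir, "kinetic_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cat_summary, file.path(out_dir, "category_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("pcsilac: %d proteins fitted, median kd ratio %.3f",
       nrow(fits), stats::median(fits$kd_ratio[is.finite(fits$kd_ratio)]))

  ns_args <- config$nanostring
  ns_args$seed <- if (is.null(ns_args$seed)) seed + 2 else ns_args$seed
  ns_cfg <- do.call(nano_sim_config, ns_args)
  ns <- generate_nanostring_counts(ns_cfg)
  ns_res <- process_nanostring(ns$dataset, k_ref = k_ref,
                               numerator = ns_cfg$conditions[2],
                               denominator = ns_cfg$conditions[1])
  utils::write.table(ns_res$fold_changes,
                     file.path(out_dir, "nanostring_fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("nanostring: QC %s (ratio %.2f), %d references selected",
       if (ns_res$qc$pass) "pass" else "FAIL", ns_res$qc$ratio,
       length(ns_res$genorm$selected))

  kin_tab <- fits
  names(kin_tab)[names(kin_tab) == "protein"] <- "group_ids"
  joint <- align_datasets(silac_out, kin_tab)
  utils::write.table(joint, file.path(out_dir, "joint_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- export_node_attributes(tests,
                                  file.path(out_dir, "node_attributes.tsv"),
                                  alpha = alpha)
  logf("alignment: %d joint rows, %d matched; %d network nodes",
       nrow(joint), sum(joint$matched), nrow(nodes))

  invisible(list(silac = list(sim = sim, filtered = fq, tests = tests,
                              clusters = clusters),
                 kinetics = list(sim = pc, fits = fits,
                                 categories = cat_summary),
                 nanostring = ns_res, joint = joint, nodes = nodes))
}
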