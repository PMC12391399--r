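# End-to-end orchestration from a single config: read -> log -> center ->
# scale -> filter -> impute -> DE per contrast -> Venn sets -> GO -> PCA,
# with structured logging, a file manifest with checksums, and a
# machine-readable JSON run report.

pipeline_defaults <- function() {
  list(log_base = 2, center_stat = "mean", width_stat = "sd",
       min_valid_per_group = 2, down_shift = 2, impute_width = 0.3,
       seed = NULL, alpha_f = 0.05, fc_threshold = 1, p_threshold = 0.05,
       strict = TRUE, p_axis_base = 2)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: '%s'", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("`config` must be a list or a YAML file path")
  for (key in c("protein_groups", "design")) {
    path <- config$inputs[[key]]
    if (is.null(path)) stopf("config$inputs$%s is required", key)
    if (!file.exists(path)) stopf("input file not found: '%s'", path)
  }
  if (!is.null(config$inputs$go_map) && !file.exists(config$inputs$go_map)) {
    stopf("input file not found: '%s'", config$inputs$go_map)
  }
  if (is.null(config$outdir)) stopf("config$outdir is required")
  config$params <- utils::modifyList(pipeline_defaults(),
                                     config$params %||% list())
  config
}

stage_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline from a config
#'
#' Executes every stage from a single configuration: reading and binding the
#' tables, the normalization/imputation chain, the per-isolate differential
#' expression contrasts, Venn set analysis, GO summarization of the up and
#' down sets, and PCA ordination. All intermediate tables are written to the
#' output directory, a JSON run report (stage counts, DE counts, Venn
#' regions, file manifest with MD5 checksums, full provenance) is written as
#' `report.json`, and the run is deterministic given config + seed:
#' re-running with an identical config overwrites the outputs identically.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   * `inputs`: `protein_groups`, `design`, optional `go_map` (paths);
#'   * `params`: any of `log_base`, `center_stat`, `width_stat`,
#'     `min_valid_per_group`, `down_shift`, `impute_width`, `seed`,
#'     `alpha_f`, `fc_threshold`, `p_threshold`, `strict`, `p_axis_base`;
#'   * `contrasts`: isolate labels to test (default: every isolate with both
#'     conditions);
#'   * `outdir`: output directory.
#' @param quiet suppress per-stage log messages (default `FALSE`).
#' @return the run report (class `lfq_run_report`), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config, stages = list())

  design <- read_design(config$inputs$design)
  m <- read_protein_groups(config$inputs$protein_groups, design)
  stage_log(quiet, "read", "%d proteins x %d samples, %d missing cells",
            nrow(m$values), ncol(m$values), sum(is.na(m$values)))
  report$stages$read <- list(n_proteins = nrow(m$values),
                             n_samples = ncol(m$values),
                             n_missing = sum(is.na(m$values)))

  nm <- log_transform(m, base = p$log_base)
  nm <- center_by_sample_mean(nm, stat = p$center_stat)
  nm <- scale_by_sample_width(nm, stat = p$width_stat)
  nm <- filter_by_validity(nm, min_valid_per_group = p$min_valid_per_group)
  n_removed <- nrow(attr(nm, "removed"))
  stage_log(quiet, "filter", "removed %d proteins (min_valid_per_group = %d)",
            n_removed, p$min_valid_per_group)
  if (sum(is.na(nm$values)) > 0 && is.null(p$seed)) {
    stopf("config$params$seed is required: the matrix has missing cells")
  }
  nm <- impute_min_probabilistic(nm, down_shift = p$down_shift,
                                 width = p$impute_width,
                                 seed = if (is.null(p$seed)) NULL else
                                   stage_seed(p$seed, "impute"))
  stage_log(quiet, "impute", "%d cells imputed (down_shift = %g, width = %g)",
            sum(nm$imputed), p$down_shift, p$impute_width)
  report$stages$preprocess <- list(n_retained = nrow(nm$values),
                                   n_removed = n_removed,
                                   n_imputed = sum(nm$imputed),
                                   provenance = nm$provenance)
  paths <- c(normalized = file.path(config$outdir, "normalized_matrix.tsv"))
  write_norm_matrix(nm, paths["normalized"])
  paths["flags"] <- file.path(config$outdir, "normalized_matrix.flags.tsv")

  contrasts <- config$contrasts %||% {
    both <- tapply(design$treatment, design$isolate,
                   function(tr) all(c("control", "treated") %in% tr))
    names(both)[both]
  }
  de_tables <- list()
  report$contrasts <- list()
  for (iso in contrasts) {
    de <- run_de_table(nm, iso, alpha_f = p$alpha_f,
                       fc_threshold = p$fc_threshold,
                       p_threshold = p$p_threshold, strict = p$strict,
                       p_axis_base = p$p_axis_base)
    de_tables[[iso]] <- de
    cnt <- attr(de, "counts")
    stage_log(quiet, "de", "%s: %d tested, %d up, %d down",
              iso, nrow(de), cnt["n_up"], cnt["n_down"])
    report$contrasts[[iso]] <- list(n_tested = nrow(de),
                                    n_up = unname(cnt["n_up"]),
                                    n_down = unname(cnt["n_down"]),
                                    n_excluded = nrow(attr(de, "excluded")))
    f <- file.path(config$outdir, sprintf("de_%s.tsv",
                                          gsub("[^A-Za-z0-9]", "", iso)))
    write_de_table(de, f)
    paths[paste0("de_", iso)] <- f
  }

  if (length(de_tables) >= 2L) {
    sets <- extract_sets(de_tables)
    for (dir in c("up", "down")) {
      f <- file.path(config$outdir, sprintf("venn_%s.tsv", dir))
      write_venn_regions(sets$regions[[dir]], f)
      paths[paste0("venn_", dir)] <- f
    }
    report$venn <- list(
      up = stats::setNames(as.list(sets$regions$up$count),
                           sets$regions$up$region),
      down = stats::setNames(as.list(sets$regions$down$count),
                             sets$regions$down$region))
    stage_log(quiet, "sets", "venn regions computed for %d isolates",
              length(de_tables))
  } else {
    sets <- NULL
  }

  if (!is.null(config$inputs$go_map)) {
    go_map <- read_go_map(config$inputs$go_map)
    for (dir in c("up", "down")) {
      prot <- unique(unlist(lapply(de_tables, function(de)
        de$accession[de$volcano_class == dir]), use.names = FALSE))
      gs <- summarize_go(prot, go_map)
      f <- file.path(config$outdir, sprintf("go_summary_%s.tsv", dir))
      write_go_summary(gs, f)
      paths[paste0("go_", dir)] <- f
      report$go[[dir]] <- list(n_terms = nrow(gs),
                               n_unannotated = length(attr(gs, "unannotated")))
    }
    stage_log(quiet, "go", "summaries written for up/down sets")
  }

  pca <- pca_lfq(nm)
  wp <- write_pca(pca, file.path(config$outdir, "pca"))
  paths[c("pca_scores", "pca_loadings", "pca_variance")] <- wp
  report$pca <- list(variance_explained = pca$variance_explained)
  stage_log(quiet, "pca", "PC1 %.1f%%, PC2 %.1f%%",
            100 * pca$variance_explained[1L],
            100 * pca$variance_explained[2L])

  report$manifest <- data.frame(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    stringsAsFactors = FALSE)
  report_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  report$de_tables <- de_tables
  report$sets <- sets
  report$normalized <- nm
  class(report) <- "lfq_run_report"
  invisible(report)
}

#' @export
print.lfq_run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  read: %d proteins, %d samples, %d missing cells\n",
              x$stages$read$n_proteins, x$stages$read$n_samples,
              x$stages$read$n_missing))
  cat(sprintf("  retained after filter: %d (imputed cells: %d)\n",
              x$stages$preprocess$n_retained, x$stages$preprocess$n_imputed))
  for (iso in names(x$contrasts)) {
    c_ <- x$contrasts[[iso]]
    cat(sprintf("  %s: %d up, %d down of %d tested\n", iso, c_$n_up,
                c_$n_down, c_$n_tested))
  }
  cat(sprintf("  outputs: %d files in %s\n", nrow(x$manifest),
              x$config$outdir))
  invisible(x)
}

#' Verify a run report's checksum manifest
#'
#' @param report an `lfq_run_report` (or a parsed `report.json`).
#' @param outdir directory holding the run outputs; defaults to the
#'   directory recorded in the report.
#' @return `TRUE` if every manifest entry matches the file on disk.
#' @export
verify_manifest <- function(report, outdir = NULL) {
  outdir <- outdir %||% report$config$outdir
  man <- as.data.frame(report$manifest)
  actual <- tools::md5sum(file.path(outdir, man$file))
  all(!is.na(actual) & actual == man$md5)
}
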