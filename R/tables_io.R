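# Reading, validating and writing the tabular artifacts of the pipeline:
# protein-groups intensity tables (MaxQuant proteinGroups dialect), sample
# design tables, and protein -> GO annotation maps.

#' Construct an LFQ intensity matrix bound to a sample design
#'
#' An `lfq_matrix` holds raw (linear-scale) protein intensities with explicit
#' missingness (`NA`) and the experimental design describing each sample.
#' Columns are stored in design order, so any column permutation of the same
#' data yields an identical object and identical downstream statistics.
#'
#' @param values numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids). `NA` marks a missing
#'   (not-detected) intensity; all present values must be strictly positive.
#' @param design a validated sample design `data.frame`, see [read_design()].
#' @return an object of class `lfq_matrix` with elements `values` and
#'   `design`.
#' @export
lfq_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  design <- validate_design(design)
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || anyNA(pid) || any(pid == "")) {
    stopf("`values` must have accession rownames")
  }
  if (anyDuplicated(pid)) {
    stopf("duplicate accession(s): %s",
          paste(unique(pid[duplicated(pid)]), collapse = ", "))
  }
  if (is.null(sid) || anyDuplicated(sid)) {
    stopf("`values` must have unique sample-id colnames")
  }
  if (nrow(values) < 1L || ncol(values) < 2L) {
    stopf("need at least 1 protein and 2 samples")
  }
  extra <- setdiff(sid, design$sample_id)
  if (length(extra)) {
    stopf("intensity column(s) with no matching design row: %s",
          paste(extra, collapse = ", "))
  }
  missing_s <- setdiff(design$sample_id, sid)
  if (length(missing_s)) {
    stopf("design sample(s) absent from the intensity table: %s",
          paste(missing_s, collapse = ", "))
  }
  present <- values[!is.na(values)]
  if (any(present <= 0)) {
    stopf("all present intensities must be > 0 (zeros are missing values)")
  }
  # canonical column order = design order; makes binding permutation-proof
  values <- values[, design$sample_id, drop = FALSE]
  structure(list(values = values, design = design), class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("LFQ intensity matrix: %d proteins x %d samples\n",
              nrow(v), ncol(v)))
  cat(sprintf("  missing cells: %d of %d (%.1f%%)\n",
              sum(is.na(v)), length(v), 100 * mean(is.na(v))))
  grp <- interaction(x$design$isolate, x$design$treatment, drop = TRUE)
  cat(sprintf("  design: %d isolates, %d groups, %d samples\n",
              length(unique(x$design$isolate)), nlevels(grp), nrow(x$design)))
  invisible(x)
}

#' Read and validate a sample design table
#'
#' The design table binds sample ids to the experimental structure: isolate,
#' treatment (`control` / `treated`), dose (micromolar) and biological
#' replicate number. Every (isolate, treatment) group must have at least two
#' replicates, otherwise within-group variance -- and hence the F-gate and
#' t-test -- is undefined.
#'
#' @param path path to a tab-separated file with columns `sample_id`,
#'   `isolate`, `treatment`, `dose`, `replicate`.
#' @return a `data.frame` of class `lfq_design`.
#' @export
read_design <- function(path) {
  validate_design(read_tsv_strict(path))
}

#' @rdname read_design
#' @param design a data.frame to validate in place of reading from a file.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "isolate", "treatment", "dose", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stopf("design lacks column(s): %s", paste(miss, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  design$sample_id <- as.character(design$sample_id)
  design$isolate <- as.character(design$isolate)
  design$treatment <- as.character(design$treatment)
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id)) stopf("duplicate sample_id in design")
  bad <- setdiff(unique(design$treatment), c("control", "treated"))
  if (length(bad)) {
    stopf("treatment must be 'control' or 'treated' (found: %s)",
          paste(bad, collapse = ", "))
  }
  if (any(is.na(design$replicate)) || any(design$replicate < 1L)) {
    stopf("replicate must be a positive integer")
  }
  triple <- paste(design$isolate, design$treatment, design$replicate, sep = "\r")
  if (anyDuplicated(triple)) {
    stopf("duplicated (isolate, treatment, replicate) triple in design")
  }
  grp <- table(paste(design$isolate, design$treatment, sep = "\r"))
  if (any(grp < 2L)) {
    one <- names(grp)[grp < 2L][1L]
    stopf("group '%s' has < 2 replicates; variance undefined",
          gsub("\r", " / ", one))
  }
  class(design) <- c("lfq_design", "data.frame")
  design
}

#' Read a protein-groups intensity table
#'
#' Reads a tab-separated protein-groups table (MaxQuant `proteinGroups`
#' dialect: one accession identifier column plus one intensity column per
#' sample) and binds the intensity columns to a sample design. Zero, blank
#' and non-numeric cells are mapped to missing: in label-free quantification
#' a zero is a non-detection, not a measured abundance of zero.
#'
#' @param path path to the tab-separated table.
#' @param design the sample design (data.frame or path readable by
#'   [read_design()]). Every non-identifier column must match a design
#'   sample id, and vice versa.
#' @param id_col name of the accession column; default the first column.
#' @param zero_as_missing map zero intensities to missing (default `TRUE`).
#' @param drop optional character vector of accessions to discard before
#'   validation (hook for contaminant/decoy lists; no default filter is
#'   applied).
#' @return an [lfq_matrix()].
#' @export
read_protein_groups <- function(path, design, id_col = NULL,
                                zero_as_missing = TRUE, drop = NULL) {
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    design <- read_design(design)
  } else {
    design <- validate_design(design)
  }
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 3L) stopf("expected an identifier column plus >= 2 intensity columns")
  id_col <- id_col %||% names(tab)[1L]
  if (!id_col %in% names(tab)) stopf("identifier column '%s' not found", id_col)
  acc <- trimws(as.character(tab[[id_col]]))
  if (anyDuplicated(acc)) {
    stopf("duplicate accession(s): %s",
          paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  ints <- tab[, setdiff(names(tab), id_col), drop = FALSE]
  vals <- vapply(ints, function(col) {
    x <- suppressWarnings(as.numeric(as.character(col)))
    x[!is.finite(x)] <- NA_real_
    if (zero_as_missing) x[!is.na(x) & x == 0] <- NA_real_
    x
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(acc, names(ints)))
  if (!is.null(drop)) {
    keep <- !(rownames(vals) %in% drop)
    vals <- vals[keep, , drop = FALSE]
  }
  lfq_matrix(vals, design)
}

#' Write an intensity matrix as a protein-groups TSV
#'
#' Inverse of [read_protein_groups()]: missing cells are written as 0 (the
#' LFQ convention), so a write/read round trip reproduces values and
#' missingness.
#'
#' @param m an [lfq_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(m, path) {
  stopifnot(inherits(m, "lfq_matrix"))
  v <- m$values
  v[is.na(v)] <- 0
  df <- data.frame(accession = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a protein-to-GO annotation map
#'
#' @param path tab-separated file with columns `accession`, `go_id`,
#'   `aspect` (one of `BP`, `CC`, `MF`) and `term_name`. An empty file with
#'   just the header yields an empty map.
#' @return a `data.frame` of class `go_map`.
#' @export
read_go_map <- function(path) {
  validate_go_map(read_tsv_strict(path))
}

#' @rdname read_go_map
#' @param map a data.frame to validate in place of reading from a file.
#' @export
validate_go_map <- function(map) {
  need <- c("accession", "go_id", "aspect", "term_name")
  miss <- setdiff(need, names(map))
  if (length(miss)) stopf("GO map lacks column(s): %s", paste(miss, collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  for (nm in need) map[[nm]] <- as.character(map[[nm]])
  bad <- setdiff(unique(map$aspect), c("BP", "CC", "MF"))
  if (length(bad)) {
    stopf("aspect must be BP, CC or MF (found: %s)", paste(bad, collapse = ", "))
  }
  key <- paste(map$accession, map$go_id, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicated (accession, go_id) annotation row")
  }
  class(map) <- c("go_map", "data.frame")
  map
}
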