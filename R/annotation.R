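# Descriptive GO-term categorization of DE protein lists against a supplied
# annotation map. This is counting by exact membership (the style of a GO
# bar chart), not over-representation testing; an optional hypergeometric
# enrichment mode is provided separately as a clearly-labelled extension.

#' Summarize a protein list by GO terms
#'
#' Counts, per (aspect, GO id), how many proteins of the input list carry
#' that direct annotation in the map. Proteins without any annotation (under
#' the aspect filter, if given) are reported separately as unannotated.
#' Terms are sorted by descending count, ties broken by GO id. Annotations
#' are direct only; no propagation up the GO hierarchy is performed.
#'
#' @param proteins character vector of accessions (e.g. an up-regulated set).
#' @param map a [read_go_map()] annotation map.
#' @param aspect optional filter: `"BP"`, `"CC"` or `"MF"`.
#' @return a `data.frame` of class `go_summary` with columns `aspect`,
#'   `go_id`, `term_name`, `count`, `accessions` (semicolon-joined), and
#'   attribute `unannotated`.
#' @export
summarize_go <- function(proteins, map, aspect = NULL) {
  map <- validate_go_map(map)
  proteins <- unique(as.character(proteins))
  if (!is.null(aspect)) {
    aspect <- match.arg(aspect, c("BP", "CC", "MF"))
    map <- map[map$aspect == aspect, , drop = FALSE]
  }
  hits <- map[map$accession %in% proteins, , drop = FALSE]
  unannotated <- setdiff(proteins, hits$accession)
  if (nrow(hits) == 0L) {
    out <- data.frame(aspect = character(), go_id = character(),
                      term_name = character(), count = integer(),
                      accessions = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("go_summary", "data.frame"),
                     unannotated = unannotated))
  }
  key <- paste(hits$aspect, hits$go_id, sep = "\r")
  grp <- split(hits, key)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(aspect = g$aspect[1L], go_id = g$go_id[1L],
               term_name = g$term_name[1L], count = nrow(g),
               accessions = paste(sort(g$accession), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$count, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("go_summary", "data.frame"),
            unannotated = unannotated)
}

#' @export
print.go_summary <- function(x, n = 10L, ...) {
  cat(sprintf("GO summary: %d term(s), %d unannotated protein(s)\n",
              nrow(x), length(attr(x, "unannotated"))))
  if (nrow(x)) {
    print(utils::head(data.frame(aspect = x$aspect, go_id = x$go_id,
                                 term = x$term_name, count = x$count), n),
          row.names = FALSE)
  }
  invisible(x)
}

#' Hypergeometric GO enrichment (optional extension)
#'
#' Over-representation test of each GO term in a protein list against a
#' stated universe, using the hypergeometric distribution. This goes beyond
#' descriptive categorization and is off the default pipeline path.
#'
#' @param proteins accession vector of interest.
#' @param universe accession vector defining the background.
#' @param map a [read_go_map()] annotation map.
#' @param aspect optional aspect filter.
#' @return a `data.frame` with per-term counts, hypergeometric `p_value`
#'   and Benjamini-Hochberg `p_adj`.
#' @export
enrich_go <- function(proteins, universe, map, aspect = NULL) {
  map <- validate_go_map(map)
  proteins <- unique(as.character(proteins))
  universe <- unique(as.character(universe))
  if (!all(proteins %in% universe)) {
    stopf("all `proteins` must be contained in `universe`")
  }
  if (!is.null(aspect)) {
    aspect <- match.arg(aspect, c("BP", "CC", "MF"))
    map <- map[map$aspect == aspect, , drop = FALSE]
  }
  map <- map[map$accession %in% universe, , drop = FALSE]
  if (nrow(map) == 0L) {
    return(data.frame(aspect = character(), go_id = character(),
                      term_name = character(), k = integer(), m = integer(),
                      p_value = numeric(), p_adj = numeric()))
  }
  key <- paste(map$aspect, map$go_id, sep = "\r")
  grp <- split(map, key)
  N <- length(universe); n <- length(proteins)
  out <- do.call(rbind, lapply(grp, function(g) {
    m <- length(unique(g$accession))                 # annotated in universe
    k <- sum(unique(g$accession) %in% proteins)      # annotated in list
    p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(aspect = g$aspect[1L], go_id = g$go_id[1L],
               term_name = g$term_name[1L], k = k, m = m, p_value = p,
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a GO summary as TSV
#'
#' @param x a [summarize_go()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_go_summary <- function(x, path) {
  stopifnot(inherits(x, "go_summary"))
  write_tsv(as.data.frame(x), path)
}
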