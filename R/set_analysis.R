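# Venn region analysis of per-isolate up/down regulated protein sets.

#' Venn regions of named sets
#'
#' Partitions the union of 2 or 3 named accession sets into the `2^k - 1`
#' exclusive Venn regions (a single set is accepted as the degenerate case).
#' Each element is counted in exactly one region, so per direction the
#' region counts sum to the size of the union.
#'
#' @param sets named list of character vectors (unique names required).
#' @return a `data.frame` of class `venn_regions` with columns `region`
#'   (set names joined by `&`), `count` and `members` (semicolon-joined);
#'   the member vectors are also available via `attr(, "members")`.
#' @export
venn_regions <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L || length(sets) > 3L) {
    stopf("`sets` must be a named list of 1 to 3 sets")
  }
  nms <- names(sets)
  if (is.null(nms) || any(is.na(nms)) || any(nms == "") ||
      anyDuplicated(nms)) {
    stopf("sets must have unique non-empty names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  # region label of each element = the subset of sets containing it
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0L) {
    memb <- matrix(logical(0), 0L, k)
  } else if (is.null(dim(memb))) {
    memb <- matrix(memb, nrow = length(universe))
  }
  # enumerate non-empty subsets in canonical order: singletons, pairs, triple
  subsets <- list()
  idx <- seq_len(k)
  for (size in idx) {
    cmb <- utils::combn(idx, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  members <- lapply(subsets, function(sub) {
    inside <- rowSums(memb[, sub, drop = FALSE]) == length(sub)
    outside <- if (length(sub) == k) rep(FALSE, length(universe)) else
      rowSums(memb[, -sub, drop = FALSE]) > 0
    universe[inside & !outside]
  })
  labels <- vapply(subsets, function(sub) paste(nms[sub], collapse = "&"), "")
  names(members) <- labels
  out <- data.frame(region = labels,
                    count = vapply(members, length, 0L),
                    members = vapply(members, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("venn_regions", "data.frame"), members = members)
}

#' @export
print.venn_regions <- function(x, ...) {
  cat(sprintf("Venn regions (%d regions, union size %d)\n",
              nrow(x), sum(x$count)))
  print(data.frame(region = x$region, count = x$count), row.names = FALSE)
  invisible(x)
}

#' Extract up/down DE sets per isolate and their Venn regions
#'
#' Collects the up- and down-regulated accession sets from per-isolate DE
#' tables (which must all have been produced under identical thresholds) and
#' computes the Venn regions for each direction.
#'
#' @param de_tables named list of [run_de_table()] results, one per isolate;
#'   names default to each table's isolate attribute.
#' @return a list of class `de_set_collection` with elements `up` and `down`
#'   (named lists of accession vectors) and `regions` (list of
#'   [venn_regions()] results per direction).
#' @export
extract_sets <- function(de_tables) {
  if (!is.list(de_tables) || !length(de_tables)) stopf("need >= 1 DE table")
  if (!all(vapply(de_tables, inherits, TRUE, "de_table"))) {
    stopf("all elements must be de_table objects")
  }
  nms <- names(de_tables) %||% vapply(de_tables, attr, "", "isolate")
  if (is.null(names(de_tables))) names(de_tables) <- nms
  ths <- lapply(de_tables, attr, "thresholds")
  if (length(unique(lapply(ths, unclass))) != 1L) {
    stopf("DE tables were produced under different thresholds; refusing to combine")
  }
  pick <- function(tab, cls) tab$accession[tab$volcano_class == cls]
  up <- lapply(de_tables, pick, "up")
  down <- lapply(de_tables, pick, "down")
  structure(list(up = up, down = down,
                 regions = list(up = venn_regions(up),
                                down = venn_regions(down)),
                 thresholds = ths[[1L]]),
            class = "de_set_collection")
}

#' @export
print.de_set_collection <- function(x, ...) {
  cat("DE set collection\n")
  for (dir in c("up", "down")) {
    sizes <- vapply(x[[dir]], length, 0L)
    cat(sprintf("  %s sets: %s\n", dir,
                paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  }
  cat("  up regions:\n")
  print(data.frame(region = x$regions$up$region, count = x$regions$up$count),
        row.names = FALSE)
  cat("  down regions:\n")
  print(data.frame(region = x$regions$down$region,
                   count = x$regions$down$count), row.names = FALSE)
  invisible(x)
}

#' Write a Venn region report as TSV
#'
#' @param x a [venn_regions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_venn_regions <- function(x, path) {
  stopifnot(inherits(x, "venn_regions"))
  write_tsv(as.data.frame(x), path)
}
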