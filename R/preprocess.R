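# The transformation chain applied to raw LFQ intensities before testing:
# log conversion, per-sample mean centering, per-sample distribution-width
# scaling, validity filtering, and probabilistic minimum imputation of
# missing values from a down-shifted Gaussian.

as_lfq_norm <- function(values, design, imputed = NULL, provenance = list()) {
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  structure(list(values = values, imputed = imputed, design = design,
                 provenance = provenance),
            class = "lfq_norm")
}

#' @export
print.lfq_norm <- function(x, ...) {
  cat(sprintf("Normalized LFQ matrix: %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing: %d | imputed: %d\n",
              sum(is.na(x$values)), sum(x$imputed)))
  steps <- vapply(x$provenance, `[[`, "", "step")
  cat("  provenance:", if (length(steps)) paste(steps, collapse = " -> ")
      else "(none)", "\n")
  invisible(x)
}

# mask of originally-valid (measured, not imputed) cells
valid_mask <- function(nm) !is.na(nm$values) & !nm$imputed

add_step <- function(nm, step, ...) {
  nm$provenance <- c(nm$provenance, list(c(list(step = step), list(...))))
  nm
}

#' Log-transform an intensity matrix
#'
#' Converts present intensities to logarithms (default base 2, the scale on
#' which fold-change thresholds are expressed downstream); missing cells
#' stay missing.
#'
#' @param m an [lfq_matrix()].
#' @param base logarithm base (default 2).
#' @return an object of class `lfq_norm` carrying values, per-cell imputation
#'   flags (all `FALSE` at this stage) and an append-only provenance record.
#' @export
log_transform <- function(m, base = 2) {
  stopifnot(inherits(m, "lfq_matrix"))
  v <- m$values
  present <- !is.na(v)
  if (any(v[present] <= 0)) stopf("non-positive present intensity")
  v[present] <- log(v[present], base = base)
  add_step(as_lfq_norm(v, m$design), "log", base = base)
}

#' Center each sample at its mean log abundance
#'
#' First normalization: each value is scaled relative to the average of all
#' protein abundances within its own sample, i.e. the per-sample mean over
#' valid (measured) cells is subtracted from every valid cell. Missing cells
#' are untouched.
#'
#' @param nm an `lfq_norm` matrix in log space.
#' @param stat centering statistic, `"mean"` (default) or `"median"`.
#' @return the centered `lfq_norm`.
#' @export
center_by_sample_mean <- function(nm, stat = c("mean", "median")) {
  stopifnot(inherits(nm, "lfq_norm"))
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else stats::median
  v <- nm$values
  for (j in seq_len(ncol(v))) {
    ok <- !is.na(v[, j])
    if (sum(ok) < 2L) stopf("sample '%s' has < 2 valid values", colnames(v)[j])
    v[ok, j] <- v[ok, j] - fun(v[ok, j])
  }
  nm$values <- v
  add_step(nm, "center", stat = stat)
}

#' Scale each sample by its distribution width
#'
#' Second normalization: valid cells of each sample are divided by that
#' sample's distribution width (standard deviation over valid cells by
#' default), equalizing acquisition dynamic range across samples. After
#' scaling each sample's valid-value SD is 1.
#'
#' @param nm a centered `lfq_norm`.
#' @param stat width statistic, `"sd"` (default) or `"iqr"` (interquartile
#'   range divided by the normal-consistency constant 1.349).
#' @return the scaled `lfq_norm`.
#' @export
scale_by_sample_width <- function(nm, stat = c("sd", "iqr")) {
  stopifnot(inherits(nm, "lfq_norm"))
  stat <- match.arg(stat)
  v <- nm$values
  for (j in seq_len(ncol(v))) {
    ok <- !is.na(v[, j])
    w <- if (stat == "sd") stats::sd(v[ok, j]) else
      stats::IQR(v[ok, j]) / (2 * stats::qnorm(0.75))
    if (!is.finite(w) || w == 0) {
      stopf("sample '%s' has zero distribution width", colnames(v)[j])
    }
    v[ok, j] <- v[ok, j] / w
  }
  nm$values <- v
  add_step(nm, "scale", stat = stat)
}

#' Filter proteins by within-group validity
#'
#' Retains proteins testable in every compared treated-vs-control pair: a
#' protein needs at least `min_valid_per_group` measured values in at least
#' one group of each pair -- the minimum for which a within-group variance,
#' and hence the F-gate and t-test, is defined. By default the pairs are the
#' (control, treated) groups of every isolate in the design that has both
#' conditions. When an explicit `groups` list is supplied instead, the
#' simpler rule applies: keep proteins with enough valid values in at least
#' one of those groups.
#'
#' @param nm an `lfq_norm`.
#' @param min_valid_per_group minimum measured values required (default 2).
#' @param groups optional named list of sample-id character vectors; when
#'   given, a protein is kept if any one group meets the threshold.
#' @return the filtered `lfq_norm`; removed accessions and the reason are
#'   recorded in `attr(, "removed")`. An empty result is allowed (warning).
#' @export
filter_by_validity <- function(nm, min_valid_per_group = 2, groups = NULL) {
  stopifnot(inherits(nm, "lfq_norm"))
  v <- nm$values
  ok <- !is.na(v)
  group_counts <- function(gr) {
    counts <- vapply(gr, function(s) rowSums(ok[, s, drop = FALSE]),
                     numeric(nrow(v)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(v))
    counts
  }
  if (!is.null(groups)) {
    keep <- apply(group_counts(groups), 1L, max) >= min_valid_per_group
  } else {
    des <- nm$design
    both <- tapply(des$treatment, des$isolate,
                   function(tr) all(c("control", "treated") %in% tr))
    isolates <- names(both)[both]
    if (!length(isolates)) stopf("design has no isolate with both conditions")
    keep <- rep(TRUE, nrow(v))
    for (iso in isolates) {
      pair <- list(des$sample_id[des$isolate == iso & des$treatment == "control"],
                   des$sample_id[des$isolate == iso & des$treatment == "treated"])
      keep <- keep & apply(group_counts(pair), 1L, max) >= min_valid_per_group
    }
  }
  removed <- data.frame(
    accession = rownames(v)[!keep],
    reason = rep(sprintf("fewer than %d valid values in every group",
                         min_valid_per_group), sum(!keep)),
    stringsAsFactors = FALSE)
  if (!any(keep)) warnf("validity filter removed every protein")
  nm$values <- v[keep, , drop = FALSE]
  nm$imputed <- nm$imputed[keep, , drop = FALSE]
  nm <- add_step(nm, "filter", min_valid_per_group = min_valid_per_group,
                 groups = groups)
  attr(nm, "removed") <- removed
  nm
}

# named list of sample ids per (isolate, treatment) group
design_groups <- function(design) {
  key <- paste(design$isolate, design$treatment, sep = "/")
  split(design$sample_id, key)
}

#' Probabilistic minimum imputation of missing values
#'
#' Replaces each missing cell of sample `s` with an independent draw from a
#' Gaussian centered `down_shift` standard deviations below that sample's
#' valid-value mean, with standard deviation `width` times the sample SD:
#' `N(mu_s - down_shift * sigma_s, (width * sigma_s)^2)`. This emulates
#' resampling of low-abundance proteins that dropped below the detection
#' limit (missing not at random). Defaults: 2 SD down-shift, width 0.3.
#'
#' @param nm a centered and scaled `lfq_norm` (the reference distribution is
#'   per sample).
#' @param down_shift down-shift in sample-SD units (default 2).
#' @param width draw SD as a fraction of the sample SD (default 0.3).
#' @param seed integer seed; mandatory whenever missing cells exist, so the
#'   imputation is reproducible.
#' @return a complete `lfq_norm` with `imputed` flags set for every filled
#'   cell.
#' @export
impute_min_probabilistic <- function(nm, down_shift = 2, width = 0.3,
                                     seed = NULL) {
  stopifnot(inherits(nm, "lfq_norm"))
  v <- nm$values
  n_missing <- sum(is.na(v))
  if (n_missing == 0L) {
    return(add_step(nm, "impute", down_shift = down_shift, width = width,
                    seed = seed, n_imputed = 0L))
  }
  if (is.null(seed)) {
    stopf("`seed` is required when missing cells exist (determinism contract)")
  }
  imputed <- nm$imputed
  nm$values <- with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      obs <- v[!miss, j]
      if (length(obs) < 2L) stopf("sample '%s' has < 2 valid values", colnames(v)[j])
      mu <- mean(obs)
      sigma <- stats::sd(obs)
      v[miss, j] <- stats::rnorm(sum(miss), mean = mu - down_shift * sigma,
                                 sd = width * sigma)
      imputed[miss, j] <- TRUE
    }
    v
  })
  nm$imputed <- imputed
  add_step(nm, "impute", down_shift = down_shift, width = width,
           seed = seed, n_imputed = n_missing)
}

#' Full normalization chain
#'
#' Convenience wrapper running the complete preprocessing chain in the
#' canonical order: log transform, mean centering, width scaling, validity
#' filtering, probabilistic minimum imputation.
#'
#' @param m an [lfq_matrix()].
#' @param log_base logarithm base (default 2).
#' @param center_stat,width_stat see [center_by_sample_mean()] and
#'   [scale_by_sample_width()].
#' @param min_valid_per_group,groups see [filter_by_validity()].
#' @param down_shift,impute_width,seed see [impute_min_probabilistic()].
#' @return a complete `lfq_norm`.
#' @export
normalize_lfq <- function(m, log_base = 2, center_stat = "mean",
                          width_stat = "sd", min_valid_per_group = 2,
                          groups = NULL, down_shift = 2, impute_width = 0.3,
                          seed = NULL) {
  nm <- log_transform(m, base = log_base)
  nm <- center_by_sample_mean(nm, stat = center_stat)
  nm <- scale_by_sample_width(nm, stat = width_stat)
  nm <- filter_by_validity(nm, min_valid_per_group = min_valid_per_group,
                           groups = groups)
  impute_min_probabilistic(nm, down_shift = down_shift, width = impute_width,
                           seed = seed)
}

#' Replay a provenance record on a raw matrix
#'
#' The provenance attached to an `lfq_norm` fully determines it: replaying
#' the recorded steps (with their recorded parameters, including the
#' imputation seed) on the original raw matrix reproduces the normalized
#' matrix exactly.
#'
#' @param m the raw [lfq_matrix()].
#' @param provenance a provenance list as found in `nm$provenance`.
#' @return the reconstructed `lfq_norm`.
#' @export
replay_provenance <- function(m, provenance) {
  nm <- m
  for (p in provenance) {
    nm <- switch(p$step,
      log = log_transform(nm, base = p$base),
      center = center_by_sample_mean(nm, stat = p$stat),
      scale = scale_by_sample_width(nm, stat = p$stat),
      filter = filter_by_validity(nm, min_valid_per_group = p$min_valid_per_group,
                                  groups = p$groups),
      impute = impute_min_probabilistic(nm, down_shift = p$down_shift,
                                        width = p$width, seed = p$seed),
      stopf("unknown provenance step '%s'", p$step))
  }
  nm
}

#' Write a normalized matrix (and its imputation flags) as TSV
#'
#' @param nm an `lfq_norm`.
#' @param path output path for the values; flags are written alongside with
#'   suffix `.flags.tsv` unless `flags_path` is given.
#' @param flags_path optional explicit path for the imputation-flag table.
#' @return `path`, invisibly.
#' @export
write_norm_matrix <- function(nm, path, flags_path = NULL) {
  stopifnot(inherits(nm, "lfq_norm"))
  df <- data.frame(accession = rownames(nm$values), nm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  flags_path <- flags_path %||% sub("(\\.tsv)?$", ".flags.tsv", path)
  fl <- data.frame(accession = rownames(nm$imputed), nm$imputed * 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(fl, flags_path)
  invisible(path)
}
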