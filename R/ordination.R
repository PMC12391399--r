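# Unsupervised ordination of normalized proteomes: PCA by singular value
# decomposition of the sample x protein matrix, with per-component variance
# explained and a deterministic sign convention.

#' Principal component analysis of a normalized LFQ matrix
#'
#' Samples are observations, proteins are features. Features are
#' mean-centered before decomposition (no per-feature unit-variance scaling:
#' sample-level normalization upstream already equalizes dynamic range).
#' Components are ordered by decreasing variance; the sign of each component
#' is fixed so that its largest-magnitude loading is positive, making output
#' reproducible across runs and platforms.
#'
#' @param nm a complete (imputed) `lfq_norm`, or a numeric matrix with
#'   samples in rows and features in columns.
#' @param n_components number of components to return; default
#'   `min(n_samples - 1, n_features)`.
#' @param center_features mean-center each feature (default `TRUE`).
#' @return an object of class `lfq_pca` with elements `scores` (sample x
#'   component), `loadings` (feature x component), `variance_explained`
#'   (fraction per returned component, computed over the full spectrum), and
#'   `design` when available.
#' @export
pca_lfq <- function(nm, n_components = NULL, center_features = TRUE) {
  design <- NULL
  if (inherits(nm, "lfq_norm")) {
    if (any(is.na(nm$values))) stopf("matrix has missing cells; impute first")
    X <- t(nm$values) # samples x proteins
    design <- nm$design
  } else if (is.matrix(nm) && is.numeric(nm)) {
    if (anyNA(nm)) stopf("matrix has missing cells; impute first")
    X <- nm
  } else {
    stopf("`nm` must be an lfq_norm or a numeric matrix (samples x features)")
  }
  n <- nrow(X); p <- ncol(X)
  max_comp <- min(n - 1L, p)
  n_components <- n_components %||% max_comp
  if (n_components > max_comp) {
    stopf("n_components must be <= min(n_samples - 1, n_features) = %d",
          max_comp)
  }
  Xc <- if (center_features) sweep(X, 2L, colMeans(X)) else X
  sv <- svd(Xc)
  d2 <- sv$d^2
  total <- sum(d2)
  if (total == 0) stopf("matrix has zero total variance")
  ve <- d2 / total
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = length(k))
  loadings <- sv$v[, k, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in k) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", k))
  dimnames(loadings) <- list(colnames(X), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[k],
                 center = if (center_features) colMeans(X) else NULL,
                 design = design),
            class = "lfq_pca")
}

#' @export
print.lfq_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  ve <- sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                100 * x$variance_explained)
  cat("  variance explained:", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' Score plot of an ordination
#'
#' @param x an `lfq_pca`.
#' @param components two component indices to display (default 1:2).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lfq_pca <- function(x, components = c(1L, 2L), ...) {
  s <- x$scores[, components, drop = FALSE]
  ve <- 100 * x$variance_explained[components]
  col <- "grey30"; pch <- 16
  if (!is.null(x$design)) {
    trt <- x$design$treatment[match(rownames(s), x$design$sample_id)]
    iso <- x$design$isolate[match(rownames(s), x$design$sample_id)]
    col <- ifelse(trt == "treated", "red3", "blue3")
    pch <- (15:18)[as.integer(factor(iso)) %% 4L + 1L]
  }
  graphics::plot(s[, 1L], s[, 2L], col = col, pch = pch,
                 xlab = sprintf("PC%d (%.1f%%)", components[1L], ve[1L]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2L], ve[2L]),
                 main = "PCA of normalized proteomes", ...)
  invisible(x)
}

#' Mean silhouette width between labelled groups
#'
#' Small self-contained silhouette computation (Euclidean distance) used to
#' quantify how well condition groups separate in ordination space. Positive
#' values mean points sit closer to their own group than to the nearest
#' other group.
#'
#' @param x numeric vector or matrix (observations in rows).
#' @param groups group labels, one per observation (>= 2 groups).
#' @return the mean silhouette width over all observations.
#' @export
silhouette_groups <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stopf("one group label per observation required")
  if (length(unique(groups)) < 2L) stopf("need >= 2 groups")
  D <- as.matrix(stats::dist(x))
  n <- nrow(x)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]
    if (sum(own) == 1L) { sil[i] <- 0; next } # singleton convention
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(D[i, groups == g]), 0))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Write ordination results as TSVs
#'
#' Writes `<prefix>_scores.tsv`, `<prefix>_loadings.tsv` and
#' `<prefix>_variance.tsv`.
#'
#' @param x an `lfq_pca`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_pca <- function(x, prefix) {
  stopifnot(inherits(x, "lfq_pca"))
  p1 <- paste0(prefix, "_scores.tsv")
  p2 <- paste0(prefix, "_loadings.tsv")
  p3 <- paste0(prefix, "_variance.tsv")
  write_tsv(data.frame(sample_id = rownames(x$scores), x$scores,
                       check.names = FALSE), p1)
  write_tsv(data.frame(accession = rownames(x$loadings), x$loadings,
                       check.names = FALSE), p2)
  write_tsv(data.frame(component = paste0("PC", seq_along(x$variance_explained)),
                       variance_explained = x$variance_explained), p3)
  invisible(c(p1, p2, p3))
}
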