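# Per-protein differential expression: F-test variance gate, gated pooled /
# Welch t-test, log2 fold change, and volcano classification. The test
# statistics are computed from the textbook formulas (vectorised across
# proteins); only the F and t distribution functions come from stats.

#' F-test variance gate
#'
#' Decides, per protein, whether the two replicate groups behave
#' homoscedastically (equal variances) or heteroscedastically. The F
#' statistic is the larger sample variance over the smaller; the p-value is
#' two-sided from the F distribution with matching degrees of freedom. A
#' protein is routed to the heteroscedastic (Welch) branch when the F-test
#' rejects at `alpha_f`, or by rule when exactly one group has zero variance.
#'
#' @param a,b numeric replicate vectors (length >= 2 each).
#' @param alpha_f significance level of the gate (default 0.05, two-sided).
#' @return list with `variance_mode` (`"homoscedastic"` or
#'   `"heteroscedastic"`), `f_stat` and `f_pvalue`.
#' @export
variance_gate <- function(a, b, alpha_f = 0.05) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 replicates")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stopf("both group variances are zero (degenerate protein)")
  if (va == 0 || vb == 0) {
    return(list(variance_mode = "heteroscedastic", f_stat = Inf, f_pvalue = 0))
  }
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(variance_mode = if (p < alpha_f) "heteroscedastic" else "homoscedastic",
       f_stat = f, f_pvalue = p)
}

#' Two-sample t-test on the branch chosen by the variance gate
#'
#' Homoscedastic: pooled-variance two-sample t-test with
#' `df = n_a + n_b - 2`. Heteroscedastic: unequal-variance (Welch) t-test
#' with Welch-Satterthwaite degrees of freedom. Two-sided p-value in both
#' branches. The statistic is oriented `a` minus `b`.
#'
#' @param a,b numeric replicate vectors (length >= 2 each).
#' @param variance_mode `"homoscedastic"` or `"heteroscedastic"`, normally
#'   the output of [variance_gate()].
#' @return list with `t_stat`, `df` and `p_value`.
#' @export
gated_t_test <- function(a, b,
                         variance_mode = c("homoscedastic", "heteroscedastic")) {
  variance_mode <- match.arg(variance_mode)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each group needs >= 2 replicates")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (variance_mode == "homoscedastic") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    # identical constant groups with equal means: no evidence of difference
    t <- 0
  } else {
    t <- d / se
  }
  list(t_stat = t, df = df,
       p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Log2 fold change between two groups
#'
#' On log2-normalized abundances the fold change is the difference of group
#' means: a difference of 1 corresponds to a two-fold intensity ratio.
#' Anti-symmetric: `fold_change(a, b) == -fold_change(b, a)`.
#'
#' @param a,b numeric vectors of normalized log2 abundances.
#' @return the log2 fold change `mean(a) - mean(b)`.
#' @export
fold_change <- function(a, b) mean(a) - mean(b)

#' Classify a protein on the volcano plot
#'
#' Up-regulated: fold change above `fc_threshold` with `p < p_threshold`;
#' down-regulated: fold change below `-fc_threshold` with `p < p_threshold`;
#' otherwise not significant. With `strict = TRUE` (default) the fold-change
#' comparison is strict (`>` / `<`), so a protein exactly at the boundary is
#' not significant; `strict = FALSE` uses `>=` / `<=`.
#'
#' @param log2_fc,p_value numeric vectors (recycled to common length).
#' @param fc_threshold log2 fold-change threshold (default 1).
#' @param p_threshold raw p-value threshold (default 0.05, always strict).
#' @param strict strict fold-change boundary handling (default `TRUE`).
#' @return character vector in `c("up", "down", "not_significant")`.
#' @export
classify_volcano <- function(log2_fc, p_value, fc_threshold = 1,
                             p_threshold = 0.05, strict = TRUE) {
  stopifnot(all(is.finite(log2_fc)), all(is.finite(p_value)))
  n <- max(length(log2_fc), length(p_value))
  log2_fc <- rep_len(log2_fc, n); p_value <- rep_len(p_value, n)
  sig <- p_value < p_threshold
  up <- if (strict) log2_fc > fc_threshold else log2_fc >= fc_threshold
  dn <- if (strict) log2_fc < -fc_threshold else log2_fc <= -fc_threshold
  out <- rep("not_significant", n)
  out[sig & up] <- "up"
  out[sig & dn] <- "down"
  out
}

#' Volcano p-value axis transform
#'
#' Maps a raw p-value to the significance axis of the volcano plot. The
#' default base-2 transform makes the p = 0.05 cut-off equal
#' `-log2(0.05) = 4.32`.
#'
#' @param p_value p-values in (0, 1].
#' @param base logarithm base (default 2).
#' @return `-log(p, base)`, non-negative.
#' @export
p_axis_transform <- function(p_value, base = 2) {
  if (any(!is.finite(p_value)) || any(p_value <= 0) || any(p_value > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  -log(p_value, base = base)
}

# Vectorised per-protein statistics for two sample groups given as matrices
# (proteins x replicates). Returns the same quantities as the scalar ops.
de_stats_matrix <- function(A, B, alpha_f) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  hi <- pmax(va, vb); lo <- pmin(va, vb)
  f <- hi / lo
  df1 <- ifelse(va >= vb, na - 1, nb - 1)
  df2 <- ifelse(va >= vb, nb - 1, na - 1)
  f_p <- pmin(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  one_zero <- (va == 0) != (vb == 0)
  f[one_zero] <- Inf; f_p[one_zero] <- 0
  hetero <- f_p < alpha_f
  d <- ma - mb
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- ifelse(hetero,
               sqrt(va / na + vb / nb),
               sqrt(sp2 * (1 / na + 1 / nb)))
  df <- ifelse(hetero,
               (va / na + vb / nb)^2 /
                 ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  t <- ifelse(se == 0, 0, d / se)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(mean_a = ma, mean_b = mb, log2_fc = d,
       f_stat = f, f_pvalue = f_p,
       variance_mode = ifelse(hetero, "heteroscedastic", "homoscedastic"),
       t_stat = t, df = df, p_value = p,
       degenerate = va == 0 & vb == 0)
}

#' Differential expression table for one isolate contrast
#'
#' Runs the variance-gated t-test for every retained protein between the
#' treated and control groups of one isolate, computes log2 fold changes
#' (treated minus control, so "up" means higher under treatment), transforms
#' the p-value axis, and classifies each protein on the volcano plot.
#' Proteins with zero variance in both groups are excluded and recorded in
#' `attr(, "excluded")`.
#'
#' @param nm a filtered, imputed `lfq_norm`.
#' @param isolate isolate label selecting the contrast groups.
#' @param alpha_f F-gate level (default 0.05).
#' @param fc_threshold,p_threshold,strict volcano thresholds, see
#'   [classify_volcano()].
#' @param p_axis_base base of the significance-axis transform (default 2).
#' @param adjust_p if `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column `p_adj` (annotation only; never alters `volcano_class`).
#' @return a `data.frame` of class `de_table` with columns `accession`,
#'   `mean_control`, `mean_treated`, `log2_fc`, `f_stat`, `f_pvalue`,
#'   `variance_mode`, `t_stat`, `df`, `p_value`, `neg_log2_p`,
#'   `volcano_class`, plus attributes `thresholds`, `isolate`, `counts`
#'   (`n_up`, `n_down`) and `excluded`.
#' @export
run_de_table <- function(nm, isolate, alpha_f = 0.05, fc_threshold = 1,
                         p_threshold = 0.05, strict = TRUE, p_axis_base = 2,
                         adjust_p = FALSE) {
  stopifnot(inherits(nm, "lfq_norm"))
  if (any(is.na(nm$values))) stopf("matrix has missing cells; impute first")
  des <- nm$design
  trt <- des$sample_id[des$isolate == isolate & des$treatment == "treated"]
  ctl <- des$sample_id[des$isolate == isolate & des$treatment == "control"]
  if (length(trt) < 2L || length(ctl) < 2L) {
    stopf("isolate '%s': each contrast group needs >= 2 samples", isolate)
  }
  A <- nm$values[, trt, drop = FALSE]
  B <- nm$values[, ctl, drop = FALSE]
  st <- de_stats_matrix(A, B, alpha_f = alpha_f)
  keep <- !st$degenerate
  excluded <- data.frame(accession = rownames(A)[!keep],
                         reason = rep("zero variance in both groups", sum(!keep)),
                         stringsAsFactors = FALSE)
  if (any(!keep)) {
    message(sprintf("excluding %d protein(s) with zero variance in both groups",
                    sum(!keep)))
  }
  idx <- which(keep)
  tab <- data.frame(
    accession = rownames(A)[idx],
    mean_control = st$mean_b[idx],
    mean_treated = st$mean_a[idx],
    log2_fc = st$log2_fc[idx],
    f_stat = st$f_stat[idx],
    f_pvalue = st$f_pvalue[idx],
    variance_mode = st$variance_mode[idx],
    t_stat = st$t_stat[idx],
    df = st$df[idx],
    p_value = st$p_value[idx],
    stringsAsFactors = FALSE)
  tab$neg_log2_p <- p_axis_transform(pmax(tab$p_value, .Machine$double.xmin),
                                     base = p_axis_base)
  tab$volcano_class <- classify_volcano(tab$log2_fc, tab$p_value,
                                        fc_threshold = fc_threshold,
                                        p_threshold = p_threshold,
                                        strict = strict)
  if (adjust_p) tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  rownames(tab) <- NULL
  structure(tab,
            class = c("de_table", "data.frame"),
            thresholds = list(alpha_f = alpha_f, fc_threshold = fc_threshold,
                              p_threshold = p_threshold, strict = strict,
                              p_axis_base = p_axis_base),
            isolate = isolate,
            counts = c(n_up = sum(tab$volcano_class == "up"),
                       n_down = sum(tab$volcano_class == "down")),
            excluded = excluded)
}

#' @export
print.de_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("DE table for isolate '%s': %d proteins tested\n",
              attr(x, "isolate"), nrow(x)))
  cat(sprintf("  up: %d | down: %d | not significant: %d\n",
              cnt["n_up"], cnt["n_down"],
              nrow(x) - cnt["n_up"] - cnt["n_down"]))
  th <- attr(x, "thresholds")
  cat(sprintf("  thresholds: |log2FC| %s %g, p < %g, F-gate alpha %g\n",
              if (th$strict) ">" else ">=", th$fc_threshold,
              th$p_threshold, th$alpha_f))
  invisible(x)
}

#' @export
summary.de_table <- function(object, ...) {
  cnt <- attr(object, "counts")
  modes <- table(object$variance_mode)
  out <- list(isolate = attr(object, "isolate"),
              n_tested = nrow(object),
              n_up = unname(cnt["n_up"]), n_down = unname(cnt["n_down"]),
              variance_modes = modes,
              thresholds = attr(object, "thresholds"),
              n_excluded = nrow(attr(object, "excluded")))
  class(out) <- "summary.de_table"
  out
}

#' @export
print.summary.de_table <- function(x, ...) {
  cat(sprintf("Contrast: %s (treated vs control)\n", x$isolate))
  cat(sprintf("  tested %d proteins (%d excluded as degenerate)\n",
              x$n_tested, x$n_excluded))
  cat(sprintf("  up-regulated: %d, down-regulated: %d\n", x$n_up, x$n_down))
  cat("  variance gate:",
      paste(sprintf("%s %d", names(x$variance_modes), x$variance_modes),
            collapse = ", "), "\n")
  invisible(x)
}

#' Volcano plot of a DE table
#'
#' @param x a `de_table`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.de_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  col <- c(up = "red3", down = "blue3", not_significant = "grey60")
  graphics::plot(x$log2_fc, x$neg_log2_p,
                 col = grDevices::adjustcolor(col[x$volcano_class], 0.7),
                 pch = 16, cex = 0.6,
                 xlab = "log2 fold-change (treated vs control)",
                 ylab = sprintf("-log%d(p-value)", th$p_axis_base),
                 main = sprintf("Volcano: %s", attr(x, "isolate")), ...)
  graphics::abline(v = c(-1, 1) * th$fc_threshold, lty = 2, col = "grey40")
  graphics::abline(h = -log(th$p_threshold, th$p_axis_base), lty = 2,
                   col = "grey40")
  invisible(x)
}

#' Write a DE table as TSV
#'
#' Writes the canonical column set: accession, mean_control, mean_treated,
#' log2_fc, f_pvalue, variance_mode, t_stat, df, p_value, neg_log2_p,
#' volcano_class.
#'
#' @param x a `de_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_table"))
  cols <- c("accession", "mean_control", "mean_treated", "log2_fc",
            "f_pvalue", "variance_mode", "t_stat", "df", "p_value",
            "neg_log2_p", "volcano_class")
  write_tsv(as.data.frame(x)[, cols], path)
}
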