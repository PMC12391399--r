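test_that("variance gate: decisions and agreement with the F-distribution oracle", {
  # equal variances -> F = 1, homoscedastic
  g <- variance_gate(c(0, 1, 2), c(5, 6, 7))
  expect_identical(g$variance_mode, "homoscedastic")
  expect_equal(g$f_stat, 1)
  # variances 1 vs 100 at n = 3: p from var.test oracle, heteroscedastic
  a <- c(-1, 0, 1)        # var 1
  b <- c(-10, 0, 10)      # var 100
  g2 <- variance_gate(a, b, alpha_f = 0.05)
  expect_identical(g2$variance_mode, "heteroscedastic")
  expect_equal(g2$f_stat, 100)
  expect_equal(g2$f_pvalue, stats::var.test(b, a)$p.value, tolerance = 1e-12)
  expect_equal(g2$f_pvalue, 0.01980198, tolerance = 1e-6)
  # one zero-variance group -> heteroscedastic by rule
  g3 <- variance_gate(c(1, 1, 1), c(1, 2, 3))
  expect_identical(g3$variance_mode, "heteroscedastic")
  # both zero -> degenerate error
  expect_error(variance_gate(c(1, 1), c(2, 2)), "zero")
})

test_that("gated t-test matches hand-computed pooled formula and t.test", {
  # a = {1,2,3}, b = {4,5,6}: pooled SE = sqrt(2/3), df = 4
  r <- gated_t_test(c(1, 2, 3), c(4, 5, 6), "homoscedastic")
  expect_equal(r$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.02131164113, tolerance = 1e-9)
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
  # Welch branch vs t.test
  set.seed(7)
  a <- rnorm(4, 0, 1); b <- rnorm(5, 1, 3)
  w <- gated_t_test(a, b, "heteroscedastic")
  tw <- stats::t.test(a, b)
  expect_equal(w$t_stat, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, tw$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  id <- gated_t_test(c(1, 2, 3), c(3, 1, 2), "homoscedastic")
  expect_equal(id$t_stat, 0)
  expect_equal(id$p_value, 1)
  # symmetry: swapping groups negates t, preserves p
  s1 <- gated_t_test(a, b, "heteroscedastic")
  s2 <- gated_t_test(b, a, "heteroscedastic")
  expect_equal(s1$t_stat, -s2$t_stat)
  expect_equal(s1$p_value, s2$p_value)
})

test_that("fold change is the log2 mean difference, anti-symmetric", {
  expect_equal(fold_change(c(1, 2), c(1, 2)), 0)
  expect_equal(fold_change(c(3, 3), c(2, 2)), 1)
  set.seed(12)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(fold_change(a, b), -fold_change(b, a))
})

test_that("volcano classification applies joint thresholds, strict boundary", {
  expect_identical(classify_volcano(1.5, 0.01), "up")
  expect_identical(classify_volcano(-2, 0.04), "down")
  expect_identical(classify_volcano(0.5, 0.001), "not_significant")
  expect_identical(classify_volcano(1.5, 0.2), "not_significant")
  # boundary |log2FC| = 1 is not significant under the strict rule,
  # significant under the inclusive variant
  expect_identical(classify_volcano(-1.0, 0.01), "not_significant")
  expect_identical(classify_volcano(1.0, 0.01), "not_significant")
  expect_identical(classify_volcano(-1.0, 0.01, strict = FALSE), "down")
  expect_identical(classify_volcano(1.0, 0.01, strict = FALSE), "up")
})

test_that("p-axis transform reproduces the 0.05 <-> 4.32 cut-off", {
  expect_equal(round(p_axis_transform(0.05), 2), 4.32)
  expect_equal(p_axis_transform(1), 0)
  expect_equal(p_axis_transform(0.25), 2)
  expect_error(p_axis_transform(0), "0, 1")
  expect_error(p_axis_transform(-0.1), "0, 1")
})

test_that("DE table equals a protein-by-protein independent oracle", {
  sim <- generate_lfq(n_proteins = 300, isolates = "A", reps = 3,
                      de_fraction = 1 / 6, effect_size = 2, group_sds = 0.3,
                      seed = 41)
  nm <- normalize_lfq(sim$matrix, seed = 42)
  de <- run_de_table(nm, "A")
  trt <- nm$design$sample_id[nm$design$treatment == "treated"]
  ctl <- nm$design$sample_id[nm$design$treatment == "control"]
  for (i in seq_len(nrow(de))) {
    p <- de$accession[i]
    o <- oracle_de(nm$values[p, trt], nm$values[p, ctl])
    expect_equal(de$f_stat[i], o$f_stat, tolerance = 1e-10)
    expect_equal(de$f_pvalue[i], o$f_pvalue, tolerance = 1e-10)
    expect_identical(de$variance_mode[i], o$variance_mode)
    expect_equal(de$t_stat[i], o$t_stat, tolerance = 1e-10)
    expect_equal(de$df[i], o$df, tolerance = 1e-10)
    expect_equal(de$p_value[i], o$p_value, tolerance = 1e-10)
    expect_equal(de$log2_fc[i], o$log2_fc, tolerance = 1e-10)
    expect_equal(de$neg_log2_p[i], -log2(de$p_value[i]))
  }
})

test_that("group-label symmetry: swapping conditions flips signs and counts", {
  sim <- generate_lfq(n_proteins = 200, isolates = "A", reps = 3,
                      de_fraction = 0.2, seed = 55)
  nm <- normalize_lfq(sim$matrix, seed = 56)
  de <- run_de_table(nm, "A", fc_threshold = 0.5)
  # swap the condition labels in the design and rerun
  des2 <- as.data.frame(nm$design)
  des2$treatment <- ifelse(des2$treatment == "treated", "control", "treated")
  nm2 <- nm
  nm2$design <- validate_design(des2)
  de2 <- run_de_table(nm2, "A", fc_threshold = 0.5)
  expect_equal(de2$log2_fc, -de$log2_fc)
  expect_equal(de2$t_stat, -de$t_stat)
  expect_equal(de2$p_value, de$p_value)
  expect_identical(sum(de2$volcano_class == "up"),
                   sum(de$volcano_class == "down"))
  expect_identical(sum(de2$volcano_class == "down"),
                   sum(de$volcano_class == "up"))
})

test_that("p-values are monotone in |mean difference| at fixed spread", {
  a0 <- c(-0.3, 0, 0.3)
  b <- c(-0.3, 0, 0.3)
  deltas <- seq(0, 3, by = 0.25)
  ps <- vapply(deltas, function(d)
    gated_t_test(a0 + d, b, "homoscedastic")$p_value, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("null homoscedastic p-values are uniform (KS at n = 10,000)", {
  set.seed(2024)
  n <- 10000
  A <- matrix(rnorm(n * 3), n)
  B <- matrix(rnorm(n * 3), n)
  ps <- vapply(seq_len(n), function(i)
    gated_t_test(A[i, ], B[i, ], "homoscedastic")$p_value, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("all-identical columns yield zero up and zero down", {
  design <- toy_design(reps = 3)
  v <- matrix(rep(rnorm(20, 20, 2), 6), 20, 6,
              dimnames = list(sprintf("P%02d", 1:20), design$sample_id))
  v <- v + matrix(rnorm(120, 0, 1e-9), 20) # break exact zero variance only
  nm <- scale_by_sample_width(center_by_sample_mean(toy_norm(v, design)))
  de <- run_de_table(nm, "ISO1")
  cnt <- attr(de, "counts")
  expect_identical(unname(cnt["n_up"]), 0L)
  expect_identical(unname(cnt["n_down"]), 0L)
})

test_that("DE table TSV has the canonical column set", {
  sim <- generate_lfq(n_proteins = 50, isolates = "A", reps = 3, seed = 61)
  nm <- normalize_lfq(sim$matrix, seed = 62)
  de <- run_de_table(nm, "A")
  path <- tempfile(fileext = ".tsv")
  write_de_table(de, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("accession", "mean_control", "mean_treated", "log2_fc",
                     "f_pvalue", "variance_mode", "t_stat", "df", "p_value",
                     "neg_log2_p", "volcano_class"))
})
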