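test_that("log transform maps present cells and preserves missingness", {
  design <- toy_design(reps = 3)
  v <- matrix(c(1, 1024, 4, 8, 16, 32,
                2, 4, 8, 16, 32, 64), nrow = 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), design$sample_id))
  v[2, 3] <- NA
  nm <- log_transform(lfq_matrix(v, design), base = 2)
  expect_identical(nm$values["P1", 1], 0)
  expect_identical(nm$values["P1", 2], 10)
  expect_true(is.na(nm$values["P2", 3]))
  expect_identical(sum(is.na(nm$values)), 1L)
})

test_that("centering subtracts the valid-value mean per sample", {
  design <- toy_design(reps = 3)
  v <- matrix(2, nrow = 3, ncol = 6,
              dimnames = list(c("P1", "P2", "P3"), design$sample_id))
  v[, 1] <- c(2, 4, 6)
  v[, 2] <- c(1, NA, 3)
  nm <- toy_norm(v, design)
  cn <- center_by_sample_mean(nm)
  expect_equal(cn$values[, 1], c(P1 = -2, P2 = 0, P3 = 2))
  expect_equal(cn$values[, 2], c(P1 = -1, P2 = NA, P3 = 1))
  # idempotence on already-centered input
  cn2 <- center_by_sample_mean(cn)
  expect_equal(cn2$values, cn$values)
  # mean over valid values is 0 within 1e-9 for every sample
  for (j in seq_len(ncol(cn$values))) {
    expect_lt(abs(mean(cn$values[, j], na.rm = TRUE)), 1e-9)
  }
})

test_that("width scaling yields unit SD per sample; center+scale = z-scores", {
  design <- toy_design(reps = 3)
  set.seed(4)
  v <- matrix(rnorm(5 * 6, 20, 3), nrow = 5,
              dimnames = list(sprintf("P%d", 1:5), design$sample_id))
  nm <- scale_by_sample_width(center_by_sample_mean(toy_norm(v, design)))
  for (j in seq_len(ncol(v))) {
    expect_lt(abs(sd(nm$values[, j]) - 1), 1e-9)
    expect_equal(nm$values[, j],
                 (v[, j] - mean(v[, j])) / sd(v[, j])) # brute-force z-score
  }
  # explicit column {-2, 0, 2}: SD 2 -> {-1, 0, 1}
  expect_equal(unname(scale_by_sample_width(center_by_sample_mean(
    toy_norm(matrix(c(-2, 0, 2), 3, 6,
                    dimnames = list(paste0("P", 1:3), design$sample_id)),
             design)))$values[, 1]),
    c(-1, 0, 1))
})

test_that("validity filter matches brute-force enumeration on mixed patterns", {
  design <- toy_design(reps = 3, isolates = c("A", "B"))
  set.seed(9)
  v <- matrix(rnorm(10 * 12, 20, 2), nrow = 10,
              dimnames = list(sprintf("P%02d", 1:10), design$sample_id))
  # plant patterns: P01 all missing, P02 fully observed, others random holes
  v[1, ] <- NA
  for (i in 3:10) v[i, sample(12, sample(0:10, 1))] <- NA
  keepable <- rownames(v)[apply(v, 1, function(r) !all(is.na(r)))]
  nm <- toy_norm_allow_na(v, design)
  filt <- filter_by_validity(nm, min_valid_per_group = 2)
  # brute-force oracle: for each isolate pair, >=2 valid in control or treated
  expected <- vapply(rownames(v), function(p) {
    all(vapply(c("A", "B"), function(iso) {
      ctl <- design$sample_id[design$isolate == iso & design$treatment == "control"]
      trt <- design$sample_id[design$isolate == iso & design$treatment == "treated"]
      sum(!is.na(v[p, ctl])) >= 2 || sum(!is.na(v[p, trt])) >= 2
    }, TRUE))
  }, TRUE)
  expect_identical(rownames(filt$values), rownames(v)[expected])
  expect_false("P01" %in% rownames(filt$values))
  expect_true("P02" %in% rownames(filt$values))
  expect_setequal(attr(filt, "removed")$accession, rownames(v)[!expected])
  # explicit groups list uses the any-group rule
  g <- split(design$sample_id, paste(design$isolate, design$treatment))
  filt2 <- filter_by_validity(nm, min_valid_per_group = 2, groups = g)
  expected2 <- vapply(rownames(v), function(p)
    any(vapply(g, function(s) sum(!is.na(v[p, s])) >= 2, TRUE)), TRUE)
  expect_identical(rownames(filt2$values), rownames(v)[expected2])
})

test_that("imputation draws from the down-shifted Gaussian, reproducibly", {
  # one sample with 10,000 valid standard-normal values and 10,000 missing
  design <- toy_design(reps = 3)
  n <- 20000
  set.seed(5)
  v <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("P%05d", 1:n), design$sample_id))
  v[10001:20000, 1] <- NA
  nm <- scale_by_sample_width(center_by_sample_mean(toy_norm_allow_na(v, design)))
  imp <- impute_min_probabilistic(nm, down_shift = 2, width = 0.3, seed = 99)
  drawn <- imp$values[imp$imputed[, 1], 1]
  expect_identical(length(drawn), 10000L)
  expect_lt(abs(mean(drawn) - (-2)), 0.01)
  expect_lt(abs(sd(drawn) - 0.3), 0.01)
  # determinism: same seed, bit-identical draws
  imp2 <- impute_min_probabilistic(nm, down_shift = 2, width = 0.3, seed = 99)
  expect_identical(imp$values, imp2$values)
  # different seed changes draws
  imp3 <- impute_min_probabilistic(nm, down_shift = 2, width = 0.3, seed = 100)
  expect_false(identical(imp$values, imp3$values))
  # flags count equals the pre-imputation missing count
  expect_identical(sum(imp$imputed), 10000L)
  expect_false(anyNA(imp$values))
})

test_that("imputation contract: seed mandatory, no-missing matrix unchanged", {
  design <- toy_design(reps = 3)
  v <- matrix(rnorm(18, 20, 2), 3, 6,
              dimnames = list(paste0("P", 1:3), design$sample_id))
  nm <- toy_norm(v, design)
  out <- impute_min_probabilistic(nm, seed = NULL)
  expect_identical(out$values, nm$values)
  expect_identical(sum(out$imputed), 0L)
  v[1, 1] <- NA
  nm2 <- toy_norm_allow_na(v, design)
  expect_error(impute_min_probabilistic(nm2), "seed")
})

test_that("provenance replay reproduces the normalized matrix exactly", {
  sim <- generate_lfq(n_proteins = 120, isolates = c("A", "B"), reps = 3,
                      seed = 21)
  nm <- normalize_lfq(sim$matrix, seed = 77)
  re <- replay_provenance(sim$matrix, nm$provenance)
  expect_identical(re$values, nm$values)
  expect_identical(re$imputed, nm$imputed)
})

test_that("stages commute with sample-column permutation of the input file", {
  sim <- generate_lfq(n_proteins = 60, isolates = "A", reps = 3, seed = 31)
  tab <- data.frame(accession = rownames(sim$matrix$values),
                    sim$matrix$values, check.names = FALSE)
  tab[is.na(tab)] <- 0
  perm <- tab[, c(1, 1 + sample(ncol(sim$matrix$values))), drop = FALSE]
  m1 <- read_protein_groups(write_fixture_tsv(tab), sim$design)
  m2 <- read_protein_groups(write_fixture_tsv(perm), sim$design)
  n1 <- normalize_lfq(m1, seed = 5)
  n2 <- normalize_lfq(m2, seed = 5)
  expect_identical(n1$values, n2$values)
  # protein-row permutation commutes with center+scale
  shuf <- sample(nrow(sim$matrix$values))
  m3 <- lfq_matrix(sim$matrix$values[shuf, ], sim$design)
  n3 <- scale_by_sample_width(center_by_sample_mean(log_transform(m3)))
  n0 <- scale_by_sample_width(center_by_sample_mean(log_transform(sim$matrix)))
  expect_equal(n3$values, n0$values[rownames(n3$values), ])
})
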