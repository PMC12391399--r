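# independent brute-force region oracle: classify every element of the
# union by its exact membership signature
brute_regions <- function(sets) {
  u <- unique(unlist(sets))
  nms <- names(sets)
  sig <- vapply(u, function(e)
    paste(nms[vapply(sets, function(s) e %in% s, TRUE)], collapse = "&"), "")
  table(factor(sig, levels = unique(sig)))
}

test_that("venn regions: disjoint, identical and degenerate cases", {
  r <- venn_regions(list(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                         C = c("c1", "c2", "c3", "c4")))
  counts <- setNames(r$count, r$region)
  expect_identical(counts[["A"]], 2L)
  expect_identical(counts[["B"]], 3L)
  expect_identical(counts[["C"]], 4L)
  expect_true(all(counts[c("A&B", "A&C", "B&C", "A&B&C")] == 0L))
  s <- paste0("x", 1:5)
  r2 <- venn_regions(list(A = s, B = s, C = s))
  counts2 <- setNames(r2$count, r2$region)
  expect_identical(counts2[["A&B&C"]], 5L)
  expect_identical(sum(counts2), 5L)
  # one set: the degenerate "Venn" is the set itself
  r3 <- venn_regions(list(only = c("p1", "p2")))
  expect_identical(r3$count, 2L)
  expect_error(venn_regions(list(c("a"), c("b"))), "names")
  expect_error(venn_regions(list(A = "a", A = "b")), "names")
})

test_that("region counts equal brute-force enumeration on random sets", {
  set.seed(314)
  pool <- sprintf("P%02d", 1:20)
  for (rep in 1:50) {
    k <- sample(2:3, 1)
    sets <- setNames(lapply(seq_len(k), function(i)
      sample(pool, sample(0:20, 1))), LETTERS[seq_len(k)])
    r <- venn_regions(sets)
    bf <- brute_regions(sets)
    for (region in r$region) {
      expected <- if (region %in% names(bf)) unname(bf[[region]]) else 0L
      expect_identical(r$count[r$region == region], as.integer(expected))
    }
    # partition property: counts sum to the union size
    expect_identical(sum(r$count), length(unique(unlist(sets))))
    # members partition the union
    memb <- attr(r, "members")
    expect_identical(sort(unname(unlist(memb))), sort(unique(unlist(sets))))
  }
})

test_that("label permutation equivariance", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = c("z"))
  r1 <- venn_regions(sets)
  r2 <- venn_regions(list(C = sets$C, A = sets$A, B = sets$B))
  for (reg in r1$region) {
    parts <- sort(strsplit(reg, "&", fixed = TRUE)[[1]])
    match2 <- vapply(r2$region, function(g)
      identical(sort(strsplit(g, "&", fixed = TRUE)[[1]]), parts), TRUE)
    expect_identical(r1$count[r1$region == reg], r2$count[match2])
  }
})

test_that("extract_sets builds per-direction sets and refuses mixed thresholds", {
  sim <- generate_lfq(n_proteins = 400, reps = 3, de_fraction = 0.1,
                      dropout = NULL, seed = 71)
  nm <- normalize_lfq(sim$matrix, seed = 72)
  isos <- unique(sim$design$isolate)
  tabs <- setNames(lapply(isos, function(i)
    run_de_table(nm, i, fc_threshold = 0.5)), isos)
  sets <- extract_sets(tabs)
  for (iso in isos) {
    expect_setequal(sets$up[[iso]],
                    tabs[[iso]]$accession[tabs[[iso]]$volcano_class == "up"])
    expect_setequal(sets$down[[iso]],
                    tabs[[iso]]$accession[tabs[[iso]]$volcano_class == "down"])
  }
  expect_identical(sum(sets$regions$up$count),
                   length(unique(unlist(sets$up))))
  # mismatched thresholds across tables is an error
  tabs2 <- tabs
  tabs2[[1]] <- run_de_table(nm, isos[1], fc_threshold = 0.9)
  expect_error(extract_sets(tabs2), "thresholds")
  # empty up classes give empty up regions
  high <- setNames(lapply(isos, function(i)
    run_de_table(nm, i, fc_threshold = 50)), isos)
  sets_hi <- extract_sets(high)
  expect_identical(sum(sets_hi$regions$up$count), 0L)
})

test_that("planted shared/exclusive Venn structure is recovered at near-zero noise", {
  isos <- c("4A+", "CC-1009", "CC-2931")
  # deterministic pattern: exclusive to each isolate, each pair, and all three
  pattern <- list(isos[1], isos[2], isos[3],
                  isos[1:2], isos[2:3], isos[c(1, 3)], isos)
  sim <- generate_lfq(n_proteins = 420, isolates = isos, reps = 3,
                      de_fraction = 1 / 6, effect_size = 2, group_sds = 0.01,
                      dropout = NULL, share_pattern = pattern, seed = 81)
  nm <- normalize_lfq(sim$matrix, seed = 82)
  tabs <- setNames(lapply(isos, function(i)
    run_de_table(nm, i, fc_threshold = 0.5)), isos)
  sets <- extract_sets(tabs)
  eff <- sim$truth$effects
  for (iso in isos) {
    expect_setequal(sets$up[[iso]], rownames(eff)[eff[, iso] > 0])
    expect_setequal(sets$down[[iso]], rownames(eff)[eff[, iso] < 0])
  }
  # region membership equals the planted design, per direction
  for (dir in c("up", "down")) {
    sgn <- if (dir == "up") 1 else -1
    planted_sets <- setNames(lapply(isos, function(iso)
      rownames(eff)[sgn * eff[, iso] > 0]), isos)
    truth_regions <- venn_regions(planted_sets)
    got <- sets$regions[[dir]]
    expect_identical(setNames(got$count, got$region),
                     setNames(truth_regions$count, truth_regions$region))
  }
})
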