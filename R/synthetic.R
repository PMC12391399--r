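# Seeded synthetic-data generator emulating the study design: 3 isolates x
# 2 conditions (control vs treated) x 3 biological replicates, log-normal
# protein abundances, a minority of proteins with planted treatment effects
# (optionally shared across isolates), and abundance-dependent (MNAR)
# logistic dropout. Full ground truth is returned for recovery scoring.

#' Generate a synthetic LFQ experiment with ground truth
#'
#' True log2 abundances are Gaussian around a per-protein baseline
#' (`N(baseline_mean, baseline_sd)` across proteins, by default N(20, 2) to
#' mimic LFQ dynamic range), plus the planted treatment effect in treated
#' samples, plus within-group noise. Raw intensity is `2^abundance`. Each
#' cell is dropped to missing with probability
#' `plogis(-slope * (abundance - midpoint))`, so dropout is non-increasing
#' in abundance (missing not at random).
#'
#' A fraction `de_fraction` of proteins receives a treatment effect of
#' `+/- effect_size` log2 units (random sign, constant across the isolates
#' sharing it). Which isolates share each effect is drawn uniformly from the
#' non-empty isolate subsets unless `share_pattern` supplies, per DE protein,
#' a character vector naming its isolates (recycled as a list).
#'
#' @param n_proteins number of proteins (default 2000).
#' @param isolates isolate labels (default the three study isolates).
#' @param reps biological replicates per (isolate, condition), >= 2.
#' @param de_fraction fraction of proteins with a planted effect, in [0, 1].
#' @param effect_size absolute planted effect, log2 units (default 2).
#' @param group_sds within-group SD; length 1, or length 2 as
#'   c(control, treated) to plant heteroscedastic proteins exercising the
#'   F-gate.
#' @param dropout `NULL` for complete data, or `list(midpoint=, slope=)` of
#'   the logistic dropout curve on the log2-abundance scale (defaults 16, 1,
#'   which give roughly 7% overall missingness under the default baseline).
#' @param baseline_mean,baseline_sd baseline log2 abundance distribution.
#' @param share_pattern optional list of isolate-label vectors assigning
#'   each DE protein to isolates (recycled); default random non-empty subsets.
#' @param seed integer seed (mandatory; everything is reproducible from it).
#' @return a list of class `lfq_sim`: `matrix` (an [lfq_matrix()]), `design`,
#'   and `truth` (list with `effects` proteins x isolates matrix of planted
#'   log2 effects, `de_accessions`, `pattern`, dropout and noise parameters,
#'   and the seed).
#' @export
generate_lfq <- function(n_proteins = 2000, isolates = c("4A+", "CC-1009", "CC-2931"),
                         reps = 3, de_fraction = 0.05, effect_size = 2,
                         group_sds = 0.3,
                         dropout = list(midpoint = 16, slope = 1),
                         baseline_mean = 20, baseline_sd = 2,
                         share_pattern = NULL, seed) {
  if (missing(seed)) stopf("`seed` is required")
  if (reps < 2L) stopf("reps must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) stopf("de_fraction must be in [0, 1]")
  if (length(group_sds) == 1L) group_sds <- rep(group_sds, 2L)
  k <- length(isolates)
  acc <- sprintf("P%05d", seq_len(n_proteins))

  design <- expand.grid(replicate = seq_len(reps),
                        treatment = c("control", "treated"),
                        isolate = isolates,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("isolate", "treatment", "replicate")]
  design$dose <- ifelse(design$treatment == "treated", 10, 0)
  design$sample_id <- sprintf("%s_%s_%d", gsub("[^A-Za-z0-9]", "", design$isolate),
                              design$treatment, design$replicate)
  design <- validate_design(design[, c("sample_id", "isolate", "treatment",
                                       "dose", "replicate")])

  out <- with_seed(stage_seed(seed, "simulate"), {
    baseline <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    n_de <- floor(de_fraction * n_proteins)
    de_idx <- if (n_de > 0) sort(sample.int(n_proteins, n_de)) else integer()
    effects <- matrix(0, n_proteins, k, dimnames = list(acc, isolates))
    pattern <- vector("list", n_de)
    if (n_de > 0) {
      subsets <- unlist(lapply(seq_len(k), function(s)
        utils::combn(isolates, s, simplify = FALSE)), recursive = FALSE)
      signs <- sample(c(-1, 1), n_de, replace = TRUE)
      for (i in seq_len(n_de)) {
        iso_i <- if (!is.null(share_pattern)) {
          share_pattern[[(i - 1L) %% length(share_pattern) + 1L]]
        } else {
          subsets[[sample.int(length(subsets), 1L)]]
        }
        pattern[[i]] <- iso_i
        effects[de_idx[i], iso_i] <- signs[i] * effect_size
      }
      names(pattern) <- acc[de_idx]
    }
    abund <- matrix(NA_real_, n_proteins, nrow(design),
                    dimnames = list(acc, design$sample_id))
    for (j in seq_len(nrow(design))) {
      treated <- design$treatment[j] == "treated"
      eff <- if (treated) effects[, design$isolate[j]] else 0
      sdj <- if (treated) group_sds[2L] else group_sds[1L]
      abund[, j] <- baseline + eff + stats::rnorm(n_proteins, 0, sdj)
    }
    miss <- matrix(FALSE, n_proteins, nrow(design))
    if (!is.null(dropout)) {
      p_miss <- stats::plogis(-dropout$slope * (abund - dropout$midpoint))
      miss <- matrix(stats::runif(length(abund)) < p_miss,
                     n_proteins, nrow(design))
    }
    list(baseline = baseline, effects = effects, pattern = pattern,
         de_idx = de_idx, abund = abund, miss = miss)
  })

  all_missing <- colSums(!out$miss) == 0
  if (any(all_missing)) {
    stopf("dropout parameters left sample(s) with no observed values: %s",
          paste(design$sample_id[all_missing], collapse = ", "))
  }
  intens <- 2^out$abund
  intens[out$miss] <- NA_real_
  truth <- list(baseline = stats::setNames(out$baseline, acc),
                effects = out$effects,
                de_accessions = acc[out$de_idx],
                pattern = out$pattern,
                group_sds = stats::setNames(group_sds, c("control", "treated")),
                dropout = dropout, baseline_mean = baseline_mean,
                baseline_sd = baseline_sd, effect_size = effect_size,
                seed = seed)
  structure(list(matrix = lfq_matrix(intens, design), design = design,
                 truth = truth),
            class = "lfq_sim")
}

#' @export
print.lfq_sim <- function(x, ...) {
  cat("Synthetic LFQ experiment\n")
  print(x$matrix)
  cat(sprintf("  planted DE proteins: %d (|log2FC| = %g)\n",
              length(x$truth$de_accessions), x$truth$effect_size))
  invisible(x)
}

#' Generate a synthetic GO annotation map
#'
#' Assigns each protein a random subset of a small built-in vocabulary of
#' Chlamydomonas-relevant GO terms (photosynthesis, translation, motility,
#' chloroplast components, binding functions, ...), spanning all three
#' aspects.
#'
#' @param protein_ids accession vector to annotate.
#' @param mean_terms expected number of terms per protein (default 2).
#' @param seed integer seed.
#' @return a validated `go_map` data.frame.
#' @export
generate_go_map <- function(protein_ids, mean_terms = 2, seed) {
  if (missing(seed)) stopf("`seed` is required")
  vocab <- data.frame(
    go_id = c("GO:0015979", "GO:0006412", "GO:0042773", "GO:0010196",
              "GO:0007017", "GO:0019253",
              "GO:0009507", "GO:0009535", "GO:0031514", "GO:0005840",
              "GO:0005737", "GO:0005930",
              "GO:0046872", "GO:0005524", "GO:0016168", "GO:0003735",
              "GO:0009055", "GO:0019843"),
    aspect = c(rep("BP", 6), rep("CC", 6), rep("MF", 6)),
    term_name = c("photosynthesis", "translation",
                  "ATP synthesis coupled electron transport",
                  "nonphotochemical quenching", "microtubule-based process",
                  "reductive pentose-phosphate cycle",
                  "chloroplast", "chloroplast thylakoid membrane",
                  "motile cilium", "ribosome", "cytoplasm", "axoneme",
                  "metal ion binding", "ATP binding", "chlorophyll binding",
                  "structural constituent of ribosome",
                  "electron transfer activity", "rRNA binding"),
    stringsAsFactors = FALSE)
  with_seed(stage_seed(seed, "go_map"), {
    rows <- lapply(protein_ids, function(p) {
      n <- stats::rpois(1L, mean_terms)
      n <- min(n, nrow(vocab))
      if (n == 0L) return(NULL)
      v <- vocab[sample.int(nrow(vocab), n), , drop = FALSE]
      data.frame(accession = p, v, stringsAsFactors = FALSE)
    })
    validate_go_map(do.call(rbind, rows))
  })
}

#' Generate synthetic pigment readings with known truth
#'
#' Draws true pigment concentrations, inverts the forward pigment equations
#' to obtain absorbances (see [absorbances_from_pigments()]), and adds
#' Gaussian read noise. With `noise_sd = 0`, [pigment_concentrations()]
#' recovers the truth exactly.
#'
#' @param n number of readings.
#' @param noise_sd SD of the absorbance read noise (default 0.005).
#' @param a720 baseline (turbidity) absorbance added to all wavelengths.
#' @param chl_a_range,chl_b_range,car_range uniform ranges of the true
#'   concentrations (ug/mL extract).
#' @param seed integer seed.
#' @return a list with `readings` (data.frame `sample_id`, `a470`, `a646`,
#'   `a663`, `a720`) and `truth` (data.frame of planted concentrations).
#' @export
generate_physiology <- function(n = 18, noise_sd = 0.005, a720 = 0.02,
                                chl_a_range = c(2, 12), chl_b_range = c(1, 5),
                                car_range = c(0.5, 4), seed) {
  if (missing(seed)) stopf("`seed` is required")
  with_seed(stage_seed(seed, "physiology"), {
    truth <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      chl_a = stats::runif(n, chl_a_range[1L], chl_a_range[2L]),
      chl_b = stats::runif(n, chl_b_range[1L], chl_b_range[2L]),
      carotenoids = stats::runif(n, car_range[1L], car_range[2L]),
      stringsAsFactors = FALSE)
    ab <- absorbances_from_pigments(truth$chl_a, truth$chl_b,
                                    truth$carotenoids, a720 = a720)
    noisy <- ab + matrix(stats::rnorm(4L * n, 0, noise_sd), n, 4L)
    noisy[noisy < 0] <- 0
    readings <- data.frame(sample_id = truth$sample_id, noisy,
                           stringsAsFactors = FALSE)
    list(readings = readings, truth = truth)
  })
}

#' Write a synthetic LFQ experiment as TSV fixtures
#'
#' Writes `protein_groups.tsv`, `design.tsv`, `go_map.tsv` and
#' `truth_effects.tsv` into a directory, mirroring the file formats the
#' readers expect.
#'
#' @param sim a [generate_lfq()] result.
#' @param dir output directory (created if needed).
#' @param go_map optional `go_map` to write alongside (default: generated
#'   from the simulation seed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_lfq_fixture <- function(sim, dir, go_map = NULL) {
  stopifnot(inherits(sim, "lfq_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(protein_groups = file.path(dir, "protein_groups.tsv"),
             design = file.path(dir, "design.tsv"),
             go_map = file.path(dir, "go_map.tsv"),
             truth = file.path(dir, "truth_effects.tsv"))
  write_protein_groups(sim$matrix, paths["protein_groups"])
  write_tsv(as.data.frame(sim$design), paths["design"])
  go_map <- go_map %||% generate_go_map(rownames(sim$matrix$values),
                                        seed = sim$truth$seed)
  write_tsv(as.data.frame(go_map), paths["go_map"])
  eff <- data.frame(accession = rownames(sim$truth$effects),
                    sim$truth$effects, check.names = FALSE)
  write_tsv(eff, paths["truth"])
  invisible(paths)
}
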