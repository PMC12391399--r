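# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# minimal valid design: one isolate, 2 conditions, `reps` replicates
toy_design <- function(reps = 3, isolates = "ISO1") {
  d <- expand.grid(replicate = seq_len(reps),
                   treatment = c("control", "treated"),
                   isolate = isolates,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$dose <- ifelse(d$treatment == "treated", 10, 0)
  d$sample_id <- sprintf("%s_%s_%d", d$isolate, d$treatment, d$replicate)
  validate_design(d[, c("sample_id", "isolate", "treatment", "dose",
                        "replicate")])
}

# raw intensity matrix around the given design; values strictly positive
toy_matrix <- function(design, n_proteins = 10, seed = 1, missing = 0) {
  set.seed(seed)
  v <- matrix(2^rnorm(n_proteins * nrow(design), 20, 2), n_proteins,
              dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                              design$sample_id))
  if (missing > 0) {
    idx <- sample.int(length(v), missing)
    v[idx] <- NA_real_
  }
  lfq_matrix(v, design)
}

# build an lfq_norm directly from a log2 values matrix (NA = missing)
toy_norm <- function(values, design) {
  m <- lfq_matrix(2^values, design)
  log_transform(m, base = 2)
}
toy_norm_allow_na <- toy_norm

write_fixture_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent scalar oracle for the gated test, built on stats::t.test /
# var.test rather than the package's formulas
oracle_de <- function(a, b, alpha_f = 0.05) {
  vt <- stats::var.test(a, b)
  # orient F as larger variance over smaller, as the gate defines it
  f <- max(stats::var(a), stats::var(b)) / min(stats::var(a), stats::var(b))
  hetero <- vt$p.value < alpha_f
  tt <- stats::t.test(a, b, var.equal = !hetero)
  list(f_stat = f, f_pvalue = vt$p.value,
       variance_mode = if (hetero) "heteroscedastic" else "homoscedastic",
       t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, log2_fc = mean(a) - mean(b))
}
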