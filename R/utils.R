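# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this,
# so global set.seed() calls by the user are never consumed or clobbered.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from the run seed so that adding a stochastic
# stage never perturbs another stage's draws. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11, impute = 29, physiology = 47, go_map = 83)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 101 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# read a TSV tolerating Windows/Unix line endings, no name mangling
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "", na.strings = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
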