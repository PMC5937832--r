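# Internal helpers shared across modules.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  # force the seed promise NOW: if the caller computed it from the RNG
  # (e.g. sample.int(...)), that draw must land before the state snapshot,
  # or restoring the snapshot would replay the same seed on the next call
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: one global seed, per-stage salts.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  salt_num <- if (is.character(salt)) {
    sum(as.integer(charToRaw(salt)) * seq_along(charToRaw(salt)))
  } else {
    as.numeric(salt)
  }
  as.integer((abs(seed) * 48271 + salt_num * 16807 + 11) %% 2147483587)
}

# Round half away from zero to `digits` decimals (display rounding used by
# the enrichment tables; base round() is round-half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

# uniform draw from the integer range [lo, hi], safe for lo == hi
# (base sample(x, 1) treats a scalar x as 1:x)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

# Write a data.frame as plain TSV (the package's only tabular interchange
# format).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
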