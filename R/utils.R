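#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (strict && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Round half away from zero
#'
#' Deterministic rounding used for integer copy-number assignment, so that a
#' segment mean sitting exactly between two states always resolves to the
#' higher-magnitude state (e.g. 4.5 -> 5), independent of the platform's
#' banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate code with a temporarily fixed RNG state; the caller's stream is
# restored afterwards so seeded generators do not perturb the session RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-item child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483587)
}

# Full-precision table writer: doubles serialized with 17 significant digits
# so that write -> read reproduces the numbers bit for bit.
write_table_full <- function(df, path, sep = "\t") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
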