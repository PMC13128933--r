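# Shared helpers: seeding, validation, coordinate conventions.

#' Derive a reproducible child seed from a master seed
#'
#' One master seed fans out to independent per-stage seeds so that any
#' generator or stochastic stage can be re-run on its own and still
#' reproduce the pipeline's output. The derivation is a fixed integer
#' hash of the stage name mixed into the master seed; results stay
#' within the 32-bit range R requires of `set.seed()`.
#'
#' @param seed integer master seed.
#' @param name character scalar naming the consumer (e.g. "genotypes").
#' @return a single integer seed.
#' @export
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gx <- function(...) stop(sprintf(...), call. = FALSE)
warn_gx <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop_gx("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop_gx("'%s' must be a number in %s%g,%g%s", name,
                   if (open_lo) "(" else "[", lo, hi,
                   if (open_hi) ")" else "]")
  invisible(x)
}

#' Convert BED half-open coordinates to 1-based inclusive
#'
#' All public distance reporting in this package is on 1-based inclusive
#' coordinates; BED input/output stays 0-based half-open. Centralising
#' the conversion avoids off-by-one drift between modules.
#'
#' @param start,end numeric vectors of BED (0-based, half-open) coords.
#' @return a list with `first` and `last`, 1-based inclusive.
#' @export
bed_to_1based <- function(start, end) {
  if (any(start >= end)) stop_gx("BED spans require start < end")
  list(first = start + 1, last = end)
}

# Benjamini-Hochberg, kept as a named wrapper for readability at call sites.
bh_fdr <- function(p) p.adjust(p, method = "BH")

# Deterministic ordering used everywhere p-value ties must break:
# smaller p first, then smaller position, then id.
order_p_pos_id <- function(p, pos, id) order(p, pos, id, method = "radix")
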