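# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. All user-facing randomness goes through this.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded sub-seed from a master seed and a counter; keeps every
# derived seed a valid 32-bit R integer.
sub_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483629L) + 1L
}

# trapezoidal mean of y(t) over its grid
trapz_mean <- function(t, y) {
  if (length(t) == 1L) return(y[1L])
  dt <- diff(t)
  sum(dt * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2) / (t[length(t)] - t[1L])
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
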