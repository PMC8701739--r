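# Shared helpers: time arithmetic, seed derivation, validation.

TZ <- "UTC"

#' Derive a reproducible sub-seed from a root seed
#'
#' Mixes a root seed with integer stream indices (person, day, stage, ...)
#' into a new seed below 2^31, so that each simulated unit gets its own
#' independent, reproducible random stream.
#'
#' @param seed Integer root seed.
#' @param ... Further non-negative integers identifying the stream.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  m <- 2147483629
  for (p in parts) {
    acc <- (acc * 48271 + (as.numeric(p) %% m) * 16807 + 12345) %% m
  }
  as.integer(acc)
}

# Run `expr` under a derived seed without disturbing the caller's RNG state.
with_derived_seed <- function(seed, ..., expr) {
  withr::with_seed(derive_seed(seed, ...), expr)
}

parse_ts <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = TZ)
}

format_ts <- function(t) {
  format(t, format = "%Y-%m-%dT%H:%M:%OS3", tz = TZ)
}

# POSIXct from numeric seconds since epoch.
ts_of <- function(secs) {
  as.POSIXct(secs, origin = "1970-01-01", tz = TZ)
}

# Fractional hour-of-day of a POSIXct (or numeric seconds) instant.
hour_of <- function(t) {
  if (inherits(t, "POSIXct")) t <- as.numeric(t)
  (t %% 86400) / 3600
}

# Floor an instant to the enclosing bin start (numeric seconds in, out).
floor_bin <- function(secs, width_s) {
  floor(secs / width_s) * width_s
}

# Overlap in seconds of [s1, e1) with [s2, e2).
overlap_s <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

bin_width_seconds <- function(bin_width) {
  if (is.numeric(bin_width)) {
    stopifnot(bin_width > 0)
    return(bin_width)
  }
  switch(match.arg(bin_width, c("10 min", "1 hour", "1 day")),
    "10 min" = 600, "1 hour" = 3600, "1 day" = 86400
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(msg) abort(msg, class = "adlsense_config_error")

empty_episodes <- function() {
  tibble(
    channel_id = character(), start = ts_of(numeric()),
    end = ts_of(numeric()), kind = character()
  )
}
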