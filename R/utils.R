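# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness flows through this so that a scenario seed gives
# byte-identical output regardless of ambient RNG use.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

# Compact ISO-8601 basic-format UTC stamp, filename-safe.
stamp_utc <- function(time) format(as_utc(time), "%Y%m%dT%H%M%SZ")

parse_stamp <- function(s) as.POSIXct(s, format = "%Y%m%dT%H%M%SZ", tz = "UTC")
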