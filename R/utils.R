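# Internal helpers shared across modules.

# Set the RNG seed, returning the previous .Random.seed (or NULL) so callers
# can restore global RNG state on exit.  Keeps exported simulators
# deterministic without clobbering the user's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a per-stream 32-bit sub-seed from a master seed; keeps derived seeds
# below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 65537) %% 2147483629 + 1
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# aggregate() wrapper returning plain columns (aggregate nests matrices when
# given multiple value columns).
group_means <- function(df, value_cols, by_cols) {
  ag <- stats::aggregate(df[value_cols], by = df[by_cols],
                         FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(stats::setNames(list(df[[value_cols[1]]]), "n"),
                          by = df[by_cols], FUN = length)
  merge(ag, cnt, by = by_cols, sort = TRUE)
}
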