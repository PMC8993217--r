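# Internal numerical and RNG helpers.

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (patterns, fidelities, noise, durations, ...), so that e.g.
#' regenerating the encoding noise never perturbs the planted patterns.
#'
#' @param seed integer root seed.
#' @param stream character substream name.
#' @return an integer seed in `[0, 2^31 - 2]`, deterministic in both inputs.
#' @export
substream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# column-wise z-score with sample sd; errors on constant columns unless
# `flag` is TRUE, in which case constant columns are returned as NA.
zscore_cols <- function(x, flag = FALSE, what = "column") {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- sdv < .Machine$double.eps^0.5
  if (any(bad) && !flag) {
    stop(sprintf("cannot z-score constant %s(s): %s", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  out <- sweep(sweep(x, 2, mu, "-"), 2, ifelse(bad, 1, sdv), "/")
  if (any(bad)) out[, bad] <- NA_real_
  out
}

# row-wise z-score (mean 0, sample sd 1 across the columns of each row)
zscore_rows <- function(x, what = "row") {
  t(zscore_cols(t(x), what = what))
}
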