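# Single-mediator path model with bias-corrected bootstrap inference.

std_or_stop <- function(v, name) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < .Machine$double.eps)
    stop("zero variance in ", name, call. = FALSE)
  (v - mean(v)) / s
}

# standardized single-mediator paths via correlation algebra:
# a from m ~ x; b, c' from y ~ m + x; c from y ~ x.
mediation_paths <- function(x, m, y) {
  rxm <- stats::cor(x, m)
  rxy <- stats::cor(x, y)
  rmy <- stats::cor(m, y)
  den <- 1 - rxm^2
  if (den < 1e-12) {
    # x and m perfectly collinear: the two-predictor fit is non-identified;
    # attribute the shared effect to the mediator (full-mediation convention)
    b <- rmy
  } else {
    b <- (rmy - rxy * rxm) / den
  }
  cp <- rxy - b * rxm
  c(a = rxm, b = b, c = rxy, cprime = cp)
}

#' Single-mediator model with bias-corrected bootstrap CI
#'
#' Standardizes the causal variable x, mediator m and outcome y, estimates
#' the paths a (m ~ x), b and c' (y ~ m + x) and the total effect c
#' (y ~ x) by OLS, and tests the indirect (mediated) effect a*b with a
#' bias-corrected (BC) percentile bootstrap over case resampling. In the
#' standardized single-mediator linear system the decomposition
#' c = c' + a*b holds exactly.
#'
#' @param x,m,y equal-length numeric vectors (n >= 10): causal variable,
#'   mediator, outcome.
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param reverse swap the causal and mediator roles (the specificity
#'   check: a real mediation should not survive the swap).
#' @return object of class `mediation_fit` with paths `a`, `b`, `c`,
#'   `cprime`, the `indirect` effect, `ci` (BC bootstrap bounds), `boot`
#'   (the bootstrap indirect effects), `n`, `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 5000, seed = 1, conf = 0.95,
                    reverse = FALSE) {
  if (length(x) != length(m) || length(x) != length(y))
    stop("x, m, y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (reverse) { tmp <- x; x <- m; m <- tmp }
  xs <- std_or_stop(x, "x"); ms <- std_or_stop(m, "m")
  ys <- std_or_stop(y, "y")
  paths <- mediation_paths(xs, ms, ys)
  est <- unname(paths["a"] * paths["b"])
  boot <- with_seed(substream_seed(seed, "mediation_boot"), {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        id <- sample.int(n, replace = TRUE)
        sx <- stats::sd(x[id]); sm <- stats::sd(m[id]); sy <- stats::sd(y[id])
        if (sx > .Machine$double.eps && sm > .Machine$double.eps &&
            sy > .Machine$double.eps) break
      }
      p <- mediation_paths(scale(x[id])[, 1], scale(m[id])[, 1],
                           scale(y[id])[, 1])
      unname(p["a"] * p["b"])
    }, numeric(1))
  })
  # bias correction: map the bootstrap quantiles through z0
  prop <- mean(boot < est)
  prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(prop)
  alpha <- (1 - conf) / 2
  lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  ci <- unname(stats::quantile(boot, c(lo, hi)))
  structure(list(a = unname(paths["a"]), b = unname(paths["b"]),
                 c = unname(paths["c"]), cprime = unname(paths["cprime"]),
                 indirect = est, ci = ci, conf = conf, boot = boot,
                 n = n, n_boot = n_boot, seed = seed, reverse = reverse),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Single-mediator model (standardized paths)\n")
  if (x$reverse) cat("  [reverse-direction specificity variant]\n")
  cat(sprintf("  a = %.4f  b = %.4f  c = %.4f  c' = %.4f\n",
              x$a, x$b, x$c, x$cprime))
  cat(sprintf("  indirect a*b = %.4f, %d%% BC bootstrap CI [%.4f, %.4f] (n_boot = %d)\n",
              x$indirect, round(100 * x$conf), x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Permutation z-test for a mediation path
#'
#' Builds a null for one path effect by shuffling that path's outcome
#' variable (the mediator for path a; the outcome y for b, c, c' and the
#' indirect effect), z-scores the observed effect against the null, and
#' converts z to a one-sided p-value via the normal survival function.
#'
#' @param effect one of `"a"`, `"b"`, `"c"`, `"cprime"`, `"indirect"`.
#' @inheritParams mediate
#' @param n_perm number of permutations (>= 2, so the null sd exists).
#' @return list with `effect` (observed), `z`, `p`, `null`.
#' @export
path_p <- function(effect = c("a", "b", "c", "cprime", "indirect"),
                   x, m, y, n_perm = 1000, seed = 1) {
  effect <- match.arg(effect)
  if (n_perm < 2) stop("n_perm must be >= 2 (null sd undefined)", call. = FALSE)
  xs <- std_or_stop(x, "x"); ms <- std_or_stop(m, "m")
  ys <- std_or_stop(y, "y")
  value <- function(xv, mv, yv) {
    p <- mediation_paths(xv, mv, yv)
    if (effect == "indirect") unname(p["a"] * p["b"]) else unname(p[effect])
  }
  obs <- value(xs, ms, ys)
  n <- length(xs)
  null <- with_seed(substream_seed(seed, paste0("path_", effect)), {
    vapply(seq_len(n_perm), function(b) {
      if (effect == "a") value(xs, ms[sample.int(n)], ys)
      else value(xs, ms, ys[sample.int(n)])
    }, numeric(1))
  })
  sdn <- stats::sd(null)
  if (!is.finite(sdn) || sdn < .Machine$double.eps)
    stop("null distribution has zero variance", call. = FALSE)
  z <- (obs - mean(null)) / sdn
  list(effect = obs, z = z, p = stats::pnorm(z, lower.tail = FALSE),
       null = null)
}
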