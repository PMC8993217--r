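# Leave-one-subject-out brain-to-behavior regression and related model
# comparisons. Fold fits use closed-form simple OLS so that permutation
# nulls stay cheap.

as_score_matrix <- function(x, template = NULL) {
  x <- as.matrix(x)
  if (!is.null(template) && !all(dim(x) == dim(template)))
    stop("score and behavior tables must share subject x story shape",
         call. = FALSE)
  x
}

# core LOSO machinery shared by the fit and its permutation null
loso_core <- function(score, behavior) {
  n <- nrow(score)
  preds <- matrix(NA_real_, n, ncol(score))
  coefs <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("intercept", "slope")))
  sse_model <- 0
  sse_base <- 0
  for (s in seq_len(n)) {
    x <- as.vector(score[-s, ])
    y <- as.vector(behavior[-s, ])
    vx <- stats::var(x)
    if (!is.finite(vx) || vx < .Machine$double.eps)
      stop("predictor has zero variance across the training set", call. = FALSE)
    slope <- stats::cov(x, y) / vx
    intercept <- mean(y) - slope * mean(x)
    pred <- intercept + slope * score[s, ]
    preds[s, ] <- pred
    coefs[s, ] <- c(intercept, slope)
    sse_model <- sse_model + sum((behavior[s, ] - pred)^2)
    sse_base <- sse_base + sum((behavior[s, ] - mean(y))^2)
  }
  if (sse_base < .Machine$double.eps)
    stop("behavior is constant: baseline SSE is zero and R^2 is undefined",
         call. = FALSE)
  list(predictions = preds, coefficients = coefs,
       r_squared = 1 - sse_model / sse_base)
}

#' Leave-one-subject-out regression of behavior on a neural score
#'
#' For each fold, fits an intercept-and-slope regression of rubric scores
#' on the neural score using the pooled subject x story pairs of the N - 1
#' training subjects, then predicts the left-out subject's story rubrics.
#' Performance is `R^2 = 1 - SSE(model) / SSE(baseline)` where the baseline
#' predicts the training-set mean rubric; R^2 may be negative and is not
#' clipped.
#'
#' @param score,behavior `n_subjects` x `n_stories` matrices with aligned
#'   indexing.
#' @return object of class `loso_fit`: held-out `predictions`, per-fold
#'   `coefficients`, and `r_squared`.
#' @export
loso_regression <- function(score, behavior) {
  score <- as_score_matrix(score)
  behavior <- as_score_matrix(behavior, score)
  if (nrow(score) < 3) stop("need at least 3 subjects", call. = FALSE)
  out <- loso_core(score, behavior)
  structure(c(out, list(n_subjects = nrow(score), n_stories = ncol(score))),
            class = "loso_fit")
}

#' @export
print.loso_fit <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out regression (%d subjects x %d stories)\n",
              x$n_subjects, x$n_stories))
  cat(sprintf("  held-out R^2 = %.4f (baseline: training-mean rubric)\n",
              x$r_squared))
  cat(sprintf("  mean fold slope = %.4f\n", mean(x$coefficients[, "slope"])))
  invisible(x)
}

#' @export
coef.loso_fit <- function(object, ...) object$coefficients

#' Permutation p-value for the LOSO R-squared
#'
#' Null built by shuffling each subject's neural scores across stories
#' (subjects stay intact, so significance reflects a within-subject
#' across-story relationship), re-running the full leave-one-out
#' regression per draw. One-sided: proportion of null R^2 >= observed.
#'
#' @inheritParams loso_regression
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `p`, `r_squared`, `z` (observed vs null) and `null`.
#' @export
loso_permutation_p <- function(score, behavior, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  score <- as_score_matrix(score)
  behavior <- as_score_matrix(behavior, score)
  obs <- loso_core(score, behavior)$r_squared
  ns <- ncol(score)
  null <- with_seed(substream_seed(seed, "loso_perm"), {
    vapply(seq_len(n_perm), function(b) {
      shuffled <- t(apply(score, 1, function(row) row[sample.int(ns)]))
      loso_core(shuffled, behavior)$r_squared
    }, numeric(1))
  })
  list(p = mean(null >= obs), r_squared = obs,
       z = (obs - mean(null)) / stats::sd(null), null = null)
}

# pooled OLS SSE helpers
sse_simple <- function(y, x) {
  f <- stats::lm.fit(cbind(1, x), y)
  sum(f$residuals^2)
}
sse_two <- function(y, x1, x2) {
  f <- stats::lm.fit(cbind(1, x1, x2), y)
  sum(f$residuals^2)
}

#' Nested-model F test for the added value of schema scores
#'
#' Compares `rubric ~ story_score` against `rubric ~ story_score +
#' schema_score` on the pooled subject x story pairs:
#' `F = (SSE_r - SSE_f) / (SSE_f / (n - 3))`. The permutation null
#' shuffles the schema scores within each subject and recomputes F.
#'
#' @param story_scores,schema_scores,behavior aligned subject x story
#'   matrices.
#' @param n_perm number of permutations for the null.
#' @param seed integer seed.
#' @return list with `F`, `p` (one-sided permutation) and `null`.
#' @export
nested_f <- function(story_scores, schema_scores, behavior, n_perm = 1000,
                     seed = 1) {
  x1 <- as.vector(as_score_matrix(story_scores))
  x2m <- as_score_matrix(schema_scores, as_score_matrix(story_scores))
  y <- as.vector(as_score_matrix(behavior, x2m))
  x2 <- as.vector(x2m)
  if (abs(stats::cor(x1, x2)) > 0.999)
    stop("story and schema scores are collinear", call. = FALSE)
  n <- length(y)
  fstat <- function(x2vec) {
    sser <- sse_simple(y, x1)
    ssef <- sse_two(y, x1, x2vec)
    num <- sser - ssef
    if (ssef < .Machine$double.eps) {
      if (num < .Machine$double.eps) return(0)
      return(Inf)
    }
    num / (ssef / (n - 3))
  }
  obs <- fstat(x2)
  null <- with_seed(substream_seed(seed, "nested_f"), {
    ns <- ncol(x2m)
    vapply(seq_len(n_perm), function(b) {
      shuf <- t(apply(x2m, 1, function(row) row[sample.int(ns)]))
      fstat(as.vector(shuf))
    }, numeric(1))
  })
  list(F = obs, p = mean(null >= obs), null = null)
}

#' Contrast of encoding vs reinstatement regression coefficients
#'
#' Paired contrast `delta = mean(encoding - reinstatement)` over subject
#' folds, with a sign-flip permutation null of the paired differences.
#' Two-sided p uses the proportion of |null| >= |delta|; q is the
#' Benjamini-Hochberg value (equal to p for a single contrast).
#'
#' @param enc_coefs,reinst_coefs per-fold slopes from two [loso_regression()]
#'   fits (equal length).
#' @param n_perm number of sign-flip draws.
#' @param seed integer seed.
#' @return list with `delta`, `z`, `p`, `q`, `null`.
#' @export
coefficient_contrast <- function(enc_coefs, reinst_coefs, n_perm = 1000,
                                 seed = 1) {
  if (length(enc_coefs) != length(reinst_coefs))
    stop("coefficient vectors have mismatched fold counts", call. = FALSE)
  d <- enc_coefs - reinst_coefs
  delta <- mean(d)
  null <- with_seed(substream_seed(seed, "coef_contrast"), {
    vapply(seq_len(n_perm), function(b)
      mean(d * sample(c(-1, 1), length(d), replace = TRUE)), numeric(1))
  })
  sdn <- stats::sd(null)
  z <- if (is.finite(sdn) && sdn > .Machine$double.eps)
    (delta - mean(null)) / sdn else NA_real_
  p <- mean(abs(null) >= abs(delta))
  list(delta = delta, z = z, p = p, q = stats::p.adjust(p, "BH"), null = null)
}

#' Regress a target score on each map unit's predictor score
#'
#' For every searchlight/ROI unit, fits the pooled slope of the target
#' score (e.g. one region's reinstatement story score) on the unit's
#' predictor score (e.g. each searchlight's encoding schema score). The
#' null shuffles the target's story values within subjects (one shuffle
#' per draw, shared across units); p is two-sided (proportion of absolute
#' null slopes above the observed absolute slope) and q is
#' Benjamini-Hochberg across units.
#'
#' @param target subject x story matrix (dependent variable).
#' @param predictors list per unit of subject x story matrices.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data frame with one row per unit: `slope`, `p`, `q`.
#' @export
predict_target_from_maps <- function(target, predictors, n_perm = 1000,
                                     seed = 1) {
  target <- as_score_matrix(target)
  xs <- lapply(predictors, as_score_matrix, template = target)
  ty <- as.vector(target)
  slope_of <- function(x, y) {
    vx <- stats::var(as.vector(x))
    if (!is.finite(vx) || vx < .Machine$double.eps)
      stop("predictor has zero variance", call. = FALSE)
    stats::cov(as.vector(x), y) / vx
  }
  obs <- vapply(xs, slope_of, numeric(1), y = ty)
  ns <- ncol(target)
  null <- with_seed(substream_seed(seed, "map_regression"), {
    vapply(seq_len(n_perm), function(b) {
      yshuf <- as.vector(t(apply(target, 1, function(row) row[sample.int(ns)])))
      vapply(xs, slope_of, numeric(1), y = yshuf)
    }, numeric(length(xs)))
  })
  null <- matrix(null, nrow = length(xs))
  p <- vapply(seq_along(xs), function(u)
    mean(abs(null[u, ]) > abs(obs[u])), numeric(1))
  data.frame(unit = seq_along(xs), slope = obs, p = p,
             q = stats::p.adjust(p, "BH"))
}
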