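#' Template variance for the reinstatement HMM
#'
#' Pooled sample variance of all K x V event-pattern beta values of a story
#' template. Serves as the isotropic emission variance of the ordered-state
#' HMM.
#'
#' @param event_patterns K x V matrix of raw (not z-scored) betas.
#' @return strictly positive scalar.
#' @export
estimate_variance <- function(event_patterns) {
  if (nrow(event_patterns) < 1 || ncol(event_patterns) < 2)
    stop("need at least one event and two vertices", call. = FALSE)
  v <- stats::var(as.vector(event_patterns))
  if (!is.finite(v) || v < .Machine$double.eps)
    stop("event patterns have zero variance", call. = FALSE)
  v
}

#' Build reinstatement story templates
#'
#' Group templates average the per-subject event betas across all
#' participants (optionally excluding one); within-subject templates are a
#' single subject's own betas. The HMM emission variance of each template
#' is its pooled beta variance.
#'
#' @param patterns [fit_study_patterns()] result (betas per subject per
#'   story).
#' @param mode `"group"` or `"within"`.
#' @param subject subject index for `mode = "within"`.
#' @param exclude_subject optional subject index excluded from the group
#'   average (off by default: the group template pools all participants).
#' @return list per story of `list(patterns = K x V, sigma2 = scalar)`.
#' @export
story_templates <- function(patterns, mode = c("group", "within"),
                            subject = NULL, exclude_subject = NULL) {
  mode <- match.arg(mode)
  s <- length(patterns[[1]])
  if (mode == "within") {
    if (is.null(subject)) stop("within mode needs a subject", call. = FALSE)
    tpl <- patterns[[subject]]
  } else {
    keep <- setdiff(seq_along(patterns), exclude_subject)
    tpl <- lapply(seq_len(s), function(i)
      Reduce(`+`, lapply(keep, function(si) patterns[[si]][[i]])) / length(keep))
  }
  lapply(tpl, function(p) list(patterns = p, sigma2 = estimate_variance(p)))
}

#' Ordered-state HMM posterior over recall timepoints
#'
#' Fits a fixed-template hidden Markov model in which the K encoding event
#' patterns are replayed in order during recall: the chain starts in state
#' 1, ends in state K, and may only stay or advance by one state per step.
#' Emissions are isotropic Gaussians on vertex-z-scored vectors,
#' \eqn{\log p(x_t | k) \propto -\|x_t - \mu_k\|^2 / (2\sigma^2)}; the
#' posterior is computed by exact forward-backward in log space.
#'
#' @param recall T x V recall timeseries (T >= K).
#' @param template a `list(patterns, sigma2)` story template (one element
#'   of [story_templates()]).
#' @param p_stay self-transition probability; default
#'   `1 - (K - 1) / (T - 1)`, which makes the expected number of advances
#'   over the recall equal K - 1.
#' @return object of class `state_posterior`: `gamma` (T x K posterior
#'   probabilities, rows summing to 1, `gamma[1, 1] = gamma[T, K] = 1`),
#'   `loglik`, and `p_stay`.
#' @export
hmm_posterior <- function(recall, template, p_stay = NULL) {
  mu <- template$patterns
  k <- nrow(mu)
  tt <- nrow(recall)
  if (tt < k)
    stop("recall has fewer timepoints than events: no monotone path exists",
         call. = FALSE)
  if (ncol(recall) != ncol(mu))
    stop("recall and template have different vertex counts", call. = FALSE)
  if (is.null(p_stay)) p_stay <- if (tt == 1) 1 else 1 - (k - 1) / (tt - 1)
  if (p_stay < 0 || p_stay > 1) stop("p_stay must be in [0, 1]", call. = FALSE)

  x <- zscore_rows(recall, what = "recall timepoint")
  muz <- zscore_rows(mu, what = "template event")
  sq <- outer(rowSums(x^2), rep(1, k)) +
    outer(rep(1, tt), rowSums(muz^2)) - 2 * (x %*% t(muz))
  logem <- -sq / (2 * template$sigma2)

  lstay <- log(p_stay)
  ladv <- log1p(-p_stay)
  neg <- -Inf

  la <- matrix(neg, tt, k)
  la[1, 1] <- logem[1, 1]
  if (tt > 1) {
    for (t in 2:tt) {
      for (j in seq_len(k)) {
        from_stay <- la[t - 1, j] + lstay
        from_adv <- if (j > 1) la[t - 1, j - 1] + ladv else neg
        la[t, j] <- logem[t, j] + logsumexp(c(from_stay, from_adv))
      }
    }
  }
  lb <- matrix(neg, tt, k)
  lb[tt, k] <- 0
  if (tt > 1) {
    for (t in (tt - 1):1) {
      for (j in seq_len(k)) {
        stay <- lstay + logem[t + 1, j] + lb[t + 1, j]
        adv <- if (j < k) ladv + logem[t + 1, j + 1] + lb[t + 1, j + 1] else neg
        lb[t, j] <- logsumexp(c(stay, adv))
      }
    }
  }
  loglik <- la[tt, k]
  if (!is.finite(loglik))
    stop("recall sequence has zero likelihood under the template HMM",
         call. = FALSE)
  lg <- la + lb - loglik
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  structure(list(gamma = gamma, loglik = loglik, p_stay = p_stay),
            class = "state_posterior")
}

#' Most probable monotone state path
#'
#' Viterbi decoding of the ordered-state HMM; by construction the path is
#' non-decreasing, starts in state 1 and ends in state K.
#'
#' @inheritParams hmm_posterior
#' @return integer vector of length T of state indices.
#' @export
hmm_viterbi <- function(recall, template, p_stay = NULL) {
  mu <- template$patterns
  k <- nrow(mu)
  tt <- nrow(recall)
  if (tt < k) stop("recall shorter than the number of events", call. = FALSE)
  if (is.null(p_stay)) p_stay <- if (tt == 1) 1 else 1 - (k - 1) / (tt - 1)
  x <- zscore_rows(recall, what = "recall timepoint")
  muz <- zscore_rows(mu, what = "template event")
  sq <- outer(rowSums(x^2), rep(1, k)) +
    outer(rep(1, tt), rowSums(muz^2)) - 2 * (x %*% t(muz))
  logem <- -sq / (2 * template$sigma2)
  lstay <- log(p_stay); ladv <- log1p(-p_stay); neg <- -Inf
  delta <- matrix(neg, tt, k); back <- matrix(1L, tt, k)
  delta[1, 1] <- logem[1, 1]
  if (tt > 1) for (t in 2:tt) for (j in seq_len(k)) {
    stay <- delta[t - 1, j] + lstay
    adv <- if (j > 1) delta[t - 1, j - 1] + ladv else neg
    if (adv > stay) { delta[t, j] <- logem[t, j] + adv; back[t, j] <- j - 1L }
    else { delta[t, j] <- logem[t, j] + stay; back[t, j] <- j }
  }
  path <- integer(tt)
  path[tt] <- k
  if (tt > 1) for (t in (tt - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' Posterior-weighted recall event patterns
#'
#' Averages recall timepoints into K event patterns using the HMM state
#' posterior as weights: `pattern_k = sum_t gamma[t, k] x_t / sum_t
#' gamma[t, k]`.
#'
#' @param recall T x V recall timeseries.
#' @param gamma T x K posterior weights with rows summing to 1.
#' @return K x V matrix of weighted recall patterns.
#' @export
weighted_recall_patterns <- function(recall, gamma) {
  if (nrow(recall) != nrow(gamma))
    stop("recall and gamma have different numbers of timepoints", call. = FALSE)
  w <- colSums(gamma)
  if (any(w <= 0))
    stop("degenerate posterior: state(s) with zero total weight: ",
         paste(which(w <= 0), collapse = ", "), call. = FALSE)
  sweep(crossprod(gamma, recall), 1, w, "/")
}

#' Reinstatement strength of a template in a recall
#'
#' Mean over events k of the correlation between encoding template event k
#' and recall event k, minus the mean correlation between template event k
#' and the non-corresponding recall events. The subtraction cancels the
#' HMM's template-matching bias, which applies equally to all templates.
#'
#' @param template_patterns K x V encoding template.
#' @param recall_patterns K x V posterior-weighted recall patterns.
#' @return scalar strength (1 for a perfect orthogonal-template replay, 0
#'   in expectation for unrelated patterns).
#' @export
reinstatement_strength <- function(template_patterns, recall_patterns) {
  if (!all(dim(template_patterns) == dim(recall_patterns)))
    stop("template and recall patterns must share K and V", call. = FALSE)
  k <- nrow(template_patterns)
  v <- ncol(template_patterns)
  zt <- zscore_rows(template_patterns, what = "template event")
  zr <- zscore_rows(recall_patterns, what = "recall event")
  cc <- tcrossprod(zt, zr) / (v - 1)  # cc[k, j] = r(mu_k, p_j)
  mean(diag(cc) - (rowSums(cc) - diag(cc)) / (k - 1))
}

#' Per-subject reinstatement similarity matrix
#'
#' Applies each of the S story-template HMMs to each of the subject's S
#' recall timeseries and records the reinstatement strength, yielding an
#' S x S matrix with templates on the rows and recalls on the columns.
#'
#' @param recalls list per story of the subject's recall timeseries.
#' @param templates [story_templates()] result (shared vertex space).
#' @param design the `story_design`.
#' @param mode stored as matrix metadata (`"across"` for group templates,
#'   `"within"` for own templates).
#' @param p_stay optional fixed self-transition probability.
#' @return S x S `similarity_matrix` (`phase = "reinstatement"`).
#' @export
reinstatement_matrix <- function(recalls, templates, design,
                                 mode = "across", p_stay = NULL) {
  s <- length(templates)
  mat <- matrix(NA_real_, s, s)
  for (j in seq_len(s)) {
    rec <- recalls[[j]]
    for (i in seq_len(s)) {
      post <- hmm_posterior(rec, templates[[i]], p_stay)
      rp <- weighted_recall_patterns(rec, post$gamma)
      mat[i, j] <- reinstatement_strength(templates[[i]]$patterns, rp)
    }
  }
  similarity_matrix(mat, mode, "reinstatement", design)
}

#' Reinstatement matrices for every subject
#'
#' @param recall a `recall_data` object.
#' @param patterns [fit_study_patterns()] encoding betas.
#' @param mode `"group"` (templates averaged across all participants) or
#'   `"within"` (each subject's own templates).
#' @param exclude_test_subject for group mode, exclude each test subject
#'   from their own templates (off by default).
#' @param p_stay optional fixed self-transition probability.
#' @return list per subject of reinstatement `similarity_matrix` objects.
#' @export
reinstatement_matrices <- function(recall, patterns,
                                   mode = c("group", "within"),
                                   exclude_test_subject = FALSE,
                                   p_stay = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(recall, "recall_data"))
  n <- recall$n_subjects
  shared <- if (mode == "group" && !exclude_test_subject)
    story_templates(patterns, "group") else NULL
  lapply(seq_len(n), function(si) {
    tpl <- if (mode == "within") story_templates(patterns, "within", subject = si)
    else if (exclude_test_subject) story_templates(patterns, "group",
                                                   exclude_subject = si)
    else shared
    reinstatement_matrix(recall$data[[si]], tpl, recall$design,
                         mode = if (mode == "group") "across" else "within",
                         p_stay = p_stay)
  })
}
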