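#' Plant the ground-truth structure of a synthetic study
#'
#' Draws the latent spatial patterns and per-subject fidelities that the
#' synthetic encoding, recall and behavior generators share. Each event k of
#' story i in subject s has the spatial pattern
#' \deqn{P_{s,i,k} = a_{s,i} G_{c(i),k} + d_{s,i} S_{i,k} + \gamma M_{m(i),k} + \eta,}
#' where G, S and M are schema-, story- and modality-specific vertex
#' patterns (i.i.d. standard normal), a, d are the subject's schema and
#' story fidelities, \eqn{\gamma} scales the shared modality component, and
#' \eqn{\eta \sim N(0, \sigma_{pat}^2)} is idiosyncratic pattern noise.
#' Behavioral rubric scores are linearly coupled to the schema fidelity a
#' and the reinstatement fidelity r.
#'
#' Fidelities default to independent Beta(2, 2) draws, spanning \[0, 1\]
#' with interior mass; pass a scalar or an `n_subjects` x `n_stories`
#' matrix to fix them (e.g. for noiseless recovery tests).
#'
#' @param design a `story_design` from [make_design()].
#' @param n_subjects number of subjects (>= 2; intersubject analyses are
#'   undefined for one). Default 30.
#' @param n_vertices number of vertices V in the simulated region (>= 2).
#'   Default 200.
#' @param a,d,r schema, story and reinstatement fidelities in \[0, 1\];
#'   `NULL` (default) draws Beta(2, 2).
#' @param gamma weight of the shared modality pattern. Default 0.3.
#' @param behavior_coefs named vector `c(b0, b_schema, b_reinst)` of the
#'   linear behavior model. Default `c(0.2, 0.3, 0.3)`.
#' @param sigma_pattern sd of the per-subject pattern noise eta. Default 0.5.
#' @param sigma_temporal sd of the temporal noise added to encoding
#'   timeseries. Default 1.
#' @param sigma_recall sd of the noise on recall timepoints. Default 1.
#' @param sigma_behavior sd of the behavioral noise. Default 0.1.
#' @param seed integer root seed; all draws flow through named substreams.
#' @return an object of class `ground_truth` holding the design, the latent
#'   patterns (`schema_patterns`, `story_patterns`, `modality_patterns` as
#'   event x vertex matrices in named lists), the realized subject event
#'   patterns `subject_patterns[[s]][[i]]` (K x V), the fidelity matrices
#'   `a`, `d`, `r`, and all generator parameters.
#' @export
make_ground_truth <- function(design, n_subjects = 30, n_vertices = 200,
                              a = NULL, d = NULL, r = NULL, gamma = 0.3,
                              behavior_coefs = c(b0 = 0.2, b_schema = 0.3,
                                                 b_reinst = 0.3),
                              sigma_pattern = 0.5, sigma_temporal = 1,
                              sigma_recall = 1, sigma_behavior = 0.1,
                              seed = 1) {
  stopifnot(inherits(design, "story_design"))
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (n_vertices < 2) stop("n_vertices must be >= 2", call. = FALSE)
  s <- nrow(design$stories)
  k <- design$n_events
  v <- n_vertices

  draw_patterns <- function(labels, stream) {
    with_seed(substream_seed(seed, stream), {
      out <- lapply(labels, function(l) {
        m <- matrix(stats::rnorm(k * v), k, v)
        rownames(m) <- sprintf("event_%d", seq_len(k))
        m
      })
      names(out) <- labels
      out
    })
  }
  schema_patterns <- draw_patterns(unique(design$stories$schema), "schema_patterns")
  story_patterns <- draw_patterns(design$stories$title, "story_patterns")
  modality_patterns <- draw_patterns(unique(design$stories$modality),
                                     "modality_patterns")

  fid <- function(x, stream) {
    if (is.null(x)) {
      with_seed(substream_seed(seed, stream),
                matrix(stats::rbeta(n_subjects * s, 2, 2), n_subjects, s))
    } else {
      m <- matrix(rep_len(as.numeric(x), n_subjects * s), n_subjects, s)
      if (any(m < 0 | m > 1)) stop("fidelities must lie in [0, 1]", call. = FALSE)
      m
    }
  }
  a <- fid(a, "fidelity_a")
  d <- fid(d, "fidelity_d")
  r <- fid(r, "fidelity_r")

  eta <- with_seed(substream_seed(seed, "pattern_noise"), {
    lapply(seq_len(n_subjects), function(si)
      lapply(seq_len(s), function(i)
        matrix(stats::rnorm(k * v, sd = sigma_pattern), k, v)))
  })
  subject_patterns <- lapply(seq_len(n_subjects), function(si) {
    lapply(seq_len(s), function(i) {
      st <- design$stories
      a[si, i] * schema_patterns[[st$schema[i]]] +
        d[si, i] * story_patterns[[st$title[i]]] +
        gamma * modality_patterns[[st$modality[i]]] +
        eta[[si]][[i]]
    })
  })

  structure(
    list(design = design, n_subjects = n_subjects, n_vertices = v,
         schema_patterns = schema_patterns, story_patterns = story_patterns,
         modality_patterns = modality_patterns,
         subject_patterns = subject_patterns,
         a = a, d = d, r = r, gamma = gamma,
         behavior_coefs = behavior_coefs,
         sigma = list(pattern = sigma_pattern, temporal = sigma_temporal,
                      recall = sigma_recall, behavior = sigma_behavior),
         seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d subjects, %d stories, %d events, %d vertices\n",
    x$n_subjects, nrow(x$design$stories), x$design$n_events, x$n_vertices))
  cat(sprintf("  mean fidelities a=%.2f d=%.2f r=%.2f; gamma=%.2f\n",
              mean(x$a), mean(x$d), mean(x$r), x$gamma))
  cat(sprintf("  behavior: %.2f + %.2f a + %.2f r + N(0, %.2f^2)\n",
              x$behavior_coefs[1], x$behavior_coefs[2], x$behavior_coefs[3],
              x$sigma$behavior))
  invisible(x)
}
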