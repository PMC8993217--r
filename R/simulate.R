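#' Simulate encoding timeseries for every subject and story
#'
#' Emits, for each subject and story, a T x V BOLD-like timeseries equal to
#' the HRF-convolved, z-scored event design matrix times the subject's
#' planted event patterns, plus white temporal noise. Because the generator
#' uses exactly the design matrix that [fit_event_patterns()] inverts, the
#' GLM recovers the planted patterns exactly when both noise sds are zero.
#'
#' @param ground_truth a [make_ground_truth()] object.
#' @param seed integer seed for the temporal noise substream; defaults to
#'   the ground truth's root seed.
#' @return an object of class `encoding_data`: list with `data[[s]][[i]]`
#'   (T x V matrices), per-story `designs` (design matrices), the `design`,
#'   and a `valid` vertex mask (all TRUE for synthetic data).
#' @export
simulate_encoding <- function(ground_truth, seed = ground_truth$seed) {
  gt <- ground_truth
  stopifnot(inherits(gt, "ground_truth"))
  design <- gt$design
  s <- nrow(design$stories)
  k <- design$n_events
  v <- gt$n_vertices
  designs <- lapply(seq_len(s), function(i)
    build_design_matrix(design$event_bounds[i, ], design$countdown,
                        design$n_trs, design$tr))
  noise_seed <- substream_seed(seed, "encoding_noise")
  data <- with_seed(noise_seed, {
    lapply(seq_len(gt$n_subjects), function(si) {
      lapply(seq_len(s), function(i) {
        x <- designs[[i]]
        b <- gt$subject_patterns[[si]][[i]]
        if (ncol(x) == k + 1) b <- rbind(b, 0)  # countdown carries no signal
        y <- x %*% b
        if (gt$sigma$temporal > 0) {
          y <- y + matrix(stats::rnorm(length(y), sd = gt$sigma$temporal),
                          nrow(y), ncol(y))
        }
        y
      })
    })
  })
  structure(list(data = data, designs = designs, design = design,
                 valid = rep(TRUE, v), n_subjects = gt$n_subjects),
            class = "encoding_data")
}

#' Simulate free-recall timeseries
#'
#' For each subject and story, draws one duration per event from
#' `durations_range` (in TRs) and emits, for every timepoint of event k,
#' the subject's planted event pattern scaled by the reinstatement fidelity
#' r plus white noise. Events appear strictly in order 1..K; no hemodynamic
#' convolution is applied (the reinstatement measure is convolution
#' agnostic, and direct pattern emission keeps the generative model an
#' exact oracle for the HMM).
#'
#' @param ground_truth a [make_ground_truth()] object.
#' @param durations_range integer vector `c(min, max)` of per-event recall
#'   durations in TRs (min >= 1). Default `c(5, 15)`.
#' @param seed integer seed for the duration and noise substreams.
#' @return object of class `recall_data`: `data[[s]][[i]]` (T_rec x V
#'   matrices, T_rec variable), `event_of_timepoint[[s]][[i]]` (true event
#'   index per timepoint), and the `design`.
#' @export
simulate_recall <- function(ground_truth, durations_range = c(5, 15),
                            seed = ground_truth$seed) {
  gt <- ground_truth
  stopifnot(inherits(gt, "ground_truth"))
  if (durations_range[1] < 1)
    stop("minimum recall event duration is one TR", call. = FALSE)
  s <- nrow(gt$design$stories)
  k <- gt$design$n_events
  v <- gt$n_vertices
  dur_seed <- substream_seed(seed, "recall_durations")
  noise_seed <- substream_seed(seed, "recall_noise")
  durations <- with_seed(dur_seed, {
    lapply(seq_len(gt$n_subjects), function(si)
      lapply(seq_len(s), function(i)
        {
          lens <- seq.int(durations_range[1], durations_range[2])
          lens[sample.int(length(lens), k, replace = TRUE)]
        }))
  })
  out <- with_seed(noise_seed, {
    lapply(seq_len(gt$n_subjects), function(si) {
      lapply(seq_len(s), function(i) {
        u <- durations[[si]][[i]]
        ev <- rep(seq_len(k), times = u)
        y <- gt$r[si, i] * gt$subject_patterns[[si]][[i]][ev, , drop = FALSE]
        if (gt$sigma$recall > 0) {
          y <- y + matrix(stats::rnorm(length(y), sd = gt$sigma$recall),
                          nrow(y), ncol(y))
        }
        list(y = y, ev = ev)
      })
    })
  })
  structure(
    list(data = lapply(out, lapply, `[[`, "y"),
         event_of_timepoint = lapply(out, lapply, `[[`, "ev"),
         design = gt$design, n_subjects = gt$n_subjects),
    class = "recall_data"
  )
}

#' Simulate behavioral rubric scores
#'
#' Rubric scores (fraction of a story's scorable details produced during
#' free recall) follow the planted linear model
#' `clip(b0 + b_schema * a + b_reinst * r + noise, 0, 1)`.
#'
#' @param ground_truth a [make_ground_truth()] object.
#' @param seed integer seed for the behavioral noise substream.
#' @return `n_subjects` x `n_stories` matrix of scores in \[0, 1\], with the
#'   planted coefficients attached as attribute `coefs`.
#' @export
simulate_behavior <- function(ground_truth, seed = ground_truth$seed) {
  gt <- ground_truth
  stopifnot(inherits(gt, "ground_truth"))
  b <- gt$behavior_coefs
  mu <- b[1] + b[2] * gt$a + b[3] * gt$r
  y <- with_seed(substream_seed(seed, "behavior_noise"), {
    if (gt$sigma$behavior > 0)
      mu + matrix(stats::rnorm(length(mu), sd = gt$sigma$behavior),
                  nrow(mu), ncol(mu))
    else mu
  })
  y <- pmin(pmax(y, 0), 1)
  dimnames(y) <- list(sprintf("sub_%02d", seq_len(nrow(y))),
                      gt$design$stories$title)
  attr(y, "coefs") <- b
  y
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper drawing a design, ground truth, encoding and recall
#' timeseries and behavior from one root seed.
#'
#' @param seed integer root seed.
#' @param durations_range recall event durations in TRs.
#' @param ... passed to [make_ground_truth()].
#' @inheritParams make_design
#' @return list with `design`, `ground_truth`, `encoding`, `recall`,
#'   `behavior`.
#' @export
simulate_study <- function(seed = 1, n_stories = 16, n_events = 4,
                           event_durations = 45, countdown = 5, tr = 1.5,
                           durations_range = c(5, 15), ...) {
  design <- make_design(n_stories, n_events, event_durations, countdown, tr)
  gt <- make_ground_truth(design, seed = seed, ...)
  list(design = design, ground_truth = gt,
       encoding = simulate_encoding(gt),
       recall = simulate_recall(gt, durations_range),
       behavior = simulate_behavior(gt))
}
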