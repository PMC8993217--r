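#' Build a balanced narrative study design
#'
#' Creates the story/schema/modality layout of a naturalistic narrative
#' experiment: `n_stories` stories split evenly between two schematic scripts
#' (restaurant, airport) and two presentation modalities (video, audio), each
#' story following the same ordered sequence of `n_events` schematic events.
#' Every story is preceded by a countdown period, and event boundaries are
#' expressed as timestamps in seconds with half-open event intervals
#' `[t_k, t_{k+1})`.
#'
#' @param n_stories number of stories; must be divisible by 4 so that each
#'   (schema, modality) cell holds the same number of stories. Default 16.
#' @param n_events number of ordered schematic events per story. Default 4.
#' @param event_durations event durations in seconds: a scalar, a length
#'   `n_events` vector, or an `n_stories` x `n_events` matrix. Default 45.
#' @param countdown duration in seconds of the countdown preceding each
#'   story. Default 5.
#' @param tr repetition time of the scanner in seconds. Default 1.5.
#' @param seed optional integer; when given, the assignment of stories to
#'   (schema, modality) cells is shuffled deterministically.
#' @return an object of class `story_design`: a list with `stories` (data
#'   frame with `id`, `schema`, `modality`, `title`), `n_events`,
#'   `event_bounds` (matrix of `n_events + 1` timestamps per story, first
#'   bound at the end of the countdown), `countdown`, `tr` and `n_trs`
#'   (number of acquired volumes per encoding run).
#' @examples
#' d <- make_design()
#' d$n_trs                      # 124 volumes for 4 x 45 s events + 5 s countdown
#' table(d$stories$schema, d$stories$modality)
#' @export
make_design <- function(n_stories = 16, n_events = 4, event_durations = 45,
                        countdown = 5, tr = 1.5, seed = NULL) {
  if (n_stories < 4 || n_stories %% 4 != 0) {
    stop("n_stories must be a positive multiple of 4 ",
         "(balanced schema x modality cells)", call. = FALSE)
  }
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  dur <- event_durations
  if (is.matrix(dur)) {
    if (!all(dim(dur) == c(n_stories, n_events)))
      stop("event_durations matrix must be n_stories x n_events", call. = FALSE)
  } else {
    dur <- matrix(rep_len(dur, n_events), n_stories, n_events, byrow = TRUE)
  }
  if (any(dur < tr))
    stop("every event duration must be at least one TR", call. = FALSE)
  if (countdown < 0) stop("countdown must be non-negative", call. = FALSE)

  per_cell <- n_stories / 4
  schema <- rep(c("restaurant", "airport"), each = n_stories / 2)
  modality <- rep(rep(c("video", "audio"), each = per_cell), 2)
  ord <- seq_len(n_stories)
  if (!is.null(seed)) ord <- with_seed(substream_seed(seed, "design"),
                                       sample.int(n_stories))
  stories <- data.frame(
    id = seq_len(n_stories),
    schema = schema[order(ord)],
    modality = modality[order(ord)],
    title = sprintf("story_%02d", seq_len(n_stories)),
    stringsAsFactors = FALSE
  )

  bounds <- t(apply(dur, 1, function(d) countdown + cumsum(c(0, d))))
  total <- countdown + rowSums(dur)
  structure(
    list(stories = stories, n_events = n_events, event_bounds = bounds,
         countdown = countdown, tr = tr,
         n_trs = as.integer(ceiling(max(total) / tr))),
    class = "story_design"
  )
}

#' @export
print.story_design <- function(x, ...) {
  cat(sprintf("Study design: %d stories x %d events, TR %.2f s, %d volumes\n",
              nrow(x$stories), x$n_events, x$tr, x$n_trs))
  print(table(schema = x$stories$schema, modality = x$stories$modality))
  invisible(x)
}

# stories in the same (schema, modality) cell as story i, excluding i
same_cell_stories <- function(design, i) {
  st <- design$stories
  which(st$schema == st$schema[i] & st$modality == st$modality[i] &
          st$id != st$id[i])
}
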