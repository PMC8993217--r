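#' Event-wise pattern similarity between two stories
#'
#' Pearson-correlates the event-k pattern of one story with the event-k
#' pattern of another, for each of the K events, and averages the K
#' correlations into a single similarity.
#'
#' @param patterns_a,patterns_b K x V event-pattern matrices.
#' @return scalar in \[-1, 1\].
#' @examples
#' a <- rbind(c(1, 2, 3), c(1, 0, 1))
#' b <- rbind(c(3, 2, 1), c(0, 1, 0))
#' pair_similarity(a, b)   # mean of -1 and -0.5 = -0.75
#' @export
pair_similarity <- function(patterns_a, patterns_b) {
  if (!all(dim(patterns_a) == dim(patterns_b)))
    stop("pattern sets must share K and V", call. = FALSE)
  k <- nrow(patterns_a)
  sda <- apply(patterns_a, 1, stats::sd)
  sdb <- apply(patterns_b, 1, stats::sd)
  bad <- which(sda < .Machine$double.eps^0.5 | sdb < .Machine$double.eps^0.5)
  if (length(bad))
    stop("zero-variance pattern for event(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  mean(vapply(seq_len(k), function(i)
    stats::cor(patterns_a[i, ], patterns_b[i, ]), numeric(1)))
}

#' Leave-one-subject-out group templates
#'
#' Averages the encoding timeseries of the N - 1 other subjects for each
#' story and fits the GLM to the averaged timecourse (average first, then
#' fit; by linearity of OLS this equals the average of the other subjects'
#' betas when designs are shared, but the averaged-timecourse order is the
#' definition).
#'
#' @param encoding an `encoding_data` object.
#' @param left_out index of the subject to exclude.
#' @return list per story of K x V template pattern matrices.
#' @export
group_templates_loo <- function(encoding, left_out) {
  stopifnot(inherits(encoding, "encoding_data"))
  n <- encoding$n_subjects
  if (n < 2) stop("leave-one-out templates require >= 2 subjects", call. = FALSE)
  keep <- setdiff(seq_len(n), left_out)
  lapply(seq_along(encoding$designs), function(i) {
    avg <- Reduce(`+`, lapply(keep, function(s) encoding$data[[s]][[i]])) /
      length(keep)
    fit_event_patterns(avg, encoding$designs[[i]])$patterns
  })
}

# wrap a similarity matrix with its metadata
similarity_matrix <- function(mat, mode, phase, design) {
  dimnames(mat) <- list(design$stories$title, design$stories$title)
  structure(mat, mode = mode, phase = phase, class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("%s similarity matrix (%s), %d x %d stories\n",
              attr(x, "phase"), attr(x, "mode"), nrow(x), ncol(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Across-subject encoding similarity matrices
#'
#' For each subject, correlates that subject's event patterns for every
#' story (rows) with the leave-one-out group templates for every story
#' (columns), event-wise, averaging the K event correlations per cell.
#' Rows are the left-out subject's stories; the matrix is not symmetric.
#'
#' @param encoding an `encoding_data` object.
#' @param patterns optional precomputed [fit_study_patterns()] result.
#' @return list per subject of S x S `similarity_matrix` objects
#'   (`mode = "across"`, `phase = "encoding"`).
#' @export
across_subject_matrices <- function(encoding, patterns = NULL) {
  stopifnot(inherits(encoding, "encoding_data"))
  if (is.null(patterns)) patterns <- fit_study_patterns(encoding)
  s <- length(encoding$designs)
  k <- nrow(patterns[[1]][[1]])
  v <- ncol(patterns[[1]][[1]])
  n <- encoding$n_subjects
  if (n < 2) stop("across-subject similarity requires >= 2 subjects",
                  call. = FALSE)
  # running sums make the N leave-one-out averages O(N) instead of O(N^2)
  totals <- lapply(seq_len(s), function(i)
    Reduce(`+`, lapply(encoding$data, `[[`, i)))
  lapply(seq_len(n), function(si) {
    templ <- lapply(seq_len(s), function(i) {
      avg <- (totals[[i]] - encoding$data[[si]][[i]]) / (n - 1)
      fit_event_patterns(avg, encoding$designs[[i]])$patterns
    })
    mat <- matrix(0, s, s)
    for (ev in seq_len(k)) {
      za <- zscore_rows(t(vapply(patterns[[si]], function(p) p[ev, ],
                                 numeric(v))), what = "pattern")
      zb <- zscore_rows(t(vapply(templ, function(p) p[ev, ], numeric(v))),
                        what = "pattern")
      mat <- mat + tcrossprod(za, zb) / (v - 1)
    }
    similarity_matrix(mat / k, "across", "encoding", encoding$design)
  })
}

#' Within-subject encoding similarity matrix
#'
#' Correlates one subject's event patterns for each story with the same
#' subject's patterns for every other story. Symmetric, with ones on the
#' principal diagonal (a story's patterns are perfectly similar to
#' themselves).
#'
#' @param patterns list per story of K x V pattern matrices (one subject).
#' @param design the `story_design`.
#' @return S x S `similarity_matrix` (`mode = "within"`,
#'   `phase = "encoding"`).
#' @export
within_subject_matrix <- function(patterns, design) {
  s <- length(patterns)
  k <- nrow(patterns[[1]])
  v <- ncol(patterns[[1]])
  mat <- matrix(0, s, s)
  for (ev in seq_len(k)) {
    z <- zscore_rows(t(vapply(patterns, function(p) p[ev, ], numeric(v))),
                     what = "pattern")
    mat <- mat + tcrossprod(z) / (v - 1)
  }
  similarity_matrix(mat / k, "within", "encoding", design)
}
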