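#' Extract per-event spatial patterns by ordinary least squares
#'
#' Fits the event design matrix to every vertex's timeseries and returns the
#' event betas (the per-event spatial patterns) together with the nuisance
#' countdown beta and per-vertex residual variance.
#'
#' @param timeseries T x V matrix.
#' @param design design matrix from [build_design_matrix()] (T x (K + 1)).
#' @return list with `patterns` (K x V event betas), `nuisance` (countdown
#'   betas, NULL when the design has no countdown column), and `sigma2`
#'   (residual variance per vertex).
#' @export
fit_event_patterns <- function(timeseries, design) {
  if (nrow(timeseries) != nrow(design))
    stop("timeseries and design have different numbers of timepoints",
         call. = FALSE)
  if (!all(is.finite(timeseries)))
    stop("timeseries contains non-finite values", call. = FALSE)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    dropped <- colnames(design)[qx$pivot[seq(qx$rank + 1, ncol(design))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, timeseries)
  resid <- timeseries - design %*% beta
  dfres <- max(nrow(design) - ncol(design), 1)
  nuis <- attr(design, "nuisance")
  ev <- setdiff(colnames(design), nuis)
  list(patterns = beta[ev, , drop = FALSE],
       nuisance = if (length(nuis)) beta[nuis, ] else NULL,
       sigma2 = colSums(resid^2) / dfres)
}

#' Fit event patterns for every subject and story
#'
#' @param encoding an `encoding_data` object.
#' @return list `betas[[subject]][[story]]` of K x V event-pattern matrices.
#' @export
fit_study_patterns <- function(encoding) {
  stopifnot(inherits(encoding, "encoding_data"))
  lapply(encoding$data, function(subj)
    lapply(seq_along(subj), function(i)
      fit_event_patterns(subj[[i]], encoding$designs[[i]])$patterns))
}
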