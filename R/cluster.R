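# Subclustering of a masked region on stacked searchlight-result features.

#' Stack per-vertex maps into a feature matrix
#'
#' Pools several whole-brain maps (e.g. the eight searchlight results:
#' story/schema scores at encoding and recall plus their behavior
#' relationships) into a vertex x feature matrix over a region mask.
#' Vertices missing (NA) in any map are dropped and reported.
#'
#' @param maps list of per-vertex numeric vectors of equal length.
#' @param mask logical vector or integer indices selecting the region.
#' @return matrix of masked vertices x features, with attributes
#'   `vertices` (kept vertex indices) and `n_dropped`.
#' @export
stack_features <- function(maps, mask) {
  if (!length(maps)) stop("no maps supplied", call. = FALSE)
  n <- length(maps[[1]])
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  mat <- vapply(maps, function(m) {
    if (length(m) != n) stop("maps must share vertex indexing", call. = FALSE)
    m[idx]
  }, numeric(length(idx)))
  mat <- matrix(mat, nrow = length(idx))
  keep <- stats::complete.cases(mat)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " vertex(es) missing in at least one map; dropped")
  mat <- mat[keep, , drop = FALSE]
  if (ncol(mat) > 1 && qr(scale(mat, scale = FALSE))$rank <= 1)
    warning("feature matrix has rank <= 1 (identical maps?)", call. = FALSE)
  attr(mat, "vertices") <- idx[keep]
  attr(mat, "n_dropped") <- dropped
  mat
}

#' k-means clustering with silhouette-based k selection
#'
#' Runs k-means (multiple random restarts) for each candidate k, scores
#' each solution by its mean silhouette width (Euclidean distance on the
#' raw features by default), and keeps the k with the largest mean
#' silhouette. Candidate k's are restricted to be smaller than the number
#' of input features, mirroring the constraint that clusters should be
#' distinguishable in the feature space.
#'
#' @param features vertex x feature matrix (e.g. from [stack_features()]).
#' @param k_candidates integer candidate cluster counts; default
#'   `2:(n_features - 1)`.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of random restarts per k (default 50).
#' @param standardize z-score features before clustering (default FALSE;
#'   stacked z-scored maps are already on comparable scales).
#' @return object of class `kmeans_selection`: `k` (chosen), `labels`
#'   (cluster index per row), `silhouette` (named mean silhouette per
#'   candidate k), `vertices` (row vertex indices if present), `seed`.
#' @export
kmeans_select <- function(features, k_candidates = NULL, seed = 1,
                          nstart = 50, standardize = FALSE) {
  features <- as.matrix(features)
  nf <- ncol(features)
  if (is.null(k_candidates)) {
    if (nf < 3) stop("need at least 3 features for default candidates",
                     call. = FALSE)
    k_candidates <- 2:(nf - 1)
  }
  if (any(k_candidates < 2))
    stop("candidate k must be >= 2", call. = FALSE)
  if (max(k_candidates) >= nrow(features))
    stop("fewer samples than the largest candidate k", call. = FALSE)
  x <- if (standardize) scale(features) else features
  if (all(apply(x, 2, stats::sd) < .Machine$double.eps^0.5))
    stop("degenerate features: all points identical", call. = FALSE)
  d <- stats::dist(x)
  sil <- numeric(length(k_candidates))
  fits <- vector("list", length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    fits[[i]] <- with_seed(substream_seed(seed, paste0("kmeans_", k)),
                           stats::kmeans(x, centers = k, nstart = nstart,
                                         iter.max = 100))
    sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
  }
  names(sil) <- k_candidates
  best <- which.max(sil)
  structure(list(k = k_candidates[best], labels = fits[[best]]$cluster,
                 silhouette = sil, vertices = attr(features, "vertices"),
                 seed = seed),
            class = "kmeans_selection")
}

#' @export
print.kmeans_selection <- function(x, ...) {
  cat(sprintf("k-means selection: k = %d (mean silhouette %.3f)\n",
              x$k, x$silhouette[as.character(x$k)]))
  cat("  candidates:",
      paste(sprintf("k=%s (%.3f)", names(x$silhouette), x$silhouette),
            collapse = ", "), "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}
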