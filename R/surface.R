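# Synthetic surface meshes, graph-distance searchlights, and vertex-level
# aggregation / FDR mapping.

new_mesh <- function(n, edges, coords = NULL, valid = rep(TRUE, n)) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges[, 1] == edges[, 2])) stop("self-loop in mesh", call. = FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  structure(list(n_vertices = n, edges = edges, graph = g, coords = coords,
                 valid = valid),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices (%d valid), %d edges\n",
              x$n_vertices, sum(x$valid), nrow(x$edges)))
  invisible(x)
}

#' Ring mesh
#'
#' A cycle graph of `n` vertices; each vertex has exactly two neighbors.
#' Useful as an analytically tractable searchlight substrate.
#'
#' @param n number of vertices.
#' @param valid optional logical validity mask.
#' @return a `surface_mesh`.
#' @export
make_ring_mesh <- function(n, valid = rep(TRUE, n)) {
  edges <- cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))
  th <- 2 * pi * (seq_len(n) - 1) / n
  new_mesh(n, edges, coords = cbind(x = cos(th), y = sin(th), z = 0),
           valid = valid)
}

#' Triangulated grid mesh
#'
#' A rectangular grid with right, down and diagonal (down-right) edges,
#' mimicking a triangulated cortical surface patch. Coordinates are in mm
#' with unit spacing, right-anterior-superior convention (columns `x`, `y`,
#' `z`).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing vertex spacing in mm.
#' @param valid optional logical validity mask.
#' @return a `surface_mesh`.
#' @export
make_grid_mesh <- function(n_rows, n_cols, spacing = 1,
                           valid = rep(TRUE, n_rows * n_cols)) {
  idx <- function(r, c) (r - 1L) * n_cols + c
  edges <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      if (c < n_cols) edges[[length(edges) + 1]] <- c(idx(r, c), idx(r, c + 1))
      if (r < n_rows) edges[[length(edges) + 1]] <- c(idx(r, c), idx(r + 1, c))
      if (r < n_rows && c < n_cols)
        edges[[length(edges) + 1]] <- c(idx(r, c), idx(r + 1, c + 1))
    }
  }
  coords <- cbind(x = rep(seq_len(n_cols), n_rows) * spacing,
                  y = -rep(seq_len(n_rows), each = n_cols) * spacing,
                  z = 0)
  new_mesh(n_rows * n_cols, do.call(rbind, edges), coords = coords,
           valid = valid)
}

#' Generate random graph-distance searchlights
#'
#' Repeatedly samples a center vertex uniformly from the valid vertices,
#' collects all valid vertices within `steps` BFS steps, keeps the
#' searchlight if it has at least `min_size` members, and stops once every
#' valid vertex is covered by at least `min_coverage` searchlights.
#'
#' @param mesh a `surface_mesh`.
#' @param steps BFS radius in graph steps (default 11, about 15 mm at
#'   1.4 mm vertex spacing).
#' @param min_size minimum number of valid member vertices (default 100).
#' @param min_coverage minimum number of searchlights covering each valid
#'   vertex (default 10).
#' @param seed integer seed.
#' @param max_attempts attempt cap before declaring coverage unreachable.
#' @return object of class `searchlight_set`: list of searchlights (each
#'   `list(center, members)`) plus the generation parameters.
#' @export
generate_searchlights <- function(mesh, steps = 11, min_size = 100,
                                  min_coverage = 10, seed = 1,
                                  max_attempts = 100000) {
  stopifnot(inherits(mesh, "surface_mesh"))
  valid_idx <- which(mesh$valid)
  if (!length(valid_idx)) stop("mesh has no valid vertices", call. = FALSE)
  balls <- new.env(parent = emptyenv())
  ball_of <- function(center) {
    key <- as.character(center)
    if (is.null(balls[[key]])) {
      nb <- igraph::ego(mesh$graph, order = steps, nodes = center)[[1]]
      members <- intersect(as.integer(nb), valid_idx)
      balls[[key]] <- sort(members)
    }
    balls[[key]]
  }
  coverage <- integer(mesh$n_vertices)
  sls <- list()
  with_seed(substream_seed(seed, "searchlights"), {
    attempts <- 0
    while (any(coverage[valid_idx] < min_coverage)) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("coverage unreachable after ", max_attempts,
             " attempts (isolated or undersized neighborhoods?)",
             call. = FALSE)
      center <- valid_idx[sample.int(length(valid_idx), 1)]
      members <- ball_of(center)
      if (length(members) < min_size) next
      sls[[length(sls) + 1]] <- list(center = center, members = members)
      coverage[members] <- coverage[members] + 1
    }
  })
  structure(list(searchlights = sls, steps = steps, min_size = min_size,
                 min_coverage = min_coverage, seed = seed,
                 n_vertices = mesh$n_vertices, valid = mesh$valid),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  sizes <- vapply(x$searchlights, function(s) length(s$members), integer(1))
  cat(sprintf(
    "Searchlight set: %d searchlights (steps=%d, min_size=%d, coverage>=%d)\n",
    length(x$searchlights), x$steps, x$min_size, x$min_coverage))
  cat(sprintf("  member counts: min %d, median %.0f, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Aggregate searchlight values (and nulls) back to vertices
#'
#' Each vertex receives the mean value of all searchlights that include
#' it; null distributions are averaged element-wise the same way. Vertices
#' in no searchlight are flagged missing (NA).
#'
#' @param values numeric vector, one value per searchlight.
#' @param searchlight_set a `searchlight_set`.
#' @param nulls optional matrix (searchlight x n_perm) of null values.
#' @return list with `values` (per vertex), `nulls` (vertex x n_perm or
#'   NULL), `n_searchlights` (coverage count per vertex) and `missing`
#'   (logical).
#' @export
vertex_aggregate <- function(values, searchlight_set, nulls = NULL) {
  sls <- searchlight_set$searchlights
  if (length(values) != length(sls))
    stop("one value per searchlight required", call. = FALSE)
  n <- searchlight_set$n_vertices
  count <- numeric(n)
  acc <- numeric(n)
  nacc <- if (!is.null(nulls)) matrix(0, n, ncol(nulls))
  for (i in seq_along(sls)) {
    m <- sls[[i]]$members
    count[m] <- count[m] + 1
    acc[m] <- acc[m] + values[i]
    if (!is.null(nulls))
      nacc[m, ] <- nacc[m, ] + matrix(nulls[i, ], length(m), ncol(nulls),
                                      byrow = TRUE)
  }
  miss <- count == 0
  out <- acc / ifelse(miss, NA, count)
  vn <- if (!is.null(nulls)) nacc / ifelse(miss, NA, count)
  list(values = out, nulls = vn, n_searchlights = count, missing = miss)
}

#' Vertex-wise q-values from aggregated nulls
#'
#' Two-sided nonparametric p per vertex (proportion of null absolute
#' values strictly above the observed absolute value), converted to
#' Benjamini-Hochberg q-values across non-missing vertices.
#'
#' @param values per-vertex map.
#' @param nulls vertex x n_perm null matrix.
#' @return list with `p` and `q` vectors (NA where the map is missing).
#' @export
vertex_q <- function(values, nulls) {
  n <- length(values)
  p <- rep(NA_real_, n)
  ok <- which(!is.na(values))
  p[ok] <- vapply(ok, function(i)
    mean(abs(nulls[i, ]) > abs(values[i])), numeric(1))
  q <- rep(NA_real_, n)
  q[ok] <- stats::p.adjust(p[ok], "BH")
  list(p = p, q = q)
}

#' Conjunction of two positively thresholded maps
#'
#' A vertex is in the conjunction iff its value is positive and below the
#' q threshold in both maps (e.g. positive schema effects at FDR < 0.001
#' intersected with positive subsequent-memory effects at FDR < 0.05).
#'
#' @param map_a,map_b per-vertex effect maps.
#' @param q_a,q_b per-vertex q-values.
#' @param thr_a,thr_b FDR thresholds.
#' @return logical vector.
#' @export
conjunction_map <- function(map_a, q_a, map_b, q_b, thr_a = 0.001,
                            thr_b = 0.05) {
  a <- !is.na(map_a) & !is.na(q_a) & map_a > 0 & q_a < thr_a
  b <- !is.na(map_b) & !is.na(q_b) & map_b > 0 & q_b < thr_b
  a & b
}

#' Hippocampal long-axis split
#'
#' Splits coordinates into anterior (y > threshold) and posterior
#' (y <= threshold) masks; the boundary plane itself is posterior. The
#' default threshold is MNI y = -20 mm.
#'
#' @param coords coordinate matrix with named columns (`x`, `y`, `z`) or a
#'   plain matrix whose second column is y.
#' @param axis coordinate used for the split.
#' @param threshold boundary in mm.
#' @return list of logical masks `anterior` and `posterior`.
#' @export
split_long_axis <- function(coords, axis = "y", threshold = -20) {
  y <- if (!is.null(colnames(coords)) && axis %in% colnames(coords))
    coords[, axis] else coords[, 2]
  list(anterior = y > threshold, posterior = y <= threshold)
}
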