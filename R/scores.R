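# Story, schema and across-modality schema contrast scores, with
# permutation nulls and the associated inferential helpers.

# similarity of story i to every story, oriented by phase: encoding
# matrices have the subject's stories on the rows; reinstatement matrices
# have templates on the rows and recalls on the columns, so the similarity
# profile of recall i is column i.
story_vector <- function(sim, i) {
  if (identical(attr(sim, "phase"), "reinstatement")) unclass(sim)[, i]
  else unclass(sim)[i, ]
}

check_story_score_defined <- function(sim) {
  if (identical(attr(sim, "mode"), "within") &&
      identical(attr(sim, "phase"), "encoding")) {
    stop("story score is undefined for within-subject encoding matrices: ",
         "a subject's template always has similarity 1 to itself",
         call. = FALSE)
  }
}

#' Story score of one story
#'
#' Similarity of story i to itself (the diagonal cell) minus the mean
#' similarity of story i to the other stories of the same schema and
#' modality. Undefined for within-subject encoding matrices, whose diagonal
#' is identically 1.
#'
#' @param sim a `similarity_matrix`.
#' @param story story index.
#' @param design the `story_design`.
#' @return scalar score.
#' @export
story_score <- function(sim, story, design) {
  check_story_score_defined(sim)
  v <- story_vector(sim, story)
  others <- same_cell_stories(design, story)
  if (!length(others))
    stop("no other story in the same schema and modality cell", call. = FALSE)
  unname(v[story] - mean(v[others]))
}

#' Schema score of one story
#'
#' Mean similarity of story i to the other same-schema stories minus its
#' mean similarity to other-schema stories, restricted to stories of the
#' same modality (so that modality differences cannot masquerade as schema
#' structure).
#'
#' @inheritParams story_score
#' @param schema_labels optional replacement schema labels (used by the
#'   permutation null).
#' @export
schema_score <- function(sim, story, design,
                         schema_labels = design$stories$schema) {
  v <- story_vector(sim, story)
  st <- design$stories
  same_mod <- st$modality == st$modality[story] & st$id != story
  same <- same_mod & schema_labels == schema_labels[story]
  other <- same_mod & schema_labels != schema_labels[story]
  if (!any(same) || !any(other))
    stop("empty schema comparison set", call. = FALSE)
  unname(mean(v[same]) - mean(v[other]))
}

#' Across-modality schema score of one story
#'
#' As [schema_score()] but comparing only against stories of the *other*
#' modality: same-schema/other-modality mean minus
#' other-schema/other-modality mean.
#'
#' @inheritParams schema_score
#' @export
cross_modality_schema_score <- function(sim, story, design,
                                        schema_labels = design$stories$schema) {
  v <- story_vector(sim, story)
  st <- design$stories
  if (length(unique(st$modality)) < 2)
    stop("across-modality score needs a two-modality design", call. = FALSE)
  other_mod <- st$modality != st$modality[story]
  same <- other_mod & schema_labels == schema_labels[story]
  other <- other_mod & schema_labels != schema_labels[story]
  if (!any(same) || !any(other))
    stop("empty schema comparison set", call. = FALSE)
  unname(mean(v[same]) - mean(v[other]))
}

# all S scores of one matrix at once (vectorized; the per-story exported
# functions are the reference definition and agree entry-wise)
scores_for_matrix <- function(sim, design, type,
                              schema_labels = design$stories$schema) {
  m <- if (identical(attr(sim, "phase"), "reinstatement"))
    t(unclass(sim)) else unclass(sim)
  if (type == "story") check_story_score_defined(sim)
  scores_from_oriented(m, design, type, schema_labels)
}

# scores from a matrix already oriented with the subject's stories on the
# rows and the comparison stories (templates) on the columns
scores_from_oriented <- function(m, design, type,
                                 schema_labels = design$stories$schema) {
  st <- design$stories
  s <- nrow(st)
  same_mod <- outer(st$modality, st$modality, "==")
  same_sch <- outer(schema_labels, schema_labels, "==")
  offdiag <- !diag(TRUE, s)
  masked_mean <- function(mask) {
    n <- rowSums(mask)
    if (any(n == 0))
      stop("empty comparison set for story score contrast", call. = FALSE)
    rowSums(m * mask) / n
  }
  if (type == "story") {
    diag(m) - masked_mean(same_mod & same_sch & offdiag)
  } else if (type == "schema") {
    masked_mean(same_mod & same_sch & offdiag) -
      masked_mean(same_mod & !same_sch)
  } else if (type == "xmod_schema") {
    if (length(unique(st$modality)) < 2)
      stop("across-modality score needs a two-modality design", call. = FALSE)
    masked_mean(!same_mod & same_sch) - masked_mean(!same_mod & !same_sch)
  } else stop("unknown score type: ", type, call. = FALSE)
}

#' Score table for a set of similarity matrices
#'
#' @param matrices list per subject of `similarity_matrix` objects (one
#'   phase/mode).
#' @param design the `story_design`.
#' @param scores which scores to compute; story scores are skipped
#'   automatically for within-subject encoding matrices.
#' @return data frame with columns `subject`, `story`, and one column per
#'   requested score named `<phase>_<score>`.
#' @export
score_table <- function(matrices, design,
                        scores = c("story", "schema", "xmod_schema")) {
  phase <- attr(matrices[[1]], "phase")
  s <- nrow(design$stories)
  out <- data.frame(subject = rep(seq_along(matrices), each = s),
                    story = rep(seq_len(s), length(matrices)))
  for (sc in scores) {
    if (sc == "story" && identical(attr(matrices[[1]], "mode"), "within") &&
        identical(phase, "encoding")) next
    vals <- unlist(lapply(matrices, scores_for_matrix, design = design,
                          type = sc))
    out[[paste(phase, sc, sep = "_")]] <- vals
  }
  out
}

#' Group-mean score
#'
#' Mean of a score over all subjects and stories; the group-level statistic
#' that the permutation nulls are built for.
#'
#' @inheritParams score_table
#' @param type `"story"`, `"schema"` or `"xmod_schema"`.
#' @export
mean_score <- function(matrices, design, type) {
  mean(vapply(matrices, function(m)
    mean(scores_for_matrix(m, design, type)), numeric(1)))
}

#' Permutation null distribution for a group-mean score
#'
#' Story scheme: story identities are permuted within each schema x
#' modality cell on the subject's own axis (the rows of an encoding
#' matrix; the recall axis of a reinstatement matrix), shuffling which of
#' the subject's stories pairs with which comparison story while the
#' template axis stays fixed. (Relabeling both axes at once would leave
#' the group-mean story score algebraically unchanged.) Schema scheme:
#' schema labels of stories are permuted within
#' modality (preserving cell sizes) and scores recomputed under the
#' relabeling. By default, labels are shuffled independently for each
#' subject within each draw; `shared = TRUE` applies one relabeling to all
#' subjects.
#'
#' @inheritParams mean_score
#' @param scheme `"story"` or `"schema"` relabeling.
#' @param n_perm number of permutation draws (default 1000).
#' @param seed integer seed.
#' @param shared share one relabeling across subjects per draw.
#' @return numeric vector of `n_perm` null group-mean scores.
#' @export
permutation_null <- function(matrices, design, type = "schema",
                             scheme = c("schema", "story"), n_perm = 1000,
                             seed = 1, shared = FALSE) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  st <- design$stories
  s <- nrow(st)
  cells <- split(seq_len(s), paste(st$schema, st$modality))
  mods <- split(seq_len(s), st$modality)

  draw_story_perm <- function() {
    p <- seq_len(s)
    for (cell in cells) p[cell] <- cell[sample.int(length(cell))]
    p
  }
  draw_schema_labels <- function() {
    lab <- st$schema
    for (idx in mods) lab[idx] <- lab[idx][sample.int(length(idx))]
    lab
  }
  if (scheme == "story" && type == "story")
    check_story_score_defined(matrices[[1]])
  # orient once: rows = the subject's own stories (the axis that the story
  # relabeling shuffles against the fixed comparison axis)
  oriented <- lapply(matrices, function(m)
    if (identical(attr(m, "phase"), "reinstatement")) t(unclass(m))
    else unclass(m))

  one_subject <- function(m) {
    if (scheme == "story") {
      mean(scores_from_oriented(m[draw_story_perm(), ], design, type))
    } else {
      mean(scores_from_oriented(m, design, type,
                                schema_labels = draw_schema_labels()))
    }
  }
  with_seed(substream_seed(seed, paste0("perm_", scheme, "_", type)), {
    vapply(seq_len(n_perm), function(b) {
      if (shared) {
        if (scheme == "story") {
          p <- draw_story_perm()
          mean(vapply(oriented, function(m)
            mean(scores_from_oriented(m[p, ], design, type)), numeric(1)))
        } else {
          lab <- draw_schema_labels()
          mean(vapply(oriented, function(m)
            mean(scores_from_oriented(m, design, type, schema_labels = lab)),
            numeric(1)))
        }
      } else {
        mean(vapply(oriented, one_subject, numeric(1)))
      }
    }, numeric(1))
  })
}

#' Permutation p-value
#'
#' One-sided: proportion of null values greater than or equal to the
#' observed value. Two-sided: proportion of null absolute values strictly
#' greater than the observed absolute value. Plug-in proportions with no
#' smoothing; a returned 0 means p < 1/n_perm.
#'
#' @param observed observed statistic.
#' @param null numeric null distribution.
#' @param sided `"one"` or `"two"`.
#' @return proportion in \[0, 1\].
#' @export
p_from_null <- function(observed, null, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!length(null)) stop("empty null distribution", call. = FALSE)
  if (sided == "one") mean(null >= observed)
  else mean(abs(null) > abs(observed))
}

#' z-score of an observation against its null
#'
#' @inheritParams p_from_null
#' @export
z_vs_null <- function(observed, null) {
  s <- stats::sd(null)
  if (!is.finite(s) || s < .Machine$double.eps)
    stop("null distribution has zero variance", call. = FALSE)
  (observed - mean(null)) / s
}

#' Bonferroni adjustment for an ROI battery
#'
#' @param p p-value(s).
#' @param n_tests number of tests in the battery (e.g. 5 cortical or 3
#'   hippocampal ROIs).
#' @return `min(1, p * n_tests)`, vectorized.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  pmin(1, p * n_tests)
}
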