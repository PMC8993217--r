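# score contrasts operate on hand-built similarity matrices so expected
# values are plain arithmetic
fake_matrix <- function(design, fill = 0.1, mode = "across",
                        phase = "encoding") {
  s <- nrow(design$stories)
  m <- matrix(fill, s, s)
  structure(m, mode = mode, phase = phase, class = "similarity_matrix")
}

test_that("story score contrasts the diagonal with the same-cell mean", {
  d <- make_design(16)
  m <- fake_matrix(d)
  cell <- which(d$stories$schema == d$stories$schema[1] &
                  d$stories$modality == d$stories$modality[1] &
                  d$stories$id != 1)
  m[1, 1] <- 0.6
  m[1, cell] <- c(0.4, 0.3, 0.2)
  expect_equal(story_score(m, 1, d), 0.6 - 0.3)
  expect_equal(story_score(fake_matrix(d), 2, d), 0)
  # identity: score + same-cell mean reconstructs the diagonal
  expect_equal(story_score(m, 1, d) + mean(m[1, cell]), m[1, 1])
})

test_that("story scores are refused for within-subject encoding matrices", {
  d <- make_design(16)
  w <- fake_matrix(d, mode = "within", phase = "encoding")
  expect_error(story_score(w, 1, d), "undefined for within-subject encoding")
  # but allowed for within-subject reinstatement
  wr <- fake_matrix(d, mode = "within", phase = "reinstatement")
  expect_equal(story_score(wr, 1, d), 0)
})

test_that("schema scores contrast same- vs other-schema, same modality", {
  d <- make_design(16)
  st <- d$stories
  m <- fake_matrix(d)
  same <- st$modality == st$modality[1] & st$schema == st$schema[1] &
    st$id != 1
  other <- st$modality == st$modality[1] & st$schema != st$schema[1]
  m[1, same] <- 0.3
  m[1, other] <- 0.1
  expect_equal(schema_score(m, 1, d), 0.2)
  expect_equal(schema_score(fake_matrix(d), 1, d), 0)
})

test_that("across-modality schema score uses only the other modality", {
  d <- make_design(16)
  st <- d$stories
  m <- fake_matrix(d)
  xsame <- st$modality != st$modality[1] & st$schema == st$schema[1]
  xother <- st$modality != st$modality[1] & st$schema != st$schema[1]
  m[1, xsame] <- 0.2
  m[1, xother] <- 0.05
  expect_equal(cross_modality_schema_score(m, 1, d), 0.15)
  # same-modality entries are ignored entirely
  m[1, st$modality == st$modality[1]] <- 99
  expect_equal(cross_modality_schema_score(m, 1, d), 0.15)

  d1 <- make_design(16)
  d1$stories$modality <- "video"
  expect_error(cross_modality_schema_score(fake_matrix(d1), 1, d1),
               "two-modality")
})

test_that("planted schema structure yields positive schema scores", {
  st <- tiny_study(n_subjects = 3, n_vertices = 60, a = 1, d = 0, gamma = 0)
  sims <- across_subject_matrices(simulate_encoding(st$gt))
  tab <- score_table(sims, st$design, scores = "schema")
  expect_true(all(tab$encoding_schema > 0))
})

test_that("vectorized score tables agree with the per-story definitions", {
  st <- tiny_study(n_subjects = 2, n_vertices = 30, sigma_pattern = 0.5,
                   a = NULL, d = NULL)
  sims <- across_subject_matrices(simulate_encoding(st$gt))
  tab <- score_table(sims, st$design)
  for (i in c(1, 7, 16)) {
    expect_equal(tab$encoding_story[i], story_score(sims[[1]], i, st$design))
    expect_equal(tab$encoding_schema[i], schema_score(sims[[1]], i, st$design))
    expect_equal(tab$encoding_xmod_schema[i],
                 cross_modality_schema_score(sims[[1]], i, st$design))
  }
})

test_that("permutation nulls are centered and degenerate cases constant", {
  d <- make_design(16)
  flat <- fake_matrix(d)
  null <- permutation_null(list(flat), d, type = "schema", scheme = "schema",
                           n_perm = 20, seed = 1)
  expect_lt(max(abs(null)), 1e-12)  # scores invariant under relabeling
  null_s <- permutation_null(list(flat), d, type = "story", scheme = "story",
                             n_perm = 20, seed = 1)
  expect_lt(max(abs(null_s)), 1e-12)

  st <- tiny_study(n_subjects = 3, n_vertices = 40, a = 0, d = 0, gamma = 0,
                   sigma_pattern = 1, sigma_temporal = 0.5)
  sims <- across_subject_matrices(simulate_encoding(st$gt))
  null2 <- permutation_null(sims, d, type = "schema", scheme = "schema",
                            n_perm = 200, seed = 2)
  expect_lt(abs(mean(null2)), 3 * sd(null2) / sqrt(200) + 0.01)
})

test_that("permutation nulls are reproducible given the seed", {
  st <- tiny_study(n_subjects = 2, n_vertices = 30, sigma_pattern = 0.5)
  sims <- across_subject_matrices(simulate_encoding(st$gt))
  n1 <- permutation_null(sims, st$design, "schema", "schema", 25, seed = 7)
  n2 <- permutation_null(sims, st$design, "schema", "schema", 25, seed = 7)
  expect_identical(n1, n2)
})

test_that("p-values follow the plug-in proportion rules", {
  expect_equal(p_from_null(0.5, c(0.1, 0.2, 0.6), "one"), 1 / 3)
  expect_equal(p_from_null(0, c(-0.2, 0.1, 0.3), "two"), 1)
  expect_equal(p_from_null(0.9, c(0.1, 0.2, 0.6), "one"), 0)  # < 1/n_perm
  null <- seq(0.001, 1, length.out = 1000)
  expect_equal(p_from_null(max(null), null, "one"), 1 / 1000)
})

test_that("z-scores against the null behave like standardization", {
  set.seed(5)
  null <- rnorm(20000)
  expect_equal(z_vs_null(mean(null), null), 0)
  expect_lt(abs(z_vs_null(2, null) - 2), 0.05)
  expect_error(z_vs_null(1, rep(0.3, 10)), "zero variance")
})

test_that("Bonferroni scaling matches the ROI battery convention", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)  # 5 cortical ROIs
  expect_equal(bonferroni_adjust(0.5, 3), 1)      # capped at 1
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
})
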