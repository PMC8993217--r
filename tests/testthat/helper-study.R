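# Shared fixture builders: small synthetic studies generated in code.

# A compact study: 16 stories x 4 events of 6 s each, 3 s countdown,
# TR 1.5 s (21 volumes per run). Fidelities and noise default to the
# noiseless fully planted case so recovery tests are exact.
tiny_study <- function(n_subjects = 3, n_vertices = 40, a = 0.6, d = 1,
                       r = 1, gamma = 0.3, sigma_pattern = 0,
                       sigma_temporal = 0, sigma_recall = 0,
                       sigma_behavior = 0, seed = 1, n_stories = 16,
                       event_duration = 6, countdown = 3, tr = 1.5, ...) {
  design <- make_design(n_stories, 4, event_duration, countdown, tr)
  gt <- make_ground_truth(design, n_subjects = n_subjects,
                          n_vertices = n_vertices, a = a, d = d, r = r,
                          gamma = gamma, sigma_pattern = sigma_pattern,
                          sigma_temporal = sigma_temporal,
                          sigma_recall = sigma_recall,
                          sigma_behavior = sigma_behavior, seed = seed, ...)
  list(design = design, gt = gt)
}

# K x V mutually orthogonal event patterns (rows of an identity-like basis
# plus centering-resistant structure); orthogonal AFTER row z-scoring.
orthogonal_patterns <- function(k, v) {
  stopifnot(v >= 2 * k)
  m <- matrix(0, k, v)
  for (i in seq_len(k)) {
    m[i, 2 * i - 1] <- 1
    m[i, 2 * i] <- -1
  }
  m
}

# adjusted Rand index between two labelings (independent of the package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
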