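test_that("ring searchlights have the exact BFS ball size", {
  mesh <- make_ring_mesh(30)
  sl <- generate_searchlights(mesh, steps = 2, min_size = 1,
                              min_coverage = 1, seed = 1)
  sizes <- vapply(sl$searchlights, function(s) length(s$members), integer(1))
  expect_true(all(sizes == 5))  # center +- 2 steps on a cycle
  sl0 <- generate_searchlights(mesh, steps = 0, min_size = 1,
                               min_coverage = 1, seed = 1)
  expect_true(all(vapply(sl0$searchlights, function(s)
    identical(s$members, s$center), logical(1))))
})

test_that("searchlight sets satisfy their construction invariants", {
  mesh <- make_grid_mesh(12, 12)
  g <- mesh$graph
  for (seed in c(1, 2, 3)) {
    sl <- generate_searchlights(mesh, steps = 3, min_size = 20,
                                min_coverage = 4, seed = seed)
    cover <- integer(mesh$n_vertices)
    for (s in sl$searchlights) {
      expect_gte(length(s$members), 20)
      dists <- igraph::distances(g, v = s$center, to = s$members)
      expect_lte(max(dists), 3)
      cover[s$members] <- cover[s$members] + 1
    }
    expect_true(all(cover[mesh$valid] >= 4))
  }
})

test_that("unreachable coverage errors instead of spinning", {
  mesh <- make_ring_mesh(12, valid = c(rep(TRUE, 11), FALSE))
  expect_error(generate_searchlights(mesh, steps = 1, min_size = 5,
                                     min_coverage = 1, seed = 1,
                                     max_attempts = 200),
               "unreachable")
})

test_that("vertex aggregation averages containing searchlights", {
  mesh <- make_ring_mesh(6)
  sls <- structure(list(searchlights = list(list(center = 1L,
                                                 members = c(1L, 2L)),
                                            list(center = 2L,
                                                 members = c(2L, 3L))),
                        n_vertices = 6, valid = rep(TRUE, 6)),
                   class = "searchlight_set")
  nulls <- rbind(c(0, 1), c(2, 3))
  out <- vertex_aggregate(c(0.2, 0.4), sls, nulls)
  expect_equal(out$values[1:3], c(0.2, 0.3, 0.4))
  expect_true(all(out$missing[4:6]))
  expect_equal(out$nulls[2, ], c(1, 2))  # element-wise mean of the nulls
  # constant searchlight values propagate unchanged
  outc <- vertex_aggregate(c(7, 7), sls)
  expect_true(all(outc$values[1:3] == 7))
})

test_that("vertex q-values apply the BH step-up over valid vertices", {
  # hand-computed BH: p = .01 .02 .03 .04 with m = 4 all give q = .04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  # the same through the vertex pipeline: craft nulls realizing those p's
  n_perm <- 100
  vals <- c(1, 1, 1, 1)
  nulls <- t(vapply(p, function(pp) {
    c(rep(2, pp * n_perm), rep(0, n_perm - pp * n_perm))
  }, numeric(n_perm)))
  out <- vertex_q(vals, nulls)
  expect_equal(out$p, p)
  expect_equal(out$q, rep(0.04, 4))
  # all p = 1 stays 1; single vertex q = p
  out1 <- vertex_q(1, matrix(2, 1, 10))
  expect_equal(out1$q, out1$p)
  allone <- vertex_q(c(0, 0), matrix(1, 2, 10))
  expect_equal(allone$q, c(1, 1))
})

test_that("conjunctions intersect positive supra-threshold sets", {
  map_a <- c(1, 1, -1, 1, 0.5)
  q_a <- c(0.0001, 0.01, 0.0001, 0.0001, 0.0001)
  map_b <- c(1, 1, 1, -2, 1)
  q_b <- c(0.01, 0.01, 0.01, 0.01, 0.2)
  got <- conjunction_map(map_a, q_a, map_b, q_b, thr_a = 0.001, thr_b = 0.05)
  expect_equal(got, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(conjunction_map(map_a, rep(1, 5), map_b, q_b)))
  same <- conjunction_map(map_b, q_b, map_b, q_b, thr_a = 0.05, thr_b = 0.05)
  expect_equal(same, map_b > 0 & q_b < 0.05)
})

test_that("the long-axis split assigns the boundary to posterior", {
  coords <- cbind(x = 0, y = c(-20, -19.9, -30, 5), z = 0)
  split <- split_long_axis(coords)
  expect_equal(split$posterior, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(split$anterior, !split$posterior)  # exhaustive partition
})
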