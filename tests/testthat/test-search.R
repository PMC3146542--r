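test_that("terminal enumeration resolves the zero-matrix tie cascade as documented", {
  # n = 5, zero energies: every a + b = 4 split ties at F = -8; the cascade
  # (fewer disordered, then smaller N-tail) selects a = 0, b = 4
  a <- enumerate_terminal(zero_matrix(5), fe_params())
  expect_equal(a$breakdown$F, -8)
  expect_equal(a$ordered, c(TRUE, rep(FALSE, 4)))
})

test_that("a strongly attached terminal residue stays ordered", {
  # residue 1 holds -10 of attraction to the core; disordering it trades
  # 10 in energy for a credit of 2
  m <- matrix_from_pairs(8, list(c(1, 5, -10, 0)))
  a <- enumerate_terminal(m, fe_params())
  expect_true(a$ordered[1])
  expect_lte(a$breakdown$F, free_energy(m, rep(TRUE, 8))$breakdown$F)
})

test_that("terminal enumeration equals the brute-force (a, b) oracle on random instances", {
  for (seed in 1:25) {
    m <- random_matrix(12, seed, attr_scale = 4, rep_frac = 0.15)
    got <- enumerate_terminal(m, fe_params())
    want <- brute_terminal(m, fe_params())
    expect_equal(got$ordered, want$ordered)
    expect_equal(got$breakdown$F, want$F, tolerance = 1e-12)
  }
})

test_that("greedy search disorders everything it can on a zero matrix", {
  g <- greedy_internal(zero_matrix(12), fe_params())
  expect_lt(g$breakdown$F, 0)
  # at most block-1 ordered residues can remain in any maximal state
  expect_lte(sum(g$ordered), 4)
})

test_that("greedy search leaves a uniformly attractive chain fully ordered", {
  n <- 12
  pairs <- list()
  for (i in 1:(n - 2)) for (j in (i + 2):n) pairs[[length(pairs) + 1]] <- c(i, j, -5, 0)
  m <- matrix_from_pairs(n, pairs)
  g <- greedy_internal(m, fe_params())
  expect_true(all(g$ordered))
})

test_that("greedy recovers a planted energetically isolated segment and matches the oracle", {
  # residues 11-14 are energetically detached; everything else is glued
  m <- generate_pair_matrix(22, planted_disordered = 11:14,
                            attr_core = -5, attr_disordered = 0, seed = 8)
  g <- greedy_internal(m, fe_params())
  expect_equal(which(!g$ordered), 11:14)
  ex <- exhaustive_search(m, fe_params())
  expect_equal(g$ordered, ex$ordered)
  expect_equal(g$breakdown$F, ex$breakdown$F, tolerance = 1e-12)
})

test_that("greedy trajectories never raise F and end at or below all-ordered", {
  for (seed in 1:6) {
    m <- random_matrix(20, seed, attr_scale = 2.5)
    g <- greedy_internal(m, fe_params())
    traj <- attr(g, "trajectory")
    Fs <- vapply(traj, function(o) free_energy(m, o)$breakdown$F, numeric(1))
    expect_true(all(diff(Fs) <= 1e-12))
    expect_lte(g$breakdown$F,
               free_energy(m, rep(TRUE, 20))$breakdown$F + 1e-12)
    # greedy can never beat the global optimum
    ex <- exhaustive_search(m, fe_params())
    expect_gte(g$breakdown$F, ex$breakdown$F - 1e-9)
  }
})

test_that("exhaustive search maximizes entropy credit on a zero matrix", {
  # n = 8: the best admissible state keeps one ordered residue; the tie
  # cascade parks it at position 1 (7 C-tail residues, F = -14)
  ex <- exhaustive_search(zero_matrix(8), fe_params())
  expect_equal(ex$breakdown$F, -14)
  expect_equal(ex$ordered, c(TRUE, rep(FALSE, 7)))
})

test_that("exhaustive search returns all-ordered under uniform strong attraction", {
  n <- 10
  pairs <- list()
  for (i in 1:(n - 2)) for (j in (i + 2):n) pairs[[length(pairs) + 1]] <- c(i, j, -6, 0)
  ex <- exhaustive_search(matrix_from_pairs(n, pairs), fe_params())
  expect_true(all(ex$ordered))
})

test_that("exhaustive search agrees with terminal enumeration when only tails are admissible", {
  p_tails_only <- fe_params(min_loop_len = 13) # no internal loop fits in n = 12
  for (seed in 1:10) {
    m <- random_matrix(12, seed, attr_scale = 4)
    expect_equal(exhaustive_search(m, p_tails_only)$ordered,
                 enumerate_terminal(m, p_tails_only)$ordered)
  }
})

test_that("exhaustive search refuses oversized problems", {
  expect_error(exhaustive_search(zero_matrix(30), fe_params()), "max_n")
})
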