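test_that("the 12-6 backend matches its closed form at landmark distances", {
  par <- energy_params()
  eps <- par$well_depth
  rA <- par$radius_by_aa[["A"]]
  sigma <- 2 * rA
  place <- function(r) {
    # residues 1 and 3 at distance r; residue 2 parked far away so only the
    # (1,3) pair can interact (|1-2|, |2-3| are bonded-excluded anyway)
    mk_model(rbind(c(0, 0, 0), c(500, 500, 500), c(r, 0, 0)))
  }
  total <- function(r) {
    m <- compute_interaction_matrix(place(r), par)
    m$e_attr[1, 3] + m$e_rep[1, 3]
  }
  # potential minimum at r = sigma
  expect_equal(total(sigma), -eps, tolerance = 1e-12)
  # beyond the cutoff
  expect_equal(total(par$cutoff + 1), 0)
  # compressed pair: direct evaluation of the closed form
  r <- 0.7 * sigma
  expected <- min(eps * ((1 / 0.7)^12 - 2 * (1 / 0.7)^6), par$rep_cap)
  m <- compute_interaction_matrix(place(r), par)
  expect_equal(m$e_rep[1, 3], expected, tolerance = 1e-9)
  expect_equal(m$e_attr[1, 3], 0)
})

test_that("backend matrices satisfy the structural invariants on random coordinates", {
  for (seed in 1:5) {
    g <- generate_ensemble(synthetic_spec(n_core = 15, n_tail_n = 4,
                                          n_models = 1, seed = seed))
    m <- compute_interaction_matrix(g$ensemble$models[[1]])
    expect_silent(validate_interaction_matrix(m))
    expect_true(all(m$e_rep <= energy_params()$rep_cap + 1e-12))
  }
})

test_that("pair tables load with mirroring, zero defaults and sign validation", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# i j e_attr e_rep", "2 5 -1.5 0.0", "1 4 -0.25 0.75"), tab)
  m <- load_interaction_matrix(tab, 6)
  expect_equal(m$e_attr[2, 5], -1.5)
  expect_equal(m$e_attr[5, 2], -1.5)
  expect_equal(m$e_rep[1, 4], 0.75)
  expect_equal(sum(m$e_attr != 0), 4) # two mirrored pairs
  expect_silent(validate_interaction_matrix(m))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  m0 <- load_interaction_matrix(empty, 4)
  expect_equal(sum(abs(m0$e_attr)) + sum(abs(m0$e_rep)), 0)

  bad_sign <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1 3 0.3 0.0", bad_sign)
  expect_error(load_interaction_matrix(bad_sign, 4), "e_attr > 0")

  bad_rep <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1 3 -0.3 -1.0", bad_rep)
  expect_error(load_interaction_matrix(bad_rep, 4), "e_rep < 0")

  oob <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1 9 -0.3 0.0", oob)
  expect_error(load_interaction_matrix(oob, 4), "out of range")

  bonded <- withr::local_tempfile(fileext = ".tsv")
  writeLines("2 3 -0.3 0.0", bonded)
  expect_error(load_interaction_matrix(bonded, 4), "bonded")
})

test_that("masked energy keeps repulsion and removes attraction touching the mask", {
  # 4-residue toy: one attractive pair (1,3), one clash pair (2,4)
  m <- matrix_from_pairs(4, list(c(1, 3, -2, 0), c(2, 4, 0, 5)))
  expect_equal(masked_energy(m, integer()), 3)   # -2 + 5
  expect_equal(masked_energy(m, 3), 5)           # attraction to 3 removed
  expect_equal(masked_energy(m, 1:4), 5)         # all masked: repulsion only
  expect_error(masked_energy(m, 7), "out of range")
})

test_that("masking obeys the exact attraction-removal decomposition", {
  for (seed in 1:6) {
    m <- random_matrix(10, seed, rep_frac = 0.2)
    mask <- withr::with_seed(seed * 31, sample(1:10, sample(0:5, 1)))
    touching <- 0
    for (i in 1:9) for (j in (i + 1):10) {
      if (i %in% mask || j %in% mask) touching <- touching + m$e_attr[i, j]
    }
    expect_equal(masked_energy(m, mask),
                 masked_energy(m, integer()) - touching,
                 tolerance = 1e-12)
    # with no repulsion anywhere, masking can only raise the energy
    m_attr <- disofold:::new_interaction_matrix(m$e_attr, matrix(0, 10, 10))
    expect_gte(masked_energy(m_attr, mask), masked_energy(m_attr, integer()) - 1e-12)
  }
})

test_that("reduced masking is inert without a mask and ignores distant segments", {
  g <- generate_ensemble(synthetic_spec(n_core = 14, n_tail_c = 5,
                                        n_models = 1, seed = 3))
  mod <- g$ensemble$models[[1]]
  expect_equal(masked_energy_reduced(mod, integer()),
               masked_energy(compute_interaction_matrix(mod), integer()),
               tolerance = 1e-12)

  # a masked tail far beyond the cutoff contributes exactly nothing
  far <- mod
  tail_idx <- which(g$ground_truth)
  far$ca[tail_idx, ] <- far$ca[tail_idx, ] + 500
  far$center[tail_idx, ] <- far$center[tail_idx, ] + 500
  core_only <- mk_model(mod$ca[!g$ground_truth, , drop = FALSE],
                        aa = mod$aa[!g$ground_truth])
  expect_equal(masked_energy_reduced(far, tail_idx),
               masked_energy(compute_interaction_matrix(core_only), integer()),
               tolerance = 1e-9)
})

test_that("reduced masked scoring is invariant to clash-free re-conformation", {
  # identical cores, two independently re-sampled clash-free tails
  g <- generate_ensemble(synthetic_spec(n_core = 30, n_tail_c = 10,
                                        n_models = 2, core_noise = 0,
                                        seed = 21))
  mask <- which(g$ground_truth)
  e1 <- masked_energy_reduced(g$ensemble$models[[1]], mask)
  e2 <- masked_energy_reduced(g$ensemble$models[[2]], mask)
  expect_equal(e1, e2, tolerance = 1e-9)
})
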