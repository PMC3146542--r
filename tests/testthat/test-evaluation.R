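test_that("ensemble-derived reference disorder behaves at the limits", {
  g <- generate_ensemble(synthetic_spec(n_core = 14, n_models = 3,
                                        core_noise = 0, seed = 2))
  # identical models: nothing deviates
  ref <- reference_from_ensemble(g$ensemble)
  expect_false(any(ref$disordered))
  expect_equal(max(ref$deviation), 0, tolerance = 1e-9)

  g2 <- generate_ensemble(synthetic_spec(n_core = 30, n_tail_n = 8,
                                         n_models = 8, seed = 14))
  # infinite threshold: all ordered
  expect_false(any(reference_from_ensemble(g2$ensemble, Inf)$disordered))
  expect_error(reference_from_ensemble(
    ensemble(list(g$ensemble$models[[1]]))), "at least 2")
})

test_that("re-sampled tails exceed the deviation threshold, the core does not", {
  for (seed in c(14, 15)) {
    g <- generate_ensemble(synthetic_spec(n_core = 30, n_tail_n = 8,
                                          n_models = 8, seed = seed))
    ref <- reference_from_ensemble(g$ensemble, 2.0)
    truth <- which(g$ground_truth)
    flagged <- which(ref$disordered)
    # planted tails recovered up to 2 boundary residues
    expect_lte(length(setdiff(truth, flagged)), 2)
    expect_lte(length(setdiff(flagged, truth)), 2)
  }
})

test_that("the accuracy score rewards matching frequencies and penalizes inversions", {
  ref <- reference_from_mask(c(1:3, 10), 12)
  perfect <- as.numeric(ref$disordered)
  expect_equal(accuracy_score(perfect, ref)$score, 1.0)
  expect_equal(accuracy_score(1 - perfect, ref)$score, 0.0)
  expect_equal(accuracy_score(rep(0.5, 12), ref)$score, 0.5)
  expect_error(accuracy_score(rep(0.5, 5), ref), "length")
  expect_equal(glance(accuracy_score(perfect, ref))$score, 1.0)
})

test_that("the null model scores the ordered fraction and matches an all-ordered profile", {
  expect_equal(null_model_score(reference_from_mask(1:10, 100))$score, 0.9)
  expect_equal(null_model_score(reference_from_mask(integer(), 7))$score, 1.0)
  expect_equal(null_model_score(reference_from_mask(1:7, 7))$score, 0.0)
  ref <- reference_from_mask(c(2, 5:9), 20)
  expect_equal(accuracy_score(rep(0, 20), ref)$score, null_model_score(ref)$score)
})

test_that("tail length differences are plain arithmetic on the assignment", {
  z <- zero_matrix(30)
  a <- free_energy(z, c(rep(FALSE, 5), rep(TRUE, 22), rep(FALSE, 3)))
  expect_equal(tail_length_accuracy(a, 5, 3), c(dN = 0, dC = 0))
  expect_equal(tail_length_accuracy(a, 20, 20), c(dN = -15, dC = -17))
})

test_that("mask files round-trip through the range dialect", {
  p <- withr::local_tempfile(fileext = ".mask")
  write_disorder_mask(c(3, 1, 2, 9, 11, 12, 13), p)
  expect_equal(read_disorder_mask(p), c(1, 2, 3, 9, 11, 12, 13))
  expect_true(any(grepl("^1-3$", readLines(p))))
  writeLines(c("# predicted disorder", "2", "5-7", ""), p)
  expect_equal(read_disorder_mask(p), c(2, 5, 6, 7))
  writeLines("5-3", p)
  expect_error(read_disorder_mask(p), "range")
  writeLines("abc", p)
  expect_error(read_disorder_mask(p), "expected index")
})

test_that("parameter scans report per-point metrics and a deterministic best point", {
  # coordinate-free benchmark: planted tails with weak attraction
  mk_entry <- function(seed) {
    n <- 14
    m <- withr::with_seed(seed, {
      A <- matrix(0, n, n)
      # each 4-residue N-tail member holds one weak contact (-1.0..-1.5);
      # core residues are multiply anchored at -1 per pair
      for (i in 1:4) A[i, i + 6] <- A[i + 6, i] <- -runif(1, 1.0, 1.5)
      for (i in 5:(n - 2)) for (j in (i + 2):n) A[i, j] <- A[j, i] <- -1
      disofold:::new_interaction_matrix(A, matrix(0, n, n))
    })
    dummy <- ensemble(list(chain_model(n)))
    list(ensemble = dummy, reference = reference_from_mask(1:4, n),
         matrices = list(m))
  }
  bench <- lapply(1:4, mk_entry)
  tab <- scan_parameters(bench, grid = list(E_d = c(1.4, 2.0, 2.6)),
                         mode = "terminal")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$metric >= 0 & tab$metric <= 1))
  # under-crediting the tails (E_d = 1.4) must not win the scan
  best <- attr(tab, "best")
  expect_true(best$E_d %in% c(2.0, 2.6))

  one <- scan_parameters(bench[1], grid = list(E_d = 2.0), mode = "internal")
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "best")$E_d, 2.0)
})
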