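# Shared fixture builders. Everything is generated in code; no binary data.

# structure model from a coordinate matrix, poly-ALA by default
mk_model <- function(ca, aa = rep("A", nrow(ca)), id = "1") {
  structure_model(aa, ca, model_id = id)
}

# straight 3.8-angstrom chain along x (degenerate geometry, handy when only
# the residue count matters)
chain_model <- function(n, aa = rep("A", n), id = "1") {
  structure_model(aa, cbind(3.8 * (seq_len(n) - 1), 0, 0), model_id = id)
}

# interaction matrix from explicit pair entries: list of c(i, j, attr, rep)
matrix_from_pairs <- function(n, pairs = list()) {
  e_attr <- matrix(0, n, n)
  e_rep <- matrix(0, n, n)
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    e_attr[i, j] <- e_attr[j, i] <- p[3]
    e_rep[i, j] <- e_rep[j, i] <- p[4]
  }
  disofold:::new_interaction_matrix(e_attr, e_rep)
}

zero_matrix <- function(n) matrix_from_pairs(n)

# random attractive-channel matrix with optional repulsive channel
random_matrix <- function(n, seed, attr_scale = 3, rep_frac = 0) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    R <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i + 1L) next
        A[i, j] <- A[j, i] <- -runif(1, 0, attr_scale)
        if (rep_frac > 0 && runif(1) < rep_frac) {
          R[i, j] <- R[j, i] <- runif(1, 0, 2)
        }
      }
    }
    disofold:::new_interaction_matrix(A, R)
  })
}

# brute-force free energy by literal hand summation (independent of the
# package's pair-sum and entropy bookkeeping)
brute_free_energy <- function(m, ordered, E_d = 2, beta = 1.5, L0 = 0.3) {
  n <- length(ordered)
  E <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ordered[i] && ordered[j]) E <- E + m$e_attr[i, j] + m$e_rep[i, j]
    }
  }
  ent <- 0
  i <- 1
  while (i <= n) {
    if (!ordered[i]) {
      j <- i
      while (j < n && !ordered[j + 1]) j <- j + 1
      len <- j - i + 1
      if (i == 1 || j == n) ent <- ent + E_d * len
      else ent <- ent + beta * log(len / L0)
      i <- j + 1
    } else i <- i + 1
  }
  E - ent
}

# brute-force terminal enumeration oracle over all (a, b) tail pairs
brute_terminal <- function(m, params = fe_params()) {
  n <- m$n
  best <- NULL
  for (a in 0:(n - 1)) {
    for (b in 0:(n - 1 - a)) {
      ordered <- rep(TRUE, n)
      if (a > 0) ordered[1:a] <- FALSE
      if (b > 0) ordered[(n - b + 1):n] <- FALSE
      F_ <- brute_free_energy(m, ordered, params$E_d, params$beta, params$L0)
      if (is.null(best) || F_ < best$F - 1e-12 ||
          (abs(F_ - best$F) <= 1e-12 &&
             (a + b < best$a + best$b ||
                (a + b == best$a + best$b && a < best$a)))) {
        best <- list(F = F_, a = a, b = b, ordered = ordered)
      }
    }
  }
  best
}

# PDB text fixture: one 3-residue ALA/GLY chain, written from a template so
# io tests do not depend on the package's own writer
pdb_lines_one_model <- function(resseq_offset = 0) {
  c(
    sprintf("ATOM      1  N   ALA A%4d      11.104   6.134  -6.504  1.00  0.00", 1 + resseq_offset),
    sprintf("ATOM      2  CA  ALA A%4d      11.639   6.071  -5.147  1.00  0.00", 1 + resseq_offset),
    sprintf("ATOM      3  CB  ALA A%4d      12.919   6.898  -5.041  1.00  0.00", 1 + resseq_offset),
    sprintf("ATOM      4  C   ALA A%4d      10.599   6.576  -4.147  1.00  0.00", 1 + resseq_offset),
    sprintf("ATOM      5  CA  GLY A%4d       9.374   5.998  -4.422  1.00  0.00", 2 + resseq_offset),
    sprintf("ATOM      6  CA  ALA A%4d       7.575   3.212  -4.000  1.00  0.00", 3 + resseq_offset),
    sprintf("ATOM      7  CB  ALA A%4d       6.930   2.575  -2.767  1.00  0.00", 3 + resseq_offset)
  )
}

write_pdb_fixture <- function(lines, path = withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}
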