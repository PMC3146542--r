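# Rigid-body superposition (Kabsch), core RMSD, and core GDT-TS.
#
# Both metrics are computed over a designated "core" (the ordered/folded
# part of the chain) only, so flexible tails and loops do not drown the
# comparison.

# Optimal rotation/translation mapping P onto Q (both k-by-3), least
# squares, via SVD with the usual reflection guard.
kabsch_transform <- function(P, Q, fit_idx = NULL) {
  if (!is.null(fit_idx)) {
    P <- P[fit_idx, , drop = FALSE]
    Q <- Q[fit_idx, , drop = FALSE]
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0)) # t(P0) %*% Q0
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

apply_transform <- function(X, tr) {
  sweep(sweep(X, 2, tr$cp) %*% t(tr$R), 2, tr$cq, `+`)
}

# RMSD between two k-by-3 coordinate sets after optimal superposition of
# `fit_idx` rows (defaults to all rows); the RMSD itself is over all rows.
superposed_rmsd <- function(P, Q, fit_idx = seq_len(nrow(P))) {
  tr <- kabsch_transform(P[fit_idx, , drop = FALSE],
                         Q[fit_idx, , drop = FALSE])
  Pt <- apply_transform(P, tr)
  sqrt(mean(rowSums((Pt - Q)^2)))
}

#' Core C-alpha RMSD against a native structure
#'
#' Optimal least-squares rigid superposition (Kabsch) of the model onto the
#' native, fitted on the core C-alphas only; returns the RMSD over those
#' same core C-alphas.
#'
#' @param model,native [structure_model()] objects of equal length.
#' @param core Integer vector of 1-based residue indices (at least 3).
#' @return RMSD in angstrom.
#' @export
core_rmsd <- function(model, native,
                      core = seq_len(n_residues(native))) {
  core <- sort(unique(as.integer(core)))
  if (length(core) < 3L) abort("core_rmsd needs at least 3 core residues")
  if (any(core < 1L) || any(core > n_residues(model)) ||
      any(core > n_residues(native))) {
    abort("core index out of range")
  }
  P <- model$ca[core, , drop = FALSE]
  Q <- native$ca[core, , drop = FALSE]
  superposed_rmsd(P, Q)
}

gdt_cutoffs <- c(1, 2, 4, 8)

# Largest fraction of core residues within `cutoff` of native after some
# rigid superposition, found by seeding from contiguous fragments and
# iteratively extending.
gdt_fraction <- function(P, Q, cutoff, seed_lengths = c(3, 5, 7)) {
  k <- nrow(P)
  best <- 0
  seeds <- list(seq_len(k)) # whole-core fit is always tried
  for (len in seed_lengths) {
    if (len > k) next
    for (s in seq_len(k - len + 1L)) {
      seeds[[length(seeds) + 1L]] <- s:(s + len - 1L)
    }
  }
  for (seed in seeds) {
    fit <- seed
    for (iter in 1:32) {
      tr <- kabsch_transform(P[fit, , drop = FALSE], Q[fit, , drop = FALSE])
      d <- sqrt(rowSums((apply_transform(P, tr) - Q)^2))
      incl <- which(d <= cutoff)
      if (length(incl) < 3L) break
      if (length(incl) == length(fit) && all(incl == fit)) break
      fit <- incl
    }
    tr <- kabsch_transform(P[fit, , drop = FALSE], Q[fit, , drop = FALSE])
    d <- sqrt(rowSums((apply_transform(P, tr) - Q)^2))
    best <- max(best, sum(d <= cutoff) / k)
  }
  best
}

#' Core GDT-TS against a native structure
#'
#' Global distance test (total score) over the core C-alphas: the mean,
#' over distance cutoffs 1, 2, 4 and 8 angstrom, of the largest fraction of
#' core residues that can be superposed within the cutoff. The maximum over
#' superpositions is searched by seeding fits from every contiguous core
#' fragment of lengths 3, 5 and 7 (plus the whole core) and iteratively
#' re-fitting on the residues currently within the cutoff until the
#' included set is stable.
#'
#' @inheritParams core_rmsd
#' @param core Integer vector of 1-based residue indices (at least 4).
#' @return GDT-TS in `[0, 1]`.
#' @export
core_gdt_ts <- function(model, native,
                        core = seq_len(n_residues(native))) {
  core <- sort(unique(as.integer(core)))
  if (length(core) < 4L) abort("core_gdt_ts needs at least 4 core residues")
  if (any(core < 1L) || any(core > n_residues(model)) ||
      any(core > n_residues(native))) {
    abort("core index out of range")
  }
  P <- model$ca[core, , drop = FALSE]
  Q <- native$ca[core, , drop = FALSE]
  mean(vapply(gdt_cutoffs, function(cf) gdt_fraction(P, Q, cf), numeric(1)))
}

# Exhaustive-subset GDT oracle: for every core subset of size >= 3, fit on
# the subset and count residues within each cutoff; the per-cutoff maximum
# over subsets bounds any superposition-search heuristic from above.
# Exponential; restricted to small cores.
core_gdt_ts_exhaustive <- function(model, native,
                                   core = seq_len(n_residues(native))) {
  core <- sort(unique(as.integer(core)))
  P <- model$ca[core, , drop = FALSE]
  Q <- native$ca[core, , drop = FALSE]
  k <- nrow(P)
  if (k > 14L) abort("exhaustive GDT oracle limited to 14 residues")
  best <- numeric(length(gdt_cutoffs))
  bits <- bitwShiftL(1L, 0:(k - 1L))
  for (mask in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(mask, bits) != 0L)
    if (length(idx) < 3L) next
    tr <- kabsch_transform(P, Q, fit_idx = idx)
    d <- sqrt(rowSums((apply_transform(P, tr) - Q)^2))
    best <- pmax(best, vapply(gdt_cutoffs,
                              function(cf) sum(d <= cf) / k, numeric(1)))
  }
  mean(best)
}

# Random rigid transform helper (uniform rotation via QR of a Gaussian
# matrix, translation ~ N(0, shift^2)).
random_rigid_transform <- function(X, shift = 20) {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(X %*% R, 2, rnorm(3, sd = shift), `+`)
}
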