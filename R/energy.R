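# Pairwise residue interaction energies with an attractive/repulsive split.
#
# The order/disorder free energy only requires a pairwise-decomposable
# interaction energy E_ij; the backend here is a coarse 12-6 potential on
# per-residue interaction centers with residue-type radii. Externally
# computed pair tables (e.g. from a full molecular-mechanics score) can be
# injected through load_interaction_matrix() and flow through every
# downstream operation unchanged.

# Per-residue interaction sphere radii (angstrom), a coarse side-chain-size
# ladder anchored at GLY = 2.0 and TRP = 3.4.
DEFAULT_RADII <- c(
  G = 2.0, A = 2.3, S = 2.4, C = 2.5, P = 2.6, T = 2.6, D = 2.6,
  V = 2.7, N = 2.7, E = 2.8, I = 2.9, L = 2.9, Q = 2.9,
  M = 3.0, H = 3.0, K = 3.0, F = 3.2, R = 3.2, Y = 3.3, W = 3.4
)

#' Energy backend parameters
#'
#' Parameters of the coarse 12-6 pair potential: per-residue sphere radii,
#' well depth, a cap on the per-pair repulsive energy (bounding the r -> 0
#' singularity so searches stay numerically stable), and a distance cutoff.
#' `min_radius` is the smallest radius in the set; it is the radius used for
#' residues placed under repulsive-only masking (see
#' [masked_energy_reduced()]).
#'
#' @param radius_by_aa Named numeric vector mapping one-letter codes to
#'   radii (angstrom).
#' @param well_depth Depth of the 12-6 well (energy units), `epsilon`.
#' @param rep_cap Maximum per-pair repulsive energy.
#' @param cutoff Distance (angstrom) beyond which a pair contributes 0.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(radius_by_aa = DEFAULT_RADII, well_depth = 3.0,
                          rep_cap = 10.0, cutoff = 12.0) {
  if (any(radius_by_aa <= 0)) abort("all radii must be positive")
  if (cutoff <= 2 * max(radius_by_aa)) {
    abort("cutoff must exceed twice the largest radius")
  }
  structure(
    list(radius_by_aa = radius_by_aa, well_depth = well_depth,
         rep_cap = rep_cap, cutoff = cutoff,
         min_radius = min(radius_by_aa)),
    class = "energy_params"
  )
}

new_interaction_matrix <- function(e_attr, e_rep) {
  n <- nrow(e_attr)
  structure(list(n = n, e_attr = e_attr, e_rep = e_rep),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> n = ", x$n,
      ", sum attractive = ", format(sum(x$e_attr) / 2, digits = 4),
      ", sum repulsive = ", format(sum(x$e_rep) / 2, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Validate an interaction matrix
#'
#' Checks symmetry, zero diagonal, the bonded-neighbor exclusion
#' (`|i - j| <= 1` pairs are zero) and the sign constraints (`e_attr <= 0`,
#' `e_rep >= 0`).
#'
#' @param m An `interaction_matrix`.
#' @return `m` invisibly; aborts on violation.
#' @export
validate_interaction_matrix <- function(m) {
  stopifnot(inherits(m, "interaction_matrix"))
  n <- m$n
  for (ch in c("e_attr", "e_rep")) {
    x <- m[[ch]]
    if (!isTRUE(all.equal(x, t(x), tolerance = 1e-9))) {
      abort(paste0(ch, " is not symmetric"))
    }
    if (any(abs(diag(x)) > 0)) abort(paste0(ch, " has nonzero diagonal"))
    if (n > 1L) {
      band <- abs(row(x) - col(x)) == 1L
      if (any(abs(x[band]) > 0)) {
        abort(paste0(ch, " has nonzero bonded-neighbor entries"))
      }
    }
  }
  if (any(m$e_attr > 1e-12)) abort("e_attr must be <= 0 elementwise")
  if (any(m$e_rep < -1e-12)) abort("e_rep must be >= 0 elementwise")
  invisible(m)
}

pair_radii <- function(aa, params) {
  r <- params$radius_by_aa[aa]
  if (any(is.na(r))) {
    abort(paste0("no radius for residue type(s): ",
                 paste(unique(aa[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

compute_matrix_impl <- function(centers, radii, params) {
  n <- nrow(centers)
  r <- as.matrix(dist(centers))
  sigma <- outer(radii, radii, `+`)
  x6 <- (sigma / pmax(r, 1e-9))^6
  term <- params$well_depth * (x6^2 - 2 * x6)
  term[r > params$cutoff] <- 0
  diag(term) <- 0
  if (n > 1L) term[abs(row(term) - col(term)) <= 1L] <- 0
  e_rep <- pmin(pmax(term, 0), params$rep_cap)
  e_attr <- pmin(term, 0)
  new_interaction_matrix(e_attr, e_rep)
}

#' Compute the pairwise interaction matrix of a model
#'
#' For every residue pair with `|i - j| > 1`, evaluates the 12-6 potential
#' `epsilon * ((sigma/r)^12 - 2 (sigma/r)^6)` on the interaction-center
#' distance `r`, with `sigma` the sum of the two residue radii. The positive
#' part (capped at `rep_cap`) goes to the repulsive channel, the negative
#' part to the attractive channel; pairs beyond `cutoff` are zero.
#'
#' @param model A [structure_model()].
#' @param params An [energy_params()] object.
#' @return An `interaction_matrix` with components `n`, `e_attr`
#'   (symmetric, `<= 0`), `e_rep` (symmetric, `>= 0`).
#' @export
compute_interaction_matrix <- function(model, params = energy_params()) {
  stopifnot(inherits(model, "structure_model"))
  compute_matrix_impl(model$center, pair_radii(model$aa, params), params)
}

#' Load an interaction matrix from a pair-table file
#'
#' Whitespace-delimited lines `i j e_attr e_rep` with 1-based indices;
#' `#`-prefixed lines are comments. Missing pairs are zero; entries are
#' mirrored to enforce symmetry. Signs are validated (`e_attr <= 0`,
#' `e_rep >= 0`), as are the diagonal/bonded exclusions.
#'
#' @param path Path to the pair table.
#' @param n Residue count of the target chain.
#' @return An `interaction_matrix`.
#' @export
load_interaction_matrix <- function(path, n) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  e_attr <- matrix(0, n, n)
  e_rep <- matrix(0, n, n)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\\s+")[[1]]
    if (length(f) != 4L) {
      abort(sprintf("pair-table line %d: expected 4 fields, got %d",
                    k, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) abort(sprintf("pair-table line %d: non-numeric field", k))
    i <- as.integer(v[1]); j <- as.integer(v[2])
    if (i < 1L || i > n || j < 1L || j > n) {
      abort(sprintf("pair-table line %d: index out of range 1..%d", k, n))
    }
    if (abs(i - j) <= 1L) {
      abort(sprintf("pair-table line %d: pair (%d,%d) is diagonal/bonded",
                    k, i, j))
    }
    if (v[3] > 0) abort(sprintf("pair-table line %d: e_attr > 0", k))
    if (v[4] < 0) abort(sprintf("pair-table line %d: e_rep < 0", k))
    e_attr[i, j] <- e_attr[j, i] <- v[3]
    e_rep[i, j] <- e_rep[j, i] <- v[4]
  }
  new_interaction_matrix(e_attr, e_rep)
}

#' Total energy with repulsive-only masking of designated residues
#'
#' Sums pair energies over all unordered pairs. Pairs with neither endpoint
#' in `mask` contribute their full energy `e_attr + e_rep`; pairs with
#' either endpoint masked — including masked-masked pairs — contribute only
#' `e_rep`. This is the re-scoring treatment of pre-designated disordered
#' residues: they cannot gain favorable energy by packing against the core
#' (or against each other) but still pay for steric clashes.
#'
#' @param m An `interaction_matrix`.
#' @param mask Integer vector of 1-based residue indices to treat as
#'   repulsive-only; may be empty.
#' @return Total energy (scalar).
#' @export
masked_energy <- function(m, mask = integer()) {
  stopifnot(inherits(m, "interaction_matrix"))
  mask <- as.integer(mask)
  if (length(mask) > 0L && (any(mask < 1L) || any(mask > m$n))) {
    abort("mask index out of range")
  }
  keep <- setdiff(seq_len(m$n), mask)
  attr_sum <- sum(m$e_attr[keep, keep]) / 2
  rep_sum <- sum(m$e_rep) / 2
  attr_sum + rep_sum
}

#' Repulsive-only masked energy with glycine-like reduction
#'
#' Like [compute_interaction_matrix()] followed by [masked_energy()], but
#' masked residues are first reduced to minimal spheres: their interaction
#' center is moved to the C-alpha and their radius replaced by
#' `params$min_radius` (the smallest radius in the set) before pair terms
#' are computed. Unmasked-unmasked pairs are unchanged. For clash-free
#' conformations of the masked segments the result depends only on the
#' unmasked coordinates.
#'
#' @param model A [structure_model()].
#' @param mask Integer vector of 1-based residue indices.
#' @param params An [energy_params()] object.
#' @return Total energy (scalar).
#' @export
masked_energy_reduced <- function(model, mask = integer(),
                                  params = energy_params()) {
  stopifnot(inherits(model, "structure_model"))
  mask <- as.integer(mask)
  n <- n_residues(model)
  if (length(mask) > 0L && (any(mask < 1L) || any(mask > n))) {
    abort("mask index out of range")
  }
  centers <- model$center
  radii <- pair_radii(model$aa, params)
  if (length(mask) > 0L) {
    centers[mask, ] <- model$ca[mask, , drop = FALSE]
    radii[mask] <- params$min_radius
  }
  m <- compute_matrix_impl(centers, radii, params)
  masked_energy(m, mask)
}
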