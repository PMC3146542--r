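# Synthetic decoy ensembles with planted order/disorder ground truth.
#
# Geometry is deliberately coarse: a compact self-avoiding C-alpha walk for
# the rigid core (3.8 angstrom virtual bonds, hard-sphere rejection),
# outward random-walk tails, and circular-arc internal loops that bulge out
# of the core with a per-model random tilt. Only the contact and deviation
# statistics matter to the methods under test; there is no Ramachandran
# realism and no side-chain placement (interaction centers are C-alphas).
# Disordered residues are glycine, ordered residues alanine, so the energy
# backend keys on realistic small radii.

#' Specification of a synthetic ensemble
#'
#' @param n_core Residue count of the compact core block (includes the
#'   positions carved out by `loops`).
#' @param n_tail_n,n_tail_c Lengths of the disordered N- and C-terminal
#'   tails (0 for none).
#' @param loops List of `c(start, length)` pairs: internal disordered
#'   stretches, indexed on the full chain, strictly inside the core block
#'   (at least one ordered residue on each side).
#' @param n_models Number of models in the ensemble.
#' @param core_noise Gaussian jitter (angstrom, sd) applied to core
#'   coordinates per model.
#' @param tail_amplitude Scale (angstrom) of the per-model re-sampling of
#'   disordered segments; controls the spread of tails and loop tilts.
#' @param collapse_fraction Fraction of models whose disordered segments
#'   are steered to pack against the core surface rather than flail free.
#' @param seed RNG seed (mandatory; generation is deterministic given it).
#' @param min_loop_len Minimum admissible internal loop length.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_core, n_tail_n = 0L, n_tail_c = 0L,
                           loops = list(), n_models = 20L,
                           core_noise = 0.3, tail_amplitude = 6.0,
                           collapse_fraction = 0, seed,
                           min_loop_len = 4L) {
  if (missing(seed)) abort("synthetic_spec requires an explicit seed")
  n_core <- as.integer(n_core)
  n_tail_n <- as.integer(n_tail_n)
  n_tail_c <- as.integer(n_tail_c)
  n <- n_tail_n + n_core + n_tail_c
  if (n_core < 8L) abort("n_core must be at least 8")
  if (n_models < 1L) abort("n_models must be >= 1")
  if (collapse_fraction < 0 || collapse_fraction > 1) {
    abort("collapse_fraction must lie in [0, 1]")
  }
  loops <- lapply(loops, function(l) as.integer(l[1:2]))
  for (l in loops) {
    s <- l[1]; len <- l[2]
    if (len < min_loop_len) {
      abort(sprintf("loop at %d shorter than min_loop_len = %d", s, min_loop_len))
    }
    if (s <= n_tail_n + 1L || s + len - 1L >= n_tail_n + n_core) {
      abort(sprintf(
        "loop at %d must lie strictly inside the core block (%d..%d)",
        s, n_tail_n + 2L, n_tail_n + n_core - 1L))
    }
  }
  if (length(loops) > 1L) {
    ss <- vapply(loops, `[`, integer(1), 1)
    ee <- ss + vapply(loops, `[`, integer(1), 2) - 1L
    o <- order(ss)
    if (any(ss[o][-1] <= ee[o][-length(o)] + 1L)) {
      abort("loops must be separated by at least one ordered residue")
    }
  }
  structure(
    list(n = n, n_core = n_core, n_tail_n = n_tail_n, n_tail_c = n_tail_c,
         loops = loops, n_models = as.integer(n_models),
         core_noise = core_noise, tail_amplitude = tail_amplitude,
         collapse_fraction = collapse_fraction, seed = as.integer(seed),
         min_loop_len = as.integer(min_loop_len)),
    class = "synthetic_spec"
  )
}

unitize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}

min_dist_to <- function(p, X) {
  if (is.null(X) || nrow(X) == 0L) return(Inf)
  sqrt(min(rowSums(sweep(X, 2, p)^2)))
}

# Compact self-avoiding walk: `n` points, 3.8 A bonds, pairwise non-bonded
# separation >= min_sep, confined to a sphere sized for compactness.
# Rows listed in `surface_rows` (tail anchors, loop anchors) must land in
# the outer shell of the walk, so segments grown from them can escape.
compact_saw <- function(n, bond = 3.8, min_sep = 4.7, surface_rows = 1L,
                        max_restarts = 500L) {
  r0 <- 3.2 * n^(1 / 3)
  for (restart in seq_len(max_restarts)) {
    X <- matrix(NA_real_, n, 3)
    # start at the confinement surface so the chain's first residue (a tail
    # anchor downstream) stays solvent-exposed
    X[1, ] <- c(0.85 * r0, 0, 0)
    dir_prev <- unitize(c(-1, 0, 0) + 0.8 * rnorm(3))
    i <- 2L
    fail <- FALSE
    while (i <= n) {
      placed <- FALSE
      for (try in 1:60) {
        pull <- 0.6 + 2.5 * max(0, (sqrt(sum(X[i - 1L, ]^2)) - 0.75 * r0) / r0)
        dir <- unitize(0.5 * dir_prev - pull * unitize(X[i - 1L, ]) +
                         rnorm(3))
        p <- X[i - 1L, ] + bond * dir
        prior <- if (i > 2L) X[seq_len(i - 2L), , drop = FALSE] else NULL
        if (min_dist_to(p, prior) >= min_sep &&
            sqrt(sum(p^2)) <= 1.25 * r0) {
          X[i, ] <- p
          dir_prev <- dir
          placed <- TRUE
          break
        }
      }
      if (!placed) { fail <- TRUE; break }
      i <- i + 1L
    }
    if (!fail) {
      cen <- colMeans(X)
      dc <- sqrt(rowSums(sweep(X, 2, cen)^2))
      if (all(dc[surface_rows] >= stats::median(dc))) return(X)
    }
  }
  abort("generation error: compact core walk failed after bounded retries")
}

# Random-walk tail grown from `anchor`: free mode keeps >= free_sep from
# the core; collapsed mode hugs the core at per-step target distances drawn
# from `band`.
sample_tail <- function(anchor, outward, L, core, collapsed,
                        wobble = 1.0, free_sep = 5.6, self_sep = 4.8,
                        band = c(3.6, 4.6), bond = 3.8,
                        max_restarts = 120L) {
  # the anchor itself is the tail's bonded neighbor, not a clash partner
  core <- core[sqrt(rowSums(sweep(core, 2, anchor)^2)) > 1e-6, , drop = FALSE]
  for (restart in seq_len(max_restarts)) {
    # if the anchor environment is too crowded for the full clearance,
    # relax it stepwise rather than fail outright
    sep_now <- if (restart <= 40L) free_sep else
      if (restart <= 80L) free_sep - 0.4 else free_sep - 0.8
    X <- matrix(NA_real_, L, 3)
    p_prev <- anchor
    dir_prev <- outward
    ok <- TRUE
    for (i in seq_len(L)) {
      tight <- collapsed && i <= 3L
      target <- if (collapsed) {
        if (tight) 3.7 else runif(1, band[1], band[2])
      } else NA_real_
      best <- NULL
      for (try in 1:80) {
        dir <- unitize(0.45 * dir_prev +
                         (if (collapsed) 0 else 0.8) * outward +
                         wobble * rnorm(3))
        p <- p_prev + bond * dir
        prior <- if (i > 2L) X[seq_len(i - 2L), , drop = FALSE] else NULL
        d_core <- min_dist_to(p, core)
        d_self <- min_dist_to(p, prior)
        if (d_self < self_sep) next
        if (collapsed) {
          if (d_core < 3.55) next
          if (tight && d_core > 3.80) next
          score <- abs(d_core - target)
          if (is.null(best) || score < best$score) best <- list(p = p, dir = dir, score = score)
        } else {
          if (d_core < sep_now) next
          best <- list(p = p, dir = dir, score = 0)
          break
        }
      }
      if (is.null(best)) { ok <- FALSE; break }
      X[i, ] <- best$p
      p_prev <- best$p
      dir_prev <- best$dir
    }
    if (ok) return(X)
  }
  abort("generation error: tail segment failed after bounded retries")
}

rodrigues <- function(v, axis, theta) {
  k <- unitize(axis)
  v * cos(theta) + pracma_cross(k, v) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Circular-arc loop of L interior residues between anchors p0 and p1,
# bulging along unit vector `w` (must not be parallel to the chord).
arc_loop <- function(p0, p1, L, w, bond_target = 3.6) {
  chord <- p1 - p0
  d <- sqrt(sum(chord^2))
  S <- max((L + 1) * bond_target, 1.05 * d)
  if (d > (L + 1) * 4.9) {
    abort("generation error: loop anchors too far apart for loop length")
  }
  e1 <- unitize(chord)
  w <- unitize(w - sum(w * e1) * e1)
  # arc half-angle: sin(a) / a = d / S
  ratio <- d / S
  f <- function(a) sin(a) / a - ratio
  a <- stats::uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-10)$root
  R <- S / (2 * a)
  mid <- (p0 + p1) / 2
  # center placement valid for minor and major arcs alike: the apex
  # O + R*w then sits at height R*(1 - cos(a)) above the chord, along +w
  O <- mid - R * cos(a) * w
  u0 <- p0 - O
  axis <- pracma_cross(e1, w) # plane normal
  # rotation by 2a about `axis` must carry p0 to p1; fix the sign
  endp <- O + rodrigues(u0, axis, 2 * a)
  if (sum((endp - p1)^2) > sum((O + rodrigues(u0, axis, -2 * a) - p1)^2)) {
    axis <- -axis
  }
  t(vapply(seq_len(L), function(i) {
    O + rodrigues(u0, axis, 2 * a * i / (L + 1))
  }, numeric(3)))
}

sample_loop <- function(p0, p1, L, core, centroid, tilt_sd, collapsed,
                        jitter = 0.3, max_restarts = 300L) {
  outward <- unitize((p0 + p1) / 2 - centroid)
  chord_axis <- unitize(p1 - p0)
  # the anchors and their immediate shells are chain neighbors of the loop,
  # not clash partners
  d0 <- sqrt(rowSums(sweep(core, 2, p0)^2))
  d1 <- sqrt(rowSums(sweep(core, 2, p1)^2))
  core <- core[d0 > 4.2 & d1 > 4.2, , drop = FALSE]
  for (restart in seq_len(max_restarts)) {
    min_core <- if (collapsed) 3.55 else
      c(5.2, 4.6, 4.0)[min(3, 1 + (restart - 1) %/% 100)]
    # after the first rounds, explore the full azimuth and lobe sizes
    psi <- if (restart <= 30L) rnorm(1, 0, tilt_sd) else runif(1, -pi, pi)
    bt <- 3.6 + 0.35 * ((restart %/% 15) %% 3)
    w <- rodrigues(outward, chord_axis, psi)
    X <- arc_loop(p0, p1, L, w, bond_target = bt)
    X <- X + matrix(rnorm(3 * L, 0, jitter), L, 3)
    dmins <- apply(X, 1, function(p) min_dist_to(p, core))
    if (all(dmins >= min_core)) return(X)
  }
  abort("generation error: loop segment failed after bounded retries")
}

#' Generate a synthetic decoy ensemble with planted disorder
#'
#' Builds a native structure (compact self-avoiding core plus clash-free
#' tails) and an ensemble of models sharing the core up to `core_noise`
#' jitter while re-sampling every disordered segment per model: tails as
#' outward random walks, internal loops as outward-bulging arcs with a
#' random per-model tilt, both with per-residue spread well above the 2
#' angstrom disorder threshold. In `collapse_fraction` of the models the
#' disordered segments are instead steered against the core surface,
#' creating the pathological attractive contacts that repulsive-only
#' masking is designed to neutralize.
#'
#' @param spec A [synthetic_spec()].
#' @return List with components `ensemble` (an [ensemble()]),
#'   `ground_truth` (logical, `TRUE` = planted disordered), `native` (a
#'   [structure_model()]) and `collapsed` (logical per model).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    # a draw can exhaust its per-segment retry budgets on unlucky geometry;
    # re-drawing the whole construct advances the (seed-determined) stream,
    # so the result is still a pure function of the seed
    last <- NULL
    for (attempt in 1:10) {
      out <- tryCatch(generate_ensemble_impl(spec), error = identity)
      if (!inherits(out, "error")) return(out)
      last <- out
    }
    stop(last)
  })
}

# per-model Gaussian jitter on the ordered core, redrawn until no
# sequence-adjacent bond leaves the (2, 5) angstrom window
jittered_core <- function(native_ca, ordered_core, sd, max_tries = 50L) {
  adj <- which(diff(ordered_core) == 1L)
  for (t in seq_len(max_tries)) {
    X <- native_ca[ordered_core, , drop = FALSE] +
      matrix(rnorm(3 * length(ordered_core), 0, sd), length(ordered_core), 3)
    if (length(adj) == 0L) return(X)
    d <- sqrt(rowSums((X[adj + 1L, , drop = FALSE] -
                         X[adj, , drop = FALSE])^2))
    if (all(d > 2.1 & d < 4.9)) return(X)
  }
  abort("generation error: core jitter failed bond constraints")
}

generate_ensemble_impl <- function(spec) {
  n <- spec$n
  core_block <- (spec$n_tail_n + 1L):(spec$n_tail_n + spec$n_core)
  loop_idx <- integer()
  for (l in spec$loops) loop_idx <- c(loop_idx, l[1]:(l[1] + l[2] - 1L))
  tail_idx <- c(seq_len(spec$n_tail_n),
                if (spec$n_tail_c > 0L) (n - spec$n_tail_c + 1L):n else integer())
  ground_truth <- seq_len(n) %in% c(loop_idx, tail_idx)
  ordered_core <- setdiff(core_block, loop_idx)

  # the compact walk covers the *ordered* core only; a disordered internal
  # loop becomes an outward lobe bridging its two anchors, which the walk
  # places as sequence-adjacent surface residues
  m <- length(ordered_core)
  surface_rows <- integer()
  if (spec$n_tail_n > 0L) surface_rows <- c(surface_rows, 1L)
  if (spec$n_tail_c > 0L) surface_rows <- c(surface_rows, m)
  for (l in spec$loops) {
    surface_rows <- c(surface_rows, match(l[1] - 1L, ordered_core),
                      match(l[1] + l[2], ordered_core))
  }
  if (length(surface_rows) == 0L) surface_rows <- 1L

  core_saw <- compact_saw(m, surface_rows = unique(surface_rows))
  native_ca <- matrix(NA_real_, n, 3)
  native_ca[ordered_core, ] <- core_saw
  centroid <- colMeans(core_saw)
  tilt_sd <- spec$tail_amplitude / 12

  core_for_clash <- native_ca[ordered_core, , drop = FALSE]
  for (l in spec$loops) {
    s <- l[1]; len <- l[2]
    native_ca[s:(s + len - 1L), ] <- sample_loop(
      native_ca[s - 1L, ], native_ca[s + len, ], len, core_for_clash,
      centroid, tilt_sd = tilt_sd, collapsed = FALSE)
  }
  if (spec$n_tail_n > 0L) {
    anchor <- native_ca[spec$n_tail_n + 1L, ]
    tail <- sample_tail(anchor, unitize(anchor - centroid), spec$n_tail_n,
                        core_for_clash, collapsed = FALSE,
                        wobble = spec$tail_amplitude / 6)
    native_ca[spec$n_tail_n:1L, ] <- tail
  }
  if (spec$n_tail_c > 0L) {
    anchor <- native_ca[n - spec$n_tail_c, ]
    tail <- sample_tail(anchor, unitize(anchor - centroid), spec$n_tail_c,
                        core_for_clash, collapsed = FALSE,
                        wobble = spec$tail_amplitude / 6)
    native_ca[(n - spec$n_tail_c + 1L):n, ] <- tail
  }

  aa <- ifelse(ground_truth, "G", "A")
  native <- structure_model(aa, native_ca, model_id = "native")

  n_collapsed <- round(spec$collapse_fraction * spec$n_models)
  collapsed <- seq_len(spec$n_models) <= n_collapsed

  models <- vector("list", spec$n_models)
  for (k in seq_len(spec$n_models)) {
    ca <- matrix(NA_real_, n, 3)
    ca[ordered_core, ] <- jittered_core(native_ca, ordered_core,
                                        spec$core_noise)
    core_k <- ca[ordered_core, , drop = FALSE]
    for (l in spec$loops) {
      s <- l[1]; len <- l[2]
      ca[s:(s + len - 1L), ] <- sample_loop(
        ca[s - 1L, ], ca[s + len, ], len, core_k, centroid,
        tilt_sd = tilt_sd, collapsed = collapsed[k])
    }
    if (spec$n_tail_n > 0L) {
      anchor <- ca[spec$n_tail_n + 1L, ]
      tail <- sample_tail(anchor, unitize(anchor - centroid), spec$n_tail_n,
                          core_k, collapsed = collapsed[k],
                          wobble = spec$tail_amplitude / 6)
      ca[spec$n_tail_n:1L, ] <- tail
    }
    if (spec$n_tail_c > 0L) {
      anchor <- ca[n - spec$n_tail_c, ]
      tail <- sample_tail(anchor, unitize(anchor - centroid), spec$n_tail_c,
                          core_k, collapsed = collapsed[k],
                          wobble = spec$tail_amplitude / 6)
      ca[(n - spec$n_tail_c + 1L):n, ] <- tail
    }
    models[[k]] <- structure_model(aa, ca, model_id = as.character(k))
  }
  list(ensemble = ensemble(models), ground_truth = ground_truth,
       native = native, collapsed = collapsed)
}

#' Generate a coordinate-free planted interaction matrix
#'
#' Builds an attractive-channel pair matrix where pairs inside the ordered
#' complement get `attr_core` and pairs touching the planted disordered set
#' get `attr_disordered` (both `<= 0`, with small multiplicative jitter).
#' Useful as a fixture with known optimal assignment for search-algorithm
#' tests.
#'
#' @param n Residue count.
#' @param planted_disordered Integer vector of planted disordered indices.
#' @param attr_core,attr_disordered Attractive energies (`<= 0`).
#' @param jitter Relative jitter amplitude (uniform, default 0.05).
#' @param seed RNG seed.
#' @return An `interaction_matrix` (pure attractive channel).
#' @export
generate_pair_matrix <- function(n, planted_disordered = integer(),
                                 attr_core = -5, attr_disordered = 0,
                                 jitter = 0.05, seed) {
  if (missing(seed)) abort("generate_pair_matrix requires an explicit seed")
  if (attr_core > 0 || attr_disordered > 0) {
    abort("attractive energies must be <= 0")
  }
  planted_disordered <- as.integer(planted_disordered)
  withr::with_seed(seed, {
    e_attr <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i + 1L) next
        base <- if (i %in% planted_disordered || j %in% planted_disordered) {
          attr_disordered
        } else attr_core
        e_attr[i, j] <- e_attr[j, i] <- base * (1 + runif(1, -jitter, jitter))
      }
    }
    new_interaction_matrix(e_attr, matrix(0, n, n))
  })
}
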