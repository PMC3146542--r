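# Scoring disorder predictions against reference disorder, and the
# parameter scan.

#' Reference disorder from an NMR-style ensemble
#'
#' Superposes every model onto the medoid model (the one with the smallest
#' summed all-C-alpha RMSD to the others) by least-squares rigid fit over
#' all C-alphas, then computes each residue's root-mean-square deviation
#' from its per-residue ensemble mean position. Residues whose deviation
#' exceeds `threshold` are labeled disordered.
#'
#' @param e An [ensemble()] with at least 2 models.
#' @param threshold Deviation threshold in angstrom (default 2.0).
#' @return A `reference_disorder`: list with logical `disordered`, numeric
#'   `deviation` (angstrom), `threshold` and `source =
#'   "ensemble-deviation"`.
#' @export
reference_from_ensemble <- function(e, threshold = 2.0) {
  stopifnot(inherits(e, "ensemble"))
  k <- length(e$models)
  if (k < 2L) abort("reference_from_ensemble needs at least 2 models")
  cas <- lapply(e$models, `[[`, "ca")
  rmsd_mat <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      rmsd_mat[i, j] <- rmsd_mat[j, i] <- superposed_rmsd(cas[[i]], cas[[j]])
    }
  }
  medoid <- which.min(rowSums(rmsd_mat))
  ref <- cas[[medoid]]
  n <- nrow(ref)
  # iterative trimmed fit: start from an all-C-alpha superposition, then
  # refit on the residues currently below threshold so that mobile
  # segments cannot drag the rigid frame with them
  fitset <- seq_len(n)
  deviation <- rep(0, n)
  for (iter in 1:10) {
    fitted <- lapply(cas, function(P) {
      apply_transform(P, kabsch_transform(P, ref, fit_idx = fitset))
    })
    arr <- simplify2array(fitted) # n x 3 x k
    mean_pos <- apply(arr, c(1, 2), mean)
    dev2 <- sapply(seq_len(k), function(m) {
      rowSums((arr[, , m] - mean_pos)^2)
    })
    deviation <- sqrt(rowMeans(matrix(dev2, ncol = k)))
    newfit <- which(deviation <= threshold)
    if (length(newfit) < 3L) break
    if (length(newfit) == length(fitset) && all(newfit == fitset)) break
    fitset <- newfit
  }
  new_reference(deviation > threshold, source = "ensemble-deviation",
                threshold = threshold, deviation = deviation)
}

new_reference <- function(disordered, source, threshold = NA_real_,
                          deviation = NULL) {
  structure(
    list(disordered = as.logical(disordered), source = source,
         threshold = threshold, deviation = deviation),
    class = "reference_disorder"
  )
}

#' @export
print.reference_disorder <- function(x, ...) {
  cat("<reference_disorder> ", sum(x$disordered), "/", length(x$disordered),
      " residues disordered (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Reference disorder from a mask
#'
#' @param mask Integer vector of 1-based disordered residue indices, or a
#'   logical vector of length `n`.
#' @param n Chain length.
#' @return A `reference_disorder` with `source = "mask-file"`.
#' @export
reference_from_mask <- function(mask, n) {
  if (is.logical(mask)) {
    if (length(mask) != n) abort("logical mask length must equal n")
    dis <- mask
  } else {
    mask <- as.integer(mask)
    if (length(mask) > 0L && (any(mask < 1L) || any(mask > n))) {
      abort("mask index out of range")
    }
    dis <- seq_len(n) %in% mask
  }
  new_reference(dis, source = "mask-file")
}

#' Read a disorder mask file
#'
#' One 1-based residue index or inclusive range `a-b` per line; `#` starts
#' a comment. This is the interchange dialect for externally predicted
#' disorder (e.g. sequence-based predictors or NMR order parameters).
#'
#' @param path File path.
#' @return Sorted integer vector of disordered residue indices.
#' @export
read_disorder_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  idx <- integer()
  for (k in seq_along(lines)) {
    l <- lines[k]
    if (grepl("^\\d+-\\d+$", l)) {
      ab <- as.integer(strsplit(l, "-")[[1]])
      if (ab[1] > ab[2]) abort(sprintf("mask line %d: empty range %s", k, l))
      idx <- c(idx, ab[1]:ab[2])
    } else if (grepl("^\\d+$", l)) {
      idx <- c(idx, as.integer(l))
    } else {
      abort(sprintf("mask line %d: expected index or range, got '%s'", k, l))
    }
  }
  sort(unique(idx))
}

#' Write a disorder mask file
#'
#' Consecutive indices are collapsed to `a-b` ranges.
#'
#' @param mask Integer vector of disordered residue indices or logical
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder_mask <- function(mask, path) {
  if (is.logical(mask)) mask <- which(mask)
  mask <- sort(unique(as.integer(mask)))
  out <- character()
  if (length(mask) > 0L) {
    brk <- c(0L, which(diff(mask) != 1L), length(mask))
    for (g in seq_len(length(brk) - 1L)) {
      a <- mask[brk[g] + 1L]; b <- mask[brk[g + 1L]]
      out <- c(out, if (a == b) as.character(a) else paste0(a, "-", b))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Prediction-accuracy score of a disorder profile
#'
#' For each residue, `P_i` is the predicted frequency of the state the
#' reference assigns to it (`freq_disordered[i]` if the reference calls it
#' disordered, `1 - freq_disordered[i]` otherwise); the score is the mean
#' of the `P_i`. A prediction matching the reference at frequency extremes
#' scores exactly 1; the inverted prediction scores 0.
#'
#' @param profile A `disorder_profile` (or a numeric frequency vector).
#' @param reference A `reference_disorder` of matching length.
#' @return An `accuracy_score`: list with `score`, `per_residue_P` and `N`.
#' @export
accuracy_score <- function(profile, reference) {
  freq <- if (inherits(profile, "disorder_profile")) {
    profile$freq_disordered
  } else as.numeric(profile)
  stopifnot(inherits(reference, "reference_disorder"))
  if (length(freq) != length(reference$disordered)) {
    abort("profile and reference lengths differ")
  }
  P <- ifelse(reference$disordered, freq, 1 - freq)
  structure(list(score = mean(P), per_residue_P = P, N = length(P)),
            class = "accuracy_score")
}

#' @export
print.accuracy_score <- function(x, ...) {
  cat(sprintf("<accuracy_score> %.4f over %d residues\n", x$score, x$N))
  invisible(x)
}

#' All-ordered null-model score
#'
#' The score of the baseline prediction that declares every residue
#' ordered: the fraction of reference residues that are ordered.
#'
#' @param reference A `reference_disorder`.
#' @return An `accuracy_score`.
#' @export
null_model_score <- function(reference) {
  stopifnot(inherits(reference, "reference_disorder"))
  accuracy_score(rep(0, length(reference$disordered)), reference)
}

#' Tail-length accuracy of a terminal assignment
#'
#' @param predicted A `disorder_assignment` (from [enumerate_terminal()]).
#' @param true_n_tail,true_c_tail True tail lengths.
#' @return Named vector `c(dN, dC)`: predicted minus true tail lengths.
#' @export
tail_length_accuracy <- function(predicted, true_n_tail, true_c_tail) {
  stopifnot(inherits(predicted, "disorder_assignment"))
  tl <- n_tail_lengths(predicted$ordered)
  c(dN = unname(tl["n_tail"]) - as.integer(true_n_tail),
    dC = unname(tl["c_tail"]) - as.integer(true_c_tail))
}

#' Scan free-energy parameters over a benchmark
#'
#' Evaluates a grid of `(E_d, beta, L0)` values on a benchmark of ensembles
#' with known reference disorder. In `"internal"` mode the metric is the
#' mean prediction-accuracy score ([accuracy_score()]) of the greedy-search
#' profile; in `"terminal"` mode it is the mean frequency of exact tail
#' recovery (both predicted tail lengths equal to the reference's).
#'
#' @param benchmark List of entries, each a list with elements `ensemble`
#'   (an [ensemble()]), `reference` (a `reference_disorder`) and optionally
#'   `matrices` (precomputed `interaction_matrix` objects, one per model,
#'   overriding the backend).
#' @param grid List with numeric vectors `E_d`, `beta`, `L0`; the scan runs
#'   over their Cartesian product. Omitted components default to the
#'   standard values.
#' @param mode `"internal"` or `"terminal"`.
#' @param backend An [energy_params()] object.
#' @param base_params An [fe_params()] giving the non-scanned parameters.
#' @return A tibble with columns `E_d`, `beta`, `L0`, `metric`; the best
#'   row (highest metric, first in grid order on ties) is in attribute
#'   `"best"`.
#' @export
scan_parameters <- function(benchmark, grid = list(),
                            mode = c("internal", "terminal"),
                            backend = energy_params(),
                            base_params = fe_params()) {
  mode <- match.arg(mode)
  if (length(benchmark) == 0L) abort("benchmark must be nonempty")
  pts <- expand.grid(
    E_d = if (is.null(grid$E_d)) base_params$E_d else grid$E_d,
    beta = if (is.null(grid$beta)) base_params$beta else grid$beta,
    L0 = if (is.null(grid$L0)) base_params$L0 else grid$L0,
    KEEP.OUT.ATTRS = FALSE
  )
  if (nrow(pts) == 0L) abort("grid must be nonempty")
  # interaction matrices do not depend on the scanned parameters; entries
  # may supply precomputed matrices (e.g. externally loaded pair tables)
  mats <- lapply(benchmark, function(entry) {
    if (!is.null(entry$matrices)) return(entry$matrices)
    lapply(entry$ensemble$models, compute_interaction_matrix, params = backend)
  })
  metric <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    params <- fe_params(E_d = pts$E_d[g], beta = pts$beta[g], L0 = pts$L0[g],
                        min_loop_len = base_params$min_loop_len,
                        block = base_params$block,
                        max_stretches = base_params$max_stretches)
    vals <- vapply(seq_along(benchmark), function(b) {
      entry <- benchmark[[b]]
      if (mode == "internal") {
        prof <- profile_ensemble(entry$ensemble, params,
                                 mode = "internal", matrices = mats[[b]])
        accuracy_score(prof, entry$reference)$score
      } else {
        true_tl <- n_tail_lengths(!entry$reference$disordered)
        hits <- vapply(mats[[b]], function(m) {
          d <- tail_length_accuracy(enumerate_terminal(m, params),
                                    true_tl["n_tail"], true_tl["c_tail"])
          all(d == 0)
        }, logical(1))
        mean(hits)
      }
    }, numeric(1))
    metric[g] <- mean(vals)
  }
  out <- tibble::as_tibble(pts)
  out$metric <- metric
  attr(out, "best") <- out[which.max(metric), ]
  out
}
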