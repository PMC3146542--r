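# Ensemble aggregation: disorder-frequency profiles and the
# entropy/enthalpy compensation table.

#' Disorder-frequency profile of an ensemble
#'
#' Runs the selected search on every model of the ensemble and records, per
#' residue, the fraction of models whose optimal assignment marks it
#' disordered.
#'
#' @param e An [ensemble()].
#' @param params An [fe_params()] object.
#' @param backend An [energy_params()] object used to compute each model's
#'   interaction matrix.
#' @param mode `"terminal"` (exhaustive two-tail enumeration) or
#'   `"internal"` (greedy block-flip search).
#' @param matrices Optional list of precomputed `interaction_matrix`
#'   objects, one per model, overriding the backend.
#' @return A `disorder_profile`: list with `freq_disordered` (length-n
#'   vector in `[0, 1]`), `n_models`, and the per-model
#'   `disorder_assignment`s in `assignments`.
#' @export
profile_ensemble <- function(e, params = fe_params(),
                             backend = energy_params(),
                             mode = c("terminal", "internal"),
                             matrices = NULL) {
  stopifnot(inherits(e, "ensemble"))
  mode <- match.arg(mode)
  if (is.null(matrices)) {
    matrices <- lapply(e$models, compute_interaction_matrix, params = backend)
  }
  search <- switch(mode,
                   terminal = enumerate_terminal,
                   internal = greedy_internal)
  assignments <- lapply(matrices, search, params = params)
  dis <- vapply(assignments, function(a) !a$ordered,
                logical(nchar(e$sequence)))
  dis <- matrix(dis, ncol = length(assignments))
  structure(
    list(freq_disordered = rowMeans(dis),
         n_models = length(assignments),
         assignments = assignments,
         sequence = e$sequence,
         mode = mode),
    class = "disorder_profile"
  )
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("<disorder_profile> ", length(x$freq_disordered), " residues, ",
      x$n_models, " model(s), mode = ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Entropy/enthalpy compensation table
#'
#' Re-evaluates a set of assignments on one interaction matrix and tabulates
#' how the retained interaction energy `E`, the total entropy credit and the
#' free energy `F` trade off as more residues are labeled disordered. Along
#' a search trajectory the entropy credit grows while `E` becomes less
#' favorable, leaving `F` comparatively flat.
#'
#' @param m An `interaction_matrix`.
#' @param params An [fe_params()] object.
#' @param assignments List of `disorder_assignment` objects or logical
#'   ordered vectors (e.g. a greedy trajectory).
#' @return A tibble with columns `n_disordered`, `E`, `entropy_term`
#'   (`tail_term + loop_term`) and `F`, sorted by `n_disordered`; class
#'   `compensation_curve` is prepended for plotting.
#' @export
compensation_curve <- function(m, params = fe_params(), assignments) {
  rows <- purrr::map(assignments, function(a) {
    ordered <- if (inherits(a, "disorder_assignment")) a$ordered else as.logical(a)
    fa <- free_energy(m, ordered, params)
    b <- fa$breakdown
    tibble::tibble(
      n_disordered = sum(!ordered),
      E = b$E,
      entropy_term = b$tail_term + b$loop_term,
      F = b$F
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$n_disordered)
  class(out) <- c("compensation_curve", class(out))
  out
}
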