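# broom-style accessors: tidy() rows per residue, glance() one-row
# summaries.

#' Tabulate an order/disorder assignment
#'
#' @param x A `disorder_assignment`.
#' @param ... Unused.
#' @return Tibble with one row per residue: `residue`, `ordered`, and the
#'   segment class (`"ordered"`, `"tail"` or `"loop"`).
#' @method tidy disorder_assignment
#' @export
tidy.disorder_assignment <- function(x, ...) {
  n <- length(x$ordered)
  segment <- rep("ordered", n)
  runs <- disorder_runs(x$ordered)
  if (length(runs$starts) > 0L) {
    lens <- integer(length(runs$starts))
    lens[runs$is_tail] <- runs$tails
    lens[!runs$is_tail] <- runs$loops
    for (k in seq_along(runs$starts)) {
      idx <- runs$starts[k]:(runs$starts[k] + lens[k] - 1L)
      segment[idx] <- if (runs$is_tail[k]) "tail" else "loop"
    }
  }
  tibble::tibble(residue = seq_len(n), ordered = x$ordered, segment = segment)
}

#' One-row free-energy breakdown of an assignment
#'
#' @param x A `disorder_assignment`.
#' @param ... Unused.
#' @return Tibble with `E`, `tail_term`, `loop_term`, `F`, `n_disordered`,
#'   `n_tail`, `c_tail`.
#' @method glance disorder_assignment
#' @export
glance.disorder_assignment <- function(x, ...) {
  b <- x$breakdown
  tl <- n_tail_lengths(x$ordered)
  tibble::tibble(
    E = b$E, tail_term = b$tail_term, loop_term = b$loop_term, F = b$F,
    n_disordered = sum(!x$ordered),
    n_tail = unname(tl["n_tail"]), c_tail = unname(tl["c_tail"])
  )
}

#' Tabulate a disorder-frequency profile
#'
#' @param x A `disorder_profile`.
#' @param ... Unused.
#' @return Tibble with `residue`, `aa`, `freq_disordered`.
#' @method tidy disorder_profile
#' @export
tidy.disorder_profile <- function(x, ...) {
  tibble::tibble(
    residue = seq_along(x$freq_disordered),
    aa = strsplit(x$sequence, "")[[1]],
    freq_disordered = x$freq_disordered
  )
}

#' @method glance disorder_profile
#' @export
glance.disorder_profile <- function(x, ...) {
  tibble::tibble(
    n_residues = length(x$freq_disordered),
    n_models = x$n_models,
    mode = x$mode,
    mean_freq_disordered = mean(x$freq_disordered)
  )
}

#' Tabulate a reference-disorder object
#'
#' @param x A `reference_disorder`.
#' @param ... Unused.
#' @return Tibble with `residue`, `disordered` and (when ensemble-derived)
#'   `deviation`.
#' @method tidy reference_disorder
#' @export
tidy.reference_disorder <- function(x, ...) {
  out <- tibble::tibble(residue = seq_along(x$disordered),
                        disordered = x$disordered)
  if (!is.null(x$deviation)) out$deviation <- x$deviation
  out
}

#' @method glance accuracy_score
#' @export
glance.accuracy_score <- function(x, ...) {
  tibble::tibble(score = x$score, N = x$N)
}

#' @method tidy accuracy_score
#' @export
tidy.accuracy_score <- function(x, ...) {
  tibble::tibble(residue = seq_len(x$N), P = x$per_residue_P)
}
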