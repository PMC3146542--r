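# ggplot2 views of the main result types.

#' Plot a disorder-frequency profile
#'
#' @param object A `disorder_profile`.
#' @param reference Optional `reference_disorder`; its disordered residues
#'   are shaded.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot disorder_profile
#' @export
autoplot.disorder_profile <- function(object, reference = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                        y = .data$freq_disordered))
  if (!is.null(reference)) {
    ref <- tidy(reference)
    ref$run <- cumsum(c(1, diff(ref$disordered) != 0))
    shade <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(ref, .data$disordered), .data$run),
      xmin = min(.data$residue) - 0.5, xmax = max(.data$residue) + 0.5,
      .groups = "drop")
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
        ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.2,
        inherit.aes = FALSE)
    }
  }
  p +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_point(size = 0.8, color = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "frequency disordered") +
    ggplot2::theme_minimal()
}

#' Plot an entropy/enthalpy compensation curve
#'
#' Shows the retained interaction energy `E`, the (negated) entropy credit
#' and the free energy `F` against the number of disordered residues: `E`
#' rises and the entropy credit grows while `F` stays comparatively flat.
#'
#' @param object A `compensation_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot compensation_curve
#' @export
autoplot.compensation_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_disordered, y = .data$value,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "residues disordered", y = "energy (model units)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble::tibble(n_disordered = df$n_disordered, component = "E",
                   value = df$E),
    tibble::tibble(n_disordered = df$n_disordered,
                   component = "-entropy credit",
                   value = -df$entropy_term),
    tibble::tibble(n_disordered = df$n_disordered, component = "F",
                   value = df$F)
  )
}
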