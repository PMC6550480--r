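#' Plot a packing curve
#'
#' Effective-to-bulk diffusivity ratio against packing fraction.  Passing
#' several curves (e.g. the aggregate sweep and the monomer model) overlays
#' them for the discriminability comparison.
#'
#' @param object A `packing_curve`.
#' @param ... Further `packing_curve`s to overlay.
#' @return A ggplot object.
#' @method autoplot packing_curve
#' @export
autoplot.packing_curve <- function(object, ...) {
  extras <- Filter(function(x) inherits(x, "packing_curve"), list(...))
  df <- dplyr::bind_rows(lapply(c(list(object), extras), as.data.frame))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_realized, y = .data$de_ratio,
                                   colour = .data$model,
                                   linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "packing fraction f",
                  y = expression(D[e] / D[bulk]),
                  colour = "model", linetype = "model") +
    ggplot2::theme_minimal()
}

#' Plot a mid-domain concentration slice
#'
#' Heat map of the steady-state concentration on the x-y plane through the
#' domain mid-depth, showing the reservoir-film-reservoir profile and the
#' funnelling of the field into the pores.
#'
#' @param object A [solve_steady_state()] result.
#' @param slice z-index of the lateral slice (default: mid-depth).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concentration_field
#' @export
autoplot.concentration_field <- function(object, slice = NULL, ...) {
  dom <- object$dom
  k <- slice %||% max(1L, dom$nz %/% 2L)
  m <- object$c[, , k]
  df <- tibble::tibble(
    x = rep((seq_len(dom$nx) - 0.5) * dom$h, times = dom$ny),
    y = rep((seq_len(dom$ny) - 0.5) * dom$h, each = dom$nx),
    c = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm, transport axis)", y = "y (nm)",
                  fill = "c") +
    ggplot2::theme_minimal()
}

#' Plot a rejection profile against Stokes radius
#'
#' Per-solute rejection with the MWCO threshold line; the standard way to
#' read off a membrane's cut-off from the probe series.
#'
#' @param records Data frame with `stokes_radius` and `rejection_pct`
#'   columns (e.g. from [generate_rejection_profile()]).
#' @param threshold Threshold percent drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_rejection_profile <- function(records, threshold = 90) {
  records <- tibble::as_tibble(records)
  ggplot2::ggplot(records, ggplot2::aes(.data$stokes_radius,
                                        .data$rejection_pct)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Stokes radius (nm)", y = "rejection (%)") +
    ggplot2::theme_minimal()
}
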