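circle_polygons <- function(patches, n_vertices = 60) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)
  purrr::map_dfr(seq_len(nrow(patches)), function(i) {
    tibble::tibble(
      id = patches$id[i], cohort = patches$cohort[i],
      px = patches$x[i] + patches$diameter[i] / 2 * cos(th),
      py = patches$y[i] + patches$diameter[i] / 2 * sin(th)
    )
  })
}

#' Map of a disc patch pattern
#'
#' Draws the patch discs to scale inside the window, colored by cohort.
#' Tiny patches can be inflated to a minimum drawing diameter so the
#' youngest cohort stays visible.
#'
#' @param patches A patch table.
#' @param window A [rect_window()].
#' @param min_draw_diameter Smallest rendered diameter (m, display only).
#' @return A ggplot object.
#' @export
plot_patches <- function(patches, window, min_draw_diameter = 0) {
  window <- as_rect_window(window)
  shown <- dplyr::mutate(
    patches, diameter = pmax(.data$diameter, min_draw_diameter)
  )
  ggplot2::ggplot(circle_polygons(shown)) +
    ggplot2::geom_polygon(
      ggplot2::aes(.data$px, .data$py, group = .data$id, fill = .data$cohort),
      colour = NA
    ) +
    ggplot2::annotate("rect", xmin = window$x_min, xmax = window$x_max,
                      ymin = window$y_min, ymax = window$y_max,
                      fill = NA, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "cohort") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.patch_sumfun <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$reliable),
                  ggplot2::aes(.data$r, .data$value)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "patch-edge distance r (m)",
                  y = if (identical(attr(object, "kind"), "pccf")) "g12(r)" else "g(r)") +
    ggplot2::theme_minimal()
}

#' Plot a simulation envelope
#'
#' `style = "envelope"` overlays the observed summary function on the
#' pointwise min/max band of the null simulations. `style = "delta"` plots
#' the envelope bounds minus the observed function, so the band straddling
#' zero shows where (and by how much) the observed function escapes the
#' null; this is the conventional presentation when several cohorts are
#' compared side by side.
#'
#' @param object A [build_envelope()] result.
#' @param style `"envelope"` (default) or `"delta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.patch_envelope <- function(object, style = c("envelope", "delta"), ...) {
  style <- match.arg(style)
  df <- dplyr::filter(tidy(object), .data$reliable)
  ylab <- if (identical(object$kind, "pccf")) "g12(r)" else "g(r)"
  if (style == "envelope") {
    ggplot2::ggplot(df, ggplot2::aes(.data$r)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           fill = "grey80") +
      ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
      ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
      ggplot2::labs(x = "patch-edge distance r (m)", y = ylab) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$r)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$lo - .data$observed,
                     ymax = .data$hi - .data$observed),
        fill = "grey80"
      ) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::labs(x = "patch-edge distance r (m)",
                    y = paste0("delta ", ylab)) +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.intensity_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "intensity (m^-2)") +
    ggplot2::theme_minimal()
}
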