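#' Rectangular study window
#'
#' Constructs the rectangular observation window (in meters) inside which all
#' patch discs must lie. Real study sites are rarely perfect rectangles; the
#' package supports rectangles only and treats them as an approximation of the
#' true site boundary (see the methods vignette).
#'
#' @param x_min,y_min,x_max,y_max Window corners in meters, `x_max > x_min`,
#'   `y_max > y_min`. Conventionally the origin sits at the lower-left corner.
#' @return An object of class `rect_window` with fields `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @examples
#' w <- rect_window(0, 0, 125, 250)
#' window_area(w)
#' @export
rect_window <- function(x_min = 0, y_min = 0, x_max, y_max) {
  vals <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (!all(is.finite(vals))) {
    abort("window coordinates must be finite numbers")
  }
  if (x_max <= x_min || y_max <= y_min) {
    abort("window must satisfy x_max > x_min and y_max > y_min")
  }
  structure(
    list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
    class = "rect_window"
  )
}

#' @export
print.rect_window <- function(x, ...) {
  cat(sprintf(
    "<rect_window> [%g, %g] x [%g, %g]  (%g m x %g m, area %g m^2)\n",
    x$x_min, x$x_max, x$y_min, x$y_max,
    window_width(x), window_height(x), window_area(x)
  ))
  invisible(x)
}

#' @rdname rect_window
#' @param window A `rect_window`.
#' @export
window_area <- function(window) {
  window_width(window) * window_height(window)
}

#' @rdname rect_window
#' @export
window_width <- function(window) window$x_max - window$x_min

#' @rdname rect_window
#' @export
window_height <- function(window) window$y_max - window$y_min

as_rect_window <- function(x) {
  if (inherits(x, "rect_window")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    return(rect_window(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  abort("`window` must be a rect_window or a numeric vector (x_min, y_min, x_max, y_max)")
}
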