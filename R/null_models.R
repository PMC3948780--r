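#' Null model configuration
#'
#' Parameters shared by the two constrained Monte Carlo null models.
#'
#' @param kernel_sd Standard deviation (m) of the isotropic 2-D Gaussian
#'   kernel defining the heterogeneous Poisson intensity of the bivariate
#'   null (default 5 m: low enough to retain large-scale cohort clusters in
#'   the null, high enough not to absorb short-range interaction).
#' @param lattice_step Evaluation lattice step (m) for the intensity surface
#'   (default 0.5).
#' @param max_attempts Placement attempts per patch before the whole
#'   simulation restarts (default 10000).
#' @param max_restarts Full restarts before giving up (default 100).
#' @return A list of class `null_config`.
#' @export
null_config <- function(kernel_sd = 5, lattice_step = 0.5,
                        max_attempts = 10000, max_restarts = 100) {
  stopifnot(kernel_sd > 0, lattice_step > 0, max_attempts >= 1, max_restarts >= 1)
  structure(
    list(kernel_sd = kernel_sd, lattice_step = lattice_step,
         max_attempts = max_attempts, max_restarts = max_restarts),
    class = "null_config"
  )
}

# Shared placement engine: places discs with the given diameters (largest
# first, ties by id) under containment + non-overlap constraints, optionally
# with lattice-weighted proposals. Returns a patch table in placement order.
place_patches <- function(template, window, fixed = NULL, config = null_config(),
                          surface = NULL) {
  window <- as_rect_window(window)
  n <- nrow(template)
  ord <- order(-template$diameter, template$id)
  template <- template[ord, , drop = FALSE]
  if (is.null(fixed) || !nrow(fixed)) {
    fx <- fy <- fr <- numeric(0)
  } else {
    fx <- fixed$x; fy <- fixed$y; fr <- fixed$diameter / 2
  }
  if (is.null(surface)) {
    weights <- numeric(0); nx <- ny <- 0L; sx <- sy <- 0
  } else {
    weights <- surface$value
    if (!any(weights > 0)) abort("intensity surface is zero everywhere")
    nx <- attr(surface, "nx"); ny <- attr(surface, "ny")
    sx <- attr(surface, "step_x"); sy <- attr(surface, "step_y")
  }
  for (restart in seq_len(config$max_restarts)) {
    res <- cpp_place_discs(
      template$diameter / 2, window$x_min, window$y_min, window$x_max, window$y_max,
      fx, fy, fr, config$max_attempts, weights, nx, ny, sx, sy
    )
    if (nrow(res) == n && n > 0) {
      out <- template
      out$x <- res[, 1]
      out$y <- res[, 2]
      return(out)
    }
    if (n == 0) return(template)
    failed <- -res[1, 1]
  }
  abort(sprintf(
    "packing infeasible: patch id %d (diameter %.3g m) could not be placed after %d attempts x %d restarts",
    template$id[failed], template$diameter[failed], config$max_attempts, config$max_restarts
  ))
}

#' Univariate null model: constrained homogeneous randomization
#'
#' Relocates the patches of one cohort (same count, same diameters) to
#' i.i.d.-uniform centroids inside the window, subject to whole-disc
#' containment, non-overlap among the randomized patches, and non-overlap
#' with the patches of older cohorts, which stay where they were observed.
#' Patches are placed one at a time from largest to smallest (ties broken by
#' patch id); a patch that cannot be placed within `max_attempts` triggers a
#' full restart. Conditioning on the observed count (a binomial process
#' rather than a Poisson one) matches the relocation reading of the
#' randomization and is standard for envelope tests. This null detects
#' within-cohort clustering beyond what hard-core packing imposes.
#'
#' @param cohort Patch table of the cohort to randomize.
#' @param fixed Patch table of patches kept fixed (typically all older
#'   cohorts); may be `NULL`.
#' @param window A [rect_window()].
#' @param config A [null_config()].
#' @return A patch table with the same ids and diameters, new centroids.
#' @export
simulate_univariate_null <- function(cohort, fixed = NULL, window,
                                     config = null_config()) {
  place_patches(cohort, window, fixed = fixed, config = config)
}

#' Gaussian-kernel intensity surface
#'
#' Sum of isotropic bivariate Gaussian kernels (SD `kernel_sd`) centered at
#' the given centroids, evaluated at the cell centers of a regular lattice
#' tiling the window. No boundary renormalization is applied: the same
#' uncorrected surface is used for sampling, so envelopes built from it are
#' internally consistent. The lattice integral is therefore at most the
#' number of centroids.
#'
#' @param centroids A data frame with columns `x`, `y` (>= 1 row).
#' @param window A [rect_window()].
#' @param kernel_sd Gaussian SD (m).
#' @param lattice_step Target cell size (m); cells are stretched minimally so
#'   the lattice tiles the window exactly.
#' @return A tibble of class `intensity_surface` with columns `x`, `y`
#'   (cell centers) and `value` (intensity, m^-2), plus lattice attributes.
#' @export
estimate_intensity <- function(centroids, window, kernel_sd = 5,
                               lattice_step = 0.5) {
  window <- as_rect_window(window)
  if (!nrow(centroids)) abort("need at least one centroid")
  stopifnot(kernel_sd > 0, lattice_step > 0)
  w <- window_width(window); h <- window_height(window)
  nx <- max(1L, round(w / lattice_step))
  ny <- max(1L, round(h / lattice_step))
  sx <- w / nx; sy <- h / ny
  gx <- window$x_min + (seq_len(nx) - 0.5) * sx
  gy <- window$y_min + (seq_len(ny) - 0.5) * sy
  m <- cpp_gauss_kde(centroids$x, centroids$y, gx, gy, kernel_sd)
  out <- tibble::tibble(
    x = rep(gx, times = ny),
    y = rep(gy, each = nx),
    value = as.vector(m) # column-major: x fastest, matching rep() above
  )
  attr(out, "nx") <- nx; attr(out, "ny") <- ny
  attr(out, "step_x") <- sx; attr(out, "step_y") <- sy
  attr(out, "window") <- window
  attr(out, "kernel_sd") <- kernel_sd
  class(out) <- c("intensity_surface", class(out))
  out
}

#' Total mass of an intensity surface
#'
#' Lattice integral `sum(value) * cell_area`; for kernels far from the window
#' edge each centroid contributes ~1.
#'
#' @param surface An [estimate_intensity()] result.
#' @return Numeric scalar.
#' @export
intensity_mass <- function(surface) {
  sum(surface$value) * attr(surface, "step_x") * attr(surface, "step_y")
}

#' Bivariate null model: density-preserving heterogeneous randomization
#'
#' Randomizes one (non-large-adult) cohort according to a heterogeneous
#' Poisson process whose intensity is the Gaussian kernel density
#' ([estimate_intensity()]) of the cohort's observed centroids, conditioned
#' on the observed count and diameters, whole-disc containment, and
#' non-overlap with the conditioning patches (older cohorts) and previously
#' placed patches. Because large-scale cohort clusters are preserved in the
#' null, excursions of the cross-correlation function against large adults
#' isolate short-range attraction/repulsion rather than shared large-scale
#' structure. Proposals are drawn by lattice-cell sampling proportional to
#' intensity with uniform jitter within the cell; placement order is largest
#' first as in the univariate null.
#'
#' @param cohort Patch table of the cohort to randomize.
#' @param conditioning Patch table of patches kept fixed (by default in the
#'   pipeline: all cohorts older than `cohort`); may be `NULL`.
#' @param window A [rect_window()].
#' @param config A [null_config()].
#' @param surface Optional precomputed [estimate_intensity()] surface of the
#'   observed cohort centroids (recomputed otherwise; pass it when running
#'   many simulations of the same cohort).
#' @return A patch table with the same ids and diameters, new centroids.
#' @export
simulate_bivariate_null <- function(cohort, conditioning = NULL, window,
                                    config = null_config(), surface = NULL) {
  if (!nrow(cohort)) abort("`cohort` must contain at least one patch")
  if (is.null(surface)) {
    surface <- estimate_intensity(cohort, window,
                                  kernel_sd = config$kernel_sd,
                                  lattice_step = config$lattice_step)
  }
  place_patches(cohort, window, fixed = conditioning, config = config,
                surface = surface)
}
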