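#' Cohort labels in increasing age (= increasing patch size) order
#'
#' Shrub cohorts are proxied by equivalent-circle canopy diameter classes:
#' unbranched individuals (`UI`), branched juveniles (`J_B`), small adults
#' (`A_S`), medium adults (`A_M`) and large adults (`A_L`).
#'
#' @return Character vector of the five cohort labels, youngest first.
#' @export
cohort_levels <- function() c("UI", "J_B", "A_S", "A_M", "A_L")

#' Classify patch diameters into cohorts
#'
#' Maps an equivalent-circle diameter (meters) onto one of the five cohort
#' labels using half-open intervals `[lower, upper)`:
#' `(0, 0.25)` UI, `[0.25, 0.50)` J_B, `[0.50, 1.00)` A_S, `[1.00, 2.00)` A_M,
#' `[2.00, Inf)` A_L. The half-open convention makes the classification total
#' on (0, Inf): every positive diameter maps to exactly one cohort.
#'
#' @param diameter Numeric vector of positive diameters (m).
#' @param thresholds Strictly increasing class boundaries (m); default
#'   `c(0.25, 0.50, 1.00, 2.00)`.
#' @return A factor with levels [cohort_levels()].
#' @examples
#' classify_cohort(c(0.10, 0.30, 4.2))
#' @export
classify_cohort <- function(diameter, thresholds = c(0.25, 0.50, 1.00, 2.00)) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be 4 strictly increasing diameters")
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    abort("`diameter` must be positive and finite")
  }
  idx <- findInterval(diameter, thresholds) + 1L # [lower, upper) intervals
  factor(cohort_levels()[idx], levels = cohort_levels())
}

#' Assemble and validate a patch table
#'
#' A patch table is a tibble with one row per vegetation patch and columns
#' `id` (stable integer identifier), `x`, `y` (centroid, m), `diameter`
#' (equivalent-circle diameter, m) and `cohort`. `patch_table()` fills in
#' missing `id`/`cohort` columns and validates geometry: positive diameters,
#' whole-disc containment in `window`, and (optionally) global non-overlap,
#' i.e. minimum pairwise patch-edge distance >= 0.
#'
#' @param patches A data frame with at least `x`, `y`, `diameter`.
#' @param window A [rect_window()].
#' @param thresholds Cohort boundaries passed to [classify_cohort()].
#' @param check_overlap Validate global non-overlap (default `TRUE`).
#' @param tol Numeric tolerance for containment/overlap checks.
#' @return A validated tibble with columns `id`, `x`, `y`, `diameter`, `cohort`.
#' @export
patch_table <- function(patches, window, thresholds = c(0.25, 0.50, 1.00, 2.00),
                        check_overlap = TRUE, tol = 1e-9) {
  window <- as_rect_window(window)
  need <- c("x", "y", "diameter")
  missing <- setdiff(need, names(patches))
  if (length(missing)) {
    abort(paste0("patch table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  patches <- tibble::as_tibble(patches)
  if (!"id" %in% names(patches)) {
    patches$id <- seq_len(nrow(patches))
  }
  patches$id <- as.integer(patches$id)
  if (anyDuplicated(patches$id)) abort("duplicated patch id in table")
  if (nrow(patches) && any(!is.finite(patches$diameter) | patches$diameter <= 0)) {
    bad <- which(!is.finite(patches$diameter) | patches$diameter <= 0)
    abort(paste0("non-positive diameter in row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  if (!"cohort" %in% names(patches)) {
    patches$cohort <- if (nrow(patches)) classify_cohort(patches$diameter, thresholds) else
      factor(character(), levels = cohort_levels())
  } else {
    patches$cohort <- factor(as.character(patches$cohort), levels = cohort_levels())
    if (anyNA(patches$cohort)) abort("unknown cohort label in patch table")
  }
  patches <- dplyr::select(patches, "id", "x", "y", "diameter", "cohort")
  validate_patches(patches, window, check_overlap = check_overlap, tol = tol)
  patches
}

#' Validate patch geometry against a window
#'
#' Checks whole-disc containment of every patch in `window` and, when
#' `check_overlap = TRUE`, that no two discs overlap (minimum pairwise
#' patch-edge distance >= 0). Errors with the offending patch ids.
#'
#' @inheritParams patch_table
#' @return `patches`, invisibly.
#' @export
validate_patches <- function(patches, window, check_overlap = TRUE, tol = 1e-9) {
  window <- as_rect_window(window)
  if (!nrow(patches)) return(invisible(patches))
  r <- patches$diameter / 2
  outside <- patches$x - r < window$x_min - tol | patches$x + r > window$x_max + tol |
    patches$y - r < window$y_min - tol | patches$y + r > window$y_max + tol
  if (any(outside)) {
    abort(paste0(
      "patch disc(s) not wholly inside the window, id(s): ",
      paste(head(patches$id[outside], 5), collapse = ", ")
    ))
  }
  if (check_overlap && nrow(patches) > 1) {
    m <- cpp_min_edge_each(patches$x, patches$y, r)
    if (min(m) < -tol) {
      abort(paste0(
        "overlapping patch disc(s), id(s): ",
        paste(head(patches$id[m < -tol], 6), collapse = ", ")
      ))
    }
  }
  invisible(patches)
}

#' Shortest distance between patch edges
#'
#' The patch-edge distance between two discs is the centroid distance minus
#' both radii: `||c1 - c2|| - d1/2 - d2/2`. It is symmetric, zero for tangent
#' discs and negative when discs overlap. All second-order statistics in this
#' package use patch-edge distances as the abscissa instead of centroid
#' distances, so that patch extent is accounted for.
#'
#' @param x1,y1,d1 Centroid coordinates and diameter of the first patch (m).
#'   Vectorized.
#' @param x2,y2,d2 Same for the second patch.
#' @return Numeric vector of edge distances (m).
#' @examples
#' edge_distance(0, 0, 2, 5, 0, 4) # centers 5 m apart, radii 1 and 2 -> 2
#' @export
edge_distance <- function(x1, y1, d1, x2, y2, d2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2) - d1 / 2 - d2 / 2
}

#' Per-patch isolation status
#'
#' A patch is isolated when its canopy touches no other canopy, i.e. its
#' patch-edge distance to every other patch is strictly positive. Isolated
#' unbranched individuals are the pattern signature of density-type seed
#' limitation or small-scale allogenic habitat patchiness.
#'
#' @param patches A patch table (all cohorts pooled).
#' @param id Optional single patch id; when given, returns one logical and
#'   errors if the id is absent from `patches`.
#' @return Logical vector (one per row of `patches`), or a single logical when
#'   `id` is supplied.
#' @export
is_isolated <- function(patches, id = NULL) {
  n <- nrow(patches)
  iso <- if (n <= 1) rep(TRUE, n) else
    cpp_min_edge_each(patches$x, patches$y, patches$diameter / 2) > 0
  if (is.null(id)) return(iso)
  pos <- match(id, patches$id)
  if (is.na(pos)) abort(paste0("patch id ", id, " not found in `patches`"))
  iso[pos]
}

#' Fractional vegetation cover
#'
#' Total disc area divided by window area. Because validated patches are
#' pairwise disjoint discs fully inside the window, the plain sum of
#' `pi * (diameter/2)^2` is the exact covered area.
#'
#' @param patches A patch table (any subset of cohorts).
#' @param window A [rect_window()].
#' @param validate Re-check containment before summing (default `TRUE`).
#' @return Cover fraction in `[0, 1]`.
#' @examples
#' w <- rect_window(0, 0, 10, 10)
#' p <- patch_table(data.frame(x = 5, y = 5, diameter = 2), w)
#' fvc(p, w) # pi / 100
#' @export
fvc <- function(patches, window, validate = TRUE) {
  window <- as_rect_window(window)
  if (validate) validate_patches(patches, window, check_overlap = FALSE)
  sum(pi * (patches$diameter / 2)^2) / window_area(window)
}

#' Patch density per hectare
#'
#' @param n Number of patches.
#' @param area_ha Site area in hectares.
#' @return Patches per hectare.
#' @examples
#' patches_per_ha(1056, 2.86)
#' @export
patches_per_ha <- function(n, area_ha) {
  if (area_ha <= 0) abort("`area_ha` must be positive")
  n / area_ha
}

#' Summarize a multi-cohort patch pattern
#'
#' Per-cohort and total patch counts, fractional vegetation cover, and density
#' per hectare for a validated patch table.
#'
#' @param patches A patch table.
#' @param window A [rect_window()].
#' @return A tibble with one row per cohort plus a `total` row, columns
#'   `cohort`, `n`, `fvc`, `density_ha`.
#' @export
pattern_summary <- function(patches, window) {
  window <- as_rect_window(window)
  area_ha <- window_area(window) / 1e4
  per <- patches |>
    dplyr::group_by(.data$cohort, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      fvc = sum(pi * (.data$diameter / 2)^2) / window_area(window),
      .groups = "drop"
    ) |>
    dplyr::mutate(cohort = as.character(.data$cohort))
  out <- dplyr::bind_rows(
    per,
    tibble::tibble(cohort = "total", n = nrow(patches), fvc = fvc(patches, window, validate = FALSE))
  )
  dplyr::mutate(out, density_ha = patches_per_ha(.data$n, area_ha))
}
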