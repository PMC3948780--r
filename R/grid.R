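#' Build a square-plot sampling grid
#'
#' Lays a regular lattice of axis-aligned square plots of side `side` over the
#' window, anchored at the window's lower-left corner plus `origin_offset`.
#' Only cells that fall entirely inside the window are retained, mirroring
#' field practice of discarding boundary plots. Cells are half-open
#' `[x, x + side) x [y, y + side)` so every point belongs to at most one plot.
#'
#' @param window A [rect_window()].
#' @param side Plot side length (m), `0 < side`.
#' @param origin_offset Length-2 numeric `(dx, dy)` shifting the lattice
#'   anchor; the plot side is unchanged. Default `c(0, 0)`.
#' @return A tibble of retained plots with columns `plot_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`; attribute `side` records the side length. Zero rows
#'   (with a warning) when the side exceeds a window dimension.
#' @examples
#' build_grid(rect_window(0, 0, 42, 42), side = 21) # 2 x 2 tiling
#' @export
build_grid <- function(window, side, origin_offset = c(0, 0)) {
  window <- as_rect_window(window)
  if (!is.numeric(side) || length(side) != 1 || side <= 0) {
    abort("`side` must be a single positive number")
  }
  x0 <- window$x_min + origin_offset[[1]]
  y0 <- window$y_min + origin_offset[[2]]
  xs <- seq(x0, window$x_max, by = side)
  ys <- seq(y0, window$y_max, by = side)
  cells <- tidyr::expand_grid(x_min = xs, y_min = ys) |>
    dplyr::mutate(x_max = .data$x_min + side, y_max = .data$y_min + side) |>
    dplyr::filter(
      .data$x_min >= window$x_min, .data$y_min >= window$y_min,
      .data$x_max <= window$x_max, .data$y_max <= window$y_max
    ) |>
    dplyr::arrange(.data$y_min, .data$x_min) |>
    dplyr::mutate(plot_id = dplyr::row_number(), .before = 1)
  if (!nrow(cells)) {
    warn("plot side exceeds the window dimensions: empty grid")
  }
  attr(cells, "side") <- side
  cells
}

#' Per-plot cohort statistics
#'
#' Assigns each patch to the plot containing its centroid (half-open cells)
#' and tabulates, per plot and cohort, the patch count, the density
#' (count / side^2) and the fractional vegetation cover. Each disc's full area
#' is attributed to its centroid's plot rather than clipped at cell borders:
#' the attribution error is negligible when the plot side is much larger than
#' the largest patch diameter. Patches whose centroid lies in no retained plot
#' are ignored.
#'
#' @param patches A patch table.
#' @param grid A grid from [build_grid()].
#' @return A long tibble with columns `plot_id`, `cohort`, `n`, `density`,
#'   `fvc`; every retained plot appears for every cohort level.
#' @export
plot_stats <- function(patches, grid) {
  if (!nrow(grid)) abort("`grid` has no plots")
  side <- attr(grid, "side")
  assigned <- patches |>
    dplyr::mutate(plot_id = assign_plot(.data$x, .data$y, grid)) |>
    dplyr::filter(!is.na(.data$plot_id))
  counts <- assigned |>
    dplyr::group_by(.data$plot_id, .data$cohort, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      area = sum(pi * (.data$diameter / 2)^2),
      .groups = "drop"
    )
  tidyr::expand_grid(
    plot_id = grid$plot_id,
    cohort = factor(cohort_levels(), levels = cohort_levels())
  ) |>
    dplyr::left_join(counts, by = c("plot_id", "cohort")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      density = .data$n / side^2,
      fvc = dplyr::coalesce(.data$area, 0) / side^2
    ) |>
    dplyr::select("plot_id", "cohort", "n", "density", "fvc")
}

# plot_id containing each centroid (NA when in no retained cell); half-open cells
assign_plot <- function(x, y, grid) {
  if (!length(x)) return(integer(0))
  hit <- rep(NA_integer_, length(x))
  for (k in seq_len(nrow(grid))) {
    inside <- x >= grid$x_min[k] & x < grid$x_max[k] &
      y >= grid$y_min[k] & y < grid$y_max[k]
    hit[inside] <- grid$plot_id[k]
  }
  hit
}

# Pearson (or rank) correlation with two-sided p; NA-safe zero-variance guard
cor_result <- function(a, b, method = "pearson", alpha = 0.05) {
  n <- length(a)
  if (n < 3 || sd(a) == 0 || sd(b) == 0) {
    return(tibble::tibble(
      r = NA_real_, p_value = NA_real_, n_plots = n,
      significant = FALSE, degenerate = TRUE
    ))
  }
  ct <- cor.test(a, b, method = method, exact = FALSE)
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value, n_plots = n,
    significant = is.finite(ct$p.value) && ct$p.value < alpha,
    degenerate = FALSE
  )
}

#' Distance seed-limitation test (Corr1)
#'
#' Under distance seed limitation, recruits are confined to parent seed
#' shadows, so per-plot adult cover should predict per-plot recruit density.
#' The test correlates adult fractional vegetation cover with unbranched
#' individual (UI) density across square plots at two plot sizes (defaults:
#' five and ten times the largest observed patch diameter, reflecting
#' uncertainty in seed-shadow extent). The hypothesis is supported when at
#' least one correlation is significantly *positive* at `alpha`: seed shadows
#' can only produce a positive cover-density association, and the hard-core
#' geometry of non-overlapping patches by itself induces a weak negative one
#' (plots rich in adult cover mechanically exclude recruits), so a
#' significant negative correlation is evidence against distance seed
#' limitation, never for it.
#'
#' @param patches A patch table with all cohorts.
#' @param window A [rect_window()].
#' @param sides Plot side lengths (m); default `c(5, 10) * max(diameter)`.
#' @param alpha Significance level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `sl_test`: `verdict` (`"supported"`/`"rejected"`),
#'   `results` (per-side tibble), `alpha`. Degenerate (zero-variance)
#'   correlations are flagged and never count as significant.
#' @export
distance_sl_test <- function(patches, window,
                             sides = c(5, 10) * max(patches$diameter),
                             alpha = 0.05, method = "pearson") {
  window <- as_rect_window(window)
  adult_levels <- c("A_S", "A_M", "A_L")
  res <- purrr::map_dfr(sides, function(side) {
    grid <- build_grid(window, side)
    if (nrow(grid) < 3) {
      return(tibble::tibble(
        side = side, r = NA_real_, p_value = NA_real_,
        n_plots = nrow(grid), significant = FALSE, degenerate = TRUE
      ))
    }
    stats <- plot_stats(patches, grid)
    adult_fvc <- stats |>
      dplyr::filter(.data$cohort %in% adult_levels) |>
      dplyr::group_by(.data$plot_id) |>
      dplyr::summarise(v = sum(.data$fvc), .groups = "drop")
    ui_density <- stats |>
      dplyr::filter(.data$cohort == "UI") |>
      dplyr::select("plot_id", v = "density")
    joined <- dplyr::inner_join(adult_fvc, ui_density, by = "plot_id")
    dplyr::bind_cols(tibble::tibble(side = side),
                     cor_result(joined$v.x, joined$v.y, method, alpha))
  })
  positive <- res$significant & !is.na(res$r) & res$r > 0
  verdict <- if (any(positive)) "supported" else "rejected"
  structure(list(verdict = verdict, results = res, alpha = alpha),
            class = "sl_test")
}

#' @export
print.sl_test <- function(x, ...) {
  cat("Distance seed-limitation test:", x$verdict,
      sprintf("(alpha = %g)\n", x$alpha))
  print(x$results)
  invisible(x)
}

#' Pairwise cohort density correlations
#'
#' Correlates per-plot patch densities between every pair of the five cohorts
#' on a single square-plot grid (conventionally the smaller, 5 x largest-
#' diameter grid). Returns the lower triangle of the 5 x 5 correlation matrix
#' as a tidy table of 10 pairs. Raw p-values are reported; an optional Holm
#' correction can be applied.
#'
#' @param patches A patch table with all cohorts.
#' @param grid A grid from [build_grid()].
#' @param alpha Significance level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param p_adjust `"none"` (default, raw p-values) or `"holm"`.
#' @return A tibble with columns `cohort_a`, `cohort_b` (a older than b),
#'   `r`, `p_value`, `n_plots`, `significant`, `degenerate`.
#' @export
cohort_density_correlations <- function(patches, grid, alpha = 0.05,
                                        method = "pearson",
                                        p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stats <- plot_stats(patches, grid)
  wide <- stats |>
    dplyr::select("plot_id", "cohort", "density") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "density")
  lv <- cohort_levels()
  pairs <- tidyr::expand_grid(i = seq_along(lv), j = seq_along(lv)) |>
    dplyr::filter(.data$i < .data$j)
  out <- purrr::map2_dfr(pairs$i, pairs$j, function(i, j) {
    dplyr::bind_cols(
      tibble::tibble(cohort_a = lv[i], cohort_b = lv[j]),
      cor_result(wide[[lv[i]]], wide[[lv[j]]], method, alpha)
    )
  })
  if (p_adjust == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$significant <- !out$degenerate & !is.na(out$p_value) & out$p_value < alpha
  }
  out
}

#' Static versus dynamic large-scale habitat patchiness (Corr2)
#'
#' Static large-scale allogenic habitat patchiness forces successive cohorts
#' into the same habitat patches, producing many significant between-cohort
#' density correlations; dynamic patchiness (habitat patches that move over
#' time) produces few. The verdict is `"dynamic"` when fewer than `threshold`
#' of the 10 cohort pairs correlate significantly, `"static"` otherwise. The
#' threshold default (5, i.e. a majority rule over 10 pairs) operationalizes a
#' qualitative criterion and is exposed for sensitivity analysis.
#'
#' @param corr A correlation table from [cohort_density_correlations()].
#' @param threshold Minimum number of significant pairs for a `"static"`
#'   verdict (default 5).
#' @return A list of class `corr2_test`: `verdict`, `n_significant`,
#'   `significant_pairs` (tibble), `threshold`.
#' @export
static_vs_dynamic <- function(corr, threshold = 5) {
  if (nrow(corr) != 10) {
    abort("`corr` must contain the 10 cohort pairs")
  }
  sig <- dplyr::filter(corr, .data$significant)
  structure(
    list(
      verdict = if (nrow(sig) < threshold) "dynamic" else "static",
      n_significant = nrow(sig),
      significant_pairs = dplyr::select(sig, "cohort_a", "cohort_b", "r", "p_value"),
      threshold = threshold
    ),
    class = "corr2_test"
  )
}

#' @export
print.corr2_test <- function(x, ...) {
  cat(sprintf(
    "Large-scale habitat patchiness: %s (%d of 10 cohort pairs significant; static when >= %d)\n",
    x$verdict, x$n_significant, x$threshold
  ))
  if (nrow(x$significant_pairs)) print(x$significant_pairs)
  invisible(x)
}
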