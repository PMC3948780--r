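#' Build a simulation envelope
#'
#' Runs `simulate_fn` `n_sims` times (each call must return a summary
#' function, e.g. [pcf_edge()] of a null-model pattern, on the same `r` grid
#' as `observed`) and records the pointwise minimum, maximum and mean of the
#' simulated functions alongside the observed one. With `n_sims = 499` the
#' min/max band is the conventional reference for detecting candidate
#' deviating distance intervals; their significance must then be assessed
#' with [gof_test()] on an independent second batch.
#'
#' @param observed A `patch_sumfun` (the observed summary function).
#' @param simulate_fn A function of no arguments returning a summary function
#'   (data frame with columns `r`, `value`) on the same grid.
#' @param n_sims Number of simulations (default 499).
#' @return An object of class `patch_envelope` with fields `r`, `observed`,
#'   `lo`, `hi`, `mean`, `sims` (matrix, one column per simulation),
#'   `reliable`, `n_sims`, `kind`.
#' @export
build_envelope <- function(observed, simulate_fn, n_sims = 499) {
  if (n_sims < 1) abort("`n_sims` must be >= 1")
  r <- observed$r
  sims <- matrix(NA_real_, nrow = length(r), ncol = n_sims)
  for (i in seq_len(n_sims)) {
    s <- simulate_fn()
    if (!isTRUE(all.equal(s$r, r))) {
      abort(sprintf("simulation %d returned a different r grid", i))
    }
    sims[, i] <- s$value
  }
  structure(
    list(
      r = r,
      observed = observed$value,
      lo = apply(sims, 1, min),
      hi = apply(sims, 1, max),
      mean = rowMeans(sims),
      sims = sims,
      reliable = if ("reliable" %in% names(observed)) observed$reliable else rep(TRUE, length(r)),
      n_sims = n_sims,
      kind = attr(observed, "kind") %||% "summary"
    ),
    class = "patch_envelope"
  )
}

#' @export
print.patch_envelope <- function(x, ...) {
  cat(sprintf("<patch_envelope> %s, %d simulations, %d r values on [%g, %g] m\n",
              x$kind, x$n_sims, length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

#' @export
tidy.patch_envelope <- function(x, ...) {
  tibble::tibble(r = x$r, observed = x$observed, lo = x$lo, hi = x$hi,
                 mean = x$mean, reliable = x$reliable)
}

#' @export
glance.patch_envelope <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_sims = x$n_sims, n_r = length(x$r),
                 r_min = min(x$r), r_max = max(x$r))
}

#' Candidate deviating distance intervals
#'
#' Maximal contiguous runs of the distance grid where the observed function
#' falls above the envelope maximum (`sign = "above"`) or below the envelope
#' minimum (`sign = "below"`). Runs shorter than `min_width` grid steps are
#' discarded as single-point noise (default 2; set to 1 for a literal
#' pointwise reading). Grid points with undefined or unreliable values
#' (r below the kernel bandwidth) never enter a run. Intervals are
#' candidates only: their significance must be established by [gof_test()].
#'
#' @param envelope A [build_envelope()] result.
#' @param min_width Minimum run length in grid steps (default 2).
#' @return A tibble with columns `interval_id`, `r_start`, `r_end`, `sign`,
#'   `n_points`; zero rows when the observed function stays inside the band.
#' @export
find_deviation_intervals <- function(envelope, min_width = 2) {
  usable <- envelope$reliable & is.finite(envelope$observed) &
    is.finite(envelope$lo) & is.finite(envelope$hi)
  state <- rep("inside", length(envelope$r))
  state[usable & envelope$observed > envelope$hi] <- "above"
  state[usable & envelope$observed < envelope$lo] <- "below"
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values %in% c("above", "below") & runs$lengths >= min_width
  out <- tibble::tibble(
    r_start = envelope$r[starts[keep]],
    r_end = envelope$r[ends[keep]],
    sign = runs$values[keep],
    n_points = runs$lengths[keep]
  )
  dplyr::mutate(dplyr::arrange(out, .data$r_start),
                interval_id = dplyr::row_number(), .before = 1)
}

# Loosmore-type u statistics for a matrix of functions (rows = grid points in
# the interval, cols = functions): u_j = sum_k (f_j - mean_{-j})^2 * dr with
# the leave-one-out pointwise mean.
gof_u <- function(f, dr) {
  m <- ncol(f)
  s <- rowSums(f)
  dev <- (m * f - s) / (m - 1) # f_j - (s - f_j) / (m - 1)
  colSums(dev^2) * dr
}

#' Rank-based goodness-of-fit test for deviating intervals
#'
#' For each candidate interval, converts the summary-function values of the
#' observed pattern and of each simulation in an independent second batch
#' into the Loosmore-type statistic
#' `u_j = sum_k (f_j(r_k) - fbar_{-j}(r_k))^2 * dr` (leave-one-out pointwise
#' mean, grid-step weighted). The null model is rejected for the interval
#' when the observed `u` ranks among the `k` highest or `k` lowest of all
#' `n_sims + 1` values; with the defaults k = 5 and 499 simulations this is a
#' per-tail level of 5/500 = 0.01 (the two-sided level is 0.02; both ranks
#' are reported). Ties are broken by treating the observed value as the more
#' extreme, avoiding conservatism from exactly tied simulated values.
#'
#' @param intervals A tibble from [find_deviation_intervals()] (possibly
#'   filtered); intervals must lie inside the grid of `envelope2`.
#' @param envelope2 A [build_envelope()] result built from a second,
#'   independent simulation batch (its stored observed function and
#'   simulations are used for the test).
#' @param k Rejection rank (default 5).
#' @return `intervals` augmented with `u_obs`, `rank_high`, `rank_low`,
#'   `p_high`, `p_low` (per-tail rank p-values `rank / (n_sims + 1)`),
#'   `p_two` and `significant`.
#' @export
gof_test <- function(intervals, envelope2, k = 5) {
  n_total <- envelope2$n_sims + 1
  if (k < 1 || k >= n_total) abort("`k` must satisfy 1 <= k < n_sims + 1")
  r <- envelope2$r
  dr <- if (length(r) > 1) stats::median(diff(r)) else 1
  res <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    sel <- r >= intervals$r_start[i] - 1e-9 & r <= intervals$r_end[i] + 1e-9
    sel <- sel & envelope2$reliable & is.finite(envelope2$observed)
    if (!any(sel)) abort("interval lies outside the usable r grid")
    f <- cbind(envelope2$sims[sel, , drop = FALSE], envelope2$observed[sel])
    u <- gof_u(f, dr)
    u_obs <- u[length(u)]
    u_sim <- u[-length(u)]
    rank_high <- 1 + sum(u_sim > u_obs) # ties favour the observed extreme
    rank_low <- 1 + sum(u_sim < u_obs)
    tibble::tibble(
      u_obs = u_obs, rank_high = rank_high, rank_low = rank_low,
      p_high = rank_high / n_total, p_low = rank_low / n_total,
      p_two = min(1, 2 * min(rank_high, rank_low) / n_total),
      significant = rank_high <= k | rank_low <= k
    )
  })
  dplyr::bind_cols(intervals, res)
}

#' Deviation strength of tested intervals
#'
#' A dimensionless score of how strongly the observed function departs from
#' the null over an interval: the mean over the interval's grid points of
#' `|nearest envelope bound - 1| / (hi - lo)`, i.e. proportional to the
#' envelope's displacement from the null line g = 1 and inversely
#' proportional to the envelope's width. Points where the envelope is
#' degenerate (`hi == lo`) are skipped; an interval where the observed
#' function lies inside the envelope scores 0.
#'
#' @param intervals A tibble with `r_start`, `r_end`, `sign` (from
#'   [find_deviation_intervals()] / [gof_test()]).
#' @param envelope The (first, detection) [build_envelope()] result.
#' @return `intervals` with an added `strength` column.
#' @export
deviation_strength <- function(intervals, envelope) {
  r <- envelope$r
  strength <- purrr::map_dbl(seq_len(nrow(intervals)), function(i) {
    sel <- r >= intervals$r_start[i] - 1e-9 & r <= intervals$r_end[i] + 1e-9
    bound <- if (intervals$sign[i] == "above") envelope$hi[sel] else envelope$lo[sel]
    width <- envelope$hi[sel] - envelope$lo[sel]
    outside <- if (intervals$sign[i] == "above") {
      envelope$observed[sel] > envelope$hi[sel]
    } else {
      envelope$observed[sel] < envelope$lo[sel]
    }
    ok <- width > 0 & is.finite(bound) & outside
    if (!any(ok)) return(0)
    mean(abs(bound[ok] - 1) / width[ok])
  })
  dplyr::mutate(intervals, strength = strength)
}

#' Cluster scale from a univariate PCF analysis
#'
#' The diameter of within-cohort clusters is read off the PCF analysis as the
#' upper end `r_end` of the first significant above-envelope interval that
#' starts at (or within `gap` grid steps of) the smallest reliable distance.
#' Returns `NA` when no such interval exists.
#'
#' @param intervals A tested interval table from [gof_test()] for a PCF.
#' @param envelope The matching [build_envelope()] result (for the grid and
#'   reliability flags).
#' @param gap Start tolerance in grid steps (default 1).
#' @return Cluster scale in meters, or `NA_real_`.
#' @export
cluster_scale <- function(intervals, envelope, gap = 1) {
  cand <- dplyr::filter(intervals, .data$sign == "above", .data$significant)
  if (!nrow(cand)) return(NA_real_)
  usable <- envelope$reliable & is.finite(envelope$observed)
  if (!any(usable)) return(NA_real_)
  r0 <- min(envelope$r[usable])
  dr <- if (length(envelope$r) > 1) stats::median(diff(envelope$r)) else 0
  cand <- dplyr::filter(cand, .data$r_start <= r0 + gap * dr + 1e-9) |>
    dplyr::arrange(.data$r_start)
  if (!nrow(cand)) return(NA_real_)
  cand$r_end[1]
}
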