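#' Bimodal patch-size model
#'
#' Two-component lognormal mixture over equivalent-circle diameters. Because
#' log-area is an affine function of log-diameter, a bimodal log-diameter
#' mixture yields the bimodal log-area histogram characteristic of nebkha
#' fields, with the trough between the modes sitting near the boundary
#' between unbranched and branched individuals. Defaults center the
#' components near 0.15 m (unbranched recruits) and 1 m (adults); they are
#' illustrative landscape-generator settings, not estimates of any field
#' data set.
#'
#' @param meanlog,sdlog Length-2 log-scale means and SDs of the diameter
#'   components.
#' @param weight Length-2 mixture weights summing to 1.
#' @return A list of class `size_model`.
#' @export
size_model <- function(meanlog = log(c(0.15, 1.0)), sdlog = c(0.35, 0.35),
                       weight = c(0.5, 0.5)) {
  stopifnot(length(meanlog) == 2, length(sdlog) == 2, all(sdlog > 0),
            length(weight) == 2, all(weight >= 0), abs(sum(weight) - 1) < 1e-8)
  structure(list(meanlog = meanlog, sdlog = sdlog, weight = weight),
            class = "size_model")
}

#' Draw patch diameters from a size model
#'
#' I.i.d. draws from the mixture; when `cohort` is given, draws are rejected
#' until they fall in that cohort's diameter class, so generated cohorts are
#' consistent with [classify_cohort()].
#'
#' @param n Number of diameters.
#' @param model A [size_model()].
#' @param cohort Optional cohort label to condition on.
#' @param thresholds Cohort boundaries (see [classify_cohort()]).
#' @param max_draw Safety cap on rejection rounds.
#' @return Numeric vector of diameters (m).
#' @export
sample_diameters <- function(n, model = size_model(), cohort = NULL,
                             thresholds = c(0.25, 0.50, 1.00, 2.00),
                             max_draw = 1000) {
  draw <- function(m) {
    comp <- 1L + (runif(m) > model$weight[1])
    rlnorm(m, model$meanlog[comp], model$sdlog[comp])
  }
  if (is.null(cohort)) return(draw(n))
  lv <- match(cohort, cohort_levels())
  if (is.na(lv)) abort("unknown cohort label")
  bounds <- c(0, thresholds, Inf)
  lo <- bounds[lv]; hi <- bounds[lv + 1]
  out <- numeric(0)
  for (i in seq_len(max_draw)) {
    d <- draw(max(2 * n, 20))
    out <- c(out, d[d >= lo & d < hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  abort("size model places almost no mass in the requested cohort class")
}

#' Generate a completely spatially random (CSR) cohort
#'
#' Fixed-count binomial process with hard-core non-overlap: centroids are
#' proposed i.i.d. uniform and accepted under whole-disc containment and
#' non-overlap with previously placed and `fixed` patches, using the same
#' placement engine as the null models, so a CSR cohort is exactly a draw
#' from the univariate null.
#'
#' @param window A [rect_window()].
#' @param n Number of patches.
#' @param diameters Optional diameter vector (length `n`); otherwise drawn
#'   from `model` (conditioned on `cohort` when given).
#' @param cohort Optional cohort label for the size draw.
#' @param model A [size_model()].
#' @param fixed Patch table of already-present patches (may be `NULL`).
#' @param config A [null_config()] (placement limits).
#' @param id_start First patch id.
#' @return A patch table of `n` patches.
#' @export
generate_csr_cohort <- function(window, n, diameters = NULL, cohort = NULL,
                                model = size_model(), fixed = NULL,
                                config = null_config(), id_start = 1L) {
  window <- as_rect_window(window)
  if (is.null(diameters)) diameters <- sample_diameters(n, model, cohort)
  stopifnot(length(diameters) == n)
  template <- tibble::tibble(
    id = id_start + seq_len(n) - 1L, x = NA_real_, y = NA_real_,
    diameter = diameters,
    cohort = if (n) classify_cohort(diameters) else factor(character(), levels = cohort_levels())
  )
  out <- place_patches(template, window, fixed = fixed, config = config)
  dplyr::arrange(out, .data$id)
}

#' Generate a Thomas cluster-process cohort
#'
#' Poisson cluster process: parents are Poisson with intensity `kappa` on the
#' window dilated by `dilation` (so clusters straddling the boundary are
#' represented and the process restricted to the window is stationary),
#' offspring counts are Poisson(`mu`) per parent, and offspring are displaced
#' from their parent by isotropic Gaussian jumps with SD `sigma`. Offspring
#' whose centroid falls outside the window are discarded; an offspring whose
#' disc cannot be contained or overlaps existing vegetation has its
#' displacement redrawn up to `config$max_attempts` times and is dropped
#' afterwards (rare at realistic cover). For point-sized patches the pair
#' correlation function of the output follows the closed form
#' `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi kappa sigma^2)`.
#'
#' @param window A [rect_window()].
#' @param kappa Parent intensity (parents per m^2).
#' @param mu Mean offspring per parent.
#' @param sigma Gaussian dispersal SD (m).
#' @param cohort,model Size draw controls as in [generate_csr_cohort()].
#' @param fixed Patch table of already-present patches (may be `NULL`).
#' @param parents Optional parent table (columns `x`, `y`); supply to share
#'   parents across cohorts (static cohort overlap).
#' @param parent_shift Length-2 displacement added to the (supplied or drawn)
#'   parents before offspring generation; models slowly moving habitat
#'   patches.
#' @param dilation Parent-window dilation (m); default `4 * sigma`.
#' @param config A [null_config()].
#' @param id_start First patch id.
#' @return A list: `patches` (patch table), `parents` (tibble of the parents
#'   used, before any shift).
#' @export
generate_thomas_cohort <- function(window, kappa, mu, sigma, cohort = NULL,
                                   model = size_model(), fixed = NULL,
                                   parents = NULL, parent_shift = c(0, 0),
                                   dilation = 4 * sigma,
                                   config = null_config(), id_start = 1L) {
  window <- as_rect_window(window)
  stopifnot(kappa > 0, mu > 0, sigma > 0)
  if (is.null(parents)) {
    ax <- window$x_min - dilation; bx <- window$x_max + dilation
    ay <- window$y_min - dilation; by <- window$y_max + dilation
    n_par <- rpois(1, kappa * (bx - ax) * (by - ay))
    parents <- tibble::tibble(x = runif(n_par, ax, bx), y = runif(n_par, ay, by))
  }
  shifted <- dplyr::mutate(parents, x = .data$x + parent_shift[1],
                           y = .data$y + parent_shift[2])
  n_off <- if (nrow(shifted)) rpois(nrow(shifted), mu) else integer(0)
  parent_of <- rep(seq_len(nrow(shifted)), n_off)
  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  if (!is.null(fixed) && nrow(fixed)) {
    all_x <- fixed$x; all_y <- fixed$y; all_r <- fixed$diameter / 2
  } else {
    all_x <- numeric(0); all_y <- numeric(0); all_r <- numeric(0)
  }
  total <- length(parent_of)
  diam <- if (total) {
    sort(sample_diameters(total, model, cohort), decreasing = TRUE)
  } else numeric(0)
  # big offspring first so the hard-core constraint is satisfiable; each
  # offspring is matched to a random parent draw order
  parent_of <- sample(parent_of)
  keep_x <- keep_y <- keep_d <- numeric(0)
  for (k in seq_len(total)) {
    px <- shifted$x[parent_of[k]]; py <- shifted$y[parent_of[k]]
    r <- diam[k] / 2
    cx <- px + rnorm(1, 0, sigma); cy <- py + rnorm(1, 0, sigma)
    in_win <- cx >= window$x_min && cx <= window$x_max &&
      cy >= window$y_min && cy <= window$y_max
    if (!in_win) next # discard: keeps the restriction stationary
    ok <- FALSE
    for (att in seq_len(config$max_attempts)) {
      contained <- cx - r >= window$x_min && cx + r <= window$x_max &&
        cy - r >= window$y_min && cy + r <= window$y_max
      if (contained) {
        clash <- length(all_x) &&
          any((cx - all_x)^2 + (cy - all_y)^2 < (r + all_r)^2)
        if (!clash) { ok <- TRUE; break }
      }
      cx <- px + rnorm(1, 0, sigma); cy <- py + rnorm(1, 0, sigma)
      if (cx < window$x_min || cx > window$x_max ||
          cy < window$y_min || cy > window$y_max) next
    }
    if (!ok) next
    keep_x <- c(keep_x, cx); keep_y <- c(keep_y, cy); keep_d <- c(keep_d, diam[k])
    all_x <- c(all_x, cx); all_y <- c(all_y, cy); all_r <- c(all_r, r)
  }
  n <- length(keep_x)
  patches <- tibble::tibble(
    id = id_start + seq_len(n) - 1L, x = keep_x, y = keep_y, diameter = keep_d,
    cohort = if (n) classify_cohort(keep_d) else factor(character(), levels = cohort_levels())
  ) |> dplyr::arrange(.data$id)
  list(patches = patches, parents = parents)
}

#' Impose short-range interaction around adult patches
#'
#' Modifies a cohort in an annulus of edge distances `[a, b]` around the
#' adult discs. Competition deletes each cohort patch whose edge distance to
#' the nearest adult edge lies in the annulus with probability `strength`.
#' Facilitation adds patches inside the annulus until the annulus density
#' reaches `(1 + strength * boost_factor)` times the cohort's window-wide
#' background density; added patches draw their diameters from the existing
#' cohort's diameters and respect containment and non-overlap. Annulus area
#' is computed per adult as `pi ((R + b)^2 - (R + a)^2)`, ignoring annulus
#' overlap and window clipping (adequate at low adult cover).
#'
#' @param cohort Patch table of the cohort to modify.
#' @param adults Patch table generating the interaction (e.g. large adults).
#' @param window A [rect_window()].
#' @param mode `"none"`, `"facilitation"` or `"competition"`.
#' @param annulus Length-2 numeric `c(a, b)` in meters, `a < b`.
#' @param strength Interaction strength in `[0, 1]`.
#' @param boost_factor Facilitation density multiplier scale (default 3).
#' @param others Additional patch table the added patches must not overlap.
#' @param config A [null_config()].
#' @return The modified cohort patch table; attribute `interaction` records
#'   counts of removed/added patches.
#' @export
impose_interaction <- function(cohort, adults, window,
                               mode = c("none", "facilitation", "competition"),
                               annulus = c(0, 1), strength = 1,
                               boost_factor = 3, others = NULL,
                               config = null_config()) {
  mode <- match.arg(mode)
  window <- as_rect_window(window)
  stopifnot(length(annulus) == 2, annulus[1] < annulus[2],
            strength >= 0, strength <= 1)
  if (mode == "none" || strength == 0 || !nrow(adults)) {
    attr(cohort, "interaction") <- list(mode = mode, removed = 0L, added = 0L)
    return(cohort)
  }
  a <- annulus[1]; b <- annulus[2]
  if (mode == "competition") {
    # a patch suffers competition when ANY adult edge lies at band distance,
    # not only the nearest: with clustered adults this is what produces an
    # actual cross-pair deficit over [a, b]
    dd <- sqrt(outer(cohort$x, adults$x, "-")^2 +
                 outer(cohort$y, adults$y, "-")^2) -
      outer(cohort$diameter / 2, adults$diameter / 2, "+")
    in_band <- rowSums(dd >= a & dd <= b) > 0
    kill <- in_band & runif(nrow(cohort)) < strength
    out <- cohort[!kill, , drop = FALSE]
    attr(out, "interaction") <- list(mode = mode, removed = sum(kill), added = 0L)
    return(out)
  }
  # facilitation
  background <- nrow(cohort) / window_area(window)
  radii <- adults$diameter / 2
  area_each <- pi * ((radii + b)^2 - (radii + a)^2)
  n_add <- round(strength * boost_factor * background * sum(area_each))
  obstacles <- dplyr::bind_rows(cohort, adults, others)
  new_d <- if (nrow(cohort)) {
    sample(cohort$diameter, n_add, replace = TRUE)
  } else {
    sample_diameters(n_add, cohort = "J_B")
  }
  next_id <- if (nrow(obstacles)) max(obstacles$id) + 1L else 1L
  added <- list()
  for (k in seq_len(n_add)) {
    r_new <- new_d[k] / 2
    placed <- FALSE
    for (att in seq_len(config$max_attempts)) {
      ad <- sample.int(nrow(adults), 1, prob = area_each)
      u <- runif(1, a, b)
      th <- runif(1, 0, 2 * pi)
      rho <- radii[ad] + r_new + u
      cx <- adults$x[ad] + rho * cos(th)
      cy <- adults$y[ad] + rho * sin(th)
      if (cx - r_new < window$x_min || cx + r_new > window$x_max ||
          cy - r_new < window$y_min || cy + r_new > window$y_max) next
      if (any((cx - obstacles$x)^2 + (cy - obstacles$y)^2 <
              (r_new + obstacles$diameter / 2)^2)) next
      new_row <- tibble::tibble(
        id = next_id, x = cx, y = cy, diameter = new_d[k],
        cohort = classify_cohort(new_d[k])
      )
      added[[length(added) + 1]] <- new_row
      obstacles <- dplyr::bind_rows(obstacles, new_row)
      next_id <- next_id + 1L
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  out <- dplyr::bind_rows(cohort, added)
  attr(out, "interaction") <- list(mode = mode, removed = 0L,
                                   added = length(added))
  out
}

expected_report <- function(supported) {
  tibble::tibble(hypothesis = hypothesis_labels(), supported = supported)
}

#' Scenario presets for synthetic nebkha landscapes
#'
#' `scenario_dynamic()` is the canonical positive-control landscape. Every
#' cohort establishes in large (> 10 m) Thomas clusters; the cluster parents
#' of successive cohorts are the same base set displaced by `cohort_shift`
#' meters per cohort age step along the window's long axis, emulating
#' habitat patches that move slowly over time (dynamic large-scale allogenic
#' habitat patchiness): consecutive cohorts overlap partially, distant
#' cohorts hardly at all, so only a minority of cohort density correlations
#' come out significant. On top of the cluster structure, branched juveniles
#' are strongly facilitated within 1 m of large-adult edges and medium
#' adults are suppressed between 1.5 and 3.25 m from large-adult edges
#' (autogenic facilitation and competition; both interactions are set to
#' full strength so the positive control has high detection power).
#' Unbranched recruits lie four shift steps from the adults, so adult cover
#' does not predict recruit density (no distance seed limitation), and at a
#' few percent cover recruits occur isolated (density-limitation signature).
#'
#' `scenario_static()` shares one fixed parent set across all cohorts
#' (immobile habitat patches: many significant cohort correlations).
#' `scenario_csr()` is the negative control: every cohort completely
#' spatially random with no interaction, so all mechanism hypotheses are
#' expected rejected (sparse CSR recruits are still isolated, hence the
#' isolation-driven hypothesis pair stays supported).
#'
#' Cohort target counts default to a realistic nebkha census (500, 125, 178,
#' 171, 82 patches for UI, J_B, A_S, A_M, A_L) in a 125 m x 250 m window.
#'
#' @param window A [rect_window()].
#' @param n_cohort Named target counts per cohort, youngest first.
#' @param sigma Cluster dispersal SD (m) of the Thomas components.
#' @param n_parents Expected parents per cohort (sets `kappa`).
#' @param cohort_shift Parent displacement (m) per cohort age step; `NA`
#'   draws independent parents per cohort.
#' @param facilitation,competition Length-2 annuli (m) of the interaction
#'   bands around large-adult edges.
#' @param fac_strength,comp_strength Interaction strengths in `[0, 1]`.
#' @param boost_factor Facilitation density multiplier (default 9: the
#'   facilitation annulus reaches ten times the background density).
#' @return A list of class `scenario_config` with an `expected` ground-truth
#'   verdict table.
#' @export
scenario_dynamic <- function(window = rect_window(0, 0, 125, 250),
                             n_cohort = c(UI = 500, J_B = 125, A_S = 178,
                                          A_M = 171, A_L = 82),
                             sigma = 5, n_parents = 25, cohort_shift = 6,
                             facilitation = c(0, 1), competition = c(1.5, 3.25),
                             fac_strength = 1, comp_strength = 1,
                             boost_factor = 9) {
  structure(
    list(
      window = window, kind = "thomas",
      n_cohort = n_cohort, sigma = sigma, n_parents = n_parents,
      # habitat patches relocate between recruitment episodes: consecutive
      # cohorts within a group share (slightly drifted) parents, groups are
      # mutually independent
      parent_group = c(UI = 3, J_B = 2, A_S = 2, A_M = 1, A_L = 1),
      parent_shift_y = c(UI = 0, J_B = cohort_shift, A_S = 0,
                         A_M = cohort_shift, A_L = 0),
      interaction = list(
        list(cohort = "J_B", mode = "facilitation", annulus = facilitation,
             strength = fac_strength, boost_factor = boost_factor),
        list(cohort = "A_M", mode = "competition", annulus = competition,
             strength = comp_strength, boost_factor = NA_real_)
      ),
      expected = expected_report(c("n", "y", "y", "n", "y", "y", "y"))
    ),
    class = "scenario_config"
  )
}

#' @rdname scenario_dynamic
#' @export
scenario_static <- function(window = rect_window(0, 0, 125, 250),
                            n_cohort = c(UI = 500, J_B = 125, A_S = 178,
                                         A_M = 171, A_L = 82),
                            sigma = 5, n_parents = 25) {
  structure(
    list(
      window = window, kind = "thomas",
      n_cohort = n_cohort, sigma = sigma, n_parents = n_parents,
      parent_group = c(UI = 1, J_B = 1, A_S = 1, A_M = 1, A_L = 1),
      parent_shift_y = c(UI = 0, J_B = 0, A_S = 0, A_M = 0, A_L = 0),
      interaction = NULL,
      expected = expected_report(c("n", "y", "y", "y", "n", "n", "n"))
    ),
    class = "scenario_config"
  )
}

#' @rdname scenario_dynamic
#' @export
scenario_csr <- function(window = rect_window(0, 0, 125, 250),
                         n_cohort = c(UI = 500, J_B = 125, A_S = 178,
                                      A_M = 171, A_L = 82)) {
  structure(
    list(
      window = window, kind = "csr",
      n_cohort = n_cohort, sigma = NA_real_, n_parents = NA_real_,
      parent_group = NULL, parent_shift_y = NULL,
      interaction = NULL,
      expected = expected_report(c("n", "y", "y", "n", "n", "n", "n"))
    ),
    class = "scenario_config"
  )
}

#' Generate a multi-cohort synthetic landscape
#'
#' Builds the five cohorts oldest first (each younger cohort respects the
#' hard-core constraint against all older vegetation), applies any
#' interaction bands the scenario specifies, and returns the combined,
#' validated patch table with the scenario's ground truth.
#'
#' @param scenario A `scenario_config` from [scenario_dynamic()],
#'   [scenario_static()] or [scenario_csr()].
#' @param model A [size_model()].
#' @param config A [null_config()] (placement limits).
#' @return A list of class `patch_landscape`: `patches`, `window`, `truth`
#'   (expected verdicts, per-cohort parents, scenario).
#' @export
generate_landscape <- function(scenario, model = size_model(),
                               config = null_config()) {
  window <- as_rect_window(scenario$window)
  area <- window_area(window)
  old_first <- rev(cohort_levels())
  placed <- NULL
  parents_by_cohort <- list()
  group_parents <- list()
  if (scenario$kind == "thomas") {
    # one base parent set per independent parent group, drawn on a window
    # dilated enough to cover the group's shifted cohorts (shifts go to +y)
    dil <- 4 * scenario$sigma
    kappa <- scenario$n_parents / area
    for (g in unique(scenario$parent_group)) {
      max_shift <- max(scenario$parent_shift_y[scenario$parent_group == g])
      ax <- window$x_min - dil; bx <- window$x_max + dil
      ay <- window$y_min - dil - max_shift; by <- window$y_max + dil
      n_par <- rpois(1, kappa * (bx - ax) * (by - ay))
      group_parents[[as.character(g)]] <- tibble::tibble(
        x = runif(n_par, ax, bx), y = runif(n_par, ay, by)
      )
    }
  }
  next_id <- 1L
  for (co in old_first) {
    n_target <- scenario$n_cohort[[co]]
    if (scenario$kind == "csr") {
      pat <- generate_csr_cohort(window, n_target, cohort = co, model = model,
                                 fixed = placed, config = config,
                                 id_start = next_id)
    } else {
      kappa <- scenario$n_parents / area
      mu <- n_target / scenario$n_parents
      res <- generate_thomas_cohort(
        window, kappa = kappa, mu = mu, sigma = scenario$sigma, cohort = co,
        model = model, fixed = placed,
        parents = group_parents[[as.character(scenario$parent_group[[co]])]],
        parent_shift = c(0, scenario$parent_shift_y[[co]]),
        config = config, id_start = next_id
      )
      pat <- res$patches
      parents_by_cohort[[co]] <- res$parents
    }
    for (ia in scenario$interaction %||% list()) {
      if (!identical(ia$cohort, co)) next
      adults <- dplyr::filter(placed, .data$cohort == "A_L")
      older_rest <- dplyr::filter(placed, .data$cohort != "A_L")
      pat <- impose_interaction(pat, adults, window, mode = ia$mode,
                                annulus = ia$annulus, strength = ia$strength,
                                boost_factor = ia$boost_factor %||% 3,
                                others = older_rest, config = config)
    }
    placed <- dplyr::bind_rows(placed, pat)
    next_id <- if (nrow(placed)) max(placed$id) + 1L else 1L
  }
  patches <- dplyr::arrange(placed, .data$id)
  validate_patches(patches, window)
  structure(
    list(
      patches = patches, window = window,
      truth = list(expected = scenario$expected, parents = parents_by_cohort,
                   scenario = scenario)
    ),
    class = "patch_landscape"
  )
}

#' @export
print.patch_landscape <- function(x, ...) {
  cat(sprintf("<patch_landscape> %d patches in a %g x %g m window\n",
              nrow(x$patches), window_width(x$window), window_height(x$window)))
  print(dplyr::count(x$patches, .data$cohort, .drop = FALSE))
  invisible(x)
}
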