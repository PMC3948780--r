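#' Analysis configuration
#'
#' Collects every tunable parameter of the full inference pipeline. Defaults
#' follow the conventional analysis: cohort boundaries at 0.25/0.50/1.00/2.00
#' m; square plots of five and ten times the largest observed diameter; 499
#' null simulations per batch with a rank-5 rejection rule (per-tail level
#' 5/500 = 0.01); correlation tests at alpha 0.05; a 5 m Gaussian kernel for
#' the heterogeneous null intensity. `n_sims` and `gof_k` can be scaled down
#' together (e.g. 99 and 1) while preserving the 0.01 per-tail level.
#'
#' @param thresholds Cohort diameter boundaries (m), strictly increasing.
#' @param plot_multipliers Plot sides as multiples of the largest observed
#'   diameter (default `c(5, 10)`; the first is also the cohort-correlation
#'   grid).
#' @param n_sims Simulations per envelope batch (>= 19; default 499).
#' @param gof_k Rejection rank of the GoF test (default 5).
#' @param alpha_corr Significance level of the correlation tests (0.05).
#' @param corr_method `"pearson"` (default) or `"spearman"`.
#' @param static_threshold Significant pairs needed for a "static" verdict.
#' @param kernel_sd Gaussian kernel SD (m) of the bivariate null intensity.
#' @param lattice_step Intensity lattice step (m).
#' @param pcf_r_max,pcf_r_n PCF distance grid: maximum (default quarter of
#'   the shorter window side) and number of points.
#' @param pccf_r_max,pccf_r_n PCCF distance grid (default 0-10 m), resolving
#'   the short-range interaction scales.
#' @param pcf_bandwidth PCF kernel bandwidth (m); `NULL` = Stoyan rule.
#' @param pccf_bandwidth PCCF kernel bandwidth (m; default 0.5, fine enough
#'   for sub-meter interaction bands).
#' @param min_width Minimum deviating-run width in grid steps (default 2).
#' @param large_scale Cluster-scale threshold (m) for "large-scale" (10).
#' @param conditioning `"older"` (default: bivariate null conditions on all
#'   older cohorts) or `"large_adults"` (large adults only).
#' @param min_cohort_n Cohorts with fewer patches are skipped in the
#'   second-order analyses (default 5).
#' @param seed Root seed; `NULL` draws one and records it.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = c(0.25, 0.50, 1.00, 2.00),
                            plot_multipliers = c(5, 10),
                            n_sims = 499, gof_k = 5,
                            alpha_corr = 0.05, corr_method = "pearson",
                            static_threshold = 5,
                            kernel_sd = 5, lattice_step = 0.5,
                            pcf_r_max = NULL, pcf_r_n = 64,
                            pccf_r_max = 10, pccf_r_n = 64,
                            pcf_bandwidth = NULL, pccf_bandwidth = 0.5,
                            min_width = 2, large_scale = 10,
                            conditioning = c("older", "large_adults"),
                            min_cohort_n = 5, seed = NULL) {
  conditioning <- match.arg(conditioning)
  stopifnot(length(thresholds) == 4, all(diff(thresholds) > 0),
            length(plot_multipliers) == 2, all(plot_multipliers > 0),
            n_sims >= 19, gof_k >= 1, gof_k < n_sims + 1,
            alpha_corr > 0, alpha_corr < 1, kernel_sd > 0, lattice_step > 0)
  structure(
    list(thresholds = thresholds, plot_multipliers = plot_multipliers,
         n_sims = n_sims, gof_k = gof_k, alpha_corr = alpha_corr,
         corr_method = corr_method, static_threshold = static_threshold,
         kernel_sd = kernel_sd, lattice_step = lattice_step,
         pcf_r_max = pcf_r_max, pcf_r_n = pcf_r_n,
         pccf_r_max = pccf_r_max, pccf_r_n = pccf_r_n,
         pcf_bandwidth = pcf_bandwidth, pccf_bandwidth = pccf_bandwidth,
         min_width = min_width, large_scale = large_scale,
         conditioning = conditioning, min_cohort_n = min_cohort_n,
         seed = seed),
    class = "analysis_config"
  )
}

#' Plot side from the largest observed patch
#'
#' The sampling-plot side is a fixed multiple of the largest observed
#' equivalent-circle diameter, tying the plot scale to the seed-source scale.
#'
#' @param max_diameter Largest observed diameter (m).
#' @param multiplier Side multiplier (default 5).
#' @return Side length in meters.
#' @examples
#' plot_side(4.2, 5) # 21
#' @export
plot_side <- function(max_diameter, multiplier = 5) {
  if (any(max_diameter <= 0) || any(multiplier <= 0)) abort("inputs must be positive")
  multiplier * max_diameter
}

# deterministic child seeds derived from one root seed
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# one cohort's univariate PCF analysis: two independent envelope batches,
# candidate intervals from batch 1, GoF on batch 2
analyse_pcf_cohort <- function(cohort_patches, older, window, cfg, r, seeds) {
  bw <- cfg$pcf_bandwidth %||% stoyan_bandwidth(nrow(cohort_patches), window_area(window))
  nc <- null_config(kernel_sd = cfg$kernel_sd, lattice_step = cfg$lattice_step)
  obs <- pcf_edge(cohort_patches, window, r = r, bandwidth = bw)
  sim_fn <- function() {
    pcf_edge(simulate_univariate_null(cohort_patches, older, window, nc),
             window, r = r, bandwidth = bw)
  }
  set.seed(seeds[1])
  env1 <- build_envelope(obs, sim_fn, n_sims = cfg$n_sims)
  set.seed(seeds[2])
  env2 <- build_envelope(obs, sim_fn, n_sims = cfg$n_sims)
  intervals <- find_deviation_intervals(env1, min_width = cfg$min_width)
  if (nrow(intervals)) {
    intervals <- gof_test(intervals, env2, k = cfg$gof_k) |>
      deviation_strength(env1)
  }
  scale <- if (nrow(intervals)) cluster_scale(intervals, env1) else NA_real_
  direction <- if (!nrow(intervals) || !any(intervals$significant)) "none" else {
    sig <- intervals[intervals$significant, ]
    sig$sign[which.min(sig$r_start)]
  }
  list(envelope = env1, envelope_test = env2, intervals = intervals,
       cluster_scale = scale, direction = direction)
}

# one cohort's bivariate PCCF-vs-A_L analysis
analyse_pccf_cohort <- function(cohort_patches, large_adults, conditioning,
                                window, cfg, r, seeds) {
  nc <- null_config(kernel_sd = cfg$kernel_sd, lattice_step = cfg$lattice_step)
  surface <- estimate_intensity(cohort_patches, window,
                                kernel_sd = cfg$kernel_sd,
                                lattice_step = cfg$lattice_step)
  obs <- pccf_edge(large_adults, cohort_patches, window, r = r,
                   bandwidth = cfg$pccf_bandwidth)
  sim_fn <- function() {
    sim <- simulate_bivariate_null(cohort_patches, conditioning, window, nc,
                                   surface = surface)
    pccf_edge(large_adults, sim, window, r = r, bandwidth = cfg$pccf_bandwidth)
  }
  set.seed(seeds[1])
  env1 <- build_envelope(obs, sim_fn, n_sims = cfg$n_sims)
  set.seed(seeds[2])
  env2 <- build_envelope(obs, sim_fn, n_sims = cfg$n_sims)
  intervals <- find_deviation_intervals(env1, min_width = cfg$min_width)
  if (nrow(intervals)) {
    intervals <- gof_test(intervals, env2, k = cfg$gof_k) |>
      deviation_strength(env1)
  }
  list(envelope = env1, envelope_test = env2, intervals = intervals)
}

#' Run the full recruitment-inference pipeline
#'
#' Executes, on a validated multi-cohort patch table: cohort classification;
#' the isolated-recruit check; plot-grid statistics and the two correlation
#' tests (distance seed limitation at two plot sizes; between-cohort density
#' correlations with the static/dynamic verdict); per-cohort edge-distance
#' PCFs against the constrained homogeneous null with envelope detection and
#' rank GoF testing on an independent simulation batch; per-cohort
#' edge-distance PCCFs against large adults under the density-preserving
#' heterogeneous null; and the decision framework. All randomness flows from
#' `config$seed` (drawn and recorded when `NULL`), so a rerun with the same
#' seed reproduces the report exactly.
#'
#' @param patches A patch table (will be validated; classified if the
#'   `cohort` column is absent).
#' @param window A [rect_window()].
#' @param config An [analysis_config()].
#' @return A list of class `recruitment_analysis` with elements `report`
#'   (the hypothesis verdict table), `evidence`, `summary`, `grids`,
#'   `plot_stats`, `corr1`, `corr_matrix`, `corr2`, `pcf`, `pccf`, `config`,
#'   `seed`.
#' @export
run_full_pipeline <- function(patches, window, config = analysis_config()) {
  window <- as_rect_window(window)
  patches <- patch_table(patches, window, thresholds = config$thresholds)
  seed <- config$seed %||% sample.int(.Machine$integer.max - 1L, 1)
  seeds <- derive_seeds(seed, 2 * 2 * length(cohort_levels()) + 1)
  si <- 0L
  next_seeds <- function() {
    si <<- si + 2L
    seeds[(si - 1L):si]
  }

  summary_tbl <- pattern_summary(patches, window)
  ui <- dplyr::filter(patches, .data$cohort == "UI")
  iso_ui <- nrow(ui) > 0 && any(is_isolated(patches)[patches$cohort == "UI"])

  max_d <- max(patches$diameter)
  sides <- plot_side(max_d, config$plot_multipliers)
  grid_small <- build_grid(window, sides[1])
  grid_large <- build_grid(window, sides[2])
  stats_small <- plot_stats(patches, grid_small)
  corr1 <- distance_sl_test(patches, window, sides = sides,
                            alpha = config$alpha_corr,
                            method = config$corr_method)
  corr_matrix <- cohort_density_correlations(patches, grid_small,
                                             alpha = config$alpha_corr,
                                             method = config$corr_method)
  corr2 <- static_vs_dynamic(corr_matrix, threshold = config$static_threshold)

  r_pcf <- seq(0, config$pcf_r_max %||%
                 (min(window_width(window), window_height(window)) / 4),
               length.out = config$pcf_r_n)
  r_pccf <- seq(0, config$pccf_r_max, length.out = config$pccf_r_n)
  by_cohort <- split(patches, patches$cohort)
  older_than <- function(co) {
    idx <- match(co, cohort_levels())
    dplyr::filter(patches, as.integer(.data$cohort) > idx)
  }

  pcf_results <- list()
  pcf_verdicts <- purrr::map_dfr(cohort_levels(), function(co) {
    pat <- by_cohort[[co]]
    sd2 <- next_seeds()
    if (nrow(pat) < max(2, config$min_cohort_n)) {
      return(tibble::tibble(cohort = co, direction = "none",
                            cluster_scale = NA_real_, n = nrow(pat),
                            skipped = TRUE))
    }
    res <- analyse_pcf_cohort(pat, older_than(co), window, config, r_pcf, sd2)
    pcf_results[[co]] <<- res
    tibble::tibble(cohort = co, direction = res$direction,
                   cluster_scale = res$cluster_scale, n = nrow(pat),
                   skipped = FALSE)
  })

  large_adults <- by_cohort[["A_L"]]
  pccf_results <- list()
  pccf_sig <- purrr::map_dfr(setdiff(cohort_levels(), "A_L"), function(co) {
    pat <- by_cohort[[co]]
    sd2 <- next_seeds()
    if (nrow(pat) < config$min_cohort_n || nrow(large_adults) < 1) {
      return(tibble::tibble(cohort = character(), sign = character(),
                            r_start = numeric(), r_end = numeric(),
                            strength = numeric()))
    }
    conditioning <- if (config$conditioning == "older") older_than(co) else large_adults
    res <- analyse_pccf_cohort(pat, large_adults, conditioning, window,
                               config, r_pccf, sd2)
    pccf_results[[co]] <<- res
    if (!nrow(res$intervals)) return(tibble::tibble(
      cohort = character(), sign = character(), r_start = numeric(),
      r_end = numeric(), strength = numeric()
    ))
    res$intervals |>
      dplyr::filter(.data$significant) |>
      dplyr::transmute(cohort = co, sign = .data$sign,
                       r_start = .data$r_start, r_end = .data$r_end,
                       strength = .data$strength)
  })

  evidence <- evidence_bundle(iso_ui, pcf_verdicts, pccf_sig, corr1, corr2)
  report <- evaluate_framework(evidence, large_scale = config$large_scale)

  structure(
    list(report = report, evidence = evidence, summary = summary_tbl,
         grids = list(small = grid_small, large = grid_large),
         plot_stats = stats_small, corr1 = corr1, corr_matrix = corr_matrix,
         corr2 = corr2, pcf = pcf_results, pccf = pccf_results,
         config = config, seed = seed),
    class = "recruitment_analysis"
  )
}

#' @export
print.recruitment_analysis <- function(x, ...) {
  cat("Recruitment-hypothesis analysis\n")
  cat(sprintf("  %d patches; seed %d; %d simulations per envelope batch\n",
              sum(x$summary$n[x$summary$cohort != "total"]), x$seed,
              x$config$n_sims))
  cat(report_markdown(x$report))
  invisible(x)
}

#' @export
tidy.recruitment_analysis <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' @export
glance.recruitment_analysis <- function(x, ...) {
  tibble::tibble(
    n_patches = sum(x$summary$n[x$summary$cohort != "total"]),
    fvc_total = x$summary$fvc[x$summary$cohort == "total"],
    iso_ui = x$evidence$iso_ui,
    corr1 = x$corr1$verdict,
    corr2 = x$corr2$verdict,
    n_corr_significant = x$corr2$n_significant,
    n_pccf_significant = nrow(x$evidence$pccf_intervals),
    n_sims = x$config$n_sims,
    seed = x$seed
  )
}

#' Empirical calibration of the rank GoF rule
#'
#' Estimates the per-tail type I error of the rank-based goodness-of-fit
#' rejection rule under its own null: in each replicate a hard-core CSR disc
#' pattern is drawn (a draw from the univariate null model itself), its
#' edge-distance PCF is computed on a fixed grid, a reference batch of
#' `n_sims` univariate-null simulations is built, the Loosmore-type `u` is
#' computed for all `n_sims + 1` functions over the whole grid, and a
#' rejection is recorded when the observed `u` ranks among the `k` highest.
#' The rejection frequency estimates the nominal per-tail level
#' `k / (n_sims + 1)`.
#'
#' @param n_reps Number of replicates (default 300).
#' @param n_discs Discs per pattern (default 30).
#' @param window A [rect_window()] (default 50 m x 50 m).
#' @param n_sims Simulations per reference batch (default 99).
#' @param k Rejection rank (default 1; with `n_sims = 99` the nominal
#'   per-tail level is 1/100 = 0.01).
#' @param r Distance grid (default 24 points on 0.25-6 m).
#' @param bandwidth Kernel bandwidth (default 0.5 m).
#' @param model A [size_model()] for the disc diameters.
#' @return A list: `rate` (empirical one-tail rejection frequency),
#'   `nominal` (`k / (n_sims + 1)`), `n_reps`, `rejections`.
#' @export
gof_calibration <- function(n_reps = 300, n_discs = 30,
                            window = rect_window(0, 0, 50, 50),
                            n_sims = 99, k = 1,
                            r = seq(0.25, 6, length.out = 24),
                            bandwidth = 0.5, model = size_model()) {
  window <- as_rect_window(window)
  rejections <- logical(n_reps)
  for (rep in seq_len(n_reps)) {
    observed <- generate_csr_cohort(window, n_discs, model = model)
    obs_fn <- pcf_edge(observed, window, r = r, bandwidth = bandwidth)
    env <- build_envelope(obs_fn, function() {
      pcf_edge(simulate_univariate_null(observed, NULL, window), window,
               r = r, bandwidth = bandwidth)
    }, n_sims = n_sims)
    iv <- tibble::tibble(r_start = min(r), r_end = max(r))
    res <- gof_test(iv, env, k = k)
    rejections[rep] <- res$rank_high <= k
  }
  list(rate = mean(rejections), nominal = k / (n_sims + 1),
       n_reps = n_reps, rejections = rejections)
}
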