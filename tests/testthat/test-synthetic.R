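test_that("CSR cohorts conserve N, validate, and disperse like Poisson", {
  w <- rect_window(0, 0, 105, 105)
  set.seed(71)
  p <- generate_csr_cohort(w, 150, cohort = "A_S")
  expect_equal(nrow(p), 150)
  expect_true(all(p$cohort == "A_S"))
  expect_no_error(validate_patches(p, w))
  pts <- generate_csr_cohort(w, 250, diameters = rep(1e-9, 250))
  s <- plot_stats(pts, build_grid(w, 21))
  counts <- s$n[s$cohort == "UI"]
  id <- var(counts) / mean(counts)
  bounds <- stats::qchisq(c(0.005, 0.995), df = 24) / 24
  expect_gt(id, bounds[1])
  expect_lt(id, bounds[2])
})

test_that("Thomas cohorts hit the expected count and closed-form PCF", {
  w <- rect_window(0, 0, 100, 100)
  kappa <- 0.005; mu <- 10; sigma <- 2
  set.seed(72)
  ns <- replicate(30, nrow(generate_thomas_cohort(w, kappa, mu, sigma,
                                                  model = point_sizes())$patches))
  expected <- kappa * mu * 1e4
  expect_lt(abs(mean(ns) - expected), 3 * sqrt(expected * (1 + mu) / 30))
  # closed-form pair correlation at a few distances, averaged over patterns
  r <- c(1, 2, 4, 6)
  closed <- 1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * kappa * sigma^2)
  vals <- replicate(30, {
    th <- generate_thomas_cohort(w, kappa, mu, sigma, model = point_sizes())
    pcf_edge(th$patches, w, r = r, bandwidth = 0.75)$value
  })
  se <- apply(vals, 1, sd) / sqrt(30)
  expect_true(all(abs(rowMeans(vals) - closed) < 3 * se))
})

test_that("shared parents induce plot-density correlation, independent ones none", {
  w <- rect_window(0, 0, 125, 250)
  kappa <- 25 / window_area(w)
  set.seed(73)
  r_shared <- numeric(5); r_indep <- numeric(5)
  for (i in 1:5) {
    a <- generate_thomas_cohort(w, kappa, 7, 5, cohort = "A_M")
    b <- generate_thomas_cohort(w, kappa, 7, 5, cohort = "A_S",
                                fixed = a$patches, parents = a$parents)
    c_ <- generate_thomas_cohort(w, kappa, 7, 5, cohort = "J_B",
                                 fixed = dplyr::bind_rows(a$patches, b$patches))
    g <- build_grid(w, 21)
    s <- plot_stats(dplyr::bind_rows(a$patches, b$patches, c_$patches), g)
    dens <- tidyr::pivot_wider(s[, c("plot_id", "cohort", "density")],
                               names_from = "cohort", values_from = "density")
    r_shared[i] <- cor(dens$A_M, dens$A_S)
    r_indep[i] <- cor(dens$A_M, dens$J_B)
  }
  expect_gt(mean(r_shared), 0.5)
  expect_lt(mean(abs(r_indep)), 0.3)
})

test_that("interactions modify the annulus and nothing else", {
  w <- rect_window(0, 0, 80, 80)
  set.seed(74)
  adults <- generate_csr_cohort(w, 25, diameters = runif(25, 2, 3))
  cohort <- generate_csr_cohort(w, 60, diameters = runif(60, 0.3, 0.45),
                                fixed = adults, id_start = 26L)
  same <- impose_interaction(cohort, adults, w, mode = "none")
  expect_identical(same$id, cohort$id)
  zero <- impose_interaction(cohort, adults, w, mode = "competition",
                             annulus = c(1, 3), strength = 0)
  expect_identical(zero$x, cohort$x)
  thin <- impose_interaction(cohort, adults, w, mode = "competition",
                             annulus = c(1, 3), strength = 1)
  dd <- sqrt(outer(thin$x, adults$x, "-")^2 + outer(thin$y, adults$y, "-")^2) -
    outer(thin$diameter / 2, adults$diameter / 2, "+")
  expect_equal(sum(dd >= 1 & dd <= 3), 0)
  grown <- impose_interaction(cohort, adults, w, mode = "facilitation",
                              annulus = c(0, 1), strength = 1, boost_factor = 5)
  expect_gt(nrow(grown), nrow(cohort))
  expect_no_error(validate_patches(dplyr::bind_rows(grown, adults), w))
})

test_that("imposed facilitation is detected against the bivariate null", {
  w <- rect_window(0, 0, 80, 120)
  set.seed(75)
  n_rep <- 15
  detected <- logical(n_rep)
  r <- seq(0, 6, length.out = 40)
  for (i in seq_len(n_rep)) {
    adults <- generate_csr_cohort(w, 30, diameters = runif(30, 2, 3))
    cohort <- generate_csr_cohort(w, 60, diameters = runif(60, 0.3, 0.45),
                                  fixed = adults, id_start = 31L)
    cohort <- impose_interaction(cohort, adults, w, mode = "facilitation",
                                 annulus = c(0, 1), strength = 1,
                                 boost_factor = 9)
    surface <- estimate_intensity(cohort, w, kernel_sd = 5, lattice_step = 1)
    obs <- pccf_edge(adults, cohort, w, r = r, bandwidth = 0.5)
    sim_fn <- function() {
      sim <- simulate_bivariate_null(cohort, adults, w,
                                     config = null_config(lattice_step = 1),
                                     surface = surface)
      pccf_edge(adults, sim, w, r = r, bandwidth = 0.5)
    }
    env1 <- build_envelope(obs, sim_fn, n_sims = 99)
    env2 <- build_envelope(obs, sim_fn, n_sims = 99)
    iv <- find_deviation_intervals(env1)
    if (nrow(iv)) iv <- gof_test(iv, env2, k = 1)
    detected[i] <- nrow(iv) > 0 &&
      any(iv$significant & iv$sign == "above" & iv$r_start <= 1.5)
  }
  expect_gte(mean(detected), 0.8)
})

test_that("the size model yields a bimodal log-area distribution", {
  set.seed(76)
  d <- sample_diameters(4000)
  log_area <- log(pi * (d / 2)^2)
  km <- stats::kmeans(log_area, centers = 2, nstart = 5)
  mu <- sort(km$centers[, 1])
  pooled_sd <- sqrt(mean(unlist(lapply(split(log_area, km$cluster), var))))
  expect_gt(diff(mu) / pooled_sd, 2)
  # cohort-conditioned draws respect the class bounds
  jb <- sample_diameters(200, cohort = "J_B")
  expect_true(all(jb >= 0.25 & jb < 0.5))
})

test_that("generated landscapes validate and carry their ground truth", {
  set.seed(77)
  L <- generate_landscape(scenario_dynamic(
    window = rect_window(0, 0, 100, 150),
    n_cohort = c(UI = 120, J_B = 50, A_S = 60, A_M = 60, A_L = 30)
  ))
  expect_s3_class(L, "patch_landscape")
  expect_no_error(validate_patches(L$patches, L$window))
  expect_equal(L$truth$expected$supported, c("n", "y", "y", "n", "y", "y", "y"))
  expect_true(all(cohort_levels() %in% L$patches$cohort))
  set.seed(78)
  Lc <- generate_landscape(scenario_csr(
    window = rect_window(0, 0, 80, 100),
    n_cohort = c(UI = 60, J_B = 25, A_S = 25, A_M = 25, A_L = 12)
  ))
  expect_no_error(validate_patches(Lc$patches, Lc$window))
  expect_equal(nrow(Lc$patches), 147)
})
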