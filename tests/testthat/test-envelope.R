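const_fn <- function(r, v) tibble::tibble(r = r, value = rep(v, length(r)))

test_that("a degenerate simulation batch collapses the envelope", {
  r <- seq(0.5, 5, by = 0.5)
  obs <- structure(const_fn(r, 1.3), class = c("patch_sumfun", "tbl_df", "tbl", "data.frame"))
  attr(obs, "kind") <- "pcf"
  env <- build_envelope(obs, function() const_fn(r, 1), n_sims = 25)
  expect_equal(env$lo, rep(1, length(r)))
  expect_equal(env$hi, rep(1, length(r)))
  expect_equal(env$mean, rep(1, length(r)))
  expect_equal(env$n_sims, 25)
  expect_equal(glance(env)$n_sims, 25)
  expect_error(build_envelope(obs, function() const_fn(r + 1, 1), 5),
               "different r grid")
})

test_that("pointwise exceedance of a same-null envelope is 2/(n+1) per point", {
  set.seed(51)
  n_sims <- 49
  n_pts <- 3000
  sims <- matrix(rnorm(n_pts * n_sims), n_pts, n_sims)
  obs <- rnorm(n_pts)
  env <- make_envelope(seq_len(n_pts), obs, sims)
  frac <- mean(obs > env$hi | obs < env$lo)
  expect_equal(frac, 2 / (n_sims + 1), tolerance = 0.3)
  expect_lt(abs(frac - 2 / 50), 0.015)
})

test_that("envelope bounds widen monotonically with batch size", {
  set.seed(52)
  r <- 1:20
  sims <- matrix(rnorm(20 * 60), 20, 60)
  small <- make_envelope(r, rnorm(20), sims[, 1:20])
  large <- make_envelope(r, small$observed, sims)
  expect_true(all(large$lo <= small$lo))
  expect_true(all(large$hi >= small$hi))
})

test_that("deviating intervals are maximal runs filtered by width", {
  r <- seq(0.1, 2, by = 0.1)
  sims <- matrix(1, length(r), 10) # envelope exactly [1, 1]
  inside <- make_envelope(r, rep(1, length(r)), sims)
  expect_equal(nrow(find_deviation_intervals(inside)), 0)

  obs <- rep(1, length(r))
  obs[r >= 0.5 & r <= 1.0] <- 1.1 # constructed exceedance on [0.5, 1.0]
  env <- make_envelope(r, obs, sims)
  iv <- find_deviation_intervals(env)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$sign, "above")
  expect_equal(iv$r_start, 0.5)
  expect_equal(iv$r_end, 1.0)

  alt <- rep(1, length(r))
  alt[seq(1, length(r), by = 2)] <- 2 # alternating single-point spikes
  expect_equal(nrow(find_deviation_intervals(make_envelope(r, alt, sims),
                                             min_width = 2)), 0)
  below <- rep(1, length(r)); below[5:8] <- 0.5
  ivb <- find_deviation_intervals(make_envelope(r, below, sims))
  expect_equal(ivb$sign, "below")
})

test_that("the u statistic matches hand computation on a tiny case", {
  # 3 functions on 2 grid points, dr = 0.5; leave-one-out means by hand
  r <- c(1, 1.5)
  sims <- cbind(c(1, 2), c(3, 1))
  obs <- c(2, 5)
  env <- make_envelope(r, obs, sims)
  iv <- tibble::tibble(r_start = 1, r_end = 1.5)
  res <- gof_test(iv, env, k = 1)
  expect_equal(res$u_obs, 6.125) # 0.5 * ((2-2)^2 + (5-1.5)^2)
  expect_equal(res$rank_high, 1)
  expect_true(res$significant)
})

test_that("a constant offset yields u = delta^2 * interval length", {
  r <- seq(1, 3, by = 0.25)
  delta <- 0.37
  sims <- matrix(1.4, length(r), 40)
  obs <- rep(1.4 + delta, length(r))
  env <- make_envelope(r, obs, sims)
  res <- gof_test(tibble::tibble(r_start = 1, r_end = 3), env, k = 1)
  expect_equal(res$u_obs, delta^2 * length(r) * 0.25)
})

test_that("the u ranking is invariant to adding a constant to all functions", {
  set.seed(53)
  r <- seq(0.5, 4, by = 0.25)
  sims <- matrix(rnorm(length(r) * 30, 1, 0.2), length(r), 30)
  obs <- rnorm(length(r), 1, 0.2)
  iv <- tibble::tibble(r_start = 0.5, r_end = 4)
  base <- gof_test(iv, make_envelope(r, obs, sims), k = 1)
  shifted <- gof_test(iv, make_envelope(r, obs + 7, sims + 7), k = 1)
  expect_equal(base$u_obs, shifted$u_obs)
  expect_equal(base$rank_high, shifted$rank_high)
})

test_that("deviation strength scales with envelope offset and width", {
  r <- seq(1, 2, by = 0.1)
  sims <- cbind(rep(0.8, length(r)), rep(1.2, length(r)))
  env <- make_envelope(r, rep(1.5, length(r)), sims)
  iv <- tibble::tibble(r_start = 1, r_end = 2, sign = "above")
  expect_equal(deviation_strength(iv, env)$strength, 0.5) # |1.2-1| / 0.4
  wide <- make_envelope(r, rep(1.5, length(r)),
                        cbind(rep(0.6, length(r)), rep(1.2, length(r))))
  expect_lt(deviation_strength(iv, wide)$strength,
            deviation_strength(iv, env)$strength)
  inside <- make_envelope(r, rep(1.0, length(r)), sims)
  expect_equal(deviation_strength(iv, inside)$strength, 0)
})

test_that("cluster scale reads the first near-origin significant above-interval", {
  r <- seq(0.5, 20, by = 0.5)
  sims <- matrix(1, length(r), 5)
  env <- make_envelope(r, rep(1, length(r)), sims)
  iv <- tibble::tibble(r_start = 0.5, r_end = 10, sign = "above",
                       significant = TRUE)
  expect_equal(cluster_scale(iv, env), 10)
  none <- iv[0, ]
  expect_true(is.na(cluster_scale(none, env)))
  far <- tibble::tibble(r_start = 8, r_end = 12, sign = "above",
                        significant = TRUE)
  expect_true(is.na(cluster_scale(far, env)))
  insig <- tibble::tibble(r_start = 0.5, r_end = 10, sign = "above",
                          significant = FALSE)
  expect_true(is.na(cluster_scale(insig, env)))
})

test_that("cluster scale recovers the Thomas cluster diameter within a factor 2", {
  w <- rect_window(0, 0, 100, 100)
  sigma <- 5
  truth <- 4 * sigma
  set.seed(54)
  scales <- numeric(10)
  r <- seq(0, 30, length.out = 40)
  for (i in seq_len(10)) {
    th <- generate_thomas_cohort(w, kappa = 12 / 1e4, mu = 15, sigma = sigma,
                                 model = point_sizes())
    p <- th$patches
    obs <- pcf_edge(p, w, r = r, bandwidth = 2)
    sim_fn <- function() {
      pcf_edge(simulate_univariate_null(p, NULL, w), w, r = r, bandwidth = 2)
    }
    env1 <- build_envelope(obs, sim_fn, n_sims = 99)
    env2 <- build_envelope(obs, sim_fn, n_sims = 99)
    iv <- find_deviation_intervals(env1)
    if (nrow(iv)) iv <- gof_test(iv, env2, k = 1)
    scales[i] <- if (nrow(iv)) cluster_scale(iv, env1) else NA_real_
  }
  expect_gte(sum(!is.na(scales)), 8)
  med <- stats::median(scales, na.rm = TRUE)
  expect_gte(med, truth / 2)
  expect_lte(med, truth * 2)
})
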