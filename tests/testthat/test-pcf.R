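test_that("the PCF of a CSR pattern is close to 1", {
  w <- rect_window(0, 0, 100, 100)
  set.seed(31)
  p <- generate_csr_cohort(w, 2000, diameters = rep(1e-6, 2000))
  f <- pcf_edge(p, w, r = seq(1, 20, length.out = 40), bandwidth = 1)
  expect_true(all(abs(f$value - 1) < 0.1))
})

test_that("box-kernel estimator reproduces the histogram oracle exactly", {
  w <- rect_window(0, 0, 60, 60)
  set.seed(32)
  p <- generate_csr_cohort(w, 150, diameters = runif(150, 0.1, 1.5))
  breaks <- seq(0.5, 12, by = 0.5)
  h <- pcf_histogram(p, w, breaks)
  f <- pcf_edge(p, w, r = h$r, bandwidth = 0.25, kernel = "box")
  expect_lt(max(abs(f$value - h$value)), 1e-10)
  # without edge correction too
  h0 <- pcf_histogram(p, w, breaks, edge_correction = "none")
  f0 <- pcf_edge(p, w, r = h0$r, bandwidth = 0.25, kernel = "box",
                 edge_correction = "none")
  expect_lt(max(abs(f0$value - h0$value)), 1e-10)
})

test_that("histogram oracle puts a lone pair in the half-open bin holding it", {
  w <- rect_window(0, 0, 50, 50)
  p <- pt(c(20, 24), c(20, 20), c(1, 1)) # edge distance exactly 3.0
  h <- pcf_histogram(p, w, breaks = 0:6, edge_correction = "none")
  expect_equal(h$n_pairs[h$lo == 3], 2L) # [3, 4) under the half-open rule
  expect_equal(sum(h$n_pairs), 2L)
  expect_equal(sum(h$n_pairs[h$lo != 3]), 0L)
})

test_that("histogram oracle conserves the ordered pair count", {
  w <- rect_window(0, 0, 30, 30)
  set.seed(33)
  p <- generate_csr_cohort(w, 40, diameters = runif(40, 0.1, 0.8))
  h <- pcf_histogram(p, w, breaks = seq(0, 45, by = 0.5))
  expect_equal(sum(h$n_pairs), 40L * 39L)
})

test_that("a 4-patch toy pattern matches hand-computed bin estimates", {
  w <- rect_window(0, 0, 20, 20)
  p <- pt(c(5, 9, 5, 15), c(5, 5, 12, 15), c(2, 2, 2, 4))
  # centroid distances and edge distances computed by hand
  cd <- as.matrix(dist(cbind(p$x, p$y)))
  ed <- cd - outer(p$diameter / 2, p$diameter / 2, "+")
  h <- pcf_histogram(p, w, breaks = 0:12, edge_correction = "none")
  for (b in seq_len(12)) {
    manual <- sum(ed[upper.tri(ed)] >= b - 1 & ed[upper.tri(ed)] < b) * 2
    expect_equal(h$n_pairs[b], manual)
    expect_equal(
      h$value[b],
      400 * manual / (2 * pi * (b - 0.5) * 4 * 3 * 1)
    )
  }
})

test_that("edge-distance PCF reduces to the centroid PCF for point patches", {
  w <- rect_window(0, 0, 50, 50)
  set.seed(34)
  p <- generate_csr_cohort(w, 60, diameters = rep(1e-9, 60))
  r <- seq(0.5, 10, length.out = 25)
  f <- pcf_edge(p, w, r = r, bandwidth = 1)
  ref <- centroid_pcf_reference(p$x, p$y, w, r, h = 1)
  expect_lt(max(abs(f$value - ref)), 1e-8)
  f0 <- pcf_edge(p, w, r = r, bandwidth = 1, edge_correction = "none")
  ref0 <- centroid_pcf_reference(p$x, p$y, w, r, h = 1, translation = FALSE)
  expect_lt(max(abs(f0$value - ref0)), 1e-8)
})

test_that("PCF input contracts are enforced", {
  w <- rect_window(0, 0, 10, 10)
  expect_error(pcf_edge(pt(5, 5, 1), w), "at least 2")
  p <- pt(c(3, 7), c(5, 5), c(1, 1))
  expect_error(pcf_edge(p, w, r = c(2, 1), bandwidth = 0.5), "increasing")
  expect_error(pcf_edge(p, w, r = 1:3, bandwidth = -1), "positive")
  f <- pcf_edge(p, w, r = seq(0, 2, by = 0.5), bandwidth = 1)
  expect_true(is.na(f$value[f$r == 0]))
  expect_false(any(f$reliable[f$r < 1]))
})

test_that("cross-correlation of independent patterns is near 1 and symmetric", {
  w <- rect_window(0, 0, 100, 100)
  set.seed(35)
  a <- generate_csr_cohort(w, 500, diameters = rep(1e-6, 500))
  b <- generate_csr_cohort(w, 500, diameters = rep(1e-6, 500))
  r <- seq(1, 15, length.out = 30)
  f_ab <- pccf_edge(a, b, w, r = r, bandwidth = 1.5)
  f_ba <- pccf_edge(b, a, w, r = r, bandwidth = 1.5)
  expect_true(all(abs(f_ab$value - 1) < 0.25))
  expect_equal(mean(f_ab$value), 1, tolerance = 0.05)
  expect_lt(max(abs(f_ab$value - f_ba$value)), 1e-10)
})

test_that("constructed attraction elevates the PCCF inside the annulus", {
  w <- rect_window(0, 0, 80, 80)
  set.seed(36)
  n_rep <- 25
  inside_minus_outside <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    adults <- generate_csr_cohort(w, 30, diameters = runif(30, 2, 3))
    b <- impose_interaction(
      generate_csr_cohort(w, 40, diameters = rep(0.3, 40), fixed = adults),
      adults, w, mode = "facilitation", annulus = c(0, 1), strength = 1,
      boost_factor = 10
    )
    f <- pccf_edge(adults, b, w, r = seq(0.25, 6, by = 0.25), bandwidth = 0.5)
    inside <- mean(f$value[f$r >= 0.5 & f$r <= 1])
    outside <- mean(f$value[f$r >= 3 & f$r <= 6])
    inside_minus_outside[i] <- inside - outside
  }
  expect_gte(mean(inside_minus_outside > 0), 0.95)
})

test_that("Stoyan bandwidth follows the intensity rule", {
  expect_equal(stoyan_bandwidth(100, 10000), 0.15 / sqrt(0.01))
  expect_error(stoyan_bandwidth(0, 100))
})
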