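test_that("grids tile the window with fully contained cells", {
  expect_equal(nrow(build_grid(rect_window(0, 0, 42, 42), 21)), 4)
  expect_equal(nrow(build_grid(rect_window(0, 0, 84, 126), 42)), 6)
  expect_equal(nrow(build_grid(rect_window(0, 0, 125, 250), 21)), 55)
  g <- build_grid(rect_window(0, 0, 50, 50), 21, origin_offset = c(4, 4))
  expect_true(all(g$x_min >= 4 & g$x_max <= 50))
  expect_warning(build_grid(rect_window(0, 0, 10, 10), 21), "empty grid")
})

test_that("patches are counted in the half-open cell holding their centroid", {
  w <- rect_window(0, 0, 42, 42)
  g <- build_grid(w, 21)
  one <- pt(10.5, 10.5, 0.3)
  s <- plot_stats(one, g)
  expect_equal(sum(s$n), 1)
  expect_equal(s$n[s$plot_id == 1 & s$cohort == "J_B"], 1)
  # centroid exactly on a shared edge belongs to exactly one plot
  edge <- pt(21, 10, 0.3)
  s2 <- plot_stats(edge, g)
  expect_equal(sum(s2$n), 1)
  expect_equal(unique(s2$plot_id[s2$n > 0]), 2)
  expect_equal(s$density, s$n / 21^2)
})

test_that("plot counts sum to N when the grid tiles the window", {
  w <- rect_window(0, 0, 42, 42)
  set.seed(2)
  p <- generate_csr_cohort(w, 80, model = size_model())
  s <- plot_stats(p, build_grid(w, 21))
  expect_equal(sum(s$n), 80)
  # ragged grid drops patches outside retained plots
  s2 <- plot_stats(p, build_grid(w, 25))
  expect_lte(sum(s2$n), 80)
})

test_that("CSR plot counts have unit index of dispersion", {
  w <- rect_window(0, 0, 105, 231) # exact 5 x 11 tiling at side 21
  set.seed(14)
  p <- generate_csr_cohort(w, 200, diameters = rep(1e-6, 200))
  s <- plot_stats(p, build_grid(w, 21))
  counts <- s$n[s$cohort == "UI"]
  id <- var(counts) / mean(counts)
  # (n-1) * ID ~ chi-square(n-1) under Poisson counts
  bounds <- stats::qchisq(c(0.005, 0.995), df = 54) / 54
  expect_gt(id, bounds[1])
  expect_lt(id, bounds[2])
})

test_that("correlation machinery matches first-principles formulas", {
  set.seed(8)
  a <- rnorm(30)
  b <- 0.5 * a + rnorm(30)
  res <- patchpcf:::cor_result(a, b)
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_manual, tolerance = 1e-12)
  # two-sided t p-value vs a permutation reference
  set.seed(9)
  perm <- replicate(1e4, abs(cor(a, sample(b))))
  expect_lt(abs(mean(perm >= abs(r_manual)) - res$p_value), 0.02)
  # zero variance is flagged, never significant
  degen <- patchpcf:::cor_result(rep(1, 10), rnorm(10))
  expect_true(degen$degenerate)
  expect_false(degen$significant)
})

test_that("distance seed limitation is detected when recruits track adult cover", {
  w <- rect_window(0, 0, 105, 210)
  hits <- 0L
  n_rep <- 30
  set.seed(21)
  for (i in seq_len(n_rep)) {
    adults <- generate_thomas_cohort(w, kappa = 10 / window_area(w), mu = 6,
                                     sigma = 6, cohort = "A_M")$patches
    # recruits confined to seed shadows: within 5 m of adult edges
    ui_xy <- t(vapply(seq_len(100), function(k) {
      repeat {
        a <- sample.int(nrow(adults), 1)
        rho <- adults$diameter[a] / 2 + 0.05 + runif(1, 0, 5)
        th <- runif(1, 0, 2 * pi)
        cx <- adults$x[a] + rho * cos(th)
        cy <- adults$y[a] + rho * sin(th)
        if (cx > 0.1 && cx < 104.9 && cy > 0.1 && cy < 209.9) return(c(cx, cy))
      }
    }, numeric(2)))
    ui <- pt(ui_xy[, 1], ui_xy[, 2], rep(0.1, 100),
             id = max(adults$id) + seq_len(100))
    res <- distance_sl_test(dplyr::bind_rows(adults, ui), w,
                            sides = c(21, 42))
    if (res$verdict == "supported" &&
        any(res$results$r > 0 & res$results$significant, na.rm = TRUE)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("distance-SL rejection rate under independence is near alpha", {
  w <- rect_window(0, 0, 105, 210)
  set.seed(22)
  n_rep <- 150
  sig <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    adults <- generate_thomas_cohort(w, kappa = 12 / window_area(w), mu = 6,
                                     sigma = 6, cohort = "A_M")$patches
    ui <- generate_csr_cohort(w, 100, diameters = rep(0.1, 100), fixed = adults)
    res <- distance_sl_test(dplyr::bind_rows(adults, ui), w, sides = 21)
    sig[i] <- res$results$significant[1]
  }
  # one test at alpha = 0.05; generous binomial band around the nominal level
  expect_gte(mean(sig), 1 / 150)
  expect_lte(mean(sig), 16 / 150)
})

test_that("cohort density correlations separate shared from independent clusters", {
  w <- rect_window(0, 0, 125, 250)
  set.seed(23)
  kappa <- 25 / window_area(w)
  shared <- generate_thomas_cohort(w, kappa, mu = 6, sigma = 5, cohort = "A_M")
  twin <- generate_thomas_cohort(w, kappa, mu = 8, sigma = 5, cohort = "A_S",
                                 fixed = shared$patches, parents = shared$parents)
  indep <- generate_thomas_cohort(
    w, kappa, mu = 25, sigma = 5, cohort = "UI",
    fixed = dplyr::bind_rows(shared$patches, twin$patches)
  )
  all_p <- dplyr::bind_rows(shared$patches, twin$patches, indep$patches)
  corr <- cohort_density_correlations(all_p, build_grid(w, 21))
  same <- corr[corr$cohort_a == "A_S" & corr$cohort_b == "A_M", ]
  expect_gt(same$r, 0.3)
  expect_true(same$significant)
  # self-correlation of a cohort's density with itself is exactly 1
  s <- plot_stats(all_p, build_grid(w, 21))
  am <- s$density[s$cohort == "A_M"]
  expect_equal(cor(am, am), 1)
})

test_that("static/dynamic verdict follows the significant-pair count", {
  fake <- function(n_sig) {
    tibble::tibble(
      cohort_a = rep("UI", 10), cohort_b = rep("J_B", 10),
      r = 0.5, p_value = 0.01, n_plots = 55,
      significant = c(rep(TRUE, n_sig), rep(FALSE, 10 - n_sig)),
      degenerate = FALSE
    )
  }
  expect_equal(static_vs_dynamic(fake(4))$verdict, "dynamic")
  expect_equal(static_vs_dynamic(fake(10))$verdict, "static")
  expect_equal(static_vs_dynamic(fake(0))$verdict, "dynamic")
  # monotone: adding a significant pair never flips static -> dynamic
  v <- vapply(0:10, function(k) static_vs_dynamic(fake(k))$verdict, character(1))
  expect_true(all(diff(v == "static") >= 0))
  expect_error(static_vs_dynamic(fake(4)[1:5, ]), "10")
})
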