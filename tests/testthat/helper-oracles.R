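# Independent reference implementations used as oracles. These are written
# in plain R, directly from the estimator definitions, and share no code with
# the package internals they check.

# classical centroid-distance pair correlation function, kernel-smoothed
centroid_pcf_reference <- function(x, y, window, r, h,
                                   kernel = c("epanechnikov", "box"),
                                   translation = TRUE) {
  kernel <- match.arg(kernel)
  n <- length(x)
  w <- window$x_max - window$x_min
  hh <- window$y_max - window$y_min
  area <- w * hh
  kfun <- function(t) {
    if (kernel == "box") {
      ifelse(t > -h & t <= h, 0.5 / h, 0)
    } else {
      u <- t / h
      ifelse(abs(u) < 1, 0.75 * (1 - u^2) / h, 0)
    }
  }
  s <- numeric(length(r))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      d <- sqrt(dx^2 + dy^2)
      wt <- if (translation) area / ((w - abs(dx)) * (hh - abs(dy))) else 1
      s <- s + 2 * wt * kfun(r - d)
    }
  }
  area * s / (2 * pi * r * n * (n - 1))
}

# brute-force all-pairs isolation check
isolation_reference <- function(patches) {
  n <- nrow(patches)
  vapply(seq_len(n), function(i) {
    if (n == 1) return(TRUE)
    others <- setdiff(seq_len(n), i)
    d <- sqrt((patches$x[i] - patches$x[others])^2 +
                (patches$y[i] - patches$y[others])^2) -
      (patches$diameter[i] + patches$diameter[others]) / 2
    all(d > 0)
  }, logical(1))
}

# quick patch-table literal
pt <- function(x, y, diameter, id = seq_along(x)) {
  tibble::tibble(id = id, x = x, y = y, diameter = diameter,
                 cohort = classify_cohort(diameter))
}

# hand-built envelope object for unit tests of the inference stages
make_envelope <- function(r, observed, sims, reliable = NULL, kind = "pcf") {
  structure(
    list(
      r = r, observed = observed,
      lo = apply(sims, 1, min), hi = apply(sims, 1, max),
      mean = rowMeans(sims), sims = sims,
      reliable = reliable %||% rep(TRUE, length(r)),
      n_sims = ncol(sims), kind = kind
    ),
    class = "patch_envelope"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# point-sized discs so hard-core effects vanish
point_sizes <- function() size_model(meanlog = log(c(1e-6, 1e-6)), sdlog = c(0.01, 0.01))
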