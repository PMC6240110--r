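test_that("five-extreme normalization maps the extremes as documented", {
  ramp <- seq(0, 1, length.out = 100)
  nr <- normalize_profile(ramp)
  ## the 5-point extreme averages sit slightly inside [0, 1], so the
  ## normalized ramp slightly exceeds the unit interval at its ends
  expect_lt(nr[1], 0)
  expect_gt(nr[100], 1)
  expect_equal(mean(sort(nr)[1:5]), 0)
  expect_equal(mean(sort(nr, decreasing = TRUE)[1:5]), 1)
  ## affine invariance
  expect_equal(normalize_profile(3 * ramp + 2), nr)
  ## pass-through mode and preconditions
  expect_identical(normalize_profile(ramp, "none"), ramp)
  expect_error(normalize_profile(ramp[1:9]), "10 samples")
  expect_error(normalize_profile(rep(1, 20)), "degenerate")
})

test_that("cell-first averaging halves an outlier line's weight", {
  x <- seq(0, 10, by = 1)
  base <- rep(1, length(x))
  lines <- rbind(base, base + 10,  # cell 1: one outlier line
                 base, base,       # cell 2
                 base, base)       # cell 3
  av <- average_ensemble(lines, cell_ids = c(1, 1, 2, 2, 3, 3), x = x)
  ## cell-first: cell 1 mean = base + 5, cross-cell mean = base + 5/3
  expect_equal(av$mean, base + 5 / 3)
  ## pooled averaging would give base + 10/6: the outlier's weight halves
  expect_equal(av$n, 3)
  same <- average_ensemble(rbind(base, base), cell_ids = c(1, 2), x = x)
  expect_equal(same$sd, rep(0, length(x)))
})

test_that("decay-length fitting recovers exponentials with baselines", {
  x <- seq(0, 20, by = 0.25)
  expect_equal(fit_decay_length(exp(-x / 8.3), x)$decay_um, 8.3,
               tolerance = 1e-4)
  f <- fit_decay_length(2.5 * exp(-x / 6) + 0.4, x)
  expect_equal(f$decay_um, 6, tolerance = 1e-3)
  expect_equal(f$baseline, 0.4, tolerance = 1e-3)
  expect_error(fit_decay_length(exp(-x / 8) - 0.5, x), "positive")
})

test_that("peak detection matches the closed-form bump position", {
  x <- spatial_grid(35, 0.05)
  p <- rac1_profile(gtpase_params(), x)
  expect_equal(detect_peak(p), 5 * log(2), tolerance = 0.05)
  ## sweep the GAP-strength ratio: detected peak tracks the closed form,
  ## and r >= 1 profiles are edge-peaked
  for (r in c(0.6, 0.3, 0.2, 0.1)) {
    pr <- rac1_profile(gtpase_params(beta_r = r, beta_b = 1), x)
    expect_equal(detect_peak(pr), bump_position(10, 5, r), tolerance = 0.1)
  }
  for (r in c(1, 2)) {
    pr <- rac1_profile(gtpase_params(beta_r = r, beta_b = 1), x)
    pk <- detect_peak(pr)
    expect_true(is.na(pk))
    expect_true(isTRUE(attr(pk, "edge_peaked")))
  }
  ## monotone Cdc42 profile is edge-peaked
  expect_true(is.na(detect_peak(cdc42_profile(gtpase_params(), x))))
})

test_that("extent measurement equals lambda ln 2 for pure exponentials", {
  ## infinite-window, zero-baseline limit
  x <- seq(0, 200, by = 0.05)
  v <- exp(-x / 7)
  expect_equal(measure_extent(v, x), 7 * log(2), tolerance = 0.01)
  ## calibrated shape round trip on the default window
  cdc <- calibrate_cdc42_shape()
  expect_equal(measure_extent(normalize_profile(cdc$values), cdc$x), 8.9,
               tolerance = 0.01)
  ## no crossing within the window is flagged, not fabricated
  flat <- measure_extent(seq(1, 0.8, length.out = 50), seq(0, 49))
  expect_true(is.na(flat))
  expect_true(isTRUE(attr(flat, "censored")))
})

test_that("pointwise rank-sum comparison is empty for identical ensembles", {
  cdc <- calibrate_cdc42_shape()
  cfg <- generator_config()
  a <- sample_fret_profiles(cdc, 19, cfg, seed = 1)
  b <- sample_fret_profiles(cdc, 19, cfg, seed = 1)
  cmp <- pointwise_compare(a, b)
  expect_equal(sum(cmp$significant), 0)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_error(pointwise_compare(a$values[1:4, ], b$values), "5 cells")
})

test_that("differently shaped ensembles differ where the shapes differ", {
  cfg <- generator_config()
  cdc <- calibrate_cdc42_shape()
  rac <- calibrate_rac1_shape()
  a <- sample_fret_profiles(cdc, 19, cfg, seed = 21)
  b <- sample_fret_profiles(rac, 31, cfg, seed = 22)
  ## compare normalized per-cell profiles (cross-reporter convention)
  an <- a; an$values <- t(apply(a$values, 1, normalize_profile))
  bn <- b; bn$values <- t(apply(b$values, 1, normalize_profile))
  cmp <- pointwise_compare(an, bn)
  near_edge <- cmp$x <= 3
  expect_gt(mean(cmp$significant[near_edge]), 0.5)
})

test_that("input-output extent comparison discriminates the two GAP models", {
  x <- spatial_grid(35, 0.05)
  rec <- membrane_recruitment(linear_gradient(slope_class = 4), 5)
  gef_o <- opto_gef_profile(rec, 100)
  gef_e <- regulator_profile("GEF", "exponential", 1, decay_length = 10)
  gap_u <- regulator_profile("GAP", "uniform", 0.5)
  gap_b <- regulator_profile("GAP", "exponential", 1, decay_length = 5)
  input <- activity_profile(x, rec$value)
  ## uniform GAP: output mirrors the input (match)
  out_u <- steady_state_ratio(list(gef_o, gef_e), gap_u, x)
  m_u <- profiles_match(input, out_u)
  expect_true(m_u$match)
  ## localized GAP: the output is reshaped, extent grows beyond resolution
  out_b <- steady_state_ratio(list(gef_o, gef_e), list(gap_u, gap_b), x)
  m_b <- profiles_match(input, out_b)
  expect_false(m_b$match)
  expect_gt(m_b$difference, 2)
  ## identical profiles match with difference 0
  m_id <- profiles_match(input, input)
  expect_true(m_id$match)
  expect_equal(m_id$difference, 0)
})

test_that("ratio images are exact on constants and background-invariant", {
  n <- 40
  mask <- disk_mask(n, 20, 20, 12)
  fret <- matrix(200, n, n); donor <- matrix(100, n, n)
  r <- ratio_image(fret, donor, mask, bg_fret = 0, bg_donor = 0)
  expect_true(all(r[mask] == 2))
  expect_true(all(is.na(r[!mask])))
  r2 <- ratio_image(fret + 30, donor + 30, mask, bg_fret = 30,
                    bg_donor = 30)
  expect_equal(r2[mask], r[mask])
  expect_error(ratio_image(fret, matrix(1, n, n), mask, bg_fret = 0,
                           bg_donor = 5), "low-signal")
})

test_that("linescans are rotation-invariant and width-symmetric", {
  n <- 101
  xs <- matrix(rep(1:n, each = n), n, n)
  img <- exp(-(xs - 10) / 20)  # laterally uniform horizontal gradient
  base <- linescan(img, c(10, 51), 0, 15, width_px = 10, pixel_size_um = 0.25)
  w1 <- linescan(img, c(10, 51), 0, 15, width_px = 1, pixel_size_um = 0.25)
  expect_equal(base$value, w1$value, tolerance = 1e-12)
  ## rotate the sampling geometry on a radially symmetric image
  ys <- t(xs)
  rad <- exp(-sqrt((xs - 51)^2 + (ys - 51)^2) / 15)
  l0 <- linescan(rad, c(51, 51), 0, 10, width_px = 1, pixel_size_um = 0.25)
  l37 <- linescan(rad, c(51, 51), 37, 10, width_px = 1,
                  pixel_size_um = 0.25)
  expect_lt(max(abs(l0$value - l37$value)) / max(l0$value), 0.02)
  expect_error(linescan(rad, c(51, 51), 0, 100, pixel_size_um = 0.25),
               "bounds")
})

test_that("edge enrichment counts rim-bright perimeter segments", {
  n <- 120; px <- 0.25
  mask <- disk_mask(n, 60, 60, 40)
  d_in <- as.array(EBImage::distmap(EBImage::Image(mask * 1))) * px
  base <- matrix(100, n, n)
  set.seed(4)
  noisy <- base + matrix(rnorm(n * n, 0, 3), n, n)
  expect_equal(edge_enrichment_fraction(noisy, mask, px), 0.5,
               tolerance = 0.15)
  ## bright rim on 60% of the perimeter (noiseless elsewhere -> exact ties
  ## count as not enriched)
  xs <- matrix(rep(1:n, each = n), n, n); ys <- t(xs)
  ang <- atan2(ys - 60, xs - 60)
  rim60 <- mask & d_in > 0 & d_in <= 1 & ang > -pi & ang < (-pi + 0.6 * 2 * pi)
  expect_equal(edge_enrichment_fraction(base + 50 * rim60, mask, px), 0.6,
               tolerance = 0.05)
  rim_all <- mask & d_in > 0 & d_in <= 1
  expect_gt(edge_enrichment_fraction(base + 50 * rim_all, mask, px), 0.95)
  expect_error(edge_enrichment_fraction(base, disk_mask(n, 5, 60, 40), px),
               "border")
})
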