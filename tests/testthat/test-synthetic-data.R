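test_that("Cdc42 shape calibration hits its summary-statistic targets", {
  cdc <- calibrate_cdc42_shape()
  expect_gt(cdc$plateau_um, 0)
  ## round trip: quantification of the noiseless shape returns the targets
  expect_equal(measure_extent(normalize_profile(cdc$values), cdc$x), 8.9,
               tolerance = 0.01)
  expect_equal(
    fit_decay_length(cdc$values, cdc$x,
                     fit_range = c(cdc$plateau_um, 20))$decay_um,
    8.3, tolerance = 0.02 * 8.3)
  ## as the extent target approaches the windowed extent of the plain
  ## exponential, the plateau vanishes
  x <- seq(0, 200, by = 0.25)
  e0 <- measure_extent(normalize_profile(exp(-x / 8)), x)
  pure <- calibrate_cdc42_shape(target_decay = 8, target_extent = e0 + 0.1,
                                window_um = 200, spacing_um = 0.25)
  expect_lt(pure$plateau_um, 0.5)
  expect_error(calibrate_cdc42_shape(target_extent = 25), "window")
})

test_that("Rac1 shape calibration hits its summary-statistic targets", {
  rac <- calibrate_rac1_shape()
  expect_equal(detect_peak(rac$values, rac$x), 5.8, tolerance = 0.01)
  expect_equal(measure_extent(normalize_profile(rac$values), rac$x), 14.6,
               tolerance = 0.01)
  ## the asymptotic tail is the tail-decay target by construction, and the
  ## closed-form bump position at the calibrated parameters sits near the
  ## peak target (detect_peak smoothing accounts for the small offset)
  expect_equal(rac$lambda_um, 9.6)
  expect_equal(bump_position(rac$lambda_um, rac$gamma_um, rac$r), 5.8,
               tolerance = 0.05)
  ## the model-aware tail fit recovers the asymptotic decay exactly
  expect_equal(fit_localized_gap_profile(rac$values, rac$x)$tail_decay_um,
               9.6, tolerance = 0.01)
  expect_error(calibrate_rac1_shape(target_peak = 16), "peak")
})

test_that("profile ensembles have the configured noise structure", {
  cdc <- calibrate_cdc42_shape()
  cfg0 <- generator_config(amplitude_sigma = 0, noise_sigma = 0)
  e0 <- sample_fret_profiles(cdc, 5, cfg0, seed = 1)
  for (i in 1:5) expect_equal(e0$values[i, ], cdc$values)

  ## determinism: same seed, identical ensembles
  cfg <- generator_config()
  e1 <- sample_fret_profiles(cdc, 19, cfg, seed = 42)
  e2 <- sample_fret_profiles(cdc, 19, cfg, seed = 42)
  expect_identical(e1$values, e2$values)

  ## ensemble mean converges to (mean amplitude) x shape at large n
  big <- sample_fret_profiles(cdc, 1000, cfg, seed = 7)
  expected <- mean(big$amplitudes) * cdc$values
  tol <- 3 * cfg$noise_sigma * max(cdc$values) / sqrt(1000)
  expect_lt(max(abs(colMeans(big$values) - expected)), tol)

  ## per-position s.d. scales as configured
  flat_sd <- apply(big$values - outer(big$amplitudes, cdc$values), 2, sd)
  expect_equal(mean(flat_sd), cfg$noise_sigma * max(cdc$values),
               tolerance = 0.05)
})

test_that("rendered image stacks round-trip to the input profile", {
  cfg <- generator_config()
  rec <- membrane_recruitment(linear_gradient(slope_class = 4), 5)
  st <- render_cell_images(rec, cfg, n_frames = 3, n_prestim = 1,
                           shot_noise = FALSE, read_sd = 0)
  diffst <- subtract_prestimulus(st)
  expect_equal(attr(diffst, "clipped_fraction"), 0)
  ls <- linescan(diffst$reporter[, , 1], st$edge_origin_px, 0, 34,
                 width_px = 10, pixel_size_um = cfg$pixel_size_um)
  truth <- approx(rec$x, rec$value, xout = ls$x, rule = 2)$y * 100
  interior <- ls$x >= 1 & ls$x <= 33
  expect_lt(max(abs(ls$value - truth)[interior]) / max(truth), 0.01)

  ## with default noise, 10-px averaged recovery stays within 5% of peak
  ## (signed differential: per-frame clipping would bias dim regions)
  set.seed(11)
  stn <- render_cell_images(rec, cfg, n_frames = 12, n_prestim = 2)
  dn <- subtract_prestimulus(stn, clip_negative = FALSE)
  expect_gt(attr(dn, "clipped_fraction"), 0)
  expect_lt(attr(dn, "clipped_fraction"), 0.5)
  avg <- Reduce(`+`, lapply(seq_len(dim(dn$reporter)[3]), function(t)
    dn$reporter[, , t])) / dim(dn$reporter)[3]
  lsn <- linescan(avg, stn$edge_origin_px, 0, 34, width_px = 10,
                  pixel_size_um = cfg$pixel_size_um)
  rmse <- sqrt(mean((lsn$value - truth)[interior]^2))
  expect_lt(rmse / max(truth), 0.05)
})

test_that("image stacks survive the TIFF + sidecar round trip", {
  cfg <- generator_config(image_px = 60, pixel_size_um = 0.25)
  rec <- membrane_recruitment(linear_gradient(slope_class = 2,
                                              diameter_um = 14,
                                              grid = spatial_grid(14, 0.05)),
                              5)
  st <- render_cell_images(rec, cfg, diameter_um = 14, n_frames = 2,
                           n_prestim = 1, seed = 3)
  prefix <- file.path(tempdir(), "stack_test")
  write_image_stack(st, prefix)
  st2 <- read_image_stack(prefix)
  expect_equal(dim(st2$reporter), dim(st$reporter))
  ## 16-bit quantization at the recorded intensity scale
  expect_lt(max(abs(st2$reporter - st$reporter)),
            2 * max(st$reporter) / 65535)
  expect_identical(st2$mask, st$mask)
  expect_equal(st2$pixel_size_um, st$pixel_size_um)
  expect_equal(st2$n_prestim, st$n_prestim)
})

test_that("migration simulation honors its degenerate limits", {
  ## zero speed: measured instantaneous speed sits below the noise floor
  still <- simulate_migration(mean_speed_um_min = 0, kappa = 2,
                              duration_min = 20, frame_interval_min = 2,
                              n_cells = 2, speed_sd = 0, seed = 5)
  masks <- segment_cells(still$movies[[1]])
  traj <- track_centroid(masks, still$pixel_size_um,
                         still$frame_interval_min)
  expect_lt(instantaneous_speed(traj)$mean_speed_um_min, 0.15)

  ## kappa -> Inf: all headings at 0, so angular precision -> 1
  tight <- simulate_migration(kappa = 1e8, n_cells = 12,
                              render_movies = FALSE, seed = 6)
  expect_lt(max(abs(tight$truth$heading_rad)), 1e-3)

  ## kappa = 0: uniform headings, mean resultant length ~ 1/sqrt(n)
  set.seed(8)
  unif <- rvonmises(1000, 0, 0)
  expect_lt(angular_precision(unif, n_boot = 10)$precision, 0.06)
  expect_gt(suppressWarnings(stats::ks.test(unif,
                                            "punif", -pi, pi)$p.value),
            0.01)
})
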