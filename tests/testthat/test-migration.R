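test_that("segmentation recovers disks and rejects ambiguous fields", {
  n <- 120
  img <- matrix(0.05, n, n)
  img[disk_mask(n, 60, 60, 30)] <- 1
  masks <- segment_cells(list(img))
  expect_equal(sum(masks[[1]]) / sum(disk_mask(n, 60, 60, 30)), 1,
               tolerance = 0.02)
  two <- matrix(0.05, n, n)
  two[disk_mask(n, 30, 30, 25)] <- 1
  two[disk_mask(n, 90, 90, 25)] <- 1
  expect_error(segment_cells(list(two)), "dominant")
})

test_that("centroid tracking is exact for translated masks", {
  n <- 80
  masks <- lapply(0:3, function(k) disk_mask(n, 30 + 2 * k, 40, 15))
  traj <- track_centroid(masks, pixel_size_um = 0.5, frame_interval_min = 1)
  expect_equal(diff(traj$x_um), rep(1, 3), tolerance = 1e-9)
  expect_equal(diff(traj$y_um), rep(0, 3), tolerance = 1e-9)
  static <- track_centroid(rep(masks[1], 4), 0.5, 1)
  expect_equal(diff(static$x_um), rep(0, 3))
})

test_that("segmentation-based centroids track ground truth closely", {
  ens <- simulate_migration(mean_speed_um_min = 0.5, kappa = 2,
                            duration_min = 30, frame_interval_min = 2,
                            n_cells = 3, seed = 13)
  for (ci in 1:3) {
    masks <- segment_cells(ens$movies[[ci]])
    traj <- track_centroid(masks, ens$pixel_size_um,
                           ens$frame_interval_min)
    err <- sqrt((traj$x_um - ens$tracks[[ci]][, 1])^2 +
                  (traj$y_um - ens$tracks[[ci]][, 2])^2)
    expect_lt(max(err), 0.5)
  }
})

test_that("instantaneous speed is exact for uniform motion and bounded for noise", {
  traj <- structure(data.frame(frame = 1:21, t_min = (0:20) * 2,
                               x_um = (0:20) * 1.2, y_um = 0),
                    class = c("trajectory", "data.frame"))
  expect_equal(instantaneous_speed(traj)$mean_speed_um_min, 0.6)
  ## interval averaging selects the requested window
  expect_equal(instantaneous_speed(traj,
                                   interval_min = c(15, 45))$mean_speed_um_min,
               0.6)
  expect_error(instantaneous_speed(traj, interval_min = c(100, 120)),
               "interval")
  ## stationary cell with tracking noise: positive bias ~ sigma sqrt(pi)/dt
  set.seed(9)
  sigma <- 0.1; dt <- 2
  est <- replicate(200, {
    tn <- structure(data.frame(frame = 1:16, t_min = (0:15) * dt,
                               x_um = rnorm(16, 0, sigma),
                               y_um = rnorm(16, 0, sigma)),
                    class = c("trajectory", "data.frame"))
    instantaneous_speed(tn)$mean_speed_um_min
  })
  floor_theory <- sigma * sqrt(pi) / dt  # E|step| for 2D Gaussian steps
  expect_equal(mean(est), floor_theory, tolerance = 0.1 * floor_theory)
})

test_that("displacement angles follow the track geometry", {
  mk <- function(xs, ys) structure(
    data.frame(frame = seq_along(xs), t_min = seq_along(xs) - 1,
               x_um = xs, y_um = ys),
    class = c("trajectory", "data.frame"))
  expect_equal(displacement_angle(mk(0:9, rep(0, 10))), 0)
  expect_equal(abs(displacement_angle(mk(9:0, rep(0, 10)))), pi)
  ## net drift at 30 degrees with noise stays within a noise bound
  set.seed(10)
  th <- 30 * pi / 180
  xs <- (0:19) * cos(th) + rnorm(20, 0, 0.05)
  ys <- (0:19) * sin(th) + rnorm(20, 0, 0.05)
  expect_equal(displacement_angle(mk(xs, ys)), th, tolerance = 0.02)
  ## zero displacement is flagged, not fabricated
  a0 <- displacement_angle(mk(rep(1, 10), rep(1, 10)))
  expect_true(is.na(a0))
  expect_true(isTRUE(attr(a0, "undefined")))
  expect_error(displacement_angle(mk(1:5, 1:5)), "6 frames")
})

test_that("angular precision is the mean resultant length with seeded bootstrap", {
  ident <- angular_precision(rep(0.7, 10), n_boot = 50, seed = 1)
  expect_equal(ident$precision, 1)
  expect_true(all(ident$boot == 1))
  anti <- angular_precision(rep(c(0, pi), 8), n_boot = 10, seed = 1)
  expect_equal(anti$precision, 0, tolerance = 1e-12)
  set.seed(2)
  unif <- runif(1000, -pi, pi)
  expect_lt(angular_precision(unif, n_boot = 10, seed = 1)$precision, 0.06)
  ## rotation invariance of the point estimate
  set.seed(3)
  a <- rvonmises(40, 0, 3)
  p1 <- angular_precision(a, n_boot = 10, seed = 5)$precision
  rotated <- ((a + 1.1 + pi) %% (2 * pi)) - pi
  p2 <- angular_precision(rotated, n_boot = 10, seed = 5)$precision
  expect_equal(p1, p2, tolerance = 1e-12)
  ## bootstrap reproducibility and convergence to the point estimate
  b1 <- angular_precision(a, n_boot = 1000, seed = 7)
  b2 <- angular_precision(a, n_boot = 1000, seed = 7)
  expect_identical(b1$boot, b2$boot)
  b3 <- angular_precision(a, n_boot = 1e4, seed = 8)
  expect_equal(mean(b3$boot), b3$precision, tolerance = 0.02)
  expect_error(angular_precision(c(0, 1), n_boot = 10), "3")
})

test_that("morphodynamic maps read zero for static and isotropic growth", {
  n <- 200
  m1 <- disk_mask(n, 100, 100, 60)
  static <- morphodynamic_map(list(m1, m1), 0, 180, pixel_size_um = 1,
                              frame_interval_min = 1)
  expect_equal(max(abs(static$velocity)), 0)
  ## uniformly dilating disk: constant positive velocity, and the map mean
  ## times the perimeter matches the area change rate (Green's check)
  m2 <- disk_mask(n, 100, 100, 62)
  grow <- morphodynamic_map(list(m1, m2), 0, 360, pixel_size_um = 1,
                            frame_interval_min = 1)
  expect_true(all(grow$velocity > 0))
  expect_equal(mean(grow$velocity), 2, tolerance = 0.15)
  flux <- mean(grow$velocity) * 2 * pi * 61
  expect_equal(flux / (sum(m2) - sum(m1)), 1, tolerance = 0.05)
})

test_that("directed migration shows a protrusive band on the gradient axis", {
  ens <- simulate_migration(mean_speed_um_min = 0.6, kappa = 1e8,
                            duration_min = 40, frame_interval_min = 2,
                            n_cells = 1, seed = 17)
  masks <- segment_cells(ens$movies[[1]])
  mm <- morphodynamic_map(masks, ens$gradient_axis_deg, 180,
                          ens$pixel_size_um, ens$frame_interval_min)
  front <- abs(mm$contour_coord) < pi / 3
  back <- abs(abs(mm$contour_coord) - pi) < pi / 3
  expect_gt(mean(mm$velocity[front, ], na.rm = TRUE), 0.2)
  expect_lt(mean(mm$velocity[back, ], na.rm = TRUE), -0.2)
})

test_that("kappa estimation inverts the mean resultant length without bias", {
  set.seed(20)
  ## I1/I0 inversion is exact on noiseless resultant lengths
  for (k in c(0.5, 2, 8)) {
    r <- besselI(k, 1, expon.scaled = TRUE) /
      besselI(k, 0, expon.scaled = TRUE)
    expect_equal(mrl_to_kappa(r), k, tolerance = 1e-6)
  }
  ## the small-sample corrected estimator is nearly unbiased at n = 18
  ests <- replicate(400, estimate_kappa(rvonmises(18, 0, 2)))
  expect_equal(mean(ests), 2, tolerance = 0.15)
})

test_that("trajectories round-trip through CSV", {
  traj <- structure(data.frame(frame = 1:6, t_min = (0:5) * 2,
                               x_um = 1:6, y_um = rep(2, 6)),
                    class = c("trajectory", "data.frame"))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f, cell_id = 3)
  back <- read_trajectory_csv(f)
  expect_equal(length(back), 1)
  expect_equal(back[["3"]]$x_um, traj$x_um)
})
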