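#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle; large `kappa` concentrates tightly around
#' `mu`. Implemented in-package because no circular-statistics dependency is
#' used.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (kappa == 0) {
    th <- stats::runif(n, -pi, pi)
    return(wrap_angle(th + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      c_ <- kappa * (rr - f)
      if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
        out[i] <- sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out + mu)
}

wrap_angle <- function(th) {
  w <- (th + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' Simulate an ensemble of migrating cells with ground truth
#'
#' Emulates the optogenetic migration assay: cells released from a round
#' micropattern migrate with a per-cell heading drawn from a von Mises
#' distribution centered on the gradient axis (angle 0) and a mean speed with
#' Gaussian per-frame jitter. Each cell is rendered as a fluorescence mask
#' movie: a disk with a smooth radial boundary perturbation and a mild
#' protrusive elongation toward the heading, translating along the track, so
#' morphodynamic maps show a positive edge-velocity band centered on the
#' gradient direction. Ground truth (headings, speeds, centroid tracks, seed)
#' is stored alongside the movies for recovery testing.
#'
#' @param mean_speed_um_min mean migration speed, um/min.
#' @param kappa von Mises concentration of headings about the gradient axis
#'   (>= 0; 0 = undirected).
#' @param duration_min movie duration, min (>= 3 frames).
#' @param frame_interval_min frame interval, min.
#' @param n_cells number of cells.
#' @param speed_sd Gaussian per-frame speed jitter, um/min.
#' @param cell_diameter_um cell diameter, um (default 35, the pattern size).
#' @param pixel_size_um rendering pixel size, um/px (default 0.5).
#' @param wobble relative amplitude of the radial boundary perturbation.
#' @param elongation relative elongation toward the heading.
#' @param fg_level,bg_level,noise_sd fluorescence rendering parameters.
#' @param render_movies render fluorescence movies (default `TRUE`); when
#'   `FALSE` only ground-truth tracks are generated (fast path for
#'   trajectory-level statistics).
#' @param seed optional integer seed.
#' @return a `trajectory_ensemble`: list with per-cell `movies` (list of 3D
#'   intensity arrays), `truth` (data.frame of heading, mean speed), `tracks`
#'   (list of true centroid matrices, um), and the condition parameters.
#' @export
simulate_migration <- function(mean_speed_um_min = 0.5, kappa = 2,
                               duration_min = 60, frame_interval_min = 2,
                               n_cells = 18, speed_sd = 0.1,
                               cell_diameter_um = 35, pixel_size_um = 0.5,
                               wobble = 0.02, elongation = 0.06,
                               fg_level = 1, bg_level = 0.05,
                               noise_sd = 0.02, render_movies = TRUE,
                               seed = NULL) {
  n_frames <- floor(duration_min / frame_interval_min) + 1
  if (n_frames < 3) stop("duration must span at least 3 frames")
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  R <- cell_diameter_um / 2
  travel <- mean_speed_um_min * duration_min
  field_um <- 2 * R + 2 * travel + 10
  n_px <- ceiling(field_um / pixel_size_um)
  headings <- rvonmises(n_cells, 0, kappa)

  movies <- vector("list", n_cells)
  tracks <- vector("list", n_cells)
  nharm <- 4
  for (ci in seq_len(n_cells)) {
    th <- headings[ci]
    speeds <- pmax(stats::rnorm(n_frames - 1, mean_speed_um_min, speed_sd), 0)
    steps <- speeds * frame_interval_min
    start <- c(field_um / 2 - travel * cos(th) / 2,
               field_um / 2 - travel * sin(th) / 2)
    pos <- rbind(start,
                 cbind(start[1] + cumsum(steps * cos(th)),
                       start[2] + cumsum(steps * sin(th))))
    ## smooth boundary perturbation: random Fourier modes of order >= 2 per
    ## cell (order-1 modes translate the centroid off the ground-truth
    ## track), phases drifting slowly over time
    harm <- seq(2, nharm + 1)
    amps <- stats::rnorm(nharm, 0, wobble)
    phases <- stats::runif(nharm, 0, 2 * pi)
    drift <- stats::rnorm(nharm, 0, 0.2)
    if (!render_movies) {
      tracks[[ci]] <- cbind(pos[, 1] + elongation * R * cos(th),
                            pos[, 2] + elongation * R * sin(th))
      next
    }
    mov <- array(0, c(n_px, n_px, n_frames))
    xs <- matrix(rep(seq_len(n_px), each = n_px), n_px, n_px) * pixel_size_um
    ys <- matrix(rep(seq_len(n_px), times = n_px), n_px, n_px) * pixel_size_um
    for (t in seq_len(n_frames)) {
      dx <- xs - pos[t, 1]
      dy <- ys - pos[t, 2]
      phi <- atan2(dy, dx)
      pert <- rep(0, length(phi))
      for (k in seq_len(nharm))
        pert <- pert + amps[k] * cos(harm[k] * phi + phases[k] +
                                       drift[k] * t)
      r_phi <- R * (1 + pert + elongation * cos(phi - th))
      inside <- dx^2 + dy^2 <= r_phi^2
      frame <- ifelse(inside, fg_level, bg_level)
      if (noise_sd > 0)
        frame <- pmax(frame + matrix(stats::rnorm(n_px^2, 0, noise_sd), n_px),
                      0)
      mov[, , t] <- frame
    }
    movies[[ci]] <- mov
    ## ground truth is the centroid of the rendered (protrusion-biased)
    ## shape: the elongation lobe shifts it by ~elongation * R along the
    ## heading relative to the disk center
    tracks[[ci]] <- cbind(pos[, 1] + elongation * R * cos(th),
                          pos[, 2] + elongation * R * sin(th))
  }
  if (!render_movies) movies <- NULL
  structure(list(movies = movies, tracks = tracks,
                 truth = data.frame(cell = seq_len(n_cells),
                                    heading_rad = headings,
                                    mean_speed_um_min = mean_speed_um_min),
                 condition = list(mean_speed_um_min = mean_speed_um_min,
                                  kappa = kappa,
                                  duration_min = duration_min,
                                  frame_interval_min = frame_interval_min,
                                  speed_sd = speed_sd),
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 gradient_axis_deg = 0, seed = seed),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %d cells, %d frames at %g min (speed %g um/min, kappa %g)%s\n",
    length(x$tracks), nrow(x$tracks[[1]]), x$frame_interval_min,
    x$condition$mean_speed_um_min, x$condition$kappa,
    if (is.null(x$movies)) " [tracks only]" else ""))
  invisible(x)
}

#' Ground-truth track as a trajectory
#'
#' Converts a true centroid track from [simulate_migration()] into the
#' `trajectory` class used by the analysis functions.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param cell cell index.
#' @return a `trajectory`.
#' @export
true_trajectory <- function(ensemble, cell) {
  pos <- ensemble$tracks[[cell]]
  structure(data.frame(frame = seq_len(nrow(pos)),
                       t_min = (seq_len(nrow(pos)) - 1) *
                         ensemble$frame_interval_min,
                       x_um = pos[, 1], y_um = pos[, 2]),
            class = c("trajectory", "data.frame"))
}
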