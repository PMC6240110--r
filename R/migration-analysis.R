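#' Threshold segmentation of single-cell fluorescence movies
#'
#' Per frame: global Otsu threshold, largest connected component, holes
#' filled. The field must contain a single dominant cell; frames whose
#' second-largest component is comparable to the largest (> half its area)
#' raise an error.
#'
#' @param frames 3D intensity array `[rows, cols, frames]` or list of
#'   matrices.
#' @return list of logical masks, one per frame.
#' @export
segment_cells <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  lapply(frames, function(fr) {
    rng <- range(fr)
    if (diff(rng) <= 0) stop("segmentation error: constant frame")
    norm <- (fr - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm))
    bw <- norm > th
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    areas <- table(lab[lab > 0])
    if (length(areas) == 0) stop("segmentation error: empty mask")
    areas <- sort(areas, decreasing = TRUE)
    if (length(areas) > 1 && areas[2] > 0.5 * areas[1])
      stop("segmentation error: more than one dominant object in the field")
    keep <- as.integer(names(areas)[1])
    mask <- matrix(lab == keep, nrow(fr), ncol(fr))
    filled <- EBImage::fillHull(EBImage::Image(mask * 1))
    matrix(as.array(filled) > 0, nrow(fr), ncol(fr))
  })
}

#' Centroid track of a segmented cell
#'
#' Area centroid of each mask, converted to um.
#'
#' @param masks list of logical masks (one per frame).
#' @param pixel_size_um pixel size, um/px.
#' @param frame_interval_min frame interval, min.
#' @return a `trajectory`: data.frame with `frame`, `t_min`, `x_um`, `y_um`.
#' @export
track_centroid <- function(masks, pixel_size_um, frame_interval_min = 1) {
  cent <- t(vapply(masks, function(m) {
    if (!any(m)) stop("segmentation error: empty mask")
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]))  # (x = col, y = row)
  }, numeric(2)))
  structure(data.frame(frame = seq_along(masks),
                       t_min = (seq_along(masks) - 1) * frame_interval_min,
                       x_um = cent[, 1] * pixel_size_um,
                       y_um = cent[, 2] * pixel_size_um),
            class = c("trajectory", "data.frame"))
}

#' Windowed instantaneous migration speed
#'
#' Frame-to-frame centroid displacement divided by the frame interval,
#' boxcar-smoothed over `smoothing_window` consecutive frames (default 5),
#' then averaged over the requested time interval. Note the estimator has a
#' positive noise floor: for a stationary cell with isotropic Gaussian
#' tracking noise of s.d. sigma per coordinate, the expected step length is
#' `sigma * sqrt(pi)` per frame.
#'
#' @param traj a `trajectory` (or data.frame with `t_min`, `x_um`, `y_um`).
#' @param smoothing_window boxcar width in frames (default 5).
#' @param interval_min optional `c(t0, t1)` averaging window in min; default
#'   is the whole trajectory.
#' @return list with `mean_speed_um_min` and a `series` data.frame
#'   (`t_min`, `speed_um_min`, smoothed).
#' @export
instantaneous_speed <- function(traj, smoothing_window = 5,
                                interval_min = NULL) {
  if (nrow(traj) < 2) stop("trajectory too short")
  dt <- diff(traj$t_min)
  v <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2) / dt
  t_mid <- (traj$t_min[-1] + traj$t_min[-nrow(traj)]) / 2
  k <- min(smoothing_window, length(v))
  sm <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  ## shrink the boxcar at the ends instead of dropping frames
  for (i in which(is.na(sm))) {
    lo <- max(1, i - (k %/% 2)); hi <- min(length(v), i + (k %/% 2))
    sm[i] <- mean(v[lo:hi])
  }
  if (is.null(interval_min)) interval_min <- range(t_mid)
  sel <- t_mid >= interval_min[1] & t_mid <= interval_min[2]
  if (!any(sel))
    stop("averaging interval lies outside the trajectory")
  list(mean_speed_um_min = mean(sm[sel]),
       series = data.frame(t_min = t_mid, speed_um_min = sm))
}

#' Net displacement angle relative to the gradient axis
#'
#' The displacement vector runs from the initial centroid (mean of the first
#' three frames) to the final centroid (mean of the last three frames); the
#' returned angle is measured against the stimulation-gradient axis, in
#' (-pi, pi], with 0 = toward the gradient maximum. Zero net displacement is
#' undefined: `NA_real_` with attribute `undefined = TRUE` (excluded from
#' precision statistics).
#'
#' @param traj a `trajectory` with at least 6 frames.
#' @param gradient_axis_deg gradient direction in image coordinates, degrees.
#' @return angle in radians, or `NA_real_`.
#' @export
displacement_angle <- function(traj, gradient_axis_deg = 0) {
  if (nrow(traj) < 6) stop("at least 6 frames are required")
  p0 <- c(mean(traj$x_um[1:3]), mean(traj$y_um[1:3]))
  nlast <- nrow(traj)
  p1 <- c(mean(traj$x_um[(nlast - 2):nlast]),
          mean(traj$y_um[(nlast - 2):nlast]))
  v <- p1 - p0
  if (sqrt(sum(v^2)) < 1e-9)
    return(structure(NA_real_, undefined = TRUE))
  wrap_angle(atan2(v[2], v[1]) - gradient_axis_deg * pi / 180)
}

#' Angular precision of a set of displacement angles
#'
#' The mean resultant length
#' \deqn{p = \sqrt{(\frac{1}{n}\sum \sin\theta_i)^2 +
#'                 (\frac{1}{n}\sum \cos\theta_i)^2} \in [0, 1],}
#' which is 1 iff all angles coincide (mod 2pi) and ~1/sqrt(n) for uniform
#' angles. The sampling distribution is obtained by bootstrap (resampling the
#' n angles with replacement, default 1000 replicates, seeded); the point
#' estimate on the original sample is primary and the bootstrap s.d. is the
#' reported uncertainty. `NA` angles (undefined displacements) are excluded
#' and counted.
#'
#' @param angles displacement angles, radians.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return an `angular_stats` object: list with `precision`, `boot_sd`,
#'   `boot` (replicate values), `n`, `n_excluded`.
#' @export
angular_precision <- function(angles, n_boot = 1000, seed = NULL) {
  excl <- sum(is.na(angles))
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 3) stop("at least 3 non-degenerate angles are required")
  mrl <- function(th) sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b)
    mrl(angles[sample.int(n, n, replace = TRUE)]), numeric(1))
  structure(list(precision = mrl(angles), boot_sd = stats::sd(boot),
                 boot = boot, n = n, n_excluded = excl),
            class = "angular_stats")
}

#' @export
print.angular_stats <- function(x, ...) {
  cat(sprintf(
    "<angular_stats> precision %.3f +/- %.3f (bootstrap s.d., n = %d%s)\n",
    x$precision, x$boot_sd, x$n,
    if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Invert the mean resultant length to a von Mises concentration
#'
#' Solves \eqn{I_1(\kappa)/I_0(\kappa) = p} for `kappa` (0 for p <= 0,
#' Inf for p >= 1).
#'
#' @param p mean resultant length in \[0, 1).
#' @return concentration estimate.
#' @export
mrl_to_kappa <- function(p) {
  vapply(p, function(r) {
    if (r <= 0) return(0)
    if (r >= 1) return(Inf)
    a_ratio <- function(k)
      besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
    stats::uniroot(function(k) a_ratio(k) - r, c(1e-8, 1e4),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Von Mises concentration of a sample of angles
#'
#' Maximum-likelihood concentration via mean-resultant-length inversion with
#' Fisher's small-sample bias correction (the raw inversion overestimates
#' kappa noticeably below n ~ 30).
#'
#' @param angles sample of angles, radians (`NA`s dropped).
#' @return bias-corrected concentration estimate.
#' @export
estimate_kappa <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 3) stop("at least 3 angles are required")
  k <- mrl_to_kappa(sqrt(mean(sin(angles))^2 + mean(cos(angles))^2))
  if (k < 2) max(k - 2 / (n * k), 0) else k * (n - 1)^3 / (n^3 + n)
}

#' Morphodynamic (edge-velocity) map of a mask movie
#'
#' For each pair of consecutive frames the contour of the earlier mask is
#' resampled to `n_contour_points` by arc length, starting at the point in
#' the gradient direction from the centroid and proceeding counter-clockwise;
#' the local edge velocity is the signed distance from each contour point to
#' the next frame's mask boundary (positive outward, via distance
#' transforms) divided by the frame interval. Rows are ordered so that
#' contour coordinate 0 (the gradient direction) sits in the middle of the
#' map.
#'
#' @param masks list of logical masks (simply connected).
#' @param gradient_axis_deg gradient direction, degrees.
#' @param n_contour_points contour samples per frame (default 360).
#' @param pixel_size_um pixel size, um/px.
#' @param frame_interval_min frame interval, min.
#' @return a `morphodynamic_map`: list with `velocity` (matrix contour x
#'   time, um/min), `contour_coord` (radians in (-pi, pi], 0 = gradient
#'   direction), `t_min`.
#' @export
morphodynamic_map <- function(masks, gradient_axis_deg = 0,
                              n_contour_points = 360, pixel_size_um,
                              frame_interval_min = 1) {
  n_frames <- length(masks)
  if (n_frames < 2) stop("at least 2 frames are required")
  vel <- matrix(NA_real_, n_contour_points, n_frames - 1)
  axis_rad <- gradient_axis_deg * pi / 180
  for (t in seq_len(n_frames - 1)) {
    pts <- tryCatch(
      contour_points(masks[[t]], n_contour_points, axis_rad),
      error = function(e) NULL)
    if (is.null(pts)) next  # topology problem: leave the column missing
    ## signed distance fields (positive inside); differencing the two
    ## frames' fields at the same sub-pixel contour points cancels the
    ## half-pixel bias of the discrete distance transform
    phi <- function(m) {
      as.array(EBImage::distmap(EBImage::Image(m * 1))) -
        as.array(EBImage::distmap(EBImage::Image((!m) * 1)))
    }
    d1 <- interp_bilinear(phi(masks[[t]]), pts[, 1], pts[, 2])
    d2 <- interp_bilinear(phi(masks[[t + 1]]), pts[, 1], pts[, 2])
    vel[, t] <- (d2 - d1) * pixel_size_um / frame_interval_min
  }
  ## center the map: row order by signed contour coordinate
  coord <- wrap_angle(2 * pi * (seq_len(n_contour_points) - 1) /
                        n_contour_points)
  ord <- order(coord)
  structure(list(velocity = vel[ord, , drop = FALSE],
                 contour_coord = coord[ord],
                 t_min = (seq_len(n_frames - 1)) * frame_interval_min,
                 gradient_axis_deg = gradient_axis_deg),
            class = "morphodynamic_map")
}

## Resample the outer contour of a mask to n points by arc length,
## counter-clockwise, starting at the boundary point in direction
## `start_angle` from the centroid. Returns (n x 2) (x, y) pixel coords.
contour_points <- function(mask, n, start_angle = 0) {
  cont <- mask_contour(mask)
  cent <- c(mean(which(mask, arr.ind = TRUE)[, 2]),
            mean(which(mask, arr.ind = TRUE)[, 1]))
  ang <- atan2(cont[, 2] - cent[2], cont[, 1] - cent[1])
  ## enforce counter-clockwise orientation (positive signed area)
  xs <- cont[, 1]; ys <- cont[, 2]
  area2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
  if (area2 < 0) {
    cont <- cont[rev(seq_len(nrow(cont))), ]
    ang <- rev(ang)
  }
  start <- which.min(abs(wrap_angle(ang - start_angle)))
  cont <- rbind(cont[start:nrow(cont), , drop = FALSE],
                cont[seq_len(start - 1), , drop = FALSE])
  seg <- sqrt(rowSums((cont - rbind(cont[-1, ], cont[1, ]))^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  want <- seq(0, total, length.out = n + 1)[-(n + 1)]
  closed <- rbind(cont, cont[1, ])
  xi <- stats::approx(cum, closed[, 1], xout = want)$y
  yi <- stats::approx(cum, closed[, 2], xout = want)$y
  cbind(xi, yi)
}

#' @export
print.morphodynamic_map <- function(x, ...) {
  cat(sprintf("<morphodynamic_map> %d contour points x %d intervals\n",
              nrow(x$velocity), ncol(x$velocity)))
  invisible(x)
}

#' @export
plot.morphodynamic_map <- function(x, ...) {
  graphics::image(x$t_min, x$contour_coord, t(x$velocity),
                  xlab = "time (min)",
                  ylab = "contour coordinate (rad, 0 = gradient)",
                  main = "edge velocity (um/min)", ...)
  invisible(x)
}

#' Write a trajectory as CSV (frame, t_min, x_um, y_um, cell_id)
#' @param traj a `trajectory`.
#' @param path file path.
#' @param cell_id cell identifier column value.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, cell_id = 1) {
  d <- cbind(as.data.frame(traj), cell_id = cell_id)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$cell_id), function(di) {
    structure(di[order(di$frame),
                 c("frame", "t_min", "x_um", "y_um")],
              class = c("trajectory", "data.frame"))
  })
}
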