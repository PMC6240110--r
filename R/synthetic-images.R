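#' Render a TIRF-like two-channel image stack of a patterned cell
#'
#' A 35 um disk-shaped cell (the micropattern footprint) is rendered with a
#' reporter channel whose intensity follows a 1D profile applied along the
#' stimulation axis (distance measured from the illuminated cell edge) on top
#' of a uniform baseline, and a uniform reference channel. Pre-stimulus
#' frames contain the baseline only. Noise is Poisson shot noise plus
#' Gaussian read noise; set `shot_noise = FALSE` and `read_sd = 0` for
#' noiseless renders.
#'
#' @param profile 1D signal profile (an `activity_profile`,
#'   `recruitment_profile`, or numeric values with `profile_x`): recruited
#'   reporter density versus distance from the cell edge, covering the disk
#'   diameter.
#' @param config a [generator_config()].
#' @param profile_x grid of the profile (if numeric).
#' @param diameter_um cell/pattern diameter, um (default 35).
#' @param n_frames total frames (default 5).
#' @param n_prestim pre-stimulus frames (default 1).
#' @param baseline baseline intensity inside the cell, counts (default 100).
#' @param amplitude intensity scale of the signal at profile value 1, counts
#'   (default 100).
#' @param bg_level background intensity outside the cell (default 10).
#' @param stim_axis_deg gradient direction in image coordinates (default 0).
#' @param shot_noise apply Poisson noise (default TRUE).
#' @param read_sd Gaussian read noise s.d., counts (default 2).
#' @param seed optional integer seed.
#' @return a `cell_image_stack`; the edge point where the profile starts is
#'   recorded in `edge_origin_px`.
#' @export
render_cell_images <- function(profile, config = generator_config(),
                               profile_x = NULL, diameter_um = 35,
                               n_frames = 5, n_prestim = 1, baseline = 100,
                               amplitude = 100, bg_level = 10,
                               stim_axis_deg = 0, shot_noise = TRUE,
                               read_sd = 2, seed = NULL) {
  p <- as_xv(if (inherits(profile, "recruitment_profile"))
    list(x = profile$x, value = profile$value) else profile, profile_x)
  if (max(p$x) < diameter_um - 1e-9)
    stop("config error: profile window must cover the disk diameter")
  if (!is.null(seed)) set.seed(seed)
  n <- config$image_px
  px <- config$pixel_size_um
  if (n * px < diameter_um)
    stop("config error: image too small for the cell diameter")
  cx <- (n + 1) / 2
  radius_px <- diameter_um / 2 / px
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index (x)
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index (y)
  mask <- (xs - cx)^2 + (ys - cx)^2 <= radius_px^2

  th <- stim_axis_deg * pi / 180
  ## distance from the illuminated edge along the stimulation axis
  proj <- ((xs - cx) * cos(th) + (ys - cx) * sin(th) + radius_px) * px
  signal <- matrix(stats::approx(p$x, p$value, xout = pmin(proj, max(p$x)),
                                 rule = 2)$y, n, n)
  clean_post <- ifelse(mask, baseline + amplitude * signal, bg_level)
  clean_pre <- ifelse(mask, baseline, bg_level)

  add_noise <- function(img) {
    out <- if (shot_noise)
      matrix(stats::rpois(length(img), img), nrow(img)) else img
    if (read_sd > 0)
      out <- out + matrix(stats::rnorm(length(img), 0, read_sd), nrow(img))
    pmax(out, 0)
  }
  reporter <- array(0, c(n, n, n_frames))
  reference <- array(0, c(n, n, n_frames))
  ref_clean <- ifelse(mask, baseline, bg_level)
  for (t in seq_len(n_frames)) {
    clean <- if (t <= n_prestim) clean_pre else clean_post
    reporter[, , t] <- add_noise(clean)
    reference[, , t] <- add_noise(ref_clean)
  }
  edge <- c(cx - radius_px * cos(th), cx - radius_px * sin(th))
  cell_image_stack(reporter, reference, mask, pixel_size_um = px,
                   frame_interval_min = config$frame_interval_min,
                   stim_axis_deg = stim_axis_deg, n_prestim = n_prestim,
                   edge_origin_px = edge)
}
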