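#' FRET/donor ratio image
#'
#' Per-pixel background-subtracted ratio within the cell mask; pixels outside
#' the mask are `NA`. Backgrounds default to the mean intensity outside the
#' mask in each channel. Adding the same constant to a channel and its
#' background estimate leaves the ratio unchanged.
#'
#' @param fret,donor registered intensity matrices of the same shape.
#' @param mask logical cell mask.
#' @param bg_fret,bg_donor scalar backgrounds; estimated outside the mask
#'   when `NULL`.
#' @return matrix of ratios (`NA` outside the mask).
#' @export
ratio_image <- function(fret, donor, mask, bg_fret = NULL, bg_donor = NULL) {
  stopifnot(all(dim(fret) == dim(donor)), all(dim(mask) == dim(fret)))
  mask <- mask > 0
  if (is.null(bg_fret)) bg_fret <- mean(fret[!mask])
  if (is.null(bg_donor)) bg_donor <- mean(donor[!mask])
  den <- donor - bg_donor
  bad <- mask & den <= 0
  if (sum(bad) > 0.01 * sum(mask))
    stop("low-signal error: donor - background <= 0 at > 1% of mask pixels")
  out <- matrix(NA_real_, nrow(fret), ncol(fret))
  ok <- mask & den > 0
  out[ok] <- (fret[ok] - bg_fret) / den[ok]
  out
}

#' Subtract the pre-stimulus baseline from an image stack
#'
#' The mean of the pre-stimulus frames is subtracted from every post-stimulus
#' frame so that only stimulus-induced recruitment remains (avoiding volume
#' artifacts). With `clip_negative = TRUE` (default) negative differences are
#' clipped to zero and the clipped fraction is recorded in the
#' `clipped_fraction` attribute; with `clip_negative = FALSE` the signed
#' differential images are kept (preferable when frames are averaged
#' afterwards, since per-frame clipping biases dim regions upward).
#'
#' @param stack a `cell_image_stack` with at least one pre-stimulus frame.
#' @param clip_negative clip negative differences to zero (default `TRUE`).
#' @return a `cell_image_stack` of the differential post-stimulus frames
#'   (`n_prestim = 0`).
#' @export
subtract_prestimulus <- function(stack, clip_negative = TRUE) {
  stopifnot(inherits(stack, "cell_image_stack"))
  if (stack$n_prestim < 1)
    stop("at least one pre-stimulus frame is required")
  pre <- seq_len(stack$n_prestim)
  post <- setdiff(seq_len(dim(stack$reporter)[3]), pre)
  baseline <- apply(stack$reporter[, , pre, drop = FALSE], c(1, 2), mean)
  diffed <- stack$reporter[, , post, drop = FALSE]
  for (t in seq_along(post)) diffed[, , t] <- diffed[, , t] - baseline
  clipped <- mean(diffed < 0)
  if (clip_negative) diffed[diffed < 0] <- 0
  out <- cell_image_stack(pmax(diffed, 0),
                          if (!is.null(stack$reference))
                            stack$reference[, , post, drop = FALSE],
                          stack$mask, stack$pixel_size_um,
                          stack$frame_interval_min, stack$stim_axis_deg,
                          n_prestim = 0,
                          edge_origin_px = stack$edge_origin_px)
  if (!clip_negative) out$reporter <- diffed  # signed differential kept
  attr(out, "clipped_fraction") <- clipped
  out
}

## Vectorized bilinear interpolation; xq/yq in pixel coordinates where
## pixel (i, j) = (col x, row y) has center (j, i). Out-of-range -> NA.
interp_bilinear <- function(img, xq, yq) {
  nr <- nrow(img); nc <- ncol(img)
  j0 <- floor(xq); i0 <- floor(yq)
  fj <- xq - j0;   fi <- yq - i0
  ok <- j0 >= 1 & j0 <= nc - 1 & i0 >= 1 & i0 <= nr - 1
  out <- rep(NA_real_, length(xq))
  if (!any(ok)) return(out)
  j0 <- j0[ok]; i0 <- i0[ok]; fj <- fj[ok]; fi <- fi[ok]
  v00 <- img[cbind(i0, j0)]
  v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]
  v11 <- img[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - fi) * (1 - fj) + v01 * (1 - fi) * fj +
    v10 * fi * (1 - fj) + v11 * fi * fj
  out
}

#' Linescan across an image
#'
#' Intensity sampled by bilinear interpolation along a line starting at the
#' cell edge, averaged across a perpendicular width of `width_px` pixels
#' (default 10, the convention used for manual linescans in protrusive
#' regions). Sampling spacing equals the pixel size.
#'
#' @param image intensity matrix.
#' @param origin_px start of the line `c(x, y)` in pixel coordinates (the
#'   cell edge; position 0).
#' @param direction_deg direction of increasing distance, degrees (0 = +x).
#' @param length_um line length in um.
#' @param width_px averaging width in pixels (>= 1); symmetric around the
#'   line for odd widths, offset by half a pixel for even widths.
#' @param pixel_size_um pixel size, um/px.
#' @return an `activity_profile` (species "reporter").
#' @export
linescan <- function(image, origin_px, direction_deg, length_um, width_px = 10,
                     pixel_size_um) {
  if (width_px < 1) stop("`width_px` must be >= 1")
  th <- direction_deg * pi / 180
  d <- c(cos(th), sin(th))      # along-line unit vector (x, y)
  nvec <- c(-sin(th), cos(th))  # perpendicular unit vector
  pos <- seq(0, length_um, by = pixel_size_um)
  offs <- (seq_len(width_px) - (width_px + 1) / 2)  # px offsets across width
  vals <- matrix(NA_real_, length(pos), width_px)
  for (k in seq_len(width_px)) {
    xq <- origin_px[1] + pos / pixel_size_um * d[1] + offs[k] * nvec[1]
    yq <- origin_px[2] + pos / pixel_size_um * d[2] + offs[k] * nvec[2]
    vals[, k] <- interp_bilinear(image, xq, yq)
  }
  if (any(is.na(vals)))
    stop("geometry error: linescan exits the image bounds")
  ## differential images can dip below zero, so this is a plain linescan
  ## profile rather than a (non-negative) model activity
  structure(list(x = pos, value = rowMeans(vals), species = "reporter",
                 condition = "linescan", width_px = width_px),
            class = c("linescan", "activity_profile"))
}

#' Fraction of the cell perimeter enriched at the edge
#'
#' The mask boundary is discretized into arc segments (default 1 um of arc
#' length). For each segment the mean intensity in the outer 1 um-thick band
#' just inside the cell edge is compared with the adjacent band on its
#' cytosolic side (1-2 um deep); the returned value is the fraction of
#' segments where the edge band is brighter. A spatially uniform cell gives
#' about 0.5 (noise-driven coin flips); a cell with a bright rim along its
#' whole perimeter gives about 1.
#'
#' @param image intensity matrix.
#' @param mask logical cell mask, not touching the image border.
#' @param pixel_size_um pixel size, um/px.
#' @param band_um thickness of each band, um (default 1).
#' @param arc_um arc length of a boundary segment, um (default 1).
#' @return fraction in \[0, 1\].
#' @export
edge_enrichment_fraction <- function(image, mask, pixel_size_um,
                                     band_um = 1, arc_um = 1) {
  mask <- mask > 0
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("geometry error: mask touches the image border")
  contour <- mask_contour(mask)  # ordered boundary, pixel coords (x, y)
  seglen <- sqrt(rowSums((contour - rbind(contour[-1, ], contour[1, ]))^2))
  cum <- cumsum(c(0, seglen[-length(seglen)])) * pixel_size_um
  seg_id <- floor(cum / arc_um) + 1
  d_in <- EBImage::distmap(EBImage::Image(mask * 1)) * pixel_size_um
  idx <- which(mask & d_in > 0, arr.ind = TRUE)
  depth <- d_in[idx]
  band <- ifelse(depth <= band_um, 1L, ifelse(depth <= 2 * band_um, 2L, 0L))
  keep <- band > 0
  idx <- idx[keep, , drop = FALSE]
  band <- band[keep]
  ## assign each band pixel to the nearest contour point's segment
  px <- idx[, 2]; py <- idx[, 1]
  nearest <- vapply(seq_along(px), function(i)
    which.min((contour[, 1] - px[i])^2 + (contour[, 2] - py[i])^2),
    integer(1))
  pix_seg <- seg_id[nearest]
  vals <- image[idx]
  segs <- sort(unique(seg_id))
  enriched <- vapply(segs, function(s) {
    outer_m <- vals[pix_seg == s & band == 1L]
    inner_m <- vals[pix_seg == s & band == 2L]
    if (length(outer_m) == 0 || length(inner_m) == 0) return(NA)
    mean(outer_m) > mean(inner_m)
  }, logical(1))
  mean(enriched, na.rm = TRUE)
}

## Ordered outer contour of a logical mask as a (n x 2) matrix of (x, y)
## pixel coordinates (1-based, matrix row = y, column = x).
mask_contour <- function(mask) {
  img <- EBImage::Image(mask * 1)
  oc <- EBImage::ocontour(EBImage::bwlabel(img))
  if (length(oc) == 0) stop("empty mask")
  biggest <- which.max(vapply(oc, nrow, integer(1)))
  cont <- oc[[biggest]] + 1  # ocontour is 0-based
  ## EBImage images are indexed [x, y]; our matrices are [row=y, col=x],
  ## and Image(mask) transposes nothing: Image dims = dim(mask) = (rows, cols)
  ## so ocontour's first column runs along matrix rows. Swap to (x=col, y=row).
  cbind(x = cont[, 2], y = cont[, 1])
}
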