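#' Two-channel time-lapse image stack
#'
#' Container for synthetic or imported TIRF-like acquisitions of a single
#' cell: a reporter channel, an optional reference (donor) channel, a cell
#' mask, and acquisition metadata.
#'
#' @param reporter 3D array `[rows, cols, frames]` of non-negative
#'   intensities (a matrix is promoted to one frame).
#' @param reference optional 3D array of the same shape.
#' @param mask logical matrix, the cell footprint.
#' @param pixel_size_um pixel size, um/px.
#' @param frame_interval_min time between frames, min.
#' @param stim_axis_deg direction of the stimulation gradient in image
#'   coordinates (0 = +x, i.e. the gradient decays along +x).
#' @param n_prestim number of pre-stimulus frames at the start of the stack.
#' @param edge_origin_px pixel coordinates `c(x, y)` of the cell edge point
#'   where profiles start (x = 0).
#' @return an object of class `cell_image_stack`.
#' @export
cell_image_stack <- function(reporter, reference = NULL, mask,
                             pixel_size_um, frame_interval_min = 1,
                             stim_axis_deg = 0, n_prestim = 0,
                             edge_origin_px = NULL) {
  if (is.matrix(reporter))
    reporter <- array(reporter, dim = c(dim(reporter), 1))
  stopifnot(length(dim(reporter)) == 3)
  if (any(reporter < 0))
    stop("intensities must be non-negative")
  if (!is.null(reference)) {
    if (is.matrix(reference))
      reference <- array(reference, dim = c(dim(reference), 1))
    stopifnot(all(dim(reference) == dim(reporter)))
  }
  stopifnot(is.matrix(mask), all(dim(mask) == dim(reporter)[1:2]))
  if (n_prestim >= dim(reporter)[3])
    stop("`n_prestim` must leave at least one post-stimulus frame")
  structure(list(reporter = reporter, reference = reference,
                 mask = mask > 0, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 stim_axis_deg = stim_axis_deg, n_prestim = n_prestim,
                 edge_origin_px = edge_origin_px),
            class = "cell_image_stack")
}

#' @export
print.cell_image_stack <- function(x, ...) {
  d <- dim(x$reporter)
  cat(sprintf(
    "<cell_image_stack> %dx%d px, %d frames (%d pre-stimulus), %g um/px\n",
    d[1], d[2], d[3], x$n_prestim, x$pixel_size_um))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Channels are written as `<prefix>_reporter.tif` and (if present)
#' `<prefix>_reference.tif` (16-bit, one page per frame, intensities scaled
#' by the `intensity_scale` recorded in the sidecar) and metadata plus the
#' mask to `<prefix>.json`.
#'
#' @param stack a `cell_image_stack`.
#' @param prefix file path prefix (no extension).
#' @return `write_image_stack` returns `prefix` invisibly; `read_image_stack`
#'   returns a `cell_image_stack`.
#' @export
write_image_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "cell_image_stack"))
  scale <- max(stack$reporter, stack$reference, 1e-12)
  pages <- function(a) lapply(seq_len(dim(a)[3]),
                              function(t) a[, , t] / scale)
  tiff::writeTIFF(pages(stack$reporter),
                  paste0(prefix, "_reporter.tif"),
                  bits.per.sample = 16L, reduce = FALSE)
  if (!is.null(stack$reference))
    tiff::writeTIFF(pages(stack$reference),
                    paste0(prefix, "_reference.tif"),
                    bits.per.sample = 16L, reduce = FALSE)
  meta <- list(intensity_scale = scale,
               pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               stim_axis_deg = stack$stim_axis_deg,
               n_prestim_frames = stack$n_prestim,
               channels = c("reporter",
                            if (!is.null(stack$reference)) "reference"),
               edge_origin_px = stack$edge_origin_px,
               mask_rle = list(lengths = rle(as.vector(stack$mask))$lengths,
                               values = rle(as.vector(stack$mask))$values,
                               nrow = nrow(stack$mask)))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  to_array <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
      (meta$intensity_scale %||% 1)
  }
  reporter <- to_array(paste0(prefix, "_reporter.tif"))
  reference <- if ("reference" %in% meta$channels)
    to_array(paste0(prefix, "_reference.tif"))
  mask_vec <- inverse.rle(list(lengths = meta$mask_rle$lengths,
                               values = as.logical(meta$mask_rle$values)))
  mask <- matrix(mask_vec, nrow = meta$mask_rle$nrow)
  cell_image_stack(reporter, reference, mask,
                   pixel_size_um = meta$pixel_size_um,
                   frame_interval_min = meta$frame_interval_min,
                   stim_axis_deg = meta$stim_axis_deg,
                   n_prestim = meta$n_prestim_frames,
                   edge_origin_px = meta$edge_origin_px)
}
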