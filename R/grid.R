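#' Uniform spatial grid of distances from the cell edge
#'
#' All profiles in the package live on a uniform 1D grid of distances from
#' the cell edge, in micrometers. `x = 0` is the protruding edge; the default
#' domain length is 35 um, the diameter of the round micropatterns that
#' constrain cell shape in the stimulation experiments.
#'
#' @param length_um domain length in um (default 35).
#' @param spacing_um grid spacing in um (default 0.05).
#' @return numeric vector of positions, starting at 0, uniformly spaced.
#' @examples
#' x <- spatial_grid(35, 0.05)
#' head(x)
#' @export
spatial_grid <- function(length_um = 35, spacing_um = 0.05) {
  if (!is.numeric(length_um) || length_um <= 0)
    stop("`length_um` must be a positive number")
  if (!is.numeric(spacing_um) || spacing_um <= 0)
    stop("`spacing_um` must be a positive number")
  if (spacing_um >= length_um)
    stop("`spacing_um` must be smaller than `length_um`")
  seq(0, length_um, by = spacing_um)
}

## Validate that `x` is a uniform grid starting at 0; returns the spacing.
check_grid <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("a spatial grid needs at least two positions")
  if (abs(x[1]) > 1e-9)
    stop("spatial grid must start at 0 (the cell edge)")
  dx <- diff(x)
  if (any(dx <= 0) || (max(dx) - min(dx)) > 1e-8 * mean(dx))
    stop("spatial grid must be strictly increasing and uniformly spaced")
  mean(dx)
}

#' Activity profile container
#'
#' A 1D profile of active GTPase (or reporter fluorescence) versus distance
#' from the cell edge. Values are in arbitrary units; the model performs no
#' global normalization (normalization is a quantification-stage concern).
#'
#' @param x spatial grid (um from the cell edge).
#' @param value non-negative, finite values, one per grid position.
#' @param species one of "Cdc42", "Rac1", "reporter".
#' @param condition free-text condition label (e.g. "wild-type", "siCdc42").
#' @return an object of class `activity_profile`.
#' @export
activity_profile <- function(x, value, species = "reporter",
                             condition = "model") {
  check_grid(x)
  if (length(value) != length(x))
    stop("`value` must have one entry per grid position")
  if (any(!is.finite(value)))
    stop("activity values must be finite at every grid point")
  if (any(value < 0))
    stop("activity values must be non-negative")
  structure(list(x = as.numeric(x), value = as.numeric(value),
                 species = species, condition = condition),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s (%s): %d points on [0, %g] um\n",
              x$species, x$condition, length(x$x), max(x$x)))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.activity_profile <- function(x, ...) {
  data.frame(x_um = x$x, value = x$value, species = x$species,
             condition = x$condition, stringsAsFactors = FALSE)
}

#' @export
plot.activity_profile <- function(x, ...) {
  graphics::plot(x$x, x$value, type = "l",
                 xlab = "distance from cell edge (um)",
                 ylab = "activity (a.u.)",
                 main = sprintf("%s (%s)", x$species, x$condition), ...)
  invisible(x)
}

## Accept either an activity_profile-like object or raw vectors.
## Returns list(x, value).
as_xv <- function(profile, x = NULL) {
  if (inherits(profile, "activity_profile") ||
      (is.list(profile) && !is.null(profile$x) && !is.null(profile$value)))
    return(list(x = profile$x, value = profile$value))
  if (is.null(x))
    stop("supply an activity_profile, or `x` alongside a numeric vector")
  list(x = x, value = as.numeric(profile))
}

#' Write / read a profile as CSV
#'
#' Columns: `x_um`, `value`, `species`, `condition`.
#'
#' @param profile an `activity_profile`.
#' @param path file path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns an `activity_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  activity_profile(d$x_um, d$value, species = d$species[1],
                   condition = d$condition[1])
}
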