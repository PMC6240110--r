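#' Linear light gradient on a round micropattern
#'
#' DMD-patterned illumination along the stimulation axis. Slope classes
#' follow the gradient nomenclature of the stimulation experiments: a 1x
#' gradient spans the full cell diameter, a 2x gradient spans half of it
#' (hence twice the slope for the same amplitude), and so on. Custom
#' (amplitude, extent) pairs allow designs that decouple slope, amplitude,
#' and spatial extent.
#'
#' @param slope_class 1, 2, 3 or 4 (or "1x".."4x"); mutually exclusive with
#'   `extent_um`.
#' @param extent_um distance in um over which the ramp falls to zero; must be
#'   in `(0, diameter_um]`.
#' @param diameter_um micropattern diameter in um (default 35).
#' @param amplitude relative peak intensity in `(0, 1]` (8-bit DMD gray
#'   levels are mapped to \[0, 1\]).
#' @param grid spatial grid; defaults to the cell diameter at 0.05 um.
#' @return an object of class `illumination_pattern` with fields `x`,
#'   `intensity`, `extent_um`, `amplitude`, `slope_class`.
#' @examples
#' g4 <- linear_gradient(slope_class = 4)
#' max(g4$x[g4$intensity > 0])  # ramp support is a quarter diameter
#' @export
linear_gradient <- function(slope_class = NULL, extent_um = NULL,
                            diameter_um = 35, amplitude = 1, grid = NULL) {
  if (is.null(grid)) grid <- spatial_grid(diameter_um)
  check_grid(grid)
  if (!is.null(slope_class)) {
    if (!is.null(extent_um))
      stop("give either `slope_class` or `extent_um`, not both")
    sc <- as.numeric(sub("x$", "", as.character(slope_class)))
    if (is.na(sc) || sc <= 0)
      stop("`slope_class` must be one of 1, 2, 3, 4 (or '1x'..'4x')")
    extent_um <- diameter_um / sc
  } else {
    sc <- diameter_um / extent_um
  }
  if (is.null(extent_um) || extent_um <= 0 || extent_um > diameter_um)
    stop("`extent_um` must be in (0, diameter]")
  if (amplitude <= 0 || amplitude > 1)
    stop("`amplitude` must be in (0, 1]")
  structure(list(x = grid,
                 intensity = amplitude * pmax(0, 1 - grid / extent_um),
                 extent_um = extent_um, amplitude = amplitude,
                 slope_class = sc, diameter_um = diameter_um),
            class = "illumination_pattern")
}

#' Uniform illumination (control condition)
#'
#' @inheritParams linear_gradient
#' @return an `illumination_pattern` with constant intensity.
#' @export
uniform_illumination <- function(amplitude = 1, diameter_um = 35,
                                 grid = NULL) {
  if (is.null(grid)) grid <- spatial_grid(diameter_um)
  check_grid(grid)
  if (amplitude <= 0 || amplitude > 1)
    stop("`amplitude` must be in (0, 1]")
  structure(list(x = grid, intensity = rep(amplitude, length(grid)),
                 extent_um = Inf, amplitude = amplitude, slope_class = NA,
                 diameter_um = max(grid)),
            class = "illumination_pattern")
}

#' Membrane recruitment of the optogenetic dimer under patterned light
#'
#' Light-recruited CRY2/CIBN dimers diffuse laterally at the membrane before
#' unbinding, which adds an exponentially decaying tail of characteristic
#' length `kernel_um` (measured as 5 um) to the illumination pattern. The
#' forward model convolves the illumination with the steady-state Green's
#' function of lateral diffusion with first-order unbinding, a symmetric
#' two-sided exponential \eqn{e^{-|x|/\ell}/(2\ell)}, under no-flux
#' (reflecting) boundaries at both cell edges, implemented by the method of
#' images. Each source column is renormalized to unit mass on the domain, so
#' the total recruited amount equals the total illumination dose exactly and
#' uniform light yields uniform recruitment.
#'
#' @param pattern an `illumination_pattern`.
#' @param kernel_um characteristic diffusion length of the kernel, um (> 0).
#' @return an object of class `recruitment_profile` with fields `x`, `value`,
#'   `kernel_um`, `pattern`.
#' @export
membrane_recruitment <- function(pattern, kernel_um = 5) {
  stopifnot(inherits(pattern, "illumination_pattern"))
  if (!is.numeric(kernel_um) || kernel_um <= 0)
    stop("`kernel_um` must be > 0")
  x <- pattern$x
  dx <- check_grid(x)
  L <- max(x)
  g <- function(d) exp(-abs(d) / kernel_um) / (2 * kernel_um)
  ## method of images for no-flux boundaries at 0 and L
  W <- matrix(0, length(x), length(x))
  dmat <- outer(x, x, `-`)
  smat <- outer(x, x, `+`)
  for (k in -2:2) {
    W <- W + g(dmat + 2 * k * L) + g(smat + 2 * k * L)
  }
  ## per-source mass renormalization (corrects discretization of the cusp)
  W <- sweep(W, 2, colSums(W) * dx, `/`)
  value <- as.vector(W %*% pattern$intensity) * dx
  structure(list(x = x, value = value, kernel_um = kernel_um,
                 pattern = pattern),
            class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf(
    "<recruitment_profile> kernel %g um, %d points on [0, %g] um\n",
    x$kernel_um, length(x$x), max(x$x)))
  invisible(x)
}

#' Fit the characteristic length of a recruitment tail
#'
#' Inverse check of the recruitment model: beyond the edge of an
#' illumination pattern the recruited density decays with the kernel's
#' characteristic length. On a closed domain the reflecting far boundary
#' bends the tail into \eqn{\cosh((L-x)/\ell)}; by default the fit uses this
#' boundary-corrected shape (least squares with the amplitude profiled out,
#' robust to additive measurement noise), which reduces to an exponential
#' fit far from the boundary. Set `correct_boundary = FALSE` for the plain
#' log-linear slope estimate (requires strictly positive values).
#'
#' @param profile a `recruitment_profile`, or anything with `x` and `value`.
#' @param boundary_um position of the illumination edge, um.
#' @param guess_um initial guess for the length (default 5 um); sets the
#'   default fit range `[boundary + guess, boundary + 4 * guess]` (clipped to
#'   the domain).
#' @param fit_range optional explicit range `c(lo, hi)` in um.
#' @param correct_boundary account for the reflecting far boundary (default
#'   `TRUE`).
#' @return fitted characteristic length in um.
#' @export
fit_tail_length <- function(profile, boundary_um, guess_um = 5,
                            fit_range = NULL, correct_boundary = TRUE) {
  p <- as_xv(profile)
  L <- max(p$x)
  if (is.null(fit_range))
    fit_range <- c(boundary_um + guess_um,
                   min(boundary_um + 4 * guess_um, L))
  sel <- p$x >= fit_range[1] & p$x <= fit_range[2]
  if (sum(sel) < 4)
    stop("fit range contains fewer than 4 samples")
  xs <- p$x[sel]
  vs <- p$value[sel]
  if (!correct_boundary) {
    if (any(vs <= 0))
      stop("fit-domain error: non-positive values in the fitted range")
    slope <- stats::coef(stats::lm(log(vs) ~ xs))[2]
    if (slope >= 0) stop("fit-domain error: tail is not decaying")
    return(as.numeric(-1 / slope))
  }
  if (all(vs <= 0))
    stop("fit-domain error: non-positive values in the fitted range")
  ss <- function(ell) {
    ## cosh((L - x)/ell) scaled to its value at the range start, to keep
    ## the profiled amplitude well conditioned
    h <- cosh((L - xs) / ell) / cosh((L - xs[1]) / ell)
    a <- sum(vs * h) / sum(h * h)
    sum((vs - a * h)^2)
  }
  stats::optimize(ss, interval = c(guess_um / 10, guess_um * 10))$minimum
}

#' Convert a recruitment profile into an optogenetic GEF term
#'
#' The recruited GEF density times its activation rate gives a tabulated GEF
#' regulator ready to be appended to the GEF list of [steady_state_ratio()].
#' In the stimulation experiments the optogenetic term dominates the
#' endogenous GEF activity (`alpha_opto >> alpha_c`).
#'
#' @param recruitment a `recruitment_profile`.
#' @param alpha_opto activation rate (>= 0); 0 encodes the no-activation
#'   control.
#' @return a tabulated GEF `regulator_profile`.
#' @export
opto_gef_profile <- function(recruitment, alpha_opto) {
  stopifnot(inherits(recruitment, "recruitment_profile"))
  if (!is.numeric(alpha_opto) || alpha_opto < 0)
    stop("`alpha_opto` must be >= 0")
  regulator_profile("GEF", "tabulated",
                    values = alpha_opto * recruitment$value,
                    x = recruitment$x)
}

#' Write an illumination or recruitment profile as CSV (x_um, value)
#' @param object an `illumination_pattern` or `recruitment_profile`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_opto_csv <- function(object, path) {
  v <- if (inherits(object, "illumination_pattern")) object$intensity
       else object$value
  utils::write.csv(data.frame(x_um = object$x, value = v), path,
                   row.names = FALSE)
  invisible(path)
}
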