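#' Spatial profile of a GTPase regulator (GEF or GAP)
#'
#' A regulator profile carries the product of a concentration profile and its
#' effective rate, i.e. the term \eqn{\alpha_i [GEF]_i(x)} or
#' \eqn{\beta_i [GAP]_i(x)} entering the steady-state activity ratio. Three
#' forms are supported: spatially uniform, exponentially decaying from the
#' cell edge, and tabulated on a grid (e.g. an optogenetically recruited GEF).
#'
#' @param role "GEF" or "GAP".
#' @param form "uniform", "exponential" or "tabulated".
#' @param amplitude effective rate at the cell edge, arbitrary units, >= 0.
#' @param decay_length decay length in um (> 0); exponential form only.
#' @param values tabulated non-negative rates; tabulated form only.
#' @param x grid on which `values` are tabulated; tabulated form only.
#' @return an object of class `regulator_profile`.
#' @examples
#' gef <- regulator_profile("GEF", "exponential", amplitude = 1,
#'                          decay_length = 10)
#' gap <- regulator_profile("GAP", "uniform", amplitude = 0.5)
#' @export
regulator_profile <- function(role = c("GEF", "GAP"),
                              form = c("uniform", "exponential", "tabulated"),
                              amplitude = 1, decay_length = NULL,
                              values = NULL, x = NULL) {
  role <- match.arg(role)
  form <- match.arg(form)
  if (form != "tabulated") {
    if (!is.numeric(amplitude) || amplitude < 0)
      stop("`amplitude` must be >= 0")
  }
  if (form == "exponential") {
    if (is.null(decay_length) || decay_length <= 0)
      stop("exponential regulators need `decay_length` > 0")
  }
  if (form == "tabulated") {
    if (is.null(values) || is.null(x))
      stop("tabulated regulators need `values` and `x`")
    check_grid(x)
    if (length(values) != length(x))
      stop("`values` must match the grid length")
    if (any(!is.finite(values)) || any(values < 0))
      stop("tabulated regulator values must be finite and >= 0")
  }
  structure(list(role = role, form = form, amplitude = amplitude,
                 decay_length = decay_length,
                 values = if (form == "tabulated") as.numeric(values),
                 x = if (form == "tabulated") as.numeric(x)),
            class = "regulator_profile")
}

#' @export
print.regulator_profile <- function(x, ...) {
  extra <- switch(x$form,
    uniform = sprintf("amplitude %g", x$amplitude),
    exponential = sprintf("amplitude %g, decay %g um", x$amplitude,
                          x$decay_length),
    tabulated = sprintf("%d tabulated values on [0, %g] um", length(x$values),
                        max(x$x)))
  cat(sprintf("<regulator_profile> %s, %s (%s)\n", x$role, x$form, extra))
  invisible(x)
}

#' Evaluate a regulator profile on a grid
#'
#' Tabulated profiles defined on a different grid are linearly interpolated
#' (with a warning); extrapolation beyond the tabulated domain holds the end
#' values.
#'
#' @param regulator a `regulator_profile`.
#' @param x target grid (um).
#' @return numeric vector of rates on `x`.
#' @export
regulator_values <- function(regulator, x) {
  stopifnot(inherits(regulator, "regulator_profile"))
  switch(regulator$form,
    uniform = rep(regulator$amplitude, length(x)),
    exponential = regulator$amplitude * exp(-x / regulator$decay_length),
    tabulated = {
      if (length(regulator$x) == length(x) &&
          max(abs(regulator$x - x)) < 1e-9) {
        regulator$values
      } else {
        warning("tabulated regulator interpolated onto a different grid")
        stats::approx(regulator$x, regulator$values, xout = x,
                      rule = 2)$y
      }
    })
}
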