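#' Rate parameters of the minimal GEF/GAP gradient model
#'
#' Effective rates are in arbitrary units: the absolute amplitude of Rho
#' GTPase activity is not measurable by the FRET readout, so only ratios
#' matter. Defaults are the worked values used for the model figures:
#' `alpha_c = alpha_r = 1`, `beta_c = beta_r = 0.5`, `beta_b = 1`, GEF decay
#' length `lambda = 10` um, localized-GAP decay length `gamma = 5` um.
#' The crosstalk coefficients `beta_cb = 0.4` and `beta_rb = 0.3` set how
#' strongly Cdc42 and Rac1 themselves drive the tip-localized GAP
#' (beta2-chimaerin). `alpha_opto` and `lambda_o` describe the optogenetic
#' activation term \eqn{\alpha_{opto} e^{-x/\lambda_o}}.
#'
#' @param alpha_c,beta_c Cdc42 GEF / GAP effective rates.
#' @param alpha_r,beta_r Rac1 GEF / uniform-GAP effective rates.
#' @param beta_b effective rate of the tip-localized Rac1 GAP.
#' @param lambda GEF decay length, um (> 0).
#' @param gamma localized-GAP decay length, um (> 0). A finite interior bump
#'   position requires `lambda > gamma`.
#' @param beta_cb,beta_rb crosstalk coefficients (Cdc42-driven and
#'   Rac1-driven components of the localized GAP).
#' @param alpha_opto optogenetic activation rate.
#' @param lambda_o optogenetic recruitment tail length, um (default 5).
#' @return an object of class `gtpase_params`.
#' @export
gtpase_params <- function(alpha_c = 1, beta_c = 0.5, alpha_r = 1,
                          beta_r = 0.5, beta_b = 1, lambda = 10, gamma = 5,
                          beta_cb = 0.4, beta_rb = 0.3, alpha_opto = 0,
                          lambda_o = 5) {
  p <- list(alpha_c = alpha_c, beta_c = beta_c, alpha_r = alpha_r,
            beta_r = beta_r, beta_b = beta_b, lambda = lambda, gamma = gamma,
            beta_cb = beta_cb, beta_rb = beta_rb, alpha_opto = alpha_opto,
            lambda_o = lambda_o)
  rates <- c("alpha_c", "beta_c", "alpha_r", "beta_r", "beta_b", "beta_cb",
             "beta_rb", "alpha_opto")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop(sprintf("`%s` must be a single rate >= 0", nm))
  if (p$lambda <= 0 || p$gamma <= 0 || p$lambda_o <= 0)
    stop("length scales `lambda`, `gamma`, `lambda_o` must be > 0")
  structure(p, class = "gtpase_params")
}

#' @export
print.gtpase_params <- function(x, ...) {
  cat("<gtpase_params>\n")
  cat(sprintf("  Cdc42: alpha_c = %g, beta_c = %g\n", x$alpha_c, x$beta_c))
  cat(sprintf("  Rac1:  alpha_r = %g, beta_r = %g, beta_b = %g\n",
              x$alpha_r, x$beta_r, x$beta_b))
  cat(sprintf("  lengths: lambda = %g um, gamma = %g um\n", x$lambda,
              x$gamma))
  cat(sprintf("  crosstalk: beta_cb = %g, beta_rb = %g\n", x$beta_cb,
              x$beta_rb))
  cat(sprintf("  optogenetics: alpha_opto = %g, lambda_o = %g um\n",
              x$alpha_opto, x$lambda_o))
  invisible(x)
}

#' Write / read model parameters as JSON
#' @param params a `gtpase_params` object.
#' @param path file path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns a `gtpase_params`.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "gtpase_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  do.call(gtpase_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Steady-state activity from balanced activation and deactivation
#'
#' Under fast first-order activation/deactivation kinetics and non-limiting
#' total GTPase, the local fraction of active GTPase is set purely locally by
#' the ratio of summed GEF to summed GAP rates:
#' \deqn{R^*(x)/R_{tot} = \sum_i \alpha_i[GEF]_i(x) \; / \;
#'       \sum_i \beta_i[GAP]_i(x).}
#' There is no transport term: diffusion and flow are deliberately excluded
#' (they are the rejected alternative for gradient shaping).
#'
#' @param gefs a `regulator_profile` or list of them (role "GEF"). An empty
#'   list yields an all-zero profile with a warning.
#' @param gaps a `regulator_profile` or non-empty list of them (role "GAP").
#'   The summed GAP rate must be positive at every grid point.
#' @param grid spatial grid from [spatial_grid()].
#' @param species,condition labels passed to the resulting profile.
#' @return an `activity_profile`.
#' @examples
#' x <- spatial_grid(35, 0.05)
#' gef <- regulator_profile("GEF", "exponential", 1, decay_length = 10)
#' gap <- regulator_profile("GAP", "uniform", 0.5)
#' p <- steady_state_ratio(gef, gap, x)
#' p$value[1]  # 2 at the cell edge
#' @export
steady_state_ratio <- function(gefs, gaps, grid, species = "reporter",
                               condition = "model") {
  if (inherits(gefs, "regulator_profile")) gefs <- list(gefs)
  if (inherits(gaps, "regulator_profile")) gaps <- list(gaps)
  if (length(gaps) == 0)
    stop("at least one GAP profile is required")
  check_grid(grid)
  den <- Reduce(`+`, lapply(gaps, regulator_values, x = grid))
  if (any(den <= 0))
    stop("degenerate model: total GAP rate is zero at some grid points")
  if (length(gefs) == 0) {
    warning("no GEF profiles supplied; returning an all-zero profile")
    num <- rep(0, length(grid))
  } else {
    num <- Reduce(`+`, lapply(gefs, regulator_values, x = grid))
  }
  activity_profile(grid, num / den, species = species, condition = condition)
}

#' Steady-state Cdc42 activity profile
#'
#' Cdc42 follows its exponentially distributed GEF under a uniform GAP:
#' \deqn{Cdc42^*(x) \propto \alpha_C e^{-x/\lambda} / \beta_C,}
#' a monotonically decreasing gradient peaking at the cell edge.
#'
#' @param params a [gtpase_params()] object; `beta_c` must be > 0.
#' @param grid spatial grid.
#' @param condition condition label.
#' @return an `activity_profile` (species "Cdc42").
#' @export
cdc42_profile <- function(params = gtpase_params(), grid = spatial_grid(),
                          condition = "wild-type") {
  stopifnot(inherits(params, "gtpase_params"))
  if (params$beta_c <= 0)
    stop("degenerate model: `beta_c` must be > 0")
  check_grid(grid)
  activity_profile(grid,
                   params$alpha_c * exp(-grid / params$lambda) / params$beta_c,
                   species = "Cdc42", condition = condition)
}

#' Steady-state Rac1 activity profile with a tip-localized GAP
#'
#' Rac1 sees the same exponentially distributed GEF (decay `lambda`) and
#' uniform GAP as Cdc42, plus a second GAP (beta2-chimaerin) exponentially
#' localized at the tip with its own length `gamma`:
#' \deqn{Rac1^*(x) \propto \alpha_R e^{-x/\lambda} /
#'       (\beta_R + \beta_b e^{-x/\gamma}).}
#' The localized GAP chops the profile off at the cell edge, producing a
#' bell-shaped gradient whose interior maximum sits at [bump_position()].
#'
#' @param params a [gtpase_params()]; `beta_r` or `beta_b` must be > 0.
#' @param grid spatial grid.
#' @param condition condition label.
#' @return an `activity_profile` (species "Rac1").
#' @export
rac1_profile <- function(params = gtpase_params(), grid = spatial_grid(),
                         condition = "wild-type") {
  stopifnot(inherits(params, "gtpase_params"))
  if (params$beta_r <= 0 && params$beta_b <= 0)
    stop("degenerate model: `beta_r` and `beta_b` cannot both be zero")
  check_grid(grid)
  den <- params$beta_r + params$beta_b * exp(-grid / params$gamma)
  activity_profile(grid, params$alpha_r * exp(-grid / params$lambda) / den,
                   species = "Rac1", condition = condition)
}

#' Position of the interior Rac1 activity maximum
#'
#' Closed form for the bump position of the localized-GAP profile:
#' \deqn{x_{bump} = \gamma \ln\left(\frac{\lambda-\gamma}{r\,\gamma}\right),
#'   \quad r = \beta_R/\beta_b.}
#' A strictly interior bump exists iff `r < (lambda - gamma)/gamma` (see
#' [bump_exists()]); with the measured lengths (`lambda` = 10, `gamma` = 5)
#' the condition reduces to `r < 1`. When the expression is negative there is
#' no interior maximum and `NA` is returned ("absent"), so callers can
#' distinguish edge-peaked from bumped profiles; exactly 0 (at
#' `r = (lambda-gamma)/gamma`) means the maximum sits at the edge itself.
#'
#' @param lambda GEF decay length, um; must exceed `gamma`.
#' @param gamma localized-GAP decay length, um (> 0).
#' @param r ratio of the uniform GAP strength to the localized GAP strength,
#'   `beta_r / beta_b` (> 0).
#' @return bump position in um, or `NA_real_` when absent.
#' @examples
#' bump_position(10, 5, 0.5)  # 5 * log(2)
#' bump_position(10, 5, 2)    # NA: no interior bump
#' @export
bump_position <- function(lambda, gamma, r) {
  if (!is.numeric(lambda) || !is.numeric(gamma) || gamma <= 0 ||
      lambda <= gamma)
    stop("`lambda > gamma > 0` is required for a finite bump position")
  if (!is.numeric(r) || any(r <= 0))
    stop("`r` must be > 0")
  pos <- gamma * log((lambda - gamma) / (r * gamma))
  pos[pos < 0] <- NA_real_
  pos
}

#' Does the Rac1 profile have a strictly interior maximum?
#'
#' @inheritParams bump_position
#' @return logical: `TRUE` iff `r < (lambda - gamma)/gamma`.
#' @export
bump_exists <- function(lambda, gamma, r) {
  if (!is.numeric(lambda) || !is.numeric(gamma) || gamma <= 0 ||
      lambda <= gamma)
    stop("`lambda > gamma > 0` is required")
  if (!is.numeric(r) || any(r <= 0))
    stop("`r` must be > 0")
  r < (lambda - gamma) / gamma
}

#' Rac1 profile with concentration-dependent localized GAP and knockdowns
#'
#' Refinement of the localized-GAP model in which the effective rate of the
#' tip GAP is a linear function of the local Cdc42 and Rac1 activities,
#' \deqn{\beta_b(x) = (\beta_{Cb}\,Cdc42(x) + \beta_{Rb}\,Rac1(x))\,
#'       e^{-x/\gamma_a},}
#' where the localization factor \eqn{e^{-x/\gamma_a}} with
#' \eqn{\gamma_a = (1/\gamma - 1/\lambda)^{-1}} represents the actin/adaptor
#' tip machinery required for GAP localization, chosen so that the
#' Cdc42-driven component decays with the measured GAP length `gamma`. At
#' each position the resulting scalar quadratic in Rac1 is solved by its
#' unique non-negative root.
#'
#' In-silico knockdowns: `"cdc42"` scales `alpha_c` (removing the
#' Cdc42-driven GAP component and the Cdc42 profile), `"chimaerin"` scales
#' both crosstalk coefficients (removing the localized GAP entirely).
#' Partial knockdowns use `efficiency` in \[0, 1\] (1 = complete).
#'
#' @param params a [gtpase_params()].
#' @param grid spatial grid.
#' @param knockdowns character subset of `c("cdc42", "chimaerin")`.
#' @param efficiency knockdown efficiency in \[0, 1\]; affected rates are
#'   multiplied by `1 - efficiency`.
#' @return list with elements `rac1` and `cdc42` (`activity_profile`s) and
#'   `beta_b` (tabulated `regulator_profile` of the localized GAP rate).
#' @export
crosstalk_rac1_profile <- function(params = gtpase_params(),
                                   grid = spatial_grid(),
                                   knockdowns = character(),
                                   efficiency = 1) {
  stopifnot(inherits(params, "gtpase_params"))
  check_grid(grid)
  if (length(knockdowns) > 0)
    knockdowns <- match.arg(knockdowns, c("cdc42", "chimaerin"),
                            several.ok = TRUE)
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1)
    stop("`efficiency` must be in [0, 1]")
  keep <- 1 - efficiency
  alpha_c <- params$alpha_c * if ("cdc42" %in% knockdowns) keep else 1
  fb <- if ("chimaerin" %in% knockdowns) keep else 1
  beta_cb <- params$beta_cb * fb
  beta_rb <- params$beta_rb * fb
  if (params$lambda <= params$gamma)
    stop("`lambda > gamma` is required for the localization length gamma_a")
  gamma_a <- 1 / (1 / params$gamma - 1 / params$lambda)

  cdc42 <- alpha_c * exp(-grid / params$lambda) / params$beta_c
  loc <- exp(-grid / gamma_a)
  a_num <- params$alpha_r * exp(-grid / params$lambda)
  d0 <- params$beta_r + beta_cb * cdc42 * loc
  k <- beta_rb * loc
  if (all(d0 <= 0) && all(k <= 0))
    stop("degenerate model: no Rac1 deactivation left")
  disc <- d0^2 + 4 * k * a_num
  stopifnot(all(disc >= 0))  # non-negative by construction
  rac1 <- ifelse(k > 1e-14,
                 (-d0 + sqrt(disc)) / (2 * k),
                 a_num / d0)
  beta_b_x <- (beta_cb * cdc42 + beta_rb * rac1) * loc
  cond <- if (length(knockdowns) == 0) "wild-type" else
    paste0("si", paste(knockdowns, collapse = "+si"))
  list(rac1 = activity_profile(grid, rac1, "Rac1", cond),
       cdc42 = activity_profile(grid, cdc42, "Cdc42", cond),
       beta_b = regulator_profile("GAP", "tabulated", values = beta_b_x,
                                  x = grid))
}

#' Diffusion length scale of an active GTPase
#'
#' The length \eqn{\ell_{diff} = \sqrt{\tau D}} a transported species would
#' add to its source distribution; provided for reasoning about the rejected
#' transport hypothesis, not used inside the purely local model.
#'
#' @param tau lifetime of the GTP-bound state, s (>= 0).
#' @param D lateral diffusion coefficient, um^2/s (>= 0).
#' @return length in um.
#' @examples diffusion_length(25, 1)  # 5 um
#' @export
diffusion_length <- function(tau, D) {
  if (!is.numeric(tau) || !is.numeric(D) || any(tau < 0) || any(D < 0))
    stop("`tau` and `D` must be >= 0")
  sqrt(tau * D)
}
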