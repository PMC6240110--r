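#' Five-extreme profile normalization
#'
#' The quantification convention for comparing profiles of different
#' reporters: 0 is the average of the five minimal values and 1 the average
#' of the five maximal values. Profiles from the same reporter compared
#' across experimental conditions are deliberately left non-normalized
#' (`mode = "none"`).
#'
#' @param values numeric profile (>= 10 samples for `"five_extreme"`).
#' @param mode `"five_extreme"` or `"none"` (pass-through).
#' @return normalized values.
#' @export
normalize_profile <- function(values, mode = c("five_extreme", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(values)
  if (length(values) < 10)
    stop("five-extreme normalization needs at least 10 samples")
  s <- sort(values)
  m <- mean(s[1:5])
  M <- mean(s[(length(s) - 4):length(s)])
  if (M - m <= 1e-12 * max(abs(M), 1))
    stop("degenerate normalization: profile is constant")
  (values - m) / (M - m)
}

#' Cell-first ensemble averaging
#'
#' Replicate linescans are first averaged within each cell, then the per-cell
#' means are averaged (unweighted) across cells, so a cell contributing more
#' lines does not dominate the ensemble mean.
#'
#' @param lines matrix of profiles, one row per linescan, on a common grid;
#'   or a `profile_ensemble` (one row per cell).
#' @param cell_ids vector assigning each row to a cell (ignored for
#'   ensembles).
#' @param x grid positions (taken from the ensemble if omitted).
#' @return list with `x`, `mean`, `sd` (cross-cell s.d.), `n` (cells).
#' @export
average_ensemble <- function(lines, cell_ids = NULL, x = NULL) {
  if (inherits(lines, "profile_ensemble")) {
    x <- lines$x
    mat <- lines$values
    cell_ids <- seq_len(nrow(mat))
  } else {
    mat <- as.matrix(lines)
    if (is.null(cell_ids)) cell_ids <- seq_len(nrow(mat))
    if (is.null(x)) x <- seq_len(ncol(mat)) - 1
  }
  if (length(cell_ids) != nrow(mat))
    stop("`cell_ids` must have one entry per line")
  per_cell <- rowsum(mat, group = cell_ids, reorder = FALSE) /
    as.vector(table(factor(cell_ids, levels = unique(cell_ids))))
  if (nrow(per_cell) < 2)
    stop("at least two cells are required")
  list(x = x, mean = colMeans(per_cell), sd = apply(per_cell, 2, stats::sd),
       n = nrow(per_cell))
}

#' Exponential decay length of a profile
#'
#' Nonlinear least-squares fit of \eqn{A e^{-x/\lambda} + B} with a free
#' baseline `B` over `fit_range`, robust to the nonzero far-field FRET
#' baseline seen in non-normalized profiles.
#'
#' @param profile an `activity_profile` or numeric values.
#' @param x grid (if `profile` is numeric).
#' @param fit_range range `c(lo, hi)` in um; defaults to the full profile.
#' @return list with `decay_um`, `amplitude`, `baseline` and the `nls` fit.
#' @export
fit_decay_length <- function(profile, x = NULL, fit_range = NULL) {
  p <- as_xv(profile, x)
  if (is.null(fit_range)) fit_range <- range(p$x)
  sel <- p$x >= fit_range[1] & p$x <= fit_range[2]
  xs <- p$x[sel]
  vs <- p$value[sel]
  if (length(xs) < 5)
    stop("fit range contains fewer than 5 samples")
  if (any(vs <= 0))
    stop("profile must be strictly positive over the fit range")
  ## log-linear starting values, baseline from the far end
  b0 <- max(min(vs) * 0.5, 0)
  lf <- stats::lm(log(pmax(vs - b0, max(vs) * 1e-6)) ~ xs)
  l0 <- unname(-1 / stats::coef(lf)[2])
  if (!is.finite(l0) || l0 <= 0) l0 <- diff(range(xs)) / 2
  a0 <- unname(exp(stats::coef(lf)[1]))
  fit <- minpack.lm::nls.lm(
    par = c(A = a0, l = l0, B = b0),
    lower = c(0, 1e-3, -Inf),
    fn = function(par) vs - (par[1] * exp(-xs / par[2]) + par[3]),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0 || fit$info == 5)
    stop("fit error: exponential decay fit did not converge (",
         fit$message, ")")
  co <- fit$par
  list(decay_um = unname(co["l"]), amplitude = unname(co["A"]),
       baseline = unname(co["B"]), fit = fit)
}

#' Asymptotic tail decay length of a bumped (localized-GAP) profile
#'
#' For bell-shaped Rac1-like profiles the apparent post-peak decay inside a
#' finite measurement window is flatter than the asymptotic tail: the
#' localized GAP still relaxes over the window, so a windowed
#' exponential-plus-baseline fit cannot recover the tail length (it is not
#' even well-posed; see the methods vignette). This estimator instead fits
#' the localized-GAP steady-state form
#' \eqn{a\,e^{-x/\lambda} / (r + e^{-x/\gamma})}
#' to the whole profile (rising flank included, which pins `gamma` and `r`)
#' and reports the asymptotic tail decay `lambda`.
#'
#' @param profile an `activity_profile` or numeric values.
#' @param x grid (if `profile` is numeric).
#' @param fit_range range `c(lo, hi)` in um; default the full profile.
#' @return list with `tail_decay_um` (lambda), `gamma_um`, `r`, `amplitude`,
#'   and the `nls.lm` fit object.
#' @export
fit_localized_gap_profile <- function(profile, x = NULL, fit_range = NULL) {
  p <- as_xv(profile, x)
  if (is.null(fit_range)) fit_range <- range(p$x)
  sel <- p$x >= fit_range[1] & p$x <= fit_range[2]
  xs <- p$x[sel]
  scale <- max(p$value[sel])
  if (scale <= 0) stop("profile must have positive values in the fit range")
  vs <- p$value[sel] / scale
  fn <- function(par)
    vs - par[1] * exp(-xs / par[2]) / (par[4] + exp(-xs / par[3]))
  fit <- minpack.lm::nls.lm(
    par = c(a = 1, l = 12, g = 5, r = 0.3),
    lower = c(1e-3, 1, 0.5, 1e-3), upper = c(Inf, 50, 20, 10),
    fn = fn, control = minpack.lm::nls.lm.control(maxiter = 1000))
  if (fit$info == 0 || fit$info == 5)
    stop("fit error: localized-GAP profile fit did not converge")
  co <- fit$par
  list(tail_decay_um = unname(co["l"]), gamma_um = unname(co["g"]),
       r = unname(co["r"]), amplitude = unname(co["a"]) * scale, fit = fit)
}

## Gaussian smoothing on a uniform grid, kernel renormalized at the edges.
smooth_gaussian <- function(values, dx, sigma_um) {
  if (sigma_um <= 0) return(values)
  half <- max(1L, ceiling(4 * sigma_um / dx))
  k <- stats::dnorm(seq(-half, half) * dx, sd = sigma_um)
  n <- length(values)
  padded <- c(rep(NA_real_, half), values, rep(NA_real_, half))
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- k
    seg <- padded[i:(i + 2 * half)]
    ok <- !is.na(seg)
    out[i] <- sum(seg[ok] * w[ok]) / sum(w[ok])
  }
  out
}

#' Position of the activity peak
#'
#' The profile is smoothed with a Gaussian kernel (default sigma 0.5 um,
#' edge-renormalized), the global maximum located (ties broken toward the
#' cell edge), and the position refined by quadratic interpolation around the
#' maximal sample. A maximum at either domain end is reported as
#' "edge-peaked": `NA_real_` with attribute `edge_peaked = TRUE`.
#'
#' @param profile an `activity_profile` or numeric values.
#' @param x grid (if `profile` is numeric).
#' @param smoothing_um Gaussian smoothing scale, um (default 0.5).
#' @return peak position in um, or `NA_real_` (edge-peaked).
#' @export
detect_peak <- function(profile, x = NULL, smoothing_um = 0.5) {
  p <- as_xv(profile, x)
  dx <- check_grid(p$x)
  v <- smooth_gaussian(p$value, dx, smoothing_um)
  i <- which.max(v)  # which.max takes the first (edge-ward) tie
  if (i == 1L || i == length(v))
    return(structure(NA_real_, edge_peaked = TRUE))
  ## quadratic refinement through the three samples around the maximum
  num <- v[i - 1] - v[i + 1]
  den <- v[i - 1] - 2 * v[i] + v[i + 1]
  delta <- if (abs(den) < 1e-300) 0 else 0.5 * num / den
  delta <- max(-0.5, min(0.5, delta))
  p$x[i] + delta * dx
}

#' Half-amplitude extent of a normalized profile
#'
#' The distance from the cell tip to the first position beyond the profile's
#' maximum where the (five-extreme normalized) signal crosses 0.5, located by
#' linear interpolation between samples. The crossing is searched beyond the
#' maximum only, so bumped profiles measure their decaying flank.
#'
#' @param profile normalized profile (an `activity_profile` or numeric).
#' @param x grid (if `profile` is numeric).
#' @return extent in um; `NA_real_` with attribute `censored = TRUE` when the
#'   signal never crosses 0.5 within the window (extent >= window).
#' @export
measure_extent <- function(profile, x = NULL) {
  p <- as_xv(profile, x)
  v <- p$value
  i0 <- which.max(v)
  below <- which(v[i0:length(v)] < 0.5)
  if (length(below) == 0)
    return(structure(NA_real_, censored = TRUE))
  j <- i0 + below[1] - 1  # first sample below 0.5, j > i0
  x1 <- p$x[j - 1]; x2 <- p$x[j]
  v1 <- v[j - 1]; v2 <- v[j]
  x1 + (0.5 - v1) * (x2 - x1) / (v2 - v1)
}

#' Pointwise rank-sum comparison of two profile ensembles
#'
#' Two-sided Wilcoxon rank-sum test at every grid position, uncorrected for
#' multiple testing (matching how profile comparisons are displayed in the
#' source experiments); Benjamini-Hochberg correction is available but off by
#' default.
#'
#' @param a,b `profile_ensemble`s (or matrices, one row per cell) on a common
#'   grid; at least 5 cells each.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param x grid (taken from `a` if it is an ensemble).
#' @return an object of class `profile_comparison`: list with `x`, `p_value`,
#'   `significant`, `alpha`.
#' @export
pointwise_compare <- function(a, b, alpha = 0.05,
                              adjust = c("none", "BH"), x = NULL) {
  adjust <- match.arg(adjust)
  ma <- if (inherits(a, "profile_ensemble")) a$values else as.matrix(a)
  mb <- if (inherits(b, "profile_ensemble")) b$values else as.matrix(b)
  if (is.null(x) && inherits(a, "profile_ensemble")) x <- a$x
  if (is.null(x)) x <- seq_len(ncol(ma)) - 1
  if (ncol(ma) != ncol(mb))
    stop("ensembles must share a common grid")
  if (nrow(ma) < 5 || nrow(mb) < 5)
    stop("at least 5 cells per ensemble are required")
  p <- vapply(seq_len(ncol(ma)), function(j)
    stats::wilcox.test(ma[, j], mb[, j], exact = FALSE)$p.value,
    numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  structure(list(x = x, p_value = p, significant = p < alpha, alpha = alpha),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(
    "<profile_comparison> %d positions, %d significant at alpha = %g\n",
    length(x$x), sum(x$significant), x$alpha))
  invisible(x)
}

#' Do an input and an output profile have the same spatial extent?
#'
#' The model-discrimination logic of the input-output stimulation
#' experiments: two profiles "match" when their half-amplitude extents agree
#' within the measurement resolution (about 2 um, two standard deviations of
#' the extent estimate). Profiles are five-extreme normalized on their common
#' window before the extents are measured.
#'
#' @param input,output profiles on the same window (`activity_profile`,
#'   `recruitment_profile` or numeric).
#' @param resolution_um match tolerance in um (default 2).
#' @param x grid (if profiles are numeric).
#' @return list with `match` (logical), `extent_input`, `extent_output` and
#'   `difference` (output minus input, um).
#' @export
profiles_match <- function(input, output, resolution_um = 2, x = NULL) {
  pi_ <- as_xv(input, x)
  po <- as_xv(output, x)
  if (length(pi_$x) != length(po$x) || max(abs(pi_$x - po$x)) > 1e-9)
    stop("profiles must be defined on the same window")
  ei <- measure_extent(normalize_profile(pi_$value), pi_$x)
  eo <- measure_extent(normalize_profile(po$value), po$x)
  if (is.na(ei) || is.na(eo))
    stop("extent not measurable within the window for one of the profiles")
  diff_um <- eo - ei
  list(match = abs(diff_um) < resolution_um, extent_input = ei,
       extent_output = eo, difference = diff_um)
}
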