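# Independent oracles used across the test files.

# Damped fixed-point solver for the concentration-dependent localized-GAP
# Rac1 profile (independent of the closed-form quadratic implementation).
fixed_point_rac1 <- function(params, x, damping = 0.5, tol = 1e-10,
                             max_iter = 1e4) {
  gamma_a <- 1 / (1 / params$gamma - 1 / params$lambda)
  C <- params$alpha_c * exp(-x / params$lambda) / params$beta_c
  A <- params$alpha_r * exp(-x / params$lambda)
  loc <- exp(-x / gamma_a)
  R <- A / params$beta_r
  for (i in seq_len(max_iter)) {
    Rn <- A / (params$beta_r +
                 (params$beta_cb * C + params$beta_rb * R) * loc)
    Rn <- damping * R + (1 - damping) * Rn
    if (max(abs(Rn - R)) < tol) return(Rn)
    R <- Rn
  }
  stop("fixed-point iteration did not converge")
}

# Brute-force interior argmax of the localized-GAP profile on a fine grid.
brute_force_bump <- function(lambda, gamma, r, dx = 0.005, L = 35) {
  x <- seq(0, L, by = dx)
  v <- exp(-x / lambda) / (r + exp(-x / gamma))
  i <- which.max(v)
  if (i == 1 || i == length(x)) return(NA_real_)
  x[i]
}

# Disk mask helper (matrix [row, col] indexing, center/radius in pixels).
disk_mask <- function(n, cx, cy, radius) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}
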