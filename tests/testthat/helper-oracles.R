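# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles enumerate/exhaust rather than reuse package code
# paths wherever they check a package computation.

# brute-force unwrap: for each angle try N = 0..N_max and keep the
# smallest giving a strictly increasing sequence
bf_unwrap <- function(thetas, N_max = 5) {
  out <- numeric(length(thetas))
  out[1] <- thetas[1]
  for (i in seq_along(thetas)[-1]) {
    for (N in 0:N_max) {
      cand <- thetas[i] + 360 * N
      if (cand > out[i - 1]) { out[i] <- cand; break }
    }
  }
  out
}

# brute-force phi: try N in -2..2 and return the unique value in [-90, 270)
bf_phi <- function(theta, sp_value) {
  for (N in -2:2) {
    cand <- theta + 360 * N - sp_value
    if (cand >= -90 && cand < 270) return(cand)
  }
  stop("no N placed phi in range")
}

# exhaustive pairwise cylinder-surface distance table
bf_dpp <- function(theta_deg, H_mm, r) {
  n <- length(theta_deg)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dth <- theta_deg[i] - theta_deg[j]
      dth <- ((dth + 180) %% 360) - 180
      d <- sqrt((H_mm[i] - H_mm[j])^2 + (r * dth * pi / 180)^2)
      best <- min(best, d)
    }
    out[i] <- best
  }
  out
}

# two-leaf frame whose spline takes a chosen value at the midpoint
frame_with_sp <- function(H = c(100, 150), theta_c = c(0, 240)) {
  fit_phyllotaxis_spline(H, theta_c)
}

# noise-free spiral stem: exact golden-angle divergence, constant internodes
make_spiral_stem <- function(n_leaves = 5, divergence = 137.5,
                             internode = 50, theta0 = 10) {
  theta_c <- theta0 + divergence * (0:(n_leaves - 1))
  stem_record("spiral", rep("leaf", n_leaves),
              theta_c %% 360, internode * (1:n_leaves))
}

random_valid_params <- function() {
  repeat {
    tt <- sort(stats::runif(3, -1, 2))
    if (tt[3] > 0) break
  }
  model_params(stats::runif(1, 0.01, 1), stats::runif(1, -1, 1),
               tt[1], tt[2], tt[3])
}
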