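# Observed-pattern density estimation (2D Gaussian KDE), correlation cost
# against the model grid, and constrained multistart BFGS fitting of the
# five model parameters.

#' Fitting configuration
#'
#' @param n_starts Number of multistart BFGS runs (production default
#'   1e4; use ~100 for quick runs and tests).
#' @param seed Integer seed controlling the initial parameter draws.
#' @param N_d Grid division for both model and KDE grids (default 100).
#' @param bandwidth_fallback_fraction Fraction of the axis range used as
#'   kernel standard deviation when the normal-reference bandwidth
#'   degenerates (default 0.25).
#' @param use_reciprocal Correlate the KDE against the reciprocal
#'   intensity `1/f` (default) rather than `f` itself.
#' @param frame Angular frame for the model grid: `"spline"` (default,
#'   matching how observed phi is measured) or `"primordium"`; see
#'   [model_density_grid()].
#' @param periodic_phi Replicate points at `phi +/- 360` degrees before
#'   the KDE for a circular-correct estimate (default off, matching the
#'   plain non-periodic 2D KDE).
#' @param maxit Maximum BFGS iterations per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 1e4, seed = 1, N_d = 100,
                       bandwidth_fallback_fraction = 0.25,
                       use_reciprocal = TRUE,
                       frame = c("spline", "primordium"),
                       periodic_phi = FALSE, maxit = 200) {
  frame <- match.arg(frame)
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (bandwidth_fallback_fraction <= 0 || bandwidth_fallback_fraction > 1)
    stop("bandwidth_fallback_fraction must be in (0, 1]")
  structure(
    list(n_starts = as.integer(n_starts), seed = as.integer(seed),
         N_d = as.integer(N_d),
         bandwidth_fallback_fraction = bandwidth_fallback_fraction,
         use_reciprocal = isTRUE(use_reciprocal),
         frame = frame,
         periodic_phi = isTRUE(periodic_phi),
         maxit = as.integer(maxit)),
    class = "fit_config"
  )
}

# normal-reference kernel sd (the spread actually used by the classic 2D
# KDE implementations); degenerate axes fall back to a fraction of the
# grid-axis range.
nrd_sigma <- function(x, axis_range, fallback_fraction, axis_name) {
  n <- length(x)
  s <- if (n >= 2) {
    1.06 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
  } else NA_real_
  if (!is.finite(s) || s <= 0) {
    s <- fallback_fraction * axis_range
    message(sprintf(
      "kde2d_estimate: degenerate %s axis; bandwidth fallback %.4g (= %.2f x range)",
      axis_name, s, fallback_fraction))
  }
  s
}

#' 2D kernel density estimate of an observed prickle pattern
#'
#' Axis-aligned product-Gaussian KDE of `(phi, h)` points, evaluated on
#' the same `N_d x N_d` lattice the model grid uses: phi from -90 to 270
#' degrees (half-open, step `360/N_d`) and `t` from 0 to 1 (half-open,
#' step `1/N_d`). Per-axis kernel standard deviation follows the
#' normal-reference rule `1.06 min(sd, IQR/1.34) n^(-1/5)`; a degenerate
#' axis (zero spread or a single point) falls back to
#' `fallback_fraction x axis range`. Density units are per (degree x h),
#' so the grid sums to about 1 after cell-area weighting, up to boundary
#' truncation.
#'
#' @param phi_deg Prickle angles in degrees, each in `[-90, 270)`.
#' @param h Relative heights in `[0, 1]`.
#' @param N_d Grid division (default 100).
#' @param fallback_fraction Degenerate-axis bandwidth fraction.
#' @param periodic_phi Replicate points at `phi +/- 360` before smoothing.
#' @return A `density_grid` with `meaning = "kde_density"`.
#' @export
kde2d_estimate <- function(phi_deg, h, N_d = 100, fallback_fraction = 0.25,
                           periodic_phi = FALSE) {
  n <- length(phi_deg)
  if (n == 0) stop("kde2d_estimate: no points")
  if (length(h) != n) stop("phi_deg and h must have equal length")
  if (any(phi_deg < -90 | phi_deg >= 270))
    stop("phi_deg must lie in [-90, 270)")
  if (any(h < 0 | h > 1)) stop("h must lie in [0, 1]")
  phi_axis_deg <- -90 + 360 * (0:(N_d - 1)) / N_d
  t_axis <- (0:(N_d - 1)) / N_d
  s_phi <- nrd_sigma(phi_deg, 360, fallback_fraction, "phi")
  s_h <- nrd_sigma(h, 1, fallback_fraction, "h")
  px <- phi_deg
  hx <- h
  w <- rep(1, n)
  if (periodic_phi) {
    px <- c(phi_deg - 360, phi_deg, phi_deg + 360)
    hx <- rep(h, 3)
    w <- rep(1, 3 * n)
  }
  # values[i, j] = mean_k dnorm(phi_i - phi_k) dnorm(t_j - h_k)
  A <- outer(phi_axis_deg, px, function(a, b) stats::dnorm(a - b, 0, s_phi))
  B <- outer(t_axis, hx, function(a, b) stats::dnorm(a - b, 0, s_h))
  vals <- (A %*% t(B * w)) / n
  density_grid(vals, phi_axis_deg * pi / 180, t_axis, meaning = "kde_density")
}

#' Total mass of a density grid
#'
#' Cell-area-weighted sum, with phi measured in degrees (matching the KDE
#' units). Close to 1 for a KDE of interior points.
#'
#' @param grid A `density_grid`.
#' @return Scalar mass.
#' @export
grid_mass <- function(grid) {
  dphi <- mean(diff(grid$phi_axis)) * 180 / pi
  dt <- mean(diff(grid$t_axis))
  sum(grid$values) * dphi * dt
}

#' Correlation cost between model and observed grids
#'
#' Pearson correlation of the flattened grid values, multiplied by -1 so
#' that lower is better; the quantity the optimiser minimises.
#'
#' @param model,observed `density_grid` objects on identical axes.
#' @return Cost in `[-1, 1]`.
#' @export
pearson_cost <- function(model, observed) {
  if (!isTRUE(all.equal(model$phi_axis, observed$phi_axis)) ||
      !isTRUE(all.equal(model$t_axis, observed$t_axis)))
    stop("grids must share identical axes")
  x <- as.vector(model$values)
  y <- as.vector(observed$values)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate grid: zero variance")
  -stats::cor(x, y)
}

# --- constraint-preserving reparameterisation --------------------------
# alpha = exp(a); beta free; nested logistic maps give
# T_c in (0, 2), T_b in (-1, T_c), T_a in (-1, T_b), hence
# T_a < T_b < T_c, -T <= T_a, 0 < T_c <= 2T for T = 1 at every iterate.

raw_to_params <- function(raw, Phi = golden_angle()) {
  # clamp the logistic away from 0/1 so the ordering T_a < T_b < T_c
  # survives floating point when an iterate wanders far out
  sig <- function(x) pmin(pmax(stats::plogis(x), 1e-6), 1 - 1e-6)
  T_c <- 2 * sig(raw[5])
  T_b <- -1 + (T_c + 1) * sig(raw[4])
  T_a <- -1 + (T_b + 1) * sig(raw[3])
  model_params(alpha = exp(raw[1]), beta = raw[2],
               T_a = T_a, T_b = T_b, T_c = T_c, Phi = Phi)
}

params_to_raw <- function(p) {
  c(log(p$alpha), p$beta,
    stats::qlogis((p$T_a + 1) / (p$T_b + 1)),
    stats::qlogis((p$T_b + 1) / (p$T_c + 1)),
    stats::qlogis(p$T_c / 2))
}

# uniform feasible draw: alpha in (0, 1], beta in [-1, 1], ordered triple
# from the box [-1, 2] resampled until T_c > 0.
draw_start <- function() {
  repeat {
    tt <- sort(stats::runif(3, -1, 2))
    if (tt[3] > 0 && tt[1] < tt[2] && tt[2] < tt[3]) break
  }
  list(alpha = stats::runif(1, 1e-3, 1), beta = stats::runif(1, -1, 1),
       T_a = tt[1], T_b = tt[2], T_c = tt[3])
}

#' Fit the inhibitor-field model to an observed density grid
#'
#' Minimises [pearson_cost()] between the model density grid (evaluated on
#' the observed grid's axes) and the observed KDE grid over the five
#' parameters `(alpha, beta, T_a, T_b, T_c)`, using BFGS from `n_starts`
#' random feasible initial points. Constraints are enforced by a smooth
#' bijective reparameterisation, so every iterate is feasible. Distinct
#' converged basins (parameter vectors differing by more than 1e-2 in any
#' coordinate) are reported alongside the best optimum.
#'
#' @param observed A `density_grid` (typically from [kde2d_estimate()]).
#' @param config A [fit_config()].
#' @param Phi Divergence angle in radians.
#' @return An object of class `fit_result`: `params` (best
#'   `model_params`), `correlation` (Pearson r of the best fit),
#'   `n_converged`, `all_optima` (list of `list(params, correlation)` per
#'   distinct basin, best first), `config` and `seed`.
#' @export
optimize_params <- function(observed, config = fit_config(n_starts = 100),
                            Phi = golden_angle()) {
  set.seed(config$seed)
  cost_fn <- function(raw) {
    tryCatch({
      p <- raw_to_params(raw, Phi)
      g <- model_density_grid(
        p, phi_axis = observed$phi_axis, t_axis = observed$t_axis,
        reciprocal = config$use_reciprocal, frame = config$frame
      )
      pearson_cost(g, observed)
    }, error = function(e) 2)
  }
  starts <- replicate(config$n_starts, draw_start(), simplify = FALSE)
  runs <- vector("list", config$n_starts)
  for (i in seq_len(config$n_starts)) {
    s <- starts[[i]]
    raw0 <- params_to_raw(s)
    fit <- tryCatch(
      stats::optim(raw0, cost_fn, method = "BFGS",
                   control = list(maxit = config$maxit)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value) || fit$value > 1) next
    runs[[i]] <- fit
  }
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0)
    stop("optimize_params: no start converged to a finite cost; ",
         "check the observed grid for degeneracy")
  vals <- vapply(runs, `[[`, numeric(1), "value")
  ord <- order(vals)
  runs <- runs[ord]
  n_converged <- sum(vapply(runs, function(r) r$convergence == 0, logical(1)))
  # greedy basin clustering in parameter space, best first
  par_mat <- t(vapply(runs, function(r) {
    p <- raw_to_params(r$par, Phi)
    c(p$alpha, p$beta, p$T_a, p$T_b, p$T_c)
  }, numeric(5)))
  basins <- list()
  for (i in seq_along(runs)) {
    dup <- FALSE
    for (b in basins) {
      if (all(abs(par_mat[i, ] - b$vec) <= 1e-2)) { dup <- TRUE; break }
    }
    if (!dup) {
      basins[[length(basins) + 1]] <- list(
        vec = par_mat[i, ],
        params = raw_to_params(runs[[i]]$par, Phi),
        correlation = -runs[[i]]$value
      )
    }
  }
  best <- basins[[1]]
  structure(
    list(params = best$params, correlation = best$correlation,
         n_converged = n_converged,
         all_optima = lapply(basins, function(b)
           list(params = b$params, correlation = b$correlation)),
         config = config, seed = config$seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: correlation %.4f, %d/%d starts converged, %d distinct basin(s)\n",
              x$correlation, x$n_converged, x$config$n_starts,
              length(x$all_optima)))
  print(x$params)
  invisible(x)
}

#' Score a fixed parameter set against an observed grid
#'
#' Evaluates the Pearson correlation between the model density at `params`
#' (on the observed grid's axes) and the observed grid, without any
#' optimisation. Useful for re-scoring published parameter sets.
#'
#' @param params A `model_params` object.
#' @param observed A `density_grid`.
#' @param config A [fit_config()] (only the grid/cost options are used).
#' @return Pearson correlation (higher is better).
#' @export
evaluate_fit <- function(params, observed, config = fit_config(n_starts = 1)) {
  g <- model_density_grid(
    params, phi_axis = observed$phi_axis, t_axis = observed$t_axis,
    reciprocal = config$use_reciprocal, frame = config$frame
  )
  -pearson_cost(g, observed)
}
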