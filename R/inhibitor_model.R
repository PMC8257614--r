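# Inhibitor-field model: secretion schedule k(t), concentration parameter
# m(t), von Mises per-primordium intensity and the three-primordium
# superposition f(phi, t); density grids on the (phi, t) lattice.

#' The golden angle in radians
#'
#' `2 * pi * (1 - 1/g)` with `g` the golden ratio, approximately 2.39996
#' rad (137.5 deg); the default divergence angle of spiral phyllotaxis.
#' @export
golden_angle <- function() {
  g <- (1 + sqrt(5)) / 2
  2 * pi * (1 - 1 / g)
}

#' Construct and validate model parameters
#'
#' The five free parameters of the inhibitor-field model, in units of the
#' plastochron `T` (fixed to 1): `alpha` (> 0) is the rate at which the
#' concentration parameter grows as a primordium recedes from the shoot
#' apex, `beta` its value at `t = 0`; `T_a < T_b < T_c` are the start,
#' peak and end of the secretion window, constrained to `-T <= T_a` and
#' `0 < T_c <= 2T` so only the three primordia nearest the priming zone
#' contribute.
#'
#' @param alpha Concentration growth rate, `> 0`.
#' @param beta Concentration offset at `t = 0` (may be negative; the
#'   concentration is clamped at 0).
#' @param T_a,T_b,T_c Secretion start, peak and end times.
#' @param T Plastochron, fixed to 1.
#' @param Phi Divergence angle in radians (default the golden angle).
#' @return An object of class `model_params`.
#' @export
model_params <- function(alpha, beta, T_a, T_b, T_c, T = 1,
                         Phi = golden_angle()) {
  p <- list(alpha = alpha, beta = beta, T_a = T_a, T_b = T_b, T_c = T_c,
            T = T, Phi = Phi)
  viol <- validate_params(p)
  if (length(viol)) stop("invalid model parameters: ",
                         paste(viol, collapse = "; "))
  structure(p, class = "model_params")
}

#' List violated parameter constraints
#'
#' @param p A list or `model_params` with fields `alpha`, `T_a`, `T_b`,
#'   `T_c`, `T`.
#' @return Character vector of violated constraints (empty when valid).
#' @export
validate_params <- function(p) {
  viol <- character(0)
  if (!is.finite(p$alpha) || p$alpha <= 0) viol <- c(viol, "alpha > 0")
  if (!(p$T_a < p$T_b)) viol <- c(viol, "T_a < T_b")
  if (!(p$T_b < p$T_c)) viol <- c(viol, "T_b < T_c")
  if (!(-p$T <= p$T_a)) viol <- c(viol, "-T <= T_a")
  if (!(p$T_c > 0 && p$T_c <= 2 * p$T)) viol <- c(viol, "0 < T_c <= 2T")
  viol
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: alpha=%.4g beta=%.4g T_a=%.4g T_b=%.4g T_c=%.4g (T=%g, Phi=%.4f rad)\n",
    x$alpha, x$beta, x$T_a, x$T_b, x$T_c, x$T, x$Phi
  ))
  invisible(x)
}

#' Optimised 'Red Queen' rose parameters
#'
#' The parameter set that best reproduces the observed prickle density on
#' *Rosa hybrida* 'Red Queen' stems (prickles concentrated at phi between
#' 90 and 135 degrees).
#' @return A `model_params` object.
#' @export
redqueen_params <- function() {
  model_params(alpha = 0.267, beta = 0.139,
               T_a = -0.909, T_b = 0.071, T_c = 1.661)
}

#' Optimised paired-pattern parameters
#'
#' The parameter set reproducing the paired prickles flanking the leaf
#' base seen in e.g. *Acacia seyal* and *Rosa hirtula* (two points near
#' `h = 0.95`, `phi = +/-60` degrees).
#' @return A `model_params` object.
#' @export
aseyal_params <- function() {
  model_params(alpha = 0.044, beta = 0.102,
               T_a = 0.109, T_b = 1.419, T_c = 1.925)
}

#' Secretion schedule k(t)
#'
#' Piecewise-linear secretion rate of the inhibitor: rises linearly from 0
#' at `T_a` to 1 at `T_b`, falls linearly back to 0 at `T_c`, and is 0
#' outside `(T_a, T_c)`. Continuous everywhere.
#'
#' @param t Time(s) in plastochron units.
#' @param params A `model_params` object.
#' @return Values in `[0, 1]`.
#' @export
secretion_rate <- function(t, params) {
  k <- numeric(length(t))
  up <- t > params$T_a & t < params$T_b
  dn <- t >= params$T_b & t < params$T_c
  k[up] <- (t[up] - params$T_a) / (params$T_b - params$T_a)
  k[dn] <- (params$T_c - t[dn]) / (params$T_c - params$T_b)
  k
}

#' Concentration parameter m(t)
#'
#' Von Mises concentration of the inhibitor footprint from a primordium at
#' age `t`: `m(t) = max(alpha * t + beta, 0)`. Grows as the source recedes
#' from the priming circle centre.
#'
#' @inheritParams secretion_rate
#' @return Non-negative values.
#' @export
concentration_param <- function(t, params) {
  pmax(params$alpha * t + params$beta, 0)
}

#' Inhibitor intensity from a single primordium
#'
#' `k(t) * exp(m(t) * cos(phi - phi_source))`: a von Mises angular profile
#' (normalising constant deliberately omitted; the downstream Pearson
#' correlation is scale-invariant) scaled by the secretion schedule.
#'
#' @param phi Angle(s) on the priming circle, radians.
#' @param t Primordium age(s), plastochron units.
#' @param phi_source Angular direction of the primordium, radians.
#' @param params A `model_params` object.
#' @return Non-negative intensities.
#' @export
primordium_intensity <- function(phi, t, phi_source, params) {
  secretion_rate(t, params) *
    exp(concentration_param(t, params) * cos(phi - phi_source))
}

#' Total inhibitor intensity f(phi, t)
#'
#' Superposition of the three primordia that can secrete while the priming
#' zone is between the n-th and (n+1)-th node: the previous primordium at
#' age `t + T` and angle `-Phi`... concretely
#' `f = k(t-T) e^{m(t-T) cos(phi - Phi)} + k(t) e^{m(t) cos phi} +
#' k(t+T) e^{m(t+T) cos(phi + Phi)}`. 2*pi-periodic in `phi`.
#'
#' @param phi Angle(s), radians. Recycled against `t`.
#' @param t Time(s) in `[0, T]`.
#' @param params A `model_params` object.
#' @return Non-negative intensities.
#' @export
total_intensity <- function(phi, t, params) {
  primordium_intensity(phi, t - params$T,  params$Phi, params) +
    primordium_intensity(phi, t,            0,          params) +
    primordium_intensity(phi, t + params$T, -params$Phi, params)
}

#' Construct a density grid object
#'
#' @param values `N_d x N_d` matrix, rows indexed by `phi_axis`, columns by
#'   `t_axis`; all finite and `>= 0`.
#' @param phi_axis Strictly increasing angles in radians.
#' @param t_axis Strictly increasing times in `[0, T)`.
#' @param meaning `"model_density"` or `"kde_density"`.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, phi_axis, t_axis,
                         meaning = c("model_density", "kde_density")) {
  meaning <- match.arg(meaning)
  values <- as.matrix(values)
  if (nrow(values) != length(phi_axis) || ncol(values) != length(t_axis))
    stop("values dimensions must match axes")
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid values must be finite and >= 0")
  if (any(diff(phi_axis) <= 0) || any(diff(t_axis) <= 0))
    stop("axes must be strictly increasing")
  structure(
    list(values = values, phi_axis = phi_axis, t_axis = t_axis,
         N_d = nrow(values), meaning = meaning),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "density_grid (%s): %d x %d, phi in [%.1f, %.1f] deg, t in [%g, %g]\n",
    x$meaning, nrow(x$values), ncol(x$values),
    min(x$phi_axis) * 180 / pi, max(x$phi_axis) * 180 / pi,
    min(x$t_axis), max(x$t_axis)
  ))
  invisible(x)
}

#' Model prickle density on the (phi, t) lattice
#'
#' Prickle emergence probability is proportional to the reciprocal of the
#' total inhibitor intensity; this samples `1 / max(f(phi_i, t_j), eps)`
#' on the `N_d x N_d` lattice `phi_i = 2 pi i / N_d`,
#' `t_j = j T / N_d`, `i, j = 0..N_d - 1`. The floor `eps` keeps entries
#' finite where all three secretion windows vanish; it is far below any
#' attainable intensity so occupied regions are unaffected.
#'
#' @param params A `model_params` object.
#' @param N_d Grid division (default 100).
#' @param epsilon Intensity floor before taking the reciprocal.
#' @param phi_axis,t_axis Optional custom lattices (radians / plastochron
#'   units), e.g. to align with an observed KDE grid; the model is
#'   2*pi-periodic so any phi origin is valid.
#' @param reciprocal If `FALSE`, return the intensity `f` itself instead of
#'   its reciprocal.
#' @param frame Angular reference frame of the grid's phi axis.
#'   `"spline"` (default) measures phi from the phyllotaxis spline, the
#'   frame in which observed prickles are expressed: as the priming ring
#'   moves through the internode the spline reference advances by
#'   `Phi * t / T`, so the intensity is evaluated at
#'   `phi + Phi * t / T` relative to the n-th primordium.
#'   `"primordium"` keeps phi fixed to the n-th primordium direction
#'   (no advance), useful for inspecting the raw field.
#' @return A `density_grid` with `meaning = "model_density"`.
#' @export
model_density_grid <- function(params, N_d = 100, epsilon = 1e-12,
                               phi_axis = NULL, t_axis = NULL,
                               reciprocal = TRUE,
                               frame = c("spline", "primordium")) {
  frame <- match.arg(frame)
  if (is.null(phi_axis)) {
    if (N_d < 2) stop("N_d must be >= 2")
    phi_axis <- 2 * pi * (0:(N_d - 1)) / N_d
  }
  if (is.null(t_axis)) t_axis <- (0:(length(phi_axis) - 1)) * params$T / length(phi_axis)
  nphi <- length(phi_axis)
  nt <- length(t_axis)
  if (nphi < 2 || nt < 2) stop("N_d must be >= 2")
  f <- matrix(0, nphi, nt)
  # vectorised three-term superposition; PH[i, j] is the angle relative
  # to the n-th primordium at lattice point (i, j)
  PH <- if (frame == "spline") {
    outer(phi_axis, params$Phi * t_axis / params$T, "+")
  } else {
    matrix(phi_axis, nphi, nt)
  }
  for (shift in list(c(-params$T, params$Phi), c(0, 0),
                     c(params$T, -params$Phi))) {
    tt <- t_axis + shift[1]
    k <- secretion_rate(tt, params)
    m <- concentration_param(tt, params)
    f <- f + rep(k, each = nphi) *
      exp(rep(m, each = nphi) * cos(PH - shift[2]))
  }
  vals <- if (reciprocal) 1 / pmax(f, epsilon) else f
  density_grid(vals, phi_axis, t_axis, meaning = "model_density")
}

#' Aggregate a density grid over time
#'
#' Sums the grid over the t axis, giving the marginal density profile over
#' phi (used e.g. to locate the modal phi band).
#'
#' @param grid A `density_grid`.
#' @return Data frame with `phi_deg` and `density`.
#' @export
phi_profile <- function(grid) {
  data.frame(
    phi_deg = grid$phi_axis * 180 / pi,
    density = rowSums(grid$values)
  )
}
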