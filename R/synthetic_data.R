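# Synthetic stems and prickle patterns with the statistical structure the
# analysis assumes: spiral phyllotaxis with noise and occasional extreme
# divergences, internode lengths, model-density prickle sampling with a
# hard-core minimum spacing, plus in-literature fixtures.

#' Synthetic-stem configuration
#'
#' Defaults describe a rose-like lateral shoot: spiral phyllotaxis at the
#' golden angle with ~10 degrees of noise and a 5% chance of an extreme
#' internode (divergence drawn from (270, 330) degrees), internode lengths
#' around 35 mm, a few prickles per internode, and a 5 mm hard-core
#' minimum spacing between prickles.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param mean_divergence_deg Mean divergence angle (default 137.5).
#' @param divergence_sd_deg SD of divergence noise (default 10).
#' @param big_deviation_prob Probability an internode's divergence is
#'   replaced by a uniform draw in (270, 330) degrees (default 0.05).
#' @param internode_mean_mm,internode_sd_mm Internode length distribution
#'   (truncated normal, > 1 mm).
#' @param prickles_per_internode_mean Poisson mean prickle count per
#'   internode (default 3).
#' @param min_spacing_mm Hard-core minimum pairwise prickle distance on
#'   the stem surface (default 5).
#' @param stem_radius_mm Stem radius for the surface metric (default 5).
#' @param params `model_params` used as the sampling density (default the
#'   'Red Queen' optimum).
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_leaves = 10, mean_divergence_deg = 137.5,
                         divergence_sd_deg = 10, big_deviation_prob = 0.05,
                         internode_mean_mm = 35, internode_sd_mm = 10,
                         prickles_per_internode_mean = 3,
                         min_spacing_mm = 5, stem_radius_mm = 5,
                         params = redqueen_params(), seed = 1) {
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  if (divergence_sd_deg < 0 || internode_sd_mm < 0 ||
      prickles_per_internode_mean < 0 || min_spacing_mm < 0)
    stop("counts, sds and spacings must be >= 0")
  if (big_deviation_prob < 0 || big_deviation_prob > 1)
    stop("big_deviation_prob must be in [0, 1]")
  if (internode_mean_mm <= 1) stop("internode_mean_mm must exceed 1 mm")
  structure(
    list(n_leaves = as.integer(n_leaves),
         mean_divergence_deg = mean_divergence_deg,
         divergence_sd_deg = divergence_sd_deg,
         big_deviation_prob = big_deviation_prob,
         internode_mean_mm = internode_mean_mm,
         internode_sd_mm = internode_sd_mm,
         prickles_per_internode_mean = prickles_per_internode_mean,
         min_spacing_mm = min_spacing_mm,
         stem_radius_mm = stem_radius_mm,
         params = params, seed = as.integer(seed)),
    class = "synth_config"
  )
}

rtruncnorm_gt <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic stem (leaves only)
#'
#' Places `n_leaves` leaves up the stem with divergence angles drawn from
#' `Normal(mean_divergence_deg, divergence_sd_deg)`, each independently
#' replaced with probability `big_deviation_prob` by an extreme draw
#' uniform in (270, 330) degrees; internode lengths are truncated-normal
#' (> 1 mm). Deterministic for a fixed `seed`.
#'
#' @param config A [synth_config()].
#' @return A [stem_record()] containing only leaves.
#' @export
generate_stem <- function(config) {
  set.seed(config$seed)
  n <- config$n_leaves
  div <- stats::rnorm(n - 1, config$mean_divergence_deg,
                      config$divergence_sd_deg)
  big <- stats::runif(n - 1) < config$big_deviation_prob
  if (any(big)) div[big] <- stats::runif(sum(big), 270, 330)
  theta0 <- stats::runif(1, 0, 360)
  theta_c <- cumsum(c(theta0, div))
  internodes <- rtruncnorm_gt(n, config$internode_mean_mm,
                              config$internode_sd_mm, 1)
  H <- cumsum(internodes)
  stem_record(
    stem_id = sprintf("synthetic-seed%d", config$seed),
    kind = rep("leaf", n),
    theta_deg = theta_c %% 360,
    H_mm = H
  )
}

# multinomial cell draw + within-cell uniform jitter from a density grid;
# returns (phi_deg, t) in the half-open cells of the lattice.
sample_grid_points <- function(grid, n) {
  p <- as.vector(grid$values)
  p <- p / sum(p)
  cells <- sample.int(length(p), n, replace = TRUE, prob = p)
  i <- (cells - 1) %% nrow(grid$values) + 1   # phi index
  j <- (cells - 1) %/% nrow(grid$values) + 1  # t index
  dphi <- mean(diff(grid$phi_axis)) * 180 / pi
  dt <- mean(diff(grid$t_axis))
  data.frame(
    phi_deg = grid$phi_axis[i] * 180 / pi + stats::runif(n, 0, dphi),
    h = grid$t_axis[j] + stats::runif(n, 0, dt)
  )
}

#' Sample prickles onto a synthetic stem
#'
#' Per internode, draws a Poisson prickle count and samples `(phi, h)` by
#' cell-level multinomial draws from the normalised model density grid at
#' `config$params` (with uniform within-cell jitter), then converts to
#' absolute `(theta, H)` through the stem's own phyllotaxis spline — the
#' exact inverse of the measurement transform. Candidates closer than
#' `min_spacing_mm` (cylinder-surface metric) to an accepted prickle are
#' redrawn up to 100 times, then dropped with a warning (hard-core
#' thinning). Deterministic for a fixed `config$seed`.
#'
#' @param stem A [stem_record()] with >= 2 leaves (e.g. from
#'   [generate_stem()]).
#' @param config A [synth_config()].
#' @return A `stem_record` with the sampled prickles added.
#' @export
sample_prickles <- function(stem, config) {
  lv <- leaf_rows(stem)
  if (nrow(lv) < 2) stop("insufficient leaves: need >= 2")
  set.seed(config$seed + 1L)
  frame <- fit_phyllotaxis_spline(lv$H_mm, unwrap_leaf_angles(lv$theta_deg))
  grid <- model_density_grid(
    config$params,
    phi_axis = (-90 + 360 * (0:99) / 100) * pi / 180,
    t_axis = (0:99) / 100
  )
  acc_theta <- numeric(0)
  acc_H <- numeric(0)
  n_dropped <- 0
  for (k in seq_len(nrow(lv) - 1)) {
    H_lo <- lv$H_mm[k]
    H_up <- lv$H_mm[k + 1]
    count <- stats::rpois(1, config$prickles_per_internode_mean)
    for (q in seq_len(count)) {
      placed <- FALSE
      for (attempt in seq_len(100)) {
        pt <- sample_grid_points(grid, 1)
        H <- H_lo + pt$h * (H_up - H_lo)
        theta <- (pt$phi_deg + frame$spline(H)) %% 360
        ok <- if (length(acc_H) == 0) TRUE else {
          dth <- ((theta - acc_theta + 180) %% 360) - 180
          d <- sqrt((H - acc_H)^2 + (config$stem_radius_mm * dth * pi / 180)^2)
          all(d >= config$min_spacing_mm)
        }
        if (ok) {
          acc_theta <- c(acc_theta, theta)
          acc_H <- c(acc_H, H)
          placed <- TRUE
          break
        }
      }
      if (!placed) n_dropped <- n_dropped + 1
    }
  }
  if (n_dropped > 0)
    warning(sprintf(
      "sample_prickles: dropped %d prickle(s) after exhausting the hard-core rejection budget",
      n_dropped))
  stem_record(
    stem$stem_id,
    c(stem$organs$kind, rep("prickle", length(acc_H))),
    c(stem$organs$theta_deg, acc_theta),
    c(stem$organs$H_mm, acc_H),
    mirrored = stem$mirrored
  )
}

#' Paired-prickle fixture
#'
#' The literature-derived paired pattern seen at the leaf base of
#' *Acacia seyal* (and *Rosa hirtula*): exactly two points at `h = 0.95`,
#' `phi = +60` and `-60` degrees.
#'
#' @return A data frame with columns `phi_deg` and `h` (two rows).
#' @export
aseyal_pair_fixture <- function() {
  data.frame(phi_deg = c(60, -60), h = c(0.95, 0.95))
}

#' Synthetic 'Red Queen'-like point pattern
#'
#' `n` points in the `(phi, h)` plane sampled from the model density grid
#' at the optimised 'Red Queen' parameters — a stand-in for the
#' unreleased nine-stem measurement set, reproducing its density but not
#' its raw measurements. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n Number of points (>= 1).
#' @return A data frame with columns `phi_deg` (in `[-90, 270)`) and `h`.
#' @export
redqueen_fixture <- function(seed, n) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  grid <- model_density_grid(
    redqueen_params(),
    phi_axis = (-90 + 360 * (0:99) / 100) * pi / 180,
    t_axis = (0:99) / 100
  )
  sample_grid_points(grid, n)
}
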