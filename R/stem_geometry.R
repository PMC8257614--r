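# Measurement geometry: raw (theta, H) organ positions -> leaf-relative
# (phi, h) coordinates and descriptive statistics.

#' Construct a stem record
#'
#' A stem record holds the ordered organ observations (leaves and prickles)
#' of one shoot. Organs are sorted by height `H_mm` ascending; ties keep
#' input order.
#'
#' @param stem_id Character identifier for the shoot.
#' @param kind Character vector, each element `"leaf"` or `"prickle"`.
#' @param theta_deg Numeric vector of angular positions in `[0, 360)`
#'   degrees. `theta = 0` points from the lateral shoot towards the primary
#'   shoot.
#' @param H_mm Numeric vector of heights in mm from the base of the lateral
#'   shoot, all `>= 0`.
#' @param mirrored Logical, whether the angles have already been reflected
#'   to the right-handed frame (see [mirror_if_left_handed()]).
#'
#' @return An object of class `stem_record` with components `stem_id`,
#'   `organs` (a data frame with columns `kind`, `theta_deg`, `H_mm`) and
#'   `mirrored`.
#' @export
stem_record <- function(stem_id, kind, theta_deg, H_mm, mirrored = FALSE) {
  kind <- as.character(kind)
  if (!all(kind %in% c("leaf", "prickle")))
    stop("kind must be 'leaf' or 'prickle'")
  theta_deg <- as.numeric(theta_deg)
  H_mm <- as.numeric(H_mm)
  n <- length(kind)
  if (length(theta_deg) != n || length(H_mm) != n)
    stop("kind, theta_deg and H_mm must have equal length")
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0 | theta_deg >= 360))
    stop("theta_deg must lie in [0, 360)")
  if (any(!is.finite(H_mm)) || any(H_mm < 0))
    stop("H_mm must be finite and >= 0")
  ord <- order(H_mm)  # stable: ties keep input order
  structure(
    list(
      stem_id = as.character(stem_id)[1],
      organs = data.frame(
        kind = kind[ord], theta_deg = theta_deg[ord], H_mm = H_mm[ord],
        stringsAsFactors = FALSE
      ),
      mirrored = isTRUE(mirrored)
    ),
    class = "stem_record"
  )
}

#' @export
print.stem_record <- function(x, ...) {
  n_leaf <- sum(x$organs$kind == "leaf")
  n_prk <- sum(x$organs$kind == "prickle")
  cat(sprintf(
    "stem_record '%s': %d leaves, %d prickles, H in [%g, %g] mm%s\n",
    x$stem_id, n_leaf, n_prk,
    if (nrow(x$organs)) min(x$organs$H_mm) else NA,
    if (nrow(x$organs)) max(x$organs$H_mm) else NA,
    if (x$mirrored) " (mirrored)" else ""
  ))
  invisible(x)
}

leaf_rows <- function(stem) stem$organs[stem$organs$kind == "leaf", , drop = FALSE]

#' Unwrap leaf angles into cumulative angles
#'
#' Replaces each measured angle `theta` in `[0, 360)` by the cumulative
#' angle `theta_c = theta + 360 N`, where the non-negative integers `N` are
#' the smallest that make the sequence strictly increasing from the bottom
#' of the shoot to its apex. Consecutive equal angles are resolved by
#' incrementing `N`, so the output is always strictly increasing.
#'
#' @param leaf_thetas Numeric vector of leaf angles in degrees, ordered
#'   bottom to top, each in `[0, 360)`.
#' @return Numeric vector of cumulative angles (degrees), strictly
#'   increasing, with `theta_c %% 360 == theta` elementwise.
#' @export
unwrap_leaf_angles <- function(leaf_thetas) {
  if (length(leaf_thetas) == 0) stop("no leaf angles to unwrap")
  if (any(leaf_thetas < 0 | leaf_thetas >= 360))
    stop("leaf angles must lie in [0, 360)")
  theta_c <- numeric(length(leaf_thetas))
  theta_c[1] <- leaf_thetas[1]
  if (length(leaf_thetas) > 1) {
    for (i in 2:length(leaf_thetas)) {
      # smallest N >= 0 with theta + 360 N > previous cumulative angle
      N <- max(0, floor((theta_c[i - 1] - leaf_thetas[i]) / 360) + 1)
      theta_c[i] <- leaf_thetas[i] + 360 * N
    }
  }
  theta_c
}

#' Reflect a stem measured on a left-handed spiral
#'
#' Both clockwise and counterclockwise spiral phyllotaxis occur; analysis
#' is performed in a frame where the mean leaf-to-leaf divergence angle is
#' below 180 degrees. If the mean divergence of the (minimally unwrapped)
#' leaf angles is `>= 180` degrees, every organ angle is reflected,
#' `theta -> (360 - theta) mod 360`, and the `mirrored` flag is set.
#'
#' @param stem A [stem_record()] with at least 2 leaves.
#' @return A `stem_record`, reflected if necessary. Applying the function
#'   twice gives the same result as applying it once.
#' @export
mirror_if_left_handed <- function(stem) {
  lv <- leaf_rows(stem)
  if (nrow(lv) < 2) stop("insufficient leaves: need >= 2 for handedness")
  theta_c <- unwrap_leaf_angles(lv$theta_deg)
  if (mean(diff(theta_c)) < 180) return(stem)
  stem_record(
    stem$stem_id,
    stem$organs$kind,
    (360 - stem$organs$theta_deg) %% 360,
    stem$organs$H_mm,
    mirrored = TRUE
  )
}

#' Fit the phyllotaxis spline
#'
#' Interpolating natural cubic spline through the leaf knots
#' `(H, theta_c)`; this is the continuous reference curve
#' `theta_sp(H)` against which prickle angles are measured. With exactly
#' two leaves the spline degenerates to the connecting straight line.
#'
#' @param leaf_H Strictly increasing leaf heights (mm).
#' @param leaf_theta_c Strictly increasing cumulative leaf angles (degrees),
#'   as returned by [unwrap_leaf_angles()].
#' @return An object of class `phyllotaxis_frame` with components `leaf_H`,
#'   `leaf_theta_c` and `spline` (a function of `H` returning degrees,
#'   defined on `[min(leaf_H), max(leaf_H)]`).
#' @export
fit_phyllotaxis_spline <- function(leaf_H, leaf_theta_c) {
  if (length(leaf_H) < 2) stop("insufficient leaves: need >= 2 knots")
  if (length(leaf_H) != length(leaf_theta_c))
    stop("leaf_H and leaf_theta_c must have equal length")
  if (any(diff(leaf_H) <= 0)) stop("leaf_H must be strictly increasing")
  if (any(diff(leaf_theta_c) <= 0))
    stop("leaf_theta_c must be strictly increasing")
  sp <- stats::splinefun(leaf_H, leaf_theta_c, method = "natural")
  structure(
    list(leaf_H = leaf_H, leaf_theta_c = leaf_theta_c, spline = sp),
    class = "phyllotaxis_frame"
  )
}

#' @export
print.phyllotaxis_frame <- function(x, ...) {
  cat(sprintf(
    "phyllotaxis_frame: %d leaves, H in [%g, %g] mm, mean divergence %.1f deg\n",
    length(x$leaf_H), min(x$leaf_H), max(x$leaf_H),
    mean(diff(x$leaf_theta_c))
  ))
  invisible(x)
}

#' Leaf-to-leaf divergence angles
#'
#' Successive differences of the cumulative leaf angles. Values can exceed
#' 270 degrees where the spiral deviates strongly from the regular pattern.
#'
#' @param frame A [fit_phyllotaxis_spline()] frame.
#' @return Numeric vector of divergence angles in degrees (length =
#'   number of leaves minus one).
#' @export
divergence_angles <- function(frame) {
  if (length(frame$leaf_theta_c) < 2) stop("insufficient leaves")
  diff(frame$leaf_theta_c)
}

#' Relative prickle angle phi
#'
#' `phi = (theta + 360 N) - theta_sp(H)` with the unique integer `N`
#' placing `phi` in `[-90, 270)` degrees: `phi = 0` lies on the phyllotaxis
#' spline, positive phi is ahead of the spiral.
#'
#' @param prickle_theta Measured prickle angle(s) in degrees.
#' @param prickle_H Prickle height(s) in mm, inside the spline domain.
#' @param frame A `phyllotaxis_frame`.
#' @return Numeric vector of phi in `[-90, 270)` degrees; `NA` (with a
#'   warning) for prickles outside the internode range spanned by the
#'   leaves.
#' @export
compute_phi <- function(prickle_theta, prickle_H, frame) {
  out <- rep(NA_real_, length(prickle_theta))
  inside <- prickle_H >= min(frame$leaf_H) & prickle_H <= max(frame$leaf_H)
  if (any(!inside))
    warning(sprintf("%d prickle(s) outside internode range skipped",
                    sum(!inside)))
  if (any(inside)) {
    raw <- prickle_theta[inside] - frame$spline(prickle_H[inside])
    out[inside] <- raw - 360 * floor((raw + 90) / 360)
  }
  out
}

#' Relative prickle height h
#'
#' Rescales an absolute height into its internode: `h = 0` at the lower
#' node (leaf) and `h = 1` at the upper node. A prickle exactly at a node
#' belongs to the internode above it (`h = 0`), except at the topmost leaf
#' where it closes the last internode (`h = 1`).
#'
#' @param prickle_H Prickle height(s) in mm, between the lowest and highest
#'   leaf.
#' @param frame A `phyllotaxis_frame`.
#' @return A data frame with columns `h` in `[0, 1]` and `internode_index`
#'   (1-based index of the internode's lower leaf); `NA` rows for heights
#'   outside the leaf span.
#' @export
compute_h <- function(prickle_H, frame) {
  H <- frame$leaf_H
  n <- length(H)
  h <- rep(NA_real_, length(prickle_H))
  idx <- rep(NA_integer_, length(prickle_H))
  inside <- prickle_H >= H[1] & prickle_H <= H[n]
  if (any(inside)) {
    # leftmost.closed gives the node -> upper-internode tie-break
    i <- findInterval(prickle_H[inside], H)
    i[i >= n] <- n - 1L  # topmost leaf closes the last internode
    h[inside] <- (prickle_H[inside] - H[i]) / (H[i + 1L] - H[i])
    idx[inside] <- i
  }
  data.frame(h = h, internode_index = idx)
}

#' Nearest-prickle distances on the stem surface
#'
#' For each prickle, the distance `d_pp` to its nearest neighbour measured
#' on the cylinder surface: `sqrt(dH^2 + (r * dtheta)^2)` with the angular
#' difference wrapped into `(-pi, pi]`.
#'
#' @param theta_deg,H_mm Prickle angles (degrees) and heights (mm).
#' @param stem_radius_mm Stem radius in mm (default 5).
#' @return Numeric vector of `d_pp` in mm, one per prickle; empty if fewer
#'   than 2 prickles.
#' @export
nearest_prickle_distances <- function(theta_deg, H_mm, stem_radius_mm = 5) {
  if (stem_radius_mm <= 0) stop("stem_radius_mm must be > 0")
  n <- length(theta_deg)
  if (n < 2) return(numeric(0))
  dth <- outer(theta_deg, theta_deg, "-")
  dth <- ((dth + 180) %% 360) - 180          # wrapped into (-180, 180]
  arc <- stem_radius_mm * dth * pi / 180
  dH <- outer(H_mm, H_mm, "-")
  d <- sqrt(dH^2 + arc^2)
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Split prickles into three height layers
#'
#' Partitions prickles by absolute height into the bottom, middle and top
#' third of `[0, H_top]` (half-open lower two layers, closed top layer) and
#' returns the phi values per layer, for layer-wise distribution analysis.
#'
#' @param prickles Data frame with columns `phi_deg` and `H_mm`.
#' @param H_top Height of the topmost leaf (mm), `> 0`.
#' @return Named list of three numeric phi vectors: `bottom`, `middle`,
#'   `top`. Empty layers are allowed.
#' @export
layer_split <- function(prickles, H_top) {
  if (H_top <= 0) stop("H_top must be > 0")
  if (nrow(prickles) == 0)
    return(list(bottom = numeric(0), middle = numeric(0), top = numeric(0)))
  b <- H_top / 3
  lay <- ifelse(prickles$H_mm < b, 1L,
                ifelse(prickles$H_mm < 2 * b, 2L, 3L))
  list(
    bottom = prickles$phi_deg[lay == 1L],
    middle = prickles$phi_deg[lay == 2L],
    top = prickles$phi_deg[lay == 3L]
  )
}

#' Process one stem into leaf-relative prickle coordinates
#'
#' Full measurement pipeline for a single shoot: reflect to the
#' right-handed frame, unwrap the leaf angles, fit the phyllotaxis spline,
#' and convert every prickle to `(phi, h)`. Prickles below the lowest or
#' above the highest leaf are dropped with a warning. Nearest-neighbour
#' distances are computed on all prickles of the stem.
#'
#' @param stem A [stem_record()] with at least 2 leaves.
#' @param stem_radius_mm Radius used for the `d_pp` surface metric.
#' @return A data frame with one row per retained prickle: `stem_id`,
#'   `phi_deg`, `h`, `H_mm`, `internode_index`, `d_pp_mm`.
#' @export
process_stem <- function(stem, stem_radius_mm = 5) {
  stem <- mirror_if_left_handed(stem)
  lv <- leaf_rows(stem)
  frame <- fit_phyllotaxis_spline(lv$H_mm, unwrap_leaf_angles(lv$theta_deg))
  pk <- stem$organs[stem$organs$kind == "prickle", , drop = FALSE]
  empty <- data.frame(
    stem_id = character(0), phi_deg = numeric(0), h = numeric(0),
    H_mm = numeric(0), internode_index = integer(0), d_pp_mm = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(pk) == 0) return(empty)
  phi <- compute_phi(pk$theta_deg, pk$H_mm, frame)
  hh <- compute_h(pk$H_mm, frame)
  keep <- !is.na(phi)
  if (!any(keep)) return(empty)
  dpp_all <- if (nrow(pk) >= 2) {
    nearest_prickle_distances(pk$theta_deg, pk$H_mm, stem_radius_mm)
  } else rep(NA_real_, nrow(pk))
  data.frame(
    stem_id = stem$stem_id,
    phi_deg = phi[keep],
    h = hh$h[keep],
    H_mm = pk$H_mm[keep],
    internode_index = hh$internode_index[keep],
    d_pp_mm = dpp_all[keep],
    stringsAsFactors = FALSE
  )
}
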