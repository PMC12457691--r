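# Bent-rod cell contour generator: a circular-arc centerline dilated by half
# the cell width, with semicircular poles and an optional smooth width-noise
# profile. Ground truth (analytic centerline and width profile) is returned
# so morphometric descriptors can be scored against known curvature.

#' Configuration for the bent-rod contour generator
#'
#' @param length pole-to-pole cell length including the semicircular caps,
#'   um (so the cylindrical body has centerline arclength `length - width`).
#' @param width cell width (diameter), um; must be < `length`.
#' @param curvature signed centerline curvature, 1/um; 0 gives a straight
#'   rod (stadium shape). The magnitude is limited so the inner contour wall
#'   does not fold onto itself (`|curvature| * width / 2 < 0.95`) and the rod
#'   does not bend past a half circle.
#' @param width_noise_sd SD of a smooth width perturbation along the cell
#'   axis, um. The perturbation is a cubic-spline interpolation of
#'   independent Gaussian knots so that the marginal SD of the local width
#'   equals `width_noise_sd`.
#' @param n_points number of contour vertices (>= 20).
#' @param n_knots number of width-noise knots along the axis.
#' @param seed integer seed or `NULL`.
#' @return an object of class `contour_sim_config`.
#' @export
contour_sim_config <- function(length = 3, width = 0.9, curvature = 0,
                               width_noise_sd = 0, n_points = 200,
                               n_knots = 8, seed = NULL) {
  check_cfg(length > 0, "length", "must be > 0")
  check_cfg(width > 0, "width", "must be > 0")
  check_cfg(length > width, "length", "must exceed width")
  check_cfg(is.finite(curvature), "curvature", "must be finite")
  check_cfg(abs(curvature) * width / 2 < 0.95, "curvature",
            "is too high: inner wall would self-intersect")
  check_cfg(abs(curvature) * (length - width) <= pi, "curvature",
            "is too high: rod would bend past a half circle")
  check_cfg(width_noise_sd >= 0, "width_noise_sd", "must be >= 0")
  check_cfg(n_points >= 20, "n_points", "must be >= 20")
  structure(list(length = length, width = width, curvature = curvature,
                 width_noise_sd = width_noise_sd,
                 n_points = as.integer(n_points),
                 n_knots = as.integer(n_knots), seed = seed),
            class = "contour_sim_config")
}

# Arc centerline of given curvature through the origin, oriented along +x at
# its midpoint; returns positions and unit normals at arclengths s.
arc_centerline <- function(s, curvature) {
  if (abs(curvature) < 1e-12) {
    pos <- cbind(s, 0)
    nrm <- cbind(0, rep(1, length(s)))
  } else {
    r <- 1 / curvature
    phi <- s / r
    pos <- cbind(r * sin(phi), r * (1 - cos(phi)))
    # left-hand normal of the travel direction (cos phi, sin phi)
    nrm <- cbind(-sin(phi), cos(phi))
  }
  list(pos = pos, normal = nrm)
}

#' Simulate a bent-rod cell contour with analytic ground truth
#'
#' The centerline is a circular arc of the configured curvature (a straight
#' segment when curvature is 0), centered on the origin. The contour is the
#' centerline dilated by half the (possibly noisy) width, closed by
#' semicircular caps at the poles.
#'
#' @param cfg a [contour_sim_config()].
#' @return list with `contour` (n x 2 matrix of vertices, counter-clockwise,
#'   open), `centerline` (dense ground-truth centerline), `width_profile`
#'   (ground-truth width at the centerline samples), and `config`. The
#'   generated polygon is checked to be simple.
#' @export
simulate_bent_rod_contour <- function(cfg) {
  stopifnot(inherits(cfg, "contour_sim_config"))
  with_seed_if(cfg$seed, {
    n_side <- max(10L, as.integer(round(cfg$n_points * 0.38)))
    n_cap <- max(5L, as.integer(round((cfg$n_points - 2 * n_side) / 2)))
    body_len <- cfg$length - cfg$width
    s <- seq(-body_len / 2, body_len / 2, length.out = n_side)
    cl <- arc_centerline(s, cfg$curvature)

    w <- rep(cfg$width, n_side)
    if (cfg$width_noise_sd > 0) {
      ks <- seq(-body_len / 2, body_len / 2, length.out = cfg$n_knots)
      kv <- rnorm(cfg$n_knots, 0, cfg$width_noise_sd)
      nz <- spline(ks, kv, xout = s)$y
      # rescale so the realized width profile has exactly the requested SD
      nz <- nz * (cfg$width_noise_sd / max(sd(nz), 1e-12))
      w <- pmax(cfg$width + nz, 0.2 * cfg$width)  # keep the polygon valid
    }

    upper <- cl$pos + cl$normal * (w / 2)
    lower <- cl$pos - cl$normal * (w / 2)

    # semicircular caps around the pole points; a counter-clockwise sweep of
    # pi starting from the given offset direction passes through the outward
    # pole tangent for both ends
    cap_at <- function(idx, start_vec) {
      p <- cl$pos[idx, ]
      ang0 <- atan2(start_vec[2], start_vec[1])
      sweep <- seq(0, pi, length.out = n_cap + 2)[-c(1, n_cap + 2)]
      cbind(p[1] + w[idx] / 2 * cos(ang0 + sweep),
            p[2] + w[idx] / 2 * sin(ang0 + sweep))
    }
    # traverse: lower side left->right, right cap, upper side right->left,
    # left cap; orientation comes out counter-clockwise
    right_cap <- cap_at(n_side, -cl$normal[n_side, ])
    left_cap <- cap_at(1, cl$normal[1, ])
    contour <- rbind(lower, right_cap,
                     upper[rev(seq_len(n_side)), , drop = FALSE],
                     left_cap)
    if (polygon_area(rbind(contour)) <= 0 || !polygon_is_simple(contour))
      cfg_error("curvature", "produced a self-intersecting contour")
    list(contour = contour, centerline = cl$pos, width_profile = w,
         config = cfg)
  })
}
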