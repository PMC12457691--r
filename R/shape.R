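# Rod-cell morphometrics: medial-axis extraction from a cell contour and
# the four curvature descriptors (solidity, lateral and longitudinal
# asymmetry, width variation) plus width/length statistics.

#' Extract the medial axis of a rod-shaped cell contour
#'
#' Iterative chord method: chords are drawn perpendicular to the current
#' centerline estimate (initially the principal axis of the contour), and
#' their midpoints, smoothed, become the next centerline. Widths are the
#' chord lengths; poles are the contour points extremal along the end
#' tangents, and the centerline is extended to them.
#'
#' @param contour n x 2 vertex matrix (um) of a simple polygon with
#'   elongation (length/width) above ~1.5.
#' @param step_um spacing of the chord stations along the axis.
#' @param n_iter chord/midpoint refinement passes.
#' @return object of class `medial_axis`: list with `centerline` (m x 2,
#'   pole to pole), `width` (chord length at each interior centerline
#'   point; `NA` at the two poles), `s` (arclength of each centerline
#'   point), `poles` (2 x 2 matrix).
#' @export
extract_medial_axis <- function(contour, step_um = 0.05, n_iter = 3) {
  contour <- as.matrix(contour)
  if (!polygon_is_simple(contour))
    stop("shape extraction failed: contour polygon is not simple")
  ctr <- colMeans(contour)
  cen <- sweep(contour, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  elong <- sqrt(ev$values[1] / max(ev$values[2], 1e-12))
  if (elong < 1.2)
    stop("shape extraction failed: contour is not elongated (round cell?)")
  ax <- ev$vectors[, 1]

  # initial stations along the principal axis
  proj <- cen %*% ax
  lo <- min(proj); hi <- max(proj)
  margin <- 0.08 * (hi - lo)
  st <- seq(lo + margin, hi - margin, by = step_um)
  line <- sweep(outer(st, ax), 2, ctr, "+")
  tangents <- matrix(ax, nrow = length(st), ncol = 2, byrow = TRUE)

  for (it in seq_len(n_iter)) {
    mids <- matrix(NA_real_, nrow(line), 2)
    wids <- rep(NA_real_, nrow(line))
    for (i in seq_len(nrow(line))) {
      ch <- polygon_chord(contour, line[i, ], c(-tangents[i, 2], tangents[i, 1]))
      if (!is.null(ch)) {
        mids[i, ] <- (ch$a + ch$b) / 2
        wids[i] <- sqrt(sum((ch$b - ch$a)^2))
      }
    }
    ok <- complete.cases(mids)
    if (sum(ok) < 3)
      stop("shape extraction failed: could not place chords")
    mids <- mids[ok, , drop = FALSE]
    # local-linear smoothing of the midpoint polyline, coordinate-wise;
    # unlike a moving average it does not drag the endpoints inward
    idx <- seq_len(nrow(mids))
    f <- min(0.9, max(0.2, 8 / nrow(mids)))
    mids <- cbind(lowess(idx, mids[, 1], f = f, iter = 0)$y,
                  lowess(idx, mids[, 2], f = f, iter = 0)$y)
    # resample by arclength and recompute local tangents
    s_cum <- polyline_arclength(mids)
    s_new <- seq(0, s_cum[length(s_cum)], by = step_um)
    pa <- polyline_point_at(mids, s_cum, s_new)
    line <- pa$point
    tangents <- pa$tangent
  }

  # final chords on the refined centerline
  wids <- rep(NA_real_, nrow(line))
  for (i in seq_len(nrow(line))) {
    ch <- polygon_chord(contour, line[i, ], c(-tangents[i, 2], tangents[i, 1]))
    if (!is.null(ch)) wids[i] <- sqrt(sum((ch$b - ch$a)^2))
  }

  # poles: contour vertices extremal along the end tangents
  t_end <- tangents[nrow(tangents), ]
  t_start <- tangents[1, ]
  pole_hi <- unname(contour[which.max(contour %*% t_end), ])
  pole_lo <- unname(contour[which.max(contour %*% (-t_start)), ])
  centerline <- unname(rbind(pole_lo, line, pole_hi))
  wids <- c(NA_real_, wids, NA_real_)
  s <- polyline_arclength(centerline)
  structure(list(centerline = centerline, width = wids, s = s,
                 poles = rbind(pole_lo, pole_hi)),
            class = "medial_axis")
}

# Longest inside interval of the line point + t*dir clipped by the polygon;
# returns the two boundary points or NULL.
polygon_chord <- function(poly, point, dir) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  e <- b - a
  denom <- dir[1] * e[, 2] - dir[2] * e[, 1]
  w1 <- a[, 1] - point[1]
  w2 <- a[, 2] - point[2]
  t <- (w1 * e[, 2] - w2 * e[, 1]) / denom
  u <- (w1 * dir[2] - w2 * dir[1]) / denom
  hit <- is.finite(t) & u >= 0 & u < 1
  ts <- sort(t[hit])
  if (length(ts) < 2) return(NULL)
  # successive pairs bound inside intervals (even-odd rule)
  ts <- ts[seq_len(length(ts) - length(ts) %% 2)]
  if (!length(ts)) return(NULL)
  starts <- ts[seq(1, length(ts), by = 2)]
  ends <- ts[seq(2, length(ts), by = 2)]
  lens <- ends - starts
  k <- which.max(lens)
  list(a = point + starts[k] * dir, b = point + ends[k] * dir)
}

#' Solidity of a cell contour
#'
#' Ratio of the polygon area to the area of its convex hull: 1 for convex
#' shapes, lower the more the cell is bent.
#'
#' @param contour n x 2 vertex matrix (um).
#' @return solidity in (0, 1].
#' @export
solidity <- function(contour) {
  contour <- as.matrix(contour)
  a <- polygon_area(contour)
  if (a <= 0) stop("degenerate polygon: zero area")
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  a / polygon_area(hull)
}

#' Lateral or longitudinal asymmetry of a cell contour
#'
#' Overlap between the cell and its mirror image across an axis derived
#' from the medial axis, as intersection-over-union (1 = perfect symmetry).
#' The lateral reflection axis is the straight (total-least-squares) line
#' fitted to the medial-axis polyline: for a straight cell this is the
#' medial axis itself, and for a bent cell the overlap with the mirrored
#' cell drops with curvature. (Reflecting point-wise across the *curved*
#' axis would map any tube-shaped cell exactly onto itself and score every
#' uniformly bent rod as perfectly symmetric, which is not a useful
#' curvature descriptor.) The longitudinal reflection axis is the
#' perpendicular to the fitted line at the medial-axis arclength midpoint.
#' Note a uniformly bent (circular-arc) rod is genuinely longitudinally
#' symmetric, so that descriptor responds to asymmetric bending only.
#'
#' The IoU is estimated on a uniform point grid over the cell; because the
#' reflection is an isometry, `|A| = |mirror(A)|` and
#' `IoU = n_int / (2 n_A - n_int)`.
#'
#' @param contour n x 2 vertex matrix (um).
#' @param axis `"lateral"` or `"longitudinal"`.
#' @param medial optional precomputed [extract_medial_axis()] result.
#' @param resolution grid spacing, um; default adapts to the cell width.
#' @return overlap ratio in (0, 1].
#' @export
asymmetry <- function(contour, axis = c("lateral", "longitudinal"),
                      medial = NULL, resolution = NULL) {
  axis <- match.arg(axis)
  contour <- as.matrix(contour)
  if (is.null(medial)) medial <- extract_medial_axis(contour)
  cl <- medial$centerline
  s_cum <- medial$s
  total_s <- s_cum[length(s_cum)]
  mean_w <- mean(medial$width, na.rm = TRUE)
  if (is.null(resolution)) resolution <- max(mean_w / 40, total_s / 400)

  # straight axis fitted to the interior centerline (total least squares);
  # the appended pole vertices are single contour points and too noisy to
  # anchor a reflection axis
  int <- cl[2:(nrow(cl) - 1), , drop = FALSE]
  ctr <- colMeans(int)
  cen <- sweep(int, 2, ctr)
  u <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)$vectors[, 1]
  if (axis == "lateral") {
    anchor <- ctr
    dir <- u
  } else {
    anchor <- polyline_point_at(cl, s_cum, total_s / 2)$point[1, ]
    dir <- c(-u[2], u[1])
  }

  # half-cell offset keeps grid points off the polygon boundary, where
  # inside/outside ties would bias the overlap
  rx <- range(contour[, 1]); ry <- range(contour[, 2])
  gx <- seq(rx[1] + resolution / 2, rx[2], by = resolution)
  gy <- seq(ry[1] + resolution / 2, ry[2], by = resolution)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  ins <- points_in_polygon(grid, contour)
  pts <- grid[ins, , drop = FALSE]
  if (!nrow(pts)) stop("degenerate polygon: no interior grid points")

  # reflect across the line through `anchor` with direction `dir`
  rel <- sweep(pts, 2, anchor)
  along <- rel %*% dir
  perp <- rel - along %*% t(dir)
  mir_xy <- sweep(along %*% t(dir) - perp, 2, anchor, "+")
  mir_in <- points_in_polygon(mir_xy, contour)
  n_a <- nrow(pts)
  n_int <- sum(mir_in)
  n_int / (2 * n_a - n_int)
}

#' Width statistics along the medial axis
#'
#' Widths are resampled at `spacing_um` along the centerline; samples closer
#' than `mean_width / 2` to either pole are excluded because chords through
#' the hemispherical caps understate the cylinder diameter. Width variation
#' is the SD of the remaining widths (the resolution-matched analogue of
#' measuring the width one pixel apart).
#'
#' @param medial an [extract_medial_axis()] result.
#' @param spacing_um sampling interval along the axis (typically one pixel).
#' @return list: `width_variation_um`, `mean_width_um`, `length_um`
#'   (pole-to-pole centerline arclength), `n_samples`.
#' @export
width_stats <- function(medial, spacing_um = 0.05) {
  stopifnot(inherits(medial, "medial_axis"))
  ok <- !is.na(medial$width)
  s_ok <- medial$s[ok]
  w_ok <- medial$width[ok]
  total <- medial$s[length(medial$s)]
  mean_w0 <- mean(w_ok)
  cap <- mean_w0 / 2
  s_new <- seq(cap, total - cap, by = spacing_um)
  if (length(s_new) < 3)
    stop("fewer than 3 width samples remain after cap exclusion")
  w_new <- approx(s_ok, w_ok, xout = s_new, rule = 2)$y
  list(width_variation_um = sd(w_new), mean_width_um = mean(w_new),
       length_um = total, n_samples = length(s_new))
}

#' All shape descriptors for one cell contour
#'
#' @param contour n x 2 vertex matrix (um).
#' @param spacing_um width sampling interval (one pixel of the source
#'   image, typically).
#' @param cell_id identifier copied into the output.
#' @return one-row data.frame: `cell_id`, `solidity`, `lateral_asymmetry`,
#'   `longitudinal_asymmetry`, `width_variation_um`, `mean_width_um`,
#'   `length_um`.
#' @export
shape_descriptors <- function(contour, spacing_um = 0.05, cell_id = NA) {
  medial <- extract_medial_axis(contour)
  ws <- width_stats(medial, spacing_um)
  data.frame(cell_id = cell_id,
             solidity = solidity(contour),
             lateral_asymmetry = asymmetry(contour, "lateral", medial),
             longitudinal_asymmetry = asymmetry(contour, "longitudinal", medial),
             width_variation_um = ws$width_variation_um,
             mean_width_um = ws$mean_width_um,
             length_um = ws$length_um)
}

#' Convert a label mask to cell contours
#'
#' Extracts one contour per labeled object, scales pixel coordinates to um
#' under the package convention (position = (index - 1) * pixel_size) and
#' smooths each contour with a short moving average.
#'
#' @param mask integer label matrix (0 = background) or logical matrix.
#' @param pixel_size um/px.
#' @param smooth_window moving-average window (vertices).
#' @return named list of n x 2 contour matrices (um), one per label.
#' @export
mask_to_contours <- function(mask, pixel_size, smooth_window = 5) {
  stopifnot(pixel_size > 0)
  img <- EBImage::Image(t(mask != 0) * 1)  # EBImage is column-major x,y
  lab <- EBImage::bwlabel(img)
  if (is.integer(mask) || is.numeric(mask)) {
    if (max(mask) > 1) lab <- EBImage::Image(t(mask))
  }
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(m) {
    # ocontour returns 0-based (x, y) pixel coordinates
    xy <- cbind(m[, 1], m[, 2]) * pixel_size
    if (nrow(xy) >= smooth_window * 2) {
      xy <- apply(xy, 2, function(col) {
        smoothed <- stats::filter(c(tail(col, smooth_window), col,
                                    head(col, smooth_window)),
                                  rep(1 / smooth_window, smooth_window),
                                  sides = 2)
        as.numeric(smoothed)[(smooth_window + 1):(smooth_window + length(col))]
      })
    }
    # the trace runs through boundary-pixel centers, half a pixel inside the
    # object support; push each vertex out along its local outward normal
    n <- nrow(xy)
    nxt <- xy[c(2:n, 1), , drop = FALSE]
    prv <- xy[c(n, 1:(n - 1)), , drop = FALSE]
    tang <- nxt - prv
    len <- sqrt(rowSums(tang^2))
    len[len == 0] <- 1
    nrm <- cbind(-tang[, 2], tang[, 1]) / len
    ctr <- colMeans(xy)
    flip <- sign(rowSums(nrm * sweep(xy, 2, ctr)))
    flip[flip == 0] <- 1
    xy + nrm * flip * (pixel_size / 2)
  })
}
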