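# Shared geometry and config helpers.

# Configuration error naming the offending field, so callers can trap it.
cfg_error <- function(field, msg) {
  stop(structure(
    class = c("rodtrack_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration: `%s` %s", field, msg),
         call = NULL)
  ))
}

check_cfg <- function(ok, field, msg) {
  if (!isTRUE(ok)) cfg_error(field, msg)
  invisible(TRUE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL uses the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly two-column matrix of vertices (x, y), open (last vertex not
#'   repeated) or closed.
#' @return area in squared input units.
#' @keywords internal
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ]) && nrow(poly) > 1)
    poly <- poly[-nrow(poly), , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:length(x), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ]) && nrow(poly) > 1)
    poly <- poly[-nrow(poly), , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:length(x), 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Vectorized point-in-polygon; pts is an n x 2 matrix.
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- as.matrix(poly)
  if (!all(poly[1, ] == poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, pts)
}

# Does the closed polygon self-intersect? O(n^2) segment test; used only on
# simulated contours at generation time.
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ]) && nrow(poly) > 1)
    poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    if (i + 2 > n) break
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip shared-vertex neighbours
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Proper intersection test of segment p1-p2 against rows of q1/q2.
segments_intersect <- function(p1, p2, q1, q2) {
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  d <- p2 - p1
  e <- q2 - q1
  denom <- d[1] * e[, 2] - d[2] * e[, 1]
  w <- cbind(q1[, 1] - p1[1], q1[, 2] - p1[2])
  t <- (w[, 1] * e[, 2] - w[, 2] * e[, 1]) / denom
  u <- (w[, 1] * d[2] - w[, 2] * d[1]) / denom
  ok <- is.finite(t) & is.finite(u)
  ok & t > 0 & t < 1 & u > 0 & u < 1
}

# Arclength-parameterised polyline helpers ---------------------------------

polyline_arclength <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}

# Point on polyline at arclength s (clamped); also returns unit tangent.
polyline_point_at <- function(xy, s_cum, s) {
  s <- pmin(pmax(s, 0), s_cum[length(s_cum)])
  i <- findInterval(s, s_cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(xy) - 1)
  seg_len <- s_cum[i + 1] - s_cum[i]
  t <- ifelse(seg_len > 0, (s - s_cum[i]) / seg_len, 0)
  p <- xy[i, , drop = FALSE] + (xy[i + 1, , drop = FALSE] - xy[i, , drop = FALSE]) * t
  tang <- xy[i + 1, , drop = FALSE] - xy[i, , drop = FALSE]
  nrm <- sqrt(rowSums(tang^2))
  tang <- tang / ifelse(nrm > 0, nrm, 1)
  list(point = p, tangent = tang)
}

# For each point (rows of pts), nearest location on the polyline: arclength s,
# signed offset d (positive on the left of the travel direction).
polyline_project <- function(pts, xy) {
  n_seg <- nrow(xy) - 1
  s_cum <- polyline_arclength(xy)
  best_d2 <- rep(Inf, nrow(pts))
  best_s <- numeric(nrow(pts))
  best_off <- numeric(nrow(pts))
  for (i in seq_len(n_seg)) {
    a <- xy[i, ]; b <- xy[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      cross <- ab[1] * (pts[upd, 2] - py[upd]) - ab[2] * (pts[upd, 1] - px[upd])
      best_d2[upd] <- d2[upd]
      best_s[upd] <- s_cum[i] + t[upd] * sqrt(len2)
      best_off[upd] <- sign(cross) * sqrt(d2[upd])
    }
  }
  list(s = best_s, d = best_off)
}
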