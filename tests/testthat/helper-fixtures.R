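# Small track/contour builders used across test files.

# Straight-line track at constant speed v (um/s), orientation theta.
ballistic_track <- function(n = 20, v = 0.05, t_lag = 1, theta = 0,
                            noise_sd = 0, id = 1) {
  t <- (seq_len(n) - 1) * t_lag
  x <- cos(theta) * v * t
  y <- sin(theta) * v * t
  if (noise_sd > 0) {
    x <- x + rnorm(n, sd = noise_sd)
    y <- y + rnorm(n, sd = noise_sd)
  }
  data.frame(traj_id = id, frame = seq_len(n), t_s = t, x_um = x, y_um = y)
}

# Pure Brownian track with diffusion coefficient d (um^2/s).
brownian_track <- function(n = 20, d = 0.01, t_lag = 0.1, id = 1) {
  steps <- matrix(rnorm(2 * (n - 1), sd = sqrt(2 * d * t_lag)), n - 1, 2)
  xy <- rbind(c(0, 0), apply(steps, 2, cumsum))
  data.frame(traj_id = id, frame = seq_len(n), t_s = (seq_len(n) - 1) * t_lag,
             x_um = xy[, 1], y_um = xy[, 2])
}

# Stationary track at a fixed point.
stationary_track <- function(n = 12, x = 1, y = 2, t_lag = 1, id = 1) {
  data.frame(traj_id = id, frame = seq_len(n), t_s = (seq_len(n) - 1) * t_lag,
             x_um = x, y_um = y)
}

# Fraction of a polygon's bounding-box grid inside it, times bbox area:
# rasterization area oracle, independent of the shoelace formula.
raster_area <- function(poly, res = 0.01) {
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  gx <- seq(rx[1] + res / 2, rx[2], by = res)
  gy <- seq(ry[1] + res / 2, ry[2], by = res)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), grid)
  sum(inside) * res^2
}

# All permutations of a small vector (brute-force assignment oracle).
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}
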