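# MSD computation, directed/diffusive classification and the summary
# statistics of the directional subpopulation (speed, fraction, surface
# density).

#' Mean squared displacement of one trajectory
#'
#' Overlapping-pair estimator: MSD at lag n is the mean of
#' `|r(i+n) - r(i)|^2` over all valid i. Lag 0 is excluded.
#'
#' @param traj single-trajectory track table (columns `frame`, `t_s`,
#'   `x_um`, `y_um`), with contiguous frames.
#' @param max_lag_frames largest lag computed; defaults to `n - 1`.
#' @return object of class `msd_profile`: data.frame with `lag_frames`,
#'   `lag_s`, `msd`, `n_pairs`, plus attributes `n_points` and `t_lag`.
#' @export
compute_msd <- function(traj, max_lag_frames = NULL) {
  stopifnot(nrow(traj) >= 2)
  traj <- traj[order(traj$frame), , drop = FALSE]
  n <- nrow(traj)
  if (is.null(max_lag_frames)) max_lag_frames <- n - 1
  max_lag_frames <- min(max_lag_frames, n - 1)
  t_lag <- min(diff(traj$t_s))
  xy <- cbind(traj$x_um, traj$y_um)
  lags <- seq_len(max_lag_frames)
  msd <- numeric(length(lags))
  np <- integer(length(lags))
  for (k in lags) {
    d <- xy[(1 + k):n, , drop = FALSE] - xy[seq_len(n - k), , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    np[k] <- n - k
  }
  structure(data.frame(lag_frames = lags, lag_s = lags * t_lag,
                       msd = msd, n_pairs = np),
            n_points = n, t_lag = t_lag, class = c("msd_profile", "data.frame"))
}

#' Classify one trajectory as directed or diffusive from its MSD
#'
#' The MSD over a short fit window is fitted to a ballistic model
#' (`MSD = (v t)^2`, fitted as `sqrt(MSD) = v t` which is linear in the
#' speed) and to a free-diffusion model (`MSD = 4 D t`, zero intercept by
#' default). A track is `directed` when the ballistic R^2 reaches `r2_dir`;
#' otherwise `diffusive` when the linear R^2 reaches `r2_diff`; otherwise
#' `unclassified`. Tracks shorter than `min_frames` are `too_short`.
#' Directed is tested first because a ballistic track also fits a line well.
#'
#' The fit window is the first `max(3, min(floor(n/4), 10))` lags (n = track
#' length): long lags of the overlapping estimator are noisy, and fewer than
#' 3 points make R^2 degenerate. R^2 is `1 - SS_res/SS_tot` on the window.
#'
#' @param msd an `msd_profile` from [compute_msd()], or a single-trajectory
#'   track table (the MSD is then computed internally).
#' @param r2_dir,r2_diff acceptance thresholds for the ballistic and
#'   diffusive fits.
#' @param min_frames minimum trajectory duration, frames.
#' @param noise_intercept if `TRUE` the diffusive fit gains a free intercept
#'   absorbing localization noise (`MSD = 4 D t + c`).
#' @return list of class `motion_classification`: `label`, `r2_dir`,
#'   `r2_diff`, `speed_um_s`, `d_msd_um2_s`, `n_frames`.
#' @export
classify_trajectory <- function(msd, r2_dir = 0.9, r2_diff = 0.8,
                                min_frames = 10, noise_intercept = FALSE) {
  # the fit window never exceeds 10 lags, so longer lags are not needed
  if (!inherits(msd, "msd_profile")) msd <- compute_msd(msd, max_lag_frames = 10)
  n <- attr(msd, "n_points")
  res <- list(label = "too_short", r2_dir = NA_real_, r2_diff = NA_real_,
              speed_um_s = NA_real_, d_msd_um2_s = NA_real_, n_frames = n)
  class(res) <- "motion_classification"
  if (n < min_frames) return(res)

  w <- max(3L, min(n %/% 4L, 10L))
  w <- min(w, nrow(msd))
  t <- msd$lag_s[seq_len(w)]
  y <- msd$msd[seq_len(w)]

  if (all(y == 0)) {
    # perfectly stationary: zero-diffusion model fits exactly
    res$label <- "diffusive"
    res$d_msd_um2_s <- 0
    res$r2_diff <- 1
    return(res)
  }

  # ballistic: sqrt(MSD) = v * t through the origin
  ry <- sqrt(y)
  v <- sum(t * ry) / sum(t^2)
  res$r2_dir <- r_squared(ry, v * t)

  # diffusive: MSD = 4 D t (+ optional intercept)
  if (noise_intercept) {
    fit <- lm(y ~ t)
    dcoef <- coef(fit)[["t"]] / 4
    pred <- fitted(fit)
  } else {
    dcoef <- sum(4 * t * y) / sum((4 * t)^2)
    pred <- 4 * dcoef * t
  }
  res$r2_diff <- r_squared(y, pred)

  if (res$r2_dir >= r2_dir) {
    res$label <- "directed"
    res$speed_um_s <- v
  } else if (res$r2_diff >= r2_diff) {
    res$label <- "diffusive"
    res$d_msd_um2_s <- max(dcoef, 0)
  } else {
    res$label <- "unclassified"
  }
  res
}

r_squared <- function(y, pred) {
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - pred)^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}

#' Classify every trajectory of a track table
#'
#' @param tracks track table with one or more trajectories.
#' @inheritParams classify_trajectory
#' @return data.frame with one row per trajectory: `traj_id`, `label`,
#'   `r2_dir`, `r2_diff`, `speed_um_s`, `d_msd_um2_s`, `n_frames`.
#' @export
classify_tracks <- function(tracks, r2_dir = 0.9, r2_diff = 0.8,
                            min_frames = 10, noise_intercept = FALSE) {
  ids <- unique(tracks$traj_id)
  subs <- split(tracks, factor(tracks$traj_id, levels = ids))
  rows <- lapply(ids, function(id) {
    cl <- classify_trajectory(subs[[as.character(id)]], r2_dir = r2_dir,
                              r2_diff = r2_diff, min_frames = min_frames,
                              noise_intercept = noise_intercept)
    data.frame(traj_id = id, label = cl$label, r2_dir = cl$r2_dir,
               r2_diff = cl$r2_diff, speed_um_s = cl$speed_um_s,
               d_msd_um2_s = cl$d_msd_um2_s, n_frames = cl$n_frames)
  })
  do.call(rbind, rows)
}

#' Summary of the directed subpopulation
#'
#' @param classifications data.frame from [classify_tracks()].
#' @return list: `mean_speed_um_s`, `sd_speed_um_s` (both `NA` when no track
#'   is directed), `n_directed`, `n_classifiable` (tracks meeting the
#'   duration filter), `directional_fraction` = directed / (directed +
#'   diffusive + unclassified).
#' @export
summarize_directed <- function(classifications) {
  stopifnot(nrow(classifications) >= 1)
  cl <- classifications[classifications$label != "too_short", , drop = FALSE]
  n_dir <- sum(cl$label == "directed")
  speeds <- cl$speed_um_s[cl$label == "directed"]
  list(mean_speed_um_s = if (n_dir) mean(speeds) else NA_real_,
       sd_speed_um_s = if (n_dir > 1) sd(speeds) else NA_real_,
       n_directed = n_dir,
       n_classifiable = nrow(cl),
       directional_fraction = if (nrow(cl)) n_dir / nrow(cl) else NA_real_)
}

#' Surface density of directionally moving foci
#'
#' For each frame, counts the foci of directed-classified trajectories whose
#' position falls inside the cell mask and divides by the mask area; the
#' mean over frames is the reported density. The denominator is the cell
#' area, not the imaged field.
#'
#' @param classifications data.frame from [classify_tracks()].
#' @param tracks the track table the classifications came from.
#' @param mask cell mask: polygon (n x 2 matrix, um), list of polygons, or a
#'   logical/binary matrix with `pixel_size` given.
#' @param n_frames number of movie frames; defaults to the largest frame
#'   index present.
#' @param pixel_size um/px, required when `mask` is a matrix mask.
#' @return list of class `density_estimate`: `mean_density_um2`,
#'   `sd_density_um2`, `per_frame` (density per frame), `cell_area_um2`,
#'   `n_directed_foci` (count per frame).
#' @export
compute_density <- function(classifications, tracks, mask, n_frames = NULL,
                            pixel_size = NULL) {
  if (is.matrix(mask) && !is.null(pixel_size) &&
      (is.logical(mask) || all(mask %in% c(0, 1)))) {
    area <- sum(mask != 0) * pixel_size^2
    inside_fun <- function(pts) {
      r <- round(pts[, 2] / pixel_size) + 1
      c <- round(pts[, 1] / pixel_size) + 1
      ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
      ins <- rep(FALSE, nrow(pts))
      ins[ok] <- mask[cbind(r[ok], c[ok])] != 0
      ins
    }
  } else {
    polys <- if (is.list(mask)) mask else list(mask)
    area <- sum(vapply(polys, polygon_area, 0))
    inside_fun <- function(pts) {
      ins <- rep(FALSE, nrow(pts))
      for (p in polys) ins <- ins | points_in_polygon(pts, p)
      ins
    }
  }
  if (area <= 0) stop("cell mask area must be > 0")
  if (is.null(n_frames)) n_frames <- max(tracks$frame)
  dir_ids <- classifications$traj_id[classifications$label == "directed"]
  pts <- tracks[tracks$traj_id %in% dir_ids, , drop = FALSE]
  counts <- integer(n_frames)
  if (nrow(pts)) {
    ins <- inside_fun(cbind(pts$x_um, pts$y_um))
    tab <- table(factor(pts$frame[ins], levels = seq_len(n_frames)))
    counts <- as.integer(tab)
  }
  dens <- counts / area
  structure(list(mean_density_um2 = mean(dens),
                 sd_density_um2 = if (n_frames > 1) sd(dens) else NA_real_,
                 per_frame = dens, cell_area_um2 = area,
                 n_directed_foci = counts),
            class = "density_estimate")
}
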