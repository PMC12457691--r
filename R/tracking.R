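# Spot detection (scale-matched Laplacian-of-Gaussian) and frame-to-frame
# linking by linear-assignment matching, mirroring TrackMate's LoG detector
# and LAP connector with zero frame gap.

#' Detect diffraction-limited spots in a stack
#'
#' Each frame is convolved with a scale-normalized Laplacian-of-Gaussian
#' kernel whose scale sigma = `radius_um / sqrt(2)` matches blobs of the
#' requested radius. Local maxima of the response above `threshold` are kept,
#' refined to subpixel precision by a quadratic fit to the 3x3 response
#' neighbourhood, and pruned so that no two detections in one frame are
#' closer than `radius_um` (the brighter one wins).
#'
#' The response, and therefore `threshold`, is in the image's intensity
#' units: the peak response of an ideal spot scales with its amplitude, so
#' the threshold must be chosen relative to the camera scaling of the data
#' at hand.
#'
#' @param stack an [image_stack()], normally preprocessed with
#'   [preprocess_stack()].
#' @param radius_um blob radius, um; must be at least one pixel.
#' @param threshold minimum LoG response (quality) retained.
#' @return data.frame with columns `frame`, `x_um`, `y_um`, `quality`,
#'   `intensity` (raw pixel value at the peak).
#' @export
detect_spots <- function(stack, radius_um = 0.25, threshold = 100) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- stack$pixel_size
  if (radius_um < ps)
    cfg_error("radius_um", "must be at least one pixel")
  sigma_px <- (radius_um / sqrt(2)) / ps
  kern <- log_kernel(sigma_px)
  d <- dim(stack$pixels)
  out <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    frame <- stack$pixels[, , f]
    resp <- EBImage::filter2(frame, kern, boundary = "replicate")
    pk <- local_maxima(resp, threshold)
    if (!nrow(pk)) next
    # subpixel refinement: 1D quadratic through the 3 response values per axis
    sub <- t(apply(pk, 1, function(rc) {
      r <- rc[1]; c <- rc[2]
      dr <- dc <- 0
      if (r > 1 && r < d[1]) {
        den <- resp[r - 1, c] - 2 * resp[r, c] + resp[r + 1, c]
        if (den < 0) dr <- 0.5 * (resp[r - 1, c] - resp[r + 1, c]) / den
      }
      if (c > 1 && c < d[2]) {
        den <- resp[r, c - 1] - 2 * resp[r, c] + resp[r, c + 1]
        if (den < 0) dc <- 0.5 * (resp[r, c - 1] - resp[r, c + 1]) / den
      }
      c(dr, dc)
    }))
    sub[!is.finite(sub)] <- 0
    sub <- pmin(pmax(sub, -0.5), 0.5)
    det <- data.frame(frame = f,
                      x_um = (pk[, 2] - 1 + sub[, 2]) * ps,
                      y_um = (pk[, 1] - 1 + sub[, 1]) * ps,
                      quality = resp[pk],
                      intensity = frame[pk])
    out[[f]] <- suppress_close(det, radius_um)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      quality = numeric(), intensity = numeric())
  rownames(res) <- NULL
  res
}

# Scale-normalized LoG kernel (-sigma^2 * Laplacian of Gaussian),
# sign-flipped so bright blobs give positive peaks, and zero-mean so
# constant regions respond 0. The response scale is linear in blob
# amplitude; its absolute value depends on image scaling, which is why the
# detection threshold is a free configuration value.
log_kernel <- function(sigma_px) {
  r <- max(2L, as.integer(ceiling(4 * sigma_px)))
  xs <- -r:r
  g <- exp(-xs^2 / (2 * sigma_px^2))
  x2 <- outer(rep(1, length(xs)), xs^2)
  y2 <- t(x2)
  gg <- outer(g, g)
  k <- -((x2 + y2 - 2 * sigma_px^2) / sigma_px^2) * (gg / sum(gg))
  k - mean(k)
}

# Row/col indices of strict 8-neighbour local maxima above `thr`.
local_maxima <- function(m, thr) {
  nr <- nrow(m); nc <- ncol(m)
  core <- m[2:(nr - 1), 2:(nc - 1)]
  ok <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & core >= m[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  which(ok, arr.ind = TRUE) + 1L
}

# Greedy non-maximum suppression: keep the highest-quality detection of any
# pair closer than min_dist.
suppress_close <- function(det, min_dist) {
  if (nrow(det) < 2) return(det)
  o <- order(-det$quality)
  det <- det[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det) - 1)) {
    if (!keep[i]) next
    js <- (i + 1):nrow(det)
    d2 <- (det$x_um[js] - det$x_um[i])^2 + (det$y_um[js] - det$y_um[i])^2
    keep[js][d2 < min_dist^2] <- FALSE
  }
  det[keep, , drop = FALSE]
}

#' Link detections into trajectories
#'
#' Frame-to-frame association is solved as an optimal linear assignment:
#' candidate links cost their squared displacement, capped at
#' `max_dist_um^2`; the alternative (ending a track / starting a new one)
#' costs the cap, so a detection pair is linked exactly when it improves on
#' that alternative and the total squared displacement is minimal.
#' With `max_gap = 0` (the only supported value) a trajectory ends as soon as
#' no admissible match exists in the next frame. Single-detection tracks are
#' discarded (a trajectory has at least two points).
#'
#' @param dets detection table from [detect_spots()].
#' @param max_dist_um maximum linking distance, um.
#' @param max_gap maximum number of skipped frames; only 0 is supported (no
#'   gap closing).
#' @param t_lag frame interval used to fill the `t_s` column, s.
#' @return track table (`traj_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `quality`, `intensity`) sorted by trajectory then frame.
#' @export
link_detections <- function(dets, max_dist_um = 0.4, max_gap = 0, t_lag = 1) {
  if (max_gap != 0)
    cfg_error("max_gap", "gap closing is not supported; use 0")
  empty <- data.frame(traj_id = integer(), frame = integer(), t_s = numeric(),
                      x_um = numeric(), y_um = numeric(), quality = numeric(),
                      intensity = numeric())
  if (is.null(dets) || !nrow(dets)) return(empty)
  if (!"quality" %in% names(dets)) dets$quality <- NA_real_
  if (!"intensity" %in% names(dets)) dets$intensity <- NA_real_
  dets <- dets[order(dets$frame), , drop = FALSE]
  frames <- sort(unique(dets$frame))
  cap <- max_dist_um^2
  big <- 1e12

  # active tracks: list of integer row-index vectors into dets
  active <- list()
  done <- list()
  prev_frame <- frames[1]
  idx <- which(dets$frame == frames[1])
  active <- as.list(idx)
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]
    idx <- which(dets$frame == f)
    if (f != prev_frame + 1 || !length(active)) {
      done <- c(done, active)
      active <- as.list(idx)
      prev_frame <- f
      next
    }
    n1 <- length(active); n2 <- length(idx)
    last <- vapply(active, function(v) v[length(v)], 0L)
    dx <- outer(dets$x_um[last], dets$x_um[idx], "-")
    dy <- outer(dets$y_um[last], dets$y_um[idx], "-")
    cost <- dx^2 + dy^2
    cost[cost > cap] <- big
    # augmented square LAP: real links, track deaths, spot births
    m <- matrix(big, n1 + n2, n1 + n2)
    m[seq_len(n1), seq_len(n2)] <- cost
    m[cbind(seq_len(n1), n2 + seq_len(n1))] <- cap
    m[cbind(n1 + seq_len(n2), seq_len(n2))] <- cap
    m[n1 + seq_len(n2), n2 + seq_len(n1)] <- t(cost)
    asg <- solve_assignment(m)
    new_active <- list()
    linked_cols <- logical(n2)
    for (i in seq_len(n1)) {
      j <- asg[i]
      if (j <= n2 && cost[i, j] < big) {
        new_active[[length(new_active) + 1]] <- c(active[[i]], idx[j])
        linked_cols[j] <- TRUE
      } else {
        done <- c(done, active[i])
      }
    }
    for (j in which(!linked_cols))
      new_active[[length(new_active) + 1]] <- idx[j]
    active <- new_active
    prev_frame <- f
  }
  done <- c(done, active)
  done <- done[vapply(done, length, 0L) >= 2]
  if (!length(done)) return(empty)
  out <- do.call(rbind, lapply(seq_along(done), function(k) {
    rows <- dets[done[[k]], , drop = FALSE]
    data.frame(traj_id = k, frame = rows$frame,
               t_s = (rows$frame - 1) * t_lag,
               x_um = rows$x_um, y_um = rows$y_um,
               quality = rows$quality, intensity = rows$intensity)
  }))
  rownames(out) <- NULL
  out
}

#' Solve a square linear assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix via the
#' Jonker-Volgenant shortest-augmenting-path algorithm (O(n^3)).
#'
#' @param cost square numeric cost matrix (finite values).
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1                   # columns are offset by 1 (col 1 is virtual)
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j] + 1] <- u[p[j] + 1] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  asg <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) asg[p[j]] <- j - 1
  asg
}

#' Filter trajectories by duration and cell mask
#'
#' Keeps trajectories with at least `min_frames` points and, when a mask is
#' given, whose centroid lies inside it. Counts of kept and dropped
#' trajectories are attached as attributes.
#'
#' @param tracks track table.
#' @param min_frames minimum number of points per trajectory.
#' @param mask optional cell mask: a polygon (n x 2 matrix, um) or a list of
#'   polygons.
#' @return filtered track table with attributes `n_kept` and `n_dropped`.
#' @export
filter_tracks <- function(tracks, min_frames = 10, mask = NULL) {
  if (is.null(tracks) || !nrow(tracks)) {
    out <- tracks
    attr(out, "n_kept") <- 0L
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  ids <- unique(tracks$traj_id)
  subs <- split(tracks, factor(tracks$traj_id, levels = ids))
  keep <- vapply(ids, function(id) {
    sub <- subs[[as.character(id)]]
    if (nrow(sub) < min_frames) return(FALSE)
    if (!is.null(mask)) {
      ctr <- matrix(c(mean(sub$x_um), mean(sub$y_um)), 1)
      polys <- if (is.list(mask)) mask else list(mask)
      if (!any(vapply(polys, function(p) points_in_polygon(ctr, p), FALSE)))
        return(FALSE)
    }
    TRUE
  }, FALSE)
  out <- tracks[tracks$traj_id %in% ids[keep], , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
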