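# TIRF-like movie renderer: diffraction-limited spots on a dark background
# inside rod-shaped cell footprints, with Poisson-Gaussian camera noise.

#' Configuration for the movie simulator
#'
#' @param frame_shape integer `c(rows, cols)` in pixels.
#' @param pixel_size um/px.
#' @param n_frames number of frames.
#' @param cell_footprints list of rod polygons (n x 2 matrices, um) inside
#'   which foci live. All footprints must fit inside the frame.
#' @param psf_sigma SD of the 2D Gaussian point-spread function, um.
#' @param spot_amplitude integrated photon count of one focus (the rendered
#'   Gaussian sums to this value over pixels).
#' @param background constant background offset, counts.
#' @param poisson_noise apply Poisson shot noise to (signal + background)?
#' @param gaussian_sd SD of additive Gaussian read noise, counts.
#' @param trajectory_config optional [trajectory_sim_config()] used by
#'   [simulate_movie()] to generate foci tracks inside the footprints.
#' @param seed integer seed or `NULL`.
#' @return an object of class `movie_sim_config`.
#' @export
movie_sim_config <- function(frame_shape, pixel_size, n_frames,
                             cell_footprints, psf_sigma = 0.1,
                             spot_amplitude = 500, background = 100,
                             poisson_noise = TRUE, gaussian_sd = 2,
                             trajectory_config = NULL, seed = NULL) {
  check_cfg(length(frame_shape) == 2 && all(frame_shape >= 4), "frame_shape",
            "must be c(rows, cols) with both >= 4")
  check_cfg(pixel_size > 0, "pixel_size", "must be > 0")
  check_cfg(n_frames >= 1, "n_frames", "must be >= 1")
  check_cfg(psf_sigma > 0, "psf_sigma", "must be > 0")
  check_cfg(spot_amplitude >= 0, "spot_amplitude", "must be >= 0")
  check_cfg(background >= 0, "background", "must be >= 0")
  check_cfg(gaussian_sd >= 0, "gaussian_sd", "must be >= 0")
  if (!is.list(cell_footprints)) cell_footprints <- list(cell_footprints)
  lim_x <- (frame_shape[2] - 1) * pixel_size
  lim_y <- (frame_shape[1] - 1) * pixel_size
  for (fp in cell_footprints) {
    fp <- as.matrix(fp)
    if (any(fp[, 1] < 0) || any(fp[, 1] > lim_x) ||
        any(fp[, 2] < 0) || any(fp[, 2] > lim_y))
      cfg_error("cell_footprints", "must lie inside the frame")
  }
  structure(list(frame_shape = as.integer(frame_shape),
                 pixel_size = pixel_size, n_frames = as.integer(n_frames),
                 cell_footprints = lapply(cell_footprints, as.matrix),
                 psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
                 background = background, poisson_noise = poisson_noise,
                 gaussian_sd = gaussian_sd,
                 trajectory_config = trajectory_config, seed = seed),
            class = "movie_sim_config")
}

# Render one spot into a frame (in place). The Gaussian is integrated over
# pixel boundaries per axis, so the rendered spot sums exactly to `amp`
# (up to the +-5 sigma window truncation).
render_spot <- function(frame, x_um, y_um, amp, psf_sigma, pixel_size) {
  sx <- psf_sigma / pixel_size
  cx <- x_um / pixel_size + 1
  cy <- y_um / pixel_size + 1
  r <- ceiling(5 * sx)
  cols <- max(1, floor(cx - r)):min(ncol(frame), ceiling(cx + r))
  rows <- max(1, floor(cy - r)):min(nrow(frame), ceiling(cy + r))
  if (!length(cols) || !length(rows)) return(frame)
  gx <- pnorm(cols + 0.5, cx, sx) - pnorm(cols - 0.5, cx, sx)
  gy <- pnorm(rows + 0.5, cy, sx) - pnorm(rows - 0.5, cy, sx)
  frame[rows, cols] <- frame[rows, cols] + amp * outer(gy, gx)
  frame
}

#' Simulate a TIRF-like movie with ground truth
#'
#' Each focus is rendered as an integrated 2D Gaussian of SD `psf_sigma` at
#' its true subpixel position; the constant background is added and
#' Poisson/Gaussian noise applied. Foci trajectories are either supplied
#' (`tracks`; any table with `traj_id`, `frame`, `x_um`, `y_um`) or generated
#' from `cfg$trajectory_config` with start positions placed uniformly inside
#' the cell footprints (directed tracks are oriented perpendicular to the
#' footprint long axis and rejected until they stay inside).
#'
#' @param cfg a [movie_sim_config()].
#' @param tracks optional track table overriding the internal generator;
#'   frames beyond `cfg$n_frames` are ignored.
#' @return list with `stack` (an [image_stack()]; `t_lag` from the trajectory
#'   config or 1 s), `tracks` (ground-truth table actually rendered) and
#'   `config`.
#' @export
simulate_movie <- function(cfg, tracks = NULL) {
  stopifnot(inherits(cfg, "movie_sim_config"))
  with_seed_if(cfg$seed, {
    t_lag <- 1
    if (is.null(tracks)) {
      if (!is.null(cfg$trajectory_config)) {
        tracks <- place_tracks_in_footprints(cfg)
        t_lag <- cfg$trajectory_config$t_lag
      } else {
        tracks <- data.frame(traj_id = integer(), frame = integer(),
                             x_um = numeric(), y_um = numeric())
      }
    } else if ("t_s" %in% names(tracks) && nrow(tracks) > 1) {
      dt <- diff(sort(unique(tracks$t_s)))
      if (length(dt)) t_lag <- min(dt)
    }
    tracks <- tracks[tracks$frame >= 1 & tracks$frame <= cfg$n_frames, ,
                     drop = FALSE]
    d <- cfg$frame_shape
    px <- array(cfg$background, dim = c(d[1], d[2], cfg$n_frames))
    if (nrow(tracks)) {
      for (f in sort(unique(tracks$frame))) {
        sub <- tracks[tracks$frame == f, , drop = FALSE]
        fr <- px[, , f]
        for (i in seq_len(nrow(sub)))
          fr <- render_spot(fr, sub$x_um[i], sub$y_um[i],
                            cfg$spot_amplitude, cfg$psf_sigma, cfg$pixel_size)
        px[, , f] <- fr
      }
    }
    if (cfg$poisson_noise)
      px[] <- rpois(length(px), lambda = px)
    if (cfg$gaussian_sd > 0)
      px[] <- px + rnorm(length(px), sd = cfg$gaussian_sd)
    list(stack = image_stack(px, cfg$pixel_size, t_lag),
         tracks = tracks, config = cfg)
  })
}

# Generate trajectories from cfg$trajectory_config and translate each to a
# uniformly drawn start inside a randomly chosen footprint; directed tracks
# are re-oriented perpendicular to the footprint long axis and re-drawn until
# the whole noise-free path stays inside (up to 200 attempts).
place_tracks_in_footprints <- function(cfg) {
  tc <- cfg$trajectory_config
  sim <- simulate_trajectories(tc)
  tr <- sim$tracks
  out <- vector("list", tc$n_traj)
  for (i in seq_len(tc$n_traj)) {
    sub <- tr[tr$traj_id == i, , drop = FALSE]
    fp <- cfg$cell_footprints[[sample.int(length(cfg$cell_footprints), 1)]]
    ax <- footprint_axis(fp)
    rel <- cbind(sub$x_true_um - sub$x_true_um[1],
                 sub$y_true_um - sub$y_true_um[1])
    if (sub$true_class[1] == "directed") {
      # re-orient the straight path perpendicular to the cell long axis
      len <- sqrt(rowSums(rel^2))
      dir <- c(-ax[2], ax[1]) * sample(c(-1, 1), 1)
      rel <- outer(len, dir)
    }
    ok <- FALSE
    for (try in seq_len(200)) {
      start <- random_point_in_polygon(fp)
      pos <- sweep(rel, 2, start, "+")
      if (all(points_in_polygon(pos, fp))) { ok <- TRUE; break }
    }
    if (!ok)
      cfg_error("cell_footprints",
                "cannot accommodate a trajectory; footprint too small")
    noise <- if (tc$loc_noise_sd > 0)
      matrix(rnorm(2 * nrow(sub), sd = tc$loc_noise_sd), ncol = 2)
    else matrix(0, nrow(sub), 2)
    sub$x_true_um <- pos[, 1]; sub$y_true_um <- pos[, 2]
    sub$x_um <- pos[, 1] + noise[, 1]; sub$y_um <- pos[, 2] + noise[, 2]
    out[[i]] <- sub
  }
  do.call(rbind, out)
}

footprint_axis <- function(fp) {
  ctr <- sweep(as.matrix(fp), 2, colMeans(fp))
  v <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

random_point_in_polygon <- function(poly, max_try = 1000) {
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  for (i in seq_len(max_try)) {
    p <- c(runif(1, rx[1], rx[2]), runif(1, ry[1], ry[2]))
    if (points_in_polygon(matrix(p, 1), poly)) return(p)
  }
  stop("failed to sample a point inside the polygon")
}

#' Ground-truth tracks holding a constant number of directed foci per frame
#'
#' Builds a schedule of back-to-back directed tracks so that exactly
#' `n_present` foci are present in every frame of an `n_frames` movie, all
#' inside `footprint` and moving perpendicular to its long axis at `speed`.
#' Used to simulate movies whose true directional-foci surface density is
#' known exactly: `n_present / polygon_area(footprint)`.
#'
#' @param footprint rod polygon (um).
#' @param n_present directed foci present in each frame.
#' @param n_frames movie length, frames.
#' @param track_frames length of each individual track, frames (the last
#'   track of a slot is truncated to fit).
#' @param speed directed speed, um/s.
#' @param t_lag frame interval, s.
#' @param seed integer seed or `NULL`.
#' @return ground-truth track table (`traj_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `true_class`) with noise-free positions.
#' @export
constant_density_tracks <- function(footprint, n_present, n_frames,
                                    track_frames = 15, speed = 0.0565,
                                    t_lag = 1, seed = NULL) {
  with_seed_if(seed, {
    ax <- footprint_axis(footprint)
    perp <- c(-ax[2], ax[1])
    out <- list()
    id <- 0
    for (slot in seq_len(n_present)) {
      f0 <- 1
      while (f0 <= n_frames) {
        nf <- min(track_frames, n_frames - f0 + 1)
        path_len <- speed * t_lag * (nf - 1)
        dir <- perp * sample(c(-1, 1), 1)
        for (try in seq_len(500)) {
          start <- random_point_in_polygon(footprint)
          ends <- rbind(start, start + dir * path_len)
          steps <- outer((seq_len(nf) - 1) * speed * t_lag, dir)
          pos <- sweep(steps, 2, start, "+")
          if (all(points_in_polygon(pos, footprint))) break
          if (try == 500)
            stop("footprint too narrow for the requested track length")
        }
        id <- id + 1
        out[[length(out) + 1]] <- data.frame(
          traj_id = id, frame = f0:(f0 + nf - 1),
          t_s = (f0:(f0 + nf - 1) - 1) * t_lag,
          x_um = pos[, 1], y_um = pos[, 2], true_class = "directed")
        f0 <- f0 + nf
      }
    }
    do.call(rbind, out)
  })
}

#' Stadium-shaped cell footprint polygon
#'
#' A rectangle of the given length capped by two semicircles; the standard
#' idealization of a rod-shaped bacterium. Centered at `center`, long axis
#' along x.
#'
#' @param length pole-to-pole length, um.
#' @param width cell width, um.
#' @param center numeric length-2 center, um.
#' @param n_arc points per cap.
#' @return n x 2 polygon matrix (um), counter-clockwise.
#' @export
stadium_polygon <- function(length, width, center = c(0, 0), n_arc = 24) {
  stopifnot(length > width, width > 0)
  hl <- (length - width) / 2   # half-length of the straight section
  r <- width / 2
  a_right <- seq(-pi / 2, pi / 2, length.out = n_arc)
  a_left <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  poly <- rbind(
    cbind(hl + r * cos(a_right), r * sin(a_right)),
    cbind(-hl + r * cos(a_left), r * sin(a_left)))
  sweep(poly, 2, center, "+")
}
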