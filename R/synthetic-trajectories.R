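# Trajectory simulator: mixture of two Brownian populations plus a directed
# subpopulation, with Gaussian localization noise. This is the ground-truth
# generator against which the whole analysis pipeline is validated.

#' Configuration for the trajectory simulator
#'
#' Defines a cohort of 2D single-particle trajectories: a fraction
#' `frac_directed` moves at constant speed along a fixed random orientation
#' (the TIRF-plane appearance of circumferential motion of the cell-wall
#' elongation machinery); the rest are Brownian, split between a slow and a
#' fast diffusive population. Defaults are the wild-type conditions of the
#' study this package quantifies: slow/fast diffusion coefficients 0.0024 and
#' 0.0147 um^2/s with the slow population at 23%, directed speed 56.5 nm/s,
#' 100 ms frame interval.
#'
#' @param n_traj number of trajectories.
#' @param frac_directed fraction of trajectories moving ballistically, in
#'   \[0,1\].
#' @param frac_slow fraction of the *non-directed* population belonging to the
#'   slow diffusive component (the mixture weight w1), in \[0,1\].
#' @param d_slow,d_fast diffusion coefficients of the two Brownian
#'   populations, um^2/s; `d_slow < d_fast` unless both are zero.
#' @param speed directed speed, um/s.
#' @param n_frames maximum trajectory length in frames.
#' @param min_frames minimum trajectory length (only used by the geometric
#'   length distribution).
#' @param length_dist `"fixed"` (all tracks `n_frames` long) or `"geometric"`
#'   (lengths `min_frames + Geom(p)` truncated at `n_frames`, with `p` chosen
#'   so the mean untruncated length is `mean_frames`). The geometric default
#'   exercises the minimum-duration filter downstream.
#' @param mean_frames target mean length for the geometric distribution.
#' @param t_lag frame interval, s.
#' @param loc_noise_sd localization error SD added independently to each
#'   reported coordinate, um.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return an object of class `trajectory_sim_config`.
#' @seealso [simulate_trajectories()]
#' @export
trajectory_sim_config <- function(n_traj = 1000,
                                  frac_directed = 0.125,
                                  frac_slow = 0.23,
                                  d_slow = 0.0024,
                                  d_fast = 0.0147,
                                  speed = 0.0565,
                                  n_frames = 40,
                                  min_frames = 20,
                                  length_dist = c("geometric", "fixed"),
                                  mean_frames = (min_frames + n_frames) / 2,
                                  t_lag = 0.1,
                                  loc_noise_sd = 0.02,
                                  seed = NULL) {
  length_dist <- match.arg(length_dist)
  check_cfg(is.numeric(n_traj) && n_traj >= 1, "n_traj", "must be >= 1")
  check_cfg(frac_directed >= 0 && frac_directed <= 1, "frac_directed",
            "must be in [0, 1]")
  check_cfg(frac_slow >= 0 && frac_slow <= 1, "frac_slow", "must be in [0, 1]")
  check_cfg(d_slow >= 0, "d_slow", "must be >= 0")
  check_cfg(d_fast >= 0, "d_fast", "must be >= 0")
  check_cfg(d_slow < d_fast || (d_slow == d_fast),
            "d_slow", "must not exceed d_fast")
  check_cfg(d_slow <= d_fast, "d_slow", "must be <= d_fast")
  check_cfg(speed >= 0, "speed", "must be >= 0")
  check_cfg(n_frames >= 2, "n_frames", "must be >= 2")
  check_cfg(min_frames >= 2 && min_frames <= n_frames, "min_frames",
            "must be in [2, n_frames]")
  check_cfg(t_lag > 0, "t_lag", "must be > 0")
  check_cfg(loc_noise_sd >= 0, "loc_noise_sd", "must be >= 0")
  structure(
    list(n_traj = as.integer(n_traj), frac_directed = frac_directed,
         frac_slow = frac_slow, d_slow = d_slow, d_fast = d_fast,
         speed = speed, n_frames = as.integer(n_frames),
         min_frames = as.integer(min_frames), length_dist = length_dist,
         mean_frames = mean_frames, t_lag = t_lag,
         loc_noise_sd = loc_noise_sd, seed = seed),
    class = "trajectory_sim_config")
}

#' Simulate a cohort of single-particle trajectories with known ground truth
#'
#' Brownian steps are drawn per axis with variance `2 * D * t_lag`; directed
#' trajectories advance `speed * t_lag` per frame along a fixed random
#' orientation. Independent Gaussian localization noise of SD `loc_noise_sd`
#' is added to every reported position. Reported positions keep their
#' noise-free counterparts (`x_true_um`, `y_true_um`) so recovery can be
#' scored exactly.
#'
#' @param cfg a [trajectory_sim_config()].
#' @return list with components
#'   \describe{
#'     \item{tracks}{data.frame with columns `traj_id`, `frame`, `t_s`,
#'       `x_um`, `y_um`, `x_true_um`, `y_true_um`, `true_class`,
#'       `true_param` (D in um^2/s for diffusive tracks, speed in um/s for
#'       directed ones).}
#'     \item{truth}{one row per trajectory: `traj_id`, `class`
#'       (`"directed"`, `"slow"`, `"fast"`), `d_true`, `speed_true`,
#'       `theta` (directed orientation, rad), `n_frames`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "trajectory_sim_config"))
  with_seed_if(cfg$seed, {
    n <- cfg$n_traj
    directed <- runif(n) < cfg$frac_directed
    slow <- !directed & (runif(n) < cfg$frac_slow)
    cls <- ifelse(directed, "directed", ifelse(slow, "slow", "fast"))
    d_true <- ifelse(cls == "slow", cfg$d_slow,
                     ifelse(cls == "fast", cfg$d_fast, NA_real_))
    theta <- ifelse(directed, runif(n, 0, 2 * pi), NA_real_)
    lens <- if (cfg$length_dist == "fixed") {
      rep(cfg$n_frames, n)
    } else {
      mu_extra <- max(cfg$mean_frames - cfg$min_frames, 0.5)
      pmin(cfg$min_frames + rgeom(n, 1 / (mu_extra + 1)), cfg$n_frames)
    }
    step_sd <- ifelse(directed, 0, sqrt(2 * d_true * cfg$t_lag))
    tracks <- vector("list", n)
    for (i in seq_len(n)) {
      nf <- lens[i]
      if (directed[i]) {
        tt <- (seq_len(nf) - 1) * cfg$t_lag
        xy <- cbind(cos(theta[i]), sin(theta[i]))[rep(1, nf), ] * cfg$speed * tt
      } else if (step_sd[i] > 0) {
        xy <- apply(matrix(rnorm(2 * (nf - 1), sd = step_sd[i]),
                           nf - 1, 2), 2, cumsum)
        xy <- rbind(c(0, 0), xy)
      } else {
        xy <- matrix(0, nf, 2)
      }
      obs <- xy
      if (cfg$loc_noise_sd > 0)
        obs <- obs + matrix(rnorm(2 * nf, sd = cfg$loc_noise_sd), nf, 2)
      tracks[[i]] <- data.frame(
        traj_id = i, frame = seq_len(nf),
        t_s = (seq_len(nf) - 1) * cfg$t_lag,
        x_um = obs[, 1], y_um = obs[, 2],
        x_true_um = xy[, 1], y_true_um = xy[, 2],
        true_class = if (directed[i]) "directed" else "diffusive",
        true_param = if (directed[i]) cfg$speed else d_true[i])
    }
    list(tracks = do.call(rbind, tracks),
         truth = data.frame(traj_id = seq_len(n), class = cls,
                            d_true = d_true, speed_true = ifelse(directed, cfg$speed, NA_real_),
                            theta = theta, n_frames = lens),
         config = cfg)
  })
}

#' Write / read a simulated or measured track table as CSV
#'
#' Columns `traj_id`, `frame`, `t_s`, `x_um`, `y_um` are required on read;
#' extra columns are preserved.
#'
#' @param tracks a track table data.frame.
#' @param path file path.
#' @export
write_track_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  tab <- read.csv(path)
  need <- c("traj_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("track CSV is missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Read a TrackMate spot/track export
#'
#' Accepts the CSV TrackMate writes for spots ("Spots in tracks statistics"),
#' using the column subset `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`,
#' `POSITION_T` (and `QUALITY` when present), so real acquisitions can enter
#' the pipeline downstream of detection and linking. TrackMate counts frames
#' from 0; they are shifted to 1-based.
#'
#' @param path path to the TrackMate CSV.
#' @return a track table data.frame (`traj_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, optional `quality`), sorted by trajectory then frame.
#' @export
read_trackmate_csv <- function(path) {
  raw <- read.csv(path)
  # TrackMate >= 7 adds three header junk rows below the column names
  num <- suppressWarnings(as.numeric(raw$FRAME))
  raw <- raw[!is.na(num), , drop = FALSE]
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y", "POSITION_T")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("TrackMate CSV is missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    traj_id = as.numeric(raw$TRACK_ID),
    frame = as.numeric(raw$FRAME) + 1,
    t_s = as.numeric(raw$POSITION_T),
    x_um = as.numeric(raw$POSITION_X),
    y_um = as.numeric(raw$POSITION_Y))
  if ("QUALITY" %in% names(raw)) out$quality <- as.numeric(raw$QUALITY)
  out <- out[!is.na(out$traj_id), , drop = FALSE]
  out[order(out$traj_id, out$frame), , drop = FALSE]
}
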