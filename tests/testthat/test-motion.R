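test_that("stationary trajectories have identically zero MSD and classify as D = 0", {
  tr <- stationary_track(n = 15)
  msd <- compute_msd(tr)
  expect_true(all(msd$msd == 0))
  cl <- classify_trajectory(msd)
  expect_equal(cl$label, "diffusive")
  expect_equal(cl$d_msd_um2_s, 0)
  expect_equal(cl$r2_diff, 1)
})

test_that("ballistic MSD follows the exact closed form", {
  tr <- ballistic_track(n = 20, v = 0.05, t_lag = 1)
  msd <- compute_msd(tr)
  # MSD(n tau) = (v n tau)^2
  expect_equal(msd$msd[2], (0.05 * 2)^2, tolerance = 1e-12)
  expect_equal(msd$msd, (0.05 * msd$lag_s)^2, tolerance = 1e-12)
})

test_that("MSD equals exhaustive pair enumeration on a toy trajectory", {
  set.seed(17)
  tr <- brownian_track(n = 5, d = 0.02, t_lag = 0.5)
  msd <- compute_msd(tr)
  # independent brute-force oracle: double loop over all (i, i + n) pairs
  xy <- cbind(tr$x_um, tr$y_um)
  for (lag in 1:4) {
    acc <- c()
    for (i in seq_len(5 - lag)) {
      acc <- c(acc, sum((xy[i + lag, ] - xy[i, ])^2))
    }
    expect_equal(msd$msd[lag], mean(acc), tolerance = 1e-12)
    expect_equal(msd$n_pairs[lag], length(acc))
  }
})

test_that("noiseless ballistic tracks classify directed with the true speed", {
  tr <- ballistic_track(n = 30, v = 0.0565, t_lag = 1, theta = 0.7)
  cl <- classify_trajectory(tr)
  expect_equal(cl$label, "directed")
  expect_equal(cl$r2_dir, 1, tolerance = 1e-9)
  expect_equal(cl$speed_um_s, 0.0565, tolerance = 1e-9)
})

test_that("classification is invariant to rigid motions of the trajectory", {
  set.seed(23)
  tr <- brownian_track(n = 30, d = 0.01, t_lag = 0.1)
  cl0 <- classify_trajectory(tr)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(tr$x_um, tr$y_um) %*% rot
  tr2 <- tr
  tr2$x_um <- xy[, 1] + 5
  tr2$y_um <- xy[, 2] - 3
  cl2 <- classify_trajectory(tr2)
  expect_equal(cl2$label, cl0$label)
  expect_equal(cl2$r2_dir, cl0$r2_dir, tolerance = 1e-9)
  expect_equal(cl2$r2_diff, cl0$r2_diff, tolerance = 1e-9)
  expect_equal(cl2$d_msd_um2_s, cl0$d_msd_um2_s, tolerance = 1e-9)
})

test_that("nine-frame tracks fall under the ten-frame duration filter", {
  tr <- ballistic_track(n = 9, v = 0.05)
  cl <- classify_trajectory(tr, min_frames = 10)
  expect_equal(cl$label, "too_short")
  tr10 <- ballistic_track(n = 10, v = 0.05)
  expect_equal(classify_trajectory(tr10, min_frames = 10)$label, "directed")
})

test_that("Brownian cohorts are mostly diffusive and rarely directed", {
  cfg <- trajectory_sim_config(n_traj = 2000, frac_directed = 0, frac_slow = 0,
                               d_slow = 0.001, d_fast = 0.01, n_frames = 30,
                               min_frames = 30, length_dist = "fixed",
                               t_lag = 0.1, loc_noise_sd = 0, seed = 71)
  tr <- simulate_trajectories(cfg)$tracks
  cls <- classify_tracks(tr)
  frac <- table(factor(cls$label, levels = c("directed", "diffusive",
                                             "unclassified", "too_short"))) / nrow(cls)
  expect_gte(frac[["diffusive"]], 0.80)
  expect_lte(frac[["directed"]], 0.05)
  # label fractions partition the classifiable tracks
  expect_equal(sum(frac[c("directed", "diffusive", "unclassified")]), 1)
})

test_that("fitted D from the MSD slope is unbiased over many Brownian tracks", {
  d_true <- 0.01
  cfg <- trajectory_sim_config(n_traj = 500, frac_directed = 0, frac_slow = 0,
                               d_slow = 0.001, d_fast = d_true, n_frames = 30,
                               min_frames = 30, length_dist = "fixed",
                               t_lag = 0.1, loc_noise_sd = 0, seed = 73)
  tr <- simulate_trajectories(cfg)$tracks
  cls <- classify_tracks(tr)
  ds <- cls$d_msd_um2_s[cls$label == "diffusive"]
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - d_true), 3 * se)
})

test_that("directed summaries report the cohort speed and fraction", {
  set.seed(29)
  trs <- do.call(rbind, lapply(1:6, function(i)
    ballistic_track(n = 20, v = 0.04, theta = runif(1, 0, 2 * pi), id = i)))
  cls <- classify_tracks(trs)
  sm <- summarize_directed(cls)
  expect_equal(sm$mean_speed_um_s, 0.04, tolerance = 1e-9)
  expect_equal(sm$sd_speed_um_s, 0, tolerance = 1e-9)
  expect_equal(sm$directional_fraction, 1)

  # no directed tracks: fraction 0, speed reported missing
  set.seed(30)
  trd <- do.call(rbind, lapply(1:5, function(i) {
    b <- brownian_track(n = 25, d = 0.01, t_lag = 0.1, id = i)
    b
  }))
  cld <- classify_tracks(trd)
  cld$label[cld$label == "directed"] <- "unclassified"  # force none directed
  smd <- summarize_directed(cld)
  expect_equal(smd$n_directed, 0)
  expect_equal(smd$directional_fraction, 0)
  expect_true(is.na(smd$mean_speed_um_s))
})

test_that("directional fraction is recovered on a mixed cohort", {
  cfg <- trajectory_sim_config(n_traj = 800, frac_directed = 0.12,
                               frac_slow = 0.23, n_frames = 30,
                               min_frames = 30, length_dist = "fixed",
                               speed = 0.0565, t_lag = 1,
                               loc_noise_sd = 0.02, seed = 83)
  sim <- simulate_trajectories(cfg)
  cls <- classify_tracks(sim$tracks)
  sm <- summarize_directed(cls)
  true_frac <- mean(sim$truth$class == "directed")
  expect_lt(abs(sm$directional_fraction - true_frac), 0.05)
})

test_that("density arithmetic matches the definition", {
  # one directed focus present in every frame, cell area 5 um^2 -> 0.2
  area5 <- stadium_polygon(5.442, 1, center = c(2.8, 0.6))  # area ~ 5
  a <- rodtrack:::polygon_area(area5)
  tr <- data.frame(traj_id = 1, frame = 1:10, t_s = 0:9,
                   x_um = 2.8, y_um = 0.6)
  cls <- data.frame(traj_id = 1, label = "directed")
  dn <- compute_density(cls, tr, mask = area5, n_frames = 10)
  expect_equal(dn$mean_density_um2, 1 / a, tolerance = 1e-9)
  expect_equal(dn$cell_area_um2, a)

  # no directed foci -> zero density
  cls0 <- data.frame(traj_id = 1, label = "diffusive")
  dn0 <- compute_density(cls0, tr, mask = area5, n_frames = 10)
  expect_equal(dn0$mean_density_um2, 0)

  # degenerate mask
  degen <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(compute_density(cls, tr, mask = degen), "area")
})
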