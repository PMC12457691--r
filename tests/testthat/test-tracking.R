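make_spot_stack <- function(positions, ps = 0.065, shape = c(40, 60),
                            amp = 400, sigma = 0.1) {
  # positions: list of per-frame n x 2 matrices (um)
  px <- array(0, dim = c(shape, length(positions)))
  for (f in seq_along(positions)) {
    fr <- matrix(0, shape[1], shape[2])
    pos <- positions[[f]]
    if (!is.null(pos) && nrow(pos)) {
      for (i in seq_len(nrow(pos)))
        fr <- rodtrack:::render_spot(fr, pos[i, 1], pos[i, 2], amp, sigma, ps)
    }
    px[, , f] <- fr
  }
  image_stack(px, pixel_size = ps, t_lag = 1)
}

test_that("blank frames yield no detections", {
  st <- image_stack(array(0, dim = c(30, 30, 3)), pixel_size = 0.065, t_lag = 1)
  det <- detect_spots(st, radius_um = 0.25, threshold = 1)
  expect_equal(nrow(det), 0)
})

test_that("a high-SNR spot is localized within half a pixel", {
  true <- c(1.873, 1.211)
  st <- make_spot_stack(list(matrix(true, 1)))
  det <- detect_spots(st, radius_um = 0.25, threshold = 2)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - true[1]), 0.5 * 0.065)
  expect_lt(abs(det$y_um - true[2]), 0.5 * 0.065)
})

test_that("two spots separated by five radii give exactly two detections", {
  pos <- rbind(c(1.0, 1.0), c(1.0 + 5 * 0.25, 1.0))
  st <- make_spot_stack(list(pos))
  det <- detect_spots(st, radius_um = 0.25, threshold = 2)
  expect_equal(nrow(det), 2)
})

test_that("sub-pixel radii are rejected", {
  st <- image_stack(array(0, dim = c(30, 30, 2)), pixel_size = 0.065, t_lag = 1)
  expect_error(detect_spots(st, radius_um = 0.01), "radius_um")
})

test_that("detections within the linking distance form a single trajectory", {
  det <- data.frame(frame = 1:6,
                    x_um = 0.1 * (0:5), y_um = 0.5,
                    quality = 10, intensity = 100)
  tr <- link_detections(det, max_dist_um = 0.4, t_lag = 1)
  expect_equal(length(unique(tr$traj_id)), 1)
  expect_equal(nrow(tr), 6)
})

test_that("a jump beyond the linking distance splits the trajectory", {
  det <- data.frame(frame = 1:4,
                    x_um = c(0, 0.1, 0.6, 0.7), y_um = 0,
                    quality = 10, intensity = 100)
  tr <- link_detections(det, max_dist_um = 0.4, t_lag = 1)
  expect_equal(length(unique(tr$traj_id)), 2)
  lens <- table(tr$traj_id)
  expect_true(all(lens == 2))
})

test_that("empty detection input gives an empty track table", {
  tr <- link_detections(data.frame(frame = integer(), x_um = numeric(),
                                   y_um = numeric()))
  expect_equal(nrow(tr), 0)
  expect_true(all(c("traj_id", "frame", "x_um", "y_um") %in% names(tr)))
})

test_that("crossing particles are linked by minimum total squared displacement", {
  # two particles crossing on 3 frames; the optimal matching keeps each
  # particle on its straight path
  pa <- cbind(x = c(0.0, 0.15, 0.30), y = c(0.0, 0.15, 0.30))
  pb <- cbind(x = c(0.30, 0.15, 0.00), y = c(0.0, 0.15, 0.30))
  # offset the middle frame slightly so the two detections are distinct
  pb[2, 1] <- pb[2, 1] + 0.02
  det <- data.frame(frame = rep(1:3, each = 2),
                    x_um = as.numeric(rbind(pa[, 1], pb[, 1])),
                    y_um = as.numeric(rbind(pa[, 2], pb[, 2])),
                    quality = 1, intensity = 1)
  tr <- link_detections(det, max_dist_um = 0.4, t_lag = 1)
  expect_equal(length(unique(tr$traj_id)), 2)

  # brute-force oracle: enumerate both two-frame assignments jointly and
  # minimize the total squared displacement
  frames <- split(det, det$frame)
  best_cost <- Inf; best <- NULL
  for (p1 in all_perms(1:2)) for (p2 in all_perms(1:2)) {
    cost <- 0
    for (k in 1:2) {
      a <- frames[[1]][k, c("x_um", "y_um")]
      b <- frames[[2]][p1[k], c("x_um", "y_um")]
      c3 <- frames[[3]][p2[p1[k]], c("x_um", "y_um")]
      cost <- cost + sum((b - a)^2) + sum((c3 - b)^2)
    }
    if (cost < best_cost) { best_cost <- cost; best <- list(p1, p2) }
  }
  # cost actually achieved by the linker
  got_cost <- sum(vapply(split(tr, tr$traj_id), function(s) {
    sum(diff(s$x_um)^2 + diff(s$y_um)^2)
  }, 0))
  expect_equal(got_cost, best_cost, tolerance = 1e-12)
})

test_that("the assignment solver matches brute-force enumeration", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    m <- matrix(runif(n * n), n)
    asg <- rodtrack:::solve_assignment(m)
    expect_true(all(sort(asg) == 1:n))
    got <- sum(m[cbind(1:n, asg)])
    best <- min(vapply(all_perms(1:n),
                       function(p) sum(m[cbind(1:n, p)]), 0))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("linking is invariant to detection row order", {
  set.seed(7)
  det <- data.frame(frame = rep(1:5, each = 3),
                    x_um = runif(15, 0, 3), y_um = runif(15, 0, 3),
                    quality = 1, intensity = 1)
  t1 <- link_detections(det, max_dist_um = 0.6, t_lag = 1)
  t2 <- link_detections(det[sample(nrow(det)), ], max_dist_um = 0.6, t_lag = 1)
  key <- function(tr) {
    sets <- lapply(split(tr, tr$traj_id), function(s)
      paste(s$frame, round(s$x_um, 9), round(s$y_um, 9), collapse = ";"))
    sort(unname(unlist(sets)))
  }
  expect_equal(key(t1), key(t2))
})

test_that("well-separated simulated particles are recovered nearly losslessly", {
  set.seed(13)
  n <- 20
  starts <- cbind(rep(seq(0, 19) * 3, 1), rep(c(0, 3), length.out = n) + 10)
  dets <- list()
  truth <- list()
  for (i in seq_len(n)) {
    tr <- brownian_track(n = 12, d = 0.01, t_lag = 0.1, id = i)
    tr$x_um <- tr$x_um + starts[i, 1]
    tr$y_um <- tr$y_um + starts[i, 2]
    truth[[i]] <- tr
  }
  all_tr <- do.call(rbind, truth)
  det <- data.frame(frame = all_tr$frame, x_um = all_tr$x_um,
                    y_um = all_tr$y_um, quality = 1, intensity = 1)
  linked <- link_detections(det, max_dist_um = 0.4, t_lag = 0.1)
  expect_equal(length(unique(linked$traj_id)), n)
  # each recovered track must coincide with one ground-truth track
  rec <- split(linked, linked$traj_id)
  matched <- vapply(rec, function(s) {
    any(vapply(truth, function(g) {
      nrow(s) == nrow(g) && all(abs(s$x_um - g$x_um) < 1e-9)
    }, FALSE))
  }, FALSE)
  expect_gte(mean(matched), 0.95)
})

test_that("duration and mask filters keep exactly the qualifying tracks", {
  t9 <- ballistic_track(n = 9, id = 1)
  t10 <- ballistic_track(n = 10, id = 2)
  both <- rbind(t9, t10)
  kept <- filter_tracks(both, min_frames = 10)
  expect_equal(unique(kept$traj_id), 2)
  expect_equal(attr(kept, "n_kept"), 1)
  expect_equal(attr(kept, "n_dropped"), 1)

  # empty input passes through
  empty <- filter_tracks(both[0, ], min_frames = 10)
  expect_equal(nrow(empty), 0)

  # all tracks inside the mask: identity
  mask <- stadium_polygon(20, 10, center = c(1, 1))
  kept2 <- filter_tracks(both, min_frames = 2, mask = mask)
  expect_equal(sort(unique(kept2$traj_id)), c(1, 2))
})

test_that("TrackMate-style CSV exports can be read back", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(TRACK_ID = c(0, 0, 1, 1), FRAME = c(0, 1, 0, 1),
                   POSITION_X = c(1, 1.1, 3, 3.2),
                   POSITION_Y = c(2, 2.1, 4, 4.1),
                   POSITION_T = c(0, 0.1, 0, 0.1),
                   QUALITY = c(55, 54, 60, 61))
  write.csv(df, path, row.names = FALSE)
  tab <- read_trackmate_csv(path)
  expect_equal(nrow(tab), 4)
  expect_equal(sort(unique(tab$traj_id)), c(0, 1))
  expect_equal(min(tab$frame), 1)   # shifted to 1-based
  expect_true(all(c("t_s", "x_um", "y_um", "quality") %in% names(tab)))
  unlink(path)
})
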