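# Per-trajectory diffusion-coefficient estimation via the displacement-CDF
# model and decomposition of the coefficient distribution into two
# log-normal subpopulations by maximum likelihood. This is the core
# quantification the package exists for.

#' Displacement magnitudes of a trajectory at a fixed lag
#'
#' Overlapping displacements `|r(i + lag) - r(i)|` for all valid i. The
#' observation period used downstream is `delta_t = lag_frames * t_lag`;
#' the default lag of 4 frames trades displacement size against the number
#' of displacements per track.
#'
#' @param traj single-trajectory track table.
#' @param lag_frames lag in frames.
#' @return numeric vector of displacement magnitudes (um); empty when the
#'   track is not longer than the lag.
#' @export
displacements_at_lag <- function(traj, lag_frames = 4) {
  traj <- traj[order(traj$frame), , drop = FALSE]
  n <- nrow(traj)
  if (n <= lag_frames) return(numeric(0))
  xy <- cbind(traj$x_um, traj$y_um)
  d <- xy[(1 + lag_frames):n, , drop = FALSE] -
    xy[seq_len(n - lag_frames), , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Estimate a diffusion coefficient from the displacement CDF
#'
#' For free 2D diffusion the displacement magnitude r observed over a period
#' `delta_t` follows `CDF(r) = 1 - exp(-r^2 / (4 D delta_t))`. D is
#' estimated by least squares between this model and the empirical CDF of
#' the observed displacements, evaluated at the Hazen plotting positions
#' `(i - 0.5) / n` (chosen for unbiased tail behaviour in the small
#' per-trajectory samples). The closed-form moment/ML estimator
#' `mean(r^2) / (4 delta_t)` of the same model seeds and brackets the
#' optimization.
#'
#' @param r_values displacement magnitudes (um) from
#'   [displacements_at_lag()].
#' @param delta_t observation period, s (lag in frames times `t_lag`).
#' @return list of class `dc_estimate`: `d_um2_s`, `n_displacements`,
#'   `fit_residual` (sum of squared CDF deviations), `degenerate` (`TRUE`
#'   when all displacements are zero).
#' @export
estimate_dc_cdf <- function(r_values, delta_t) {
  stopifnot(length(r_values) >= 1, delta_t > 0)
  r <- sort(r_values)
  n <- length(r)
  if (all(r == 0)) {
    return(structure(list(d_um2_s = 0, n_displacements = n,
                          fit_residual = 0, degenerate = TRUE),
                     class = "dc_estimate"))
  }
  p <- (seq_len(n) - 0.5) / n
  d_mle <- mean(r^2) / (4 * delta_t)
  obj <- function(log_d) {
    sum((p - (1 - exp(-r^2 / (4 * exp(log_d) * delta_t))))^2)
  }
  opt <- optimize(obj, log(c(d_mle / 50, d_mle * 50)))
  structure(list(d_um2_s = exp(opt$minimum), n_displacements = n,
                 fit_residual = opt$objective, degenerate = FALSE),
            class = "dc_estimate")
}

#' Per-trajectory diffusion coefficients for a cohort
#'
#' Applies [displacements_at_lag()] + [estimate_dc_cdf()] to every
#' trajectory of at least `min_frames` points, skipping trajectories
#' classified as directed (the directional subpopulation would bias the
#' diffusive mixture and is excluded before this analysis).
#'
#' @param tracks track table.
#' @param classifications optional data.frame from [classify_tracks()];
#'   trajectories labeled `"directed"` are excluded.
#' @param lag_frames displacement lag, frames.
#' @param t_lag frame interval, s; defaults to the smallest time step in the
#'   table.
#' @param min_frames minimum trajectory duration.
#' @return data.frame `traj_id`, `d_um2_s`, `n_displacements`,
#'   `fit_residual`.
#' @export
estimate_dc_table <- function(tracks, classifications = NULL, lag_frames = 4,
                              t_lag = NULL, min_frames = 10) {
  if (is.null(t_lag)) t_lag <- min(diff(sort(unique(tracks$t_s))))
  delta_t <- lag_frames * t_lag
  ids <- unique(tracks$traj_id)
  if (!is.null(classifications)) {
    dir_ids <- classifications$traj_id[classifications$label == "directed"]
    ids <- setdiff(ids, dir_ids)
  }
  subs <- split(tracks, factor(tracks$traj_id, levels = unique(tracks$traj_id)))
  rows <- lapply(ids, function(id) {
    sub <- subs[[as.character(id)]]
    if (nrow(sub) < min_frames) return(NULL)
    r <- displacements_at_lag(sub, lag_frames)
    if (!length(r)) return(NULL)
    est <- estimate_dc_cdf(r, delta_t)
    data.frame(traj_id = id, d_um2_s = est$d_um2_s,
               n_displacements = est$n_displacements,
               fit_residual = est$fit_residual)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(traj_id = numeric(), d_um2_s = numeric(),
                      n_displacements = integer(), fit_residual = numeric())
  out
}

#' Two-component log-normal mixture of diffusion coefficients
#'
#' Maximum-likelihood fit of
#' `w1 * LogNormal(log d1, sigma1) + (1 - w1) * LogNormal(log d2, sigma2)`
#' to a set of per-trajectory diffusion coefficients — equivalently a
#' 2-component Gaussian mixture on log D, fitted by EM. Initialization is
#' k-means on log D plus `n_restarts` random restarts; the best likelihood
#' wins. Components are ordered so `d1 < d2`, making `w1` the weight of the
#' slow subpopulation. Zero or negative coefficients are excluded (the
#' log-normal has positive support) with their count reported.
#'
#' @param dc_values diffusion coefficients, um^2/s.
#' @param n_restarts random restarts after the k-means initialization.
#' @param seed integer seed or `NULL`.
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter EM iteration cap per start.
#' @param min_points minimum number of positive values required.
#' @param sep_log when `|log(d2) - log(d1)|` falls below this the two
#'   components are flagged as effectively a single population.
#' @return object of class `mixture_fit`: `d1_um2_s`, `d2_um2_s` (component
#'   medians, i.e. exponentiated log-space means), `sigma1`, `sigma2`
#'   (log-space SDs), `w1`, `loglik`, `loglik_trace` (per EM iteration of
#'   the winning start), `converged`, `effectively_unimodal`, `n_points`,
#'   `n_excluded`.
#' @export
fit_lognormal_mixture <- function(dc_values, n_restarts = 5, seed = NULL,
                                  tol = 1e-8, max_iter = 1000,
                                  min_points = 20, sep_log = 0.5) {
  pos <- dc_values[is.finite(dc_values) & dc_values > 0]
  n_excluded <- length(dc_values) - length(pos)
  if (length(pos) < min_points)
    stop("insufficient data: ", length(pos), " positive coefficients (< ",
         min_points, "); ", n_excluded, " excluded as non-positive")
  x <- log(pos)
  with_seed_if(seed, {
    starts <- list(kmeans_start(x))
    for (k in seq_len(n_restarts)) starts <- c(starts, list(random_start(x)))
    best <- NULL
    for (st in starts) {
      fit <- em_gauss2(x, st, tol = tol, max_iter = max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    o <- order(best$mu)
    structure(list(d1_um2_s = exp(best$mu[o][1]),
                   d2_um2_s = exp(best$mu[o][2]),
                   sigma1 = best$sigma[o][1], sigma2 = best$sigma[o][2],
                   w1 = best$w[o][1], loglik = best$loglik,
                   loglik_trace = best$trace, converged = best$converged,
                   effectively_unimodal =
                     abs(diff(best$mu[o])) < sep_log,
                   n_points = length(x), n_excluded = n_excluded),
              class = "mixture_fit")
  })
}

kmeans_start <- function(x) {
  km <- suppressWarnings(kmeans(x, 2, nstart = 5))
  s <- as.numeric(tapply(x, km$cluster, sd))
  s[!is.finite(s) | s < 1e-3] <- max(sd(x) / 4, 1e-3)
  list(mu = as.numeric(km$centers), sigma = s,
       w = as.numeric(tabulate(km$cluster, 2)) / length(x))
}

random_start <- function(x) {
  mu <- sample(x, 2)
  list(mu = mu, sigma = rep(max(sd(x) / 2, 1e-3), 2),
       w = c(0.5, 0.5))
}

# EM for a 2-component Gaussian mixture in 1D. Returns the log-likelihood
# trace so monotonicity is checkable.
em_gauss2 <- function(x, start, tol = 1e-8, max_iter = 1000) {
  mu <- start$mu; sigma <- pmax(start$sigma, 1e-6); w <- start$w
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6); w <- w / sum(w)
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g <- d1 / tot
    s1 <- sum(g); s2 <- n - s1
    if (s1 < 1e-8 || s2 < 1e-8) break  # a component died
    w <- c(s1, s2) / n
    mu <- c(sum(g * x) / s1, sum((1 - g) * x) / s2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / s1,
                    sum((1 - g) * (x - mu[2])^2) / s2))
    sigma <- pmax(sigma, 1e-6)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = trace[length(trace)],
       trace = trace, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "log-normal mixture fit (n = %d, %d excluded)\n  slow: D1 = %.5g um^2/s (sigma %.3g), w1 = %.3f\n  fast: D2 = %.5g um^2/s (sigma %.3g)\n  loglik = %.4f, converged = %s%s\n",
    x$n_points, x$n_excluded, x$d1_um2_s, x$sigma1, x$w1, x$d2_um2_s,
    x$sigma2, x$loglik, x$converged,
    if (x$effectively_unimodal) " (effectively unimodal)" else ""))
  invisible(x)
}

#' Aggregate per-replicate mixture fits per strain
#'
#' The per-strain estimate of each mixture parameter is the median across
#' biological replicates.
#'
#' @param fits data.frame with columns `strain`, `replicate`, `w1`, `d1`,
#'   `d2` (one row per replicate fit), and optionally `n_trajectories`.
#' @return data.frame with one row per strain: medians of `w1`, `d1`, `d2`
#'   and the replicate count.
#' @export
aggregate_replicates <- function(fits) {
  stopifnot(nrow(fits) >= 1,
            all(c("strain", "w1", "d1", "d2") %in% names(fits)))
  strains <- unique(fits$strain)
  out <- do.call(rbind, lapply(strains, function(s) {
    sub <- fits[fits$strain == s, , drop = FALSE]
    data.frame(strain = s, n_replicates = nrow(sub),
               w1_median = median(sub$w1),
               d1_median = median(sub$d1),
               d2_median = median(sub$d2))
  }))
  rownames(out) <- NULL
  out
}

#' Fold change of a mixture parameter between two strains
#'
#' Ratio of per-strain medians, `strain_b / strain_a`.
#'
#' @param summary data.frame from [aggregate_replicates()].
#' @param strain_a,strain_b strain labels (reference first).
#' @param param one of `"w1"`, `"d1"`, `"d2"`.
#' @return numeric fold change.
#' @export
fold_change <- function(summary, strain_a, strain_b, param = "w1") {
  col <- paste0(param, "_median")
  stopifnot(col %in% names(summary))
  a <- summary[[col]][summary$strain == strain_a]
  b <- summary[[col]][summary$strain == strain_b]
  stopifnot(length(a) == 1, length(b) == 1)
  b / a
}
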