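# End-to-end orchestration: simulate or ingest tracks, classify, summarize
# the directed subpopulation, estimate per-trajectory diffusion
# coefficients on the non-directed remainder, fit the per-replicate
# log-normal mixture and aggregate replicate medians per strain.

#' Configuration for an SPT pipeline run
#'
#' @param replicates list of replicate descriptors. Each element is a list
#'   with `strain`, `replicate` labels and either `tracks` (a track table)
#'   or `sim` (a [trajectory_sim_config()] to generate one).
#' @param min_frames minimum trajectory duration, frames.
#' @param r2_dir,r2_diff MSD classification thresholds.
#' @param lag_frames displacement lag for the CDF estimator.
#' @param mixture_restarts random EM restarts.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param out_dir optional directory; when given, intermediate tables and
#'   the run manifest are written there.
#' @return object of class `spt_run_config`.
#' @export
spt_run_config <- function(replicates, min_frames = 10, r2_dir = 0.9,
                           r2_diff = 0.8, lag_frames = 4,
                           mixture_restarts = 5, seed = 1, out_dir = NULL) {
  check_cfg(is.list(replicates) && length(replicates) >= 1, "replicates",
            "must be a non-empty list")
  for (rep in replicates) {
    check_cfg(!is.null(rep$strain), "replicates", "elements need a strain label")
    check_cfg(!is.null(rep$tracks) || !is.null(rep$sim), "replicates",
              "elements need either tracks or a sim config")
  }
  check_cfg(is.numeric(seed) && length(seed) == 1, "seed",
            "must be a single integer (mandatory for stochastic steps)")
  structure(list(replicates = replicates, min_frames = min_frames,
                 r2_dir = r2_dir, r2_diff = r2_diff,
                 lag_frames = lag_frames,
                 mixture_restarts = mixture_restarts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "spt_run_config")
}

#' Run the SPT quantification pipeline
#'
#' Stages per replicate: minimum-duration filter, MSD classification,
#' summary of the directed subpopulation, exclusion of directed tracks,
#' per-trajectory CDF diffusion coefficients, two-component log-normal
#' mixture fit. Per-strain summaries are replicate medians. Counts at each
#' filtering stage are conserved and reported.
#'
#' @param cfg an [spt_run_config()].
#' @return object of class `spt_report`: list with `replicate_fits` (one
#'   row per replicate: strain, replicate, w1, d1, d2, n_trajectories,
#'   counts), `strain_summary` (replicate medians), `directed` (per-strain
#'   speed and directional fraction), `stage_counts`, `config`.
#' @export
run_spt_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "spt_run_config"))
  fits <- list()
  directed_rows <- list()
  counts <- list()
  for (k in seq_along(cfg$replicates)) {
    rep_cfg <- cfg$replicates[[k]]
    stage <- "input"
    res <- tryCatch({
      tracks <- if (!is.null(rep_cfg$tracks)) {
        rep_cfg$tracks
      } else {
        sim_cfg <- rep_cfg$sim
        sim_cfg$seed <- (cfg$seed * 1000L + k) %% .Machine$integer.max
        simulate_trajectories(sim_cfg)$tracks
      }
      n_input <- length(unique(tracks$traj_id))

      stage <- "duration filter"
      kept <- filter_tracks(tracks, min_frames = cfg$min_frames)
      n_kept <- attr(kept, "n_kept")

      stage <- "MSD classification"
      cls <- classify_tracks(kept, r2_dir = cfg$r2_dir,
                             r2_diff = cfg$r2_diff,
                             min_frames = cfg$min_frames)
      dir_sum <- summarize_directed(cls)

      stage <- "CDF diffusion estimation"
      dc <- estimate_dc_table(kept, cls, lag_frames = cfg$lag_frames,
                              min_frames = cfg$min_frames)

      stage <- "mixture fit"
      mix <- fit_lognormal_mixture(
        dc$d_um2_s, n_restarts = cfg$mixture_restarts,
        seed = (cfg$seed * 1000L + 500L + k) %% .Machine$integer.max)

      list(tracks = kept, cls = cls, dir_sum = dir_sum, dc = dc, mix = mix,
           n_input = n_input, n_kept = n_kept)
    }, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s' for %s/%s: %s",
                   stage, rep_cfg$strain, rep_cfg$replicate,
                   conditionMessage(e)), call. = FALSE)
    })

    fits[[k]] <- data.frame(
      strain = rep_cfg$strain,
      replicate = if (!is.null(rep_cfg$replicate)) rep_cfg$replicate else k,
      w1 = res$mix$w1, d1 = res$mix$d1_um2_s, d2 = res$mix$d2_um2_s,
      n_trajectories = res$mix$n_points,
      converged = res$mix$converged)
    directed_rows[[k]] <- data.frame(
      strain = rep_cfg$strain,
      replicate = fits[[k]]$replicate,
      mean_speed_um_s = res$dir_sum$mean_speed_um_s,
      sd_speed_um_s = res$dir_sum$sd_speed_um_s,
      directional_fraction = res$dir_sum$directional_fraction,
      n_directed = res$dir_sum$n_directed)
    counts[[k]] <- data.frame(
      strain = rep_cfg$strain, replicate = fits[[k]]$replicate,
      n_input = res$n_input, n_after_duration = res$n_kept,
      n_dropped_duration = res$n_input - res$n_kept,
      n_directed = res$dir_sum$n_directed,
      n_dc_estimated = nrow(res$dc),
      n_excluded_nonpositive = res$mix$n_excluded)

    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      tag <- sprintf("%s_rep%s", rep_cfg$strain, fits[[k]]$replicate)
      write.csv(res$cls, file.path(cfg$out_dir,
                                   paste0("classification_", tag, ".csv")),
                row.names = FALSE)
      write.csv(res$dc, file.path(cfg$out_dir, paste0("dc_", tag, ".csv")),
                row.names = FALSE)
    }
  }
  fits <- do.call(rbind, fits)
  directed <- do.call(rbind, directed_rows)
  counts <- do.call(rbind, counts)
  report <- structure(
    list(replicate_fits = fits,
         strain_summary = aggregate_replicates(fits),
         directed = directed,
         stage_counts = counts,
         config = cfg),
    class = "spt_report")
  if (!is.null(cfg$out_dir)) {
    write.csv(fits, file.path(cfg$out_dir, "replicate_fits.csv"),
              row.names = FALSE)
    write.csv(report$strain_summary,
              file.path(cfg$out_dir, "strain_summary.csv"), row.names = FALSE)
    manifest <- list(seed = cfg$seed, min_frames = cfg$min_frames,
                     r2_dir = cfg$r2_dir, r2_diff = cfg$r2_diff,
                     lag_frames = cfg$lag_frames,
                     mixture_restarts = cfg$mixture_restarts,
                     n_replicates = length(cfg$replicates),
                     package_version = as.character(
                       utils::packageVersion("rodtrack")))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.spt_report <- function(x, ...) {
  cat("SPT pipeline report\n")
  cat("-- per-strain mixture medians --\n")
  print(x$strain_summary, row.names = FALSE)
  cat("-- directed subpopulation --\n")
  print(x$directed, row.names = FALSE)
  invisible(x)
}

#' Run the shape-descriptor pipeline
#'
#' Computes the descriptor set for every contour; contours that fail shape
#' extraction are skipped and counted, the run continues.
#'
#' @param contours named list of contour matrices (um), or a list of lists
#'   `list(strain =, contour =)`.
#' @param strain optional vector of strain labels parallel to `contours`.
#' @param spacing_um width sampling interval.
#' @param out_dir optional output directory for the per-cell CSV.
#' @return list: `per_cell` (descriptor data.frame, one row per valid
#'   cell), `per_strain` (medians by strain, when labels given),
#'   `n_failed`, `failures` (messages).
#' @export
run_shape_pipeline <- function(contours, strain = NULL, spacing_um = 0.05,
                               out_dir = NULL) {
  empty <- data.frame(cell_id = character(), solidity = numeric(),
                      lateral_asymmetry = numeric(),
                      longitudinal_asymmetry = numeric(),
                      width_variation_um = numeric(),
                      mean_width_um = numeric(), length_um = numeric(),
                      strain = character())
  rows <- list()
  failures <- character()
  for (i in seq_along(contours)) {
    id <- if (!is.null(names(contours)) && nzchar(names(contours)[i]))
      names(contours)[i] else as.character(i)
    res <- tryCatch(
      shape_descriptors(contours[[i]], spacing_um, cell_id = id),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s: %s", id, res))
    } else {
      res$strain <- if (!is.null(strain)) strain[i] else NA_character_
      rows[[length(rows) + 1]] <- res
    }
  }
  per_cell <- if (length(rows)) do.call(rbind, rows) else empty
  per_strain <- NULL
  if (!is.null(strain) && nrow(per_cell)) {
    per_strain <- do.call(rbind, lapply(unique(per_cell$strain), function(s) {
      sub <- per_cell[per_cell$strain == s, , drop = FALSE]
      data.frame(strain = s, n_cells = nrow(sub),
                 solidity = median(sub$solidity),
                 lateral_asymmetry = median(sub$lateral_asymmetry),
                 longitudinal_asymmetry = median(sub$longitudinal_asymmetry),
                 width_variation_um = median(sub$width_variation_um),
                 mean_width_um = median(sub$mean_width_um),
                 length_um = median(sub$length_um))
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(per_cell, file.path(out_dir, "shape_descriptors.csv"),
              row.names = FALSE)
  }
  list(per_cell = per_cell, per_strain = per_strain,
       n_failed = length(failures), failures = failures)
}
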