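# Image-stack container, the two-step preprocessing used before spot
# detection, kymograph extraction, and multi-page TIFF IO.
#
# Coordinate convention used throughout the package: x = column, y = row,
# origin at the center of the top-left pixel, so position in um equals
# (pixel index - 1) * pixel_size.

#' TIRF image-stack container
#'
#' @param pixels 3D numeric array `[row, col, frame]` of intensity counts, or
#'   a matrix for a single frame.
#' @param pixel_size pixel size, um/px. There is no default: the physical
#'   scale must always be supplied.
#' @param t_lag frame interval, s.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size, t_lag) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1))
  check_cfg(is.array(pixels) && length(dim(pixels)) == 3, "pixels",
            "must be a [row, col, frame] array")
  check_cfg(is.numeric(pixel_size) && pixel_size > 0, "pixel_size",
            "must be > 0")
  check_cfg(is.numeric(t_lag) && t_lag > 0, "t_lag", "must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size, t_lag = t_lag),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %d x %d px, %d frames, %.4g um/px, t_lag %.4g s\n",
              d[1], d[2], d[3], x$pixel_size, x$t_lag))
  invisible(x)
}

n_frames <- function(stack) dim(stack$pixels)[3]

#' Preprocess a TIRF stack for spot detection
#'
#' Two steps: (1) subtract the minimum projection of the whole stack from
#' every frame, removing static background; (2) average over a sliding
#' window of two consecutive frames (stride 1) to raise the signal-to-noise
#' ratio. Output frame k is the mean of the background-subtracted frames k
#' and k+1, so the result has one frame fewer than the input and no negative
#' values.
#'
#' @param stack an [image_stack()] with at least 2 frames.
#' @return an [image_stack()] with `n_frames - 1` frames.
#' @export
preprocess_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (nf < 2)
    stop("preprocess_stack() needs at least 2 frames, got ", nf)
  px <- stack$pixels
  minproj <- apply(px, c(1, 2), min)
  sub <- sweep(px, c(1, 2), minproj)
  out <- (sub[, , seq_len(nf - 1), drop = FALSE] +
            sub[, , 2:nf, drop = FALSE]) / 2
  image_stack(out, stack$pixel_size, stack$t_lag)
}

#' Extract a kymograph along a line
#'
#' Builds a space-time image: row t is the bilinearly interpolated intensity
#' profile along the line at frame t, averaged over `width_px` parallel
#' profiles offset perpendicular to the line. Drawn perpendicular to the cell
#' long axis, processive circumferential foci appear as sloped traces whose
#' slope is the inverse speed.
#'
#' @param stack an [image_stack()].
#' @param line numeric length-4 vector `c(x1, y1, x2, y2)` in um, or a 2x2
#'   matrix of endpoints (rows), inside the frame.
#' @param width_px number of 1-px-spaced parallel lines averaged.
#' @return object of class `kymograph`: list with `pixels` (time x position
#'   matrix), `positions` (um along the line), `t_lag`, `line`.
#' @export
extract_kymograph <- function(stack, line, width_px = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.matrix(line)) line <- c(line[1, ], line[2, ])
  stopifnot(length(line) == 4)
  ps <- stack$pixel_size
  d <- dim(stack$pixels)
  lim_x <- (d[2] - 1) * ps
  lim_y <- (d[1] - 1) * ps
  if (any(line[c(1, 3)] < 0) || any(line[c(1, 3)] > lim_x) ||
      any(line[c(2, 4)] < 0) || any(line[c(2, 4)] > lim_y))
    stop("kymograph line endpoints fall outside the frame")
  p1 <- line[1:2]; p2 <- line[3:4]
  len <- sqrt(sum((p2 - p1)^2))
  n_samp <- max(2L, as.integer(round(len / ps)) + 1L)
  tt <- seq(0, 1, length.out = n_samp)
  base_x <- p1[1] + tt * (p2[1] - p1[1])
  base_y <- p1[2] + tt * (p2[2] - p1[2])
  perp <- c(-(p2[2] - p1[2]), p2[1] - p1[1]) / len
  offsets <- (seq_len(width_px) - (width_px + 1) / 2) * ps

  nf <- d[3]
  kymo <- matrix(0, nf, n_samp)
  for (f in seq_len(nf)) {
    frame <- stack$pixels[, , f]
    acc <- numeric(n_samp)
    for (o in offsets) {
      acc <- acc + bilinear_sample(frame, base_x + o * perp[1],
                                   base_y + o * perp[2], ps)
    }
    kymo[f, ] <- acc / length(offsets)
  }
  structure(list(pixels = kymo, positions = tt * len,
                 t_lag = stack$t_lag, line = line),
            class = "kymograph")
}

# Bilinear interpolation of a frame at physical coordinates (um); samples
# outside the frame return 0.
bilinear_sample <- function(frame, x_um, y_um, pixel_size) {
  cx <- x_um / pixel_size + 1  # fractional column index
  ry <- y_um / pixel_size + 1  # fractional row index
  nr <- nrow(frame); nc <- ncol(frame)
  c0 <- pmax(pmin(floor(cx), nc - 1), 1)
  r0 <- pmax(pmin(floor(ry), nr - 1), 1)
  fx <- cx - c0
  fy <- ry - r0
  out <- frame[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
    frame[cbind(r0, c0 + 1)] * fx * (1 - fy) +
    frame[cbind(r0 + 1, c0)] * (1 - fx) * fy +
    frame[cbind(r0 + 1, c0 + 1)] * fx * fy
  out[cx < 1 | cx > nc | ry < 1 | ry > nr] <- 0
  out
}

#' Read / write an image stack as multi-page TIFF
#'
#' Intensities are stored as 32-bit floats; `pixel_size` and `t_lag` are not
#' carried by the file and must be supplied on read.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @param pixel_size,t_lag physical calibration for the stack being read.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(seq_len(n_frames(stack)),
                   function(f) stack$pixels[, , f])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, pixel_size, t_lag) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  px <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  image_stack(px, pixel_size, t_lag)
}
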