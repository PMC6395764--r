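#' Calibrated image stack
#'
#' An `er_stack` holds a multi-channel, multi-frame grayscale intensity
#' array together with its physical calibration. Data are stored as a 4-D
#' array indexed `[y, x, channel, time]` (row = y increases downwards,
#' origin top-left); external tabular output uses 0-based `(y, x)` pixel
#' coordinates and microns for physical coordinates.
#'
#' @param data Numeric array: a matrix (one frame, one channel), a 3-D array
#'   `[y, x, t]`, or a 4-D array `[y, x, c, t]`. Intensities must be
#'   non-negative.
#' @param pixel_size_nm Pixel spacing in nanometres (20--80 nm typical).
#' @param frame_interval_s Time between frames in seconds (e.g. 0.41).
#' @param bit_depth 8 or 16; together with `max_value` defines the full
#'   intensity range used for fixed-range binning.
#' @param max_value Intensity corresponding to full scale. Defaults to 1 for
#'   float data in `[0, 1]`, or `2^bit_depth - 1` for integer data.
#' @return An object of class `er_stack`.
#' @export
er_stack <- function(data, pixel_size_nm, frame_interval_s = NA_real_,
                     bit_depth = 8L, max_value = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) {
    d <- dim(data); dim(data) <- c(d[1], d[2], 1L, d[3])
  }
  stopifnot(length(dim(data)) == 4L)
  if (any(data < 0)) stop("er_stack: intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("er_stack: pixel_size_nm must be positive")
  nt <- dim(data)[4]
  if (nt > 1 && (is.na(frame_interval_s) || frame_interval_s <= 0))
    stop("er_stack: frame_interval_s must be positive for time series")
  if (is.null(max_value))
    max_value <- if (max(data) <= 1) 1 else 2^bit_depth - 1
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 bit_depth = as.integer(bit_depth),
                 max_value = max_value),
            class = "er_stack")
}

#' @export
print.er_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ER image stack: %d x %d px, %d channel(s), %d frame(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size %.1f nm (%.2f um field), frame interval %s s\n",
              x$pixel_size_nm, d[2] * x$pixel_size_nm / 1000,
              ifelse(is.na(x$frame_interval_s), "NA",
                     format(x$frame_interval_s))))
  invisible(x)
}

#' @export
dim.er_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[4]
n_channels <- function(stack) dim(stack$data)[3]

#' Extract one frame of one channel as a matrix
#'
#' @param stack An [er_stack].
#' @param t Frame index (1-based).
#' @param channel Channel index (1-based).
#' @return Numeric matrix `[y, x]`.
#' @export
get_frame <- function(stack, t = 1L, channel = 1L) {
  stack$data[, , channel, t]
}

#' Read a TIFF stack from disk
#'
#' Reads a single- or multi-page grayscale TIFF (8- or 16-bit) and arranges
#' the pages as a `[y, x, channel, time]` array. Pages are assumed ordered
#' channel-fastest (c1 t1, c2 t1, c1 t2, ...). RGB or float TIFFs without an
#' explicit mapping are rejected. Pixel size and frame interval come from
#' `config_meta` since plain TIFF carries no physical calibration.
#'
#' @param path Path to the TIFF file.
#' @param config_meta A list with `pixel_size_nm`, optionally
#'   `frame_interval_s`, `n_channels`, `bit_depth`.
#' @return An [er_stack].
#' @export
read_stack <- function(path, config_meta) {
  if (!file.exists(path)) stop("read_stack: file not found: ", path)
  if (is.null(config_meta$pixel_size_nm))
    stop("read_stack: pixel_size_nm missing from metadata/config")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L)
    stop("read_stack: RGB TIFF without an explicit channel mapping")
  nc <- if (is.null(config_meta$n_channels)) 1L else as.integer(config_meta$n_channels)
  np <- length(pages)
  if (np %% nc != 0)
    stop("read_stack: page count ", np, " not divisible by n_channels ", nc)
  nt <- np %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(ny, nx, nc, nt))
  k <- 1L
  for (t in seq_len(nt)) for (ch in seq_len(nc)) {
    arr[, , ch, t] <- pages[[k]]; k <- k + 1L
  }
  bd <- if (is.null(config_meta$bit_depth)) 8L else config_meta$bit_depth
  er_stack(arr, pixel_size_nm = config_meta$pixel_size_nm,
           frame_interval_s = if (is.null(config_meta$frame_interval_s))
             NA_real_ else config_meta$frame_interval_s,
           bit_depth = bd, max_value = 1)
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the stack's `max_value`. Pages
#' are written channel-fastest, matching [read_stack].
#'
#' @param stack An [er_stack].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) for (ch in seq_len(d[3])) {
    pages[[k]] <- pmin(pmax(stack$data[, , ch, t] / stack$max_value, 0), 1)
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
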