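#' Multi-channel time-lapse stack container
#'
#' Canonical in-memory representation of a movie: a 5-D pixel array indexed
#' (t, z, channel, row, col), acquisition timestamps in hours, channel
#' labels, pixel size and the inducer-addition time.
#'
#' @param pixels 5-D numeric array (T, Z, C, Y, X), or 2-D/3-D/4-D arrays
#'   which are promoted by prepending unit axes (a plain 2-D image becomes
#'   T = Z = C = 1).
#' @param timestamps Strictly increasing times, hours.
#' @param channels Channel labels; length must equal `dim(pixels)[3]`.
#' @param pixel_size_um Lateral pixel size, micrometres.
#' @param t_inducer Inducer addition time, hours (`NA` if not applicable).
#' @param z_spacing_um Plane spacing, micrometres.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(pixels, timestamps, channels = NULL,
                            pixel_size_um = NA_real_, t_inducer = NA_real_,
                            z_spacing_um = NA_real_) {
  d <- dim(pixels)
  if (is.null(d)) stop("pixels must be an array")
  while (length(dim(pixels)) < 5)
    dim(pixels) <- c(1L, dim(pixels))
  d <- dim(pixels)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[3]))
  stopifnot(length(channels) == d[3], length(timestamps) == d[1])
  if (d[1] > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(
    list(pixels = pixels, timestamps = timestamps, channels = channels,
         pixel_size_um = pixel_size_um, t_inducer = t_inducer,
         z_spacing_um = z_spacing_um),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("timelapse_stack: %d t x %d z x %d ch x %d x %d px\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  t = %s h; inducer at %s h\n",
              paste(signif(range(x$timestamps), 4), collapse = ".."),
              format(x$t_inducer)))
  invisible(x)
}

#' Write a stack to a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written in T-major (t, z, c) order as 32-bit samples after
#' scaling into \[0, 1\] by a power of two recorded in the sidecar. Axis
#' sizes, timestamps, channel labels, pixel size and inducer time go to
#' `<path>.json`. The round trip through [read_stack()] restores pixel
#' values to within 2^-32 of full scale (far below the quantization of any
#' detector), and all other fields exactly.
#'
#' @param stack A `timelapse_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$pixels)
  mx <- max(abs(stack$pixels), 1e-300)
  # power-of-two scale: division is exact in binary floating point
  scale <- 2^ceiling(log2(mx))
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 1
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    pages[[i]] <- matrix(stack$pixels[t, z, c, , ] / scale, d[4], d[5])
    i <- i + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  meta <- list(axes = "TZCYX", dim = d, scale = scale,
               timestamps = stack$timestamps,
               channels = stack$channels,
               pixel_size_um = stack$pixel_size_um,
               t_inducer = stack$t_inducer,
               z_spacing_um = stack$z_spacing_um)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a TIFF stack into the canonical TZCYX representation
#'
#' Reads a multi-page TIFF written by [write_stack()] (metadata from the
#' JSON sidecar) or any plain TIFF, in which case axis sizes must be given.
#' A single-page 2-D TIFF is promoted to T = Z = C = 1.
#'
#' @param path TIFF file path.
#' @param dim_tzc Integer vector `c(T, Z, C)` when no sidecar exists;
#'   pages must be in T-major (t, z, c) order.
#' @param timestamps,channels,t_inducer Metadata overrides when no sidecar.
#' @return A `timelapse_stack`.
#' @export
read_stack <- function(path, dim_tzc = NULL, timestamps = NULL,
                       channels = NULL, t_inducer = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(meta)) {
    dim_tzc <- meta$dim[1:3]
    timestamps <- as.numeric(meta$timestamps)
    channels <- meta$channels
    t_inducer <- if (is.null(meta$t_inducer)) NA_real_
                 else as.numeric(meta$t_inducer)
  }
  if (is.null(dim_tzc)) {
    if (length(pages) != 1)
      stop("multi-page TIFF without sidecar: supply dim_tzc = c(T, Z, C)")
    dim_tzc <- c(1L, 1L, 1L)
  }
  if (prod(dim_tzc) != length(pages))
    stop("dim_tzc does not match the number of TIFF pages")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  scale <- if (!is.null(meta) && !is.null(meta$scale)) meta$scale else 1
  px <- array(0, dim = c(dim_tzc, ny, nx))
  i <- 1
  for (t in seq_len(dim_tzc[1])) for (z in seq_len(dim_tzc[2]))
    for (c in seq_len(dim_tzc[3])) {
      px[t, z, c, , ] <- pages[[i]] * scale
      i <- i + 1
    }
  if (is.null(timestamps)) timestamps <- seq_len(dim_tzc[1]) - 1
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  timelapse_stack(px, timestamps = timestamps, channels = channels,
                  pixel_size_um = num_or_na(meta$pixel_size_um),
                  t_inducer = t_inducer,
                  z_spacing_um = num_or_na(meta$z_spacing_um))
}
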