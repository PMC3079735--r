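#' Construct a multi-channel 3D image stack
#'
#' An `ImageStack` holds one 3D intensity array per fluorescence channel,
#' together with the physical calibration needed downstream. Channels follow
#' the standard three-color confocal setup for labeled 3D matrix cultures:
#' `nuclei` (DAPI), `fibronectin` (immunofluorescence), and `tmp`
#' (bulk-labeled total matrix protein).
#'
#' Arrays are indexed `[y, x, z]` (row, column, plane). Plane index 1 is the
#' *topmost* focal plane, i.e. the one farthest from the substrate; "below"
#' always means increasing plane index. This orientation is stored explicitly
#' in the object because acquisition software does not fix a scan direction.
#'
#' @param channels Named list of numeric 3D arrays, one per channel. All
#'   channels must share identical `(y, x, z)` dimensions and contain finite,
#'   non-negative intensities. Must include `nuclei`, `fibronectin` and `tmp`
#'   (additional channels are carried along untouched).
#' @param z_spacing_um Physical spacing between consecutive focal planes in
#'   micrometers. Default 0.5, the standard fine z-step for these cultures.
#' @param pixel_size_um Lateral pixel size in micrometers.
#' @param z_orientation Orientation flag; only `"top_first"` is supported.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(channels, z_spacing_um = 0.5, pixel_size_um = 0.5,
                        z_orientation = "top_first") {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of 3D arrays", call. = FALSE)
  required <- c("nuclei", "fibronectin", "tmp")
  missing_ch <- setdiff(required, names(channels))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "), call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array indexed [y, x, z]", call. = FALSE)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share identical (y, x, z) dimensions", call. = FALSE)
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!all(is.finite(v)))
      stop("channel '", ch, "' contains non-finite intensities", call. = FALSE)
    if (any(v < 0))
      stop("channel '", ch, "' contains negative intensities", call. = FALSE)
  }
  if (!is.numeric(z_spacing_um) || length(z_spacing_um) != 1L || z_spacing_um <= 0)
    stop("`z_spacing_um` must be a single positive number", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  z_orientation <- match.arg(z_orientation, "top_first")
  structure(
    list(channels = channels,
         z_spacing_um = z_spacing_um,
         pixel_size_um = pixel_size_um,
         z_orientation = z_orientation),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<%s> %d x %d px, %d planes, channels: %s\n",
              class(x)[1], d[1], d[2], d[3],
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  z-spacing %.3g um (plane 1 = top), pixel size %.3g um\n",
              x$z_spacing_um, x$pixel_size_um))
  if (inherits(x, "ScaledStack"))
    cat("  intensities on the 0-225 scale\n")
  invisible(x)
}

n_planes <- function(stack) dim(stack$channels[[1]])[3]
field_dim <- function(stack) dim(stack$channels[[1]])[1:2]

get_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present in stack", call. = FALSE)
  stack$channels[[channel]]
}

get_plane <- function(stack, channel, z) get_channel(stack, channel)[, , z]

#' Write a multi-channel stack to a multi-page TIFF
#'
#' Pages are stored z-major: for each plane (top first) one page per channel,
#' in the channel order of the stack. Intensities are stored as 16-bit
#' samples, so integer-valued stacks in `[0, 65535]` round-trip losslessly
#' through [read_stack()]. Physical calibration is *not* embedded in the file;
#' it is supplied again on reading (metadata comes from configuration, never
#' guessed from the file).
#'
#' @param stack An [image_stack()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  nz <- n_planes(stack)
  chn <- names(stack$channels)
  pages <- vector("list", nz * length(chn))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in chn) {
      v <- round(stack$channels[[ch]][, , z])
      if (any(v > 65535))
        stop("intensities exceed the 16-bit storage range", call. = FALSE)
      pages[[k]] <- v / 65535
      k <- k + 1L
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Read a multi-channel stack from a multi-page TIFF
#'
#' @param path Path to a multi-page TIFF whose pages are stored z-major with a
#'   fixed number of channel pages per plane (the layout written by
#'   [write_stack()]).
#' @param channel_map Named list mapping each channel role to its 1-based page
#'   position within one z-group, e.g. `list(nuclei = 1, fibronectin = 2,
#'   tmp = 3)`. Must cover `nuclei`, `fibronectin` and `tmp`.
#' @param z_spacing_um,pixel_size_um Physical calibration, from the
#'   experiment's configuration.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = list(nuclei = 1, fibronectin = 2, tmp = 3),
                       z_spacing_um = 0.5, pixel_size_um = 0.5) {
  required <- c("nuclei", "fibronectin", "tmp")
  missing_ch <- setdiff(required, names(channel_map))
  if (length(missing_ch))
    stop("channel_map does not assign channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("cannot read TIFF from '", path, "'", call. = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channel_map)
  if (length(pages) %% n_ch != 0L)
    stop("page count (", length(pages), ") is not a multiple of the ",
         n_ch, " mapped channels", call. = FALSE)
  nz <- length(pages) %/% n_ch
  shp <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shp)) != 1L)
    stop("pages have non-uniform plane shapes", call. = FALSE)
  d <- dim(pages[[1]])
  channels <- lapply(channel_map, function(offset) {
    offset <- as.integer(offset)
    if (offset < 1L || offset > n_ch)
      stop("channel_map offsets must lie in 1..", n_ch, call. = FALSE)
    arr <- array(0, c(d[1], d[2], nz))
    for (z in seq_len(nz)) arr[, , z] <- pages[[(z - 1L) * n_ch + offset]]
    arr
  })
  image_stack(channels, z_spacing_um = z_spacing_um, pixel_size_um = pixel_size_um)
}

#' Rescale a stack onto the 0-225 intensity scale
#'
#' All scoring thresholds in this package (stain-positive detection, the
#' 90/225 high-intensity bin) are defined on a closed 0-225 pseudo-color
#' scale, so raw stacks are first mapped onto it by an order-preserving
#' affine transform, clipped to the ends of the scale.
#'
#' Two modes are available. `"fixed"` maps a stated raw range `(lo, hi)` to
#' `(0, 225)`; all stacks of one experiment should share a single fixed range
#' (conventionally the untreated day-0 control's range) so that scores are
#' comparable across conditions. `"global"` uses each channel's own min/max,
#' appropriate for a single stack in isolation. A constant-intensity channel
#' in global mode maps to 0 (conservative: no spurious high-intensity area).
#'
#' @param stack An [image_stack()].
#' @param mode `"fixed"` (default, with `range`) or `"global"` (per-channel
#'   min-max).
#' @param range Length-2 numeric `(lo, hi)` used in fixed mode for every
#'   channel, or a named list of per-channel ranges. Default `c(0, 225)`
#'   (identity for data already on the scale).
#' @return A `ScaledStack`: an `ImageStack` whose every pixel lies in
#'   `[0, 225]`, with the applied ranges in `$scale_params`.
#' @export
rescale_to_225 <- function(stack, mode = c("fixed", "global"), range = c(0, 225)) {
  stopifnot(inherits(stack, "ImageStack"))
  mode <- match.arg(mode)
  out <- stack
  params <- list()
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]]
    if (mode == "global") {
      lo <- min(v); hi <- max(v)
      if (hi <= lo) { # degenerate constant channel
        out$channels[[ch]] <- array(0, dim(v))
        params[[ch]] <- c(lo = lo, hi = lo)
        next
      }
    } else {
      r <- if (is.list(range)) range[[ch]] else range
      if (is.null(r) || length(r) != 2L)
        stop("fixed mode needs a (lo, hi) range for channel '", ch, "'",
             call. = FALSE)
      lo <- r[1]; hi <- r[2]
      if (hi <= lo)
        stop("fixed range must satisfy hi > lo (channel '", ch, "')",
             call. = FALSE)
    }
    out$channels[[ch]] <- pmin(pmax(225 * (v - lo) / (hi - lo), 0), 225)
    params[[ch]] <- c(lo = lo, hi = hi)
  }
  out$scale_params <- params
  class(out) <- c("ScaledStack", "ImageStack")
  out
}

assert_scaled <- function(stack) {
  if (!inherits(stack, "ScaledStack"))
    stop("a ScaledStack (see rescale_to_225()) is required here", call. = FALSE)
  invisible(stack)
}
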