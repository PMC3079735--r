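# Maximum-intensity projections, orthogonal reslices, and the
# coverage-driven top/middle/bottom partition of a z-stack.

#' Per-plane stain-positive coverage
#'
#' For each focal plane, the fraction of field pixels at or above the
#' detection threshold. The fibronectin coverage curve drives the layer
#' partition: the top of the matrix is where coverage first reaches 20%
#' of the field, the bottom where staining covers the entire field.
#'
#' @param stack A `ScaledStack` (0-225 scale).
#' @param channel Channel to evaluate, default `"fibronectin"`.
#' @param positive_threshold Stain-positive cutoff on the 0-225 scale.
#'   Default 30: a *detection* threshold, deliberately below the 90 cutoff of
#'   the high-intensity scoring bin, so that a fully covered (detected)
#'   bottom plane still retains a genuine low-intensity area for scoring.
#' @return Numeric vector, one fraction in `[0, 1]` per plane (top first).
#' @export
coverage_profile <- function(stack, channel = "fibronectin",
                             positive_threshold = 30) {
  assert_scaled(stack)
  arr <- get_channel(stack, channel)
  nz <- dim(arr)[3]
  if (nz < 1L) stop("empty stack", call. = FALSE)
  vapply(seq_len(nz), function(z) mean(arr[, , z] >= positive_threshold), 0)
}

#' Partition a stack into top, middle and bottom layers
#'
#' Applies the coverage rules, scanning from the topmost plane downward:
#' *top* is the first plane on which at least `top_coverage` (20%) of the
#' field is stain-positive for fibronectin, plus one additional plane below;
#' *bottom* is the first plane (at or below the top plane) where staining is
#' detected over the entire field, plus one additional plane above; *middle*
#' is the one (odd span) or two (even span) halfway planes of the span from
#' top to bottom. "Entire field" is operationalized as coverage `>=
#' full_coverage` (default 0.995), since noisy fields never reach exactly 1.
#'
#' If no plane reaches full coverage — as can happen for heavily degraded
#' matrices — the deepest plane achieving the maximum coverage is used
#' instead and the partition is flagged `bottom_fallback` (with a warning)
#' rather than aborting on the very phenotype of interest. In thin stacks
#' the layer sets may overlap; overlap is permitted and reported, never
#' silently merged.
#'
#' @param stack A `ScaledStack`, or a bare numeric coverage curve (useful for
#'   checking the rules directly).
#' @param channel Channel whose coverage defines the layers.
#' @param positive_threshold Detection cutoff passed to [coverage_profile()].
#' @param top_coverage Coverage fraction that defines the top plane (0.20).
#' @param full_coverage Coverage fraction treated as "entire field" (0.995).
#' @return A `LayerPartition`: list with integer plane-index vectors `top`,
#'   `middle`, `bottom` (1-based, plane 1 = topmost), `span`, the thresholds
#'   used, the `coverage_curve`, and a `bottom_fallback` flag.
#' @export
detect_layers <- function(stack, channel = "fibronectin",
                          positive_threshold = 30,
                          top_coverage = 0.20, full_coverage = 0.995) {
  cov <- if (is.numeric(stack)) as.numeric(stack)
         else coverage_profile(stack, channel, positive_threshold)
  nz <- length(cov)
  if (nz < 2L) stop("need at least two planes to partition", call. = FALSE)
  t1 <- which(cov >= top_coverage)[1]
  if (is.na(t1))
    stop("no plane reaches ", top_coverage * 100,
         "% stain-positive coverage (no matrix detected)", call. = FALSE)
  top <- unique(c(t1, min(t1 + 1L, nz)))
  below <- t1:nz
  full_idx <- below[cov[below] >= full_coverage]
  fallback <- length(full_idx) == 0L
  if (fallback) {
    mx <- max(cov[below])
    b <- max(below[cov[below] >= mx]) # deepest plane achieving the maximum
    warning("no plane reaches full-field coverage; using deepest plane of ",
            "maximum coverage as bottom (bottom_fallback)", call. = FALSE)
  } else {
    b <- full_idx[1]
  }
  bottom <- sort(unique(c(max(b - 1L, 1L), b)))
  span <- t1:b
  len <- length(span)
  middle <- if (len %% 2L == 1L) span[(len + 1L) %/% 2L]
            else span[c(len %/% 2L, len %/% 2L + 1L)]
  structure(
    list(top = as.integer(top), middle = as.integer(middle),
         bottom = as.integer(bottom),
         span = c(top_start = t1, bottom_end = b),
         positive_threshold = positive_threshold,
         top_coverage = top_coverage, full_coverage = full_coverage,
         coverage_curve = cov, bottom_fallback = fallback),
    class = "LayerPartition")
}

#' @export
print.LayerPartition <- function(x, ...) {
  cat("<LayerPartition>\n")
  cat("  top:    planes", paste(x$top, collapse = ", "), "\n")
  cat("  middle: planes", paste(x$middle, collapse = ", "), "\n")
  cat("  bottom: planes", paste(x$bottom, collapse = ", "),
      if (x$bottom_fallback) "(fallback)" else "", "\n")
  cat(sprintf("  coverage: %s\n",
              paste(sprintf("%.2f", x$coverage_curve), collapse = " ")))
  invisible(x)
}

layer_planes <- function(partition, layer) {
  partition[[match.arg(layer, c("top", "middle", "bottom"))]]
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum of a channel over a set of focal planes, collapsing the
#' selected part of the stack to a 2D image of the same lateral dimensions.
#'
#' @param stack A `ScaledStack`.
#' @param channel Channel name.
#' @param planes Integer plane indices; `NULL` projects all planes.
#' @return A 2D matrix.
#' @export
max_projection <- function(stack, channel, planes = NULL) {
  assert_scaled(stack)
  arr <- get_channel(stack, channel)
  nz <- dim(arr)[3]
  if (is.null(planes)) planes <- seq_len(nz)
  if (!length(planes)) stop("empty plane list", call. = FALSE)
  if (any(planes < 1L | planes > nz))
    stop("plane indices out of range 1..", nz, call. = FALSE)
  out <- arr[, , planes[1]]
  for (z in planes[-1]) out <- pmax(out, arr[, , z])
  out
}

#' Orthogonal (XZ) reslice
#'
#' Side-view reconstruction through a stack: for every (x, z) position, the
#' maximum intensity over the image rows lying within a band of physical
#' thickness `thickness_um` centered on a chosen y-row — the standard
#' "90-degree" view used to inspect where cells sit within the matrix.
#'
#' @param stack A `ScaledStack`.
#' @param channel Channel name.
#' @param line Center y-row (1-based).
#' @param thickness_um Band thickness in micrometers (default 10).
#' @return Matrix of dimension `(n_planes, x)`; row 1 is the topmost plane.
#' @export
orthogonal_reslice <- function(stack, channel, line, thickness_um = 10) {
  assert_scaled(stack)
  arr <- get_channel(stack, channel)
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nz <- dim(arr)[3]
  if (line < 1L || line > ny) stop("line out of field", call. = FALSE)
  half <- thickness_um / 2
  rows <- which(abs(seq_len(ny) - line) * stack$pixel_size_um <= half)
  if (!length(rows)) rows <- line
  out <- matrix(0, nz, nx)
  for (z in seq_len(nz)) {
    band <- arr[rows, , z, drop = FALSE]
    out[z, ] <- apply(band, 2, max)
  }
  out
}
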