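# Cell-region segmentation and the high/low intensity area-ratio
# remodeling score -- the quantitative core of the pipeline.

# Rasterize the convex hull of a set of pixel coordinates (rows r, cols c)
# into a logical matrix. Half-plane test against each hull edge, vectorized
# over the bounding box; exact for convex polygons, boundary inclusive.
fill_convex_hull <- function(r, c, ny, nx) {
  out <- matrix(FALSE, ny, nx)
  pts <- unique(cbind(r, c))
  if (nrow(pts) < 3L) { out[pts] <- TRUE; return(out) }
  h <- grDevices::chull(pts[, 2], pts[, 1]) # x = col, y = row
  hx <- pts[h, 2]; hy <- pts[h, 1]
  if (length(h) < 3L) { out[pts] <- TRUE; return(out) }
  rows <- max(1, min(hy)):min(ny, max(hy))
  cols <- max(1, min(hx)):min(nx, max(hx))
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  inside_pos <- rep(TRUE, length(px))
  inside_neg <- rep(TRUE, length(px))
  n <- length(h)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside_pos <- inside_pos & (cr >= -1e-9)
    inside_neg <- inside_neg & (cr <= 1e-9)
  }
  inside <- inside_pos | inside_neg
  out[cbind(py[inside], px[inside])] <- TRUE
  out
}

dilate_mask <- function(mask, radius_px) {
  if (radius_px < 1L) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0.5
}

new_region_mask <- function(cell_mask, devoid_mask, provenance) {
  structure(list(cell_mask = cell_mask, devoid_mask = devoid_mask,
                 provenance = provenance),
            class = "RegionMask")
}

#' Segment cell-containing vs cell-devoid regions from the nuclei channel
#'
#' Automated stand-in for manually tracing around cell clumps on the DAPI
#' image: nuclei are Otsu-thresholded on the nuclei projection, blobs smaller
#' than `min_blob_area` discarded, nearby blobs grouped into clumps by a
#' morphological dilation of `dilation_radius_um`, and each clump is enclosed
#' by the filled convex hull of its dilated extent (the "circumvention").
#' The cell-devoid region is the remainder of the field minus a buffer ring
#' of `buffer_um` around the cell region, which keeps halo signal at the
#' clump border out of the control region.
#'
#' @param nuclei_projection 2D nuclei image on the 0-225 scale (typically
#'   [max_projection()] of the full stack's nuclei channel).
#' @param min_blob_area Minimum nucleus blob area in pixels.
#' @param dilation_radius_um Clump-grouping / circumvention margin.
#' @param buffer_um Width of the excluded ring between the two regions.
#' @param pixel_size_um Lateral pixel size used to convert the distances.
#' @param threshold Optional fixed nuclei threshold (0-225); `NULL` uses Otsu.
#' @return A `RegionMask` with logical `cell_mask` and `devoid_mask`
#'   (mutually exclusive; their union need not cover the field) and
#'   `provenance = "auto"`.
#' @export
segment_cell_region <- function(nuclei_projection, min_blob_area = 40,
                                dilation_radius_um = 5, buffer_um = 10,
                                pixel_size_um = 0.5, threshold = NULL) {
  ny <- nrow(nuclei_projection); nx <- ncol(nuclei_projection)
  img01 <- pmin(pmax(nuclei_projection / 225, 0), 1)
  if (is.null(threshold)) {
    thr <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  } else {
    thr <- threshold / 225
  }
  bw <- img01 > thr
  if (!any(bw))
    stop("no nuclei detected: cell region is empty, scoring impossible",
         call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  sizes <- table(as.vector(lab[lab > 0]))
  keep <- as.integer(names(sizes)[sizes >= min_blob_area])
  if (!length(keep))
    stop("no nuclei blob reaches min_blob_area = ", min_blob_area,
         "; cell region is empty", call. = FALSE)
  blobs <- matrix(as.vector(lab) %in% keep, ny, nx)
  dil_px <- max(1L, round(dilation_radius_um / pixel_size_um))
  clump_img <- dilate_mask(blobs, dil_px)
  clumps <- EBImage::bwlabel(EBImage::Image(clump_img * 1))
  cell_mask <- matrix(FALSE, ny, nx)
  for (lbl in seq_len(max(clumps))) {
    idx <- which(as.matrix(clumps) == lbl, arr.ind = TRUE)
    cell_mask <- cell_mask | fill_convex_hull(idx[, 1], idx[, 2], ny, nx)
  }
  buf_px <- max(0L, round(buffer_um / pixel_size_um))
  devoid_mask <- !dilate_mask(cell_mask, buf_px)
  new_region_mask(cell_mask, devoid_mask, "auto")
}

#' Build a region mask from manually traced polygons
#'
#' Fidelity path for users who trace cell clumps by hand: each polygon is a
#' list/matrix of vertices in pixel coordinates (origin top-left, `x`
#' rightward, `y` downward). Pixels inside any polygon (even-odd rule) form
#' the cell region; the devoid region is the complement minus the buffer.
#'
#' @param polygons List of vertex matrices/data.frames with columns `x`, `y`.
#' @param field_shape `(y, x)` field size in pixels.
#' @param buffer_um,pixel_size_um As in [segment_cell_region()].
#' @return A `RegionMask` with `provenance = "manual-polygon"`.
#' @export
polygon_region <- function(polygons, field_shape, buffer_um = 10,
                           pixel_size_um = 0.5) {
  ny <- field_shape[1]; nx <- field_shape[2]
  cell_mask <- matrix(FALSE, ny, nx)
  py <- rep(seq_len(ny), times = nx)
  px <- rep(seq_len(nx), each = ny)
  for (poly in polygons) {
    poly <- as.matrix(as.data.frame(poly)[, c("x", "y")])
    vx <- poly[, 1]; vy <- poly[, 2]
    n <- length(vx)
    crossings <- rep(0L, length(px))
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      crossings <- crossings + crosses
    }
    cell_mask <- cell_mask | matrix(crossings %% 2L == 1L, ny, nx)
  }
  if (!any(cell_mask))
    stop("polygons enclose no pixels; cell region is empty", call. = FALSE)
  buf_px <- max(0L, round(buffer_um / pixel_size_um))
  devoid_mask <- !dilate_mask(cell_mask, buf_px)
  new_region_mask(cell_mask, devoid_mask, "manual-polygon")
}

#' High/low intensity area ratio within a region
#'
#' The elementary statistic: within the masked region of a projection on the
#' 0-225 scale, the number of pixels whose intensity falls in the
#' high-intensity bin `[90, 225]` divided by the number below 90. The lower
#' bound is closed — a pixel at exactly 90 counts as high. With smoothing, a
#' half count is added to both bins, guarding against an empty bin;
#' `smoothing = "auto"` (default) applies the guard only when a bin is empty
#' and flags that it did.
#'
#' @param projection 2D image on the 0-225 scale.
#' @param mask Logical region mask (non-empty).
#' @param high_range `(lo, hi)` of the high bin; default `c(90, 225)`.
#' @param smoothing `"auto"`, `"on"` or `"off"`.
#' @return The ratio, with attributes `n_high`, `n_low` (raw counts) and
#'   `smoothing_applied`.
#' @export
area_ratio <- function(projection, mask, high_range = c(90, 225),
                       smoothing = c("auto", "on", "off")) {
  smoothing <- match.arg(smoothing)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  v <- projection[mask]
  n_high <- sum(v >= high_range[1])
  n_low <- sum(v < high_range[1])
  apply_s <- switch(smoothing,
                    on = TRUE, off = FALSE,
                    auto = (n_high == 0L || n_low == 0L))
  if (!apply_s && n_low == 0L)
    stop("low-intensity bin is empty and smoothing is off", call. = FALSE)
  s <- if (apply_s) 0.5 else 0
  structure((n_high + s) / (n_low + s),
            n_high = n_high, n_low = n_low, smoothing_applied = apply_s)
}

#' Remodeling score of one projection
#'
#' The cell-induced intensity change, expressed as the percent difference of
#' the high/low area ratio in the cell-containing region relative to the
#' adjacent cell-devoid region: `100 * ratio_cell / ratio_devoid`. A score of
#' 100 means no cell-induced change; below 100, matrix degradation; above
#' 100, matrix accumulation/contraction.
#'
#' @param projection 2D image on the 0-225 scale.
#' @param region A `RegionMask`.
#' @param high_range,smoothing Passed to [area_ratio()].
#' @return One-row data.frame: `ratio_cell`, `ratio_devoid`, `score_percent`,
#'   the four bin counts, and `smoothing_applied`.
#' @export
remodeling_score <- function(projection, region, high_range = c(90, 225),
                             smoothing = "auto") {
  rc <- area_ratio(projection, region$cell_mask, high_range, smoothing)
  rd <- area_ratio(projection, region$devoid_mask, high_range, smoothing)
  data.frame(
    ratio_cell = as.numeric(rc),
    ratio_devoid = as.numeric(rd),
    score_percent = 100 * as.numeric(rc) / as.numeric(rd),
    n_high_cell = attr(rc, "n_high"), n_low_cell = attr(rc, "n_low"),
    n_high_devoid = attr(rd, "n_high"), n_low_devoid = attr(rd, "n_low"),
    smoothing_applied = attr(rc, "smoothing_applied") ||
      attr(rd, "smoothing_applied"))
}

#' Score a stack per layer and channel
#'
#' For each layer (top/middle/bottom) and matrix channel, builds the
#' maximum-intensity projection over the layer's planes and computes the
#' remodeling score against the region mask: six scores per field.
#'
#' @param stack A `ScaledStack`.
#' @param layers A `LayerPartition` from [detect_layers()]; `NULL` detects it
#'   from the stack.
#' @param region A `RegionMask`; `NULL` segments it from the nuclei channel's
#'   full-stack projection with default parameters.
#' @param channels Matrix channels to score.
#' @param high_range,smoothing Passed to [area_ratio()].
#' @return Data.frame with one row per (layer, channel).
#' @export
score_stack <- function(stack, layers = NULL, region = NULL,
                        channels = c("fibronectin", "tmp"),
                        high_range = c(90, 225), smoothing = "auto") {
  assert_scaled(stack)
  if (is.null(layers)) layers <- detect_layers(stack)
  if (is.null(region))
    region <- segment_cell_region(max_projection(stack, "nuclei"),
                                  pixel_size_um = stack$pixel_size_um)
  out <- list()
  for (layer in c("top", "middle", "bottom")) {
    planes <- layers[[layer]]
    for (ch in channels) {
      proj <- max_projection(stack, ch, planes)
      row <- remodeling_score(proj, region, high_range, smoothing)
      out[[length(out) + 1L]] <- cbind(
        data.frame(layer = layer, channel = ch), row)
    }
  }
  do.call(rbind, out)
}

#' Normalize scores to the untreated control's bottom layer
#'
#' Re-expresses scores relative to the mean bottom-layer score of the
#' untreated control (per channel), which maps to 100 exactly — the
#' convention used when comparing inhibitor conditions.
#'
#' @param scores Data.frame with columns `channel`, `layer`, `score_percent`.
#' @param control Data.frame of untreated-control scores, same columns; must
#'   contain bottom-layer rows for every channel present in `scores`.
#' @return `scores` with an added `score_norm` column.
#' @export
normalize_to_control <- function(scores, control) {
  out <- scores
  out$score_norm <- NA_real_
  for (ch in unique(scores$channel)) {
    ctrl <- control$score_percent[control$layer == "bottom" &
                                    control$channel == ch]
    if (!length(ctrl))
      stop("control has no bottom-layer score for channel '", ch, "'",
           call. = FALSE)
    m <- mean(ctrl)
    if (!is.finite(m) || m == 0)
      stop("control bottom-layer mean is zero for channel '", ch, "'",
           call. = FALSE)
    sel <- out$channel == ch
    out$score_norm[sel] <- out$score_percent[sel] / m * 100
  }
  out
}

# Default neutral margin for phenotype classification: three times the
# between-field standard deviation (15) of the top-layer score under the
# null (no-remodeling) simulation at default parameters (see the methods
# vignette for the calibration).
ECM_DELTA_DEFAULT <- 45

#' Classify the remodeling phenotype of a field
#'
#' The deciding layer is the top of the matrix, where both cell types induce
#' their largest intensity change: a mean top-layer score below `100 - delta`
#' calls a degrader, above `100 + delta` an accumulator, otherwise neutral.
#'
#' @param scores Data.frame from [score_stack()] (must contain top-layer
#'   rows).
#' @param delta Neutral margin around 100; the default is calibrated as three
#'   null-simulation standard deviations of the top-layer score.
#' @param channel Optional single channel to decide on; default averages the
#'   top-layer scores of all channels present.
#' @return A `PhenotypeCall`: list with `label`, `deciding_layer`, `delta`
#'   and the deciding `top_score`.
#' @export
classify_phenotype <- function(scores, delta = ECM_DELTA_DEFAULT,
                               channel = NULL) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  sel <- scores$layer == "top"
  if (!is.null(channel)) sel <- sel & scores$channel == channel
  top_scores <- scores$score_percent[sel]
  if (!length(top_scores))
    stop("no top-layer score available; classification needs the top layer",
         call. = FALSE)
  s <- mean(top_scores)
  label <- if (s < 100 - delta) "degrader"
           else if (s > 100 + delta) "accumulator"
           else "neutral"
  structure(list(label = label, deciding_layer = "top", delta = delta,
                 top_score = s),
            class = "PhenotypeCall")
}

#' @export
print.PhenotypeCall <- function(x, ...) {
  cat(sprintf("<PhenotypeCall> %s (top-layer score %.1f, neutral band 100 +/- %g)\n",
              x$label, x$top_score, x$delta))
  invisible(x)
}

#' Per-region intensity trajectory of a tracked field over time
#'
#' For a series of repeatedly imaged 2D field images of the same location
#' (e.g. days 0/7/10), the mean intensity inside the cell-containing and
#' cell-devoid regions per day, plus the day-over-day percent change. A
#' degrading culture shows a decreasing cell-region trajectory, a
#' contracting one an increasing trajectory, and matrices kept without cells
#' do not change.
#'
#' @param series List of elements `list(day = <numeric>, image = <matrix>)`,
#'   at least two days, all images of identical dimensions.
#' @param region A `RegionMask` for the (fixed) field geometry.
#' @return Data.frame with columns `day`, `region`, `mean_intensity`,
#'   `pct_change` (vs the previous day; `NA` for the first).
#' @export
timelapse_change <- function(series, region) {
  if (length(series) < 2L) stop("need at least two days", call. = FALSE)
  days <- vapply(series, function(e) e$day, 0)
  dims <- vapply(series, function(e) paste(dim(e$image), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("mismatched field sizes across days", call. = FALSE)
  ord <- order(days)
  rows <- list()
  for (reg in c("cell", "devoid")) {
    mask <- if (reg == "cell") region$cell_mask else region$devoid_mask
    means <- vapply(series[ord], function(e) mean(e$image[mask]), 0)
    pct <- c(NA_real_, 100 * diff(means) / means[-length(means)])
    rows[[reg]] <- data.frame(day = days[ord], region = reg,
                              mean_intensity = means, pct_change = pct)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
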