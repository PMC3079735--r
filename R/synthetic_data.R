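# Synthetic 3D matrix cultures with known ground truth.
#
# The generator emulates the phenomenology the scoring pipeline is built to
# measure: a fiber-textured labeled matrix whose per-plane coverage tapers
# toward the top of the stack and saturates at the bottom, nuclei clusters
# marking the cell-containing footprint, and two remodeling transforms --
# local depletion under clusters (degrader) and local concentration with
# apical deposition (accumulator/contractor).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default per-plane matrix coverage profile
#'
#' Fraction of the field that is stain-positive (at the detection threshold)
#' on each focal plane, from the topmost plane down. The default tapers from
#' near-zero at the top — where only the tallest fibers protrude — through a
#' 20% crossing about a third of the way down, to full-field coverage in the
#' dense bottom planes, mimicking the depth profile of a fibroblast-derived
#' matrix culture.
#'
#' @param n_planes Number of focal planes.
#' @return Numeric vector of length `n_planes`, non-decreasing, in `[0, 1]`.
#' @export
default_z_profile <- function(n_planes = 12) {
  anchor <- c(0.02, 0.08, 0.15, 0.25, 0.40, 0.55, 0.70, 0.85, 0.95, 1, 1, 1)
  if (n_planes == length(anchor)) return(anchor)
  y <- stats::approx(seq(0, 1, length.out = length(anchor)), anchor,
                     xout = seq(0, 1, length.out = n_planes))$y
  cummax(pmin(pmax(y, 0), 1))
}

#' Parameters of one synthetic matrix-culture experiment
#'
#' Bundles the full specification (geometry, texture, effect, noise, seed) of
#' a synthetic multi-channel stack, validated up front. Identical parameters
#' and seed always produce identical stacks.
#'
#' Raw intensities live on the same 0-225 convention the scoring uses (fiber
#' peaks around `fiber_intensity_mean`, dense bottom carpet around
#' `carpet_mean`), so `rescale_to_225()` with the default fixed `(0, 225)`
#' range is essentially the identity apart from clipping.
#'
#' @param field_shape `(y, x)` field size in pixels.
#' @param n_planes Number of focal planes (plane 1 = top).
#' @param z_spacing_um,pixel_size_um Physical calibration (micrometers).
#' @param z_profile Per-plane stain-positive coverage fractions, non-decreasing
#'   from top to bottom; see [default_z_profile()].
#' @param fiber_intensity_mean,fiber_intensity_sd Fiber peak intensity
#'   distribution on the raw scale.
#' @param fiber_length_frac Fiber length range as a fraction of the shorter
#'   field side.
#' @param fiber_sigma_px Range of the Gaussian cross-section sigma (pixels).
#' @param carpet_mean,carpet_sd Intensity distribution of the dense
#'   full-coverage bottom planes.
#' @param n_clusters Number of cell clusters.
#' @param cluster_centers Optional list of `(y, x)` centers; random placement
#'   (margin-respecting, minimum separation) when `NULL`.
#' @param cluster_radius_px Cluster footprint radius in pixels.
#' @param n_nuclei_per_cluster Nuclei rendered per cluster.
#' @param nucleus_sigma_px Semi-axes (sigma, pixels) of one elliptical nucleus.
#' @param phenotype `"none"`, `"degrader"` or `"accumulator"`.
#' @param effect_size Multiplicative effect at the top plane: depletion factor
#'   in `(0, 1)` for a degrader, concentration factor `> 1` for an
#'   accumulator. `NULL` picks the phenotype default (0.3 / 3).
#' @param depth_floor Fraction of the full effect still applied at the bottom
#'   plane; the effect weight falls linearly from 1 (top) to this value,
#'   making remodeling strongest in the top layer.
#' @param apical_fraction Fraction of the accumulated signal re-deposited on
#'   top of the cluster (top two planes), emulating apical matrix build-up.
#' @param conservation_fraction Fraction of moved signal withdrawn from an
#'   annulus around the cluster (1 = pure redistribution).
#' @param annulus_width_um Width of that annulus.
#' @param noise_sd Additive Gaussian noise sigma (truncated at 0).
#' @param timepoints Imaging days for [simulate_timecourse()].
#' @param effect_scaling Per-day effect scale factors, non-decreasing,
#'   matching `timepoints`.
#' @param detection_threshold Stain-positive cutoff (0-225) the coverage
#'   profile is defined against.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A validated `SimulationParams` list.
#' @export
sim_params <- function(field_shape = c(256, 256),
                       n_planes = 12,
                       z_spacing_um = 0.5,
                       pixel_size_um = 0.5,
                       z_profile = default_z_profile(n_planes),
                       fiber_intensity_mean = 150,
                       fiber_intensity_sd = 15,
                       fiber_length_frac = c(0.06, 0.15),
                       fiber_sigma_px = c(0.9, 1.4),
                       carpet_mean = 110,
                       carpet_sd = 25,
                       n_clusters = 4,
                       cluster_centers = NULL,
                       cluster_radius_px = 36,
                       n_nuclei_per_cluster = 12,
                       nucleus_sigma_px = c(6, 4),
                       phenotype = c("none", "degrader", "accumulator"),
                       effect_size = NULL,
                       depth_floor = 0.01,
                       apical_fraction = 0.25,
                       conservation_fraction = 0.5,
                       annulus_width_um = 15,
                       noise_sd = 4,
                       timepoints = c(0, 7, 10),
                       effect_scaling = c(0, 0.6, 1),
                       detection_threshold = 30,
                       seed = 1) {
  phenotype <- match.arg(phenotype)
  if (is.null(effect_size))
    effect_size <- switch(phenotype, none = 1, degrader = 0.3, accumulator = 3)
  # effect_size = 1 is the identity boundary (no effect), legal for either
  # phenotype so that factor sweeps can include the null level
  if (phenotype == "degrader" && !(effect_size > 0 && effect_size <= 1))
    stop("degrader effect_size must lie in (0, 1]", call. = FALSE)
  if (phenotype == "accumulator" && !(effect_size >= 1))
    stop("accumulator effect_size must be >= 1", call. = FALSE)
  if (length(z_profile) != n_planes)
    stop("z_profile must have one value per plane", call. = FALSE)
  if (any(z_profile < 0 | z_profile > 1))
    stop("z_profile values must lie in [0, 1]", call. = FALSE)
  if (any(diff(z_profile) < 0))
    stop("z_profile must be non-decreasing from top toward bottom", call. = FALSE)
  if (length(timepoints) != length(effect_scaling))
    stop("effect_scaling must match timepoints", call. = FALSE)
  if (any(diff(effect_scaling) < 0))
    stop("effect_scaling must be non-decreasing over days", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!(depth_floor > 0 && depth_floor <= 1))
    stop("depth_floor must lie in (0, 1]", call. = FALSE)
  p <- as.list(environment())
  class(p) <- "SimulationParams"
  p
}

# Render one fiber (line segment, Gaussian cross-section) into `plane` by
# per-pixel maximum; returns list(plane, new_positive) where new_positive is
# the number of pixels newly raised to >= thr.
render_fiber <- function(plane, x0, y0, x1, y1, sigma, peak, thr) {
  ny <- nrow(plane); nx <- ncol(plane)
  pad <- ceiling(3 * sigma)
  r0 <- max(1, floor(min(y0, y1)) - pad); r1 <- min(ny, ceiling(max(y0, y1)) + pad)
  c0 <- max(1, floor(min(x0, x1)) - pad); c1 <- min(nx, ceiling(max(x0, x1)) + pad)
  if (r0 > r1 || c0 > c1)
    return(list(plane = plane, new_positive = 0L))
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  t <- if (len2 > 0) pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1) else 0
  dx <- px - (x0 + t * vx); dy <- py - (y0 + t * vy)
  val <- peak * exp(-(dx * dx + dy * dy) / (2 * sigma * sigma))
  old <- plane[rows, cols]
  new <- pmax(old, matrix(val, length(rows), length(cols)))
  list(plane = {plane[rows, cols] <- new; plane},
       new_positive = sum(new >= thr & old < thr))
}

# One focal plane of matrix texture at a target stain-positive coverage.
# Dense planes (coverage >= 0.99) are rendered as a noisy carpet; sparser
# planes are filled fiber by fiber until the positive-pixel count reaches
# the target.
make_plane_texture <- function(p, target_cov) {
  ny <- p$field_shape[1]; nx <- p$field_shape[2]
  npx <- ny * nx
  if (target_cov >= 0.99)
    return(matrix(pmax(stats::rnorm(npx, p$carpet_mean, p$carpet_sd), 0), ny, nx))
  plane <- matrix(0, ny, nx)
  target <- round(target_cov * npx)
  if (target <= 0) return(plane)
  lmin <- p$fiber_length_frac[1] * min(ny, nx)
  lmax <- p$fiber_length_frac[2] * min(ny, nx)
  # fiber centers are drawn from a border-padded domain so the texture is
  # stationary across the field (no dim band at the field edges)
  pad <- lmax / 2 + 3 * p$fiber_sigma_px[2]
  pos <- 0L
  for (i in seq_len(5000L)) {
    if (pos >= target) break
    cx <- stats::runif(1, 1 - pad, nx + pad)
    cy <- stats::runif(1, 1 - pad, ny + pad)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, lmin, lmax)
    sg <- stats::runif(1, p$fiber_sigma_px[1], p$fiber_sigma_px[2])
    pk <- min(max(stats::rnorm(1, p$fiber_intensity_mean, p$fiber_intensity_sd), 60), 225)
    r <- render_fiber(plane,
                      cx - cos(ang) * len / 2, cy - sin(ang) * len / 2,
                      cx + cos(ang) * len / 2, cy + sin(ang) * len / 2,
                      sg, pk, p$detection_threshold)
    plane <- r$plane
    pos <- pos + r$new_positive
  }
  plane
}

disk_mask <- function(ny, nx, cy, cx, radius) {
  dy <- matrix(seq_len(ny) - cy, ny, nx)
  dx <- matrix(seq_len(nx) - cx, ny, nx, byrow = TRUE)
  dy * dy + dx * dx <= radius * radius
}

place_clusters <- function(p) {
  ny <- p$field_shape[1]; nx <- p$field_shape[2]
  r <- p$cluster_radius_px
  if (!is.null(p$cluster_centers)) {
    centers <- p$cluster_centers
  } else {
    margin <- r + 5
    if (2 * margin >= min(ny, nx))
      stop("cluster footprint exceeds the field", call. = FALSE)
    centers <- list()
    for (restart in seq_len(50L)) {
      centers <- list()
      for (i in seq_len(p$n_clusters)) {
        placed <- FALSE
        for (try_i in seq_len(200L)) {
          cand <- c(stats::runif(1, margin, ny - margin),
                    stats::runif(1, margin, nx - margin))
          far <- all(vapply(centers, function(cc)
            sqrt(sum((cc - cand)^2)) >= 2.1 * r, TRUE))
          if (far) { centers[[i]] <- cand; placed <- TRUE; break }
        }
        if (!placed) break
      }
      if (length(centers) == p$n_clusters) break
    }
    if (length(centers) != p$n_clusters)
      stop("could not place ", p$n_clusters, " non-overlapping clusters ",
           "of radius ", r, " in the field", call. = FALSE)
  }
  for (cc in centers)
    if (cc[1] - r < 1 || cc[1] + r > ny || cc[2] - r < 1 || cc[2] + r > nx)
      stop("cluster footprint exceeds the field", call. = FALSE)
  centers
}

render_nuclei <- function(p, centers) {
  ny <- p$field_shape[1]; nx <- p$field_shape[2]
  img <- matrix(0, ny, nx)
  sa <- p$nucleus_sigma_px[1]; sb <- p$nucleus_sigma_px[2]
  pad <- ceiling(3 * sa)
  for (cc in centers) {
    for (k in seq_len(p$n_nuclei_per_cluster)) {
      rr <- 0.85 * p$cluster_radius_px * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cy <- cc[1] + rr * sin(th); cx <- cc[2] + rr * cos(th)
      rot <- stats::runif(1, 0, pi)
      pk <- stats::runif(1, 180, 220)
      rows <- max(1, floor(cy) - pad):min(ny, ceiling(cy) + pad)
      cols <- max(1, floor(cx) - pad):min(nx, ceiling(cx) + pad)
      py <- rep(rows, times = length(cols)) - cy
      px <- rep(cols, each = length(rows)) - cx
      u <- cos(rot) * px + sin(rot) * py
      v <- -sin(rot) * px + cos(rot) * py
      val <- pk * exp(-(u * u / (2 * sa * sa) + v * v / (2 * sb * sb)))
      img[rows, cols] <- pmax(img[rows, cols],
                              matrix(val, length(rows), length(cols)))
    }
  }
  img
}

# Clean (no remodeling, no noise) stack plus ground truth.
sim_clean_stack <- function(p) {
  ny <- p$field_shape[1]; nx <- p$field_shape[2]
  nz <- p$n_planes
  centers <- place_clusters(p)
  cell_mask <- Reduce(`|`, lapply(centers, function(cc)
    disk_mask(ny, nx, cc[1], cc[2], p$cluster_radius_px)),
    accumulate = FALSE, init = matrix(FALSE, ny, nx))
  fib <- array(0, c(ny, nx, nz))
  for (z in seq_len(nz)) fib[, , z] <- make_plane_texture(p, p$z_profile[z])
  tmp <- pmin(fib * 1.05, 65535) # same fiber geometry, bulk label slightly brighter
  nuc2d <- render_nuclei(p, centers)
  nuc <- array(0, c(ny, nx, nz))
  ref_planes <- seq(max(1L, floor(nz * 0.35)), max(1L, ceiling(nz * 0.7)))
  for (z in ref_planes) nuc[, , z] <- nuc2d
  stack <- image_stack(list(nuclei = nuc, fibronectin = fib, tmp = tmp),
                       z_spacing_um = p$z_spacing_um,
                       pixel_size_um = p$pixel_size_um)
  direction <- switch(p$phenotype, none = 0, degrader = -1, accumulator = +1)
  truth <- structure(
    list(cell_mask = cell_mask,
         phenotype = p$phenotype,
         effect_size = p$effect_size,
         centers = centers,
         radius_px = p$cluster_radius_px,
         layer_direction = c(top = direction, middle = direction,
                             bottom = direction)),
    class = "GroundTruth")
  list(stack = stack, truth = truth)
}

add_noise <- function(stack, sd, seed) {
  if (sd <= 0) return(stack)
  with_seed(seed, {
    for (ch in names(stack$channels)) {
      v <- stack$channels[[ch]]
      stack$channels[[ch]] <- pmax(v + array(stats::rnorm(length(v), 0, sd), dim(v)), 0)
    }
    stack
  })
}

#' Apply a remodeling phenotype to a matrix stack
#'
#' Transforms the matrix channels (`fibronectin`, `tmp`) inside the known
#' cell footprint; the nuclei channel is never touched. The effect is
#' weighted by a depth profile `w(z)`: 1 at and above `surface_plane` (where
#' the cells meet the free matrix surface), decaying as
#' `((bottom - z)/(bottom - surface))^depth_power` down to `depth_floor` at
#' the bottom plane — remodeling is strongest in the top layer and barely
#' reaches the dense bottom of the culture. With `depth_floor = 1` the
#' effect is uniform over depth.
#'
#' * **degrader** — multiplies intensities inside the footprint by
#'   `1 - (1 - effect_size) * w(z)` (i.e. by `effect_size` at the surface).
#' * **accumulator** — multiplies inside the footprint by
#'   `1 + (effect_size - 1) * w(z)`; deposits `apical_fraction` of the total
#'   added signal onto the existing masked signal of the top third of the
#'   stack (proportionally, so matrix piles up on the fibers already at the
#'   surface); and withdraws `conservation_fraction` of all added signal
#'   from an annulus of width `annulus_width_um` around the footprint,
#'   weighted by the same depth profile (contraction moves matrix rather
#'   than creating it; with `conservation_fraction = 1` the channel total is
#'   exactly preserved).
#'
#' @param stack An [image_stack()] (raw scale).
#' @param truth A `GroundTruth` from [simulate_matrix_stack()] (supplies the
#'   cell footprint).
#' @param phenotype `"degrader"` or `"accumulator"`.
#' @param effect_size Top-plane multiplicative factor; `(0, 1)` for degrader,
#'   `> 1` for accumulator. `effect_size = 1` is the identity.
#' @param apical_fraction,conservation_fraction,annulus_width_um,depth_floor
#'   See above.
#' @param surface_plane Plane index of the matrix surface the depth profile
#'   anchors to (1 = effect profile spans the whole stack).
#' @param depth_power Exponent of the depth decay (larger = more
#'   surface-concentrated).
#' @return The remodeled stack.
#' @export
apply_remodeling <- function(stack, truth,
                             phenotype = c("degrader", "accumulator"),
                             effect_size,
                             apical_fraction = 0,
                             conservation_fraction = 1,
                             annulus_width_um = 15,
                             depth_floor = 1,
                             surface_plane = 1,
                             depth_power = 4) {
  phenotype <- match.arg(phenotype)
  mask <- truth$cell_mask
  nz <- n_planes(stack)
  # depth profile: full effect at and above the matrix surface plane,
  # decaying as a steep power law to depth_floor at the bottom plane --
  # remodeling concentrates where the cells meet the free matrix surface
  # and barely reaches the dense bottom carpet
  w <- if (nz > 1 && surface_plane < nz) {
    rel <- pmax(nz - seq_len(nz), 0) / (nz - surface_plane)
    pmin(depth_floor + (1 - depth_floor) * pmin(rel, 1)^depth_power, 1)
  } else rep(1, nz)
  matrix_channels <- intersect(c("fibronectin", "tmp"), names(stack$channels))
  if (phenotype == "degrader") {
    if (!(effect_size > 0 && effect_size <= 1))
      stop("degrader effect_size must lie in (0, 1]", call. = FALSE)
    for (ch in matrix_channels) {
      arr <- stack$channels[[ch]]
      for (z in seq_len(nz)) {
        f_z <- 1 - (1 - effect_size) * w[z]
        pl <- arr[, , z]; pl[mask] <- pl[mask] * f_z; arr[, , z] <- pl
      }
      stack$channels[[ch]] <- arr
    }
    return(stack)
  }
  if (!(effect_size >= 1))
    stop("accumulator effect_size must be >= 1", call. = FALSE)
  ann_px <- max(1L, round(annulus_width_um / stack$pixel_size_um))
  brush <- EBImage::makeBrush(2L * ann_px + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0.5
  annulus <- dil & !mask
  n_mask <- sum(mask)
  for (ch in matrix_channels) {
    arr <- stack$channels[[ch]]
    total_added <- 0
    for (z in seq_len(nz)) {
      f_z <- 1 + (effect_size - 1) * w[z]
      pl <- arr[, , z]
      total_added <- total_added + (f_z - 1) * sum(pl[mask])
      pl[mask] <- pl[mask] * f_z
      arr[, , z] <- pl
    }
    if (total_added > 0) {
      # apical build-up: deposit new matrix uniformly over the cluster
      # footprint on the two surface planes (accumulated material lands on
      # top of the cells)
      apical_add <- 0
      if (apical_fraction > 0 && n_mask > 0) {
        top_k <- seq(surface_plane, min(nz, surface_plane + 1L))
        apical_add <- apical_fraction * total_added
        per_px <- apical_add / (length(top_k) * n_mask)
        for (z in top_k) {
          pl <- arr[, , z]; pl[mask] <- pl[mask] + per_px; arr[, , z] <- pl
        }
      }
      # withdraw the moved signal from the annulus, proportionally to the
      # signal present: every annulus voxel loses the same fraction
      withdraw <- conservation_fraction * (total_added + apical_add)
      if (withdraw > 0) {
        ann3 <- array(annulus, dim(arr))
        s_ann <- sum(arr[ann3])
        if (s_ann > 0) {
          fac <- max(1 - withdraw / s_ann, 0)
          arr[ann3] <- arr[ann3] * fac
        }
      }
    }
    stack$channels[[ch]] <- arr
  }
  stack
}

#' Simulate one synthetic matrix-culture stack
#'
#' Generates the three-channel stack described by `params`: anisotropic
#' fiber texture in the matrix channels following the per-plane coverage
#' profile, elliptical nuclei confined to the cluster footprints, the
#' requested remodeling phenotype applied at `effect_size`, then truncated
#' Gaussian noise. Deterministic given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return `list(stack = ImageStack, truth = GroundTruth)`; `truth` carries
#'   the exact cluster footprint, phenotype label and expected per-layer
#'   intensity-change direction.
#' @export
simulate_matrix_stack <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  base <- with_seed(params$seed, sim_clean_stack(params))
  stack <- base$stack
  if (params$phenotype != "none")
    stack <- apply_remodeling(stack, base$truth,
                              phenotype = params$phenotype,
                              effect_size = params$effect_size,
                              apical_fraction = params$apical_fraction,
                              conservation_fraction = params$conservation_fraction,
                              annulus_width_um = params$annulus_width_um,
                              depth_floor = params$depth_floor,
                              surface_plane = surface_plane_of(params))
  stack <- add_noise(stack, params$noise_sd, params$seed + 77003L)
  list(stack = stack, truth = base$truth)
}

# plane where the matrix surface sits: the 20%-coverage crossing of the
# generating profile (the same convention the layer partition uses)
surface_plane_of <- function(params) {
  k <- which(params$z_profile >= 0.2)[1]
  if (is.na(k)) 1L else as.integer(k)
}

#' Simulate a fixed-field time course (days 0/7/10)
#'
#' Emulates repeated imaging of the same preselected field over the culture
#' period: the geometry (fibers, clusters, nuclei) is generated once from
#' `params$seed`, the phenotype effect is applied at the per-day scaling
#' factors (day 0 is always unremodeled), and fresh noise is drawn per day.
#'
#' @param params A [sim_params()]; `params$timepoints` and
#'   `params$effect_scaling` define the schedule (scaling must be
#'   non-decreasing over days).
#' @return List with one element per day:
#'   `list(day = <numeric>, stack = ImageStack, truth = GroundTruth)`.
#' @export
simulate_timecourse <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!length(params$timepoints))
    stop("timepoints must be non-empty", call. = FALSE)
  if (any(diff(params$effect_scaling) < 0))
    stop("effect_scaling must be non-decreasing over days", call. = FALSE)
  base <- with_seed(params$seed, sim_clean_stack(params))
  out <- vector("list", length(params$timepoints))
  for (i in seq_along(params$timepoints)) {
    s <- params$effect_scaling[i]
    stack <- base$stack
    if (params$phenotype != "none" && s > 0) {
      f_day <- if (params$phenotype == "degrader")
        1 - (1 - params$effect_size) * s
      else
        1 + (params$effect_size - 1) * s
      stack <- apply_remodeling(stack, base$truth,
                                phenotype = params$phenotype,
                                effect_size = f_day,
                                apical_fraction = params$apical_fraction,
                                conservation_fraction = params$conservation_fraction,
                                annulus_width_um = params$annulus_width_um,
                                depth_floor = params$depth_floor,
                                surface_plane = surface_plane_of(params))
    }
    stack <- add_noise(stack, params$noise_sd, params$seed + 77003L + 101L * i)
    out[[i]] <- list(day = params$timepoints[i], stack = stack,
                     truth = base$truth)
  }
  out
}
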