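# Brute-force oracles and small fixtures shared across the suite.
# Every oracle is a direct, loop-level restatement of the definition,
# independent of the implementation it checks.

# Desk-scale simulation fixture: 96x96 px, 8 planes. Fast (~0.2 s) while
# keeping the full depth structure (taper, carpet, clusters).
small_params <- function(seed = 1, phenotype = "none",
                         cluster_radius_px = 18, ...) {
  sim_params(field_shape = c(96, 96), n_planes = 8,
             z_profile = default_z_profile(8),
             n_clusters = 2, cluster_radius_px = cluster_radius_px,
             n_nuclei_per_cluster = 8, nucleus_sigma_px = c(4, 3),
             phenotype = phenotype, seed = seed, ...)
}

small_segment <- function(scaled) {
  segment_cell_region(max_projection(scaled, "nuclei"),
                      min_blob_area = 15,
                      pixel_size_um = scaled$pixel_size_um)
}

# random valid raw stack (integer intensities) for I/O tests
random_stack <- function(ny = 16, nx = 12, nz = 3, max_int = 225, seed = 1) {
  set.seed(seed)
  mk <- function() array(sample(0:max_int, ny * nx * nz, replace = TRUE),
                         c(ny, nx, nz))
  image_stack(list(nuclei = mk(), fibronectin = mk(), tmp = mk()))
}

oracle_area_ratio <- function(img, mask, thr = 90) {
  n_high <- 0L; n_low <- 0L
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (!mask[i, j]) next
    if (img[i, j] >= thr) n_high <- n_high + 1L else n_low <- n_low + 1L
  }
  n_high / n_low
}

oracle_max_projection <- function(arr, planes) {
  out <- matrix(-Inf, dim(arr)[1], dim(arr)[2])
  for (i in seq_len(dim(arr)[1])) for (j in seq_len(dim(arr)[2]))
    for (z in planes) out[i, j] <- max(out[i, j], arr[i, j, z])
  out
}

oracle_reslice <- function(arr, rows) {
  nz <- dim(arr)[3]; nx <- dim(arr)[2]
  out <- matrix(-Inf, nz, nx)
  for (z in seq_len(nz)) for (j in seq_len(nx))
    for (i in rows) out[z, j] <- max(out[z, j], arr[i, j, z])
  out
}

# definitional BH step-up: sort ascending, adj_(k) = min_{j>=k} m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, m * p[o[j]] / j)
    adj_sorted[k] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

oracle_anova_F <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}
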