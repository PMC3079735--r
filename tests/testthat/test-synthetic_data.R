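test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_matrix_stack(small_params(seed = 9, phenotype = "degrader"))
  b <- simulate_matrix_stack(small_params(seed = 9, phenotype = "degrader"))
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cell_mask, b$truth$cell_mask)
  c <- simulate_matrix_stack(small_params(seed = 10, phenotype = "degrader"))
  expect_false(identical(a$stack$channels$fibronectin,
                         c$stack$channels$fibronectin))
})

test_that("without remodeling the texture is the same inside and outside clusters", {
  # dense carpet planes: the tightest case for the <2% homogeneity bound
  p <- small_params(seed = 4, noise_sd = 0)
  p$n_planes <- 4; p$z_profile <- rep(1, 4)
  sim <- simulate_matrix_stack(p)
  m <- sim$truth$cell_mask
  for (z in 1:4) {
    pl <- sim$stack$channels$fibronectin[, , z]
    expect_lt(abs(mean(pl[m]) / mean(pl[!m]) - 1), 0.02)
  }
})

test_that("per-plane stain-positive fractions track the requested z-profile", {
  zp <- c(0.1, 0.25, 0.6, 1.0)
  fracs <- sapply(1:12, function(s) {
    p <- small_params(seed = 40 + s, noise_sd = 0)
    p$n_planes <- 4; p$z_profile <- zp
    st <- simulate_matrix_stack(p)$stack
    sapply(1:4, function(z) mean(st$channels$fibronectin[, , z] >= 30))
  })
  expect_true(all(abs(rowMeans(fracs) - zp) <= 0.03))
})

test_that("effect size 1 is the identity for both phenotypes", {
  p <- small_params(seed = 12)
  clean <- simulate_matrix_stack(p)
  for (ph in c("degrader", "accumulator")) {
    rem <- apply_remodeling(clean$stack, clean$truth, ph, effect_size = 1,
                            apical_fraction = 0.25)
    expect_identical(rem$channels, clean$stack$channels)
  }
})

test_that("uniform-depth degrader scales the masked region exactly by f", {
  p <- small_params(seed = 13, noise_sd = 0)
  clean <- simulate_matrix_stack(p)
  m <- clean$truth$cell_mask
  rem <- apply_remodeling(clean$stack, clean$truth, "degrader",
                          effect_size = 0.5, depth_floor = 1)
  for (z in seq_len(p$n_planes)) {
    pre <- clean$stack$channels$tmp[, , z]
    post <- rem$channels$tmp[, , z]
    expect_equal(mean(post[m]), 0.5 * mean(pre[m]), tolerance = 1e-12)
    expect_identical(post[!m], pre[!m])
  }
  expect_identical(rem$channels$nuclei, clean$stack$channels$nuclei)
})

test_that("a fully conservative accumulator preserves the channel total", {
  p <- small_params(seed = 14, noise_sd = 0)
  clean <- simulate_matrix_stack(p)
  pre <- sum(clean$stack$channels$fibronectin)
  rem <- apply_remodeling(clean$stack, clean$truth, "accumulator",
                          effect_size = 2, apical_fraction = 0,
                          conservation_fraction = 1, depth_floor = 1)
  expect_lt(abs(sum(rem$channels$fibronectin) - pre) / pre, 1e-6)
  # apical deposition is also drawn from the annulus when conserving
  rem2 <- apply_remodeling(clean$stack, clean$truth, "accumulator",
                           effect_size = 2, apical_fraction = 0.3,
                           conservation_fraction = 1, depth_floor = 1)
  expect_lt(abs(sum(rem2$channels$fibronectin) - pre) / pre, 1e-6)
  # partial conservation creates net signal
  rem3 <- apply_remodeling(clean$stack, clean$truth, "accumulator",
                           effect_size = 2, apical_fraction = 0,
                           conservation_fraction = 0.5, depth_floor = 1)
  expect_gt(sum(rem3$channels$fibronectin), pre)
})

test_that("the two phenotypes move the masked mean in opposite directions", {
  for (s in 1:4) {
    p <- small_params(seed = 20 + s)
    clean <- simulate_matrix_stack(p)
    m <- clean$truth$cell_mask
    zs <- 3 # surface plane of the 8-plane default profile
    base <- mean(clean$stack$channels$tmp[, , zs][m])
    for (ph in c("degrader", "accumulator")) {
      f <- if (ph == "degrader") 0.4 else 2.5
      rem <- apply_remodeling(clean$stack, clean$truth, ph, f,
                              surface_plane = zs, depth_floor = 0.01)
      delta <- mean(rem$channels$tmp[, , zs][m]) - base
      expect_true(if (ph == "degrader") delta < 0 else delta > 0)
    }
  }
})

test_that("cluster footprints must fit inside the field", {
  expect_error(simulate_matrix_stack(small_params(cluster_radius_px = 60)),
               "exceeds the field|could not place")
  p <- small_params()
  p$cluster_centers <- list(c(5, 48)) # radius 18 disk crosses the border
  expect_error(simulate_matrix_stack(p), "exceeds the field")
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(phenotype = "degrader", effect_size = 1.5), "0, 1")
  expect_error(sim_params(phenotype = "accumulator", effect_size = 0.5), ">= 1")
  expect_error(sim_params(n_planes = 4, z_profile = c(0.5, 0.4, 0.8, 1)),
               "non-decreasing")
  expect_error(sim_params(n_planes = 4, z_profile = c(0.5, 1.2, 1, 1)),
               "0, 1")
  expect_error(sim_params(effect_scaling = c(0, 1, 0.5)), "non-decreasing")
  # identity boundary is legal for factor sweeps
  expect_s3_class(sim_params(phenotype = "degrader", effect_size = 1),
                  "SimulationParams")
})

test_that("time courses scale the effect monotonically on a fixed field", {
  p <- small_params(seed = 31, phenotype = "degrader")
  tc <- simulate_timecourse(p)
  expect_equal(vapply(tc, function(e) e$day, 0), c(0, 7, 10))
  m <- tc[[1]]$truth$cell_mask
  mm <- vapply(tc, function(e) mean(e$stack$channels$tmp[, , 3][m]), 0)
  expect_true(all(diff(mm) < 0))
  p2 <- small_params(seed = 31, phenotype = "accumulator")
  mm2 <- vapply(simulate_timecourse(p2),
                function(e) mean(e$stack$channels$tmp[, , 3][m]), 0)
  expect_true(all(diff(mm2) > 0))
  # day-0 stack carries no effect: matches the phenotype-free simulation up
  # to the day-specific noise draw
  p0 <- small_params(seed = 31)
  ref <- simulate_matrix_stack(p0)$stack$channels$tmp[, , 3]
  expect_lt(abs(mean(tc[[1]]$stack$channels$tmp[, , 3]) - mean(ref)), 1)
  p3 <- small_params(seed = 31, phenotype = "degrader",
                     timepoints = 0, effect_scaling = 0)
  expect_length(simulate_timecourse(p3), 1)
})
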