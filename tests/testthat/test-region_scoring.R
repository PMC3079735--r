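test_that("area_ratio matches its definition, boundary and smoothing rules", {
  img <- matrix(10, 10, 10)
  img[1:4, ] <- 200 # 40 px high, 60 px low
  mask <- matrix(TRUE, 10, 10)
  expect_equal(as.numeric(area_ratio(img, mask)), 40 / 60)
  # the lower bound of the high bin is closed: 90 counts as high
  img90 <- matrix(c(90, 89.999), 2, 2)
  r <- area_ratio(img90, matrix(TRUE, 2, 2))
  expect_equal(attr(r, "n_high"), 2L)
  # all-high region with smoothing: (n + 0.5) / 0.5
  hi <- matrix(150, 5, 5)
  expect_equal(as.numeric(area_ratio(hi, matrix(TRUE, 5, 5), smoothing = "on")),
               25.5 / 0.5)
  s <- area_ratio(hi, matrix(TRUE, 5, 5), smoothing = "auto")
  expect_true(attr(s, "smoothing_applied"))
  expect_error(area_ratio(hi, matrix(TRUE, 5, 5), smoothing = "off"), "empty")
  expect_error(area_ratio(img, matrix(FALSE, 10, 10)), "empty mask")
})

test_that("area_ratio equals brute-force pixel enumeration on random images", {
  set.seed(71)
  for (i in 1:30) {
    img <- matrix(runif(64 * 64, 0, 225), 64, 64)
    mask <- matrix(runif(64 * 64) < 0.5, 64, 64)
    expect_identical(as.numeric(area_ratio(img, mask, smoothing = "off")),
                     oracle_area_ratio(img, mask))
  }
})

test_that("remodeling_score is 100 for identical regions and scales as a ratio", {
  # two regions with pixel-for-pixel identical intensity composition
  half <- matrix(runif(50 * 100, 0, 225), 50, 100)
  img <- rbind(half, half)
  region <- structure(list(
    cell_mask = rbind(matrix(TRUE, 50, 100), matrix(FALSE, 50, 100)),
    devoid_mask = rbind(matrix(FALSE, 50, 100), matrix(TRUE, 50, 100)),
    provenance = "auto"), class = "RegionMask")
  sc <- remodeling_score(img, region)
  expect_equal(sc$score_percent, 100)
  # ratio_cell 0.25 vs ratio_devoid 0.5 -> 50
  img2 <- img
  img2[region$cell_mask] <- rep(c(200, 10, 10, 10, 10), length.out = 5000)
  img2[region$devoid_mask] <- rep(c(200, 10, 10), length.out = 5000)
  sc2 <- remodeling_score(img2, region)
  expect_equal(sc2$ratio_cell, (1000) / (4000))
  expect_equal(sc2$ratio_devoid, round(5000 / 3) / (5000 - round(5000 / 3)))
  expect_equal(sc2$score_percent, 100 * sc2$ratio_cell / sc2$ratio_devoid)
  # pixel-replication upsampling leaves the score unchanged
  up <- img2[rep(1:100, each = 2), rep(1:100, each = 2)]
  region_up <- structure(list(
    cell_mask = region$cell_mask[rep(1:100, each = 2), rep(1:100, each = 2)],
    devoid_mask = region$devoid_mask[rep(1:100, each = 2), rep(1:100, each = 2)],
    provenance = "auto"), class = "RegionMask")
  expect_equal(remodeling_score(up, region_up)$score_percent,
               sc2$score_percent)
})

test_that("segmentation requires nuclei and encloses solid clumps", {
  blank <- matrix(0, 64, 64)
  expect_error(segment_cell_region(blank), "no nuclei")
  disk <- matrix(0, 64, 64)
  cy <- 32; cx <- 32
  for (i in 1:64) for (j in 1:64)
    if ((i - cy)^2 + (j - cx)^2 <= 10^2) disk[i, j] <- 200
  reg <- segment_cell_region(disk, min_blob_area = 20, pixel_size_um = 1)
  in_disk <- (row(disk) - cy)^2 + (col(disk) - cx)^2 <= 10^2
  expect_true(all(reg$cell_mask[in_disk]))        # mask contains the disk
  expect_true(!any(reg$devoid_mask & in_disk))    # devoid excludes it
  expect_true(!any(reg$cell_mask & reg$devoid_mask))
})

test_that("automated masks recover the simulated cluster footprint", {
  jac <- sapply(1:5, function(s) {
    sim <- simulate_matrix_stack(sim_params(seed = 80 + s))
    sc <- rescale_to_225(sim$stack)
    reg <- segment_cell_region(max_projection(sc, "nuclei"),
                               pixel_size_um = sc$pixel_size_um)
    sum(reg$cell_mask & sim$truth$cell_mask) /
      sum(reg$cell_mask | sim$truth$cell_mask)
  })
  expect_gte(mean(jac), 0.7)
})

test_that("manual polygon tracing produces an equivalent region mask", {
  poly <- data.frame(x = c(10, 30, 30, 10), y = c(10, 10, 25, 25))
  reg <- polygon_region(list(poly), field_shape = c(48, 48),
                        buffer_um = 2, pixel_size_um = 1)
  expect_identical(reg$provenance, "manual-polygon")
  expect_true(reg$cell_mask[15, 20])
  expect_false(reg$cell_mask[40, 40])
  expect_false(any(reg$cell_mask & reg$devoid_mask))
  expect_false(reg$devoid_mask[26, 20]) # inside the buffer ring
  expect_true(reg$devoid_mask[40, 40])
})

test_that("phenotype classification follows the neutral band around 100", {
  mk <- function(top) data.frame(layer = c("top", "bottom"),
                                 channel = "fibronectin",
                                 score_percent = c(top, 100))
  expect_equal(classify_phenotype(mk(100), delta = 1)$label, "neutral")
  expect_equal(classify_phenotype(mk(100), delta = 60)$label, "neutral")
  # the two reported top-layer fibronectin anchors split correctly
  expect_equal(classify_phenotype(mk(28))$label, "degrader")
  expect_equal(classify_phenotype(mk(244))$label, "accumulator")
  expect_error(classify_phenotype(
    data.frame(layer = "bottom", channel = "tmp", score_percent = 50)),
    "top")
})

test_that("normalization maps the untreated bottom layer to exactly 100", {
  ctrl <- data.frame(channel = "tmp", layer = c("top", "bottom", "bottom"),
                     score_percent = c(80, 90, 110))
  out <- normalize_to_control(ctrl, ctrl)
  expect_equal(mean(out$score_norm[out$layer == "bottom"]), 100)
  one <- data.frame(channel = "tmp", layer = "top", score_percent = 50)
  ctrl2 <- data.frame(channel = "tmp", layer = "bottom", score_percent = 100)
  expect_equal(normalize_to_control(one, ctrl2)$score_norm, 50)
  # normalization preserves ordering
  set.seed(91)
  sc <- data.frame(channel = "tmp", layer = "top",
                   score_percent = runif(20, 10, 300))
  nn <- normalize_to_control(sc, ctrl2)
  expect_equal(order(nn$score_norm), order(sc$score_percent))
  expect_error(normalize_to_control(one, one), "bottom")
})

test_that("score_stack emits one score per layer and channel", {
  sim <- simulate_matrix_stack(small_params(seed = 95))
  sc <- rescale_to_225(sim$stack)
  s <- score_stack(sc, region = small_segment(sc))
  expect_equal(nrow(s), 6)
  expect_setequal(unique(s$layer), c("top", "middle", "bottom"))
  expect_setequal(unique(s$channel), c("fibronectin", "tmp"))
  expect_true(all(s$score_percent > 0))
})

test_that("timelapse trajectories separate the phenotypes and flag no change", {
  region <- structure(list(
    cell_mask = rbind(matrix(TRUE, 4, 8), matrix(FALSE, 4, 8)),
    devoid_mask = rbind(matrix(FALSE, 4, 8), matrix(TRUE, 4, 8)),
    provenance = "auto"), class = "RegionMask")
  cst <- lapply(c(0, 7, 10), function(d) list(day = d, image = matrix(50, 8, 8)))
  tl <- timelapse_change(cst, region)
  expect_true(all(tl$pct_change[!is.na(tl$pct_change)] == 0))
  expect_error(timelapse_change(cst[1], region), "two days")
  bad <- cst; bad[[2]]$image <- matrix(50, 9, 8)
  expect_error(timelapse_change(bad, region), "mismatched")
  # simulated degrader series: strictly decreasing cell-region trajectory
  p <- small_params(seed = 33, phenotype = "degrader")
  tc <- simulate_timecourse(p)
  reg2 <- structure(list(cell_mask = tc[[1]]$truth$cell_mask,
                         devoid_mask = !tc[[1]]$truth$cell_mask,
                         provenance = "auto"), class = "RegionMask")
  # widefield-like field image: depth-integrated (mean over z) intensity
  series <- lapply(tc, function(e)
    list(day = e$day, image = apply(e$stack$channels$tmp, c(1, 2), mean)))
  tl2 <- timelapse_change(series, reg2)
  cell_traj <- tl2$mean_intensity[tl2$region == "cell"]
  expect_true(all(diff(cell_traj) < 0))
  # matrices without cells do not change over time
  p0 <- small_params(seed = 33)
  s0 <- lapply(simulate_timecourse(p0), function(e)
    list(day = e$day, image = apply(e$stack$channels$tmp, c(1, 2), mean)))
  tl0 <- timelapse_change(s0, reg2)
  expect_true(all(abs(tl0$pct_change[!is.na(tl0$pct_change)]) < 2))
})
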