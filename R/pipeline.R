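# End-to-end orchestration: simulate or read stacks, partition, segment,
# score, classify, test, and render a figure-style report.

#' Pipeline configuration
#'
#' Collects every tunable of one reproducible run. All thresholds are on the
#' 0-225 scale; the seed is recorded in every output.
#'
#' @param preset Simulation preset standing in for an imaging experiment:
#'   `"null"` (no remodeling), `"ovcar5_like"` (degrader, effect 0.3) or
#'   `"ovcar10_like"` (accumulator, effect 3); ignored when `input_paths` is
#'   given.
#' @param input_paths Optional character vector of multi-page TIFF paths to
#'   analyze instead of simulating; read via [read_stack()] with
#'   `channel_map`.
#' @param channel_map Channel-to-page assignment for [read_stack()].
#' @param n_fields Number of fields (replicate stacks) to simulate.
#' @param seed Integer seed; field `i` uses `seed + i`.
#' @param detection_threshold Stain-positive cutoff for layering (0-225).
#' @param high_range High-intensity scoring bin, default `c(90, 225)`.
#' @param full_coverage Coverage fraction treated as full field.
#' @param scale_range Fixed raw range mapped to 0-225, shared by all stacks
#'   of the run.
#' @param min_blob_area,dilation_radius_um,buffer_um Segmentation parameters.
#' @param delta Neutral margin for [classify_phenotype()].
#' @param alpha_sig,alpha_fdr Statistics cutoffs.
#' @param sim Optional [sim_params()] overriding the preset's simulation
#'   parameters (its `phenotype`/`effect_size` still follow the preset).
#' @param out_dir Output directory.
#' @return A `RunConfig` list.
#' @export
run_config <- function(preset = c("null", "ovcar5_like", "ovcar10_like"),
                       input_paths = NULL,
                       channel_map = list(nuclei = 1, fibronectin = 2, tmp = 3),
                       n_fields = 5, seed = 1,
                       detection_threshold = 30,
                       high_range = c(90, 225),
                       full_coverage = 0.995,
                       scale_range = c(0, 225),
                       min_blob_area = 40, dilation_radius_um = 5,
                       buffer_um = 10,
                       delta = ECM_DELTA_DEFAULT,
                       alpha_sig = 0.01, alpha_fdr = 0.05,
                       sim = NULL, out_dir = tempfile("ecmscore_run_")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

preset_params <- function(preset, seed, sim = NULL) {
  base <- if (is.null(sim)) sim_params(seed = seed) else sim
  base$seed <- seed
  switch(preset,
         null = { base$phenotype <- "none"; base$effect_size <- 1 },
         ovcar5_like = { base$phenotype <- "degrader"; base$effect_size <- 0.3 },
         ovcar10_like = { base$phenotype <- "accumulator"; base$effect_size <- 3 })
  base
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

score_one_field <- function(stack, config, field_id) {
  scaled <- rescale_to_225(stack, mode = "fixed", range = config$scale_range)
  layers <- detect_layers(scaled,
                          positive_threshold = config$detection_threshold,
                          full_coverage = config$full_coverage)
  region <- segment_cell_region(max_projection(scaled, "nuclei"),
                                min_blob_area = config$min_blob_area,
                                dilation_radius_um = config$dilation_radius_um,
                                buffer_um = config$buffer_um,
                                pixel_size_um = scaled$pixel_size_um)
  scores <- score_stack(scaled, layers, region,
                        high_range = config$high_range)
  scores <- cbind(data.frame(field = field_id), scores)
  list(scores = scores, layers = layers, region = region, scaled = scaled)
}

#' Run the full scoring pipeline
#'
#' Simulates (or reads) the configured fields, rescales them onto the 0-225
#' scale with the run's shared fixed range, partitions each into layers,
#' segments cell vs devoid regions, scores every layer and channel, and
#' classifies the per-field and consensus phenotype. Writes `scores.csv`,
#' `phenotype.json`, `run_config.json` and `run.log` into `out_dir`;
#' deterministic given the seed (re-running the same config yields
#' byte-identical CSVs).
#'
#' @param config A [run_config()].
#' @return Invisibly, a result bundle: `scores` (data.frame), `calls`
#'   (per-field `PhenotypeCall`s), `consensus` label, `fields` (per-field
#'   layers/region/scaled stack), `config`, `hash`, and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("ecmscore run | config hash %s | seed %d",
                         hash, config$seed))
  fields <- list()
  all_scores <- list()
  if (!is.null(config$input_paths)) {
    for (i in seq_along(config$input_paths)) {
      stack <- read_stack(config$input_paths[i], config$channel_map)
      fields[[i]] <- score_one_field(stack, config, i)
    }
  } else {
    for (i in seq_len(config$n_fields)) {
      p <- preset_params(config$preset, seed = config$seed + i, sim = config$sim)
      stack <- simulate_matrix_stack(p)$stack
      fields[[i]] <- score_one_field(stack, config, i)
    }
  }
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    all_scores[[i]] <- f$scores
    log_lines <- c(log_lines, sprintf(
      "field %d | layers top=%s middle=%s bottom=%s%s | cell px=%d devoid px=%d | smoothing=%s",
      i,
      paste(f$layers$top, collapse = ","),
      paste(f$layers$middle, collapse = ","),
      paste(f$layers$bottom, collapse = ","),
      if (f$layers$bottom_fallback) " (fallback)" else "",
      sum(f$region$cell_mask), sum(f$region$devoid_mask),
      paste(f$scores$smoothing_applied, collapse = ",")))
  }
  scores <- do.call(rbind, all_scores)
  calls <- lapply(fields, function(f)
    classify_phenotype(f$scores, delta = config$delta))
  labels <- vapply(calls, function(x) x$label, "")
  consensus <- names(sort(table(labels), decreasing = TRUE))[1]
  paths <- list(
    scores = file.path(config$out_dir, "scores.csv"),
    phenotype = file.path(config$out_dir, "phenotype.json"),
    config = file.path(config$out_dir, "run_config.json"),
    log = file.path(config$out_dir, "run.log"))
  utils::write.csv(format(scores, digits = 10, trim = TRUE, scientific = FALSE),
                   paths$scores, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed, consensus = consensus,
         fields = lapply(seq_along(calls), function(i)
           list(field = i, label = calls[[i]]$label,
                top_score = calls[[i]]$top_score, delta = calls[[i]]$delta))),
    paths$phenotype, auto_unbox = TRUE, digits = NA)
  cfg_out <- unclass(config)
  cfg_out$sim <- if (!is.null(cfg_out$sim)) unclass(cfg_out$sim) else NULL
  jsonlite::write_json(c(list(config_hash = hash), cfg_out), paths$config,
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, paths$log)
  invisible(list(scores = scores, calls = calls, consensus = consensus,
                 fields = fields, config = config, hash = hash, paths = paths))
}

#' 226-level pseudo-color map for the 0-225 scale
#'
#' Discrete colormap with one color per intensity level: blue/black for low
#' intensities through red and white for the highest.
#'
#' @return Character vector of 226 colors (levels 0..225).
#' @export
intensity_colormap <- function() {
  grDevices::colorRampPalette(c("black", "#00004B", "blue", "red",
                                "white"))(226)
}

#' Render a projection as a pseudo-colored RGB array
#'
#' @param projection 2D image on the 0-225 scale.
#' @param outline Optional logical mask whose boundary is overlaid in green
#'   (typically the cell region).
#' @return `(y, x, 3)` array in `[0, 1]`, ready for [png::writePNG()].
#' @export
pseudocolor <- function(projection, outline = NULL) {
  lv <- pmin(pmax(round(projection), 0), 225)
  cmap <- grDevices::col2rgb(intensity_colormap()) / 255
  rgb <- array(0, c(nrow(lv), ncol(lv), 3))
  for (k in 1:3) rgb[, , k] <- matrix(cmap[k, lv + 1], nrow(lv), ncol(lv))
  if (!is.null(outline)) {
    er <- EBImage::erode(EBImage::Image(outline * 1),
                         EBImage::makeBrush(3, "box")) > 0.5
    edge <- outline & !er
    for (k in 1:3) {
      pl <- rgb[, , k]; pl[edge] <- c(0, 1, 0)[k]; rgb[, , k] <- pl
    }
  }
  rgb
}

#' Render a figure-style report for a pipeline run
#'
#' Writes one pseudo-colored PNG per (field, layer, channel) projection with
#' the cell-region outline overlaid, plus an `index.html` that embeds the
#' images and the score table (the same values as `scores.csv`).
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory; defaults to the run's.
#' @return Invisibly, the paths of the written files.
#' @export
render_report <- function(bundle, out_dir = bundle$config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img_paths <- character()
  for (i in seq_along(bundle$fields)) {
    f <- bundle$fields[[i]]
    for (layer in c("top", "middle", "bottom")) {
      for (ch in unique(bundle$scores$channel)) {
        proj <- max_projection(f$scaled, ch, f$layers[[layer]])
        p <- file.path(out_dir, sprintf("field%d_%s_%s.png", i, layer, ch))
        png::writePNG(pseudocolor(proj, f$region$cell_mask), p)
        img_paths <- c(img_paths, p)
      }
    }
  }
  tab <- bundle$scores
  html <- c("<html><head><title>ECM remodeling report</title></head><body>",
            sprintf("<h1>ECM remodeling report</h1><p>config hash %s, consensus phenotype: <b>%s</b></p>",
                    bundle$hash, bundle$consensus),
            "<h2>Scores</h2><table border='1'><tr>",
            paste0("<th>", names(tab), "</th>", collapse = ""), "</tr>")
  for (r in seq_len(nrow(tab)))
    html <- c(html, paste0("<tr>", paste0("<td>",
      vapply(tab[r, ], function(v) format(v, digits = 8), ""),
      "</td>", collapse = ""), "</tr>"))
  html <- c(html, "</table><h2>Layer projections</h2>",
            sprintf("<p><img src='%s' title='%s'/></p>",
                    basename(img_paths), basename(img_paths)),
            "</body></html>")
  index <- file.path(out_dir, "index.html")
  writeLines(html, index)
  invisible(list(images = img_paths, index = index))
}
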