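# Image and table IO plus the end-to-end pipeline driver. Images travel as
# 8-bit single-channel PNG/TIFF with the mm calibration in a JSON sidecar
# `<image>.meta.json` (keys: px_per_mm, descriptor, seed), since neither
# format carries a reliable physical-scale tag.

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a skin image with its calibration sidecar
#'
#' Writes the 8-bit raster as PNG or TIFF (by file extension) and the
#' calibration/provenance metadata to `<image>.meta.json`.
#'
#' @param image a [skin_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_skin_image <- function(image, path) {
  stopifnot(inherits(image, "skin_image"))
  g <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(g, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(g, path, bits.per.sample = 8L)
  } else {
    cm_stop(sprintf("unsupported image extension '.%s' (use png/tif/tiff).",
                    ext), "cm_invalid_parameter")
  }
  meta <- c(list(px_per_mm = image$px_per_mm), image$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a skin image
#'
#' Reads an 8-bit single-channel PNG or TIFF and its calibration. Calibration
#' comes from the `<image>.meta.json` sidecar when present, else from the
#' `px_per_mm` argument; with neither, an error explains the sidecar
#' convention. Multi-channel input is converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B) with a warning; deeper-than-8-bit input
#' is rescaled so that full scale maps to 255, with a warning.
#'
#' @param path image path.
#' @param px_per_mm calibration override (used when no sidecar exists).
#' @return a [skin_image]; sidecar metadata is carried in `$meta`.
#' @export
read_skin_image <- function(path, px_per_mm = NULL) {
  if (!file.exists(path))
    cm_stop(sprintf("no such image: %s", path), "cm_invalid_input")
  ext <- tolower(tools::file_ext(path))
  g <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else cm_stop(sprintf("unsupported image extension '.%s'.", ext),
               "cm_invalid_input")
  # depth check on the stored channels, before any channel mixing
  if (max(abs(g * 255 - round(g * 255))) > 1e-6)
    warning("image depth exceeds 8 bits; rescaled so full scale maps to 255.")
  if (length(dim(g)) == 3) {
    ch <- dim(g)[3]
    if (ch >= 3) {
      warning("multi-channel image converted to luminance.")
      g <- 0.2126 * g[, , 1] + 0.7152 * g[, , 2] + 0.0722 * g[, , 3]
    } else {
      g <- g[, , 1]
    }
  }
  px255 <- g * 255
  px <- clip8(round_half_away(px255))
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    px_per_mm <- px_per_mm %||% meta$px_per_mm
  }
  if (is.null(px_per_mm))
    cm_stop(sprintf(
      paste("no calibration for %s: supply `px_per_mm` or provide a",
            "`%s` sidecar with a px_per_mm key."), path, sc),
      "cm_missing_calibration")
  skin_image(px, px_per_mm, meta = meta[setdiff(names(meta), "px_per_mm")])
}

#' Pipeline configuration
#'
#' One document describing a full synthetic run: which surfaces to render,
#' how to score them, and the trial simulation/analysis settings. Serializes
#' losslessly to YAML via [save_pipeline_config] / [load_pipeline_config].
#'
#' @param seed master seed; stage seeds derive from it deterministically.
#' @param surfaces list of surface descriptions, each a list with `name`,
#'   `type` ("flat", "sinusoid" or "dimples") and type-specific parameters
#'   (`amplitude_mm`, `wavelength_mm`, `orientation_deg`, `n_dimples`, ...).
#' @param px_per_mm render calibration; default 10.
#' @param noise_sd render sensor noise SD in grey levels; default 2.
#' @param score list of [score_params] arguments.
#' @param trial list of [trial_config] arguments.
#' @param stages character vector of stages to run, in order, from
#'   `c("images", "score", "trial", "analyze")`.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L,
                            surfaces = list(
                              list(name = "flat", type = "flat"),
                              list(name = "ridges", type = "sinusoid",
                                   amplitude_mm = 0.2, wavelength_mm = 10,
                                   orientation_deg = 0),
                              list(name = "dimples", type = "dimples",
                                   n_dimples = 40)),
                            px_per_mm = 10, noise_sd = 2,
                            score = list(), trial = list(),
                            stages = c("images", "score", "trial",
                                       "analyze")) {
  bad <- setdiff(stages, c("images", "score", "trial", "analyze"))
  if (length(bad))
    cm_stop(paste("unknown stage(s):", paste(bad, collapse = ", ")),
            "cm_config_error")
  structure(list(seed = as.integer(seed), surfaces = surfaces,
                 px_per_mm = px_per_mm, noise_sd = noise_sd,
                 score = score, trial = trial, stages = stages),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML has no empty-vector type: `[]` comes back as list(), which the
  # config treats as an empty numeric (e.g. no withdrawal weeks)
  fix_empty <- function(x) {
    if (is.list(x) && length(x) == 0) return(numeric(0))
    if (is.list(x) && is.null(names(x)) == FALSE)
      return(lapply(x, fix_empty))
    x
  }
  raw$trial <- fix_empty(raw$trial %||% list())
  raw$score <- fix_empty(raw$score %||% list())
  if (length(raw$trial) == 0) raw$trial <- list()
  if (length(raw$score) == 0) raw$score <- list()
  do.call(pipeline_config, raw)
}

build_surface <- function(sp, extent_mm, grid_spacing_mm, seed) {
  switch(sp$type,
    flat = make_flat_field(extent_mm, grid_spacing_mm),
    sinusoid = make_undulation_field(
      amplitude_mm = sp$amplitude_mm %||% 0.2,
      wavelength_mm = sp$wavelength_mm %||% 10,
      orientation_deg = sp$orientation_deg %||% 0,
      phase_rad = sp$phase_rad %||% 0,
      extent_mm = extent_mm, grid_spacing_mm = grid_spacing_mm),
    dimples = make_dimple_field(
      n_dimples = sp$n_dimples %||% 40,
      depth_mm_range = sp$depth_mm_range %||% c(0.3, 0.8),
      radius_mm_range = sp$radius_mm_range %||% c(3, 8),
      extent_mm = extent_mm, grid_spacing_mm = grid_spacing_mm,
      seed = seed),
    cm_stop(sprintf("unknown surface type '%s'.", sp$type),
            "cm_config_error"))
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order — render synthetic images, score
#' them, simulate a trial, analyse it — writing all artifacts under
#' `out_dir`: `images/*.png` (+ sidecars), `scores.csv`, `trial.csv`,
#' `ledger.csv`, `grades.csv`, `likert.csv` and `results.json`. Runs are
#' deterministic for a fixed config, so a second run reproduces the artifacts
#' bit for bit.
#'
#' @param config a [pipeline_config] or path to its YAML form.
#' @param out_dir output directory (created if needed).
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  sp <- do.call(score_params, config$score)
  extent <- c(sp$n_rois * sp$roi_width_mm + 4, sp$roi_height_mm + 4)
  images <- list()

  if ("images" %in% config$stages) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_along(config$surfaces)) {
      spf <- config$surfaces[[i]]
      field <- build_surface(spf, extent, 1 / config$px_per_mm,
                             seed = config$seed + i)
      img <- render_image(field, illumination_model(),
                          px_per_mm = config$px_per_mm,
                          noise_sd = config$noise_sd,
                          seed = config$seed + 100L + i)
      p <- file.path(img_dir, paste0(spf$name, ".png"))
      write_skin_image(img, p)
      images[[spf$name]] <- img
      artifacts[[paste0("image_", spf$name)]] <- p
    }
  }

  if ("score" %in% config$stages && length(images)) {
    scores <- do.call(rbind, lapply(names(images), function(nm) {
      sc <- score_image(images[[nm]], region_origin_mm = c(2, 2), params = sp)
      data.frame(image_id = nm, total = sc$total,
                 t(stats::setNames(sc$roi_scores,
                                   sprintf("roi%02d", seq_along(sc$roi_scores)))))
    }))
    p <- file.path(out_dir, "scores.csv")
    utils::write.csv(scores, p, row.names = FALSE)
    artifacts$scores <- p
  }

  if ("trial" %in% config$stages) {
    tc <- do.call(trial_config, c(config$trial,
                                  if (is.null(config$trial$seed))
                                    list(seed = config$seed)))
    ds <- simulate_trial(tc)
    grades <- simulate_grades(tc, ds)
    likert <- simulate_likert(
      tc, participants = ds$ledger$participant[ds$ledger$completed])
    paths <- list(trial = ds$data, ledger = ds$ledger, grades = grades,
                  likert = likert)
    for (nm in names(paths)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(paths[[nm]], p, row.names = FALSE, na = "")
      artifacts[[nm]] <- p
    }

    if ("analyze" %in% config$stages) {
      comp <- completers(ds)
      outcomes <- names(tc$outcome_models)
      results <- list(
        summary = summarize_trial(comp),
        anova = lapply(stats::setNames(outcomes, outcomes), function(o) {
          a <- rm_anova(comp, o)
          as.data.frame(a)
        }),
        contrasts = lapply(stats::setNames(outcomes, outcomes), function(o)
          as.data.frame(baseline_contrasts(comp, o, arm = "herbal"))),
        wilcoxon = lapply(split(likert, likert$question), function(q) {
          w <- wilcoxon_signed_rank(q$herbal_score, q$placebo_score)
          unclass(w)
        }),
        grades = aggregate_grades(grades)
      )
      p <- file.path(out_dir, "results.json")
      jsonlite::write_json(results, p, auto_unbox = TRUE, digits = 10,
                           dataframe = "rows", na = "null")
      artifacts$results <- p
    }
  }
  invisible(artifacts)
}
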