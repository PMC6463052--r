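# Dataset layout on disk
#
# A phantom (or real acquisition in the same layout) is one directory:
#   meta.json                fps, frames, slice count, timing, pixel size
#   longitudinal/bmode.rds   time x depth x width array
#   longitudinal/doppler.rds
#   cross/<k>/bmode.rds      k = 001.. inlet to outlet
#   cross/<k>/doppler.rds
#   truth.rds                ground truth (phantoms only)
# Arrays are stored as R serialization; everything else is JSON.

#' Write a phantom dataset to the on-disk layout
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "longitudinal"), recursive = TRUE,
             showWarnings = FALSE)
  d <- dim(dataset$cross[[1]]$bmode$frames)
  meta <- list(
    fps = dataset$cross[[1]]$bmode$fps,
    frames_per_sequence = d[1],
    image_dim = d[2:3],
    n_slices = length(dataset$cross),
    slice_spacing_um = dataset$config$slice_spacing_um,
    pixel_size_um = dataset$config$pixel_size_um,
    beam_tilt_deg = dataset$config$beam_tilt_deg,
    period_ms_true = dataset$truth$period_ms
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(dataset$longitudinal$bmode,
          file.path(dir, "longitudinal", "bmode.rds"))
  saveRDS(dataset$longitudinal$doppler,
          file.path(dir, "longitudinal", "doppler.rds"))
  for (k in seq_along(dataset$cross)) {
    kd <- file.path(dir, "cross", sprintf("%03d", k))
    dir.create(kd, recursive = TRUE, showWarnings = FALSE)
    saveRDS(dataset$cross[[k]]$bmode, file.path(kd, "bmode.rds"))
    saveRDS(dataset$cross[[k]]$doppler, file.path(kd, "doppler.rds"))
  }
  saveRDS(dataset$truth, file.path(dir, "truth.rds"))
  saveRDS(dataset$config, file.path(dir, "config.rds"))
  invisible(dir)
}

#' Read a dataset written by [write_phantom_dataset()]
#' @param dir dataset directory.
#' @return A `phantom_dataset`.
#' @export
read_phantom_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  kd <- sort(list.dirs(file.path(dir, "cross"), recursive = FALSE))
  cross <- lapply(kd, function(p) {
    list(bmode = readRDS(file.path(p, "bmode.rds")),
         doppler = readRDS(file.path(p, "doppler.rds")))
  })
  truth <- if (file.exists(file.path(dir, "truth.rds"))) {
    readRDS(file.path(dir, "truth.rds"))
  }
  config <- if (file.exists(file.path(dir, "config.rds"))) {
    readRDS(file.path(dir, "config.rds"))
  }
  structure(list(
    longitudinal = list(
      bmode = readRDS(file.path(dir, "longitudinal", "bmode.rds")),
      doppler = readRDS(file.path(dir, "longitudinal", "doppler.rds"))
    ),
    cross = cross, truth = truth, config = config, meta = meta
  ), class = "phantom_dataset")
}

#' Export one frame of a sequence as PNG
#'
#' @param seq a `bmode_sequence` or `doppler_sequence`.
#' @param frame frame index.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_frame_png <- function(seq, frame, path) {
  img <- seq$frames[frame, , ]
  rng <- range(img)
  if (diff(rng) < 1e-12) rng <- rng + c(0, 1)
  grDevices::png(path, width = ncol(img) * 4, height = nrow(img) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                  zlim = rng, axes = FALSE, useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Write a synchronized dataset to disk
#'
#' Stores the normalized-cycle volume and Doppler arrays, the phase
#' schedule and the cumulative-phase diagnostics.
#'
#' @param synced a `synced_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synced_dataset <- function(synced, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(synced, file.path(dir, "synced.rds"))
  utils::write.csv(as.data.frame(synced$schedule),
                   file.path(dir, "phase_schedule.csv"), row.names = FALSE)
  if (!is.null(synced$curve)) {
    utils::write.csv(as.data.frame(synced$curve),
                     file.path(dir, "cumulative_phase.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write a contour series as a tidy CSV table
#'
#' One row per (slice, phase) with area, centroid and closure flag; vertex
#' coordinates are stored as JSON strings so the table stays rectangular.
#'
#' @param series a `cross_section_series`.
#' @param path output CSV path.
#' @param vertices include the vertex lists (default FALSE).
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(series, path, vertices = FALSE) {
  df <- tidy.cross_section_series(series)
  if (vertices) {
    df$vertices <- vapply(seq_len(nrow(df)), function(i) {
      ct <- series$contours[[df$slice[i]]][[df$phase[i]]]
      if (is.null(ct$vertices)) "" else
        as.character(jsonlite::toJSON(round(ct$vertices, 6)))
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
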