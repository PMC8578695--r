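#' Read and write ECT images
#'
#' Format is inferred from the extension. `.csv` is a lossless
#' delimited-text matrix; `.png` (8-bit) and `.tif`/`.tiff` (16-bit)
#' store intensities scaled to the full integer range, with the original
#' `min`, `max` and `fov` recorded in a JSON sidecar (`<path>.json`) so
#' the round trip recovers physical values to within quantization.
#'
#' @param path file path ending in `.csv`, `.png`, `.tif` or `.tiff`.
#' @param image an [ect_image()].
#' @param fov field-of-view half-width used when reading a bare CSV with
#'   no sidecar.
#' @return `read_image` returns an [ect_image()]; `write_image` returns
#'   `path` invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "ect_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(format(image$data, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    sidecar <- list(fov = image$fov, format = "csv")
  } else if (ext %in% c("png", "tif", "tiff")) {
    lo <- min(image$data); hi <- max(image$data)
    scaled <- if (hi > lo) (image$data - lo) / (hi - lo) else
      matrix(0, nrow(image$data), ncol(image$data))
    if (ext == "png") {
      png::writePNG(scaled, path)
    } else {
      tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
    }
    sidecar <- list(fov = image$fov, format = ext, min = lo, max = hi)
  } else {
    stop("unknown image extension '", ext, "' (use csv, png, tif)",
         call. = FALSE)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, fov = 1.0) {
  ext <- tolower(tools::file_ext(path))
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (!is.null(sidecar$fov)) fov <- sidecar$fov
  if (ext == "csv") {
    m <- read_matrix_csv(path)
  } else if (ext %in% c("png", "tif", "tiff")) {
    raw <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    lo <- if (!is.null(sidecar$min)) sidecar$min else 0
    hi <- if (!is.null(sidecar$max)) sidecar$max else 1
    m <- raw * (hi - lo) + lo
  } else {
    stop("unknown image extension '", ext, "'", call. = FALSE)
  }
  ect_image(m, fov)
}

# Strict rectangular CSV reader: every row must have the same number of
# fields; the error names the first offending row.
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged matrix in %s: row %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    flat_bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value in %s at row %d, column %d", path,
                 (flat_bad - 1) %/% widths[1] + 1,
                 (flat_bad - 1) %% widths[1] + 1), call. = FALSE)
  }
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

#' Read and write sinograms
#'
#' The projection matrix goes to a CSV (views x detector bins); the view
#' angles, detector coordinates, and field of view go to a JSON sidecar
#' (`<path>.json`).
#'
#' @param sino an [ect_sinogram()].
#' @param path CSV file path.
#' @return `read_sinogram` returns an [ect_sinogram()]; `write_sinogram`
#'   returns `path` invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "ect_sinogram"))
  utils::write.table(format(sino$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(angles_deg = sino$angles_deg,
                            detector_coords = sino$detector_coords,
                            fov = sino$fov),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("sinogram sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  m <- read_matrix_csv(path)
  ect_sinogram(m, meta$angles_deg, meta$detector_coords, meta$fov)
}

#' Read and write gated series
#'
#' A gated series is stored as a directory of per-frame CSV images
#' (`frame_01.csv`, ...) plus `series.json` holding the gating metadata
#' (frame count, heart rate, slice thickness, ED/ES frame indices, outer
#' radius, field of view).
#'
#' @param series a `gated_series`.
#' @param dir directory path (created if needed).
#' @return `read_gated_series` returns a `gated_series`;
#'   `write_gated_series` returns `dir` invisibly.
#' @export
write_gated_series <- function(series, dir) {
  stopifnot(inherits(series, "gated_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(series$frames)) {
    write_image(series$frames[[k]],
                file.path(dir, sprintf("frame_%02d.csv", k)))
  }
  meta <- list(n_frames = length(series$frames),
               heart_rate = series$heart_rate,
               slice_thickness = series$slice_thickness,
               ed_index = series$ed_index,
               es_index = series$es_index,
               outer_radius = series$outer_radius,
               inner_radii = series$inner_radii,
               fov = series$fov)
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_gated_series
#' @export
read_gated_series <- function(dir) {
  meta_path <- file.path(dir, "series.json")
  if (!file.exists(meta_path))
    stop("series metadata not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- lapply(seq_len(meta$n_frames), function(k) {
    read_image(file.path(dir, sprintf("frame_%02d.csv", k)), fov = meta$fov)
  })
  structure(list(frames = frames,
                 inner_radii = meta$inner_radii,
                 ed_index = meta$ed_index,
                 es_index = meta$es_index,
                 heart_rate = meta$heart_rate,
                 slice_thickness = meta$slice_thickness,
                 outer_radius = meta$outer_radius,
                 fov = meta$fov),
            class = "gated_series")
}
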