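#' @title File interfaces
#' @description
#' Readers and writers for the pipeline's on-disk formats: tab-separated
#' gaze streams (Tobii-like column layout), JSON scene manifests, numbered
#' PNG frame sequences, and binary AOI masks as per-frame PNGs or as
#' polygon JSON (both readers are supported).
#' @name io
NULL

#' Read / write a gaze-stream TSV
#'
#' Columns: `timestamp_ms`, `gx_left_px`, `gy_left_px`, `gx_right_px`,
#' `gy_right_px`, `pupil_left_mm`, `pupil_right_mm`, `valid_left`,
#' `valid_right`.
#'
#' @param path File path.
#' @param samples Raw binocular sample data frame.
#' @return `read_gaze_tsv` returns the sample data frame.
#' @export
read_gaze_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "gx_left_px", "gy_left_px", "gx_right_px",
            "gy_right_px", "pupil_left_mm", "pupil_right_mm",
            "valid_left", "valid_right")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gaze TSV missing columns: ",
                         paste(miss, collapse = ", "))
  df$valid_left <- as.logical(df$valid_left)
  df$valid_right <- as.logical(df$valid_right)
  df
}

#' @rdname read_gaze_tsv
#' @export
write_gaze_tsv <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a scene manifest as JSON
#'
#' @param path File path.
#' @param manifest Manifest data frame (see [segment_scenes()]).
#' @return `read_scene_manifest` returns the manifest data frame.
#' @export
read_scene_manifest <- function(path) {
  df <- jsonlite::fromJSON(path)
  stopifnot(all(c("video", "scene", "category", "onset_ms", "offset_ms")
                %in% names(df)))
  df
}

#' @rdname read_scene_manifest
#' @export
write_scene_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write / read a frame sequence as numbered PNGs
#'
#' Frames are written as `frame_000001.png` etc., avoiding video-codec
#' nondeterminism, with a small JSON manifest carrying fps and dimensions.
#'
#' @param frames List of HxWx3 arrays in `[0, 1]`.
#' @param dir Output directory (created).
#' @param fps Frame rate recorded in the manifest.
#' @return `read_frames_png` returns `list(frames, fps)`.
#' @export
write_frames_png <- function(frames, dir, fps = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]], file.path(dir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(
    list(n_frames = length(frames), fps = fps,
         height = dim(frames[[1]])[1], width = dim(frames[[1]])[2]),
    file.path(dir, "frames.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "frames.json"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  list(frames = lapply(files, png::readPNG), fps = meta$fps)
}

#' Write / read AOI masks as per-frame PNGs
#'
#' One greyscale PNG per label per frame (`<label>_000001.png`), white
#' inside the region.
#'
#' @param aoi Per-label list of per-frame logical masks.
#' @param dir Output directory.
#' @return `read_aoi_masks_png` returns the per-label mask list.
#' @export
write_aoi_masks_png <- function(aoi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(aoi)) {
    for (i in seq_along(aoi[[lab]])) {
      m <- aoi[[lab]][[i]]
      png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)),
                    file.path(dir, sprintf("%s_%06d.png", lab, i)))
    }
  }
  invisible(dir)
}

#' @rdname write_aoi_masks_png
#' @export
read_aoi_masks_png <- function(dir) {
  files <- list.files(dir, pattern = "_\\d+\\.png$")
  labs <- unique(sub("_\\d+\\.png$", "", files))
  out <- list()
  for (lab in labs) {
    lf <- sort(files[startsWith(files, paste0(lab, "_"))])
    out[[lab]] <- lapply(lf, function(f) {
      png::readPNG(file.path(dir, f)) > 0.5
    })
  }
  out
}

#' Read AOI regions from polygon JSON
#'
#' The JSON maps each label to a list of per-frame polygons
#' (`{"face": [{"frame": 1, "x": [...], "y": [...]}, ...], ...}`) in frame
#' pixel coordinates; polygons are rasterized to binary masks by even-odd
#' point-in-polygon filling.
#'
#' @param path JSON path.
#' @param height,width Frame dimensions for rasterization.
#' @param n_frames Number of frames (polygons persist until replaced).
#' @return Per-label list of per-frame logical masks.
#' @export
read_aoi_polygons <- function(path, height, width, n_frames) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (lab in names(spec)) {
    masks <- vector("list", n_frames)
    current <- matrix(FALSE, height, width)
    polys <- spec[[lab]]
    frames_with <- vapply(polys, function(p) as.integer(p$frame), 1L)
    for (f in seq_len(n_frames)) {
      hit <- which(frames_with == f)
      if (length(hit)) {
        p <- polys[[hit[1]]]
        current <- rasterize_polygon(unlist(p$x), unlist(p$y), height, width)
      }
      masks[[f]] <- current
    }
    out[[lab]] <- masks
  }
  out
}

# even-odd fill of a closed polygon given vertex vectors (frame px coords)
rasterize_polygon <- function(px, py, height, width) {
  m <- matrix(FALSE, height, width)
  n <- length(px)
  for (row in seq_len(height)) {
    yc <- row - 0.5
    xs <- c()
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > yc) != (py[j] > yc)) {
        xs <- c(xs, px[i] + (yc - py[i]) / (py[j] - py[i]) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- max(ceiling(xs[k] + 0.5), 1)
        c1 <- min(floor(xs[k + 1] + 0.5), width)
        if (c0 <= c1) m[row, c0:c1] <- TRUE
      }
    }
  }
  m
}
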