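## I/O surface: multi-page TIFF stacks with a JSON calibration sidecar,
## ROI and polyline JSON, dual-band composites, and CSV metric tables.
## Calibration lives in the sidecar rather than in TIFF tags for dialect
## safety; 16-bit integer data round-trip exactly, float data are stored
## min-max scaled in 32-bit with the bounds recorded in the sidecar.

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

.truthToList <- function(truth) {
  list(
    seed = truth@seed,
    vessels = lapply(truth@vessels, function(v) list(
      centerline = unname(v@centerline), trueWidth = v@trueWidth,
      depth = v@depth, peakIntensity = v@peakIntensity)),
    boluses = lapply(truth@boluses, function(vb) lapply(vb, function(tr)
      list(velocity = tr@velocity, startTimes = tr@startTimes,
           bolusLength = tr@bolusLength, amplitude = tr@amplitude))))
}

.truthFromList <- function(x) {
  vessels <- lapply(x$vessels, function(v)
    VesselSpec(matrix(unlist(v$centerline), ncol = 2),
               trueWidth = v$trueWidth, depth = v$depth,
               peakIntensity = v$peakIntensity))
  boluses <- lapply(x$boluses, function(vb) lapply(vb, function(tr)
    BolusTrain(velocity = tr$velocity, startTimes = unlist(tr$startTimes),
               bolusLength = tr$bolusLength, amplitude = tr$amplitude)))
  if (length(boluses) != length(vessels))
    boluses <- rep(list(list()), length(vessels))
  new("GroundTruth", vessels = vessels, boluses = boluses,
      seed = as.integer(x$seed %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Integer stacks within the camera range are stored as 16-bit pages
#' (lossless). Non-integer stacks (e.g. processed residual stacks) are
#' min-max scaled and stored as 32-bit float pages, with the bounds
#' recorded in the sidecar so reading restores the values to float
#' precision. The sidecar also carries the calibration, the band and,
#' when supplied, the full simulation ground truth and the resolved
#' configuration, so every simulation run is self-describing.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param path output TIFF path; the sidecar is written next to it with a
#'   \code{.json} extension.
#' @param truth optional \code{\link{GroundTruth}} to embed.
#' @param config optional list echoed verbatim into the sidecar.
#' @return \code{path}, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' writeStack(ImageStack(array(0:7, c(2, 2, 2))), tf)
#' @export
writeStack <- function(stack, path, truth = NULL, config = NULL) {
  d <- stack@data
  maxVal <- 2^stack@bitDepth - 1
  isInt <- all(d == round(d)) && min(d) >= 0 && max(d) <= maxVal
  meta <- list(pixel_pitch_mm = stack@pixelPitch,
               frame_interval_s = stack@frameInterval, band = stack@band,
               bit_depth = stack@bitDepth,
               storage = if (isInt) "uint16" else "float32")
  if (isInt) {
    pages <- lapply(seq_len(dim(d)[3]), function(f) d[, , f] / maxVal)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    lo <- min(d); hi <- max(d)
    scale <- if (hi > lo) hi - lo else 1
    meta$bounds <- c(lo, hi)
    pages <- lapply(seq_len(dim(d)[3]), function(f) (d[, , f] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  if (!is.null(truth)) meta$ground_truth <- .truthToList(truth)
  if (!is.null(config)) meta$config <- config
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack and its sidecar
#'
#' @param path TIFF path written by \code{\link{writeStack}} (or any
#'   multi-page grayscale TIFF). A missing sidecar falls back to default
#'   calibration (0.1 mm/px, 0.1 s/frame, SWIR) with a warning.
#' @return An \code{\link{ImageStack}}.
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' writeStack(ImageStack(array(0:7, c(2, 2, 2))), tf)
#' readStack(tf)
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent page shapes in ", path)
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    warning("no calibration sidecar for ", path, "; using defaults")
    meta <- list()
  }
  bitDepth <- as.integer(meta$bit_depth %||% 16L)
  storage <- meta$storage %||% "uint16"
  d <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  d <- if (storage == "float32") {
    b <- meta$bounds
    d * (b[2] - b[1]) + b[1]
  } else round(d * (2^bitDepth - 1))
  ImageStack(d, pixelPitch = meta$pixel_pitch_mm %||% 0.1,
             frameInterval = meta$frame_interval_s %||% 0.1,
             band = meta$band %||% "SWIR", bitDepth = bitDepth)
}

#' Read the ground truth embedded in a stack sidecar
#'
#' @param path the TIFF (or sidecar JSON) path.
#' @return A \code{\link{GroundTruth}}, or \code{NULL} when the sidecar
#'   has none.
#' @export
readGroundTruth <- function(path) {
  side <- if (grepl("\\.json$", path)) path else .sidecarPath(path)
  if (!file.exists(side)) return(NULL)
  meta <- jsonlite::read_json(side, simplifyVector = FALSE)
  if (is.null(meta$ground_truth)) return(NULL)
  .truthFromList(meta$ground_truth)
}

#' Write / read a simulation (stack + ground truth) as one unit
#'
#' @param sim a list with \code{stack} and \code{truth}, as returned by
#'   \code{\link{simulateLymphStack}}.
#' @param dir output directory (created if needed).
#' @param config optional resolved configuration echoed to the sidecar.
#' @return \code{writeSimulation}: the directory, invisibly.
#'   \code{readSimulation}: a list with \code{stack} and \code{truth}.
#' @rdname simulation-io
#' @export
writeSimulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStack(sim$stack, file.path(dir, "stack.tif"), truth = sim$truth,
             config = config)
  invisible(dir)
}

#' @rdname simulation-io
#' @export
readSimulation <- function(dir) {
  path <- file.path(dir, "stack.tif")
  list(stack = readStack(path), truth = readGroundTruth(path))
}

## Even-odd ray-casting point-in-polygon test on pixel centres.
.polygonMask <- function(rows, cols, vertices) {
  x <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  y <- matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
  inside <- matrix(FALSE, rows, cols)
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read ROI definitions from JSON
#'
#' The JSON is a list of objects with \code{type} (\code{"circle"} or
#' \code{"polygon"}), an \code{id}, and either \code{centre} + \code{radius}
#' or \code{vertices}, all in 0-based pixel coordinates.
#'
#' @param path JSON file.
#' @param rows,cols frame shape the masks are built for.
#' @return Named list of \code{\link{PixelMask}} objects.
#' @export
readRoiJson <- function(path, rows, cols) {
  rois <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (r in rois) {
    m <- switch(r$type,
      circle = circleMask(rows, cols, unlist(r$centre), r$radius),
      polygon = PixelMask(.polygonMask(
        rows, cols, matrix(unlist(r$vertices), ncol = 2, byrow = TRUE))),
      stop("unknown ROI type: ", r$type))
    out[[r$id %||% as.character(length(out) + 1L)]] <- m
  }
  out
}

#' Read a drawn polyline from JSON
#'
#' @param path JSON file with \code{vertices_px} (list of (x, y), 0-based
#'   pixels) and \code{calibration_mm_per_px}.
#' @return A list: \code{vertices} (n x 2 matrix) and \code{calibration}.
#' @export
readPolylineJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(vertices = matrix(unlist(x$vertices_px), ncol = 2, byrow = TRUE),
       calibration = x$calibration_mm_per_px %||% 0.1)
}

#' Composite co-registered NIR and SWIR frames
#'
#' After independent max-normalization, the NIR frame drives the red and
#' blue channels (purple) and the SWIR frame drives green; a pixel bright
#' in both bands therefore renders white. Inputs must be pre-aligned.
#'
#' @param nir,swir 2-D matrices of equal shape.
#' @return A \code{\link{CompositeImage}}.
#' @examples
#' comp <- overlayChannels(diag(4), matrix(1, 4, 4))
#' dim(comp@rgb)
#' @export
overlayChannels <- function(nir, swir) {
  if (!all(dim(nir) == dim(swir)))
    stop("nir and swir frames must have the same shape")
  norm1 <- function(m) {
    hi <- max(m)
    if (hi > 0) pmax(m, 0) / hi else m * 0
  }
  nN <- norm1(nir)
  sN <- norm1(swir)
  rgb <- array(0, c(dim(nir), 3L))
  rgb[, , 1] <- nN
  rgb[, , 2] <- sN
  rgb[, , 3] <- nN
  new("CompositeImage", rgb = rgb,
      provenance = list(red = "NIR", green = "SWIR", blue = "NIR"),
      bounds = list(nir = max(nir), swir = max(swir)))
}

#' Write a composite image as PNG
#'
#' @param composite a \code{\link{CompositeImage}}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeComposite <- function(composite, path) {
  png::writePNG(composite@rgb, path)
  invisible(path)
}

#' Write architectural metrics to CSV
#'
#' One row per drawn line and band with stable column order
#' (\code{id, band, distinguishability, n_vessels, line_length_cm,
#' resolution_mean_mm, resolution_sd_mm}); mean and sd are separate
#' numeric fields and undefined values are written as \code{NA}. With
#' \code{summary = TRUE}, \code{mean} and \code{sd} rows over the numeric
#' columns are appended, mirroring the usual band-comparison table layout.
#'
#' @param metrics list of \code{\link{VesselMetrics}} (possibly named).
#' @param path output CSV path.
#' @param summary append mean and sd rows.
#' @return The written data.frame, invisibly.
#' @export
writeMetrics <- function(metrics, path, summary = FALSE) {
  rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    id <- names(metrics)[i]
    data.frame(id = if (!is.null(id) && nzchar(id)) id else
                 paste0("line", i),
               band = m@band, distinguishability = m@distinguishability,
               n_vessels = m@nVessels, line_length_cm = m@lineLengthCm,
               resolution_mean_mm = m@resolutionMean,
               resolution_sd_mm = m@resolutionSd)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), band = character(0),
               distinguishability = numeric(0), n_vessels = integer(0),
               line_length_cm = numeric(0), resolution_mean_mm = numeric(0),
               resolution_sd_mm = numeric(0))
  if (summary && nrow(df)) {
    num <- c("distinguishability", "line_length_cm", "resolution_mean_mm")
    mrow <- df[1, ]
    mrow$id <- "mean"; mrow$band <- ""
    mrow$n_vessels <- NA_integer_; mrow$resolution_sd_mm <- NA_real_
    srow <- mrow
    srow$id <- "sd"
    for (cn in num) {
      mrow[[cn]] <- mean(df[[cn]], na.rm = TRUE)
      srow[[cn]] <- if (nrow(df) > 1) sd(df[[cn]], na.rm = TRUE) else NA_real_
    }
    df <- rbind(df, mrow, srow)
  }
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(df)
}

#' Read a metrics CSV back
#'
#' @param path CSV written by \code{\link{writeMetrics}}.
#' @return data.frame.
#' @export
readMetrics <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Read a scene configuration (YAML or JSON)
#'
#' The file holds \code{camera}, \code{scattering}, \code{vessels},
#' \code{boluses} (optional) blocks plus \code{duration},
#' \code{pixel_pitch_mm}, \code{frame_interval_s} and a mandatory
#' \code{seed}; \code{runSceneConfig} dispatches on its \code{mode}
#' (\code{"phantom"} with a \code{depths} list, or \code{"invivo"}).
#'
#' @param path YAML (\code{.yml}/\code{.yaml}) or JSON file.
#' @return The parsed configuration list.
#' @rdname scene-config
#' @export
readSceneConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("scene config must set a seed")
  cfg
}

#' @param cfg a parsed scene configuration.
#' @rdname scene-config
#' @export
runSceneConfig <- function(cfg) {
  cam <- do.call(CameraModel, c(list(band = cfg$camera$band %||% "SWIR"),
    cfg$camera[setdiff(names(cfg$camera), "band")]))
  sc <- ScatteringModel(
    blurRate = unlist(cfg$scattering$blur_rate %||%
                        c(NIR = 0.12, SWIR = 0.06)),
    backgroundLevel = unlist(cfg$scattering$background_level %||%
                               c(NIR = 300, SWIR = 60)))
  vessels <- lapply(cfg$vessels, function(v)
    VesselSpec(matrix(unlist(v$centerline), ncol = 2, byrow = TRUE),
               trueWidth = v$true_width %||% 0.22, depth = v$depth %||% 1,
               peakIntensity = v$peak_intensity %||% 2000))
  mode <- cfg$mode %||% "invivo"
  if (mode == "phantom") {
    simulateCapillaryPhantom(vessels[[1]], sc, cam,
      depths = unlist(cfg$depths), pixelPitch = cfg$pixel_pitch_mm %||% 0.1,
      seed = cfg$seed)
  } else {
    boluses <- lapply(cfg$boluses %||% rep(list(NULL), length(vessels)),
      function(b) if (is.null(b)) NULL else
        BolusTrain(velocity = b$velocity %||% 7,
                   startTimes = unlist(b$start_times),
                   bolusLength = b$bolus_length %||% 2,
                   amplitude = b$amplitude %||% 1))
    simulateLymphStack(vessels, boluses, sc, cam,
      duration = cfg$duration, pixelPitch = cfg$pixel_pitch_mm %||% 0.1,
      frameInterval = cfg$frame_interval_s %||% 0.1, seed = cfg$seed)
  }
}
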