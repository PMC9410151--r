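#' Write a rendered phantom image and its ground truth to disk
#'
#' Stores the pixel array as a losslessly quantized 16-bit grayscale TIFF
#' and the acquisition metadata plus ground truth (corner layout, rendered
#' contrasts, seeds, grid offset) as a versioned JSON sidecar next to it.
#' Pixel counts are rounded to integers before writing; the quantized
#' render is returned so that a write-read cycle is exactly lossless.
#'
#' @param render A `cdmam_render` (or a bare `cdmam_image`, in which case
#'   no truth sidecar content beyond the metadata is available).
#' @param dir Output directory (created if needed).
#' @param name Base file name (without extension).
#' @return Invisibly, a list with `tiff`, `json` paths and the quantized
#'   `render`.
#' @export
write_fixture <- function(render, dir, name = "phantom") {
  if (inherits(render, "cdmam_image")) {
    render <- structure(list(image = render, truth = NULL),
                        class = "cdmam_render")
  }
  stopifnot(inherits(render, "cdmam_render"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop_data(sprintf("Cannot create '%s'.", dir))
  }
  img <- render$image
  px <- round(img$pixels)
  if (max(px) > 65535) stop_data("Pixel counts exceed the 16-bit range.")
  px[px < 0] <- 0
  img$pixels <- px
  render$image <- img

  tif <- file.path(dir, paste0(name, ".tif"))
  jsn <- file.path(dir, paste0(name, ".json"))
  ok <- tryCatch(
    tiff::writeTIFF(px / 65535, tif, bits.per.sample = 16L,
                    compression = "none"),
    error = function(e) stop_data(sprintf("TIFF write failed: %s",
                                          conditionMessage(e))))

  sidecar <- list(
    schema = 1L,
    meta = img$meta,
    truth = if (!is.null(render$truth)) {
      tr <- render$truth
      list(
        corners = tr$corners,
        contrast = tr$contrast,
        focus_height = tr$focus_height,
        heights = tr$heights,
        seeds = tr$seeds,
        grid_offset_mm = tr$grid_offset_mm,
        noiseless = tr$noiseless
      )
    }
  )
  jsonlite::write_json(sidecar, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(list(tiff = tif, json = jsn, render = render))
}

#' Read a phantom image from disk
#'
#' Loads a 16-bit TIFF written by [write_fixture()] (or any 16-bit
#' grayscale TIFF), restoring integer pixel counts. When a JSON sidecar of
#' the same base name exists its acquisition metadata is attached;
#' otherwise the metadata is explicitly marked unknown. An orientation
#' configuration supports images stored rotated by a multiple of 90
#' degrees and images with an inverted pixel-intensity relationship
#' (`intensity_sign = -1` flips values as `max - x`; applying it twice
#' restores the original).
#'
#' @param path Path to the TIFF file.
#' @param rotate Rotation to undo, in degrees: 0, 90, 180 or 270.
#' @param intensity_sign `+1` (more exposure = larger value) or `-1`.
#' @param pitch Pixel pitch in mm, required if no sidecar provides
#'   `pixel_spacing`.
#' @return A `cdmam_image` with `provenance = "loaded"`.
#' @export
read_phantom_image <- function(path, rotate = 0, intensity_sign = 1L,
                               pitch = NULL) {
  if (!file.exists(path)) stop_data(sprintf("No such image file: %s", path))
  raw <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop_data(
                    sprintf("Not a readable TIFF: %s", conditionMessage(e))))
  px <- round(raw * 65535)
  if (!rotate %in% c(0, 90, 180, 270)) {
    stop_config("`rotate` must be one of 0, 90, 180, 270.")
  }
  rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  for (i in seq_len((rotate %% 360) / 90)) px <- rot90cw(px)
  if (intensity_sign == -1L) px <- 65535 - px

  jsn <- sub("\\.tiff?$", ".json", path)
  meta <- NULL
  if (file.exists(jsn)) {
    sidecar <- jsonlite::read_json(jsn, simplifyVector = TRUE)
    meta <- sidecar$meta
  }
  if (is.null(meta)) {
    meta <- list(unknown = TRUE,
                 pixel_spacing = pitch %||% NA_real_)
  }
  if (is.null(meta$pixel_spacing) || is.na(meta$pixel_spacing)) {
    if (is.null(pitch)) {
      stop_data("No pixel spacing in sidecar; supply `pitch`.")
    }
    meta$pixel_spacing <- pitch
  }
  structure(
    list(pixels = px, pitch = as.numeric(meta$pixel_spacing), meta = meta,
         provenance = "loaded"),
    class = "cdmam_image"
  )
}

#' Read a ground-truth sidecar
#'
#' @param path Path to the JSON sidecar (or to the TIFF; the extension is
#'   swapped). A missing sidecar yields an explicit "no ground truth"
#'   object (`available = FALSE`) rather than an error.
#' @return A list with `available` plus, when available, `corners`,
#'   `contrast`, `seeds`, `grid_offset_mm`, `focus_height`.
#' @export
read_ground_truth <- function(path) {
  jsn <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(jsn)) {
    return(list(available = FALSE))
  }
  sidecar <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  tr <- sidecar$truth
  if (is.null(tr)) return(list(available = FALSE))
  tr$corners <- tibble::as_tibble(tr$corners)
  tr$contrast <- tibble::as_tibble(tr$contrast)
  tr$available <- TRUE
  tr
}

#' Extract exposure metadata
#'
#' Collects the exposure conditions of an image into a tidy one-row table,
#' probing the standard header fields (`KVP`,
#' `ExposureInMilliampereSeconds`, `OrganDose`, `PixelSpacing`,
#' anode/filter either as separate materials or a combined `"W/Rh"`-style
#' string). Works on a `cdmam_image`, a named header list, or a JSON
#' sidecar path. Absent fields come back as `NA` and are listed in the
#' `missing` attribute -- never silently defaulted.
#'
#' @param x A `cdmam_image`, a named list of header fields, or a file path.
#' @return A one-row tibble: `kvp`, `mas`, `anode`, `filter`, `agd`,
#'   `pixel_spacing`, `mode`, `resolution`, `dose`, with attribute
#'   `missing` naming the fields that were absent.
#' @export
extract_exposure_meta <- function(x) {
  if (inherits(x, "cdmam_image")) {
    hdr <- x$meta
  } else if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_data(sprintf("No such file: %s", x))
    sidecar <- tryCatch(jsonlite::read_json(x, simplifyVector = TRUE),
                        error = function(e) stop_data(
                          sprintf("Not a readable header: %s",
                                  conditionMessage(e))))
    hdr <- sidecar$meta %||% sidecar
  } else if (is.list(x)) {
    hdr <- x
  } else {
    stop_data("Cannot extract exposure metadata from this object.")
  }

  probe <- function(...) {
    for (key in c(...)) {
      v <- hdr[[key]]
      if (!is.null(v) && !all(is.na(v))) return(v)
    }
    NA
  }
  anode <- probe("anode", "AnodeTargetMaterial")
  filt <- probe("filter", "FilterMaterial")
  af <- probe("anode_filter", "AnodeFilter")
  if ((is.na(anode) || is.na(filt)) && !is.na(af)) {
    parts <- strsplit(as.character(af), "/", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) {
      anode <- parts[1L]
      filt <- parts[2L]
    }
  }
  ps <- probe("pixel_spacing", "PixelSpacing")
  out <- tibble(
    kvp = as.numeric(probe("kvp", "KVP")),
    mas = as.numeric(probe("mas", "ExposureInMilliampereSeconds", "Exposure")),
    anode = as.character(anode),
    filter = as.character(filt),
    agd = as.numeric(probe("agd", "OrganDose")),
    pixel_spacing = as.numeric(ps[1L]),
    mode = as.character(probe("mode")),
    resolution = as.character(probe("resolution")),
    dose = as.character(probe("dose"))
  )
  attr(out, "missing") <- names(out)[vapply(out, function(v) is.na(v[1L]),
                                            logical(1))]
  out
}

#' Percent increase in average glandular dose
#'
#' @param a,b AGD values in mGy (numeric), or exposure-metadata rows from
#'   [extract_exposure_meta()] carrying an `agd` column; `a` is the
#'   reference.
#' @return A one-row tibble with `percent` (exact) and `percent_rounded`
#'   (nearest integer).
#' @export
#' @examples
#' agd_percent_increase(1.15, 1.61)
agd_percent_increase <- function(a, b) {
  get_agd <- function(v) {
    if (is.data.frame(v)) v <- v$agd
    as.numeric(v)
  }
  a <- get_agd(a); b <- get_agd(b)
  if (length(a) != 1L || length(b) != 1L || anyNA(c(a, b)) ||
      a <= 0 || b <= 0) {
    stop_data("Both AGD values must be present and positive.")
  }
  pct <- 100 * (b - a) / a
  tibble(percent = pct, percent_rounded = round(pct))
}
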