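#' Acquisition configuration
#'
#' Bundles the acquisition physics of one exposure mode. The dual-mode DBT
#' system being emulated offers a 2D contact mode (0.05 mm pixels), a
#' standard-resolution tomosynthesis mode (ST: 0.1 mm pixels, 15 degree
#' sweep) and a high-resolution mode (HR: 0.05 mm pixels, 40 degree sweep),
#' each at a normal (N) and a high (H) dose; the default tube loads (mAs)
#' and average glandular doses per mode follow the clinical settings of
#' such a unit (2D: 71/100 mAs; ST: 32/40 mAs; HR: 50/63 mAs).
#'
#' The noise model is quantum (Poisson) plus electronic (Gaussian) noise;
#' the background photon count per pixel is `gain * mas * pixel_pitch^2`,
#' so dose mode scales counts through the mAs ratio and pixel size enters
#' through the pixel area. Disk contrast follows exponential attenuation in
#' the gold thickness with a single effective coefficient `mu_gold`
#' (see [thickness_to_contrast()]).
#'
#' @param mode One of `"2D"`, `"TL"` (tomographic layer), `"s2D"`.
#' @param resolution `"ST"` or `"HR"` (ignored for 2D, which always uses
#'   0.05 mm pixels).
#' @param dose `"N"` (normal) or `"H"` (high).
#' @param pixel_pitch Pixel size in mm. Defaults to the mode's convention.
#' @param gain Detector gain in photons per mm^2 per mAs.
#' @param mas Tube load; defaults to the mode's clinical setting.
#' @param electronic_sigma Electronic noise standard deviation in counts.
#' @param mu_gold Effective gold attenuation per um of thickness.
#' @param psf_sigma Gaussian system blur (mm); default 0.8 pixels.
#' @param sweep_angle Total tomosynthesis sweep angle in degrees
#'   (15 for ST, 40 for HR, 0 for 2D).
#' @param tl_spacing Tomographic layer spacing in mm.
#' @param focus_height Height (mm) of the phantom disk plane above the
#'   breast support, i.e. the in-focus layer.
#' @param defocus_k Parallax factor of the out-of-focus directional blur:
#'   blur length = `defocus_k * tan(sweep_angle/2) * |dh|`.
#' @param intensity_sign `+1` if more exposure means larger pixel values.
#' @return A list of class `acquisition_config`.
#' @export
#' @examples
#' acquisition_config("TL", "ST", "H")$mean_counts
acquisition_config <- function(mode = c("2D", "TL", "s2D"),
                               resolution = c("ST", "HR"),
                               dose = c("N", "H"),
                               pixel_pitch = NULL,
                               gain = 1500,
                               mas = NULL,
                               electronic_sigma = 4,
                               mu_gold = 0.15,
                               psf_sigma = NULL,
                               sweep_angle = NULL,
                               tl_spacing = 1,
                               focus_height = 22,
                               defocus_k = 2,
                               intensity_sign = 1L) {
  mode <- match.arg(mode)
  resolution <- match.arg(resolution)
  dose <- match.arg(dose)

  mas_default <- list(
    `2D` = c(N = 71, H = 100),
    ST = c(N = 32, H = 40),
    HR = c(N = 50, H = 63)
  )
  agd_default <- list(
    `2D` = c(N = 1.15, H = 1.61),
    ST = c(N = 1.61, H = 2.00),
    HR = c(N = 2.51, H = 3.15)
  )
  key <- if (mode == "2D") "2D" else resolution
  mas <- mas %||% mas_default[[key]][[dose]]
  agd <- agd_default[[key]][[dose]]
  pixel_pitch <- pixel_pitch %||%
    if (mode == "2D" || resolution == "HR") 0.05 else 0.1
  sweep_angle <- sweep_angle %||%
    if (mode == "2D") 0 else if (resolution == "ST") 15 else 40
  psf_sigma <- psf_sigma %||% (0.8 * pixel_pitch)
  if (mas <= 0 || gain <= 0) stop_config("`gain` and `mas` must be positive.")
  if (!pixel_pitch %in% c(0.05, 0.1)) {
    stop_config("`pixel_pitch` must be 0.05 or 0.1 mm for this system.")
  }

  structure(
    list(
      mode = mode, resolution = resolution, dose = dose,
      pixel_pitch = pixel_pitch, gain = gain, mas = mas,
      mean_counts = gain * mas * pixel_pitch^2,
      electronic_sigma = electronic_sigma, mu_gold = mu_gold,
      psf_sigma = psf_sigma, sweep_angle = sweep_angle,
      tl_spacing = tl_spacing, focus_height = focus_height,
      defocus_k = defocus_k, intensity_sign = as.integer(intensity_sign),
      kvp = if (mode == "2D") 30 else 33,
      anode = "W",
      filter = if (mode == "2D") "Rh" else "Al",
      agd = agd
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> %s %s-mode (%s), %.2f mm pixels, %g mAs, %.0f counts/px\n",
              x$mode, x$dose, x$resolution, x$pixel_pitch, x$mas, x$mean_counts))
  invisible(x)
}

#' Fractional disk contrast from gold thickness
#'
#' A gold disk of thickness `t` um attenuates the beam by a fraction
#' `1 - exp(-mu_gold * t)` relative to the background; this fractional
#' signal deficit is strictly increasing in thickness.
#'
#' @param t Gold thickness in um (>= 0).
#' @param mu_gold Effective attenuation coefficient per um.
#' @return Contrast fraction in `[0, 1)`.
#' @export
#' @examples
#' thickness_to_contrast(2, mu_gold = 0.5)  # 1 - exp(-1)
thickness_to_contrast <- function(t, mu_gold = 0.15) {
  if (any(t < 0)) stop_config("Gold thickness must be non-negative.")
  if (mu_gold < 0) stop_config("`mu_gold` must be non-negative.")
  1 - exp(-mu_gold * t)
}

# --- internal rendering helpers ---------------------------------------------

# Pixel-coverage patch of one disk (value-scaled). Pixel centres sit at
# (index - 0.5) * pitch. Coverage uses a linear edge profile of one-pixel
# width; tiny disks (r < 1.5 px) are renormalised so the integrated signal
# matches the true disk area.
disk_patch <- function(x_mm, y_mm, r_mm, value, pitch, ny, nx) {
  if (value <= 0 || r_mm <= 0) return(NULL)
  pad <- 2
  i0 <- max(1L, floor((y_mm - r_mm) / pitch) - pad)
  i1 <- min(ny, ceiling((y_mm + r_mm) / pitch) + pad)
  j0 <- max(1L, floor((x_mm - r_mm) / pitch) - pad)
  j1 <- min(nx, ceiling((x_mm + r_mm) / pitch) + pad)
  if (i0 > i1 || j0 > j1) return(NULL)
  yc <- (i0:i1 - 0.5) * pitch
  xc <- (j0:j1 - 0.5) * pitch
  dist <- sqrt(outer((yc - y_mm)^2, (xc - x_mm)^2, `+`))
  cov <- pmin(pmax((r_mm - dist) / pitch + 0.5, 0), 1)
  s <- sum(cov)
  if (s > 0 && r_mm < 1.5 * pitch) {
    cov <- cov * (pi * r_mm^2 / pitch^2) / s
  }
  list(rows = i0:i1, cols = j0:j1, patch = value * cov)
}

# Ideal (noise-free, unblurred) contrast map of the phantom, plus the truth
# table of rendered per-cell contrasts. Disks are added by sub-assignment in
# this frame so the full-field matrix is never copied per disk.
contrast_map <- function(phantom, cfg, dims, offset_mm) {
  C <- matrix(0, dims[1L], dims[2L])
  ny <- dims[1L]; nx <- dims[2L]
  pitch <- cfg$pixel_pitch
  cells <- phantom$cells[phantom$cells$present, ]
  offs <- corner_offsets(phantom)
  contr <- thickness_to_contrast(cells$thickness, cfg$mu_gold)
  for (k in seq_len(nrow(cells))) {
    if (contr[k] <= 0) next
    r <- cells$diameter[k] / 2
    cx <- cells$x[k] + offset_mm[1L]
    cy <- cells$y[k] + offset_mm[2L]
    co <- offs[cells$corner[k], ]
    for (p in list(disk_patch(cx, cy, r, contr[k], pitch, ny, nx),
                   disk_patch(cx + co[1L], cy + co[2L], r, contr[k],
                              pitch, ny, nx))) {
      if (!is.null(p)) C[p$rows, p$cols] <- C[p$rows, p$cols] + p$patch
    }
  }
  list(C = C, contrast = tibble(cell_id = cells$cell_id,
                                diameter = cells$diameter,
                                thickness = cells$thickness,
                                contrast = contr))
}

field_dims <- function(phantom, cfg, field) {
  pitch <- cfg$pixel_pitch
  if (is.character(field)) {
    field <- match.arg(field, c("full", "tight"))
    if (field == "full") {
      wh <- phantom$field_mm
    } else {
      wh <- phantom$extent_mm + 16  # 8 mm margin per side
    }
  } else {
    wh <- c(x = field[[1L]], y = field[[2L]])
  }
  if (any(wh < phantom$extent_mm)) {
    stop_config("Requested field does not cover the phantom grid.")
  }
  dims <- c(ny = ceiling(wh[["y"]] / pitch), nx = ceiling(wh[["x"]] / pitch))
  offset <- c(x = (wh[["x"]] - phantom$extent_mm[["x"]]) / 2,
              y = (wh[["y"]] - phantom$extent_mm[["y"]]) / 2)
  list(dims = dims, offset = offset, wh = wh)
}

noise_field <- function(dims, cfg, seed) {
  q <- with_seed(derive_seed(seed, "quantum"), {
    matrix(rpois(prod(dims), cfg$mean_counts), dims[1L], dims[2L])
  }) - cfg$mean_counts
  if (cfg$electronic_sigma > 0) {
    e <- with_seed(derive_seed(seed, "electronic"), {
      matrix(rnorm(prod(dims), 0, cfg$electronic_sigma), dims[1L], dims[2L])
    })
    q <- q + e
  }
  q
}

new_cdmam_image <- function(pixels, cfg, grid_offset_mm, wh,
                            height = NA_real_, provenance = "synthetic",
                            mode = cfg$mode) {
  structure(
    list(
      pixels = pixels,
      pitch = cfg$pixel_pitch,
      meta = list(
        mode = mode, resolution = cfg$resolution, dose = cfg$dose,
        pixel_spacing = cfg$pixel_pitch, kvp = cfg$kvp, mas = cfg$mas,
        agd = cfg$agd, anode = cfg$anode, filter = cfg$filter,
        psf_sigma = cfg$psf_sigma, mean_counts = cfg$mean_counts,
        electronic_sigma = cfg$electronic_sigma, mu_gold = cfg$mu_gold,
        sweep_angle = cfg$sweep_angle, height = height,
        focus_height = cfg$focus_height,
        grid_offset_mm = unname(grid_offset_mm),
        field_mm = unname(wh),
        intensity_sign = cfg$intensity_sign
      ),
      provenance = provenance
    ),
    class = "cdmam_image"
  )
}

#' @export
print.cdmam_image <- function(x, ...) {
  cat(sprintf("<cdmam_image> %d x %d px at %.2f mm (%s %s-mode %s%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch,
              x$meta$mode %||% "?", x$meta$dose %||% "?",
              x$meta$resolution %||% "?",
              if (!is.na(x$meta$height %||% NA)) {
                sprintf(", layer %g mm", x$meta$height)
              } else ""))
  invisible(x)
}

#' Render a 2D phantom exposure
#'
#' Produces one noisy synthetic exposure of the phantom: the ideal contrast
#' map (disks as fractional deficits of the background count) is blurred by
#' the Gaussian system PSF and superimposed with white quantum-plus-
#' electronic noise. The render is bit-reproducible for a fixed `seed`;
#' corner placement uses the phantom's own seed, so the same phantom can be
#' re-rendered under many noise realisations.
#'
#' @param phantom A [cdmam_phantom()].
#' @param cfg An [acquisition_config()] with `mode = "2D"` (or any mode when
#'   called internally).
#' @param seed Integer seed for the quantum and electronic noise streams.
#' @param field `"full"` (18 x 24 cm), `"tight"` (grid bounding box plus an
#'   8 mm margin) or a numeric `c(width_mm, height_mm)`.
#' @param noiseless If `TRUE`, return the noise-free expected image.
#' @return A list of class `cdmam_render` with elements `image`
#'   (a `cdmam_image`) and `truth` (corner layout, rendered contrasts,
#'   seeds, grid offset).
#' @export
render_phantom <- function(phantom, cfg, seed = 1L, field = "full",
                           noiseless = FALSE) {
  stopifnot(inherits(phantom, "cdmam_phantom"),
            inherits(cfg, "acquisition_config"))
  fd <- field_dims(phantom, cfg, field)
  cm <- contrast_map(phantom, cfg, fd$dims, fd$offset)
  Cb <- blur_gaussian(cm$C, cfg$psf_sigma / cfg$pixel_pitch)
  S <- cfg$mean_counts * (1 - Cb)
  pixels <- if (noiseless) S else pmax(S + noise_field(fd$dims, cfg, seed), 0)
  img <- new_cdmam_image(pixels, cfg, fd$offset, fd$wh)
  truth <- list(
    schema = 1L,
    corners = phantom$cells[phantom$cells$present,
                            c("cell_id", "corner", "diameter", "thickness")],
    contrast = cm$contrast,
    focus_height = NA_real_,
    seeds = list(seed = as.integer(seed), corner_seed = phantom$corner_seed,
                 quantum = derive_seed(seed, "quantum"),
                 electronic = derive_seed(seed, "electronic")),
    grid_offset_mm = unname(fd$offset),
    noiseless = noiseless
  )
  structure(list(image = img, truth = truth), class = "cdmam_render")
}

#' Render a tomographic-layer stack
#'
#' Renders the set of reconstructed DBT layers of a phantom exposure. The
#' layer containing the phantom's disk plane (`cfg$focus_height`) is
#' rendered exactly like a 2D exposure; layers a distance `dh` away receive
#' an additional directional blur of length
#' `defocus_k * tan(sweep_angle/2) * |dh|` along the tube-sweep axis, so the
#' wider HR sweep defocuses faster than ST. All layers of one stack share a
#' single noise realisation, reflecting that every reconstructed slice
#' derives from the same projection set; detectability is therefore maximal
#' at the in-focus layer and decays with `|dh|`.
#'
#' @inheritParams render_phantom
#' @param heights Numeric vector of layer heights (mm) to render. Defaults
#'   to the full stack `seq(0, focus_height + 2, by = tl_spacing)`.
#' @return A list of class `cdmam_tl_stack`: `images` (a named list of
#'   `cdmam_image`, one per height) and `truth`.
#' @export
render_tl_stack <- function(phantom, cfg, seed = 1L, heights = NULL,
                            field = "full", noiseless = FALSE) {
  stopifnot(inherits(phantom, "cdmam_phantom"),
            inherits(cfg, "acquisition_config"))
  if (cfg$mode != "TL") stop_config("`cfg$mode` must be 'TL' for a layer stack.")
  heights <- heights %||% seq(0, cfg$focus_height + 2, by = cfg$tl_spacing)
  if (!any(abs(heights - cfg$focus_height) < 1e-9)) {
    stop_config("`heights` must include the in-focus layer (cfg$focus_height).")
  }
  fd <- field_dims(phantom, cfg, field)
  cm <- contrast_map(phantom, cfg, fd$dims, fd$offset)
  Cb <- blur_gaussian(cm$C, cfg$psf_sigma / cfg$pixel_pitch)
  noise <- if (noiseless) 0 else noise_field(fd$dims, cfg, seed)

  images <- lapply(heights, function(h) {
    dh <- abs(h - cfg$focus_height)
    L <- cfg$defocus_k * tan(cfg$sweep_angle / 2 * pi / 180) * dh
    Ch <- blur_box_x(Cb, L / cfg$pixel_pitch)
    pmax(cfg$mean_counts * (1 - Ch) + noise, 0)
  })
  images <- purrr::map2(images, heights, function(px, h) {
    new_cdmam_image(px, cfg, fd$offset, fd$wh, height = h)
  })
  names(images) <- sprintf("h%g", heights)

  truth <- list(
    schema = 1L,
    corners = phantom$cells[phantom$cells$present,
                            c("cell_id", "corner", "diameter", "thickness")],
    contrast = cm$contrast,
    focus_height = cfg$focus_height,
    heights = heights,
    seeds = list(seed = as.integer(seed), corner_seed = phantom$corner_seed,
                 quantum = derive_seed(seed, "quantum"),
                 electronic = derive_seed(seed, "electronic")),
    grid_offset_mm = unname(fd$offset),
    noiseless = noiseless
  )
  structure(list(images = images, truth = truth), class = "cdmam_tl_stack")
}

#' Synthesize a 2D image from tomographic layers
#'
#' Emulates the synthesized-2D (s2D) view as a weighted pixel-wise
#' flattening of reconstructed layers. The default window is five layers
#' centred one layer off the in-focus plane (a flattening that, like a real
#' synthesis over the whole volume, is not anchored on the phantom's disk
#' plane): the in-focus disk contrast is diluted by the defocused
#' neighbours while the (shared) noise is not averaged away, so the s2D
#' image is by construction noisier relative to its signal than the
#' in-focus layer. Vendor-specific iterative synthesis is deliberately not
#' imitated.
#'
#' @param stack A `cdmam_tl_stack` from [render_tl_stack()], or a plain list
#'   of `cdmam_image` objects with identical dimensions.
#' @param weights Numeric weights, one per selected layer, summing to 1.
#'   Default: uniform over the selected layers.
#' @param heights For a `cdmam_tl_stack`, which layer heights to flatten
#'   (default: five layers centred one spacing above the focus height,
#'   clipped to the available stack).
#' @return A `cdmam_image` with mode `"s2D"`.
#' @export
synthesize_s2d <- function(stack, weights = NULL, heights = NULL) {
  if (inherits(stack, "cdmam_tl_stack")) {
    hs <- stack$truth$heights
    if (is.null(heights)) {
      want <- stack$truth$focus_height + c(-1, 0, 1, 2, 3)
      heights <- want[want %in% hs]
    }
    sel <- match(heights, hs)
    if (anyNA(sel)) stop_data("Requested layer heights are not in the stack.")
    imgs <- stack$images[sel]
  } else {
    imgs <- stack
  }
  if (length(imgs) == 0L) stop_data("Empty image stack.")
  dims <- lapply(imgs, function(im) dim(im$pixels))
  if (length(unique(dims)) != 1L) {
    stop_data("Stack images have mismatched dimensions.")
  }
  weights <- weights %||% rep(1 / length(imgs), length(imgs))
  if (length(weights) != length(imgs)) {
    stop_config("Need one weight per stack image.")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop_config("`weights` must sum to 1.")
  px <- Reduce(`+`, purrr::map2(imgs, weights, function(im, w) w * im$pixels))
  out <- imgs[[which.max(weights)]]
  out$pixels <- px
  out$meta$mode <- "s2D"
  out$meta$height <- NA_real_
  out
}

# Separable Gaussian blur (sigma in pixels); no-op for sigma ~ 0.
blur_gaussian <- function(x, sigma_px) {
  if (sigma_px <= 1e-6) return(x)
  EBImage::gblur(x, sigma = sigma_px)
}

# Directional box blur along the image x-axis (matrix columns), width in px.
blur_box_x <- function(x, width_px) {
  n <- 2L * floor(width_px / 2) + 1L
  if (n <= 1L) return(x)
  k <- matrix(1 / n, nrow = 1L, ncol = n)
  EBImage::filter2(x, k)
}
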