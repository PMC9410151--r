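#' Locate the phantom grid in an image
#'
#' Maps phantom-frame cell coordinates into pixel coordinates. For
#' synthetic images the grid offset is known exactly (from the render
#' metadata or a ground-truth sidecar) and the residual is zero. Without a
#' hint, the offset is estimated by maximising the matched-filter response
#' of the thickest central disks over a translation search around the
#' nominal (centred) mount position; an image whose best response stays
#' below `min_score` is flagged as a registration failure rather than
#' scored.
#'
#' @param image A `cdmam_image`.
#' @param phantom The [cdmam_phantom()] the image depicts.
#' @param truth Optional ground-truth sidecar (from a render or
#'   [read_ground_truth()]) supplying the exact grid offset.
#' @param search_mm,step_mm Half-width and step of the blind translation
#'   search.
#' @param min_score Minimum mean probe statistic accepted as a lock.
#' @return A list of class `cdmam_grid` with `offset_mm`, `pitch` and
#'   `residual_mm`.
#' @export
locate_grid <- function(image, phantom, truth = NULL,
                        search_mm = 2, step_mm = 0.5, min_score = 3) {
  stopifnot(inherits(image, "cdmam_image"), inherits(phantom, "cdmam_phantom"))
  hint <- NULL
  if (!is.null(truth)) {
    if (isFALSE(truth$available %||% TRUE)) {
      hint <- NULL
    } else {
      hint <- truth$grid_offset_mm
    }
  }
  hint <- hint %||% image$meta$grid_offset_mm
  if (!is.null(hint)) {
    return(structure(list(offset_mm = as.numeric(hint), pitch = image$pitch,
                          residual_mm = 0),
                     class = "cdmam_grid"))
  }

  dims <- dim(image$pixels)
  wh <- c(x = dims[2L] * image$pitch, y = dims[1L] * image$pitch)
  nominal <- c((wh[["x"]] - phantom$extent_mm[["x"]]) / 2,
               (wh[["y"]] - phantom$extent_mm[["y"]]) / 2)
  cells <- phantom$cells
  probes <- cells[cells$present & cells$thickness >= 0.5 & cells$diameter >= 0.4, ]
  probes <- head(probes[order(-probes$thickness * probes$diameter), ], 15L)
  cache <- new.env(parent = emptyenv())

  steps <- seq(-search_mm, search_mm, by = step_mm)
  best <- list(score = -Inf, offset = nominal)
  for (dx in steps) {
    for (dy in steps) {
      off <- nominal + c(dx, dy)
      geom <- structure(list(offset_mm = off, pitch = image$pitch,
                             residual_mm = step_mm / 2),
                        class = "cdmam_grid")
      s <- mean(vapply(seq_len(nrow(probes)), function(k) {
        loc <- c(probes$x[k], probes$y[k]) + off
        tryCatch(
          statistic_at(image, loc, probes$diameter[k], cache,
                       psf_sigma = image$meta$psf_sigma %||% (0.8 * image$pitch)),
          error = function(e) NA_real_)
      }, numeric(1)), na.rm = TRUE)
      if (is.finite(s) && s > best$score) best <- list(score = s, offset = off)
    }
  }
  if (best$score < min_score) {
    abort(sprintf(
      "Grid registration failed: best probe statistic %.2f below %.2f.",
      best$score, min_score), class = "cdmam_registration_error")
  }
  structure(list(offset_mm = best$offset, pitch = image$pitch,
                 residual_mm = step_mm / 2),
            class = "cdmam_grid")
}

# --- matched-filter statistic ------------------------------------------------

# Template for a disk of given diameter: PSF-blurred coverage weights plus a
# surrounding background annulus.
make_template <- function(diameter, pitch, psf_sigma) {
  r <- diameter / 2
  r_in <- r + 2 * psf_sigma + pitch
  r_out <- r_in + max(3 * pitch, 0.6 * r)
  half <- ceiling(r_out / pitch) + ceiling(3 * psf_sigma / pitch) + 1L
  g <- (-half:half) * pitch
  dist <- sqrt(outer(g^2, g^2, `+`))
  cov <- pmin(pmax((r - dist) / pitch + 0.5, 0), 1)
  if (sum(cov) > 0 && r < 1.5 * pitch) {
    cov <- cov * (pi * r^2 / pitch^2) / sum(cov)
  }
  sig <- psf_sigma / pitch
  if (sig > 1e-6) {
    n <- 2L * half + 1L
    kidx <- outer(seq_len(n), seq_len(n), `-`)
    B <- dnorm(kidx, sd = sig)
    B <- B / rowSums(B)
    cov <- B %*% cov %*% t(B)
  }
  w <- cov / sum(cov)
  ann <- dist >= r_in & dist <= r_out
  # SE factor of (annulus mean - template-weighted mean) in pixel-sigma units
  norm <- sqrt(sum(w^2) + 1 / sum(ann))
  list(w = w, ann = ann, half = half, norm = norm)
}

template_cached <- function(diameter, pitch, psf_sigma, cache) {
  key <- sprintf("d%.5f", diameter)
  tpl <- cache[[key]]
  if (is.null(tpl)) {
    tpl <- make_template(diameter, pitch, psf_sigma)
    cache[[key]] <- tpl
  }
  tpl
}

statistic_at <- function(image, location_mm, diameter, cache, psf_sigma) {
  tpl <- template_cached(diameter, image$pitch, psf_sigma, cache)
  px <- image$pixels
  cy <- round(location_mm[2L] / image$pitch + 0.5)
  cx <- round(location_mm[1L] / image$pitch + 0.5)
  h <- tpl$half
  if (cy - h < 1L || cy + h > nrow(px) || cx - h < 1L || cx + h > ncol(px)) {
    stop_data("Template footprint exceeds the image bounds.")
  }
  patch <- px[(cy - h):(cy + h), (cx - h):(cx + h)]
  bg <- patch[tpl$ann]
  num <- mean(bg) - sum(tpl$w * patch)
  if (abs(num) <= 1e-9 * (abs(mean(bg)) + 1)) num <- 0  # constant patch
  num / (sd(bg) * tpl$norm + 1e-9)
}

#' Matched-filter detection statistic
#'
#' Evaluates the disk-detection statistic at an arbitrary image location:
#' the difference between the mean of a surrounding background annulus and
#' the template-weighted mean under a PSF-blurred disk template of the
#' given diameter, scaled by the standard error of that difference under
#' the annulus noise estimate (a z-like detectability index). Larger values are
#' more disk-like (disks are signal deficits); the statistic is exactly
#' zero on a constant image.
#'
#' @param image A `cdmam_image`.
#' @param geom A `cdmam_grid` from [locate_grid()] (used for its pixel
#'   pitch; the location is given in absolute image mm).
#' @param diameter Disk diameter in mm.
#' @param location_mm Numeric `c(x, y)` location in mm in the image frame.
#' @return A single numeric score.
#' @export
detection_statistic <- function(image, geom, diameter, location_mm) {
  stopifnot(inherits(image, "cdmam_image"))
  cache <- new.env(parent = emptyenv())
  statistic_at(image, location_mm, diameter, cache,
               psf_sigma = image$meta$psf_sigma %||% (0.8 * image$pitch))
}

#' Score a single phantom cell
#'
#' Runs both four-alternative forced-choice tasks for one cell: the
#' peripheral task evaluates the statistic at the four cell corners and
#' picks the argmax (ties resolve to the lowest corner index, NE-NW-SE-SW),
#' correct when it matches the phantom's randomized layout; the central
#' task compares the statistic at the cell centre against three disk-free
#' decoy positions on the cell-edge midpoints, so both tasks have a 25%
#' chance level and need no absolute threshold.
#'
#' @param image A `cdmam_image`.
#' @param phantom The [cdmam_phantom()].
#' @param geom A `cdmam_grid` from [locate_grid()].
#' @param cell_id Identifier of a present cell.
#' @return A one-row tibble (see [score_image()] for the columns).
#' @export
score_cell <- function(image, phantom, geom, cell_id) {
  cells <- phantom$cells
  hit <- cells[cells$cell_id == cell_id, ]
  if (nrow(hit) != 1L) stop_lookup(sprintf("Unknown cell '%s'.", cell_id))
  if (!hit$present) stop_lookup(sprintf("Cell '%s' carries no disks.", cell_id))
  cache <- new.env(parent = emptyenv())
  score_cell_impl(image, phantom, geom, hit, cache,
                  psf_sigma = image$meta$psf_sigma %||% (0.8 * image$pitch))
}

score_cell_impl <- function(image, phantom, geom, cell, cache, psf_sigma) {
  base <- c(cell$x, cell$y) + geom$offset_mm
  corners <- corner_offsets(phantom)
  cs <- vapply(seq_len(4L), function(k) {
    statistic_at(image, base + corners[k, ], cell$diameter, cache, psf_sigma)
  }, numeric(1))
  chosen <- rownames(corners)[which.max(cs)]
  corner_correct <- identical(chosen, cell$corner)

  decoys <- decoy_offsets(phantom)
  ds <- vapply(seq_len(3L), function(k) {
    statistic_at(image, base + decoys[k, ], cell$diameter, cache, psf_sigma)
  }, numeric(1))
  centre_stat <- statistic_at(image, base, cell$diameter, cache, psf_sigma)
  center_detected <- which.max(c(centre_stat, ds)) == 1L

  status <- if (corner_correct && center_detected) "both"
            else if (corner_correct || center_detected) "one"
            else "neither"
  tibble(
    cell_id = cell$cell_id, row = cell$row, col = cell$col,
    diameter = cell$diameter, thickness = cell$thickness,
    present = TRUE, true_corner = cell$corner, chosen_corner = chosen,
    s_NE = cs[1L], s_NW = cs[2L], s_SE = cs[3L], s_SW = cs[4L],
    center_stat = centre_stat,
    corner_correct = corner_correct, center_detected = center_detected,
    status = status, credited = NA
  )
}

#' Score every cell of an image
#'
#' Applies [score_cell()] to all 205 present cells and returns the
#' uncorrected detection matrix. Apply [apply_corrections()] before
#' computing [total_detected()].
#'
#' @inheritParams score_cell
#' @param geom Optional `cdmam_grid`; located automatically when `NULL`.
#' @param image_id Label recorded on the result.
#' @return A tibble of class `cdmam_detections` with one row per present
#'   cell: the cell descriptors, the four corner statistics, the chosen
#'   corner, `corner_correct`, `center_detected` and the combined `status`
#'   (`"both"`, `"one"`, `"neither"`). Attributes record `corrected` (FALSE)
#'   and the correction `scheme` (NA).
#' @export
score_image <- function(image, phantom, geom = NULL, image_id = "image") {
  stopifnot(inherits(image, "cdmam_image"), inherits(phantom, "cdmam_phantom"))
  geom <- geom %||% locate_grid(image, phantom)
  psf_sigma <- image$meta$psf_sigma %||% (0.8 * image$pitch)
  cache <- new.env(parent = emptyenv())
  cells <- phantom$cells[phantom$cells$present, ]
  out <- purrr::list_rbind(lapply(seq_len(nrow(cells)), function(k) {
    score_cell_impl(image, phantom, geom, cells[k, ], cache, psf_sigma)
  }))
  attr(out, "corrected") <- FALSE
  attr(out, "scheme") <- NA_character_
  attr(out, "image_id") <- image_id
  class(out) <- c("cdmam_detections", class(out))
  out
}

#' Apply detection-matrix correction rules
#'
#' Two corrections are supported. The missing-corner rule is always
#' applied: each of the two disk-free matrix corners is counted as detected
#' exactly when both of its two in-grid neighbours are fully detected
#' (status `"both"`). Optionally (`scheme = "nn"`), a nearest-neighbour
#' smoothing pass first promotes a cell to detected when at least two of
#' its grid neighbours are fully detected and its own corner choice was the
#' true corner or one adjacent to it; `scheme = "none"` (the default)
#' leaves the 205 scored cells untouched, since only the missing-corner
#' rule is part of the core scoring definition.
#'
#' @param dm An uncorrected `cdmam_detections` from [score_image()].
#' @param phantom The [cdmam_phantom()] that produced it.
#' @param scheme `"none"` or `"nn"`.
#' @return A `cdmam_detections` with 207 rows: the (possibly smoothed) 205
#'   cells plus the two matrix corners with `credited` TRUE/FALSE. The
#'   `corrected` attribute is TRUE and `scheme` records the scheme id.
#' @export
apply_corrections <- function(dm, phantom, scheme = c("none", "nn")) {
  scheme <- tryCatch(match.arg(scheme),
                     error = function(e) stop_config("Unknown correction scheme."))
  if (isTRUE(attr(dm, "corrected"))) {
    stop_data("Detection matrix is already corrected.")
  }
  cells <- phantom$cells

  if (scheme == "nn") {
    adjacent <- list(NE = c("NW", "SE"), NW = c("NE", "SW"),
                     SE = c("SW", "NE"), SW = c("SE", "NW"))
    both0 <- dm$status == "both"
    promote <- vapply(seq_len(nrow(dm)), function(k) {
      if (both0[k]) return(FALSE)
      nb <- neighbors_of(phantom, dm$cell_id[k])
      nb_both <- sum(both0[match(nb$cell_id, dm$cell_id)], na.rm = TRUE)
      ok_corner <- dm$chosen_corner[k] %in%
        c(dm$true_corner[k], adjacent[[dm$true_corner[k]]])
      nb_both >= 2L && ok_corner
    }, logical(1))
    dm$corner_correct[promote] <- TRUE
    dm$center_detected[promote] <- TRUE
    dm$status[promote] <- "both"
  }

  absent <- cells[!cells$present, ]
  extra <- purrr::list_rbind(lapply(seq_len(nrow(absent)), function(k) {
    nb <- neighbors_of(phantom, absent$cell_id[k])
    credited <- all(dm$status[match(nb$cell_id, dm$cell_id)] == "both")
    tibble(
      cell_id = absent$cell_id[k], row = absent$row[k], col = absent$col[k],
      diameter = absent$diameter[k], thickness = absent$thickness[k],
      present = FALSE, true_corner = NA_character_,
      chosen_corner = NA_character_,
      s_NE = NA_real_, s_NW = NA_real_, s_SE = NA_real_, s_SW = NA_real_,
      center_stat = NA_real_,
      corner_correct = NA, center_detected = NA,
      status = if (credited) "both" else "neither",
      credited = credited
    )
  }))
  out <- bind_rows(dm, extra)
  attr(out, "corrected") <- TRUE
  attr(out, "scheme") <- scheme
  attr(out, "image_id") <- attr(dm, "image_id")
  class(out) <- c("cdmam_detections", class(tibble()))
  out
}

#' Flag an erratically scored image
#'
#' A well-behaved contrast-detail image detects thick, large disks first
#' and loses thin, small ones, so the per-cell detection outcome correlates
#' strongly with the disk detectability index thickness x diameter. An
#' image whose detection pattern is essentially random (the failure mode
#' occasionally produced by automated analysers on reconstructed layers)
#' shows no such correlation. The guard computes the pooled point-biserial
#' correlation between the peripheral detection outcome and
#' log(thickness x diameter) and flags the image as erratic below
#' `min_cor` (default 0.25: ordered images score around 0.4-0.7, random
#' patterns 0 +- 0.07).
#'
#' @param dm A `cdmam_detections` (corrected or not).
#' @param min_cor Correlation threshold below which the image is erratic.
#' @return A list with `erratic` (logical) and `score` (the correlation;
#'   NA when detection has no variance, which is never flagged).
#' @export
flag_erratic <- function(dm, min_cor = 0.25) {
  d <- dm[dm$present, ]
  x <- as.numeric(d$corner_correct)
  score <- suppressWarnings(cor(x, log(d$thickness * d$diameter)))
  list(erratic = is.finite(score) && score < min_cor, score = score)
}

#' Text contrast-detail score diagram
#'
#' Renders the detection matrix as a text grid in matrix coordinates:
#' `#` both disks detected, `+` one, `.` neither, `o` a credited matrix
#' corner, space an unoccupied position.
#'
#' @param dm A `cdmam_detections`.
#' @return A character vector of 16 lines, invisibly; printed as a side
#'   effect when `quiet = FALSE`.
#' @param quiet Suppress printing.
#' @export
format_score_diagram <- function(dm, quiet = FALSE) {
  grid <- matrix(" ", 16, 16)
  sym <- c(both = "#", one = "+", neither = ".")
  for (k in seq_len(nrow(dm))) {
    ch <- if (!dm$present[k]) {
      if (isTRUE(dm$credited[k])) "o" else "-"
    } else {
      sym[[dm$status[k]]]
    }
    grid[dm$row[k], dm$col[k]] <- ch
  }
  lines <- apply(grid, 1L, paste0, collapse = "")
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
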