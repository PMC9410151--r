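#' Default gold-disk diameter and thickness series
#'
#' The contrast-detail grid carries 16 disk diameters (2.00 mm down to
#' 0.06 mm) and 16 gold thicknesses (0.03 um up to 2.00 um) on a
#' near-geometric ladder. Eleven of the diameters (0.10-1.00 mm) are the
#' standard reporting columns of the CDMAM 3.4 phantom; the full series is
#' overridable through [cdmam_phantom()] for phantoms with a different
#' layout.
#'
#' @return A list with numeric vectors `diameters` (mm, strictly decreasing)
#'   and `thicknesses` (um, strictly increasing), each of length 16.
#' @export
#' @examples
#' cdmam_series()$diameters
cdmam_series <- function() {
  list(
    diameters = c(2.00, 1.60, 1.25, 1.00, 0.80, 0.63, 0.50, 0.40,
                  0.31, 0.25, 0.20, 0.16, 0.13, 0.10, 0.08, 0.06),
    thicknesses = c(0.03, 0.04, 0.05, 0.06, 0.08, 0.10, 0.13, 0.16,
                    0.20, 0.25, 0.36, 0.50, 0.71, 1.00, 1.42, 2.00)
  )
}

#' Default occupancy mask of the contrast-detail grid
#'
#' Which of the 16 x 16 (diameter row, thickness column) positions carry a
#' cell. The default is a staircase band of 207 positions: every diameter
#' row samples 13 consecutive thicknesses (12 for row 8), shifted towards
#' thicker gold as the disks shrink. Two of the 207 positions -- the
#' (thinnest gold, largest diameter) and (thickest gold, smallest diameter)
#' matrix corners -- exist in the grid but carry no disks; the remaining
#' 205 are scoreable cells.
#'
#' @return A 16 x 16 logical matrix; rows index diameters (largest first),
#'   columns index thicknesses (thinnest first).
#' @export
default_occupancy <- function() {
  a <- c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L)
  occ <- matrix(FALSE, 16, 16)
  for (i in seq_len(16)) {
    b <- if (i == 8L) a[i] + 11L else a[i] + 12L
    occ[i, a[i]:b] <- TRUE
  }
  occ
}

#' Build a contrast-detail phantom model
#'
#' Constructs the full geometric ground truth of a CDMAM-style phantom: a
#' 16 x 16 matrix of square cells rotated by -45 degrees with respect to
#' the detector, where rows share a disk diameter and columns share a gold
#' thickness. Each present cell holds one disk at its centre and an
#' identical disk in one of its four corners, chosen at random with a
#' dedicated seed so that corner layouts are reproducible independently of
#' any rendering noise. The two matrix-corner positions (thinnest gold at
#' the largest diameter, thickest gold at the smallest diameter) are part
#' of the grid but carry no disks.
#'
#' @param diameters Numeric vector of 16 disk diameters in mm, strictly
#'   decreasing. Defaults to [cdmam_series()].
#' @param thicknesses Numeric vector of 16 gold thicknesses in um, strictly
#'   increasing. Defaults to [cdmam_series()].
#' @param cell_mm Side of a grid cell in mm (phantom frame).
#' @param corner_seed Integer seed for the random peripheral-corner layout.
#' @param occupancy 16 x 16 logical occupancy mask, see
#'   [default_occupancy()].
#' @param rotation Grid rotation relative to the detector, in degrees.
#' @return An object of class `cdmam_phantom`: a list with the cell table
#'   (see [phantom_cells()]), the series, the rotation matrix, the grid
#'   extent in mm and the physical description (0.5 mm aluminium base,
#'   PMMA cover equivalent to 5 cm PMMA / 6 cm compressed breast,
#'   18 x 24 cm field).
#' @export
#' @examples
#' ph <- cdmam_phantom(corner_seed = 7)
#' sum(phantom_cells(ph)$present)
cdmam_phantom <- function(diameters = cdmam_series()$diameters,
                          thicknesses = cdmam_series()$thicknesses,
                          cell_mm = 7,
                          corner_seed = 1L,
                          occupancy = default_occupancy(),
                          rotation = -45) {
  if (length(diameters) != 16L || length(thicknesses) != 16L) {
    stop_config("`diameters` and `thicknesses` must each have 16 entries.")
  }
  if (anyDuplicated(diameters) || any(diff(diameters) >= 0)) {
    stop_config("`diameters` must be strictly decreasing with no duplicates.")
  }
  if (anyDuplicated(thicknesses) || any(diff(thicknesses) <= 0)) {
    stop_config("`thicknesses` must be strictly increasing with no duplicates.")
  }
  if (any(diameters < 0.04) || any(diameters > 2.5)) {
    stop_config("`diameters` must lie in a plausible 0.04-2.5 mm range.")
  }
  if (any(thicknesses < 0) || any(thicknesses > 2.5)) {
    stop_config("`thicknesses` must lie in 0-2.5 um.")
  }
  if (!is.matrix(occupancy) || !identical(dim(occupancy), c(16L, 16L)) ||
      !is.logical(occupancy)) {
    stop_config("`occupancy` must be a 16 x 16 logical matrix.")
  }
  if (!occupancy[1L, 1L] || !occupancy[16L, 16L]) {
    stop_config(paste0("`occupancy` must include the two matrix corners ",
                       "(row 1, col 1) and (row 16, col 16)."))
  }

  idx <- which(occupancy, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  row <- idx[, 1L]
  col <- idx[, 2L]
  absent <- (row == 1L & col == 1L) | (row == 16L & col == 16L)

  theta <- rotation * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

  # unrotated cell-centre coordinates (u right, v down), then rotate
  u <- (col - 1) * cell_mm
  v <- (row - 1) * cell_mm
  xy <- cbind(u, v) %*% t(rot)
  xy[, 1L] <- xy[, 1L] - min(xy[, 1L])
  xy[, 2L] <- xy[, 2L] - min(xy[, 2L])

  n <- length(row)
  corner <- rep(NA_character_, n)
  corner[!absent] <- with_seed(derive_seed(corner_seed, "corner"),
                               sample(c("NE", "NW", "SE", "SW"),
                                      sum(!absent), replace = TRUE))

  cells <- tibble(
    cell_id = sprintf("r%02dc%02d", row, col),
    row = as.integer(row),
    col = as.integer(col),
    diameter = diameters[row],
    thickness = thicknesses[col],
    present = !absent,
    corner = corner,
    x = xy[, 1L],
    y = xy[, 2L]
  )

  structure(
    list(
      cells = cells,
      diameters = diameters,
      thicknesses = thicknesses,
      cell_mm = cell_mm,
      corner_seed = as.integer(corner_seed),
      occupancy = occupancy,
      rotation = rotation,
      rot = rot,
      extent_mm = c(x = max(xy[, 1L]), y = max(xy[, 2L])),
      field_mm = c(x = 180, y = 240),
      base = list(material = "aluminum", thickness_mm = 0.5),
      cover_equivalence = list(pmma_cm = 5, breast_cm = 6)
    ),
    class = "cdmam_phantom"
  )
}

#' @export
print.cdmam_phantom <- function(x, ...) {
  cat("<cdmam_phantom>\n")
  cat(sprintf("  cells: %d present, %d absent grid corners\n",
              sum(x$cells$present), sum(!x$cells$present)))
  cat(sprintf("  diameters: %.2f-%.2f mm; thicknesses: %.2f-%.2f um\n",
              min(x$diameters), max(x$diameters),
              min(x$thicknesses), max(x$thicknesses)))
  cat(sprintf("  cell %.1f mm, rotation %g deg, grid extent %.1f x %.1f mm\n",
              x$cell_mm, x$rotation, x$extent_mm[["x"]], x$extent_mm[["y"]]))
  cat(sprintf("  corner seed %d\n", x$corner_seed))
  invisible(x)
}

#' Cell table of a phantom
#'
#' @param phantom A [cdmam_phantom()] object.
#' @return A tibble with one row per grid cell: `cell_id`, matrix `row`
#'   (constant diameter) and `col` (constant thickness), `diameter` (mm),
#'   `thickness` (um), `present` (FALSE for the two empty matrix corners),
#'   the randomized peripheral `corner` (NE/NW/SE/SW, NA when absent) and
#'   the cell-centre position `x`, `y` in mm in the detector frame (grid
#'   bounding box starting at the origin).
#' @export
phantom_cells <- function(phantom) {
  stopifnot(inherits(phantom, "cdmam_phantom"))
  phantom$cells
}

#' Grid neighbours of a cell
#'
#' Returns the cells adjacent to `cell_id` along its matrix row and column
#' (up to four). The two disk-free matrix corners have exactly two in-grid
#' neighbours; those neighbours decide whether the corner is credited as
#' detected by [apply_corrections()].
#'
#' @param phantom A [cdmam_phantom()] object.
#' @param cell_id A cell identifier present in `phantom_cells(phantom)`.
#' @return A tibble of neighbouring cells (subset of [phantom_cells()]).
#' @export
neighbors_of <- function(phantom, cell_id) {
  stopifnot(inherits(phantom, "cdmam_phantom"))
  cells <- phantom$cells
  hit <- cells[cells$cell_id == cell_id, ]
  if (nrow(hit) != 1L) {
    stop_lookup(sprintf("Cell '%s' is not part of this phantom.", cell_id))
  }
  r <- hit$row
  k <- hit$col
  nb <- cells[(cells$row == r & abs(cells$col - k) == 1L) |
                (cells$col == k & abs(cells$row - r) == 1L), ]
  nb
}

# Corner/decoy offsets in the detector frame for a given phantom.
# Corners sit a quarter cell in from the cell centre along both cell axes;
# centre-task decoys sit on three cell-edge midpoints, far enough from every
# disk that their matched-filter footprints never overlap a real disk.
corner_offsets <- function(phantom) {
  q <- phantom$cell_mm / 4
  uv <- rbind(NE = c(q, -q), NW = c(-q, -q), SE = c(q, q), SW = c(-q, q))
  uv %*% t(phantom$rot)
}

decoy_offsets <- function(phantom) {
  m <- phantom$cell_mm / 2
  uv <- rbind(midN = c(0, -m), midE = c(m, 0), midS = c(0, m))
  uv %*% t(phantom$rot)
}

#' Read or write a phantom configuration file
#'
#' The phantom geometry is fully described by a small YAML file: the two
#' series, the cell size, the corner seed and the occupancy mask (as row
#' ranges). This keeps phantom variants as data rather than code.
#'
#' @param path File path.
#' @param phantom For `write_phantom_config()`, a [cdmam_phantom()].
#' @return `read_phantom_config()` returns a `cdmam_phantom`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
read_phantom_config <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("No such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  occ <- default_occupancy()
  if (!is.null(cfg$occupancy_rows)) {
    occ <- matrix(FALSE, 16, 16)
    for (i in seq_along(cfg$occupancy_rows)) {
      rng <- cfg$occupancy_rows[[i]]
      occ[i, rng[[1]]:rng[[2]]] <- TRUE
    }
    if (isTRUE(cfg$drop_row8_last)) {
      occ[8, max(which(occ[8, ]))] <- FALSE
    }
  }
  cdmam_phantom(
    diameters = cfg$diameters %||% cdmam_series()$diameters,
    thicknesses = cfg$thicknesses %||% cdmam_series()$thicknesses,
    cell_mm = cfg$cell_mm %||% 7,
    corner_seed = cfg$corner_seed %||% 1L,
    occupancy = occ,
    rotation = cfg$rotation %||% -45
  )
}

#' @rdname read_phantom_config
#' @export
write_phantom_config <- function(phantom, path) {
  stopifnot(inherits(phantom, "cdmam_phantom"))
  occ <- phantom$occupancy
  rows <- lapply(seq_len(16), function(i) {
    j <- which(occ[i, ])
    c(min(j), max(j))
  })
  yaml::write_yaml(
    list(
      diameters = phantom$diameters,
      thicknesses = phantom$thicknesses,
      cell_mm = phantom$cell_mm,
      corner_seed = phantom$corner_seed,
      rotation = phantom$rotation,
      occupancy_rows = rows,
      drop_row8_last = sum(occ[8, ]) < (max(which(occ[8, ])) - min(which(occ[8, ])) + 1)
    ),
    path
  )
  invisible(path)
}
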