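#' Inverse image-quality figure
#'
#' The scalar image-quality score of a contrast-detail reading:
#' `IQF_inv = 100 / sum_i(t_thr,i * d_i)` over the 16 diameter columns,
#' where `t_thr,i` is the threshold gold thickness (um) of the column with
#' diameter `d_i` (mm). Thinner thresholds mean better image quality and a
#' larger score; the score is strictly decreasing in every threshold and
#' scales inversely (halving all thresholds doubles it).
#'
#' @param thresholds Numeric vector of 16 threshold thicknesses (um).
#' @param diameters Numeric vector of 16 diameters (mm), pairing
#'   `thresholds`.
#' @return A single numeric score.
#' @export
#' @examples
#' iqf_inv(rep(2, 16), cdmam_series()$diameters)
iqf_inv <- function(thresholds, diameters) {
  if (length(thresholds) != 16L || length(diameters) != 16L) {
    stop_config("`thresholds` and `diameters` must each have 16 entries.")
  }
  if (any(!is.finite(thresholds)) || any(!is.finite(diameters)) ||
      any(thresholds <= 0) || any(diameters <= 0)) {
    stop_config("All thresholds and diameters must be positive and finite.")
  }
  100 / sum(thresholds * diameters)
}

#' Total detected score
#'
#' The percentage of grid squares with both disks detected: the cells with
#' status `"both"` plus any credited matrix corners, out of all 207 grid
#' positions (205 cells + 2 corners). Requires a corrected detection
#' matrix, since the corner-crediting rule is part of the definition.
#'
#' @param dm A corrected `cdmam_detections` (see [apply_corrections()]).
#' @return Percentage in `[0, 100]`.
#' @export
total_detected <- function(dm) {
  if (!isTRUE(attr(dm, "corrected"))) {
    stop_data("Apply `apply_corrections()` before computing total_detected().")
  }
  100 * sum(dm$status == "both") / nrow(dm)
}

#' Group score of an image set
#'
#' Aggregates per-image scores into a group score. `"mean_of_images"`
#' (default) takes arithmetic means of the per-image `IQF_inv` and
#' total-detected values. `"score_of_pooled"` instead recomputes `IQF_inv`
#' from the thresholds of the pooled detection data (supply `dms`), which
#' is how an analyser working on pooled psychometric curves would
#' aggregate; the two generally differ and the method used is recorded on
#' the result.
#'
#' @param per_image A tibble with `iqf_inv` and `total_detected` columns,
#'   one row per image.
#' @param method `"mean_of_images"` or `"score_of_pooled"`.
#' @param dms For `"score_of_pooled"`: the list of corrected
#'   `cdmam_detections` to pool.
#' @param ... Passed to [threshold_table()] for the pooled method.
#' @return A one-row tibble with `method`, `iqf_inv`, `total_detected`,
#'   `n_images`.
#' @export
group_score <- function(per_image,
                        method = c("mean_of_images", "score_of_pooled"),
                        dms = NULL, ...) {
  method <- match.arg(method)
  if (nrow(per_image) == 0L) stop_data("No per-image scores to aggregate.")
  if (method == "mean_of_images") {
    tibble(method = method,
           iqf_inv = mean(per_image$iqf_inv),
           total_detected = mean(per_image$total_detected),
           n_images = nrow(per_image))
  } else {
    if (is.null(dms)) {
      stop_config("`score_of_pooled` needs the detection matrices in `dms`.")
    }
    tt <- threshold_table(dms, ...)
    tibble(method = method,
           iqf_inv = iqf_inv(tt$t_auto, tt$diameter),
           total_detected = mean(per_image$total_detected),
           n_images = nrow(per_image))
  }
}

#' EUREF performance limits
#'
#' The European-protocol acceptable and achievable threshold-thickness
#' limits for 2D mammography at the four reference disk diameters.
#'
#' @return A tibble with `diameter` (mm), `acceptable` (um), `achievable`
#'   (um).
#' @export
euref_limits <- function() {
  tibble(
    diameter = c(1, 0.5, 0.25, 0.1),
    acceptable = c(0.091, 0.15, 0.352, 1.68),
    achievable = c(0.056, 0.103, 0.244, 1.1)
  )
}

#' Classify thresholds against EUREF limits
#'
#' Compares fit-to-predicted-human threshold thicknesses at the four EUREF
#' reference diameters against the limits: `above_acceptable` when the
#' threshold exceeds the acceptable limit, `achievable` when at or below
#' the achievable limit, `acceptable` in between. Boundaries pass (a
#' threshold exactly equal to a limit satisfies it); the protocol prints
#' limits without a boundary rule, so the lenient reading is used and
#' documented here.
#'
#' @param data A tibble with `diameter` and `t_fit` columns covering every
#'   limit diameter.
#' @param limits A limits tibble, defaulting to [euref_limits()].
#' @return A tibble with `diameter`, `t_fit`, `acceptable`, `achievable`,
#'   `status` and `above_acceptable`.
#' @export
#' @examples
#' euref_classify(tibble::tibble(diameter = c(1, 0.5, 0.25, 0.1),
#'                               t_fit = c(0.05, 0.09, 0.23, 1.23)))
euref_classify <- function(data, limits = euref_limits()) {
  stopifnot(all(c("diameter", "t_fit") %in% names(data)))
  if (any(limits$achievable >= limits$acceptable)) {
    stop_config("Achievable limits must lie below acceptable limits.")
  }
  out <- left_join(limits, data[, c("diameter", "t_fit")], by = "diameter")
  if (anyNA(out$t_fit)) {
    stop_data(sprintf("Missing thresholds at diameter(s): %s mm.",
                      paste(out$diameter[is.na(out$t_fit)], collapse = ", ")))
  }
  out$status <- dplyr::case_when(
    out$t_fit > out$acceptable ~ "above_acceptable",
    out$t_fit <= out$achievable ~ "achievable",
    TRUE ~ "acceptable"
  )
  out$above_acceptable <- out$status == "above_acceptable"
  out[, c("diameter", "t_fit", "acceptable", "achievable",
          "status", "above_acceptable")]
}

#' Stack index of a tomographic layer
#'
#' Reconstructed layers are numbered from 1 starting at the layer at the
#' breast-support surface (`origin`), so the layer at `height` mm with
#' `spacing` mm between layers is image `round((height - origin)/spacing) + 1`
#' of the stack -- e.g. the 22 mm layer of a 1 mm stack is the 23rd image.
#'
#' @param height Layer height in mm.
#' @param spacing Layer spacing in mm (> 0).
#' @param origin Height of the first layer in mm.
#' @return The 1-based integer stack index.
#' @export
#' @examples
#' tl_index_for_height(22, 1, 0)
tl_index_for_height <- function(height, spacing = 1, origin = 0) {
  if (spacing <= 0) stop_config("`spacing` must be positive.")
  if (height < origin - 1e-9) stop_config("`height` is below the stack origin.")
  steps <- (height - origin) / spacing
  if (abs(steps - round(steps)) > 1e-6) {
    stop_config("`height` is not on the layer grid within tolerance.")
  }
  as.integer(round(steps)) + 1L
}
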