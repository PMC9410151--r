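#' Score a set of phantom images
#'
#' The full scoring pipeline for one acquisition mode: registers and scores
#' each image, applies the correction rules, screens for erratically
#' scored images, computes per-image scores (`IQF_inv` from the per-image
#' monotone threshold envelope, total-detected from the corrected matrix),
#' pools the usable images into psychometric fits and a threshold table,
#' and classifies the contrast-detail curve against the EUREF limits.
#'
#' Per-image thresholds use the monotone envelope of the peripheral-task
#' outcomes (the thinnest gold above which every thicker disk in the
#' column was detected); pooled thresholds come from the psychometric fits
#' of [threshold_table()].
#'
#' @param images A list of `cdmam_image` or `cdmam_render` objects.
#' @param phantom The [cdmam_phantom()] depicted.
#' @param correction Correction scheme for [apply_corrections()].
#' @param group_method Aggregation for [group_score()].
#' @param erratic_min_cor Threshold for [flag_erratic()]; erratic images
#'   are excluded from the group score and pooled fits and listed in the
#'   report.
#' @param r,b,degree Psychometric-stage settings, see [threshold_table()].
#' @return An object of class `cd_report`: a list with `per_image`,
#'   `group`, `thresholds`, `euref`, `detections` (corrected matrices),
#'   `excluded` (image ids) and `settings`.
#' @export
cd_score_set <- function(images, phantom,
                         correction = c("none", "nn"),
                         group_method = c("mean_of_images", "score_of_pooled"),
                         erratic_min_cor = 0.25,
                         r = 1.47, b = 1, degree = 3) {
  correction <- match.arg(correction)
  group_method <- match.arg(group_method)
  if (length(images) == 0L) stop_data("No images to score.")
  images <- lapply(images, function(im) {
    if (inherits(im, "cdmam_render")) im$image else im
  })
  ids <- names(images) %||% sprintf("image%02d", seq_along(images))
  if (is.null(names(images))) names(images) <- ids

  dms <- purrr::imap(images, function(im, id) {
    geom <- locate_grid(im, phantom)
    dm <- score_image(im, phantom, geom, image_id = id)
    apply_corrections(dm, phantom, scheme = correction)
  })

  per_image <- purrr::imap(dms, function(dm, id) {
    er <- flag_erratic(dm, min_cor = erratic_min_cor)
    thr <- image_thresholds(dm, phantom)
    tibble(
      image_id = id,
      iqf_inv = iqf_inv(thr$t_thr, thr$diameter),
      total_detected = total_detected(dm),
      erratic = er$erratic,
      erratic_score = er$score
    )
  }) |> purrr::list_rbind()

  usable <- per_image$image_id[!per_image$erratic]
  excluded <- per_image$image_id[per_image$erratic]
  if (length(usable) == 0L) {
    stop_data("All images were flagged erratic; nothing to aggregate.")
  }
  grp <- group_score(per_image[!per_image$erratic, ],
                     method = group_method, dms = dms[usable],
                     r = r, b = b, degree = degree)
  tt <- threshold_table(dms[usable], r = r, b = b, degree = degree)
  eu <- tryCatch(euref_classify(tt[, c("diameter", "t_fit")]),
                 error = function(e) NULL)

  structure(
    list(
      per_image = per_image,
      group = grp,
      thresholds = tt,
      euref = eu,
      detections = dms,
      excluded = excluded,
      settings = list(
        correction = correction,
        group_method = group_method,
        erratic_min_cor = erratic_min_cor,
        conversion = c(r = r, b = b),
        degree = degree,
        phantom_digest = rlang::hash(phantom),
        n_images = length(images)
      )
    ),
    class = "cd_report"
  )
}

# Per-image monotone threshold envelope for one detection matrix.
image_thresholds <- function(dm, phantom) {
  d <- dm[dm$present, ]
  d |>
    group_by(.data$diameter) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(g$thickness), ]
      det <- g$corner_correct
      t_thr <- if (all(det)) {
        min(g$thickness)
      } else if (!det[length(det)]) {
        max(g$thickness)
      } else {
        g$thickness[max(which(!det)) + 1L]
      }
      tibble(t_thr = t_thr)
    }) |>
    ungroup() |>
    arrange(dplyr::desc(.data$diameter))
}

#' @export
print.cd_report <- function(x, ...) {
  cat("<cd_report>\n")
  cat(sprintf("  %d image(s), %d excluded as erratic\n",
              x$settings$n_images, length(x$excluded)))
  cat(sprintf("  group (%s): IQF_inv %.2f, total detected %.2f%%\n",
              x$group$method, x$group$iqf_inv, x$group$total_detected))
  if (!is.null(x$euref)) {
    cat(sprintf("  EUREF: %s\n",
                paste(sprintf("%.2g mm %s", x$euref$diameter, x$euref$status),
                      collapse = "; ")))
  }
  invisible(x)
}

#' Write report CSVs
#'
#' Serialises a `cd_report` into flat CSV files: per-image scores with the
#' group row appended, and the three-row threshold table. Every file
#' embeds the correction scheme, aggregation method and configuration
#' digest as a comment header so reports are self-describing.
#'
#' @param report A `cd_report`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report_csv <- function(report, dir, prefix = "cdmam") {
  stopifnot(inherits(report, "cd_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# correction=%s group_method=%s phantom=%s",
                 report$settings$correction, report$settings$group_method,
                 report$settings$phantom_digest)

  scores <- file.path(dir, paste0(prefix, "_scores.csv"))
  per <- report$per_image
  grp_row <- data.frame(image_id = "Group Score",
                        iqf_inv = round(report$group$iqf_inv, 2),
                        total_detected = round(report$group$total_detected, 2),
                        erratic = NA, erratic_score = NA)
  tab <- rbind(
    data.frame(image_id = per$image_id,
               iqf_inv = round(per$iqf_inv, 2),
               total_detected = round(per$total_detected, 2),
               erratic = per$erratic,
               erratic_score = round(per$erratic_score, 3)),
    grp_row)
  writeLines(hdr, scores)
  suppressWarnings(utils::write.table(tab, scores, sep = ",", append = TRUE,
                                      row.names = FALSE, qmethod = "double"))

  thr <- file.path(dir, paste0(prefix, "_thresholds.csv"))
  write_threshold_csv(report$thresholds, thr)

  paths <- c(scores = scores, thresholds = thr)
  if (!is.null(report$euref)) {
    eu <- file.path(dir, paste0(prefix, "_euref.csv"))
    utils::write.csv(report$euref, eu, row.names = FALSE)
    paths <- c(paths, euref = eu)
  }
  invisible(paths)
}
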