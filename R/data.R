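#' Example per-image scores of an eight-image 2D set
#'
#' Per-image `IQF_inv` and total-detected scores reported by a commercial
#' contrast-detail analyser for a set of eight 2D N-mode exposures of the
#' phantom on a clinical DBT unit, bundled as a worked aggregation example.
#' The analyser's own printed group values are attached as the
#' `"reported_group"` attribute; note its group `IQF_inv` (141.59) is not
#' the arithmetic mean of the per-image values (142.17), whereas the group
#' total-detected is -- see [group_score()] for the two aggregation methods
#' offered.
#'
#' @return A tibble with `image`, `iqf_inv`, `total_detected`.
#' @export
#' @examples
#' mean(example_image_scores()$total_detected)
example_image_scores <- function() {
  out <- tibble(
    image = 1:8,
    iqf_inv = c(148.19, 118.69, 144.99, 143.48, 144.94, 159.34, 135.80, 141.95),
    total_detected = c(67.61, 65.34, 67.61, 68.18, 69.32, 69.89, 68.47, 67.61)
  )
  attr(out, "reported_group") <- c(iqf_inv = 141.59, total_detected = 68.00)
  out
}

#' Example average threshold table of an eight-image 2D set
#'
#' The averaged automatic, predicted-human and fit-to-predicted-human
#' threshold gold thicknesses (um) per disk diameter reported by a
#' commercial analyser for the same eight-image 2D set as
#' [example_image_scores()]. Two entries of this table are apparent
#' decimal-shift misprints in the source report (`t_auto = 1.133` at
#' 0.25 mm breaks the row's monotone trend, as do `t_pred = 0.585` and
#' `t_fit = 0.590` at 0.80 mm); they are flagged in the `anomalous` column
#' and left uncorrected.
#'
#' @return A tibble with `diameter`, `t_auto`, `t_pred`, `t_fit`,
#'   `anomalous`.
#' @export
example_threshold_table <- function() {
  tibble(
    diameter = c(0.10, 0.13, 0.16, 0.20, 0.25, 0.31, 0.40, 0.50, 0.63, 0.80, 1.00),
    t_auto = c(0.839, 0.463, 0.292, 0.197, 1.133, 0.086, 0.059, 0.047,
               0.037, 0.028, 0.023),
    t_pred = c(1.231, 0.723, 0.479, 0.337, 0.237, 0.160, 0.114, 0.094,
               0.075, 0.585, 0.049),
    t_fit = c(1.240, 0.723, 0.488, 0.329, 0.229, 0.167, 0.119, 0.092,
              0.072, 0.590, 0.050),
    anomalous = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                  FALSE, TRUE, FALSE)
  )
}

#' Reference mode-by-mode evaluation of a dual-resolution DBT unit
#'
#' Fit-to-predicted-human threshold thicknesses at the four EUREF reference
#' diameters, exposure factors, average glandular dose and summary scores
#' for every clinical acquisition mode of a dual-resolution DBT
#' mammography unit (2D, synthesized-2D and in-focus tomographic layer;
#' normal and high dose; standard and high resolution), as reported by a
#' commercial analyser. `reported_above_acceptable` reproduces the
#' emphasis of the source report (thresholds flagged as exceeding the
#' EUREF acceptable limits) and serves as the fixture for
#' [euref_classify()]. The in-focus high-dose HR tomographic row is based
#' on a single usable image (`single_image`).
#'
#' @return A long tibble, one row per mode and reference diameter:
#'   `source`, `mode`, `resolution`, `dose`, `pixel_mm`, `agd_mgy`,
#'   `anode_filter`, `kvp`, `mas`, `iqf_inv`, `total_detected`,
#'   `single_image`, `diameter`, `t_fit`, `reported_above_acceptable`.
#' @export
#' @examples
#' dbt_mode_results() |> euref_by_mode()
dbt_mode_results <- function() {
  modes <- tibble(
    source = c("2D:N-mode", "2D:H-mode",
               "Sview:N-mode (ST)", "Sview:H-mode (ST)",
               "Sview:N-mode (HR)", "Sview:H-mode (HR)",
               "TL22:N-mode (ST)", "TL22:H-mode (ST)",
               "TL22:N-mode (HR)", "TL22:H-mode (HR)"),
    mode = c("2D", "2D", "s2D", "s2D", "s2D", "s2D", "TL", "TL", "TL", "TL"),
    resolution = c(NA, NA, "ST", "ST", "HR", "HR", "ST", "ST", "HR", "HR"),
    dose = c("N", "H", "N", "H", "N", "H", "N", "H", "N", "H"),
    pixel_mm = c(0.05, 0.05, 0.1, 0.1, 0.05, 0.05, 0.1, 0.1, 0.05, 0.05),
    agd_mgy = c(1.15, 1.61, 1.61, 2.00, 2.51, 3.15, 1.61, 2.00, 2.51, 3.15),
    anode_filter = c("W/Rh", "W/Rh", rep("W/Al", 8)),
    kvp = c(30, 30, rep(33, 8)),
    mas = c(71, 100, 32, 40, 50, 63, 32, 40, 50, 63),
    iqf_inv = c(141.59, 162.24, 80.26, 94.28, 62.16, 64.92,
                121.43, 150.45, 139.56, 157.32),
    total_detected = c(68, 69.7, 58.84, 61.65, 53.44, 54.08,
                       65.48, 68.61, 67.22, 69.32),
    single_image = c(rep(FALSE, 9), TRUE)
  )
  tfit <- rbind(
    c(1.23, 0.23, 0.09, 0.05),
    c(0.91, 0.21, 0.09, 0.04),
    c(2.24, 0.42, 0.16, 0.07),
    c(2.08, 0.34, 0.13, 0.06),
    c(2.49, 0.57, 0.22, 0.10),
    c(2.63, 0.50, 0.22, 0.11),
    c(1.36, 0.26, 0.11, 0.06),
    c(1.26, 0.20, 0.09, 0.05),
    c(0.87, 0.24, 0.12, 0.07),
    c(0.93, 0.21, 0.10, 0.05)
  )
  flagged <- rbind(
    c(FALSE, FALSE, FALSE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE),
    c(TRUE,  TRUE,  TRUE,  FALSE),
    c(TRUE,  FALSE, FALSE, FALSE),
    c(TRUE,  TRUE,  TRUE,  TRUE),
    c(TRUE,  TRUE,  TRUE,  TRUE),
    c(FALSE, FALSE, FALSE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE)
  )
  diam <- c(0.1, 0.25, 0.5, 1)
  long <- purrr::list_rbind(lapply(seq_len(nrow(modes)), function(i) {
    tibble(modes[i, ], diameter = diam, t_fit = tfit[i, ],
           reported_above_acceptable = flagged[i, ])
  }))
  long
}

#' EUREF classification per acquisition mode
#'
#' Runs [euref_classify()] on each mode of a long threshold table such as
#' [dbt_mode_results()].
#'
#' @param data A long tibble with `source`, `diameter`, `t_fit` columns.
#' @param limits Limits tibble, see [euref_limits()].
#' @return The input plus `status` and `above_acceptable` columns.
#' @export
euref_by_mode <- function(data, limits = euref_limits()) {
  data |>
    group_by(.data$source) |>
    dplyr::group_modify(function(g, key) {
      cls <- euref_classify(g[, c("diameter", "t_fit")], limits)
      left_join(g, cls[, c("diameter", "status", "above_acceptable")],
                by = "diameter")
    }) |>
    ungroup()
}
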