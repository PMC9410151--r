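#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Contrast-detail curve plot
#'
#' Plots threshold gold thickness against disk diameter on log-log axes
#' (the conventional contrast-detail curve; lower is better) together with
#' the EUREF acceptable and achievable limit curves.
#'
#' @param data A [threshold_table()] or any tibble with `diameter` and
#'   `t_fit` columns (extra curves may be supplied long-format with a
#'   `source` column).
#' @param limits Limits tibble, see [euref_limits()].
#' @return A ggplot object.
#' @export
plot_cd_curve <- function(data, limits = euref_limits()) {
  lim_long <- tidyr::pivot_longer(limits, c("acceptable", "achievable"),
                                  names_to = "limit", values_to = "t")
  has_source <- "source" %in% names(data)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$diameter, y = .data$t_fit)) +
    ggplot2::geom_line(ggplot2::aes(group = if (has_source) .data$source else 1,
                                    colour = if (has_source) .data$source else "measured")) +
    ggplot2::geom_point(ggplot2::aes(colour = if (has_source) .data$source else "measured")) +
    ggplot2::geom_line(data = lim_long,
                       ggplot2::aes(x = .data$diameter, y = .data$t,
                                    linetype = .data$limit),
                       colour = "grey35", inherit.aes = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Disk diameter (mm)",
                  y = "Threshold gold thickness (µm)",
                  colour = NULL, linetype = "EUREF limit") +
    ggplot2::theme_minimal()
  p
}

#' @rdname plot_cd_curve
#' @param object A `threshold_table`.
#' @param ... Unused.
#' @export
autoplot.threshold_table <- function(object, ...) {
  plot_cd_curve(object)
}

#' Plot a contrast-detail report
#'
#' @param object A `cd_report`.
#' @param ... Unused.
#' @return A ggplot contrast-detail curve of the pooled thresholds.
#' @export
autoplot.cd_report <- function(object, ...) {
  plot_cd_curve(object$thresholds)
}

#' Plot psychometric detection curves
#'
#' Empirical corner-correct fractions and the fitted 4-AFC psychometric
#' curves against gold thickness, one panel per disk diameter.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  s <- object$samples
  s$p <- s$k / s$n
  fits <- object$fits[object$fits$fit_ok, ]
  curves <- purrr::list_rbind(lapply(seq_len(nrow(fits)), function(i) {
    rng <- range(s$thickness[abs(s$diameter - fits$diameter[i]) < 1e-9])
    t <- exp(seq(log(rng[1L]), log(rng[2L]), length.out = 80))
    tibble(diameter = fits$diameter[i], thickness = t,
           p = psy_p(t, fits$c[i], fits$t0[i]))
  }))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$thickness, y = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::geom_hline(yintercept = c(0.25, 0.625), linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~diameter, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Gold thickness (µm)",
                  y = "P(correct corner)") +
    ggplot2::theme_minimal()
}

#' Plot a contrast-detail score diagram
#'
#' The dot-diagram view of a detection matrix in matrix coordinates:
#' filled points where both disks were detected, open where one, blank
#' where neither; credited matrix corners are marked separately.
#'
#' @param object A `cdmam_detections`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdmam_detections <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$outcome <- factor(d$status, levels = c("both", "one", "neither"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  shape = .data$outcome,
                                  colour = .data$outcome)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_shape_manual(values = c(both = 16, one = 1, neither = 4)) +
    ggplot2::scale_colour_manual(values = c(both = "red3", one = "pink3",
                                            neither = "grey70")) +
    ggplot2::labs(x = "Thickness column (thin → thick)",
                  y = "Diameter row (large → small)",
                  shape = "Detected", colour = "Detected") +
    ggplot2::theme_minimal()
}
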