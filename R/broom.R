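#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return The per-diameter fit tibble (`diameter`, `c`, `t0`, `fit_ok`,
#'   `deviance`, `n_levels`, `n_trials`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  x$fits
}

#' Glance at a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_diameters`, `n_ok`, `n_trials`,
#'   `total_deviance`.
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(
    n_diameters = nrow(x$fits),
    n_ok = sum(x$fits$fit_ok),
    n_trials = sum(x$fits$n_trials),
    total_deviance = sum(x$fits$deviance[x$fits$fit_ok])
  )
}

#' Tidy a contrast-detail report
#'
#' @param x A `cd_report`.
#' @param ... Unused.
#' @return The per-image score tibble.
#' @export
tidy.cd_report <- function(x, ...) {
  x$per_image
}

#' Glance at a contrast-detail report
#'
#' @param x A `cd_report`.
#' @param ... Unused.
#' @return A one-row tibble with the group scores, image counts and the
#'   number of EUREF diameters above the acceptable limit.
#' @export
glance.cd_report <- function(x, ...) {
  tibble(
    method = x$group$method,
    iqf_inv = x$group$iqf_inv,
    total_detected = x$group$total_detected,
    n_images = x$settings$n_images,
    n_excluded = length(x$excluded),
    n_above_acceptable = if (is.null(x$euref)) NA_integer_
                         else sum(x$euref$above_acceptable)
  )
}
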