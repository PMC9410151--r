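#' Pool detection outcomes across images
#'
#' Aggregates the per-cell peripheral-task outcomes of one or more
#' detection matrices into trial counts per (diameter, thickness), the
#' input format of [fit_psychometric()].
#'
#' @param dms A `cdmam_detections` or a list of them.
#' @return A tibble with `diameter`, `thickness`, `n` (trials) and `k`
#'   (correct corner choices).
#' @export
pool_detections <- function(dms) {
  if (inherits(dms, "cdmam_detections")) dms <- list(dms)
  purrr::list_rbind(lapply(dms, function(d) {
    tibble::as_tibble(d[d$present, c("diameter", "thickness", "corner_correct")])
  })) |>
    group_by(.data$diameter, .data$thickness) |>
    summarise(n = dplyr::n(), k = sum(.data$corner_correct), .groups = "drop") |>
    arrange(dplyr::desc(.data$diameter), .data$thickness)
}

# Negative log-likelihood of the 4-AFC psychometric model
# p(t) = 0.25 + 0.75 / (1 + exp(-c (ln t - ln t0))).
psy_p <- function(t, c, t0) 0.25 + 0.75 * plogis(c * (log(t) - log(t0)))

psy_nll <- function(par, t, n, k) {
  p <- psy_p(t, exp(par[1L]), exp(par[2L]))
  p <- pmin(pmax(p, 0.25 + 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

fit_one_diameter <- function(t, n, k) {
  phat <- k / n
  degenerate_hi <- all(phat >= 0.95)
  degenerate_lo <- all(phat <= 0.35)
  if (degenerate_hi || degenerate_lo || length(unique(t)) < 2L) {
    return(list(c = NA_real_, t0 = NA_real_, fit_ok = FALSE,
                deviance = NA_real_))
  }
  # start t0 at the first crossing of the 62.5% criterion, c at a mid slope
  above <- which(phat >= 0.625)
  lnt0 <- if (length(above) > 0) log(t[min(above)]) else log(max(t))
  fit <- tryCatch(
    optim(c(log(3), lnt0), psy_nll, t = t, n = n, k = k,
          method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(c = NA_real_, t0 = NA_real_, fit_ok = FALSE,
                deviance = NA_real_))
  }
  cc <- exp(fit$par[1L]); t0 <- exp(fit$par[2L])
  ok <- fit$convergence == 0 && is.finite(t0) && is.finite(cc) &&
    cc > 0.05 && cc < 200 && t0 > min(t) / 50 && t0 < max(t) * 50
  list(c = cc, t0 = t0, fit_ok = ok, deviance = 2 * fit$value)
}

#' Fit psychometric detection curves
#'
#' For each disk diameter, fits the 4-AFC psychometric function
#' `p(t) = 0.25 + 0.75 / (1 + exp(-c (ln t - ln t0)))` to the pooled
#' corner-correct counts by maximum likelihood. The lower asymptote is the
#' 25% chance level of the forced-choice task and `t0` is the thickness at
#' the 62.5% criterion (the midpoint of the 25-100% range), the
#' conventional threshold definition for a 4-AFC task. Degenerate columns
#' (fully detected, fully undetected, or a failed optimisation) return
#' `fit_ok = FALSE` rather than an error; [auto_thresholds()] applies the
#' boundary rules for those.
#'
#' @param data A tibble with columns `diameter`, `thickness`, `n`, `k`
#'   (see [pool_detections()]).
#' @return An object of class `psychometric_fit`: a list with `fits` (a
#'   tibble of `diameter`, `c`, `t0`, `fit_ok`, `deviance`, `n_levels`,
#'   `n_trials`) and `samples` (the input data).
#' @export
#' @examples
#' d <- tibble::tibble(diameter = 0.5,
#'                     thickness = c(0.06, 0.1, 0.16, 0.25, 0.5),
#'                     n = 16, k = c(4, 6, 11, 15, 16))
#' fit_psychometric(d)$fits
fit_psychometric <- function(data) {
  if (is.null(data) || nrow(data) == 0L) stop_data("No detection samples.")
  stopifnot(all(c("diameter", "thickness", "n", "k") %in% names(data)))
  if (any(data$n < data$k) || any(data$k < 0)) {
    stop_data("Trial counts must satisfy 0 <= k <= n.")
  }
  fits <- data |>
    group_by(.data$diameter) |>
    dplyr::group_modify(function(g, key) {
      if (length(unique(g$thickness)) < 2L) {
        stop_data("Need >= 2 distinct thicknesses per diameter.")
      }
      f <- fit_one_diameter(g$thickness, g$n, g$k)
      tibble(c = f$c, t0 = f$t0, fit_ok = f$fit_ok, deviance = f$deviance,
             n_levels = length(unique(g$thickness)), n_trials = sum(g$n))
    }) |>
    ungroup() |>
    arrange(dplyr::desc(.data$diameter))
  structure(list(fits = fits, samples = data), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>\n")
  print(x$fits, ...)
  invisible(x)
}

#' Threshold gold thickness for one diameter column
#'
#' Converts one diameter's psychometric fit into a threshold gold
#' thickness. If the fit succeeded and its 62.5% point lies inside the
#' column's sampled thickness range, the threshold is `t0`. A column
#' already detected at its thinnest sampled gold takes the smallest
#' thickness of its series (completely visible); one never reaching the
#' criterion takes the largest (completely invisible). When the fit failed
#' but the empirical rates do cross the criterion, the threshold is
#' interpolated linearly in log thickness.
#'
#' @param fit A `psychometric_fit` from [fit_psychometric()].
#' @param diameter The diameter (mm) to extract.
#' @return A list with `t_thr` (um) and `boundary` (one of `"none"`,
#'   `"floor"`, `"ceiling"`, `"interp"`).
#' @export
column_threshold <- function(fit, diameter) {
  stopifnot(inherits(fit, "psychometric_fit"))
  row <- fit$fits[abs(fit$fits$diameter - diameter) < 1e-9, ]
  if (nrow(row) != 1L) stop_lookup("No fit for that diameter.")
  s <- fit$samples[abs(fit$samples$diameter - diameter) < 1e-9, ]
  s <- s[order(s$thickness), ]
  series <- s$thickness
  phat <- s$k / s$n

  if (row$fit_ok && row$t0 >= min(series) && row$t0 <= max(series)) {
    return(list(t_thr = row$t0, boundary = "none"))
  }
  if (phat[1L] >= 0.625) {
    return(list(t_thr = min(series), boundary = "floor"))
  }
  if (max(phat) < 0.625) {
    return(list(t_thr = max(series), boundary = "ceiling"))
  }
  if (row$fit_ok) {  # fitted t0 fell outside the sampled range
    return(list(t_thr = min(max(row$t0, min(series)), max(series)),
                boundary = if (row$t0 < min(series)) "floor" else "ceiling"))
  }
  j <- min(which(phat >= 0.625))
  lt <- log(series[c(j - 1L, j)])
  pp <- phat[c(j - 1L, j)]
  t_thr <- exp(lt[1L] + (0.625 - pp[1L]) / (pp[2L] - pp[1L]) * diff(lt))
  list(t_thr = t_thr, boundary = "interp")
}

#' Automatic thresholds for all diameters
#'
#' Vectorised [column_threshold()] over every fitted diameter.
#'
#' @param fit A `psychometric_fit`.
#' @return A tibble with `diameter`, `t_auto` (um) and `boundary`.
#' @export
auto_thresholds <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  purrr::list_rbind(lapply(fit$fits$diameter, function(d) {
    ct <- column_threshold(fit, d)
    tibble(diameter = d, t_auto = ct$t_thr, boundary = ct$boundary)
  }))
}

#' Predicted-human threshold conversion
#'
#' Automated observers outperform human readers; reported thresholds are
#' therefore rescaled to predicted-human values with a power law
#' `t_pred = r * t_auto^b`. The default `r = 1.47`, `b = 1` matches the
#' ratio printed by the commercial analyser this package mirrors; the
#' conversion is system-specific and fully overridable. Being strictly
#' increasing, it preserves every ranking of acquisition modes.
#'
#' @param t_auto Automatic threshold thickness(es), um, positive.
#' @param r,b Power-law coefficients.
#' @return Predicted-human threshold thickness(es), um.
#' @export
predict_human <- function(t_auto, r = 1.47, b = 1) {
  if (any(!is.finite(t_auto)) || any(t_auto <= 0)) {
    stop_config("`t_auto` must be positive and finite.")
  }
  r * t_auto^b
}

#' Fit the smooth contrast-detail curve
#'
#' Least-squares polynomial fit (default cubic) of log threshold thickness
#' against log diameter, evaluated back at each diameter. This smooths the
#' per-diameter predicted-human thresholds into the final contrast-detail
#' curve used for reporting and EUREF comparison.
#'
#' @param data A tibble with `diameter` and `t_pred` columns.
#' @param degree Polynomial degree in log-log space.
#' @return A tibble with `diameter` and `t_fit`.
#' @export
fit_cd_curve <- function(data, degree = 3) {
  stopifnot(all(c("diameter", "t_pred") %in% names(data)))
  keep <- is.finite(data$t_pred) & data$t_pred > 0
  d <- data[keep, ]
  if (nrow(d) < 4L) stop_data("Need >= 4 diameters to fit the curve.")
  degree <- min(degree, nrow(d) - 1L)
  fit <- lm(log(t_pred) ~ poly(log(diameter), degree), data = d)
  tibble(diameter = data$diameter,
         t_fit = unname(exp(predict(fit, newdata = data))))
}

#' Threshold table for an image set
#'
#' The full psychometric stage in one call: pools detection matrices, fits
#' the per-diameter psychometric curves, applies the boundary rules,
#' converts to predicted-human thresholds and smooths them into the
#' contrast-detail curve.
#'
#' @param dms A `cdmam_detections` or list of them.
#' @param r,b Conversion coefficients, see [predict_human()].
#' @param degree Contrast-detail fit degree, see [fit_cd_curve()].
#' @param fit_subset Which rows feed the curve fit: `"interior"` (default)
#'   uses only non-boundary thresholds when at least four exist, `"all"`
#'   uses every diameter.
#' @return A tibble of class `threshold_table` with `diameter`, `t_auto`,
#'   `t_pred`, `t_fit`, `boundary` and `fit_ok`.
#' @export
threshold_table <- function(dms, r = 1.47, b = 1, degree = 3,
                            fit_subset = c("interior", "all")) {
  fit_subset <- match.arg(fit_subset)
  pooled <- pool_detections(dms)
  fit <- fit_psychometric(pooled)
  ta <- auto_thresholds(fit)
  ta$t_pred <- predict_human(ta$t_auto, r = r, b = b)
  fit_rows <- if (fit_subset == "interior" &&
                  sum(ta$boundary %in% c("none", "interp")) >= 4L) {
    ta$boundary %in% c("none", "interp")
  } else {
    rep(TRUE, nrow(ta))
  }
  if (sum(fit_rows) < 4L) stop_data("Need >= 4 diameters to fit the curve.")
  refit <- lm(log(t_pred) ~ poly(log(diameter), min(degree, sum(fit_rows) - 1L)),
              data = ta[fit_rows, ])
  ta$t_fit <- unname(exp(predict(refit, newdata = ta)))
  out <- left_join(ta, fit$fits[, c("diameter", "fit_ok")], by = "diameter")
  class(out) <- c("threshold_table", class(out))
  attr(out, "conversion") <- c(r = r, b = b)
  attr(out, "degree") <- degree
  out
}

#' Write a threshold table as CSV
#'
#' Serialises a [threshold_table()] in the conventional three-row layout:
#' one column per disk diameter, rows for the automatic, predicted-human
#' and fit-to-predicted-human threshold thicknesses (um).
#'
#' @param tt A `threshold_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_threshold_csv <- function(tt, path) {
  tt <- tt[order(-tt$diameter), ]
  m <- rbind(T_auto = round(tt$t_auto, 3),
             T_pred = round(tt$t_pred, 3),
             T_Fit = round(tt$t_fit, 3))
  df <- data.frame(Score = rownames(m), m, check.names = FALSE)
  names(df) <- c("Score", sprintf("%.2f", tt$diameter))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
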