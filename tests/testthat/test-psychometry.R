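# Independent oracle: likelihood grid search over (c, t0) for the 4-AFC
# psychometric model, used to validate the MLE fit.
grid_search_fit <- function(t, n, k) {
  cs <- exp(seq(log(0.5), log(30), length.out = 80))
  t0s <- exp(seq(log(min(t)), log(max(t)), length.out = 240))
  best <- c(NA, NA); best_nll <- Inf
  for (cc in cs) {
    p <- outer(log(t), log(t0s), function(lt, lt0) {
      0.25 + 0.75 * plogis(cc * (lt - lt0))
    })
    p <- pmin(pmax(p, 0.25 + 1e-9), 1 - 1e-9)
    nll <- -colSums(k * log(p) + (n - k) * log(1 - p))
    j <- which.min(nll)
    if (nll[j] < best_nll) {
      best_nll <- nll[j]
      best <- c(cc, t0s[j])
    }
  }
  list(c = best[1], t0 = best[2])
}

test_that("the fitted psychometric curve passes 62.5% at t0", {
  d <- tibble::tibble(diameter = 0.5,
                      thickness = c(0.06, 0.1, 0.16, 0.25, 0.5),
                      n = 16, k = c(4, 6, 11, 15, 16))
  fit <- fit_psychometric(d)
  row <- fit$fits[1, ]
  expect_true(row$fit_ok)
  expect_equal(cdmamqc:::psy_p(row$t0, row$c, row$t0), 0.625)
})

test_that("parameters are recovered from simulated 16-image ensembles", {
  set.seed(202)
  series <- cdmam_series()$thicknesses
  true_c <- 4; true_t0 <- 0.5
  t0s <- vapply(1:3, function(rep) {
    k <- rbinom(length(series), 16, cdmamqc:::psy_p(series, true_c, true_t0))
    d <- tibble::tibble(diameter = 0.25, thickness = series, n = 16, k = k)
    fit <- fit_psychometric(d)$fits
    expect_true(fit$fit_ok)
    # the MLE agrees with an independent likelihood grid search
    oracle <- grid_search_fit(series, rep(16, length(series)), k)
    expect_lt(abs(fit$t0 - oracle$t0) / oracle$t0, 0.05)
    fit$t0
  }, numeric(1))
  expect_lt(abs(mean(t0s) - true_t0) / true_t0, 0.15)
})

test_that("degenerate columns fail softly and boundary rules take over", {
  series <- cdmam_series()$thicknesses
  all_correct <- tibble::tibble(diameter = 1, thickness = series, n = 8, k = 8)
  fit_hi <- fit_psychometric(all_correct)
  expect_false(fit_hi$fits$fit_ok)
  thr_hi <- column_threshold(fit_hi, 1)
  expect_equal(thr_hi$t_thr, 0.03)
  expect_identical(thr_hi$boundary, "floor")

  at_chance <- tibble::tibble(diameter = 0.06, thickness = series, n = 8,
                              k = rbinom(16, 8, 0.25))
  fit_lo <- fit_psychometric(at_chance)
  thr_lo <- column_threshold(fit_lo, 0.06)
  expect_equal(thr_lo$t_thr, 2)
  expect_identical(thr_lo$boundary, "ceiling")

  expect_error(fit_psychometric(tibble::tibble()), class = "cdmam_data_error")
  expect_error(
    fit_psychometric(tibble::tibble(diameter = 1, thickness = 0.1, n = 8, k = 4)),
    class = "cdmam_data_error")
})

test_that("an in-range converged fit returns its own t0", {
  d <- tibble::tibble(diameter = 0.5,
                      thickness = c(0.06, 0.1, 0.16, 0.25, 0.5),
                      n = 16, k = c(4, 6, 11, 15, 16))
  fit <- fit_psychometric(d)
  thr <- column_threshold(fit, 0.5)
  expect_identical(thr$boundary, "none")
  expect_equal(thr$t_thr, fit$fits$t0[1])
  expect_error(column_threshold(fit, 0.77), class = "cdmam_lookup_error")
})

test_that("predicted-human conversion matches the analyser's printed ratio", {
  expect_equal(predict_human(0.7, r = 1, b = 1), 0.7)
  # printed predicted/automatic ratio at 0.1 mm: 1.231 / 0.839
  expect_lt(abs(1.231 / 0.839 - 1.47), 0.005)
  expect_lt(abs(predict_human(0.839) - 1.231) / 1.231, 0.005)
  expect_error(predict_human(0), class = "cdmam_config_error")
  expect_error(predict_human(-1), class = "cdmam_config_error")
  # strictly increasing, hence ranking-preserving
  x <- sort(runif(10, 0.01, 2))
  expect_true(all(diff(predict_human(x, r = 1.47, b = 0.9)) > 0))
})

test_that("the contrast-detail fit reproduces log-log-linear input exactly", {
  d <- tibble::tibble(diameter = cdmam_series()$diameters,
                      t_pred = exp(2 - 1.3 * log(cdmam_series()$diameters)))
  out <- fit_cd_curve(d)
  expect_equal(out$t_fit, d$t_pred, tolerance = 1e-8)
  expect_error(fit_cd_curve(d[1:3, ]), class = "cdmam_data_error")
})

test_that("the contrast-detail fit reproduces the printed smoothed row within 5%", {
  tt <- example_threshold_table()
  # exclude the apparent decimal-shift misprint at 0.80 mm from the input
  inp <- tt[tt$diameter != 0.80, ]
  out <- fit_cd_curve(dplyr::transmute(inp, diameter = diameter, t_pred = t_pred))
  cmp <- dplyr::left_join(out, inp[, c("diameter", "t_fit")], by = "diameter")
  at <- cmp[cmp$diameter %in% c(0.1, 0.25, 0.5, 1), ]
  expect_true(all(abs(at$t_fit.x - at$t_fit.y) / at$t_fit.y < 0.05))
})

test_that("the contrast-detail fit is stable to dropping one interior point", {
  tt <- example_threshold_table()
  inp <- dplyr::transmute(tt[tt$diameter != 0.80, ],
                          diameter = diameter, t_pred = t_pred)
  full <- fit_cd_curve(inp)
  drop1 <- fit_cd_curve(inp[inp$diameter != 0.25, ])
  cmp <- dplyr::inner_join(full, drop1, by = "diameter")
  expect_lt(max(abs(cmp$t_fit.x - cmp$t_fit.y) / cmp$t_fit.x), 0.10)
})

test_that("pooled thresholds decrease with diameter on clean simulations", {
  # simulate a clean monotone system: t0 proportional to 1/sqrt(diameter)
  set.seed(303)
  ph <- test_phantom()
  cells <- phantom_cells(ph)
  cells <- cells[cells$present, ]
  t0_of <- function(d) 0.1 / d^0.7
  samples <- cells |>
    dplyr::group_by(diameter, thickness) |>
    dplyr::summarise(n = 64 * dplyr::n(), .groups = "drop") |>
    dplyr::mutate(k = rbinom(dplyr::n(), n,
                             cdmamqc:::psy_p(thickness, 6, t0_of(diameter))))
  fit <- fit_psychometric(samples)
  ta <- auto_thresholds(fit)
  ta <- ta[order(ta$diameter), ]
  # thresholds fall as disks grow (allowing boundary-clipped columns to tie)
  expect_true(all(diff(ta$t_auto) <= 1e-9))
})

test_that("threshold tables serialise in the three-row layout", {
  d <- tidyr::crossing(diameter = c(1, 0.5, 0.25, 0.1),
                       thickness = cdmam_series()$thicknesses) |>
    dplyr::mutate(n = 16,
                  k = rbinom(dplyr::n(), 16,
                             cdmamqc:::psy_p(thickness, 4, 0.1 / diameter^0.8)))
  dm_like <- fit_psychometric(d)
  path <- withr::local_tempfile(fileext = ".csv")
  ta <- auto_thresholds(dm_like)
  ta$t_pred <- predict_human(ta$t_auto)
  cd <- fit_cd_curve(ta)
  ta$t_fit <- cd$t_fit
  class(ta) <- c("threshold_table", class(ta))
  write_threshold_csv(ta, path)
  got <- utils::read.csv(path, check.names = FALSE)
  expect_identical(got$Score, c("T_auto", "T_pred", "T_Fit"))
  expect_identical(names(got)[-1], c("1.00", "0.50", "0.25", "0.10"))
})
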