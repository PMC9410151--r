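test_that("thickness_to_contrast follows exponential attenuation", {
  expect_equal(thickness_to_contrast(0), 0)
  expect_equal(thickness_to_contrast(2, mu_gold = 0.5), 1 - exp(-1))
  # strictly increasing in thickness for any positive coefficient
  for (mu in c(0.05, 0.15, 1)) {
    ct <- thickness_to_contrast(cdmam_series()$thicknesses, mu_gold = mu)
    expect_true(all(diff(ct) > 0))
    expect_gt(thickness_to_contrast(2, mu), thickness_to_contrast(0.03, mu))
  }
  expect_error(thickness_to_contrast(-1), class = "cdmam_config_error")
})

test_that("renders are bit-identical for a fixed seed and differ across seeds", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N")
  a <- render_phantom(ph, cfg, seed = 5, field = "tight")
  b <- render_phantom(ph, cfg, seed = 5, field = "tight")
  c <- render_phantom(ph, cfg, seed = 6, field = "tight")
  expect_identical(a$image$pixels, b$image$pixels)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("the full field covers 18 x 24 cm at the configured pitch", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N")
  fd <- cdmamqc:::field_dims(ph, cfg, "full")
  expect_equal(unname(fd$dims), c(2400, 1800))
  expect_error(cdmamqc:::field_dims(ph, cfg, c(100, 100)),
               class = "cdmam_config_error")
})

test_that("background noise follows quantum-plus-electronic statistics", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N", mu_gold = 0)
  img <- test_render_zero()$image
  v <- var(as.numeric(img$pixels))
  expect_lt(abs(v - (cfg$mean_counts + cfg$electronic_sigma^2)) /
              (cfg$mean_counts + cfg$electronic_sigma^2), 0.05)

  # doubling the counts lowers the relative noise by sqrt(2)
  cfg2 <- acquisition_config("TL", "ST", "N", mu_gold = 0,
                             mas = 2 * cfg$mas, electronic_sigma = 0)
  cfg1 <- acquisition_config("TL", "ST", "N", mu_gold = 0,
                             electronic_sigma = 0)
  r1 <- render_phantom(ph, cfg1, seed = 21, field = "tight")$image$pixels
  r2 <- render_phantom(ph, cfg2, seed = 22, field = "tight")$image$pixels
  rel1 <- sd(as.numeric(r1)) / mean(r1)
  rel2 <- sd(as.numeric(r2)) / mean(r2)
  expect_lt(abs(rel1 / rel2 - sqrt(2)), 0.05)
})

test_that("a zero-contrast phantom renders as pure background", {
  ph <- test_phantom()
  img <- test_render_zero()$image
  truth <- test_render_zero()$truth
  expect_true(all(truth$contrast$contrast == 0))
  # mean over the largest disk footprint is within the noise CI of background
  cells <- phantom_cells(ph)
  big <- cells[cells$present & cells$diameter == 2, ][1, ]
  off <- img$meta$grid_offset_mm
  cx <- (big$x + off[1]) / img$pitch
  cy <- (big$y + off[2]) / img$pitch
  rpx <- 1 / img$pitch
  rows <- round(cy + (-rpx:rpx)); cols <- round(cx + (-rpx:rpx))
  patch <- img$pixels[rows, cols]
  n <- length(patch)
  se <- sd(as.numeric(img$pixels)) / sqrt(n)
  expect_lt(abs(mean(patch) - mean(img$pixels)), 4 * se)
})

test_that("TL stack: in-focus layer equals the 2D render and defocus grows off-plane", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N")
  st <- render_tl_stack(ph, cfg, seed = 31, heights = c(20, 22, 24),
                        field = "tight")
  flat <- render_phantom(ph, cfg, seed = 31, field = "tight")
  expect_identical(st$images[["h22"]]$pixels, flat$image$pixels)

  # noise-free: matched-filter response at a small disk decays with |dh|
  stn <- render_tl_stack(ph, cfg, seed = 1, heights = c(18, 20, 22),
                         field = "tight", noiseless = TRUE)
  cells <- phantom_cells(ph)
  small <- cells[cells$present & cells$diameter == 0.25 &
                   cells$thickness >= 1, ][1, ]
  off <- stn$truth$grid_offset_mm
  loc <- c(small$x + off[1], small$y + off[2])
  geom <- locate_grid(stn$images[[1]], ph)
  resp <- vapply(stn$images, function(im) {
    patch_mean <- detection_statistic(im, geom, small$diameter, loc)
  }, numeric(1))
  expect_true(resp[["h22"]] > resp[["h20"]])
  expect_true(resp[["h20"]] > resp[["h18"]])
})

test_that("TL stack validates focus coverage and mode", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N")
  expect_error(render_tl_stack(ph, cfg, heights = 0:5, field = "tight"),
               class = "cdmam_config_error")
  expect_error(render_tl_stack(ph, acquisition_config("2D"), field = "tight"),
               class = "cdmam_config_error")
})

test_that("s2D synthesis is an identity for a single layer and validates inputs", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N")
  st <- render_tl_stack(ph, cfg, seed = 41, heights = 21:23, field = "tight")
  one <- synthesize_s2d(st, weights = 1, heights = 22)
  expect_equal(one$pixels, st$images[["h22"]]$pixels)
  expect_identical(one$meta$mode, "s2D")

  expect_error(synthesize_s2d(st, weights = c(0.5, 0.5), heights = 22),
               class = "cdmam_config_error")
  expect_error(synthesize_s2d(st, weights = c(0.7, 0.7, 0.7)),
               class = "cdmam_config_error")
  expect_error(synthesize_s2d(list()), class = "cdmam_data_error")
  shrunk <- st$images[["h21"]]
  shrunk$pixels <- shrunk$pixels[1:10, 1:10]
  expect_error(synthesize_s2d(list(shrunk, st$images[["h22"]])),
               class = "cdmam_data_error")
})

test_that("s2D flattening dilutes in-focus disk contrast", {
  ph <- test_phantom()
  cfg <- acquisition_config("TL", "ST", "N")
  st <- render_tl_stack(ph, cfg, seed = 1, heights = 21:25, field = "tight",
                        noiseless = TRUE)
  s2d <- synthesize_s2d(st)
  cells <- phantom_cells(ph)
  small <- cells[cells$present & cells$diameter == 0.25 &
                   cells$thickness >= 1, ][1, ]
  off <- st$truth$grid_offset_mm
  loc <- c(small$x + off[1], small$y + off[2])
  geom <- locate_grid(st$images[[1]], ph)
  expect_gt(detection_statistic(st$images[["h22"]], geom, small$diameter, loc),
            detection_statistic(s2d, geom, small$diameter, loc))
})

test_that("higher dose yields higher disk CNR for every disk", {
  ph <- test_phantom()
  disk_cnr <- function(dose, seed) {
    cfg <- acquisition_config("TL", "ST", dose)
    r <- render_phantom(ph, cfg, seed = seed, field = "tight")
    # noise estimated on a disk-free margin region
    bg <- r$image$pixels[1:60, 1:60]
    depth <- r$truth$contrast$contrast * cfg$mean_counts
    depth / sd(as.numeric(bg))
  }
  # mAs 40 vs 32 at fixed contrast: CNR must rise for every disk
  n <- disk_cnr("N", 61)
  h <- disk_cnr("H", 62)
  expect_true(all(h >= n))
  expect_gt(median(h[n > 0] / n[n > 0]), sqrt(40 / 32) - 0.05)
})
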