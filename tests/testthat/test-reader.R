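test_that("the detection statistic is zero on a constant image and large on a disk", {
  ph <- test_phantom()
  img <- test_render_zero()$image
  flat <- img
  flat$pixels <- matrix(500, nrow(img$pixels), ncol(img$pixels))
  geom <- locate_grid(flat, ph)
  expect_equal(detection_statistic(flat, geom, 1, c(40, 40)), 0)

  # a thick rendered disk separates clearly from a matched background spot
  r <- test_render_st()
  cells <- phantom_cells(ph)
  thick <- cells[cells$present & cells$diameter == 1 & cells$thickness >= 0.2, ]
  thick <- thick[which.max(thick$thickness), ]
  off <- r$truth$grid_offset_mm
  geom <- locate_grid(r$image, ph)
  s_disk <- detection_statistic(r$image, geom, thick$diameter,
                                c(thick$x + off[1], thick$y + off[2]))
  # matched empty location: the decoy edge-midpoint of the same cell
  dec <- cdmamqc:::decoy_offsets(ph)[1, ]
  s_bg <- detection_statistic(r$image, geom, thick$diameter,
                              c(thick$x + off[1] + dec[1],
                                thick$y + off[2] + dec[2]))
  expect_gt(s_disk, s_bg + 5)
})

test_that("the expected statistic scales linearly with contrast at small contrast", {
  ph <- test_phantom()
  cells <- phantom_cells(ph)
  target <- cells[cells$present & cells$diameter == 0.5, ]
  target <- target[order(target$thickness), ]
  # noise-free ladder: response vs rendered contrast should be proportional
  r <- test_render_noiseless()
  geom <- locate_grid(r$image, ph)
  off <- r$truth$grid_offset_mm
  resp <- vapply(seq_len(nrow(target)), function(k) {
    tpl <- cdmamqc:::make_template(target$diameter[k], r$image$pitch,
                                   r$image$meta$psf_sigma)
    loc <- c(target$x[k] + off[1], target$y[k] + off[2])
    cy <- round(loc[2] / r$image$pitch + 0.5)
    cx <- round(loc[1] / r$image$pitch + 0.5)
    h <- tpl$half
    patch <- r$image$pixels[(cy - h):(cy + h), (cx - h):(cx + h)]
    mean(patch[tpl$ann]) - sum(tpl$w * patch)
  }, numeric(1))
  contrast <- thickness_to_contrast(target$thickness, r$image$meta$mu_gold)
  small <- contrast < 0.05
  fit <- lm(resp[small] ~ 0 + contrast[small])
  rel <- abs(resp[small] / (coef(fit)[1] * contrast[small]) - 1)
  expect_lt(max(rel), 0.05)
})

test_that("template footprints outside the image raise a data error", {
  r <- test_render_st()
  geom <- locate_grid(r$image, test_phantom())
  expect_error(detection_statistic(r$image, geom, 2, c(0.5, 0.5)),
               class = "cdmam_data_error")
})

test_that("score_cell matches a brute-force corner comparison on a noise-free image", {
  ph <- test_phantom()
  r <- test_render_noiseless()
  img <- r$image
  geom <- locate_grid(img, ph)
  off <- r$truth$grid_offset_mm
  corners <- cdmamqc:::corner_offsets(ph)
  cells <- phantom_cells(ph)
  cells <- cells[cells$present, ]
  bg <- max(img$pixels)  # noise-free background level

  brute_choice <- vapply(seq_len(nrow(cells)), function(k) {
    r_mm <- cells$diameter[k] / 2
    sums <- vapply(1:4, function(j) {
      loc <- c(cells$x[k] + off[1] + corners[j, 1],
               cells$y[k] + off[2] + corners[j, 2])
      cx <- loc[1] / img$pitch; cy <- loc[2] / img$pitch
      hw <- ceiling(r_mm / img$pitch) + 2
      rows <- round(cy) + (-hw:hw); cols <- round(cx) + (-hw:hw)
      sum(bg - img$pixels[rows, cols])
    }, numeric(1))
    rownames(corners)[which.max(sums)]
  }, character(1))

  dm <- score_image(img, ph, geom)
  expect_identical(dm$chosen_corner, brute_choice)
  # with no noise every choice is also the true corner and every cell "both"
  expect_true(all(dm$corner_correct))
  expect_true(all(dm$center_detected))
  expect_true(all(dm$status == "both"))
})

test_that("zero-contrast scoring sits at the 25% chance level", {
  ph <- test_phantom()
  dm <- score_image(test_render_zero()$image, ph)
  rate <- mean(dm$corner_correct)
  n <- nrow(dm)
  expect_lt(abs(rate - 0.25), 4 * sqrt(0.25 * 0.75 / n))
  # status mapping is consistent with the two booleans
  expect_identical(dm$status == "both", dm$corner_correct & dm$center_detected)
  expect_identical(dm$status == "one", xor(dm$corner_correct, dm$center_detected))
})

test_that("detection rate increases with thickness within a diameter row", {
  dm <- test_dm_st()
  d <- dm[dm$diameter %in% c(0.5, 0.31, 0.25), ]
  lo <- d[d$thickness <= 0.08, ]
  hi <- d[d$thickness >= 0.36, ]
  expect_gt(mean(hi$corner_correct), mean(lo$corner_correct))
})

test_that("blind grid registration recovers the offset and fails on pure noise", {
  ph <- test_phantom()
  r <- test_render_st()
  img <- r$image
  true_off <- img$meta$grid_offset_mm
  img$meta$grid_offset_mm <- NULL  # forget the hint
  geom <- locate_grid(img, ph, search_mm = 1.5, step_mm = 0.5)
  expect_lt(max(abs(geom$offset_mm - true_off)), 0.5)
  expect_gt(geom$residual_mm, 0)

  noise <- test_render_zero()$image
  noise$meta$grid_offset_mm <- NULL
  expect_error(locate_grid(noise, ph, search_mm = 1, step_mm = 0.5),
               class = "cdmam_registration_error")
})

test_that("the missing-corner rule credits a corner only when both neighbours are 'both'", {
  ph <- test_phantom()
  dm <- test_dm_st()
  nb1 <- neighbors_of(ph, "r01c01")$cell_id

  dm1 <- dm
  dm1$status[dm1$cell_id %in% nb1] <- "both"
  cor1 <- apply_corrections(dm1, ph)
  expect_true(cor1$credited[cor1$cell_id == "r01c01"])
  expect_identical(cor1$status[cor1$cell_id == "r01c01"], "both")

  dm2 <- dm
  dm2$status[dm2$cell_id == nb1[1]] <- "both"
  dm2$status[dm2$cell_id == nb1[2]] <- "one"
  cor2 <- apply_corrections(dm2, ph)
  expect_false(cor2$credited[cor2$cell_id == "r01c01"])

  # scheme "none" leaves the 205 scored cells untouched
  expect_identical(cor1$status[cor1$present], dm1$status)
  expect_equal(nrow(cor1), 207L)
  expect_true(attr(cor1, "corrected"))

  expect_error(apply_corrections(cor1, ph), class = "cdmam_data_error")
  expect_error(apply_corrections(dm, ph, scheme = "bogus"),
               class = "cdmam_config_error")
})

test_that("nearest-neighbour smoothing promotes only well-supported near misses", {
  ph <- test_phantom()
  dm <- test_dm_st()
  # engineer one miss surrounded by detections, with an adjacent-corner choice
  target <- "r05c05"
  nbs <- neighbors_of(ph, target)$cell_id
  dm$status[dm$cell_id %in% nbs] <- "both"
  i <- which(dm$cell_id == target)
  dm$status[i] <- "neither"
  dm$corner_correct[i] <- FALSE
  dm$center_detected[i] <- FALSE
  dm$true_corner[i] <- "NE"
  dm$chosen_corner[i] <- "NW"  # edge-adjacent to NE
  out <- apply_corrections(dm, ph, scheme = "nn")
  expect_identical(out$status[out$cell_id == target], "both")

  # a diagonal (opposite) corner choice is not promoted
  dm$chosen_corner[i] <- "SW"
  out2 <- apply_corrections(dm, ph, scheme = "nn")
  expect_identical(out2$status[out2$cell_id == target], "neither")
  expect_identical(attr(out2, "scheme"), "nn")
})

test_that("erratic detection patterns are flagged, ordered ones are not", {
  dm <- test_dm_st()
  good <- flag_erratic(dm)
  expect_false(good$erratic)
  expect_gt(good$score, 0.25)

  shuffled <- dm
  set.seed(99)
  shuffled$corner_correct <- sample(shuffled$corner_correct)
  bad <- flag_erratic(shuffled)
  expect_true(bad$erratic)
})

test_that("the score diagram text grid mirrors the matrix layout", {
  ph <- test_phantom()
  dm <- apply_corrections(test_dm_st(), ph)
  lines <- format_score_diagram(dm, quiet = TRUE)
  expect_length(lines, 16L)
  expect_true(all(nchar(lines) == 16L))
  chars <- unlist(strsplit(lines, ""))
  expect_equal(sum(chars != " "), 207L)
})
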