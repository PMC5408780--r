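make_field <- function(H = 100, W = 100) {
  set.seed(31)
  image_field(list(green = matrix(runif(H * W, 0, 4095), H, W),
                   red = matrix(runif(H * W, 0, 4095), H, W)),
              image_id = "f1")
}

test_that("extract_crop cuts the exact window and zero-pads at borders", {
  f <- make_field()
  rec <- data.frame(image_id = "f1", x = 50, y = 50)
  cr <- extract_crop(f, rec, size = 64L)
  # center (50, 50), half = 32: rows 19..82, cols 19..82 (1-based)
  expect_equal(cr$pixels[, , 1], f$pixels$green[19:82, 19:82],
               ignore_attr = TRUE)
  expect_equal(cr$pixels[, , 2], f$pixels$red[19:82, 19:82],
               ignore_attr = TRUE)

  # corner cell: top-left 32x32 of the crop is padding zeros
  cr0 <- extract_crop(f, data.frame(image_id = "f1", x = 0, y = 0))
  expect_true(all(cr0$pixels[1:32, 1:32, ] == 0))
  expect_equal(cr0$pixels[33:64, 33:64, 1], f$pixels$green[1:32, 1:32],
               ignore_attr = TRUE)

  expect_error(extract_crop(f, data.frame(image_id = "f1", x = 120, y = 4)),
               class = "locnet_range_error")
  expect_error(extract_crop(f, data.frame(image_id = "other", x = 5, y = 5)),
               class = "locnet_data_error")
})

test_that("percentile normalization maps to [0,1] with saturation", {
  # linear ramp: quantiles are exact, median maps to ~0.5
  ramp <- array(0:4095, c(64, 64, 1))
  nc <- normalize_crop(cell_crop(ramp))
  expect_equal(min(nc$pixels), 0)
  expect_equal(max(nc$pixels), 1)
  expect_equal(median(nc$pixels), 0.5, tolerance = 1e-3)
  expect_true(nc$normalized)
  expect_error(normalize_crop(nc), class = "locnet_data_error")

  # one extreme hot pixel among 4096 is clipped; the bulk keeps dynamic range
  v <- runif(4095, 100, 200)
  hot <- array(c(v, 60000), c(64, 64, 1))
  nh <- normalize_crop(cell_crop(hot))
  qlo <- quantile(c(v, 60000), 0.001)
  qhi <- quantile(c(v, 60000), 0.999)
  expect_equal(max(nh$pixels), 1)
  # plain min-max would squash the bulk below (200-60)/60000 ~ 0.0024;
  # after saturation the bulk spans nearly the full unit range
  bulk <- nh$pixels[, , 1][hot[, , 1] < 1000]
  expect_gt(diff(range(bulk)), 0.9)
  expect_equal(sort(unique(as.vector(nh$pixels == 1))), c(FALSE, TRUE))
  expect_equal((pmin(pmax(hot, qlo), qhi) - qlo) / (qhi - qlo),
               nh$pixels, ignore_attr = TRUE, tolerance = 1e-12)

  # constant channel degenerates to zeros with a warning
  const <- array(7, c(64, 64, 1))
  expect_warning(nz <- normalize_crop(cell_crop(const)), "constant")
  expect_true(all(nz$pixels == 0))

  # labels survive preprocessing
  cr <- simulate_cell("bud_neck", seed = 2)
  expect_identical(normalize_crop(cr)$label, "bud_neck")
})

test_that("augmentation draws valid dihedral patches deterministically", {
  crop <- normalize_crop(simulate_cell("cell_periphery", seed = 6))
  a1 <- augment_crop(crop, seed = 44)
  a2 <- augment_crop(crop, seed = 44)
  expect_identical(a1$pixels, a2$pixels)
  expect_identical(dim(a1$pixels), c(60L, 60L, 2L))
  expect_identical(a1$label, crop$label)
  # rotating any patch four times returns it
  p <- a1$pixels
  q <- p
  for (i in 1:4) q <- aperm(q, c(2, 1, 3))[60:1, , , drop = FALSE]
  expect_equal(q, p, ignore_attr = TRUE)
  # offsets cover the full 5x5 grid across seeds (coarse distribution check)
  flat <- normalize_crop(cell_crop(array(seq_len(64 * 64),
                                         c(64, 64, 1)) / 4096))
  firsts <- vapply(1:200, function(s)
    augment_crop(flat, seed = s)$pixels[1, 1, 1], 0)
  expect_gte(length(unique(firsts)), 20)
  expect_error(augment_crop(crop, seed = 1, patch = 65L),
               class = "locnet_size_error")
})

test_that("eval_crops returns the documented five offsets", {
  crop <- normalize_crop(simulate_cell("mitochondria", seed = 3))
  ec <- eval_crops(crop)
  expect_length(ec, 5L)
  px <- crop$pixels
  expect_identical(ec[[1]]$pixels, px[3:62, 3:62, ])   # center (2,2)
  expect_identical(ec[[2]]$pixels, px[1:60, 1:60, ])   # top-left
  expect_identical(ec[[3]]$pixels, px[1:60, 5:64, ])   # top-right
  expect_identical(ec[[4]]$pixels, px[5:64, 1:60, ])   # bottom-left
  expect_identical(ec[[5]]$pixels, px[5:64, 5:64, ])   # bottom-right
  # spatially constant crop: all five identical
  suppressWarnings(const <- normalize_crop(cell_crop(array(1, c(64, 64, 2)))))
  ecc <- eval_crops(const)
  for (k in 2:5) expect_identical(ecc[[k]]$pixels, ecc[[1]]$pixels)
})
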