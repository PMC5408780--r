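test_that("TIFF images round-trip exactly, without rescaling", {
  set.seed(1)
  g <- matrix(sample(0:65535, 64 * 64, TRUE), 64, 64)
  r <- matrix(sample(0:65535, 64 * 64, TRUE), 64, 64)
  g[1, 1] <- 65535                      # 16-bit extremes survive
  field <- image_field(list(green = g, red = r), image_id = "rt")
  tf <- file.path(tempdir(), "rt.tif")
  write_image(field, tf)
  back <- read_image(tf, channels = c("green", "red"))
  expect_equal(back$pixels$green, g, ignore_attr = TRUE)
  expect_equal(back$pixels$red, r, ignore_attr = TRUE)
  expect_equal(max(back$pixels$green), 65535)
  expect_identical(back$channels, c("green", "red"))

  # 8-bit path
  m8 <- matrix(sample(0:255, 32 * 48, TRUE), 32, 48)
  t8 <- file.path(tempdir(), "rt8.tif")
  write_image(image_field(list(a = m8), image_id = "x"), t8, bits = 8L)
  expect_equal(read_image(t8)$pixels[[1]], m8, ignore_attr = TRUE)
})

test_that("our TIFF writer/reader agree with an independent codec", {
  g <- matrix(0:4095, 64, 64)
  tf <- file.path(tempdir(), "oracle.tif")
  write_image(image_field(list(g = g, r = g + 1), image_id = "o"), tf)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile; a = tifffile.imread('%s'); print(a.shape[0], int(a[0].sum()), int(a[1].sum()))",
    tf))), stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals, c(2, sum(g), sum(g + 1)))

  # and read one written by the independent codec
  pf <- file.path(tempdir(), "py.tif")
  system2("python", c("-c", shQuote(sprintf(
    "import numpy, tifffile; tifffile.imwrite('%s', (numpy.arange(1200, dtype=numpy.uint16) * 7).reshape(30, 40))",
    pf))))
  back <- read_image(pf)$pixels[[1]]
  expect_equal(back, matrix((0:1199) * 7, 30, 40, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("PNG grayscale round-trips and interoperates", {
  set.seed(2)
  m <- matrix(sample(0:65535, 40 * 56, TRUE), 40, 56)
  pf <- file.path(tempdir(), "rt.png")
  write_image(image_field(list(g = m), image_id = "p"), pf)
  expect_equal(read_image(pf)$pixels[[1]], m, ignore_attr = TRUE)
  # a PNG with non-trivial row filters written by an independent codec
  qf <- file.path(tempdir(), "py.png")
  system2("python", c("-c", shQuote(sprintf(
    "from PIL import Image; import numpy; a = (numpy.arange(2000) %% 251).astype(numpy.uint8).reshape(50, 40); Image.fromarray(a, mode='L').save('%s')",
    qf))))
  expect_equal(read_image(qf)$pixels[[1]],
               matrix((0:1999) %% 251, 50, 40, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("channel count mismatches and unreadable files are errors", {
  m <- matrix(0:255, 16, 16)
  pf <- file.path(tempdir(), "one.png")
  write_image(image_field(list(g = m), image_id = "x"), pf, bits = 8L)
  expect_error(read_image(pf, channels = c("green", "red")),
               class = "locnet_config_error")
  expect_error(read_image(file.path(tempdir(), "nope.tif")),
               class = "locnet_io_error")
  junk <- file.path(tempdir(), "junk.tif")
  writeBin(as.raw(1:32), junk)
  expect_error(read_image(junk), class = "locnet_io_error")
})

test_that("cell tables parse, validate, and preserve unknown columns", {
  tf <- file.path(tempdir(), "cells.tsv")
  writeLines(c("image_id\tx\ty\tlabel\twell",
               "img1\t10\t20\tnucleus\tA01",
               "img1\t30\t40\tcytoplasm\tA01",
               "img2\t5\t6\tnucleus\tB02"), tf)
  tab <- read_cell_table(tf)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$x, c(10, 30, 5))
  expect_identical(tab$well, c("A01", "A01", "B02"))  # opaque metadata kept

  # CSV auto-detection
  cf <- file.path(tempdir(), "cells.csv")
  writeLines(c("image_id,x,y", "img1,1,2"), cf)
  expect_equal(read_cell_table(cf)$y, 2)

  # header-only table
  hf <- file.path(tempdir(), "empty.tsv")
  writeLines("image_id\tx\ty", hf)
  expect_equal(nrow(read_cell_table(hf)), 0L)

  # schema and parse errors
  bf <- file.path(tempdir(), "bad.tsv")
  writeLines(c("image_id\tx", "img1\t3"), bf)
  expect_error(read_cell_table(bf), class = "locnet_schema_error")
  pf2 <- file.path(tempdir(), "badnum.tsv")
  writeLines(c("image_id\tx\ty", "img1\t3\t4", "img1\tabc\t5"), pf2)
  expect_error(read_cell_table(pf2), "row 2",
               class = "locnet_parse_error")
})

test_that("write_table round-trips floats at full precision", {
  df <- data.frame(protein_id = c("P1", "P2"), class = c("a", "b"),
                   t_score = c(pi * 1e3, -sqrt(2) * 1e-4),
                   outlier_posterior = c(1 / 3, 2 / 7))
  tf <- file.path(tempdir(), "scores.tsv")
  write_table(df, tf)
  back <- data.table::fread(tf, data.table = FALSE)
  expect_identical(names(back), names(df))
  expect_equal(back$t_score, df$t_score, tolerance = 1e-9)
  expect_equal(back$outlier_posterior, df$outlier_posterior,
               tolerance = 1e-9)

  # empty result set -> header-only file
  ef <- file.path(tempdir(), "empty_out.tsv")
  write_table(df[0, ], ef)
  expect_equal(length(readLines(ef)), 1L)
})

test_that("run config validates fields", {
  cf <- file.path(tempdir(), "run.json")
  jsonlite::write_json(list(crop_size = 64, seed = 3,
                            classes = c("a", "b")), cf, auto_unbox = TRUE)
  cfg <- read_run_config(cf)
  expect_equal(cfg$crop_size, 64)
  bad <- file.path(tempdir(), "bad.json")
  jsonlite::write_json(list(crop_size = -3), bad, auto_unbox = TRUE)
  expect_error(read_run_config(bad), "crop_size",
               class = "locnet_config_error")
})
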