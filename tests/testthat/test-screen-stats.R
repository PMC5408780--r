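test_that("welch_t follows the textbook formula and its symmetries", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(welch_t(a, b), -welch_t(b, a))
  # explicit formula
  expect_equal(welch_t(a, b),
               (mean(b) - mean(a)) /
                 sqrt(var(a) / 10 + var(b) / 12))
  # preconditions
  expect_true(is.na(welch_t(1, c(1, 2))))             # too few
  expect_true(is.na(welch_t(c(1, 1), c(2, 2))))       # zero variances
  expect_true(is.na(welch_t(a, b, min_cells = 15L)))
})

test_that("the outlier mixture is calibrated and EM is monotone", {
  set.seed(31)
  x <- rnorm(500, 2, 3)
  fit <- fit_outlier_mixture(x)
  expect_equal(fit$mu, 2, tolerance = 0.5)
  expect_equal(sqrt(fit$sigma2), 3, tolerance = 0.5)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_equal(fit$pi_out, 0.01)
  # tight scores, none extreme: no outlier calls
  y <- runif(200, -1, 1)
  fit2 <- fit_outlier_mixture(y)
  expect_equal(sum(fit2$outlier), 0L)
  # the call rule is exactly the weighted-density comparison
  dens_out <- fit$pi_out / diff(fit$support)
  dens_bg <- (1 - fit$pi_out) * dnorm(fit$scores, fit$mu, sqrt(fit$sigma2))
  expect_identical(fit$outlier, dens_out > dens_bg)
  # degenerate inputs
  expect_error(fit_outlier_mixture(rep(1, 20)), class = "locnet_data_error")
  expect_error(fit_outlier_mixture(rnorm(5)), class = "locnet_data_error")
})

test_that("abundance fold change applies the strict two-fold rule", {
  expect_equal(abundance_fold_change(2, 1),
               list(dpl = 1, abundance_flag = FALSE))  # boundary not >1
  expect_equal(abundance_fold_change(1, 1),
               list(dpl = 0, abundance_flag = FALSE))
  fc <- abundance_fold_change(3, 1)
  expect_equal(fc$dpl, log2(3), tolerance = 1e-12)
  expect_true(fc$abundance_flag)
  expect_true(is.na(abundance_fold_change(0, 1)$dpl))
  # mean_abundance basics
  expect_equal(mean_abundance(5), 5)
  expect_equal(mean_abundance(c(2, 4) * 3), 2 * mean_abundance(c(3, 6)))
  expect_error(mean_abundance(numeric(0)), class = "locnet_data_error")
})

test_that("score_screen produces coherent change tables on the benchmark screen", {
  sr <- screen_result()
  sc <- sr$scores
  expect_s3_class(sc, "change_score_table")
  expect_equal(nrow(sc), 100 * 6)
  expect_true(all(is.na(sc$outlier_posterior) | (sc$outlier_posterior >= 0 &
                                                 sc$outlier_posterior <= 1)))
  # planted shifts produce the largest scores
  mx <- tapply(abs(sc$t_score), sc$protein_id, max, na.rm = TRUE)
  expect_true(all(names(sort(mx, decreasing = TRUE))[1:3] %in%
                  sr$screen$planted_shifts))
  # planted abundance effects are recovered
  dpl <- unique(sc[, c("protein_id", "dpl")])
  expect_equal(dpl$dpl[dpl$protein_id == "P010"], 1, tolerance = 0.3)
  expect_equal(dpl$dpl[dpl$protein_id == "P020"], log2(0.4),
               tolerance = 0.3)
  flagged <- unique(sc$protein_id[sc$abundance_flag])
  expect_true("P020" %in% flagged)   # |log2 0.4| = 1.32 > 1
  # dominant-class bookkeeping: shifted proteins change argmax
  dom <- unique(sc[, c("protein_id", "dominant_changed")])
  expect_gte(sum(dom$dominant_changed[dom$protein_id %in%
                                      sr$screen$planted_shifts]), 4)
})

test_that("a null screen yields few outlier calls", {
  tm <- trained_model()
  scr <- simulate_screen(120, 8, shift_fraction = 0, seed = 201,
                         classes = SIX_CLASSES)
  pt <- predict_cells(tm$network, normalize_batch(scr$crops), scr$cells)
  sc <- score_screen(pt)
  called <- mean(sc$outlier[!sc$skipped])
  expect_lte(called, 0.02)
})

test_that("flux networks apply the magnitude filter and argmax-source rule", {
  base <- expand.grid(protein_id = c("P1", "P2"),
                      class = c("cytoplasm", "nucleus", "vacuole"),
                      stringsAsFactors = FALSE)
  base$t_score <- 0
  base$t_score[base$protein_id == "P1" &
               base$class == "cytoplasm"] <- 12
  base$t_score[base$protein_id == "P1" & base$class == "nucleus"] <- -15
  base$skipped <- FALSE
  base$outlier_posterior <- 0.5; base$outlier <- FALSE
  base$dominant_a <- "nucleus"; base$dominant_b <- "cytoplasm"
  base$dominant_changed <- TRUE
  base$dpl <- 0.2; base$abundance_flag <- FALSE
  attr(base, "classes") <- c("cytoplasm", "nucleus", "vacuole")
  class(base) <- c("change_score_table", "data.frame")
  net <- build_flux_network(base, threshold = 10)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$from, "nucleus")
  expect_equal(net$edges$to, "cytoplasm")
  expect_equal(net$edges$weight, 12)          # weight = |t| of the gain
  expect_equal(net$edges$protein_id, "P1")
  expect_s3_class(net$graph, "igraph")
  # all |t| below threshold -> empty network
  base$t_score <- 1
  expect_equal(nrow(build_flux_network(base, threshold = 10)$edges), 0L)
})
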