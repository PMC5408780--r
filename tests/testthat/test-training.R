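test_that("lr_schedule is a non-increasing staircase", {
  cfg <- train_config(base_lr = 0.5, decay = 0.9, decay_every = 10L)
  lr <- lr_schedule(0:99, cfg)
  expect_true(all(diff(lr) <= 0))
  expect_equal(unique(lr), 0.5 * 0.9^(0:9))
  expect_equal(rle(lr)$lengths, rep(10L, 10L))
})

test_that("sample_per_class samples with replacement only when scarce", {
  y <- c(rep("a", 3), rep("b", 100))
  idx <- sample_per_class(y, 5, seed = 1)
  ia <- idx[y[idx] == "a"]; ib <- idx[y[idx] == "b"]
  expect_length(ia, 5L)
  expect_lt(length(unique(ia)), 5L)           # repeats forced (3 unique)
  expect_length(unique(ib), 5L)               # no repeats needed
  expect_identical(idx, sample_per_class(y, 5, seed = 1))
  expect_error(sample_per_class(y, 2, seed = 1, classes = c("a", "c")),
               class = "locnet_data_error")
})

test_that("train_network honors max_iters = 0 and validates labels", {
  net <- build_network(tiny_config(2L), seed = 1)
  net$class_vocab <- c("a", "b")
  x <- array(runif(8 * 8 * 1 * 10), c(8, 8, 1, 10))
  y <- rep(c("a", "b"), 5)
  before <- locnet:::net_get_params(net)
  fit <- train_network(net, x, y, train_config(max_iters = 0L))
  expect_identical(locnet:::net_get_params(fit$network), before)
  expect_error(train_network(net, x, rep("a", 10),
                             train_config(max_iters = 1L)),
               class = "locnet_data_error")  # class b has no samples
})

test_that("short runs are deterministic and reduce the loss", {
  dat <- gen_crops(c("nucleus", "cell_periphery"), 20, 55)
  cfg2 <- model_config(input_size = 60L, in_channels = 2L,
                       conv_widths = c(4L, 4L), pool_after = c(1L, 2L),
                       fc_widths = 8L, n_classes = 2L)
  run <- function() {
    net <- build_network(cfg2, seed = 2)
    net$class_vocab <- c("cell_periphery", "nucleus")
    train_network(net, dat$x, dat$y,
                  train_config(batch_size = 16L, max_iters = 40L,
                               checkpoint_every = 40L, seed = 3))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log$loss, f2$log$loss)            # bit-reproducible
  expect_lt(mean(tail(f1$log$loss, 5)), mean(head(f1$log$loss, 5)))
  expect_identical(names(f1$log), c("iteration", "lr", "loss",
                                    "val_accuracy"))
})

test_that("the scaled benchmark run selected its best checkpoint", {
  tm <- trained_model()
  ck <- tm$fit$checkpoints
  expect_true(all(ck$val_accuracy <= tm$fit$best_val_accuracy))
  expect_true(tm$fit$best_iteration %in% ck$iteration)
  expect_gte(tm$fit$best_val_accuracy, 0.9)
  # training log bookkeeping
  expect_equal(nrow(tm$fit$log), 1500L)
  expect_equal(tm$fit$log$lr, 0.1 * 0.96^floor((0:1499) / 25))
})

test_that("transfer keeps pretrained weights except the final layer", {
  tb <- transfer_bench()
  tm <- trained_model()
  net <- tb$pretrained$network
  expect_identical(net$class_vocab, TRANSFER_CLASSES)
  nl <- length(net$layers)
  expect_equal(dim(net$layers[[nl]]$W)[2], 4L)
  # per-resampling accuracies are reported with mean/sd
  expect_equal(mean(tb$pretrained$accuracies),
               tb$pretrained$mean_accuracy)
  # incompatible architectures are rejected
  other <- build_network(tiny_config(2L, in_channels = 1L), seed = 1)
  expect_error(
    transfer_network(other, tb$pool$x, tb$pool$y, TRANSFER_CLASSES,
                     tb$cfg, test_x = tb$test$x, test_y = tb$test$y,
                     base_config = tm$network$config),
    class = "locnet_config_error")
})

test_that("zero-iteration transfer predicts with a fresh final layer over frozen features", {
  tm <- trained_model()
  tb <- transfer_bench()
  cfg0 <- transfer_config(samples_per_class = 2L, n_resamplings = 1L,
                          iters = 0L, min_iters = 0L, seed = 3)
  res <- transfer_network(tm$network, tb$pool$x, tb$pool$y,
                          TRANSFER_CLASSES, cfg0,
                          test_x = tb$test$x[, , , 1:8, drop = FALSE],
                          test_y = tb$test$y[1:8])
  # all layers except the last must equal the pretrained ones
  nl <- length(res$network$layers)
  for (i in seq_len(nl - 1L)) {
    expect_identical(res$network$layers[[i]]$W,
                     tm$network$layers[[i]]$W)
  }
  expect_false(identical(dim(res$network$layers[[nl]]$W),
                         dim(tm$network$layers[[nl]]$W)))
})

test_that("feature baselines separate well-separated classes", {
  tm <- trained_model()
  tb <- transfer_bench()
  acc <- feature_classifier_baselines(tm$network, tb$pool$x, tb$pool$y,
                                      n_per_class = 25L, seed = 2,
                                      test_x = tb$test$x,
                                      test_y = tb$test$y)
  expect_named(acc, c("nearest_neighbor", "linear", "random_forest"))
  expect_true(all(acc > 0.5, na.rm = TRUE))   # far above the 0.25 chance
  # 1-NN memorizes its own training points
  idx <- sample_per_class(tb$pool$y, 1, seed = 5)
  acc1 <- feature_classifier_baselines(tm$network,
                                       tb$pool$x, tb$pool$y, 1L, seed = 5,
                                       test_x = tb$pool$x[, , , idx,
                                                          drop = FALSE],
                                       test_y = tb$pool$y[idx])
  expect_equal(unname(acc1["nearest_neighbor"]), 1)
  # fine-tuning beats the best frozen-feature baseline at n = 25
  cfg25 <- transfer_config(samples_per_class = 25L, n_resamplings = 2L,
                           batch_size = 16L, seed = 31)
  ft <- transfer_network(tm$network, tb$pool$x, tb$pool$y,
                         TRANSFER_CLASSES, cfg25,
                         test_x = tb$test$x, test_y = tb$test$y)
  expect_gte(ft$mean_accuracy, max(acc, na.rm = TRUE) - 0.05)
})
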