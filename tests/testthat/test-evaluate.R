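test_that("five-crop prediction averages correctly and stays a distribution", {
  net <- build_network(model_config(input_size = 4L, in_channels = 1L,
                                    conv_widths = 3L, pool_after = 1L,
                                    fc_widths = 4L, n_classes = 3L),
                       seed = 2)
  net$class_vocab <- c("a", "b", "c")
  # spatially constant crop: the five-crop mean equals a single forward pass
  suppressWarnings({
    const <- array(0.7, c(6, 6, 1, 1))
    pt <- predict_cells(net, const)
    single <- forward(net, array(0.7, c(4, 4, 1, 1)))
  })
  expect_equal(unname(as.matrix(pt[, c("p_a", "p_b", "p_c")])), single,
               tolerance = 1e-10)
  # probabilities sum to one
  set.seed(4)
  x <- array(runif(6 * 6 * 1 * 9), c(6, 6, 1, 9))
  pt2 <- predict_cells(net, x, chunk = 4L)   # exercise chunking
  expect_equal(rowSums(pt2[, c("p_a", "p_b", "p_c")]), rep(1, 9),
               tolerance = 1e-6)
})

test_that("five-crop averaging does not hurt accuracy on the benchmark model", {
  tm <- trained_model()
  te <- tm$test
  pt5 <- predict_cells(tm$network, te$x)
  cls <- SIX_CLASSES
  pred5 <- cls[max.col(as.matrix(pt5[, paste0("p_", cls)]))]
  # center-crop-only predictions
  xc <- te$x[3:62, 3:62, , , drop = FALSE]
  p1 <- forward(tm$network, xc)
  pred1 <- tm$network$class_vocab[max.col(p1)]
  acc5 <- mean(pred5 == te$y); acc1 <- mean(pred1 == te$y)
  expect_gte(acc5, acc1 - 0.02)
})

test_that("aggregate_protein computes unweighted means per group", {
  pt <- data.frame(cell_id = as.character(1:3),
                   protein_id = c("P1", "P1", "P2"),
                   p_a = c(0.2, 0.4, 1), p_b = c(0.8, 0.6, 0))
  attr(pt, "classes") <- c("a", "b")
  class(pt) <- c("prediction_table", "data.frame")
  prof <- aggregate_protein(pt)
  expect_equal(prof$p_a[prof$protein_id == "P1"], 0.3)
  expect_equal(prof$p_b[prof$protein_id == "P1"], 0.7)
  expect_equal(prof$n_cells, c(2L, 1L))
  expect_equal(prof$p_a[prof$protein_id == "P2"], 1)   # single-cell group
  expect_equal(rowSums(prof[, c("p_a", "p_b")]), c(1, 1))
  # permutation invariance
  prof2 <- aggregate_protein(pt[c(3, 1, 2), ])
  expect_equal(prof2[order(prof2$protein_id), ],
               prof[order(prof$protein_id), ], ignore_attr = TRUE)
})

test_that("average precision satisfies its defining properties", {
  # perfect ranking
  expect_equal(average_precision(c(9, 8, 7, 1, 2), c(1, 1, 1, 0, 0)), 1)
  # one positive of two, ranked second
  expect_equal(average_precision(c(5, 3), c(0, 1)), 0.5)
  # invariance to strictly monotone transforms
  set.seed(11)
  s <- runif(30); l <- rbinom(30, 1, 0.4); l[1] <- 1
  expect_equal(average_precision(s, l),
               average_precision(log(s + 1), l))
  expect_equal(average_precision(s, l),
               average_precision(rank(s), l))
  expect_warning(ap0 <- average_precision(s, rep(0, 30)), "no positive")
  expect_true(is.na(ap0))
  # mean AP bounded in [0, 1]
  S <- matrix(runif(60), 20, 3); L <- matrix(rbinom(60, 1, 0.5), 20, 3)
  L[1, ] <- 1
  m <- mean_average_precision(S, L)
  expect_gte(m$mean_ap, 0); expect_lte(m$mean_ap, 1)
  expect_length(m$per_class, 3L)
})

test_that("confusion matrix normalizes rows and averages per-class accuracy", {
  # 3-class toy: 6 cells, one error in class B
  probs <- rbind(c(.9, .05, .05), c(.8, .1, .1),    # A -> A, A
                 c(.1, .8, .1), c(.2, .7, .1), c(.6, .3, .1),  # B,B,B->A
                 c(0, .2, .8))                       # C -> C
  pt <- data.frame(cell_id = as.character(1:6))
  pt <- cbind(pt, setNames(as.data.frame(probs), c("p_A", "p_B", "p_C")))
  attr(pt, "classes") <- c("A", "B", "C")
  class(pt) <- c("prediction_table", "data.frame")
  truth <- c("A", "A", "B", "B", "B", "C")
  cm <- confusion_matrix(pt, truth)
  expect_equal(unname(cm$per_class_accuracy), c(1, 2 / 3, 1))
  expect_equal(cm$average_accuracy, (1 + 2 / 3 + 1) / 3)
  expect_equal(unname(rowSums(cm$matrix)), c(1, 1, 1))
  # perfect predictions -> identity
  cmp <- confusion_matrix(pt[c(1, 3, 6), ], c("A", "B", "C"))
  expect_equal(unname(cmp$matrix), diag(3))
  expect_error(confusion_matrix(pt, c(truth[-6], "unknown")),
               class = "locnet_data_error")
})
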