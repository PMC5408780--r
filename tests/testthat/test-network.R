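test_that("spatial arithmetic: default config flattens to 256*8*8", {
  tr <- locnet:::config_trace(model_config())
  expect_equal(unname(tr$flat["h"]), 8)      # 60 -> 30 -> 15 -> 8 (ceil)
  expect_equal(unname(tr$flat["w"]), 8)
  expect_equal(unname(tr$flat["c"]), 256)
  expect_equal(prod(tr$flat), 16384)
})

test_that("degenerate config yields a single affine map", {
  cfg <- model_config(input_size = 1L, in_channels = 1L,
                      conv_widths = integer(0), pool_after = integer(0),
                      fc_widths = integer(0), n_classes = 1L,
                      batch_norm = FALSE)
  net <- build_network(cfg, seed = 1)
  expect_equal(count_parameters(net), 2)
  p <- forward(net, array(0.3, c(1, 1, 1, 2)))
  expect_equal(dim(p), c(2L, 1L))
  expect_equal(as.vector(p), c(1, 1))        # softmax over one class
})

test_that("initialization is truncated-normal and seed-deterministic", {
  n1 <- build_network(tiny_config(), seed = 5)
  n2 <- build_network(tiny_config(), seed = 5)
  n3 <- build_network(tiny_config(), seed = 6)
  expect_identical(locnet:::net_get_params(n1), locnet:::net_get_params(n2))
  expect_false(identical(n1$layers[[1]]$W, n3$layers[[1]]$W))
  big <- build_network(model_config(conv_widths = 64L,
                                    pool_after = integer(0),
                                    fc_widths = integer(0),
                                    input_size = 6L), seed = 2)
  w <- big$layers[[1]]$W
  expect_true(all(abs(w) <= 2 * 0.1))
  expect_equal(sd(w), 0.088, tolerance = 0.05)   # sd of trunc-normal(0.1, 2sd)
})

test_that("forward produces proper distributions, batch-independently", {
  net <- build_network(tiny_config(4L), seed = 8)
  set.seed(1)
  x <- array(runif(8 * 8 * 1 * 6), c(8, 8, 1, 6))
  p <- forward(net, x)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  # batch independence in eval mode
  p1 <- forward(net, x[, , , 1, drop = FALSE])
  expect_equal(as.vector(p1), p[1, ], tolerance = 1e-10)
  # zeroed final layer -> uniform distribution
  net$layers[[length(net$layers)]]$W[] <- 0
  net$layers[[length(net$layers)]]$b[] <- 0
  pu <- forward(net, x)
  expect_equal(as.vector(pu), rep(0.25, 24))
  # shape errors
  expect_error(forward(net, array(0, c(9, 9, 1, 2))),
               class = "locnet_shape_error")
})

test_that("count_parameters matches closed forms on a hand-traced config", {
  # conv widths [4] on 8x8 1-channel input, pool after 1, fc [3], 2 classes
  cfg <- model_config(input_size = 8L, in_channels = 1L, conv_widths = 4L,
                      pool_after = 1L, fc_widths = 3L, n_classes = 2L)
  # conv: 9*1*4 + 4 + 2*4; flatten: 4*4*4 = 64; fc: 64*3 + 3 + 2*3;
  # out: 3*2 + 2
  expect_equal(count_parameters(build_network(cfg, 1)),
               (36 + 4 + 8) + (192 + 3 + 6) + (6 + 2))
})

test_that("extract_activations exposes spatial maps, reduced vectors, and fc features", {
  net <- build_network(tiny_config(3L), seed = 4)
  set.seed(2)
  x <- array(runif(8 * 8 * 1 * 5), c(8, 8, 1, 5))
  a2 <- extract_activations(net, x, "conv2")
  expect_equal(dim(a2$maps), c(4L, 4L, 4L, 5L))     # (H, W, F, N)
  expect_equal(dim(a2$reduced), c(5L, 4L))
  # reduced vector really is the spatial max
  expect_equal(a2$reduced[3, 2], max(a2$maps[, , 2, 3]))
  f1 <- extract_activations(net, x, "fc1")
  expect_equal(dim(f1$features), c(5L, 5L))
  expect_error(extract_activations(net, x, "conv9"),
               class = "locnet_name_error")
  expect_error(extract_activations(net, x, "pool1"),
               class = "locnet_name_error")

  # default-scale widths: conv8 reduces to 256 features, fc2 to 512
  cfg <- model_config()
  expect_equal(cfg$conv_widths[8], 256L)
  expect_equal(cfg$fc_widths[2], 512L)
})

test_that("spatial-max reduction is stable under pooling-stride translation", {
  # a bright blob placed at positions shifted by the total pooling stride
  # (4 px for the tiny config) excites nearly the same reduced features
  net <- build_network(tiny_config(3L), seed = 10)
  mk <- function(oy, ox) {
    m <- matrix(0, 8, 8)
    m[(1:2) + oy, (1:2) + ox] <- 1
    array(m, c(8, 8, 1, 1))
  }
  r1 <- extract_activations(net, mk(0, 0), "conv2")$reduced
  r2 <- extract_activations(net, mk(4, 4), "conv2")$reduced
  expect_gt(cor(as.vector(r1), as.vector(r2)), 0.9)
})

test_that("checkpoints round-trip through JSON", {
  net <- build_network(tiny_config(3L), seed = 12)
  net$class_vocab <- c("a", "b", "c")
  tf <- file.path(tempdir(), "ckpt.json")
  save_checkpoint(net, tf)
  back <- load_checkpoint(tf)
  set.seed(3)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  expect_equal(forward(back, x), forward(net, x), tolerance = 1e-12)
  expect_identical(back$class_vocab, c("a", "b", "c"))
})

test_that("analytic gradients match finite differences on a tiny network", {
  net <- build_network(tiny_config(3L), seed = 7)
  ln <- asNamespace("locnet")
  set.seed(42)
  xb <- array(runif(8 * 8 * 1 * 4), c(8, 8, 1, 4))
  yb <- c(1L, 2L, 3L, 1L)
  snap <- ln$net_get_params(net)
  loss_of <- function(i, p, k, delta) {
    ln$net_set_params(net, snap)
    net$layers[[i]][[p]][k] <- net$layers[[i]][[p]][k] + delta
    fw <- ln$net_forward_layers(net$layers, xb, mode = "train")
    ln$softmax_xent(fw$logits, yb)$loss
  }
  ln$net_set_params(net, snap)
  fw <- ln$net_forward_layers(net$layers, xb, mode = "train",
                              want_cache = TRUE)
  s <- ln$softmax_xent(fw$logits, yb)
  bw <- ln$net_backward_layers(net$layers, fw$caches, s$dlogits)
  eps <- 1e-5
  set.seed(9)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    for (p in setdiff(ly$params, "b")) {  # bias grads under BN are ~0
      g <- bw$grads[[i]][[p]]
      for (k in sample(length(g), min(length(g), 4))) {
        fd <- (loss_of(i, p, k, eps) - loss_of(i, p, k, -eps)) / (2 * eps)
        expect_equal(g[k], fd, tolerance = 1e-4)
      }
    }
  }
  ln$net_set_params(net, snap)
})
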