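# Shared fixtures.  Expensive artifacts (the scaled-down trained model, the
# synthetic screen scoring, the transfer benchmark) are built once on first
# use and cached for the whole run; tests that need them all draw from the
# same fixed-seed world.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

SIX_CLASSES <- c("cytoplasm", "nucleus", "nuclear_periphery",
                 "cell_periphery", "punctate_k8", "bud_neck")
TRANSFER_CLASSES <- c("vacuole", "mitochondria", "nucleolus", "punctate_k3")

sim_params <- function(...) morphology_params(...)

# normalized labeled crops for a class list
gen_crops <- function(classes, n_per_class, seed0,
                      params = sim_params()) {
  n <- n_per_class * length(classes)
  x <- array(0, c(64, 64, 2, n))
  y <- character(n)
  i <- 0L
  for (cl in classes) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      cr <- simulate_cell(cl, params, seed = derive_seed(seed0, i))
      x[, , , i] <- cr$pixels
      y[i] <- cl
    }
  }
  list(x = normalize_batch(x), y = y)
}

# The scaled-down benchmark model: widths 8,8,16,16 (pool after every
# block, one hidden fc of 64), 6 synthetic classes x 200 crops, 1,500
# iterations.  Batch size 64 keeps the run inside the desk-scale budget.
trained_model <- function() fixture("trained_model", function() {
  tr <- gen_crops(SIX_CLASSES, 200, 1)
  va <- gen_crops(SIX_CLASSES, 50, 2)
  te <- gen_crops(SIX_CLASSES, 50, 3)
  net <- build_network(scaled_model_config(6L), seed = 11)
  net$class_vocab <- SIX_CLASSES
  cfg <- train_config(batch_size = 64L, max_iters = 1500L,
                      checkpoint_every = 500L, seed = 5)
  fit <- train_network(net, tr$x, tr$y, cfg, va$x, va$y)
  pt <- predict_cells(fit$network, te$x)
  cm <- confusion_matrix(pt, te$y)
  list(fit = fit, network = fit$network, test = te, train = tr,
       confusion = cm, test_accuracy = cm$average_accuracy)
})

# 100-protein screen with 5 planted localization shifts and two planted
# abundance effects, scored with the trained model.
screen_result <- function() fixture("screen_result", function() {
  tm <- trained_model()
  scr <- simulate_screen(100, 20, shift_fraction = 0.05,
                         abundance_effects = c(P010 = 2, P020 = 0.4),
                         seed = 77, classes = SIX_CLASSES)
  xn <- normalize_batch(scr$crops)
  pt <- predict_cells(tm$network, xn, scr$cells)
  scores <- score_screen(pt)
  list(screen = scr, predictions = pt, scores = scores)
})

# Transfer benchmark: pretrained (from trained_model) vs scratch under an
# identical budget on 4 held-out pattern classes, 5 samples/class, 5
# resamplings.  Batch size 16 matches the 20-example training pools.  The
# new dataset is rendered at lower SNR (dimmer green, more noise), standing
# in for the differently-acquired dataset a real transfer targets.
transfer_params <- function() sim_params(green_level = 2500, noise_sd = 60)

transfer_bench <- function() fixture("transfer_bench", function() {
  tm <- trained_model()
  pool <- gen_crops(TRANSFER_CLASSES, 40, 4, params = transfer_params())
  te <- gen_crops(TRANSFER_CLASSES, 40, 6, params = transfer_params())
  cfg <- transfer_config(samples_per_class = 5L, batch_size = 16L,
                         seed = 21)
  pre <- transfer_network(tm$network, pool$x, pool$y, TRANSFER_CLASSES,
                          cfg, test_x = te$x, test_y = te$y)
  scr <- transfer_network(NULL, pool$x, pool$y, TRANSFER_CLASSES, cfg,
                          test_x = te$x, test_y = te$y,
                          base_config = tm$network$config)
  list(pool = pool, test = te, pretrained = pre, scratch = scr, cfg = cfg)
})

# tiny architecture for mechanical tests (fast to build and run)
tiny_config <- function(n_classes = 3L, in_channels = 1L, ...) {
  model_config(input_size = 8L, in_channels = in_channels,
               conv_widths = c(3L, 4L), pool_after = c(1L, 2L),
               fc_widths = 5L, n_classes = n_classes, ...)
}

# 4-connected component count above a threshold mask (independent oracle
# for the punctate generator)
count_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && !seen[i, j]) {
        n <- n + 1L
        stack <- list(c(i, j))
        seen[i, j] <- TRUE
        while (length(stack)) {
          cur <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
            ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
            if (ii >= 1 && ii <= nrow(mask) && jj >= 1 &&
                jj <= ncol(mask) && mask[ii, jj] && !seen[ii, jj]) {
              seen[ii, jj] <- TRUE
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  n
}

# brute-force average precision: rank-by-rank precision-weighted sum
ap_bruteforce <- function(scores, labels) {
  ord <- order(-scores)
  lab <- as.logical(labels)[ord]
  npos <- sum(lab)
  total <- 0
  hits <- 0
  for (k in seq_along(lab)) {
    if (lab[k]) {
      hits <- hits + 1
      total <- total + hits / k
    }
  }
  total / npos
}
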