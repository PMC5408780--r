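#' Training protocol configuration
#'
#' Defaults follow the full-scale protocol: Adam with a learning rate
#' starting at 0.1 and an exponential staircase decay of 0.96 applied
#' every 25 iterations, batch size 128, 10,000 iterations, and
#' checkpoint-based model selection every 500 iterations.
#'
#' @param base_lr initial learning rate.
#' @param decay multiplicative decay factor.
#' @param decay_every iterations between decay applications.
#' @param batch_size minibatch size.
#' @param max_iters total training iterations.
#' @param checkpoint_every iterations between validation checkpoints.
#' @param seed integer seed controlling batch sampling and augmentation.
#' @param dropout inverted-dropout rate on the final layer input during
#'   training (0 disables; used by the transfer protocol).
#' @return an object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.1, decay = 0.96, decay_every = 25L,
                         batch_size = 128L, max_iters = 10000L,
                         checkpoint_every = 500L, seed = 1L, dropout = 0) {
  if (base_lr <= 0 || decay <= 0 || decay_every < 1 || batch_size < 1 ||
      max_iters < 0 || checkpoint_every < 1)
    stop_locnet("config", "train_config fields must be positive")
  if (dropout < 0 || dropout >= 1)
    stop_locnet("config", "dropout must be in [0, 1)")
  structure(list(base_lr = base_lr, decay = decay,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 max_iters = as.integer(max_iters),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed), dropout = dropout),
            class = "train_config")
}

#' Staircase learning-rate schedule
#'
#' `base_lr * decay^floor(iteration / decay_every)`: piecewise constant
#' with period `decay_every`, non-increasing for `decay <= 1`.
#'
#' @param iteration 0-based iteration index.
#' @param cfg a [train_config()].
#' @return the learning rate at that iteration.
#' @export
lr_schedule <- function(iteration, cfg = train_config()) {
  stopifnot(all(iteration >= 0))
  cfg$base_lr * cfg$decay^floor(iteration / cfg$decay_every)
}

# eval-mode accuracy using the center patch only (used for checkpoint
# selection; cheap relative to five-crop averaging)
center_crop_accuracy <- function(network, x, yi, chunk = 256L) {
  patch <- network$config$input_size
  size <- dim(x)[1]
  off <- eval_offsets(size, patch)[[1]]
  xc <- x[(off[1] + 1):(off[1] + patch), (off[2] + 1):(off[2] + patch), , ,
          drop = FALSE]
  n <- dim(xc)[4]
  pred <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    p <- forward(network, xc[, , , i:j, drop = FALSE], mode = "eval")
    pred[i:j] <- max.col(p, ties.method = "first")
    i <- j + 1L
  }
  mean(pred == yi)
}

#' Train the classifier with augmentation and checkpoint selection
#'
#' Minimizes softmax cross-entropy with Adam on augmented minibatches
#' (random 60x60 patches with reflections and quarter rotations drawn
#' uniformly over the training set).  Every `checkpoint_every` iterations
#' the validation accuracy of the current model is recorded and the best
#' checkpoint (highest validation accuracy; earliest on ties) is returned.
#' Without a validation set the final model is returned.  The run is
#' deterministic given `cfg$seed`.
#'
#' @param network a freshly built (or pretrained) `locnet_network`.
#' @param x `(S, S, C, N)` array of normalized crops, `S >=` the network
#'   input size.
#' @param y character vector of class labels (length `N`).
#' @param cfg a [train_config()].
#' @param val_x,val_y optional validation crops/labels, disjoint from the
#'   training set.
#' @return list with `network` (best checkpoint), `log` (per-iteration
#'   data.frame: `iteration`, `lr`, `loss`, `val_accuracy`),
#'   `best_iteration`, `best_val_accuracy`, and `checkpoints`.
#' @export
train_network <- function(network, x, y, cfg = train_config(),
                          val_x = NULL, val_y = NULL) {
  stopifnot(inherits(network, "locnet_network"))
  vocab <- network$class_vocab %||% sort(unique(y))
  network$class_vocab <- vocab
  yi <- match(y, vocab)
  if (anyNA(yi))
    stop_locnet("data", "labels outside the class vocabulary: %s",
                paste(unique(y[is.na(yi)]), collapse = ", "))
  if (!all(seq_along(vocab) %in% yi))
    stop_locnet("data", "class(es) without training samples: %s",
                paste(vocab[!(seq_along(vocab) %in% yi)], collapse = ", "))
  vyi <- NULL
  if (!is.null(val_x)) {
    vyi <- match(val_y, vocab)
    if (anyNA(vyi))
      stop_locnet("data", "validation labels outside the class vocabulary")
  }
  if (cfg$max_iters == 0L)
    return(list(network = network,
                log = data.frame(iteration = integer(0), lr = numeric(0),
                                 loss = numeric(0),
                                 val_accuracy = numeric(0)),
                best_iteration = 0L, best_val_accuracy = NA_real_,
                checkpoints = data.frame(iteration = integer(0),
                                         val_accuracy = numeric(0))))
  N <- dim(x)[4]
  set.seed(cfg$seed)
  adam <- adam_init(network$layers)
  loss_log <- numeric(cfg$max_iters)
  lr_log <- numeric(cfg$max_iters)
  val_log <- rep(NA_real_, cfg$max_iters)
  ck_it <- integer(0); ck_acc <- numeric(0)
  best_acc <- -Inf; best_snap <- NULL; best_it <- NA_integer_
  for (it in seq_len(cfg$max_iters)) {
    lr <- lr_schedule(it - 1L, cfg)
    idx <- sample.int(N, cfg$batch_size, replace = TRUE)
    xb <- augment_batch(x[, , , idx, drop = FALSE],
                        patch = network$config$input_size)
    fw <- net_forward_layers(network$layers, xb, mode = "train",
                             want_cache = TRUE, dropout_rate = cfg$dropout)
    ls <- softmax_xent(fw$logits, yi[idx])
    if (!is.finite(ls$loss))
      stop_locnet("numeric",
                  "non-finite loss at iteration %d (lr = %g); aborting",
                  it, lr)
    bw <- net_backward_layers(network$layers, fw$caches, ls$dlogits,
                              need_input_grad = FALSE)
    adam <- adam_step(network$layers, bw$grads, adam, lr, it)
    loss_log[it] <- ls$loss; lr_log[it] <- lr
    if (it %% cfg$checkpoint_every == 0L || it == cfg$max_iters) {
      if (!is.null(vyi)) {
        acc <- center_crop_accuracy(network, val_x, vyi)
        val_log[it] <- acc
        ck_it <- c(ck_it, it); ck_acc <- c(ck_acc, acc)
        if (acc > best_acc) {
          best_acc <- acc; best_it <- it
          best_snap <- net_get_params(network)
        }
      } else {
        ck_it <- c(ck_it, it); ck_acc <- c(ck_acc, NA_real_)
      }
    }
  }
  if (!is.null(best_snap)) net_set_params(network, best_snap)
  list(network = network,
       log = data.frame(iteration = seq_len(cfg$max_iters), lr = lr_log,
                        loss = loss_log, val_accuracy = val_log),
       best_iteration = if (is.na(best_it)) cfg$max_iters else best_it,
       best_val_accuracy = if (is.finite(best_acc)) best_acc else NA_real_,
       checkpoints = data.frame(iteration = ck_it, val_accuracy = ck_acc))
}

#' Per-class subsampling with replacement fallback
#'
#' For each class, draws `n_per_class` samples without replacement when
#' enough unique samples exist and with replacement otherwise.
#' Deterministic given `seed`.
#'
#' @param y character vector of class labels.
#' @param n_per_class draws per class.
#' @param seed integer seed.
#' @param classes class vocabulary (defaults to classes present in `y`);
#'   a listed class with no samples is a data error.
#' @return integer vector of indices into `y` (possibly with repeats).
#' @export
sample_per_class <- function(y, n_per_class, seed = 1L,
                             classes = sort(unique(y))) {
  stopifnot(n_per_class >= 1)
  with_seed(seed, {
    out <- integer(0)
    for (cl in classes) {
      idx <- which(y == cl)
      if (!length(idx))
        stop_locnet("data", "class '%s' has no samples", cl)
      draw <- if (length(idx) >= n_per_class)
        idx[sample.int(length(idx), n_per_class)]
      else idx[sample.int(length(idx), n_per_class, replace = TRUE)]
      out <- c(out, draw)
    }
    out
  })
}

#' Transfer-learning configuration
#'
#' Defaults follow the fine-tuning protocol: Adam at a constant learning
#' rate of 0.003 for at least 500 iterations with batch size 128, dropout
#' on the final layer, five independent resamplings per training-set
#' size, and with-replacement sampling when unique samples are scarce.
#'
#' @param lr fine-tuning learning rate.
#' @param iters fine-tuning iterations (clamped up to `min_iters`).
#' @param min_iters minimum fine-tuning iterations.
#' @param batch_size minibatch size.
#' @param final_layer_dropout dropout rate on the final-layer input.
#' @param samples_per_class labeled examples drawn per class.
#' @param n_resamplings independent training subsets per size.
#' @param seed integer seed.
#' @return an object of class `transfer_config`.
#' @export
transfer_config <- function(lr = 0.003, iters = 500L, min_iters = 500L,
                            batch_size = 128L, final_layer_dropout = 0.5,
                            samples_per_class = 5L, n_resamplings = 5L,
                            seed = 1L) {
  if (lr <= 0 || batch_size < 1 || samples_per_class < 1 ||
      n_resamplings < 1)
    stop_locnet("config", "transfer_config fields must be positive")
  structure(list(lr = lr, iters = max(as.integer(iters),
                                      as.integer(min_iters)),
                 min_iters = as.integer(min_iters),
                 batch_size = as.integer(batch_size),
                 final_layer_dropout = final_layer_dropout,
                 samples_per_class = as.integer(samples_per_class),
                 n_resamplings = as.integer(n_resamplings),
                 seed = as.integer(seed)),
            class = "transfer_config")
}

# copy all parameters except the final layer from src into dst
copy_pretrained <- function(dst, src) {
  nl <- length(dst$layers)
  if (length(src$layers) != nl)
    stop_locnet("config", "pretrained network has incompatible depth")
  for (i in seq_len(nl - 1L)) {
    a <- dst$layers[[i]]; b <- src$layers[[i]]
    if (a$type != b$type ||
        !identical(dim(a$W %||% matrix(0)), dim(b$W %||% matrix(0))))
      stop_locnet("config", "pretrained layer %d incompatible", i)
    for (p in c(a$params, if (isTRUE(a$bn)) c("rmean", "rvar")))
      a[[p]] <- b[[p]]
  }
  invisible(dst)
}

# five-crop accuracy on a labeled test set
five_crop_accuracy <- function(network, x, y) {
  vocab <- network$class_vocab
  meta <- data.frame(cell_id = as.character(seq_len(dim(x)[4])))
  pt <- predict_cells(network, x, meta)
  pred <- vocab[max.col(as.matrix(pt[, paste0("p_", vocab)]),
                        ties.method = "first")]
  mean(pred == y)
}

#' Transfer a pretrained network to a new class vocabulary
#'
#' For each of `cfg$n_resamplings` independent subsets of
#' `cfg$samples_per_class` examples per class, initializes a new network
#' whose final layer matches the new vocabulary, loads the pretrained
#' parameters for every layer except the final one (all parameters are
#' then updated during fine-tuning), applies dropout to the final layer,
#' and fine-tunes with Adam at constant `cfg$lr`.  With
#' `pretrained = NULL` the same budget is spent from random
#' initialization, giving the matched from-scratch comparison.
#'
#' @param pretrained a trained `locnet_network`, or `NULL` for scratch.
#' @param x `(S, S, C, N)` normalized crops of the new dataset.
#' @param y character labels over `new_vocab`.
#' @param new_vocab class vocabulary of the new dataset.
#' @param cfg a [transfer_config()].
#' @param test_x,test_y held-out evaluation set (five-crop accuracy).
#' @param base_config model architecture; defaults to the pretrained
#'   network's config (required when `pretrained = NULL`).
#' @return list with `accuracies` (per resampling), `mean_accuracy`,
#'   `sd_accuracy`, and `network` (the fine-tuned model from the last
#'   resampling).
#' @export
transfer_network <- function(pretrained, x, y, new_vocab,
                             cfg = transfer_config(), test_x, test_y,
                             base_config = NULL) {
  if (is.null(base_config)) {
    if (is.null(pretrained))
      stop_locnet("config", "need base_config when pretrained is NULL")
    base_config <- pretrained$config
  }
  if (!is.null(pretrained) &&
      !identical(unclass(base_config)[setdiff(names(base_config),
                                              "n_classes")],
                 unclass(pretrained$config)[setdiff(names(base_config),
                                                    "n_classes")]))
    stop_locnet("config", "pretrained config incompatible with base_config")
  new_cfg <- base_config
  new_cfg$n_classes <- length(new_vocab)
  accs <- numeric(cfg$n_resamplings)
  net <- NULL
  for (r in seq_len(cfg$n_resamplings)) {
    seed_r <- derive_seed(cfg$seed, r)
    idx <- sample_per_class(y, cfg$samples_per_class, seed = seed_r,
                            classes = new_vocab)
    net <- build_network(new_cfg, seed = seed_r)
    net$class_vocab <- new_vocab
    if (!is.null(pretrained)) copy_pretrained(net, pretrained)
    tcfg <- train_config(base_lr = cfg$lr, decay = 1, decay_every = 1L,
                         batch_size = cfg$batch_size,
                         max_iters = cfg$iters,
                         checkpoint_every = max(1L, cfg$iters),
                         seed = seed_r,
                         dropout = cfg$final_layer_dropout)
    fit <- train_network(net, x[, , , idx, drop = FALSE], y[idx], tcfg)
    net <- fit$network
    accs[r] <- five_crop_accuracy(net, test_x, test_y)
  }
  list(accuracies = accs, mean_accuracy = mean(accs),
       sd_accuracy = stats::sd(accs), network = net)
}

#' Classifier baselines on extracted deep features
#'
#' Uses the pretrained network as a fixed feature extractor (activations
#' of the last hidden fully connected layer on the center patch) and fits
#' simple classifiers on a per-class subsample: one-nearest-neighbor,
#' a multinomial linear model (ridge-penalized, via glmnet), and a small
#' bagged-tree forest.  Reports held-out accuracy of each.
#'
#' @param pretrained a trained `locnet_network`.
#' @param x,y training crops (normalized `(S, S, C, N)`) and labels.
#' @param n_per_class examples drawn per class (see [sample_per_class()]).
#' @param seed integer seed.
#' @param test_x,test_y held-out evaluation crops and labels.
#' @return named numeric vector of accuracies:
#'   `nearest_neighbor`, `linear`, `random_forest`.
#' @export
feature_classifier_baselines <- function(pretrained, x, y, n_per_class,
                                         seed = 1L, test_x, test_y) {
  cfg <- pretrained$config
  fc_name <- paste0("fc", length(cfg$fc_widths))
  feats <- function(xx) {
    patch <- cfg$input_size
    off <- eval_offsets(dim(xx)[1], patch)[[1]]
    xc <- xx[(off[1] + 1):(off[1] + patch),
             (off[2] + 1):(off[2] + patch), , , drop = FALSE]
    extract_activations(pretrained, xc, fc_name)$features
  }
  ftr <- feats(x); fte <- feats(test_x)
  idx <- sample_per_class(y, n_per_class, seed = seed)
  Xtr <- ftr[idx, , drop = FALSE]; ytr <- y[idx]
  out <- c(nearest_neighbor = NA_real_, linear = NA_real_,
           random_forest = NA_real_)
  # one-nearest-neighbor
  d2 <- outer(rowSums(fte^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(fte)), rowSums(Xtr^2)) - 2 * fte %*% t(Xtr)
  out["nearest_neighbor"] <- mean(ytr[max.col(-d2, ties.method = "first")]
                                  == test_y)
  # ridge-penalized multinomial linear model
  out["linear"] <- tryCatch({
    fit <- glmnet::glmnet(Xtr, factor(ytr, levels = sort(unique(y))),
                          family = "multinomial", alpha = 0,
                          lambda = 0.01)
    pred <- predict(fit, fte, type = "class")
    mean(as.character(pred) == test_y)
  }, error = function(e) NA_real_)
  # small bagged forest
  out["random_forest"] <- tryCatch({
    rf <- rf_fit(Xtr, ytr, seed = derive_seed(seed, 7L))
    mean(rf_predict(rf, fte) == test_y)
  }, error = function(e) NA_real_)
  out
}
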