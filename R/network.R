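#' Declarative architecture description
#'
#' Describes the convolutional classifier: a stack of 3x3/stride-1
#' same-padding convolutional blocks (bias, then batch normalization, then
#' ReLU), 2x2/stride-2 ceil-mode max pooling after selected blocks, a
#' flattening step, hidden fully connected blocks, and a final linear layer
#' followed by softmax.  The defaults realize the full-scale localization
#' classifier: eight convolutional blocks of widths 64, 64, 128, 128, 256,
#' 256, 256, 256 with pooling after blocks 2, 4 and 8, two hidden
#' fully connected layers of 512 units, and 19 output classes on 60x60
#' two-channel inputs.
#'
#' The number of output units is configurable because the training corpus
#' the full model was built on used 17 annotation classes (15 compartments
#' plus two quality-control classes) while the realized output layer had
#' 19 units; neither choice is privileged here.
#'
#' @param input_size spatial size of (square) network inputs, in pixels.
#'   Training and evaluation patches are 60x60 by default.
#' @param in_channels number of image channels (GFP + marker channels).
#' @param conv_widths integer vector of feature-map counts per
#'   convolutional block; may be empty.
#' @param pool_after indices of convolutional blocks after which 2x2
#'   max pooling is applied.
#' @param fc_widths widths of the hidden fully connected layers; may be
#'   empty.
#' @param n_classes number of localization classes (output units).
#' @param batch_norm apply batch normalization before every hidden ReLU.
#' @param init_sd standard deviation of the truncated-normal weight
#'   initializer (truncated at +/- 2 sd).
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_size = 60L, in_channels = 2L,
                         conv_widths = c(64L, 64L, 128L, 128L,
                                         256L, 256L, 256L, 256L),
                         pool_after = c(2L, 4L, 8L),
                         fc_widths = c(512L, 512L),
                         n_classes = 19L, batch_norm = TRUE,
                         init_sd = 0.1) {
  conv_widths <- as.integer(conv_widths)
  pool_after <- as.integer(pool_after)
  fc_widths <- as.integer(fc_widths)
  if (input_size < 1) stop_locnet("config", "input_size must be positive")
  if (in_channels < 1) stop_locnet("config", "in_channels must be positive")
  if (length(conv_widths) && any(conv_widths < 1))
    stop_locnet("config", "conv widths must be positive")
  if (length(fc_widths) && any(fc_widths < 1))
    stop_locnet("config", "fc widths must be positive")
  if (length(pool_after) &&
      (any(pool_after < 1) || any(pool_after > length(conv_widths))))
    stop_locnet("config", "pool_after must index into conv_widths")
  if (n_classes < 1) stop_locnet("config", "n_classes must be >= 1")
  if (init_sd <= 0) stop_locnet("config", "init_sd must be positive")
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 conv_widths = conv_widths,
                 pool_after = sort(unique(pool_after)),
                 fc_widths = fc_widths,
                 n_classes = as.integer(n_classes),
                 batch_norm = isTRUE(batch_norm),
                 init_sd = init_sd),
            class = "model_config")
}

#' A reduced architecture for desk-scale experiments
#'
#' Convolutional widths 8, 8, 16, 16 with pooling after every block, one
#' hidden fully connected layer of 64 units.  Training this model on the
#' synthetic generator takes minutes on one CPU while preserving the
#' structure (conv blocks + batch norm + pooling + fc stack) of the full
#' model.
#'
#' @param n_classes number of output classes.
#' @param ... overrides passed to [model_config()].
#' @return a `model_config`.
#' @export
scaled_model_config <- function(n_classes = 6L, ...) {
  model_config(conv_widths = c(8L, 8L, 16L, 16L), pool_after = 1:4,
               fc_widths = 64L, n_classes = n_classes, ...)
}

# spatial trace of a config: sizes entering each conv block, and the final
# (h, w, c) entering flatten
config_trace <- function(config) {
  h <- config$input_size; w <- config$input_size
  c_in <- config$in_channels
  trace <- list()
  for (i in seq_along(config$conv_widths)) {
    trace[[i]] <- c(h = h, w = w, c_in = c_in, c_out = config$conv_widths[i])
    c_in <- config$conv_widths[i]
    if (i %in% config$pool_after) {        # ceil-mode pooling
      h <- (h + 1L) %/% 2L
      w <- (w + 1L) %/% 2L
    }
  }
  list(conv = trace, flat = c(h = h, w = w, c = c_in))
}

#' Build the realized network from a configuration
#'
#' Weights and biases are drawn from a normal distribution with standard
#' deviation `config$init_sd`, truncated at two standard deviations; batch
#' norm scale/offset start at 1/0.  Deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling initialization.
#' @return an object of class `locnet_network`.
#' @export
build_network <- function(config, seed = 1L) {
  if (!inherits(config, "model_config"))
    stop_locnet("config", "config must be a model_config")
  tr <- config_trace(config)
  net <- new.env(parent = emptyenv())
  net$config <- config
  layers <- list()
  with_seed(seed, {
    for (i in seq_along(config$conv_widths)) {
      ci <- tr$conv[[i]]
      layers[[length(layers) + 1L]] <-
        new_conv_layer(ci["c_in"], ci["c_out"], ci["h"], ci["w"],
                       config$batch_norm, relu = TRUE, config$init_sd)
      if (i %in% config$pool_after) {
        layers[[length(layers) + 1L]] <-
          new_pool_layer(ci["h"], ci["w"], ci["c_out"])
      }
    }
    fl <- tr$flat
    layers[[length(layers) + 1L]] <- new_flatten_layer(fl["h"], fl["w"], fl["c"])
    n_in <- as.integer(fl["h"]) * as.integer(fl["w"]) * as.integer(fl["c"])
    for (wd in config$fc_widths) {
      layers[[length(layers) + 1L]] <-
        new_fc_layer(n_in, wd, config$batch_norm, relu = TRUE, config$init_sd)
      n_in <- wd
    }
    layers[[length(layers) + 1L]] <-
      new_fc_layer(n_in, config$n_classes, batch_norm = FALSE, relu = FALSE,
                   config$init_sd)
  })
  net$layers <- layers
  net$seed <- as.integer(seed)
  class(net) <- "locnet_network"
  net
}

#' @export
print.locnet_network <- function(x, ...) {
  cfg <- x$config
  cat("<locnet_network>\n")
  cat(sprintf("  input: %dx%dx%d\n", cfg$input_size, cfg$input_size,
              cfg$in_channels))
  cat(sprintf("  conv blocks: %s (pool after %s)\n",
              paste(cfg$conv_widths, collapse = ","),
              paste(cfg$pool_after, collapse = ",")))
  cat(sprintf("  fc: %s -> %d classes\n",
              paste(cfg$fc_widths, collapse = ","), cfg$n_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts every trainable scalar: convolutional kernels and biases, batch
#' norm scale/offset pairs, and fully connected weights and biases.  Batch
#' norm running statistics are not trainable and are excluded.
#'
#' @param network a `locnet_network`.
#' @return integer-valued count (numeric, to avoid 32-bit overflow).
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "locnet_network"))
  total <- 0
  for (ly in network$layers) {
    for (p in ly$params) total <- total + length(ly[[p]])
  }
  total
}

# coerce forward input to (H, W, C, N)
as_batch_array <- function(x, input_size, in_channels) {
  if (inherits(x, "cell_crop")) x <- x$pixels
  if (is.list(x)) x <- stack_crops(x)$x
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  if (length(d) != 4L)
    stop_locnet("shape", "expected an (H, W, C, N) array")
  if (d[1] != input_size || d[2] != input_size)
    stop_locnet("shape", "input spatial size %dx%d does not match config %d",
                d[1], d[2], input_size)
  if (d[3] != in_channels)
    stop_locnet("shape", "input has %d channels, config expects %d",
                d[3], in_channels)
  x
}

#' Forward pass producing class probabilities
#'
#' In `"eval"` mode batch normalization uses running statistics, so outputs
#' are independent of batch composition; in `"train"` mode batch statistics
#' are used and running statistics are updated.
#'
#' @param network a `locnet_network`.
#' @param x an `(H, W, C, N)` array, a single `(H, W, C)` array, a
#'   `cell_crop`, or a list of crops, with spatial size
#'   `network$config$input_size`.
#' @param mode `"eval"` or `"train"`.
#' @return an `N x n_classes` matrix of softmax probabilities (rows sum
#'   to 1).
#' @export
forward <- function(network, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  cfg <- network$config
  x <- as_batch_array(x, cfg$input_size, cfg$in_channels)
  fw <- net_forward_layers(network$layers, x, mode = mode)
  softmax_rows(fw$logits)
}

# index of the i-th conv layer / i-th fc layer in the realized layer list
layer_index <- function(network, name) {
  types <- vapply(network$layers, function(l) l$type, "")
  m <- regmatches(name, regexec("^(conv|fc)([0-9]+)$", name))[[1]]
  if (length(m) != 3L)
    stop_locnet("name", "unknown layer '%s' (use conv<k> or fc<k>)", name)
  k <- as.integer(m[3])
  idx <- which(types == m[2])
  if (k < 1 || k > length(idx))
    stop_locnet("name", "layer '%s' out of range (%d %s layers)", name,
                length(idx), m[2])
  idx[k]
}

#' Extract intermediate activations
#'
#' For convolutional layers, returns both the per-feature spatial maps and
#' the spatial-max-reduced vector per cell (the maximum activation of each
#' feature across spatial coordinates), which removes spatial dependence
#' before embedding.  For fully connected layers, returns the activation
#' vector.  Layers are addressed as `"conv<k>"` / `"fc<k>"`; under the
#' default configuration `"conv8"` yields 256 reduced features and `"fc2"`
#' yields 512.
#'
#' @param network a `locnet_network`.
#' @param x input batch (see [forward()]).
#' @param layer layer name such as `"conv8"` or `"fc2"`.
#' @return for conv layers, `list(maps = (H, W, F, N) array,
#'   reduced = N x F matrix)`; for fc layers, `list(features = N x F
#'   matrix)`.
#' @export
extract_activations <- function(network, x, layer = "conv8") {
  cfg <- network$config
  x <- as_batch_array(x, cfg$input_size, cfg$in_channels)
  li <- layer_index(network, layer)
  fw <- net_forward_layers(network$layers, x, mode = "eval", capture = li)
  act <- fw$activations[[as.character(li)]]
  if (network$layers[[li]]$type == "conv") {
    # internal layout is (H, W, N, F); expose maps as (H, W, F, N)
    reduced <- apply(act, c(3, 4), max)        # N x F
    if (!is.matrix(reduced)) reduced <- matrix(reduced, dim(act)[3],
                                               dim(act)[4])
    list(maps = aperm(act, c(1, 2, 4, 3)), reduced = reduced)
  } else {
    list(features = act)
  }
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a plain-text JSON container holding the configuration,
#' class vocabulary, and every named parameter array (including batch norm
#' running statistics).  Loading verifies that the stored configuration
#' matches the one used to rebuild the network.
#'
#' @param network a `locnet_network`.
#' @param path file path.
#' @return `load_checkpoint` returns a `locnet_network`.
#' @export
save_checkpoint <- function(network, path) {
  snap <- net_get_params(network)
  payload <- list(
    config = unclass(network$config),
    class_vocab = network$class_vocab,
    seed = network$seed,
    params = lapply(snap, function(lp) lapply(lp, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    }))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfgl <- payload$config
  cfg <- model_config(
    input_size = cfgl$input_size, in_channels = cfgl$in_channels,
    conv_widths = unlist(cfgl$conv_widths),
    pool_after = unlist(cfgl$pool_after) %||% integer(0),
    fc_widths = unlist(cfgl$fc_widths) %||% integer(0),
    n_classes = cfgl$n_classes, batch_norm = cfgl$batch_norm,
    init_sd = cfgl$init_sd)
  net <- build_network(cfg, seed = payload$seed %||% 1L)
  if (!is.null(payload$class_vocab))
    net$class_vocab <- unlist(payload$class_vocab)
  snap <- payload$params
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    stored <- snap[[i]]
    for (p in names(stored)) {
      v <- as.numeric(unlist(stored[[p]]$data))
      d <- unlist(stored[[p]]$dim)
      if (length(d) == 2L) dim(v) <- d
      ly[[p]] <- v
    }
  }
  net
}
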