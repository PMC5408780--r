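# Feature-space interpretation: 2-D embedding of spatial-max-reduced
# convolutional activations, and activation-maximization synthesis of
# class- or feature-preferred inputs (naive and regularized gradient
# ascent on the pixels of a fixed network).

#' Embed conv-layer activations of cells into 2-D
#'
#' Activations of the last convolutional layer are reduced by taking each
#' feature's maximum across the spatial coordinates (removing spatial
#' dependence), then embedded with a seeded stochastic neighbor embedding
#' (exact t-SNE).  Deterministic given `seed`.
#'
#' @param network a trained `locnet_network`.
#' @param crops `(S, S, C, N)` array of normalized input patches at the
#'   network input size (N >= 10).
#' @param seed integer seed.
#' @param layer conv layer name (default: the last one).
#' @param perplexity t-SNE perplexity.
#' @return `N x 2` matrix of embedding coordinates.
#' @export
embed_features <- function(network, crops, seed = 1L, layer = NULL,
                           perplexity = 15) {
  if (is.null(layer))
    layer <- paste0("conv", length(network$config$conv_widths))
  if (is.list(crops) && !is.array(crops)) crops <- stack_crops(crops)$x
  d <- dim(crops)
  if (length(d) == 3L) dim(crops) <- c(d, 1L)
  if (dim(crops)[4] < 10)
    stop_locnet("data", "need at least 10 cells to embed, got %d",
                dim(crops)[4])
  red <- extract_activations(network, crops, layer)$reduced
  tsne_embed(red, perplexity = perplexity, seed = seed)
}

#' Synthesis configuration for activation maximization
#'
#' Regularizer defaults (step size on normalized inputs, blur cadence,
#' small-contribution clip percentile) are implementation choices tuned
#' for stable syntheses on the synthetic-trained models; all are
#' configurable and recorded in the result.
#'
#' @param target list: either `list(class = j)` for an output class or
#'   `list(layer = "conv4", feature = f)` for a conv feature (ascent on
#'   the feature map's spatial mean).
#' @param steps gradient-ascent steps.
#' @param step_size ascent step on RMS-normalized gradients.
#' @param l2_decay multiplicative pixel decay per step (0 disables).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param blur_every apply blur every this many steps.
#' @param clip_percentile zero pixels whose contribution `|x * grad|`
#'   falls below this percentile (0 disables).
#' @param clamp_red keep the red channel fixed at its initial content,
#'   updating only the green channel.
#' @param cell_mask optional logical `S x S` mask; updates outside it are
#'   zeroed.
#' @param seed integer seed for the uniform-noise initialization.
#' @return an object of class `synthesis_config`.
#' @export
synthesis_config <- function(target, steps = 200L, step_size = 1.0,
                             l2_decay = 0, blur_sigma = 0, blur_every = 4L,
                             clip_percentile = 0, clamp_red = FALSE,
                             cell_mask = NULL, seed = 1L) {
  if (steps < 1) stop_locnet("config", "steps must be >= 1")
  if (l2_decay < 0 || blur_sigma < 0 || clip_percentile < 0 ||
      clip_percentile > 1)
    stop_locnet("config", "regularizer coefficients must be non-negative")
  structure(list(target = target, steps = as.integer(steps),
                 step_size = step_size, l2_decay = l2_decay,
                 blur_sigma = blur_sigma, blur_every = as.integer(blur_every),
                 clip_percentile = clip_percentile,
                 clamp_red = isTRUE(clamp_red), cell_mask = cell_mask,
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Regularized defaults used for class-level visualizations
#'
#' @param target as in [synthesis_config()].
#' @param cell_mask logical mask of the cell area.
#' @param ... further overrides.
#' @return a `synthesis_config`.
#' @export
regularized_synthesis_config <- function(target, cell_mask = NULL, ...) {
  synthesis_config(target, l2_decay = 0.01, blur_sigma = 1,
                   blur_every = 4L, clip_percentile = 0.1,
                   clamp_red = !is.null(cell_mask), cell_mask = cell_mask,
                   ...)
}

# separable Gaussian blur of one channel (reflect-free, renormalized edges)
gaussian_blur2d <- function(m, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  n <- nrow(m)
  pad <- matrix(0, r, ncol(m))
  mm <- rbind(pad, m, pad)
  sm <- matrix(0, n, ncol(m))
  wt <- numeric(n)
  for (i in seq_along(k)) {
    sm <- sm + k[i] * mm[i:(i + n - 1L), , drop = FALSE]
  }
  # columns
  mm <- cbind(matrix(0, n, r), sm, matrix(0, n, r))
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * mm[, i:(i + ncol(m) - 1L), drop = FALSE]
  }
  out
}

# gradient of the synthesis objective wrt the input pixels
input_gradient <- function(network, x, target) {
  d <- dim(x)
  x4 <- x; dim(x4) <- c(d, 1L)
  layers <- network$layers
  if (!is.null(target$class)) {
    fw <- net_forward_layers(layers, x4, mode = "eval", want_cache = TRUE)
    j <- target$class
    K <- network$config$n_classes
    if (j < 1 || j > K) stop_locnet("name", "class index %d out of range", j)
    dtop <- matrix(0, 1, K)
    dtop[1, j] <- 1                     # ascent on the class logit
    val <- fw$logits[1, j]
    bw <- net_backward_layers(layers, fw$caches, dtop)
  } else {
    li <- layer_index(network, target$layer)
    f <- target$feature
    fw <- net_forward_layers(layers, x4, mode = "eval", want_cache = TRUE,
                             capture = li)
    act <- fw$activations[[as.character(li)]]      # (H, W, N=1, F)
    da <- dim(act)
    if (f < 1 || f > da[4])
      stop_locnet("name", "feature index %d out of range (%d features)",
                  f, da[4])
    val <- mean(act[, , 1, f])          # spatial mean of the feature map
    dtop <- array(0, da)
    dtop[, , 1, f] <- 1 / (da[1] * da[2])
    bw <- net_backward_layers(layers, fw$caches, dtop, from = li)
  }
  g <- bw$dinput
  dim(g) <- d
  list(grad = g, value = val)
}

#' Activation maximization: synthesize a preferred input
#'
#' Starts from uniform noise (or a supplied image) and performs gradient
#' ascent on the target activation while the network parameters stay
#' fixed.  In naive mode (all regularizers zero) the update is a plain
#' RMS-normalized ascent step.  The regularized mode additionally applies,
#' each step: multiplicative L2 decay of the pixels, periodic Gaussian
#' blur of the updated (green) channel, zeroing of pixels whose
#' contribution `|x * grad|` falls below the configured percentile,
#' clamping of the red channel to its initial content, and masking of
#' updates outside the cell area.  With all regularizers disabled the two
#' modes coincide step for step.
#'
#' @param network a trained `locnet_network`.
#' @param cfg a [synthesis_config()].
#' @param init optional `(S, S, C)` starting image; defaults to uniform
#'   noise in `[0, 1)` drawn with `cfg$seed`.
#' @return list with `image` (synthesized `(S, S, C)` array), `trace`
#'   (per-step target activation), and `cfg`.
#' @export
activation_maximization <- function(network, cfg, init = NULL) {
  S <- network$config$input_size
  C <- network$config$in_channels
  x <- if (is.null(init)) {
    with_seed(cfg$seed, array(runif(S * S * C), c(S, S, C)))
  } else {
    if (inherits(init, "cell_crop")) init <- init$pixels
    stopifnot(all(dim(init) == c(S, S, C)))
    init
  }
  init_x <- x
  red_ch <- if (C >= 2) 2L else NULL
  trace <- numeric(cfg$steps)
  for (s in seq_len(cfg$steps)) {
    ig <- input_gradient(network, x, cfg$target)
    if (!all(is.finite(ig$grad)) || !is.finite(ig$value))
      stop_locnet("numeric",
                  "synthesis diverged at step %d (non-finite activation)", s)
    trace[s] <- ig$value
    g <- ig$grad
    if (cfg$clamp_red && !is.null(red_ch)) g[, , red_ch] <- 0
    if (!is.null(cfg$cell_mask)) {
      for (ch in seq_len(C)) g[, , ch] <- g[, , ch] * cfg$cell_mask
    }
    rms <- sqrt(mean(g^2))
    if (rms > 0) g <- g / rms
    x <- x + cfg$step_size * g
    if (cfg$l2_decay > 0) {
      upd <- x * (1 - cfg$l2_decay)
      # decay only what we are allowed to update
      if (cfg$clamp_red && !is.null(red_ch)) upd[, , red_ch] <- x[, , red_ch]
      if (!is.null(cfg$cell_mask)) {
        for (ch in seq_len(C))
          upd[, , ch] <- ifelse(cfg$cell_mask, upd[, , ch], x[, , ch])
      }
      x <- upd
    }
    if (cfg$blur_sigma > 0 && s %% cfg$blur_every == 0L) {
      chans <- if (cfg$clamp_red && !is.null(red_ch))
        setdiff(seq_len(C), red_ch) else seq_len(C)
      for (ch in chans) {
        blurred <- gaussian_blur2d(x[, , ch], cfg$blur_sigma)
        x[, , ch] <- if (!is.null(cfg$cell_mask))
          ifelse(cfg$cell_mask, blurred, x[, , ch]) else blurred
      }
    }
    if (cfg$clip_percentile > 0) {
      contrib <- abs(x * ig$grad)
      chans <- if (cfg$clamp_red && !is.null(red_ch))
        setdiff(seq_len(C), red_ch) else seq_len(C)
      for (ch in chans) {
        thr <- quantile(contrib[, , ch], cfg$clip_percentile, names = FALSE)
        kill <- contrib[, , ch] < thr
        if (!is.null(cfg$cell_mask)) kill <- kill & cfg$cell_mask
        xc <- x[, , ch]
        xc[kill] <- 0
        x[, , ch] <- xc
      }
    }
    if (cfg$clamp_red && !is.null(red_ch)) x[, , red_ch] <- init_x[, , red_ch]
    if (!is.null(cfg$cell_mask)) {
      for (ch in seq_len(C))
        x[, , ch] <- ifelse(cfg$cell_mask, x[, , ch], init_x[, , ch])
    }
  }
  list(image = x, trace = trace, cfg = cfg, init = init_x)
}
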