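#' @useDynLib locnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile var dnorm predict setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_locnet <- function(kind, msg, ...) {
  cond <- structure(
    class = c(paste0("locnet_", kind, "_error"), "locnet_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  stop(cond)
}

#' Expand a global seed into per-module seeds
#'
#' A single run seed is expanded into independent per-purpose seeds with a
#' documented counter scheme: `seed * 101 + counter`, reduced modulo
#' `2^31 - 1` so the result is always a valid R integer seed.  Counters are
#' fixed per subsystem so that partial re-runs of a pipeline reuse the same
#' stream.
#'
#' @param seed integer global seed.
#' @param counter non-negative integer stream counter.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, counter = 0L) {
  as.integer((as.numeric(seed) * 101 + as.numeric(counter)) %% 2147483647)
}

# Draws from N(0, sd^2) truncated at +/- 2 sd, by rejection.  Deterministic
# under the current RNG state.
rtruncnorm2 <- function(n, sd) {
  x <- rnorm(n, 0, sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > 2 * sd]
  }
  x
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stack a list of cell_crop objects (or plain H x W x C arrays) into a
# (H, W, C, N) array plus the label vector
#' Stack single-cell crops into a batch array
#'
#' @param crops list of `cell_crop` objects or `H x W x C` arrays.
#' @return list with `x` (`H x W x C x N` array) and `labels`
#'   (character vector, `NA` where unlabeled).
#' @export
stack_crops <- function(crops) {
  stopifnot(length(crops) >= 1)
  first <- crop_pixels(crops[[1]])
  d <- dim(first)
  x <- array(0, c(d, length(crops)))
  labels <- rep(NA_character_, length(crops))
  for (i in seq_along(crops)) {
    p <- crop_pixels(crops[[i]])
    if (!identical(dim(p), d))
      stop_locnet("shape", "crop %d has dims %s, expected %s", i,
                  paste(dim(p), collapse = "x"), paste(d, collapse = "x"))
    x[, , , i] <- p
    lb <- crop_label(crops[[i]])
    if (!is.null(lb)) labels[i] <- lb
  }
  list(x = x, labels = labels)
}

crop_pixels <- function(crop) {
  if (inherits(crop, "cell_crop")) crop$pixels else crop
}

crop_label <- function(crop) {
  if (inherits(crop, "cell_crop")) crop$label else attr(crop, "label")
}
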