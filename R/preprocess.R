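#' Single-cell crop
#'
#' A fixed-size multi-channel image patch centered on one cell, with its
#' normalization state, optional class label, and the originating cell
#' record.
#'
#' @param pixels `H x W x C` numeric array.
#' @param label optional class name.
#' @param normalized logical; `TRUE` once values have been mapped to
#'   `[0, 1]`.
#' @param source optional originating cell record (one-row data.frame).
#' @param channels optional character vector of channel role names.
#' @return an object of class `cell_crop`.
#' @export
cell_crop <- function(pixels, label = NULL, normalized = FALSE,
                      source = NULL, channels = NULL) {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L)
    stop_locnet("shape", "pixels must be an H x W x C array")
  if (d[1] != d[2])
    stop_locnet("shape", "crop spatial dims must be square, got %dx%d",
                d[1], d[2])
  structure(list(pixels = pixels, label = label,
                 normalized = isTRUE(normalized), source = source,
                 channels = channels),
            class = "cell_crop")
}

#' @export
print.cell_crop <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cell_crop> %dx%d, %d channel(s)%s%s\n", d[1], d[2], d[3],
              if (!is.null(x$label)) paste0(", label=", x$label) else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Extract a fixed-size crop centered on a cell
#'
#' Cuts a `size x size` window centered on the record's `(x, y)` pixel
#' coordinates (0-based; `x` = column, `y` = row) from every channel of the
#' field.  For even sizes the center pixel sits at offset `size/2` within
#' the window, so a 64-crop at `(x, y)` spans columns `x-32 .. x+31`.
#' Regions falling outside the field are zero-padded, which after
#' normalization is indistinguishable from dark background.
#'
#' @param field an `image_field`.
#' @param record one-row data.frame (or list) with `x`, `y`, optional
#'   `image_id` and `label`.
#' @param size crop side length in pixels.
#' @return an unnormalized [cell_crop()].
#' @export
extract_crop <- function(field, record, size = 64L) {
  stopifnot(inherits(field, "image_field"))
  size <- as.integer(size)
  if (!is.null(record$image_id) && !is.na(record$image_id) &&
      record$image_id != field$image_id)
    stop_locnet("data", "record image_id '%s' does not match field '%s'",
                record$image_id, field$image_id)
  H <- nrow(field$pixels[[1]]); W <- ncol(field$pixels[[1]])
  cx <- as.numeric(record$x); cy <- as.numeric(record$y)
  if (is.na(cx) || is.na(cy) || cx < 0 || cy < 0 || cx >= W || cy >= H)
    stop_locnet("range", "cell center (%s, %s) outside image bounds %dx%d",
                format(cx), format(cy), W, H)
  half <- size %/% 2L
  # 0-based source window [x0, x0+size) x [y0, y0+size)
  x0 <- round(cx) - half; y0 <- round(cy) - half
  out <- array(0, c(size, size, length(field$pixels)))
  sx <- max(0, x0); ex <- min(W, x0 + size)        # valid source cols
  sy <- max(0, y0); ey <- min(H, y0 + size)
  if (ex > sx && ey > sy) {
    for (ch in seq_along(field$pixels)) {
      out[(sy - y0 + 1L):(ey - y0), (sx - x0 + 1L):(ex - x0), ch] <-
        field$pixels[[ch]][(sy + 1L):ey, (sx + 1L):ex]
    }
  }
  cell_crop(out, label = if (!is.null(record$label) &&
                             !is.na(record$label %||% NA)) record$label,
            normalized = FALSE,
            source = as.data.frame(record, stringsAsFactors = FALSE),
            channels = field$channels)
}

# per-channel percentile normalization of a (H, W, C) array
normalize_array <- function(px, saturation_pct = 0.001) {
  d <- dim(px)
  for (ch in seq_len(d[3])) {
    v <- px[, , ch]
    q <- quantile(v, c(saturation_pct, 1 - saturation_pct), names = FALSE,
                  type = 7)
    if (q[2] <= q[1]) {
      warning(sprintf("channel %d is constant after saturation; mapped to 0",
                      ch), call. = FALSE)
      px[, , ch] <- 0
    } else {
      v <- pmin(pmax(v, q[1]), q[2])
      px[, , ch] <- (v - q[1]) / (q[2] - q[1])
    }
  }
  px
}

#' Normalize a crop to [0, 1] with percentile saturation
#'
#' Per channel, values are clipped to the `saturation_pct` and
#' `1 - saturation_pct` empirical quantiles (linear-interpolation quantiles;
#' by default the 0.1 and 99.9 percentiles) and affinely mapped to
#' `[0, 1]`.  A channel whose two quantiles coincide carries no usable
#' signal and is mapped to all zeros with a warning.
#'
#' @param crop a [cell_crop()]; must not be normalized already.
#' @param saturation_pct fraction saturated at each tail (default 0.001,
#'   i.e. the 0.1 percentile).
#' @return the normalized `cell_crop`.
#' @export
normalize_crop <- function(crop, saturation_pct = 0.001) {
  stopifnot(inherits(crop, "cell_crop"))
  if (crop$normalized)
    stop_locnet("data", "crop is already normalized")
  crop$pixels <- normalize_array(crop$pixels, saturation_pct)
  crop$normalized <- TRUE
  crop
}

#' Normalize a batch of crops
#'
#' Applies [normalize_crop()]'s per-channel, per-crop percentile mapping to
#' an `(H, W, C, N)` array in place.
#'
#' @param x `(H, W, C, N)` array.
#' @param saturation_pct as in [normalize_crop()].
#' @return array of the same shape with every crop/channel mapped to
#'   `[0, 1]`.
#' @export
normalize_batch <- function(x, saturation_pct = 0.001) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  for (i in seq_len(d[4]))
    x[, , , i] <- normalize_array(x[, , , i, drop = TRUE], saturation_pct)
  x
}

# Apply patch extraction + dihedral transform given draws; px is (H, W, C).
# ox, oy are 0-based offsets; fh/fv flip columns/rows; rot in {0,1,2,3}
# counter-clockwise quarter turns.
apply_patch_transform <- function(px, patch, ox, oy, fh, fv, rot) {
  p <- px[(oy + 1L):(oy + patch), (ox + 1L):(ox + patch), , drop = FALSE]
  if (fv) p <- p[patch:1L, , , drop = FALSE]
  if (fh) p <- p[, patch:1L, , drop = FALSE]
  if (rot > 0L) for (r in seq_len(rot)) {
    # 90 degree counter-clockwise rotation of each channel
    p <- aperm(p, c(2L, 1L, 3L))[patch:1L, , , drop = FALSE]
  }
  p
}

#' Random training augmentation: 60x60 patch, flips, quarter rotations
#'
#' Draws a uniform random patch offset over the valid positions, two
#' independent fair coin flips for vertical/horizontal reflection, and a
#' uniform rotation in \{0, 90, 180, 270\} degrees.  All transforms are
#' pixel permutations within the chosen window, so the multiset of pixel
#' values (and the label) is preserved.  Deterministic given `seed`.
#'
#' @param crop a normalized [cell_crop()] (64x64 by default usage).
#' @param seed integer seed.
#' @param patch output patch size (default 60).
#' @return an augmented `cell_crop` of size `patch x patch`.
#' @export
augment_crop <- function(crop, seed, patch = 60L) {
  stopifnot(inherits(crop, "cell_crop"))
  if (!crop$normalized)
    stop_locnet("data", "augmentation expects a normalized crop")
  d <- dim(crop$pixels)
  if (d[1] < patch)
    stop_locnet("size", "crop size %d smaller than patch size %d",
                d[1], patch)
  span <- d[1] - patch
  px <- with_seed(seed, {
    ox <- sample.int(span + 1L, 1L) - 1L
    oy <- sample.int(span + 1L, 1L) - 1L
    fv <- runif(1) < 0.5
    fh <- runif(1) < 0.5
    rot <- sample.int(4L, 1L) - 1L
    apply_patch_transform(crop$pixels, patch, ox, oy, fh, fv, rot)
  })
  cell_crop(px, label = crop$label, normalized = TRUE, source = crop$source,
            channels = crop$channels)
}

# batch augmentation drawing from the current RNG stream (training loop)
augment_batch <- function(x, patch = 60L) {
  d <- dim(x)
  span <- d[1] - patch
  out <- array(0, c(patch, patch, d[3], d[4]))
  ox <- sample.int(span + 1L, d[4], replace = TRUE) - 1L
  oy <- sample.int(span + 1L, d[4], replace = TRUE) - 1L
  fv <- runif(d[4]) < 0.5
  fh <- runif(d[4]) < 0.5
  rot <- sample.int(4L, d[4], replace = TRUE) - 1L
  for (i in seq_len(d[4])) {
    xi <- x[, , , i]
    dim(xi) <- d[1:3]
    out[, , , i] <- apply_patch_transform(xi, patch, ox[i], oy[i], fh[i],
                                          fv[i], rot[i])
  }
  out
}

#' Deterministic five-crop evaluation patches
#'
#' Returns the center `patch x patch` crop plus the four corner crops, in
#' the fixed order: center (offset `(2, 2)` for 64 to 60), then corners
#' top-left `(0, 0)`, top-right `(0, 4)`, bottom-left `(4, 0)`,
#' bottom-right `(4, 4)` (offsets given as `(row, col)`).  Test-time
#' predictions average the network outputs over these five patches.
#'
#' @param crop a normalized [cell_crop()].
#' @param patch patch size (default 60).
#' @return list of five `cell_crop` patches.
#' @export
eval_crops <- function(crop, patch = 60L) {
  stopifnot(inherits(crop, "cell_crop"))
  if (!crop$normalized)
    stop_locnet("data", "evaluation crops expect a normalized crop")
  d <- dim(crop$pixels)
  if (d[1] < patch)
    stop_locnet("size", "crop size %d smaller than patch size %d",
                d[1], patch)
  span <- d[1] - patch
  ctr <- span %/% 2L
  offs <- list(c(ctr, ctr), c(0L, 0L), c(0L, span), c(span, 0L),
               c(span, span))
  lapply(offs, function(o) {
    cell_crop(crop$pixels[(o[1] + 1L):(o[1] + patch),
                          (o[2] + 1L):(o[2] + patch), , drop = FALSE],
              label = crop$label, normalized = TRUE, source = crop$source,
              channels = crop$channels)
  })
}

# offsets used by eval_crops, exposed for batch prediction
eval_offsets <- function(size, patch) {
  span <- size - patch
  ctr <- span %/% 2L
  list(c(ctr, ctr), c(0L, 0L), c(0L, span), c(span, 0L), c(span, span))
}
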