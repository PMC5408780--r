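# Synthetic fluorescence-microscopy generator: 64x64 two-channel single-cell
# crops (channel 1 = green/GFP pattern, channel 2 = red cytosolic marker),
# whole fields with coordinate tables, and two-condition screens with planted
# localization shifts and abundance fold changes.

CROP_SIZE <- 64L

#' Morphology and intensity parameters for the synthetic generator
#'
#' Cell bodies are anti-aliased ellipses with random orientation averaging
#' 49 pixels along the major axis and 37 along the minor axis, matching the
#' size statistics of budding yeast in the imaging setup the classifier
#' targets.  Intensities are rendered in a 16-bit-like range and left
#' un-normalized so the percentile-saturation path is exercised downstream.
#'
#' @param major_axis_px mean cell major axis (pixels).
#' @param minor_axis_px mean cell minor axis (pixels).
#' @param axis_cv coefficient of variation of both axes.
#' @param background_level red-channel background intensity; the green
#'   background is one tenth of it (GFP imaging is low-background).
#' @param noise_sd additive Gaussian noise scale (both channels; clipped
#'   at zero).
#' @param green_level peak green signal amplitude.
#' @param red_level peak red (cell body) amplitude.
#' @param class_pattern named list of per-class pattern parameter
#'   overrides (e.g. `punctate = list(n_spots = 8, spot_sigma = 1.6)`).
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(major_axis_px = 49, minor_axis_px = 37,
                              axis_cv = 0.12, background_level = 100,
                              noise_sd = 25, green_level = 8000,
                              red_level = 3000, class_pattern = list()) {
  if (major_axis_px <= 0 || minor_axis_px <= 0)
    stop_locnet("config", "axes must be positive")
  if (axis_cv < 0 || noise_sd < 0)
    stop_locnet("config", "axis_cv and noise_sd must be non-negative")
  structure(list(major_axis_px = major_axis_px,
                 minor_axis_px = minor_axis_px, axis_cv = axis_cv,
                 background_level = background_level, noise_sd = noise_sd,
                 green_level = green_level, red_level = red_level,
                 class_pattern = class_pattern),
            class = "morphology_params")
}

#' Names of the built-in localization pattern generators
#'
#' Nine visually distinct compartment patterns.  Punctate classes may carry
#' an explicit spot count in the class name, e.g. `"punctate_k8"`.
#'
#' @return character vector of base pattern names.
#' @export
pattern_classes <- function() {
  c("cytoplasm", "nucleus", "nucleolus", "nuclear_periphery",
    "cell_periphery", "punctate", "bud_neck", "vacuole", "mitochondria")
}

# parse "punctate_k8" -> list(base = "punctate", n_spots = 8)
parse_class_name <- function(class_name) {
  m <- regmatches(class_name, regexec("^(.*)_k([0-9]+)$", class_name))[[1]]
  if (length(m) == 3L) list(base = m[2], n_spots = as.integer(m[3]))
  else list(base = class_name, n_spots = NULL)
}

# ---- geometry --------------------------------------------------------------

# soft-edged unit-radius indicator: 1 inside, 0 outside, linear over `w`
soft_in <- function(r, edge = 0.08) pmin(1, pmax(0, (1 - r) / edge + 0.5))

# soft ring at radius r0 with half-thickness th (same units as r)
soft_ring <- function(r, r0, th) pmin(1, pmax(0, (th - abs(r - r0)) / th))

# elliptical radius field for a 64x64 crop
ellipse_radius <- function(cx, cy, a, b, theta) {
  x <- matrix(rep(0:(CROP_SIZE - 1L), each = CROP_SIZE), CROP_SIZE) - cx
  y <- matrix(rep(0:(CROP_SIZE - 1L), times = CROP_SIZE), CROP_SIZE) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

gauss_spot <- function(cx, cy, sigma) {
  x <- matrix(rep(0:(CROP_SIZE - 1L), each = CROP_SIZE), CROP_SIZE) - cx
  y <- matrix(rep(0:(CROP_SIZE - 1L), times = CROP_SIZE), CROP_SIZE) - cy
  exp(-(x^2 + y^2) / (2 * sigma^2))
}

# ---- pattern renderers -----------------------------------------------------
# Each renderer receives the cell geometry and returns list(green = 64x64
# pattern in [0, 1] units, mask = logical pattern mask).  Randomness uses
# the current RNG stream.

render_pattern <- function(base, n_spots, geo, params) {
  cp <- params$class_pattern
  r <- geo$r                 # elliptical radius field
  body <- geo$body
  switch(base,
    cytoplasm = {
      nuc <- soft_in(geo$rn, 0.2)
      g <- body * (1 - 0.6 * nuc)
      list(green = g, mask = body > 0.5 & nuc < 0.5)
    },
    nucleus = {
      g <- soft_in(geo$rn, 0.15)
      list(green = g, mask = geo$rn <= 1)
    },
    nucleolus = {
      # compact blob displaced within the nucleus
      ang <- runif(1, 0, 2 * pi)
      off <- 0.45 * geo$rn_px
      g <- gauss_spot(geo$ncx + off * cos(ang), geo$ncy + off * sin(ang),
                      (cp$nucleolus$sigma %||% 2.2))
      list(green = g, mask = g > 0.5)
    },
    nuclear_periphery = {
      th <- cp$nuclear_periphery$thickness %||% 0.25
      g <- soft_ring(geo$rn, 1, th)
      list(green = g, mask = abs(geo$rn - 1) <= th)
    },
    cell_periphery = {
      th <- cp$cell_periphery$thickness %||% 0.08
      g <- soft_ring(r, 0.92, th)
      list(green = g, mask = abs(r - 0.92) <= th)
    },
    punctate = {
      k <- n_spots %||% (cp$punctate$n_spots %||% 6L)
      sigma <- cp$punctate$spot_sigma %||% 1.6
      mind <- cp$punctate$min_dist %||% 7
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(pts) < k && tries < 500L) {
        tries <- tries + 1L
        ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.7
        u <- rad * geo$a * cos(ang); v <- rad * geo$b * sin(ang)
        px <- geo$cx + u * cos(geo$theta) - v * sin(geo$theta)
        py <- geo$cy + u * sin(geo$theta) + v * cos(geo$theta)
        if (nrow(pts) == 0 ||
            min(sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)) >= mind)
          pts <- rbind(pts, c(px, py))
      }
      g <- matrix(0, CROP_SIZE, CROP_SIZE)
      for (i in seq_len(nrow(pts)))
        g <- pmax(g, gauss_spot(pts[i, 1], pts[i, 2], sigma))
      list(green = g, mask = g > 0.5)
    },
    bud_neck = {
      # bright band at the major-axis tip, elongated perpendicular to it
      tipx <- geo$cx + geo$a * cos(geo$theta)
      tipy <- geo$cy + geo$a * sin(geo$theta)
      x <- matrix(rep(0:(CROP_SIZE - 1L), each = CROP_SIZE), CROP_SIZE) - tipx
      y <- matrix(rep(0:(CROP_SIZE - 1L), times = CROP_SIZE), CROP_SIZE) - tipy
      u <- x * cos(geo$theta) + y * sin(geo$theta)
      v <- -x * sin(geo$theta) + y * cos(geo$theta)
      g <- exp(-(u^2 / (2 * 1.8^2) + v^2 / (2 * 4.5^2)))
      list(green = g, mask = g > 0.5)
    },
    vacuole = {
      rv <- cp$vacuole$radius %||% 0.45
      th <- cp$vacuole$thickness %||% 0.1
      g <- soft_ring(r, rv, th) + 0.15 * soft_in(r / rv, 0.2)
      list(green = pmin(g, 1), mask = abs(r - rv) <= th)
    },
    mitochondria = {
      sigma <- cp$mitochondria$sigma %||% 1.2
      g <- matrix(0, CROP_SIZE, CROP_SIZE)
      for (f in 1:3) {
        ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.5
        px <- geo$cx + rad * geo$a * cos(ang)
        py <- geo$cy + rad * geo$b * sin(ang)
        dirang <- runif(1, 0, 2 * pi)
        for (s in 1:22) {
          g <- pmax(g, gauss_spot(px, py, sigma))
          dirang <- dirang + rnorm(1, 0, 0.35)
          px <- px + 1.3 * cos(dirang); py <- py + 1.3 * sin(dirang)
          # turn back when leaving the body
          u <- (px - geo$cx) * cos(geo$theta) + (py - geo$cy) * sin(geo$theta)
          v <- -(px - geo$cx) * sin(geo$theta) + (py - geo$cy) * cos(geo$theta)
          if (sqrt((u / geo$a)^2 + (v / geo$b)^2) > 0.85) dirang <- dirang + pi
        }
      }
      list(green = g, mask = g > 0.5)
    },
    stop_locnet("vocabulary", "unknown localization class '%s'", base)
  )
}

# draw cell geometry from the current RNG stream
draw_geometry <- function(params, jitter = 2) {
  theta <- runif(1, 0, pi)
  a <- params$major_axis_px / 2 *
    max(0.4, 1 + params$axis_cv * rnorm(1))
  b <- params$minor_axis_px / 2 *
    max(0.4, 1 + params$axis_cv * rnorm(1))
  cx <- (CROP_SIZE - 1) / 2 + runif(1, -jitter, jitter)
  cy <- (CROP_SIZE - 1) / 2 + runif(1, -jitter, jitter)
  r <- ellipse_radius(cx, cy, a, b, theta)
  body <- soft_in(r, 0.08)
  # nucleus: disk of ~1/3 the minor semi-axis, slightly offset
  rn_px <- 0.32 * b * 2
  ncx <- cx + rnorm(1, 0, 1.2); ncy <- cy + rnorm(1, 0, 1.2)
  nx <- matrix(rep(0:(CROP_SIZE - 1L), each = CROP_SIZE), CROP_SIZE) - ncx
  ny <- matrix(rep(0:(CROP_SIZE - 1L), times = CROP_SIZE), CROP_SIZE) - ncy
  rn <- sqrt(nx^2 + ny^2) / rn_px
  list(theta = theta, a = a, b = b, cx = cx, cy = cy, r = r, body = body,
       rn = rn, rn_px = rn_px, ncx = ncx, ncy = ncy)
}

# Render one cell's noiseless signal channels.  Returns green/red signal
# (no background, no noise) plus masks.
render_cell_signal <- function(class_name, params, abundance = 1) {
  pc <- parse_class_name(class_name)
  if (!(pc$base %in% pattern_classes()))
    stop_locnet("vocabulary", "unknown localization class '%s'", class_name)
  geo <- draw_geometry(params)
  pat <- render_pattern(pc$base, pc$n_spots, geo, params)
  green <- abundance * params$green_level * pat$green
  red <- params$red_level * geo$body
  list(green = green, red = red, body_mask = geo$body > 0.5,
       pattern_mask = pat$mask, geo = geo)
}

#' Simulate a labeled single-cell crop
#'
#' Renders a 64x64 two-channel crop (channel 1 green/GFP following the
#' class pattern, channel 2 red marker filling the cell body), adds
#' background and clipped Gaussian noise, and attaches the generator's own
#' body and pattern masks as attributes `"body_mask"` and `"pattern_mask"`.
#' Deterministic given `(class_name, params, seed)`.
#'
#' @param class_name a registered pattern name (see [pattern_classes()]);
#'   punctate classes may carry a spot count suffix, e.g. `"punctate_k8"`.
#' @param params a [morphology_params()].
#' @param seed integer seed.
#' @param abundance green-signal multiplier (used by [simulate_screen()]
#'   to plant fold changes).
#' @return a labeled, unnormalized [cell_crop()].
#' @export
simulate_cell <- function(class_name, params = morphology_params(),
                          seed = 1L, abundance = 1) {
  with_seed(seed, {
    sig <- render_cell_signal(class_name, params, abundance)
    gbg <- params$background_level * 0.1
    g <- sig$green + gbg
    r <- sig$red + params$background_level
    if (params$noise_sd > 0) {
      g <- g + rnorm(length(g), 0, params$noise_sd)
      r <- r + rnorm(length(r), 0, params$noise_sd)
    }
    px <- array(0, c(CROP_SIZE, CROP_SIZE, 2L))
    px[, , 1] <- pmin(pmax(g, 0), 65535)
    px[, , 2] <- pmin(pmax(r, 0), 65535)
    crop <- cell_crop(px, label = class_name, normalized = FALSE,
                      channels = c("green", "red"))
    attr(crop, "body_mask") <- sig$body_mask
    attr(crop, "pattern_mask") <- sig$pattern_mask
    attr(crop, "green_signal") <- sig$green
    crop
  })
}

#' Simulate a whole field with a coordinate table
#'
#' Places `n_cells` cells on a jittered grid (touching allowed, as in real
#' images), renders each cell's 64x64 signal stamp into the field, then
#' adds background and noise once.  Returned records hold the true rendered
#' centers as 0-based `(x, y)` pixel coordinates.
#'
#' @param n_cells number of cells (>= 0).
#' @param params a [morphology_params()].
#' @param seed integer seed.
#' @param classes class names to sample labels from.
#' @return list with `field` (an `image_field`), `cells` (data.frame with
#'   `image_id`, `x`, `y`, `label`), and attribute `"green_mass"` giving
#'   each cell's total rendered green signal.
#' @export
simulate_field <- function(n_cells, params = morphology_params(), seed = 1L,
                           classes = pattern_classes()) {
  stopifnot(n_cells >= 0)
  with_seed(seed, {
    ncol_grid <- max(1L, ceiling(sqrt(n_cells)))
    nrow_grid <- max(1L, ceiling(n_cells / ncol_grid))
    pitch <- 52L
    Wf <- ncol_grid * pitch + CROP_SIZE
    Hf <- nrow_grid * pitch + CROP_SIZE
    green <- matrix(0, Hf, Wf)
    red <- matrix(0, Hf, Wf)
    image_id <- sprintf("synthetic_field_%d", seed)
    cells <- data.frame(image_id = character(0), x = integer(0),
                        y = integer(0), label = character(0),
                        stringsAsFactors = FALSE)
    masses <- numeric(0)
    if (n_cells > 0) {
      labels <- sample(classes, n_cells, replace = TRUE)
      for (i in seq_len(n_cells)) {
        gi <- (i - 1L) %% ncol_grid
        gj <- (i - 1L) %/% ncol_grid
        cx <- CROP_SIZE %/% 2L + gi * pitch + sample(-6:6, 1)
        cy <- CROP_SIZE %/% 2L + gj * pitch + sample(-6:6, 1)
        sig <- render_cell_signal(labels[i], params)
        # stamp center within its 64x64 buffer
        scx <- round(sig$geo$cx); scy <- round(sig$geo$cy)
        x0 <- cx - scx; y0 <- cy - scy        # 0-based top-left of stamp
        x0 <- max(0L, min(Wf - CROP_SIZE, x0))
        y0 <- max(0L, min(Hf - CROP_SIZE, y0))
        cx <- x0 + scx; cy <- y0 + scy        # true rendered center
        rows <- (y0 + 1L):(y0 + CROP_SIZE)
        cols <- (x0 + 1L):(x0 + CROP_SIZE)
        green[rows, cols] <- green[rows, cols] + sig$green
        red[rows, cols] <- red[rows, cols] + sig$red
        cells <- rbind(cells, data.frame(image_id = image_id, x = cx, y = cy,
                                         label = labels[i],
                                         stringsAsFactors = FALSE))
        masses <- c(masses, sum(sig$green))
      }
    }
    gbg <- params$background_level * 0.1
    green <- green + gbg
    red <- red + params$background_level
    if (params$noise_sd > 0) {
      green <- green + rnorm(length(green), 0, params$noise_sd)
      red <- red + rnorm(length(red), 0, params$noise_sd)
    }
    field <- image_field(list(green = pmin(pmax(green, 0), 65535),
                              red = pmin(pmax(red, 0), 65535)),
                         channels = c("green", "red"), image_id = image_id)
    out <- list(field = field, cells = cells)
    attr(out, "green_mass") <- masses
    out
  })
}

#' Simulate a two-condition screen with planted effects
#'
#' Generates per-protein cell populations under two conditions.  A fraction
#' of proteins change localization class between conditions
#' (`planted_shifts`); named proteins in `abundance_effects` have their
#' green signal scaled by the stated fold change in condition B.  With
#' `shift_fraction = 0` and no abundance effects, both conditions are drawn
#' from identical distributions per protein.
#'
#' Each cell's mean green intensity within the generator's body mask is
#' recorded in the cell table (`green_mean`), standing in for the
#' segmentation-based per-cell intensity a real pipeline would extract.
#'
#' @param n_proteins number of proteins.
#' @param cells_per_protein cells imaged per protein per condition.
#' @param shift_fraction fraction of proteins with a planted localization
#'   shift (class change in condition B).
#' @param abundance_effects named numeric vector of green-intensity fold
#'   changes keyed by protein id (e.g. `c(P003 = 2)`), or `NULL`.
#' @param params a [morphology_params()].
#' @param seed integer seed.
#' @param classes class vocabulary to assign base classes from.
#' @return an object of class `synthetic_screen` with fields `crops`
#'   (`64 x 64 x 2 x N` array), `cells` (data.frame: `cell_id`,
#'   `protein_id`, `condition`, `class`, `green_mean`), `truth`
#'   (per-protein classes and fold changes), `planted_shifts`,
#'   `planted_abundance`.
#' @export
simulate_screen <- function(n_proteins, cells_per_protein,
                            shift_fraction = 0, abundance_effects = NULL,
                            params = morphology_params(), seed = 1L,
                            classes = c("cytoplasm", "nucleus",
                                        "nuclear_periphery",
                                        "cell_periphery", "punctate_k8",
                                        "bud_neck")) {
  stopifnot(shift_fraction >= 0, shift_fraction <= 1, n_proteins >= 1,
            cells_per_protein >= 1)
  protein_ids <- sprintf("P%03d", seq_len(n_proteins))
  if (!is.null(abundance_effects)) {
    if (is.null(names(abundance_effects)) ||
        !all(names(abundance_effects) %in% protein_ids))
      stop_locnet("config",
                  "abundance_effects must be named by valid protein ids")
    if (any(abundance_effects <= 0))
      stop_locnet("config", "fold changes must be positive")
  }
  n_shift <- round(shift_fraction * n_proteins)
  assign_seed <- derive_seed(seed, 0L)
  setup <- with_seed(assign_seed, {
    class_a <- sample(rep_len(classes, n_proteins))
    shifted <- if (n_shift > 0) sort(sample(protein_ids, n_shift))
               else character(0)
    class_b <- class_a
    for (p in shifted) {
      i <- match(p, protein_ids)
      class_b[i] <- sample(setdiff(classes, class_a[i]), 1L)
    }
    list(class_a = class_a, class_b = class_b, shifted = shifted)
  })
  fold <- setNames(rep(1, n_proteins), protein_ids)
  if (!is.null(abundance_effects))
    fold[names(abundance_effects)] <- abundance_effects

  total <- n_proteins * cells_per_protein * 2L
  crops <- array(0, c(CROP_SIZE, CROP_SIZE, 2L, total))
  cells <- data.frame(cell_id = character(total),
                      protein_id = character(total),
                      condition = character(total),
                      class = character(total),
                      green_mean = numeric(total),
                      stringsAsFactors = FALSE)
  idx <- 0L
  counter <- 0L
  for (i in seq_len(n_proteins)) {
    for (cond in c("A", "B")) {
      cls <- if (cond == "A") setup$class_a[i] else setup$class_b[i]
      ab <- if (cond == "B") fold[i] else 1
      for (j in seq_len(cells_per_protein)) {
        counter <- counter + 1L
        idx <- idx + 1L
        crop <- simulate_cell(cls, params, seed = derive_seed(seed, counter),
                              abundance = ab)
        crops[, , , idx] <- crop$pixels
        bm <- attr(crop, "body_mask")
        cells$cell_id[idx] <- sprintf("%s_%s_%03d", protein_ids[i], cond, j)
        cells$protein_id[idx] <- protein_ids[i]
        cells$condition[idx] <- cond
        cells$class[idx] <- cls
        cells$green_mean[idx] <- mean(crop$pixels[, , 1][bm])
      }
    }
  }
  structure(list(crops = crops, cells = cells,
                 truth = data.frame(protein_id = protein_ids,
                                    class_a = setup$class_a,
                                    class_b = setup$class_b,
                                    fold_change = unname(fold),
                                    shifted = protein_ids %in% setup$shifted,
                                    stringsAsFactors = FALSE),
                 planted_shifts = setup$shifted,
                 planted_abundance = fold[fold != 1],
                 classes = classes, params = params, seed = seed),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_screen> %d proteins x %d cells x 2 ",
                     "conditions\n  planted shifts: %d; abundance effects: ",
                     "%d\n"),
              nrow(x$truth), sum(x$cells$protein_id == x$truth$protein_id[1] &
                                 x$cells$condition == "A"),
              length(x$planted_shifts), length(x$planted_abundance)))
  invisible(x)
}
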