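# Minimal baseline TIFF (uncompressed, grayscale pages = channels) and PNG
# (grayscale, zlib via memCompress) codecs.  No image I/O package is
# assumed; intensities are read and written without any rescaling.

# ---- byte helpers ----------------------------------------------------------

u16_le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8), 255L)))
u32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
u32_be <- function(x) rev(u32_le(x))

rd_u16 <- function(b, off, le) {
  v <- as.integer(b[off + 1:2])
  if (le) v[1] + 256L * v[2] else v[2] + 256L * v[1]
}
rd_u32 <- function(b, off, le) {
  v <- as.numeric(as.integer(b[off + 1:4]))
  if (!le) v <- rev(v)
  v[1] + 256 * v[2] + 65536 * v[3] + 16777216 * v[4]
}

# ---- TIFF ------------------------------------------------------------------

# channels: list of H x W numeric matrices, written as one grayscale page
# each, little-endian, single strip, no compression.
write_tiff <- function(channels, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_len <- H * W * (bits %/% 8L)
  data_len_pad <- data_len + data_len %% 2L
  con <- file(path, "wb")
  on.exit(close(con))
  # header
  writeBin(charToRaw("II"), con)
  writeBin(u16_le(42L), con)
  first_ifd <- 8 + data_len_pad
  writeBin(u32_le(first_ifd), con)
  offset <- 8
  for (i in seq_along(channels)) {
    m <- channels[[i]]
    if (nrow(m) != H || ncol(m) != W)
      stop_locnet("io", "all channels must share height and width")
    v <- as.integer(round(as.vector(t(m))))   # row-major
    if (bits == 8L) {
      writeBin(as.raw(pmin(pmax(v, 0L), 255L)), con)
    } else {
      writeBin(pmin(pmax(v, 0L), 65535L), con, size = 2L,
               endian = "little")
    }
    if (data_len %% 2L) writeBin(as.raw(0L), con)
    ifd_off <- offset + data_len_pad
    next_off <- if (i < length(channels))
      ifd_off + ifd_size + data_len_pad else 0
    entry <- function(tag, type, count, value) {
      c(u16_le(tag), u16_le(type), u32_le(count),
        if (type == 3L) c(u16_le(value), u16_le(0L)) else u32_le(value))
    }
    ifd <- c(u16_le(n_entries),
             entry(256L, 4L, 1L, W),
             entry(257L, 4L, 1L, H),
             entry(258L, 3L, 1L, bits),
             entry(259L, 3L, 1L, 1L),          # no compression
             entry(262L, 3L, 1L, 1L),          # black is zero
             entry(273L, 4L, 1L, offset),      # strip offset
             entry(277L, 3L, 1L, 1L),
             entry(278L, 4L, 1L, H),
             entry(279L, 4L, 1L, data_len),
             entry(339L, 3L, 1L, 1L),          # unsigned integer data
             u32_le(next_off))
    writeBin(ifd, con)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

read_tiff <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 8) stop_locnet("io", "'%s' is not a TIFF file", path)
  le <- if (rawToChar(b[1:2]) == "II") TRUE
        else if (rawToChar(b[1:2]) == "MM") FALSE
        else stop_locnet("io", "'%s' is not a TIFF file", path)
  if (rd_u16(b, 2, le) != 42L)
    stop_locnet("io", "'%s' is not a TIFF file", path)
  ifd_off <- rd_u32(b, 4, le)
  pages <- list()
  while (ifd_off != 0) {
    n <- rd_u16(b, ifd_off, le)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2 + (k - 1) * 12
      tag <- rd_u16(b, e, le)
      type <- rd_u16(b, e + 2, le)
      count <- rd_u32(b, e + 4, le)
      type_size <- c(1, 1, 2, 4)[type]
      if (is.na(type_size))
        { tags[[as.character(tag)]] <- NULL; next }
      inline <- count * type_size <= 4
      voff <- if (inline) e + 8 else rd_u32(b, e + 8, le)
      vals <- numeric(count)
      for (j in seq_len(count)) {
        vals[j] <- switch(as.character(type),
          "1" = as.integer(b[voff + j]),
          "3" = rd_u16(b, voff + (j - 1) * 2, le),
          "4" = rd_u32(b, voff + (j - 1) * 4, le),
          NA_real_)
      }
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- rd_u32(b, ifd_off + 2 + n * 12, le)
  }
  lapply(pages, function(tags) {
    W <- tags[["256"]][1]; H <- tags[["257"]][1]
    bits <- tags[["258"]][1] %||% 8
    comp <- tags[["259"]][1] %||% 1
    spp <- tags[["277"]][1] %||% 1
    if (comp != 1)
      stop_locnet("io", "compressed TIFF (compression=%d) not supported",
                  comp)
    if (spp != 1)
      stop_locnet("io", "only 1 sample per pixel supported (multi-channel = multi-page)")
    if (!(bits %in% c(8, 16)))
      stop_locnet("io", "unsupported bit depth %d", bits)
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    raw_data <- do.call(c, lapply(seq_along(offs), function(i)
      b[(offs[i] + 1):(offs[i] + cnts[i])]))
    if (bits == 8) {
      v <- as.integer(raw_data)
    } else {
      ints <- as.integer(raw_data)
      i1 <- ints[seq(1, length(ints), 2)]
      i2 <- ints[seq(2, length(ints), 2)]
      v <- if (le) i1 + 256L * i2 else i2 + 256L * i1
    }
    t(matrix(v[seq_len(H * W)], W, H))
  })
}

# ---- CRC32 (for PNG chunks) ------------------------------------------------

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L                       # 0xEDB88320
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L)) bitwXor(poly, bitwShiftR(cc, 1L))
            else bitwShiftR(cc, 1L)
    }
    tab[n + 1L] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  ints <- as.integer(bytes)
  for (byte in ints) {
    crc <- bitwXor(crc32_table[bitwAnd(bitwXor(crc, byte), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  # to unsigned
  if (crc < 0) crc + 4294967296 else as.numeric(crc)
}

# ---- PNG (grayscale 8/16-bit) ----------------------------------------------

png_chunk <- function(type, data) {
  c(u32_be(length(data)), charToRaw(type), data,
    u32_be(crc32(c(charToRaw(type), data))))
}

write_png <- function(m, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  H <- nrow(m); W <- ncol(m)
  v <- as.integer(round(as.vector(t(m))))
  if (bits == 8L) {
    v <- pmin(pmax(v, 0L), 255L)
    rows <- matrix(v, nrow = W, ncol = H)      # columns = image rows
    stream <- as.raw(rbind(0L, rows))
  } else {
    v <- pmin(pmax(v, 0L), 65535L)
    hi <- v %/% 256L; lo <- v %% 256L
    inter <- as.integer(rbind(hi, lo))          # big-endian sample bytes
    rows <- matrix(inter, nrow = 2L * W, ncol = H)
    stream <- as.raw(rbind(0L, rows))
  }
  idat <- memCompress(stream, "gzip")           # zlib stream
  ihdr <- c(u32_be(W), u32_be(H), as.raw(c(bits, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

png_paeth <- function(a, b, cc) {
  p <- a + b - cc
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
}

read_png <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  if (length(b) < 8 || !identical(b[1:8], sig))
    stop_locnet("io", "'%s' is not a PNG file", path)
  off <- 8
  W <- H <- bits <- color <- NULL
  idat <- raw(0)
  while (off < length(b)) {
    len <- rd_u32(b, off, FALSE)
    type <- rawToChar(b[(off + 5):(off + 8)])
    data <- if (len > 0) b[(off + 9):(off + 8 + len)] else raw(0)
    if (type == "IHDR") {
      W <- rd_u32(data, 0, FALSE); H <- rd_u32(data, 4, FALSE)
      bits <- as.integer(data[9]); color <- as.integer(data[10])
      if (color != 0L)
        stop_locnet("io", "only grayscale PNG supported (color type %d)",
                    color)
      if (!(bits %in% c(8L, 16L)))
        stop_locnet("io", "unsupported PNG bit depth %d", bits)
      if (as.integer(data[13]) != 0L)
        stop_locnet("io", "interlaced PNG not supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    off <- off + 12 + len
  }
  stream <- as.integer(memDecompress(idat, "gzip"))
  bpp <- bits %/% 8L
  rowbytes <- W * bpp
  prev <- integer(rowbytes)
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    base <- (r - 1L) * (rowbytes + 1L)
    filt <- stream[base + 1L]
    cur <- stream[base + 1L + seq_len(rowbytes)]
    if (filt == 1L) {
      for (i in (bpp + 1L):rowbytes) cur[i] <- (cur[i] + cur[i - bpp]) %% 256L
    } else if (filt == 2L) {
      cur <- (cur + prev) %% 256L
    } else if (filt == 3L) {
      for (i in seq_len(rowbytes)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        cur[i] <- (cur[i] + (a + prev[i]) %/% 2L) %% 256L
      }
    } else if (filt == 4L) {
      for (i in seq_len(rowbytes)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        cc <- if (i > bpp) prev[i - bpp] else 0L
        cur[i] <- (cur[i] + png_paeth(a, prev[i], cc)) %% 256L
      }
    } else if (filt != 0L) {
      stop_locnet("io", "unsupported PNG filter %d", filt)
    }
    prev <- cur
    out[r, ] <- if (bpp == 1L) cur
                else cur[seq(1, rowbytes, 2)] * 256L + cur[seq(2, rowbytes, 2)]
  }
  out
}
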