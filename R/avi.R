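# Uncompressed RGB24 AVI (RIFF) container support.
#
# Frames are stored as BI_RGB device-independent bitmaps: 24 bits per pixel,
# BGR byte order, rows bottom-up and padded to 4-byte boundaries. This is the
# intra-only, lossless layout every mainstream decoder accepts, so fixture
# geometry is never perturbed by compression. Compressed streams are refused
# with an explicit error rather than mis-decoded.

.fourcc <- function(x) {
  stopifnot(nchar(x) == 4L)
  charToRaw(x)
}

.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

.read_u32 <- function(con, n = 1L) {
  readBin(con, "integer", n = n, size = 4L, endian = "little")
}

.read_fourcc <- function(con) {
  raw <- readBin(con, "raw", n = 4L)
  if (length(raw) < 4L) return(NA_character_)
  rawToChar(raw)
}

# Encode one H x W x 3 RGB integer frame (0..255) as a padded bottom-up BGR
# pixel buffer.
.encode_dib <- function(frame) {
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  # rows bottom-up, channels BGR, channel fastest then x then y
  arr <- aperm(frame[h:1L, , 3:1, drop = FALSE], c(3L, 2L, 1L))
  rowbytes <- 3L * w
  pad <- (4L - rowbytes %% 4L) %% 4L
  if (pad > 0L) {
    m <- matrix(as.integer(arr), nrow = rowbytes, ncol = h)
    m <- rbind(m, matrix(0L, nrow = pad, ncol = h))
    as.raw(as.vector(m))
  } else {
    as.raw(as.vector(arr))
  }
}

.decode_dib <- function(bytes, w, h) {
  rowbytes <- 3L * w
  pad <- (4L - rowbytes %% 4L) %% 4L
  stride <- rowbytes + pad
  m <- matrix(as.integer(bytes), nrow = stride, ncol = h)
  v <- m[seq_len(rowbytes), , drop = FALSE]       # BGR, x fastest, rows bottom-up
  a <- array(v, dim = c(3L, w, h))
  flip <- h:1L
  out <- array(0L, dim = c(h, w, 3L))
  out[, , 1L] <- t(a[3L, , ])[flip, , drop = FALSE]
  out[, , 2L] <- t(a[2L, , ])[flip, , drop = FALSE]
  out[, , 3L] <- t(a[1L, , ])[flip, , drop = FALSE]
  out
}

# Write a list of H x W x 3 integer RGB frames as an uncompressed AVI.
# fps may be fractional; it is stored as the rational round(fps*1000)/1000.
write_avi <- function(frames, path, fps) {
  stopifnot(length(frames) >= 1L, fps > 0)
  d <- dim(frames[[1L]])
  h <- d[1L]; w <- d[2L]
  n <- length(frames)
  rowbytes <- 3L * w
  stride <- rowbytes + (4L - rowbytes %% 4L) %% 4L
  framebytes <- stride * h

  rate <- as.integer(round(fps * 1000))
  scale <- 1000L
  usec <- as.integer(round(1e6 * scale / rate))

  avih <- c(.fourcc("avih"), .u32(56L),
            .u32(usec), .u32(framebytes * as.integer(ceiling(fps))), .u32(0L),
            .u32(0x10L),                      # AVIF_HASINDEX
            .u32(n), .u32(0L), .u32(1L), .u32(framebytes),
            .u32(w), .u32(h), .u32(rep(0L, 4L)))

  strh <- c(.fourcc("strh"), .u32(56L),
            .fourcc("vids"), .fourcc("DIB "),
            .u32(0L), .u32(0L), .u32(0L),
            .u32(scale), .u32(rate),
            .u32(0L), .u32(n), .u32(framebytes), .u32(0L), .u32(0L),
            .u16(c(0L, 0L, w, h)))

  strf <- c(.fourcc("strf"), .u32(40L),
            .u32(40L), .u32(w), .u32(h),
            .u16(1L), .u16(24L),
            .u32(0L),                         # BI_RGB
            .u32(framebytes), .u32(0L), .u32(0L), .u32(0L), .u32(0L))

  strl <- c(.fourcc("LIST"), .u32(4L + length(strh) + length(strf)),
            .fourcc("strl"), strh, strf)
  hdrl <- c(.fourcc("LIST"), .u32(4L + length(avih) + length(strl)),
            .fourcc("hdrl"), avih, strl)

  movi_body_len <- n * (8L + framebytes)
  movi_hdr <- c(.fourcc("LIST"), .u32(4L + movi_body_len), .fourcc("movi"))

  idx <- vector("list", n)
  off <- 4L
  for (i in seq_len(n)) {
    idx[[i]] <- c(.fourcc("00db"), .u32(0x10L), .u32(off), .u32(framebytes))
    off <- off + 8L + framebytes
  }
  idx1 <- c(.fourcc("idx1"), .u32(16L * n), unlist(idx))

  riff_len <- 4L + length(hdrl) + length(movi_hdr) + movi_body_len + length(idx1)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(.fourcc("RIFF"), .u32(riff_len), .fourcc("AVI ")), con)
  writeBin(hdrl, con)
  writeBin(movi_hdr, con)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (!identical(dim(fr), d)) {
      stop("frame ", i, " dimensions differ from frame 1")
    }
    writeBin(c(.fourcc("00db"), .u32(framebytes)), con)
    writeBin(.encode_dib(fr), con)
  }
  writeBin(idx1, con)
  invisible(path)
}

# Parse an AVI file's structure: metadata plus the byte offset and size of
# every video-frame chunk. Does not load pixel data.
parse_avi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  if (!identical(.read_fourcc(con), "RIFF")) {
    stop("cannot decode '", path, "': not a RIFF/AVI container", call. = FALSE)
  }
  .read_u32(con)
  if (!identical(.read_fourcc(con), "AVI ")) {
    stop("cannot decode '", path, "': RIFF file is not an AVI", call. = FALSE)
  }

  meta <- list(width = NA_integer_, height = NA_integer_, fps = NA_real_,
               total_frames = NA_integer_, compression = NA_integer_,
               bitcount = NA_integer_)
  offsets <- integer(0)
  sizes <- integer(0)

  walk <- function(end) {
    repeat {
      pos <- seek(con, NA)
      if (pos >= end) break
      id <- .read_fourcc(con)
      if (is.na(id)) break
      size <- .read_u32(con)
      data_pos <- seek(con, NA)
      if (id == "LIST") {
        type <- .read_fourcc(con)
        if (type %in% c("hdrl", "strl", "movi")) {
          walk(data_pos + size)
        }
        seek(con, data_pos + size + size %% 2L)
      } else {
        if (id == "avih") {
          v <- .read_u32(con, 14L)
          meta$total_frames <<- v[5L]
          meta$width <<- v[9L]
          meta$height <<- v[10L]
        } else if (id == "strh") {
          type <- .read_fourcc(con)
          if (identical(type, "vids")) {
            .read_fourcc(con)            # handler
            v <- .read_u32(con, 7L)
            if (v[4L] > 0L) meta$fps <<- v[5L] / v[4L]
          }
        } else if (id == "strf" && is.na(meta$compression)) {
          v <- .read_u32(con, 3L)
          pb <- readBin(con, "integer", n = 2L, size = 2L,
                        endian = "little", signed = FALSE)
          meta$bitcount <<- pb[2L]
          meta$compression <<- .read_u32(con)
        } else if (grepl("^..d[bc]$", id)) {
          offsets <<- c(offsets, data_pos)
          sizes <<- c(sizes, size)
        }
        seek(con, data_pos + size + size %% 2L)
      }
    }
  }
  file_end <- file.size(path)
  walk(file_end)

  if (is.na(meta$width) || length(offsets) == 0L && is.na(meta$total_frames)) {
    stop("cannot decode '", path, "': no AVI headers found", call. = FALSE)
  }
  if (!is.na(meta$compression) && meta$compression != 0L) {
    stop("cannot decode '", path,
         "': compressed video stream (biCompression=", meta$compression,
         ") is not supported; use uncompressed RGB24", call. = FALSE)
  }
  if (!is.na(meta$bitcount) && meta$bitcount != 24L) {
    stop("cannot decode '", path, "': only 24-bit RGB frames are supported",
         call. = FALSE)
  }
  list(meta = meta, offsets = offsets, sizes = sizes)
}

.read_avi_frame <- function(con, offset, size, w, h) {
  seek(con, offset)
  bytes <- readBin(con, "raw", n = size)
  .decode_dib(bytes, w, h)
}
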