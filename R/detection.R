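#' HSV colour threshold window
#'
#' A detection target is defined by an inclusive window in hue/saturation/
#' value space. Hue is in degrees on the colour circle, `[0, 360)`;
#' saturation and value are fractions in `[0, 1]`. Because red straddles 0
#' degrees, the hue interval may wrap: `h_low > h_high` means the window
#' runs from `h_low` up through 360/0 to `h_high`, so a red tail-mark can be
#' selected with e.g. `hsv_range(350, 10, 0.5, 1, 0.3, 1)`.
#'
#' @param h_low,h_high Hue bounds in degrees, each in `[0, 360)`.
#' @param s_low,s_high Saturation bounds in `[0, 1]`, `s_low <= s_high`.
#' @param v_low,v_high Value bounds in `[0, 1]`, `v_low <= v_high`.
#' @return An `hsv_range`.
#' @export
hsv_range <- function(h_low, h_high, s_low, s_high, v_low, v_high) {
  vals <- c(h_low, h_high, s_low, s_high, v_low, v_high)
  if (any(!is.finite(vals))) stop("hsv_range: all bounds must be finite")
  if (h_low < 0 || h_low >= 360 || h_high < 0 || h_high > 360) {
    stop("hsv_range: hue bounds must lie in [0, 360]")
  }
  if (s_low > s_high) stop("hsv_range: s_low > s_high")
  if (v_low > v_high) stop("hsv_range: v_low > v_high")
  if (any(c(s_low, s_high, v_low, v_high) < 0) ||
      any(c(s_low, s_high, v_low, v_high) > 1)) {
    stop("hsv_range: saturation and value bounds must lie in [0, 1]")
  }
  structure(list(h_low = h_low, h_high = h_high, s_low = s_low,
                 s_high = s_high, v_low = v_low, v_high = v_high),
            class = "hsv_range")
}

#' @export
print.hsv_range <- function(x, ...) {
  cat(sprintf("<hsv_range> H [%g, %g]%s deg, S [%g, %g], V [%g, %g]\n",
              x$h_low, x$h_high,
              if (x$h_low > x$h_high) " (wrapped)" else "",
              x$s_low, x$s_high, x$v_low, x$v_high))
  invisible(x)
}

# Convert an RGB integer frame to HSV planes: hue in degrees [0, 360),
# saturation and value in [0, 1].
frame_to_hsv <- function(frame) {
  d <- dim(frame)
  hsv <- grDevices::rgb2hsv(r = as.vector(frame[, , 1L]),
                            g = as.vector(frame[, , 2L]),
                            b = as.vector(frame[, , 3L]),
                            maxColorValue = 255)
  list(h = matrix(hsv[1L, ] * 360, d[1L], d[2L]),
       s = matrix(hsv[2L, ], d[1L], d[2L]),
       v = matrix(hsv[3L, ], d[1L], d[2L]))
}

#' Threshold a frame by an HSV window
#'
#' A mask pixel is set iff the pixel's HSV triple lies inside the window,
#' all bounds inclusive, with hue wraparound when `h_low > h_high`.
#' Enlarging the window can only add mask pixels, never remove them.
#'
#' @param frame `height x width x 3` integer RGB array.
#' @param range An [hsv_range()].
#' @return A logical matrix of the frame's height and width.
#' @export
threshold_frame <- function(frame, range) {
  stopifnot(inherits(range, "hsv_range"))
  d <- dim(frame)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("frame must be a height x width x 3 colour array; ",
         "single-channel input is not supported")
  }
  p <- frame_to_hsv(frame)
  hue_ok <- if (range$h_low <= range$h_high) {
    p$h >= range$h_low & p$h <= range$h_high
  } else {
    p$h >= range$h_low | p$h <= range$h_high
  }
  hue_ok & p$s >= range$s_low & p$s <= range$s_high &
    p$v >= range$v_low & p$v <= range$v_high
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels that touch only diagonally are merged afterwards with union-find,
# matching the connectivity of contour-based detectors.
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)

  h <- nrow(lab); w <- ncol(lab)
  a <- lab[-h, -w]; b <- lab[-1, -1]    # NW-SE diagonal neighbours
  c_ <- lab[-h, -1]; d_ <- lab[-1, -w]  # NE-SW diagonal neighbours
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c_), as.vector(d_))
  )
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Minimum-area rotated rectangle of a point set via rotating calipers over
# the convex hull. Points are (x, y) rows. Returns centre, the two side
# lengths normalised so l >= w, and the orientation of the long side in
# degrees [0, 180) measured from +x towards +y (image convention).
min_rotated_rect <- function(pts) {
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n == 1L) {
    return(list(cx = hp[1, 1], cy = hp[1, 2], w = 0, l = 0, angle = 0))
  }
  best <- NULL
  best_area <- Inf
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) {
    e <- hp[nxt[i], ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (area < best_area - 1e-12) {
      best_area <- area
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      centre <- as.numeric(cu * u + cv * v)
      if (du >= dv) {
        axis <- u; l <- du; w <- dv
      } else {
        axis <- v; l <- dv; w <- du
      }
      ang <- atan2(axis[2L], axis[1L]) * 180 / pi
      ang <- ang %% 180
      best <- list(cx = centre[1L], cy = centre[2L], w = w, l = l,
                   angle = ang)
    }
  }
  best
}

# Boundary pixels of a logical component mask (pixels with a missing
# 4-neighbour); keeps the rotated-rectangle point cloud small.
.boundary_mask <- function(comp) {
  h <- nrow(comp); w <- ncol(comp)
  up <- rbind(FALSE, comp[-h, , drop = FALSE])
  dn <- rbind(comp[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, comp[, -w, drop = FALSE])
  rt <- cbind(comp[, -1, drop = FALSE], FALSE)
  comp & !(up & dn & lf & rt)
}

#' Find the largest connected object in a binary mask
#'
#' Labels 8-connected components, discards those smaller than `min_area`
#' (a salt-noise guard), and returns the geometry of the largest remaining
#' one: its area (filled pixel count), its area-weighted centroid, and its
#' minimum rotated rectangle with sides normalised so length >= width.
#' Ties on area are broken deterministically by the smallest bounding-box
#' origin (top-most, then left-most).
#'
#' Coordinates are 0-based: pixel centre `(x, y)` corresponds to matrix
#' entry `mask[y + 1, x + 1]`. Rectangle sides are measured over pixel
#' extents (a 10 x 10 pixel square has `rect_w = rect_l = 10`).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Minimum component area in pixels squared; smaller
#'   components are ignored.
#' @return A list with `found = TRUE`, `centroid_x`, `centroid_y`, `area`,
#'   `rect_cx`, `rect_cy`, `rect_w`, `rect_l`, `rect_angle`; or
#'   `list(found = FALSE)` when no component qualifies (a value, not an
#'   error).
#' @export
find_largest_object <- function(mask, min_area = 20) {
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list(found = FALSE))
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(list(found = FALSE))

  amax <- max(areas[keep])
  cand <- keep[areas[keep] == amax]
  if (length(cand) > 1L) {
    # tie-break: top-most then left-most bounding-box origin
    origin <- t(vapply(cand, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(min(idx[, 1L]), min(idx[, 2L]))
    }, numeric(2)))
    cand <- cand[order(origin[, 1L], origin[, 2L])]
  }
  target <- cand[1L]

  idx <- which(lab == target, arr.ind = TRUE)
  xs <- idx[, 2L] - 1L   # 0-based pixel-centre coordinates
  ys <- idx[, 1L] - 1L

  comp <- lab == target
  bidx <- which(.boundary_mask(comp), arr.ind = TRUE)
  bx <- bidx[, 2L] - 1L
  by <- bidx[, 1L] - 1L
  corners <- cbind(x = rep(bx, each = 4L) + c(-0.5, -0.5, 0.5, 0.5),
                   y = rep(by, each = 4L) + c(-0.5, 0.5, -0.5, 0.5))
  rect <- min_rotated_rect(corners)

  list(found = TRUE,
       centroid_x = mean(xs), centroid_y = mean(ys),
       area = length(xs),
       rect_cx = rect$cx, rect_cy = rect$cy,
       rect_w = rect$w, rect_l = rect$l, rect_angle = rect$angle)
}

#' Detect the target object in a single frame
#'
#' Optionally crops the frame, thresholds it by the HSV window, optionally
#' applies a morphological opening, and selects the largest connected
#' object. Coordinates are in cropped-frame space when a crop is given.
#'
#' @param frame `height x width x 3` integer RGB array.
#' @param range An [hsv_range()].
#' @param crop A [crop_rect()] or `NULL`.
#' @param min_area Minimum object area in pixels squared.
#' @param open_radius Radius of an optional morphological opening applied to
#'   the mask before component analysis; 0 (the default) disables it.
#' @return As [find_largest_object()].
#' @export
detect_in_frame <- function(frame, range, crop = NULL, min_area = 20,
                            open_radius = 0) {
  if (!is.null(crop)) frame <- crop_frame(frame, crop)
  mask <- threshold_frame(frame, range)
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(open_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::opening(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                             brush) > 0
  }
  find_largest_object(mask, min_area = min_area)
}

#' Read or write an HSV threshold preset file
#'
#' Presets are plain-text `key=value` files with keys `h_low`, `h_high`,
#' `s_low`, `s_high`, `v_low`, `v_high` and optionally `min_area`. The
#' native dialect uses hue in degrees `[0, 360)` and saturation/value in
#' `[0, 1]`. Files written by tools using the 8-bit OpenCV convention (hue
#' 0-179, saturation/value 0-255) are converted when `dialect = "opencv"`
#' is given explicitly; the dialect is never guessed.
#'
#' @param path Preset file path.
#' @param dialect `"degrees"` (native) or `"opencv"`.
#' @return `read_preset`: a list with `range` (an [hsv_range()]) and
#'   `min_area` (or `NULL` when absent).
#' @export
read_preset <- function(path, dialect = c("degrees", "opencv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("preset file '", path, "' does not exist")
  kv <- read_keyvalue(path)
  need <- c("h_low", "h_high", "s_low", "s_high", "v_low", "v_high")
  miss <- setdiff(need, names(kv))
  if (length(miss)) {
    stop("preset '", path, "' is missing keys: ", paste(miss, collapse = ", "))
  }
  num <- function(k) as.numeric(kv[[k]])
  if (dialect == "opencv") {
    range <- hsv_range(num("h_low") * 2, num("h_high") * 2,
                       num("s_low") / 255, num("s_high") / 255,
                       num("v_low") / 255, num("v_high") / 255)
  } else {
    range <- hsv_range(num("h_low"), num("h_high"), num("s_low"),
                       num("s_high"), num("v_low"), num("v_high"))
  }
  list(range = range,
       min_area = if ("min_area" %in% names(kv)) num("min_area") else NULL)
}

#' @rdname read_preset
#' @param range An [hsv_range()] to write.
#' @param min_area Optional minimum area to record in the preset.
#' @export
write_preset <- function(range, path, min_area = NULL) {
  stopifnot(inherits(range, "hsv_range"))
  kv <- unclass(range)
  if (!is.null(min_area)) kv$min_area <- min_area
  write_keyvalue(kv, path)
  invisible(path)
}

# key=value text files: one pair per line, '#' comments allowed.
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed key=value line in '", path, "': ", lines[bad][1L])
  }
  vals <- lapply(kv, function(p) trimws(p[2L]))
  names(vals) <- vapply(kv, function(p) trimws(p[1L]), character(1))
  vals
}

write_keyvalue <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    paste0(k, "=", if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
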