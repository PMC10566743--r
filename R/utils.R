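# Internal numeric/image primitives shared across modules.
#
# Coordinate convention (used everywhere in the package): pixel coordinates
# are 0-based with origin at the top-left corner; x indexes columns, y indexes
# rows; bounding boxes are half-open [x0, x1) x [y0, y1). Matrix element
# [r, c] (1-based) therefore corresponds to pixel (x = c - 1, y = r - 1).

eh_stop <- function(..., field = NULL) {
  msg <- paste0(...)
  if (!is.null(field)) msg <- sprintf("invalid '%s': %s", field, msg)
  stop(msg, call. = FALSE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generation inside
#' the package never perturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stream seed below 2^31 from a base seed and a label.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.numeric(seed) %% 2147483563
  for (p in parts) {
    for (cc in utf8ToInt(p)) {
      h <- (h * 31 + cc) %% 2147483563
    }
  }
  as.integer(h)
}

# --- bounding boxes ---------------------------------------------------------

validate_bbox <- function(bbox, frame_shape = NULL) {
  if (length(bbox) != 4L || anyNA(bbox)) {
    eh_stop("bounding box must be c(x0, y0, x1, y1)", field = "bbox")
  }
  bbox <- as.integer(round(bbox))
  if (bbox[3L] <= bbox[1L] || bbox[4L] <= bbox[2L]) {
    eh_stop("box is empty (half-open [x0,x1) x [y0,y1))", field = "bbox")
  }
  if (!is.null(frame_shape)) {
    h <- frame_shape[1L]; w <- frame_shape[2L]
    if (bbox[1L] < 0L || bbox[2L] < 0L || bbox[3L] > w || bbox[4L] > h) {
      eh_stop("box exceeds the frame", field = "bbox")
    }
  }
  bbox
}

bbox_width <- function(bbox) bbox[3L] - bbox[1L]
bbox_height <- function(bbox) bbox[4L] - bbox[2L]
bbox_area <- function(bbox) bbox_width(bbox) * bbox_height(bbox)

# Tight bounding box of a full-frame logical mask; NULL when the mask is empty.
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) return(NULL)
  c(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows))
}

# --- resampling -------------------------------------------------------------

# Bilinear lookup of matrix `m` at fractional 1-based coordinates (rows `ry`,
# cols `cx`), replicating the border outside the support.
bilinear_sample <- function(m, ry, cx) {
  h <- nrow(m); w <- ncol(m)
  ry <- clamp(ry, 1, h); cx <- clamp(cx, 1, w)
  r0 <- pmin(floor(ry), h - 1L); c0 <- pmin(floor(cx), w - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- ry - r0; fc <- cx - c0
  i00 <- (c0 - 1) * h + r0
  v <- m[i00] * (1 - fr) * (1 - fc) +
    m[i00 + 1] * fr * (1 - fc) +
    m[i00 + h] * (1 - fr) * fc +
    m[i00 + h + 1] * fr * fc
  v
}

resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ry <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  cx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  grid_r <- rep(ry, times = out_w)
  grid_c <- rep(cx, each = out_h)
  matrix(bilinear_sample(m, grid_r, grid_c), out_h, out_w)
}

# 2x decimation by 2x2 block averaging (odd trailing row/col dropped).
downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  (m[seq(1L, h, 2L), seq(1L, w, 2L), drop = FALSE] +
     m[seq(2L, h, 2L), seq(1L, w, 2L), drop = FALSE] +
     m[seq(1L, h, 2L), seq(2L, w, 2L), drop = FALSE] +
     m[seq(2L, h, 2L), seq(2L, w, 2L), drop = FALSE]) / 4
}

# Sum over a centred (2r+1)^2 window via integral images; border handled by
# zero padding (window shrinks at the edges numerically).
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2L * r, w + 2L * r)
  p[(r + 1L):(r + h), (r + 1L):(r + w)] <- m
  cs <- apply(p, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  cs <- rbind(0, cbind(0, cs))
  k <- 2L * r + 1L
  ri <- seq_len(h); ci <- seq_len(w)
  cs[ri + k, ci + k, drop = FALSE] - cs[ri, ci + k, drop = FALSE] -
    cs[ri + k, ci, drop = FALSE] + cs[ri, ci, drop = FALSE]
}

# --- frame storage ----------------------------------------------------------

# Frames are stored 8-bit (raw, with a dim attribute H x W x 3) to keep a
# whole task in memory; arithmetic happens on double copies in [0, 1].

quantize_frame <- function(frame) {
  r <- as.raw(clamp(round(frame * 255), 0, 255))
  dim(r) <- dim(frame)
  r
}

frame_to_double <- function(frame) {
  if (is.raw(frame)) {
    d <- as.numeric(as.integer(frame)) / 255
    dim(d) <- dim(frame)
    d
  } else {
    frame
  }
}

frame_gray <- function(frame) {
  0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
}

# L1-normalized histogram of values in [lo, hi] over n equal bins.
norm_hist <- function(x, n, lo = 0, hi = 1) {
  if (length(x) == 0L) return(numeric(n))
  b <- floor((x - lo) / (hi - lo) * n) + 1L
  b <- clamp(b, 1L, n)
  tabulate(b, nbins = n) / length(x)
}
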