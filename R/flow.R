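# Dense optical flow: coarse-to-fine Lucas-Kanade with windowed least
# squares. The flow algorithm is a pluggable contract throughout the
# package — any function mapping two intensity frames to per-pixel (u, v)
# can be supplied wherever a `flow_fn` argument appears; downstream feature
# code relies only on qualitative properties (zero flow for identical
# frames, approximately uniform flow under global translation).

lk_step <- function(I0, I1w, win = 3L, eps = 1e-3) {
  h <- nrow(I0); w <- ncol(I0)
  # central-difference spatial gradients on the reference frame
  Ix <- matrix(0, h, w); Iy <- matrix(0, h, w)
  Ix[, 2:(w - 1)] <- (I0[, 3:w] - I0[, 1:(w - 2)]) / 2
  Iy[2:(h - 1), ] <- (I0[3:h, ] - I0[1:(h - 2), ]) / 2
  It <- I1w - I0
  Sxx <- box_sum(Ix * Ix, win) + eps
  Syy <- box_sum(Iy * Iy, win) + eps
  Sxy <- box_sum(Ix * Iy, win)
  Sxt <- box_sum(Ix * It, win)
  Syt <- box_sum(Iy * It, win)
  det <- Sxx * Syy - Sxy * Sxy
  u <- -(Syy * Sxt - Sxy * Syt) / det
  v <- -(Sxx * Syt - Sxy * Sxt) / det
  bad <- !is.finite(u) | !is.finite(v)
  u[bad] <- 0; v[bad] <- 0
  list(u = u, v = v)
}

warp_image <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  ry <- rep(seq_len(h), times = w) + as.vector(v)
  cx <- rep(seq_len(w), each = h) + as.vector(u)
  matrix(bilinear_sample(img, ry, cx), h, w)
}

#' Dense optical flow between two intensity frames
#'
#' Pyramidal Lucas-Kanade: the frames are decimated `levels - 1` times, flow
#' is estimated coarse-to-fine with the running estimate used to warp the
#' second frame before each refinement. Displacements up to roughly
#' `2^levels` pixels are recovered; identical frames give exactly zero flow.
#'
#' @param I0,I1 intensity matrices (same size, values in \[0, 1\]).
#' @param levels pyramid levels (>= 1).
#' @param win half-width of the least-squares window at each level.
#' @param iters warp-and-refine iterations per level.
#' @param work_scale 1 or 0.5: at 0.5 the estimate is computed on a 2x
#'   decimated image and the result upsampled, quartering the cost; the
#'   output is always full-resolution per-pixel flow.
#' @return list with matrices `u` (x-displacement, columns) and `v`
#'   (y-displacement, rows), in pixels/frame.
#' @export
dense_flow <- function(I0, I1, levels = 3L, win = 3L, iters = 1L,
                       work_scale = 0.5) {
  if (!all(dim(I0) == dim(I1))) {
    eh_stop("frames must share geometry", field = "frames")
  }
  full_dim <- dim(I0)
  scaled <- work_scale == 0.5 && min(full_dim) >= 64L
  if (scaled) {
    I0 <- downsample2(I0); I1 <- downsample2(I1)
  }
  pyr0 <- list(I0); pyr1 <- list(I1)
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr0[[l]])) < 16L) break
    pyr0[[l + 1L]] <- downsample2(pyr0[[l]])
    pyr1[[l + 1L]] <- downsample2(pyr1[[l]])
  }
  L <- length(pyr0)
  u <- matrix(0, nrow(pyr0[[L]]), ncol(pyr0[[L]]))
  v <- u
  for (l in rev(seq_len(L))) {
    if (l < L) {
      u <- 2 * upsample_nearest(u, nrow(pyr0[[l]]), ncol(pyr0[[l]]))
      v <- 2 * upsample_nearest(v, nrow(pyr0[[l]]), ncol(pyr0[[l]]))
    }
    for (it in seq_len(iters)) {
      I1w <- if (all(u == 0) && all(v == 0)) pyr1[[l]] else warp_image(pyr1[[l]], u, v)
      d <- lk_step(pyr0[[l]], I1w, win = win)
      u <- u + d$u
      v <- v + d$v
    }
  }
  if (scaled) {
    u <- 2 * upsample_nearest(u, full_dim[1L], full_dim[2L])
    v <- 2 * upsample_nearest(v, full_dim[1L], full_dim[2L])
  }
  list(u = u, v = v)
}

upsample_nearest <- function(m, out_h, out_w) {
  ri <- pmin.int((seq_len(out_h) + 1L) %/% 2L, nrow(m))
  ci <- pmin.int((seq_len(out_w) + 1L) %/% 2L, ncol(m))
  m[ri, ci, drop = FALSE]
}
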