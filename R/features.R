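# Region-differenced colour / motion / shape descriptors for one hand
# instance, and batch extraction over a task.
#
# An instance is one hand in one frame. Its bounding box splits the frame
# into three regions: the hand (segmentation mask), the non-hand remainder
# of the box, and the background outside the box. Colour and motion
# features are signed bin-wise differences of L1-normalized histograms over
# the three region pairs (hand-nonhand, hand-background,
# nonhand-background); shape is a HOG over the box; the hand-role variant
# appends the normalized hand-size changes over the ten subsequent frames.

#' Feature configuration
#'
#' @param hsv_bins histogram bins per HSV channel.
#' @param flow_bins bins for flow magnitude and direction histograms.
#' @param flow_max magnitude clip, pixels/frame (bins cover `[0, flow_max]`).
#' @param hog_size side of the square canonical crop for HOG.
#' @param hog_cell HOG cell side in pixels.
#' @param hog_block HOG block side in cells.
#' @param hog_bins unsigned orientation bins over `[0, pi)`.
#' @param size_window number of subsequent frames for the size-change block.
#' @param flow_fn dense-flow function `(I0, I1) -> list(u, v)`;
#'   defaults to [dense_flow()].
#' @return a `feature_config` object with a `fingerprint` string.
#' @export
feature_config <- function(hsv_bins = 16L, flow_bins = 16L, flow_max = 8,
                           hog_size = 64L, hog_cell = 8L, hog_block = 2L,
                           hog_bins = 9L, size_window = 10L,
                           flow_fn = dense_flow) {
  cfg <- list(hsv_bins = as.integer(hsv_bins), flow_bins = as.integer(flow_bins),
              flow_max = flow_max, hog_size = as.integer(hog_size),
              hog_cell = as.integer(hog_cell), hog_block = as.integer(hog_block),
              hog_bins = as.integer(hog_bins), size_window = as.integer(size_window),
              flow_fn = flow_fn)
  nb <- hog_size %/% hog_cell - hog_block + 1L
  cfg$len_colour <- 3L * 3L * cfg$hsv_bins
  cfg$len_motion <- 3L * 2L * cfg$flow_bins
  cfg$len_shape <- nb * nb * hog_block * hog_block * cfg$hog_bins
  cfg$len_size <- cfg$size_window
  cfg$fingerprint <- paste("eh", hsv_bins, flow_bins, flow_max, hog_size,
                           hog_cell, hog_block, hog_bins, size_window, sep = "-")
  class(cfg) <- "feature_config"
  cfg
}

#' Length of a feature vector for a variant
#'
#' @param config a [feature_config()].
#' @param variant `"interaction"` (colour + motion + shape) or `"role"`
#'   (the same plus the size-change block).
#' @export
feature_length <- function(config, variant = c("interaction", "role")) {
  variant <- match.arg(variant)
  n <- config$len_colour + config$len_motion + config$len_shape
  if (variant == "role") n <- n + config$len_size
  n
}

#' Partition a frame into hand / non-hand / background regions
#'
#' @param frame_shape `c(height, width)` in pixels.
#' @param bbox hand bounding box, 0-based half-open `c(x0, y0, x1, y1)`.
#' @param hand_mask logical matrix of the box's dimensions (rows = y);
#'   `TRUE` marks hand pixels. An all-`FALSE` mask is accepted and flagged
#'   via the `empty_hand` field.
#' @return a `region_partition`.
#' @export
partition_regions <- function(frame_shape, bbox, hand_mask) {
  bbox <- validate_bbox(bbox, frame_shape)
  if (!is.logical(hand_mask) ||
      nrow(hand_mask) != bbox_height(bbox) || ncol(hand_mask) != bbox_width(bbox)) {
    eh_stop("must be a logical matrix matching the box", field = "hand_mask")
  }
  structure(list(frame_shape = as.integer(frame_shape), bbox = bbox,
                 hand_mask = hand_mask, empty_hand = !any(hand_mask)),
            class = "region_partition")
}

#' Pixel counts of the three regions of a partition
#' @param partition a [partition_regions()] result.
#' @return named vector `hand`, `nonhand`, `background`.
#' @export
region_sizes <- function(partition) {
  hand <- sum(partition$hand_mask)
  box <- bbox_area(partition$bbox)
  total <- prod(partition$frame_shape)
  c(hand = hand, nonhand = box - hand, background = total - box)
}

count_hist <- function(x, n, lo = 0, hi = 1) {
  if (length(x) == 0L) return(integer(n))
  b <- as.integer((x - lo) * (n / (hi - lo))) + 1L
  over <- b > n; if (any(over)) b[over] <- n
  under <- b < 1L; if (any(under)) b[under] <- 1L
  tabulate(b, nbins = n)
}

normalize_counts <- function(counts) {
  s <- sum(counts)
  if (s == 0) numeric(length(counts)) else counts / s
}

# Histogram machinery shared by the colour and motion blocks: `channels` is
# a list of full-frame value matrices with ranges; per channel, region
# histograms are built from counts (background = full-frame minus box).
region_channel_hists <- function(channels, partition, n_bins) {
  bbox <- partition$bbox
  rows <- (bbox[2L] + 1L):bbox[4L]
  cols <- (bbox[1L] + 1L):bbox[3L]
  mask <- partition$hand_mask
  lapply(channels, function(ch) {
    sub <- ch$values[rows, cols, drop = FALSE]
    hand <- count_hist(sub[mask], n_bins, ch$lo, ch$hi)
    box <- count_hist(sub, n_bins, ch$lo, ch$hi)
    full <- if (is.null(ch$full_counts)) count_hist(ch$values, n_bins, ch$lo, ch$hi) else ch$full_counts
    list(hand = normalize_counts(hand),
         nonhand = normalize_counts(box - hand),
         background = normalize_counts(full - box))
  })
}

frame_hsv <- function(frame) {
  hsvm <- grDevices::rgb2hsv(rbind(as.vector(frame[, , 1L]),
                                   as.vector(frame[, , 2L]),
                                   as.vector(frame[, , 3L])), maxColorValue = 1)
  d <- dim(frame)[1:2]
  list(h = matrix(hsvm[1L, ], d[1L], d[2L]),
       s = matrix(hsvm[2L, ], d[1L], d[2L]),
       v = matrix(hsvm[3L, ], d[1L], d[2L]))
}

#' Colour block: pairwise HSV-histogram differences
#'
#' For each region pair (hand-nonhand, hand-background,
#' nonhand-background) and each HSV channel, the signed bin-wise difference
#' of the two L1-normalized histograms. Empty regions contribute zero
#' histograms. Layout: pair-major, then channel (H, S, V), then bin.
#'
#' @param frame colour frame, H x W x 3 array in \[0, 1\] (or the 8-bit raw
#'   form used inside tasks).
#' @param partition a [partition_regions()] result.
#' @param config a [feature_config()].
#' @return numeric vector of length `3 * 3 * hsv_bins`.
#' @export
hsv_histogram_diff <- function(frame, partition, config = feature_config()) {
  frame <- frame_to_double(frame)
  hsv <- frame_hsv(frame)
  channels <- lapply(hsv, function(m) list(values = m, lo = 0, hi = 1,
                                           full_counts = NULL))
  per_ch <- region_channel_hists(channels, partition, config$hsv_bins)
  # pair-major layout: for each region pair, channels H, S, V
  blocks <- list(
    hn = lapply(per_ch, function(h) h$hand - h$nonhand),
    hb = lapply(per_ch, function(h) h$hand - h$background),
    nb = lapply(per_ch, function(h) h$nonhand - h$background)
  )
  unlist(lapply(blocks, unlist, use.names = FALSE), use.names = FALSE)
}

#' Per-region optical-flow histograms
#'
#' L1-normalized histograms of flow magnitude (clipped to
#' `[0, flow_max]`) and direction (`[0, 2*pi)`) for each region.
#'
#' @param flow list with `u`, `v` matrices (e.g. from [dense_flow()]).
#' @param partition a [partition_regions()] result.
#' @param config a [feature_config()].
#' @return list of regions, each with `mag` and `dir` histograms.
#' @export
flow_region_histograms <- function(flow, partition, config = feature_config()) {
  mag <- pmin(sqrt(flow$u^2 + flow$v^2), config$flow_max)
  dir <- atan2(flow$v, flow$u) %% (2 * pi)
  channels <- list(
    mag = list(values = mag, lo = 0, hi = config$flow_max, full_counts = NULL),
    dir = list(values = dir, lo = 0, hi = 2 * pi, full_counts = NULL)
  )
  per_ch <- region_channel_hists(channels, partition, config$flow_bins)
  list(
    hand = list(mag = per_ch$mag$hand, dir = per_ch$dir$hand),
    nonhand = list(mag = per_ch$mag$nonhand, dir = per_ch$dir$nonhand),
    background = list(mag = per_ch$mag$background, dir = per_ch$dir$background)
  )
}

#' Motion block: pairwise flow-histogram differences
#'
#' Dense flow is estimated from `frame_t` to `frame_t_plus_1` (unless a
#' precomputed `flow` is supplied); per region, magnitude and direction
#' histograms are built and differenced over the three region pairs.
#' Layout: pair-major (hand-nonhand, hand-background, nonhand-background),
#' magnitude bins then direction bins within each pair.
#'
#' @param frame_t,frame_t_plus_1 consecutive colour frames, same geometry.
#' @param partition a [partition_regions()] result (from `frame_t`).
#' @param config a [feature_config()].
#' @param flow optional precomputed flow (list `u`, `v`).
#' @return numeric vector of length `3 * 2 * flow_bins`.
#' @export
flow_histograms <- function(frame_t, frame_t_plus_1, partition,
                            config = feature_config(), flow = NULL) {
  if (is.null(flow)) {
    frame_t <- frame_to_double(frame_t)
    frame_t_plus_1 <- frame_to_double(frame_t_plus_1)
    if (!all(dim(frame_t) == dim(frame_t_plus_1))) {
      eh_stop("frames must share geometry", field = "frames")
    }
    flow <- config$flow_fn(frame_gray(frame_t), frame_gray(frame_t_plus_1))
  }
  h <- flow_region_histograms(flow, partition, config)
  c(h$hand$mag - h$nonhand$mag, h$hand$dir - h$nonhand$dir,
    h$hand$mag - h$background$mag, h$hand$dir - h$background$dir,
    h$nonhand$mag - h$background$mag, h$nonhand$dir - h$background$dir)
}

#' Shape block: HOG descriptor of the bounding-box crop
#'
#' The crop is converted to intensity, resized to a square canonical size,
#' and a standard HOG is computed: gradient magnitude votes (hard
#' assignment) into unsigned orientation bins per cell, overlapping blocks
#' of cells L2-normalized. A uniform crop yields the all-zero descriptor.
#'
#' @param frame colour frame.
#' @param bbox hand bounding box, 0-based half-open.
#' @param config a [feature_config()].
#' @return numeric vector of fixed length (1764 at the defaults).
#' @export
hog_descriptor <- function(frame, bbox, config = feature_config()) {
  frame <- frame_to_double(frame)
  bbox <- validate_bbox(bbox, dim(frame)[1:2])
  g <- frame_gray(frame)[(bbox[2L] + 1L):bbox[4L], (bbox[1L] + 1L):bbox[3L], drop = FALSE]
  n <- config$hog_size
  g <- resize_bilinear(g, n, n)
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- (g[, 3:n] - g[, 1:(n - 2)]) / 2
  gy[2:(n - 1), ] <- (g[3:n, ] - g[1:(n - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- clamp(floor(ang / pi * config$hog_bins) + 1L, 1L, config$hog_bins)

  ncell <- n %/% config$hog_cell
  # block-sum projector: P %*% M %*% t(P) sums cell_size x cell_size cells
  P <- matrix(0, ncell, n)
  for (k in seq_len(ncell)) {
    P[k, ((k - 1L) * config$hog_cell + 1L):(k * config$hog_cell)] <- 1
  }
  cells <- array(0, c(ncell, ncell, config$hog_bins))
  for (b in seq_len(config$hog_bins)) {
    cells[, , b] <- P %*% (mag * (bin == b)) %*% t(P)
  }

  nb <- ncell - config$hog_block + 1L
  out <- numeric(nb * nb * config$hog_block^2 * config$hog_bins)
  blen <- config$hog_block^2 * config$hog_bins
  k <- 0L
  for (by in seq_len(nb)) {
    for (bx in seq_len(nb)) {
      v <- as.vector(cells[by:(by + config$hog_block - 1L),
                           bx:(bx + config$hog_block - 1L), ])
      nrm <- sqrt(sum(v^2) + 1e-12)
      if (nrm > 1e-6) v <- v / nrm else v <- v * 0
      out[(k * blen + 1L):((k + 1L) * blen)] <- v
      k <- k + 1L
    }
  }
  out
}

#' Size-change block: normalized hand-size changes over subsequent frames
#'
#' Consecutive differences of hand-mask pixel counts over the instance
#' frame and up to `size_window` subsequent frames, normalized by the
#' instance's bounding-box area. When fewer frames are available (task
#' end, or the hand leaves the frame) the remaining entries are zero.
#'
#' @param areas mask pixel counts, instance frame first (length >= 1).
#' @param box_area bounding-box area of the instance frame, pixels.
#' @param config a [feature_config()].
#' @return numeric vector of length `size_window`.
#' @export
hand_size_change <- function(areas, box_area, config = feature_config()) {
  if (length(areas) < 1L) eh_stop("need at least one mask area", field = "areas")
  if (!is.numeric(box_area) || box_area <= 0) {
    eh_stop("must be positive", field = "box_area")
  }
  d <- diff(areas) / box_area
  d <- d[seq_len(min(length(d), config$size_window))]
  c(d, numeric(config$size_window - length(d)))
}

#' Marker for an instance without a detected bounding box
#'
#' Hands with no box are categorized downstream as no interaction and no
#' role without consulting the classifier.
#'
#' @param frame_index,hand_side instance address.
#' @return a `no_box` object.
#' @export
no_box_marker <- function(frame_index, hand_side) {
  structure(list(frame_index = frame_index, hand_side = hand_side),
            class = "no_box")
}

#' Test for the no-box marker
#' @param x object.
#' @export
is_no_box <- function(x) inherits(x, "no_box")

task_observation <- function(task, frame_index, hand_side) {
  task$observations[[paste0(frame_index, "_", hand_side)]]
}

# Mask areas for the instance frame and the `size_window` subsequent
# frames; stops at the first missing observation (hand left the frame).
size_change_areas <- function(task, frame_index, hand_side, config) {
  areas <- numeric(0)
  n <- length(task$frames)
  for (j in frame_index:min(frame_index + config$size_window, n - 1L)) {
    ob <- task_observation(task, j, hand_side)
    if (is.null(ob)) break
    areas <- c(areas, ob$area)
  }
  # at the task end the last available mask is treated as repeating, which
  # the zero padding of hand_size_change encodes directly
  areas
}

#' Build the feature vector for one hand instance
#'
#' Concatenates colour, motion and shape blocks (interaction variant) plus
#' the size-change block (role variant). An instance whose hand has no
#' bounding box returns the distinguished no-box marker instead of numbers.
#'
#' @param task an `eh_task` (see [get_task()]).
#' @param frame_index 0-based frame index.
#' @param hand_side `"left"` or `"right"`.
#' @param variant `"interaction"` or `"role"`.
#' @param config a [feature_config()].
#' @return numeric feature vector, or a [no_box_marker()].
#' @export
build_feature_vector <- function(task, frame_index, hand_side,
                                 variant = c("interaction", "role"),
                                 config = feature_config()) {
  variant <- match.arg(variant)
  ob <- task_observation(task, frame_index, hand_side)
  if (is.null(ob)) return(no_box_marker(frame_index, hand_side))
  n <- length(task$frames)
  f_t <- frame_to_double(task$frames[[frame_index + 1L]])
  part <- partition_regions(c(task$frame_height, task$frame_width), ob$bbox, ob$mask)
  colour <- hsv_histogram_diff(f_t, part, config)
  if (frame_index + 2L <= n) {
    f_t1 <- frame_to_double(task$frames[[frame_index + 2L]])
  } else {
    f_t1 <- f_t   # last frame: repeated, zero flow
  }
  motion <- flow_histograms(f_t, f_t1, part, config)
  shape <- hog_descriptor(f_t, ob$bbox, config)
  out <- c(colour, motion, shape)
  if (variant == "role") {
    areas <- size_change_areas(task, frame_index, hand_side, config)
    out <- c(out, hand_size_change(areas, bbox_area(ob$bbox), config))
  }
  out
}

#' Extract features for every hand instance of a task
#'
#' One pass over the task: per consecutive frame pair the dense flow and the
#' full-frame HSV representation are computed once and shared by both hands.
#' All blocks including size change are extracted, so the result serves both
#' the interaction and the role variants (the interaction variant simply
#' drops the trailing size-change columns). Frames where a hand has no
#' bounding box yield a metadata row flagged `no_box` with `NA` features.
#'
#' @param task an `eh_task`.
#' @param config a [feature_config()].
#' @return list with `meta` (data frame: participant_id, task_id,
#'   task_kind, env, frame_index, hand_side, interaction, role, no_box)
#'   and `X` (numeric matrix, one row per meta row, role-variant width).
#' @export
extract_task_features <- function(task, config = feature_config()) {
  n <- length(task$frames)
  H <- task$frame_height; W <- task$frame_width
  p_role <- feature_length(config, "role")
  labs <- task$labels
  labs <- labs[order(labs$frame, labs$side), , drop = FALSE]
  n_rows <- nrow(labs)
  X <- matrix(NA_real_, n_rows, p_role)
  no_box <- logical(n_rows)
  row_of <- function(fi, side) which(labs$frame == fi & labs$side == side)

  f_cur <- frame_to_double(task$frames[[1L]])
  g_cur <- frame_gray(f_cur)
  for (i in 0:(n - 1L)) {
    if (i + 2L <= n) {
      f_nxt <- frame_to_double(task$frames[[i + 2L]])
      g_nxt <- frame_gray(f_nxt)
    } else {
      f_nxt <- f_cur; g_nxt <- g_cur
    }
    sides_present <- c(
      if (!is.null(task_observation(task, i, "left"))) "left",
      if (!is.null(task_observation(task, i, "right"))) "right"
    )
    if (length(sides_present) > 0L) {
      hsv <- frame_hsv(f_cur)
      flow <- if (identical(g_nxt, g_cur)) {
        list(u = matrix(0, H, W), v = matrix(0, H, W))
      } else {
        config$flow_fn(g_cur, g_nxt)
      }
      mag <- pmin(sqrt(flow$u^2 + flow$v^2), config$flow_max)
      dir <- atan2(flow$v, flow$u) %% (2 * pi)
      channels <- list(
        h = list(values = hsv$h, lo = 0, hi = 1,
                 full_counts = count_hist(hsv$h, config$hsv_bins, 0, 1)),
        s = list(values = hsv$s, lo = 0, hi = 1,
                 full_counts = count_hist(hsv$s, config$hsv_bins, 0, 1)),
        v = list(values = hsv$v, lo = 0, hi = 1,
                 full_counts = count_hist(hsv$v, config$hsv_bins, 0, 1)),
        mag = list(values = mag, lo = 0, hi = config$flow_max,
                   full_counts = count_hist(mag, config$flow_bins, 0, config$flow_max)),
        dir = list(values = dir, lo = 0, hi = 2 * pi,
                   full_counts = count_hist(dir, config$flow_bins, 0, 2 * pi))
      )
      for (side in sides_present) {
        ob <- task_observation(task, i, side)
        part <- partition_regions(c(H, W), ob$bbox, ob$mask)
        per_ch <- c(region_channel_hists(channels[1:3], part, config$hsv_bins),
                    region_channel_hists(channels[4:5], part, config$flow_bins))
        colour <- c(
          unlist(lapply(per_ch[1:3], function(h) h$hand - h$nonhand), use.names = FALSE),
          unlist(lapply(per_ch[1:3], function(h) h$hand - h$background), use.names = FALSE),
          unlist(lapply(per_ch[1:3], function(h) h$nonhand - h$background), use.names = FALSE)
        )
        hm <- per_ch$mag; hd <- per_ch$dir
        motion <- c(hm$hand - hm$nonhand, hd$hand - hd$nonhand,
                    hm$hand - hm$background, hd$hand - hd$background,
                    hm$nonhand - hm$background, hd$nonhand - hd$background)
        shape <- hog_descriptor(f_cur, ob$bbox, config)
        areas <- size_change_areas(task, i, side, config)
        sc <- hand_size_change(areas, bbox_area(ob$bbox), config)
        X[row_of(i, side), ] <- c(colour, motion, shape, sc)
      }
    }
    for (side in c("left", "right")) {
      if (!(side %in% sides_present)) no_box[row_of(i, side)] <- TRUE
    }
    f_cur <- f_nxt; g_cur <- g_nxt
  }

  meta <- data.frame(
    participant_id = task$participant_id,
    task_id = if (is.null(task$task_id)) NA_character_ else task$task_id,
    task_kind = task$task_kind, env = task$env,
    frame_index = labs$frame, hand_side = labs$side,
    interaction = labs$interaction, role = labs$role,
    no_box = no_box, stringsAsFactors = FALSE
  )
  list(meta = meta, X = X, config_fingerprint = config$fingerprint)
}

#' Extract features for every task of a dataset
#'
#' Renders (or reads) and featurizes tasks one at a time so that frames of
#' at most one task are held in memory.
#'
#' @param dataset an `eh_dataset`.
#' @param config a [feature_config()].
#' @param verbose print one line per task.
#' @return list with stacked `meta` and `X` as in [extract_task_features()].
#' @export
featurize_dataset <- function(dataset, config = feature_config(), verbose = FALSE) {
  m <- dataset$manifest
  metas <- vector("list", nrow(m)); Xs <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    task <- get_task(dataset, m$participant_id[k], m$task_id[k])
    fe <- extract_task_features(task, config)
    metas[[k]] <- fe$meta; Xs[[k]] <- fe$X
    if (verbose) {
      message(sprintf("featurized %s/%s (%s, %s): %d instances",
                      m$participant_id[k], m$task_id[k], m$task_kind[k],
                      m$env[k], nrow(fe$meta)))
    }
    rm(task)
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  structure(list(meta = meta, X = do.call(rbind, Xs),
                 config_fingerprint = config$fingerprint),
            class = "eh_features")
}

#' Persist a feature table as CSV
#'
#' One row per instance: metadata and label columns followed by the feature
#' columns `f0001..` in stable order; no-box rows carry `NA` features.
#'
#' @param features an `eh_features` (or [extract_task_features()] result).
#' @param path output CSV path.
#' @export
write_feature_csv <- function(features, path) {
  X <- features$X
  colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  utils::write.csv(cbind(features$meta, as.data.frame(X)), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#' @param path CSV path.
#' @param config the [feature_config()] the features were extracted with.
#' @return an `eh_features`.
#' @export
read_feature_csv <- function(path, config = feature_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]{4}$", names(df))
  structure(list(meta = df[, -fcols, drop = FALSE],
                 X = as.matrix(df[, fcols, drop = FALSE]),
                 config_fingerprint = config$fingerprint),
            class = "eh_features")
}
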