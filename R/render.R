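# Rendering of scene scripts into frames, ground-truth observations and
# labels, and the in-memory / on-disk dataset representations.

hsv_to_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

object_palette <- matrix(c(
  0.60, 0.80, 0.80,   # blue
  0.33, 0.75, 0.70,   # green
  0.83, 0.70, 0.80,   # magenta
  0.50, 0.75, 0.75    # teal
), ncol = 3L, byrow = TRUE)

# Effective ellipse axes for a hand at a given aperture (closed hands are
# flatter and slightly shorter).
hand_axes <- function(ax, ay, aperture) {
  c(ax * (0.75 + 0.25 * aperture), ay * (0.5 + 0.5 * aperture))
}

#' Render a scene script into frames, observations and labels
#'
#' Produces a complete synthetic task: 8-bit colour frames (textured
#' background translated by the camera offset, object rectangle, skin-toned
#' hand ellipses deformed when closed, sensor noise), one ground-truth
#' observation (tight bounding box + exact mask) per visible hand per frame,
#' and the per-frame, per-hand label track.
#'
#' Uses the current RNG state (texture, object colour, noise); wrap in a
#' seeded context for reproducibility, or use [get_task()] which does so.
#'
#' @param script a `scene_script` from [script_task()].
#' @param spec the [cohort_spec()].
#' @param profile participant profile row (skin tone); when `NULL`, band
#'   centre values are used.
#' @return an `eh_task`: list with `frames` (raw H x W x 3 arrays),
#'   `observations` (named list, key `"<frame>_<side>"`), `labels`
#'   (data frame: frame, side, present, interaction, role), `task_kind`,
#'   `participant_id`, `env`, `fps`.
#' @export
render_frames <- function(script, spec, profile = NULL) {
  W <- script$frame_width; H <- script$frame_height
  ep <- env_params(spec$env)
  M <- ep$cam_max
  for (side in c("left", "right")) {
    h <- script$hands[[side]]
    if (2 * max(h$ax) >= W || 2 * max(h$ay) >= H) {
      eh_stop("frame size smaller than hand axes", field = "frame")
    }
  }

  # static background: coarse smooth field plus fine speckle, per channel
  bh <- H + 2L * M; bw <- W + 2L * M
  bg <- array(0, c(bh, bw, 3L))
  for (ch in 1:3) {
    coarse <- matrix(stats::runif(12 * 20, 0.25, 0.65), 12, 20)
    bg[, , ch] <- resize_bilinear(coarse, bh, bw) +
      matrix(stats::runif(bh * bw, -0.04, 0.04), bh, bw)
  }
  bg <- clamp(bg, 0, 1)

  obj_col <- object_palette[sample.int(nrow(object_palette), 1L), ]
  obj_rgb <- hsv_to_rgb(obj_col[1L], obj_col[2L], obj_col[3L])
  if (is.null(profile)) {
    skin <- c(0.07, 0.45, 0.85)
  } else {
    skin <- c(profile$skin_h, profile$skin_s, profile$skin_v)
  }
  skin_rgb <- hsv_to_rgb(skin[1L], skin[2L], skin[3L])

  n <- script$n_frames
  frames <- vector("list", n)
  observations <- list()
  lab_rows <- vector("list", 2L * n)

  for (i in seq_len(n)) {
    dx <- script$camera$dx[i]; dy <- script$camera$dy[i]
    fr <- bg[(M + 1L + dy):(M + H + dy), (M + 1L + dx):(M + W + dx), , drop = FALSE]

    # object rectangle (scene coords + camera offset), gradient-textured so
    # that its motion is trackable
    ob <- script$object$bbox + c(script$object$dx[i], 0, script$object$dx[i], 0)
    ob <- ob + c(dx, dy, dx, dy)
    c0 <- max(0L, floor(ob[1L])); c1 <- min(W, ceiling(ob[3L]))
    r0 <- max(0L, floor(ob[2L])); r1 <- min(H, ceiling(ob[4L]))
    if (c1 > c0 && r1 > r0) {
      cols <- (c0 + 1L):c1; rows <- (r0 + 1L):r1
      gx <- (cols - 1 - ob[1L]) / (ob[3L] - ob[1L])
      shade <- matrix(0.7 + 0.3 * gx, length(rows), length(cols), byrow = TRUE)
      for (ch in 1:3) fr[rows, cols, ch] <- obj_rgb[ch] * shade
    }

    for (side in c("left", "right")) {
      hrow <- script$hands[[side]][i, ]
      key <- paste0(i - 1L, "_", side)
      if (!hrow$present) next
      axes <- hand_axes(hrow$ax, hrow$ay, hrow$aperture)
      cx <- hrow$cx + dx; cy <- hrow$cy + dy
      wc0 <- max(0L, floor(cx - axes[1L] - 1)); wc1 <- min(W, ceiling(cx + axes[1L] + 1))
      wr0 <- max(0L, floor(cy - axes[2L] - 1)); wr1 <- min(H, ceiling(cy + axes[2L] + 1))
      if (wc1 <= wc0 || wr1 <= wr0) next
      cols <- (wc0 + 1L):wc1; rows <- (wr0 + 1L):wr1
      # pixel centres at (col-1, row-1) + 0.5 in 0-based coords
      px <- cols - 0.5; py <- rows - 0.5
      rr <- outer(((py - cy) / axes[2L])^2, ((px - cx) / axes[1L])^2, `+`)
      mloc <- rr <= 1
      if (!any(mloc)) next
      shade <- 1 - 0.3 * rr
      for (ch in 1:3) {
        sub <- fr[rows, cols, ch]
        sub[mloc] <- (skin_rgb[ch] * shade)[mloc]
        fr[rows, cols, ch] <- sub
      }
      # tight bbox of the rendered mask, in frame coordinates
      mb <- mask_bbox(mloc)
      bbox <- c(wc0 + mb[1L], wr0 + mb[2L], wc0 + mb[3L], wr0 + mb[4L])
      mask <- mloc[(mb[2L] + 1L):mb[4L], (mb[1L] + 1L):mb[3L], drop = FALSE]
      observations[[key]] <- list(
        frame = i - 1L, side = side, bbox = bbox,
        mask = mask, area = sum(mask)
      )
    }

    noise <- matrix(stats::rnorm(H * W, 0, ep$noise_sd), H, W)
    for (ch in 1:3) fr[, , ch] <- fr[, , ch] + noise
    frames[[i]] <- quantize_frame(clamp(fr, 0, 1))

    for (k in 1:2) {
      side <- c("left", "right")[k]
      hrow <- script$hands[[side]][i, ]
      lab_rows[[2L * (i - 1L) + k]] <- data.frame(
        frame = i - 1L, side = side,
        present = !is.null(observations[[paste0(i - 1L, "_", side)]]),
        interaction = as.integer(hrow$contact),
        role = hrow$role, stringsAsFactors = FALSE
      )
    }
  }

  structure(list(
    participant_id = script$participant_id,
    task_kind = script$task_kind,
    env = spec$env,
    fps = spec$fps,
    frame_width = W, frame_height = H,
    frames = frames,
    observations = observations,
    labels = do.call(rbind, lab_rows)
  ), class = "eh_task")
}

# Label track directly from a script (no rendering); `present` here reflects
# the scripted presence flag, which matches rendering for interior hands.
script_labels <- function(script) {
  out <- list()
  for (side in c("left", "right")) {
    h <- script$hands[[side]]
    out[[side]] <- data.frame(
      frame = h$frame, side = side, present = h$present,
      interaction = as.integer(h$contact), role = h$role,
      stringsAsFactors = FALSE
    )
  }
  lab <- rbind(out$left, out$right)
  lab[order(lab$frame, lab$side), , drop = FALSE]
}

#' Generate a synthetic cohort (labels and scripts; frames on demand)
#'
#' Samples participant profiles, schedules tasks (one negative task and at
#' least one bimanual task per participant, bimanual manipulator alternating
#' between hands across tasks), scripts every task, and assembles the
#' manifest with realized class fractions. Frames are not rasterized here;
#' [get_task()] renders a single task reproducibly, so arbitrarily large
#' cohorts never hold all pixels in memory at once.
#'
#' Realized fractions follow the convention documented in [cohort_spec()]:
#' the interaction fraction is computed over hand instances of non-negative
#' tasks, the manipulation fraction over interaction instances of bimanual
#' tasks.
#'
#' @param spec a [cohort_spec()].
#' @return an `eh_dataset` (source `"memory"`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  profiles <- sample_cohort(spec)
  sched <- task_schedule(spec$tasks_per_participant)
  prefix <- if (spec$env == "home") "T" else "L"

  scripts <- list()
  man_rows <- list()
  labels <- list()
  for (p in seq_len(nrow(profiles))) {
    prof <- profiles[p, ]
    bi_seen <- 0L
    for (j in seq_along(sched)) {
      tid <- sprintf("%s%02d", prefix, j)
      kind <- sched[j]
      manip <- "less_affected"
      if (kind == "bimanual") {
        bi_seen <- bi_seen + 1L
        if (bi_seen %% 2L == 0L) manip <- "more_affected"
      }
      key <- paste(prof$participant_id, tid, sep = "/")
      scripts[[key]] <- with_seed(
        derive_seed(spec$seed, "script", spec$env, key),
        script_task(prof, kind, spec$frames_per_task, spec, manipulator = manip)
      )
      labels[[key]] <- script_labels(scripts[[key]])
      man_rows[[key]] <- data.frame(
        participant_id = prof$participant_id, task_id = tid,
        task_kind = kind, env = spec$env,
        n_frames = spec$frames_per_task, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, man_rows)
  rownames(manifest) <- NULL

  ds <- structure(list(
    source = "memory", spec = spec, profiles = profiles,
    manifest = manifest, scripts = scripts, labels = labels
  ), class = "eh_dataset")
  ds$realized <- realized_fractions(ds)
  ds
}

# Realized interaction fraction (instances of non-negative tasks) and
# manipulation fraction (interaction instances of bimanual tasks).
realized_fractions <- function(dataset) {
  m <- dataset$manifest
  n_int <- 0L; n_inst <- 0L; n_man <- 0L; n_bi_int <- 0L
  for (k in seq_len(nrow(m))) {
    key <- paste(m$participant_id[k], m$task_id[k], sep = "/")
    lab <- dataset$labels[[key]]
    lab <- lab[lab$present, , drop = FALSE]
    if (m$task_kind[k] != "negative") {
      n_inst <- n_inst + nrow(lab)
      n_int <- n_int + sum(lab$interaction)
    }
    if (m$task_kind[k] == "bimanual") {
      n_bi_int <- n_bi_int + sum(lab$interaction)
      n_man <- n_man + sum(lab$role == "manipulation")
    }
  }
  list(interaction_fraction = n_int / n_inst,
       manipulation_fraction = n_man / n_bi_int)
}

#' Fetch one task of a dataset, with frames and observations
#'
#' For in-memory datasets the task is rendered on the fly under a seed
#' derived from the cohort seed and the task key, so repeated calls are
#' byte-identical; for on-disk datasets it is read back from the layout
#' written by [write_dataset()].
#'
#' @param dataset an `eh_dataset`.
#' @param participant_id,task_id task address as in `dataset$manifest`.
#' @return an `eh_task`.
#' @export
get_task <- function(dataset, participant_id, task_id) {
  key <- paste(participant_id, task_id, sep = "/")
  if (dataset$source == "memory") {
    script <- dataset$scripts[[key]]
    if (is.null(script)) eh_stop("unknown task ", key, field = "task_id")
    prof <- dataset$profiles[dataset$profiles$participant_id == participant_id, ]
    spec <- dataset$spec
    env <- dataset$manifest$env[dataset$manifest$participant_id == participant_id &
                                  dataset$manifest$task_id == task_id]
    spec$env <- env
    task <- with_seed(derive_seed(spec$seed, "render", env, key),
                      render_frames(script, spec, prof))
  } else {
    task <- read_task(dataset, participant_id, task_id)
  }
  task$task_id <- task_id
  task
}

#' Write a dataset to disk in the standard layout
#'
#' Layout: `<root>/<participant>/<task>/frames/%06d.png`,
#' `<root>/<participant>/<task>/masks/<side>_%06d.png` (8-bit 0/255),
#' one `annotations.csv` per task (columns `frame_index`, `hand_side`,
#' `x0`, `y0`, `x1`, `y1`, `interaction`, `role`; one row per visible hand,
#' boxes 0-based half-open), and a top-level `manifest.json` echoing the
#' spec, profiles, task table and realized fractions.
#'
#' @param dataset an in-memory `eh_dataset`.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) eh_stop("cannot create ", root, field = "root")
  probe <- file.path(root, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE))) {
    eh_stop("directory not writable: ", root, field = "root")
  }
  unlink(probe)

  m <- dataset$manifest
  for (k in seq_len(nrow(m))) {
    pid <- m$participant_id[k]; tid <- m$task_id[k]
    task <- get_task(dataset, pid, tid)
    tdir <- file.path(root, pid, tid)
    dir.create(file.path(tdir, "frames"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(tdir, "masks"), recursive = TRUE, showWarnings = FALSE)
    H <- task$frame_height; W <- task$frame_width
    for (i in seq_along(task$frames)) {
      png::writePNG(frame_to_double(task$frames[[i]]),
                    file.path(tdir, "frames", sprintf("%06d.png", i - 1L)))
    }
    ann <- list()
    for (ob in task$observations) {
      full <- matrix(0, H, W)
      full[(ob$bbox[2L] + 1L):ob$bbox[4L], (ob$bbox[1L] + 1L):ob$bbox[3L]][ob$mask] <- 1
      png::writePNG(full, file.path(tdir, "masks",
                                    sprintf("%s_%06d.png", ob$side, ob$frame)))
      lab <- task$labels[task$labels$frame == ob$frame & task$labels$side == ob$side, ]
      ann[[paste0(ob$frame, "_", ob$side)]] <- data.frame(
        frame_index = ob$frame, hand_side = ob$side,
        x0 = ob$bbox[1L], y0 = ob$bbox[2L], x1 = ob$bbox[3L], y1 = ob$bbox[4L],
        interaction = lab$interaction, role = lab$role, stringsAsFactors = FALSE
      )
    }
    ann <- do.call(rbind, ann)
    ann <- ann[order(ann$frame_index, ann$hand_side), , drop = FALSE]
    utils::write.csv(ann, file.path(tdir, "annotations.csv"), row.names = FALSE)
  }

  manifest <- list(
    spec = unclass(dataset$spec),
    profiles = dataset$profiles,
    tasks = m,
    realized = dataset$realized
  )
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(root)
}

#' Generate a synthetic dataset on disk
#'
#' Convenience wrapper: [generate_cohort()] followed by [write_dataset()].
#'
#' @inheritParams generate_cohort
#' @param root output directory.
#' @return `root`, invisibly.
#' @export
generate_dataset <- function(spec, root) {
  write_dataset(generate_cohort(spec), root)
}

#' Open an on-disk dataset
#'
#' @param root directory written by [write_dataset()].
#' @return an `eh_dataset` (source `"disk"`); tasks load via [get_task()].
#' @export
read_dataset <- function(root) {
  mf <- file.path(root, "manifest.json")
  if (!file.exists(mf)) eh_stop("no manifest.json under ", root, field = "root")
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  spec <- man$spec
  structure(list(
    source = "disk", root = root, spec = spec,
    profiles = as.data.frame(man$profiles),
    manifest = as.data.frame(man$tasks),
    realized = man$realized
  ), class = "eh_dataset")
}

read_task <- function(dataset, participant_id, task_id) {
  tdir <- file.path(dataset$root, participant_id, task_id)
  ann <- utils::read.csv(file.path(tdir, "annotations.csv"),
                         stringsAsFactors = FALSE)
  ffiles <- sort(list.files(file.path(tdir, "frames"), full.names = TRUE))
  frames <- lapply(ffiles, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    quantize_frame(a[, , 1:3, drop = FALSE])
  })
  n <- length(frames)
  mrow <- dataset$manifest[dataset$manifest$participant_id == participant_id &
                             dataset$manifest$task_id == task_id, ]
  observations <- list()
  for (k in seq_len(nrow(ann))) {
    r <- ann[k, ]
    mf <- file.path(tdir, "masks", sprintf("%s_%06d.png", r$hand_side, r$frame_index))
    full <- png::readPNG(mf)
    if (length(dim(full)) == 3L) full <- full[, , 1L]
    bbox <- c(r$x0, r$y0, r$x1, r$y1)
    mask <- full[(r$y0 + 1L):r$y1, (r$x0 + 1L):r$x1, drop = FALSE] > 0.5
    observations[[paste0(r$frame_index, "_", r$hand_side)]] <-
      list(frame = r$frame_index, side = r$hand_side, bbox = bbox,
           mask = mask, area = sum(mask))
  }
  labels <- expand.grid(frame = 0:(n - 1L), side = c("left", "right"),
                        stringsAsFactors = FALSE)
  labels <- labels[order(labels$frame, labels$side), ]
  idx <- match(paste0(labels$frame, "_", labels$side),
               paste0(ann$frame_index, "_", ann$hand_side))
  labels$present <- !is.na(idx)
  labels$interaction <- ifelse(is.na(idx), 0L, ann$interaction[idx])
  labels$role <- ifelse(is.na(idx), "none", ann$role[idx])
  rownames(labels) <- NULL
  structure(list(
    participant_id = participant_id, task_id = task_id,
    task_kind = mrow$task_kind, env = mrow$env, fps = dataset$spec$fps,
    frame_width = ncol(frames[[1L]]) , frame_height = nrow(frames[[1L]]),
    frames = frames, observations = observations, labels = labels
  ), class = "eh_task")
}

#' Combine two cohorts of the same participants into one study dataset
#'
#' Typical use: a `"home"` cohort plus a `"homelab"` cohort generated from
#' the same seed (hence identical participant profiles), mirroring a study
#' with home recordings supplemented by laboratory sessions. Task ids are
#' env-prefixed (`T..` home, `L..` homelab) so keys never collide.
#'
#' @param a,b in-memory `eh_dataset`s sharing identical profiles.
#' @return a merged `eh_dataset`.
#' @export
combine_datasets <- function(a, b) {
  stopifnot(a$source == "memory", b$source == "memory")
  if (!isTRUE(all.equal(a$profiles, b$profiles))) {
    eh_stop("participant profiles differ between the two datasets", field = "profiles")
  }
  ds <- a
  ds$manifest <- rbind(a$manifest, b$manifest)
  rownames(ds$manifest) <- NULL
  ds$scripts <- c(a$scripts, b$scripts)
  ds$labels <- c(a$labels, b$labels)
  ds$spec_b <- b$spec
  ds
}
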