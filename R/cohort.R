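# Synthetic cohort specification, participant sampling and task scripting.

#' Specify a synthetic egocentric cohort
#'
#' A `cohort_spec` fixes everything the synthetic-scene generator needs to
#' produce a reproducible multi-participant, multi-task dataset emulating
#' home (`env = "home"`, noisier, larger camera motion) or home-laboratory
#' (`env = "homelab"`, cleaner) egocentric recordings of stroke survivors.
#'
#' `interaction_prior` is the targeted fraction of interaction-positive hand
#' instances *within interaction (non-negative) tasks*: every participant
#' additionally receives one all-negative task (hands present, no object
#' manipulation), so an overall fraction as high as the prior could not be
#' realized otherwise. `manipulation_prior` is the targeted fraction of
#' manipulation frames among interaction frames of bimanual tasks.
#'
#' @param n_participants number of participants (>= 2; leave-one-subject-out
#'   evaluation needs at least one held-out subject and one trainer).
#' @param tasks_per_participant tasks per participant (>= 3; at least one
#'   negative and one bimanual task are always scheduled).
#' @param frames_per_task frames per task (>= 11; the hand-size-change
#'   feature looks ten frames ahead).
#' @param frame_width,frame_height frame size in pixels. The default
#'   320 x 180 keeps the 16:9 aspect of typical egocentric analysis
#'   resolutions at desk-scale cost.
#' @param fps frame rate in frames per second.
#' @param seed integer seed; identical specs generate identical cohorts.
#' @param env recording environment, `"home"` or `"homelab"`.
#' @param interaction_prior targeted interaction fraction in (0, 1).
#' @param manipulation_prior targeted manipulation fraction in (0, 1).
#' @param out_of_frame_rate probability that the idle hand of a unimanual
#'   task leaves the frame for a scripted span (exercises the missing-box
#'   rule). Free parameter of the generator, not an emulated quantity.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        tasks_per_participant = 4L,
                        frames_per_task = 300L,
                        frame_width = 320L,
                        frame_height = 180L,
                        fps = 30,
                        seed = 1L,
                        env = c("home", "homelab"),
                        interaction_prior = 0.7,
                        manipulation_prior = 0.2,
                        out_of_frame_rate = 0.15) {
  env <- match.arg(env)
  chk_int <- function(x, field, min) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < min) {
      eh_stop(sprintf("must be a single integer >= %d", min), field = field)
    }
    as.integer(x)
  }
  spec <- list(
    n_participants = chk_int(n_participants, "n_participants", 2L),
    tasks_per_participant = chk_int(tasks_per_participant, "tasks_per_participant", 3L),
    frames_per_task = chk_int(frames_per_task, "frames_per_task", 11L),
    frame_width = chk_int(frame_width, "frame_width", 64L),
    frame_height = chk_int(frame_height, "frame_height", 48L),
    fps = fps,
    seed = chk_int(seed, "seed", 0L),
    env = env,
    interaction_prior = interaction_prior,
    manipulation_prior = manipulation_prior,
    out_of_frame_rate = out_of_frame_rate
  )
  for (f in c("interaction_prior", "manipulation_prior")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      eh_stop("must lie strictly between 0 and 1", field = f)
    }
  }
  if (out_of_frame_rate < 0 || out_of_frame_rate > 1) {
    eh_stop("must lie in [0, 1]", field = "out_of_frame_rate")
  }
  class(spec) <- "cohort_spec"
  spec
}

# Environment-dependent rendering parameters. "home" recordings carry more
# camera motion and sensor noise than the controlled "homelab" setting.
env_params <- function(env) {
  if (env == "home") {
    list(cam_step_sd = 1.2, cam_max = 8L, noise_sd = 0.030)
  } else {
    list(cam_step_sd = 0.3, cam_max = 2L, noise_sd = 0.008)
  }
}

#' Sample participant profiles for a cohort
#'
#' Draws one profile per participant: the side of the more-affected hand
#' (fair coin), an impairment severity in \[0, 1\] (Beta(2, 2)), and the
#' probability that the more-affected hand is rendered closed while not
#' interacting. The closed-hand probability increases linearly with
#' severity (`0.1 + 0.8 * severity`), reproducing the confound that closed
#' fists are common at rest after stroke and become more so with impairment.
#'
#' @param spec a [cohort_spec()].
#' @return a data frame with columns `participant_id`, `affected_side`,
#'   `severity`, `closed_hand_prob`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, "profiles"), {
    n <- spec$n_participants
    severity <- stats::rbeta(n, 2, 2)
    data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      affected_side = ifelse(stats::runif(n) < 0.5, "left", "right"),
      severity = severity,
      closed_hand_prob = 0.1 + 0.8 * severity,
      # per-participant skin-tone jitter around a fixed HSV band
      skin_h = clamp(stats::rnorm(n, 0.07, 0.012), 0.02, 0.12),
      skin_s = clamp(stats::rnorm(n, 0.45, 0.05), 0.25, 0.65),
      skin_v = clamp(stats::rnorm(n, 0.85, 0.04), 0.6, 0.97),
      stringsAsFactors = FALSE
    )
  })
}

# Task-kind schedule for one participant: always one negative task, and
# bimanual/unimanual tasks filling the rest (bimanual-weighted so that both
# the role classifier and high interaction priors are servable).
task_schedule <- function(tasks_per_participant) {
  extra <- tasks_per_participant - 1L
  n_bi <- ceiling(extra * 2 / 3)
  n_uni <- extra - n_bi
  c("negative", rep("bimanual", n_bi), rep("unimanual", n_uni))
}

# Episode fraction needed inside interaction tasks so that the realized
# interaction fraction over non-negative tasks matches the prior.
episode_fraction <- function(spec) {
  sched <- task_schedule(spec$tasks_per_participant)
  n_bi <- sum(sched == "bimanual")
  n_uni <- sum(sched == "unimanual")
  e <- spec$interaction_prior * 2 * (n_bi + n_uni) / (2 * n_bi + n_uni)
  clamp(e, 0.05, 0.95)
}

other_side <- function(side) ifelse(side == "left", "right", "left")

#' Script one synthetic task
#'
#' Lays out, frame by frame, the state of both hands (centre, ellipse axes,
#' aperture, presence), the manipulated object, per-hand contact and role
#' flags, and the camera offset. The script is pure geometry in scene
#' coordinates; [render_frames()] turns it into pixels.
#'
#' Task kinds:
#' \describe{
#'   \item{negative}{both hands present and swaying, no contact anywhere.}
#'   \item{unimanual}{the less-affected hand manipulates the object during a
#'     contiguous episode; the idle hand may leave the frame for a scripted
#'     span.}
#'   \item{bimanual}{both hands contact the object during the episode; one
#'     designated hand manipulates (sliding along the object with a pulsing
#'     aperture, so its contact area changes every frame) for sub-spans and
#'     stabilizes otherwise; the other hand stabilizes throughout (static
#'     contact, constant contact area).}
#' }
#' During non-contact frames the more-affected hand is closed with the
#' profile's `closed_hand_prob` (independently per frame).
#'
#' @param profile one row of [sample_cohort()].
#' @param task_kind `"unimanual"`, `"bimanual"` or `"negative"`.
#' @param n_frames number of frames (>= 11).
#' @param spec the [cohort_spec()] (frame geometry, env, priors).
#' @param manipulator which hand manipulates in a bimanual task
#'   (`"more_affected"` or `"less_affected"`).
#' @return a `scene_script` object.
#' @export
script_task <- function(profile, task_kind, n_frames, spec,
                        manipulator = "less_affected") {
  task_kind <- match.arg(task_kind, c("unimanual", "bimanual", "negative"))
  if (n_frames < 11L) eh_stop("must be >= 11", field = "n_frames")
  W <- spec$frame_width; H <- spec$frame_height
  ep <- env_params(spec$env)
  scale <- W / 320

  hand_ax <- 17 * scale; hand_ay <- 12 * scale
  obj_w <- 46 * scale; obj_h <- 30 * scale
  # object centred in the lower middle of the scene
  ocx <- W * 0.5; ocy <- H * 0.62
  obj <- c(ocx - obj_w / 2, ocy - obj_h / 2, ocx + obj_w / 2, ocy + obj_h / 2)

  affected <- profile$affected_side
  less_aff <- other_side(affected)

  t <- seq_len(n_frames)
  hands <- list()
  for (side in c("left", "right")) {
    home_x <- if (side == "left") W * 0.22 else W * 0.78
    home_y <- H * 0.55
    sway_ph <- stats::runif(1, 0, 2 * pi)
    hands[[side]] <- data.frame(
      frame = t - 1L,
      cx = home_x + 3 * scale * sin(2 * pi * t / 90 + sway_ph),
      cy = home_y + 2 * scale * cos(2 * pi * t / 70 + sway_ph),
      ax = hand_ax, ay = hand_ay,
      aperture = 1, present = TRUE,
      contact = FALSE, role = "none",
      stringsAsFactors = FALSE
    )
  }

  e <- episode_fraction(spec)
  ep_len <- max(11L, round(e * n_frames))
  ep_start <- if (ep_len >= n_frames - 4L) 1L else
    sample.int(n_frames - ep_len - 3L, 1L) + 2L
  episode <- seq(ep_start, ep_start + ep_len - 1L)

  contact_depth <- hand_ax * 0.55  # how far the hand centre sits past the object edge

  if (task_kind == "unimanual") {
    act <- less_aff
    # active hand grips the object's near edge and drags it back and forth at
    # a constant ~0.8 px/frame (triangular wave): a dynamic interaction in
    # which the object moves with the hand on every frame
    drift <- (abs(((seq_along(episode) * 0.8) %% 24) - 12) - 6) * scale
    side_sign <- if (act == "left") -1 else 1
    gx <- if (act == "left") obj[1L] else obj[3L]
    hands[[act]]$cx[episode] <- gx - side_sign * (hand_ax - contact_depth) + drift
    hands[[act]]$cy[episode] <- ocy
    hands[[act]]$contact[episode] <- TRUE
    hands[[act]]$role[episode] <- "manipulation"
    obj_dx <- numeric(n_frames); obj_dx[episode] <- drift
    # idle hand occasionally leaves the frame for a contiguous span
    if (stats::runif(1) < spec$out_of_frame_rate) {
      span_len <- max(10L, round(n_frames * 0.2))
      s0 <- sample.int(n_frames - span_len, 1L)
      hands[[other_side(act)]]$present[seq(s0, s0 + span_len - 1L)] <- FALSE
    }
  } else if (task_kind == "bimanual") {
    man <- if (manipulator == "more_affected") affected else less_aff
    stab <- other_side(man)
    man_sign <- if (man == "left") -1 else 1
    stab_sign <- -man_sign
    # stabilizer: static grip on its side of the object, constant overlap
    sx <- if (stab == "left") obj[1L] else obj[3L]
    hands[[stab]]$cx[episode] <- sx - stab_sign * (hand_ax - contact_depth)
    hands[[stab]]$cy[episode] <- ocy
    hands[[stab]]$contact[episode] <- TRUE
    hands[[stab]]$role[episode] <- "stabilization"
    # manipulator: grips the opposite edge; during manipulation sub-spans the
    # penetration depth ramps at ~1 px/frame (triangular wave) and the
    # aperture pulses, so the contact area changes frame to frame
    mx_edge <- if (man == "left") obj[1L] else obj[3L]
    base_pen <- contact_depth
    n_ep <- length(episode)
    manip_frac <- clamp(2 * spec$manipulation_prior, 0.05, 0.95)
    n_man <- max(1L, round(manip_frac * n_ep))
    m0 <- if (n_man >= n_ep) 1L else sample.int(n_ep - n_man, 1L)
    man_idx <- seq(m0, m0 + n_man - 1L)           # indices within the episode
    pen <- rep(base_pen, n_ep)
    tri <- abs(((seq_len(n_man) %/% 1L) %% 14L) - 7L) - 3.5   # +-3.5 px, 1 px/frame
    pen[man_idx] <- base_pen + tri * scale
    hands[[man]]$cx[episode] <- mx_edge - man_sign * (hand_ax - pen)
    hands[[man]]$cy[episode] <- ocy
    hands[[man]]$contact[episode] <- TRUE
    hands[[man]]$role[episode] <- "stabilization"
    hands[[man]]$role[episode[man_idx]] <- "manipulation"
    ap <- rep(1, n_ep)
    ap[man_idx] <- 0.8 + 0.2 * sin(2 * pi * seq_len(n_man) / 10)
    hands[[man]]$aperture[episode] <- ap
    obj_dx <- numeric(n_frames)
  } else {
    obj_dx <- numeric(n_frames)
  }

  # closed-hand confound on the more-affected side during non-contact frames
  closed <- stats::runif(n_frames) < profile$closed_hand_prob
  idx <- !hands[[affected]]$contact & closed
  hands[[affected]]$aperture[idx] <- 0.15

  # camera motion: clipped integer random walk
  steps_x <- round(stats::rnorm(n_frames, 0, ep$cam_step_sd))
  steps_y <- round(stats::rnorm(n_frames, 0, ep$cam_step_sd))
  cam_x <- clamp(cumsum(steps_x), -ep$cam_max, ep$cam_max)
  cam_y <- clamp(cumsum(steps_y), -ep$cam_max, ep$cam_max)

  script <- structure(list(
    task_kind = task_kind,
    n_frames = as.integer(n_frames),
    participant_id = profile$participant_id,
    hands = hands,
    object = list(bbox = obj, dx = obj_dx),
    camera = data.frame(frame = t - 1L, dx = as.integer(cam_x), dy = as.integer(cam_y)),
    frame_width = W, frame_height = H
  ), class = "scene_script")
  validate_script(script)
  script
}

# Continuous-geometry contact area between a hand ellipse and the object
# rectangle, on a fine subgrid (used for script validation, not rendering).
script_contact_area <- function(script, side, i) {
  h <- script$hands[[side]][i, ]
  ob <- script$object$bbox + c(script$object$dx[i], 0, script$object$dx[i], 0)
  ax <- h$ax * (0.75 + 0.25 * h$aperture)
  ay <- h$ay * (0.5 + 0.5 * h$aperture)
  xs <- seq(h$cx - ax, h$cx + ax, by = 0.5)
  ys <- seq(h$cy - ay, h$cy + ay, by = 0.5)
  inside <- outer(ys, xs, function(y, x) {
    ((x - h$cx) / ax)^2 + ((y - h$cy) / ay)^2 <= 1 &
      x >= ob[1L] & x < ob[3L] & y >= ob[2L] & y < ob[4L]
  })
  sum(inside) * 0.25
}

validate_script <- function(script) {
  for (side in c("left", "right")) {
    h <- script$hands[[side]]
    if (any(h$role != "none" & !h$contact)) {
      eh_stop("role flags present on non-contact frames", field = "script")
    }
    if (script$task_kind == "negative" && any(h$contact)) {
      eh_stop("negative task contains contact frames", field = "script")
    }
  }
  invisible(script)
}
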