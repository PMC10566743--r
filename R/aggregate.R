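# Fusion of multiple predictions per hand into final per-frame decisions,
# and mapping of external contact categories to interaction labels.

#' Fuse duplicate predictions for one hand in one frame
#'
#' When a hand receives several predictions (e.g. two right hands detected
#' in a frame), the final prediction is the average; an average >= 0.5 is a
#' positive decision (interaction, or manipulation for the role task). The
#' tie at exactly 0.5 is positive by that inclusive inequality.
#'
#' @param probs non-empty numeric vector of probabilities in \[0, 1\].
#' @return integer 0/1 decision.
#' @export
fuse_duplicates <- function(probs) {
  if (length(probs) == 0L) {
    eh_stop("no predictions to fuse (apply the no-box rule upstream)",
            field = "probs")
  }
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    eh_stop("probabilities must lie in [0, 1]", field = "probs")
  }
  as.integer(mean(probs) >= 0.5)
}

#' Fuse overlapping-window predictions for one frame
#'
#' Windowed classifiers cover each frame with (typically two) overlapping
#' windows; if either window predicts an interaction the frame is an
#' interaction — a logical OR, equivalently `max()`.
#'
#' @param window_preds binary predictions of the windows covering a frame.
#' @return integer 0/1 decision.
#' @export
fuse_windows <- function(window_preds) {
  if (length(window_preds) == 0L) eh_stop("need >= 1 window prediction", field = "window_preds")
  if (!all(window_preds %in% c(0, 1))) {
    eh_stop("window predictions must be binary", field = "window_preds")
  }
  as.integer(any(window_preds == 1))
}

#' Half-overlapping window spans covering a task
#'
#' Windows of even length step by half their length (50% overlap), so every
#' frame is covered by at least one span and interior frames by exactly
#' two. When the task is shorter than one window, a single truncated span
#' is returned, flagged.
#'
#' @param n_frames number of frames in the task.
#' @param window_len window length in frames (even, >= 2); the study
#'   settings are 32 frames for interaction and 16 for hand role.
#' @param overlap fractional overlap; only 0.5 is supported.
#' @return data frame with 0-based half-open spans `start`, `end` and a
#'   `truncated` flag.
#' @export
windows_for_task <- function(n_frames, window_len, overlap = 0.5) {
  if (window_len < 2L || window_len %% 2L != 0L) {
    eh_stop("must be an even integer >= 2", field = "window_len")
  }
  if (overlap != 0.5) eh_stop("only 50% overlap is supported", field = "overlap")
  if (n_frames < window_len) {
    return(data.frame(start = 0L, end = as.integer(n_frames), truncated = TRUE))
  }
  step <- window_len %/% 2L
  starts <- seq.int(0L, n_frames - window_len, by = step)
  # a final truncated window (padded by repeating the last frame) covers any
  # remainder at the task end
  spans <- data.frame(start = starts, end = starts + window_len, truncated = FALSE)
  last_end <- spans$end[nrow(spans)]
  if (last_end < n_frames) {
    spans <- rbind(spans, data.frame(start = last_end - step,
                                     end = as.integer(n_frames), truncated = TRUE))
  }
  spans
}

#' Map an external contact category to a binary interaction label
#'
#' Contact-detection networks categorize each hand as one of self-contact,
#' no contact, other-person contact, portable-object contact or
#' non-portable-object contact. Only portable-object contact counts as a
#' hand-object interaction; every other category maps to no interaction.
#'
#' @param category character vector of contact categories.
#' @return integer 0/1 vector.
#' @export
map_contact <- function(category) {
  valid <- c("self_contact", "no_contact", "other_person_contact",
             "portable_object_contact", "nonportable_object_contact")
  bad <- setdiff(unique(category), valid)
  if (length(bad) > 0L) {
    eh_stop("unknown contact category: ", paste(bad, collapse = ", "),
            field = "category")
  }
  as.integer(category == "portable_object_contact")
}

#' Final per-frame, per-hand decisions for a set of instances
#'
#' Groups predicted probabilities by (participant, task, frame, hand),
#' applies the no-box rule (no bounding box: decision 0, forest not
#' consulted) and the duplicate-averaging rule, and records provenance.
#'
#' @param meta instance metadata (columns `participant_id`, `task_id`,
#'   `frame_index`, `hand_side`, optional `no_box`).
#' @param probs probabilities aligned with `meta` rows.
#' @return a data frame with one row per (participant, task, frame, hand):
#'   `decision`, `n_sources`, `rule`.
#' @export
decision_track <- function(meta, probs) {
  stopifnot(nrow(meta) == length(probs))
  nb <- isTRUE_vec(meta$no_box)
  key <- paste(meta$participant_id, meta$task_id, meta$frame_index,
               meta$hand_side, sep = "\r")
  first <- !duplicated(key)
  out <- meta[first, c("participant_id", "task_id", "frame_index", "hand_side")]
  ukey <- key[first]
  grp <- match(key, ukey)
  n_sources <- tabulate(grp, nbins = length(ukey))
  any_box <- as.logical(tapply(!nb, grp, any))
  mean_p <- as.numeric(tapply(ifelse(nb, NA_real_, probs), grp, mean, na.rm = TRUE))
  out$decision <- ifelse(any_box, as.integer(mean_p >= 0.5), 0L)
  out$n_sources <- n_sources
  out$rule <- ifelse(!any_box, "no_box",
                     ifelse(n_sources > 1L, "mean_threshold", "single"))
  rownames(out) <- NULL
  out
}
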