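# Synthetic cohort generator: determinism, label soundness, geometry.

test_that("cohort sampling is deterministic and validates its spec", {
  s <- cohort_spec(n_participants = 4, seed = 7)
  p1 <- sample_cohort(s)
  p2 <- sample_cohort(s)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4L)
  expect_true(all(p1$affected_side %in% c("left", "right")))
  expect_true(all(p1$severity >= 0 & p1$severity <= 1))
  # closed-hand probability rises with severity
  expect_true(all(diff(p1$closed_hand_prob[order(p1$severity)]) >= 0))

  expect_error(cohort_spec(n_participants = 1), "n_participants")
  expect_error(cohort_spec(n_participants = 4, frames_per_task = 10), "frames_per_task")
  expect_error(cohort_spec(n_participants = 4, interaction_prior = 1.2),
               "interaction_prior")
})

test_that("a study-sized cohort yields one profile per participant", {
  p <- sample_cohort(cohort_spec(n_participants = 21, seed = 3))
  expect_equal(nrow(p), 21L)
  expect_equal(anyDuplicated(p$participant_id), 0L)
})

test_that("task scripts satisfy contact/role soundness by kind", {
  spec <- tiny_spec()
  prof <- sample_cohort(spec)[1, ]
  set.seed(11)
  neg <- script_task(prof, "negative", 60, spec)
  for (side in c("left", "right")) {
    expect_false(any(neg$hands[[side]]$contact))
    expect_true(all(neg$hands[[side]]$role == "none"))
  }
  bi <- script_task(prof, "bimanual", 60, spec)
  roles <- c(bi$hands$left$role, bi$hands$right$role)
  contact <- c(bi$hands$left$contact, bi$hands$right$contact)
  expect_gte(sum(roles == "manipulation"), 1L)
  expect_gte(sum(roles == "stabilization"), 1L)
  expect_true(all(roles[!contact] == "none"))
})

test_that("manipulation changes the contact geometry; stabilization holds it", {
  spec <- tiny_spec()
  prof <- sample_cohort(spec)[1, ]
  set.seed(5)
  bi <- script_task(prof, "bimanual", 80, spec)
  for (side in c("left", "right")) {
    h <- bi$hands[[side]]
    man <- which(h$role == "manipulation")
    man <- man[man > 1 & h$role[man - 1] == "manipulation"]
    if (length(man) > 0) {
      deltas <- vapply(man, function(i) {
        abs(script_contact_area_(bi, side, i) - script_contact_area_(bi, side, i - 1))
      }, numeric(1))
      expect_gt(mean(deltas > 0.5), 0.9)
    }
    stab <- which(h$role == "stabilization")
    stab <- stab[stab > 1 & h$role[stab - 1] == "stabilization"]
    if (length(stab) > 0) {
      areas <- vapply(c(stab[1] - 1, stab), function(i) {
        script_contact_area_(bi, side, i)
      }, numeric(1))
      expect_lt(max(abs(diff(areas))), 2 + 1e-9)
    }
  }
})

test_that("a maximally impaired hand is closed in most non-contact frames", {
  spec <- cohort_spec(n_participants = 2, frames_per_task = 1000, seed = 9)
  prof <- sample_cohort(spec)[1, ]
  prof$severity <- 1.0
  prof$closed_hand_prob <- 0.1 + 0.8 * 1.0
  set.seed(21)
  sc <- script_task(prof, "negative", 1000, spec)
  h <- sc$hands[[prof$affected_side]]
  closed_frac <- mean(h$aperture[!h$contact] < 0.5)
  expect_gt(closed_frac, 0.5)
  # binomial tolerance around closed_hand_prob at n = 1000
  tol <- 4 * sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs(closed_frac - prof$closed_hand_prob), tol)
})

test_that("rendered masks are consistent with their bounding boxes", {
  task <- tiny_task()
  expect_gt(length(task$observations), 0L)
  for (ob in task$observations) {
    expect_gt(ob$area, 0L)
    expect_equal(dim(ob$mask), c(ob$bbox[4] - ob$bbox[2], ob$bbox[3] - ob$bbox[1]))
    # tightness: every box edge touches at least one mask pixel
    expect_true(any(ob$mask[1, ]))
    expect_true(any(ob$mask[nrow(ob$mask), ]))
    expect_true(any(ob$mask[, 1]))
    expect_true(any(ob$mask[, ncol(ob$mask)]))
  }
})

test_that("a static script renders identically up to sensor noise", {
  spec <- cohort_spec(n_participants = 2, tasks_per_participant = 3,
                      frames_per_task = 12, seed = 4, env = "homelab")
  prof <- sample_cohort(spec)[1, ]
  set.seed(2)
  sc <- script_task(prof, "negative", 12, spec)
  # freeze all motion
  sc$camera$dx[] <- 0L; sc$camera$dy[] <- 0L
  for (side in c("left", "right")) {
    for (col in c("cx", "cy", "aperture")) {
      sc$hands[[side]][[col]] <- rep(sc$hands[[side]][[col]][1], 12)
    }
  }
  set.seed(2)
  task <- render_frames(sc, spec, prof)
  f1 <- frame_to_double(task$frames[[1]])
  f2 <- frame_to_double(task$frames[[2]])
  expect_lt(mean(abs(f1 - f2)), 5 * env_params_("homelab")$noise_sd)
})

test_that("contact frames render hand-object overlap", {
  task <- tiny_task()
  labs <- task$labels
  contact <- labs[labs$interaction == 1 & labs$present, ]
  expect_gt(nrow(contact), 0L)
  sc <- tiny_cohort()$scripts[["P01/T02"]]
  some <- contact[sample.int(nrow(contact), min(10, nrow(contact))), ]
  for (k in seq_len(nrow(some))) {
    area <- script_contact_area_(sc, some$side[k], some$frame[k] + 1L)
    expect_gt(area, 0)
  }
})

test_that("generated datasets meet structural and prior contracts", {
  ds <- tiny_cohort()
  m <- ds$manifest
  expect_equal(nrow(m), 2 * 3)
  for (pid in unique(m$participant_id)) {
    kinds <- m$task_kind[m$participant_id == pid]
    expect_gte(sum(kinds == "negative"), 1L)
    expect_gte(sum(kinds == "bimanual"), 1L)
  }
  # label soundness
  for (key in names(ds$labels)) {
    lab <- ds$labels[[key]]
    expect_true(all(lab$role[lab$interaction == 0] == "none"))
    kind <- m$task_kind[paste(m$participant_id, m$task_id, sep = "/") == key]
    if (kind == "negative") expect_equal(sum(lab$interaction), 0L)
  }
  # realized fractions near priors
  expect_lt(abs(ds$realized$interaction_fraction - ds$spec$interaction_prior), 0.10)
  expect_lt(abs(ds$realized$manipulation_fraction - ds$spec$manipulation_prior), 0.10)
})

test_that("identical specs produce byte-identical manifests and labels", {
  d1 <- generate_cohort(tiny_spec(seed = 31))
  d2 <- generate_cohort(tiny_spec(seed = 31))
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$profiles, d2$profiles)
  t1 <- get_task(d1, "P01", "T02")
  t2 <- get_task(d2, "P01", "T02")
  expect_identical(t1$frames, t2$frames)
})

test_that("realized class fractions approach the priors as tasks lengthen", {
  short <- generate_cohort(cohort_spec(n_participants = 3, frames_per_task = 20,
                                       seed = 13, interaction_prior = 0.75))
  long <- generate_cohort(cohort_spec(n_participants = 3, frames_per_task = 400,
                                      seed = 13, interaction_prior = 0.75))
  err_short <- abs(short$realized$interaction_fraction - 0.75)
  err_long <- abs(long$realized$interaction_fraction - 0.75)
  expect_lte(err_long, err_short + 0.02)
  expect_lt(abs(long$realized$interaction_fraction - 0.75), 0.10)
})

test_that("homelab renders are cleaner than home renders", {
  mean_diff <- function(env) {
    spec <- cohort_spec(n_participants = 2, tasks_per_participant = 3,
                        frames_per_task = 50, seed = 17, env = env)
    ds <- generate_cohort(spec)
    tid <- ds$manifest$task_id[1]
    task <- get_task(ds, "P01", tid)
    d <- 0
    for (i in 1:49) {
      d <- d + mean(abs(frame_to_double(task$frames[[i + 1]]) -
                          frame_to_double(task$frames[[i]])))
    }
    d / 49
  }
  expect_lt(mean_diff("homelab"), mean_diff("home"))
})

test_that("dataset round-trips through the on-disk layout", {
  root <- withr::local_tempdir()
  spec <- cohort_spec(n_participants = 2, tasks_per_participant = 3,
                      frames_per_task = 12, seed = 23)
  ds <- generate_cohort(spec)
  generate_dataset(spec, root)
  expect_true(file.exists(file.path(root, "manifest.json")))
  # 6 task directories + manifest
  task_dirs <- list.dirs(root, recursive = FALSE)
  expect_equal(length(task_dirs), 2L)
  back <- read_dataset(root)
  expect_equal(nrow(back$manifest), nrow(ds$manifest))
  t_mem <- get_task(ds, "P01", "T02")
  t_disk <- get_task(back, "P01", "T02")
  expect_equal(length(t_disk$frames), length(t_mem$frames))
  expect_identical(frame_to_double(t_disk$frames[[3]]),
                   frame_to_double(t_mem$frames[[3]]))
  ob_m <- t_mem$observations[["0_left"]]; ob_d <- t_disk$observations[["0_left"]]
  expect_identical(is.null(ob_m), is.null(ob_d))
  if (!is.null(ob_m)) {
    expect_equal(ob_d$bbox, ob_m$bbox)
    expect_equal(ob_d$area, ob_m$area)
  }
  expect_equal(t_disk$labels$interaction, t_mem$labels$interaction)
})
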