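# Shared fixtures, built in code. Heavy objects are memoized per test run.

# internal helpers under test
script_contact_area_ <- egohand:::script_contact_area
env_params_ <- egohand:::env_params
confusion_add_ <- egohand:::confusion_add

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A tiny cohort with rendering kept cheap: 2 participants x 3 tasks x 40
# frames. Enough to exercise every pipeline stage.
tiny_spec <- function(seed = 7, ...) {
  cohort_spec(n_participants = 2, tasks_per_participant = 3,
              frames_per_task = 40, seed = seed, ...)
}

tiny_cohort <- function() memo("tiny_cohort", function() generate_cohort(tiny_spec()))

tiny_task <- function() memo("tiny_task", function() {
  get_task(tiny_cohort(), "P01", "T02")   # bimanual
})

tiny_features <- function() memo("tiny_features", function() {
  featurize_dataset(tiny_cohort())
})

# A flat synthetic frame: uniform colour everywhere.
uniform_frame <- function(h = 40, w = 60, rgb = c(0.4, 0.5, 0.6)) {
  fr <- array(0, c(h, w, 3L))
  for (ch in 1:3) fr[, , ch] <- rgb[ch]
  fr
}

# Frame with a rectangular patch of colour A on colour B.
two_colour_frame <- function(h, w, patch, rgb_a, rgb_b) {
  fr <- uniform_frame(h, w, rgb_b)
  rows <- (patch[2] + 1):patch[4]; cols <- (patch[1] + 1):patch[3]
  for (ch in 1:3) fr[rows, cols, ch] <- rgb_a[ch]
  fr
}

# Separable two-cluster instance set for classifier tests.
cluster_instances <- function(n_per_class = 200, p = 12, sep = 6, seed = 42,
                              target = "interaction") {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * p), n_per_class, p),
             matrix(stats::rnorm(n_per_class * p, mean = sep), n_per_class, p))
  label <- rep(c(0L, 1L), each = n_per_class)
  n <- 2 * n_per_class
  meta <- data.frame(
    participant_id = rep(c("P01", "P02"), length.out = n),
    task_id = "T01", task_kind = "bimanual", env = "home",
    frame_index = seq_len(n) - 1L, hand_side = "left",
    interaction = label, role = ifelse(label == 1L, "manipulation", "stabilization"),
    no_box = FALSE, label = label, stringsAsFactors = FALSE
  )
  structure(list(meta = meta, X = X, target = target,
                 config_fingerprint = "test-clusters"),
            class = "eh_instances")
}

random_confusion <- function(max_count = 1e4) {
  cc <- sample.int(max_count, 4L)
  confusion_from_counts(cc[1], cc[2], cc[3], cc[4])
}

confusion_from_counts <- function(tp, fp, tn, fn) {
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn), class = "confusion_counts")
}

# Expand a 2x2 table into aligned binary vectors (oracle helper).
expand_table <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  dec <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  list(truth = truth, dec = dec)
}
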