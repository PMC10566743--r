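# Leave-one-subject-out cross-validation, confusion-matrix metrics, macro /
# micro averaging and hand-stratified reporting.

#' Construct leave-one-subject-out folds
#'
#' One fold per participant who has home-environment tasks. The testing set
#' is all home tasks of the held-out participant; the validation set is one
#' bimanual home task from each remaining participant (the feature-based
#' forest does not consume it, but the fold structure is shared across
#' model variants); the training set is every remaining task, restricted to
#' home tasks under `condition = "home_only"` and including homelab tasks
#' of the non-held-out participants under `condition = "both"`.
#'
#' @param manifest task table (`participant_id`, `task_id`, `task_kind`,
#'   `env`).
#' @param condition `"home_only"` or `"both"`.
#' @return list of folds: `held_out`, `test`, `validation`, `train`
#'   (character keys `"<participant>/<task>"`).
#' @export
losocv_folds <- function(manifest, condition = c("home_only", "both")) {
  condition <- match.arg(condition)
  m <- manifest
  m$key <- paste(m$participant_id, m$task_id, sep = "/")
  home_pids <- sort(unique(m$participant_id[m$env == "home"]))
  if (length(home_pids) < 2L) {
    eh_stop("need >= 2 participants with home tasks", field = "manifest")
  }
  lapply(home_pids, function(pid) {
    test <- m$key[m$participant_id == pid & m$env == "home"]
    others <- setdiff(home_pids, pid)
    validation <- character(0)
    for (op in others) {
      cand <- m$key[m$participant_id == op & m$env == "home" &
                      m$task_kind == "bimanual"]
      if (length(cand) == 0L) {
        eh_stop("participant ", op, " has no bimanual home task", field = "manifest")
      }
      validation <- c(validation, sort(cand)[1L])
    }
    pool <- m[m$participant_id != pid, , drop = FALSE]
    if (condition == "home_only") pool <- pool[pool$env == "home", , drop = FALSE]
    train <- setdiff(pool$key, validation)
    list(held_out = pid, condition = condition,
         test = test, validation = validation, train = train)
  })
}

#' Confusion counts for binary truth/decision vectors
#'
#' @param truth,decisions equal-length binary vectors.
#' @return a `confusion_counts` list: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, decisions) {
  if (length(truth) != length(decisions)) {
    eh_stop("truth and decisions differ in length", field = "decisions")
  }
  if (!all(truth %in% c(0, 1)) || !all(decisions %in% c(0, 1))) {
    eh_stop("entries must be binary", field = "truth")
  }
  structure(list(
    TP = sum(truth == 1 & decisions == 1),
    FP = sum(truth == 0 & decisions == 1),
    TN = sum(truth == 0 & decisions == 0),
    FN = sum(truth == 1 & decisions == 0)
  ), class = "confusion_counts")
}

confusion_add <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                 TN = a$TN + b$TN, FN = a$FN + b$FN),
            class = "confusion_counts")
}

confusion_zero <- function() {
  structure(list(TP = 0, FP = 0, TN = 0, FN = 0), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' whenever a factor of the denominator is 0.
#'
#' @param c a [confusion()] result.
#' @return value in \[-1, 1\].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Precision, recall, F1 and accuracy
#'
#' Undefined ratios (empty denominators) are reported as 0.
#'
#' @param c a [confusion()] result.
#' @return named vector `P`, `R`, `F`, `A`.
#' @export
prf_accuracy <- function(c) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  P <- safe(c$TP, c$TP + c$FP)
  R <- safe(c$TP, c$TP + c$FN)
  F1 <- safe(2 * P * R, P + R)
  A <- safe(c$TP + c$TN, c$TP + c$FP + c$TN + c$FN)
  c(P = P, R = R, F = F1, A = A)
}

#' Macro average across participants
#'
#' @param per_participant metric values, one per held-out participant.
#' @return list `mean`, `sd` (sample SD, `NA` for a single value).
#' @export
macro_average <- function(per_participant) {
  if (length(per_participant) == 0L) eh_stop("no values", field = "per_participant")
  list(mean = mean(per_participant), sd = stats::sd(per_participant))
}

#' Micro average: pool counts, then apply the metric formulas once
#'
#' @param per_participant_counts list of [confusion()] results.
#' @return named vector `M`, `F`, `P`, `R`, `A`.
#' @export
micro_average <- function(per_participant_counts) {
  if (length(per_participant_counts) == 0L) {
    eh_stop("no counts", field = "per_participant_counts")
  }
  total <- Reduce(confusion_add, per_participant_counts, confusion_zero())
  pr <- prf_accuracy(total)
  c(M = mcc(total), F = unname(pr["F"]), P = unname(pr["P"]),
    R = unname(pr["R"]), A = unname(pr["A"]))
}

#' Stratify decisions by hand impairment status
#'
#' Assigns each instance to the more- or less-affected stratum from the
#' participant profiles and accumulates confusion counts per stratum; the
#' overall counts are the element-wise sum of the two strata.
#'
#' @param decisions data frame with `participant_id`, `hand_side`,
#'   `decision`, `truth`.
#' @param profiles participant profiles (with `affected_side`).
#' @return list of [confusion()] counts: `more_affected`, `less_affected`,
#'   `overall`.
#' @export
stratify <- function(decisions, profiles) {
  aff <- profiles$affected_side[match(decisions$participant_id,
                                      profiles$participant_id)]
  if (anyNA(aff)) {
    eh_stop("participant without a profile: ",
            paste(unique(decisions$participant_id[is.na(aff)]), collapse = ", "),
            field = "decisions")
  }
  stratum <- ifelse(decisions$hand_side == aff, "more_affected", "less_affected")
  out <- list()
  for (s in c("more_affected", "less_affected")) {
    sel <- stratum == s
    out[[s]] <- confusion(decisions$truth[sel], decisions$decision[sel])
  }
  out$overall <- confusion_add(out$more_affected, out$less_affected)
  out
}

metrics_of <- function(counts) {
  pr <- prf_accuracy(counts)
  c(M = mcc(counts), F = unname(pr["F"]), P = unname(pr["P"]),
    R = unname(pr["R"]), A = unname(pr["A"]))
}

#' Run the full leave-one-subject-out experiment
#'
#' For each requested target and condition: build folds, fit the forest on
#' each fold's training tasks, predict the held-out participant's home
#' tasks, fuse duplicate predictions and apply the no-box rule, and report
#' macro (mean +/- SD across participants) and micro (pooled counts)
#' MCC / F1 / precision / recall / accuracy for the more-affected,
#' less-affected and overall strata.
#'
#' @param dataset an `eh_dataset` (or combined study dataset).
#' @param features optional precomputed `eh_features` for the dataset;
#'   extracted once here when missing.
#' @param targets subset of `c("interaction", "role")`.
#' @param conditions subset of `c("home_only", "both")`.
#' @param weight_ratio positive-class weight for the forest (the study's
#'   hand-role weighted loss uses 20).
#' @param n_trees forest size.
#' @param seed integer seed controlling all fold fits.
#' @param config a [feature_config()].
#' @param model_variant label recorded in the results rows.
#' @param verbose log per-fold instance counts and class fractions.
#' @return a results data frame, one row per (target, condition, stratum,
#'   average type), with columns `model_variant`, `condition`, `target`,
#'   `stratum`, `average_type`, `M`, `F`, `P`, `R`, `A`, `sd_M`..`sd_A`,
#'   `n_participants`, `n_instances`.
#' @export
run_experiment <- function(dataset, features = NULL,
                           targets = "interaction",
                           conditions = "home_only",
                           weight_ratio = 1, n_trees = 150L, seed = 1L,
                           config = feature_config(),
                           model_variant = if (weight_ratio == 1) "rf" else "rf_weighted",
                           verbose = FALSE) {
  if (is.null(features)) features <- featurize_dataset(dataset, config, verbose = verbose)
  fkey <- paste(features$meta$participant_id, features$meta$task_id, sep = "/")
  rows <- list()
  for (target in targets) {
    inst_all <- build_instances(features, target, config)
    ikey <- paste(inst_all$meta$participant_id, inst_all$meta$task_id, sep = "/")
    for (condition in conditions) {
      folds <- losocv_folds(dataset$manifest, condition)
      per_part <- list()
      for (fold in folds) {
        stopifnot(length(intersect(fold$test, fold$train)) == 0L,
                  length(intersect(fold$test, fold$validation)) == 0L,
                  !any(startsWith(fold$train, paste0(fold$held_out, "/"))),
                  !any(startsWith(fold$validation, paste0(fold$held_out, "/"))))
        tr_sel <- ikey %in% fold$train
        te_sel <- ikey %in% fold$test
        train <- structure(list(meta = inst_all$meta[tr_sel, , drop = FALSE],
                                X = inst_all$X[tr_sel, , drop = FALSE],
                                target = target,
                                config_fingerprint = inst_all$config_fingerprint),
                           class = "eh_instances")
        test <- structure(list(meta = inst_all$meta[te_sel, , drop = FALSE],
                               X = inst_all$X[te_sel, , drop = FALSE],
                               target = target,
                               config_fingerprint = inst_all$config_fingerprint),
                          class = "eh_instances")
        if (nrow(test$meta) == 0L) next
        if (verbose) {
          fit_rows <- !isTRUE_vec(train$meta$no_box)
          message(sprintf(
            "[%s/%s] fold %s: %d train instances (%.0f%% positive), %d test",
            target, condition, fold$held_out, sum(fit_rows),
            100 * mean(train$meta$label[fit_rows]), nrow(test$meta)))
        }
        model <- train_rf(train, n_trees = n_trees, weight_ratio = weight_ratio,
                          seed = derive_seed(seed, target, condition, fold$held_out))
        probs <- predict_proba(model, test)
        dec <- decision_track(test$meta, probs)
        tkey <- paste(test$meta$participant_id, test$meta$task_id,
                      test$meta$frame_index, test$meta$hand_side, sep = "\r")
        dkey <- paste(dec$participant_id, dec$task_id, dec$frame_index,
                      dec$hand_side, sep = "\r")
        dec$truth <- test$meta$label[match(dkey, tkey)]
        per_part[[fold$held_out]] <- stratify(dec, dataset$profiles)
      }
      for (stratum in c("more_affected", "less_affected", "overall")) {
        counts <- lapply(per_part, `[[`, stratum)
        sizes <- vapply(counts, function(c) c$TP + c$FP + c$TN + c$FN, numeric(1))
        counts_nz <- counts[sizes > 0]
        per_metrics <- vapply(counts_nz, metrics_of, numeric(5L))
        macro <- apply(per_metrics, 1L, function(v) unlist(macro_average(v)))
        micro <- micro_average(counts_nz)
        base <- data.frame(model_variant = model_variant, condition = condition,
                           target = target, stratum = stratum,
                           stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- cbind(
          base, average_type = "macro",
          as.data.frame(as.list(macro["mean", ])),
          stats::setNames(as.data.frame(as.list(macro["sd", ])),
                          paste0("sd_", c("M", "F", "P", "R", "A"))),
          n_participants = length(counts_nz), n_instances = sum(sizes))
        rows[[length(rows) + 1L]] <- cbind(
          base, average_type = "micro",
          as.data.frame(as.list(micro)),
          stats::setNames(as.data.frame(as.list(rep(NA_real_, 5L))),
                          paste0("sd_", c("M", "F", "P", "R", "A"))),
          n_participants = length(counts_nz), n_instances = sum(sizes))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write experiment results as CSV
#' @param results a [run_experiment()] result.
#' @param path output path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
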