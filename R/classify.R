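# Instance construction and random-forest classification for interaction
# detection and hand-role classification.

#' Build the instance set for a classification target
#'
#' An instance is one hand in one frame, treated as an independent sample;
#' a frame with two hands contributes two instances.
#'
#' \describe{
#'   \item{interaction}{all tasks, all labelled hands; label 1 = interaction.
#'     Frames where a hand has no bounding box are kept as rows flagged
#'     `no_box` (they are excluded from fitting and forced negative at
#'     prediction).}
#'   \item{role}{bimanual tasks only, interaction frames only; label 1 =
#'     manipulation, 0 = stabilization.}
#' }
#'
#' @param features an `eh_features` (from [featurize_dataset()]) or an
#'   `eh_dataset` (featurized on the fly).
#' @param target `"interaction"` or `"role"`.
#' @param config a [feature_config()] (used when `features` is a dataset,
#'   and to slice the variant's columns).
#' @return an `eh_instances`: list with `meta` (adds `label`), `X` (variant
#'   width), `target`, `config_fingerprint`.
#' @export
build_instances <- function(features, target = c("interaction", "role"),
                            config = feature_config()) {
  target <- match.arg(target)
  if (inherits(features, "eh_dataset")) {
    features <- featurize_dataset(features, config)
  }
  meta <- features$meta
  X <- features$X
  if (target == "interaction") {
    keep <- rep(TRUE, nrow(meta))
    label <- meta$interaction
    X <- X[, seq_len(feature_length(config, "interaction")), drop = FALSE]
  } else {
    keep <- meta$task_kind == "bimanual" & meta$interaction == 1L & !meta$no_box
    if (!any(keep)) {
      eh_stop("no bimanual interaction instances available for the role target",
              field = "target")
    }
    label <- as.integer(meta$role == "manipulation")
  }
  meta <- meta[keep, , drop = FALSE]
  meta$label <- label[keep]
  rownames(meta) <- NULL
  structure(list(meta = meta, X = X[keep, , drop = FALSE], target = target,
                 config_fingerprint = features$config_fingerprint),
            class = "eh_instances")
}

canonical_order <- function(meta) {
  order(meta$participant_id, meta$task_id, meta$frame_index, meta$hand_side)
}

#' Train the binary random forest
#'
#' A 150-tree binary forest (the `ranger` implementation with its default
#' depth, leaf-size and feature-subsampling settings, which are recorded in
#' the fingerprint by implication of the package version). The weighted
#' loss is realized as class weights: weight `weight_ratio` on the positive
#' (minority: interaction / manipulation) class, 1 on the other — for hand
#' roles the study setting is a ratio of 20. Rows flagged `no_box` are
#' excluded from fitting. Instances are sorted into a canonical
#' (participant, task, frame, hand) order before fitting, so training-row
#' order never affects the model.
#'
#' @param train an `eh_instances`.
#' @param n_trees number of trees.
#' @param weight_ratio positive-class weight (1 = unweighted).
#' @param seed integer seed; fits are deterministic given it.
#' @param num_threads forest threads (1 keeps results machine-stable).
#' @return an `eh_model`.
#' @export
train_rf <- function(train, n_trees = 150L, weight_ratio = 1, seed = 1L,
                     num_threads = 1L) {
  stopifnot(inherits(train, "eh_instances"))
  fit_rows <- !isTRUE_vec(train$meta$no_box)
  meta <- train$meta[fit_rows, , drop = FALSE]
  X <- train$X[fit_rows, , drop = FALSE]
  y <- meta$label
  if (length(unique(y)) < 2L) {
    missing_cls <- if (all(y == 1L)) "negative" else "positive"
    eh_stop("training set lacks the ", missing_cls, " class", field = "train")
  }
  ord <- canonical_order(meta)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  yf <- factor(ifelse(y == 1L, "pos", "neg"), levels = c("neg", "pos"))
  fit <- ranger::ranger(
    x = as.data.frame(X), y = yf,
    num.trees = n_trees, probability = TRUE,
    class.weights = c(neg = 1, pos = weight_ratio),
    seed = as.integer(seed), num.threads = num_threads,
    verbose = FALSE
  )
  structure(list(
    fit = fit, n_trees = n_trees, weight_ratio = weight_ratio,
    target = train$target, n_features = ncol(X),
    fingerprint = paste(train$config_fingerprint, train$target, ncol(X), sep = "|"),
    seed = as.integer(seed)
  ), class = "eh_model")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Positive-class probabilities for instances
#'
#' Returns the forest's probability of the positive class (interaction /
#' manipulation) for each row; rows flagged `no_box` (or a single
#' [no_box_marker()]) get probability 0 by rule, without consulting the
#' forest. Refuses feature matrices whose width does not match the model's
#' fingerprint.
#'
#' @param model an `eh_model`.
#' @param instances an `eh_instances`, a numeric matrix/vector of features,
#'   or a [no_box_marker()].
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, instances) {
  stopifnot(inherits(model, "eh_model"))
  if (is_no_box(instances)) return(0)
  if (inherits(instances, "eh_instances")) {
    fp <- paste(instances$config_fingerprint, instances$target,
                ncol(instances$X), sep = "|")
    if (!identical(fp, model$fingerprint)) {
      eh_stop("feature fingerprint mismatch: model ", model$fingerprint,
              " vs instances ", fp, field = "instances")
    }
    X <- instances$X
    nb <- isTRUE_vec(instances$meta$no_box)
  } else {
    X <- if (is.null(dim(instances))) matrix(instances, nrow = 1L) else instances
    nb <- rep(FALSE, nrow(X))
  }
  if (ncol(X) != model$n_features) {
    eh_stop("expected ", model$n_features, " features, got ", ncol(X),
            field = "instances")
  }
  probs <- numeric(nrow(X))
  if (any(!nb)) {
    Xp <- X[!nb, , drop = FALSE]
    colnames(Xp) <- sprintf("f%04d", seq_len(ncol(Xp)))
    pr <- stats::predict(model$fit, data = as.data.frame(Xp),
                         num.threads = 1L)$predictions
    probs[!nb] <- pr[, "pos"]
  }
  probs
}

#' Save / load a trained model artifact
#'
#' Single-file serialization with the embedded configuration fingerprint;
#' [predict_proba()] refuses instances whose fingerprint disagrees.
#'
#' @param model an `eh_model`.
#' @param path artifact path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "eh_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "eh_model")) eh_stop("not a model artifact", field = "path")
  model
}
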