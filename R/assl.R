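#' Configuration of the transfer-learning + ASSL loop
#'
#' Defaults encode the reference procedure: aim for at least 80 percent of
#' the whole dataset correctly segmented, split the labelled pool 90/10 into
#' training and validation, reset the model to the pretrained weights at each
#' round, and stop on target, round budget, or a plateau of the
#' correct-segmentation count.
#'
#' @param target_correct_fraction stop once the accepted fraction over the
#'   whole dataset reaches this value. Default 0.80.
#' @param max_rounds maximum number of ASSL rounds after round 0. Default 10.
#' @param plateau_patience stop after this many consecutive rounds without
#'   improvement of the accepted count. Default 2.
#' @param val_fraction fraction of the labelled pool held out for metric
#'   evaluation, in `(0, 0.5)`. Default 0.10.
#' @param seed base seed; round `r` uses `seed + r` for its training RNG.
#' @param thresholds a [validation_thresholds()] for the simulated oracle.
#' @param training a [training_config()].
#' @param binarize_threshold probability threshold for mask prediction.
#'   `NULL` (the default) uses the loss-matched neutral threshold
#'   [focal_neutral_threshold()] of the configured focal loss (about 0.40 for
#'   the default alpha 0.25, gamma 2), which corrects the systematic
#'   under-segmentation a flat 0.5 causes under an asymmetric loss.
#' @return A list of class `assl_config`.
#' @export
assl_config <- function(target_correct_fraction = 0.80, max_rounds = 10,
                        plateau_patience = 2, val_fraction = 0.10,
                        seed = 1L, thresholds = validation_thresholds(),
                        training = training_config(),
                        binarize_threshold = NULL) {
  if (val_fraction <= 0 || val_fraction >= 0.5)
    abort_wa("val_fraction must be in (0, 0.5)")
  if (target_correct_fraction <= 0 || target_correct_fraction > 1)
    abort_wa("target_correct_fraction must be in (0, 1]")
  if (!inherits(thresholds, "validation_thresholds"))
    abort_wa("thresholds must be created with validation_thresholds()")
  if (!inherits(training, "training_config"))
    abort_wa("training must be created with training_config()")
  if (is.null(binarize_threshold))
    binarize_threshold <- focal_neutral_threshold(training$loss)
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    abort_wa("binarize_threshold must be in (0, 1)")
  structure(list(
    target_correct_fraction = target_correct_fraction,
    max_rounds = as.integer(max_rounds),
    plateau_patience = as.integer(plateau_patience),
    val_fraction = val_fraction,
    seed = as.integer(seed),
    thresholds = thresholds,
    training = training,
    binarize_threshold = binarize_threshold
  ), class = "assl_config")
}

dataset_ids <- function(dataset)
  vapply(dataset$samples, `[[`, "", "sample_id")

sample_by_id <- function(dataset, ids) {
  all_ids <- dataset_ids(dataset)
  dataset$samples[match(ids, all_ids)]
}

default_oracle <- function(thresholds) {
  function(pred, sample) oracle_validate(pred, sample$truth_mask, thresholds)
}

# resolve an accept/discard decision to a validation_result
resolve_decision <- function(pred, sample, oracle, decisions) {
  if (!is.null(decisions)) {
    row <- decisions[decisions$sample_id == sample$sample_id, , drop = FALSE]
    if (nrow(row) == 0)
      abort_wa("missing human decision for sample: ", sample$sample_id)
    acc <- isTRUE(as.logical(row$accepted[1]))
    return(structure(list(covers_wound = acc, only_wound = acc,
                          boundary_ok = acc, accepted = acc),
                     class = "validation_result"))
  }
  res <- oracle(pred, sample)
  if (is.logical(res))
    res <- structure(list(covers_wound = res, only_wound = res,
                          boundary_ok = res, accepted = res),
                     class = "validation_result")
  res
}

make_pool <- function(labeled, unlabeled, total) {
  if (length(intersect(labeled, unlabeled)) > 0)
    abort_wa("labeled and unlabeled pools overlap")
  if (length(labeled) + length(unlabeled) != total)
    abort_wa("pool does not partition the dataset")
  list(labeled = labeled, unlabeled = unlabeled, total = total)
}

#' Round 0: bootstrap the labelled pool with the pretrained model
#'
#' The pretrained (source-domain) model predicts a mask for every image in the
#' dataset without any fine-tuning; every accepted prediction enters the
#' labelled pool with its predicted mask as its label. This substitutes the
#' manual annotation of the initial round. If nothing is accepted, a warning
#' is emitted and an empty-pool state is returned (the loop cannot start).
#'
#' @param pretrained a `wound_model`.
#' @param dataset a `wound_dataset`.
#' @param cfg an [assl_config()].
#' @param oracle optional decision function `function(pred_mask, sample)`
#'   returning a `validation_result` or a logical; defaults to the simulated
#'   oracle against each sample's ground-truth mask.
#' @param decisions optional data frame of recorded human decisions with
#'   columns `sample_id`, `accepted` (used instead of `oracle`).
#' @return A list with `pool`, `round` (the round-0 `round_state`) and
#'   `labels` (named list of accepted masks).
#' @export
bootstrap_round0 <- function(pretrained, dataset, cfg = assl_config(),
                             oracle = NULL, decisions = NULL) {
  if (length(dataset$samples) == 0) abort_wa("dataset is empty")
  if (is.null(oracle)) oracle <- default_oracle(cfg$thresholds)
  ids <- dataset_ids(dataset)
  preds <- predict_masks(pretrained, dataset$samples, cfg$binarize_threshold)
  accepted <- logical(length(ids))
  labels <- list()
  for (i in seq_along(ids)) {
    res <- resolve_decision(preds[[i]], dataset$samples[[i]], oracle, decisions)
    accepted[i] <- res$accepted
    if (res$accepted) labels[[ids[i]]] <- preds[[i]]
  }
  if (!any(accepted))
    warning("round 0 accepted no masks; ASSL cannot start from this pretrained model")
  pool <- make_pool(ids[accepted], ids[!accepted], length(ids))
  round <- structure(list(
    round_index = 0L,
    n_train = 0L, n_val = 0L,
    n_correct = sum(accepted),
    f1 = NA_real_, iou = NA_real_,
    pool = pool,
    train_ids = character(0), val_ids = character(0),
    start_fingerprint = weight_fingerprint(pretrained)
  ), class = "round_state")
  list(pool = pool, round = round, labels = labels)
}

#' Split a labelled pool into training and validation sets
#'
#' Disjoint, exhaustive split with `n_val = max(1, round(val_fraction * n))`,
#' deterministic given the seed. In the ASSL loop the validation set is drawn
#' once (at the first trained round) and held fixed afterwards; newly accepted
#' samples enter training only.
#'
#' @param labeled_ids character vector of labelled sample ids (at least 2).
#' @param val_fraction validation fraction. Default 0.10.
#' @param seed integer seed.
#' @param val_count optional explicit validation count overriding the
#'   fraction rule.
#' @return A list with `train` and `val` id vectors.
#' @export
split_pool <- function(labeled_ids, val_fraction = 0.10, seed = 1L,
                       val_count = NULL) {
  n <- length(labeled_ids)
  if (n < 2) abort_wa("need at least 2 labelled samples to split")
  n_val <- if (!is.null(val_count)) as.integer(val_count)
           else max(1L, as.integer(round(val_fraction * n)))
  if (n_val >= n) abort_wa("validation set would swallow the whole pool")
  val <- withr::with_seed(seed, sample(labeled_ids, n_val))
  list(train = setdiff(labeled_ids, val), val = val)
}

#' Run one ASSL round
#'
#' Resets the model to the pretrained weights, trains on the current training
#' split (pseudo-labels), evaluates F1/IoU on the frozen validation split,
#' predicts masks for the whole dataset, validates every prediction, and
#' promotes newly accepted unlabeled samples into the labelled pool with their
#' predicted masks as labels.
#'
#' @param pool pool state from the previous round.
#' @param pretrained the fixed pretrained `wound_model` (restored at the start
#'   of every round).
#' @param dataset a `wound_dataset`.
#' @param cfg an [assl_config()].
#' @param labels named list of current pseudo-label masks for labelled ids.
#' @param round_index 1-based round number.
#' @param val_ids frozen validation ids, or `NULL` at the first trained round
#'   (the split is then drawn and returned for reuse).
#' @param oracle,decisions see [bootstrap_round0()].
#' @return A list with `pool`, `round` (a `round_state`), `model` (trained),
#'   `labels`, `val_ids`.
#' @export
run_round <- function(pool, pretrained, dataset, cfg, labels,
                      round_index = 1L, val_ids = NULL,
                      oracle = NULL, decisions = NULL) {
  if (length(pool$labeled) == 0) abort_wa("labelled pool is empty")
  if (is.null(oracle)) oracle <- default_oracle(cfg$thresholds)
  ids <- dataset_ids(dataset)
  round_seed <- cfg$seed + as.integer(round_index)

  if (is.null(val_ids)) {
    sp <- split_pool(pool$labeled, cfg$val_fraction, seed = round_seed)
    val_ids <- sp$val
  }
  train_ids <- setdiff(pool$labeled, val_ids)

  model <- reset_weights(pretrained, pretrained)
  start_fp <- weight_fingerprint(model)

  tr_cfg <- cfg$training
  tr_cfg$seed <- round_seed
  fit <- train_model(model,
                     images = sample_by_id(dataset, train_ids),
                     masks = labels[train_ids],
                     val_images = sample_by_id(dataset, val_ids),
                     val_masks = labels[val_ids],
                     cfg = tr_cfg)
  model <- fit$model

  val_preds <- predict_masks(model, sample_by_id(dataset, val_ids),
                             cfg$binarize_threshold)
  rep <- evaluate_masks(val_preds, labels[val_ids])

  preds <- predict_masks(model, dataset$samples, cfg$binarize_threshold)
  accepted <- logical(length(ids))
  for (i in seq_along(ids)) {
    res <- resolve_decision(preds[[i]], dataset$samples[[i]], oracle, decisions)
    accepted[i] <- res$accepted
  }
  newly <- setdiff(ids[accepted], pool$labeled)
  for (id in newly) labels[[id]] <- preds[[match(id, ids)]]
  labeled <- union(pool$labeled, newly)
  new_pool <- make_pool(labeled, setdiff(ids, labeled), pool$total)

  round <- structure(list(
    round_index = as.integer(round_index),
    n_train = length(train_ids), n_val = length(val_ids),
    n_correct = sum(accepted),
    f1 = rep$f1, iou = rep$iou,
    pool = new_pool,
    train_ids = train_ids, val_ids = val_ids,
    start_fingerprint = start_fp
  ), class = "round_state")
  list(pool = new_pool, round = round, model = model, labels = labels,
       val_ids = val_ids)
}

#' Run the full transfer-learning + ASSL loop
#'
#' Bootstraps the labelled pool with the pretrained model (round 0), then
#' iterates rounds of reset-train-predict-validate-grow until the accepted
#' fraction over the whole dataset reaches the target, the round budget is
#' exhausted, or the accepted count plateaus.
#'
#' @inheritParams bootstrap_round0
#' @return A list of class `assl_run` with `history` (list of `round_state`),
#'   `model` (last trained model, or the pretrained one if no round ran),
#'   `config`, and `labels`.
#' @export
run_assl <- function(dataset, pretrained, cfg = assl_config(),
                     oracle = NULL, decisions = NULL) {
  boot <- bootstrap_round0(pretrained, dataset, cfg, oracle, decisions)
  history <- list(boot$round)
  pool <- boot$pool
  labels <- boot$labels
  model <- pretrained
  total <- pool$total
  if (length(pool$labeled) < 2) {
    return(structure(list(history = history, model = model, config = cfg,
                          labels = labels, status = "empty-round0"),
                     class = "assl_run"))
  }
  status <- "max-rounds"
  val_ids <- NULL
  best <- boot$round$n_correct
  stall <- 0L
  if (best / total >= cfg$target_correct_fraction) {
    status <- "target-reached"
  } else {
    for (r in seq_len(cfg$max_rounds)) {
      res <- run_round(pool, pretrained, dataset, cfg, labels,
                       round_index = r, val_ids = val_ids,
                       oracle = oracle, decisions = decisions)
      pool <- res$pool; labels <- res$labels
      model <- res$model; val_ids <- res$val_ids
      history[[length(history) + 1]] <- res$round
      if (res$round$n_correct / total >= cfg$target_correct_fraction) {
        status <- "target-reached"
        break
      }
      if (res$round$n_correct > best) {
        best <- res$round$n_correct
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$plateau_patience) {
          status <- "plateau"
          break
        }
      }
    }
  }
  structure(list(history = history, model = model, config = cfg,
                 labels = labels, status = status),
            class = "assl_run")
}

#' Per-round accounting table
#'
#' One row per round: sizes of the training and validation splits (with
#' percentages of the labelled pool), number of accepted segmentations over
#' the whole dataset (with percentage of the total), and the validation F1
#' and IoU scores.
#'
#' @param history an `assl_run` or a list of `round_state`s.
#' @return A data frame.
#' @export
round_report <- function(history) {
  if (inherits(history, "assl_run")) history <- history$history
  if (length(history) == 0) abort_wa("empty round history")
  rows <- lapply(history, function(r) {
    n_lab <- r$n_train + r$n_val
    data.frame(
      round = r$round_index,
      n_train = r$n_train,
      pct_train = if (n_lab > 0) 100 * r$n_train / n_lab else NA_real_,
      n_val = r$n_val,
      pct_val = if (n_lab > 0) 100 * r$n_val / n_lab else NA_real_,
      n_correct = r$n_correct,
      pct_correct = 100 * r$n_correct / r$pool$total,
      f1 = r$f1,
      iou = r$iou
    )
  })
  do.call(rbind, rows)
}

#' @export
print.assl_run <- function(x, ...) {
  cat("ASSL run:", length(x$history), "round state(s), status:", x$status, "\n")
  print(round_report(x), row.names = FALSE, digits = 4)
  invisible(x)
}
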