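# shared mini fixtures for the round manager: 32x32 images and a small
# backbone keep a full multi-round run under a minute
assl_spec <- backbone_spec("tiny", input_size = 32)

mini_pretrained <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- pretrain_base_model(assl_spec, n_images = 30, epochs = 25,
                                    data_seed = 777, seed = 99)
    cache
  }
})

mini_target <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_config(30, image_size = 32, seed = 42))
    cache
  }
})

mini_cfg <- function(...) {
  assl_config(training = training_config(epochs = 8, learning_rate = 1e-3,
                                         seed = 5),
              seed = 5, ...)
}

test_that("split_pool follows the 90/10 rule and is deterministic", {
  ids <- sprintf("s%03d", 1:100)
  sp <- split_pool(ids, 0.1, seed = 3)
  expect_length(sp$train, 90)
  expect_length(sp$val, 10)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  # 143 labelled -> 129/14 under the stated rule
  ids143 <- sprintf("s%03d", 1:143)
  sp143 <- split_pool(ids143, 0.1, seed = 3)
  expect_length(sp143$val, 14)
  expect_length(sp143$train, 129)
  # an explicit validation count can override the fraction rule
  sp16 <- split_pool(ids143, 0.1, seed = 3, val_count = 16)
  expect_length(sp16$val, 16)
  expect_identical(split_pool(ids, 0.1, seed = 3), sp)
  expect_false(identical(split_pool(ids, 0.1, seed = 4)$val, sp$val))
  expect_error(split_pool("one"), "at least 2")
})

test_that("bootstrap accepts what the oracle accepts and partitions the pool", {
  boot <- bootstrap_round0(mini_pretrained(), mini_target(), mini_cfg())
  pool <- boot$pool
  expect_length(intersect(pool$labeled, pool$unlabeled), 0)
  expect_equal(length(pool$labeled) + length(pool$unlabeled), 30)
  expect_equal(boot$round$round_index, 0L)
  expect_equal(boot$round$n_correct, length(pool$labeled))
  expect_setequal(names(boot$labels), pool$labeled)
  # partial initial acceptance: strictly between none and all
  expect_gt(length(pool$labeled), 0)
  expect_lt(length(pool$labeled), 30)
})

test_that("a model predicting empty masks yields a warned empty round 0", {
  broken <- mini_pretrained()
  nb <- length(broken$weights)
  broken$weights[[nb]][] <- -25  # head bias: probability ~0 everywhere
  expect_warning(boot <- bootstrap_round0(broken, mini_target(), mini_cfg()),
                 "no masks")
  expect_length(boot$pool$labeled, 0)
  run <- suppressWarnings(run_assl(mini_target(), broken, mini_cfg()))
  expect_length(run$history, 1)
  expect_equal(run$status, "empty-round0")
})

test_that("an accept-everything policy degenerates to plain self-training", {
  accept_all <- function(pred, sample) TRUE
  run <- run_assl(mini_target(), mini_pretrained(), mini_cfg(),
                  oracle = accept_all)
  expect_equal(run$status, "target-reached")
  expect_length(run$history, 1)  # everything accepted at round 0
  expect_equal(run$history[[1]]$n_correct, 30)
  expect_length(run$history[[1]]$pool$labeled, 30)
  # whereas the real oracle gates pool growth
  gated <- bootstrap_round0(mini_pretrained(), mini_target(), mini_cfg())
  expect_lt(length(gated$pool$labeled), 30)
})

test_that("recorded human decisions replace the oracle and must be complete", {
  ds <- mini_target()
  ids <- vapply(ds$samples, `[[`, "", "sample_id")
  dec <- data.frame(sample_id = ids, accepted = rep(c(TRUE, FALSE), 15))
  boot <- bootstrap_round0(mini_pretrained(), ds, mini_cfg(), decisions = dec)
  expect_setequal(boot$pool$labeled, ids[dec$accepted])
  expect_error(
    bootstrap_round0(mini_pretrained(), ds, mini_cfg(),
                     decisions = dec[1:10, ]),
    "missing human decision")
})

test_that("a seeded multi-round run obeys the structural invariants", {
  run <- run_assl(mini_target(), mini_pretrained(),
                  mini_cfg(max_rounds = 3, plateau_patience = 3))
  h <- run$history
  expect_gte(length(h), 2)
  pre_fp <- weight_fingerprint(mini_pretrained())
  for (r in seq_along(h)) {
    st <- h[[r]]
    # conservation
    expect_equal(length(st$pool$labeled) + length(st$pool$unlabeled),
                 st$pool$total)
    # round-start weights identical to the pretrained state
    expect_identical(st$start_fingerprint, pre_fp)
    if (r > 1) {
      prev <- h[[r - 1]]
      # labelled pool is monotone non-decreasing
      expect_true(all(prev$pool$labeled %in% st$pool$labeled))
      # split accounting
      expect_equal(st$n_train + st$n_val, length(prev$pool$labeled))
      # no leakage: validation ids never train, in any round
      for (other in h[-1])
        expect_length(intersect(st$val_ids, other$train_ids), 0)
      # the validation set is frozen after the first trained round
      if (r > 2) expect_setequal(st$val_ids, h[[2]]$val_ids)
      expect_true(st$f1 >= 0 && st$f1 <= 1)
      expect_true(st$iou >= 0 && st$iou <= 1)
    }
  }
})

test_that("seeded runs are exactly reproducible", {
  run1 <- run_assl(mini_target(), mini_pretrained(),
                   mini_cfg(max_rounds = 2, plateau_patience = 2))
  run2 <- run_assl(mini_target(), mini_pretrained(),
                   mini_cfg(max_rounds = 2, plateau_patience = 2))
  expect_identical(run1$history, run2$history)
  expect_identical(round_report(run1), round_report(run2))
})

test_that("round report mirrors the history and round-trips through JSON", {
  run <- run_assl(mini_target(), mini_pretrained(),
                  mini_cfg(max_rounds = 2, plateau_patience = 2))
  rep <- round_report(run)
  expect_equal(nrow(rep), length(run$history))
  expect_named(rep, c("round", "n_train", "pct_train", "n_val", "pct_val",
                      "n_correct", "pct_correct", "f1", "iou"))
  for (i in seq_len(nrow(rep))) {
    st <- run$history[[i]]
    expect_equal(rep$n_correct[i], st$n_correct)
    expect_equal(rep$pct_correct[i], 100 * st$n_correct / st$pool$total)
    if (st$n_train + st$n_val > 0)
      expect_equal(rep$pct_train[i], 100 * st$n_train / (st$n_train + st$n_val))
  }
  f <- withr::local_tempfile(fileext = ".json")
  write_history(run, f)
  back <- read_history(f)
  expect_equal(back, run$history, tolerance = 1e-12)
  expect_equal(round_report(back), rep, tolerance = 1e-12)
})

test_that("a five-round mock history renders a five-row table", {
  mock <- lapply(0:4, function(r) {
    structure(list(round_index = r, n_train = 90 + r, n_val = 10,
                   n_correct = 100 + 10 * r, f1 = 0.98, iou = 0.96,
                   pool = list(labeled = character(0),
                               unlabeled = character(0), total = 200),
                   train_ids = character(0), val_ids = character(0),
                   start_fingerprint = c(n = 1)), class = "round_state")
  })
  rep <- round_report(mock)
  expect_equal(nrow(rep), 5)
  expect_equal(rep$pct_correct, 100 * (100 + 10 * 0:4) / 200)
})

test_that("config constructor rejects invalid values", {
  expect_error(assl_config(val_fraction = 0.7), "val_fraction")
  expect_error(assl_config(target_correct_fraction = 0), "target")
  expect_error(assl_config(thresholds = list()), "thresholds")
})
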