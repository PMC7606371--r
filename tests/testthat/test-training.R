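# Threshold and bookkeeping rules are exercised with stub models whose CLF
# bias pins the output distribution: logits c(20, 0, 0) give p ~ (1, 0, 0)
# for any input (confident pass); c(0.5, 0, 0) gives max prob ~ 0.43
# (never confident).

test_that("training configuration validates its invariants", {
  cfg <- train_config()
  expect_equal(cfg$th_s, 0.9)
  expect_equal(cfg$th_v, 0.9)
  expect_equal(cfg$ssl_iters, 2L)
  expect_equal(cfg$st_iters, 2L)
  expect_equal(cfg$lr, 1e-5)
  expect_equal(cfg$decay, 5e-8)
  expect_error(train_config(th_s = 1.2), "th_s")
  expect_error(train_config(optimizer = "sgd"), "rmsprop")
})

test_that("pseudo-labeling selects exactly the confident slices", {
  confident <- stub_model(c(20, 0, 0))
  hesitant <- stub_model(c(0.5, 0, 0))
  labeled <- labeled_slices(rep("pass", 3))
  unlabeled <- labeled_slices(rep("questionable", 5))
  unlabeled$label <- NA_character_
  unlabeled$provenance <- NA_character_
  unlabeled$slice_id <- paste0("u", seq_len(5))

  # nothing clears the threshold -> pool unchanged
  r0 <- ssl_round(hesitant, labeled, unlabeled, th_s = 0.9)
  expect_equal(r0$counts$selected, 0L)
  expect_equal(nrow(r0$labeled), 3)

  # a confident model pseudo-labels everything as pass
  r1 <- ssl_round(confident, labeled, unlabeled, th_s = 0.9)
  expect_equal(r1$counts$selected, 5L)
  added <- dplyr::anti_join(r1$labeled, labeled, by = "slice_id")
  expect_true(all(added$label == "pass"))
  expect_true(all(added$provenance == "pseudo"))

  # selected count equals a brute-force recount over the probabilities
  expect_equal(r1$counts$selected,
               sum(apply(r1$probs, 1, max) > 0.9))
})

test_that("self-training keeps by agreement OR confidence, relabels, removes", {
  confident <- stub_model(c(20, 0, 0))    # predicts pass, p ~ 1
  hesitant <- stub_model(c(0.5, 0, 0))    # predicts pass, p ~ 0.43

  # condition 1: agreement at low confidence -> kept, label unchanged
  sl <- labeled_slices(c("pass", "fail"))
  r <- slice_self_train_round(hesitant, sl, th_s = 0.9)
  expect_equal(r$slices$label, c("pass", "fail"))
  expect_equal(r$slices$provenance, c("inherited", "removed"))
  expect_equal(r$counts$kept, 1L)
  expect_equal(r$counts$removed, 1L)

  # condition 2: disagreement at high confidence -> kept and relabeled
  sl2 <- labeled_slices(c("fail", "pass"))
  r2 <- slice_self_train_round(confident, sl2, th_s = 0.9)
  expect_equal(r2$slices$label, c("pass", "pass"))
  expect_equal(r2$slices$provenance, c("relabeled", "inherited"))
  expect_equal(r2$counts$relabeled, 1L)
  expect_equal(r2$counts$removed, 0L)

  # all removed -> degenerate-selection error
  sl3 <- labeled_slices(c("fail", "questionable"))
  expect_error(slice_self_train_round(hesitant, sl3, th_s = 0.9),
               "degenerate selection")
})

test_that("the OR keep-rule equals the union of two single-condition passes", {
  set.seed(10)
  sl <- labeled_slices(sample(quality_levels(), 12, replace = TRUE))
  m <- stub_model(c(2, 0.5, 0))  # moderately confident pass-ish model
  probs <- asNamespace("dmriqa")$predict_slice_probs(m, sl)
  r <- slice_self_train_round(m, sl, th_s = 0.6)

  pred <- quality_levels()[max.col(probs, ties.method = "last")]
  kept_agree <- pred == sl$label
  kept_conf <- apply(probs, 1, max) > 0.6
  expect_equal(r$slices$provenance != "removed", kept_agree | kept_conf)
  expect_equal(r$counts$kept, sum(kept_agree | kept_conf))
})

test_that("provenance transitions are exclusive and auditable", {
  sl <- labeled_slices(sample(quality_levels(), 10, replace = TRUE))
  m <- stub_model(c(3, 0, 0))
  r <- slice_self_train_round(m, sl, th_s = 0.5)
  # a record is never simultaneously removed and relabeled, and every
  # record has a defined provenance
  expect_true(all(r$slices$provenance %in% provenance_levels()))
  expect_equal(r$counts$kept + r$counts$removed, nrow(sl))
  # removed records are excluded from training batches
  kept <- asNamespace("dmriqa")$training_slices(r$slices)
  expect_true(all(kept$provenance != "removed"))
})

test_that("volume self-training applies the same rules at volume level", {
  spec <- tiny_spec(n_slices = 4L)
  sq <- stub_model(c(20, 0, 0), spec)
  vq <- vqa_net(spec, seed = 1)
  sl <- small_split()
  vols <- small_split()$volumes
  feats <- asNamespace("dmriqa")$extract_volume_features(
    sq, sl$slices, vols$volume_id)
  r <- volume_self_train_round(vq, vols, feats, th_v = 0.999999)
  # an untrained VQA-Net is never confident at that threshold, so volumes
  # survive only by agreement with their current label
  pred <- r$volumes$p_pass
  expect_true(all(r$volumes$provenance %in% provenance_levels()))
  expect_equal(r$counts$kept + r$counts$removed, nrow(vols))
})

test_that("pretraining aborts when a class is absent", {
  sl <- labeled_slices(rep("pass", 8))
  expect_error(pretrain_sqa(sl, toy_train_config(epochs = 1L)),
               "empty class")
})

test_that("a one-epoch fit runs end to end and is seed-deterministic", {
  sl <- labeled_slices(rep(quality_levels(), c(4, 3, 3)))
  cfg <- train_config(lr = 1e-3, epochs = 2L, batch_size = 4L,
                      augment = TRUE, seed = 5)
  spec <- tiny_spec()
  m1 <- pretrain_sqa(sl, cfg, model = sqa_net(spec, seed = 5))
  m2 <- pretrain_sqa(sl, cfg, model = sqa_net(spec, seed = 5))
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
  expect_equal(nrow(m1$history), 2)
})

test_that("semi-supervised fitting respects round counts and degenerates", {
  sl <- labeled_slices(rep(quality_levels(), c(4, 3, 3)))
  cfg <- train_config(lr = 1e-3, epochs = 1L, retrain_epochs = 1L,
                      batch_size = 4L, ssl_iters = 2L, augment = FALSE,
                      seed = 6)
  spec <- tiny_spec()

  # empty unlabeled pool -> identical to plain pretraining
  m0 <- pretrain_sqa(sl, cfg, model = sqa_net(spec, seed = 6))
  r <- semi_supervised_fit(sl, sl[0, ], cfg,
                           model = pretrain_sqa(sl, cfg,
                                                model = sqa_net(spec,
                                                                seed = 6)))
  expect_equal(r$model$params, m0$params, tolerance = 1e-12)
  expect_equal(nrow(r$history), 0)

  # with an unlabeled pool, exactly ssl_iters retraining rounds happen
  ul <- labeled_slices(rep("pass", 6))
  ul$label <- NA_character_; ul$provenance <- NA_character_
  ul$slice_id <- paste0("u", 1:6)
  r2 <- semi_supervised_fit(sl, ul, cfg, model = m0)
  expect_equal(nrow(r2$history), 2)
  rounds <- grep("^ssl_round", r2$model$history$stage, value = TRUE)
  expect_equal(length(unique(rounds)), 2)
})
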