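#' Build the three synthetic splits of the label-noise recovery study
#'
#' The study conditions: a small labeled pool with weak (volume-inherited)
#' slice labels and 20% volume-label flips, a larger unlabeled pool, and an
#' accurately annotated held-out test set — one, two, and one subject of
#' 12 volumes x 16 slices at 64 x 64.
#'
#' @param seed Integer seed; the three splits use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param flip_rate Volume label-flip rate in the labeled split
#'   (default 0.2).
#' @return Named list of [qa_split()]s: `labeled`, `unlabeled`, `test`.
#' @export
recovery_splits <- function(seed, flip_rate = 0.2) {
  list(
    labeled = generate_split(
      sim_config(n_subjects = 1, flip_rate = flip_rate,
                 weak_labeling = TRUE, seed = seed),
      name = "labeled_train"),
    unlabeled = generate_split(
      sim_config(n_subjects = 2, seed = seed + 1L),
      name = "unlabeled"),
    test = generate_split(
      sim_config(n_subjects = 1, seed = seed + 2L),
      name = "test")
  )
}

#' One replicate of the label-noise recovery study
#'
#' Trains (i) a pretraining-only baseline and (ii) the full pipeline on the
#' weakly/noisily labeled synthetic splits, and scores everything against
#' the simulator's ground truth:
#' * `acc_slice_pretrain` / `acc_slice_pipeline` — held-out slice-label
#'   accuracy of the baseline vs. the refined slice model;
#' * `acc_vol_pretrain` / `acc_vol_ssl` / `acc_vol_full` — held-out volume
#'   accuracy of VQA-Net trained on features from, respectively, the
#'   pretrained model, the model after semi-supervised learning (no
#'   self-training), and the fully refined pipeline (slice and volume
#'   self-training). Consecutive differences isolate the contribution of
#'   semi-supervised learning and of self-training;
#' * `weak_label_acc` / `cleaned_label_acc` — accuracy of the stored
#'   training slice labels against simulator truth before the pipeline and
#'   after self-training cleansing (kept slices only).
#'
#' @param seed Integer seed for this replicate.
#' @param cfg A [train_config()]; defaults to the desk-scale configuration
#'   with this seed.
#' @param flip_rate Volume label-flip rate (default 0.2).
#' @return One-row tibble of the metrics above.
#' @export
recovery_experiment <- function(seed,
                                cfg = toy_train_config(seed = seed),
                                flip_rate = 0.2) {
  sp <- recovery_splits(seed, flip_rate = flip_rate)

  model0 <- pretrain_sqa(sp$labeled$slices, cfg)
  pipe <- fit_full_pipeline(sp$labeled, sp$unlabeled, cfg,
                            sqa_model = model0, keep_stage_models = TRUE)

  slice_acc <- function(m) {
    pr <- predict_slices(m, sp$test)
    mean(pr$pred == sp$test$slices$true_label)
  }
  vol_acc_for <- function(sqa, vqa) {
    pr <- predict_volumes(sqa, vqa, sp$test)
    mean(pr$pred == sp$test$volumes$true_label)
  }
  vqa_for <- function(sqa) {
    vqa_stage(sqa, sp$labeled, sp$unlabeled, cfg, st_iters = 0L)$vqa
  }

  kept <- training_slices(pipe$slices)
  tibble(
    seed = seed,
    acc_slice_pretrain = slice_acc(model0),
    acc_slice_pipeline = slice_acc(pipe$sqa),
    acc_vol_pretrain = vol_acc_for(model0, vqa_for(model0)),
    acc_vol_ssl = vol_acc_for(pipe$stage_models$ssl,
                              vqa_for(pipe$stage_models$ssl)),
    acc_vol_full = vol_acc_for(pipe$sqa, pipe$vqa),
    weak_label_acc = mean(sp$labeled$slices$label ==
                            sp$labeled$slices$true_label),
    cleaned_label_acc = mean(kept$label == kept$true_label)
  )
}
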