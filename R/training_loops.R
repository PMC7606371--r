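#' Training configuration
#'
#' Collects all stage-orchestration settings: the confidence thresholds for
#' slices (`th_s`, shared by semi-supervised pseudo-labeling and slice
#' self-training) and volumes (`th_v`), both strict (`> th`), iteration
#' counts, loss parameters, optimizer settings, and the seed. The
#' RMSprop defaults (`lr = 1e-5`, `decay = 5e-8`) are the settings used at
#' acquisition scale; desk-scale runs on the synthetic fixture use a larger
#' rate (see `toy_train_config()`).
#'
#' @param th_s,th_v Confidence thresholds in `(0, 1)` (defaults 0.9).
#' @param ssl_iters Semi-supervised pseudo-label/retrain rounds (default 2).
#' @param st_iters Self-training rounds per stage (default 2). Both counts
#'   may be 0, which reduces the pipeline to supervised pretraining plus
#'   rule-based volume initialization.
#' @param optimizer Optimizer name (only `"rmsprop"` is implemented).
#' @param lr,decay Learning rate and its per-step decay
#'   (`lr_t = lr / (1 + decay * t)`).
#' @param epochs Epochs for the initial fit of each network.
#' @param retrain_epochs Epochs for each retraining round (defaults to
#'   `epochs`).
#' @param batch_size Slices per gradient step (default 32).
#' @param augment Apply rotation/flip augmentation during training.
#' @param kappa,lambda Focal-loss focusing exponent and L2 coefficient.
#' @param seed Integer seed controlling every stochastic choice.
#' @return A list of class `train_config`.
#' @export
train_config <- function(th_s = 0.9, th_v = 0.9, ssl_iters = 2L,
                         st_iters = 2L, optimizer = "rmsprop",
                         lr = 1e-5, decay = 5e-8, epochs = 20L,
                         retrain_epochs = epochs, batch_size = 32L,
                         augment = TRUE, kappa = 2, lambda = 0.01,
                         seed = 1L) {
  stopifnot(th_s > 0, th_s < 1, th_v > 0, th_v < 1,
            ssl_iters >= 0, st_iters >= 0, epochs >= 1,
            identical(optimizer, "rmsprop"))
  structure(
    list(th_s = th_s, th_v = th_v, ssl_iters = as.integer(ssl_iters),
         st_iters = as.integer(st_iters), optimizer = optimizer,
         lr = lr, decay = decay, epochs = as.integer(epochs),
         retrain_epochs = as.integer(retrain_epochs),
         batch_size = as.integer(batch_size), augment = augment,
         kappa = kappa, lambda = lambda, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Desk-scale training configuration
#'
#' The [train_config()] used for the synthetic 64x64 fixture: a larger
#' learning rate with a per-step decay that keeps annealing across
#' retraining rounds, and few epochs per fit, so each fit takes seconds on
#' one CPU while the thresholds and iteration counts keep their standard
#' values.
#'
#' @param ... Overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
toy_train_config <- function(...) {
  args <- modifyList(list(lr = 1e-3, decay = 0.005, epochs = 10L,
                          retrain_epochs = 3L),
                     list(...))
  do.call(train_config, args)
}

#' Pre-train SQA-Net on the labeled slices
#'
#' Supervised training with the class-balanced focal loss and (by default)
#' rotation/flip augmentation. Slice labels are typically weak: inherited
#' from each slice's volume annotation.
#'
#' @param slices Slice tibble (e.g. `split$slices`) with non-missing
#'   labels; `provenance = "removed"` rows are excluded.
#' @param cfg A [train_config()].
#' @param model Optional pre-initialized [sqa_net()]; by default one is
#'   created to match the slice size.
#' @return A fitted `sqa_net` (training history in `$history`).
#' @export
pretrain_sqa <- function(slices, cfg = toy_train_config(), model = NULL) {
  sl <- training_slices(slices)
  if (nrow(sl) == 0) abort("no labeled slices to pre-train on")
  withr::with_seed(cfg$seed, {
    if (is.null(model)) {
      spec <- net_spec(nrow(sl$image[[1]]))
      model <- sqa_net(spec, seed = cfg$seed)
    }
    fit_sqa_net(model, sl, cfg, stage = "pretrain")
  })
}

#' One semi-supervised pseudo-labeling round
#'
#' Predicts every unlabeled slice with the current model; slices whose
#' maximal probability strictly exceeds `th_s` join the labeled pool with
#' the predicted label and provenance `pseudo`.
#'
#' @param model A fitted [sqa_net()].
#' @param labeled Labeled slice tibble.
#' @param unlabeled Unlabeled slice tibble.
#' @param th_s Confidence threshold (strict).
#' @return List with `labeled` (augmented pool), `counts`
#'   (`tibble(selected, skipped)`), and `probs` (the prediction matrix over
#'   `unlabeled`).
#' @export
ssl_round <- function(model, labeled, unlabeled, th_s = 0.9) {
  if (nrow(unlabeled) == 0) {
    return(list(labeled = labeled,
                counts = tibble(selected = 0L, skipped = 0L),
                probs = matrix(numeric(), 0, 3)))
  }
  p <- predict_slice_probs(model, unlabeled)
  maxp <- apply(p, 1, max)
  cls <- argmax_severe(p)
  sel <- maxp > th_s
  picked <- unlabeled[sel, ]
  if (nrow(picked) > 0) {
    picked$label <- class_to_label(cls[sel])
    picked$provenance <- "pseudo"
    picked$p_pass <- p[sel, 1]; picked$p_ques <- p[sel, 2]
    picked$p_fail <- p[sel, 3]
  }
  list(labeled = dplyr::bind_rows(labeled, picked),
       counts = tibble(selected = sum(sel), skipped = sum(!sel)),
       probs = p)
}

#' Iterative semi-supervised fitting of SQA-Net
#'
#' Pre-trains on the labeled pool, then alternates pseudo-labeling
#' ([ssl_round()]) and retraining for `cfg$ssl_iters` rounds. Pseudo-labels
#' are refreshed from scratch each round (the original labeled pool is
#' never modified). With an empty unlabeled pool this degenerates to
#' [pretrain_sqa()].
#'
#' @param labeled,unlabeled Slice tibbles.
#' @param cfg A [train_config()].
#' @param model Optional already-pretrained model; if `NULL`, pretraining
#'   runs first.
#' @return List with `model` (fitted `sqa_net`), `history` (per-round
#'   pseudo-label counts), and `pool` (the labeled pool merged with the
#'   last round's confident pseudo-labeled slices).
#' @export
semi_supervised_fit <- function(labeled, unlabeled,
                                cfg = toy_train_config(), model = NULL) {
  if (is.null(model)) model <- pretrain_sqa(labeled, cfg)
  hist <- list()
  pool <- labeled
  if (nrow(unlabeled) > 0 && cfg$ssl_iters > 0) {
    ref <- training_slices(labeled)
    best <- model
    best_acc <- ref_slice_accuracy(model, ref)
    for (r in seq_len(cfg$ssl_iters)) {
      rd <- ssl_round(model, labeled, unlabeled, cfg$th_s)
      pool <- rd$labeled
      hist[[r]] <- dplyr::mutate(rd$counts, round = r, .before = 1)
      withr::with_seed(cfg$seed + r, {
        model <- fit_sqa_net(model, training_slices(rd$labeled), cfg,
                             stage = sprintf("ssl_round_%d", r))
      })
      acc <- ref_slice_accuracy(model, ref)
      if (acc < best_acc - 0.005) {
        # diverged round: reject it (keep the audit trail) and continue
        # from the best model so far
        best$history <- model$history
        model <- best
      } else if (acc > best_acc) {
        best <- model; best_acc <- acc
      }
    }
  }
  list(model = model, history = dplyr::bind_rows(hist), pool = pool)
}

# accuracy of a slice model against the stored labels of a reference pool;
# the convergence yardstick for iterative refinement ("until performance
# improvement is minimal"), and the guard that detects a diverged retrain
ref_slice_accuracy <- function(model, ref) {
  p <- predict_slice_probs(model, ref)
  mean(class_to_label(argmax_severe(p)) == ref$label)
}

# shared keep/relabel/remove rule on a records tibble with label/provenance
# columns; probs is the aligned n x 3 prediction matrix
self_train_update <- function(records, probs, th) {
  active <- !is.na(records$label) &
    (is.na(records$provenance) | records$provenance != "removed")
  maxp <- apply(probs, 1, max)
  cls <- class_to_label(argmax_severe(probs))
  agrees <- cls == records$label
  confident <- maxp > th
  keep <- active & (agrees | confident)
  relabel <- active & confident & !agrees
  remove <- active & !keep

  records$label[relabel] <- cls[relabel]
  records$provenance[relabel] <- "relabeled"
  records$provenance[remove] <- "removed"
  records$p_pass[active] <- probs[active, 1]
  records$p_ques[active] <- probs[active, 2]
  records$p_fail[active] <- probs[active, 3]
  if (!any(keep)) {
    abort("degenerate selection: self-training removed every record")
  }
  list(records = records,
       counts = tibble(kept = sum(keep), relabeled = sum(relabel),
                       removed = sum(remove)))
}

#' One slice self-training round
#'
#' Predicts every active (labeled, not removed) slice and keeps those whose
#' predicted label agrees with their current label *or* whose maximal
#' probability strictly exceeds `th_s`. Kept high-confidence slices are
#' relabeled to the prediction (provenance `relabeled`); everything else is
#' marked `removed`. Removed slices stay in the table for auditability but
#' are excluded from all later training. Retraining is the caller's job
#' (see [fit_full_pipeline()]).
#'
#' @param model A fitted [sqa_net()].
#' @param slices Slice tibble whose active rows all carry labels.
#' @param th_s Confidence threshold (strict).
#' @return List with `slices` (updated table) and `counts`
#'   (`tibble(kept, relabeled, removed)`).
#' @export
slice_self_train_round <- function(model, slices, th_s = 0.9) {
  p <- predict_slice_probs(model, slices)
  up <- self_train_update(slices, p, th_s)
  list(slices = up$records, counts = up$counts)
}

#' One volume self-training round
#'
#' The volume-level analogue of [slice_self_train_round()]: volumes whose
#' VQA prediction agrees with their current label or clears `th_v` are
#' kept (and relabeled when confident); the rest are removed.
#'
#' @param model A fitted [vqa_net()].
#' @param volumes Volume tibble.
#' @param features `(h, w, c, n_s, n_v)` slice-feature array aligned with
#'   the rows of `volumes` (from the frozen SQA-Net).
#' @param th_v Confidence threshold (strict).
#' @return List with `volumes` and `counts`.
#' @export
volume_self_train_round <- function(model, volumes, features, th_v = 0.9) {
  p <- as.matrix(vqa_fwd_full(model, features, training = FALSE)$probs)
  up <- self_train_update(volumes, p, th_v)
  list(volumes = up$records, counts = up$counts)
}

#' Fit the full hierarchical pipeline
#'
#' Executes the complete training sequence: SQA-Net pretraining on weak
#' slice labels, iterative semi-supervised pseudo-labeling, slice
#' self-training, rule-based initialization of unlabeled volume ratings
#' from predicted slice labels, VQA-Net training on frozen slice features,
#' and volume self-training. Every label change is recorded with its
#' provenance.
#'
#' @param labeled_split `labeled_train` [qa_split()].
#' @param unlabeled_split `unlabeled` [qa_split()] (may have 0 rows).
#' @param cfg A [train_config()].
#' @param sqa_model Optional already-pretrained [sqa_net()] (skips
#'   pretraining).
#' @param keep_stage_models Keep snapshots of the slice model after
#'   pretraining and after semi-supervised learning (in `$stage_models`),
#'   e.g. for stage-wise comparisons.
#' @return Object of class `qa_pipeline`: `sqa`, `vqa`, `slices` and
#'   `volumes` (final label tables), `history` (per-stage counts), `cfg`.
#' @export
fit_full_pipeline <- function(labeled_split, unlabeled_split,
                              cfg = toy_train_config(), sqa_model = NULL,
                              keep_stage_models = FALSE) {
  stopifnot(inherits(labeled_split, "qa_split"),
            inherits(unlabeled_split, "qa_split"))
  history <- list()
  log_stage <- function(stage, counts) {
    history[[length(history) + 1L]] <<-
      dplyr::mutate(counts, stage = stage, .before = 1)
  }
  stage_models <- list()

  # --- slice stage: pretrain, SSL, slice self-training ---
  model <- sqa_model %||% pretrain_sqa(labeled_split$slices, cfg)
  if (keep_stage_models) stage_models$pretrain <- model
  ssl <- semi_supervised_fit(labeled_split$slices, unlabeled_split$slices,
                             cfg, model = model)
  model <- ssl$model
  if (keep_stage_models) stage_models$ssl <- model
  if (nrow(ssl$history)) log_stage("ssl", ssl$history)

  # self-training refines the merged pool (weak labels + confident pseudo)
  slices <- ssl$pool
  if (cfg$st_iters > 0) {
    ref <- training_slices(labeled_split$slices)
    best <- model; best_slices <- slices
    best_acc <- ref_slice_accuracy(model, ref)
    for (r in seq_len(cfg$st_iters)) {
      rd <- slice_self_train_round(model, slices, cfg$th_s)
      slices <- rd$slices
      log_stage(sprintf("slice_self_train_%d", r), rd$counts)
      withr::with_seed(cfg$seed + 100L + r, {
        model <- fit_sqa_net(model, training_slices(slices), cfg,
                             stage = sprintf("slice_st_%d", r))
      })
      acc <- ref_slice_accuracy(model, ref)
      if (acc < best_acc - 0.005) {
        # diverged round: reject its relabeling and model, keep the log
        best$history <- model$history
        model <- best
        slices <- best_slices
      } else if (acc > best_acc) {
        best <- model; best_slices <- slices; best_acc <- acc
      }
    }
  }

  vs <- vqa_stage(model, labeled_split, unlabeled_split, cfg,
                  st_iters = cfg$st_iters, log_stage = log_stage)

  structure(
    list(sqa = model, vqa = vs$vqa, slices = slices, volumes = vs$volumes,
         history = dplyr::bind_rows(history), cfg = cfg,
         stage_models = if (keep_stage_models) stage_models),
    class = "qa_pipeline"
  )
}

# volume stage shared by the pipeline and stage-wise experiments:
# rule-based initialization of unlabeled volume ratings from predicted
# slice labels, VQA training on frozen slice features, optional volume
# self-training
vqa_stage <- function(model, labeled_split, unlabeled_split, cfg,
                      st_iters = 0L, log_stage = function(...) NULL) {
  volumes <- labeled_split$volumes
  if (nrow(unlabeled_split$volumes) > 0) {
    uvol <- unlabeled_split$volumes
    up <- predict_slice_probs(model, unlabeled_split$slices)
    usl <- unlabeled_split$slices
    usl$pred <- class_to_label(argmax_severe(up))
    init <- aggregate_volume_labels(usl, label_col = "pred")
    uvol$label <- init$label[match(uvol$volume_id, init$volume_id)]
    uvol$provenance <- "pseudo"
    volumes <- dplyr::bind_rows(volumes, uvol)
  }

  all_slices <- dplyr::bind_rows(labeled_split$slices,
                                 unlabeled_split$slices)
  tv <- training_volumes(volumes)
  feats <- extract_volume_features(model, all_slices, tv$volume_id)
  vspec <- model$spec
  vspec$n_slices <- dim(feats)[4]
  vqa <- vqa_net(vspec, seed = cfg$seed)
  withr::with_seed(cfg$seed + 200L, {
    vqa <- fit_vqa_net(vqa, feats, tv$label, cfg, stage = "vqa_fit")
  })

  if (st_iters > 0) {
    ref_labels <- tv$label
    ref_acc <- function(m) {
      p <- vqa_fwd_full(m, feats, training = FALSE)$probs
      mean(class_to_label(argmax_severe(p)) == ref_labels)
    }
    best <- vqa; best_tv <- tv
    best_acc <- ref_acc(vqa)
    for (r in seq_len(st_iters)) {
      rd <- volume_self_train_round(vqa, tv, feats, cfg$th_v)
      tv <- rd$volumes
      log_stage(sprintf("volume_self_train_%d", r), rd$counts)
      act <- !is.na(tv$label) &
        (is.na(tv$provenance) | tv$provenance != "removed")
      withr::with_seed(cfg$seed + 300L + r, {
        vqa <- fit_vqa_net(vqa, feats[, , , , act, drop = FALSE],
                           tv$label[act], cfg,
                           stage = sprintf("volume_st_%d", r))
      })
      acc <- ref_acc(vqa)
      if (acc < best_acc - 0.005) {
        # diverged round: reject it, keep the log
        best$history <- vqa$history
        vqa <- best
        tv <- best_tv
      } else if (acc > best_acc) {
        best <- vqa; best_tv <- tv; best_acc <- acc
      }
    }
  }

  volumes <- dplyr::rows_update(volumes, tv, by = "volume_id")
  list(vqa = vqa, volumes = volumes)
}

#' @export
print.qa_pipeline <- function(x, ...) {
  cat(sprintf("<qa_pipeline: %d slices, %d volumes tracked>\n",
              nrow(x$slices), nrow(x$volumes)))
  print(x$history)
  invisible(x)
}

#' Predict slice quality labels
#'
#' @param object A fitted `sqa_net` (or a `qa_pipeline`).
#' @param slices Slice tibble with an `image` list-column (or a
#'   [qa_split()]).
#' @param ... Unused.
#' @return Tibble with `slice_id` (when available), class probabilities,
#'   and `pred`.
#' @export
predict_slices <- function(object, slices, ...) {
  if (inherits(object, "qa_pipeline")) object <- object$sqa
  if (inherits(slices, "qa_split")) slices <- slices$slices
  p <- predict_slice_probs(object, slices)
  out <- prob_tibble(p)
  out$pred <- class_to_label(argmax_severe(p))
  if ("slice_id" %in% names(slices)) {
    out <- dplyr::bind_cols(slices["slice_id"], out)
  }
  out
}

#' Predict volume quality labels
#'
#' Runs the frozen SQA-Net to extract slice features and VQA-Net to rate
#' each volume.
#'
#' @param sqa,vqa Fitted networks (or pass a `qa_pipeline` as `sqa`).
#' @param split A [qa_split()].
#' @return Tibble with `volume_id`, class probabilities, and `pred`.
#' @export
predict_volumes <- function(sqa, vqa = NULL, split) {
  if (inherits(sqa, "qa_pipeline")) {
    vqa <- sqa$vqa; sqa <- sqa$sqa
  }
  vids <- split$volumes$volume_id
  feats <- extract_volume_features(sqa, split$slices, vids)
  out <- vqa_forward(vqa, feats)
  dplyr::bind_cols(tibble(volume_id = vids), out)
}

#' Predict subject quality labels from volume predictions
#'
#' Applies the subject decision rule to predicted volume labels.
#'
#' @param volume_preds Output of [predict_volumes()] joined with
#'   `subject_id` (or a tibble with `subject_id` and `pred`).
#' @return Tibble with `subject_id` and `pred`.
#' @export
predict_subjects <- function(volume_preds) {
  stopifnot(all(c("subject_id", "pred") %in% names(volume_preds)))
  volume_preds |>
    dplyr::summarise(pred = subject_label(.data$pred), .by = "subject_id")
}
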