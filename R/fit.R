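# RMSprop optimizer and the shared mini-batch training loops for the slice
# and volume networks. All loops are deterministic given the caller's RNG
# state (shuffling and augmentation both draw from R's RNG).

# balancing weights for a training stage; initial fits refuse an absent
# class outright, while self-training retrains (where removal can empty a
# class) fall back to weight 1 for the missing classes with a warning
stage_class_weights <- function(t_all, stage, strict) {
  counts <- tabulate(t_all, 3)
  if (all(counts > 0)) return(class_weights(counts))
  if (strict) {
    abort(sprintf("empty class in training data (%s): counts %s", stage,
                  paste(counts, collapse = "/")))
  }
  warn(sprintf("class absent during %s; unweighted for missing classes",
               stage))
  alpha <- rep(1, 3)
  present <- counts > 0
  alpha[present] <- max(counts[present]) / counts[present]
  alpha
}

rms_update <- function(p, g, v, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      res <- rms_update(p[[nm]], g[[nm]], v[[nm]] %||% list(), lr, rho, eps)
      p[[nm]] <- res$p
      v[[nm]] <- res$v
    } else {
      vv <- (v[[nm]] %||% 0) * rho + (1 - rho) * g[[nm]]^2
      p[[nm]] <- p[[nm]] - lr * g[[nm]] / (sqrt(vv) + eps)
      v[[nm]] <- vv
    }
  }
  list(p = p, v = v)
}

# one gradient step; returns updated model + optimizer state + batch stats
sqa_step <- function(model, opt, xb, t, lp, lr) {
  fw <- sqa_fwd_full(model, xb, training = TRUE)
  model <- fw$model
  dz <- focal_grad_logits(fw$probs, t, lp$alpha, lp$kappa)
  bw <- sqa_bwd_full(model, fw$caches, dz)
  g <- add_l2_grads(bw$grads, model$params, lp$lambda, opt$n_w)
  up <- rms_update(model$params, g, opt$v, lr)
  model$params <- up$p
  opt$v <- up$v
  loss <- focal_loss(fw$probs, t, lp, collect_l2_weights(model$params))
  acc <- mean(argmax_severe(fw$probs) == t)
  list(model = model, opt = opt, loss = loss, acc = acc)
}

# slices: tibble with image list-column and labels; trains in place
fit_sqa_net <- function(model, slices, cfg, stage = "fit") {
  t_all <- label_to_class(slices$label)
  lp <- loss_params(kappa = cfg$kappa, lambda = cfg$lambda,
                    alpha = stage_class_weights(t_all, stage,
                                                strict = stage == "pretrain"))
  opt <- list(v = list(), n_w = length(collect_l2_weights(model$params)))
  n <- nrow(slices)
  # the decay schedule continues across retraining rounds of one model
  step <- model$opt_step %||% 0L
  hist <- list()
  epochs <- if (stage == "pretrain") cfg$epochs else cfg$retrain_epochs
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c(); accs <- c()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      imgs <- slices$image[idx]
      if (cfg$augment) imgs <- lapply(imgs, augment_slice)
      xb <- images_to_batch(imgs)
      lr <- cfg$lr / (1 + cfg$decay * step)
      st <- sqa_step(model, opt, xb, t_all[idx], lp, lr)
      model <- st$model; opt <- st$opt
      losses <- c(losses, st$loss); accs <- c(accs, st$acc)
      step <- step + 1L
    }
    hist[[ep]] <- tibble(stage = stage, epoch = ep,
                         loss = mean(losses), acc = mean(accs),
                         n_slices = n)
  }
  model$opt_step <- step
  model <- bn_recalibrate(model, slices, cfg)
  model$history <- dplyr::bind_rows(model$history, dplyr::bind_rows(hist))
  model
}

# re-estimate batch-norm running statistics exactly over the (unaugmented)
# training set: running averages lag the fast-moving weights during short
# fits, so inference-mode statistics are recomputed as the equal-weight
# mean of per-batch moments after every fit
bn_recalibrate <- function(model, slices, cfg) {
  n <- nrow(slices)
  i <- 0L
  for (b0 in seq(1, n, by = cfg$batch_size)) {
    idx <- b0:min(b0 + cfg$batch_size - 1, n)
    xb <- images_to_batch(slices$image[idx])
    i <- i + 1L
    fw <- sqa_fwd_full(model, xb, training = TRUE,
                       momentum = 1 - 1 / i)
    model <- fw$model
  }
  model
}

vqa_step <- function(model, opt, feats, t, lp, lr) {
  fw <- vqa_fwd_full(model, feats, training = TRUE)
  dz <- focal_grad_logits(fw$probs, t, lp$alpha, lp$kappa)
  bw <- vqa_bwd_full(model, fw$caches, dz)
  g <- add_l2_grads(bw$grads, model$params, lp$lambda, opt$n_w)
  up <- rms_update(model$params, g, opt$v, lr)
  model$params <- up$p
  opt$v <- up$v
  loss <- focal_loss(fw$probs, t, lp, collect_l2_weights(model$params))
  acc <- mean(argmax_severe(fw$probs) == t)
  list(model = model, opt = opt, loss = loss, acc = acc)
}

# feats: (hf, wf, c4, n_s, n_v) aligned with labels
fit_vqa_net <- function(model, feats, labels, cfg, stage = "vqa_fit") {
  t_all <- label_to_class(labels)
  lp <- loss_params(kappa = cfg$kappa, lambda = cfg$lambda,
                    alpha = stage_class_weights(t_all, stage,
                                                strict = stage == "vqa_fit"))
  opt <- list(v = list(), n_w = length(collect_l2_weights(model$params)))
  n_v <- dim(feats)[5]
  step <- model$opt_step %||% 0L
  hist <- list()
  epochs <- if (stage == "vqa_fit") cfg$epochs else cfg$retrain_epochs
  bs <- max(4L, cfg$batch_size %/% 4L)  # volumes are heavier than slices
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_v)
    losses <- c(); accs <- c()
    for (b0 in seq(1, n_v, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1, n_v)]
      fb <- feats[, , , , idx, drop = FALSE]
      lr <- cfg$lr / (1 + cfg$decay * step)
      st <- vqa_step(model, opt, fb, t_all[idx], lp, lr)
      model <- st$model; opt <- st$opt
      losses <- c(losses, st$loss); accs <- c(accs, st$acc)
      step <- step + 1L
    }
    hist[[ep]] <- tibble(stage = stage, epoch = ep,
                         loss = mean(losses), acc = mean(accs),
                         n_slices = n_v)
  }
  model$opt_step <- step
  model$history <- dplyr::bind_rows(model$history, dplyr::bind_rows(hist))
  model
}

# chunked inference over a slice table; returns n x 3 probability matrix
predict_slice_probs <- function(model, slices, chunk = 64L) {
  n <- nrow(slices)
  out <- matrix(NA_real_, n, 3)
  for (b0 in seq(1, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1, n)
    xb <- images_to_batch(slices$image[idx])
    out[idx, ] <- sqa_fwd_full(model, xb, training = FALSE)$probs
  }
  out
}

# NLR feature maps for every slice, grouped by volume in slice_index order;
# returns (hf, wf, c4, n_s, n_v) aligned with `volume_ids`
extract_volume_features <- function(model, slices, volume_ids,
                                    chunk = 64L) {
  sl <- slices[order(match(slices$volume_id, volume_ids),
                     slices$slice_index), ]
  sl <- sl[sl$volume_id %in% volume_ids, ]
  n_s <- nrow(sl) / length(volume_ids)
  stopifnot(n_s == round(n_s))
  fs <- model$spec$feature_size
  c4 <- model$spec$channels[4]
  feats <- array(0, c(fs, fs, c4, nrow(sl)))
  for (b0 in seq(1, nrow(sl), by = chunk)) {
    idx <- b0:min(b0 + chunk - 1, nrow(sl))
    xb <- images_to_batch(sl$image[idx])
    feats[, , , idx] <- sqa_fwd_full(model, xb, training = FALSE)$feat
  }
  array(feats, c(fs, fs, c4, n_s, length(volume_ids)))
}
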