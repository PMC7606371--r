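#' Network architecture specification
#'
#' The slice network (SQA-Net) is DSR(c1) -> DSR(c2) -> NLDR(c3) ->
#' NLDR(c4) -> NLR(c4) -> CLF(3); each DSR/NLDR halves the spatial size, so
#' a `144 x 144` input reaches the NLR block at `9 x 9`. The volume network
#' (VQA-Net) reduces each slice's NLR feature map to `reduce_channels` with
#' a shared 1x1 convolution, concatenates the reduced maps of all
#' `n_slices` slices along the channel axis, and applies an NLR and a CLF
#' block.
#'
#' At the acquisition scale the channel progression is
#' `32, 64, 128, 256, 256, 3` with a 16-channel reduction; the default
#' desk-scale spec quarters the channels (`8, 16, 32, 64, 64, 3`, 8-channel
#' reduction) on `64 x 64` inputs so everything trains on a CPU.
#'
#' @param input_size Slice side length; must be a multiple of 16 (four
#'   pooling stages).
#' @param channels Length-4 channel progression for DSR1, DSR2, NLDR3,
#'   NLDR4 (the NLR block preserves NLDR4's channels). Default: quarter
#'   scale for inputs below 144, full scale otherwise.
#' @param n_slices Slices per volume consumed by VQA-Net.
#' @param reduce_channels Channels after the VQA 1x1 reduction.
#' @return A list of class `net_spec`.
#' @export
#' @examples
#' net_spec(144, n_slices = 60)  # acquisition-scale geometry
net_spec <- function(input_size = 64,
                     channels = NULL,
                     n_slices = 16,
                     reduce_channels = NULL) {
  if (input_size %% 16 != 0) {
    abort("input_size must be a multiple of 16 (four 2x2 poolings)")
  }
  channels <- channels %||%
    if (input_size >= 144) c(32L, 64L, 128L, 256L) else c(8L, 16L, 32L, 64L)
  stopifnot(length(channels) == 4)
  reduce_channels <- reduce_channels %||%
    if (input_size >= 144) 16L else 8L
  structure(
    list(input_size = as.integer(input_size),
         channels = as.integer(channels),
         n_slices = as.integer(n_slices),
         reduce_channels = as.integer(reduce_channels),
         feature_size = as.integer(input_size / 16)),
    class = "net_spec"
  )
}

#' Initialize a slice quality assessment network (SQA-Net)
#'
#' @param spec A [net_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `sqa_net`.
#' @export
sqa_net <- function(spec = net_spec(), seed = 1L) {
  ch <- spec$channels
  withr::with_seed(as.integer(seed), {
    params <- list(
      b1 = block_params_unseeded("dsr", 1L, ch[1]),
      b2 = block_params_unseeded("dsr", ch[1], ch[2]),
      b3 = block_params_unseeded("nldr", ch[2], ch[3]),
      b4 = block_params_unseeded("nldr", ch[3], ch[4]),
      b5 = block_params_unseeded("nlr", ch[4]),
      clf = block_params_unseeded("clf", ch[4])
    )
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 history = NULL),
            class = "sqa_net")
}

# block_params without its own seed scoping (used inside model init)
block_params_unseeded <- function(type, c_in, c_out = NULL) {
  switch(type,
    dsr = list(ds1 = ds_init(c_in, c_out), bn1 = bn_init(c_out),
               ds2 = ds_init(c_out, c_out), bn2 = bn_init(c_out),
               sc = he_conv(1L, 1L, c_in, c_out)),
    nldr = list(ds1 = ds_init(c_in, c_out), bn1 = bn_init(c_out),
                ds2 = ds_init(c_out, c_out), bn2 = bn_init(c_out),
                nl = nl_init(c_out), sc = he_conv(1L, 1L, c_in, c_out)),
    nlr = list(nl = nl_init(c_in)),
    clf = list(W = he_conv(3L, 3L, c_in, 3L), b = rep(0, 3))
  )
}

#' @export
print.sqa_net <- function(x, ...) {
  cat(sprintf("<sqa_net: %dx%d input, channels %s, %d parameters>\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$channels, collapse = "/"), param_count(x)))
  invisible(x)
}

# full forward with caches; x (h, w, 1, n)
sqa_fwd_full <- function(model, x, training = FALSE, momentum = 0.9) {
  p <- model$params
  c1 <- dsr_fwd(x, p$b1, training, nonlocal = FALSE, momentum = momentum)
  p$b1 <- c1$p
  c2 <- dsr_fwd(c1$y, p$b2, training, nonlocal = FALSE, momentum = momentum)
  p$b2 <- c2$p
  c3 <- dsr_fwd(c2$y, p$b3, training, nonlocal = TRUE, momentum = momentum)
  p$b3 <- c3$p
  c4 <- dsr_fwd(c3$y, p$b4, training, nonlocal = TRUE, momentum = momentum)
  p$b4 <- c4$p
  c5 <- nlr_fwd(c4$y, p$b5)
  cc <- clf_fwd(c5$y, p$clf)
  model$params <- p
  list(probs = cc$probs, feat = c5$y, model = model,
       caches = list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                     c4 = c4$cache, c5 = c5$cache, clf = cc$cache))
}

sqa_bwd_full <- function(model, caches, dz) {
  p <- model$params
  g_clf <- clf_bwd(dz, caches$clf, p$clf)
  g5 <- nlr_bwd(g_clf$dx, caches$c5, p$b5)
  g4 <- dsr_bwd(g5$dx, caches$c4, p$b4, nonlocal = TRUE)
  g3 <- dsr_bwd(g4$dx, caches$c3, p$b3, nonlocal = TRUE)
  g2 <- dsr_bwd(g3$dx, caches$c2, p$b2, nonlocal = FALSE)
  g1 <- dsr_bwd(g2$dx, caches$c1, p$b1, nonlocal = FALSE)
  list(grads = list(b1 = g1$grads, b2 = g2$grads, b3 = g3$grads,
                    b4 = g4$grads, b5 = g5$grads, clf = g_clf$grads),
       dx = g1$dx)
}

#' Run SQA-Net on preprocessed slices
#'
#' @param model An [sqa_net()].
#' @param images A single matrix, a list of matrices, or a
#'   `(h, w, 1, n)` array of preprocessed slices matching
#'   `model$spec$input_size`.
#' @param training Use batch statistics in batch norm (training mode).
#' @return A list with `probs` (tibble with `p_pass`, `p_ques`, `p_fail`,
#'   one row per slice) and `features` (the `(h/16, w/16, c4, n)` NLR
#'   feature maps consumed by VQA-Net).
#' @export
sqa_forward <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "sqa_net"))
  x <- images_to_batch(images)
  sz <- model$spec$input_size
  if (dim(x)[1] != sz || dim(x)[2] != sz) {
    abort(sprintf("expected %dx%d slices, got %dx%d",
                  sz, sz, dim(x)[1], dim(x)[2]))
  }
  fw <- sqa_fwd_full(model, x, training = training)
  list(probs = prob_tibble(fw$probs), features = fw$feat)
}

images_to_batch <- function(images) {
  if (is.matrix(images)) images <- list(images)
  if (is.list(images)) {
    h <- nrow(images[[1]]); w <- ncol(images[[1]])
    # (h, w, n) memory doubles as (h, w, 1, n)
    x <- array(unlist(images, use.names = FALSE),
               c(h, w, 1L, length(images)))
    return(x)
  }
  if (length(dim(images)) == 3) {
    d <- dim(images)
    return(array(images, c(d[1], d[2], 1L, d[3])))
  }
  stopifnot(length(dim(images)) == 4)
  images
}

prob_tibble <- function(p) {
  tibble(p_pass = p[, 1], p_ques = p[, 2], p_fail = p[, 3])
}

# argmax with ties broken toward the more severe label
argmax_severe <- function(p) {
  max.col(p, ties.method = "last")
}

#' Initialize a volume quality assessment network (VQA-Net)
#'
#' @param spec A [net_spec()]; `spec$n_slices` fixes how many slice feature
#'   maps are concatenated.
#' @param seed Integer seed.
#' @return An object of class `vqa_net`.
#' @export
vqa_net <- function(spec = net_spec(), seed = 1L) {
  c4 <- spec$channels[4]
  cr <- spec$reduce_channels
  cc <- cr * spec$n_slices
  withr::with_seed(as.integer(seed), {
    params <- list(
      reduce = he_conv(1L, 1L, c4, cr),
      nl = nl_init(cc),
      clf = block_params_unseeded("clf", cc)
    )
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 history = NULL),
            class = "vqa_net")
}

#' @export
print.vqa_net <- function(x, ...) {
  cat(sprintf(
    "<vqa_net: %d slices x %d-ch reduced features, %d parameters>\n",
    x$spec$n_slices, x$spec$reduce_channels, param_count(x)))
  invisible(x)
}

# feats: (hf, wf, c4, n_s, n_v)
vqa_fwd_full <- function(model, feats, training = FALSE) {
  d <- dim(feats)
  stopifnot(length(d) == 5)
  if (d[4] != model$spec$n_slices) {
    abort(sprintf("expected %d slices per volume, got %d",
                  model$spec$n_slices, d[4]))
  }
  n_sv <- d[4] * d[5]
  x4 <- array(feats, c(d[1], d[2], d[3], n_sv))
  red <- conv_fwd(x4, model$params$reduce, NULL, 1L, 0L)
  rr <- relu_fwd(red)
  cr <- dim(red)[3]
  # (hf, wf, cr, n_s, n_v) memory is already (hf, wf, cr * n_s, n_v)
  z <- array(rr$y, c(d[1], d[2], cr * d[4], d[5]))
  c5 <- nlr_fwd(z, list(nl = model$params$nl))
  cc <- clf_fwd(c5$y, model$params$clf)
  list(probs = cc$probs,
       caches = list(x4 = x4, mask = rr$mask, zdim = dim(z),
                     rdim = dim(red), c5 = c5$cache, clf = cc$cache))
}

vqa_bwd_full <- function(model, caches, dz) {
  p <- model$params
  g_clf <- clf_bwd(dz, caches$clf, p$clf)
  g5 <- nlr_bwd(g_clf$dx, caches$c5, list(nl = p$nl))
  dred <- array(g5$dx, caches$rdim)
  dred <- relu_bwd(dred, caches$mask)
  cb <- conv_bwd(caches$x4, p$reduce, dred, 1L, 0L)
  list(grads = list(reduce = cb$dW, nl = g5$grads$nl, clf = g_clf$grads))
}

#' Run VQA-Net on the slice feature maps of one or more volumes
#'
#' @param model A [vqa_net()].
#' @param features Either a `(h, w, c, n_s)` array (one volume), a list of
#'   such arrays, or a `(h, w, c, n_s, n_v)` array. Slice order matters:
#'   features are concatenated along the channel axis in the order given,
#'   so permuting slices changes the input (and possibly the output).
#' @return Tibble with `p_pass`, `p_ques`, `p_fail`, and `pred` (argmax
#'   label, ties broken toward the more severe class), one row per volume.
#' @export
vqa_forward <- function(model, features) {
  stopifnot(inherits(model, "vqa_net"))
  if (is.list(features)) {
    d0 <- dim(features[[1]])
    for (f in features) {
      if (!identical(dim(f), d0)) abort("mismatched feature shapes")
    }
    features <- array(unlist(features, use.names = FALSE),
                      c(d0, length(features)))
  }
  if (length(dim(features)) == 4) {
    features <- array(features, c(dim(features), 1L))
  }
  fw <- vqa_fwd_full(model, features, training = FALSE)
  out <- prob_tibble(fw$probs)
  out$pred <- class_to_label(argmax_severe(fw$probs))
  out
}

#' Save / load a model checkpoint
#'
#' The weight container is a serialized R object; a JSON sidecar
#' (`<path>.json`) records the architecture spec, seed, and parameter
#' count for provenance.
#'
#' @param model An `sqa_net` or `vqa_net`.
#' @param path File path for the weight container.
#' @return `path` (for `save_model`); the model (for `load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(class = class(model)[1],
         spec = unclass(model$spec),
         seed = model$seed,
         n_params = param_count(model)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
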