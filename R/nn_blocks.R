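# Network building blocks. Public functions (dsconv, dsr_block, nldr_block,
# nlr_block, clf_block) run a block forward on a feature map given a
# parameter list from block_params(); the internal .*_fwd/.*_bwd pairs carry
# the caches used during training.

#' Depthwise separable convolution
#'
#' A 3x3 per-channel (depthwise) convolution followed by a 1x1 pointwise
#' convolution mixing channels, the cheap drop-in for a full 3x3
#' convolution: `9*c_in + c_in*c_out` weights (plus `c_out` biases if used)
#' versus `9*c_in*c_out`.
#'
#' @param x Feature map: `(h, w, c_in)` array, matrix (`c_in = 1`), or
#'   `(h, w, c_in, n)` batch.
#' @param dw Depthwise kernel, `(3, 3, c_in)` array.
#' @param pw Pointwise kernel, `(1, 1, c_in, c_out)` array.
#' @param bias Optional length-`c_out` bias.
#' @return Feature map with `c_out` channels, same spatial size, same rank
#'   as the input.
#' @export
dsconv <- function(x, dw, pw, bias = NULL) {
  xb <- as_feature_batch(x)
  y <- conv_fwd(dwconv_fwd_cpp(xb, dw), pw, bias, 1L, 0L)
  drop_batch(y, x)
}

drop_batch <- function(y, x_orig) {
  if (is.matrix(x_orig) || length(dim(x_orig)) == 3) {
    d <- dim(y)
    return(array(y, d[1:3]))
  }
  y
}

#' Closed-form parameter count of a depthwise separable convolution
#'
#' @param c_in,c_out Channel counts.
#' @param kernel Spatial kernel size (default 3).
#' @param bias Include `c_out` bias terms?
#' @return Integer parameter count.
#' @export
#' @examples
#' dsconv_param_count(32, 64)          # 2336, vs 18432 for a full 3x3 conv
dsconv_param_count <- function(c_in, c_out, kernel = 3, bias = FALSE) {
  kernel^2 * c_in + c_in * c_out + if (bias) c_out else 0L
}

ds_init <- function(cin, cout) {
  list(dw = he_dw(3L, 3L, cin), pw = he_conv(1L, 1L, cin, cout))
}

ds_fwd <- function(x, p) {
  y1 <- dwconv_fwd_cpp(x, p$dw)
  y <- conv_fwd(y1, p$pw, p$bias, 1L, 0L)
  list(y = y, cache = list(x = x, y1 = y1))
}

ds_bwd <- function(dy, cache, p) {
  cv <- conv_bwd(cache$y1, p$pw, dy, 1L, 0L, has_bias = !is.null(p$bias))
  dw <- dwconv_bwd_cpp(cache$x, p$dw, cv$dx)
  g <- list(dw = dw$dW, pw = cv$dW)
  if (!is.null(p$bias)) g$bias <- cv$db
  list(dx = dw$dx, grads = g)
}

#' Initialize parameters for a network block
#'
#' @param type `"dsr"`, `"nldr"`, `"nlr"`, or `"clf"`.
#' @param c_in Input channels.
#' @param c_out Output channels (`dsr`/`nldr` only; `nlr` preserves
#'   channels, `clf` outputs 3 class logits).
#' @param seed Integer seed for the He-normal initialization.
#' @return Nested parameter list for the matching `*_block()` function.
#' @export
block_params <- function(type = c("dsr", "nldr", "nlr", "clf"),
                         c_in, c_out = NULL, seed = 1L) {
  type <- match.arg(type)
  withr::with_seed(as.integer(seed), {
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
  })
}

# ---- DSR ----

dsr_fwd <- function(x, p, training = FALSE, nonlocal = FALSE,
                    momentum = 0.9) {
  d <- dim(x)
  if (d[1] %% 2 || d[2] %% 2) {
    abort("DSR/NLDR blocks require even spatial dimensions")
  }
  a1 <- ds_fwd(x, p$ds1)
  b1 <- bn_fwd(a1$y, p$bn1, training, momentum); p$bn1 <- b1$p
  r1 <- relu_fwd(b1$y)
  a2 <- ds_fwd(r1$y, p$ds2)
  b2 <- bn_fwd(a2$y, p$bn2, training, momentum); p$bn2 <- b2$p
  r2 <- relu_fwd(b2$y)
  pre_pool <- r2$y
  nlc <- NULL
  if (nonlocal) {
    nlc <- nl_fwd(r2$y, p$nl)
    pre_pool <- r2$y + nlc$y   # residual insertion of the nonlocal branch
  }
  mp <- maxpool2_fwd_cpp(pre_pool)
  sc <- conv_fwd(x, p$sc, NULL, 2L, 0L)
  y <- mp$y + sc
  list(y = y, p = p,
       cache = list(a1 = a1$cache, bn1 = b1$cache, m1 = r1$mask,
                    a2 = a2$cache, bn2 = b2$cache, m2 = r2$mask,
                    nl = nlc$cache, idx = mp$idx, xdim = d, x = x,
                    prepool_dim = dim(pre_pool)))
}

dsr_bwd <- function(dy, cache, p, nonlocal = FALSE) {
  dpre <- maxpool2_bwd_cpp(dy, cache$idx, as.integer(cache$prepool_dim))
  gnl <- NULL
  if (nonlocal) {
    nb <- nl_bwd(dpre, cache$nl, p$nl)
    gnl <- nb$grads
    dpre <- dpre + nb$dx       # gradient through the residual add
  }
  dr2 <- relu_bwd(dpre, cache$m2)
  b2 <- bn_bwd(dr2, cache$bn2, p$bn2$gamma)
  d2 <- ds_bwd(b2$dx, cache$a2, p$ds2)
  dr1 <- relu_bwd(d2$dx, cache$m1)
  b1 <- bn_bwd(dr1, cache$bn1, p$bn1$gamma)
  d1 <- ds_bwd(b1$dx, cache$a1, p$ds1)
  csc <- conv_bwd(cache$x, p$sc, dy, 2L, 0L)
  dx <- d1$dx + csc$dx
  g <- list(ds1 = d1$grads,
            bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
            ds2 = d2$grads,
            bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
            sc = csc$dW)
  if (nonlocal) g$nl <- gnl
  list(dx = dx, grads = g)
}

#' Depthwise separable residual (DSR) block
#'
#' Main path: two (DSConv -> batch norm -> ReLU) stages followed by 2x2
#' max-pooling; shortcut: 1x1 convolution with stride 2. The two paths are
#' summed, halving the spatial size and mapping `c_in` to `c_out` channels.
#'
#' @param x Feature map (matrix, `(h, w, c)` array, or `(h, w, c, n)`
#'   batch); `h` and `w` must be even.
#' @param p Parameters from `block_params("dsr", ...)`.
#' @param training Use batch statistics (`TRUE`) or running averages in the
#'   batch-norm layers.
#' @return Feature map of shape `(h/2, w/2, c_out)` (batched if `x` was).
#' @export
dsr_block <- function(x, p, training = FALSE) {
  xb <- as_feature_batch(x)
  drop_batch(dsr_fwd(xb, p, training = training, nonlocal = FALSE)$y, x)
}

#' Nonlocal depthwise separable residual (NLDR) block
#'
#' A DSR block with a nonlocal attention branch inserted immediately before
#' the max-pooling layer as a residual add (`z = r + nonlocal(r)`), so the
#' block mixes global context into the local features before downsampling.
#'
#' @inheritParams dsr_block
#' @param p Parameters from `block_params("nldr", ...)`.
#' @return Feature map of shape `(h/2, w/2, c_out)`.
#' @export
nldr_block <- function(x, p, training = FALSE) {
  xb <- as_feature_batch(x)
  drop_batch(dsr_fwd(xb, p, training = training, nonlocal = TRUE)$y, x)
}

# ---- NLR ----

nlr_fwd <- function(x, p) {
  nlc <- nl_fwd(x, p$nl)
  list(y = x + nlc$y, cache = nlc$cache)
}

nlr_bwd <- function(dy, cache, p) {
  nb <- nl_bwd(dy, cache, p$nl)
  list(dx = dy + nb$dx, grads = list(nl = nb$grads))
}

#' Nonlocal residual (NLR) block
#'
#' Identity shortcut around a nonlocal attention branch:
#' `y = x + nonlocal(x)`. Channels and spatial size are preserved.
#'
#' @inheritParams dsr_block
#' @param p Parameters from `block_params("nlr", ...)`.
#' @return Feature map with the same shape as `x`.
#' @export
nlr_block <- function(x, p) {
  xb <- as_feature_batch(x)
  drop_batch(nlr_fwd(xb, p)$y, x)
}

# ---- CLF ----

clf_fwd <- function(x, p) {
  cv <- conv_fwd(x, p$W, p$b, 1L, 1L)
  g <- gap_fwd(cv)
  probs <- softmax_rows(g$z)
  list(probs = probs, cache = list(x = x, gdim = g$d))
}

# dz: gradient w.r.t. the 3 logits (n x 3)
clf_bwd <- function(dz, cache, p) {
  dconv <- gap_bwd(dz, cache$gdim)
  cb <- conv_bwd(cache$x, p$W, dconv, 1L, 1L, has_bias = TRUE)
  list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
}

#' Classifier (CLF) block
#'
#' A 3x3 convolution to 3 channels (unit stride, zero padding), global
#' average pooling, and a softmax over the three quality classes.
#'
#' @inheritParams dsr_block
#' @param p Parameters from `block_params("clf", ...)`.
#' @return An `n x 3` matrix of class probabilities (one row per batch
#'   element), columns ordered pass/questionable/fail; each row sums to 1.
#' @export
clf_block <- function(x, p) {
  xb <- as_feature_batch(x)
  clf_fwd(xb, p)$probs
}

# ---- parameter utilities ----

bn_state_names <- c("mean", "var")

#' Count trainable parameters in a parameter list or model
#'
#' Batch-norm running statistics are excluded; gamma/beta scale-shift pairs
#' and all convolution/attention weights and biases are counted.
#'
#' @param p A parameter list from [block_params()], or a fitted/initialized
#'   `sqa_net` / `vqa_net` model.
#' @return Integer number of trainable parameters.
#' @export
param_count <- function(p) {
  if (inherits(p, c("sqa_net", "vqa_net"))) p <- p$params
  n <- 0L
  walk <- function(q) {
    for (nm in names(q)) {
      if (nm %in% bn_state_names) next
      if (is.list(q[[nm]])) walk(q[[nm]]) else n <<- n + length(q[[nm]])
    }
  }
  walk(p)
  n
}

# names of leaves subject to L2 regularization (conv/attention weights;
# biases and batch-norm parameters are excluded)
l2_leaf_names <- c("dw", "pw", "sc", "W", "Wphi", "Wpsi", "Wg", "reduce")

collect_l2_weights <- function(p) {
  out <- list()
  walk <- function(q, path = "") {
    for (nm in names(q)) {
      if (is.list(q[[nm]])) {
        walk(q[[nm]], paste0(path, nm, "."))
      } else if (nm %in% l2_leaf_names) {
        out[[paste0(path, nm)]] <<- q[[nm]]
      }
    }
  }
  walk(p)
  out
}

# add (lambda / n_w) * W to the matching gradient leaves
add_l2_grads <- function(g, p, lambda, n_w) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      g[[nm]] <- add_l2_grads(g[[nm]], p[[nm]], lambda, n_w)
    } else if (nm %in% l2_leaf_names) {
      g[[nm]] <- g[[nm]] + (lambda / n_w) * p[[nm]]
    }
  }
  g
}
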