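test_that("dsconv with delta depthwise kernels is a pointwise convolution", {
  set.seed(1)
  x <- array(runif(6 * 6 * 3), c(6, 6, 3))
  dw <- array(0, c(3, 3, 3)); dw[2, 2, ] <- 1   # centered delta
  pw <- array(rnorm(3 * 5), c(1, 1, 3, 5))
  y <- dsconv(x, dw, pw)
  # oracle: mix channels with the pointwise weights directly
  X <- matrix(x, 36, 3)
  Yref <- X %*% matrix(pw, 3, 5)
  expect_equal(matrix(y, 36, 5), Yref, tolerance = 1e-12)
})

test_that("dsconv parameter count follows its closed form", {
  expect_equal(dsconv_param_count(32, 64), 2336)     # 288 + 2048
  expect_equal(9 * 32 * 64, 18432)                   # full conv for contrast
  expect_equal(dsconv_param_count(8, 8, bias = TRUE), 72 + 64 + 8)
})

test_that("dsconv bias gives a constant map on zero input", {
  x <- array(0, c(4, 4, 2))
  dw <- array(rnorm(18), c(3, 3, 2))
  pw <- array(rnorm(2 * 3), c(1, 1, 2, 3))
  y <- dsconv(x, dw, pw, bias = c(1, -2, 0.5))
  expect_equal(unique(as.vector(y[, , 1])), 1)
  expect_equal(unique(as.vector(y[, , 2])), -2)
  expect_equal(unique(as.vector(y[, , 3])), 0.5)
})

test_that("nonlocal attention matches a naive double-loop oracle", {
  set.seed(2)
  for (rep in 1:5) {
    x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
    Wphi <- matrix(rnorm(2), 2, 1)
    Wpsi <- matrix(rnorm(2), 2, 1)
    Wg <- matrix(rnorm(4), 2, 2)
    res <- nonlocal_attention(x, Wphi, Wpsi, Wg, return_attention = TRUE)

    X <- matrix(x, 25, 2)
    ref <- matrix(0, 25, 2)
    for (i in 1:25) {
      f <- numeric(25)
      for (j in 1:25) {
        f[j] <- exp(sum((X[i, ] %*% Wphi) * (X[j, ] %*% Wpsi)))
      }
      wsum <- c(0, 0)
      for (j in 1:25) wsum <- wsum + f[j] * (X[j, ] %*% Wg)
      ref[i, ] <- wsum / sum(f)
    }
    expect_equal(matrix(res$y, 25, 2), ref, tolerance = 1e-5)
    expect_equal(rowSums(res$attention), rep(1, 25), tolerance = 1e-6)
  }
})

test_that("attention collapses to g under degenerate geometry", {
  # all positions share the same feature vector -> r_i = g(v) everywhere
  v <- c(0.3, -1.2)
  x <- array(rep(v, each = 16), c(4, 4, 2))
  Wg <- matrix(rnorm(4), 2, 2)
  y <- nonlocal_attention(x, matrix(rnorm(2)), matrix(rnorm(2)), Wg)
  gv <- as.vector(v %*% Wg)
  expect_equal(as.vector(y[2, 3, ]), gv, tolerance = 1e-10)

  # a single position -> r = g(x) regardless of phi and psi
  x1 <- array(c(1.5, -0.5), c(1, 1, 2))
  y1 <- nonlocal_attention(x1, matrix(rnorm(2) * 10),
                           matrix(rnorm(2) * 10), Wg)
  expect_equal(as.vector(y1), as.vector(c(1.5, -0.5) %*% Wg),
               tolerance = 1e-10)
})

test_that("the two-position scalar attention matches hand arithmetic", {
  x <- array(c(0, log(3)), c(2, 1, 1))
  I <- matrix(1, 1, 1)
  y <- nonlocal_attention(x, I, I, I)
  # from position 1: weights softmax(0, 0) = (1/2, 1/2)
  expect_equal(y[1, 1, 1], log(3) / 2, tolerance = 1e-10)
  # from position 2: weights softmax(0, log(3)^2)
  w2 <- exp(log(3)^2) / (1 + exp(log(3)^2))
  expect_equal(y[2, 1, 1], w2 * log(3), tolerance = 1e-10)
})

test_that("DSR blocks meet their shape contract and degenerate cases", {
  p <- block_params("dsr", 1, 4, seed = 1)
  x <- array(runif(16 * 16), c(16, 16, 1))
  y <- dsr_block(x, p)
  expect_equal(dim(y), c(8, 8, 4))

  # all-zero weights (inference mode, unit BN stats) give zero output
  p0 <- rapply(p, function(w) w * 0, how = "replace")
  p0$bn1$var <- p0$bn2$var <- rep(1, 4)
  expect_equal(dsr_block(x, p0), array(0, c(8, 8, 4)))

  expect_error(dsr_block(array(runif(15 * 15), c(15, 15, 1)), p), "even")
})

test_that("gradients flow through both DSR branches (finite differences)", {
  kern <- asNamespace("dmriqa")
  p <- block_params("dsr", 2, 3, seed = 2)
  x <- array(runif(8 * 8 * 2 * 1), c(8, 8, 2, 1))
  fw <- kern$dsr_fwd(x, p, training = TRUE)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- kern$dsr_bwd(dy, fw$cache, fw$p)
  # numeric gradient w.r.t. a few input pixels
  for (idx in c(1L, 37L, 100L)) {
    eps <- 1e-6
    xp <- x; xp[idx] <- xp[idx] + eps
    xm <- x; xm[idx] <- xm[idx] - eps
    lp <- sum(kern$dsr_fwd(xp, p, training = TRUE)$y * dy)
    lm <- sum(kern$dsr_fwd(xm, p, training = TRUE)$y * dy)
    expect_equal(bw$dx[idx], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("NLDR equals DSR plus a disabled nonlocal branch when g is zero", {
  p <- block_params("nldr", 2, 4, seed = 3)
  p$nl$Wg[] <- 0
  pd <- p[c("ds1", "bn1", "ds2", "bn2", "sc")]
  x <- array(runif(12 * 12 * 2), c(12, 12, 2))
  expect_equal(nldr_block(x, p), dsr_block(x, pd), tolerance = 1e-12)

  y <- nldr_block(array(runif(36 * 36 * 2), c(36, 36, 2)), p)
  expect_equal(dim(y), c(18, 18, 4))
})

test_that("NLDR output stays finite across random inputs", {
  p <- block_params("nldr", 2, 4, seed = 4)
  set.seed(4)
  for (i in 1:20) {
    y <- nldr_block(array(rnorm(8 * 8 * 2), c(8, 8, 2)), p)
    expect_true(all(is.finite(y)))
  }
})

test_that("NLR is an identity-shortcut around the nonlocal branch", {
  p <- block_params("nlr", 3, seed = 5)
  x <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  y <- nlr_block(x, p)
  expect_equal(dim(y), dim(x))
  branch <- nonlocal_attention(x, p$nl$Wphi, p$nl$Wpsi, p$nl$Wg)
  expect_equal(y - x, branch, tolerance = 1e-12)

  p$nl$Wg[] <- 0
  expect_equal(nlr_block(x, p), x, tolerance = 1e-12)
})

test_that("CLF produces shift-invariant probability triples", {
  p <- block_params("clf", 4, seed = 6)
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))

  p0 <- p; p0$W[] <- 0; p0$b <- rep(0, 3)
  expect_equal(as.vector(clf_block(x, p0)), rep(1 / 3, 3))

  pr <- clf_block(x, p)
  pshift <- p; pshift$b <- p$b + 5
  expect_equal(clf_block(x, pshift), pr, tolerance = 1e-12)

  set.seed(6)
  for (i in 1:20) {
    pi <- clf_block(array(rnorm(100), c(5, 5, 4)), p)
    expect_equal(sum(pi), 1, tolerance = 1e-9)
  }
})

test_that("block parameter counts match their closed forms", {
  cin <- 3L; cout <- 8L
  p <- block_params("dsr", cin, cout)
  expected <- dsconv_param_count(cin, cout) +      # ds1
    dsconv_param_count(cout, cout) +               # ds2
    2 * (2 * cout) +                               # bn gamma/beta
    cin * cout                                     # 1x1 shortcut
  expect_equal(param_count(p), expected)

  pn <- block_params("nlr", 8L)
  expect_equal(param_count(pn), 2 * 8 * 4 + 8 * 8)  # phi, psi, g

  pc <- block_params("clf", 8L)
  expect_equal(param_count(pc), 9 * 8 * 3 + 3)
})

test_that("SQA-Net obeys its shape trace and is deterministic", {
  spec <- tiny_spec()
  m <- sqa_net(spec, seed = 1)
  imgs <- replicate(3, make_phantom(32, seed = 8), simplify = FALSE)
  out1 <- sqa_forward(m, imgs)
  out2 <- sqa_forward(m, imgs)
  expect_equal(out1, out2)
  expect_equal(dim(out1$features), c(2, 2, 5, 3))
  expect_prob_rows(out1$probs)
  expect_error(sqa_forward(m, matrix(0, 64, 64)), "expected 32x32")
})

test_that("VQA-Net consumes ordered slice features", {
  spec <- tiny_spec(n_slices = 4L)
  sq <- sqa_net(spec, seed = 2)
  vq <- vqa_net(spec, seed = 2)
  imgs <- lapply(1:4, function(i) {
    corrupt_slice(make_phantom(32, seed = 3),
                  artifact_params(0.2 * i, seed = i))
  })
  fe <- sqa_forward(sq, imgs)$features
  out <- vqa_forward(vq, fe)
  expect_equal(nrow(out), 1)
  expect_prob_rows(out[, c("p_pass", "p_ques", "p_fail")])
  expect_true(out$pred %in% quality_levels())

  # single-slice volumes are valid
  spec1 <- tiny_spec(n_slices = 1L)
  vq1 <- vqa_net(spec1, seed = 2)
  out1 <- vqa_forward(vq1, fe[, , , 1, drop = FALSE])
  expect_prob_rows(out1[, c("p_pass", "p_ques", "p_fail")])

  # slice order is part of the contract: permuting slices changes the
  # concatenated input (equality of outputs is not guaranteed)
  perm <- fe[, , , c(3, 1, 4, 2)]
  expect_false(identical(fe, perm))

  expect_error(
    vqa_forward(vq, list(fe[, , , 1, drop = TRUE], array(0, c(3, 3, 5)))),
    "mismatched")
})

test_that("the desk-scale net masters a clean, well-separated slice set", {
  # 600 slices at 64x64, three cleanly separated severity bands
  make_clean <- function(n_per, seed) {
    withr::with_seed(seed, {
      sev <- c(runif(n_per, 0, 0.08), runif(n_per, 0.42, 0.5),
               runif(n_per, 0.88, 1))
      lab <- rep(quality_levels(), each = n_per)
      imgs <- lapply(seq_along(sev), function(i) {
        corrupt_slice(make_phantom(64, seed = seed * 1000L + i),
                      artifact_params(sev[i], seed = seed * 2000L + i))
      })
      tibble::tibble(slice_id = as.character(seq_along(sev)),
                     volume_id = "v", subject_id = "s",
                     slice_index = seq_along(sev), label = lab,
                     provenance = "given", p_pass = NA_real_,
                     p_ques = NA_real_, p_fail = NA_real_, severity = sev,
                     true_label = lab, image = imgs)
    })
  }
  tr <- make_clean(200, 11)
  cfg <- toy_train_config(epochs = 8L, augment = FALSE, seed = 11)
  m <- pretrain_sqa(tr, cfg)
  pr <- predict_slices(m, tr)
  train_acc <- mean(pr$pred == tr$label)
  expect_gte(train_acc, 0.95)
  # the confidence thresholds assume the training-accuracy regime > 0.85
  expect_gt(tail(m$history$acc, 1), 0.85)
})

test_that("full-chain training gradients match finite differences", {
  kern <- asNamespace("dmriqa")
  spec <- net_spec(16, channels = c(2L, 3L, 4L, 5L), n_slices = 2L)
  m <- sqa_net(spec, seed = 3)
  xb <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  t <- c(1L, 3L)
  lp <- loss_params(kappa = 2, lambda = 0, alpha = c(1, 1.5, 2))
  fw <- kern$sqa_fwd_full(m, xb, training = TRUE)
  dz <- kern$focal_grad_logits(fw$probs, t, lp$alpha, lp$kappa)
  bw <- kern$sqa_bwd_full(fw$model, fw$caches, dz)

  loss_of <- function(m2) {
    focal_loss(kern$sqa_fwd_full(m2, xb, training = TRUE)$probs, t, lp)
  }
  check <- function(path) {
    g <- bw$grads; for (nm in path) g <- g[[nm]]
    m2 <- m
    for (i in utils::head(seq_along(g), 2)) {
      eps <- 1e-5
      mp <- m; mp$params <- modify_leaf(m$params, path, i, eps)
      mm <- m; mm$params <- modify_leaf(m$params, path, i, -eps)
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = paste(paste(path, collapse = "$"), i))
    }
  }
  modify_leaf <- function(params, path, i, delta) {
    if (length(path) == 1) {
      params[[path]][i] <- params[[path]][i] + delta
      return(params)
    }
    params[[path[1]]] <- modify_leaf(params[[path[1]]], path[-1], i, delta)
    params
  }
  check(c("b1", "ds1", "dw"))
  check(c("b3", "nl", "Wphi"))
  check(c("b4", "ds2", "pw"))
  check(c("b2", "bn2", "gamma"))
  check(c("clf", "W"))
})
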