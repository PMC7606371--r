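# Primitive differentiable layers on batches stored as (h, w, c, n) arrays.
# Convolutions and pooling call the compiled kernels; everything here is
# vectorized R. Each *_fwd returns the output plus whatever the matching
# *_bwd needs.

as_feature_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4)
  x
}

conv_fwd <- function(x, W, bias = NULL, stride = 1L, pad = 0L) {
  conv2d_fwd_cpp(x, W, bias, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, W, dy, stride = 1L, pad = 0L, has_bias = FALSE) {
  conv2d_bwd_cpp(x, W, dy, as.integer(stride), as.integer(pad), has_bias)
}

# ---- batch normalization (per channel over batch and space) ----

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       mean = rep(0, c), var = rep(1, c))
}

bn_fwd <- function(x, p, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mo <- bn_moments_cpp(x)
    m <- mo$mean; v <- mo$var
    p$mean <- momentum * p$mean + (1 - momentum) * m
    p$var <- momentum * p$var + (1 - momentum) * v
  } else {
    m <- p$mean; v <- p$var
  }
  inv <- 1 / sqrt(v + eps)
  nr <- bn_norm_cpp(x, m, inv, p$gamma, p$beta)
  list(y = nr$y, p = p, cache = list(xhat = nr$xhat, inv = inv))
}

bn_bwd <- function(dy, cache, gamma) {
  bn_bwd_cpp(dy, cache$xhat, gamma, cache$inv)
}

# ---- ReLU ----

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(dy, mask) dy * mask

# ---- nonlocal attention ----

#' Nonlocal attention over all positions of a feature map
#'
#' Computes, at every spatial position `i`, the response
#' `r_i = (1 / C_i(x)) * sum_j f(x_i, x_j) g(x_j)` with embedded-Gaussian
#' weights `f(x_i, x_j) = exp(phi(x_i)' psi(x_j))` and normalizer
#' `C_i(x) = sum_j f(x_i, x_j)`, so the attention weights form a softmax
#' over positions `j` for each `i`. `phi`, `psi`, and `g` are linear maps
#' (1x1 convolutions) given by the weight matrices.
#'
#' @param x Feature map, `(h, w, c)` array (a matrix is treated as
#'   `c = 1`).
#' @param Wphi,Wpsi `c x c_e` embedding weights.
#' @param Wg `c x c_g` representation weights (`c_g = c` inside the
#'   residual blocks so the output can be added back to the input).
#' @param return_attention If `TRUE`, also return the `(hw x hw)`
#'   row-stochastic attention matrix.
#' @return `(h, w, c_g)` array, or a list with `y` and `attention`.
#' @export
nonlocal_attention <- function(x, Wphi, Wpsi, Wg,
                               return_attention = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3])
  fw <- nl_attend(X, Wphi, Wpsi, Wg)
  y <- array(fw$R, c(d[1], d[2], ncol(Wg)))
  if (return_attention) list(y = y, attention = fw$A) else y
}

row_max <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

# core attention on a positions-by-channels matrix
nl_attend <- function(X, Wphi, Wpsi, Wg) {
  Phi <- X %*% Wphi
  Psi <- X %*% Wpsi
  G <- X %*% Wg
  S <- tcrossprod(Phi, Psi)
  S <- S - row_max(S)  # row-wise shift for stable softmax
  A <- exp(S)
  A <- A / rowSums(A)
  list(R = A %*% G, A = A, Phi = Phi, Psi = Psi, G = G, X = X)
}

nl_init <- function(c) {
  ce <- max(c %/% 2L, 1L)
  list(Wphi = he_mat(c, ce), Wpsi = he_mat(c, ce), Wg = he_mat(c, c))
}

# batch forward: x (h, w, c, n) -> r (h, w, c, n). The three 1x1
# projections run as one GEMM over all samples; the attention itself is
# per sample.
nl_fwd <- function(x, p) {
  d <- dim(x); hw <- d[1] * d[2]; c <- d[3]; n <- d[4]
  Xall <- matrix(aperm(x, c(1, 2, 4, 3)), hw * n, c)
  Phi <- Xall %*% p$Wphi
  Psi <- Xall %*% p$Wpsi
  G <- Xall %*% p$Wg
  y <- array(0, d)
  caches <- vector("list", n)
  # aperm(c(1,2,4,3)) gives dims (h, w, n, c): row = i + h*(j-1) + hw*(s-1)
  for (s in seq_len(n)) {
    rows <- seq.int((s - 1) * hw + 1, s * hw)
    As <- tcrossprod(Phi[rows, , drop = FALSE], Psi[rows, , drop = FALSE])
    As <- exp(As - row_max(As))
    As <- As / rowSums(As)
    y[, , , s] <- As %*% G[rows, , drop = FALSE]
    caches[[s]] <- As
  }
  list(y = y,
       cache = list(A = caches, Xall = Xall, Phi = Phi, Psi = Psi, G = G,
                    d = d))
}

nl_bwd <- function(dy, cache, p) {
  d <- cache$d; hw <- d[1] * d[2]; c <- d[3]; n <- d[4]
  dPhi <- matrix(0, hw * n, ncol(p$Wphi))
  dPsi <- matrix(0, hw * n, ncol(p$Wpsi))
  dG <- matrix(0, hw * n, ncol(p$Wg))
  for (s in seq_len(n)) {
    rows <- seq.int((s - 1) * hw + 1, s * hw)
    A <- cache$A[[s]]
    dR <- matrix(dy[, , , s], hw, c)
    Gs <- cache$G[rows, , drop = FALSE]
    dA <- tcrossprod(dR, Gs)
    dG[rows, ] <- crossprod(A, dR)
    rs <- rowSums(A * dA)
    dS <- A * (dA - rs)
    dPhi[rows, ] <- dS %*% cache$Psi[rows, , drop = FALSE]
    dPsi[rows, ] <- crossprod(dS, cache$Phi[rows, , drop = FALSE])
  }
  dXall <- tcrossprod(dPhi, p$Wphi) + tcrossprod(dPsi, p$Wpsi) +
    tcrossprod(dG, p$Wg)
  dx <- aperm(array(dXall, c(d[1], d[2], n, c)), c(1, 2, 4, 3))
  list(dx = dx,
       grads = list(Wphi = crossprod(cache$Xall, dPhi),
                    Wpsi = crossprod(cache$Xall, dPsi),
                    Wg = crossprod(cache$Xall, dG)))
}

# ---- global average pooling and softmax ----

gap_fwd <- function(x) {
  d <- dim(x); hw <- d[1] * d[2]
  z <- t(matrix(.colMeans(x, hw, d[3] * d[4]), d[3], d[4]))  # n x c
  list(z = z, d = d)
}

gap_bwd <- function(dz, d) {
  hw <- d[1] * d[2]
  # dz is n x c; expand each entry uniformly over its spatial positions
  dx <- array(0, d)
  for (s in seq_len(d[4])) {
    dx[, , , s] <- rep(dz[s, ] / hw, each = hw)
  }
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- initializers ----

he_mat <- function(cin, cout) {
  matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
}

he_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

he_dw <- function(kh, kw, c) {
  array(rnorm(kh * kw * c, sd = sqrt(2 / (kh * kw))), c(kh, kw, c))
}
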