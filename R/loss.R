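#' Class-balancing weights from per-class sample counts
#'
#' `alpha_t = max(N_1, N_2, N_3) / N_t`, so the largest class gets weight 1
#' and rarer classes are up-weighted in proportion to their deficit. Counts
#' are per stage: slice counts when training the slice network, volume
#' counts when training the volume network.
#'
#' @param N Length-3 vector of per-class counts (pass, questionable, fail),
#'   all `>= 1`.
#' @return Length-3 numeric vector of weights.
#' @export
#' @examples
#' class_weights(c(85, 25, 40))  # the cohort's training volume counts
class_weights <- function(N) {
  stopifnot(length(N) == 3)
  if (any(N < 1)) abort("empty class: every class needs at least one sample")
  max(N) / N
}

#' Focal-loss parameters
#'
#' @param kappa Focusing exponent `>= 0`; 0 recovers weighted cross-entropy.
#'   The default 2 is the conventional focusing strength.
#' @param lambda L2 coefficient (default 0.01).
#' @param alpha Length-3 class weights (default all 1); see
#'   [class_weights()].
#' @return A list of class `loss_params`.
#' @export
loss_params <- function(kappa = 2, lambda = 0.01, alpha = c(1, 1, 1)) {
  stopifnot(kappa >= 0, lambda >= 0, length(alpha) == 3, all(alpha > 0))
  structure(list(kappa = kappa, lambda = lambda, alpha = alpha),
            class = "loss_params")
}

#' Class-balanced focal loss with L2 regularization
#'
#' `L = -alpha_t (1 - p_t)^kappa log(p_t) + lambda / (2 n_w) * sum_w
#' ||W_w||^2`, averaged over samples. `p_t` is the predicted probability of
#' the true class; probabilities of exactly 0 are clamped to `1e-7` (with a
#' warning) rather than raising an error. The regularizer runs over the
#' supplied weight matrices (`n_w` of them); batch-norm parameters and
#' biases are not regularized.
#'
#' @param p Probability matrix (`n x 3`) or a single length-3 probability
#'   vector.
#' @param true_class Integer class indices in 1..3, or quality labels.
#' @param params A [loss_params()].
#' @param weights Optional list of weight arrays for the L2 term (e.g.
#'   `collect_l2_weights(model$params)` internally, or any list of
#'   matrices).
#' @return Scalar loss value.
#' @export
#' @examples
#' focal_loss(c(0.5, 0.3, 0.2), 1, loss_params(kappa = 0, lambda = 0))
focal_loss <- function(p, true_class, params = loss_params(),
                       weights = NULL) {
  if (is.vector(p) && is.numeric(p)) p <- matrix(p, 1)
  if (is.character(true_class) || is.factor(true_class)) {
    true_class <- label_to_class(true_class)
  }
  stopifnot(ncol(p) == 3, length(true_class) == nrow(p),
            all(true_class %in% 1:3))
  pt <- p[cbind(seq_len(nrow(p)), true_class)]
  if (any(pt <= 0)) {
    warn("clamping zero probabilities to 1e-7 in focal loss")
    pt <- pmax(pt, 1e-7)
  }
  at <- params$alpha[true_class]
  data_term <- mean(-at * (1 - pt)^params$kappa * log(pt))
  data_term + l2_penalty(weights, params$lambda)
}

#' L2 weight penalty
#'
#' `lambda / (2 n_w)` times the total sum of squared entries over the
#' `n_w` supplied weight arrays.
#'
#' @param weights List of numeric arrays (possibly empty or `NULL`).
#' @param lambda L2 coefficient.
#' @return Scalar penalty.
#' @export
l2_penalty <- function(weights, lambda) {
  if (is.null(weights) || length(weights) == 0 || lambda == 0) return(0)
  n_w <- length(weights)
  lambda / (2 * n_w) * sum(vapply(weights, function(w) sum(w^2), 0))
}

# gradient of the mean focal data term w.r.t. the 3 logits per sample
focal_grad_logits <- function(p, true_class, alpha, kappa) {
  n <- nrow(p)
  pt <- pmax(p[cbind(seq_len(n), true_class)], 1e-7)
  at <- alpha[true_class]
  u <- 1 - pt
  # dL/dp_t; the kappa * u^(kappa-1) term vanishes identically at kappa = 0
  dldpt <- if (kappa == 0) {
    -at / pt
  } else {
    at * kappa * u^(kappa - 1) * log(pt) - at * u^kappa / pt
  }
  onehot <- matrix(0, n, 3)
  onehot[cbind(seq_len(n), true_class)] <- 1
  dz <- (dldpt * pt) * (onehot - p)
  dz / n
}
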