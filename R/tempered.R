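#' Tempered logarithm
#'
#' `log_t(x) = (x^(1-t) - 1) / (1 - t)` for `t != 1`, converging to
#' `log(x)` as `t -> 1`. Controls how heavily the loss penalizes small
#' predicted probabilities: `t < 1` bounds the penalty, making training
#' robust to mislabeled targets.
#'
#' @param x positive numeric vector.
#' @param t temperature.
#' @return numeric vector, `log_t(1) = 0` for any `t`.
#' @export
log_t <- function(x, t) {
  if (t == 1) log(x) else (x^(1 - t) - 1) / (1 - t)
}

#' Tempered exponential
#'
#' Inverse of [log_t()]: `exp_t(x) = [1 + (1-t) x]_+ ^ (1/(1-t))` for
#' `t != 1` and `e^x` for `t = 1`. For `t > 1` the function has a heavier
#' tail than the exponential, which gives the tempered softmax bounded
#' influence of extreme logits.
#'
#' @param x numeric vector.
#' @param t temperature.
#' @return non-negative numeric vector; `exp_t(0) = 1`.
#' @export
exp_t <- function(x, t) {
  if (t == 1) return(exp(x))
  base <- 1 + (1 - t) * x
  if (t > 1) {
    # base <= 0 corresponds to the pole x >= 1/(t-1)
    ifelse(base > 0, base^(1 / (1 - t)), Inf)
  } else {
    pmax(base, 0)^(1 / (1 - t))
  }
}

#' Tempered softmax activation
#'
#' Maps a logit vector to probabilities via
#' `y_i = exp_t2(a_i - lambda(a))`, with the normalizer `lambda(a)` chosen
#' so the outputs sum to one. `t2 = 1` recovers the ordinary softmax. The
#' normalizer is found by bisection on the monotone map
#' `lambda -> sum(exp_t2(a - lambda))`, bracketed analytically, to the
#' requested tolerance.
#'
#' @param logits numeric vector, or a matrix of row-wise logit vectors.
#' @param t2 temperature, `>= 1`.
#' @param tol tolerance on `|sum - 1|` (default 1e-9).
#' @param max_iter maximum bisection iterations.
#' @return probabilities of the same shape as `logits`; rows sum to 1.
#' @export
tempered_softmax <- function(logits, t2, tol = 1e-9, max_iter = 200L) {
  vec <- is.null(dim(logits))
  A <- if (vec) matrix(logits, 1) else as.matrix(logits)
  if (any(!is.finite(A))) stop("logits must be finite")
  if (t2 < 1) stop("t2 must be >= 1")
  N <- ncol(A)
  if (t2 == 1) {
    Z <- exp(A - apply(A, 1, max))
    Y <- Z / rowSums(Z)
    return(if (vec) drop(Y) else Y)
  }
  # bracketing: at lambda = max(a), sum >= 1 (the max term is 1);
  # at lambda = max(a) + (N^(t2-1) - 1)/(t2-1), every term <= 1/N.
  lo <- apply(A, 1, max)
  hi <- lo + (N^(t2 - 1) - 1) / (t2 - 1)
  f <- function(lam) rowSums(exp_t(A - lam, t2)) - 1
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    up <- v > 0            # sum too big -> raise lambda
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(abs(v)) < tol && max(hi - lo) < 1e-12) break
  }
  lam <- (lo + hi) / 2
  if (max(abs(f(lam))) > sqrt(tol))
    stop(sprintf("tempered_softmax normalizer failed to converge (residual %.3g)",
                 max(abs(f(lam)))))
  Y <- exp_t(A - lam, t2)
  Y <- Y / rowSums(Y)      # remove residual bisection error
  if (vec) drop(Y) else Y
}

#' Bi-tempered logistic loss
#'
#' Robust two-temperature generalization of softmax cross-entropy:
#' per class, `y (log_t1 y - log_t1 yhat) - (y^(2-t1) - yhat^(2-t1))/(2-t1)`,
#' summed over classes. At `t1 = t2 = 1` (with [tempered_softmax()]
#' predictions) this is exactly the KL divergence with softmax activation.
#' Used with the sharpened cluster-assignment target distribution as `y`.
#'
#' @param target probability vector (or matrix of row-wise distributions).
#' @param predicted probability vector/matrix of the same shape.
#' @param t1 temperature in `(0, 1]`.
#' @return non-negative loss, one value per row; 0 iff `target == predicted`.
#' @export
bitempered_loss <- function(target, predicted, t1) {
  if (t1 <= 0 || t1 > 1) stop("t1 must be in (0, 1]")
  vec <- is.null(dim(target))
  Y <- if (vec) matrix(target, 1) else as.matrix(target)
  Yh <- if (vec) matrix(predicted, 1) else as.matrix(predicted)
  if (!all(dim(Y) == dim(Yh))) stop("target/predicted shape mismatch")
  ylogy <- Y * log_t(pmax(Y, 1e-300), t1)    # y log_t y, with 0 log 0 = 0
  ylogy[Y == 0] <- 0
  ylogyh <- Y * log_t(pmax(Yh, 1e-300), t1)
  ylogyh[Y == 0 & t1 == 1] <- 0
  term <- ylogy - ylogyh - (Y^(2 - t1) - Yh^(2 - t1)) / (2 - t1)
  out <- rowSums(term)
  if (vec) drop(out) else out
}

#' Gradient of the bi-tempered loss with respect to the logits
#'
#' Closed-form chain rule through the tempered softmax:
#' with `h_j = yhat_j^(1 - t1 + t2) - y_j yhat_j^(t2 - t1)`,
#' `dL/da_k = h_k - yhat_k^t2 * sum(h) / sum(yhat^t2)`.
#'
#' @param target,predicted row-wise probability matrices.
#' @param t1,t2 temperatures.
#' @return matrix of the same shape as `predicted`.
#' @keywords internal
bitempered_grad_logits <- function(target, predicted, t1, t2) {
  Y <- as.matrix(target); Yh <- as.matrix(predicted)
  H <- Yh^(1 - t1 + t2) - Y * Yh^(t2 - t1)
  Wt <- Yh^t2
  H - Wt * (rowSums(H) / rowSums(Wt))
}

#' Center loss
#'
#' Half the summed squared distance of each feature vector to the centroid
#' of its own cluster, `L_c = 1/2 sum_j ||x_j - c_{label(j)}||^2`. Shrinks
#' intra-cluster variation of the learned representation; its gradient with
#' respect to the features is simply `x_j - c_{label(j)}` (centroids are
#' treated as constants within a training epoch).
#'
#' @param features numeric matrix, one row per sample.
#' @param labels cluster id per row.
#' @param centroids optional matrix of per-cluster centroids with rownames
#'   equal to cluster ids; recomputed from `features`/`labels` when absent.
#' @return scalar loss (attribute `grad` holds the per-feature gradient).
#' @export
center_loss <- function(features, labels, centroids = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (is.null(centroids)) {
    centroids <- rowsum(features, labels) / as.vector(table(labels)[sort(unique(labels))])
  }
  diff <- features - centroids[labels, , drop = FALSE]
  loss <- 0.5 * sum(diff^2)
  attr(loss, "grad") <- diff
  loss
}
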