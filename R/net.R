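#' Network configuration
#'
#' Describes the 3-layer convolutional feature extractor and its training
#' head. Each stage is conv -> ReLU -> batch norm -> 2x2 max pool; the last
#' pooling output is flattened into the spatial representation and a single
#' fully connected layer of width `n_clusters` produces the training
#' logits. Defaults target 48 x 48 expression images; for larger grids
#' (e.g. 85 x 85) a bigger `kernel_size` shrinks the output.
#'
#' @param input_shape `c(H, W)` of the gene images.
#' @param n_filters filters per convolutional layer.
#' @param kernel_size odd kernel width (same padding).
#' @param pool_size max-pooling width/stride.
#' @param n_clusters width of the classifier head = number of training
#'   clusters.
#' @param t1,t2 temperatures of the bi-tempered loss (`t1` in (0,1],
#'   `t2 >= 1`).
#' @param center_loss_weight weight of the optional center loss (0 = off).
#' @param seed seed used for weight initialization.
#' @return an object of class `net_config`.
#' @export
net_config <- function(input_shape = c(48L, 48L), n_filters = c(8L, 16L, 32L),
                       kernel_size = 3L, pool_size = 2L, n_clusters = 30L,
                       t1 = 0.8, t2 = 1.2, center_loss_weight = 0,
                       seed = 1L) {
  if (t1 <= 0 || t1 > 1) stop("t1 must be in (0, 1]")
  if (t2 < 1) stop("t2 must be >= 1")
  if (length(n_filters) != 3L) stop("three convolutional layers are required")
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd (same padding)")
  if (center_loss_weight < 0) stop("center_loss_weight must be >= 0")
  h <- input_shape[1]; w <- input_shape[2]
  for (l in 1:3) { h <- h %/% pool_size; w <- w %/% pool_size }
  if (h < 1L || w < 1L) stop("input too small for three pooling stages")
  structure(list(input_shape = as.integer(input_shape),
                 n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 n_clusters = as.integer(n_clusters),
                 t1 = t1, t2 = t2,
                 center_loss_weight = center_loss_weight,
                 feature_dim = as.integer(h * w * n_filters[3]),
                 out_shape = c(h, w),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("net_config: %dx%d input, filters (%s) k=%d, %d-dim features, head width %d\n",
              x$input_shape[1], x$input_shape[2],
              paste(x$n_filters, collapse = ","), x$kernel_size,
              x$feature_dim, x$n_clusters))
  cat(sprintf("  t1=%.2f t2=%.2f center_loss_weight=%.2f seed=%d\n",
              x$t1, x$t2, x$center_loss_weight, x$seed))
  invisible(x)
}

xavier_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize the convolutional network
#'
#' All convolutional and fully connected weights are drawn from a Xavier
#' uniform distribution under the config seed; batch-norm scale/shift start
#' at 1/0 and running statistics at 0/1. Identical seeds give bit-identical
#' parameters.
#'
#' @param config a [net_config()].
#' @return an object of class `conv_net` (feature extractor + classifier
#'   head).
#' @export
init_network <- function(config) {
  stopifnot(inherits(config, "net_config"))
  set.seed(config$seed)
  k2 <- config$kernel_size^2
  chans <- c(1L, config$n_filters)
  params <- list()
  for (l in 1:3) {
    cin <- chans[l]; cout <- chans[l + 1]
    params[[paste0("W", l)]] <- xavier_uniform(k2 * cin, cout,
                                               fan_in = k2 * cin,
                                               fan_out = k2 * cout)
    params[[paste0("b", l)]] <- numeric(cout)
    params[[paste0("gamma", l)]] <- rep(1, cout)
    params[[paste0("beta", l)]] <- numeric(cout)
  }
  params$Wfc <- xavier_uniform(config$feature_dim, config$n_clusters,
                               fan_in = config$feature_dim,
                               fan_out = config$n_clusters)
  params$bfc <- numeric(config$n_clusters)
  running <- list()
  for (l in 1:3) {
    running[[paste0("mean", l)]] <- numeric(config$n_filters[l])
    running[[paste0("var", l)]] <- rep(1, config$n_filters[l])
  }
  structure(list(config = config, params = params, running = running,
                 bn_momentum = 0.1, bn_eps = 1e-5),
            class = "conv_net")
}

#' @export
print.conv_net <- function(x, ...) {
  cat("conv_net with", length(unlist(x$params)), "parameters\n")
  print(x$config)
  invisible(x)
}

# ---- array helpers: activations are stored (H, W, B, C) -------------------

# im2col: patches of a zero-padded (H, W, B, C) array as an
# (H*W*B) x (k*k*C) matrix; column order is (offset-major, channel-minor).
# One block copy per kernel offset (all channels at once) keeps the R
# subscript overhead negligible next to the BLAS matmul that follows.
im2col <- function(A, k) {
  d <- dim(A); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  p <- (k - 1L) %/% 2L
  Ap <- array(0, dim = c(H + 2L * p, W + 2L * p, B, C))
  Ap[p + seq_len(H), p + seq_len(W), , ] <- A
  P <- matrix(0, H * W * B, k * k * C)
  o <- 0L
  for (dy in seq_len(k) - 1L) for (dx in seq_len(k) - 1L) {
    s <- Ap[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE]
    P[, o * C + seq_len(C)] <- s
    o <- o + 1L
  }
  P
}

# col2im: scatter-add the patch-gradient matrix back to input shape
col2im <- function(dP, H, W, B, C, k) {
  p <- (k - 1L) %/% 2L
  dAp <- array(0, dim = c(H + 2L * p, W + 2L * p, B, C))
  o <- 0L
  for (dy in seq_len(k) - 1L) for (dx in seq_len(k) - 1L) {
    blk <- dP[, o * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(H, W, B, C)
    dAp[dy + seq_len(H), dx + seq_len(W), , ] <-
      dAp[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE] + blk
    o <- o + 1L
  }
  dAp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

maxpool_forward <- function(A, s) {
  d <- dim(A); Ho <- d[1] %/% s; Wo <- d[2] %/% s
  ri <- seq_len(Ho * s); ci <- seq_len(Wo * s)
  Ac <- A[ri, ci, , , drop = FALSE]
  slices <- vector("list", s * s)
  idx <- 0L
  for (dy in seq_len(s) - 1L) for (dx in seq_len(s) - 1L) {
    idx <- idx + 1L
    slices[[idx]] <- Ac[seq(1L + dy, Ho * s, by = s), seq(1L + dx, Wo * s, by = s), , ,
                        drop = FALSE]
  }
  out <- slices[[1]]
  for (i in 2:(s * s)) out <- pmax(out, slices[[i]])
  list(out = out, slices = slices, in_dim = d)
}

maxpool_backward <- function(cache, dOut, s) {
  d <- cache$in_dim
  Ho <- d[1] %/% s; Wo <- d[2] %/% s
  dA <- array(0, dim = d)
  taken <- array(FALSE, dim = dim(dOut))
  out <- cache$slices[[1]]
  for (i in 2:(s * s)) out <- pmax(out, cache$slices[[i]])
  idx <- 0L
  for (dy in seq_len(s) - 1L) for (dx in seq_len(s) - 1L) {
    idx <- idx + 1L
    hit <- (cache$slices[[idx]] == out) & !taken     # ties go to the first slice
    taken <- taken | hit
    dA[seq(1L + dy, Ho * s, by = s), seq(1L + dx, Wo * s, by = s), , ] <-
      hit * dOut
  }
  dA
}

# column-wise scale / shift without sweep() (whose aperm dominates at these
# sizes): X * diag(a) runs in BLAS, rank-one shifts via tcrossprod.
cscale <- function(M, a) M %*% diag(a, length(a))
cshift <- function(M, b) M + tcrossprod(rep.int(1, nrow(M)), b)

# batch norm over the channel axis of an (H, W, B, C) array
bn_forward <- function(A, gamma, beta, rmean, rvar, eps, train) {
  d <- dim(A)
  M <- A; dim(M) <- c(prod(d[1:3]), d[4])
  if (train) {
    mu <- colMeans(M)
    xc <- cshift(M, -mu)
    v <- colMeans(xc^2)
  } else {
    mu <- rmean; v <- rvar
    xc <- cshift(M, -mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- cscale(xc, inv)
  out <- cshift(cscale(xhat, gamma), beta)
  dim(out) <- d
  list(out = out, xhat = xhat, inv = inv, mu = mu, v = v)
}

bn_backward <- function(cache, dOut, gamma) {
  d <- dim(dOut)
  dM <- dOut; dim(dM) <- c(prod(d[1:3]), d[4])
  n <- nrow(dM)
  dgamma <- colSums(dM * cache$xhat)
  dbeta <- colSums(dM)
  dxhat <- cscale(dM, gamma)
  dx <- cscale(cshift(dxhat, -colMeans(dxhat)) -
                 cscale(cache$xhat, colMeans(dxhat * cache$xhat)),
               cache$inv)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# full forward pass; input X is a (B x H*W) row-major matrix of images.
# The compiled path is used throughout; the `_ref` functions below are the
# plain-R reference implementation kept for equivalence testing.
net_forward <- function(net, X, train = FALSE, with_head = TRUE) {
  cfg <- net$config
  cpp_net_forward(X, net$params, net$running, cfg$input_shape, cfg$n_filters,
                  cfg$kernel_size, cfg$pool_size, train, with_head,
                  net$bn_eps, net$bn_momentum)
}

net_backward <- function(net, fwd, dLogits = NULL, dFeatures = NULL) {
  if (is.null(fwd$cache_ptr))
    stop("backward pass requires a training-mode forward pass")
  cfg <- net$config
  cpp_net_backward(fwd$cache_ptr, net$params, dLogits, dFeatures,
                   cfg$kernel_size, cfg$pool_size)
}

net_forward_ref <- function(net, X, train = FALSE, with_head = TRUE) {
  cfg <- net$config; p <- net$params
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]; B <- nrow(X)
  k <- cfg$kernel_size; s <- cfg$pool_size
  A <- t(X)                                   # (H*W) x B, row-major pixels
  dim(A) <- c(W, H, B)                        # row-major: col index fastest
  A <- aperm(A, c(2, 1, 3))
  dim(A) <- c(H, W, B, 1L)
  cache <- list(B = B)
  for (l in 1:3) {
    d <- dim(A)
    P <- im2col(A, k)
    Z <- cshift(P %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    dim(Z) <- c(d[1], d[2], d[3], ncol(Z))
    R <- Z * (Z > 0)
    bn <- bn_forward(R, p[[paste0("gamma", l)]], p[[paste0("beta", l)]],
                     net$running[[paste0("mean", l)]],
                     net$running[[paste0("var", l)]], net$bn_eps, train)
    pl <- maxpool_forward(bn$out, s)
    cache[[paste0("l", l)]] <- list(in_dim = d, P = P, relu_mask = (Z > 0),
                                    bn = bn, pool = pl)
    A <- pl$out
  }
  d <- dim(A)                                  # (h, w, B, C)
  Fm <- aperm(A, c(3, 1, 2, 4))
  dim(Fm) <- c(B, prod(d[c(1, 2, 4)]))         # flattened features, B x D
  cache$feat_dim <- d
  out <- list(features = Fm, cache = cache)
  if (with_head) out$logits <- cshift(Fm %*% p$Wfc, p$bfc)
  out
}

# backward pass; dLogits (B x N) and optionally dFeatures (B x D) are the
# gradients flowing into the head and the flattened features.
net_backward_ref <- function(net, fwd, dLogits = NULL, dFeatures = NULL) {
  cfg <- net$config; p <- net$params
  k <- cfg$kernel_size; s <- cfg$pool_size
  grads <- list()
  dF <- if (is.null(dFeatures)) 0 else dFeatures
  if (!is.null(dLogits)) {
    grads$Wfc <- crossprod(fwd$features, dLogits)
    grads$bfc <- colSums(dLogits)
    dF <- dF + dLogits %*% t(p$Wfc)
  }
  d <- fwd$cache$feat_dim
  dA <- dF
  dim(dA) <- c(fwd$cache$B, d[1], d[2], d[4])
  dA <- aperm(dA, c(2, 3, 1, 4))
  for (l in 3:1) {
    cl <- fwd$cache[[paste0("l", l)]]
    dBN <- maxpool_backward(cl$pool, dA, s)
    bb <- bn_backward(cl$bn, dBN, p[[paste0("gamma", l)]])
    grads[[paste0("gamma", l)]] <- bb$dgamma
    grads[[paste0("beta", l)]] <- bb$dbeta
    dZ <- bb$dx * cl$relu_mask
    dim(dZ) <- c(prod(cl$in_dim[1:3]), ncol(p[[paste0("W", l)]]))
    grads[[paste0("W", l)]] <- crossprod(cl$P, dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1) {
      dP <- dZ %*% t(p[[paste0("W", l)]])
      dA <- col2im(dP, cl$in_dim[1], cl$in_dim[2], cl$in_dim[3], cl$in_dim[4], k)
    }
  }
  grads
}

# update batch-norm running statistics from a training forward pass
net_update_running <- function(net, fwd) {
  if (!is.null(fwd$running)) {           # compiled path returns them directly
    net$running <- fwd$running
    return(net)
  }
  m <- net$bn_momentum
  for (l in 1:3) {
    bn <- fwd$cache[[paste0("l", l)]]$bn
    net$running[[paste0("mean", l)]] <-
      (1 - m) * net$running[[paste0("mean", l)]] + m * bn$mu
    net$running[[paste0("var", l)]] <-
      (1 - m) * net$running[[paste0("var", l)]] + m * bn$v
  }
  net
}

#' Extract spatial representations from a stack
#'
#' Forwards every gene image through the (trained or untrained) network in
#' evaluation mode (batch-norm running statistics, no batch dependence) and
#' returns the flattened, L2-normalized output of the last max-pooling
#' layer: one unit-norm feature row per gene.
#'
#' @param net a `conv_net`.
#' @param stack a `gene_image_stack` whose grid matches the net config.
#' @param batch_size forward batch size (memory knob only).
#' @return a `G x D` feature matrix with genes as rownames.
#' @export
extract_features <- function(net, stack, batch_size = 128L) {
  stopifnot(inherits(net, "conv_net"), inherits(stack, "gene_image_stack"))
  if (!all(stack_dim(stack) == net$config$input_shape))
    stop("stack grid does not match the network input shape")
  X <- stack_matrix(stack)
  G <- nrow(X)
  out <- matrix(0, G, net$config$feature_dim, dimnames = list(stack$genes, NULL))
  for (start in seq(1L, G, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, G)
    fw <- net_forward(net, X[idx, , drop = FALSE], train = FALSE, with_head = FALSE)
    out[idx, ] <- fw$features
  }
  nrm <- sqrt(rowSums(out^2))
  nrm[nrm == 0] <- 1
  out / nrm
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the parameters, batch-norm running
#' statistics and the full configuration (also embedded as JSON for
#' inspection outside R).
#'
#' @param net a `conv_net`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the net.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "conv_net"))
  obj <- unclass(net)
  obj$config_json <- jsonlite::toJSON(unclass(net$config), auto_unbox = TRUE,
                                      digits = NA)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  obj$config_json <- NULL
  obj$config <- structure(obj$config, class = "net_config")
  structure(obj, class = "conv_net")
}
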