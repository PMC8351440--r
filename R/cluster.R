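# Exact k-nearest-neighbour search via BLAS cross-products. Returns the
# uwot-style precomputed-neighbour list (self included as first neighbour).
exact_knn <- function(X, k) {
  G <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  idx <- matrix(0L, G, k + 1L)
  dst <- matrix(0, G, k + 1L)
  for (i in seq_len(G)) {
    o <- order(D2[i, ])[seq_len(k + 1L)]
    o <- c(i, setdiff(o, i))[seq_len(k + 1L)]   # ensure self first
    idx[i, ] <- o
    dst[i, ] <- sqrt(D2[i, o])
  }
  dst[, 1] <- 0
  list(idx = idx, dist = dst)
}

#' UMAP embedding of the spatial representations
#'
#' Reduces the L2-normalized feature matrix to `n_components` dimensions
#' with UMAP (`n_neighbors = 20`, `min_dist = 0` by default) before mixture
#' clustering. Neighbours are found exactly (BLAS distance matrix) rather
#' than by an approximate index, which keeps the embedding deterministic
#' under a fixed seed.
#'
#' @param features `G x D` feature matrix.
#' @param n_components embedding dimensionality (default 30).
#' @param seed integer seed.
#' @param n_neighbors,min_dist UMAP graph/layout parameters.
#' @param n_epochs UMAP layout optimization epochs.
#' @return a `G x n_components` embedding matrix (genes as rownames).
#' @export
embed <- function(features, n_components = 30L, seed = 1L,
                  n_neighbors = 20L, min_dist = 0, n_epochs = 150L) {
  features <- as.matrix(features)
  G <- nrow(features)
  if (G <= n_components)
    stop("need more samples than embedding components")
  rng <- apply(features, 2, function(col) diff(range(col)))
  if (all(rng < 1e-12)) stop("degenerate input: all feature rows identical")
  k <- min(n_neighbors, G - 1L)
  nn <- exact_knn(features, k)
  set.seed(seed)
  E <- tryCatch(
    uwot::umap(features, nn_method = nn, n_components = n_components,
               min_dist = min_dist, n_epochs = n_epochs,
               init = "spca", n_threads = 1, n_sgd_threads = 0,
               verbose = FALSE),
    error = function(e) {
      # scaled-PCA init fails when the input has rank < n_components
      # (e.g. many duplicate rows); fall back to a seeded random layout
      set.seed(seed)
      uwot::umap(features, nn_method = nn, n_components = n_components,
                 min_dist = min_dist, n_epochs = n_epochs,
                 init = "rand", n_threads = 1, n_sgd_threads = 0,
                 verbose = FALSE)
    })
  rownames(E) <- rownames(features)
  E
}

#' Gaussian mixture clustering of an embedding
#'
#' Fits a full-covariance Gaussian mixture with `n_clusters` components to
#' the embedding (k-means initialization, regularizing conjugate prior, EM
#' to convergence) and returns the maximum-a-posteriori labels. Components
#' may end up empty; such clusters simply contribute no labels.
#'
#' @param embedding `G x d` matrix.
#' @param n_clusters number of mixture components (default 30).
#' @param seed integer seed (k-means initialization).
#' @param max_iter EM iteration cap.
#' @return integer labels in `1..n_clusters`.
#' @export
cluster_gmm <- function(embedding, n_clusters = 30L, seed = 1L,
                        max_iter = 100L) {
  embedding <- as.matrix(embedding)
  G <- nrow(embedding)
  if (n_clusters > G) stop("n_clusters exceeds the number of samples")
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(embedding, centers = n_clusters, nstart = 3L, iter.max = 50L),
    error = function(e) NULL)
  init <- if (is.null(km)) {
    # degenerate data (duplicate rows): fall back to a random balanced init
    sample(rep_len(seq_len(n_clusters), G))
  } else km$cluster
  z0 <- mclust::unmap(init, groups = seq_len(n_clusters))
  fit <- tryCatch(
    mclust::me(data = embedding, modelName = "VVV", z = z0,
               prior = mclust::priorControl(),
               control = mclust::emControl(itmax = max_iter)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$z) || anyNA(fit$z)) return(as.integer(init))
  as.integer(mclust::map(fit$z))
}

#' Cluster centroids and sizes
#'
#' Mean embedding vector and member count per occupied cluster.
#'
#' @param embedding `G x d` matrix.
#' @param labels cluster id per row.
#' @return list with `centroids` (one row per occupied cluster, rownames =
#'   cluster ids) and `sizes` (named integer vector; sums to G).
#' @export
centroids <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  lab <- as.character(labels)
  cs <- rowsum(embedding, lab)
  sizes <- table(lab)[rownames(cs)]
  list(centroids = cs / as.vector(sizes),
       sizes = stats::setNames(as.integer(sizes), rownames(cs)))
}

#' Inverse-distance soft cluster assignment
#'
#' Assigns each sample probabilities over clusters from its Euclidean
#' distances `d_i` to the centroids: `p_i = exp(1/d_i) / sum_j exp(1/d_j)`.
#' Distances are clamped below at `eps` and the exponent vector is
#' max-shifted before exponentiation, so coincident samples and tiny
#' distances are handled without overflow; exact ties receive equal
#' probabilities.
#'
#' @param embedding `G x d` matrix.
#' @param centroids centroid matrix (one row per cluster), e.g. from
#'   [centroids()].
#' @param eps distance clamp (default 1e-8).
#' @return a `G x K` probability matrix `P`; rows sum to 1, columns carry
#'   the centroid rownames.
#' @export
soft_assign <- function(embedding, centroids, eps = 1e-8) {
  embedding <- as.matrix(embedding)
  C <- as.matrix(centroids)
  if (nrow(C) == 0L) stop("no centroids supplied")
  d2 <- outer(rowSums(embedding^2), rowSums(C^2), `+`) - 2 * embedding %*% t(C)
  d <- sqrt(pmax(d2, 0))
  u <- 1 / pmax(d, eps)
  u <- u - apply(u, 1, max)
  P <- exp(u)
  P <- P / rowSums(P)
  dimnames(P) <- list(rownames(embedding), rownames(C))
  P
}

#' Auxiliary target distribution
#'
#' Sharpens a soft-assignment matrix into the training target: each
#' probability is squared and normalized by its cluster frequency
#' `f_i = sum_j p_ij`, then renormalized per sample:
#' `q_ij = (p_ij^2 / f_i) / sum_i (p_ij^2 / f_i)`. Squaring up-weights
#' confident assignments; the frequency normalization prevents large
#' clusters from absorbing everything.
#'
#' @param P a `G x K` soft-assignment matrix (rows sum to 1).
#' @return a `G x K` matrix `Q` with rows summing to 1.
#' @export
target_distribution <- function(P) {
  P <- as.matrix(P)
  f <- colSums(P)
  W <- sweep(P^2, 2, ifelse(f > 0, f, 1), `/`)
  W[, f == 0] <- 0
  Q <- W / rowSums(W)
  dimnames(Q) <- dimnames(P)
  Q
}
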