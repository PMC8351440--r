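full_dist <- function(Fm) {
  sq <- rowSums(Fm^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Fm)
  sqrt(pmax(D2, 0))
}

#' Per-gene nearest-neighbor sets
#'
#' Euclidean k-nearest neighbors of every gene in feature space, self
#' excluded, at one or several set sizes. Ties are broken by gene order,
#' which keeps the sets stable across runs.
#'
#' @param features `G x D` feature matrix with gene rownames.
#' @param sizes integer vector of neighbor-set sizes.
#' @return a named list (one element per size) of `G x size` character
#'   matrices of neighbor gene names, genes as rownames.
#' @export
knn_sets <- function(features, sizes = c(5, 10, 15, 20, 25, 30, 40, 50, 100)) {
  Fm <- as.matrix(features)
  G <- nrow(Fm)
  if (max(sizes) >= G) stop("largest neighbor-set size must be < number of genes")
  genes <- rownames(Fm)
  if (is.null(genes)) genes <- as.character(seq_len(G))
  D <- full_dist(Fm)
  diag(D) <- Inf
  kmax <- max(sizes)
  ord <- matrix(0L, G, kmax)
  for (i in seq_len(G)) ord[i, ] <- order(D[i, ])[seq_len(kmax)]  # order() is stable
  out <- lapply(sizes, function(k) {
    m <- matrix(genes[ord[, seq_len(k)]], G, k)
    rownames(m) <- genes
    m
  })
  names(out) <- as.character(sizes)
  out
}

#' Jaccard similarity of two sets
#'
#' @param a,b vectors treated as sets.
#' @return `|a intersect b| / |a union b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Call spatially-expressed genes by ensemble neighbor stability
#'
#' For every gene and every neighbor-set size, the mean Jaccard similarity
#' of its k-nearest-neighbor sets across all model pairs of the ensemble
#' is computed. A gene whose neighborhood is reproducible across
#' independently trained models reflects a real, collective spatial
#' pattern; a gene is called stable (SE) if its mean Jaccard exceeds the
#' threshold at one or more sizes.
#'
#' @param ensemble a `spatial_ensemble` (or a plain list of feature
#'   matrices over the same genes).
#' @param sizes neighbor-set sizes (default 5, 10, 15, 20, 25, 30, 40, 50,
#'   100).
#' @param threshold stability cutoff on the mean Jaccard (default 0.2).
#' @return a data.frame with `gene`, `stable`, `best_size`, `max_jaccard`
#'   and one `jaccard_<size>` column per size.
#' @export
call_se_genes <- function(ensemble, sizes = c(5, 10, 15, 20, 25, 30, 40, 50, 100),
                          threshold = 0.2) {
  feats <- if (inherits(ensemble, "spatial_ensemble")) ensemble$features
           else ensemble
  M <- length(feats)
  if (M < 2L) stop("need at least two models")
  genes <- rownames(feats[[1]])
  sets <- lapply(feats, knn_sets, sizes = sizes)
  G <- length(genes)
  prof <- matrix(0, G, length(sizes),
                 dimnames = list(genes, paste0("jaccard_", sizes)))
  pairs <- utils::combn(M, 2)
  for (s in seq_along(sizes)) {
    acc <- numeric(G)
    for (p in seq_len(ncol(pairs))) {
      a <- sets[[pairs[1, p]]][[s]]
      b <- sets[[pairs[2, p]]][[s]]
      k <- ncol(a)
      inter <- vapply(seq_len(G),
                      function(i) length(intersect(a[i, ], b[i, ])), 0L)
      acc <- acc + inter / (2 * k - inter)
    }
    prof[, s] <- acc / ncol(pairs)
  }
  mx <- apply(prof, 1, max)
  best <- sizes[apply(prof, 1, which.max)]
  data.frame(gene = genes, stable = mx > threshold, best_size = best,
             max_jaccard = mx, prof, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call genes spatially correlated with a query gene
#'
#' Within each model of the ensemble, the Euclidean distances from the
#' query to all other SE genes form the null distribution; candidates whose
#' distance z-score falls below `z_threshold` are significant in that
#' model. A gene is called correlated when it is significant in at least
#' `min_models` models.
#'
#' @param query query gene name (must be among `se_genes`).
#' @param ensemble a `spatial_ensemble` or list of feature matrices.
#' @param se_genes character vector of SE genes defining the null.
#' @param z_threshold z cutoff (default -2.323, one-sided p < 0.01).
#' @param min_models minimum number of supporting models (default 3).
#' @return a data.frame with `gene`, per-model z-scores, mean distance,
#'   `n_models_significant` and `final`.
#' @export
call_correlated <- function(query, ensemble, se_genes, z_threshold = -2.323,
                            min_models = 3L) {
  feats <- if (inherits(ensemble, "spatial_ensemble")) ensemble$features
           else ensemble
  if (!query %in% se_genes) stop("query must be an SE gene")
  cand <- setdiff(se_genes, query)
  if (length(cand) < 3L) stop("need at least 3 SE genes for a null distribution")
  M <- length(feats)
  Z <- matrix(NA_real_, length(cand), M,
              dimnames = list(cand, paste0("z_model", seq_len(M))))
  Dm <- matrix(NA_real_, length(cand), M)
  for (m in seq_len(M)) {
    Fm <- feats[[m]]
    dq <- sqrt(rowSums(sweep(Fm[cand, , drop = FALSE], 2,
                             Fm[query, ], `-`)^2))
    Z[, m] <- (dq - mean(dq)) / stats::sd(dq)
    Dm[, m] <- dq
  }
  nsig <- rowSums(Z < z_threshold)
  data.frame(gene = cand, Z, mean_distance = rowMeans(Dm),
             n_models_significant = nsig,
             final = nsig >= min_models, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' SE-gene calling against reference patterns by a permutation null
#'
#' For every gene, its image is independently permuted `n_perm` times; each
#' permuted image is forwarded through the network and its feature distance
#' to each reference pattern's features forms the null distribution for
#' that gene-reference pair. The true distance is converted to a z-score
#' against this null, and a gene is called SE when it is significantly
#' close (z below the threshold) to at least one reference pattern.
#'
#' @param stack `gene_image_stack` of query genes.
#' @param reference_patterns `gene_image_stack` of reference pattern images
#'   on the same grid (e.g. cell-type expression maps).
#' @param net a trained (or untrained) `conv_net`.
#' @param n_perm permutations per gene (default 100).
#' @param z_threshold z cutoff (default -2.323).
#' @param seed integer seed.
#' @return list with `z` (genes x references z matrix), `true_dist`,
#'   `null_mean`, `null_sd`, `null` (genes x references x n_perm array) and
#'   `se` (logical per gene: significant vs >= 1 reference).
#' @export
permutation_null_call <- function(stack, reference_patterns, net,
                                  n_perm = 100L, z_threshold = -2.323,
                                  seed = 1L) {
  if (!all(stack_dim(stack) == stack_dim(reference_patterns)))
    stop("stack and reference grids differ")
  Fg <- extract_features(net, stack)
  Fr <- extract_features(net, reference_patterns)
  G <- n_genes(stack); R <- n_genes(reference_patterns)
  true_d <- full_cross_dist(Fg, Fr)
  X <- stack_matrix(stack)
  P <- ncol(X)
  null <- array(NA_real_, dim = c(G, R, n_perm),
                dimnames = list(stack$genes, reference_patterns$genes, NULL))
  set.seed(seed)
  d <- stack_dim(stack)
  for (r in seq_len(n_perm)) {
    Xp <- X
    for (g in seq_len(G)) Xp[g, ] <- X[g, sample.int(P)]  # independent per gene
    pst <- matrix_stack(Xp, d[1], d[2])
    Fp <- extract_features(net, pst)
    null[, , r] <- full_cross_dist(Fp, Fr)
  }
  mu <- apply(null, c(1, 2), mean)
  sdv <- apply(null, c(1, 2), stats::sd)
  z <- (true_d - mu) / sdv
  list(z = z, true_dist = true_d, null_mean = mu, null_sd = sdv, null = null,
       se = apply(z < z_threshold, 1, any))
}

full_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  out <- sqrt(pmax(d2, 0))
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' Cluster SE genes into spatial pattern groups
#'
#' UMAP-reduces the SE-gene features, clusters them into `k` groups with a
#' GMM, and returns the mean expression image of each group computed from
#' 0-1 scaled raw counts (for display).
#'
#' @param features feature matrix restricted to SE genes.
#' @param stack the `gene_image_stack` holding the raw images of those
#'   genes.
#' @param k number of pattern groups.
#' @param seed integer seed.
#' @param umap_dims embedding dimensionality (capped at the number of
#'   genes minus one).
#' @return list with `labels` (named integer vector) and `mean_images`
#'   (list of `H x W` matrices, one per occupied cluster).
#' @export
cluster_se_genes <- function(features, stack, k, seed = 1L, umap_dims = 30L) {
  genes <- rownames(features)
  if (is.null(genes) || !all(genes %in% stack$genes))
    stop("features rownames must be genes present in the stack")
  if (k == 1L) {
    labels <- stats::setNames(rep(1L, length(genes)), genes)
  } else {
    E <- embed(features, n_components = min(umap_dims, length(genes) - 1L),
               seed = seed)
    labels <- stats::setNames(cluster_gmm(E, k, seed = seed), genes)
  }
  mean_images <- lapply(sort(unique(labels)), function(cl) {
    members <- genes[labels == cl]
    imgs <- lapply(members, function(g) scale_unit(stack$images[, , g]))
    Reduce(`+`, imgs) / length(imgs)
  })
  names(mean_images) <- sort(unique(labels))
  list(labels = labels, mean_images = mean_images)
}

#' Linear intrinsic dimensionality (two-NN estimator)
#'
#' For each point the ratio `mu = d2/d1` of the distances to its second and
#' first nearest neighbors is computed; under a locally uniform density in
#' d dimensions, `-log(1 - F(mu)) = d * log(mu)`. The LID is the slope of
#' the origin-constrained fit of `-log(1 - F_hat(mu))` on `log(mu)` over
#' the sorted ratios. Lower values mean more tightly clustered
#' representations. Exact duplicates (`d1 = 0`) are excluded; their count
#' is reported as an attribute.
#'
#' @param features numeric matrix, one row per point.
#' @return positive scalar LID with attribute `n_excluded`.
#' @export
lid <- function(features, trim = 0.1) {
  Fm <- as.matrix(features)
  D <- full_dist(Fm)
  diag(D) <- Inf
  d12 <- t(apply(D, 1, function(r) sort(r, partial = 2)[1:2]))
  # duplicates: d1 indistinguishable from 0 at the scale of typical
  # second-neighbor distances (floating-point noise in the cross-product
  # distance computation is far below this)
  scale <- stats::median(d12[, 2])
  if (scale == 0) stop("all points are duplicates; LID undefined")
  keep <- d12[, 1] > 1e-5 * scale
  n_excl <- sum(!keep)
  mu <- d12[keep, 2] / d12[keep, 1]
  n <- length(mu)
  if (n < 3L) stop("too few non-duplicate points for the LID estimate")
  mu <- sort(mu)
  m <- max(2L, floor(n * (1 - trim)))   # drop the heavy upper tail
  x <- log(mu[seq_len(m)])
  y <- -log(1 - seq_len(m) / n)
  ok <- x > 0                           # ratios of exactly 1 carry no signal
  slope <- sum(x[ok] * y[ok]) / sum(x[ok]^2)
  structure(slope, n_excluded = n_excl)
}

#' Confusion matrix of cluster labels against truth
#'
#' @param labels predicted labels.
#' @param truth true class labels.
#' @return a contingency table with truth as rows (row sums equal the true
#'   class sizes).
#' @export
confusion_matrix <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("length mismatch")
  table(truth = truth, label = labels)
}

#' Mean silhouette width of a labeled embedding
#'
#' @param embedding numeric matrix.
#' @param labels cluster labels (at least two distinct values).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(embedding, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette is undefined for a single cluster")
  sil <- cluster::silhouette(labels, stats::dist(embedding))
  mean(sil[, "sil_width"])
}
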