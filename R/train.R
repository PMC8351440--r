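# deterministic per-stage seed derivation from one run seed
seed_for <- function(seed, tag, offset = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + offset * 1299721) %%
               2147483629)
}

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

extract_raw_features <- function(net, stack, batch_size = 128L) {
  X <- stack_matrix(stack)
  G <- nrow(X)
  out <- matrix(0, G, net$config$feature_dim, dimnames = list(stack$genes, NULL))
  for (start in seq(1L, G, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, G)
    fw <- net_forward(net, X[idx, , drop = FALSE], train = FALSE, with_head = FALSE)
    out[idx, ] <- fw$features
  }
  out
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies (natural log); invariant to label renaming, 1 for identical
#' partitions, 0 for independent ones. Two constant labelings are defined
#' as identical (NMI 1); one constant against a varying labeling gives 0.
#'
#' @param a,b label vectors of equal length.
#' @return a value in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  N <- sum(tab)
  pj <- rowSums(tab) / N
  pk <- colSums(tab) / N
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  Ha <- ent(pj); Hb <- ent(pk)
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  t <- tab / N
  E <- outer(pj, pk)
  mi <- sum(t[t > 0] * log(t[t > 0] / E[t > 0]))
  max(0, min(1, mi / ((Ha + Hb) / 2)))
}

#' Train the spatial representation by iterated pseudo-labeling
#'
#' Each epoch (1) extracts features from the current network in evaluation
#' mode, (2) embeds them with UMAP and clusters the embedding with a
#' full-covariance GMM, (3) converts the clustering into the sharpened
#' auxiliary target distribution Q, and (4) updates the network by
#' mini-batch Adam on the bi-tempered logistic loss between Q and the
#' classifier head (plus, optionally, center loss on the flattened
#' features). Q and the feature-space centroids are held fixed within an
#' epoch. Convergence is monitored by the NMI between consecutive-epoch
#' cluster labels; training stops early once the NMI change stays below
#' `nmi_tol` for `patience` consecutive epochs.
#'
#' @param stack a `gene_image_stack` (normalized upstream if desired).
#' @param config a [net_config()]; `center_loss_weight > 0` enables center
#'   loss.
#' @param epochs maximum number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param umap_dims embedding dimensionality used for clustering.
#' @param seed run seed; initialization and every per-epoch stochastic
#'   stage derive their seeds from it.
#' @param umap_epochs UMAP layout optimization epochs per clustering round.
#' @param nmi_tol,patience early-stopping rule on consecutive-epoch NMI.
#' @param keep_epoch_features keep the per-epoch feature matrices (needed
#'   by [neighbor_overlap_trace()]).
#' @param verbose print per-epoch NMI and losses.
#' @return an object of class `spatial_fit`: the trained `net`, final
#'   `features` (L2-normalized), final `labels` (fresh embedding + GMM on
#'   the trained features) with their maximum soft-assignment probability
#'   `assign_prob`, `trace` (per-epoch NMI and mean losses), the `seed`,
#'   and optionally `epoch_features`.
#' @export
train <- function(stack, config, epochs = 20L, lr = 1e-3, batch_size = 128L,
                  umap_dims = 30L, seed = config$seed, umap_epochs = 150L,
                  nmi_tol = 0.02, patience = 3L,
                  keep_epoch_features = FALSE, verbose = FALSE) {
  stopifnot(inherits(stack, "gene_image_stack"), inherits(config, "net_config"))
  config$seed <- as.integer(seed)
  net <- init_network(config)
  G <- n_genes(stack)
  X <- stack_matrix(stack)
  N <- config$n_clusters
  lambda_c <- config$center_loss_weight
  opt <- adam_init(net$params)
  prev_labels <- NULL
  trace <- data.frame(epoch = integer(), nmi_prev = numeric(),
                      loss_bitempered = numeric(), loss_center = numeric())
  epoch_features <- if (keep_epoch_features) vector("list", epochs) else NULL
  stable_run <- 0L
  prev_nmi <- NA_real_
  for (e in seq_len(epochs)) {
    raw <- extract_raw_features(net, stack)
    feats <- l2_normalize_rows(raw)
    if (keep_epoch_features) epoch_features[[e]] <- feats
    E <- embed(feats, n_components = min(umap_dims, G - 1L),
               seed = seed_for(seed, "embed", e), n_epochs = umap_epochs)
    labels <- cluster_gmm(E, N, seed = seed_for(seed, "gmm", e))
    cs <- centroids(E, labels)
    P <- soft_assign(E, cs$centroids)
    Q <- target_distribution(P)
    Qfull <- matrix(0, G, N)
    Qfull[, as.integer(colnames(Q))] <- Q
    nmi_e <- if (is.null(prev_labels)) NA_real_ else nmi(labels, prev_labels)
    prev_labels <- labels
    # center-loss centroids in the flattened feature space, fixed per epoch
    if (lambda_c > 0) {
      cf <- rowsum(raw, labels)
      cf <- cf / as.vector(table(labels)[rownames(cf)])
      cmap <- cf[as.character(labels), , drop = FALSE]
    }
    set.seed(seed_for(seed, "batches", e))
    ord <- sample.int(G)
    bt_sum <- 0; cl_sum <- 0
    for (start in seq(1L, G, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, G)]
      B <- length(idx)
      fw <- net_forward(net, X[idx, , drop = FALSE], train = TRUE)
      if (lr > 0) net <- net_update_running(net, fw)   # lr 0 = full no-op
      yhat <- tempered_softmax(fw$logits, config$t2)
      Qb <- Qfull[idx, , drop = FALSE]
      loss_rows <- bitempered_loss(Qb, yhat, config$t1)
      if (any(!is.finite(loss_rows)))
        stop("non-finite bi-tempered loss; check inputs and learning rate")
      bt_sum <- bt_sum + sum(loss_rows)
      dLogits <- bitempered_grad_logits(Qb, yhat, config$t1, config$t2) / B
      dFeat <- NULL
      if (lambda_c > 0) {
        dcl <- fw$features - cmap[idx, , drop = FALSE]
        cl_sum <- cl_sum + 0.5 * sum(dcl^2)
        dFeat <- lambda_c * dcl / B
      }
      grads <- net_backward(net, fw, dLogits = dLogits, dFeatures = dFeat)
      if (lr > 0) {
        upd <- adam_step(net$params, grads, opt, lr)
        net$params <- upd$params
        opt <- upd$state
      }
    }
    trace <- rbind(trace, data.frame(epoch = e, nmi_prev = nmi_e,
                                     loss_bitempered = bt_sum / G,
                                     loss_center = cl_sum / G))
    if (verbose)
      message(sprintf("epoch %2d  NMI(t,t-1)=%s  L_bt=%.4f  L_c=%.4f", e,
                      ifelse(is.na(nmi_e), "  -  ", sprintf("%.3f", nmi_e)),
                      bt_sum / G, cl_sum / G))
    if (!is.na(nmi_e) && !is.na(prev_nmi) && abs(nmi_e - prev_nmi) < nmi_tol)
      stable_run <- stable_run + 1L
    else
      stable_run <- 0L
    prev_nmi <- nmi_e
    if (stable_run >= patience) break
  }
  final_feats <- extract_features(net, stack)
  final_E <- embed(final_feats, n_components = min(umap_dims, G - 1L),
                   seed = seed_for(seed, "final-embed"), n_epochs = umap_epochs)
  final_labels <- cluster_gmm(final_E, N, seed = seed_for(seed, "final-gmm"))
  final_P <- soft_assign(final_E, centroids(final_E, final_labels)$centroids)
  structure(list(net = net, features = final_feats, labels = final_labels,
                 assign_prob = apply(final_P, 1, max),
                 embedding = final_E, trace = trace, seed = as.integer(seed),
                 epochs_run = nrow(trace),
                 epoch_features = if (keep_epoch_features)
                   epoch_features[seq_len(nrow(trace))] else NULL),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf("spatial_fit: %d genes, %d epochs (seed %d)\n",
              nrow(x$features), x$epochs_run, x$seed))
  last <- utils::tail(x$trace$nmi_prev[!is.na(x$trace$nmi_prev)], 1)
  if (length(last)) cat(sprintf("  final consecutive-epoch NMI: %.3f\n", last))
  invisible(x)
}

#' Train an ensemble of independent models
#'
#' Trains `n_models` networks on the identical stack with distinct seeds
#' (`base_seed + 0 .. n_models-1`). The resulting feature matrices feed the
#' neighbor-stability SE-gene statistic and the correlated-gene calls.
#'
#' @param stack a `gene_image_stack`.
#' @param config a [net_config()].
#' @param n_models ensemble size (default 5).
#' @param base_seed first seed.
#' @param ... passed to [train()].
#' @return an object of class `spatial_ensemble`: lists `fits`, `features`,
#'   `seeds`.
#' @export
train_ensemble <- function(stack, config, n_models = 5L, base_seed = 1L, ...) {
  seeds <- as.integer(base_seed) + seq_len(n_models) - 1L
  fits <- lapply(seeds, function(s) train(stack, config, seed = s, ...))
  structure(list(fits = fits,
                 features = lapply(fits, `[[`, "features"),
                 seeds = seeds),
            class = "spatial_ensemble")
}

#' @export
print.spatial_ensemble <- function(x, ...) {
  cat(sprintf("spatial_ensemble: %d models (seeds %s)\n", length(x$fits),
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Neighbor overlap across training epochs
#'
#' For each query gene, counts how many of its k nearest neighbors (by
#' Euclidean distance in feature space) are retained from one epoch to the
#' next. Stable neighborhoods late in training indicate strong, reliably
#' learned spatial relationships.
#'
#' @param feature_list list of per-epoch feature matrices (e.g.
#'   `fit$epoch_features` from [train()] with `keep_epoch_features = TRUE`).
#' @param query_genes character vector of genes to track.
#' @param k neighbor-set size (default 30).
#' @return an `(epochs-1) x length(query_genes)` matrix of overlap counts.
#' @export
neighbor_overlap_trace <- function(feature_list, query_genes, k = 30L) {
  if (length(feature_list) < 2L) stop("need at least two epochs of features")
  sets <- lapply(feature_list, function(Fm) {
    nn <- knn_sets(Fm, sizes = k)[[1]]
    nn[query_genes, , drop = FALSE]
  })
  out <- matrix(0L, length(feature_list) - 1L, length(query_genes),
                dimnames = list(NULL, query_genes))
  for (t in 2:length(feature_list))
    for (g in seq_along(query_genes))
      out[t - 1L, g] <- length(intersect(sets[[t]][g, ], sets[[t - 1L]][g, ]))
  out
}
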