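#' Truth-NMI of a feature matrix under pattern-count clustering
#'
#' Clusters learned (or raw) features into `k` groups — UMAP reduction
#' followed by a GMM, the same post-training grouping step a user applies
#' once a model is trained — and returns the normalized mutual information
#' against the true pattern labels.
#'
#' @param features `G x D` feature matrix.
#' @param truth integer vector of true pattern labels (length G).
#' @param k number of clusters; defaults to the number of distinct truth
#'   labels.
#' @param seed integer seed.
#' @param umap_dims embedding dimensionality (default 30, capped at G-1).
#' @return NMI in `[0, 1]`.
#' @export
truth_nmi <- function(features, truth, k = length(unique(truth)), seed = 1L,
                      umap_dims = 30L) {
  E <- embed(features, n_components = min(umap_dims, nrow(features) - 1L),
             seed = seed)
  nmi(cluster_gmm(E, k, seed = seed), truth)
}

#' Five-pattern synthetic benchmark run
#'
#' The package's reference experiment: simulate `k` spatial patterns with
#' `n_per_pattern` genes each at a given residual-noise variance, train the
#' representation with the default iterated pseudo-label protocol (30
#' training clusters, 30 UMAP dimensions), and score the trained features
#' by [truth_nmi()] against the known pattern memberships. Optionally the
#' stack is perturbed by the shared-permutation shuffle before training
#' (spatial-information control), and center loss can be enabled.
#'
#' @param noise_variance residual error variance of the simulation.
#' @param seed run seed (drives simulation, initialization and training).
#' @param n_per_pattern genes per pattern (default 100; the headline
#'   configuration in the original study design is 2000).
#' @param k number of patterns (default 5).
#' @param shuffle apply one shared pixel permutation to every gene image
#'   before training.
#' @param center_loss_weight weight of the center loss (0 = off).
#' @param epochs training epoch cap (early stopping applies).
#' @param umap_epochs UMAP optimization epochs per clustering round.
#' @return a list with `nmi` (truth-NMI of the trained features), `fit`
#'   (the [train()] result), `truth`, and for shuffled runs
#'   `max_cor_change`, the largest absolute change in pixel-wise inter-gene
#'   Pearson correlation caused by the shuffle (identically 0 up to float
#'   reordering).
#' @export
five_pattern_run <- function(noise_variance, seed, n_per_pattern = 100L,
                             k = 5L, shuffle = FALSE,
                             center_loss_weight = 0, epochs = 10L,
                             umap_epochs = 100L) {
  sim <- simulate_study(k = k, n_per_pattern = n_per_pattern,
                        noise_variance = noise_variance,
                        seed = seed_for(seed, "sim"))
  stack <- sim$stack
  max_cor_change <- NULL
  if (shuffle) {
    sh <- shuffle_stack(stack, seed = seed_for(seed, "shuffle"))
    M0 <- stack_matrix(stack); M1 <- stack_matrix(sh$stack)
    set.seed(seed_for(seed, "corpairs"))
    pairs <- replicate(25, sample.int(nrow(M0), 2))
    max_cor_change <- max(abs(vapply(seq_len(ncol(pairs)), function(i)
      stats::cor(M0[pairs[1, i], ], M0[pairs[2, i], ]) -
        stats::cor(M1[pairs[1, i], ], M1[pairs[2, i], ]), 0)))
    stack <- sh$stack
  }
  cfg <- net_config(center_loss_weight = center_loss_weight)
  fit <- train(stack, cfg, epochs = epochs, seed = seed,
               umap_epochs = umap_epochs)
  list(nmi = truth_nmi(fit$features, sim$truth$pattern, k = k,
                       seed = seed_for(seed, "eval")),
       fit = fit, truth = sim$truth, max_cor_change = max_cor_change)
}

#' Untrained-network clustering baseline
#'
#' Forwards the five-pattern simulation through a freshly initialized
#' (untrained) network and clusters the resulting features with the full
#' training protocol (30 UMAP dimensions, 30-component GMM). The NMI
#' against truth quantifies how much structure the random-filter features
#' alone retain before any pseudo-label training.
#'
#' @inheritParams five_pattern_run
#' @param n_clusters GMM components for the baseline clustering
#'   (default 30, the training default).
#' @return a list with `nmi` and the untrained `features`.
#' @export
initialization_baseline <- function(noise_variance, seed,
                                    n_per_pattern = 100L, k = 5L,
                                    n_clusters = 30L) {
  sim <- simulate_study(k = k, n_per_pattern = n_per_pattern,
                        noise_variance = noise_variance,
                        seed = seed_for(seed, "sim"))
  net <- init_network(net_config(seed = seed))
  feats <- extract_features(net, sim$stack)
  E <- embed(feats, n_components = min(30L, nrow(feats) - 1L),
             seed = seed_for(seed, "embed"))
  labels <- cluster_gmm(E, n_clusters, seed = seed_for(seed, "gmm"))
  list(nmi = nmi(labels, sim$truth$pattern), features = feats,
       truth = sim$truth)
}
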