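test_that("knn sets use stable Euclidean neighbors excluding self", {
  Fm <- matrix(c(0, 1, 5), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  ks <- knn_sets(Fm, sizes = c(1, 2))
  expect_equal(unname(ks[["1"]]["a", ]), "b")       # 1-NN of 0 is 1
  expect_equal(unname(ks[["2"]]["c", ]), c("b", "a"))
  set.seed(3)
  Fr <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
  ks2 <- knn_sets(Fr, sizes = c(5, 10))
  expect_equal(ncol(ks2[["5"]]), 5L)
  expect_equal(ncol(ks2[["10"]]), 10L)
  for (g in rownames(Fr)[1:10]) expect_false(g %in% ks2[["10"]][g, ])
  expect_error(knn_sets(Fr, sizes = 50), "< number of genes")
})

test_that("jaccard similarity counts set overlap", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("a", "b", "d")), 0.5)
})

test_that("SE calling is driven by cross-model neighbor stability", {
  set.seed(17)
  G <- 120
  genes <- paste0("g", seq_len(G))
  base <- matrix(rnorm(G * 6), G, 6, dimnames = list(genes, NULL))
  # five identical models: every gene perfectly stable with profile 1
  same <- replicate(5, base, simplify = FALSE)
  calls <- call_se_genes(same, sizes = c(5, 10))
  expect_true(all(calls$stable))
  expect_equal(calls$max_jaccard, rep(1, G))
  # five mutually random models: expected Jaccard ~ 0, nothing stable
  rand <- replicate(5, {
    m <- matrix(rnorm(G * 6), G, 6); rownames(m) <- genes; m
  }, simplify = FALSE)
  calls0 <- call_se_genes(rand, sizes = c(5, 10))
  expect_lt(mean(calls0$max_jaccard), 0.1)
  expect_lt(mean(calls0$stable), 0.05)
  # invariance to model order and to gene order
  calls_perm <- call_se_genes(rand[c(3, 1, 5, 2, 4)], sizes = c(5, 10))
  expect_equal(calls_perm$max_jaccard, calls0$max_jaccard)
  shuf <- sample(G)
  calls_g <- call_se_genes(lapply(rand, function(m) m[shuf, ]),
                           sizes = c(5, 10))
  expect_equal(calls_g$max_jaccard[match(genes, calls_g$gene)],
               calls0$max_jaccard)
})

test_that("correlated-gene calls need support in enough models", {
  set.seed(19)
  G <- 40
  genes <- paste0("g", seq_len(G))
  feats <- replicate(5, {
    m <- matrix(rnorm(G * 5), G, 5, dimnames = list(genes, NULL))
    m[2, ] <- m[1, ]                      # g2 duplicates the query g1
    m
  }, simplify = FALSE)
  res <- call_correlated("g1", feats, genes)
  expect_true(res$final[res$gene == "g2"])
  expect_equal(res$n_models_significant[res$gene == "g2"], 5)
  # significant in only 2 of 5 models -> not final
  two <- feats
  for (m in 3:5) two[[m]][2, ] <- -two[[m]][1, ] + 10
  res2 <- call_correlated("g1", two, genes)
  expect_false(res2$final[res2$gene == "g2"])
  expect_error(call_correlated("g1", feats, c("g1", "g2")), "at least 3")
  expect_error(call_correlated("zz", feats, genes), "SE gene")
  # z-scores invariant to global feature rescaling
  res3 <- call_correlated("g1", lapply(feats, `*`, 17), genes)
  expect_equal(res3$z_model1, res$z_model1, tolerance = 1e-9)
})

test_that("correlated-call rate on pure noise matches the normal tail", {
  set.seed(23)
  G <- 400
  genes <- paste0("g", seq_len(G))
  feats <- replicate(5, matrix(rnorm(G * 30), G, 30,
                               dimnames = list(genes, NULL)),
                     simplify = FALSE)
  res <- call_correlated("g1", feats, genes, min_models = 1L)
  # distances to random points are ~Gaussian; one-sided tail at z < -2.323
  p <- pnorm(-2.323)
  rate <- mean(res$n_models_significant) / 5
  # distances are only approximately Gaussian, so allow a small systematic
  # offset on top of the Monte-Carlo error
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / (5 * (G - 1))) + 0.008)
})

test_that("permutation null calls a reference against itself", {
  sim <- small_study(noise = 0.3, npp = 4L, seed = 51)
  tps <- make_pattern_templates(3, 24, 24, seed = 51)
  refs <- gene_image_stack(lapply(tps, function(t) t$mask * 1),
                           genes = paste0("ref", 1:3))
  both <- gene_image_stack(
    array(c(refs$images, sim$stack$images[, , 1:6]), c(24, 24, 9)),
    genes = c(refs$genes, sim$stack$genes[1:6]))
  net <- init_network(small_config())
  pn <- permutation_null_call(both, refs, net, n_perm = 30, seed = 3)
  expect_equal(dim(pn$null), c(9L, 3L, 30L))
  expect_equal(unname(pn$true_dist["ref1", "ref1"]), 0, tolerance = 1e-9)
  expect_true(pn$se["ref1"])                    # zero distance beats its null
  expect_true(all(pn$z["ref1", "ref1"] < -2.323))
})

test_that("pattern-group clustering returns labels and mean images", {
  sim <- small_study(noise = 0.2, npp = 30L, seed = 53)
  fit <- quick_train(sim$stack, small_config(), seed = 2, epochs = 5)
  res <- cluster_se_genes(fit$features, sim$stack, k = 5, seed = 2,
                          umap_dims = 10)
  expect_length(res$labels, n_genes(sim$stack))
  expect_gt(nmi(res$labels, sim$truth$pattern), 0.9)
  one <- cluster_se_genes(fit$features[1:10, ], sim$stack, k = 1)
  scaled <- lapply(1:10, function(g) scale_unit(sim$stack$images[, , g]))
  expect_equal(one$mean_images[[1]], Reduce(`+`, scaled) / 10)
})

test_that("the two-NN intrinsic dimension estimator recovers known dimensions", {
  set.seed(29)
  # 1000 points on a line segment embedded in 10-D
  line <- cbind(runif(1000)) %*% matrix(rnorm(10), 1, 10)
  expect_lt(abs(as.numeric(lid(line)) - 1), 0.2)
  # uniform 2-D disc
  r <- sqrt(runif(1000)); th <- runif(1000, 0, 2 * pi)
  disc <- cbind(r * cos(th), r * sin(th))
  expect_lt(abs(as.numeric(lid(disc)) - 2), 0.3)
  # scale invariance and duplicate exclusion
  expect_equal(as.numeric(lid(disc * 100)), as.numeric(lid(disc)),
               tolerance = 1e-9)
  dup <- rbind(disc, disc[1:50, ])
  ld <- lid(dup)
  expect_equal(attr(ld, "n_excluded"), 100L)     # both members of each pair
  expect_lt(abs(as.numeric(ld) - 2), 0.3)
})

test_that("confusion matrix and silhouette summarize label quality", {
  truth <- rep(1:3, times = c(5, 3, 2))
  perfect <- confusion_matrix(truth, truth)
  expect_equal(sum(diag(perfect)), 10L)
  expect_equal(unname(rowSums(confusion_matrix(sample(truth), truth))),
               c(5L, 3L, 2L))
  set.seed(31)
  lab <- rep(1:2, each = 30)
  blobs <- matrix(rnorm(60 * 2, sd = 0.2), 60, 2) + 3 * (lab == 2)
  expect_gt(silhouette_score(blobs, lab), 0.5)
  expect_lte(silhouette_score(blobs, sample(lab)), 0.05)
  expect_error(silhouette_score(blobs, rep(1, 60)), "single cluster")
})
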