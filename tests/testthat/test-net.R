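test_that("network initialization is seeded and shape-correct", {
  cfg <- net_config()
  n1 <- init_network(cfg)
  n2 <- init_network(cfg)
  expect_identical(n1$params, n2$params)
  expect_equal(ncol(n1$params$Wfc), 30L)          # head width = n_clusters
  expect_equal(cfg$out_shape, c(6, 6))            # 48 -> 24 -> 12 -> 6
  expect_equal(cfg$feature_dim, 6L * 6L * 32L)
  n3 <- init_network(net_config(seed = 2))
  expect_false(identical(n1$params$W1, n3$params$W1))
  expect_error(net_config(input_shape = c(6, 6)), "too small")
  expect_error(net_config(t1 = 0), "t1")
  expect_error(net_config(t2 = 0.9), "t2")
})

test_that("extract_features yields unit rows, is pure, and checks shapes", {
  sim <- small_study(npp = 6L)
  net <- init_network(small_config())
  F1 <- extract_features(net, sim$stack)
  expect_equal(unname(sqrt(rowSums(F1^2))), rep(1, n_genes(sim$stack)),
               tolerance = 1e-6)
  expect_identical(F1, extract_features(net, sim$stack))
  # duplicated gene -> identical feature row
  dup <- gene_image_stack(array(sim$stack$images[, , c(1, 1)], c(24, 24, 2)),
                          genes = c("a", "b"))
  Fd <- extract_features(net, dup)
  expect_equal(Fd[1, ], Fd[2, ], ignore_attr = TRUE)
  wrong <- gene_image_stack(array(0.5, c(12, 12, 2)))
  expect_error(extract_features(net, wrong), "input shape")
  # batch size must not change the result (no batch dependence in eval mode)
  expect_equal(extract_features(net, sim$stack, batch_size = 7L), F1)
})

test_that("compiled forward/backward agree with the plain-R reference", {
  spc <- asNamespace("spaceclust")
  set.seed(31)
  cfg <- net_config(input_shape = c(16, 16), n_filters = c(2, 3, 4),
                    n_clusters = 5, seed = 8)
  net <- init_network(cfg)
  X <- matrix(runif(6 * 256), 6, 256)
  for (train_mode in c(TRUE, FALSE)) {
    fc <- spc$net_forward(net, X, train = train_mode)
    fr <- spc$net_forward_ref(net, X, train = train_mode)
    expect_equal(fc$features, fr$features, tolerance = 1e-12)
    expect_equal(fc$logits, fr$logits, tolerance = 1e-12)
  }
  fc <- spc$net_forward(net, X, train = TRUE)
  fr <- spc$net_forward_ref(net, X, train = TRUE)
  dL <- matrix(rnorm(6 * 5), 6, 5)
  dFt <- matrix(rnorm(6 * ncol(fc$features)), 6)
  gc <- spc$net_backward(net, fc, dLogits = dL, dFeatures = dFt)
  gr <- spc$net_backward_ref(net, fr, dLogits = dL, dFeatures = dFt)
  for (nm in names(gr)) expect_equal(gc[[nm]], gr[[nm]], tolerance = 1e-9,
                                     ignore_attr = TRUE)
})

test_that("analytic gradients through the full network pass a numeric check", {
  spc <- asNamespace("spaceclust")
  set.seed(12)
  cfg <- net_config(input_shape = c(16, 16), n_filters = c(2, 3, 4),
                    n_clusters = 4, seed = 3)
  net <- init_network(cfg)
  X <- matrix(runif(5 * 256), 5, 256)
  Q <- matrix(runif(20), 5, 4); Q <- Q / rowSums(Q)
  lab <- c(1, 2, 1, 2, 1)
  lossfun <- function(nn) {
    fw <- spc$net_forward(nn, X, train = TRUE)
    yh <- tempered_softmax(fw$logits, cfg$t2)
    cen <- rowsum(fw$features, lab) / as.vector(table(lab))
    sum(bitempered_loss(Q, yh, cfg$t1)) +
      0.3 * 0.5 * sum((fw$features - cen[lab, ])^2)
  }
  fw <- spc$net_forward(net, X, train = TRUE)
  yh <- tempered_softmax(fw$logits, cfg$t2)
  cen <- rowsum(fw$features, lab) / as.vector(table(lab))
  grads <- spc$net_backward(net, fw,
                            dLogits = spc$bitempered_grad_logits(Q, yh, cfg$t1, cfg$t2),
                            dFeatures = 0.3 * (fw$features - cen[lab, ]))
  eps <- 1e-5
  for (nm in c("W1", "b2", "gamma2", "beta3", "W3", "Wfc", "bfc")) {
    p <- net$params[[nm]]
    for (j in sample(length(p), min(4, length(p)))) {
      n2 <- net
      n2$params[[nm]][j] <- p[j] + eps; up <- lossfun(n2)
      n2$params[[nm]][j] <- p[j] - eps; dn <- lossfun(n2)
      num <- (up - dn) / (2 * eps)
      tol <- max(1e-4, 1e-4 * abs(num))
      expect_equal(grads[[nm]][j], num, tolerance = tol, ignore_attr = TRUE)
    }
  }
})

test_that("checkpoints round-trip through save_model/load_model", {
  net <- init_network(small_config())
  path <- tempfile(fileext = ".rds")
  save_model(net, path)
  net2 <- load_model(path)
  expect_identical(net2$params, net$params)
  expect_identical(net2$config, net$config)
  sim <- small_study(npp = 4L)
  expect_identical(extract_features(net2, sim$stack),
                   extract_features(net, sim$stack))
})

test_that("trained features separate a gene from its shuffled copies", {
  sim <- small_study(npp = 40L, seed = 21)
  fit <- quick_train(sim$stack, small_config(), seed = 4, epochs = 4)
  g <- sim$stack$genes[1]
  fg <- fit$features[g, ]
  dists <- vapply(1:20, function(s) {
    sh <- shuffle_stack(sim$stack, seed = 100 + s)
    sqrt(sum((extract_features(fit$net, sh$stack)[g, ] - fg)^2))
  }, 0)
  expect_true(all(dists > 0))
})
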