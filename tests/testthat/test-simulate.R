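test_that("pattern templates are deterministic, distinct and mid-coverage", {
  t1 <- make_pattern_templates(5, 48, 48, seed = 3)
  t2 <- make_pattern_templates(5, 48, 48, seed = 3)
  expect_identical(t1, t2)
  for (tp in t1) {
    expect_gte(tp$coverage, 0.10)
    expect_lte(tp$coverage, 0.40)
  }
  for (i in 1:4) for (j in (i + 1):5)
    expect_gt(sum(t1[[i]]$mask != t1[[j]]$mask), 0)
  expect_error(make_pattern_templates(9, 48, 48), "8")
  expect_error(make_pattern_templates(1, 48, 48), "at least 2")
})

test_that("patterned genes are base signal plus the requested noise", {
  tp <- make_pattern_templates(2, 20, 20, seed = 1)[[1]]
  noiseless <- simulate_se_genes(tp, 3, noise_variance = 0, seed = 5)
  base <- 1.0 * tp$mask + 0.2 * (1 - tp$mask)
  for (g in 1:3) expect_equal(noiseless$images[, , g], base,
                              ignore_attr = TRUE)

  # empirical per-pixel residual variance over many genes ~ sigma^2 (+-10%);
  # mu_out is raised so clipping at zero does not bias the sample variance
  big <- simulate_se_genes(tp, 2000, noise_variance = 0.3, seed = 9,
                           mu_in = 6, mu_out = 5)
  v <- apply(big$images, c(1, 2), var)
  expect_lt(abs(mean(v) - 0.3) / 0.3, 0.1)
  expect_equal(n_genes(big), 2000L)
})

test_that("non-SE genes are spatially unstructured", {
  s <- simulate_non_se_genes(40, 20, 20, seed = 2)
  expect_identical(n_genes(s), 40L)
  expect_identical(s$images, simulate_non_se_genes(40, 20, 20, seed = 2)$images)
  mi <- vapply(seq_len(40), function(g) moran_oracle(s$images[, , g]), 0)
  expect_lt(abs(mean(mi)), 0.05)
})

test_that("SE/non-SE mixing ratios are exact and templates separable at zero noise", {
  for (f in c(0.9, 0.5, 0.1)) {
    sim <- small_study(npp = 18L, seed = 2, se_fraction = f)
    n_se <- sum(sim$truth$is_se)
    expect_equal(n_se, 5L * 18L)
    expect_equal(round(n_se * (1 - f) / f), sum(!sim$truth$is_se))
  }
  # nearest-centroid accuracy 1 in pixel space at sigma^2 = 0
  sim0 <- small_study(noise = 0, npp = 10L, seed = 3)
  M <- stack_matrix(sim0$stack)
  cent <- rowsum(M, sim0$truth$pattern) / 10
  d <- outer(rowSums(M^2), rowSums(cent^2), `+`) - 2 * M %*% t(cent)
  expect_equal(unname(apply(d, 1, which.min)), sim0$truth$pattern)
})

test_that("masking zeroes the region for exactly the chosen half", {
  sim <- small_study(npp = 10L, seed = 4)
  region <- matrix(0, 24, 24); region[1:8, 1:8] <- 1
  mk <- apply_mask(sim$stack, region, fraction = 0.5, seed = 9)
  expect_length(mk$masked_genes, round(0.5 * 50))
  for (g in mk$masked_genes[1:3])
    expect_true(all(mk$stack$images[1:8, 1:8, g] == 0))
  untouched <- setdiff(sim$stack$genes, mk$masked_genes)
  expect_identical(mk$stack$images[, , untouched],
                   sim$stack$images[, , untouched])
})

test_that("shared shuffle preserves pixel multisets and pairwise correlation", {
  sim <- small_study(npp = 8L, seed = 5)
  sh <- shuffle_stack(sim$stack, seed = 11)
  M0 <- stack_matrix(sim$stack); M1 <- stack_matrix(sh$stack)
  for (g in 1:5) expect_equal(sort(M0[g, ]), sort(M1[g, ]))
  # pixelwise Pearson correlation between any two genes is unchanged
  set.seed(1)
  pairs <- replicate(10, sample(n_genes(sim$stack), 2))
  for (p in seq_len(ncol(pairs)))
    expect_equal(cor(M0[pairs[1, p], ], M0[pairs[2, p], ]),
                 cor(M1[pairs[1, p], ], M1[pairs[2, p], ]))
  # inverse permutation recovers the stack exactly
  rec <- shuffle_stack(sh$stack, permutation = order(sh$permutation))
  expect_identical(rec$stack$images, sim$stack$images)
})

test_that("shuffling destroys spatial autocorrelation of patterned images", {
  tp <- make_pattern_templates(3, 24, 24, seed = 6)[[2]]
  img_stack <- simulate_se_genes(tp, 1, noise_variance = 0.2, seed = 7)
  i0 <- moran_oracle(img_stack$images[, , 1])
  drops <- vapply(1:100, function(s) {
    i0 - moran_oracle(shuffle_stack(img_stack, seed = s)$stack$images[, , 1])
  }, 0)
  expect_gt(median(drops), 0)
  expect_gt(i0, 0.3)            # the pattern itself is strongly autocorrelated
})

test_that("partial shuffle interpolates between identity and full shuffle", {
  sim <- small_study(npp = 6L, seed = 8)
  expect_identical(partial_shuffle(sim$stack, 0, seed = 3)$stack$images,
                   sim$stack$images)
  expect_identical(partial_shuffle(sim$stack, 1, seed = 3)$stack$images,
                   shuffle_stack(sim$stack, seed = 3)$stack$images)
  M0 <- stack_matrix(sim$stack)
  Mh <- stack_matrix(partial_shuffle(sim$stack, 0.5, seed = 3)$stack)
  expect_equal(cor(M0[1, ], M0[2, ]), cor(Mh[1, ], Mh[2, ]))
})
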