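# Shared fixtures: everything is generated in code at test time.

# a tiny deterministic stack of hand-chosen images
tiny_stack <- function() {
  g1 <- matrix(0, 4, 4); g1[1, 1] <- 5
  g2 <- matrix(1:16, 4, 4)
  g3 <- matrix(c(rep(0, 8), rep(2, 8)), 4, 4)
  gene_image_stack(list(a = g1, b = g2, c = g3))
}

# small synthetic study used by several integration tests
small_study <- function(noise = 0.2, npp = 60L, seed = 42L, H = 24L, W = 24L,
                        k = 5L, se_fraction = 1) {
  simulate_study(k = k, n_per_pattern = npp, noise_variance = noise,
                 se_fraction = se_fraction, H = H, W = W, seed = seed)
}

# a network configuration small and fast enough for unit tests
small_config <- function(H = 24L, W = 24L, ...) {
  net_config(input_shape = c(H, W), n_filters = c(4L, 8L, 16L),
             n_clusters = 10L, ...)
}

# quick training wrapper for property tests
quick_train <- function(stack, config, seed = 1L, epochs = 5L, ...) {
  train(stack, config, epochs = epochs, seed = seed, umap_epochs = 60L,
        umap_dims = 10L, ...)
}

# independent Moran's-I-style spatial autocorrelation oracle (rook weights)
moran_oracle <- function(img) {
  H <- nrow(img); W <- ncol(img)
  n <- H * W
  idx <- function(r, c) (c - 1L) * H + r
  ii <- jj <- integer(0)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (r < H) { ii <- c(ii, idx(r, c)); jj <- c(jj, idx(r + 1L, c)) }
    if (c < W) { ii <- c(ii, idx(r, c)); jj <- c(jj, idx(r, c + 1L)) }
  }
  x <- as.vector(img)
  xc <- x - mean(x)
  num <- sum(xc[ii] * xc[jj]) * 2           # symmetric pairs
  den <- sum(xc^2)
  if (den == 0) return(0)
  (n / (2 * length(ii))) * num / den
}

# textbook two-loop NMI oracle (arithmetic normalization)
nmi_oracle <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  ha <- -sum(vapply(ua, function(x) { p <- sum(a == x) / n; p * log(p) }, 0))
  hb <- -sum(vapply(ub, function(y) { p <- sum(b == y) / n; p * log(p) }, 0))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}
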