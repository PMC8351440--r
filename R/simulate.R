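#' Deterministic spatial pattern templates
#'
#' Generates `k` geometrically distinct binary region masks (stripe, blob,
#' ring, corner wedge, crescent, diagonal band, twin blobs, L-shape) on an
#' `H x W` grid, each covering 10-40% of pixels. The seed only jitters
#' shape placement slightly; the same seed always reproduces the same
#' templates. These play the role of the tissue-derived expression domains
#' used in benchmarking studies, without requiring any external data.
#'
#' @param k number of templates (2..8).
#' @param H,W grid dimensions.
#' @param seed integer seed for placement jitter.
#' @return a list of `k` templates, each a list with `mask` (binary `H x W`
#'   matrix), `pattern_id` and `coverage` (fraction of active pixels).
#' @export
make_pattern_templates <- function(k, H = 48L, W = 48L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (k > 8L) stop("only 8 built-in template shapes are available")
  set.seed(seed)
  jit <- stats::runif(16, -0.02, 0.02)
  u <- matrix(rep((seq_len(H) - 0.5) / H, W), H, W)          # row coord in (0,1)
  v <- matrix(rep((seq_len(W) - 0.5) / W, each = H), H, W)   # col coord in (0,1)
  disc <- function(cu, cv, r) (u - cu)^2 + (v - cv)^2 < r^2
  shapes <- list(
    stripe   = v > 0.35 + jit[1] & v < 0.65 + jit[2],
    blob     = disc(0.35 + jit[3], 0.35 + jit[4], 0.28),
    ring     = disc(0.60 + jit[5], 0.60 + jit[6], 0.38) &
               !disc(0.60 + jit[5], 0.60 + jit[6], 0.18),
    wedge    = u + v < 0.70 + jit[7],
    crescent = disc(0.50 + jit[8], 0.72 + jit[9], 0.30) &
               !disc(0.50 + jit[8], 0.60 + jit[9], 0.24),
    diagonal = abs(u - v) < 0.15 + jit[10],
    twinblob = disc(0.25 + jit[11], 0.70 + jit[12], 0.17) |
               disc(0.75 + jit[13], 0.30 + jit[14], 0.17),
    lshape   = u > 0.76 + jit[15] | v < 0.18 + jit[16]
  )
  out <- vector("list", k)
  for (i in seq_len(k)) {
    mask <- shapes[[i]] * 1
    cov <- mean(mask)
    if (cov < 0.10 || cov > 0.40)
      stop(sprintf("template '%s' coverage %.2f outside [0.10, 0.40] on this grid",
                   names(shapes)[i], cov))
    out[[i]] <- list(mask = mask, pattern_id = i, coverage = cov,
                     name = names(shapes)[i])
  }
  out
}

#' Simulate spatially-expressed genes from a template
#'
#' Each simulated gene image is the template's noiseless base signal (mean
#' `mu_in` on active pixels, `mu_out` elsewhere) plus i.i.d. Gaussian
#' residual noise of the requested variance added to every pixel
#' independently, clipped at zero to preserve count-like non-negativity.
#'
#' @param template a template from [make_pattern_templates()].
#' @param n_per_pattern number of genes to simulate.
#' @param noise_variance residual error variance (the benchmark range is
#'   0.2-0.6).
#' @param seed integer seed.
#' @param mu_in,mu_out base signal means inside / outside the region.
#' @return a `gene_image_stack` of `n_per_pattern` genes.
#' @export
simulate_se_genes <- function(template, n_per_pattern, noise_variance,
                              seed = 1L, mu_in = 1.0, mu_out = 0.2) {
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  set.seed(seed)
  H <- nrow(template$mask); W <- ncol(template$mask)
  base <- mu_in * template$mask + mu_out * (1 - template$mask)
  noise <- array(stats::rnorm(H * W * n_per_pattern, 0, sqrt(noise_variance)),
                 dim = c(H, W, n_per_pattern))
  imgs <- pmax(array(base, dim = c(H, W, n_per_pattern)) + noise, 0)
  gene_image_stack(imgs,
                   genes = sprintf("P%d_g%04d", template$pattern_id,
                                   seq_len(n_per_pattern)))
}

#' Simulate spatially unstructured (non-SE) genes
#'
#' Images are i.i.d. noise around a flat mean, clipped at zero: no pixel is
#' correlated with its neighbors, so their expected spatial autocorrelation
#' is zero. They mimic genes without any spatial pattern mixed into real
#' datasets.
#'
#' @param n number of genes.
#' @param H,W grid dimensions.
#' @param seed integer seed.
#' @param mean flat mean level (default 0.4, the grand mean of a typical
#'   patterned gene at ~25% coverage).
#' @param noise_variance pixel variance (default 0.4, mid-range of the
#'   patterned simulations).
#' @return a `gene_image_stack` of `n` genes.
#' @export
simulate_non_se_genes <- function(n, H = 48L, W = 48L, seed = 1L,
                                  mean = 0.4, noise_variance = 0.4) {
  set.seed(seed)
  imgs <- pmax(array(stats::rnorm(H * W * n, mean, sqrt(noise_variance)),
                     dim = c(H, W, n)), 0)
  gene_image_stack(imgs, genes = sprintf("NSE_g%04d", seq_len(n)))
}

#' Simulate a full multi-pattern study
#'
#' Convenience wrapper reproducing the benchmark design: `k` templates, the
#' same number of spatially-expressed genes per pattern, and optionally a
#' complement of non-SE genes so that the requested SE fraction holds
#' exactly.
#'
#' @param k number of patterns.
#' @param n_per_pattern SE genes per pattern.
#' @param noise_variance residual error variance.
#' @param se_fraction fraction of all genes that are SE (1 = no non-SE
#'   genes). Mixing ratios from 90:10 to 10:90 are produced exactly.
#' @param H,W grid dimensions.
#' @param seed integer seed.
#' @param mu_in,mu_out base signal means.
#' @return a list with `stack` (all genes, SE first) and `truth`, a
#'   data.frame with columns `gene`, `pattern` (0 for non-SE) and `is_se`.
#' @export
simulate_study <- function(k = 5L, n_per_pattern = 400L, noise_variance = 0.2,
                           se_fraction = 1, H = 48L, W = 48L, seed = 1L,
                           mu_in = 1.0, mu_out = 0.2) {
  if (se_fraction <= 0 || se_fraction > 1) stop("se_fraction must be in (0, 1]")
  templates <- make_pattern_templates(k, H, W, seed = seed)
  stacks <- lapply(templates, function(tp)
    simulate_se_genes(tp, n_per_pattern, noise_variance,
                      seed = seed + 101L * tp$pattern_id,
                      mu_in = mu_in, mu_out = mu_out))
  n_se <- k * n_per_pattern
  imgs <- array(unlist(lapply(stacks, function(s) s$images), use.names = FALSE),
                dim = c(H, W, n_se))
  genes <- unlist(lapply(stacks, function(s) s$genes), use.names = FALSE)
  pattern <- rep(seq_len(k), each = n_per_pattern)
  if (se_fraction < 1) {
    n_non <- as.integer(round(n_se * (1 - se_fraction) / se_fraction))
    non <- simulate_non_se_genes(n_non, H, W, seed = seed + 7919L)
    imgs <- array(c(imgs, non$images), dim = c(H, W, n_se + n_non))
    genes <- c(genes, non$genes)
    pattern <- c(pattern, rep(0L, n_non))
  }
  stack <- gene_image_stack(imgs, genes = genes)
  list(stack = stack,
       truth = data.frame(gene = genes, pattern = pattern,
                          is_se = pattern > 0L, stringsAsFactors = FALSE))
}

#' Mask a region in a random half of the genes
#'
#' Suppresses expression to zero inside `region` for `round(fraction * G)`
#' randomly chosen genes, leaving the rest untouched. Mimics a tissue area
#' obscured or under-sampled for technical reasons in part of the genes.
#'
#' @param stack a `gene_image_stack`.
#' @param region binary `H x W` matrix (1 = masked area).
#' @param fraction fraction of genes to mask (default 0.5).
#' @param seed integer seed for the gene choice.
#' @return a list with `stack` (masked copy) and `masked_genes` (character).
#' @export
apply_mask <- function(stack, region, fraction = 0.5, seed = 1L) {
  d <- stack_dim(stack)
  if (!all(dim(region) == d)) stop("region shape does not match the stack grid")
  set.seed(seed)
  G <- n_genes(stack)
  n_mask <- round(fraction * G)
  picked <- sort(sample.int(G, n_mask))
  imgs <- stack$images
  keep <- 1 - region
  for (g in picked) imgs[, , g] <- imgs[, , g] * keep
  list(stack = gene_image_stack(imgs, genes = stack$genes,
                                grid_meta = stack$grid_meta),
       masked_genes = stack$genes[picked])
}

#' Shared-permutation pixel shuffle
#'
#' Flattens every gene image row-major and applies the SAME position
#' permutation to all genes before reshaping. Pixel-wise relationships
#' between genes (overlap, Pearson correlation) are exactly preserved while
#' spatial neighborhoods are destroyed, which makes this the canonical
#' negative control for methods that claim to use spatial shape.
#'
#' @param stack a `gene_image_stack`.
#' @param seed integer seed for the permutation.
#' @param permutation optionally, an explicit permutation of `1:(H*W)`;
#'   output pixel `p` takes the value of input pixel `permutation[p]`.
#' @return a list with `stack` (shuffled) and `permutation`.
#' @export
shuffle_stack <- function(stack, seed = 1L, permutation = NULL) {
  P <- prod(stack_dim(stack))
  if (is.null(permutation)) {
    set.seed(seed)
    permutation <- sample.int(P)
  }
  if (length(permutation) != P || anyDuplicated(permutation))
    stop("permutation must be a permutation of 1:(H*W)")
  m <- stack_matrix(stack)[, permutation, drop = FALSE]
  d <- stack_dim(stack)
  list(stack = matrix_stack(m, d[1], d[2], grid_meta = stack$grid_meta),
       permutation = permutation)
}

#' Partially shared-permutation shuffle
#'
#' Only a random fraction of pixel positions participates in the shared
#' permutation; the rest stay in place. `fraction = 0` is the identity and
#' `fraction = 1` equals [shuffle_stack()] with the same seed.
#'
#' @param stack a `gene_image_stack`.
#' @param fraction fraction of positions shuffled, in `[0, 1]`.
#' @param seed integer seed.
#' @return a list with `stack` and the effective `permutation`.
#' @export
partial_shuffle <- function(stack, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  P <- prod(stack_dim(stack))
  set.seed(seed)
  if (fraction == 1) {
    perm <- sample.int(P)
  } else {
    sel <- sample.int(P, round(fraction * P))
    perm <- seq_len(P)
    perm[sel] <- sel[sample.int(length(sel))]
  }
  shuffle_stack(stack, permutation = perm)
}
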