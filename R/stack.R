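#' Gene-image stack
#'
#' Container for G aligned per-gene expression images over one shared H x W
#' pixel grid. Internally images are stored as an `H x W x G` array with gene
#' identifiers on the third dimension; `grid_meta` records how spot
#' coordinates were mapped onto the grid (bin size, origin, original extent)
#' so that results can be related back to experiment units.
#'
#' @param images an `H x W x G` numeric array, or a list of G equally-sized
#'   matrices.
#' @param genes character vector of G unique, non-empty gene identifiers.
#'   If `images` has dimnames/names these are used as default.
#' @param grid_meta optional list with elements such as `bin_size`, `origin`
#'   (x0, y0) and `extent`.
#' @return An object of class `gene_image_stack`.
#' @export
gene_image_stack <- function(images, genes = NULL, grid_meta = list()) {
  if (is.list(images) && !is.array(images)) {
    if (length(images) == 0L) stop("empty image list")
    dims <- vapply(images, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all images must share the same H x W shape")
    if (is.null(genes)) genes <- names(images)
    images <- array(unlist(images, use.names = FALSE),
                    dim = unname(c(dims[1, 1], dims[2, 1], length(genes))))
  }
  if (length(dim(images)) == 2L) images <- array(images, dim = c(dim(images), 1L))
  if (length(dim(images)) != 3L) stop("images must be an H x W x G array")
  if (is.null(genes)) genes <- dimnames(images)[[3]]
  if (is.null(genes)) genes <- paste0("gene", seq_len(dim(images)[3]))
  genes <- as.character(genes)
  if (length(genes) != dim(images)[3]) stop("length(genes) != number of images")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (any(!nzchar(genes))) stop("gene identifiers must be non-empty")
  if (any(!is.finite(images))) stop("images contain NaN/Inf")
  dimnames(images) <- list(NULL, NULL, genes)
  structure(list(genes = genes, images = images, grid_meta = grid_meta),
            class = "gene_image_stack")
}

#' @export
print.gene_image_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("gene_image_stack: %d genes on a %d x %d grid\n", d[3], d[1], d[2]))
  if (length(x$grid_meta))
    cat("  grid_meta:", paste(names(x$grid_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of genes in a stack
#' @param stack a `gene_image_stack`.
#' @return integer count of genes.
#' @export
n_genes <- function(stack) length(stack$genes)

#' Grid dimensions of a stack
#' @param stack a `gene_image_stack`.
#' @return integer vector `c(H, W)`.
#' @export
stack_dim <- function(stack) unname(dim(stack$images)[1:2])

#' Flatten a stack to a gene-by-pixel matrix
#'
#' Each gene image is flattened row-major (all entries of row 1, then row 2,
#' ...), the same convention used by the shared-permutation shuffle, so that
#' pixel `p` of the flattened vector is grid position
#' `(floor((p-1)/W)+1, (p-1) %% W + 1)`.
#'
#' @param stack a `gene_image_stack`.
#' @return a `G x (H*W)` matrix with genes as rownames.
#' @export
stack_matrix <- function(stack) {
  d <- dim(stack$images)
  m <- aperm(stack$images, c(2, 1, 3))       # (W, H, G): columns vary fastest
  dim(m) <- c(d[1] * d[2], d[3])
  m <- t(m)
  rownames(m) <- stack$genes
  m
}

#' Rebuild a stack from a gene-by-pixel matrix
#'
#' Inverse of [stack_matrix()] (row-major pixel order).
#'
#' @param m a `G x (H*W)` matrix, rownames taken as gene identifiers.
#' @param H,W grid dimensions.
#' @param grid_meta passed through to [gene_image_stack()].
#' @return a `gene_image_stack`.
#' @export
matrix_stack <- function(m, H, W, grid_meta = list()) {
  if (ncol(m) != H * W) stop("ncol(m) != H*W")
  a <- t(m)
  dim(a) <- c(W, H, nrow(m))
  gene_image_stack(aperm(a, c(2, 1, 3)), genes = rownames(m), grid_meta = grid_meta)
}

#' Bin a spot table into a gene-image stack
#'
#' Aggregates per-spot counts onto a regular pixel grid: spot `(x, y)` is
#' assigned to pixel row `floor((y - y0)/s) + 1`, column `floor((x - x0)/s) + 1`
#' (row index = vertical axis), and each pixel holds the sum of counts of all
#' spots mapping into it. The binned grid is then cropped / zero-padded
#' symmetrically to `out_shape`; no interpolation is performed, so total
#' counts are conserved up to spots falling outside the crop.
#'
#' @param spots a spot table: data.frame with numeric columns `x`, `y` and one
#'   numeric count column per gene (wide format, as returned by
#'   [read_spot_table()]).
#' @param bin_factor size of a pixel in spot-coordinate units (`s` above).
#'   `NULL` (default) chooses the smallest `s` for which the binned extent
#'   fits inside `out_shape`.
#' @param out_shape integer vector `c(H, W)` of the output grid.
#' @return a `gene_image_stack` with `grid_meta` recording `bin_size`,
#'   `origin` and the original extent.
#' @export
bin_spot_table <- function(spots, bin_factor = NULL, out_shape = c(48L, 48L)) {
  if (!all(c("x", "y") %in% names(spots))) stop("spot table needs x and y columns")
  if (nrow(spots) == 0L) stop("empty spot table")
  gcols <- setdiff(names(spots), c("x", "y", "spot_id"))
  if (length(gcols) == 0L) stop("spot table has no gene columns")
  counts <- as.matrix(spots[, gcols, drop = FALSE])
  if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be finite and non-negative")
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y))) stop("coordinates must be finite")
  H <- as.integer(out_shape[1]); W <- as.integer(out_shape[2])
  if (H < 1L || W < 1L) stop("out_shape must be positive")
  x0 <- min(spots$x); y0 <- min(spots$y)
  if (is.null(bin_factor)) {
    ex <- max(spots$x) - x0; ey <- max(spots$y) - y0
    bin_factor <- max(ey / H, ex / W, .Machine$double.eps)
    bin_factor <- bin_factor * (1 + 1e-9)    # keep the max spot inside the grid
  }
  if (bin_factor < 1 && !is.null(bin_factor) && bin_factor <= 0)
    stop("bin_factor must be positive")
  row <- floor((spots$y - y0) / bin_factor) + 1L
  col <- floor((spots$x - x0) / bin_factor) + 1L
  nr <- max(row); nc <- max(col)
  # symmetric crop / zero-pad of the binned extent onto out_shape
  roff <- floor((H - nr) / 2); coff <- floor((W - nc) / 2)
  rr <- row + roff; cc <- col + coff
  keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  imgs <- array(0, dim = c(H, W, length(gcols)),
                dimnames = list(NULL, NULL, gcols))
  pix <- rr[keep] + (cc[keep] - 1L) * H
  for (g in seq_along(gcols)) {
    v <- counts[keep, g]
    s <- rowsum(v, pix)
    imgs[as.integer(rownames(s)) + (g - 1L) * H * W] <- s
  }
  gene_image_stack(imgs, genes = gcols,
                   grid_meta = list(bin_size = bin_factor, origin = c(x0, y0),
                                    extent = c(nr, nc)))
}

#' Pixel-wise log-total normalization
#'
#' Divides every gene's value at pixel `p` by `log(T_p + pseudocount)`,
#' where `T_p` is the total count at that pixel summed over all genes
#' (natural log). This removes systematic per-location coverage differences
#' so the learned representation reflects spatial covariance rather than
#' detection density. Pixels with zero total coverage are set to 0 for every
#' gene; the pseudocount keeps the divisor at least `log(1 + pseudocount)`
#' wherever data exist.
#'
#' @param stack a `gene_image_stack` of non-negative values.
#' @param pseudocount added to the pixel total inside the log; default 1.
#' @return a normalized `gene_image_stack`.
#' @export
normalize_pixelwise <- function(stack, pseudocount = 1) {
  imgs <- stack$images
  if (any(imgs < 0)) stop("normalize_pixelwise expects non-negative values")
  tot <- rowSums(imgs, dims = 2)             # H x W pixel totals over genes
  div <- log(tot + pseudocount)
  scale <- ifelse(tot > 0, 1 / div, 0)       # zero-coverage pixels -> 0
  out <- imgs * as.vector(scale)             # (H*W) recycles over genes
  gene_image_stack(out, genes = stack$genes, grid_meta = stack$grid_meta)
}

#' Scale an image to the unit interval
#'
#' Divides by the maximum value so that `max(out) == 1`, unless the image is
#' all zero (returned unchanged). Used for visualization of raw counts.
#'
#' @param image a non-negative numeric matrix.
#' @return a matrix with values in `[0, 1]`.
#' @export
scale_unit <- function(image) {
  if (any(image < 0)) stop("scale_unit expects non-negative values")
  m <- max(image)
  if (m == 0) image else image / m
}

#' Read a spot table from TSV/CSV
#'
#' Two layouts are supported. Wide: columns `x`, `y` (optionally `spot_id`)
#' followed by one count column per gene. Long: columns `x`, `y`, `gene`,
#' `count` (one row per spot-gene observation), which is widened with
#' missing combinations treated as 0.
#'
#' @param path file path (delimiter sniffed by [data.table::fread()]).
#' @return a wide-format spot table data.frame.
#' @export
read_spot_table <- function(path) {
  dt <- data.table::fread(path, data.table = TRUE)
  if (all(c("x", "y", "gene", "count") %in% names(dt))) {
    wide <- data.table::dcast(dt, x + y ~ gene, value.var = "count",
                              fun.aggregate = sum, fill = 0)
    return(as.data.frame(wide))
  }
  if (!all(c("x", "y") %in% names(dt))) stop("spot table needs x/y columns")
  as.data.frame(dt)
}

#' Read a Matrix Market spot-by-gene matrix with sidecars
#'
#' @param mtx path to an MTX triplet file (spots x genes or genes x spots;
#'   orientation resolved from the sidecar lengths).
#' @param genes_file one gene identifier per line.
#' @param coords_file TSV with columns `spot_id`, `x`, `y` in the same order
#'   as the MTX spot axis (barcodes file optional; row order is used).
#' @return a wide-format spot table data.frame.
#' @export
read_spot_mtx <- function(mtx, genes_file, coords_file) {
  m <- Matrix::readMM(mtx)
  genes <- readLines(genes_file)
  coords <- data.table::fread(coords_file, data.table = FALSE)
  if (!all(c("x", "y") %in% names(coords))) stop("coords file needs x/y columns")
  if (nrow(m) == length(genes) && ncol(m) == nrow(coords)) m <- Matrix::t(m)
  if (ncol(m) != length(genes) || nrow(m) != nrow(coords))
    stop("MTX dimensions do not match sidecars")
  out <- data.frame(x = coords$x, y = coords$y, as.matrix(m), check.names = FALSE)
  names(out)[-(1:2)] <- genes
  out
}

#' Write / read a stack container
#'
#' Single-file array store holding `genes`, `images` and `grid_meta`;
#' round-trips bit-identically.
#'
#' @param stack a `gene_image_stack`.
#' @param path output file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns the
#'   stack.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "gene_image_stack"))
  saveRDS(unclass(stack), path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  x <- readRDS(path)
  gene_image_stack(x$images, genes = x$genes, grid_meta = x$grid_meta)
}

#' Export per-gene PNG images for inspection
#'
#' Each image is 0-1 scaled with [scale_unit()] and written as a greyscale
#' PNG named after the gene.
#'
#' @param stack a `gene_image_stack`.
#' @param dir output directory (created if needed).
#' @param genes subset of genes to export; default all.
#' @return invisibly, the written file paths.
#' @export
write_stack_png <- function(stack, dir, genes = stack$genes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(genes))
  for (i in seq_along(genes)) {
    img <- scale_unit(stack$images[, , genes[i]])
    paths[i] <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", genes[i]), ".png"))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
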