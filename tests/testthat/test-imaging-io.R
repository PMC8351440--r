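test_that("gene_image_stack validates its invariants", {
  expect_error(gene_image_stack(list()), "empty")
  expect_error(gene_image_stack(list(a = matrix(0, 2, 2), b = matrix(0, 3, 3))),
               "same H x W")
  expect_error(gene_image_stack(array(0, c(2, 2, 2)), genes = c("g", "g")),
               "unique")
  expect_error(gene_image_stack(array(NaN, c(2, 2, 1)), genes = "g"), "NaN")
  s <- tiny_stack()
  expect_s3_class(s, "gene_image_stack")
  expect_identical(n_genes(s), 3L)
  expect_identical(stack_dim(s), c(4L, 4L))
})

test_that("stack_matrix flattens row-major and round-trips", {
  img <- matrix(1:6, 2, 3)                      # rows (1,3,5), (2,4,6)
  s <- gene_image_stack(list(g = img))
  m <- stack_matrix(s)
  expect_equal(as.vector(m), c(1, 3, 5, 2, 4, 6))   # row 1 then row 2
  back <- matrix_stack(m, 2, 3)
  expect_equal(back$images[, , 1], img)
})

test_that("bin_spot_table sums counts into pixels and conserves totals", {
  # one spot, count 5 -> the single covering pixel holds 5
  one <- data.frame(x = 3.2, y = 1.7, geneA = 5)
  st <- bin_spot_table(one, bin_factor = 1, out_shape = c(4, 4))
  expect_equal(sum(st$images), 5)
  expect_equal(sum(st$images > 0), 1)

  # four spots with counts 1,2,3,4 in one bin -> that pixel holds 10
  four <- data.frame(x = c(0.1, 0.4, 0.2, 0.9), y = c(0.1, 0.6, 0.9, 0.3),
                     g = 1:4)
  st4 <- bin_spot_table(four, bin_factor = 1, out_shape = c(3, 3))
  expect_equal(max(st4$images), 10)
  expect_equal(sum(st4$images), 10)

  # conservation identity over random tables when nothing is cropped
  set.seed(7)
  spots <- data.frame(x = runif(200, 0, 10), y = runif(200, 0, 10),
                      gA = rpois(200, 3), gB = rpois(200, 1))
  st <- bin_spot_table(spots, bin_factor = NULL, out_shape = c(12, 12))
  expect_equal(sum(st$images), sum(spots$gA) + sum(spots$gB))

  expect_error(bin_spot_table(spots[0, ], 1, c(4, 4)), "empty")
  spots$gA[1] <- -1
  expect_error(bin_spot_table(spots, 1, c(4, 4)), "non-negative")
})

test_that("normalize_pixelwise follows the log-total contract", {
  # pixel total e - pseudocount -> divisor 1, values unchanged there
  img1 <- matrix(0, 2, 2); img1[1, 1] <- exp(1) - 1
  s <- gene_image_stack(list(g1 = img1))
  out <- normalize_pixelwise(s)
  expect_equal(unname(out$images[1, 1, 1]), exp(1) - 1)

  # value 4 with pixel total + pseudocount = e^2 -> 2.0
  a <- matrix(0, 2, 2); a[1, 1] <- 4
  b <- matrix(0, 2, 2); b[1, 1] <- exp(2) - 1 - 4
  out2 <- normalize_pixelwise(gene_image_stack(list(a = a, b = b)))
  expect_equal(unname(out2$images[1, 1, "a"]), 2.0)

  # zero-coverage pixels -> 0 everywhere, never NaN/Inf
  expect_equal(unname(out$images[2, 2, 1]), 0)
  set.seed(1)
  rs <- gene_image_stack(array(rbinom(5 * 5 * 10, 3, 0.2), c(5, 5, 10)))
  rn <- normalize_pixelwise(rs)
  expect_true(all(is.finite(rn$images)))
})

test_that("scale_unit maps onto [0,1] with degenerate cases intact", {
  expect_equal(scale_unit(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_equal(scale_unit(matrix(2.5, 2, 2)), matrix(1, 2, 2))
  expect_equal(scale_unit(matrix(c(1, 4), 1)), matrix(c(0.25, 1), 1))
})

test_that("stack container round-trips bit-identically", {
  s <- small_study(npp = 5L, H = 12L, W = 12L)$stack
  path <- tempfile(fileext = ".rds")
  write_stack(s, path)
  s2 <- read_stack(path)
  expect_identical(s2$images, s$images)
  expect_identical(s2$genes, s$genes)
})

test_that("spot-table readers handle wide, long and MTX layouts", {
  wide <- data.frame(x = c(1, 2), y = c(1, 2), gA = c(3, 0), gB = c(0, 7))
  f <- tempfile(fileext = ".csv")
  write.csv(wide, f, row.names = FALSE)
  got <- read_spot_table(f)
  expect_equal(got$gA, c(3, 0))

  long <- data.frame(x = c(1, 1, 2), y = c(1, 1, 2),
                     gene = c("gA", "gB", "gA"), count = c(3, 2, 4))
  fl <- tempfile(fileext = ".tsv")
  write.table(long, fl, sep = "\t", row.names = FALSE)
  gl <- read_spot_table(fl)
  expect_equal(sort(setdiff(names(gl), c("x", "y"))), c("gA", "gB"))
  expect_equal(sum(gl$gA), 7)

  m <- Matrix::Matrix(c(1, 0, 2, 5, 0, 3), 2, 3, sparse = TRUE)  # spots x genes
  fm <- tempfile(fileext = ".mtx"); Matrix::writeMM(m, fm)
  fg <- tempfile(); writeLines(c("g1", "g2", "g3"), fg)
  fc <- tempfile()
  write.table(data.frame(spot_id = c("s1", "s2"), x = c(0, 1), y = c(0, 1)),
              fc, sep = "\t", row.names = FALSE)
  sp <- read_spot_mtx(fm, fg, fc)
  expect_equal(dim(sp), c(2L, 5L))
  expect_equal(sp$g2, c(2, 5))
})

test_that("PNG export writes one readable file per gene", {
  s <- tiny_stack()
  d <- tempfile()
  paths <- write_stack_png(s, d)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths[1])
  expect_equal(dim(img)[1:2], c(4L, 4L))
})
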