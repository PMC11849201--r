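plus_sign <- function(size = 64, half = 15) {
  c0 <- size / 2
  img <- matrix(FALSE, size, size)
  img[c0, (c0 - half):(c0 + half)] <- TRUE
  img[(c0 - half):(c0 + half), c0] <- TRUE
  img
}

test_that("skeleton graph classifies lines, crossings and empty images", {
  # 50-pixel horizontal line: one branch, 49 unit steps
  l <- matrix(FALSE, 60, 60); l[30, 6:55] <- TRUE
  g <- skeleton_graph(l)
  expect_identical(g$n_junctions, 0L)
  expect_identical(g$n_endpoints, 2L)
  expect_equal(g$total_length_um, 49)
  expect_identical(nrow(g$branches), 1L)
  # 10-step diagonal
  d <- matrix(FALSE, 20, 20)
  for (i in 1:10) d[i + 2, i + 2] <- TRUE
  expect_equal(skeleton_graph(d)$total_length_um, 9 * sqrt(2))
  # plus sign: one junction cluster, four endpoints, four branches; the
  # cluster absorbs the four centre-adjacent pixels, so each 15-px arm
  # contributes 13 internal steps plus its connection step
  g2 <- skeleton_graph(plus_sign())
  expect_identical(g2$n_junctions, 1L)
  expect_identical(g2$n_endpoints, 4L)
  expect_identical(nrow(g2$branches), 4L)
  expect_equal(g2$total_length_um, 4 * 14)
  expect_equal(g2$avg_length_um, 14)
  # empty image
  e <- skeleton_graph(matrix(FALSE, 10, 10))
  expect_identical(e$n_junctions, 0L)
  expect_identical(e$total_length_um, 0)
})

test_that("thinning reduces a thick bar to a unit-width skeleton", {
  img <- matrix(FALSE, 30, 30)
  img[14:16, 5:25] <- TRUE  # 3-px-thick bar
  sk <- skeletonize_image(img)
  # unit width everywhere (blunt ends erode by up to 2 px, as usual for
  # two-subiteration thinning)
  expect_true(all(colSums(sk) <= 1))
  expect_gte(sum(sk), 15)
  g <- skeleton_graph(sk)
  expect_identical(g$n_junctions, 0L)
  expect_identical(g$n_endpoints, 2L)
})

test_that("gliding-box lacunarity matches enumerable patterns", {
  expect_equal(gliding_box_lacunarity(matrix(TRUE, 16, 16)), 1)
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2 == 1)
  # r = 1: boxes hold 0 or 1 with equal probability -> E[m^2]/E[m]^2 = 2
  expect_equal(gliding_box_lacunarity(cb, box_sizes = 1), 2)
  # r = 2 boxes always hold exactly 2 -> 1
  expect_equal(gliding_box_lacunarity(cb, box_sizes = 2), 1)
  expect_error(gliding_box_lacunarity(matrix(FALSE, 8, 8)), "undefined")
  expect_error(gliding_box_lacunarity(matrix(TRUE, 4, 4), box_sizes = 8), "fits")
})

test_that("clustering raises lacunarity at matched density", {
  set.seed(21)
  n <- 64
  uniform <- matrix(runif(n^2) < 0.2, n, n)
  clustered <- matrix(FALSE, n, n)
  centres <- cbind(sample(8:56, 10), sample(8:56, 10))
  for (k in seq_len(nrow(centres))) {
    clustered[centres[k, 1] + (-4:4), centres[k, 2] + (-4:4)] <- TRUE
  }
  expect_gt(gliding_box_lacunarity(clustered),
            gliding_box_lacunarity(uniform))
})

test_that("derived ratios are the exact quotients", {
  r <- derived_ratios(73117, 299, 541, 10386)
  expect_equal(r$branching_rate, 0.00409, tolerance = 1e-3)
  expect_equal(r$endpoint_rate, 0.00740, tolerance = 1e-3)
  expect_equal(r$protein_width_um, 7.04, tolerance = 1e-3)
  degenerate <- derived_ratios(1, 0, 0, 1)
  expect_equal(unlist(degenerate), c(branching_rate = 0, endpoint_rate = 0,
                                     protein_width_um = 1))
  expect_error(derived_ratios(0, 1, 1, 1), "protein_area")
  expect_error(derived_ratios(1, 1, 1, 0), "total_length")
})

test_that("network metrics are translation- and rotation-invariant", {
  # boxes must stay clear of the frame border for the gliding-box statistic
  # to be exactly translation-invariant, so the box set stops at 8 here
  boxes <- c(2, 4, 8)
  base <- gen_network_image(4, 10, 48, seed = 1, rotate = FALSE)$img
  m0 <- network_metrics(base, box_sizes = boxes)
  shifted <- matrix(FALSE, 48, 48)
  shifted[7:48, 5:48] <- base[1:42, 1:44]
  m1 <- network_metrics(shifted, box_sizes = boxes)
  rotated <- t(base[nrow(base):1, ])  # 90 degrees
  m2 <- network_metrics(rotated, box_sizes = boxes)
  for (m in list(m1, m2)) {
    expect_identical(m$n_junctions, m0$n_junctions)
    expect_identical(m$n_endpoints, m0$n_endpoints)
    expect_equal(m$total_length_um, m0$total_length_um)
    expect_equal(m$protein_area_um2, m0$protein_area_um2)
    expect_equal(m$lacunarity, m0$lacunarity)
  }
})

test_that("pixel size scales lengths linearly and areas quadratically", {
  img <- plus_sign()
  m1 <- network_metrics(img, pixel_size = 1)
  m2 <- network_metrics(img, pixel_size = 2)
  expect_equal(m2$total_length_um, 2 * m1$total_length_um)
  expect_equal(m2$protein_area_um2, 4 * m1$protein_area_um2)
  expect_equal(m2$protein_width_um, 2 * m1$protein_width_um)
  expect_identical(m2$n_junctions, m1$n_junctions)
  expect_equal(m2$lacunarity, m1$lacunarity)
})

test_that("image files round-trip through the binary reader", {
  skip_if_not_installed("png")
  img <- plus_sign(32, 8)
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img * 1, tmp)
  back <- read_network_image(tmp, threshold = 0.5)
  expect_identical(back, img)
  # grayscale + Otsu
  gray <- img * 0.8 + 0.05
  png::writePNG(gray, tmp)
  expect_identical(read_network_image(tmp), img)
})
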