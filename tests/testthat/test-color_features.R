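test_that("multi-color lift handles the achromatic extremes by convention", {
  black <- rgb_to_multicolor(c(0, 0, 0))
  expect_equal(as.numeric(black),
               c(0, 0, 0, 0, 128 / 255, 128 / 255, 0, 0, 0, 1),
               tolerance = 1e-7)
  white <- rgb_to_multicolor(c(1, 1, 1))
  expect_equal(unname(white[1, "S"]), 0)
  expect_equal(unname(white[1, "V"]), 1)
  expect_equal(unname(white[1, "L"]), 1, tolerance = 1e-7)
  expect_equal(as.numeric(white[1, c("C", "M", "Y", "K")]), rep(0, 4))
  gray <- rgb_to_multicolor(c(0.5, 0.5, 0.5))
  expect_equal(unname(gray[1, "K"]), 0.5)
  expect_equal(as.numeric(gray[1, c("a", "b")]), rep(128 / 255, 2),
               tolerance = 1e-7)
  expect_error(rgb_to_multicolor(c(1.5, 0, 0)), class = "rcs_validation_error")
})

test_that("multi-color lift matches the independent reference conversion", {
  set.seed(19)
  rgb <- matrix(runif(300), ncol = 3)
  expect_lt(max(abs(rgb_to_multicolor(rgb) - oracle_multicolor(rgb))), 1e-6)
})

test_that("Lab channel agrees with farver within color-management slack", {
  skip_if_not_installed("farver")
  set.seed(23)
  rgb <- matrix(runif(150), ncol = 3)
  ours <- rgb_to_multicolor(rgb)
  lab <- farver::convert_colour(rgb * 255, from = "rgb", to = "lab")
  theirs <- cbind(lab[, 1] / 100, (lab[, 2] + 128) / 255,
                  (lab[, 3] + 128) / 255)
  expect_lt(max(abs(ours[, c("L", "a", "b")] - theirs)), 0.01)
})

test_that("Eigen-color basis is an orthonormal PCA with conserved variance", {
  set.seed(29)
  X <- rgb_to_multicolor(matrix(runif(1500), ncol = 3))
  basis <- fit_eigen_basis(X)
  G <- t(basis$components) %*% basis$components
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(basis$explained_variance) <= 1e-12))
  expect_equal(sum(basis$explained_variance), sum(diag(stats::cov(X))),
               tolerance = 1e-8)
  expect_error(fit_eigen_basis(X[1, , drop = FALSE]),
               class = "rcs_validation_error")
})

test_that("rank-1 pixel data yields exactly one nonzero variance component", {
  t_ <- seq(0, 1, length.out = 50)
  X <- outer(t_, c(1, 2, 0.5, 0, 1, 1, 3, 0.2, 0.1, 0.7))
  ev <- fit_eigen_basis(X)$explained_variance
  expect_gt(ev[1], 0)
  expect_lt(max(ev[-1]), 1e-12)
})

test_that("PCA components match an independent SVD computation up to sign", {
  set.seed(31)
  X <- matrix(runif(5000), ncol = 10)
  basis <- fit_eigen_basis(X)
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  for (j in 1:10) {
    v <- sv$v[, j]
    d <- min(max(abs(basis$components[, j] - v)),
             max(abs(basis$components[, j] + v)))
    expect_lt(d, 1e-8)
  }
  expect_equal(basis$explained_variance, sv$d^2 / (nrow(X) - 1),
               tolerance = 1e-8)
})

test_that("full projection and back-projection reconstruct the features", {
  set.seed(37)
  X <- rgb_to_multicolor(matrix(runif(900), ncol = 3))
  basis <- fit_eigen_basis(X)
  rec <- backproject_eigen(basis, project_eigen(basis, X))
  expect_lt(max(abs(rec - X)), 1e-8)
})

test_that("region reduction recovers uniform and palette colors exactly", {
  img <- flat_image(10, 10, c(0.2, 0.6, 0.3))
  mask <- matrix(TRUE, 10, 10)
  f <- multicolor_features(img, mask)
  part <- reduce_to_regions(f, mask, n_regions = 5, seed = 1)
  expect_identical(part$n_regions, 1L)
  expect_equal(as.numeric(part$ackmr),
               as.numeric(rgb_to_multicolor(c(0.2, 0.6, 0.3))))

  # two well-separated colors -> the two palette rows exactly
  px <- array(0, c(10, 10, 3))
  px[, 1:5, ] <- rep(c(0.9, 0.1, 0.1), each = 50)
  px[, 6:10, ] <- rep(c(0.1, 0.2, 0.9), each = 50)
  img2 <- rcs_image(px)
  f2 <- multicolor_features(img2, matrix(TRUE, 10, 10))
  part2 <- reduce_to_regions(f2, matrix(TRUE, 10, 10), n_regions = 2,
                             seed = 1)
  expect_identical(part2$n_regions, 2L)
  want <- rgb_to_multicolor(rbind(c(0.9, 0.1, 0.1), c(0.1, 0.2, 0.9)))
  got <- part2$ackmr[order(part2$ackmr[, "H"]), ]
  want <- want[order(want[, "H"]), ]
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("region partition labels cover the mask and AC-KMR rows are the region means", {
  fx <- generate_pair(tiny_spec(seed = 41))
  mask <- fx$truth_vis
  f <- multicolor_features(fx$pair$vis, mask)
  part <- reduce_to_regions(f, mask, n_regions = 8, seed = 2)
  expect_lte(part$n_regions, 8L)
  expect_true(all(part$labels[mask$pixels] >= 0L))
  expect_true(all(part$labels[!mask$pixels] == -1L))
  lab <- part$labels[mask$pixels] + 1L
  for (k in seq_len(part$n_regions)) {
    expect_equal(as.numeric(part$ackmr[k, ]),
                 as.numeric(colMeans(f[lab == k, , drop = FALSE])),
                 tolerance = 1e-10)
  }
  expect_error(reduce_to_regions(f[0, ], matrix(FALSE, 2, 2), 1),
               class = "rcs_empty_mask_error")
})

test_that("k-means solution is a Lloyd fixed point no worse than restart oracles", {
  set.seed(43)
  X <- matrix(runif(10000), ncol = 10)
  mask <- matrix(TRUE, 100, 10)
  attr(X, "index") <- seq_len(1000)
  part <- reduce_to_regions(X, mask, n_regions = 10, seed = 3,
                            use_eigen = FALSE)
  # an independent Lloyd pass started at the returned centroids cannot improve
  orc <- rcseg:::lloyd_kmeans(X, part$centroids)
  expect_equal(orc$inertia, part$inertia, tolerance = 1e-6)
})

test_that("paired FLU+VIS features have 20 columns and use the reference color out of frame", {
  fx <- generate_pair(tiny_spec(seed = 47))
  tf <- fx$applied_transform
  mask <- rcs_mask(matrix(TRUE, dim(fx$pair$vis)[1], dim(fx$pair$vis)[2]),
                   "VIS")
  pf <- pair_features(fx$pair, mask, tf)
  expect_identical(ncol(pf), 20L)
  expect_true(all(pf >= 0 & pf <= 1))
})
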