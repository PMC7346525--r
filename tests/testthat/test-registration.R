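blob_mask <- function(seed = 1L, h = 200L, w = 200L) {
  fx <- generate_pair(tiny_spec(seed = seed, stage = "II"))
  m <- matrix(FALSE, h, w)
  src <- fx$truth_flu$pixels
  m[1:min(h, nrow(src)), 1:min(w, ncol(src))] <-
    src[1:min(h, nrow(src)), 1:min(w, ncol(src))]
  rcs_mask(m, "FLU")
}

test_that("transform algebra: matrix round trip, inversion and composition", {
  t1 <- rcs_transform(scale = 1.2, rotation = 8, translation = c(5, -3),
                      center = c(50, 60))
  t2 <- rcs_transform(scale = 0.9, rotation = -4, translation = c(-2, 7))
  p <- cbind(c(0, 10, 33.5), c(0, -4, 12.25))
  expect_equal(apply_transform(compose_transforms(t1, t2), p),
               apply_transform(t1, apply_transform(t2, p)), tolerance = 1e-10)
  inv <- invert_transform(t1)
  expect_equal(apply_transform(inv, apply_transform(t1, p)), p,
               tolerance = 1e-10)
  back <- rcseg:::transform_from_matrix(transform_matrix(t1))
  expect_equal(transform_matrix(back), transform_matrix(t1),
               tolerance = 1e-10)
  expect_error(rcs_transform(scale = -1), class = "rcs_validation_error")
})

test_that("mask transfer: identity is exact and translations move pixels", {
  m <- blob_mask(2)
  idt <- rcs_transform()
  expect_identical(transfer_mask(m, idt, dim(m))$pixels, m$pixels)

  single <- matrix(FALSE, 20, 20)
  single[10, 8] <- TRUE
  out <- transfer_mask(rcs_mask(single, "FLU"),
                       rcs_transform(translation = c(3, 0)), c(20, 20))
  expect_identical(which(out$pixels), which(single) + 3L * 20L)
})

test_that("inverse-mapping transfer agrees with a forward rasterization oracle", {
  # contractive scale: forward rasterization is dense there, so the two
  # resampling routes must agree almost everywhere
  m <- blob_mask(3)
  tf <- rcs_transform(scale = 0.95, rotation = 7, translation = c(12, -6),
                      center = c(100, 100))
  got <- transfer_mask(m, tf, c(240, 240))$pixels
  want <- oracle_forward_rasterize(m$pixels, tf, c(240, 240))
  expect_gte(dice(got, want), 0.98)
})

test_that("self-alignment returns the identity within tolerance", {
  m <- blob_mask(4)
  tf <- estimate_similarity_transform(m, rcs_mask(m$pixels, "VIS"))
  expect_lte(abs(tf$translation[1]), 0.5)
  expect_lte(abs(tf$translation[2]), 0.5)
  expect_lte(abs(tf$rotation), 0.1)
  expect_lte(abs(tf$scale - 1), 0.005)
})

test_that("known translations and rotation/scale misalignments are recovered", {
  m <- blob_mask(5)
  t_shift <- rcs_transform(translation = c(12, -7))
  vis <- transfer_mask(m, t_shift, c(220, 220))
  got <- estimate_similarity_transform(m, vis)
  ctr <- rcseg:::mask_centroid(m$pixels)
  err <- apply_transform(got, rbind(ctr)) - apply_transform(t_shift, rbind(ctr))
  expect_lte(abs(err[1]), 1)
  expect_lte(abs(err[2]), 1)

  ctr_m <- rcseg:::mask_centroid(m$pixels)
  t_rs <- rcs_transform(scale = 1.2, rotation = 5, center = ctr_m)
  vis2 <- transfer_mask(m, t_rs, c(260, 260))
  got2 <- estimate_similarity_transform(m, vis2)
  expect_lte(abs(got2$rotation - 5), 0.5)
  expect_lte(abs(got2$scale / 1.2 - 1), 0.01)
})

test_that("estimation on (mask, transfer(mask, T)) composes to the identity", {
  m <- blob_mask(6)
  tf <- rcs_transform(scale = 1.1, rotation = -6, translation = c(15, 9),
                      center = c(90, 90))
  vis <- transfer_mask(m, tf, c(260, 260))
  est <- estimate_similarity_transform(m, vis)
  comp <- compose_transforms(invert_transform(est), tf)
  ctr <- rcseg:::mask_centroid(m$pixels)
  moved <- apply_transform(comp, rbind(ctr))
  expect_lte(sqrt(sum((moved - rbind(ctr))^2)), 1.5)
  expect_lte(abs(comp$scale - 1), 0.01)
  expect_lte(abs(comp$rotation), 0.6)
})

test_that("registration never worsens the initial overlap on misaligned fixtures", {
  for (s in 1:3) {
    fx <- generate_pair(tiny_spec(seed = 40 + s, stage = "II"))
    fp <- preseg_mask(fx$pair$flu, fx$pair$flu_ref)
    vp <- preseg_mask(fx$pair$vis, fx$pair$vis_ref)
    unreg <- transfer_mask(fp, rcs_transform(), dim(vp))
    est <- estimate_similarity_transform(fp, vp)
    reg <- transfer_mask(fp, est, dim(vp))
    expect_gte(dice(reg, vp), dice(unreg, vp))
  }
})

test_that("registering empty masks raises a registration error", {
  m <- blob_mask(7)
  empty <- rcs_mask(matrix(FALSE, 50, 50), "VIS")
  expect_error(estimate_similarity_transform(m, empty),
               class = "rcs_registration_error")
  expect_error(estimate_similarity_transform(empty, m),
               class = "rcs_registration_error")
})

test_that("transform JSON round trip preserves the mapping", {
  tf <- rcs_transform(scale = 1.27, rotation = 2.5, translation = c(55.5, -4),
                      center = c(64, 80))
  f <- withr::local_tempfile(fileext = ".json")
  save_transform(tf, f)
  back <- load_transform(f)
  expect_equal(transform_matrix(back), transform_matrix(tf),
               tolerance = 1e-12)
})
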