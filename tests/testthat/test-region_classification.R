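test_that("every member separates a well-margined two-blob training table", {
  tab <- separable_table(seed = 51)
  ens <- suppressWarnings(train_ensemble(tab$X, tab$y, seed = 1))
  expect_identical(names(ens$members),
                   c("bayes", "da", "glm", "gpr", "linmod", "svm", "svmreg",
                     "net"))
  preds <- predict_ensemble(ens, tab$X)
  for (acr in rownames(preds))
    expect_identical(unname(preds[acr, ]), tab$y, label = acr)
})

test_that("degenerate training tables are rejected or survived", {
  tab <- separable_table(seed = 52)
  expect_error(train_ensemble(tab$X, rep(1L, nrow(tab$X))),
               class = "rcs_training_error")
  # minimal viable table: 8 rows, 4 per class
  Xs <- tab$X[c(1:4, 31:34), ]
  ys <- tab$y[c(1:4, 31:34)]
  ens <- suppressWarnings(train_ensemble(Xs, ys, seed = 1))
  expect_length(ens$members, 8L)
  # constant feature dropped with a warning, ensemble still trains
  Xc <- cbind(tab$X, 0.5)
  w <- capture_warnings(ens2 <- train_ensemble(Xc, tab$y))
  expect_true(any(grepl("constant", w)))
  expect_identical(ens2$feature_dim, 11L)
  expect_identical(length(ens2$normalization$kept), 10L)
})

test_that("the fuzzy-estimate threshold is exactly 0.5 with ties going to plant", {
  # linear regressor trained on y = x reproduces FE = x exactly
  X <- matrix(seq(0, 1, length.out = 21), ncol = 1)
  member <- rcseg:::train_one_member("linmod",
                                     rcseg:::feat_df(X),
                                     as.numeric(X), 10L, 1L)
  member$norm <- list(min = 0, max = 1, kept = 1L)
  expect_identical(predict_member(member, matrix(0.5)), 1L)
  expect_identical(predict_member(member, matrix(0.49)), 0L)
  expect_identical(predict_member(member, matrix(0.51)), 1L)
})

test_that("median and fusion combination follow the vote conventions", {
  all1 <- matrix(1L, 8, 3)
  expect_identical(combine_predictions(all1),
                   list(median = rep(1L, 3), fusion = rep(1L, 3)))
  one1 <- matrix(0L, 8, 3); one1[5, ] <- 1L
  expect_identical(combine_predictions(one1)$fusion, rep(1L, 3))
  expect_identical(combine_predictions(one1)$median, rep(0L, 3))
  tie <- matrix(0L, 8, 1); tie[1:4, 1] <- 1L
  expect_identical(combine_predictions(tie)$median, 1L)  # 4-4 tie -> plant
  expect_error(combine_predictions(matrix(0L, 7, 2)),
               class = "rcs_validation_error")
})

test_that("fusion is the union of member masks and contains the median mask", {
  tab <- separable_table(seed = 53, margin = 0.8)
  ens <- suppressWarnings(train_ensemble(tab$X, tab$y, seed = 2))
  set.seed(54)
  Xnew <- matrix(runif(400, -0.5, 1.3), ncol = 10)
  L <- predict_ensemble(ens, Xnew)
  comb <- combine_predictions(L)
  expect_identical(comb$fusion, as.integer(colSums(L) > 0))
  expect_true(all(comb$fusion >= comb$median))
})

test_that("predictions are equivariant under region permutation", {
  tab <- separable_table(seed = 55)
  ens <- suppressWarnings(train_ensemble(tab$X, tab$y, seed = 1))
  set.seed(56)
  Xnew <- matrix(runif(200), ncol = 10)
  perm <- sample(nrow(Xnew))
  expect_identical(predict_ensemble(ens, Xnew)[, perm],
                   predict_ensemble(ens, Xnew[perm, ]))
})

test_that("region labels broadcast back to the pre-segmentation support", {
  fx <- generate_pair(tiny_spec(seed = 57))
  mask <- fx$truth_vis
  f <- multicolor_features(fx$pair$vis, mask)
  part <- reduce_to_regions(f, mask, n_regions = 10, seed = 1)
  tab <- separable_table(seed = 58)
  ens <- suppressWarnings(train_ensemble(tab$X, tab$y, seed = 1))
  always1 <- ens
  for (a in names(always1$members))
    always1$members[[a]] <- structure(list(kind = "stub", acronym = a,
                                           label = 1,
                                           norm = ens$members[[a]]$norm),
                                      class = NULL)
  m1 <- segment_regions(part, always1, combine = "median")
  expect_identical(m1$pixels, mask$pixels)
  always0 <- always1
  for (a in names(always0$members)) always0$members[[a]]$label <- 0
  m0 <- segment_regions(part, always0, combine = "median")
  expect_false(any(m0$pixels))
  expect_error(segment_regions(part, structure(list(
    members = ens$members, feature_dim = 20L,
    normalization = ens$normalization, fe_threshold = 0.5),
    class = "rcs_ensemble")), class = "rcs_validation_error")
})

test_that("model bundles round trip losslessly and reject broken bundles", {
  tab <- separable_table(seed = 59)
  ens <- suppressWarnings(train_ensemble(tab$X, tab$y, seed = 4))
  filt <- suppressWarnings(train_object_filter(
    data.frame(size = c(5, 900, 8, 700, 12, 800, 4, 600),
               r_over_b = c(2, 1, 2.2, 1.1, 1.9, 0.9, 2.1, 1),
               r_over_g = c(1.5, 0.6, 1.4, 0.5, 1.6, 0.6, 1.5, 0.5),
               g_over_b = c(1.2, 2.2, 1.3, 2.4, 1.1, 2.3, 1.2, 2.2),
               vicinity = c(80, 0, 90, 0, 70, 0, 60, 0)),
    c(0, 1, 0, 1, 0, 1, 0, 1), seed = 1))
  model <- case_scenario_model(ens, filt,
                               list(species = "synthetic-rosette",
                                    view = "top", modality = "VIS",
                                    stages = "I", n_regions = 10L))
  d <- withr::local_tempdir()
  bundle <- file.path(d, "model")
  save_model(model, bundle)
  back <- load_model(bundle)
  set.seed(60)
  Xnew <- matrix(runif(300), ncol = 10)
  expect_identical(predict_ensemble(back$ensemble, Xnew),
                   predict_ensemble(model$ensemble, Xnew))
  expect_identical(back$meta$stages, "I")
  expect_false(is.null(back$object_filter))

  expect_error(load_model(file.path(d, "nothere")),
               class = "rcs_model_load_error")
  file.remove(file.path(bundle, "members", "gpr.rds"))
  expect_error(load_model(bundle), regexp = "gpr",
               class = "rcs_model_load_error")
})

test_that("scenario metadata invariants are enforced", {
  tab <- separable_table(seed = 61)
  ens <- suppressWarnings(train_ensemble(tab$X, tab$y))
  expect_error(case_scenario_model(ens, NULL,
                                   list(species = "s", view = "top",
                                        modality = "VIS", stages = character(),
                                        n_regions = 10L)),
               class = "rcs_validation_error")
  expect_error(case_scenario_model(ens, NULL,
                                   list(species = "s", view = "top",
                                        modality = "VIS", stages = "I",
                                        n_regions = 5L)),
               class = "rcs_validation_error")
})
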