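test_that("accuracy follows the confusion-matrix formula on worked examples", {
  expect_equal(accuracy(list(tp = 2, fp = 0, fn = 0, tn = 2)), 1.0)
  expect_equal(accuracy(list(tp = 1, fp = 1, fn = 1, tn = 1)), 0.5)
  expect_equal(accuracy(list(tp = 90, fp = 5, fn = 3, tn = 2)), 0.92)
  expect_error(accuracy(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "rcs_undefined_accuracy_error")
})

test_that("region confusion matches enumeration and handles edge patterns", {
  set.seed(81)
  truth <- rbinom(30, 1, 0.5)
  pred <- rbinom(30, 1, 0.5)
  cm <- region_confusion(truth, pred)
  want <- oracle_confusion(truth, pred)
  expect_identical(c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn), want)

  same <- region_confusion(truth, truth)
  expect_identical(same$fp + same$fn, 0L)

  allplant <- region_confusion(rep(c(1, 0), 10), rep(1, 20))
  expect_identical(allplant$fp, 10L)
  expect_identical(allplant$fn, 0L)

  expect_error(region_confusion(c(1, 0), c(1, 0, 1)),
               class = "rcs_validation_error")
  expect_error(region_confusion(c(1, 2), c(1, 0)),
               class = "rcs_validation_error")
})

test_that("accuracy is invariant under simultaneous label flip", {
  set.seed(83)
  for (i in 1:10) {
    truth <- rbinom(25, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(25, 1, runif(1, 0.2, 0.8))
    a <- accuracy(region_confusion(truth, pred))
    b <- accuracy(region_confusion(1 - truth, 1 - pred))
    expect_equal(a, b)
    expect_equal(a, 1 - mean(truth != pred))  # 1 - region error rate
  }
})

test_that("region truth labelling uses majority with ties to plant", {
  labels <- matrix(-1L, 4, 4)
  labels[1, 1:4] <- 0L      # region 0: 2 of 4 plant -> tie -> plant
  labels[2, 1:3] <- 1L      # region 1: 1 of 3 plant -> background
  part <- structure(list(labels = labels, n_regions = 2L), class = "rcs_regions")
  truth <- matrix(FALSE, 4, 4)
  truth[1, 1:2] <- TRUE
  truth[2, 1] <- TRUE
  expect_identical(region_truth_labels(part, truth), c(1L, 0L))
})

test_that("the scenario grid emits 8 records per model and test set", {
  set.seed(85)
  mk_samples <- function(n) lapply(seq_len(n), function(i) {
    tab <- separable_table(n_per_class = 8, seed = 1000 + i)
    list(X = tab$X, y = tab$y)
  })
  datasets <- list(I = list(train = mk_samples(2), test = mk_samples(1)),
                   II = list(train = mk_samples(2), test = mk_samples(1)),
                   III = list(train = mk_samples(2), test = mk_samples(1)))
  grid <- list(species = "synthetic-rosette", view = "top", modality = "VIS",
               stage_combos = list("I", "II", "III", c("I", "II"),
                                   c("I", "III"), c("II", "III"),
                                   c("I", "II", "III")))
  rec <- suppressWarnings(run_scenario_grid(datasets, grid, seed = 1))
  # 7 stage combinations x 8 classifiers x 4 test sets
  expect_identical(nrow(rec), 7L * 8L * 4L)
  expect_identical(length(unique(paste(rec$stages, rec$classifier))), 56L)
  expect_setequal(unique(rec$test_set), c("0", "I", "II", "III"))
  expect_true(all(abs(rec$accuracy -
                      (rec$tp + rec$tn) /
                      (rec$tp + rec$fp + rec$fn + rec$tn)) < 1e-12))

  expect_error(run_scenario_grid(datasets[c("I", "II")], grid, seed = 1),
               class = "rcs_configuration_error")

  s <- summarize_records(rec)
  expect_named(s, c("mean", "median", "sd", "min", "max"))
  d <- withr::local_tempdir()
  export_records(rec, file.path(d, "records.csv"), file.path(d, "summary.json"))
  back <- utils::read.csv(file.path(d, "records.csv"))
  expect_identical(nrow(back), nrow(rec))
  js <- jsonlite::read_json(file.path(d, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$mean, s$mean, tolerance = 1e-12)
})

test_that("training-set records dominate held-out records on separable data", {
  set.seed(87)
  mk <- function(mu, n) lapply(seq_len(n), function(i) {
    X0 <- matrix(rnorm(80, 0, 0.4), ncol = 8)
    X1 <- matrix(rnorm(80, mu, 0.4), ncol = 8)
    list(X = rbind(X0, X1), y = rep(c(0L, 1L), each = 10))
  })
  datasets <- list(I = list(train = mk(1.2, 2), test = mk(1.2, 1)),
                   II = list(train = mk(0.9, 2), test = mk(0.9, 1)),
                   III = list(train = mk(0.6, 2), test = mk(0.6, 1)))
  grid <- list(species = "s", view = "top", modality = "VIS",
               stage_combos = list("I", "II", "III"))
  rec <- suppressWarnings(run_scenario_grid(datasets, grid, seed = 2))
  a0 <- mean(rec$accuracy[rec$test_set == "0"])
  aT <- mean(rec$accuracy[rec$test_set != "0"])
  expect_gte(a0, aT)
})
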