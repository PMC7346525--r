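MEMBER_ACRONYMS <- c("bayes", "da", "glm", "gpr", "linmod", "svm", "svmreg",
                     "net")

feat_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df
}

normalize_features <- function(X, norm) {
  X <- as.matrix(X)[, norm$kept, drop = FALSE]
  sweep(sweep(X, 2, norm$min[norm$kept]), 2,
        norm$max[norm$kept] - norm$min[norm$kept], `/`)
}

train_one_member <- function(acronym, Xn, y, net_hidden, seed) {
  df <- feat_df(Xn)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(acronym,
    bayes = list(kind = "classifier",
                 fit = e1071::naiveBayes(df, yf)),
    da = list(kind = "classifier",
              fit = MASS::lda(Xn, grouping = yf)),
    glm = list(kind = "regressor",
               fit = suppressWarnings(
                 stats::glm(y ~ ., data = cbind(df, y = y),
                            family = stats::binomial()))),
    gpr = list(kind = "regressor",
               fit = with_rng(seed, {
                 g <- NULL
                 utils::capture.output(
                   g <- kernlab::gausspr(x = as.matrix(Xn),
                                         y = as.numeric(y)))
                 g
               })),
    linmod = list(kind = "regressor",
                  fit = stats::lm(y ~ ., data = cbind(df, y = y))),
    svm = list(kind = "classifier",
               fit = e1071::svm(as.matrix(Xn), yf, kernel = "linear",
                                scale = FALSE)),
    svmreg = list(kind = "regressor",
                  fit = e1071::svm(as.matrix(Xn), as.numeric(y),
                                   type = "eps-regression", kernel = "linear",
                                   scale = FALSE)),
    net = list(kind = "regressor",
               fit = with_rng(seed, nnet::nnet(
                 x = as.matrix(Xn), y = matrix(as.numeric(y), ncol = 1),
                 size = net_hidden, entropy = TRUE, maxit = 500L,
                 decay = 1e-4, trace = FALSE))))
  fit$acronym <- acronym
  fit
}

member_fe <- function(member, Xn) {
  if (member$kind == "stub") return(rep(member$label, nrow(Xn)))
  df <- feat_df(Xn)
  fe <- switch(member$acronym,
    bayes = as.numeric(as.character(
      predict(member$fit, df, type = "class", eps = 1e-9,
              threshold = 1e-3))),
    da = as.numeric(as.character(predict(member$fit, as.matrix(Xn))$class)),
    glm = as.numeric(predict(member$fit, df, type = "response")),
    gpr = as.numeric(kernlab::predict(member$fit, as.matrix(Xn))),
    linmod = as.numeric(predict(member$fit, df)),
    svm = as.numeric(as.character(predict(member$fit, as.matrix(Xn)))),
    svmreg = as.numeric(predict(member$fit, as.matrix(Xn))),
    net = as.numeric(predict(member$fit, as.matrix(Xn))))
  pmin(pmax(fe, 0), 1)
}

stub_member <- function(acronym, y) {
  n1 <- sum(y == 1)
  list(kind = "stub", acronym = acronym,
       label = if (n1 >= length(y) - n1) 1 else 0)
}

#' Train the eight-member plant/background region classifier ensemble
#'
#' Trains the eight binary models used throughout the pipeline on AC-KMR
#' descriptors: naive Bayes (`bayes`), linear discriminant analysis (`da`),
#' binomial logistic regression (`glm`), Gaussian-process regression on 0/1
#' targets (`gpr`), ordinary linear regression on 0/1 targets (`linmod`), a
#' linear support-vector classifier (`svm`), linear support-vector regression
#' on 0/1 targets (`svmreg`), and a single-hidden-layer feed-forward network
#' (`net`). Regression-type members produce fuzzy estimates `FE` that are
#' clipped to `[0, 1]` and thresholded at 0.5 (`FE >= 0.5` is plant).
#' Features are min-max normalized using the training table's ranges;
#' constant features are dropped with a warning. A member whose fit fails on
#' degenerate input is replaced by a majority-vote stub with a warning.
#'
#' @param X `m x D` matrix of AC-KMR descriptors (`D` 10 or 20)
#' @param y binary labels (0 background, 1 plant); both classes required
#' @param net_hidden hidden units of the `net` member (default 10)
#' @param seed seed for the stochastic members (`net` weight init, `gpr`
#'   kernel-width heuristic)
#' @return object of class `rcs_ensemble`
#' @export
train_ensemble <- function(X, y, net_hidden = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X))
    rcs_validation_error("X rows and y entries are not aligned")
  if (!all(y %in% c(0L, 1L)))
    rcs_validation_error("labels must be 0 (background) or 1 (plant)")
  if (length(unique(y)) < 2L)
    rcs_error("training table must contain both classes",
              "rcs_training_error")
  cmin <- apply(X, 2, min)
  cmax <- apply(X, 2, max)
  kept <- which(cmax > cmin)
  if (length(kept) == 0L)
    rcs_error("all features are constant", "rcs_training_error")
  if (length(kept) < ncol(X))
    warning(sprintf("%d constant feature(s) dropped from training",
                    ncol(X) - length(kept)), call. = FALSE)
  norm <- list(min = cmin, max = cmax, kept = kept)
  Xn <- normalize_features(X, norm)
  members <- lapply(MEMBER_ACRONYMS, function(acr) {
    m <- tryCatch(train_one_member(acr, Xn, y, net_hidden, seed),
                  error = function(e) {
                    warning(sprintf(
                      "member '%s' failed to train (%s); using majority stub",
                      acr, conditionMessage(e)), call. = FALSE)
                    stub_member(acr, y)
                  })
    m$norm <- norm
    m
  })
  names(members) <- MEMBER_ACRONYMS
  structure(list(members = members, fe_threshold = 0.5,
                 feature_dim = ncol(X), normalization = norm,
                 net_hidden = as.integer(net_hidden), seed = as.integer(seed)),
            class = "rcs_ensemble")
}

#' @export
print.rcs_ensemble <- function(x, ...) {
  cat(sprintf("<rcs_ensemble 8 members, %d-D features>\n", x$feature_dim))
  invisible(x)
}

#' Predict binary region labels with a single ensemble member
#'
#' Classifier members return hard labels; regression members return their
#' fuzzy estimate `FE`, clipped to `[0, 1]` and thresholded at exactly 0.5
#' with the tie `FE = 0.5` assigned to plant.
#'
#' @param member one element of `rcs_ensemble$members`
#' @param X `n x D` raw (unnormalized) feature matrix
#' @return integer vector of 0/1 labels
#' @export
predict_member <- function(member, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(member$norm$min))
    rcs_validation_error(sprintf(
      "feature dimension %d does not match training dimension %d",
      ncol(X), length(member$norm$min)))
  fe <- member_fe(member, normalize_features(X, member$norm))
  as.integer(fe >= 0.5)
}

#' @rdname predict_member
#' @param ensemble `rcs_ensemble`
#' @return for `predict_ensemble`: an `8 x n` binary matrix, one row per
#'   member acronym
#' @export
predict_ensemble <- function(ensemble, X) {
  n <- nrow(as.matrix(X))
  out <- vapply(ensemble$members, function(m) predict_member(m, X),
                integer(n))
  out <- t(matrix(out, nrow = n))  # vapply drops dims when n == 1
  rownames(out) <- MEMBER_ACRONYMS
  out
}

#' Combine the eight member predictions by median and fusion
#'
#' `fusion` is the logical OR across members. `median` is the per-region
#' median of the eight binary labels, with the 4-4 tie value 0.5 mapped to
#' plant — the same convention as the `FE >= 0.5` rule — so `median = 1` iff
#' at least 4 members vote plant.
#'
#' @param labels `8 x n` binary matrix (one row per member)
#' @return list with integer vectors `median` and `fusion`
#' @export
combine_predictions <- function(labels) {
  labels <- as.matrix(labels)
  if (nrow(labels) != 8L)
    rcs_validation_error("expected exactly 8 member prediction rows")
  votes <- colSums(labels)
  list(median = as.integer(votes >= 4), fusion = as.integer(votes > 0))
}

#' Classify k-means regions and broadcast labels back to a pixel mask
#'
#' Applies the model's ensemble to the partition's AC-KMR descriptors,
#' combines member votes, and returns the pixel mask of plant-labeled
#' regions within the partition's support.
#'
#' @param partition `rcs_regions` from [reduce_to_regions()]
#' @param model `rcs_model` (case-scenario bundle) or `rcs_ensemble`
#' @param combine `"median"`, `"fusion"`, or `"single:<acronym>"`
#' @return [rcs_mask()] in the partition's frame (VIS)
#' @export
segment_regions <- function(partition, model, combine = "median") {
  ensemble <- if (inherits(model, "rcs_model")) model$ensemble else model
  stopifnot(inherits(ensemble, "rcs_ensemble"), inherits(partition, "rcs_regions"))
  X <- partition$ackmr
  if (ncol(X) != ensemble$feature_dim)
    rcs_validation_error(sprintf(
      "partition feature dimension %d does not match model dimension %d",
      ncol(X), ensemble$feature_dim))
  region_labels <- predict_region_labels(partition, ensemble, combine)
  plant <- which(region_labels == 1L)
  rcs_mask(matrix(partition$labels %in% (plant - 1L), nrow(partition$labels)),
           frame = "VIS")
}

predict_region_labels <- function(partition, ensemble, combine = "median") {
  L <- predict_ensemble(ensemble, partition$ackmr)
  if (combine %in% c("median", "fusion")) {
    combine_predictions(L)[[combine]]
  } else if (startsWith(combine, "single:")) {
    acr <- sub("^single:", "", combine)
    if (!acr %in% MEMBER_ACRONYMS)
      rcs_validation_error(sprintf("unknown member acronym '%s'", acr))
    L[acr, ]
  } else {
    rcs_validation_error(sprintf("unknown combination rule '%s'", combine))
  }
}

#' Case-scenario model bundle
#'
#' Couples a trained region-classification ensemble with an optional
#' small-object filter and the scenario metadata it was trained for (species,
#' camera view, modality, developmental-stage set, region count). Models are
#' scenario-specific: segmentation re-uses the region count stored here.
#'
#' @param ensemble `rcs_ensemble`
#' @param object_filter `rcs_objfilter` from [train_object_filter()], or
#'   `NULL` for a permissive keep-everything fallback
#' @param meta list with `species`, `view` (`"top"`/`"side"`), `modality`
#'   (`"FLU"`, `"VIS"`, `"FLU+VIS"`), `stages` (subset of `c("I","II","III")`),
#'   `n_regions` (in `[10, 30]`)
#' @return object of class `rcs_model`
#' @export
case_scenario_model <- function(ensemble, object_filter = NULL, meta) {
  stopifnot(inherits(ensemble, "rcs_ensemble"))
  if (is.null(meta$stages) || length(meta$stages) == 0L)
    rcs_validation_error("scenario stage set must be non-empty")
  if (is.null(meta$n_regions) || meta$n_regions < 10 || meta$n_regions > 30)
    rcs_validation_error("scenario region count must lie in [10, 30]")
  if (!is.null(object_filter)) stopifnot(inherits(object_filter, "rcs_objfilter"))
  structure(list(ensemble = ensemble, object_filter = object_filter,
                 meta = meta),
            class = "rcs_model")
}

#' @export
print.rcs_model <- function(x, ...) {
  cat(sprintf("<rcs_model %s/%s %s stages=%s N=%d%s>\n",
              x$meta$species, x$meta$view, x$meta$modality,
              paste(x$meta$stages, collapse = "+"), x$meta$n_regions,
              if (is.null(x$object_filter)) "" else " +objfilter"))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "1"

#' Persist / restore a case-scenario model bundle
#'
#' The bundle is a directory with `meta.json` (scenario metadata, feature
#' dimension, normalization, format version) and one serialized blob per
#' ensemble member (plus the object-filter members if present). The round
#' trip is lossless: a loaded model reproduces the saved model's predictions
#' exactly.
#'
#' @param model `rcs_model`
#' @param path bundle directory
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rcs_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "members"), showWarnings = FALSE)
  meta <- list(format_version = MODEL_FORMAT_VERSION,
               scenario = model$meta,
               feature_dim = model$ensemble$feature_dim,
               fe_threshold = model$ensemble$fe_threshold,
               net_hidden = model$ensemble$net_hidden,
               seed = model$ensemble$seed,
               normalization = list(
                 min = model$ensemble$normalization$min,
                 max = model$ensemble$normalization$max,
                 kept = model$ensemble$normalization$kept),
               members = MEMBER_ACRONYMS,
               has_object_filter = !is.null(model$object_filter))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (acr in MEMBER_ACRONYMS)
    saveRDS(model$ensemble$members[[acr]],
            file.path(path, "members", paste0(acr, ".rds")))
  if (!is.null(model$object_filter)) {
    dir.create(file.path(path, "object_filter"), showWarnings = FALSE)
    for (acr in MEMBER_ACRONYMS)
      saveRDS(model$object_filter$ensemble$members[[acr]],
              file.path(path, "object_filter", paste0(acr, ".rds")))
    saveRDS(model$object_filter$ensemble[c("feature_dim", "normalization",
                                           "fe_threshold", "net_hidden",
                                           "seed")],
            file.path(path, "object_filter", "ensemble_meta.rds"))
  }
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the restored `rcs_model`
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    rcs_error(sprintf("not a model bundle (no meta.json): %s", path),
              "rcs_model_load_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), MODEL_FORMAT_VERSION))
    rcs_error(sprintf("unsupported model format version '%s'",
                      meta$format_version), "rcs_model_load_error")
  members <- list()
  for (acr in MEMBER_ACRONYMS) {
    f <- file.path(path, "members", paste0(acr, ".rds"))
    if (!file.exists(f))
      rcs_error(sprintf("model bundle is missing member '%s'", acr),
                "rcs_model_load_error")
    members[[acr]] <- readRDS(f)
  }
  norm <- list(min = as.numeric(meta$normalization$min),
               max = as.numeric(meta$normalization$max),
               kept = as.integer(meta$normalization$kept))
  ensemble <- structure(
    list(members = members, fe_threshold = meta$fe_threshold,
         feature_dim = as.integer(meta$feature_dim), normalization = norm,
         net_hidden = as.integer(meta$net_hidden),
         seed = as.integer(meta$seed)),
    class = "rcs_ensemble")
  object_filter <- NULL
  if (isTRUE(meta$has_object_filter)) {
    of_members <- list()
    for (acr in MEMBER_ACRONYMS) {
      f <- file.path(path, "object_filter", paste0(acr, ".rds"))
      if (!file.exists(f))
        rcs_error(sprintf("object filter is missing member '%s'", acr),
                  "rcs_model_load_error")
      of_members[[acr]] <- readRDS(f)
    }
    of_meta <- readRDS(file.path(path, "object_filter", "ensemble_meta.rds"))
    of_ens <- structure(c(list(members = of_members), of_meta),
                        class = "rcs_ensemble")
    object_filter <- structure(list(ensemble = of_ens),
                               class = "rcs_objfilter")
  }
  scn <- meta$scenario
  scn$stages <- as.character(scn$stages)
  case_scenario_model(ensemble, object_filter, scn)
}
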