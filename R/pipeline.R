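default_n_regions <- function(stages) {
  # juvenile, homogeneously colored plants need fewer color regions than
  # color-rich adult plants
  max(c(I = 10L, II = 20L, III = 30L)[stages])
}

features_for_modality <- function(pair, vis_mask, transform, modality) {
  if (modality == "VIS") {
    multicolor_features(pair$vis, vis_mask)
  } else if (modality == "FLU+VIS") {
    pair_features(pair, vis_mask, transform)
  } else if (modality == "FLU") {
    pf <- pair_features(pair, vis_mask, transform)
    out <- pf[, grep("^flu_", colnames(pf)), drop = FALSE]
    attr(out, "index") <- attr(pf, "index")
    out
  } else {
    rcs_validation_error(sprintf("unknown modality '%s'", modality))
  }
}

#' Run the full registration-classification segmentation on one pair
#'
#' Pipeline: distance-based pre-segmentation of both modalities, similarity
#' registration of the FLU pre-segmentation onto the VIS frame, transfer of
#' the FLU mask, k-means region reduction of the masked VIS pixels in the
#' model's color modality, ensemble region classification, and small-object
#' filtering. If either pre-segmentation is empty (no plant in front of the
#' reference background) an empty mask is returned with a warning rather
#' than an error.
#'
#' @param pair [rcs_pair()]
#' @param model `rcs_model` case-scenario bundle
#' @param combine combination rule (`"median"` default, `"fusion"`, or
#'   `"single:<acronym>"`)
#' @param n_pre,tsh pre-segmentation parameters (defaults 25 and 5)
#' @param seed seed for the k-means region reduction
#' @return list with `vis_mask` (final), `vis_mask_unfiltered`, `flu_preseg`,
#'   `vis_preseg`, `transferred`, `transform`, `partition`, `empty`
#' @export
segment_pair <- function(pair, model, combine = "median", n_pre = 25L,
                         tsh = 5, seed = 1L) {
  stopifnot(inherits(pair, "rcs_pair"), inherits(model, "rcs_model"))
  flu_pre <- preseg_mask(pair$flu, pair$flu_ref, n_clusters = n_pre, tsh = tsh)
  vis_pre <- preseg_mask(pair$vis, pair$vis_ref, n_clusters = n_pre, tsh = tsh)
  empty_result <- function() {
    warning("empty pre-segmentation: no plant detected", call. = FALSE)
    em <- rcs_mask(matrix(FALSE, dim(pair$vis)[1], dim(pair$vis)[2]), "VIS")
    list(vis_mask = em, vis_mask_unfiltered = em, flu_preseg = flu_pre,
         vis_preseg = vis_pre, transferred = em, transform = NULL,
         partition = NULL, empty = TRUE)
  }
  if (!any(flu_pre$pixels) || !any(vis_pre$pixels)) return(empty_result())
  tf <- estimate_similarity_transform(flu_pre, vis_pre)
  transferred <- transfer_mask(flu_pre, tf, dim(pair$vis))
  if (!any(transferred$pixels)) return(empty_result())
  feats <- features_for_modality(pair, transferred, tf, model$meta$modality)
  partition <- reduce_to_regions(feats, transferred,
                                 n_regions = model$meta$n_regions, seed = seed)
  mask <- segment_regions(partition, model, combine = combine)
  filtered <- filter_small_objects(mask, pair$vis, model$object_filter)
  list(vis_mask = filtered, vis_mask_unfiltered = mask, flu_preseg = flu_pre,
       vis_preseg = vis_pre, transferred = transferred, transform = tf,
       partition = partition, empty = FALSE)
}

#' Build one AC-KMR training sample from an image pair with ground truth
#'
#' Runs the pipeline up to region reduction and labels each region from the
#' pixel ground truth by majority (ties to plant).
#'
#' @param pair [rcs_pair()]
#' @param truth_vis [rcs_mask()] ground truth in the VIS frame
#' @param modality `"VIS"`, `"FLU"` or `"FLU+VIS"`
#' @param n_regions region count
#' @param seed,n_pre,tsh pipeline parameters
#' @return list with `X` (AC-KMR rows), `y` (region truth labels),
#'   `partition`, `transferred`, `transform`, `pair`, `truth_vis`
#' @export
build_training_sample <- function(pair, truth_vis, modality = "VIS",
                                  n_regions = 10L, seed = 1L, n_pre = 25L,
                                  tsh = 5) {
  flu_pre <- preseg_mask(pair$flu, pair$flu_ref, n_clusters = n_pre, tsh = tsh)
  vis_pre <- preseg_mask(pair$vis, pair$vis_ref, n_clusters = n_pre, tsh = tsh)
  tf <- estimate_similarity_transform(flu_pre, vis_pre)
  transferred <- transfer_mask(flu_pre, tf, dim(pair$vis))
  feats <- features_for_modality(pair, transferred, tf, modality)
  partition <- reduce_to_regions(feats, transferred, n_regions = n_regions,
                                 seed = seed)
  y <- region_truth_labels(partition, truth_vis)
  list(X = partition$ackmr, y = y, partition = partition,
       transferred = transferred, transform = tf, pair = pair,
       truth_vis = truth_vis)
}

object_truth_labels <- function(mask, truth_vis) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(integer())
  tpx <- if (inherits(truth_vis, "rcs_mask")) truth_vis$pixels else truth_vis
  idx <- which(lab > 0L)
  li <- lab[idx]
  n <- tabulate(li, nbins = k)
  np <- rowsum(as.numeric(tpx[idx]), li)[, 1]
  as.integer(np / n >= 0.5)
}

#' Train a case-scenario model from ground-truthed pairs
#'
#' Builds the AC-KMR training table over all training pairs, trains the
#' eight-member region ensemble, then trains the small-object filter on the
#' connected components of the median-combined segmentations of the same
#' pairs (objects labeled plant/artefact by majority overlap with the ground
#' truth). If the object population is single-class the filter is omitted
#' (permissive fallback).
#'
#' @param pairs list of [rcs_pair()]
#' @param truths list of [rcs_mask()] VIS ground-truth masks, aligned with
#'   `pairs`
#' @param meta scenario metadata (see [case_scenario_model()]); `n_regions`
#'   defaults by stage set (10 juvenile / 20 mid / 30 adult)
#' @param seed,n_pre,tsh,net_hidden training parameters
#' @return `rcs_model`; attribute `"training_table"` holds the assembled
#'   `X`/`y`
#' @export
train_scenario <- function(pairs, truths, meta, seed = 1L, n_pre = 25L,
                           tsh = 5, net_hidden = 10L) {
  if (is.null(meta$n_regions)) meta$n_regions <- default_n_regions(meta$stages)
  samples <- lapply(seq_along(pairs), function(i)
    build_training_sample(pairs[[i]], truths[[i]], modality = meta$modality,
                          n_regions = meta$n_regions,
                          seed = derive_seed(seed, i), n_pre = n_pre,
                          tsh = tsh))
  X <- do.call(rbind, lapply(samples, `[[`, "X"))
  y <- unlist(lapply(samples, `[[`, "y"))
  ensemble <- train_ensemble(X, y, net_hidden = net_hidden, seed = seed)
  # object filter training on the median-combined segmentations
  feats <- list()
  labs <- list()
  for (s in samples) {
    m <- segment_regions(s$partition, ensemble, combine = "median")
    if (!any(m$pixels)) next
    f <- extract_object_features(m, s$pair$vis)
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- object_truth_labels(m, s$truth_vis)
  }
  object_filter <- NULL
  if (length(feats) > 0L) {
    F <- do.call(rbind, feats)
    L <- unlist(labs)
    if (length(unique(L)) == 2L)
      object_filter <- train_object_filter(F, L, net_hidden = net_hidden,
                                           seed = seed)
  }
  model <- case_scenario_model(ensemble, object_filter, meta)
  attr(model, "training_table") <- list(X = X, y = y)
  model
}

#' Train matched models and evaluate segmentation over a synthetic suite
#'
#' For every (archetype, stage) cell: trains a case-scenario model on the
#' cell's training pairs, then runs the full pipeline on the held-out test
#' pairs and scores each at region level (confusion-matrix accuracy between
#' region truth and predicted region labels). Also records every ensemble
#' member's training-set self-reproduction accuracy.
#'
#' @param suite `rcs_suite` from [generate_scenario_suite()]
#' @param modality color modality for classification (default `"VIS"`)
#' @param combine combination rule for scoring (default `"median"`)
#' @param seed integer seed
#' @return list with `records` (per test pair: archetype, stage, confusion,
#'   accuracy, pixel Dice of the final mask), `self` (per cell and member:
#'   training self-reproduction accuracy), `models` (per cell)
#' @export
evaluate_suite_segmentation <- function(suite, modality = "VIS",
                                        combine = "median", seed = 1L) {
  records <- list()
  selfrec <- list()
  models <- list()
  for (arch in names(suite$cells)) {
    for (st in names(suite$cells[[arch]])) {
      cell <- suite$cells[[arch]][[st]]
      trn <- cell$fixtures[cell$train_idx]
      meta <- list(species = paste0("synthetic-", arch),
                   view = if (grepl("top", arch)) "top" else "side",
                   modality = modality, stages = st,
                   n_regions = default_n_regions(st))
      model <- train_scenario(lapply(trn, function(f) f$pair),
                              lapply(trn, function(f) f$truth_vis),
                              meta, seed = derive_seed(seed, 17L))
      models[[paste(arch, st, sep = "/")]] <- model
      tt <- attr(model, "training_table")
      preds <- predict_ensemble(model$ensemble, tt$X)
      for (acr in MEMBER_ACRONYMS) {
        selfrec[[length(selfrec) + 1L]] <- data.frame(
          archetype = arch, stage = st, classifier = acr,
          accuracy = accuracy(region_confusion(tt$y, preds[acr, ])),
          stringsAsFactors = FALSE)
      }
      for (i in cell$test_idx) {
        fx <- cell$fixtures[[i]]
        seg <- segment_pair(fx$pair, model, combine = combine,
                            seed = derive_seed(seed, 29L * i))
        if (seg$empty) {
          acc <- 0
          dsc <- 0
          cm <- list(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
        } else {
          truth <- region_truth_labels(seg$partition, fx$truth_vis)
          pred <- predict_region_labels(seg$partition, model$ensemble,
                                        combine)
          cm <- region_confusion(truth, pred)
          acc <- accuracy(cm)
          dsc <- dice(seg$vis_mask, fx$truth_vis)
        }
        records[[length(records) + 1L]] <- data.frame(
          archetype = arch, stage = st, pair = i, tp = cm$tp, fp = cm$fp,
          fn = cm$fn, tn = cm$tn, accuracy = acc, dice = dsc,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, records), self = do.call(rbind, selfrec),
       models = models)
}

#' Assemble per-stage AC-KMR datasets for the scenario grid
#'
#' Converts one archetype of a synthetic suite into the `datasets` structure
#' consumed by [run_scenario_grid()]: for every stage, the training and test
#' fixtures are reduced to AC-KMR tables with region truth labels.
#'
#' @param suite `rcs_suite`
#' @param archetype which archetype to use
#' @param modality color modality
#' @param seed integer seed
#' @param n_regions region count per pair (default: stage-dependent)
#' @return named list of stages, each `list(train = samples, test = samples)`
#' @export
assemble_grid_datasets <- function(suite, archetype, modality = "VIS",
                                   seed = 1L, n_regions = NULL) {
  cells <- suite$cells[[archetype]]
  out <- list()
  for (st in names(cells)) {
    cell <- cells[[st]]
    nr <- if (is.null(n_regions)) default_n_regions(st) else n_regions
    mk <- function(i)
      build_training_sample(cell$fixtures[[i]]$pair,
                            cell$fixtures[[i]]$truth_vis,
                            modality = modality, n_regions = nr,
                            seed = derive_seed(seed, i))[c("X", "y")]
    out[[st]] <- list(train = lapply(cell$train_idx, mk),
                      test = lapply(cell$test_idx, mk))
  }
  out
}
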