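#' Region-level confusion matrix
#'
#' Counts true/false positives/negatives over k-means color regions (not
#' pixels), with plant as the positive class. Region-level counting is more
#' sensitive to classification failures than whole-mask overlap measures
#' such as the Dice coefficient.
#'
#' @param truth,predicted binary vectors of region labels, equal length
#' @return object of class `rcs_confusion` with fields `tp`, `fp`, `fn`, `tn`
#' @export
region_confusion <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    rcs_validation_error("truth and prediction lengths differ")
  if (!all(c(truth, predicted) %in% c(0L, 1L)))
    rcs_validation_error("labels must be binary")
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fp = sum(truth == 0L & predicted == 1L),
                 fn = sum(truth == 1L & predicted == 0L),
                 tn = sum(truth == 0L & predicted == 0L)),
            class = "rcs_confusion")
}

#' @export
print.rcs_confusion <- function(x, ...) {
  cat(sprintf("<rcs_confusion TP=%d FP=%d FN=%d TN=%d A=%.4f>\n",
              x$tp, x$fp, x$fn, x$tn, accuracy(x)))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' `A = (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param confusion `rcs_confusion`, or a list/vector with elements `tp`,
#'   `fp`, `fn`, `tn`
#' @return scalar in `[0, 1]`
#' @export
accuracy <- function(confusion) {
  total <- confusion$tp + confusion$fp + confusion$fn + confusion$tn
  if (total < 1)
    rcs_error("accuracy undefined for an empty confusion matrix",
              "rcs_undefined_accuracy_error")
  (confusion$tp + confusion$tn) / total
}

#' Region ground-truth labels from a pixel ground-truth mask
#'
#' A region is labeled plant when more than half of its pixels are plant in
#' the reference mask; an exact 50% tie is resolved to plant, consistent
#' with the other tie conventions of the pipeline.
#'
#' @param partition `rcs_regions`
#' @param truth_mask [rcs_mask()] or logical matrix in the same frame
#' @return integer vector of 0/1 labels, one per region
#' @export
region_truth_labels <- function(partition, truth_mask) {
  tpx <- if (inherits(truth_mask, "rcs_mask")) truth_mask$pixels else truth_mask
  lab <- partition$labels
  if (!identical(dim(lab), dim(tpx)))
    rcs_validation_error("partition and truth mask differ in size")
  idx <- which(lab >= 0L)
  li <- lab[idx] + 1L
  n <- tabulate(li, nbins = partition$n_regions)
  np <- rowsum(as.numeric(tpx[idx]), li)
  frac <- as.numeric(np) / n
  as.integer(frac >= 0.5)
}

#' Run the case-scenario training/evaluation grid
#'
#' For every combination in the grid (scenario metadata x developmental-stage
#' combination), trains one eight-member ensemble on the union of the stage
#' combination's training samples and evaluates every member on four test
#' sets: the training table itself (test set `"0"`) and the held-out samples
#' of stages I, II and III. Emits one record per (model, member, test set).
#'
#' @param datasets named list with elements `"I"`, `"II"`, `"III"`; each a
#'   list with `train` and `test`, both lists of samples `list(X, y)` where
#'   `X` holds AC-KMR rows and `y` the region truth labels
#' @param grid list with `species`, `view`, `modality`, `stage_combos` (list
#'   of character vectors over `c("I","II","III")`), optional `net_hidden`
#' @param seed integer seed recorded in every record and used for member
#'   training
#' @return data.frame of evaluation records (one row per model/member/test
#'   set) with confusion counts and accuracy
#' @export
run_scenario_grid <- function(datasets, grid, seed = 1L) {
  stages_needed <- unique(unlist(grid$stage_combos))
  missing <- setdiff(stages_needed, names(datasets))
  if (length(missing) > 0L)
    rcs_error(sprintf("no dataset for stage(s): %s",
                      paste(missing, collapse = ", ")),
              "rcs_configuration_error")
  bind_samples <- function(samples) {
    list(X = do.call(rbind, lapply(samples, `[[`, "X")),
         y = unlist(lapply(samples, `[[`, "y")))
  }
  net_hidden <- if (is.null(grid$net_hidden)) 10L else grid$net_hidden
  records <- list()
  for (combo in grid$stage_combos) {
    train_tab <- bind_samples(unlist(lapply(combo, function(s)
      datasets[[s]]$train), recursive = FALSE))
    ens <- train_ensemble(train_tab$X, train_tab$y, net_hidden = net_hidden,
                          seed = seed)
    test_sets <- c(list(`0` = train_tab),
                   lapply(datasets, function(d) bind_samples(d$test)))
    for (ts_name in names(test_sets)) {
      ts <- test_sets[[ts_name]]
      if (is.null(ts$X) || nrow(ts$X) == 0L) next
      preds <- predict_ensemble(ens, ts$X)
      for (acr in MEMBER_ACRONYMS) {
        cm <- region_confusion(ts$y, preds[acr, ])
        records[[length(records) + 1L]] <- data.frame(
          species = grid$species, view = grid$view, modality = grid$modality,
          stages = paste(combo, collapse = "+"), classifier = acr,
          test_set = ts_name, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
          accuracy = accuracy(cm), seed = as.integer(seed),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, records)
}

#' Summary statistics of grid accuracies
#'
#' @param records data.frame from [run_scenario_grid()]
#' @return list with `mean`, `median`, `sd`, `min`, `max` accuracy
#' @export
summarize_records <- function(records) {
  a <- records$accuracy
  list(mean = mean(a), median = stats::median(a), sd = stats::sd(a),
       min = min(a), max = max(a))
}

#' Export grid records and their summary
#'
#' Writes one CSV row per evaluation record and a JSON summary with the
#' mean/median/SD/min/max accuracy over the grid.
#'
#' @param records data.frame from [run_scenario_grid()]
#' @param csv_path,json_path output paths
#' @export
export_records <- function(records, csv_path, json_path) {
  utils::write.csv(records, csv_path, row.names = FALSE)
  jsonlite::write_json(summarize_records(records), json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
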