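#' 8-connected component labelling of a binary mask
#'
#' @param mask [rcs_mask()] or logical matrix
#' @return integer matrix, 0 = background, components numbered from 1 in
#'   scan order
#' @export
label_components <- function(mask) {
  px <- if (inherits(mask, "rcs_mask")) mask$pixels else mask
  .label8_cpp(px)
}

#' Per-object features for small-object filtering
#'
#' Labels the mask's 8-connected components and computes, per component: the
#' pixel count (`size`), the mean-channel color ratios `r_over_b`,
#' `r_over_g`, `g_over_b` measured in the VIS image (denominators clamped at
#' 1/255), and the `vicinity` — the minimum Euclidean distance from the
#' component to the largest component (0 for the largest itself; size ties
#' broken by smallest label). Growing plants have no fixed size scale, so
#' these features, not a size threshold, drive artefact removal: separately
#' segmented leaf tips of small shoots can be the same size as background
#' specks but are plant-colored and close to the main shoot.
#'
#' @param mask [rcs_mask()] (non-empty for a non-trivial result)
#' @param vis [rcs_image()] the mask annotates
#' @return data.frame with columns `id`, `size`, `r_over_b`, `r_over_g`,
#'   `g_over_b`, `vicinity`
#' @export
extract_object_features <- function(mask, vis) {
  px <- if (inherits(mask, "rcs_mask")) mask$pixels else mask
  if (!identical(dim(px), dim(vis)[1:2]))
    rcs_validation_error("mask and VIS image differ in size")
  lab <- .label8_cpp(px)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(id = integer(), size = integer(), r_over_b = numeric(),
                      r_over_g = numeric(), g_over_b = numeric(),
                      vicinity = numeric()))
  idx <- which(lab > 0L)
  li <- lab[idx]
  size <- tabulate(li, nbins = k)
  clamp <- 1 / 255
  mr <- rowsum(vis$pixels[, , 1][idx], li)[, 1] / size
  mg <- rowsum(vis$pixels[, , 2][idx], li)[, 1] / size
  mb <- rowsum(vis$pixels[, , 3][idx], li)[, 1] / size
  largest <- which(size == max(size))[1]
  # distance of every pixel to the largest component: EBImage::distmap on the
  # complement of the largest component gives exact Euclidean distances
  comp <- matrix(1, nrow(px), ncol(px))
  comp[lab == largest] <- 0
  dmap <- EBImage::distmap(comp, metric = "euclidean")
  vic <- vapply(seq_len(k), function(j) {
    if (j == largest) 0 else min(dmap[lab == j])
  }, numeric(1))
  data.frame(id = seq_len(k), size = size,
             r_over_b = mr / pmax(mb, clamp),
             r_over_g = mr / pmax(mg, clamp),
             g_over_b = mg / pmax(mb, clamp),
             vicinity = vic)
}

#' Train the small-object filter (median vote of eight classifiers)
#'
#' Trains the same eight-member family as [train_ensemble()] on per-object
#' features (`size`, three color ratios, `vicinity`) with binary labels
#' (1 = plant object to keep, 0 = background artefact to remove). The
#' decision rule at filtering time is the median of the eight member labels,
#' ties resolved to keep.
#'
#' @param features data.frame from [extract_object_features()] (or any
#'   matrix with the same five feature columns)
#' @param labels binary object labels aligned with `features` rows
#' @param net_hidden,seed passed to [train_ensemble()]
#' @return object of class `rcs_objfilter`
#' @export
train_object_filter <- function(features, labels, net_hidden = 10L,
                                seed = 1L) {
  X <- as.matrix(features[, c("size", "r_over_b", "r_over_g", "g_over_b",
                              "vicinity")])
  ens <- train_ensemble(X, labels, net_hidden = net_hidden, seed = seed)
  structure(list(ensemble = ens), class = "rcs_objfilter")
}

#' Remove small non-plant objects from a segmented mask
#'
#' Every connected component except the largest is classified by the object
#' filter's eight members; a component is kept iff the median vote is plant
#' (4-4 ties keep). The largest component is always kept. With a `NULL`
#' filter the mask is returned unchanged (permissive fallback).
#'
#' @param mask [rcs_mask()]
#' @param vis [rcs_image()]
#' @param filter_model `rcs_objfilter` or `NULL`
#' @return filtered [rcs_mask()]; attribute `"decisions"` carries the
#'   per-object feature table with a `keep` column
#' @export
filter_small_objects <- function(mask, vis, filter_model) {
  px <- if (inherits(mask, "rcs_mask")) mask$pixels else mask
  frame <- if (inherits(mask, "rcs_mask")) mask$frame else "VIS"
  if (is.null(filter_model) || !any(px)) return(rcs_mask(px, frame = frame))
  stopifnot(inherits(filter_model, "rcs_objfilter"))
  feats <- extract_object_features(mask, vis)
  lab <- .label8_cpp(px)
  size <- feats$size
  largest <- which(size == max(size))[1]
  X <- as.matrix(feats[, c("size", "r_over_b", "r_over_g", "g_over_b",
                           "vicinity")])
  votes <- colSums(predict_ensemble(filter_model$ensemble, X))
  keep <- votes >= 4
  keep[largest] <- TRUE
  out <- matrix(FALSE, nrow(px), ncol(px))
  kept_ids <- which(keep)
  out[lab %in% kept_ids] <- TRUE
  res <- rcs_mask(out, frame = frame)
  feats$keep <- keep
  attr(res, "decisions") <- feats
  res
}
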