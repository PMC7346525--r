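#' Euclidean color-distance map between an image and its reference
#'
#' Per-pixel Euclidean distance in RGB between the plant-containing image and
#' the empty-background reference of the same frame. On the `[0, 1]` channel
#' scale the distance lies in `[0, sqrt(3)]`; it is zero exactly where the two
#' images agree.
#'
#' @param image,reference [rcs_image()] objects of identical size
#' @return `H x W` numeric matrix of distances
#' @export
compute_color_distance_map <- function(image, reference) {
  stopifnot(inherits(image, "rcs_image"), inherits(reference, "rcs_image"))
  if (!identical(dim(image), dim(reference)))
    rcs_validation_error("image and reference differ in size")
  d <- image$pixels - reference$pixels
  sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
}

#' Fast equidistant k-means in one dimension
#'
#' Lloyd's algorithm on scalars with centroids initialized equidistantly
#' across `[min(values), max(values)]`. Because centroids stay ordered in 1-D,
#' assignment reduces to an interval search over centroid midpoints. For large
#' inputs (`length(values) >= hist_threshold`) the iteration runs on a
#' 1024-bin histogram of the values (weighted Lloyd), which makes the cost per
#' iteration independent of image size; final labels are still assigned per
#' value. Empty clusters are dropped and labels re-indexed against the sorted
#' surviving centroids.
#'
#' @param values numeric vector (non-empty)
#' @param n_clusters requested cluster count `N` (default 25)
#' @param max_iter,tol iteration cap and relative centroid-movement tolerance
#' @param hist_threshold input size above which the histogram acceleration is
#'   used
#' @return object of class `rcs_clustering1d`: `labels` (1-based integer
#'   vector), `centroids` (sorted ascending), `n_requested`, `iterations`
#' @export
equidistant_kmeans_1d <- function(values, n_clusters = 25L, max_iter = 100L,
                                  tol = 1e-4, hist_threshold = 1e5) {
  if (length(values) == 0L) rcs_validation_error("values must be non-empty")
  if (n_clusters < 1L) rcs_validation_error("n_clusters must be >= 1")
  values <- as.numeric(values)
  rng <- range(values)
  span <- rng[2] - rng[1]
  if (span == 0) {
    return(structure(list(labels = rep.int(1L, length(values)),
                          centroids = rng[1], n_requested = as.integer(n_clusters),
                          iterations = 0L),
                     class = "rcs_clustering1d"))
  }
  # equidistant init: cluster-interval midpoints across the data range
  k <- as.integer(n_clusters)
  centroids <- rng[1] + span * (seq_len(k) - 0.5) / k

  use_hist <- length(values) >= hist_threshold
  if (use_hist) {
    nbin <- 1024L
    bin <- pmin(nbin, floor((values - rng[1]) / span * nbin) + 1L)
    counts <- tabulate(bin, nbins = nbin)
    bin_centers <- rng[1] + span * (seq_len(nbin) - 0.5) / nbin
    x <- bin_centers
    w <- counts
  } else {
    x <- values
    w <- rep.int(1, length(values))
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    bounds <- (centroids[-1] + centroids[-length(centroids)]) / 2
    lab <- findInterval(x, bounds) + 1L
    sw <- rowsum(w, lab)
    sx <- rowsum(w * x, lab)
    keep <- as.integer(rownames(sw))
    pos <- sw[, 1] > 0
    new_c <- centroids
    new_c[keep[pos]] <- sx[pos, 1] / sw[pos, 1]
    move <- max(abs(new_c - centroids)) / span
    centroids <- new_c
    if (move < tol || iter >= max_iter) break
  }

  # drop empty clusters (w.r.t. the actual values), sort, relabel
  bounds <- (centroids[-1] + centroids[-length(centroids)]) / 2
  lab <- findInterval(values, bounds) + 1L
  occupied <- sort(unique(lab))
  centroids <- centroids[occupied]
  ord <- order(centroids)
  centroids <- centroids[ord]
  remap <- integer(max(occupied))
  remap[occupied[ord]] <- seq_along(occupied)
  structure(list(labels = remap[lab], centroids = centroids,
                 n_requested = as.integer(n_clusters), iterations = iter),
            class = "rcs_clustering1d")
}

#' z-scores between image and reference color distributions per distance
#' cluster
#'
#' For each cluster of the distance-map clustering, compares the color
#' distribution of the plant-containing image against the reference over the
#' same pixel positions: per channel, the absolute difference of means is
#' standardized by the reference standard deviation (floored at
#' `sigma_floor`), and the cluster z-score is the maximum over the three
#' channels. Clusters whose colors deviate strongly from the empty background
#' get large z-scores.
#'
#' @param image,reference [rcs_image()] of identical size
#' @param clustering `rcs_clustering1d` of the distance map of the same frame
#' @param sigma_floor lower bound on the reference standard deviation
#'   (default 1/255, one 8-bit quantization step)
#' @return numeric vector of non-negative z-scores, one per cluster
#' @export
cluster_zscores <- function(image, reference, clustering,
                            sigma_floor = 1 / 255) {
  stopifnot(inherits(clustering, "rcs_clustering1d"))
  if (!identical(dim(image), dim(reference)))
    rcs_validation_error("image and reference differ in size")
  npx <- prod(dim(image))
  if (length(clustering$labels) != npx)
    rcs_validation_error("clustering labels do not match image size")
  lab <- clustering$labels
  k <- length(clustering$centroids)
  z <- matrix(0, nrow = k, ncol = 3L)
  n <- tabulate(lab, nbins = k)
  for (c in 1:3) {
    ic <- as.numeric(image$pixels[, , c])
    rc <- as.numeric(reference$pixels[, , c])
    mi <- rowsum(ic, lab)[, 1] / n
    mr <- rowsum(rc, lab)[, 1] / n
    sr2 <- rowsum(rc^2, lab)[, 1] / n - mr^2
    # sample variance with n-1; clusters of size 1 fall back to the floor
    sr2 <- ifelse(n > 1, pmax(sr2, 0) * n / (n - 1), 0)
    z[, c] <- abs(mi - mr) / pmax(sqrt(sr2), sigma_floor)
  }
  apply(z, 1, max)
}

#' Distance-based pre-segmentation
#'
#' Rough plant/background split used on both modalities before registration:
#' (1) Euclidean RGB distance map between plant image and empty-background
#' reference, (2) equidistant 1-D k-means of the distance values into
#' `n_clusters` clusters, (3) per-cluster z-scores between plant-image and
#' reference color distributions, (4) union of clusters with `z > tsh`. On
#' high-contrast FLU frames this alone yields a near-ideal plant mask; on VIS
#' frames it retains shadows and background clutter, which the downstream
#' classification removes.
#'
#' @param image,reference [rcs_image()] of identical size
#' @param n_clusters number of distance clusters `N` (default 25)
#' @param tsh z-score selection threshold (default 5); strict inequality
#' @param sigma_floor see [cluster_zscores()]
#' @param detail if `TRUE`, attach the distance map, clustering and z-scores
#'   as attributes
#' @return [rcs_mask()] in the image's frame
#' @export
preseg_mask <- function(image, reference, n_clusters = 25L, tsh = 5,
                        sigma_floor = 1 / 255, detail = FALSE) {
  dm <- compute_color_distance_map(image, reference)
  cl <- equidistant_kmeans_1d(as.numeric(dm), n_clusters = n_clusters)
  z <- cluster_zscores(image, reference, cl, sigma_floor = sigma_floor)
  sel <- which(z > tsh)
  px <- matrix(cl$labels %in% sel, nrow = nrow(dm))
  m <- rcs_mask(px, frame = image$modality)
  if (detail) {
    attr(m, "distance_map") <- dm
    attr(m, "clustering") <- cl
    attr(m, "zscores") <- z
  }
  m
}
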