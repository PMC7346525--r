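srgb_to_lab <- function(rgb) {
  # standard sRGB (IEC 61966-2-1) -> XYZ (D65/2 degrees) -> CIE L*a*b*
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1, 1.08883)
  tfun <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                             t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- tfun(xyz[, 1] / wp[1])
  fy <- tfun(xyz[, 2] / wp[2])
  fz <- tfun(xyz[, 3] / wp[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Lift RGB colors to the 10-dimensional multi-color space
#'
#' Concatenates HSV (hue as fraction of a turn), CIE L*a*b* (sRGB, D65/2
#' degrees) and naive CMYK, each channel rescaled to `[0, 1]` so that no
#' channel dominates scale-sensitive downstream steps: `L/100`,
#' `(a+128)/255`, `(b+128)/255`; `K = 1 - max(R,G,B)` with
#' `C = (1-R-K)/(1-K)` etc. and `C = M = Y = 0` at pure black. Component
#' order is `(H, S, V, L, a, b, C, M, Y, K)`.
#'
#' @param rgb numeric length-3 vector or `n x 3` matrix with values in
#'   `[0, 1]`
#' @return `n x 10` matrix with named columns
#' @export
rgb_to_multicolor <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(as.numeric(rgb), ncol = 3L)
  if (ncol(rgb) != 3L) rcs_validation_error("rgb must have three columns")
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 1)
    rcs_validation_error("rgb values must lie in [0, 1]")
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  lab <- srgb_to_lab(rgb)
  K <- 1 - pmax(rgb[, 1], pmax(rgb[, 2], rgb[, 3]))
  denom <- ifelse(K < 1, 1 - K, 1)
  cmy <- (1 - rgb - K) / denom
  cmy[K >= 1, ] <- 0
  out <- cbind(hsv[, 1], hsv[, 2], hsv[, 3],
               lab[, 1] / 100, (lab[, 2] + 128) / 255, (lab[, 3] + 128) / 255,
               cmy[, 1], cmy[, 2], cmy[, 3], K)
  colnames(out) <- c("H", "S", "V", "L", "a", "b", "C", "M", "Y", "K")
  out
}

#' Fit the Eigen-color basis by PCA of multi-color pixel features
#'
#' Mean-centered principal component analysis of the 10-D multi-color
#' representation, improving topological separability of color clusters. A
#' deterministic sign convention is applied: the largest-magnitude loading of
#' each component is made positive.
#'
#' @param pixel_features `n x D` numeric matrix, `n >= 2`
#' @return object of class `rcs_eigenbasis`: `mean` (length D), `components`
#'   (`D x D`, orthonormal columns), `explained_variance` (non-increasing)
#' @export
fit_eigen_basis <- function(pixel_features) {
  pixel_features <- as.matrix(pixel_features)
  if (nrow(pixel_features) < 2L)
    rcs_validation_error("PCA needs at least two pixels")
  p <- stats::prcomp(pixel_features, center = TRUE, scale. = FALSE)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(mean = p$center, components = rot,
                 explained_variance = p$sdev^2),
            class = "rcs_eigenbasis")
}

#' Project features onto Eigen-color components (and back)
#'
#' @param basis `rcs_eigenbasis`
#' @param features `n x D` matrix
#' @param n_components number of leading components (default: all)
#' @return projected scores (`n x n_components`), or the back-projected
#'   `n x D` reconstruction
#' @export
project_eigen <- function(basis, features, n_components = NULL) {
  k <- if (is.null(n_components)) ncol(basis$components) else n_components
  sweep(as.matrix(features), 2, basis$mean) %*% basis$components[, seq_len(k), drop = FALSE]
}

#' @rdname project_eigen
#' @param scores `n x k` matrix of Eigen-color scores
#' @export
backproject_eigen <- function(basis, scores) {
  k <- ncol(scores)
  sweep(scores %*% t(basis$components[, seq_len(k), drop = FALSE]), 2,
        basis$mean, `+`)
}

#' Multi-color features of the masked pixels of an image
#'
#' @param image [rcs_image()]
#' @param mask [rcs_mask()] or logical matrix; `NULL` takes all pixels
#' @return `n x 10` feature matrix; attribute `"index"` holds the linear
#'   (column-major) pixel indices
#' @export
multicolor_features <- function(image, mask = NULL) {
  px <- image$pixels
  npx <- prod(dim(px)[1:2])
  idx <- if (is.null(mask)) seq_len(npx)
         else which(if (inherits(mask, "rcs_mask")) mask$pixels else mask)
  rgb <- cbind(px[, , 1][idx], px[, , 2][idx], px[, , 3][idx])
  out <- rgb_to_multicolor(rgb)
  attr(out, "index") <- idx
  out
}

#' Paired FLU+VIS multi-color features under a transferred mask
#'
#' Builds the 20-D feature representation: for every VIS pixel inside the
#' mask, its 10-D multi-color vector is concatenated with the 10-D vector of
#' the FLU pixel found by inverse-transform nearest-neighbour lookup.
#' Lookups falling outside the FLU frame receive the mean color of the FLU
#' reference (empty background).
#'
#' @param pair [rcs_pair()]
#' @param vis_mask [rcs_mask()] in the VIS frame
#' @param transform `rcs_transform` mapping FLU to VIS coordinates
#' @return `n x 20` matrix (columns `vis_*` then `flu_*`); attribute
#'   `"index"` as in [multicolor_features()]
#' @export
pair_features <- function(pair, vis_mask, transform) {
  fv <- multicolor_features(pair$vis, vis_mask)
  idx <- attr(fv, "index")
  H <- dim(pair$vis)[1]
  rows <- (idx - 1L) %% H          # 0-based row
  cols <- (idx - 1L) %/% H         # 0-based col
  q <- apply_transform(invert_transform(transform), cbind(cols, rows))
  fx <- round(q[, 1])
  fy <- round(q[, 2])
  hf <- dim(pair$flu)[1]
  wf <- dim(pair$flu)[2]
  inside <- fx >= 0 & fy >= 0 & fx < wf & fy < hf
  bg <- c(mean(pair$flu_ref$pixels[, , 1]), mean(pair$flu_ref$pixels[, , 2]),
          mean(pair$flu_ref$pixels[, , 3]))
  rgbf <- matrix(rep(bg, each = length(idx)), ncol = 3L)
  if (any(inside)) {
    lin <- fy[inside] + 1L + fx[inside] * hf
    rgbf[inside, 1] <- pair$flu$pixels[, , 1][lin]
    rgbf[inside, 2] <- pair$flu$pixels[, , 2][lin]
    rgbf[inside, 3] <- pair$flu$pixels[, , 3][lin]
  }
  ff <- rgb_to_multicolor(rgbf)
  out <- cbind(fv, ff)
  colnames(out) <- c(paste0("vis_", colnames(fv)), paste0("flu_", colnames(ff)))
  attr(out, "index") <- idx
  out
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = p)
    centers[j + 1L, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ])^2))
  }
  centers
}

lloyd_kmeans <- function(x, centers, max_iter = 100L, tol = 1e-8) {
  xx <- rowSums(x^2)
  for (it in seq_len(max_iter)) {
    cc <- rowSums(centers^2)
    d2 <- outer(xx, cc, `+`) - 2 * x %*% t(centers)
    lab <- max.col(-d2, ties.method = "first")
    keep <- sort(unique(lab))
    if (length(keep) < nrow(centers)) {
      centers <- centers[keep, , drop = FALSE]
      lab <- match(lab, keep)
    }
    new_c <- rowsum(x, lab) / as.numeric(tabulate(lab, nrow(centers)))
    move <- max(abs(new_c - centers))
    centers <- new_c
    if (move < tol) break
  }
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, `+`) - 2 * x %*% t(centers)
  lab <- max.col(-d2, ties.method = "first")
  inertia <- sum(pmax(d2[cbind(seq_along(lab), lab)], 0))
  list(centers = centers, labels = lab, inertia = inertia)
}

assign_nearest <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Reduce masked pixels to N k-means color regions (AC-KMR)
#'
#' Clusters the masked pixels' color features into `n_regions` k-means
#' regions and summarizes each region by its average color vector in the raw
#' multi-color space (AC-KMR, "average colors of k-means regions"). By
#' default clustering runs in the Eigen-color projection of the features.
#' k-means uses k-means++ initialization with `n_restarts` seeded restarts,
#' keeping the solution with the lowest inertia; for very large masks the
#' centroids are fitted on a random subsample (`max_fit` pixels) and all
#' pixels are then assigned to the fitted centroids.
#'
#' @param features `n x D` raw multi-color features of the masked pixels
#'   (from [multicolor_features()] or [pair_features()]), carrying the
#'   `"index"` attribute
#' @param mask [rcs_mask()] or logical matrix the features were extracted
#'   under (non-empty)
#' @param n_regions requested region count (10-30 in typical use)
#' @param seed integer seed controlling initialization and subsampling
#' @param n_restarts k-means++ restarts (default 5)
#' @param use_eigen cluster in the Eigen-color projection (default) or in the
#'   raw channels
#' @param max_fit subsample cap for centroid fitting
#' @return object of class `rcs_regions`: `labels` (`H x W` integer, 0-based
#'   region ids, -1 outside the mask), `ackmr` (`k x D` average colors),
#'   `n_regions` (surviving count `k`), `inertia`, `seed`
#' @export
reduce_to_regions <- function(features, mask, n_regions, seed = 1L,
                              n_restarts = 5L, use_eigen = TRUE,
                              max_fit = 4000L) {
  mpx <- if (inherits(mask, "rcs_mask")) mask$pixels else mask
  n <- nrow(features)
  if (n == 0L || !any(mpx))
    rcs_error("no plant candidate pixels to cluster", "rcs_empty_mask_error")
  if (n_regions < 1L || n_regions > n)
    rcs_validation_error("n_regions must be in [1, number of masked pixels]")
  x <- as.matrix(features)
  if (use_eigen && n >= 2L) {
    basis <- fit_eigen_basis(x)
    xc <- project_eigen(basis, x)
  } else {
    basis <- NULL
    xc <- x
  }
  best <- NULL
  with_rng(seed, {
    fit_idx <- if (n > max_fit) sample.int(n, max_fit) else seq_len(n)
    xf <- xc[fit_idx, , drop = FALSE]
    k <- min(n_regions, nrow(unique(xf)))
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(xf, k)
      fit <- lloyd_kmeans(xf, init)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  lab <- assign_nearest(xc, best$centers)
  keep <- sort(unique(lab))
  lab <- match(lab, keep)
  centers <- best$centers[keep, , drop = FALSE]
  ackmr <- rowsum(x, lab) / as.numeric(tabulate(lab, length(keep)))
  labels <- matrix(-1L, nrow(mpx), ncol(mpx))
  labels[attr(features, "index")] <- lab - 1L
  structure(list(labels = labels, ackmr = ackmr,
                 n_regions = length(keep), n_requested = as.integer(n_regions),
                 centroids = centers, basis = basis, inertia = best$inertia,
                 seed = as.integer(seed)),
            class = "rcs_regions")
}

#' @export
print.rcs_regions <- function(x, ...) {
  cat(sprintf("<rcs_regions %d regions, %d-D AC-KMR, %d px>\n",
              x$n_regions, ncol(x$ackmr), sum(x$labels >= 0)))
  invisible(x)
}
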