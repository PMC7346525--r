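# Independent reference implementations used as test oracles. These are
# deliberately written as plain scalar loops / direct formula transcriptions,
# sharing no code with the package internals they check.

# plain Lloyd k-means on scalars, explicit argmin assignment
oracle_lloyd_1d <- function(values, centroids, max_iter = 100, tol = 1e-4) {
  span <- diff(range(values))
  for (it in seq_len(max_iter)) {
    lab <- vapply(values, function(v) which.min(abs(v - centroids)), 1L)
    new_c <- centroids
    for (k in seq_along(centroids)) {
      if (any(lab == k)) new_c[k] <- mean(values[lab == k])
    }
    move <- max(abs(new_c - centroids)) / span
    centroids <- new_c
    if (move < tol) break
  }
  lab <- vapply(values, function(v) which.min(abs(v - centroids)), 1L)
  wss <- sum((values - centroids[lab])^2)
  list(centroids = centroids, labels = lab, wss = wss)
}

oracle_wss <- function(values, clustering) {
  sum((values - clustering$centroids[clustering$labels])^2)
}

# scalar-loop color conversions transcribed directly from the standards:
# HSV by explicit max/min branching, CIE L*a*b* via the kappa/epsilon form,
# naive CMYK
oracle_multicolor <- function(rgb) {
  out <- matrix(0, nrow(rgb), 10)
  kappa <- 24389 / 27
  eps <- 216 / 24389
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  wp <- c(0.95047, 1, 1.08883)
  for (i in seq_len(nrow(rgb))) {
    r <- rgb[i, 1]; g <- rgb[i, 2]; b <- rgb[i, 3]
    mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
    v <- mx
    s <- if (mx == 0) 0 else d / mx
    h <- if (d == 0) 0
         else if (mx == r) ((g - b) / d) %% 6
         else if (mx == g) (b - r) / d + 2
         else (r - g) / d + 4
    h <- h / 6
    lin <- vapply(c(r, g, b), function(u)
      if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4, 0)
    xyz <- as.numeric(M %*% lin) / wp
    f <- vapply(xyz, function(t)
      if (t > eps) t^(1 / 3) else (kappa * t + 16) / 116, 0)
    L <- 116 * f[2] - 16
    a <- 500 * (f[1] - f[2])
    bb <- 200 * (f[2] - f[3])
    K <- 1 - mx
    if (K >= 1) {
      C <- Mg <- Y <- 0
    } else {
      C <- (1 - r - K) / (1 - K)
      Mg <- (1 - g - K) / (1 - K)
      Y <- (1 - b - K) / (1 - K)
    }
    out[i, ] <- c(h, s, v, L / 100, (a + 128) / 255, (bb + 128) / 255,
                  C, Mg, Y, K)
  }
  out
}

# forward rasterization of a mask through a similarity transform: map every
# foreground pixel centre, round, and mark the target pixel
oracle_forward_rasterize <- function(mask_px, transform, target_shape) {
  M <- transform_matrix(transform)
  out <- matrix(FALSE, target_shape[1], target_shape[2])
  idx <- which(mask_px, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- M %*% c(idx[i, 2] - 1, idx[i, 1] - 1, 1)
    x <- round(p[1]); y <- round(p[2])
    if (x >= 0 && y >= 0 && x < target_shape[2] && y < target_shape[1])
      out[y + 1, x + 1] <- TRUE
  }
  out
}

# brute-force confusion counting by explicit enumeration
oracle_confusion <- function(truth, pred) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1L
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# per-cluster standardized mean difference, coded directly from the
# definition with explicit loops
oracle_zscores <- function(image, reference, clustering, sigma_floor = 1 / 255) {
  k <- length(clustering$centroids)
  z <- numeric(k)
  for (kk in seq_len(k)) {
    sel <- clustering$labels == kk
    zc <- numeric(3)
    for (c in 1:3) {
      ic <- as.numeric(image$pixels[, , c])[sel]
      rc <- as.numeric(reference$pixels[, , c])[sel]
      sr <- if (length(rc) > 1) stats::sd(rc) else 0
      zc[c] <- abs(mean(ic) - mean(rc)) / max(sr, sigma_floor)
    }
    z[kk] <- max(zc)
  }
  z
}
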