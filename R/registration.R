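#' Similarity transform between the FLU and VIS frames
#'
#' Maps FLU pixel coordinates into the VIS frame: with `p = (x, y)` in
#' 0-based `(col, row)` pixel-centre coordinates,
#' `p_vis = s * R(theta) * (p_flu - c) + c + t`,
#' where `s > 0` is the scale, `R(theta)` the rotation by `rotation` degrees,
#' `c` the rotation `center` and `t` the `translation` (both in pixels).
#'
#' @param scale positive scale factor
#' @param rotation rotation angle in degrees
#' @param translation length-2 `(dx, dy)` in pixels
#' @param center length-2 rotation center `(cx, cy)` in pixels
#' @return object of class `rcs_transform`
#' @export
rcs_transform <- function(scale = 1, rotation = 0, translation = c(0, 0),
                          center = c(0, 0)) {
  if (!is.finite(scale) || scale <= 0)
    rcs_validation_error("scale must be positive")
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rcs_transform")
}

#' @export
print.rcs_transform <- function(x, ...) {
  cat(sprintf(
    "<rcs_transform scale=%.4f rot=%.3f deg t=(%.2f, %.2f) c=(%.1f, %.1f)>\n",
    x$scale, x$rotation, x$translation[1], x$translation[2],
    x$center[1], x$center[2]))
  invisible(x)
}

#' Homogeneous 3x3 matrix of a similarity transform
#'
#' Convention: `vis_coords = M %*% flu_coords` with coordinates `(col, row, 1)`.
#' @param transform `rcs_transform`
#' @return 3x3 numeric matrix
#' @export
transform_matrix <- function(transform) {
  th <- transform$rotation * pi / 180
  A <- transform$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- transform$center + transform$translation - A %*% transform$center
  rbind(cbind(A, b), c(0, 0, 1))
}

transform_from_matrix <- function(M) {
  s <- sqrt(M[1, 1]^2 + M[2, 1]^2)
  th <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  rcs_transform(scale = s, rotation = th, translation = M[1:2, 3],
                center = c(0, 0))
}

#' Apply, invert and compose similarity transforms
#'
#' @param transform,a,b `rcs_transform` objects
#' @param coords `n x 2` matrix of `(col, row)` coordinates
#' @return transformed coordinates, the inverse transform, or `a` composed
#'   after `b` (`compose_transforms(a, b)(p) = a(b(p))`)
#' @export
apply_transform <- function(transform, coords) {
  M <- transform_matrix(transform)
  coords <- matrix(as.numeric(coords), ncol = 2L)
  out <- coords %*% t(M[1:2, 1:2])
  out[, 1] <- out[, 1] + M[1, 3]
  out[, 2] <- out[, 2] + M[2, 3]
  out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  M <- transform_matrix(transform)
  transform_from_matrix(solve(M))
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  transform_from_matrix(transform_matrix(a) %*% transform_matrix(b))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @param a,b `rcs_mask` or logical matrices of equal size
#' @return scalar in `[0, 1]`
#' @export
dice <- function(a, b) {
  pa <- if (inherits(a, "rcs_mask")) a$pixels else a
  pb <- if (inherits(b, "rcs_mask")) b$pixels else b
  stopifnot(identical(dim(pa), dim(pb)))
  denom <- sum(pa) + sum(pb)
  if (denom == 0) return(1)
  2 * sum(pa & pb) / denom
}

#' Transfer a binary mask through a similarity transform
#'
#' Resamples a FLU-frame mask into the VIS frame by inverse mapping with
#' nearest-neighbour interpolation; VIS pixels mapping outside the FLU frame
#' become background.
#'
#' @param mask [rcs_mask()] in the source (FLU) frame
#' @param transform `rcs_transform` mapping source to target coordinates
#' @param target_shape `c(H, W)` of the target (VIS) frame
#' @return [rcs_mask()] in the VIS frame
#' @export
transfer_mask <- function(mask, transform, target_shape) {
  stopifnot(inherits(mask, "rcs_mask"), inherits(transform, "rcs_transform"))
  Minv <- solve(transform_matrix(transform))
  px <- .transfer_nn_cpp(mask$pixels, as.numeric(Minv[1:2, 1:2]),
                         as.numeric(Minv[1:2, 3]),
                         as.integer(target_shape[1]),
                         as.integer(target_shape[2]))
  rcs_mask(px, frame = "VIS")
}

mask_centroid <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x = col, y = row), 0-based
}

mask_rms_radius <- function(px) {
  # median radius about the centroid: robust to small far-away clutter that
  # would inflate a root-mean-square radius quadratically
  idx <- which(px, arr.ind = TRUE)
  ctr <- c(mean(idx[, 2]), mean(idx[, 1]))
  stats::median(sqrt((idx[, 2] - ctr[1])^2 + (idx[, 1] - ctr[2])^2))
}

subsample_mask <- function(px, fac) {
  if (fac == 1L) return(px)
  px[seq(1L, nrow(px), by = fac), seq(1L, ncol(px), by = fac), drop = FALSE]
}

# Overlap objective: Dice computed from forward-mapped source foreground
# pixel centres against the (subsampled) target mask. Each mapped point
# represents an s^2-pixel patch of the transferred mask, so point counts are
# weighted by scale^2 to approximate areas; without this the objective would
# be degenerate in scale (shrinking the mask keeps all points inside the
# target).
overlap_objective <- function(pts, par, center, fac, target_sub, n_target) {
  th <- par[2] * pi / 180
  A <- par[1] * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- center + par[3:4] - A %*% center
  cnt <- .forward_overlap_cpp(pts[, 1], pts[, 2], as.numeric(A),
                              as.numeric(b), fac, target_sub)
  s2 <- par[1]^2
  denom <- cnt[1] * s2 + n_target
  if (denom == 0) return(0)
  # the patch estimate of the intersection cannot exceed the target area;
  # without the cap a slight scale inflation would still score 1 on
  # identical masks
  2 * min(cnt[2] * s2, n_target) / denom
}

#' Estimate the FLU-to-VIS similarity transform from pre-segmented masks
#'
#' Coarse-to-fine maximization of mask overlap (Dice) over scale, rotation and
#' translation. Initialization: translation from the centroid difference,
#' scale from the ratio of root-mean-square mask radii, rotation zero. A
#' factor-2 image pyramid (down to minimum dimension >= 64) is traversed from
#' coarse to fine; at each level a pattern search perturbs each parameter by
#' +/- its current step, accepts the best improving move, and halves the steps
#' when no move improves the overlap by more than `tol`. Registration operates
#' on binary pre-segmentations because raw FLU/VIS intensities are not
#' comparable across modalities.
#'
#' @param flu_preseg [rcs_mask()] in the FLU frame (non-empty)
#' @param vis_preseg [rcs_mask()] in the VIS frame (non-empty)
#' @param max_iter pattern-search iteration cap per pyramid level
#' @param tol minimum Dice improvement to accept a move
#' @param min_dim coarsest pyramid level keeps both dimensions >= `min_dim`
#' @return `rcs_transform` with the estimated mapping; attribute `dice` holds
#'   the final overlap score
#' @export
estimate_similarity_transform <- function(flu_preseg, vis_preseg,
                                          max_iter = 50L, tol = 1e-4,
                                          min_dim = 64L) {
  stopifnot(inherits(flu_preseg, "rcs_mask"), inherits(vis_preseg, "rcs_mask"))
  fp <- flu_preseg$pixels
  vp <- vis_preseg$pixels
  if (!any(fp) || !any(vp))
    rcs_error("cannot register: empty pre-segmentation mask",
              "rcs_registration_error")

  ctr_f <- mask_centroid(fp)
  ctr_v <- mask_centroid(vp)
  s0 <- mask_rms_radius(vp) / mask_rms_radius(fp)
  par <- c(s0, 0, ctr_v - ctr_f)  # (scale, rotation deg, dx, dy)
  center <- ctr_f

  # pyramid factors, coarse to fine
  fac <- 1L
  while (min(dim(fp), dim(vp)) / (fac * 2L) >= min_dim) fac <- fac * 2L
  facs <- rev(2^(0:log2(fac)))

  for (f in facs) {
    vis_sub <- subsample_mask(vp, f)
    flu_sub <- subsample_mask(fp, f)
    idx <- which(flu_sub, arr.ind = TRUE)
    pts <- cbind((idx[, 2] - 1) * f, (idx[, 1] - 1) * f)  # full-res (x, y)
    n_target <- sum(vis_sub)
    obj <- function(p) overlap_objective(pts, p, center, f, vis_sub, n_target)

    steps <- c(if (f == facs[1]) 0.04 else 0.01,    # scale
               if (f == facs[1]) 2 else 0.5,        # rotation (deg)
               2 * f, 2 * f)                        # translation (px)
    step_floor <- c(0.001, 0.02, 0.2 * f, 0.2 * f)
    cur <- obj(par)
    for (it in seq_len(max_iter)) {
      best_gain <- 0
      best_par <- par
      for (j in 1:4) {
        for (sg in c(-1, 1)) {
          cand <- par
          cand[j] <- cand[j] + sg * steps[j]
          if (j == 1 && cand[1] <= 0.05) next
          v <- obj(cand)
          if (v - cur > best_gain) {
            best_gain <- v - cur
            best_par <- cand
          }
        }
      }
      if (best_gain > tol) {
        par <- best_par
        cur <- cur + best_gain
      } else {
        if (all(steps <= step_floor)) break
        steps <- pmax(steps / 2, step_floor)
      }
    }
  }

  out <- rcs_transform(scale = par[1], rotation = par[2],
                       translation = par[3:4], center = center)
  attr(out, "dice") <- dice(transfer_mask(flu_preseg, out, dim(vp)),
                            vis_preseg)
  out
}

#' Serialize / deserialize a transform as a JSON homogeneous matrix
#'
#' Convention: `vis = M %*% flu` on `(col, row, 1)` coordinates.
#' @param transform `rcs_transform`
#' @param path JSON file path
#' @export
save_transform <- function(transform, path) {
  M <- transform_matrix(transform)
  jsonlite::write_json(
    list(matrix = M,
         convention = "vis_coords = M * flu_coords, coords (col,row,1), 0-based",
         scale = transform$scale, rotation_deg = transform$rotation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  if (!file.exists(path))
    rcs_input_error(sprintf("transform file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_from_matrix(matrix(unlist(obj$matrix), 3, 3))
}
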