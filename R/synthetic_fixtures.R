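ARCHETYPES <- c("rosette-top", "grass-side", "broadleaf-side")
STAGES <- c("I", "II", "III")

# stage-dependent VIS plant palettes: juvenile plants are light green, adult
# plants dark green with yellowish patches
stage_palette <- function(stage) {
  switch(stage,
         I = list(base = c(0.45, 0.72, 0.30), yellow_frac = 0.00),
         II = list(base = c(0.30, 0.55, 0.22), yellow_frac = 0.10),
         III = list(base = c(0.20, 0.40, 0.15), yellow_frac = 0.30))
}

CLUTTER_PALETTE <- rbind(soil = c(0.38, 0.27, 0.16),
                         stone = c(0.55, 0.54, 0.50),
                         moss = c(0.36, 0.46, 0.26))

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}

#' Specification of one synthetic multimodal fixture
#'
#' Describes everything needed to render one FLU/VIS pair with ground truth:
#' frame sizes (FLU and VIS may differ, as with real camera pairs), species
#' archetype and developmental stage, the FLU-to-VIS misalignment (the motion
#' artefact on top of the fixed frame-scale difference), noise levels, and
#' the background-clutter configuration. A fixed seed yields byte-identical
#' rendered output.
#'
#' @param seed integer seed
#' @param archetype `"rosette-top"`, `"grass-side"` or `"broadleaf-side"`
#' @param stage developmental stage `"I"` (juvenile), `"II"` (mid) or
#'   `"III"` (adult)
#' @param vis_size,flu_size `c(H, W)` frame sizes
#' @param misalignment list with `scale`, `rotation` (degrees), `dx`, `dy`
#'   (VIS pixels) — the motion artefact between the two acquisitions
#' @param noise list with `sd` (Gaussian sensor noise), `illumination`
#'   (linear gradient amplitude), `shadow` (shadow opacity)
#' @param clutter list with `n` (far object count), `size` (radius range, px),
#'   `n_near` (moss-colored patches placed close to the shoot, inside the
#'   marginal-background ring that the transferred FLU mask picks up) and
#'   `near_size`
#' @param n_leaftips number of separately segmented plant leaf tips planted
#'   near the shoot (small plant-colored objects the artefact filter must
#'   keep)
#' @return object of class `rcs_fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, archetype = "rosette-top", stage = "I",
                         vis_size = c(512L, 512L), flu_size = c(400L, 400L),
                         misalignment = list(scale = 1, rotation = 0,
                                             dx = 0, dy = 0),
                         noise = list(sd = 0.01, illumination = 0.08,
                                      shadow = 0.25),
                         clutter = list(n = 6L, size = c(3, 9), n_near = 4L,
                                        near_size = c(3, 7)),
                         n_leaftips = 2L) {
  if (!archetype %in% ARCHETYPES)
    rcs_validation_error(sprintf("unknown archetype '%s'", archetype))
  if (!stage %in% STAGES)
    rcs_validation_error(sprintf("unknown stage '%s'", stage))
  misalignment <- utils::modifyList(
    list(scale = 1, rotation = 0, dx = 0, dy = 0), misalignment)
  noise <- utils::modifyList(
    list(sd = 0.01, illumination = 0.08, shadow = 0.25), noise)
  clutter <- utils::modifyList(list(n = 6L, size = c(3, 9), n_near = 4L,
                                    near_size = c(3, 7)), clutter)
  structure(list(seed = as.integer(seed), archetype = archetype,
                 stage = stage, vis_size = as.integer(vis_size),
                 flu_size = as.integer(flu_size),
                 misalignment = misalignment, noise = noise,
                 clutter = clutter, n_leaftips = as.integer(n_leaftips)),
            class = "rcs_fixture_spec")
}

disc_offsets <- function(r) {
  d <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dy = d, dx = d)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

stamp_discs <- function(mask, xs, ys, rs) {
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_along(xs)) {
    off <- disc_offsets(rs[i])
    px <- round(xs[i]) + off$dx
    py <- round(ys[i]) + off$dy
    ok <- px >= 0 & py >= 0 & px < W & py < H
    mask[cbind(py[ok] + 1L, px[ok] + 1L)] <- TRUE
  }
  mask
}

render_silhouette <- function(archetype, stage, H, W) {
  # returns logical H x W; all randomness comes from the caller's RNG state
  mindim <- min(H, W)
  Xg <- matrix(rep(0:(W - 1L), each = H), H, W)
  Yg <- matrix(rep(0:(H - 1L), W), H, W)
  si <- match(stage, STAGES)
  if (archetype == "rosette-top") {
    R <- c(0.10, 0.17, 0.25)[si] * mindim
    k <- c(6, 8, 10)[si]
    cx <- W / 2 + runif(1, -6, 6)
    cy <- H / 2 + runif(1, -6, 6)
    phase <- runif(1, 0, 2 * pi)
    dx <- Xg - cx; dy <- Yg - cy
    r <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    rim <- R * (0.35 + 0.65 * abs(sin(k * (phi + phase) / 2))^0.8)
    sil <- r <= rim
  } else if (archetype == "grass-side") {
    n_blades <- c(4, 7, 10)[si]
    L <- c(0.25, 0.40, 0.55)[si] * H
    w0 <- c(2.5, 3.5, 4.5)[si]
    bx <- W / 2 + runif(1, -10, 10)
    by <- H * 0.88
    sil <- matrix(FALSE, H, W)
    for (b in seq_len(n_blades)) {
      th <- runif(1, -0.45, 0.45)
      curv <- runif(1, -0.5, 0.5)
      ts <- seq(0, 1, length.out = 150L)
      xs <- bx + L * (sin(th) * ts + 0.5 * curv * ts^2)
      ys <- by - L * cos(th) * ts * (1 - 0.1 * abs(curv) * ts)
      ws <- w0 * (1 - 0.75 * ts) + 0.7
      sil <- stamp_discs(sil, xs, ys, ws)
    }
  } else {  # broadleaf-side
    L <- c(0.22, 0.38, 0.52)[si] * H
    n_leaves <- c(2, 4, 6)[si]
    bx <- W / 2 + runif(1, -10, 10)
    by <- H * 0.88
    ts <- seq(0, 1, length.out = 150L)
    sil <- stamp_discs(matrix(FALSE, H, W),
                       xs = rep(bx, 150L), ys = by - L * ts,
                       rs = rep(c(2, 2.5, 3)[si], 150L))
    a <- L * c(0.30, 0.30, 0.32)[si]
    b <- a * 0.35
    for (l in seq_len(n_leaves)) {
      hfrac <- 0.25 + 0.7 * (l - 0.5) / n_leaves
      side <- if (l %% 2 == 0) 1 else -1
      ang <- side * runif(1, 25, 55) * pi / 180
      cx <- bx + side * a * 0.8 * cos(abs(ang))
      cy <- by - L * hfrac - a * 0.6 * sin(abs(ang))
      ca <- cos(ang); sa <- sin(ang)
      u <- (Xg - cx) * ca + (Yg - cy) * sa
      v <- -(Xg - cx) * sa + (Yg - cy) * ca
      sil <- sil | ((u / a)^2 + (v / b)^2 <= 1)
    }
  }
  if (any(sil[1, ]) || any(sil[H, ]) || any(sil[, 1]) || any(sil[, W]))
    rcs_error("rendered silhouette exceeds the frame", "rcs_spec_error")
  sil
}

blur2d <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

#' Generate one synthetic multimodal FLU/VIS fixture pair
#'
#' Renders a parametric plant silhouette (rosette leaf lobes for top view,
#' curved blades for grass, stem plus ellipsoid leaves for broadleaf), scaled
#' by developmental stage, plus small detached leaf-tip objects near the
#' shoot. The VIS frame shows a light-gray background with a linear
#' illumination gradient, a blurred offset shadow of the plant, background
#' clutter (soil/stone/moss-colored specks; moss is deliberately green-ish so
#' color alone cannot separate the classes) and Gaussian sensor noise. The
#' FLU frame shows the same plant, bright on a dark background, rendered
#' under the inverse of the applied FLU-to-VIS transform (frame-scale
#' difference composed with the specified misalignment). Reference
#' (empty-background) frames, ground-truth masks in both frames, the applied
#' transform and per-object labels are all returned.
#'
#' @param spec [fixture_spec()]
#' @return object of class `rcs_fixture`: `pair` ([rcs_pair()]), `truth_vis`,
#'   `truth_flu` ([rcs_mask()]), `applied_transform` (full FLU-to-VIS
#'   `rcs_transform`), `misalignment` (echo of the spec's motion-artefact
#'   parameters), `objects` (data.frame of planted leaf tips and clutter with
#'   plant/artefact labels), `clutter_mask`, `spec`
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "rcs_fixture_spec"))
  H <- spec$vis_size[1]; W <- spec$vis_size[2]
  hf <- spec$flu_size[1]; wf <- spec$flu_size[2]
  with_rng(spec$seed, {
    sil <- render_silhouette(spec$archetype, spec$stage, H, W)
    pal <- stage_palette(spec$stage)

    # distance of background pixels to the silhouette, for object placement
    dist_to_sil <- as.matrix(EBImage::distmap(1 - sil, metric = "euclidean"))

    # planted leaf tips: small plant-colored discs near (but detached from)
    # the shoot; part of the ground truth
    objects <- list()
    leaftip_mask <- matrix(FALSE, H, W)
    if (spec$n_leaftips > 0L) {
      cand <- which(dist_to_sil >= 8 & dist_to_sil <= 20, arr.ind = TRUE)
      cand <- cand[cand[, 1] > 12 & cand[, 1] < H - 12 &
                   cand[, 2] > 12 & cand[, 2] < W - 12, , drop = FALSE]
      if (nrow(cand) > 0L) {
        picks <- cand[sample.int(nrow(cand), min(spec$n_leaftips, nrow(cand))),
                      , drop = FALSE]
        for (i in seq_len(nrow(picks))) {
          r <- runif(1, 2, 4)
          x <- picks[i, 2] - 1L; y <- picks[i, 1] - 1L
          if (dist_to_sil[picks[i, 1], picks[i, 2]] <= r + 3) next
          leaftip_mask <- stamp_discs(leaftip_mask, x, y, r)
          objects[[length(objects) + 1L]] <- data.frame(
            type = "plant", x = x, y = y, r = r)
        }
      }
    }

    # background clutter: never overlaps the silhouette or the leaf tips.
    # Far clutter (soil/stone/moss specks) exercises the VIS pre-segmentation
    # and the object filter; near clutter (moss growing around the shoot, a
    # standard feature of greenhouse trays) lands inside the marginal-
    # background ring that the transferred FLU mask picks up, so the region
    # classifier must separate it from plant tissue by color
    clutter_mask <- matrix(FALSE, H, W)
    clutter_color <- vector("list", 0L)
    placed <- matrix(numeric(0), ncol = 2)
    n_placed <- 0L
    place_clutter <- function(n_want, dist_lo, dist_hi, size_rng, moss_only) {
      attempts <- 0L
      placed_here <- 0L
      while (placed_here < n_want && attempts < 400L) {
        attempts <- attempts + 1L
        x <- runif(1, 15, W - 15); y <- runif(1, 15, H - 15)
        r <- runif(1, size_rng[1], size_rng[2])
        d <- dist_to_sil[round(y) + 1L, round(x) + 1L]
        if (d < dist_lo + r || d > dist_hi) next
        if (leaftip_mask[round(y) + 1L, round(x) + 1L]) next
        if (n_placed > 0L &&
            min(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)) < 2.5 * r + 8)
          next
        one <- stamp_discs(matrix(FALSE, H, W), x, y, r)
        if (any(one & (sil | leaftip_mask))) next
        clutter_mask <<- clutter_mask | one
        row <- if (moss_only) which(rownames(CLUTTER_PALETTE) == "moss")
               else sample.int(nrow(CLUTTER_PALETTE), 1L)
        col <- CLUTTER_PALETTE[row, ] + rnorm(3, 0, 0.02)
        clutter_color[[n_placed + 1L]] <<- list(mask = which(one),
                                                color = pmin(pmax(col, 0), 1))
        placed <<- rbind(placed, c(x, y))
        objects[[length(objects) + 1L]] <<- data.frame(
          type = "artefact", x = x, y = y, r = r)
        n_placed <<- n_placed + 1L
        placed_here <- placed_here + 1L
      }
    }
    place_clutter(spec$clutter$n, 45, Inf, spec$clutter$size,
                  moss_only = FALSE)
    place_clutter(spec$clutter$n_near, 5, 28, spec$clutter$near_size,
                  moss_only = TRUE)

    truth_vis <- sil | leaftip_mask

    # FLU-to-VIS transform: fixed frame-scale difference composed with the
    # motion-artefact misalignment (about the VIS frame center)
    sf <- min(H, W) / min(hf, wf)
    t_frame <- rcs_transform(scale = sf)
    t_mis <- rcs_transform(scale = spec$misalignment$scale,
                           rotation = spec$misalignment$rotation,
                           translation = c(spec$misalignment$dx,
                                           spec$misalignment$dy),
                           center = c((W - 1) / 2, (H - 1) / 2))
    t_total <- compose_transforms(t_mis, t_frame)
    M <- transform_matrix(t_total)
    truth_flu_px <- .transfer_nn_cpp(truth_vis, as.numeric(M[1:2, 1:2]),
                                     as.numeric(M[1:2, 3]), hf, wf)
    if (any(truth_flu_px[1, ]) || any(truth_flu_px[hf, ]) ||
        any(truth_flu_px[, 1]) || any(truth_flu_px[, wf]))
      rcs_error("plant silhouette exceeds the FLU frame under the specified misalignment",
                "rcs_spec_error")

    # ---- VIS frame ----
    Xg <- matrix(rep(0:(W - 1L), each = H), H, W)
    Yg <- matrix(rep(0:(H - 1L), W), H, W)
    gdir <- runif(2, -1, 1)
    gdir <- gdir / max(sqrt(sum(gdir^2)), 1e-9)
    gradient <- spec$noise$illumination *
      ((Xg / W - 0.5) * gdir[1] + (Yg / H - 0.5) * gdir[2])
    vis_bg <- c(0.80, 0.79, 0.77)
    mk_vis <- function(with_plant) {
      ch <- lapply(1:3, function(c) vis_bg[c] + gradient)
      if (with_plant) {
        # blurred offset shadow darkens the background multiplicatively
        if (spec$noise$shadow > 0) {
          sh <- matrix(FALSE, H, W)
          idx <- which(truth_vis, arr.ind = TRUE)
          sy <- pmin(pmax(idx[, 1] + 10L, 1L), H)
          sx <- pmin(pmax(idx[, 2] + 14L, 1L), W)
          sh[cbind(sy, sx)] <- TRUE
          shb <- blur2d(sh * 1, sigma = 4)
          for (c in 1:3) ch[[c]] <- ch[[c]] * (1 - spec$noise$shadow * shb)
        }
        for (cc in clutter_color)
          for (c in 1:3) ch[[c]][cc$mask] <- cc$color[c]
        pidx <- which(truth_vis)
        npp <- length(pidx)
        var_px <- matrix(rnorm(npp * 3, 0, 0.04), ncol = 3)
        base <- matrix(rep(pal$base, each = npp), ncol = 3)
        if (pal$yellow_frac > 0) {
          ny <- round(pal$yellow_frac * npp)
          if (ny > 0) {
            yi <- sample.int(npp, ny)
            base[yi, ] <- matrix(rep(c(0.55, 0.50, 0.12), each = ny),
                                 ncol = 3)
          }
        }
        for (c in 1:3) ch[[c]][pidx] <- base[, c] + var_px[, c]
      }
      px <- array(0, c(H, W, 3L))
      for (c in 1:3) {
        v <- ch[[c]]
        if (spec$noise$sd > 0) v <- v + rnorm(H * W, 0, spec$noise$sd)
        px[, , c] <- pmin(pmax(v, 0), 1)
      }
      px
    }
    vis_px <- mk_vis(TRUE)
    vis_ref_px <- mk_vis(FALSE)

    # ---- FLU frame ----
    flu_bg <- c(0.05, 0.04, 0.07)
    mk_flu <- function(with_plant) {
      ch <- lapply(1:3, function(c) matrix(flu_bg[c], hf, wf))
      if (with_plant) {
        pidx <- which(truth_flu_px)
        npp <- length(pidx)
        if (npp > 0) {
          var_px <- matrix(rnorm(npp * 3, 0, 0.04), ncol = 3)
          base <- matrix(rep(c(0.78, 0.16, 0.38), each = npp), ncol = 3)
          for (c in 1:3) ch[[c]][pidx] <- base[, c] + var_px[, c]
        }
      }
      px <- array(0, c(hf, wf, 3L))
      for (c in 1:3) {
        v <- ch[[c]]
        if (spec$noise$sd > 0) v <- v + rnorm(hf * wf, 0, spec$noise$sd)
        px[, , c] <- pmin(pmax(v, 0), 1)
      }
      px
    }
    flu_px <- mk_flu(TRUE)
    flu_ref_px <- mk_flu(FALSE)

    pair <- rcs_pair(flu = rcs_image(flu_px, "FLU"),
                     vis = rcs_image(vis_px, "VIS"),
                     flu_ref = rcs_image(flu_ref_px, "FLU"),
                     vis_ref = rcs_image(vis_ref_px, "VIS"))
    objects_df <- if (length(objects) > 0L) do.call(rbind, objects)
                  else data.frame(type = character(), x = numeric(),
                                  y = numeric(), r = numeric())
    structure(list(pair = pair,
                   truth_vis = rcs_mask(truth_vis, "VIS"),
                   truth_flu = rcs_mask(truth_flu_px, "FLU"),
                   applied_transform = t_total,
                   misalignment = spec$misalignment,
                   objects = objects_df,
                   clutter_mask = clutter_mask,
                   spec = spec),
              class = "rcs_fixture")
  })
}

#' @export
print.rcs_fixture <- function(x, ...) {
  cat(sprintf("<rcs_fixture %s stage %s, seed %d>\n", x$spec$archetype,
              x$spec$stage, x$spec$seed))
  invisible(x)
}

random_misalignment <- function() {
  list(scale = runif(1, 0.97, 1.03), rotation = runif(1, -4, 4),
       dx = runif(1, -12, 12), dy = runif(1, -12, 12))
}

#' Generate the full synthetic scenario suite
#'
#' Renders `n_per_cell` fixture pairs for every (archetype, stage) cell with
#' stage-dependent palettes and per-pair random FLU/VIS misalignment, and
#' splits each cell into training and test pairs. The suite stands in for a
#' greenhouse experiment with three species/view settings observed at three
#' developmental stages.
#'
#' @param seed integer master seed; per-pair seeds are derived from it
#' @param archetypes,stages cells to generate
#' @param n_per_cell pairs per cell (default 10)
#' @param n_train leading pairs of each cell used for training (default 5)
#' @param vis_size,flu_size frame sizes passed to [fixture_spec()]
#' @param noise,clutter,n_leaftips passed to [fixture_spec()]
#' @return object of class `rcs_suite`: nested list `cells[[archetype]][[stage]]`
#'   with elements `fixtures`, `train_idx`, `test_idx`
#' @export
generate_scenario_suite <- function(seed = 1L, archetypes = ARCHETYPES,
                                    stages = STAGES, n_per_cell = 10L,
                                    n_train = 5L,
                                    vis_size = c(512L, 512L),
                                    flu_size = c(400L, 400L),
                                    noise = list(sd = 0.01,
                                                 illumination = 0.08,
                                                 shadow = 0.25),
                                    clutter = list(n = 6L, size = c(3, 9)),
                                    n_leaftips = 2L) {
  cells <- list()
  cell_id <- 0L
  for (arch in archetypes) {
    cells[[arch]] <- list()
    for (st in stages) {
      cell_id <- cell_id + 1L
      fixtures <- lapply(seq_len(n_per_cell), function(i) {
        sub <- derive_seed(seed, cell_id * 1000L + i)
        mis <- with_rng(derive_seed(sub, 1L), random_misalignment())
        generate_pair(fixture_spec(
          seed = sub, archetype = arch, stage = st, vis_size = vis_size,
          flu_size = flu_size, misalignment = mis, noise = noise,
          clutter = clutter, n_leaftips = n_leaftips))
      })
      cells[[arch]][[st]] <- list(fixtures = fixtures,
                                  train_idx = seq_len(min(n_train, n_per_cell)),
                                  test_idx = setdiff(seq_len(n_per_cell),
                                                     seq_len(min(n_train,
                                                                 n_per_cell))))
    }
  }
  structure(list(cells = cells, seed = as.integer(seed),
                 archetypes = archetypes, stages = stages,
                 n_per_cell = as.integer(n_per_cell)),
            class = "rcs_suite")
}

#' Write a fixture to the on-disk dataset layout
#'
#' Writes `flu.png`, `vis.png`, `flu_ref.png`, `vis_ref.png`, the truth
#' masks, the applied transform and a JSON manifest (scenario metadata,
#' seed, per-file MD5 checksums) into one directory.
#'
#' @param fixture `rcs_fixture`
#' @param dir destination directory (created if needed)
#' @export
write_fixture_dataset <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- fixture$pair
  save_image(p$flu, file.path(dir, "flu.png"))
  save_image(p$vis, file.path(dir, "vis.png"))
  save_image(p$flu_ref, file.path(dir, "flu_ref.png"))
  save_image(p$vis_ref, file.path(dir, "vis_ref.png"))
  save_mask(fixture$truth_vis, file.path(dir, "truth_vis.png"))
  save_mask(fixture$truth_flu, file.path(dir, "truth_flu.png"))
  save_transform(fixture$applied_transform, file.path(dir, "transform.json"))
  files <- c("flu.png", "vis.png", "flu_ref.png", "vis_ref.png",
             "truth_vis.png", "truth_flu.png")
  manifest <- list(archetype = fixture$spec$archetype,
                   stage = fixture$spec$stage, seed = fixture$spec$seed,
                   misalignment = fixture$misalignment,
                   checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
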