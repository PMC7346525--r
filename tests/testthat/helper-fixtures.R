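# small fixture configurations for fast unit tests (reduced frames, light
# clutter); the acceptance tests use the full default conditions
tiny_spec <- function(seed = 1L, archetype = "rosette-top", stage = "I", ...) {
  fixture_spec(seed = seed, archetype = archetype, stage = stage,
               vis_size = c(160L, 160L), flu_size = c(128L, 128L),
               clutter = list(n = 3L, size = c(2, 6), n_near = 2L,
                              near_size = c(2, 5)),
               n_leaftips = 1L, ...)
}

flat_image <- function(h, w, rgb, modality = "VIS") {
  make_reference_from_color(h, w, rgb, modality = modality)
}

# image with a centred bright square on a dark background, plus its reference
square_pair <- function(h = 40L, w = 40L, side = 10L,
                        fg = c(0.9, 0.2, 0.4), bg = c(0.05, 0.05, 0.05)) {
  ref <- flat_image(h, w, bg, "FLU")
  px <- ref$pixels
  r0 <- (h - side) %/% 2L
  c0 <- (w - side) %/% 2L
  for (c in 1:3) px[r0:(r0 + side - 1L), c0:(c0 + side - 1L), c] <- fg[c]
  list(image = rcs_image(px, "FLU"), reference = ref,
       truth = {
         m <- matrix(FALSE, h, w)
         m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- TRUE
         m
       })
}

# linearly separable two-blob training table
separable_table <- function(n_per_class = 30L, d = 10L, seed = 1L,
                            margin = 2) {
  set.seed(seed)
  X0 <- matrix(stats::rnorm(n_per_class * d, 0, 0.15), ncol = d)
  X1 <- matrix(stats::rnorm(n_per_class * d, margin, 0.15), ncol = d)
  list(X = rbind(X0, X1), y = rep(c(0L, 1L), each = n_per_class))
}

# object feature table from a fixture: components of truth + clutter with
# plant/artefact labels
fixture_object_table <- function(seeds, spec_fun = tiny_spec) {
  F <- list(); L <- list()
  for (s in seeds) {
    fx <- generate_pair(spec_fun(seed = s))
    cand <- rcs_mask(fx$truth_vis$pixels | fx$clutter_mask, "VIS")
    F[[length(F) + 1L]] <- extract_object_features(cand, fx$pair$vis)
    L[[length(L) + 1L]] <- rcseg:::object_truth_labels(cand, fx$truth_vis)
  }
  list(F = do.call(rbind, F), L = unlist(L))
}
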