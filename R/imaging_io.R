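#' Raster image container
#'
#' Canonical in-memory representation of a camera frame: an `H x W x 3` array
#' of per-channel values normalized to `[0, 1]` regardless of source bit
#' depth, plus the modality tag (`"FLU"` fluorescence or `"VIS"` visible
#' light). Grayscale input is replicated to three channels; an alpha channel,
#' if present, is dropped with a warning.
#'
#' @param pixels numeric matrix (`H x W`, grayscale) or array (`H x W x 3` or
#'   `H x W x 4`) with values in `[0, 1]`
#' @param modality `"FLU"` or `"VIS"`
#' @param bit_depth source bit depth, 8 or 16 (metadata only; pixel values are
#'   always on the `[0, 1]` scale)
#' @return an object of class `rcs_image`
#' @export
rcs_image <- function(pixels, modality = c("VIS", "FLU"), bit_depth = 8L) {
  modality <- match.arg(modality)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    rcs_validation_error("pixels must be an H x W or H x W x C array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    rcs_validation_error("image must have at least one row and one column")
  if (d[3] == 4L) {
    warning("alpha channel dropped", call. = FALSE)
    pixels <- pixels[, , 1:3, drop = FALSE]
  } else if (d[3] == 1L) {
    pixels <- array(pixels[, , 1L], c(d[1], d[2], 3L))
  } else if (d[3] != 3L) {
    rcs_validation_error(sprintf("unsupported channel count: %d", d[3]))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    rcs_validation_error("pixel values must lie in [0, 1]")
  if (!bit_depth %in% c(8L, 16L))
    rcs_validation_error("bit_depth must be 8 or 16")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 modality = modality),
            class = "rcs_image")
}

#' @export
print.rcs_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rcs_image %s %dx%d, source %d-bit>\n",
              x$modality, d[1], d[2], x$bit_depth))
  invisible(x)
}

#' @export
dim.rcs_image <- function(x) dim(x$pixels)[1:2]

#' Binary mask container
#'
#' @param pixels logical `H x W` matrix (or numeric, coerced by `> 0.5`)
#' @param frame coordinate frame the mask lives in, `"FLU"` or `"VIS"`
#' @return an object of class `rcs_mask`
#' @export
rcs_mask <- function(pixels, frame = c("VIS", "FLU")) {
  frame <- match.arg(frame)
  if (!is.matrix(pixels)) rcs_validation_error("mask pixels must be a matrix")
  if (!is.logical(pixels)) pixels <- pixels > 0.5
  structure(list(pixels = pixels, frame = frame), class = "rcs_mask")
}

#' @export
print.rcs_mask <- function(x, ...) {
  cat(sprintf("<rcs_mask %s %dx%d, %d foreground px>\n", x$frame,
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
dim.rcs_mask <- function(x) dim(x$pixels)

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

#' Read a PNG or TIFF image
#'
#' Values are normalized to `[0, 1]`: 8-bit sources by 1/255, 16-bit sources
#' by 1/65535. Grayscale images are replicated to three channels.
#'
#' @param path file path (`.png`, `.tif` or `.tiff`)
#' @param modality `"FLU"` or `"VIS"`
#' @return [rcs_image()]
#' @export
load_image <- function(path, modality = c("VIS", "FLU")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    rcs_input_error(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    depth <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(px, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else {
    rcs_input_error(sprintf("unsupported image format: %s", path))
  }
  rcs_image(unclass(px), modality = modality,
            bit_depth = if (as.integer(depth) >= 16L) 16L else 8L)
}

#' Write an image as 8-bit PNG or TIFF
#'
#' @param image [rcs_image()]
#' @param path destination path; format chosen by extension
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "rcs_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(image$pixels, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(image$pixels, path)
  else rcs_input_error(sprintf("unsupported image format: %s", path))
  invisible(path)
}

#' Read / write a binary mask as single-channel 8-bit PNG (0 = background,
#' 255 = plant)
#'
#' @param path PNG path
#' @param frame `"FLU"` or `"VIS"`
#' @return [rcs_mask()]
#' @export
load_mask <- function(path, frame = c("VIS", "FLU")) {
  frame <- match.arg(frame)
  if (!file.exists(path))
    rcs_input_error(sprintf("mask file not found: %s", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  rcs_mask(px >= 0.5, frame = frame)
}

#' @rdname load_mask
#' @param mask [rcs_mask()]
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "rcs_mask"))
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' Load a multimodal FLU/VIS pair with reference frames
#'
#' The reference frames are empty-background images of the same photochamber;
#' they are the subtraction baseline for the color-distance pre-segmentation.
#' FLU and VIS frames may have different sizes (different cameras), but each
#' image must match its own reference.
#'
#' @param flu_path,vis_path plant-containing FLU and VIS images
#' @param flu_ref_path,vis_ref_path matching empty-background references
#' @return an object of class `rcs_pair` with elements `flu`, `vis`,
#'   `flu_ref`, `vis_ref`
#' @export
load_pair <- function(flu_path, vis_path, flu_ref_path, vis_ref_path) {
  pair <- list(flu = load_image(flu_path, "FLU"),
               vis = load_image(vis_path, "VIS"),
               flu_ref = load_image(flu_ref_path, "FLU"),
               vis_ref = load_image(vis_ref_path, "VIS"))
  rcs_pair(pair$flu, pair$vis, pair$flu_ref, pair$vis_ref)
}

#' Assemble a multimodal pair from in-memory images
#'
#' @param flu,vis plant-containing images
#' @param flu_ref,vis_ref empty-background references
#' @return `rcs_pair`
#' @export
rcs_pair <- function(flu, vis, flu_ref, vis_ref) {
  for (im in list(flu, vis, flu_ref, vis_ref)) stopifnot(inherits(im, "rcs_image"))
  if (!identical(dim(flu), dim(flu_ref)))
    rcs_validation_error("FLU image and FLU reference differ in size")
  if (!identical(dim(vis), dim(vis_ref)))
    rcs_validation_error("VIS image and VIS reference differ in size")
  structure(list(flu = flu, vis = vis, flu_ref = flu_ref, vis_ref = vis_ref),
            class = "rcs_pair")
}

#' Synthesize a constant-color reference frame
#'
#' Users without recorded empty-background frames can approximate them with a
#' constant image: near-black for FLU, light gray for VIS.
#'
#' @param height,width frame size in pixels (each at least 1)
#' @param rgb_color length-3 numeric in `[0, 1]`
#' @param modality `"FLU"` or `"VIS"`
#' @return [rcs_image()]
#' @export
make_reference_from_color <- function(height, width, rgb_color,
                                      modality = c("VIS", "FLU")) {
  modality <- match.arg(modality)
  if (height < 1 || width < 1)
    rcs_validation_error("reference frame must be at least 1x1")
  rgb_color <- as.numeric(rgb_color)
  if (length(rgb_color) != 3L || anyNA(rgb_color) ||
      min(rgb_color) < 0 || max(rgb_color) > 1)
    rcs_validation_error("rgb_color must be three values in [0, 1]")
  px <- array(rep(rgb_color, each = height * width), c(height, width, 3L))
  rcs_image(px, modality = modality)
}
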