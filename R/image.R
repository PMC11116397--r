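#' Construct a raster image with pixel-size metadata
#'
#' Images are plain numeric matrices (first index x, second y) carrying the
#' pixel size in nanometres and a channel tag as attributes. Counts must be
#' non-negative.
#'
#' @param data numeric matrix of non-negative values.
#' @param pixel_size_nm pixel size in nanometres (> 0).
#' @param channel channel tag, e.g. `"IM"` or `"mtDNA"`.
#' @return a `mito_image` object.
#' @export
mito_image <- function(data, pixel_size_nm, channel = "IM") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  }
  if (any(data < 0, na.rm = TRUE)) {
    stop("image counts must be non-negative", call. = FALSE)
  }
  structure(data, pixel_size_nm = as.numeric(pixel_size_nm),
            channel = channel, class = c("mito_image", "matrix", "array"))
}

#' @export
print.mito_image <- function(x, ...) {
  cat(sprintf("<mito_image> %d x %d px, %.1f nm/px, channel %s\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"),
              attr(x, "channel")))
  invisible(x)
}

#' Pixel size of an image in nanometres
#' @param img a `mito_image`.
#' @return pixel size (nm).
#' @export
pixel_size_nm <- function(img) attr(img, "pixel_size_nm")

img_matrix <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(img))
  m
}

#' Write an image to TIFF with pixel-size metadata
#'
#' Counts are stored as 32-bit float TIFF, scaled into \[0, 1\] (the range
#' the writer stores portably); the scale factor, pixel size and channel
#' tag go into a JSON sidecar (`<file>.meta.json`) that [read_image()]
#' picks up automatically, since TIFF resolution tags are not writable
#' through the available writer.
#'
#' @param img a `mito_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "mito_image"))
  m <- img_matrix(img)
  scale <- max(m, 1)
  # tiff::writeTIFF expects the transpose of our (x, y) layout
  tiff::writeTIFF(t(m) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(pixel_size_nm = pixel_size_nm(img),
               channel = attr(img, "channel"), scale = scale)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a TIFF image
#'
#' Pixel size is taken from the TIFF resolution tags when present, else from
#' the JSON sidecar written by [write_image()], else from `pixel_size_nm`.
#' If none is available an error is raised.
#'
#' @param path TIFF path.
#' @param pixel_size_nm optional pixel size override (nm).
#' @param frame frame index (1-based) for multi-frame TIFFs; single-frame
#'   files ignore it. A multi-frame file without `frame` is an error.
#' @param channel channel tag to attach.
#' @return a `mito_image`.
#' @export
read_image <- function(path, pixel_size_nm = NULL, frame = NULL,
                       channel = "IM") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(frames) > 1L && is.null(frame)) {
    stop("multi-frame TIFF: supply `frame`", call. = FALSE)
  }
  fr <- frames[[if (is.null(frame)) 1L else frame]]
  if (length(dim(fr)) == 3L) fr <- fr[, , 1L]
  scale <- 1
  px <- pixel_size_nm
  if (is.null(px)) {
    xres <- attr(fr, "x.resolution")
    unit <- attr(fr, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
      cm_per_unit <- switch(as.character(unit), inch = 2.54, cm = 1, NA_real_)
      if (is.finite(cm_per_unit)) px <- cm_per_unit / xres * 1e7
    }
  }
  if (is.null(px)) {
    side <- paste0(path, ".meta.json")
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side, simplifyVector = TRUE)
      px <- meta$pixel_size_nm
      if (!is.null(meta$scale)) scale <- meta$scale
      if (identical(channel, "IM") && !is.null(meta$channel)) {
        channel <- meta$channel
      }
    }
  }
  if (is.null(px)) {
    stop("TIFF has no resolution metadata; supply `pixel_size_nm`",
         call. = FALSE)
  }
  mito_image(t(fr) * scale, pixel_size_nm = px, channel = channel)
}
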