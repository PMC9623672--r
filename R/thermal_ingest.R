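#' Colorbar specification for a colorized thermogram
#'
#' Describes how a colorized infrared image encodes temperature: the
#' displayed temperature range and the ordered list of colors from the
#' coldest to the hottest end of the colorbar. This is the sidecar
#' information an operator reads off the image margin (the displayed
#' min/max) plus the palette the camera used.
#'
#' @param t_min,t_max displayed temperature range, degrees C; `t_max > t_min`.
#' @param colors either an `n x 3` matrix of 8-bit colors (0..255, ordered
#'   cold to hot) or the name of a built-in colormap (see
#'   [builtin_colormap()]). When a name is given, `n_colors` controls the
#'   palette size; the default `NULL` allocates one color per 0.1 degree C
#'   step of the range (e.g. 351 colors for 5-40 degrees C) so that
#'   nearest-color inversion can recover every representable temperature.
#' @param n_colors palette size when `colors` is a colormap name.
#' @return an object of class `colorbar_spec`.
#' @examples
#' cb <- colorbar_spec(5, 40, "iron")
#' nrow(cb$colors)  # 351
#' @export
colorbar_spec <- function(t_min, t_max, colors = "iron", n_colors = NULL) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_max <= t_min)
    stop("t_max must be greater than t_min")
  if (is.character(colors)) {
    if (is.null(n_colors))
      n_colors <- as.integer(floor((t_max - t_min) / 0.1 + 0.5)) + 1L
    colors <- builtin_colormap(colors, n_colors)
  }
  colors <- as.matrix(colors)
  if (nrow(colors) < 2L) stop("a colorbar needs at least 2 colors")
  if (ncol(colors) != 3L) stop("colors must have 3 channels")
  if (any(colors < 0) || any(colors > 255))
    stop("colors must be 8-bit (0..255)")
  storage.mode(colors) <- "integer"
  structure(list(t_min = t_min, t_max = t_max, colors = colors),
            class = "colorbar_spec")
}

#' Build a color-to-temperature lookup table
#'
#' The first and last colorbar colors are anchored at `t_min` and `t_max`;
#' interior colors are assigned temperatures linearly by their position in
#' the list, then quantized half-up to 0.1 degrees C. The LUT stores
#' temperatures as unsigned integers at 10 units per degree C (stored =
#' round(degC x 10)).
#'
#' @param colorbar a [colorbar_spec()].
#' @return an object of class `color_lut` with elements `colors` (`n x 3`
#'   integer matrix) and `stored` (integer vector, 0.1 degree C units).
#' @examples
#' lut <- build_lut(colorbar_spec(5, 40, "iron"))
#' range(lut$stored) / 10  # 5 40
#' @export
build_lut <- function(colorbar) {
  stopifnot(inherits(colorbar, "colorbar_spec"))
  n <- nrow(colorbar$colors)
  t <- colorbar$t_min +
    (seq_len(n) - 1) / (n - 1) * (colorbar$t_max - colorbar$t_min)
  stored <- as.integer(floor(t * 10 + 0.5))  # half-up to 0.1 degC
  if (any(stored < 0L)) stop("temperatures below 0 degC cannot be stored")
  structure(list(colors = colorbar$colors, stored = stored,
                 t_min = colorbar$t_min, t_max = colorbar$t_max),
            class = "color_lut")
}

#' Calibrated temperature map
#'
#' Single-channel image of stored unsigned integers at 0.1 degree C per
#' unit (stored = round(degC x 10)), with an acquisition-metadata record.
#'
#' @param pixels integer matrix (rows x cols) of non-negative stored values.
#' @param meta named list of acquisition metadata; defaults follow the
#'   acquisition protocol (emissivity 0.95, reflected temperature 20 degC,
#'   atmospheric temperature 23 degC, relative humidity 81%).
#' @return object of class `temperature_map`.
#' @export
temperature_map <- function(pixels, meta = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("empty image")
  if (any(pixels < 0L)) stop("stored temperatures must be non-negative")
  defaults <- list(emissivity = 0.95, reflected_temp_c = 20,
                   atmospheric_temp_c = 23, relative_humidity = 81,
                   cow_id = NA_character_, timepoint = NA_character_)
  meta <- utils::modifyList(defaults, meta)
  structure(list(pixels = pixels, scale = 0.1, meta = meta),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  cat(sprintf("<temperature_map> %d x %d px, %.1f-%.1f degC, 0.1 degC/unit\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels) / 10, max(x$pixels) / 10))
  invisible(x)
}

#' Temperatures in degrees Celsius
#'
#' @param tmap a [temperature_map()].
#' @return numeric matrix of temperatures in degrees C (stored / 10).
#' @export
temp_celsius <- function(tmap) {
  stopifnot(inherits(tmap, "temperature_map"))
  tmap$pixels / 10
}

#' Convert a colorized thermogram to a temperature map
#'
#' Each pixel is assigned the temperature of its nearest LUT color
#' (unweighted Euclidean distance over the three 8-bit channels; ties break
#' to the lower LUT index, i.e. the lower temperature). The result is a
#' [temperature_map()] of stored unsigned integers at 0.1 degree C per
#' unit, so the number of distinct stored values never exceeds the number
#' of LUT entries.
#'
#' @param image `H x W x 3` array, either 8-bit integers in 0..255 or
#'   doubles in \[0, 1\] (as returned by [png::readPNG()]).
#' @param lut a [build_lut()] result.
#' @param meta metadata list passed to [temperature_map()].
#' @return a [temperature_map()].
#' @export
convert_to_temperature <- function(image, lut, meta = list()) {
  stopifnot(inherits(lut, "color_lut"))
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be an H x W x 3 array")
  if (dim(image)[1] < 1L || dim(image)[2] < 1L) stop("empty image")
  if (is.double(image) && max(image) <= 1) image <- image * 255
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  storage.mode(px) <- "integer"
  # work on unique colors only: a rendered thermogram has few of them
  key <- px[, 1] * 65536L + px[, 2] * 256L + px[, 3]
  ukey <- unique(key)
  idx <- match(key, ukey)
  upx <- px[match(ukey, key), , drop = FALSE]
  nearest <- nearest_lut_index(upx, lut$colors)
  stored <- matrix(lut$stored[nearest][idx], nrow = h, ncol = w)
  temperature_map(stored, meta)
}

# Row-wise nearest neighbour among LUT colors, squared Euclidean distance,
# ties to the lower index. Chunked to bound the distance-matrix size.
nearest_lut_index <- function(px, lut_colors, chunk = 4096L) {
  n <- nrow(px)
  out <- integer(n)
  lut <- t(lut_colors)              # 3 x m
  lut_sq <- colSums(lut^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- px[s:e, , drop = FALSE]
    # |p - c|^2 = |p|^2 - 2 p.c + |c|^2 ; |p|^2 constant per row
    cross <- block %*% lut          # nb x m
    d2 <- sweep(-2 * cross, 2L, lut_sq, "+")
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Render a temperature map through a colorbar
#'
#' Inverse of [convert_to_temperature()]: each stored temperature is drawn
#' with the color of the LUT entry whose temperature is nearest (ties to
#' the lower index). Used by the phantom generator and useful for visual
#' checks.
#'
#' @param tmap a [temperature_map()].
#' @param lut a [build_lut()] result covering the map's range.
#' @return `H x W x 3` integer array with values in 0..255.
#' @export
render_thermogram <- function(tmap, lut) {
  stopifnot(inherits(tmap, "temperature_map"), inherits(lut, "color_lut"))
  stored <- as.vector(tmap$pixels)
  o <- order(lut$stored)
  idx_sorted <- findInterval(stored, lut$stored[o] - 0L)  # last entry <= value
  idx_sorted[idx_sorted < 1L] <- 1L
  # choose between the flanking entries by distance, tie to lower
  lo <- pmax(idx_sorted, 1L)
  hi <- pmin(idx_sorted + 1L, length(o))
  d_lo <- abs(stored - lut$stored[o][lo])
  d_hi <- abs(stored - lut$stored[o][hi])
  pick <- ifelse(d_hi < d_lo, hi, lo)
  nearest <- o[pick]
  h <- nrow(tmap$pixels); w <- ncol(tmap$pixels)
  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(lut$colors[nearest, ch], h, w)
  img
}

#' Read a colorized thermogram image file
#'
#' Reads a PNG or JPG 3-channel image as an `H x W x 3` array of 8-bit
#' values (0..255). An optional JSON sidecar with fields `t_min`, `t_max`
#' and `colormap` may sit next to the image (`<image>.json`).
#'
#' @param path image file path (`.png`, `.jpg`, `.jpeg`).
#' @return `H x W x 3` integer array; if a sidecar was found, it is
#'   attached as the `"sidecar"` attribute (a list).
#' @export
read_thermogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  out <- array(as.integer(floor(img * 255 + 0.5)), dim = dim(img))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "sidecar") <- jsonlite::fromJSON(sidecar)
  out
}

#' Write a colorized image as PNG
#'
#' @param image `H x W x 3` array, 0..255 integers or \[0,1\] doubles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thermogram_png <- function(image, path) {
  if (is.integer(image) || max(image) > 1) image <- image / 255
  png::writePNG(image, path)
  invisible(path)
}
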