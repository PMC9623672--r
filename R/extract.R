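#' Extract the full radiomic feature vector for one ROI
#'
#' Computes the named 851-biomarker set from a calibrated temperature map
#' and a binary mask under the default extraction settings: 14 shape
#' features, 93 intensity/texture features on the original image (18
#' first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM), and
#' the same 93 on each of the 8 wavelet sub-bands (shape features are not
#' recomputed on filtered images). Names follow
#' `<image>_<class>_<feature>` with image `original` or `wavelet-XXX`.
#' With `wavelet = FALSE` in the settings the vector has 107 entries.
#'
#' @param tmap a [temperature_map()].
#' @param mask logical matrix, same shape, at least one foreground pixel.
#' @param settings an [extraction_settings()].
#' @return named numeric vector (851 entries under defaults), deterministic
#'   and stably ordered.
#' @examples
#' ph <- generate_phantom(phantom_spec(width = 160, height = 120), seed = 1)
#' fv <- extract_all(ph$tmap, ph$masks[[1]])
#' length(fv)  # 851
#' @export
extract_all <- function(tmap, mask, settings = extraction_settings()) {
  stopifnot(inherits(tmap, "temperature_map"),
            inherits(settings, "extraction_settings"))
  if (!all(dim(tmap$pixels) == dim(mask))) stop("image/mask shape mismatch")
  if (!any(mask)) stop("empty mask")
  v <- temp_celsius(tmap)
  out <- numeric(0)
  if ("shape" %in% settings$classes)
    out <- c(out, prefixed("original_shape_", shape_features(mask)))
  out <- c(out, intensity_texture_features(v, mask, settings, "original"))
  if (settings$wavelet) {
    ws <- wavelet_stack(v)
    for (band in names(ws)) {
      out <- c(out, intensity_texture_features(
        ws[[band]], mask, settings, paste0("wavelet-", band)))
    }
  }
  out
}

# the 93 intensity/texture features of one (possibly filtered) image
intensity_texture_features <- function(values, mask, settings, image_name) {
  cls <- settings$classes
  need_droi <- any(c("glcm", "glrlm", "glszm", "gldm", "ngtdm") %in% cls)
  droi <- if (need_droi) discretize(values, mask, settings$bin_width)
  out <- numeric(0)
  if ("firstorder" %in% cls)
    out <- c(out, prefixed(paste0(image_name, "_firstorder_"),
                           first_order(values, mask, settings$bin_width)))
  if ("glcm" %in% cls)
    out <- c(out, prefixed(paste0(image_name, "_glcm_"),
                           glcm_features(droi, settings$glcm_symmetric)))
  if ("glrlm" %in% cls)
    out <- c(out, prefixed(paste0(image_name, "_glrlm_"),
                           glrlm_features(droi)))
  if ("glszm" %in% cls)
    out <- c(out, prefixed(paste0(image_name, "_glszm_"),
                           glszm_features(droi)))
  if ("gldm" %in% cls)
    out <- c(out, prefixed(paste0(image_name, "_gldm_"),
                           gldm_features(droi, settings$gldm_alpha)))
  if ("ngtdm" %in% cls)
    out <- c(out, prefixed(paste0(image_name, "_ngtdm_"),
                           ngtdm_features(droi)))
  out
}

prefixed <- function(prefix, x) {
  names(x) <- paste0(prefix, names(x))
  x
}

#' Extract features for several ROIs into a table
#'
#' @param tmaps list of [temperature_map()]s (recycled if length 1).
#' @param masks list of logical masks, one per ROI.
#' @param ids character vector of ROI identifiers (row names).
#' @param settings an [extraction_settings()].
#' @return numeric matrix, one row per ROI, named feature columns.
#' @export
extract_table <- function(tmaps, masks, ids = NULL,
                          settings = extraction_settings()) {
  if (inherits(tmaps, "temperature_map")) tmaps <- list(tmaps)
  if (length(tmaps) == 1L) tmaps <- rep(tmaps, length(masks))
  rows <- mapply(function(tm, mk) extract_all(tm, mk, settings),
                 tmaps, masks, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- ids %||% paste0("roi", seq_along(masks))
  tab
}

#' Write / read a feature table as CSV
#'
#' One row per ROI, a leading `roi` key column, then named feature columns.
#'
#' @param tab numeric matrix from [extract_table()] (or a compatible
#'   data.frame); `path` a CSV file path.
#' @return `read_feature_csv`: a numeric matrix with ROI row names.
#' @export
write_feature_csv <- function(tab, path) {
  if (is.null(rownames(tab))) rownames(tab) <- paste0("roi", seq_len(nrow(tab)))
  df <- data.frame(roi = rownames(tab), tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  rownames(tab) <- df[[1]]
  tab
}
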