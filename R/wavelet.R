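# One-level undecimated (stationary) Haar wavelet decomposition. The 2D
# thermogram is treated as a one-slice volume, the convention under which
# the 851-feature inventory arises (107 + 8 x 93): the transform runs
# along the singleton depth axis, then rows, then columns, with symmetric
# boundary extension, yielding 8 same-size sub-bands named over the
# (depth, row, col) axes. Symmetric extension of a singleton axis is
# constant, so the four depth-high-pass sub-bands are identically zero and
# the depth low-pass contributes a factor sqrt(2).

# undecimated Haar pair along rows: y[i] = (x[i] +/- x[i+1]) / sqrt(2),
# symmetric (half-sample) extension at the bottom edge
haar_rows <- function(m) {
  ext <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  list(L = (m + ext) / sqrt(2), H = (m - ext) / sqrt(2))
}

haar_cols <- function(m) {
  r <- haar_rows(t(m))
  list(L = t(r$L), H = t(r$H))
}

#' Wavelet sub-band stack
#'
#' One-level stationary Haar transform of the temperature image (degrees
#' C), returning the 8 sub-bands `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH`
#' named over the (singleton depth, row, column) axes. Each sub-band has
#' the input's shape. Sub-bands with a depth high-pass are identically
#' zero (the depth axis is a symmetric extension of a single slice);
#' `LLL` of a constant image is the constant times `2 sqrt(2)`.
#'
#' @param tmap a [temperature_map()] or a numeric matrix of intensities.
#' @return named list of 8 numeric matrices.
#' @export
wavelet_stack <- function(tmap) {
  v <- if (inherits(tmap, "temperature_map")) temp_celsius(tmap)
       else as.matrix(tmap)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("image smaller than the wavelet filter support")
  depth_l <- sqrt(2)   # (x + x)/sqrt(2) on the mirrored singleton axis
  rw <- haar_rows(v)
  out <- list()
  for (rn in c("L", "H")) {
    cw <- haar_cols(rw[[rn]])
    for (cn in c("L", "H")) {
      out[[paste0("L", rn, cn)]] <- depth_l * cw[[cn]]
      out[[paste0("H", rn, cn)]] <- matrix(0, nrow(v), ncol(v))
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
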