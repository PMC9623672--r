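#' Local sliding-window feature maps
#'
#' Computes a per-pixel feature map over the ROI with a sliding (stride 1)
#' square window, as used to visualize where on the teat a statistic
#' changes after milking. Supported features: `"mean"`, `"skewness"`
#' (population skewness; 0 on zero-variance windows), `"entropy"`
#' (histogram entropy of the window's in-ROI temperatures at `bin_width`
#' bins), and `"gradient_magnitude"` (`sqrt(gx^2 + gy^2)` of central
#' differences on degrees C, window-averaged by default; set
#' `window_average = FALSE` for the raw per-pixel magnitude).
#'
#' The map is defined only at in-ROI pixel centers whose window covers at
#' least `min_pixels` ROI pixels; elsewhere it is `NA`. For an even window
#' side `w`, the window spans `floor((w-1)/2)` pixels before and
#' `floor(w/2)` after the center along each axis.
#'
#' @param tmap a [temperature_map()].
#' @param mask logical ROI matrix, same shape.
#' @param feature feature name (see above).
#' @param window window side length in pixels (>= 2; default 10).
#' @param min_pixels minimum in-ROI pixels in a window for the value to be
#'   defined.
#' @param bin_width entropy histogram bin width in degrees C.
#' @param window_average window-average the gradient magnitude.
#' @return numeric matrix (class `feature_map`) with attributes `feature`
#'   and `window`; `NA` where undefined.
#' @export
local_map <- function(tmap, mask, feature = c("mean", "skewness",
                                              "gradient_magnitude", "entropy"),
                      window = 10L, min_pixels = 4L, bin_width = 0.1,
                      window_average = TRUE) {
  feature <- match.arg(feature)
  stopifnot(inherits(tmap, "temperature_map"))
  if (!all(dim(tmap$pixels) == dim(mask))) stop("image/mask shape mismatch")
  window <- as.integer(window)
  if (window < 2L) stop("window must be at least 2")
  if (window > min(dim(mask))) stop("window larger than the image")
  v <- temp_celsius(tmap)
  h <- nrow(v); w <- ncol(v)
  a <- (window - 1L) %/% 2L; b <- window %/% 2L

  vm <- v; vm[!mask] <- 0
  n_in <- window_sum(mask * 1, a, b)
  defined <- mask & n_in >= min_pixels

  out <- matrix(NA_real_, h, w)
  if (feature == "mean") {
    s1 <- window_sum(vm, a, b)
    out[defined] <- (s1 / n_in)[defined]
  } else if (feature == "skewness") {
    # center on the ROI mean first: skewness is shift invariant and the
    # centered power sums avoid catastrophic cancellation
    vc <- v - mean(v[mask]); vc[!mask] <- 0
    s1 <- window_sum(vc, a, b)
    s2 <- window_sum(vc^2, a, b)
    s3 <- window_sum(vc^3, a, b)
    mu <- s1 / n_in
    m2 <- s2 / n_in - mu^2
    m3 <- s3 / n_in - 3 * mu * s2 / n_in + 2 * mu^3
    sk <- ifelse(m2 > 1e-12, m3 / m2^1.5, 0)
    out[defined] <- sk[defined]
  } else if (feature == "gradient_magnitude") {
    g <- gradient_magnitude(v)
    if (window_average) {
      gm <- g; gm[!mask] <- 0
      out[defined] <- (window_sum(gm, a, b) / n_in)[defined]
    } else {
      out[defined] <- g[defined]
    }
  } else {
    centers <- which(defined)
    for (px in centers) {
      r <- (px - 1L) %% h + 1L
      c0 <- (px - 1L) %/% h + 1L
      rs <- max(1L, r - a):min(h, r + b)
      cs <- max(1L, c0 - a):min(w, c0 + b)
      vals <- v[rs, cs][mask[rs, cs]]
      bins <- floor((vals - min(vals)) / bin_width + 1e-9)
      p <- tabulate(bins + 1L, nbins = max(bins) + 1L)
      p <- p[p > 0] / length(vals)
      out[px] <- -sum(p * log2(p))
    }
  }
  structure(out, feature = feature, window = window, class = "feature_map")
}

# box-filter sum with clipped (truncated) windows, via padded integral image
window_sum <- function(m, a, b) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 1L, w + 1L)
  p[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(h) - a, 1L); r2 <- pmin(seq_len(h) + b, h)
  c1 <- pmax(seq_len(w) - a, 1L); c2 <- pmin(seq_len(w) + b, w)
  R1 <- matrix(r1, h, w); R2 <- matrix(r2, h, w)
  C1 <- matrix(c1, h, w, byrow = TRUE); C2 <- matrix(c2, h, w, byrow = TRUE)
  s <- p[cbind(as.vector(R2) + 1L, as.vector(C2) + 1L)] -
    p[cbind(as.vector(R1), as.vector(C2) + 1L)] -
    p[cbind(as.vector(R2) + 1L, as.vector(C1))] +
    p[cbind(as.vector(R1), as.vector(C1))]
  matrix(s, h, w)
}

# central differences (one-sided at the borders) on degrees C
gradient_magnitude <- function(v) {
  h <- nrow(v); w <- ncol(v)
  gr <- (v[pmin(seq_len(h) + 1L, h), ] - v[pmax(seq_len(h) - 1L, 1L), ]) /
    matrix(pmin(seq_len(h) + 1L, h) - pmax(seq_len(h) - 1L, 1L), h, w)
  gc <- (v[, pmin(seq_len(w) + 1L, w)] - v[, pmax(seq_len(w) - 1L, 1L)]) /
    matrix(pmin(seq_len(w) + 1L, w) - pmax(seq_len(w) - 1L, 1L), h, w,
           byrow = TRUE)
  sqrt(gr^2 + gc^2)
}

#' Difference of two feature maps
#'
#' `post - pre` on the intersection of the defined regions, `NA` elsewhere.
#' The two maps must show the same feature on images of the same shape; the
#' underlying ROIs may differ (the teat elongates after milking). Fully
#' disjoint defined regions give an all-`NA` map, not an error.
#'
#' @param map_pre,map_post [local_map()] results.
#' @return a `feature_map` of differences.
#' @export
delta_map <- function(map_pre, map_post) {
  stopifnot(inherits(map_pre, "feature_map"), inherits(map_post, "feature_map"))
  if (!identical(attr(map_pre, "feature"), attr(map_post, "feature")))
    stop("feature mismatch between maps")
  if (!all(dim(map_pre) == dim(map_post))) stop("shape mismatch between maps")
  out <- unclass(map_post) - unclass(map_pre)
  structure(out, feature = attr(map_pre, "feature"),
            window = attr(map_pre, "window"), class = "feature_map")
}

#' Render a feature map to PNG / export raw values
#'
#' Maps defined values linearly onto a perceptually ordered colormap (dark
#' blue to yellow), paints undefined pixels dark gray, appends a vertical
#' colorbar on the right, and writes a PNG. `write_map_csv` writes the raw
#' value grid (NA for undefined) as CSV.
#'
#' @param map a `feature_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_map_png <- function(map, path) {
  vals <- unclass(map)
  rng <- range(vals, na.rm = TRUE)
  cm <- display_colormap(256L) / 255
  u <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else vals * 0 + 0.5
  idx <- pmin(pmax(floor(u * 255) + 1L, 1L), 256L)
  h <- nrow(vals); w <- ncol(vals)
  img <- array(0.15, c(h, w + 14L, 3L))
  for (ch in 1:3) {
    plane <- matrix(cm[idx, ch], h, w)
    plane[is.na(vals)] <- 0.15
    img[, seq_len(w), ch] <- plane
    bar <- cm[pmin(pmax(floor(seq(1, 0, length.out = h) * 255) + 1L, 1L),
                   256L), ch]
    img[, (w + 5L):(w + 12L), ch] <- bar
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname render_map_png
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(unclass(map), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
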