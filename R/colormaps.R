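#' Built-in colormaps
#'
#' Programmatically defined colormaps used to render and invert colorized
#' thermograms. `"iron"` is an iron/hot-metal-like ramp (dark purple through
#' red and orange to near white) in which every channel is monotone
#' non-decreasing from cold to hot and every entry is a distinct 8-bit
#' triple, so nearest-color inversion is unambiguous. `"gray"` is a plain
#' gray ramp (distinct by construction only up to 256 entries).
#'
#' @param name colormap name, one of `"iron"`, `"gray"`.
#' @param n number of entries (colors), at least 2.
#' @return integer matrix `n x 3` with values in 0..255, ordered from the
#'   coldest to the hottest color.
#' @examples
#' cm <- builtin_colormap("iron", 351)
#' stopifnot(nrow(unique(cm)) == 351)
#' @export
builtin_colormap <- function(name = c("iron", "gray"), n = 256L) {
  name <- match.arg(name)
  n <- as.integer(n)
  if (n < 2L) stop("a colormap needs at least 2 entries")
  # a ramp monotone in every 8-bit channel has at most 3*255 + 1 points
  if (n > 766L)
    stop("a channel-monotone 8-bit ramp supports at most 766 distinct colors")
  u <- seq(0, 1, length.out = n)
  cm <- switch(name,
    iron = cbind(
      r = floor(255 * pmin(1, 1.6 * u)),
      g = floor(255 * pmax(0, pmin(1, 1.6 * u - 0.35))),
      b = floor(255 * u^3)
    ),
    gray = cbind(r = floor(255 * u), g = floor(255 * u), b = floor(255 * u))
  )
  storage.mode(cm) <- "integer"
  make_rows_unique_monotone(cm)
}

# Bump duplicate consecutive rows (forward pass: increment the least
# significant channel with room; backward pass: decrement, resolving
# saturation at the white end) so all rows are distinct while every channel
# stays monotone non-decreasing up to one count. Deterministic; needed
# because independently quantized smooth ramps can collide at 8 bits.
make_rows_unique_monotone <- function(cm) {
  n <- nrow(cm)
  if (n < 2L) return(cm)
  for (k in 2:n) {
    if (all(cm[k, ] <= cm[k - 1L, ])) {
      cm[k, ] <- cm[k - 1L, ]
      for (ch in c(3L, 2L, 1L)) {
        if (cm[k, ch] < 255L) {
          cm[k, ch] <- cm[k, ch] + 1L
          break
        }
      }
    }
  }
  for (k in (n - 1L):1L) {
    if (all(cm[k, ] >= cm[k + 1L, ])) {
      cm[k, ] <- cm[k + 1L, ]
      for (ch in c(3L, 2L, 1L)) {
        if (cm[k, ch] > 0L) {
          cm[k, ch] <- cm[k, ch] - 1L
          break
        }
      }
    }
  }
  if (anyDuplicated(cm)) stop("colormap could not be made unique")
  cm
}

# Perceptual-ish ramp for feature-map rendering (dark blue -> green ->
# yellow), monotone in luminance; purely for display output.
display_colormap <- function(n = 256L) {
  u <- seq(0, 1, length.out = n)
  cbind(
    r = floor(255 * pmin(1, pmax(0, 2.5 * u - 1.2))),
    g = floor(255 * u^0.9),
    b = floor(255 * pmax(0, 0.6 - 0.9 * u + 0.4 * u^2) / 0.6)
  )
}
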