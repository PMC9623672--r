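#' Polygonal region of interest
#'
#' A teat outline in 0-based pixel coordinates (row, col), with pixel
#' centers at integer coordinates. An open polyline is the raw trace of the
#' teat perimeter; [close_with_chord()] closes it with the straight chord
#' between its endpoints, mirroring the convention of tracing the teat
#' outline and closing the segment where the teat attaches to the udder.
#'
#' @param vertices numeric `n x 2` matrix of (row, col) vertices.
#' @param closed logical, whether the last vertex connects back to the first.
#' @param label free-text label (e.g. `"left hind teat"`).
#' @return object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices, closed = FALSE, label = "") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be (row, col) pairs")
  if (nrow(vertices) < 2L) stop("a polyline needs at least 2 vertices")
  if (closed && nrow(vertices) < 3L)
    stop("a closed polygon needs at least 3 vertices")
  structure(list(vertices = vertices, closed = closed, label = label),
            class = "polygon_roi")
}

#' Close an open teat trace with a chord
#'
#' Appends the straight segment from the last vertex back to the first and
#' marks the polygon closed. Errors if the polyline is already closed.
#'
#' @param poly an open [polygon_roi()] with at least 2 vertices.
#' @return the closed `polygon_roi`.
#' @export
close_with_chord <- function(poly) {
  stopifnot(inherits(poly, "polygon_roi"))
  if (poly$closed) stop("polygon is already closed")
  if (nrow(poly$vertices) < 3L)
    stop("cannot close a polyline with fewer than 3 vertices")
  polygon_roi(poly$vertices, closed = TRUE, label = poly$label)
}

#' Analytic (shoelace) area of a closed polygon
#'
#' @param poly a closed [polygon_roi()].
#' @return area in square pixels.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "polygon_roi"), poly$closed)
  v <- poly$vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Rasterize a closed polygon to a binary mask
#'
#' A pixel belongs to the mask iff its center (integer 0-based (row, col))
#' lies inside the polygon under the even-odd rule; centers exactly on the
#' boundary count as inside.
#'
#' @param poly a closed [polygon_roi()].
#' @param shape integer vector `c(rows, cols)` of the target image.
#' @return logical matrix `rows x cols` with the ROI label as attribute
#'   `"label"`.
#' @export
rasterize <- function(poly, shape) {
  stopifnot(inherits(poly, "polygon_roi"))
  if (!poly$closed) stop("polygon must be closed before rasterization")
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  rr <- rep(0:(h - 1L), times = w)
  cc <- rep(0:(w - 1L), each = h)
  inside <- points_in_polygon(rr, cc, poly$vertices)
  if (!any(inside)) stop("polygon rasterizes to an empty mask")
  m <- matrix(inside, nrow = h, ncol = w)
  attr(m, "label") <- poly$label
  m
}

# Even-odd rule with on-boundary points counted inside. Vectorized over
# query points, loop over edges.
points_in_polygon <- function(pr, pc, vertices, eps = 1e-9) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  jj <- c(n, seq_len(n - 1L))
  for (k in seq_len(n)) {
    r1 <- vertices[k, 1]; c1 <- vertices[k, 2]
    r2 <- vertices[jj[k], 1]; c2 <- vertices[jj[k], 2]
    # on-segment check
    cross <- (pc - c1) * (r2 - r1) - (pr - r1) * (c2 - c1)
    dot <- (pc - c1) * (c2 - c1) + (pr - r1) * (r2 - r1)
    len2 <- (c2 - c1)^2 + (r2 - r1)^2
    on_edge <- on_edge |
      (abs(cross) <= eps * max(1, sqrt(len2)) & dot >= -eps & dot <= len2 + eps)
    # ray casting along +col at the point's row
    crosses <- ((r1 > pr) != (r2 > pr)) &
      (pc < (c2 - c1) * (pr - r1) / (r2 - r1) + c1)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | on_edge
}

#' Dice similarity score of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`: 1.00 is perfect overlap, 0.50 means the
#' intersection covers half of each (equal-area) mask, 0 means disjoint.
#'
#' @param a,b logical matrices of identical shape; not both empty.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks have different shapes")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) stop("both masks are empty")
  2 * sum(a & b) / (sa + sb)
}

#' Summarize Dice scores with a bootstrap confidence interval
#'
#' Mean Dice score plus a percentile bootstrap interval, the interval type
#' chosen because observer-agreement Dice distributions are typically
#' skewed toward 1.
#'
#' @param scores numeric vector of Dice scores (at least 2).
#' @param level confidence level (default 0.95).
#' @param n_boot number of bootstrap resamples (at least 1000).
#' @param seed integer seed for reproducibility.
#' @return named numeric vector `c(mean, lower, upper)`.
#' @export
dice_summary <- function(scores, level = 0.95, n_boot = 2000L, seed = 1L) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (n_boot < 1000L) stop("n_boot must be at least 1000")
  set.seed(seed)
  n <- length(scores)
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(scores[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  c(mean = mean(scores), lower = ci[1], upper = ci[2])
}

#' Read / write a binary mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with foreground 255 and
#' background 0; any value above 127 reads back as foreground.
#'
#' @param path PNG file path.
#' @param mask logical matrix.
#' @return `read_mask_png`: a logical matrix; `write_mask_png`: `path`,
#'   invisibly.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write a polygon ROI as JSON
#'
#' @param poly a [polygon_roi()]; `path` a JSON file path.
#' @return `read_polygon_json`: a `polygon_roi`; `write_polygon_json`:
#'   `path`, invisibly.
#' @export
write_polygon_json <- function(poly, path) {
  stopifnot(inherits(poly, "polygon_roi"))
  jsonlite::write_json(
    list(label = poly$label, closed = poly$closed,
         vertices = unname(apply(poly$vertices, 1, as.numeric,
                                 simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygon_json
#' @export
read_polygon_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  polygon_roi(j$vertices, closed = isTRUE(j$closed), label = j$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
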