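#' Radiomic extraction settings
#'
#' Defaults reproduce the study's extraction configuration: no image
#' interpolation, fixed bin width of 0.1 degrees C, range re-segmentation
#' off, symmetric GLCM, no Laplacian-of-Gaussian smoothing, and all wavelet
#' sub-band features computed.
#'
#' @param bin_width gray-level discretization bin width in degrees C.
#' @param wavelet compute the 8 wavelet sub-band feature sets (744 extra
#'   features) in addition to the 107 original-image features.
#' @param glcm_symmetric symmetrize the co-occurrence matrix.
#' @param gldm_alpha gray-level tolerance for the dependence matrix.
#' @param classes feature classes to compute; the default is all of them.
#'   Restricting classes (e.g. `classes = "firstorder"` for large
#'   simulation studies) changes the feature count accordingly.
#' @return object of class `extraction_settings`.
#' @export
extraction_settings <- function(bin_width = 0.1, wavelet = TRUE,
                                glcm_symmetric = TRUE, gldm_alpha = 0L,
                                classes = c("shape", "firstorder", "glcm",
                                            "glrlm", "glszm", "gldm",
                                            "ngtdm")) {
  if (bin_width <= 0) stop("bin_width must be positive")
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(bin_width = bin_width, interpolation = "none",
                 range_resegmentation = FALSE, wavelet = wavelet,
                 glcm_symmetric = glcm_symmetric, gldm_alpha = gldm_alpha,
                 log_filter = FALSE, classes = classes),
            class = "extraction_settings")
}

#' Discretize ROI intensities to gray levels
#'
#' Fixed-bin-width, minimum-anchored binning:
#' `bin(x) = floor((x - min) / bin_width) + 1`, with the maximum clamped
#' into the top bin. With temperatures stored at 0.1 degC per unit and the
#' default 0.1 degC bin width this reduces to
#' `stored - min(stored) + 1`. Binning is invariant to adding a constant.
#'
#' @param values numeric matrix of intensities (degrees C for the original
#'   image; filtered intensities for wavelet sub-bands).
#' @param mask logical matrix, same shape, at least one `TRUE`.
#' @param bin_width bin width in intensity units.
#' @return list with `bins` (integer matrix, `NA` outside the mask), `ng`
#'   (highest occupied gray level), `mask`, `bin_width`.
#' @export
discretize <- function(values, mask, bin_width = 0.1) {
  values <- as.matrix(values)
  if (!all(dim(values) == dim(mask))) stop("value/mask shape mismatch")
  if (!any(mask)) stop("empty mask")
  if (bin_width <= 0) stop("bin_width must be positive")
  v <- values[mask]
  vmin <- min(v)
  nmax <- as.integer(floor((max(v) - vmin) / bin_width + 1e-9)) + 1L
  bins <- matrix(NA_integer_, nrow(values), ncol(values))
  bins[mask] <- pmin(as.integer(floor((v - vmin) / bin_width + 1e-9)) + 1L,
                     nmax)
  list(bins = bins, ng = max(bins, na.rm = TRUE), mask = mask,
       bin_width = bin_width)
}

#' First-order intensity features
#'
#' The 18 standardized first-order statistics of the in-mask intensities.
#' Entropy and Uniformity use the fixed-bin-width discretization
#' probabilities; moments are population moments (denominator N); Kurtosis
#' is not excess kurtosis (a normal sample gives ~3); percentiles use
#' linear interpolation. Total Energy equals Energy times the pixel area,
#' which is 1 for uncalibrated thermogram pixels.
#'
#' @param values numeric matrix of intensities.
#' @param mask logical matrix.
#' @param bin_width discretization bin width for Entropy/Uniformity.
#' @return named numeric vector of 18 features.
#' @export
first_order <- function(values, mask, bin_width = 0.1) {
  if (!any(mask)) stop("empty ROI")
  x <- as.matrix(values)[mask]
  n <- length(x)
  d <- discretize(values, mask, bin_width)
  p <- tabulate(d$bins[d$mask], nbins = d$ng)
  p <- p[p > 0] / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  mid <- x[x >= q[1] & x <= q[5]]
  c(
    Energy = sum(x^2),
    TotalEnergy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

#' Two-dimensional shape features of a binary mask
#'
#' The 14 shape descriptors of the segmented region. Mesh surface and
#' perimeter come from a marching-squares contour of the mask (pixel
#' centers as grid nodes, saddle cells resolved foreground-connected);
#' Sphericity is `2 sqrt(pi A) / P` with the mesh surface and perimeter,
#' and Spherical Disproportion its reciprocal. Axis lengths are
#' `4 sqrt(lambda)` from the eigenvalues of the pixel-coordinate
#' covariance. Ratio features (Sphericity, Elongation, Eccentricity,
#' Aspect Ratio, Extent, Solidity) need no absolute spatial calibration,
#' which is why they are the usable shape descriptors for uncalibrated
#' thermograms.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask) {
  if (!any(mask)) stop("empty mask")
  npx <- sum(mask)
  idx <- which(mask, arr.ind = TRUE) - 1  # 0-based centers
  ms <- marching_squares(mask)

  cov_rc <- stats::cov(idx) * (npx - 1) / max(npx, 1)  # population covariance
  if (npx == 1L) cov_rc <- matrix(0, 2, 2)
  ev <- sort(eigen(cov_rc, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])

  # maximum diameter over convex hull vertices of pixel centers
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  hp <- idx[hull, , drop = FALSE]
  maxdiam <- if (nrow(hp) == 1L) 0 else
    max(stats::dist(hp))

  bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  solidity <- npx / convex_hull_pixel_area(idx, dim(mask))

  c(
    PixelSurface = npx,
    MeshSurface = ms$area,
    Perimeter = ms$perimeter,
    PerimeterSurfaceRatio = ms$perimeter / ms$area,
    Sphericity = 2 * sqrt(pi * ms$area) / ms$perimeter,
    SphericalDisproportion = ms$perimeter / (2 * sqrt(pi * ms$area)),
    MaximumDiameter = maxdiam,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Eccentricity = if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0,
    Extent = npx / bbox,
    Solidity = solidity,
    AspectRatio = if (minor > 0) major / minor else Inf
  )
}

# Marching squares over the zero-padded mask, pixel centers as nodes,
# iso-level 0.5. Returns enclosed area and total contour length; saddle
# cells (diagonal corners set) are resolved as foreground-connected.
marching_squares <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  tl <- m[-h, -w]; tr <- m[-h, -1]; bl <- m[-1, -w]; br <- m[-1, -1]
  code <- tl + 2L * tr + 4L * br + 8L * bl + 1L
  # per-case area inside the cell and contour length (cell side 1)
  s2 <- sqrt(0.5)
  area_tab <- c(0, .125, .125, .5, .125, .75, .5, .875,
                .125, .5, .75, .875, .5, .875, .875, 1)
  len_tab <- c(0, s2, s2, 1, s2, 2 * s2, 1, s2,
               s2, 1, 2 * s2, s2, 1, s2, s2, 0)
  counts <- tabulate(code, nbins = 16L)
  # raw marching-squares contour length overestimates the length of a
  # smooth boundary by 8(sqrt(2)-1)/pi on average over orientations; apply
  # the standard isotropic correction (exact in the mean for smooth closed
  # contours, slightly short for axis-aligned polygons)
  iso <- pi / (8 * (sqrt(2) - 1))
  list(area = sum(counts * area_tab),
       perimeter = iso * sum(counts * len_tab))
}

# Pixel area of the convex hull: rasterize the hull polygon of pixel
# centers with the package's own boundary-inclusive point-in-polygon test.
convex_hull_pixel_area <- function(idx0, shape) {
  if (nrow(idx0) < 3L) return(nrow(idx0))
  hull <- grDevices::chull(idx0[, 2], idx0[, 1])
  hp <- idx0[hull, , drop = FALSE]
  if (nrow(unique(hp)) < 3L) return(nrow(unique(idx0)))
  rr <- rep(0:(shape[1] - 1L), times = shape[2])
  cc <- rep(0:(shape[2] - 1L), each = shape[1])
  keep <- rr >= min(hp[, 1]) & rr <= max(hp[, 1]) &
    cc >= min(hp[, 2]) & cc <= max(hp[, 2])
  sum(points_in_polygon(rr[keep], cc[keep], hp))
}
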