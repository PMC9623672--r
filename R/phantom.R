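#' Synthetic teat thermogram specification
#'
#' Generative description of a colorized thermogram with known ground
#' truth: a cool background with a smooth gradient, one or more warm
#' teat-shaped regions (superellipse footprint, longitudinal temperature
#' ramp toward the apex and a radial falloff toward the edge), a colorbar,
#' and optional Gaussian and impulse (salt-and-pepper) noise. Defaults
#' emulate the acquisition conditions: 640 x 480 frames, a 5-40 degC
#' displayed range, teat skin around 34 degC on a barn background around
#' 18 degC.
#'
#' @param width,height frame size in pixels.
#' @param t_min,t_max colorbar range, degrees C.
#' @param colormap built-in colormap name for rendering.
#' @param background list with `base` (degC), `gradient_r`, `gradient_c`
#'   (degC per pixel), `ripple` (degC amplitude of a smooth sinusoid).
#' @param teats list of [teat_spec()]s; default two hind teats.
#' @param noise_sigma Gaussian pixel noise SD, degrees C.
#' @param impulse_fraction fraction of rendered pixels replaced by
#'   salt-and-pepper colors (in \[0, 0.1)).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 640L, height = 480L, t_min = 5, t_max = 40,
                         colormap = "iron",
                         background = list(base = 18, gradient_r = 0.004,
                                           gradient_c = 0, ripple = 0.5),
                         teats = NULL, noise_sigma = 0,
                         impulse_fraction = 0) {
  if (impulse_fraction < 0 || impulse_fraction >= 0.1)
    stop("impulse_fraction must be in [0, 0.1)")
  if (is.null(teats)) {
    sc <- min(width / 640, height / 480)
    teats <- list(
      teat_spec(center_r = height * 0.48, center_c = width * 0.34,
                a = 45 * sc, b = 110 * sc, label = "left hind teat"),
      teat_spec(center_r = height * 0.48, center_c = width * 0.66,
                a = 45 * sc, b = 110 * sc, label = "right hind teat")
    )
  }
  spec <- structure(list(width = as.integer(width),
                         height = as.integer(height),
                         t_min = t_min, t_max = t_max, colormap = colormap,
                         background = utils::modifyList(
                           list(base = 18, gradient_r = 0.004, gradient_c = 0,
                                ripple = 0.5), background),
                         teats = teats, noise_sigma = noise_sigma,
                         impulse_fraction = impulse_fraction),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Single-teat geometry and temperature model
#'
#' A teat is a superellipse `|x'/a|^p + |y'/b|^p <= 1` (axes rotated by
#' `theta`), with temperature
#' `base_temp + apex_delta * l^apex_power + edge_delta * rho^2`, where `l`
#' in \[0, 1\] runs from the udder attachment to the apex (larger rows) and
#' `rho` is the normalized superellipse radius. `apex_power` concentrates
#' the apex gradient at the teat end; increasing it (or scaling
#' `apex_delta`) changes the apex gradient and skews the temperature
#' histogram.
#'
#' @param center_r,center_c teat center, 0-based pixel coordinates.
#' @param a,b transverse and longitudinal semi-axes, pixels.
#' @param theta long-axis rotation from vertical, radians.
#' @param power superellipse exponent (2 = ellipse; >2 rounder shoulders).
#' @param base_temp skin temperature at the attachment, degrees C.
#' @param apex_delta temperature change at the apex, degrees C.
#' @param edge_delta radial falloff at the rim, degrees C.
#' @param apex_power exponent of the longitudinal ramp.
#' @param label ROI label.
#' @return a list of class `teat_spec`.
#' @export
teat_spec <- function(center_r, center_c, a = 45, b = 110, theta = 0,
                      power = 2.5, base_temp = 34, apex_delta = -1.5,
                      edge_delta = -1, apex_power = 3, label = "teat") {
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  structure(list(center_r = center_r, center_c = center_c, a = a, b = b,
                 theta = theta, power = power, base_temp = base_temp,
                 apex_delta = apex_delta, edge_delta = edge_delta,
                 apex_power = apex_power, label = label),
            class = "teat_spec")
}

validate_phantom_spec <- function(spec) {
  for (tt in spec$teats) {
    t_lo <- tt$base_temp + min(0, tt$apex_delta) + min(0, tt$edge_delta)
    t_hi <- tt$base_temp + max(0, tt$apex_delta) + max(0, tt$edge_delta)
    if (t_lo < spec$t_min || t_hi > spec$t_max)
      stop("teat temperatures outside the colorbar range")
    if (tt$center_r - tt$b < 0 || tt$center_r + tt$b > spec$height - 1 ||
        tt$center_c - tt$a - abs(tt$b * sin(tt$theta)) < 0 ||
        tt$center_c + tt$a + abs(tt$b * sin(tt$theta)) > spec$width - 1)
      stop("teat extends outside the frame")
  }
  bg_extreme <- spec$background$base + spec$background$ripple +
    abs(spec$background$gradient_r) * spec$height +
    abs(spec$background$gradient_c) * spec$width
  if (bg_extreme > spec$t_max || spec$background$base -
      spec$background$ripple < spec$t_min)
    stop("background temperatures outside the colorbar range")
  invisible(spec)
}

teat_fields <- function(tt, height, width) {
  rr <- matrix(0:(height - 1L), height, width)
  cc <- matrix(0:(width - 1L), height, width, byrow = TRUE)
  dr <- rr - tt$center_r; dc <- cc - tt$center_c
  # x' transverse, y' longitudinal (apex toward larger rows at theta = 0)
  xp <- dc * cos(tt$theta) - dr * sin(tt$theta)
  yp <- dc * sin(tt$theta) + dr * cos(tt$theta)
  rho <- (abs(xp / tt$a)^tt$power + abs(yp / tt$b)^tt$power)^(1 / tt$power)
  inside <- rho <= 1
  l <- pmin(pmax((yp / tt$b + 1) / 2, 0), 1)
  temp <- tt$base_temp + tt$apex_delta * l^tt$apex_power +
    tt$edge_delta * rho^2
  list(inside = inside, temp = temp)
}

teat_polygon <- function(tt, n = 72L) {
  phi <- seq(-pi, pi, length.out = n + 1L)[-(n + 1L)]
  e <- 2 / tt$power
  xp <- tt$a * sign(cos(phi)) * abs(cos(phi))^e
  yp <- tt$b * sign(sin(phi)) * abs(sin(phi))^e
  r <- tt$center_r + yp * cos(tt$theta) - xp * sin(tt$theta)
  c0 <- tt$center_c + xp * cos(tt$theta) + yp * sin(tt$theta)
  polygon_roi(cbind(r, c0), closed = FALSE, label = tt$label)
}

#' Generate a synthetic thermogram with ground truth
#'
#' Builds the analytic temperature field, quantizes it to 0.1 degrees C
#' (stored x10 unsigned integers), renders it through the colorbar, and
#' returns the rendering together with the ground-truth temperature map,
#' per-teat masks and boundary polylines. With zero noise,
#' [convert_to_temperature()] applied to the rendering reproduces the
#' ground truth exactly. Reproducible for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the noise draws.
#' @param render render the colorized image (set `FALSE` to skip rendering
#'   and return only ground truth, e.g. for large simulation studies).
#' @return list with `image` (`H x W x 3` ints, or `NULL`), `tmap`
#'   ([temperature_map()]), `masks` (named list of logical matrices),
#'   `polygons` (list of open [polygon_roi()]s), `lut`, and `spec`.
#' @export
generate_phantom <- function(spec, seed = 1L, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(seed)
  h <- spec$height; w <- spec$width
  rr <- matrix(0:(h - 1L), h, w)
  cc <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  bg <- spec$background
  temp <- bg$base + bg$gradient_r * rr + bg$gradient_c * cc +
    bg$ripple * sin(2 * pi * rr / h) * cos(2 * pi * cc / w)
  masks <- list(); polys <- list()
  for (tt in spec$teats) {
    f <- teat_fields(tt, h, w)
    temp[f$inside] <- f$temp[f$inside]
    masks[[tt$label]] <- f$inside
    polys[[tt$label]] <- teat_polygon(tt)
  }
  if (length(masks) > 1L) {
    total <- Reduce(`+`, masks)
    if (any(total > 1)) stop("teats overlap")
  }
  if (spec$noise_sigma > 0)
    temp <- temp + stats::rnorm(length(temp), 0, spec$noise_sigma)
  temp <- pmin(pmax(temp, spec$t_min), spec$t_max)
  stored <- matrix(as.integer(floor(temp * 10 + 0.5)), h, w)
  tmap <- temperature_map(stored)
  lut <- build_lut(colorbar_spec(spec$t_min, spec$t_max, spec$colormap))
  image <- NULL
  if (render) {
    image <- render_thermogram(tmap, lut)
    if (spec$impulse_fraction > 0) {
      n_hit <- stats::rbinom(1, h * w, spec$impulse_fraction)
      hits <- sample.int(h * w, n_hit)
      salt <- stats::runif(n_hit) < 0.5
      extremes <- rbind(lut$colors[1, ], lut$colors[nrow(lut$colors), ])
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[hits] <- extremes[salt + 1L, ch]
        image[, , ch] <- plane
      }
    }
  }
  list(image = image, tmap = tmap, masks = masks, polygons = polys,
       lut = lut, spec = spec)
}

#' Pre/post-milking effect specification
#'
#' Describes how a post-milking teat differs from its pre-milking state:
#' a mean temperature shift, an apex-gradient scaling (gradients at the
#' teat end shrink after milking), a skewness change (via the longitudinal
#' ramp exponent), a major-axis elongation and a projected-area factor
#' (teats elongate, around +31% in major axis length, after machine
#' milking).
#'
#' @param d_mean mean temperature shift, degrees C.
#' @param elongation major-axis length factor (> 0).
#' @param area_factor projected-area factor (> 0).
#' @param apex_gradient_factor scaling of the apex temperature drop (> 0
#'   shrinks/grows the teat-end gradient).
#' @param skew_factor scaling of the longitudinal ramp exponent.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(d_mean = 0, elongation = 1, area_factor = 1,
                        apex_gradient_factor = 1, skew_factor = 1) {
  if (elongation <= 0 || area_factor <= 0 || apex_gradient_factor < 0 ||
      skew_factor <= 0)
    stop("effect factors must be positive")
  structure(list(d_mean = d_mean, elongation = elongation,
                 area_factor = area_factor,
                 apex_gradient_factor = apex_gradient_factor,
                 skew_factor = skew_factor),
            class = "effect_spec")
}

#' Apply a milking effect to a phantom specification
#'
#' Returns the post-milking [phantom_spec()]: every teat's base temperature
#' is shifted by `d_mean`, its longitudinal semi-axis scaled by
#' `elongation`, its transverse semi-axis by `area_factor / elongation`
#' (so the footprint area scales by `area_factor`), the apex temperature
#' drop by `apex_gradient_factor`, and the ramp exponent by `skew_factor`.
#' The identity effect returns an equal spec. Errors if the resulting
#' temperatures leave the colorbar range.
#'
#' @param spec a [phantom_spec()].
#' @param effect an [effect_spec()].
#' @return the modified `phantom_spec`.
#' @export
apply_effect <- function(spec, effect) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(effect, "effect_spec"))
  spec$teats <- lapply(spec$teats, function(tt) {
    tt$base_temp <- tt$base_temp + effect$d_mean
    tt$b <- tt$b * effect$elongation
    tt$a <- tt$a * effect$area_factor / effect$elongation
    tt$apex_delta <- tt$apex_delta * effect$apex_gradient_factor
    tt$apex_power <- tt$apex_power * effect$skew_factor
    tt
  })
  validate_phantom_spec(spec)
  spec
}

#' Generate a paired pre/post phantom cohort
#'
#' Produces `n_teats` independent single-teat frames: each teat gets its
#' own jittered geometry and baseline temperature (axes x U(0.9, 1.1),
#' orientation jitter, baseline + N(0, 0.5 degC) across teats), a
#' pre-milking frame, and a post-milking frame with `effect` applied. All
#' randomness derives from `seed` via per-teat sub-seeds.
#'
#' @param n_teats number of teats (>= 2); 36 mimics the 18-cow study scale.
#' @param effect an [effect_spec()] describing the post-milking change.
#' @param spec single-teat template [phantom_spec()]; the default is a
#'   240 x 180 crop around one teat.
#' @param seed integer master seed.
#' @param render render colorized images (`FALSE` returns ground-truth
#'   temperature maps only, the fast path for simulation studies).
#' @param baseline_sd across-teat SD of the baseline skin temperature, degC.
#' @return list of class `phantom_cohort`: `teats` (each with `id`, `pre`,
#'   `post` as [generate_phantom()] results), `effect`, `seed`.
#' @export
generate_cohort <- function(n_teats = 36L, effect = effect_spec(),
                            spec = NULL, seed = 1L, render = TRUE,
                            baseline_sd = 0.5) {
  if (n_teats < 2L) stop("a cohort needs at least 2 teats")
  if (is.null(spec)) spec <- single_teat_spec()
  if (length(spec$teats) != 1L)
    stop("cohort template must contain exactly one teat")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * n_teats)
  jit <- list(ab = matrix(stats::runif(2L * n_teats, 0.9, 1.1), ncol = 2),
              theta = stats::rnorm(n_teats, 0, 0.04),
              base = stats::rnorm(n_teats, 0, baseline_sd),
              apex = stats::runif(n_teats, 0.8, 1.2))
  teats <- vector("list", n_teats)
  for (i in seq_len(n_teats)) {
    sp <- spec
    tt <- sp$teats[[1]]
    tt$a <- tt$a * jit$ab[i, 1]
    tt$b <- tt$b * jit$ab[i, 2]
    tt$theta <- tt$theta + jit$theta[i]
    tt$base_temp <- tt$base_temp + jit$base[i]
    tt$apex_delta <- tt$apex_delta * jit$apex[i]
    tt$label <- sprintf("teat%02d", i)
    sp$teats <- list(tt)
    post_sp <- apply_effect(sp, effect)
    teats[[i]] <- list(
      id = sprintf("teat%02d", i),
      pre = generate_phantom(sp, seed = sub_seeds[2L * i - 1L],
                             render = render),
      post = generate_phantom(post_sp, seed = sub_seeds[2L * i],
                              render = render)
    )
  }
  structure(list(teats = teats, effect = effect, seed = seed),
            class = "phantom_cohort")
}

#' Default single-teat template for cohort generation
#'
#' A 240 x 180 crop centered on one teat, same temperature model and
#' colorbar as the full-frame default.
#'
#' @param width,height frame size.
#' @return a [phantom_spec()] with one teat.
#' @export
single_teat_spec <- function(width = 180L, height = 240L) {
  sc <- min(width / 180, height / 240)
  phantom_spec(
    width = width, height = height,
    teats = list(teat_spec(center_r = height * 0.5, center_c = width * 0.5,
                           a = 28 * sc, b = 70 * sc, label = "teat"))
  )
}

#' Extract a paired feature table from a phantom cohort
#'
#' Runs feature extraction on every teat's pre and post frames and returns
#' aligned matrices ready for [expression_screen()]. `from_image = TRUE`
#' runs the full conversion path (rendered image, LUT inversion) instead of
#' using the ground-truth temperature maps.
#'
#' @param cohort a [generate_cohort()] result.
#' @param settings an [extraction_settings()].
#' @param from_image convert rendered images rather than using ground truth.
#' @return list with matrices `pre` and `post` (rows = teats).
#' @export
cohort_feature_tables <- function(cohort, settings = extraction_settings(),
                                  from_image = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  one <- function(gen) {
    tmap <- if (from_image)
      convert_to_temperature(gen$image, gen$lut) else gen$tmap
    extract_all(tmap, gen$masks[[1]], settings)
  }
  pre <- do.call(rbind, lapply(cohort$teats, function(x) one(x$pre)))
  post <- do.call(rbind, lapply(cohort$teats, function(x) one(x$post)))
  rownames(pre) <- rownames(post) <- vapply(cohort$teats, `[[`, "", "id")
  list(pre = pre, post = post)
}
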