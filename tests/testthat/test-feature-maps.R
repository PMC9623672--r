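const_tmap <- function(h = 30, w = 30, stored = 330L)
  temperature_map(matrix(stored, h, w))

test_that("constant ROI gives constant mean, zero gradient/entropy/skewness", {
  tm <- const_tmap()
  mask <- matrix(FALSE, 30, 30); mask[6:25, 6:25] <- TRUE
  for (feat in c("skewness", "gradient_magnitude", "entropy")) {
    m <- local_map(tm, mask, feat)
    expect_equal(max(abs(m[!is.na(m)])), 0, label = feat)
  }
  mm <- local_map(tm, mask, "mean")
  expect_true(all(abs(mm[!is.na(mm)] - 33.0) < 1e-12))
  expect_true(all(is.na(mm[!mask])))
})

test_that("a linear ramp yields its slope as gradient magnitude", {
  stored <- matrix(rep(seq(200L, by = 5L, length.out = 40), each = 30), 30, 40)
  tm <- temperature_map(stored)   # 0.5 degC per column
  mask <- matrix(TRUE, 30, 40)
  g <- local_map(tm, mask, "gradient_magnitude", window_average = FALSE)
  expect_equal(max(abs(g[5:26, 5:36] - 0.5)), 0)
})

test_that("maps equal naive per-window recomputation on a random phantom", {
  ph <- generate_phantom(single_teat_spec(width = 60, height = 80), seed = 6,
                         render = FALSE)
  ph$tmap$pixels <- ph$tmap$pixels +
    matrix(sample(-3:3, 80 * 60, replace = TRUE), 80, 60)  # roughen
  mask <- ph$masks[[1]]
  v <- temp_celsius(ph$tmap)
  for (feat in c("mean", "skewness", "entropy")) {
    m <- local_map(ph$tmap, mask, feat, window = 10, min_pixels = 4)
    centers <- which(mask, arr.ind = TRUE)
    sel <- centers[seq(1, nrow(centers), by = 17), , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      o <- oracle_window_stat(v, mask, sel[k, 1], sel[k, 2], 10, feat)
      got <- m[sel[k, 1], sel[k, 2]]
      if (is.na(o)) expect_true(is.na(got)) else
        expect_equal(got, o, tolerance = 1e-9,
                     label = sprintf("%s at (%d,%d)", feat, sel[k, 1],
                                     sel[k, 2]))
    }
  }
})

test_that("window means averaged over a tiling reproduce the ROI mean", {
  ph <- generate_phantom(single_teat_spec(width = 60, height = 80), seed = 7,
                         render = FALSE)
  mask <- matrix(TRUE, 80, 60)   # full-frame ROI, no edge effects
  m <- local_map(ph$tmap, mask, "mean", window = 10, min_pixels = 1)
  # centers on a stride-10 grid tile the frame into disjoint 10x10 windows,
  # so the average of their window means is exactly the ROI mean
  centers_r <- seq(5, 75, by = 10); centers_c <- seq(5, 55, by = 10)
  expect_equal(mean(m[centers_r, centers_c]), mean(temp_celsius(ph$tmap)),
               tolerance = 1e-6)
})

test_that("maps are translation equivariant", {
  ph <- generate_phantom(single_teat_spec(width = 60, height = 80), seed = 8,
                         render = FALSE)
  mask <- ph$masks[[1]]
  v <- ph$tmap$pixels
  sh <- 7L
  v2 <- rbind(matrix(v[1, 1], sh, ncol(v)), v[1:(nrow(v) - sh), ])
  m2shift <- rbind(matrix(FALSE, sh, ncol(mask)),
                   mask[1:(nrow(mask) - sh), ])
  map1 <- local_map(ph$tmap, mask, "mean")
  map2 <- local_map(temperature_map(v2), m2shift, "mean")
  inner <- 20:60
  expect_equal(map2[inner + sh, ], map1[inner, ], ignore_attr = TRUE)
})

test_that("delta maps subtract on the common support and handle disjoint ROIs", {
  tm <- const_tmap(40, 40, 320L)
  m1 <- matrix(FALSE, 40, 40); m1[5:20, 5:20] <- TRUE
  m2 <- matrix(FALSE, 40, 40); m2[5:20, 5:20] <- TRUE
  a <- local_map(tm, m1, "mean")
  tm2 <- temperature_map(tm$pixels + 10L)
  b <- local_map(tm2, m2, "mean")
  d <- delta_map(a, b)
  expect_equal(unique(d[!is.na(d)]), 1.0)
  expect_equal(delta_map(a, a)[!is.na(a)], rep(0, sum(!is.na(a))),
               ignore_attr = TRUE)
  # disjoint ROIs -> all-NA map, no error
  m3 <- matrix(FALSE, 40, 40); m3[25:38, 25:38] <- TRUE
  cmap <- local_map(tm, m3, "mean")
  expect_true(all(is.na(delta_map(a, cmap))))
  g <- local_map(tm, m1, "gradient_magnitude")
  expect_error(delta_map(a, g), "feature mismatch")
})

test_that("map rendering and CSV export write files", {
  tm <- const_tmap()
  mask <- matrix(FALSE, 30, 30); mask[6:25, 6:25] <- TRUE
  m <- local_map(tm, mask, "mean")
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".csv")
  render_map_png(m, p1)
  write_map_csv(m, p2)
  expect_gt(file.size(p1), 100)
  grid <- as.matrix(utils::read.csv(p2, header = FALSE))
  expect_equal(dim(grid), dim(m))
})
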