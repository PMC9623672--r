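test_that("phantom generation is reproducible and geometrically faithful", {
  spec <- phantom_spec(width = 320, height = 240, noise_sigma = 0.2)
  g1 <- generate_phantom(spec, seed = 9)
  g2 <- generate_phantom(spec, seed = 9)
  expect_identical(g1$tmap$pixels, g2$tmap$pixels)
  expect_identical(g1$image, g2$image)

  # teat mask area within 2% of the analytic superellipse area
  tt <- spec$teats[[1]]
  # |x/a|^p + |y/b|^p <= 1 has area 4ab Gamma(1+1/p)^2 / Gamma(1+2/p)
  p <- tt$power
  area <- 4 * tt$a * tt$b * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
  expect_lt(abs(sum(g1$masks[[1]]) - area) / area, 0.02)
})

test_that("phantom validation rejects out-of-range and out-of-frame teats", {
  expect_error(phantom_spec(teats = list(teat_spec(240, 320, base_temp = 45))),
               "colorbar range")
  expect_error(phantom_spec(width = 100, height = 100,
                            teats = list(teat_spec(50, 50, a = 45, b = 110))),
               "outside the frame")
  expect_error(phantom_spec(impulse_fraction = 0.2), "impulse_fraction")
})

test_that("impulse noise corrupts about the requested pixel fraction", {
  spec <- phantom_spec(width = 160, height = 120, impulse_fraction = 0.05)
  clean <- generate_phantom(phantom_spec(width = 160, height = 120), seed = 10)
  noisy <- generate_phantom(spec, seed = 10)
  changed <- sum(colSums(apply(noisy$image != clean$image, c(1, 2), any)))
  n <- 160 * 120
  expect_lt(abs(changed - 0.05 * n), 4 * sqrt(n * 0.05 * 0.95) + 0.05 * n * 0.05)
})

test_that("effects transform geometry and temperature as specified", {
  spec <- single_teat_spec()
  expect_identical(apply_effect(spec, effect_spec()), spec)  # identity
  eff <- effect_spec(d_mean = 2, elongation = 1.31, area_factor = 1.5,
                     apex_gradient_factor = 0.5)
  post <- apply_effect(spec, eff)
  expect_equal(post$teats[[1]]$b, spec$teats[[1]]$b * 1.31)
  expect_equal(post$teats[[1]]$a * post$teats[[1]]$b,
               spec$teats[[1]]$a * spec$teats[[1]]$b * 1.5)
  expect_equal(post$teats[[1]]$base_temp, spec$teats[[1]]$base_temp + 2)
  expect_equal(post$teats[[1]]$apex_delta, spec$teats[[1]]$apex_delta * 0.5)
  expect_error(apply_effect(spec, effect_spec(d_mean = 10)), "colorbar range")
  # major axis length of the mask grows by the elongation factor
  g_pre <- generate_phantom(spec, seed = 11, render = FALSE)
  g_post <- generate_phantom(apply_effect(spec, effect_spec(elongation = 1.31,
                                                            area_factor = 1.31)),
                             seed = 11, render = FALSE)
  maj_pre <- shape_features(g_pre$masks[[1]])[["MajorAxisLength"]]
  maj_post <- shape_features(g_post$masks[[1]])[["MajorAxisLength"]]
  expect_equal(maj_post / maj_pre, 1.31, tolerance = 0.02)
})

test_that("injected mean shifts are recovered from ground truth", {
  spec <- single_teat_spec()
  post_spec <- apply_effect(spec, effect_spec(d_mean = 2))
  g_pre <- generate_phantom(spec, seed = 12, render = FALSE)
  g_post <- generate_phantom(post_spec, seed = 12, render = FALSE)
  m_pre <- mean(temp_celsius(g_pre$tmap)[g_pre$masks[[1]]])
  m_post <- mean(temp_celsius(g_post$tmap)[g_post$masks[[1]]])
  expect_lt(abs((m_post - m_pre) - 2), 0.05)
})

test_that("cohorts are seeded, jittered and recover the injected effect", {
  coh1 <- generate_cohort(n_teats = 8, effect = effect_spec(d_mean = 2),
                          spec = single_teat_spec(width = 90, height = 120),
                          seed = 13, render = FALSE)
  coh2 <- generate_cohort(n_teats = 8, effect = effect_spec(d_mean = 2),
                          spec = single_teat_spec(width = 90, height = 120),
                          seed = 13, render = FALSE)
  expect_identical(coh1$teats[[3]]$pre$tmap$pixels,
                   coh2$teats[[3]]$pre$tmap$pixels)
  bases <- vapply(coh1$teats,
                  function(x) x$pre$spec$teats[[1]]$base_temp, numeric(1))
  expect_gt(stats::sd(bases), 0)   # across-teat jitter present

  # estimated delta-mean within 2 SE of the injected +2 degC
  deltas <- vapply(coh1$teats, function(x) {
    mean(temp_celsius(x$post$tmap)[x$post$masks[[1]]]) -
      mean(temp_celsius(x$pre$tmap)[x$pre$masks[[1]]])
  }, numeric(1))
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 2), max(2 * se, 0.05))
  expect_error(generate_cohort(n_teats = 1), "at least 2")
})
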