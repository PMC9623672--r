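test_that("paired t-test matches the textbook formula and flags zero variance", {
  set.seed(31)
  pre <- stats::rnorm(20); post <- pre + stats::rnorm(20, 0.4, 0.6)
  res <- paired_ttest(pre, post)
  # hand-rolled sums
  dif <- post - pre; n <- length(dif)
  tstat <- mean(dif) / sqrt(sum((dif - mean(dif))^2) / (n - 1) / n)
  p <- 2 * stats::pt(-abs(tstat), n - 1)
  expect_equal(res$p_value, p, tolerance = 1e-12)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)

  z <- paired_ttest(pre, pre + 2)   # constant shift, noise-free
  expect_true(z$zero_variance)
  expect_true(is.na(z$p_value))
  z2 <- paired_ttest(pre, pre)      # all differences zero
  expect_true(z2$zero_variance)
})

test_that("Cohen's d follows the pooled-SD definition", {
  set.seed(32)
  pre <- stats::rnorm(15, 30, 1.5); post <- stats::rnorm(15, 32, 1)
  d <- cohens_d(pre, post)
  sp <- sqrt((14 * stats::var(pre) + 14 * stats::var(post)) / 28)
  expect_equal(d, (mean(post) - mean(pre)) / sp, tolerance = 1e-12)
  expect_equal(cohens_d(pre, pre), 0)
  # post = pre + s_pooled exactly -> d = 1
  expect_equal(cohens_d(pre, pre + stats::sd(pre)), 1, tolerance = 1e-12)
  # antisymmetry
  expect_equal(cohens_d(post, pre), -d, tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 5), rep(2, 5)), "zero pooled")
})

test_that("expression requires both significance and effect size", {
  set.seed(33)
  n <- 18
  base <- stats::rnorm(n, 31, 0.8)
  pre <- cbind(shifted = base,
               weak = stats::rnorm(n, 10, 1),
               null = stats::rnorm(n, 5, 1))
  post <- cbind(shifted = base + 2 + stats::rnorm(n, 0, 0.3),
                weak = pre[, "weak"] + 0.1 + stats::rnorm(n, 0, 0.12),
                null = stats::rnorm(n, 5, 1))
  res <- expression_screen(pre, post)
  expect_true(res$expressed[res$feature == "shifted"])
  expect_false(res$expressed[res$feature == "null"])
  # weak: significant (tight pairing) but |d| << 1.2 -> not expressed
  weak <- res[res$feature == "weak", ]
  expect_lt(weak$p_value, 0.01)
  expect_lt(weak$abs_d, 1.2)
  expect_false(weak$expressed)
  cnt <- expression_counts(res)
  expect_equal(cnt$expressed, 1L)
  expect_gte(cnt$significant, 2L)
  # percent difference of means
  expect_equal(res$percent_diff[res$feature == "shifted"],
               abs(mean(post[, 1]) - mean(pre[, 1])) / abs(mean(pre[, 1])) * 100)
  # invariance to feature column order
  res2 <- expression_screen(pre[, c(3, 1, 2)], post)
  expect_equal(res2[order(res2$feature), -1],
               res[order(res$feature), -1],
               ignore_attr = TRUE)
})

test_that("swapping pre/post flips d and preserves p", {
  set.seed(34)
  pre <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  post <- pre + matrix(stats::rnorm(40, 0.5, 0.7), 20, 2)
  r1 <- expression_screen(pre, post)
  r2 <- expression_screen(post, pre)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$cohens_d, -r2$cohens_d, tolerance = 1e-12)
})

test_that("interobserver comparison validates alignment and reports summaries", {
  set.seed(35)
  fa <- matrix(stats::rnorm(50, 30), 10, 5,
               dimnames = list(paste0("roi", 1:10), paste0("f", 1:5)))
  expect_error(interobserver_compare(fa, fa[sample(10), ]),
               "correspondence")
  same <- interobserver_compare(fa, fa)
  expect_true(all(same$per_feature$abs_d == 0))
  expect_true(all(same$per_feature$zero_variance))
  fb <- fa + matrix(stats::rnorm(50, 0, 0.01), 10, 5)
  res <- interobserver_compare(fa, fb)
  expect_lt(res$summary$max_abs_d, 0.36)
  expect_equal(nrow(res$per_feature), 5L)
})

test_that("tiny mask perturbations barely move phantom biomarkers", {
  s <- extraction_settings(wavelet = FALSE, classes = "firstorder")
  gens <- lapply(1:6, function(i)
    generate_phantom(single_teat_spec(width = 90, height = 120),
                     seed = 100 + i, render = FALSE))
  feat_a <- do.call(rbind, lapply(gens, function(g)
    extract_all(g$tmap, g$masks[[1]], s)))
  # observer B: erode one boundary row (1-px jitter)
  feat_b <- do.call(rbind, lapply(gens, function(g) {
    m <- g$masks[[1]]
    shrunk <- m & rbind(m[-1, ], FALSE)
    extract_all(g$tmap, shrunk, s)
  }))
  rownames(feat_a) <- rownames(feat_b) <- paste0("t", 1:6)
  res <- interobserver_compare(feat_a, feat_b)
  expect_true(is.finite(res$summary$max_abs_d))
  expect_lt(res$summary$max_abs_d, 1.2)
})
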