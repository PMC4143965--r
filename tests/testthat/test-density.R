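test_that("the common subsampling box is the componentwise minimum", {
  set.seed(81)
  p1 <- pattern_with_count(3, 1, layer = "I", sample_id = "1")
  st1 <- study_collection(list(p1))
  expect_equal(min_box(st1)$side_lengths, p1$box$side_lengths)

  mk <- function(sides, layer, id) pp3_pattern(box = box3d(sides),
                                               layer = layer, sample_id = id)
  st2 <- study_collection(list(mk(c(10, 20, 30), "I", "1"),
                               mk(c(15, 5, 30), "II", "1")))
  expect_equal(min_box(st2)$side_lengths, c(10, 5, 30))
  expect_true(all(sapply(st2$patterns, function(p)
    all(min_box(st2)$side_lengths <= p$box$side_lengths))))
})

test_that("subsampled densities behave on degenerate windows", {
  set.seed(82)
  p <- pattern_with_count(50, 10, layer = "IV", sample_id = "1")
  st <- study_collection(list(p))
  # full-box subsample always returns the sample's own density
  d <- subsample_densities(st, "IV", box = p$box, n_rep = 5, seed = 83)
  expect_equal(d, rep(estimate_intensity(p), 5))
  # empty pattern gives all-zero draws
  empty <- study_collection(list(pp3_pattern(box = box3d(c(100, 100, 100)),
                                             layer = "I", sample_id = "1")))
  expect_equal(subsample_densities(empty, "I", n_rep = 4, seed = 84),
               rep(0, 4))
  # a box larger than a sample is refused
  expect_error(subsample_densities(st, "IV", box = box3d(c(1e5, 1e5, 1e5))),
               "fit")
})

test_that("subsampling is unbiased for the generating intensity", {
  lam <- 1.0
  b <- box3d(c(5000, 5000, 4000))  # 100 um^3
  sub <- box3d(c(2500, 2500, 2000))
  set.seed(85)
  draws <- replicate(300, {
    st <- study_collection(list({
      p <- simulate_csr(b, lam)
      p$layer <- "I"
      p
    }))
    subsample_densities(st, "I", box = sub, n_rep = 1)
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - lam), 3 * se)
})

test_that("Kruskal-Wallis on draws matches the rank formula and handles ties", {
  draws <- data.frame(layer = rep(c("a", "b"), each = 2),
                      density = c(1, 2, 3, 4))
  kw <- kruskal_wallis_draws(draws)
  expect_equal(kw$H, 2.4)
  expect_equal(kw$df, 1)
  expect_equal(kw$p_value, stats::pchisq(2.4, 1, lower.tail = FALSE))

  flat <- data.frame(layer = rep(c("a", "b"), each = 2),
                     density = rep(1, 4))
  expect_equal(kruskal_wallis_draws(flat), list(H = 0, df = 1L, p_value = 1))
  expect_error(kruskal_wallis_draws(data.frame(layer = "a", density = 1)),
               "two groups")
})

test_that("pairwise Mann-Whitney p-values are Bonferroni-adjusted and exact when small", {
  draws <- data.frame(layer = rep(c("a", "b"), each = 2),
                      density = c(1, 2, 3, 4))
  pw <- pairwise_mw_bonferroni(draws)
  # single pair: no adjustment; exact two-sided p = 2 * (1 / choose(4, 2))
  expect_equal(pw["a", "b"], 1 / 3)
  expect_true(is.na(pw["a", "a"]))

  self <- data.frame(layer = rep(c("a", "b"), each = 2),
                     density = c(1, 2, 1, 2))
  expect_equal(pairwise_mw_bonferroni(self)["a", "b"], 1)

  # adjusted p-values never fall below the raw ones and stay in (0, 1]
  set.seed(86)
  many <- data.frame(layer = rep(letters[1:4], each = 10),
                     density = rlnorm(40))
  pm <- pairwise_mw_bonferroni(many)
  expect_true(all(pm[upper.tri(pm)] > 0 & pm[upper.tri(pm)] <= 1))
})

test_that("equal-intensity layers are not declared different", {
  # the subsampling draws are pseudo-replicates of the few underlying
  # samples, so the no-difference property only holds when within-draw
  # counting noise dominates the between-sample realisation noise: several
  # replicates per layer and a small subsampling window
  set.seed(87)
  b <- box3d(c(6000, 6000, 4000))
  mk <- function(layer, id) {
    p <- simulate_csr(b, 0.8, fixed_n = TRUE, sample_id = id)
    p$layer <- layer
    p
  }
  st <- study_collection(c(lapply(1:6, function(i) mk("I", as.character(i))),
                           lapply(1:6, function(i) mk("V", as.character(i)))))
  draws <- density_draws(st, box = box3d(c(1500, 1500, 1300)), n_rep = 50,
                         seed = 88)
  pw <- pairwise_mw_bonferroni(draws)
  expect_gt(pw["I", "V"], 0.05)
  lv <- levene_check(draws)
  expect_true(is.finite(lv$F) && is.finite(lv$p_value))
})
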