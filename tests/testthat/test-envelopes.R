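test_that("leave-one-out intensity pools the other samples of the layer", {
  set.seed(51)
  st <- reference_count_study()
  expect_equal(round(loo_intensity(st, "III", "10"), 3), 0.932)
  expect_equal(round(loo_intensity(st, "VI", "1"), 3), 0.457)
  # a two-sample layer reduces to the other sample's own density
  expect_equal(loo_intensity(st, "I", "1"),
               estimate_intensity(get_sample(st, "I", "2")))
  expect_error(loo_intensity(st, "I", "3"), "no sample")

  only <- study_collection(list(pattern_with_count(5, 1, layer = "I",
                                                   sample_id = "1")))
  expect_error(loo_intensity(only, "I", "1"), "at least 2 samples")
})

test_that("leave-one-out size fit pools the other samples' diameters", {
  mk <- function(id, feret, layer = "II") {
    b <- box3d(c(1e5, 1e5, 1e5))
    n <- length(feret)
    pp3_pattern(x = runif(n) * 1e5, y = runif(n) * 1e5, z = runif(n) * 1e5,
                feret = feret, box = b, layer = layer, sample_id = id)
  }
  st <- study_collection(list(mk("1", c(100, 200, 400)),
                              mk("2", c(150, 300))))
  expect_equal(loo_size(st, "II", "1"), fit_lognormal(c(150, 300)))
  expect_equal(loo_size(st, "II", "2"), fit_lognormal(c(100, 200, 400)))

  # identical remaining diameter lists give the same fit for any held-out j
  st2 <- study_collection(list(mk("1", c(100, 200)), mk("2", c(100, 200)),
                               mk("3", c(100, 200))))
  expect_equal(loo_size(st2, "II", "1"), loo_size(st2, "II", "2"))

  set.seed(52)
  st3 <- study_collection(lapply(1:5, function(i)
    mk(as.character(i), rlnorm(2000, 5.911, 0.404))))
  f <- loo_size(st3, "II", "3")
  expect_lt(abs(f$mu - 5.911), 0.03)
  expect_lt(abs(f$sigma - 0.404), 0.03)
})

test_that("envelope verdicts follow the constant-width band rule", {
  g <- seq(0, 100, 10)
  central <- matrix(rep(g, 5), ncol = 5)        # Lbar = diagonal
  env <- matrix(rep(g, 4), ncol = 4) + rep(c(-2, 2, 1, -1), each = length(g))
  # observed identical to the central curve: never outside
  res <- rsa3d:::envelope_from_l(g, g, central, env)
  expect_equal(res$w_max, 2)
  expect_false(res$reject)
  expect_length(res$exceed_distances, 0)

  # a single spike of 2 * w_max is flagged at exactly that distance
  spiked <- g + c(rep(0, 5), 4, rep(0, 5))
  res2 <- rsa3d:::envelope_from_l(g, spiked, central, env)
  expect_true(res2$reject)
  expect_equal(res2$exceed_distances, g[6])
  # dipping below the band is rejected too (two-sided)
  res3 <- rsa3d:::envelope_from_l(g, g - 5, central, env)
  expect_true(res3$reject)

  # widening the band can only turn rejections into non-rejections
  wide <- rsa3d:::envelope_from_l(g, spiked, central, 3 * (env - g) + g)
  expect_true(wide$w_max > res2$w_max)
  expect_true(all(wide$exceed_distances %in% res2$exceed_distances))
})

test_that("the global envelope test is seed-reproducible and accepts its own null", {
  b <- box3d(c(5700, 5700, 4000))  # ~130 um^3
  params <- rsa_params(1.0, cortex_global_size())
  p <- simulate_rsa(b, params, seed = 53)
  r1 <- global_envelope_test(p, params, n_central = 19, n_envelope = 19,
                             seed = 54)
  r2 <- global_envelope_test(p, params, n_central = 19, n_envelope = 19,
                             seed = 54)
  expect_identical(r1$central, r2$central)
  expect_identical(r1$w_max, r2$w_max)
  expect_false(r1$reject)
})

test_that("the leave-one-out envelope test runs end to end on a small layer", {
  set.seed(55)
  b <- box3d(c(5700, 5700, 3200))  # ~104 um^3
  params <- rsa_params(0.9, cortex_global_size())
  pats <- lapply(1:3, function(i) {
    p <- simulate_rsa(b, params, sample_id = as.character(i))
    p$layer <- "III"
    p
  })
  st <- study_collection(pats)
  res <- loo_envelope_test(st, "III", "2", n_central = 19, n_envelope = 19,
                           seed = 56)
  expect_s3_class(res, "envelope_result")
  expect_false(res$reject)
})
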