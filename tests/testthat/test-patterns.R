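test_that("box windows and pattern membership enforce the invariants", {
  b <- box3d(c(1000, 2000, 500), origin = c(10, 0, 0))
  expect_equal(volume_nm3(b), 1e9)
  expect_equal(volume_um3(b), 1)
  expect_error(box3d(c(0, 1, 1)), "positive")

  # membership is half-open per axis: the far face is outside
  expect_error(pp3_pattern(x = 1010, y = 0, z = 0, box = b), "outside")
  expect_silent(pp3_pattern(x = 10, y = 0, z = 0, box = b))
  expect_error(pp3_pattern(x = 500, y = 500, z = 100, feret = -5, box = b),
               "positive")
  expect_error(pp3_pattern(x = 500, y = 500, z = 100, box = b,
                           layer = "VII"), "layer")
})

test_that("CSV + sidecar round trip preserves every field exactly", {
  dir <- withr::local_tempdir()
  b <- box3d(c(1000, 1000, 1000))

  p0 <- pp3_pattern(box = b, sample_id = "empty", layer = "I")
  f0 <- file.path(dir, "empty.csv")
  write_pattern(p0, f0)
  expect_equal(read_pattern(f0), p0, tolerance = 0)
  expect_equal(npoints(read_pattern(f0)), 0)

  p1 <- pp3_pattern(x = 500, y = 500, z = 500, feret = 400, box = b,
                    sample_id = "one")
  f1 <- file.path(dir, "one.csv")
  write_pattern(p1, f1)
  expect_equal(read_pattern(f1), p1, tolerance = 0)

  set.seed(42)
  n <- 420
  p2 <- pp3_pattern(x = runif(n) * 1000, y = runif(n) * 1000,
                    z = runif(n) * 1000,
                    feret = ifelse(runif(n) < 0.1, NA, rlnorm(n, 5.9, 0.4)),
                    box = b, layer = "III", animal = "r2", sample_id = "big")
  f2 <- file.path(dir, "big.csv")
  write_pattern(p2, f2)
  expect_equal(read_pattern(f2), p2, tolerance = 0)

  expect_error(read_pattern(file.path(dir, "missing.csv")), "sidecar")
})

test_that("intensity is count over volume in synapses per cubic micron", {
  set.seed(7)
  p <- pattern_with_count(180, 210.61)
  expect_equal(round(estimate_intensity(p), 3), 0.855)
  p2 <- pattern_with_count(107, 280.09)
  expect_equal(round(estimate_intensity(p2), 3), 0.382)
  expect_equal(estimate_intensity(pp3_pattern(box = box3d(c(1, 1, 1)))), 0)
})

test_that("shrinkage correction rescales lengths and hence volumes", {
  set.seed(8)
  b <- box3d(c(900, 900, 900))
  p <- pp3_pattern(x = 450, y = 90, z = 9, feret = 360, box = b,
                   sample_id = "s")
  expect_equal(shrinkage_correct(p, 1.0), p)
  q <- shrinkage_correct(p, 0.90)
  expect_equal(q$box$side_lengths, c(1000, 1000, 1000))
  expect_equal(q$points$x, 500)
  expect_equal(q$points$feret, 400)
  # cube of volume 72.9 um^3 -> 100 um^3 (volumes divide by 0.9^3 = 0.729)
  cube <- pp3_pattern(box = box3d(rep(72.9^(1 / 3) * 1000, 3)))
  expect_equal(volume_um3(shrinkage_correct(cube, 0.9)$box), 100)
  expect_error(shrinkage_correct(p, 0), "linear_factor")
  expect_error(shrinkage_correct(p, 1.2), "linear_factor")
})

test_that("nearest-neighbour distances match the exhaustive scan", {
  b <- box3d(c(1000, 1000, 1000))
  two <- pp3_pattern(x = c(100, 105), y = c(1, 1), z = c(1, 1), box = b)
  expect_equal(nearest_neighbor_distances(two), c(5, 5))
  coll <- pp3_pattern(x = c(0, 3, 10), y = rep(0, 3), z = rep(0, 3), box = b)
  expect_equal(nearest_neighbor_distances(coll), c(3, 3, 7))
  expect_error(nearest_neighbor_distances(
    pp3_pattern(x = 1, y = 1, z = 1, box = b)), "two points")

  set.seed(9)
  p <- random_pattern(200)
  expect_equal(nearest_neighbor_distances(p), nn_oracle(p))
})

test_that("study collections enforce unique keys and expose groups", {
  set.seed(10)
  a <- pattern_with_count(5, 1, layer = "I", sample_id = "1", animal = "r1")
  b <- pattern_with_count(6, 1, layer = "I", sample_id = "2", animal = "r2")
  c <- pattern_with_count(7, 1, layer = "II", sample_id = "1", animal = "r1")
  st <- study_collection(list(a, b, c))
  expect_error(study_collection(list(a, a)), "unique")
  expect_length(patterns_by_layer(st, "I"), 2)
  expect_length(patterns_by_animal(st, "r1"), 2)
  expect_equal(npoints(get_sample(st, "II", "1")), 7)
  expect_error(get_sample(st, "III", "1"), "no unique sample")
})

test_that("a study round-trips through a YAML manifest", {
  set.seed(11)
  st <- study_collection(list(
    pattern_with_count(8, 2, layer = "I", sample_id = "1"),
    pattern_with_count(9, 2, layer = "II", sample_id = "1")))
  dir <- withr::local_tempdir()
  manifest <- write_study(st, dir)
  expect_equal(read_study(manifest), st, tolerance = 0)
})
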