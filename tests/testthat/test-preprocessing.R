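test_that("resample_uniform interpolates linearly on the ms grid", {
  st <- sensor_stream(c(0, 100), matrix(c(0, 10), ncol = 1))
  rs <- resample_uniform(st, 20)
  expect_equal(rs$timestamps, c(0L, 50L, 100L))
  expect_equal(unname(rs$values[, 1]), c(0, 5, 10))

  # already uniform at the requested rate: values unchanged
  st2 <- make_stream(rnorm(20), rate_hz = 40)
  rs2 <- resample_uniform(st2, 40)
  expect_equal(rs2$timestamps, st2$timestamps)
  expect_equal(rs2$values, st2$values)

  # constant stream stays constant
  st3 <- sensor_stream(c(0, 37, 81, 150), matrix(4.2, 4, 1))
  expect_true(all(resample_uniform(st3, 25)$values == 4.2))
  expect_error(resample_uniform(make_stream(1), 10), "2 samples")
})

test_that("gravity/linear decomposition follows the exponential recurrence", {
  # hand-evaluated: raw=[0,1], alpha=0.5 -> gravity=[0,0.5], linear=[0,0.5]
  st <- make_stream(c(0, 1))
  dec <- decompose_acceleration(st, 0.5)
  expect_equal(unname(dec$gravity$values[, 1]), c(0, 0.5))
  expect_equal(unname(dec$linear$values[, 1]), c(0, 0.5))

  # constant input is a fixed point
  stc <- idle_stream(50)
  decc <- decompose_acceleration(stc, 0.8)
  expect_equal(decc$gravity$values, stc$values)
  expect_true(all(abs(decc$linear$values) < 1e-12))

  # gravity + linear == raw for arbitrary input
  set.seed(3)
  str <- make_stream(matrix(rnorm(90), 30, 3))
  decr <- decompose_acceleration(str, 0.8)
  expect_equal(decr$gravity$values + decr$linear$values, str$values,
               tolerance = 1e-9)
  expect_error(decompose_acceleration(str, 1.2), "alpha")
})

test_that("magnitude reduction is Pythagorean and rotation-invariant", {
  st <- make_stream(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 1, 1)))
  mag <- reduce_to_magnitude(st)
  expect_equal(mag$channels, "mag")
  expect_equal(unname(mag$values[, 1]), c(5, 0, sqrt(3)))

  set.seed(11)
  v <- matrix(rnorm(60), 20, 3)
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
  m1 <- reduce_to_magnitude(make_stream(v))$values
  m2 <- reduce_to_magnitude(make_stream(v %*% t(R)))$values
  expect_equal(m1, m2, tolerance = 1e-9)
  expect_error(reduce_to_magnitude(make_stream(rnorm(5))), "3 channels")
})

test_that("axis angles follow arccos of the normalized components", {
  st <- make_stream(rbind(c(0, 0, 9.81), c(1, 1, 0), c(3, 4, 0)))
  ang <- axis_angles(st)
  expect_equal(unname(ang$values[1, ]), c(pi / 2, pi / 2, 0))
  expect_equal(unname(ang$values[2, ]), c(pi / 4, pi / 4, pi / 2))
  expect_equal(unname(ang$values[3, 1]), acos(0.6), tolerance = 1e-7)
  expect_warning(z <- axis_angles(make_stream(rbind(c(0, 0, 0), c(1, 0, 0)))),
                 "all-zero")
  expect_equal(unname(z$values[1, ]), c(0, 0, 0))
})

test_that("bilateral unification concatenates channels on shared timestamps", {
  l <- idle_stream(40)
  r <- idle_stream(60)
  u <- unify_bilateral(l, r)
  expect_equal(length(u$channels), 6)
  expect_lte(max(u$timestamps), min(max(l$timestamps), max(r$timestamps)))
  # unify(s, s) duplicates channels with identical values
  uu <- unify_bilateral(l, l)
  expect_equal(unname(uu$values[, 1:3]), unname(uu$values[, 4:6]))
  shifted <- shift_stream(r, 1e6)
  expect_error(unify_bilateral(l, shifted), "no timestamps")
})

test_that("windowed features: energy is per-sample spectral power, mad unscaled", {
  # constant window: both features zero
  fs <- windowed_features(idle_stream(64), 800, 400)
  expect_true(all(abs(fs$features[, 1:3]) < 1e-20))
  expect_true(all(fs$features[, 4:6] == 0))

  # full-period sinusoid of amplitude A: energy = A^2/2 (Parseval <-> variance)
  A <- 1.7
  n <- 64
  x <- A * sin(2 * pi * 4 * (0:(n - 1)) / n)
  st <- make_stream(x)
  f1 <- windowed_features(st, 1600, 1600)
  expect_equal(unname(f1$features[1, 1]), A^2 / 2, tolerance = 1e-9)
  expect_equal(unname(f1$features[1, 1]), mean((x - mean(x))^2), tolerance = 1e-9)

  # mad arithmetic on a known window: values 1,2,3,4 -> median 2.5,
  # deviations 1.5,0.5,0.5,1.5 -> mad 1
  f2 <- windowed_features(make_stream(c(1, 2, 3, 4)), 100, 100)
  expect_equal(unname(f2$features[1, 2]), 1)

  # adding a per-channel constant changes neither energy nor mad
  set.seed(5)
  y <- matrix(rnorm(96), 32, 3)
  fa <- windowed_features(make_stream(y), 400, 200)
  fb <- windowed_features(make_stream(sweep(y, 2, c(5, -2, 9.81), "+")), 400, 200)
  expect_equal(fa$features, fb$features, tolerance = 1e-9)

  expect_error(windowed_features(make_stream(rnorm(10)), 50, 25), "need >= 4")
})

test_that("apply_preprocess composes resampling, decomposition and reduction", {
  cfg_raw <- preprocess_config("raw", FALSE)
  st <- make_stream(matrix(rnorm(60), 20, 3))
  expect_equal(apply_preprocess(st, cfg_raw)$values, st$values)

  cfg_lin <- preprocess_config("linear", TRUE)
  out <- apply_preprocess(idle_stream(30), cfg_lin)
  expect_equal(length(out$channels), 1)
  expect_true(all(abs(out$values) < 1e-12))

  cfg_grav <- preprocess_config("gravity", TRUE)
  g <- apply_preprocess(idle_stream(30), cfg_grav)
  expect_equal(unname(g$values[, 1]), rep(9.81, 30))
})

test_that("preprocess fingerprints separate configurations", {
  a <- preprocess_fingerprint(preprocess_config("linear", TRUE))
  b <- preprocess_fingerprint(preprocess_config("linear", FALSE))
  c <- preprocess_fingerprint(preprocess_config("raw", TRUE))
  expect_true(length(unique(c(a, b, c))) == 3)
  expect_identical(a, preprocess_fingerprint(preprocess_config("linear", TRUE)))
})
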