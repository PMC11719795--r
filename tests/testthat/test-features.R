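test_that("fourier_magnitude matches a naive DFT and basic spectra", {
  n <- 64
  x <- sin(2 * pi * 5 * (0:(n - 1)) / n)
  spec <- fourier_magnitude(psm_signal(x, 100))
  expect_equal(which.max(spec$magnitude[-1]), 5)
  expect_equal(spec$freqs_hz, (0:(n %/% 2)) * 100 / n)

  const <- fourier_magnitude(psm_signal(rep(2, 32), 100))
  expect_true(all(const$magnitude[-1] < 1e-10))

  set.seed(8)
  for (m in c(8, 17, 32, 63)) {
    y <- rnorm(m)
    got <- fourier_magnitude(psm_signal(y, 50))$magnitude
    expect_equal(got, naive_dft_magnitude(y), tolerance = 1e-9)
  }
})

test_that("Parseval's identity holds for the full DFT underlying the spectrum", {
  set.seed(9)
  for (m in c(16, 33, 64)) {
    y <- rnorm(m)
    full <- Mod(fft(y))
    expect_equal(sum(y^2), sum(full^2) / m, tolerance = 1e-9)
  }
})

test_that("segment_stats reproduces hand values and the two-pass oracle", {
  st <- segment_stats(c(1, 2, 3))
  expect_equal(st$max, 3)
  expect_equal(st$range, 2)
  expect_equal(st$mean, 2)
  expect_equal(st$std, sqrt(2 / 3))
  expect_equal(st$rx, 4)

  stc <- segment_stats(rep(7.5, 5))
  expect_equal(stc$range, 0)
  expect_equal(stc$std, 0)
  expect_equal(stc$rx, 7.5)

  set.seed(10)
  x <- rnorm(100, 3, 12)
  st2 <- segment_stats(x)
  mu <- sum(x) / length(x)                      # two-pass textbook formulas
  expect_equal(st2$std, sqrt(sum((x - mu)^2) / length(x)), tolerance = 1e-12)
  expect_equal(st2$range, max(x) - min(x), tolerance = 1e-12)
  expect_equal(st2$rx, max(x) - min(x) + mu, tolerance = 1e-12)
  expect_error(segment_stats(numeric()), class = "psm_usage_error")
})

test_that("linreg_features recovers exact lines and matches normal equations", {
  t <- (0:99) * 0.01
  lr <- linreg_features(2 * t + 1, 0.01)
  expect_equal(lr$slope, 2, tolerance = 1e-9)
  expect_equal(lr$ordinate, 1, tolerance = 1e-9)

  lrc <- linreg_features(rep(4.2, 10), 0.05)
  expect_equal(lrc$slope, 0)
  expect_equal(lrc$ordinate, 4.2)

  set.seed(11)
  y <- rnorm(50); dt <- 0.02
  x <- (0:49) * dt
  A <- cbind(1, x)                               # normal-equation oracle
  beta <- solve(t(A) %*% A, t(A) %*% y)
  got <- linreg_features(y, dt)
  expect_equal(got$ordinate, beta[1], tolerance = 1e-10)
  expect_equal(got$slope, beta[2], tolerance = 1e-10)
})

test_that("energy Shannon entropy matches closed-form cases", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_entropy(c(1, 1, 0, 0)), 1)
  expect_equal(shannon_entropy(rep(0, 8)), 0)
  expect_equal(shannon_entropy(c(-1, 1)), 1)  # sign-free: energy based
})

test_that("class features compute from normalized S3 as documented", {
  # constant 0.5 in S3 by explicit construction of a normalized signal
  x <- c(0, 1, rep(0.5, 8))
  sig <- psm_signal(x, 100, "normalized")
  seg <- segment_signal(sig, "explicit", boundaries = c(1, 2))
  fv <- extract_class_features(seg)
  expect_equal(unname(fv["S3n-STD"]), 0)
  expect_equal(unname(fv["S3n-R"]), 0)
  expect_equal(unname(fv["S3n-Rx"]), 0.5)
  expect_equal(unname(fv["S3n-O"]), 0.5)
  expect_named(fv, class_feature_names())
})

test_that("grade features compute from original segments as documented", {
  x <- c(1, 4, 2, 5, 5, 0, 6, 3)   # S1 = 1,4,2; S2 = 5; S3 = 5,0,6,3
  sig <- psm_signal(x, 100)
  seg <- segment_signal(sig, "explicit", boundaries = c(3, 4))
  spec_n <- fourier_magnitude(
    segment_signal(normalize_signal(sig), "explicit", boundaries = c(3, 4))$S3)
  fv <- extract_grade_features(seg, spec_n)
  expect_equal(unname(fv["S1-Max"]), 4)
  expect_equal(unname(fv["S3-Max"]), 6)
  expect_equal(unname(fv["S3-R"]), 6)
  expect_equal(unname(fv["S2-R"]), 0)
  expect_named(fv, grade_feature_names())

  zseg <- segment_signal(psm_signal(c(0, 0, 0, 1e-12, rep(0, 8)), 100),
                         "explicit", boundaries = c(4, 8))
  zf <- extract_grade_features(zseg, fourier_magnitude(zseg$S3))
  expect_equal(unname(zf["S3-Max"]), 0)
  expect_equal(unname(zf["S3-We"]), 0)
})

test_that("range/std are translation-invariant; max and rx are not", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(40); c0 <- runif(1, 1, 10)
    a <- segment_stats(x); b <- segment_stats(x + c0)
    expect_equal(b$range, a$range, tolerance = 1e-12)
    expect_equal(b$std, a$std, tolerance = 1e-12)
    expect_equal(b$max, a$max + c0, tolerance = 1e-12)
    expect_equal(b$rx, a$rx + c0, tolerance = 1e-12)
  }
})

test_that("normalized-representation features ignore positive affine rescaling of the raw trace", {
  set.seed(13)
  rec <- simulate_recording(2, 4, seed = 13)
  fv1 <- extract_features(rec)
  rec2 <- rec
  rec2$omega_x <- 3.7 * rec$omega_x + 11
  fv2 <- extract_features(rec2)
  for (f in class_feature_names()) {
    expect_equal(unname(fv2[f]), unname(fv1[f]), tolerance = 1e-9)
  }
  expect_gt(abs(fv2["S3-Max"] - fv1["S3-Max"]), 1)  # original set does change
})

test_that("simulated S3 amplitude features are grade-monotone", {
  cfg <- simulation_config(noise_sd = 1)
  g0 <- t(sapply(1:100, function(i)
    extract_features(simulate_recording(0, 4, cfg, seed = 2000 + i))))
  g3 <- t(sapply(1:100, function(i)
    extract_features(simulate_recording(3, 4, cfg, seed = 4000 + i))))
  expect_gt(mean(g3[, "S3n-R"]), mean(g0[, "S3n-R"]))

  set.seed(5)
  grades <- rep(0:3, each = 50)
  s3r <- vapply(seq_along(grades), function(i) {
    extract_features(simulate_recording(grades[i], 3,
                                        seed = 5000 + i))[["S3-R"]]
  }, numeric(1))
  expect_gt(cor(grades, s3r, method = "spearman"), 0.8)
})
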