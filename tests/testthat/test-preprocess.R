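# Pre-processing primitives against hand arithmetic and brute-force
# oracles, plus the technique registry and fps-adaptive selection.

test_that("L2 normalisation yields unit-norm signals", {
  expect_equal(l2_normalise(c(3, 4)), c(0.6, 0.8))
  expect_equal(l2_normalise(1), 1)
  set.seed(1)
  v <- rnorm(100)
  expect_equal(sqrt(sum(l2_normalise(v)^2)), 1, tolerance = 1e-12)
  expect_error(l2_normalise(numeric(0)), "empty")
  expect_error(l2_normalise(c(0, 0)), "all-zero")
})

test_that("interpolation onto an even grid matches piecewise-linear evaluation", {
  expect_equal(interpolate_even(c(0, 1, 3), c(0, 1, 3)), c(0, 1.5, 3))
  even <- seq(0, 900, by = 100)
  v <- sin(even / 150)
  expect_equal(interpolate_even(v, even), v)
  # brute-force piecewise-linear oracle on the even grid
  ts <- c(0, 1, 2)
  v <- c(0, 10, 10)
  grid <- seq(0, 2, length.out = 3)
  oracle <- vapply(grid, function(g) {
    i <- max(which(ts <= g))
    if (i == length(ts)) return(v[i])
    v[i] + (v[i + 1] - v[i]) * (g - ts[i]) / (ts[i + 1] - ts[i])
  }, numeric(1))
  expect_equal(interpolate_even(v, ts), oracle)
  expect_error(interpolate_even(c(1, 2), c(5, 5)), "duplicate")
})

test_that("Hamming taper matches the window formula and endpoint attenuation", {
  expect_equal(apply_hamming(c(1, 1, 1)), c(0.08, 1, 0.08))
  expect_error(apply_hamming(5), "length >= 2")
  L <- 5
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  expect_equal(apply_hamming(rep(2, L)), 2 * w)
  set.seed(2)
  v <- rnorm(64)
  out <- apply_hamming(v)
  expect_equal(out[c(1, 64)], 0.08 * v[c(1, 64)])
})

test_that("median filter matches a brute-force zero-padded oracle", {
  expect_equal(median_filter(c(1, 9, 1), 3), c(1, 1, 1))
  expect_equal(median_filter(c(4, 2, 7), 1), c(4, 2, 7))
  expect_error(median_filter(1:5, 4), "odd")
  set.seed(3)
  v <- rnorm(50)
  for (k in c(3, 5)) {
    half <- k %/% 2
    padded <- c(rep(0, half), v, rep(0, half))
    oracle <- vapply(seq_along(v), function(i) {
      sort(padded[i:(i + k - 1)])[half + 1]
    }, numeric(1))
    expect_equal(median_filter(v, k), oracle)
  }
})

test_that("linear detrending removes exactly the least-squares line", {
  expect_equal(detrend_linear(c(1, 2, 3, 4)), rep(0, 4),
               tolerance = 1e-12)
  t <- seq_len(120)
  # centred cosine over whole periods: zero mean and, by even symmetry
  # about the midpoint, orthogonal to the (odd) linear term
  s <- cos(2 * pi * (t - 60.5) / 30)
  expect_equal(detrend_linear(s), s, tolerance = 1e-9)
  expect_equal(detrend_linear(s + 0.3 * t - 7), detrend_linear(s),
               tolerance = 1e-9)
  out <- detrend_linear(rnorm(40) + seq_len(40))
  expect_equal(mean(out), 0, tolerance = 1e-10)
  expect_equal(unname(coef(lm(out ~ seq_along(out)))[2]), 0,
               tolerance = 1e-10)
})

test_that("FFT upsampling doubles length and round-trips band-limited tones", {
  expect_length(upsample_fft(rnorm(128)), 256)
  expect_equal(upsample_fft(rep(3.5, 20)), rep(3.5, 40),
               tolerance = 1e-9)
  t <- seq(0, 1 - 1 / 64, by = 1 / 64)
  tone <- sin(2 * pi * 5 * t)
  up <- upsample_fft(tone, 2)
  expect_equal(up[seq(1, length(up), by = 2)], tone, tolerance = 1e-6)
  expect_error(upsample_fft(1:10, 0), ">= 1")
})

test_that("moving average matches a brute-force truncated-window oracle", {
  expect_equal(smooth_ma(rep(2, 10)), rep(2, 10))
  expect_equal(smooth_ma(c(0, 0, 5, 0, 0), 5)[3], 1)
  expect_error(smooth_ma(1:5, 2), "odd")
  set.seed(4)
  v <- rnorm(40)
  for (w in c(3, 5)) {
    half <- w %/% 2
    oracle <- vapply(seq_along(v), function(i) {
      lo <- max(1, i - half)
      hi <- min(length(v), i + half)
      sum(v[lo:hi]) / (hi - lo + 1)
    }, numeric(1))
    expect_equal(smooth_ma(v, w), oracle)
  }
})

test_that("technique registry composes steps in the documented order", {
  set.seed(5)
  ts <- seq(0, 990, by = 10)
  v <- 100 + 2 * sin(2 * pi * 1.2 * ts / 1000) + rnorm(100, 0, 0.1)

  expect_identical(apply_technique(v, ts, 1), v)
  expect_equal(apply_technique(c(3, 4), c(0, 10), 2), c(0.6, 0.8))
  # type 6 = normalise(hamming(interpolate(detrend))) composed by hand
  expect_equal(apply_technique(v, ts, 6),
               l2_normalise(apply_hamming(interpolate_even(
                 detrend_linear(v), ts))))
  out6 <- apply_technique(v, ts, 6)
  expect_equal(sqrt(sum(out6^2)), 1, tolerance = 1e-12)
  expect_length(out6, length(v))
  out7 <- apply_technique(v, ts, 7)
  expect_length(out7, 2 * length(v))
  expect_equal(sqrt(sum(out7^2)), 1, tolerance = 1e-12)
  for (ty in 1:7) {
    expect_true(all(is.finite(apply_technique(v, ts, ty))),
                info = paste("technique", ty))
  }
  expect_error(apply_technique(v, ts, 8), "unknown technique")
})

test_that("fps-adaptive selection switches at 15 fps", {
  expect_identical(select_technique_auto(30), 6L)
  expect_identical(select_technique_auto(12), 7L)
  expect_identical(select_technique_auto(15), 6L)
  expect_error(select_technique_auto(0), "positive")
})
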