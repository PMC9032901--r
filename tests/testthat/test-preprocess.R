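make_spec <- function(intensity, lo = 3500, mode = "protein", by = 1) {
  raw_spectrum(seq(lo, by = by, length.out = length(intensity)), intensity,
               "t", 1L, mode, check_range = FALSE)
}

test_that("mass-range trim keeps the closed interval and flags empty results", {
  s <- raw_spectrum(seq(2000, 20000, by = 100), rep(1, 181), "t", 1L,
                    "protein")
  tr <- trim_mass_range(s, 3500, 20000)
  expect_true(all(tr$mz >= 3500 & tr$mz <= 20000))
  expect_identical(tr$mz[1], 3500)  # boundary retained
  expect_identical(trim_mass_range(s, 0, 1e9)$mz, s$mz)
  expect_error(trim_mass_range(s, 2050.1, 2050.2),
               class = "fingernet_unusable_spectrum")
})

test_that("square-root transform maps intensities pointwise and keeps ranks", {
  s <- make_spec(c(9, 0, 16, 2))
  out <- sqrt_transform(s)
  expect_equal(out$intensity, c(3, 0, 4, sqrt(2)))
  expect_identical(out$mz, s$mz)
  set.seed(1)
  r <- make_spec(runif(100, 0, 50))
  expect_identical(order(sqrt_transform(r)$intensity), order(r$intensity))
})

test_that("Savitzky-Golay reproduces low-degree polynomials exactly", {
  n <- 200
  x <- seq_len(n)
  cubic <- 2 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3
  sm <- savitzky_golay_smooth(make_spec(cubic), 15L, 3L)
  expect_equal(sm$intensity, cubic, tolerance = 1e-8)
  const <- savitzky_golay_smooth(make_spec(rep(7, 80)), 10L, 3L)
  expect_equal(const$intensity, rep(7, 80), tolerance = 1e-10)
})

test_that("Savitzky-Golay equals the per-window least-squares oracle", {
  set.seed(7)
  for (hw in c(5L, 15L)) {
    y <- runif(150, 0, 10)
    sm <- savitzky_golay_smooth(make_spec(y), hw, 3L)
    expect_equal(sm$intensity, sg_oracle(y, hw, 3L), tolerance = 1e-10)
  }
  expect_error(savitzky_golay_smooth(make_spec(runif(10)), 15L, 3L),
               "smaller half_window", class = "fingernet_bad_param")
})

test_that("SNIP equals the direct two-loop oracle elementwise on random arrays", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    y <- runif(n, 0, 100)
    iters <- sample(1:30, 1)
    s <- make_spec(y)
    expect_identical(snip_baseline(s, iters), snip_oracle(y, iters))
  }
  # increasing schedule agrees with its oracle too
  y <- runif(100, 0, 10)
  expect_identical(snip_baseline(make_spec(y), 30L, decreasing = FALSE),
                   snip_oracle(y, 30L, decreasing = FALSE))
})

test_that("SNIP baseline behaviour: constants, spikes, and the envelope bound", {
  s <- make_spec(rep(3.2, 101))
  expect_equal(snip_baseline(s, 30L), rep(3.2, 101))
  spike <- rep(0, 101); spike[51] <- 10
  b <- snip_baseline(make_spec(spike), 30L)
  expect_true(b[51] <= 5)      # clipping halves an isolated spike at least once
  expect_equal(b[1:20], rep(0, 20))
  set.seed(3)
  y <- runif(200, 0, 50)
  expect_true(all(snip_baseline(make_spec(y), 30L) <= y))
})

test_that("baseline subtraction clamps at zero and validates lengths", {
  s <- make_spec(c(5, 2, 8))
  expect_equal(remove_baseline(s, c(5, 2, 8))$intensity, c(0, 0, 0))
  expect_identical(remove_baseline(s, rep(0, 3))$intensity, s$intensity)
  expect_true(all(remove_baseline(s, c(10, 10, 10))$intensity >= 0))
  expect_error(remove_baseline(s, c(1, 2)), class = "fingernet_bad_param")
})

test_that("MAD noise estimator is calibrated and outlier-resistant", {
  expect_identical(estimate_noise(make_spec(rep(4, 50))), 0)
  set.seed(42)
  g <- withr::with_seed(99L, rnorm(1e5, 0, 1))
  est <- estimate_noise(make_spec(abs(g) * sign(g) + 10))
  expect_gt(est, 0.95)
  expect_lt(est, 1.05)
  # one huge outlier moves the estimate by < 1%
  base <- withr::with_seed(100L, rnorm(1e4, 5, 1))
  e0 <- estimate_noise(make_spec(base))
  e1 <- estimate_noise(make_spec(c(base, 1e6)))
  expect_lt(abs(e1 - e0) / e0, 0.01)
  # agreement with the explicit MAD formula
  expect_equal(e0, 1.4826 * median(abs(base - median(base))),
               tolerance = 1e-12)
})

test_that("peak picking finds constructed apexes and matches an exhaustive scan", {
  n <- 501
  x <- seq_len(n)
  bell <- function(c0, h, w) h * exp(-(x - c0)^2 / (2 * w^2))
  noise_level <- 1
  y <- bell(150, 10, 5)
  pl <- detect_peaks(make_spec(y), snr_threshold = 6, peak_half_window = 20L,
                     noise = noise_level)
  expect_length(pl$mz, 1L)
  expect_equal(pl$mz, make_spec(y)$mz[150])

  y2 <- bell(150, 10, 5) + bell(350, 8, 5)
  pl2 <- detect_peaks(make_spec(y2), 6, 20L, noise = noise_level)
  expect_length(pl2$mz, 2L)

  # exhaustive scan oracle on a random rough signal
  set.seed(5)
  yr <- runif(300, 0, 12)
  plr <- detect_peaks(make_spec(yr), 6, 10L, noise = noise_level)
  oracle <- which(vapply(seq_along(yr), function(i) {
    win <- max(1, i - 10):min(length(yr), i + 10)
    before <- win[win < i]; after <- win[win > i]
    yr[i] >= 6 * noise_level &&
      all(yr[i] > yr[before]) && all(yr[i] >= yr[after])
  }, logical(1)))
  expect_equal(plr$mz, make_spec(yr)$mz[oracle])

  expect_length(detect_peaks(make_spec(y), Inf, 20L, noise = 1)$mz, 0L)
  expect_error(detect_peaks(make_spec(rep(1, 50)), 6, 20L, noise = 0),
               class = "fingernet_zero_noise")
})

test_that("peak picking is invariant under uniform intensity scaling", {
  set.seed(8)
  y <- runif(400, 0, 1) + 10 * exp(-(seq_len(400) - 100)^2 / 50) +
    8 * exp(-(seq_len(400) - 300)^2 / 50)
  s1 <- make_spec(y)
  s2 <- make_spec(y * 137.5)
  p1 <- detect_peaks(s1, 6, 20L)
  p2 <- detect_peaks(s2, 6, 20L)
  expect_identical(p1$mz, p2$mz)
})

test_that("TIC normalisation sums to one, is idempotent, and rejects empties", {
  pl <- peaklist(c(3600, 3700), c(2, 2), "t", 1L)
  out <- tic_normalize(pl)
  expect_equal(out$intensity, c(0.5, 0.5))
  expect_true(out$normalized)
  set.seed(2)
  r <- random_peaklist(20)
  expect_equal(sum(tic_normalize(r)$intensity), 1, tolerance = 1e-12)
  expect_equal(tic_normalize(tic_normalize(r)), tic_normalize(r))
  expect_error(tic_normalize(peaklist(numeric(), numeric(), "t", 1L)),
               class = "fingernet_bad_peaklist")
})

test_that("close peaks merge keeping the stronger member", {
  pl <- peaklist(c(4000, 4001, 4010, 4011.5), c(1, 5, 3, 2), "t", 1L)
  m <- merge_close_peaks(pl, 2.0)
  expect_equal(m$mz, c(4001, 4010))
  expect_equal(m$intensity, c(5, 3))
})

test_that("full pipeline recovers simulated template peaks and is deterministic", {
  cfg <- sim_config(seed = 7L)
  panel <- simulate_panel(cfg, raw = TRUE)
  recovery <- spurious <- numeric(0)
  for (k in seq_len(20)) {
    s <- panel$spectra[[k]]
    tpl <- panel$templates[[s$sample_id]]
    pl <- preprocess_pipeline(s)
    expect_true(pl$normalized)
    expect_equal(sum(pl$intensity), 1, tolerance = 1e-9)
    expect_false(is.unsorted(pl$mz, strictly = TRUE))
    recovery <- c(recovery,
                  mean(vapply(tpl$mz,
                              function(m) any(abs(pl$mz - m) <= 5),
                              logical(1))))
    spurious <- c(spurious,
                  sum(vapply(pl$mz,
                             function(m) !any(abs(tpl$mz - m) <= 5),
                             logical(1))))
  }
  expect_gte(mean(recovery), 0.90)
  expect_lte(max(spurious), 2)

  # determinism: the chain has no random stage
  s <- panel$spectra[[1]]
  expect_identical(preprocess_pipeline(s), preprocess_pipeline(s))
})

test_that("a pure-baseline spectrum is reported unusable", {
  grid <- seq(3500, 5500, by = 1)
  bg <- 100 * exp(-(grid - 3500) / 20000)
  baseline_only <- withr::with_seed(1L, {
    raw_spectrum(grid, bg + abs(rnorm(length(grid))) * sqrt(bg / 100),
                 "blank", 1L, "protein", check_range = FALSE)
  })
  expect_warning(out <- preprocess_pipeline(baseline_only),
                 class = "fingernet_unusable")
  expect_null(out)
})

test_that("the literal stage order (detect first) runs for comparison", {
  cfg <- sim_config(seed = 7L)
  panel <- simulate_panel(cfg, raw = TRUE)
  literal <- preprocess_config(
    step_order = c("trim", "detect", "sqrt", "smooth", "baseline"))
  pl <- preprocess_pipeline(panel$spectra[[1]], literal)
  expect_s3_class(pl, "peaklist")
  expect_true(pl$normalized)
})
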