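test_that("window enumeration is inclusive, ordered, and m(m+1)/2 long", {
  expect_identical(nrow(enumerate_windows(c(0, 0))), 1L)
  w3 <- enumerate_windows(c(1, 0))
  expect_identical(w3$start, c(1L, 1L, 0L))
  expect_identical(w3$end, c(1L, 0L, 0L))
  for (rg in list(c(5, 0), c(9, 3), c(30, 0), c(12, 12))) {
    m <- rg[1] - rg[2] + 1
    w <- enumerate_windows(rg)
    expect_identical(nrow(w), as.integer(m * (m + 1) / 2))
    expect_true(all(w$end <= w$start))
    expect_true(all(w$start <= rg[1] & w$end >= rg[2]))
    expect_false(any(duplicated(paste(w$start, w$end))))
  }
  expect_error(enumerate_windows(c(5, -1)), "non-negative")
  expect_error(enumerate_windows(c(2, 5)), "range_max")
})

test_that("a noise-free linear signal is recovered exactly", {
  sd <- make_signal_data(n_records = 18, true_start = 10, true_end = 4,
                         beta = 2, noise_sd = 0)
  ms <- slidingwin(response ~ 1, sd$clim, sd$biol, range = c(14, 0))
  expect_identical(ms$dataset$window_start[1L], 10L)
  expect_identical(ms$dataset$window_end[1L], 4L)
  expect_equal(ms$dataset$beta[1L], 2, tolerance = 1e-8)
  expect_equal(ms$best_r_squared, 1, tolerance = 1e-10)
  # best window is the global minimum over the whole set
  expect_true(all(ms$dataset$delta_aicc[1L] <= ms$dataset$delta_aicc))
})

test_that("the model set matches a naive per-window refit oracle", {
  sd <- make_signal_data(n_records = 16, true_start = 8, true_end = 3,
                         beta = 1.5, noise_sd = 1, seed = 13)
  for (cfg in list(list(stat = "mean", func = "lin"),
                   list(stat = "max", func = "lin"),
                   list(stat = "slope", func = "lin"),
                   list(stat = "mean", func = "quad"))) {
    ms <- suppressWarnings(
      slidingwin(response ~ 1, sd$clim, sd$biol, range = c(9, 1),
                 stat = cfg$stat, func = cfg$func))
    o <- oracle_sliding(sd$clim, sd$biol, 9, 1, cfg$stat, cfg$func)
    key <- paste(ms$dataset$window_start, ms$dataset$window_end)
    m <- match(key, paste(o$start, o$end))
    ok <- !is.na(ms$dataset$delta_aicc)
    if (cfg$stat == "slope") {
      # single-day windows have a degenerate (zero) slope regressor
      expect_true(all(ms$dataset$window_start[!ok] ==
                        ms$dataset$window_end[!ok]))
    } else {
      expect_true(all(ok))
    }
    expect_equal(ms$dataset$delta_aicc[ok], o$delta[m][ok],
                 tolerance = 1e-9, label = paste(cfg$stat, cfg$func))
    expect_equal(ms$dataset$beta[ok], o$beta[m][ok], tolerance = 1e-9)
    expect_false(is.unsorted(stats::na.omit(ms$dataset$delta_aicc)))
    expect_identical(nrow(ms$dataset), 45L)
  }
})

test_that("poisson and binomial responses run through the general path", {
  fx <- make_fixture(n_records = 30, seed = 17, lead = 30)
  cm <- climate_matrix(fx$clim, fx$mdates, 8)
  eta <- 0.3 + 0.8 * aggregate_window(cm, 6, 2, "mean")
  set.seed(18)
  counts <- stats::rpois(30, exp(eta))
  biolp <- biol_table(fx$mdates, counts)
  msp <- slidingwin(response ~ 1, fx$clim, biolp,
                    family = stats::poisson(), range = c(8, 0))
  op <- oracle_sliding(fx$clim, biolp, 8, 0, "mean", "lin",
                       stats::poisson)
  key <- paste(msp$dataset$window_start, msp$dataset$window_end)
  m <- match(key, paste(op$start, op$end))
  expect_equal(msp$dataset$delta_aicc, op$delta[m], tolerance = 1e-7)

  bin <- as.integer(stats::runif(30) < stats::plogis(eta - 0.5))
  msb <- slidingwin(response ~ 1, fx$clim, biol_table(fx$mdates, bin),
                    family = stats::binomial(), range = c(5, 0))
  expect_identical(nrow(msb$dataset), 21L)
  expect_true(all(is.finite(msb$dataset$delta_aicc)))
})

test_that("unfittable windows are flagged but retained", {
  fx <- make_fixture(n_records = 12, seed = 19)
  # climate mostly positive but with negative days: log fails on some windows
  clim2 <- climate_series(fx$clim$date, fx$clim$value + 1.2)
  expect_warning(
    ms <- slidingwin(response ~ 1, clim2,
                     biol_table(fx$mdates, stats::rnorm(12)),
                     range = c(6, 0), func = "log"),
    "flagged")
  expect_identical(nrow(ms$dataset), 28L)
  expect_true(any(ms$dataset$flag == "not_fitted"))
  expect_true(all(is.na(ms$dataset$delta_aicc[ms$dataset$flag == "not_fitted"])))
  # weights over the fitted records still sum to 1
  expect_equal(sum(ms$dataset$mod_weight, na.rm = TRUE), 1)
})

test_that("identical inputs give byte-identical model sets", {
  sd <- make_signal_data(noise_sd = 1, seed = 23)
  a <- slidingwin(response ~ 1, sd$clim, sd$biol, range = c(10, 0),
                  k = 5, seed = 42)
  b <- slidingwin(response ~ 1, sd$clim, sd$biol, range = c(10, 0),
                  k = 5, seed = 42)
  expect_identical(a$dataset, b$dataset)
})

test_that("the MSE-based AICc matches its formula and boundary cases work", {
  expect_equal(aicc_cv_value(1, 2, 20), 4 + 12 / 17)
  sd <- make_signal_data(n_records = 10, noise_sd = 0.5, seed = 29)
  base <- fit_baseline(response ~ 1, sd$biol)
  cm <- climate_matrix(sd$clim, sd$biol$date, 10)
  x <- aggregate_window(cm, 10, 4, "mean")
  # leave-one-out: 10 folds of size 1 runs without error
  expect_no_error(cv_delta_aicc(base, x, k = 10, seed = 1))
  expect_error(cv_delta_aicc(base, x, k = 11, seed = 1), "2 <= k <= N")
  expect_error(slidingwin(response ~ 1, sd$clim, sd$biol, range = c(5, 0),
                          k = 11, seed = 1), "2 <= k <= N")
  expect_error(slidingwin(response ~ 1, sd$clim, sd$biol, range = c(5, 0),
                          k = 5), "seed")
  # CV with a non-gaussian family is an explicit error
  bio2 <- biol_table(sd$biol$date, rpois(10, 3))
  expect_error(slidingwin(response ~ 1, sd$clim, bio2,
                          family = stats::poisson(), range = c(5, 0),
                          k = 5, seed = 1), "gaussian")
})

test_that("vectorized CV equals the per-fold lm loop", {
  sd <- make_signal_data(n_records = 21, noise_sd = 1, seed = 31)
  ms <- slidingwin(response ~ 1, sd$clim, sd$biol, range = c(8, 0),
                   k = 7, seed = 77)
  base <- fit_baseline(response ~ 1, sd$biol)
  set.seed(77)
  folds <- sample(rep(1:7, length.out = 21))
  cm <- climate_matrix(sd$clim, sd$biol$date, 8)
  wins <- enumerate_windows(c(8, 0))
  loop <- vapply(seq_len(nrow(wins)), function(w) {
    x <- aggregate_window(cm, wins$start[w], wins$end[w], "mean")
    cv_delta_aicc(base, x, k = 7, folds = folds)
  }, numeric(1))
  key <- paste(wins$start, wins$end)
  m <- match(key, paste(ms$dataset$window_start, ms$dataset$window_end))
  expect_equal(loop, ms$dataset$delta_aicc[m], tolerance = 1e-10)
})

test_that("cross-validated dAICc is conservative when a signal exists", {
  set.seed(37)
  res <- t(replicate(60, {
    dat <- gen_dataset(n_records = 30, true_window = c(12, 6),
                       target_r2 = 0.4, lead_in = 60,
                       seed = sample.int(2^30, 1))
    plain <- slidingwin(response ~ 1, dat$climate, dat$biol,
                        range = c(15, 0))
    cv <- slidingwin(response ~ 1, dat$climate, dat$biol,
                     range = c(15, 0), k = 10,
                     seed = sample.int(2^30, 1))
    c(plain$dataset$delta_aicc[1L], cv$dataset$delta_aicc[1L])
  }))
  expect_gt(stats::median(res[, 2]), stats::median(res[, 1]))
})
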