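test_that("Akaike weights: normalization, shift invariance, pair ratios", {
  expect_equal(akaike_weights(c(-5, -5)), c(0.5, 0.5))
  set.seed(61)
  d <- stats::rnorm(40, sd = 4)
  w <- akaike_weights(d)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(d + 17.3), w, tolerance = 1e-12)
  # pairwise ratio identity w_i/w_j = exp(0.5 (d_j - d_i))
  for (i in c(2, 9, 25)) {
    expect_equal(w[1] / w[i], exp(0.5 * (d[i] - d[1])), tolerance = 1e-9)
  }
  # flagged records get NA weight; the rest renormalize
  w2 <- akaike_weights(c(0, NA, -2, Inf))
  expect_true(is.na(w2[2]) && is.na(w2[4]))
  expect_equal(sum(w2, na.rm = TRUE), 1)
  expect_error(akaike_weights(numeric(0)), "empty")
})

fake_set <- function(deltas, starts = NULL, ends = NULL) {
  o <- order(deltas)
  data.frame(window_start = (if (is.null(starts)) seq_along(deltas) + 10
                             else starts)[o],
             window_end = (if (is.null(ends)) rep(0, length(deltas))
                           else ends)[o],
             delta_aicc = deltas[o], beta = seq_along(deltas)[o],
             mod_weight = akaike_weights(deltas)[o])
}

test_that("confidence sets are prefixes excluding the crossing record", {
  # weights (0.5, 0.3, 0.15, 0.05): cumsum 0.5 0.8 0.95 1.0 -> 3 models
  d <- -2 * log(c(0.5, 0.3, 0.15, 0.05))
  ds <- fake_set(d)
  expect_equal(ds$mod_weight, c(0.5, 0.3, 0.15, 0.05), tolerance = 1e-12)
  expect_identical(nrow(confidence_set(ds, 0.95)), 3L)
  # a dominant first model alone exceeds the level: set is that model
  dom <- fake_set(c(0, 50))
  expect_identical(nrow(confidence_set(dom, 0.95)), 1L)
  # uniform weights over M models: floor(level * M) members
  for (M in c(10, 40, 97)) {
    u <- fake_set(rep(1, M))
    expect_identical(nrow(confidence_set(u, 0.95)),
                     as.integer(floor(0.95 * M)))
    expect_equal(c_statistic(u, 0.95), 100 * floor(0.95 * M) / M)
  }
  expect_error(confidence_set(ds, 1.2), "level")
  # the set is a prefix of the sorted table
  cs <- confidence_set(ds, 0.95)
  expect_identical(cs$delta_aicc, ds$delta_aicc[seq_len(nrow(cs))])
})

test_that("model averaging uses full-set weights without renormalizing", {
  s <- data.frame(beta = c(2, 4), mod_weight = c(0.25, 0.25))
  expect_equal(model_average(s), 1.5)
  one <- data.frame(beta = -3.3, mod_weight = 1)
  expect_equal(model_average(one), -3.3)
  expect_error(model_average(s[0, ]), "empty")
})

test_that("medwin returns the weighted median window of the set", {
  # starts {10, 20, 30} with weights {.4, .2, .35} in the 95% set:
  # cumulative weight along starts crosses 0.5 at start = 20
  d <- -2 * log(c(0.4, 0.2, 0.35, 0.05))
  ds <- fake_set(d, starts = c(10, 20, 30, 99), ends = c(0, 0, 0, 0))
  got <- medwin(ds, level = 0.95)
  expect_equal(unname(got["start"]), 20)
  expect_equal(unname(got["end"]), 0)
  # singleton confidence set: that window
  dom <- fake_set(c(0, 60), starts = c(7, 2), ends = c(3, 0))
  expect_equal(unname(medwin(dom, 0.95)), c(7, 3))
  # plain median option over the same three-window set
  expect_equal(unname(medwin(ds, 0.95, weighted = FALSE)["start"]), 20)
})

test_that("randomization permutes dates as a multiset and reruns", {
  sd <- make_signal_data(n_records = 12, noise_sd = 0.6, seed = 67)
  rnd <- randwin(6, "sliding", response ~ 1, sd$clim, sd$biol,
                 seed = 101, range = c(8, 0))
  expect_identical(nrow(rnd), 6L)
  expect_true(all(is.finite(rnd$best_delta_aicc)))
  expect_true(all(rnd$c_pct >= 0 & rnd$c_pct <= 100))
  # reproducible under the same seed
  rnd2 <- randwin(6, "sliding", response ~ 1, sd$clim, sd$biol,
                  seed = 101, range = c(8, 0))
  expect_identical(rnd, rnd2)
  expect_error(randwin(0, "sliding", response ~ 1, sd$clim, sd$biol),
               "repeats")
})

test_that("a strong signal beats every randomized rerun", {
  dat <- gen_dataset(n_records = 40, true_window = c(12, 5),
                     target_r2 = 0.8, lead_in = 60, seed = 71)
  ms <- slidingwin(response ~ 1, dat$climate, dat$biol, range = c(15, 0))
  rnd <- randwin(100, "sliding", response ~ 1, dat$climate, dat$biol,
                 seed = 72, range = c(15, 0))
  expect_true(all(ms$dataset$delta_aicc[1L] < rnd$best_delta_aicc))
  p <- p_delta_aicc(ms$dataset$delta_aicc[1L], rnd)
  expect_equal(p$value, 1 / 101)
  expect_match(p$label, "^<")
})

test_that("P_dAICc rank arithmetic covers both extremes and the middle", {
  rnd <- structure(data.frame(rep = 1:99,
                              best_delta_aicc = seq(-50, -1, length.out = 99)),
                   class = c("window_randset", "data.frame"))
  # observed less negative than every randomized value
  expect_equal(p_delta_aicc(10, rnd)$value, 1)
  # observed at the randomized median
  expect_lt(abs(p_delta_aicc(stats::median(rnd$best_delta_aicc),
                             rnd)$value - 0.5), 0.02)
  expect_warning(p_delta_aicc(0, rnd[1:5, ]), "fewer than 20")
})

test_that("the logistic calibration evaluates verbatim and flips cleanly", {
  rnd0 <- structure(data.frame(rep = 1:5, best_delta_aicc = rep(-1, 5),
                               c_pct = rep(0, 5)),
                    class = c("window_randset", "data.frame"))
  # delta_C = 0, N = 0: 1 / (1 + exp(-0.54))
  expect_equal(p_c(0, rnd0, n = 0)$value, 0.6318124, tolerance = 1e-6)
  # delta_C = -0.5, N = 47: exponent sums to -5.04
  p2 <- p_c(-0.5, rnd0, n = 47, scale = "proportion")
  expect_equal(p2$value, 1 / (1 + exp(-5.04)), tolerance = 1e-12)
  expect_equal(p2$delta_c, -0.5)
  # flipped orientation is the exact complement
  p2f <- p_c(-0.5, rnd0, n = 47, scale = "proportion",
             orientation = "flipped")
  expect_equal(p2$value + p2f$value, 1, tolerance = 1e-12)
  # percent and proportion scales agree
  expect_equal(p_c(50, rnd0, n = 10)$value,
               p_c(0.5, rnd0, n = 10, scale = "proportion")$value)
  # cross-validated coefficients engage with cv = TRUE
  expect_false(isTRUE(all.equal(p_c(-0.1, rnd0, n = 20,
                                    scale = "proportion")$value,
                                p_c(-0.1, rnd0, n = 20, cv = TRUE,
                                    scale = "proportion")$value)))
  # delta_D diagnostic
  pd <- p_c(-0.2, rnd0, n = 20, scale = "proportion", observed_delta = -9)
  expect_equal(pd$delta_d, -8)
  # weighted randomization sets carry no C
  rndw <- structure(data.frame(rep = 1, best_delta_aicc = -1),
                    class = c("window_randset", "data.frame"))
  expect_error(p_c(0.5, rndw, n = 10), "no C statistic")
})

test_that("C shrinks as the signal strengthens", {
  set.seed(73)
  cstat <- sapply(c(0.2, 0.8), function(r2) {
    stats::median(replicate(12, {
      dat <- gen_dataset(n_records = 40, true_window = c(12, 5),
                         target_r2 = r2, lead_in = 60,
                         seed = sample.int(2^30, 1))
      c_statistic(slidingwin(response ~ 1, dat$climate, dat$biol,
                             range = c(15, 0)))
    }))
  })
  expect_lt(cstat[2], cstat[1])
})
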