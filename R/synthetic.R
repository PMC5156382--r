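#' Generate a synthetic daily climate series
#'
#' Daily AR(1) gaussian series with the stated lag-1 autocorrelation and
#' unit marginal variance (innovation sd `sqrt(1 - autocorr^2)`), spanning
#' the requested years plus a lead-in so that windows up to `lead_in` days
#' before the earliest record can be formed.
#'
#' @param years integer vector of calendar years to cover.
#' @param autocorr lag-1 autocorrelation in [0, 1).
#' @param lead_in days of additional climate history before 1 January of
#'   the first year.
#' @param seed integer seed.
#' @return a [climate_series()].
#' @export
gen_climate <- function(years, autocorr = 0.2, lead_in = 400L, seed = NULL) {
  if (autocorr < 0 || autocorr >= 1) {
    stop("autocorr must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  from <- as.Date(sprintf("%04d-01-01", min(years))) - as.integer(lead_in)
  to <- as.Date(sprintf("%04d-12-31", max(years)))
  dates <- seq(from, to, by = "day")
  nd <- length(dates)
  innov_sd <- sqrt(1 - autocorr^2)
  x <- numeric(nd)
  x[1L] <- stats::rnorm(1L)
  if (autocorr == 0) {
    x <- stats::rnorm(nd)
  } else {
    e <- stats::rnorm(nd - 1L, sd = innov_sd)
    for (t in 2:nd) x[t] <- autocorr * x[t - 1L] + e[t - 1L]
  }
  climate_series(dates, x, varname = "climate_sim")
}

#' Generate a synthetic climate-window dataset
#'
#' Emulates an annual study: one biological record per year on a fixed
#' measurement date whose response is a linear function of mean climate
#' inside a known true window plus gaussian noise. The noise variance is
#' chosen so the population R-squared of the true-window regression equals
#' `target_r2`, using the empirical variance of the windowed climate
#' means: `Var(noise) = Var(signal) (1 - R2) / R2`. With `target_r2 = 0`
#' the climate term is absent (`beta` forced to 0, unit noise);
#' `target_r2 = 1` is the noiseless boundary used by construction tests.
#'
#' @param n_records number of annual records (sample size N).
#' @param true_window `c(start, end)` offsets (days before the
#'   measurement date) of the true climate window.
#' @param beta true slope (response units per climate unit); ignored
#'   (forced to 0) when `target_r2 = 0`.
#' @param target_r2 target signal strength in [0, 1].
#' @param autocorr lag-1 autocorrelation of the daily climate.
#' @param measurement_day `c(day, month)` of the fixed annual measurement
#'   date.
#' @param first_year first calendar year.
#' @param intercept response intercept.
#' @param lead_in climate lead-in days (must cover the analysis range).
#' @param seed integer seed; the dataset is fully reproducible from the
#'   arguments plus seed.
#' @return list with components `climate` (a [climate_series()]), `biol`
#'   (a [biol_table()]), and `truth` (the generating parameters, true
#'   per-year window means, and realized noise sd).
#' @export
gen_dataset <- function(n_records = 47, true_window = c(40, 20), beta = 1,
                        target_r2 = 0.4, autocorr = 0.2,
                        measurement_day = c(1, 6), first_year = 1966,
                        intercept = 0, lead_in = 400L, seed = NULL) {
  if (target_r2 < 0 || target_r2 > 1) {
    stop("target_r2 must be in [0, 1]", call. = FALSE)
  }
  if (target_r2 == 0) beta <- 0
  if (target_r2 > 0 && beta == 0) {
    stop("target_r2 > 0 requires beta != 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  years <- seq(first_year, length.out = n_records)
  clim <- gen_climate(years, autocorr = autocorr, lead_in = lead_in,
                      seed = NULL)
  mdates <- as.integer(as.Date(sprintf("%04d-%02d-%02d", years,
                                       measurement_day[2L],
                                       measurement_day[1L])))
  cmat <- climate_matrix(clim, mdates, true_window[1L])
  m <- aggregate_window(cmat, true_window[1L], true_window[2L], "mean")
  signal <- beta * m
  if (target_r2 == 0) {
    noise_sd <- 1
  } else if (target_r2 == 1) {
    noise_sd <- 0
  } else {
    vs <- stats::var(signal)
    noise_sd <- sqrt(vs * (1 - target_r2) / target_r2)
  }
  y <- intercept + signal + stats::rnorm(n_records, sd = noise_sd)
  list(climate = clim,
       biol = biol_table(mdates, y),
       truth = list(n_records = n_records, true_window = true_window,
                    beta = beta, target_r2 = target_r2,
                    autocorr = autocorr, noise_sd = noise_sd,
                    window_means = m, measurement_dates = mdates))
}

#' Misclassification and R-squared bias study on synthetic data
#'
#' Runs the full pipeline (sliding-window search, 5-repeat randomization,
#' logistic-calibrated P_C classification at the 0.5 threshold) over a
#' grid of sample sizes and signal strengths, with and/or without 10-fold
#' cross-validation, and tabulates false-negative/false-positive rates and
#' the median estimated R-squared of the selected best window.
#'
#' Classification uses the flipped orientation of [p_c()] (small P_C =
#' likely real signal); see the vignette for why the verbatim orientation
#' cannot classify.
#'
#' @param n_grid sample sizes to test.
#' @param r2_grid signal strengths; include 0 for false-positive cells.
#' @param cv_grid cross-validation settings, subset of `c(0, 10)`.
#' @param reps datasets per grid cell.
#' @param range sliding-window search range `c(range_max, range_min)`.
#' @param true_window generating window (within `range`).
#' @param repeats randomization repeats per dataset.
#' @param seed integer seed.
#' @return data frame with one row per (n, r2, cv) cell: `misclass_rate`
#'   (false-negative rate where `r2 > 0`, false-positive rate where
#'   `r2 == 0`), `median_r2_hat`, and `reps`.
#' @export
performance_study <- function(n_grid = c(10, 47), r2_grid = c(0, 0.2, 0.8),
                              cv_grid = 0, reps = 25, range = c(30, 0),
                              true_window = c(25, 15), repeats = 5,
                              seed = 1) {
  set.seed(as.integer(seed))
  grid <- expand.grid(n = n_grid, r2 = r2_grid, cv = cv_grid)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]; r2 <- grid$r2[g]; k <- grid$cv[g]
    miscl <- logical(reps); r2hat <- numeric(reps)
    for (i in seq_len(reps)) {
      ds_seed <- sample.int(2^30, 1L)
      dat <- gen_dataset(n_records = n, true_window = true_window,
                         target_r2 = r2, seed = ds_seed)
      cv_seed <- sample.int(2^30, 1L)
      ms <- slidingwin(response ~ 1, dat$climate, dat$biol,
                       range = range, type = "relative",
                       k = k, seed = if (k > 0) cv_seed else NULL)
      rnd <- randwin(repeats, "sliding", response ~ 1, dat$climate,
                     dat$biol, seed = sample.int(2^30, 1L),
                     range = range, type = "relative",
                     k = k)
      pc <- p_c(c_statistic(ms), rnd, n = n, cv = k > 0,
                orientation = "flipped")
      signal_called <- pc$value < 0.5
      miscl[i] <- if (r2 > 0) !signal_called else signal_called
      r2hat[i] <- ms$best_r_squared
    }
    out[[g]] <- data.frame(n = n, r2 = r2, cv = k,
                           misclass_rate = mean(miscl),
                           median_r2_hat = stats::median(r2hat),
                           reps = reps)
  }
  do.call(rbind, out)
}
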