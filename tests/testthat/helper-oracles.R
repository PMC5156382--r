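# Independent oracles and small fixtures. The oracles deliberately avoid
# the package's internal machinery: windows are re-sliced from the raw
# daily series and fitted with stats::lm / stats::glm, with AICc taken
# from logLik() directly.

# tiny deterministic daily series around a set of measurement dates
make_fixture <- function(n_records = 8, range_max = 12, seed = 1,
                         lead = 40) {
  set.seed(seed)
  mdates <- as.integer(as.Date("2000-06-01")) + (seq_len(n_records) - 1L) * 365L
  all_days <- (min(mdates) - lead):max(mdates)
  clim <- climate_series(all_days, stats::rnorm(length(all_days)))
  list(clim = clim, mdates = mdates)
}

oracle_aicc <- function(model) {
  ll <- stats::logLik(model)
  rho <- attr(ll, "df")
  n <- stats::nobs(model)
  -2 * as.numeric(ll) + 2 * rho + 2 * rho * (rho + 1) / (n - rho - 1)
}

# slice mean/max/min/sum/slope from the raw series for one record
oracle_aggregate <- function(clim, date, start, end, stat) {
  days <- (date - start):(date - end)
  v <- clim$value[match(days, clim$date)]
  switch(stat,
         mean = mean(v), sum = sum(v), max = max(v), min = min(v),
         slope = if (length(v) == 1L) 0 else
           unname(stats::coef(stats::lm(v ~ days))[2L]))
}

# full naive sliding-window run: per-window refit with stats::lm/glm
oracle_sliding <- function(clim, biol, rmax, rmin, stat = "mean",
                           func = "lin", family = stats::gaussian()) {
  fam <- if (is.function(family)) family() else family
  df <- as.data.frame(biol)
  base <- stats::glm(response ~ 1, data = df, family = fam)
  rows <- list()
  for (s in rmax:rmin) for (e in s:rmin) {
    x <- vapply(df$date, function(d)
      oracle_aggregate(clim, d, s, e, stat), numeric(1))
    df$x <- x
    m <- switch(func,
                lin = stats::glm(response ~ 1 + x, data = df, family = fam),
                quad = stats::glm(response ~ 1 + x + I(x^2), data = df,
                                  family = fam),
                log = stats::glm(response ~ 1 + log(x), data = df,
                                 family = fam))
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = e,
      delta = oracle_aicc(m) - oracle_aicc(base),
      beta = unname(stats::coef(m)[2L]))
  }
  do.call(rbind, rows)
}

# a dataset with an exact (noise-free unless sd > 0) linear window signal
make_signal_data <- function(n_records = 20, true_start = 10, true_end = 4,
                             beta = 2, noise_sd = 0, seed = 3, lead = 60) {
  set.seed(seed)
  mdates <- as.integer(as.Date("1990-05-15")) + (seq_len(n_records) - 1L) * 365L
  all_days <- (min(mdates) - lead):max(mdates)
  clim <- climate_series(all_days, stats::rnorm(length(all_days)))
  m <- vapply(mdates, function(d)
    mean(clim$value[match((d - true_start):(d - true_end), clim$date)]),
    numeric(1))
  y <- 5 + beta * m + stats::rnorm(n_records, sd = noise_sd)
  list(clim = clim, biol = biol_table(mdates, y))
}
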