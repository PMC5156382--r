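#' Enumerate all candidate climate windows in a range
#'
#' Lists every window `(start, end)` with
#' `range_min <= end <= start <= range_max`, in deterministic order (start
#' descending, then end descending). With `m = range_max - range_min + 1`
#' offsets the count is `m (m + 1) / 2`; a full year (`range = c(365, 0)`)
#' yields 67,161 candidate windows.
#'
#' @param range integer vector `c(range_max, range_min)` in cinterval units.
#' @return data frame with integer columns `start` and `end`.
#' @export
enumerate_windows <- function(range) {
  rmax <- as.integer(range[1L]); rmin <- as.integer(range[2L])
  if (is.na(rmax) || is.na(rmin) || rmin < 0L) {
    stop("window offsets must be non-negative integers", call. = FALSE)
  }
  if (rmax < rmin) stop("range_max must be >= range_min", call. = FALSE)
  starts <- rmax:rmin
  ends <- sequence(starts - rmin + 1L, from = starts, by = -1L)
  data.frame(start = rep.int(starts, starts - rmin + 1L), end = ends)
}

#' Exhaustive sliding-window analysis
#'
#' Fits the baseline model with the aggregated climate of every candidate
#' window appended, ranks all windows by ΔAICc (ascending; most negative =
#' strongest climate support), and returns the full model set. Optionally
#' computes k-fold cross-validated ΔAICc per window (gaussian responses
#' only), in which case the cross-validated value is the ranking metric
#' while coefficients still come from full-data fits.
#'
#' Windows whose model cannot be fitted (e.g. `log` of a non-positive
#' aggregate, collinear climate) are retained as flagged records with
#' `delta_aicc = NA`, so the set always has `m (m + 1) / 2` rows.
#' Ties on ΔAICc are broken towards the shorter window, then the later
#' (smaller-offset) end.
#'
#' @param baseline model formula for the climate-free baseline (or a
#'   `cw_fit` from [fit_baseline()] fitted on `biol`).
#' @param climate a [climate_series()] (or data frame with a date column
#'   and one climate column).
#' @param biol a [biol_table()] (or data frame with a date column, the
#'   response, and any covariates/group).
#' @param family model family; gaussian, poisson, or binomial.
#' @param range `c(range_max, range_min)` in `cinterval` units.
#' @param stat aggregate statistic over the window (see
#'   [aggregate_window()]).
#' @param func functional form of the climate effect (see
#'   [attach_climate()]).
#' @param type `"relative"` (windows before each record's own date) or
#'   `"absolute"` (before a fixed reference date each year).
#' @param refday `c(day, month)` reference date; required for absolute.
#' @param k number of cross-validation folds (0 = off; otherwise
#'   `2 <= k <= N`).
#' @param centre name of the group column in `biol` for within-group
#'   centring (linear form only), or `NULL`.
#' @param cinterval resolution of window units: `"day"`, `"week"`, or
#'   `"month"`.
#' @param seed integer seed for fold assignment; required when `k > 0`.
#' @return a `window_modelset`: list with the ranked `dataset` data frame
#'   (`window_start`, `window_end`, `delta_aicc`, `beta`, `se`,
#'   `mod_weight`, ...), the run `config`, `baseline` fit and its AICc,
#'   the refitted `best_model`, `best_climate` vector, and (gaussian) the
#'   best model's R^2.
#' @export
slidingwin <- function(baseline, climate, biol, family = stats::gaussian(),
                       range = c(365, 0), stat = "mean", func = "lin",
                       type = c("relative", "absolute"), refday = NULL,
                       k = 0, centre = NULL,
                       cinterval = c("day", "week", "month"), seed = NULL) {
  type <- match.arg(type)
  cinterval <- match.arg(cinterval)
  prep <- prepare_inputs(baseline, climate, biol, family, range, type,
                         refday, cinterval, centre)
  base <- prep$base
  n <- base$nobs

  k <- as.integer(k)
  if (k != 0L) {
    if (base$family != "gaussian") {
      stop("cross-validation requires a gaussian response (MSE-based AICc)",
           call. = FALSE)
    }
    if (k < 2L || k > n) stop("need 2 <= k <= N (k = ", k, ", N = ", n, ")",
                              call. = FALSE)
    if (is.null(seed)) stop("k-fold cross-validation requires a seed",
                            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  wins <- enumerate_windows(range)
  A <- aggregate_all_windows(prep$cmat, wins, stat)

  folds <- if (k > 0L) sample(rep(seq_len(k), length.out = n)) else NULL

  fast <- base$family == "gaussian" && func == "lin" && is.null(centre)
  if (fast) {
    full <- fast_ols_scan(base, A)
    res <- data.frame(delta_aicc = full$delta, beta = full$beta,
                      se = full$se)
    if (k > 0L) res$delta_aicc <- fast_cv_scan(base, A, folds)
  } else {
    res <- general_scan(base, A, func, prep$centred_group, k, folds)
  }

  dataset <- data.frame(window_start = wins$start, window_end = wins$end,
                        res, flag = ifelse(is.na(res$delta_aicc),
                                           "not_fitted", ""))
  n_flag <- sum(is.na(dataset$delta_aicc))
  if (n_flag > 0L) {
    warning(n_flag, " window(s) could not be fitted and are flagged",
            call. = FALSE)
  }
  ord <- order(dataset$delta_aicc,
               dataset$window_start - dataset$window_end,
               dataset$window_end, na.last = TRUE)
  dataset <- dataset[ord, , drop = FALSE]
  rownames(dataset) <- NULL
  dataset$mod_weight <- akaike_weights(dataset$delta_aicc)

  best_climate <- A[, ord[1L]]
  centred <- if (!is.null(centre)) centre_split(best_climate,
                                                prep$centred_group)
  best_model <- attach_climate(base, best_climate,
                               func = if (is.null(centre)) func else "lin",
                               centred = centred)
  structure(list(
    dataset = dataset,
    config = list(range = range, stat = stat, func = func, type = type,
                  refday = refday, k = k, centre = centre,
                  cinterval = cinterval, seed = seed,
                  family = base$family,
                  formula = deparse(base$formula)),
    baseline = base, baseline_aicc = aicc(base),
    best_model = best_model, best_climate = best_climate,
    best_r_squared = best_model$r_squared,
    n_windows = nrow(dataset)),
    class = "window_modelset")
}

#' @export
print.window_modelset <- function(x, n = 5L, ...) {
  cat("<window_modelset> ", x$n_windows, " windows (", x$config$stat, "/",
      x$config$func, ", ", x$config$type, ", range ",
      x$config$range[1L], "-", x$config$range[2L], " ", x$config$cinterval,
      if (x$config$k > 0) paste0(", ", x$config$k, "-fold CV"), ")\n",
      sep = "")
  print(utils::head(x$dataset, n))
  invisible(x)
}

# ---- internal machinery -----------------------------------------------

prepare_inputs <- function(baseline, climate, biol, family, range, type,
                           refday, cinterval, centre) {
  if (!inherits(climate, "climate_series")) {
    climate <- as.data.frame(climate)
    climate <- climate_series(climate[[1L]], climate[[2L]],
                              varname = names(climate)[2L])
  }
  biol <- as.data.frame(biol)
  if (!"date" %in% names(biol)) {
    names(biol)[1L] <- "date"
  }
  bdates <- coerce_ordinal(biol$date)
  adjusted <- apply_reference(bdates, type, refday)

  rmax_units <- as.integer(range[1L])
  nd <- switch(cinterval,
               day = rmax_units,
               week = 7L * (rmax_units + 1L) - 1L,
               month = 31L * (rmax_units + 1L) - 1L)
  cmat <- climate_matrix(climate, adjusted, nd)
  if (cinterval != "day") {
    cmat <- collapse_cinterval(cmat, cinterval, adjusted)
    if (ncol(cmat) < rmax_units + 1L) {
      stop("climate span too short for ", rmax_units + 1L, " ",
           cinterval, " blocks", call. = FALSE)
    }
  }

  base <- if (inherits(baseline, "cw_fit")) baseline else
    fit_baseline(baseline, biol, family)
  if (base$nobs != nrow(cmat)) {
    stop("baseline rows do not match the biological records", call. = FALSE)
  }
  centred_group <- NULL
  if (!is.null(centre)) {
    if (!centre %in% names(biol)) {
      stop("centre column '", centre, "' not found in biol", call. = FALSE)
    }
    centred_group <- biol[[centre]]
  }
  list(base = base, cmat = cmat, adjusted = adjusted,
       centred_group = centred_group)
}

aggregate_all_windows <- function(cmat, wins, stat) {
  n <- nrow(cmat)
  if (stat %in% c("mean", "sum")) {
    P <- cmat
    for (j in seq_len(ncol(P))[-1L]) P[, j] <- P[, j] + P[, j - 1L]
    lo <- wins$end; hi <- wins$start
    A <- P[, hi + 1L, drop = FALSE] -
      cbind(0, P)[, lo + 1L, drop = FALSE]
    if (stat == "mean") A <- sweep(A, 2L, hi - lo + 1, "/")
    A <- matrix(A, nrow = n)
  } else {
    A <- matrix(NA_real_, nrow = n, ncol = nrow(wins))
    for (w in seq_len(nrow(wins))) {
      A[, w] <- aggregate_window(cmat, wins$start[w], wins$end[w], stat)
    }
  }
  A
}

# Exact OLS over all windows at once: residualize the response and every
# window aggregate against the baseline design; adding one regressor then
# reduces the RSS by (x~'y~)^2 / x~'x~.
fast_ols_scan <- function(base, A) {
  n <- base$nobs
  qrX <- qr(base$X)
  Q <- qr.Q(qrX)
  y <- as.numeric(base$y)
  yres <- y - Q %*% crossprod(Q, y)
  Ares <- A - Q %*% crossprod(Q, A)
  sxy <- drop(crossprod(Ares, yres))
  sxx <- colSums(Ares^2)
  rss_base <- sum(yres^2)
  ok <- sxx > 1e-10 * max(mean(colSums(A^2)), 1)
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- pmax(rss_base - ifelse(ok, sxy^2 / sxx, NA_real_), 1e-300)
  p <- base$rank
  rho_m <- p + 2L
  logL <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  delta <- aicc_value(logL, rho_m, n) - aicc(base)
  sigma2 <- rss / (n - p - 1L)
  se <- sqrt(sigma2 / sxx)
  list(delta = delta, beta = beta, se = ifelse(ok, se, NA_real_))
}

# Vectorized k-fold CV for the gaussian linear case. Per fold, training
# coefficients for [X, a_w] follow from residualization; test MSE feeds the
# MSE-based AICc with N = total sample size.
fast_cv_scan <- function(base, A, folds) {
  n <- base$nobs
  X <- base$X
  y <- as.numeric(base$y)
  k <- max(folds)
  W <- ncol(A)
  p <- base$rank
  rho_m <- p + 2L
  rho_b <- p + 1L
  nlmse <- matrix(NA_real_, k, W)
  nlmse_b <- numeric(k)
  for (f in seq_len(k)) {
    S <- which(folds == f); Tr <- which(folds != f)
    XT <- X[Tr, , drop = FALSE]; XS <- X[S, , drop = FALSE]
    qrT <- qr(XT)
    QT <- qr.Q(qrT)
    gamma0 <- qr.coef(qrT, y[Tr])
    G <- qr.coef(qrT, A[Tr, , drop = FALSE])
    yresT <- y[Tr] - QT %*% crossprod(QT, y[Tr])
    AresT <- A[Tr, , drop = FALSE] - QT %*% crossprod(QT, A[Tr, , drop = FALSE])
    sxy <- drop(crossprod(AresT, yresT))
    sxx <- colSums(AresT^2)
    bw <- ifelse(sxx > 1e-12 * max(mean(colSums(A^2)), 1), sxy / sxx,
                 NA_real_)
    predb <- drop(XS %*% gamma0)
    M2 <- XS %*% G
    pred <- predb + (A[S, , drop = FALSE] - M2) *
      matrix(bw, nrow = length(S), ncol = W, byrow = TRUE)
    mse <- colMeans((y[S] - pred)^2)
    nlmse[f, ] <- length(S) * log(pmax(mse, 1e-300))
    nlmse_b[f] <- length(S) * log(max(mean((y[S] - predb)^2), 1e-300))
  }
  pen_m <- 2 * rho_m + 2 * rho_m * (rho_m + 1) / (n - rho_m - 1)
  pen_b <- 2 * rho_b + 2 * rho_b * (rho_b + 1) / (n - rho_b - 1)
  colMeans(nlmse) + pen_m - (mean(nlmse_b) + pen_b)
}

general_scan <- function(base, A, func, centred_group, k, folds) {
  W <- ncol(A)
  delta <- beta <- se <- beta2 <- beta3 <- rep(NA_real_, W)
  has2 <- func %in% c("quad", "cub") || !is.null(centred_group)
  has3 <- func == "cub"
  for (w in seq_len(W)) {
    x <- A[, w]
    fit <- tryCatch({
      centred <- if (!is.null(centred_group)) centre_split(x, centred_group)
      attach_climate(base, x, func = if (is.null(centred_group)) func
                     else "lin", centred = centred)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    nb <- base$rank
    delta[w] <- delta_aicc(fit, base)
    beta[w] <- cf[nb + 1L]
    se[w] <- fit$se[nb + 1L]
    if (has2 && length(cf) >= nb + 2L) beta2[w] <- cf[nb + 2L]
    if (has3 && length(cf) >= nb + 3L) beta3[w] <- cf[nb + 3L]
    if (k > 0L && !is.na(delta[w])) {
      delta[w] <- tryCatch(
        cv_delta_aicc(base, x, func = func, k = k, folds = folds),
        error = function(e) NA_real_)
    }
  }
  out <- data.frame(delta_aicc = delta, beta = beta, se = se)
  if (has2) out$beta2 <- beta2
  if (has3) out$beta3 <- beta3
  out
}

#' k-fold cross-validated ΔAICc for one climate window
#'
#' Partitions the records into `k` near-equal folds. For each fold the
#' climate model and the baseline are fitted on the training rows, their
#' mean squared error is evaluated on the held-out rows, and each is scored
#' with the MSE-based corrected AIC (see [aicc_cv_value()]): the
#' likelihood term is scored over the held-out rows, the small-sample
#' penalty uses the total sample size. The per-fold differences (model
#' minus baseline) are averaged over folds. Gaussian responses only.
#'
#' @param base `cw_fit` baseline (gaussian).
#' @param climate aggregate climate vector for the window.
#' @param func functional form, as in [attach_climate()].
#' @param k number of folds, `2 <= k <= N`.
#' @param seed optional seed for the fold assignment.
#' @param folds optional explicit fold labels (overrides `seed`).
#' @return the cross-validated ΔAICc (mean over folds).
#' @seealso [aicc_cv_value()] for the MSE-based AICc formula.
#' @export
cv_delta_aicc <- function(base, climate, func = "lin", k, seed = NULL,
                          folds = NULL) {
  if (base$family != "gaussian") {
    stop("cross-validation requires a gaussian response", call. = FALSE)
  }
  n <- base$nobs
  k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= N", call. = FALSE)
  if (is.null(folds)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    folds <- sample(rep(seq_len(k), length.out = n))
  }
  if (any(tabulate(folds, k) == 0L)) stop("empty fold", call. = FALSE)
  terms <- climate_terms(climate, func)
  Xm <- cbind(base$X, terms)
  Xb <- base$X
  y <- as.numeric(base$y)
  rho_m <- ncol(Xm) + 1L
  rho_b <- ncol(Xb) + 1L
  dl <- numeric(k)
  for (f in seq_len(k)) {
    S <- which(folds == f); Tr <- which(folds != f)
    cm <- stats::lm.fit(Xm[Tr, , drop = FALSE], y[Tr])$coefficients
    cb <- stats::lm.fit(Xb[Tr, , drop = FALSE], y[Tr])$coefficients
    if (anyNA(cm) || anyNA(cb)) stop("rank-deficient training fit",
                                     call. = FALSE)
    mse_m <- mean((y[S] - drop(Xm[S, , drop = FALSE] %*% cm))^2)
    mse_b <- mean((y[S] - drop(Xb[S, , drop = FALSE] %*% cb))^2)
    dl[f] <- aicc_cv_value(mse_m, rho_m, n, n_lik = length(S)) -
      aicc_cv_value(mse_b, rho_b, n, n_lik = length(S))
  }
  mean(dl)
}

#' MSE-based corrected AIC used in cross-validation
#'
#' `n_lik log(MSE) + 2 rho + 2 rho (rho + 1) / (n - rho - 1)`. In the
#' per-fold computation the likelihood term is scored over the `n_lik`
#' held-out rows actually predicted, while the small-sample penalty keeps
#' the total sample size `n` (a penalty on fold size alone would be
#' undefined whenever a fold has fewer than `rho + 2` rows). Scoring the
#' likelihood on the smaller test set is what makes cross-validated
#' ΔAICc values markedly less negative than their full-data
#' counterparts.
#'
#' @param mse mean squared prediction error on the held-out rows.
#' @param rho number of estimated model parameters.
#' @param n total sample size (penalty term).
#' @param n_lik number of rows the MSE was computed over; defaults to
#'   `n`, giving the one-N form of the formula.
#' @export
aicc_cv_value <- function(mse, rho, n, n_lik = n) {
  if (n - rho - 1 <= 0) stop("need n > rho + 1", call. = FALSE)
  n_lik * log(mse) + 2 * rho + 2 * rho * (rho + 1) / (n - rho - 1)
}
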