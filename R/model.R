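#' Fit the climate-free baseline model
#'
#' Fits the user's baseline regression (gaussian, poisson, or binomial) by
#' maximum likelihood. The baseline contains covariates but no climate
#' term; climate aggregates are appended afterwards with
#' [attach_climate()], refitting on the identical rows.
#'
#' @param formula model formula, e.g. `response ~ 1` or
#'   `response ~ covariate`; must not contain a term named `climate`.
#' @param data data frame (typically a [biol_table()]).
#' @param family a [stats::family] object or its name; one of gaussian,
#'   poisson, binomial.
#' @return a `cw_fit` object: coefficients, standard errors,
#'   log-likelihood, parameter count `rho` (including the gaussian
#'   residual-variance parameter), `nobs`, fitted values, and the design
#'   matrix/response used, so climate terms can be appended on identical
#'   rows.
#' @export
fit_baseline <- function(formula, data, family = stats::gaussian()) {
  family <- resolve_family(family)
  tl <- attr(stats::terms(formula), "term.labels")
  if (any(grepl("\\bclimate\\b", tl))) {
    stop("baseline formula must not contain a term named 'climate'",
         call. = FALSE)
  }
  mf <- stats::model.frame(formula, data = as.data.frame(data),
                           na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  fit <- cw_glm(X, y, family)
  if (fit$rank < ncol(X)) stop("rank-deficient baseline design", call. = FALSE)
  if (fit$nobs < fit$rank + 2L) {
    stop("too few rows to fit the baseline (need >= rho + 2)", call. = FALSE)
  }
  fit$formula <- formula
  fit
}

resolve_family <- function(family) {
  if (is.character(family)) family <- get(family, mode = "function")()
  if (is.function(family)) family <- family()
  if (!inherits(family, "family")) stop("invalid family", call. = FALSE)
  if (!family$family %in% c("gaussian", "poisson", "binomial")) {
    stop("supported families: gaussian, poisson, binomial", call. = FALSE)
  }
  family
}

# Low-level ML fit on a design matrix. Gaussian uses least squares with the
# profile log-likelihood; other families go through glm.fit. rho counts the
# residual-variance parameter for gaussian (rank + 1), rank otherwise.
cw_glm <- function(X, y, family) {
  X <- as.matrix(X)
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite response", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite model term(s)", call. = FALSE)
  if (family$family == "gaussian") {
    fit <- stats::lm.fit(X, as.numeric(y))
    rank <- fit$rank
    rss <- sum(fit$residuals^2)
    logLik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    rho <- rank + 1L
    piv <- fit$qr$pivot[seq_len(rank)]
    Rinv <- chol2inv(fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE])
    sigma2 <- rss / max(n - rank, 1L)
    se <- rep(NA_real_, ncol(X))
    se[piv] <- sqrt(diag(Rinv) * sigma2)
    coefs <- fit$coefficients
    yc <- as.numeric(y) - mean(y)
    r2 <- if (sum(yc^2) > 0) 1 - rss / sum(yc^2) else NA_real_
    out <- list(coefficients = coefs, se = stats::setNames(se, colnames(X)),
                logLik = logLik, rho = rho, nobs = n, rank = rank,
                fitted = fit$fitted.values, residuals = fit$residuals,
                rss = rss, r_squared = r2, family = "gaussian", X = X, y = y)
  } else {
    fit <- stats::glm.fit(X, y, family = family)
    rank <- fit$rank
    logLik <- rank - fit$aic / 2
    rho <- rank
    se <- rep(NA_real_, ncol(X))
    ok <- seq_len(rank)
    covm <- chol2inv(fit$qr$qr[ok, ok, drop = FALSE])
    se[fit$qr$pivot[ok]] <- sqrt(diag(covm))
    out <- list(coefficients = fit$coefficients,
                se = stats::setNames(se, colnames(X)),
                logLik = logLik, rho = rho, nobs = n, rank = rank,
                fitted = fit$fitted.values,
                residuals = y - fit$fitted.values,
                rss = NA_real_, r_squared = NA_real_,
                family = family$family, X = X, y = y)
  }
  class(out) <- "cw_fit"
  out
}

#' @export
print.cw_fit <- function(x, ...) {
  cat("<cw_fit>", x$family, "fit,", x$nobs, "obs, rho =", x$rho,
      ", logLik =", format(x$logLik, digits = 6), "\n")
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Refit a baseline with climate terms appended
#'
#' Appends the aggregated climate variable to the baseline design under the
#' chosen functional form and refits on the identical rows:
#' `lin` adds one term, `quad` two (x, x^2), `cub` three, `log` one
#' (natural log), `inv` one (1/x). With `centred`, the single linear term
#' is replaced by the within-group deviation and the group mean.
#'
#' @param base a `cw_fit` from [fit_baseline()].
#' @param climate numeric aggregate vector, one value per baseline row.
#' @param func functional form: `"lin"`, `"quad"`, `"cub"`, `"log"`, `"inv"`.
#' @param centred optional list as returned by [centre_split()]; implies a
#'   linear form with separate within- and between-group terms.
#' @return a `cw_fit` for the climate model.
#' @export
attach_climate <- function(base, climate,
                           func = c("lin", "quad", "cub", "log", "inv"),
                           centred = NULL) {
  stopifnot(inherits(base, "cw_fit"))
  func <- match.arg(func)
  if (!is.null(centred)) {
    extra <- cbind(climate_dev = centred$deviation,
                   climate_gmean = centred$mean)
  } else {
    if (length(climate) != base$nobs) {
      stop("climate vector length must equal the number of rows (",
           base$nobs, ")", call. = FALSE)
    }
    extra <- climate_terms(climate, func)
  }
  fam <- switch(base$family, gaussian = stats::gaussian(),
                poisson = stats::poisson(), binomial = stats::binomial())
  fit <- cw_glm(cbind(base$X, extra), base$y, fam)
  if (fit$rank < ncol(base$X) + ncol(extra)) {
    stop("climate term is collinear with the baseline design ",
         "(rank-deficient fit)", call. = FALSE)
  }
  fit
}

climate_terms <- function(climate, func) {
  if (func %in% c("log", "inv") && any(climate <= 0)) {
    stop("func = '", func, "' requires strictly positive climate values",
         call. = FALSE)
  }
  switch(func,
    lin  = cbind(climate = climate),
    quad = cbind(climate = climate, climate_sq = climate^2),
    cub  = cbind(climate = climate, climate_sq = climate^2,
                 climate_cub = climate^3),
    log  = cbind(climate_log = log(climate)),
    inv  = cbind(climate_inv = 1 / climate))
}

#' Sample-size corrected AIC
#'
#' AICc = -2 logL + 2 rho + 2 rho (rho + 1) / (N - rho - 1), where rho is
#' the number of estimated parameters (including the gaussian residual
#' variance) and N the number of observations.
#'
#' @param fit a `cw_fit`, or anything with `logLik`, `rho`, `nobs` fields.
#' @return the AICc value.
#' @seealso [aicc_value()] for the bare formula.
#' @export
aicc <- function(fit) {
  aicc_value(fit$logLik, fit$rho, fit$nobs)
}

#' @rdname aicc
#' @param logLik maximized log-likelihood.
#' @param rho number of estimated parameters.
#' @param n number of observations; must exceed `rho + 1`.
#' @export
aicc_value <- function(logLik, rho, n) {
  if (n - rho - 1 <= 0) {
    stop("AICc undefined: need n > rho + 1 (n = ", n, ", rho = ", rho, ")",
         call. = FALSE)
  }
  -2 * logLik + 2 * rho + 2 * rho * (rho + 1) / (n - rho - 1)
}

#' AICc difference between a climate model and its baseline
#'
#' `delta_aicc = AICc(model) - AICc(baseline)`. Negative values mean the
#' climate model improves on the baseline; candidate windows are ranked
#' ascending so the best (most negative) window comes first.
#'
#' @param model,baseline `cw_fit` objects fitted on identical rows.
#' @return numeric ΔAICc.
#' @export
delta_aicc <- function(model, baseline) {
  if (model$nobs != baseline$nobs ||
      !isTRUE(all.equal(as.numeric(model$y), as.numeric(baseline$y)))) {
    stop("model and baseline must be fitted on identical rows", call. = FALSE)
  }
  aicc(model) - aicc(baseline)
}
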