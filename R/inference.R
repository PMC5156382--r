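#' Akaike model weights
#'
#' `w_i = exp(-0.5 (ΔAICc_i - min ΔAICc)) / sum_j exp(-0.5 (ΔAICc_j - min))`,
#' the probability that window i is the best model in the set. Non-finite
#' entries (flagged windows) receive weight `NA` and the remaining weights
#' are renormalized to sum to 1.
#'
#' @param delta_aiccs numeric vector of ΔAICc values.
#' @return numeric weight vector of the same length.
#' @export
akaike_weights <- function(delta_aiccs) {
  if (length(delta_aiccs) == 0L) stop("empty model set", call. = FALSE)
  ok <- is.finite(delta_aiccs)
  if (!any(ok)) stop("no finite delta AICc values", call. = FALSE)
  rel <- delta_aiccs[ok] - min(delta_aiccs[ok])
  w <- exp(-0.5 * rel)
  out <- rep(NA_real_, length(delta_aiccs))
  out[ok] <- w / sum(w)
  out
}

#' Confidence set of candidate windows
#'
#' The longest prefix of the ΔAICc-sorted model set whose cumulative
#' Akaike weight does not exceed `level`; the record that crosses the
#' level is excluded. If the single best window alone exceeds the level,
#' the set is that one window, so the set is never empty.
#'
#' @param modelset a `window_modelset` from [slidingwin()] (or its
#'   `dataset` data frame, sorted ascending by `delta_aicc` with a
#'   `mod_weight` column).
#' @param level cumulative-weight level in (0, 1); default 0.95.
#' @return the subset of candidate-window rows in the confidence set.
#' @export
confidence_set <- function(modelset, level = 0.95) {
  ds <- modelset_dataset(modelset)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  w <- ds$mod_weight
  cw <- cumsum(ifelse(is.na(w), 0, w))
  keep <- which(cw <= level + 1e-9)  # tolerance for accumulated rounding
  if (length(keep) == 0L) keep <- 1L
  ds[keep, , drop = FALSE]
}

modelset_dataset <- function(modelset) {
  if (inherits(modelset, "window_modelset")) return(modelset$dataset)
  as.data.frame(modelset)
}

#' C statistic: percentage of windows in the confidence set
#'
#' A small C indicates a concentrated, credible climate signal; on
#' signal-free data the confidence set spreads over most of the candidate
#' windows and C is large.
#'
#' @inheritParams confidence_set
#' @param scale `"percent"` (default) or `"proportion"`.
#' @return the size of the level-confidence set as a percentage (or
#'   proportion) of all candidate windows.
#' @export
c_statistic <- function(modelset, level = 0.95,
                        scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  ds <- modelset_dataset(modelset)
  frac <- nrow(confidence_set(ds, level)) / nrow(ds)
  if (scale == "percent") 100 * frac else frac
}

#' Model-averaged climate slope
#'
#' Sum of per-window slopes weighted by their Akaike weights as computed
#' over the full model set (weights are deliberately not renormalized
#' within the subset).
#'
#' @param set a subset of candidate-window rows (e.g. from
#'   [confidence_set()]) with `beta` and `mod_weight` columns.
#' @return the averaged slope.
#' @export
model_average <- function(set) {
  set <- as.data.frame(set)
  if (nrow(set) == 0L) stop("empty model set", call. = FALSE)
  sum(set$beta * set$mod_weight, na.rm = TRUE)
}

#' Median window of the confidence set
#'
#' Akaike-weight-weighted median of the start offsets and of the end
#' offsets within the level-confidence set: the smallest value whose
#' cumulative within-set weight reaches half the set's total weight. A
#' plain (unweighted) median is available via `weighted = FALSE`.
#'
#' @inheritParams confidence_set
#' @param weighted use Akaike weights (default) or the plain median.
#' @return named numeric vector `c(start, end)`.
#' @export
medwin <- function(modelset, level = 0.95, weighted = TRUE) {
  cs <- confidence_set(modelset, level)
  med1 <- function(v, w) {
    if (!weighted) return(stats::median(v))
    o <- order(v)
    v <- v[o]; w <- w[o]
    w[is.na(w)] <- 0
    cw <- cumsum(w) / sum(w)
    v[which(cw >= 0.5)[1L]]
  }
  c(start = med1(cs$window_start, cs$mod_weight),
    end = med1(cs$window_end, cs$mod_weight))
}

#' Randomization null distribution of the window analysis
#'
#' Repeatedly permutes the biological date column (responses and
#' covariates stay attached to their rows, climate autocorrelation is
#' preserved) and reruns the full analysis, recording the best ΔAICc of
#' each rerun and, for sliding windows, the C statistic. The resulting
#' null distribution feeds [p_delta_aicc()] and [p_c()]. A permutation
#' identical to the original ordering is redrawn once and then accepted.
#'
#' @param repeats number of randomized reruns (>= 1); large values
#'   (e.g. 1000) give the most reliable null distribution, 5-10 suffice
#'   for the logistic-calibrated [p_c()].
#' @param window `"sliding"` or `"weighted"`.
#' @param baseline,climate,biol,family as in [slidingwin()].
#' @param seed integer seed controlling all permutations (and CV folds).
#' @param level confidence-set level used for the C statistic.
#' @param ... further arguments passed to [slidingwin()] or [weightwin()]
#'   (range, stat, func, type, refday, k, weightfunc, par0, ...).
#' @return a `window_randset` data frame with columns `rep`,
#'   `best_delta_aicc`, and for sliding runs `c_pct` (C in percent).
#' @export
randwin <- function(repeats, window = c("sliding", "weighted"),
                    baseline, climate, biol, family = stats::gaussian(),
                    seed = NULL, level = 0.95, ...) {
  window <- match.arg(window)
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  biol <- as.data.frame(biol)
  if (!"date" %in% names(biol)) names(biol)[1L] <- "date"
  n <- nrow(biol)
  dots <- list(...)
  best <- cpct <- rep(NA_real_, repeats)
  for (r in seq_len(repeats)) {
    perm <- sample.int(n)
    if (identical(perm, seq_len(n))) perm <- sample.int(n)
    b2 <- biol
    b2$date <- biol$date[perm]
    args <- c(list(b2, family = family), dots)
    args <- c(list(baseline, climate), args)
    if (window == "sliding" && !is.null(dots$k) && dots$k > 0 &&
        is.null(dots$seed)) {
      args$seed <- sample.int(2^30, 1L)
    }
    res <- if (window == "sliding") {
      suppressWarnings(do.call(slidingwin, args))
    } else {
      suppressWarnings(do.call(weightwin, args))
    }
    if (window == "sliding") {
      best[r] <- res$dataset$delta_aicc[1L]
      cpct[r] <- c_statistic(res, level)
    } else {
      best[r] <- res$delta_aicc
    }
  }
  out <- data.frame(rep = seq_len(repeats), best_delta_aicc = best)
  if (window == "sliding") out$c_pct <- cpct
  structure(out, window = window, seed = seed, level = level,
            class = c("window_randset", "data.frame"))
}

#' Rank-based randomization P-value for ΔAICc
#'
#' The continuity-corrected rank of the observed best ΔAICc within the
#' randomized null distribution: `(r + 1) / (repeats + 1)` with
#' `r = #\{randomized best ΔAICc <= observed\}`, so the value is never
#' exactly 0; when no randomized value is as negative as the observed one
#' the report is labelled `< 1/(repeats+1)`.
#'
#' @param observed observed best ΔAICc.
#' @param rand a `window_randset` from [randwin()].
#' @return a `pvalue_report` with fields `metric`, `value`, `label`, and
#'   the inputs used.
#' @export
p_delta_aicc <- function(observed, rand) {
  d <- rand$best_delta_aicc
  d <- d[is.finite(d)]
  nrep <- length(d)
  if (nrep < 1L) stop("randomization set is empty", call. = FALSE)
  if (nrep < 20L) {
    warning("fewer than 20 randomizations; P_dAICc is imprecise ",
            "(consider p_c for few repeats)", call. = FALSE)
  }
  r <- sum(d <= observed)
  value <- (r + 1) / (nrep + 1)
  label <- if (r == 0L) sprintf("< %.3g", 1 / (nrep + 1)) else
    format(value, digits = 3)
  structure(list(metric = "P_dAICc", value = value, label = label,
                 inputs = list(observed = observed, repeats = nrep)),
            class = "pvalue_report")
}

#' Logistic-calibrated P-value from the C statistic
#'
#' Evaluates the logistic calibration that maps ΔC (observed C minus the
#' median randomized C, on the proportion scale) and sample size N to the
#' probability that an observed result is spurious. Without
#' cross-validation the exponent is
#' `-0.54 + 1.95 ΔC + 0.08 N + 0.31 ΔC N`; with 10-fold cross-validation
#' it is `-0.62 + 11.56 ΔC + 0.06 N + 6.88 ΔC N`, and the value is
#' `1 / (1 + exp(exponent))`.
#'
#' The printed form of this calibration has a counter-intuitive
#' orientation: evaluated verbatim it approaches 1, not 0, for strong
#' signals. `orientation = "flipped"` reports the complement
#' `1 / (1 + exp(-exponent))`, which behaves as "probability the signal is
#' spurious" (small for strong signals) and is the orientation used by the
#' classification machinery in [performance_study()]. See the package
#' vignette for the full discussion. ΔD (observed minus median randomized
#' best ΔAICc) is reported alongside as a diagnostic when the observed
#' ΔAICc is supplied.
#'
#' @param observed_c observed C statistic.
#' @param rand a `window_randset` with the `c_pct` column (sliding runs;
#'   >= 5 repeats recommended).
#' @param n sample size of the analysed dataset.
#' @param cv `TRUE` if the analysis used 10-fold cross-validation.
#' @param orientation `"verbatim"` (default) or `"flipped"`.
#' @param scale scale of `observed_c`: `"percent"` (default, matching
#'   [c_statistic()]) or `"proportion"`.
#' @param observed_delta optional observed best ΔAICc for the ΔD
#'   diagnostic.
#' @return a `pvalue_report` with `value`, `delta_c`, and optionally
#'   `delta_d`.
#' @export
p_c <- function(observed_c, rand, n, cv = FALSE,
                orientation = c("verbatim", "flipped"),
                scale = c("percent", "proportion"),
                observed_delta = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (is.null(rand$c_pct)) {
    stop("randomization set has no C statistic (weighted-window runs ",
         "cannot feed p_c)", call. = FALSE)
  }
  obs <- if (scale == "percent") observed_c / 100 else observed_c
  crand <- rand$c_pct / 100
  if (sum(is.finite(crand)) < 1L) stop("no C values in randomization set",
                                       call. = FALSE)
  dC <- obs - stats::median(crand, na.rm = TRUE)
  eta <- if (cv) {
    -0.62 + 11.56 * dC + 0.06 * n + 6.88 * dC * n
  } else {
    -0.54 + 1.95 * dC + 0.08 * n + 0.31 * dC * n
  }
  value <- if (orientation == "verbatim") 1 / (1 + exp(eta)) else
    1 / (1 + exp(-eta))
  dD <- if (!is.null(observed_delta)) {
    observed_delta - stats::median(rand$best_delta_aicc, na.rm = TRUE)
  }
  structure(list(metric = "P_C", value = value, delta_c = dC,
                 delta_d = dD,
                 inputs = list(observed_c = obs, n = n, cv = cv,
                               orientation = orientation,
                               repeats = nrow(rand))),
            class = "pvalue_report")
}

#' @export
print.pvalue_report <- function(x, ...) {
  lab <- if (!is.null(x$label)) x$label else format(x$value, digits = 3)
  cat("<pvalue_report> ", x$metric, " = ", lab, sep = "")
  if (!is.null(x$delta_c)) cat(sprintf(" (delta_C = %.3f)", x$delta_c))
  if (!is.null(x$delta_d)) cat(sprintf(" (delta_D = %.2f)", x$delta_d))
  cat("\n")
  invisible(x)
}
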