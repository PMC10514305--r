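# In vitro permeability assay analysis: initial velocities from
# absorbance time courses, V0 vs [NaCl] regression, slope comparison
# between intact (native) and sonication-broken compartments, and
# broken/native V0 ratios with compounded error.

#' Initial velocity of product formation
#'
#' Ordinary least-squares slope of absorbance vs time over an early-time
#' window.  The default window policy takes the longest initial prefix
#' (minimum `min_points` points) whose linear fit has R^2 >= `r2_min`;
#' when no prefix reaches the threshold (noisy data cap attainable R^2),
#' the prefix maximizing R^2 is used.  A fixed window can be forced with
#' `window = "fixed"`.
#'
#' @param time_s Time points (s), strictly increasing.
#' @param a280 Absorbance values, same length, >= 4 points.
#' @param window `"r2_prefix"` (default) or `"fixed"`.
#' @param min_points Minimum window length (default 5).
#' @param r2_min R^2 threshold for the prefix policy (default 0.99).
#' @param fixed_window Index range `c(first, last)` for `window = "fixed"`.
#' @return A `pw_velocity`: list with `v0` (absorbance/s), `se`, `window`
#'   (index range used), `r2`, `n`.
#' @export
initial_velocity <- function(time_s, a280, window = c("r2_prefix", "fixed"),
                             min_points = 5L, r2_min = 0.99,
                             fixed_window = NULL) {
  window <- match.arg(window)
  n <- length(time_s)
  if (n < 4L) stop("input error: need at least 4 points")
  if (length(a280) != n) stop("time and absorbance lengths differ")
  if (is.unsorted(time_s, strictly = TRUE))
    stop("input error: times must be strictly increasing")
  if (window == "fixed") {
    if (is.null(fixed_window)) stop("fixed_window required")
    k <- fixed_window[1]:fixed_window[2]
    if (k[1] < 1 || k[length(k)] > n) stop("fixed window outside series")
    return(ols_velocity(time_s[k], a280[k], c(fixed_window[1], fixed_window[2])))
  }
  min_points <- max(min_points, 2L)
  ks <- min_points:n
  r2s <- vapply(ks, function(k) prefix_r2(time_s[1:k], a280[1:k]), 1)
  hit <- which(r2s >= r2_min)
  k <- if (length(hit)) ks[max(hit)] else ks[which.max(r2s)]
  ols_velocity(time_s[1:k], a280[1:k], c(1L, k))
}

prefix_r2 <- function(t, y) {
  if (stats::var(y) < .Machine$double.eps) return(1)   # flat: fit is exact
  f <- stats::lm.fit(cbind(1, t), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

ols_velocity <- function(t, y, win) {
  n <- length(t)
  if (stats::var(y) < .Machine$double.eps)
    return(structure(list(v0 = 0, se = 0, window = win, r2 = 1, n = n),
                     class = "pw_velocity"))
  fit <- stats::lm(y ~ t)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  structure(list(v0 = unname(sm$coefficients["t", "Estimate"]),
                 se = unname(sm$coefficients["t", "Std. Error"]),
                 window = win, r2 = sm$r.squared, n = n),
            class = "pw_velocity")
}

#' @export
print.pw_velocity <- function(x, ...) {
  cat(sprintf("V0 = %.4g +/- %.2g A/s (window %d..%d, R^2 %.4f)\n",
              x$v0, x$se, x$window[1], x$window[2], x$r2))
  invisible(x)
}

#' Initial velocities for a whole assay table
#'
#' Fits [initial_velocity()] per (condition, state, replicate) series,
#' then (by default) averages replicates to one V0 +/- SE per
#' condition/state, SE = sample SD / sqrt(replicates).
#'
#' @param data Data frame with columns `time_s`, `a280`, `nacl_mM`,
#'   `state`, `replicate`.
#' @param collapse_replicates Average replicate V0s per condition/state
#'   (default TRUE; the alternative keeps one row per replicate with the
#'   per-fit SE).
#' @param ... Passed to [initial_velocity()].
#' @return Data frame with `nacl_mM`, `state`, `v0`, `se`, `n`.
#' @export
fit_initial_velocities <- function(data, collapse_replicates = TRUE, ...) {
  need <- c("time_s", "a280", "nacl_mM", "state", "replicate")
  if (!all(need %in% names(data)))
    stop("assay table missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  key <- interaction(data$nacl_mM, data$state, data$replicate, drop = TRUE)
  per <- do.call(rbind, lapply(split(data, key), function(d) {
    d <- d[order(d$time_s), ]
    v <- initial_velocity(d$time_s, d$a280, ...)
    data.frame(nacl_mM = d$nacl_mM[1], state = d$state[1],
               replicate = d$replicate[1], v0 = v$v0, se = v$se,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  if (!collapse_replicates) return(per)
  key2 <- interaction(per$nacl_mM, per$state, drop = TRUE)
  out <- do.call(rbind, lapply(split(per, key2), function(d) {
    data.frame(nacl_mM = d$nacl_mM[1], state = d$state[1],
               v0 = mean(d$v0),
               se = if (nrow(d) > 1) stats::sd(d$v0) / sqrt(nrow(d)) else d$se[1],
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$state, out$nacl_mM), ]
  rownames(out) <- NULL
  out
}

#' Linear regression of V0 against salt concentration
#'
#' OLS of V0 on [NaCl] restricted to points inside `range_mM` (inclusive).
#'
#' @param points Data frame with columns `nacl_mM` and `v0` (e.g. one
#'   state's rows from [fit_initial_velocities()]).
#' @param range_mM Inclusive concentration window, default `c(100, 500)`.
#' @return A `pw_saltfit`: list with `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `n`, `df`, `r2`, `range_mM`.
#' @export
regress_v0_vs_salt <- function(points, range_mM = c(100, 500)) {
  keep <- points$nacl_mM >= range_mM[1] & points$nacl_mM <= range_mM[2]
  d <- points[keep, ]
  if (nrow(d) < 3L)
    stop("input error: need >= 3 points inside the regression range")
  fit <- stats::lm(v0 ~ nacl_mM, data = d)
  sm <- suppressWarnings(summary(fit))   # collinear inputs are legitimate
  structure(list(slope = unname(sm$coefficients["nacl_mM", "Estimate"]),
                 slope_se = unname(sm$coefficients["nacl_mM", "Std. Error"]),
                 intercept = unname(sm$coefficients["(Intercept)", "Estimate"]),
                 intercept_se = unname(sm$coefficients["(Intercept)", "Std. Error"]),
                 n = nrow(d), df = fit$df.residual,
                 r2 = sm$r.squared, range_mM = range_mM),
            class = "pw_saltfit")
}

#' @export
print.pw_saltfit <- function(x, ...) {
  cat(sprintf("V0 ~ [NaCl]: slope %.4g +/- %.2g per mM, intercept %.4g (n=%d, R^2 %.3f)\n",
              x$slope, x$slope_se, x$intercept, x$n, x$r2))
  invisible(x)
}

#' Compare two V0-vs-salt slopes
#'
#' Two-sided t test on the difference of independent OLS slopes:
#' `t = (slope_a - slope_b) / sqrt(se_a^2 + se_b^2)` with
#' `df = n_a + n_b - 4` (equivalent to the interaction term of an
#' ANCOVA with separate intercepts).
#'
#' @param fit_a,fit_b `pw_saltfit`s.
#' @return A `pw_slope_comparison`: list with `slope_a`, `slope_b`,
#'   `difference`, `se_difference`, `t`, `df`, `p_value`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "pw_saltfit"), inherits(fit_b, "pw_saltfit"))
  diff <- fit_a$slope - fit_b$slope
  se <- sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
  df <- fit_a$n + fit_b$n - 4L
  if (se == 0) {
    tval <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    tval <- diff / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(slope_a = fit_a$slope, slope_b = fit_b$slope,
                 difference = diff, se_difference = se,
                 t = tval, df = df, p_value = p),
            class = "pw_slope_comparison")
}

#' @export
print.pw_slope_comparison <- function(x, ...) {
  cat(sprintf("slope difference %.4g +/- %.2g, t = %.3f (df %d), p = %.3g\n",
              x$difference, x$se_difference, x$t, x$df, x$p_value))
  invisible(x)
}

#' Broken/native V0 ratio with compounded error
#'
#' Ratio of two velocity estimates with first-order error propagation:
#' `SE = ratio * sqrt((se_b/b)^2 + (se_n/n)^2)`.
#'
#' @param broken,native Each a `pw_velocity`, or a list/vector with
#'   elements `v0` and `se`.
#' @return List with `ratio` and `se`.
#' @export
v0_ratio <- function(broken, native) {
  b <- broken[["v0"]]; sb <- broken[["se"]]
  n <- native[["v0"]]; sn <- native[["se"]]
  if (n == 0) stop("undefined ratio: native V0 is zero")
  ratio <- b / n
  # algebraically ratio * sqrt((sb/b)^2 + (sn/n)^2), safe at b = 0
  list(ratio = ratio, se = sqrt((sb / n)^2 + (b * sn / n^2)^2))
}

#' Final concentration after adding a stock aliquot
#'
#' `final = stock * added / total` — e.g. 10 uL of a 2000 mM stock into a
#' 100 uL reaction gives 200 mM.
#'
#' @param stock_mM Stock concentration (mM).
#' @param volume_added_uL Volume of stock added (uL), > 0.
#' @param volume_total_uL Final total volume (uL), >= added.
#' @return Final concentration (mM).
#' @export
dilution_final_concentration <- function(stock_mM, volume_added_uL,
                                         volume_total_uL) {
  if (volume_added_uL <= 0 || volume_total_uL <= 0)
    stop("input error: volumes must be > 0")
  if (volume_added_uL > volume_total_uL)
    stop("input error: added volume exceeds total volume")
  stock_mM * volume_added_uL / volume_total_uL
}
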