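# Synthetic plate-reader assay generator: noisy, initially-linear
# product-formation curves whose underlying initial velocity depends
# linearly on a salt covariate, with different slopes for intact (native)
# and sonication-broken compartments.

#' Synthetic assay parameters
#'
#' The true initial-velocity model is
#' `V0(state, c) = intercept[state] + slope[state] * c` with `c` the NaCl
#' concentration in mM, and each time course follows a saturating
#' exponential `A(t) = baseline + V0 * tau * (1 - exp(-t / tau))` plus
#' Gaussian noise, mimicking substrate/cofactor depletion at long times.
#' Defaults mirror the experimental design: 0-500 mM NaCl in 100 mM
#' increments, quadruplicates, absorbance read every 30 s for 1 h, the
#' broken state faster than native at every salt level with a steeper
#' salt slope.
#'
#' @param nacl_mM Salt concentrations assayed.
#' @param native_intercept,native_slope True V0 model for intact
#'   compartments (absorbance/s and absorbance/s/mM).
#' @param broken_intercept,broken_slope True V0 model for broken
#'   compartments.
#' @param tau_s Saturation time constant (s).
#' @param baseline Absorbance offset at t = 0.
#' @param noise_frac Noise SD as a fraction of each series' full signal
#'   amplitude (default 0.05); overridden by `noise_sd` when given.
#' @param noise_sd Absolute noise SD (absorbance units), or `NULL`.
#' @param time_s Read times (s).
#' @param replicates Replicates per condition/state.
#' @return A `pw_assay_params` list.
#' @export
assay_params <- function(nacl_mM = seq(0, 500, 100),
                         native_intercept = 1.0e-4, native_slope = 2.0e-7,
                         broken_intercept = 1.5e-4, broken_slope = 6.0e-7,
                         tau_s = 10800, baseline = 0.1,
                         noise_frac = 0.05, noise_sd = NULL,
                         time_s = seq(0, 3600, 30), replicates = 4L) {
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_frac < 0) stop("noise_frac must be >= 0")
  structure(list(nacl_mM = nacl_mM,
                 native_intercept = native_intercept,
                 native_slope = native_slope,
                 broken_intercept = broken_intercept,
                 broken_slope = broken_slope,
                 tau_s = tau_s, baseline = baseline,
                 noise_frac = noise_frac, noise_sd = noise_sd,
                 time_s = time_s, replicates = as.integer(replicates)),
            class = "pw_assay_params")
}

#' Simulate plate-reader absorbance time courses
#'
#' Deterministic given the RNG seed.  `tau_s = Inf` gives exactly linear
#' series with slope V0.
#'
#' @param params A `pw_assay_params`.
#' @param seed Optional integer passed to `set.seed()`.
#' @return Data frame with columns `time_s`, `a280`, `nacl_mM`, `state`,
#'   `replicate`; attribute `truth` holds the true V0 per condition/state.
#' @export
simulate_assay <- function(params = assay_params(), seed = NULL) {
  stopifnot(inherits(params, "pw_assay_params"))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(nacl_mM = params$nacl_mM,
                      state = c("native", "broken"),
                      replicate = seq_len(params$replicates),
                      stringsAsFactors = FALSE)
  t <- params$time_s
  tmax <- max(t)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    v0 <- if (g$state == "native")
      params$native_intercept + params$native_slope * g$nacl_mM
    else params$broken_intercept + params$broken_slope * g$nacl_mM
    signal <- if (is.finite(params$tau_s))
      v0 * params$tau_s * (1 - exp(-t / params$tau_s)) else v0 * t
    amp <- if (is.finite(params$tau_s))
      v0 * params$tau_s * (1 - exp(-tmax / params$tau_s)) else v0 * tmax
    sdv <- if (!is.null(params$noise_sd)) params$noise_sd else
      params$noise_frac * abs(amp)
    data.frame(time_s = t,
               a280 = params$baseline + signal +
                 if (sdv > 0) rnorm(length(t), 0, sdv) else 0,
               nacl_mM = g$nacl_mM, state = g$state,
               replicate = g$replicate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  truth <- unique(grid[, c("nacl_mM", "state")])
  truth$v0 <- ifelse(truth$state == "native",
                     params$native_intercept + params$native_slope * truth$nacl_mM,
                     params$broken_intercept + params$broken_slope * truth$nacl_mM)
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}
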