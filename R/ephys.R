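# Analysis operators for electrophysiological recordings: E_GABA from I-V
# data, junction correction, [Cl-]_i estimation, eIPSC train-depression
# metrics and charge transfer.

#' GABA I-V recording
#'
#' @param voltage holding potentials, mV (repeats allowed; >= 2 distinct
#'   values required).
#' @param current peak currents, pA.
#' @param junction_offset liquid junction potential to subtract off-line,
#'   mV (8 for the high-Cl-, 9 for the low-Cl- pipette solution).
#' @return an `iv_recording` data frame.
#' @export
iv_recording <- function(voltage, current, junction_offset = 0) {
  stopifnot(length(voltage) == length(current), length(voltage) >= 2)
  if (length(unique(voltage)) < 2)
    stop("at least two distinct holding voltages are required")
  reps <- table(voltage)
  if (any(reps > 3))
    warning("more than 3 repeats at some voltages (", max(reps), ")")
  structure(data.frame(voltage = voltage, current = current),
            junction_offset = junction_offset,
            class = c("iv_recording", "data.frame"))
}

#' E_GABA and slope conductance from an I-V curve
#'
#' Repeats are averaged per voltage, an ordinary least-squares line is fit,
#' and the reversal potential is the x-axis intercept corrected for the
#' junction offset (E = intercept - offset).
#'
#' @param iv an [iv_recording].
#' @return list with `e_gaba` (mV, junction-corrected), `conductance`
#'   (slope, nS for pA/mV data) and the per-voltage means used.
#' @export
fit_egaba <- function(iv) {
  stopifnot(inherits(iv, "iv_recording"))
  mu <- tapply(iv$current, iv$voltage, mean)
  v <- as.numeric(names(mu))
  fit <- stats::lm(mu ~ v)
  b <- stats::coef(fit)
  if (abs(b[2]) < .Machine$double.eps)
    stop("zero slope conductance: reversal potential undefined")
  list(e_gaba = unname(-b[1] / b[2]) - attr(iv, "junction_offset"),
       conductance = unname(b[2]),
       means = data.frame(voltage = v, current = as.numeric(mu)))
}

#' Intracellular chloride estimated from an I-V curve
#'
#' Composition of [fit_egaba] and [cl_from_reversal].
#'
#' @param iv an [iv_recording].
#' @param cond an [ion_conditions] supplying everything but Cl_in
#'   (default the recording-ACSF preset).
#' @param ratio HCO3-/Cl- permeability ratio.
#' @return estimated [Cl-]_i, mM.
#' @export
estimate_cl <- function(iv, cond = ion_preset("recording_acsf"),
                        ratio = 0.25) {
  cl_from_reversal(fit_egaba(iv)$e_gaba, cond, ratio)
}

#' Normalize and bin an eIPSC train
#'
#' Peak amplitudes are normalized to the first eIPSC and averaged in
#' 3-point windows centred on every `anchor`-th stimulus (5, 10, 15, 20,
#' 25 for the default 25-pulse train), clipping at the train end (the last
#' bin is the mean of stimuli 24 and 25).
#'
#' @param amplitudes per-stimulus peak amplitudes, pA (default length 25).
#' @param n_pulses expected train length.
#' @param anchor bin spacing in stimuli.
#' @param halfwidth half-width of the averaging window in stimuli.
#' @return data frame with `stimulus` (bin centre) and `relative` (binned
#'   normalized amplitude).
#' @export
normalize_and_bin <- function(amplitudes, n_pulses = 25, anchor = 5,
                              halfwidth = 1) {
  if (length(amplitudes) != n_pulses)
    stop("expected ", n_pulses, " amplitudes, got ", length(amplitudes))
  if (amplitudes[1] == 0) stop("first amplitude is zero; cannot normalize")
  rel <- amplitudes / amplitudes[1]
  centres <- seq(anchor, n_pulses, by = anchor)
  binned <- vapply(centres, function(k) {
    idx <- (k - halfwidth):(k + halfwidth)
    mean(rel[idx[idx >= 1 & idx <= n_pulses]])
  }, numeric(1))
  data.frame(stimulus = centres, relative = binned)
}

#' Fit a one-phase decay to binned relative amplitudes
#'
#' Fits y(n) = plateau + (1 - plateau) exp(-K (n - 1)), i.e. a
#' mono-exponential decay with unit value at the first stimulus, by
#' nonlinear least squares.
#'
#' @param binned data frame from [normalize_and_bin] (columns `stimulus`,
#'   `relative`), or any data frame with those columns (>= 3 points).
#' @return list with `plateau`, `rate` (K, per stimulus), `residual_ss`
#'   and `flags` (character vector; `"flat"` when the input carries no
#'   decay so K is unconstrained, `"plateau_clipped"` when a negative
#'   plateau was clipped to 0).
#' @export
fit_depression <- function(binned) {
  stopifnot(is.data.frame(binned), nrow(binned) >= 3,
            all(c("stimulus", "relative") %in% names(binned)))
  y <- binned$relative; n <- binned$stimulus
  flags <- character(0)
  if (stats::sd(y) < 1e-12) {
    return(list(plateau = y[1], rate = NA_real_, residual_ss = 0,
                flags = "flat"))
  }
  start <- list(p = max(min(min(y), 0.99), 0.01),
                k = 0.2)
  fit <- tryCatch(
    minpack.lm::nlsLM(relative ~ p + (1 - p) * exp(-k * (stimulus - 1)),
                      data = binned, start = start,
                      lower = c(p = -1, k = 1e-6), upper = c(p = 2, k = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("one-phase decay fit failed (start plateau = ",
                             format(start$p), ", K = ", format(start$k),
                             "): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  p <- unname(cf["p"]); k <- unname(cf["k"])
  if (p < 0) { p <- 0; flags <- c(flags, "plateau_clipped") }
  list(plateau = p, rate = k,
       residual_ss = sum(stats::resid(fit)^2), flags = flags)
}

#' Chloride-accumulation component of train depression
#'
#' Difference of end-of-train depression fractions (1 - last bin), 0 mV
#' minus -90 mV: depression at 0 mV is dominated by Cl- influx and
#' accumulation, depression at -90 mV is Cl--independent, so the
#' difference isolates the component due to Cl- accumulation.
#'
#' @param binned_0mv,binned_minus90mv data frames from
#'   [normalize_and_bin].
#' @return dimensionless depression difference.
#' @export
depression_difference <- function(binned_0mv, binned_minus90mv) {
  stopifnot(nrow(binned_0mv) == nrow(binned_minus90mv))
  last0 <- binned_0mv$relative[nrow(binned_0mv)]
  last90 <- binned_minus90mv$relative[nrow(binned_minus90mv)]
  (1 - last0) - (1 - last90)
}

#' Charge transfer over a window
#'
#' Trapezoidal integral of the baseline-subtracted current. Call twice and
#' subtract to obtain a drug-induced change in charge transfer.
#'
#' @param trace current samples, pA.
#' @param dt sample interval, ms.
#' @param window `c(start, end)` integration window, ms (defaults to the
#'   whole trace).
#' @param baseline_window optional `c(start, end)` window (ms) whose mean
#'   defines the baseline; 0 if omitted.
#' @return charge in picocoulombs.
#' @export
charge_transfer <- function(trace, dt, window = NULL,
                            baseline_window = NULL) {
  t <- (seq_along(trace) - 1) * dt
  if (is.null(window)) window <- range(t)
  if (window[1] < 0 || window[2] > max(t))
    stop("integration window outside the trace")
  base <- 0
  if (!is.null(baseline_window)) {
    sel <- t >= baseline_window[1] & t <= baseline_window[2]
    if (!any(sel)) stop("empty baseline window")
    base <- mean(trace[sel])
  }
  sel <- t >= window[1] & t <= window[2]
  y <- trace[sel] - base
  # pA * ms = fC; report pC
  sum((y[-1] + y[-length(y)]) / 2) * dt * 1e-3
}
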