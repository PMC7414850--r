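# Single-compartment dynamic model of membrane potential, [Cl-]_i and
# [K+]_o under GABA-A load and stochastic synaptic bombardment, with
# Morris-Lecar spiking. Forward Euler at dt = 0.1 ms.

.prolate_spheroid <- function(a, b) {
  # a = long semi-axis, b = equatorial semi-axis (um)
  e <- sqrt(1 - (b / a)^2)
  list(volume = 4 / 3 * pi * a * b^2,
       surface = 2 * pi * b^2 * (1 + (a / (b * e)) * asin(e)))
}

#' Point-model cell geometry
#'
#' Default volume and surface are derived from the laminar soma ellipsoid
#' (prolate, semi-axes 10.75/5.5 um for LI, 7.9/4.58 um for LII) plus two
#' dendritic cylinders (1.5 um diameter, 80 um long, lateral surface only).
#'
#' @param lamina `"LI"` or `"LII"`; sets the soma ellipsoid.
#' @param dendrite_length,dendrite_diameter,n_dendrites dendrite geometry (um).
#' @param ecs_volume_fraction extracellular volume as a fraction of cell
#'   volume (default 1/5).
#' @param volume,surface explicit overrides (um^3, um^2).
#' @return an object of class `cell_geometry`.
#' @export
cell_geometry <- function(lamina = c("LI", "LII"), dendrite_length = 80,
                          dendrite_diameter = 1.5, n_dendrites = 2,
                          ecs_volume_fraction = 1 / 5,
                          volume = NULL, surface = NULL) {
  lamina <- match.arg(lamina)
  ax <- if (lamina == "LI") c(10.75, 5.5) else c(7.9, 4.58)
  sp <- .prolate_spheroid(ax[1], ax[2])
  r <- dendrite_diameter / 2
  dvol <- n_dendrites * pi * r^2 * dendrite_length
  dsurf <- n_dendrites * pi * dendrite_diameter * dendrite_length
  if (is.null(volume)) volume <- sp$volume + dvol
  if (is.null(surface)) surface <- sp$surface + dsurf
  stopifnot(volume > 0, surface > 0, ecs_volume_fraction > 0)
  structure(list(lamina = lamina, volume = volume, surface = surface,
                 ecs_volume_fraction = ecs_volume_fraction),
            class = "cell_geometry")
}

#' Morris-Lecar spiking parameters
#'
#' In its published form, the K+ activation curve uses V4 = -30 mV, which would make
#' activation decrease with depolarisation; by default the magnitude |V4| is
#' used so that W_inf increases with V (set `as_printed = TRUE` for the
#' literal form). The gating time constant sech((V - V3)/(2 V4)) is
#' dimensionless; it is scaled by `tau_w_scale` in ms. The default of 25 ms
#' (the canonical Morris-Lecar 1/phi with phi = 0.04 ms^-1) makes the W gate
#' slower than the membrane, which is required for regenerative spikes.
#'
#' @param g_na,g_k maximal conductances, nS.
#' @param v1,v2,v3,v4 gating curve parameters, mV.
#' @param e_na sodium reversal potential, mV (not stated by the model
#'   sources; +60 mV default).
#' @param tau_w_scale gating time scale, ms.
#' @param as_printed logical; use the literal negative V4 in W_inf.
#' @return an object of class `spiking_params`.
#' @export
spiking_params <- function(g_na = 2, g_k = 8, v1 = -40, v2 = 18, v3 = -30,
                           v4 = -30, e_na = 60, tau_w_scale = 25,
                           as_printed = FALSE) {
  stopifnot(g_na >= 0, g_k >= 0, tau_w_scale > 0)
  structure(list(g_na = g_na, g_k = g_k, v1 = v1, v2 = v2, v3 = v3, v4 = v4,
                 e_na = e_na, tau_w_scale = tau_w_scale,
                 as_printed = as_printed), class = "spiking_params")
}

#' Leak, pump and extracellular potassium parameters
#'
#' Total leak conductance 1.2 nS of which 80% is K+; leak reversal -65 mV.
#' The Na/K pump contributes a constant K+ import equal to `pump_factor`
#' (1.5) times the resting leak K+ current; it enters the [K+]_o balance
#' only. [K+]_i is held at 120 mM; [K+]_o relaxes to `k_rest` = 3 mM with
#' time constant `tau_k` = 200 ms.
#'
#' @param g_leak_total total leak conductance, nS.
#' @param k_fraction fraction of leak carried by K+.
#' @param e_leak leak reversal, mV.
#' @param pump_factor pump K+ current as a multiple of resting leak K+.
#' @param k_in intracellular K+, mM (constant).
#' @param k_rest resting extracellular K+, mM.
#' @param tau_k extracellular K+ clearance time constant, ms.
#' @return an object of class `leak_pump_params`.
#' @export
leak_pump_params <- function(g_leak_total = 1.2, k_fraction = 0.8,
                             e_leak = -65, pump_factor = 1.5, k_in = 120,
                             k_rest = 3, tau_k = 200) {
  stopifnot(k_fraction >= 0, k_fraction <= 1, g_leak_total >= 0, tau_k > 0)
  structure(list(g_leak_total = g_leak_total, k_fraction = k_fraction,
                 e_leak = e_leak, pump_factor = pump_factor, k_in = k_in,
                 k_rest = k_rest, tau_k = tau_k), class = "leak_pump_params")
}

#' Synaptic drive parameters
#'
#' Poisson trains of unitary conductances with instantaneous rise and Euler
#' exponential decay: g <- g (1 - dt/tau) + g_unit on an event.
#'
#' @param f_inh,f_exc mean event frequencies, Hz.
#' @param tau_inh,tau_exc decay time constants, ms.
#' @param g_unit_inh,g_unit_exc unitary conductances, nS.
#' @param e_exc excitatory reversal potential, mV.
#' @return an object of class `synaptic_params`.
#' @export
synaptic_params <- function(f_inh = 1, f_exc = 1, tau_inh = 25, tau_exc = 15,
                            g_unit_inh = 1, g_unit_exc = 0.5, e_exc = 0) {
  stopifnot(f_inh >= 0, f_exc >= 0, tau_inh > 0, tau_exc > 0)
  structure(list(f_inh = f_inh, f_exc = f_exc, tau_inh = tau_inh,
                 tau_exc = tau_exc, g_unit_inh = g_unit_inh,
                 g_unit_exc = g_unit_exc, e_exc = e_exc),
            class = "synaptic_params")
}

#' Assemble the full point-model parameter set
#'
#' Bundles geometry, spiking, leak/pump, synaptic and KCC2 parameters and
#' precomputes the derived constants used by the integrator (membrane
#' capacitance from 0.01 pF/um^2, the conductance-to-permeability factor at
#' the test conditions Vm = -60 mV / Cl_in = 5 mM, and the constant pump
#' K+ current).
#'
#' @param geometry a [cell_geometry].
#' @param spiking a [spiking_params].
#' @param leak a [leak_pump_params].
#' @param synaptic a [synaptic_params].
#' @param kcc2 a [kcc2_params] (its `vmax` in micromole m^-2 s^-1).
#' @param conditions an [ion_conditions]; default the point-model preset
#'   (Cl_o 120 mM, HCO3 15/30 mM).
#' @param extrusion_scale dimensionless multiplier on `vmax` for the point
#'   model; see [calibrate_extrusion_scale].
#' @param hco3_to_cl_ratio HCO3-/Cl- permeability ratio.
#' @param c_m_specific specific membrane capacitance, pF/um^2.
#' @return an object of class `point_params`.
#' @export
point_params <- function(geometry = cell_geometry("LI"),
                         spiking = spiking_params(),
                         leak = leak_pump_params(),
                         synaptic = synaptic_params(),
                         kcc2 = kcc2_params(10),
                         conditions = ion_preset("point_model"),
                         extrusion_scale = 1,
                         hco3_to_cl_ratio = 0.25,
                         c_m_specific = 0.01) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(spiking, "spiking_params"),
            inherits(leak, "leak_pump_params"),
            inherits(synaptic, "synaptic_params"),
            inherits(kcc2, "kcc2_params"),
            inherits(conditions, "ion_conditions"),
            extrusion_scale >= 0)
  rtf <- rtf_mv(conditions$temperature)
  vol <- geometry$volume; surf <- geometry$surface
  ek_rest <- rtf * log(leak$k_rest / leak$k_in)
  g_lk <- leak$k_fraction * leak$g_leak_total
  test_cond <- ion_conditions(cl_in = 5, cl_out = conditions$cl_out,
                              hco3_in = conditions$hco3_in,
                              hco3_out = conditions$hco3_out,
                              k_in = leak$k_in, k_out = leak$k_rest,
                              temperature = conditions$temperature)
  pp <- list(
    rtf = rtf, far = .FARADAY,
    g_na = spiking$g_na, g_k = spiking$g_k,
    v1 = spiking$v1, v2 = spiking$v2, v3 = spiking$v3,
    v4e = if (spiking$as_printed) spiking$v4 else abs(spiking$v4),
    e_na = spiking$e_na, tws = spiking$tau_w_scale,
    g_l = leak$g_leak_total, g_lk = g_lk, e_l = leak$e_leak,
    i_pump = -leak$pump_factor * abs(g_lk * (leak$e_leak - ek_rest)),
    k_in = leak$k_in, k_rest = leak$k_rest, tau_k = leak$tau_k,
    tau_inh = synaptic$tau_inh, tau_exc = synaptic$tau_exc,
    g_unit_inh = synaptic$g_unit_inh, g_unit_exc = synaptic$g_unit_exc,
    e_exc = synaptic$e_exc,
    cl_out = conditions$cl_out,
    hco3_in = conditions$hco3_in, hco3_out = conditions$hco3_out,
    hco3_ratio = hco3_to_cl_ratio,
    p_per_ns = conductance_to_permeability(1, test_cond, v_test = -60),
    c_m = c_m_specific * surf,
    vol = vol, surf = surf, sv = surf / vol,
    sv_ecs = surf / (vol * geometry$ecs_volume_fraction),
    cl_per_pa = 1e6 / (.FARADAY * vol),
    k_per_pa = 1e6 / (.FARADAY * vol * geometry$ecs_volume_fraction),
    vs = extrusion_scale * kcc2$vmax, mich = kcc2$michaelis_scale)
  structure(list(geometry = geometry, spiking = spiking, leak = leak,
                 synaptic = synaptic, kcc2 = kcc2, conditions = conditions,
                 extrusion_scale = extrusion_scale,
                 hco3_to_cl_ratio = hco3_to_cl_ratio,
                 c_m_specific = c_m_specific, pp = pp),
            class = "point_params")
}

#' Point-model state
#'
#' @param v_m membrane potential, mV.
#' @param w Morris-Lecar K+ gating variable in [0, 1].
#' @param cl_in intracellular chloride, mM (> 0).
#' @param k_out extracellular potassium, mM (> 0).
#' @param g_inh,g_exc instantaneous synaptic conductances, nS.
#' @param time simulation time, ms.
#' @return an object of class `point_state`.
#' @export
point_state <- function(v_m, w, cl_in, k_out, g_inh = 0, g_exc = 0, time = 0) {
  stopifnot(w >= 0, w <= 1, cl_in > 0, k_out > 0)
  structure(list(v_m = v_m, w = w, cl_in = cl_in, k_out = k_out,
                 g_inh = g_inh, g_exc = g_exc, time = time),
            class = "point_state")
}

#' Default initial state for a parameter set
#'
#' V at the leak reversal, W at its equilibrium, Cl_in 5 mM (the
#' conductance-calibration test value), K_out at rest, silent synapses.
#'
#' @param params a [point_params].
#' @param cl_in initial intracellular chloride, mM.
#' @return a [point_state].
#' @export
initial_state <- function(params, cl_in = 5) {
  pp <- params$pp
  v <- pp$e_l
  w <- (1 + tanh((v - pp$v3) / pp$v4e)) / 2
  point_state(v_m = v, w = w, cl_in = cl_in, k_out = pp$k_rest)
}

#' Poisson event train
#'
#' Bernoulli per-step approximation of a Poisson process: each step of
#' width `dt` carries an event with probability `rate * dt` (dt converted
#' to seconds). Reproducible given `seed`.
#'
#' @param rate mean event rate, Hz (scalar or one value per step).
#' @param duration train duration, ms.
#' @param dt time step, ms.
#' @param seed integer seed (optional; if `NULL` the current RNG stream is
#'   used).
#' @return integer vector of 0/1 event indicators, one per step.
#' @export
poisson_train <- function(rate, duration, dt = 0.1, seed = NULL) {
  stopifnot(all(rate >= 0), dt > 0, duration > 0)
  p <- rate * dt * 1e-3
  if (any(p > 1)) stop("rate * dt exceeds 1; time step too coarse")
  n <- round(duration / dt)
  if (length(p) > 1 && length(p) != n)
    stop("per-step rate vector must have one value per step")
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::runif(n) < p)
}

#' Euler update of a synaptic conductance
#'
#' g' = g (1 - dt/tau) + g_unit * event, exactly the published discrete form
#' (Euler decay, not the exact exponential).
#'
#' @param g current conductance, nS.
#' @param tau decay time constant, ms.
#' @param dt time step, ms (must be < tau).
#' @param g_unit unitary conductance added per event, nS.
#' @param event 0/1 event indicator.
#' @return updated conductance, nS.
#' @export
synaptic_step <- function(g, tau, dt, g_unit, event) {
  stopifnot(dt < tau)
  g * (1 - dt / tau) + g_unit * event
}

#' Morris-Lecar gating functions
#'
#' @param v membrane potential, mV (vectorised).
#' @param params a [spiking_params].
#' @return list with `m_inf` (instantaneous Na+ activation), `w_inf`
#'   (K+ activation equilibrium) and `tau_w` (K+ activation time constant,
#'   ms).
#' @export
ml_gating <- function(v, params = spiking_params()) {
  stopifnot(inherits(params, "spiking_params"))
  v4e <- if (params$as_printed) params$v4 else abs(params$v4)
  list(m_inf = (1 + tanh((v - params$v1) / params$v2)) / 2,
       w_inf = (1 + tanh((v - params$v3) / v4e)) / 2,
       tau_w = params$tau_w_scale / cosh((v - params$v3) / (2 * v4e)))
}

# Core Euler step. st = c(v, w, cl, ko, gi, ge); returns the updated state
# plus the component currents c(..., icl, ihco, ikv) evaluated at the step
# start. Kept lean: it runs once per 0.1 ms inside the simulation loops.
.point_step <- function(st, pp, dt, ev_i, ev_e, clamp = NULL) {
  v <- st[1L]; w <- st[2L]; cl <- st[3L]; ko <- st[4L]
  gi <- st[5L] * (1 - dt / pp$tau_inh) + pp$g_unit_inh * ev_i
  ge <- st[6L] * (1 - dt / pp$tau_exc) + pp$g_unit_exc * ev_e
  ek <- pp$rtf * log(ko / pp$k_in)
  u <- v / pp$rtf
  p_cl <- gi * pp$p_per_ns
  if (abs(u) < 1e-7) {
    qcl <- -(cl - pp$cl_out * exp(u)) * (1 - u / 2)
    qhc <- -(pp$hco3_in - pp$hco3_out * exp(u)) * (1 - u / 2)
  } else {
    eu <- exp(u); den <- -expm1(u)
    qcl <- (cl - pp$cl_out * eu) * u / den
    qhc <- (pp$hco3_in - pp$hco3_out * eu) * u / den
  }
  icl <- p_cl * pp$far * qcl * 1e12
  ihco <- pp$hco3_ratio * p_cl * pp$far * qhc * 1e12
  m <- (1 + tanh((v - pp$v1) / pp$v2)) / 2
  ikv <- pp$g_k * w * (v - ek)
  x <- (cl - ko) / pp$mich
  j <- if (x > 0) pp$vs * x / (1 + x) else 0
  vn <- if (is.null(clamp))
    v - dt * (pp$g_l * (v - pp$e_l) + pp$g_na * m * (v - pp$e_na) + ikv +
              ge * (v - pp$e_exc) + icl + ihco) / pp$c_m
  else clamp
  winf <- (1 + tanh((v - pp$v3) / pp$v4e)) / 2
  tw <- pp$tws / cosh((v - pp$v3) / (2 * pp$v4e))
  wn <- w + dt * (winf - w) / tw
  cln <- cl + dt * 1e-3 * (icl * pp$cl_per_pa - j * pp$sv)
  kon <- ko + dt * 1e-3 * ((pp$g_lk * (v - ek) + ikv + pp$i_pump) *
                             pp$k_per_pa + j * pp$sv_ecs) +
    dt * (pp$k_rest - ko) / pp$tau_k
  c(vn, wn, cln, kon, gi, ge, icl, ihco, ikv)
}

#' One forward-Euler step of the point model
#'
#' Updates V (current balance: leak, Na+, voltage-gated K+, excitatory
#' synaptic, GABA Cl- + HCO3-), the W gate, [Cl-]_i and [K+]_o.
#'
#' @param state a [point_state].
#' @param params a [point_params].
#' @param dt time step, ms (<= 0.1 recommended).
#' @param events named vector `c(inh = 0/1, exc = 0/1)` of synaptic events
#'   arriving at this step.
#' @param clamp if non-`NULL`, V is held at this value (voltage clamp).
#' @return the updated [point_state]; component currents (pA) are attached
#'   as attribute `"currents"`.
#' @export
step_state <- function(state, params, dt = 0.1, events = c(inh = 0, exc = 0),
                       clamp = NULL) {
  stopifnot(inherits(state, "point_state"), inherits(params, "point_params"))
  st <- c(state$v_m, state$w, state$cl_in, state$k_out,
          state$g_inh, state$g_exc)
  out <- .point_step(st, params$pp, dt, events[["inh"]], events[["exc"]],
                     clamp)
  bad <- !is.finite(out[1:6])
  if (any(bad)) {
    nm <- c("v_m", "w", "cl_in", "k_out", "g_inh", "g_exc")[bad][1]
    stop("integration produced a non-finite value for state variable '",
         nm, "'")
  }
  ns <- point_state(out[1], min(max(out[2], 0), 1), out[3], out[4],
                    out[5], out[6], time = state$time + dt)
  attr(ns, "currents") <- c(i_cl = out[7], i_hco3 = out[8], i_k = out[9])
  ns
}

# Shared simulation engine. p_i / p_e are per-step event probabilities
# (scalar or per-step vectors). Returns sampled series and summary.
.run_point <- function(params, duration_s, dt, seed, p_i, p_e,
                       sample_ms = 10, clamp = NULL, init = NULL,
                       pin_cl = NA_real_, spike_threshold = -25) {
  pp <- params$pp
  n <- round(duration_s * 1000 / dt)
  set.seed(seed)
  ev_i <- stats::runif(n) < p_i
  ev_e <- stats::runif(n) < p_e
  if (is.null(init)) init <- initial_state(params)
  st <- c(init$v_m, init$w, init$cl_in, init$k_out, init$g_inh, init$g_exc)
  if (!is.na(pin_cl)) st[3L] <- pin_cl
  every <- max(1L, round(sample_ms / dt))
  ns <- n %/% every
  out <- matrix(NA_real_, ns, 10L)
  colnames(out) <- c("time_ms", "v_m", "w", "cl_in", "k_out", "g_inh",
                     "g_exc", "i_cl", "i_hco3", "i_k")
  row <- 0L
  nspike <- 0L; above <- FALSE
  # unpack constants; the loop body mirrors .point_step (equivalence is
  # asserted by a regression test)
  rtf <- pp$rtf; far <- pp$far; g_na <- pp$g_na; g_k <- pp$g_k
  v1 <- pp$v1; v2 <- pp$v2; v3 <- pp$v3; v4e <- pp$v4e; e_na <- pp$e_na
  tws <- pp$tws; g_l <- pp$g_l; g_lk <- pp$g_lk; e_l <- pp$e_l
  i_pump <- pp$i_pump; k_in <- pp$k_in; k_rest <- pp$k_rest
  tau_k <- pp$tau_k; di <- 1 - dt / pp$tau_inh; de <- 1 - dt / pp$tau_exc
  gui <- pp$g_unit_inh; gue <- pp$g_unit_exc; e_exc <- pp$e_exc
  cl_out <- pp$cl_out; h_in <- pp$hco3_in; h_out <- pp$hco3_out
  hr <- pp$hco3_ratio; p_per_ns <- pp$p_per_ns; c_m <- pp$c_m
  sv <- pp$sv; sv_ecs <- pp$sv_ecs; cl_per_pa <- pp$cl_per_pa
  k_per_pa <- pp$k_per_pa; vs <- pp$vs; mich <- pp$mich
  clamped <- !is.null(clamp)
  v <- st[1L]; w <- st[2L]; cl <- st[3L]; ko <- st[4L]
  gi <- st[5L]; ge <- st[6L]
  if (clamped) v <- clamp
  icl <- ihco <- ikv <- 0
  for (s in seq_len(n)) {
    gi <- gi * di + gui * ev_i[s]
    ge <- ge * de + gue * ev_e[s]
    ek <- rtf * log(ko / k_in)
    u <- v / rtf
    p_cl <- gi * p_per_ns
    if (abs(u) < 1e-7) {
      qcl <- -(cl - cl_out * exp(u)) * (1 - u / 2)
      qhc <- -(h_in - h_out * exp(u)) * (1 - u / 2)
    } else {
      eu <- exp(u); den <- -expm1(u)
      qcl <- (cl - cl_out * eu) * u / den
      qhc <- (h_in - h_out * eu) * u / den
    }
    icl <- p_cl * far * qcl * 1e12
    ihco <- hr * p_cl * far * qhc * 1e12
    m <- (1 + tanh((v - v1) / v2)) / 2
    ikv <- g_k * w * (v - ek)
    x <- (cl - ko) / mich
    j <- if (x > 0) vs * x / (1 + x) else 0
    vn <- if (clamped) clamp else
      v - dt * (g_l * (v - e_l) + g_na * m * (v - e_na) + ikv +
                ge * (v - e_exc) + icl + ihco) / c_m
    winf <- (1 + tanh((v - v3) / v4e)) / 2
    tw <- tws / cosh((v - v3) / (2 * v4e))
    w <- w + dt * (winf - w) / tw
    if (is.na(pin_cl)) cl <- cl + dt * 1e-3 * (icl * cl_per_pa - j * sv)
    ko <- ko + dt * 1e-3 * ((g_lk * (v - ek) + ikv + i_pump) * k_per_pa +
                              j * sv_ecs) + dt * (k_rest - ko) / tau_k
    v <- vn
    if (v > spike_threshold) {
      if (!above) { nspike <- nspike + 1L; above <- TRUE }
    } else if (v < spike_threshold - 15) above <- FALSE
    if (s %% every == 0L) {
      row <- row + 1L
      out[row, ] <- c(s * dt, v, w, cl, ko, gi, ge, icl, ihco, ikv)
    }
  }
  st <- c(v, w, cl, ko, gi, ge)
  if (any(!is.finite(st))) {
    nm <- c("v_m", "w", "cl_in", "k_out", "g_inh", "g_exc")[!is.finite(st)][1]
    stop("integration produced a non-finite value for state variable '",
         nm, "'")
  }
  series <- as.data.frame(out[seq_len(row), , drop = FALSE])
  last <- series[series$time_ms > (1 - 1 / 3) * duration_s * 1000, ,
                 drop = FALSE]
  summary <- list(
    cl_in = mean(last$cl_in), k_out = mean(last$k_out),
    v_m = mean(last$v_m),
    e_cl = nernst(mean(last$cl_in), pp$cl_out,
                  params$conditions$temperature, -1),
    e_gaba = gaba_reversal(ion_conditions(
      cl_in = mean(last$cl_in), cl_out = pp$cl_out,
      hco3_in = pp$hco3_in, hco3_out = pp$hco3_out,
      k_in = pp$k_in, k_out = mean(last$k_out),
      temperature = params$conditions$temperature), params$hco3_to_cl_ratio),
    spike_rate = nspike / duration_s,
    averaging_window_s = c((1 - 1 / 3) * duration_s, duration_s))
  structure(list(series = series, summary = summary, seed = seed, dt = dt,
                 duration_s = duration_s, params = params),
            class = "sim_result")
}

#' Simulate spontaneous synaptic activity
#'
#' Integrates the full model (spiking enabled) under Poisson inhibitory and
#' excitatory drive at the rates in `params$synaptic`, and reports steady
#' [Cl-]_i, [K+]_o and mean V averaged over the final third of the run.
#'
#' @param params a [point_params].
#' @param duration_s simulated time, s.
#' @param seed integer seed for the event trains.
#' @param dt time step, ms.
#' @param sample_ms sampling interval of the returned series, ms.
#' @param init optional initial [point_state].
#' @return a `sim_result`: `$series` (sampled time courses of state and
#'   component currents) and `$summary` (final-third means, E_Cl, E_GABA,
#'   spike rate).
#' @export
simulate_activity <- function(params, duration_s = 60, seed = 1, dt = 0.1,
                              sample_ms = 10, init = NULL) {
  stopifnot(inherits(params, "point_params"), duration_s > 0)
  syn <- params$synaptic
  .run_point(params, duration_s, dt, seed,
             p_i = syn$f_inh * dt * 1e-3, p_e = syn$f_exc * dt * 1e-3,
             sample_ms = sample_ms, init = init)
}

#' Simulate a linear rise of synaptic drive (capsaicin-like protocol)
#'
#' Event frequencies ramp linearly from `rest` to `high` rates over
#' `ramp_s` seconds (after `baseline_s` at rest), then stay at the high
#' rates for the remainder of `duration_s`.
#'
#' @param params a [point_params] (its `synaptic` rates are ignored in
#'   favour of the schedule).
#' @param rest,high `c(f_inh, f_exc)` rates in Hz at rest and at the
#'   plateau (defaults 1/1 Hz and 5/50 Hz).
#' @param baseline_s,ramp_s,duration_s protocol timing, s (`duration_s` is
#'   the total simulated time; the plateau is whatever remains).
#' @param seed,dt,sample_ms,init as in [simulate_activity].
#' @return a `sim_result`; the ramp schedule is attached as
#'   `$summary$schedule`.
#' @export
simulate_capsaicin_ramp <- function(params, rest = c(1, 1), high = c(5, 50),
                                    baseline_s = 30, ramp_s = 120,
                                    duration_s = 300, seed = 1, dt = 0.1,
                                    sample_ms = 10, init = NULL) {
  stopifnot(inherits(params, "point_params"),
            duration_s > baseline_s + ramp_s)
  n <- round(duration_s * 1000 / dt)
  t_s <- (seq_len(n) - 1) * dt * 1e-3
  frac <- pmin(1, pmax(0, (t_s - baseline_s) / ramp_s))
  f_i <- rest[1] + frac * (high[1] - rest[1])
  f_e <- rest[2] + frac * (high[2] - rest[2])
  out <- .run_point(params, duration_s, dt, seed,
                    p_i = f_i * dt * 1e-3, p_e = f_e * dt * 1e-3,
                    sample_ms = sample_ms, init = init)
  out$summary$schedule <- list(rest = rest, high = high,
                               baseline_s = baseline_s, ramp_s = ramp_s)
  out
}

#' Simulate a sustained GABA-A chloride load under voltage clamp
#'
#' Reproduces the constant, uniformly distributed GABA-mediated Cl-
#' permeability protocol: V is held at `hold_v`, P_Cl is calibrated by the
#' linearity of the GHK flux so that the magnitude of the initial net GABA
#' current (Cl- plus HCO3-) equals `target_initial_current`, and [Cl-]_i is
#' integrated to steady state against KCC2 extrusion (fixed-[K+]_o flux
#' form). [K+]_o is held at rest in this clamped scenario.
#'
#' @param params a [point_params]; `params$kcc2$vmax` (times
#'   `extrusion_scale`) sets extrusion. Synaptic and spiking parameters are
#'   unused.
#' @param hold_v holding potential, mV.
#' @param target_initial_current magnitude of the initial net GABA current,
#'   pA.
#' @param duration_s simulated time, s.
#' @param dt time step, ms.
#' @param cl_init initial [Cl-]_i, mM.
#' @param sample_ms sampling interval, ms.
#' @return a `sim_result` whose `$series` holds time courses of [Cl-]_i,
#'   I_Cl, I_HCO3, net current and E_Cl, and whose `$summary` holds the
#'   steady values, the calibrated `p_cl` (m^3/s) and a `converged` flag
#'   (absolute d[Cl-]_i/dt below 1e-4 mM/s at the end).
#' @export
simulate_gaba_load <- function(params, hold_v = -70,
                               target_initial_current = 10,
                               duration_s = 120, dt = 0.1, cl_init = 5,
                               sample_ms = 100) {
  stopifnot(inherits(params, "point_params"), duration_s > 0)
  pp <- params$pp
  unit_cl <- ghk_anion_current(1, hold_v, cl_init, pp$cl_out,
                               params$conditions$temperature)
  unit_hc <- ghk_anion_current(1, hold_v, pp$hco3_in, pp$hco3_out,
                               params$conditions$temperature)
  unit_net <- unit_cl + pp$hco3_ratio * unit_hc
  if (abs(unit_net) < .Machine$double.eps)
    stop("net GABA current vanishes at the initial state; cannot calibrate")
  p_cl <- target_initial_current / abs(unit_net)
  # GHK is linear in [Cl-]_i at fixed V: I_Cl = a*cl + b.
  u <- hold_v / rtf_mv(params$conditions$temperature)
  fac <- if (abs(u) < 1e-7) -(1 - u / 2) else u / (-expm1(u))
  a <- p_cl * .FARADAY * fac * 1e12
  b <- -a * pp$cl_out * exp(u)
  ihco <- p_cl * pp$hco3_ratio *
    ghk_anion_current(1, hold_v, pp$hco3_in, pp$hco3_out,
                      params$conditions$temperature)
  n <- round(duration_s * 1000 / dt)
  every <- max(1L, round(sample_ms / dt))
  ns <- n %/% every
  out <- matrix(NA_real_, ns, 4L)
  colnames(out) <- c("time_ms", "cl_in", "i_cl", "i_hco3")
  cl <- cl_init; row <- 0L
  mich <- pp$mich; k0 <- pp$k_rest; vs <- pp$vs
  cl_per_pa <- pp$cl_per_pa; sv <- pp$sv
  for (s in seq_len(n)) {
    icl <- a * cl + b
    x <- (cl - k0) / mich
    j <- if (x > 0) vs * x / (1 + x) else 0
    cl <- cl + dt * 1e-3 * (icl * cl_per_pa - j * sv)
    if (s %% every == 0L) {
      row <- row + 1L
      out[row, ] <- c(s * dt, cl, icl, ihco)
    }
  }
  if (!is.finite(cl))
    stop("integration produced a non-finite value for state variable 'cl_in'")
  series <- as.data.frame(out[seq_len(row), , drop = FALSE])
  series$i_net <- series$i_cl + series$i_hco3
  series$e_cl <- nernst(series$cl_in, pp$cl_out,
                        params$conditions$temperature, -1)
  icl_end <- a * cl + b
  x <- (cl - k0) / mich
  dcl_dt <- icl_end * cl_per_pa - (if (x > 0) vs * x / (1 + x) else 0) * sv
  structure(list(
    series = series,
    summary = list(cl_in = cl,
                   e_cl = nernst(cl, pp$cl_out,
                                 params$conditions$temperature, -1),
                   i_net = icl_end + ihco, p_cl = p_cl,
                   converged = abs(dcl_dt) < 1e-4,
                   hold_v = hold_v),
    dt = dt, duration_s = duration_s, params = params),
    class = "sim_result")
}

#' Calibrate the point-model extrusion scale
#'
#' With the literal units of the flux law and the laminar cell geometry,
#' maximal extrusion exceeds synaptic Cl- influx by orders of magnitude and
#' [Cl-]_i sits pinned at the transporter null point. This routine
#' implements the documented calibration: measure the mean synaptic Cl-
#' influx (in mM/s) with [Cl-]_i pinned at `target_cl` under baseline drive,
#' and return the dimensionless scale that makes extrusion at
#' `vmax_ref` balance it there, so that `target_cl` becomes the resting
#' fixed point. The same scale is then shared by all capacities so their
#' ratios are preserved.
#'
#' @param params a [point_params] whose synaptic rates define the baseline
#'   drive (default 1/1 Hz via [synaptic_params]).
#' @param vmax_ref reference extrusion capacity, micromole m^-2 s^-1.
#' @param target_cl desired resting [Cl-]_i, mM.
#' @param duration_s length of the calibration run, s.
#' @param seed integer seed.
#' @return the dimensionless extrusion scale.
#' @export
calibrate_extrusion_scale <- function(params = point_params(),
                                      vmax_ref = 10, target_cl = 5.5,
                                      duration_s = 30, seed = 1) {
  stopifnot(target_cl > params$pp$k_rest)
  run <- .run_point(params, duration_s, dt = 0.1, seed = seed,
                    p_i = params$synaptic$f_inh * 1e-4,
                    p_e = params$synaptic$f_exc * 1e-4,
                    sample_ms = 10, pin_cl = target_cl)
  last <- run$series[run$series$time_ms > duration_s * 1000 / 3, ]
  influx <- mean(last$i_cl) * params$pp$cl_per_pa   # mM/s
  x <- (target_cl - mean(last$k_out)) / params$pp$mich
  sink_unit <- vmax_ref * (x / (1 + x)) * params$pp$sv
  influx / sink_unit
}
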