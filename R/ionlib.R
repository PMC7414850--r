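# Ionic biophysics primitives: Nernst/GHK relations, GABA-A reversal,
# KCC2 transport kinetics, conductance -> permeability calibration.

.FARADAY <- 96485.33212      # C / mol
.RGAS    <- 8.314462618      # J / mol / K

#' Thermal voltage RT/F
#'
#' @param temperature temperature in degrees Celsius.
#' @return RT/F in millivolts (25.693 mV at 25 degrees C).
#' @export
rtf_mv <- function(temperature = 25) {
  stopifnot(is.numeric(temperature), temperature >= 0, temperature <= 45)
  1000 * .RGAS * (273.15 + temperature) / .FARADAY
}

#' Ionic condition set
#'
#' Bundles the intra/extracellular Cl-, HCO3- and K+ concentrations and the
#' bath temperature used by the reversal-potential and flux computations.
#'
#' @param cl_in,cl_out intra/extracellular chloride, mM.
#' @param hco3_in,hco3_out intra/extracellular bicarbonate, mM.
#' @param k_in,k_out intra/extracellular potassium, mM.
#' @param temperature degrees Celsius, in [0, 45].
#' @return an object of class `ion_conditions`.
#' @export
ion_conditions <- function(cl_in, cl_out, hco3_in, hco3_out,
                           k_in = 120, k_out = 3, temperature = 25) {
  x <- list(cl_in = cl_in, cl_out = cl_out, hco3_in = hco3_in,
            hco3_out = hco3_out, k_in = k_in, k_out = k_out,
            temperature = temperature)
  conc <- unlist(x[c("cl_in", "cl_out", "hco3_in", "hco3_out", "k_in", "k_out")])
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all ionic concentrations must be positive and finite")
  if (temperature < 0 || temperature > 45)
    stop("temperature must lie in [0, 45] degrees C")
  structure(x, class = "ion_conditions")
}

#' Named ionic condition presets
#'
#' `"recording_acsf"`: the whole-cell recording solutions. Extracellular Cl-
#' from the ACSF recipe, 126 NaCl + 2.5 KCl + 2 MgCl2 + 2 CaCl2 = 136.5 mM;
#' HCO3- 26 mM outside / 16 mM inside; high-load pipette Cl- 29 mM; 25 C.
#'
#' `"point_model"`: the dynamic single-compartment model conditions,
#' Cl-_o 120 mM, HCO3- 15 mM inside / 30 mM outside, K+ 120/3 mM, 25 C.
#'
#' @param name preset name.
#' @param cl_in optional override of the intracellular chloride, mM.
#' @return an `ion_conditions` object.
#' @export
ion_preset <- function(name = c("recording_acsf", "point_model"), cl_in = NULL) {
  name <- match.arg(name)
  cond <- switch(name,
    recording_acsf = ion_conditions(cl_in = 29, cl_out = 126 + 2.5 + 2 * 2 + 2 * 2,
                                    hco3_in = 16, hco3_out = 26,
                                    k_in = 120, k_out = 2.5, temperature = 25),
    point_model    = ion_conditions(cl_in = 5, cl_out = 120,
                                    hco3_in = 15, hco3_out = 30,
                                    k_in = 120, k_out = 3, temperature = 25))
  if (!is.null(cl_in)) {
    cond$cl_in <- cl_in
    cond <- do.call(ion_conditions, unclass(cond))
  }
  cond
}

#' KCC2 transport parameters
#'
#' The saturating K-Cl co-transport flux is
#' J = vmax * x / (1 + x), x = (Cl_in - K_out) / michaelis_scale,
#' with K_out defaulting to `null_offset` (3 mM), so that extrusion is null
#' at Cl_in = 3 mM and half-maximal at 15 mM.
#'
#' @param vmax maximal extrusion capacity, micromole m^-2 s^-1.
#' @param null_offset Cl_in at which extrusion vanishes (mM, default 3).
#' @param michaelis_scale saturation scale (mM, default 12).
#' @return an object of class `kcc2_params`.
#' @export
kcc2_params <- function(vmax, null_offset = 3, michaelis_scale = 12) {
  stopifnot(vmax >= 0, michaelis_scale > 0)
  structure(list(vmax = vmax, null_offset = null_offset,
                 michaelis_scale = michaelis_scale), class = "kcc2_params")
}

#' Nernst equilibrium potential
#'
#' E = -(RT/zF) ln(conc_in / conc_out); for a monovalent anion (z = -1) this
#' is (RT/F) ln(in/out), for K+ (z = +1) it is (RT/F) ln(out/in).
#'
#' @param conc_in,conc_out concentrations, mM (> 0).
#' @param temperature degrees Celsius.
#' @param valence ionic valence, +1 or -1.
#' @return equilibrium potential, mV.
#' @export
nernst <- function(conc_in, conc_out, temperature = 25, valence = -1) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be positive")
  if (!all(valence %in% c(-1L, 1L))) stop("valence must be +1 or -1")
  (rtf_mv(temperature) / valence) * log(conc_out / conc_in)
}

#' Goldman-Hodgkin-Katz current for a monovalent anion
#'
#' Evaluates I = P (Vm F^2 / RT) (c_in - c_out e^(VmF/RT)) / (1 - e^(VmF/RT)).
#' With `perm` in m^3 s^-1 (permeability times membrane area) and
#' concentrations in mM the result is in picoamperes. Sign convention:
#' positive current = anion influx (raises the intracellular concentration),
#' which for an anion coincides with conventional outward current. The
#' removable singularity at Vm = 0 is handled by a series expansion, so the
#' function is continuous through 0.
#'
#' @param perm permeability-area product, m^3 s^-1 (relative units fine).
#' @param v_m membrane potential, mV (vectorised).
#' @param conc_in,conc_out anion concentrations, mM.
#' @param temperature degrees Celsius.
#' @return current in pA (per unit `perm` if `perm` is relative).
#' @export
ghk_anion_current <- function(perm, v_m, conc_in, conc_out, temperature = 25) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be positive")
  u <- v_m / rtf_mv(temperature)
  quot <- ifelse(abs(u) < 1e-7,
                 # u/(1-e^u) -> -(1 - u/2), first order about 0
                 -(conc_in - conc_out * exp(u)) * (1 - u / 2),
                 (conc_in - conc_out * exp(u)) * u / (-expm1(u)))
  perm * .FARADAY * quot * 1e12
}

#' GABA-A reversal potential (two-anion GHK)
#'
#' E = (RT/F) ln[(Cl_in + r HCO3_in) / (Cl_out + r HCO3_out)] with r the
#' HCO3-/Cl- permeability ratio (default 0.25). With r = 0 this reduces to
#' the chloride Nernst potential.
#'
#' @param cond an [ion_conditions] object.
#' @param ratio HCO3-/Cl- permeability ratio (>= 0).
#' @return reversal potential, mV.
#' @export
gaba_reversal <- function(cond, ratio = 0.25) {
  stopifnot(inherits(cond, "ion_conditions"), ratio >= 0)
  num <- cond$cl_in + ratio * cond$hco3_in
  den <- cond$cl_out + ratio * cond$hco3_out
  if (num <= 0 || den <= 0) stop("degenerate anion concentrations")
  rtf_mv(cond$temperature) * log(num / den)
}

#' Intracellular chloride from a measured GABA-A reversal
#'
#' Exact algebraic inverse of [gaba_reversal] in its Cl_in argument:
#' Cl_in = e^(E / (RT/F)) (Cl_out + r HCO3_out) - r HCO3_in.
#'
#' @param e_gaba measured reversal potential, mV.
#' @param cond an [ion_conditions] object supplying everything but Cl_in.
#' @param ratio HCO3-/Cl- permeability ratio.
#' @return implied intracellular chloride, mM.
#' @export
cl_from_reversal <- function(e_gaba, cond, ratio = 0.25) {
  stopifnot(inherits(cond, "ion_conditions"), ratio >= 0)
  cl <- exp(e_gaba / rtf_mv(cond$temperature)) *
    (cond$cl_out + ratio * cond$hco3_out) - ratio * cond$hco3_in
  if (any(cl <= 0))
    stop("reversal potential of ", format(e_gaba),
         " mV implies a non-positive [Cl-]_i under these conditions; ",
         "it lies below the pure-HCO3 limit")
  cl
}

#' KCC2 chloride extrusion flux
#'
#' J = vmax * x / (1 + x) with x = (Cl_in - K_out) / michaelis_scale.
#' The transporter is treated as a pure extruder: when Cl_in <= K_out the
#' flux is clamped to zero (no reverse transport).
#'
#' @param cl_in intracellular chloride, mM (vectorised).
#' @param params a [kcc2_params] object.
#' @param k_out extracellular potassium, mM; defaults to the null offset
#'   (3 mM), giving the fixed-K form of the flux.
#' @return extrusion flux, micromole m^-2 s^-1.
#' @export
kcc2_flux <- function(cl_in, params, k_out = params$null_offset) {
  stopifnot(inherits(params, "kcc2_params"))
  x <- (cl_in - k_out) / params$michaelis_scale
  ifelse(x > 0, params$vmax * x / (1 + x), 0)
}

#' Calibrate a GHK permeability from a slope conductance
#'
#' Returns the permeability-area product P such that the GHK chloride
#' current at the test potential equals the ohmic current
#' g (v_test - E_Cl). Used to convert synaptic conductances to the
#' permeabilities the GHK fluxes need (test conditions in the dynamic model:
#' Vm = -60 mV, Cl_in = 5 mM).
#'
#' @param g conductance, nS (> 0 for a physical membrane; 0 allowed).
#' @param cond an [ion_conditions] object (uses cl_in, cl_out, temperature).
#' @param v_test test potential, mV; must differ from the Cl- Nernst
#'   potential.
#' @return permeability-area product in m^3 s^-1.
#' @export
conductance_to_permeability <- function(g, cond, v_test = -60) {
  stopifnot(inherits(cond, "ion_conditions"), g >= 0)
  e_cl <- nernst(cond$cl_in, cond$cl_out, cond$temperature, valence = -1)
  if (abs(v_test - e_cl) < 1e-9)
    stop("zero driving force at v_test; permeability is undefined")
  target <- g * (v_test - e_cl)  # nS * mV = pA, influx-positive for an anion
  unit <- ghk_anion_current(1, v_test, cond$cl_in, cond$cl_out, cond$temperature)
  target / unit
}
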