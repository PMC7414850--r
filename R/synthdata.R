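# Seeded synthetic-data generators. Each generator is a pure function of
# its arguments and seed, and attaches its ground-truth parameters to the
# output (attribute "truth") so recovery tests are self-contained.

#' Synthetic GABA I-V recording
#'
#' Currents follow the linear model g (V - E_true) plus Gaussian noise,
#' emulating voltage-step GABA puff responses (12.5 mV steps, 3 repeats
#' per voltage).
#'
#' @param e_true true reversal potential, mV.
#' @param g slope conductance, nS.
#' @param noise_sd current noise SD, pA.
#' @param voltages holding potentials, mV.
#' @param repeats repeats per voltage (>= 1).
#' @param junction_offset junction offset recorded with the data, mV.
#' @param seed integer seed.
#' @return an [iv_recording] with attribute `truth`.
#' @export
gen_iv <- function(e_true, g = 1, noise_sd = 2,
                   voltages = seq(-85, 2.5, by = 12.5), repeats = 3,
                   junction_offset = 0, seed = 1) {
  stopifnot(repeats >= 1, noise_sd >= 0)
  set.seed(seed)
  v <- rep(voltages, each = repeats)
  i <- g * (v - e_true) + stats::rnorm(length(v), 0, noise_sd)
  out <- iv_recording(v, i, junction_offset)
  attr(out, "truth") <- list(e_true = e_true, g = g, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Synthetic FLIM photon histogram
#'
#' Poisson-sampled mono-exponential decay, optionally convolved with a
#' Gaussian instrument response (centred at `irf_t0`), emulating MQAE
#' photon-counting histograms.
#'
#' @param tau true lifetime, ns.
#' @param counts expected total photon count.
#' @param irf_sigma Gaussian IRF width, ns; 0 gives a delta IRF (no IRF
#'   histogram stored).
#' @param bin_width,n_bins histogram geometry.
#' @param irf_t0 IRF centre, ns.
#' @param ksv,tau_zero Stern-Volmer parameters carried by the trace.
#' @param seed integer seed.
#' @return a [flim_trace] with attribute `truth`.
#' @export
gen_flim <- function(tau, counts = 1e5, irf_sigma = 0, bin_width = 0.05,
                     n_bins = 256, irf_t0 = 2, ksv = 32, tau_zero = 5.5,
                     seed = 1) {
  stopifnot(tau > 0, counts > 0)
  set.seed(seed)
  tt <- (seq_len(n_bins) - 0.5) * bin_width
  shape <- exp(-tt / tau)
  irf <- NULL
  if (irf_sigma > 0) {
    irf <- stats::dnorm(tt, irf_t0, irf_sigma)
    irf <- irf / sum(irf)
    shape <- .irf_convolve(irf, shape)
  }
  lam <- counts * shape / sum(shape)
  y <- stats::rpois(n_bins, lam)
  out <- flim_trace(y, bin_width, irf = irf, ksv = ksv,
                    tau_zero = tau_zero)
  attr(out, "truth") <- list(tau = tau, counts = counts,
                             irf_sigma = irf_sigma, seed = seed)
  out
}

#' Synthetic annotated laminar image
#'
#' Builds a multi-channel dorsal-horn-like image: a KCC2 channel with a
#' dorsoventral intensity gradient, an IB4 band along a known quadratic
#' axis, a CGRP band dorsal to it, optional ring cells (bright membrane
#' annulus over dimmer cytoplasm) and Gaussian noise. The dorsal white
#' matter occupies the top `wm_depth` um and carries no signal. All
#' ground-truth annotations (axis coefficients, lamina masks,
#' intracellular masks, membrane polylines, background region) are
#' returned alongside the channels.
#'
#' @param size `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param kcc2_gradient KCC2 intensity slope with depth, i.u./um.
#' @param kcc2_base KCC2 intensity at the white-matter border, i.u.
#' @param wm_depth white-matter depth, um.
#' @param ib4_centre_depth,ib4_amp,ib4_sigma IB4 band: centre depth (um),
#'   amplitude, width (um).
#' @param ib4_tilt,ib4_curv linear and quadratic coefficients (px per px
#'   and px per px^2) of the band axis about the image centre column.
#' @param cgrp_centre_depth,cgrp_amp,cgrp_sigma CGRP band geometry.
#' @param n_cells number of ring cells in the KCC2 channel.
#' @param cell_radius cell radius, um.
#' @param membrane_iu,cytoplasm_iu added membrane / cytoplasm intensity.
#' @param noise_sd Gaussian noise SD, i.u.
#' @param seed integer seed.
#' @return a `laminar_image`: list with `channels` (kcc2/ib4/cgrp
#'   matrices), `pixel_size`, `annotations` and attribute `truth`.
#' @export
gen_laminar_image <- function(size = c(256, 256), pixel_size = 0.4,
                              kcc2_gradient = 3.4, kcc2_base = 40,
                              wm_depth = 12,
                              ib4_centre_depth = 45, ib4_amp = 150,
                              ib4_sigma = 6, ib4_tilt = 0, ib4_curv = 0,
                              cgrp_centre_depth = 25, cgrp_amp = 150,
                              cgrp_sigma = 5,
                              n_cells = 6, cell_radius = 5,
                              membrane_iu = 80, cytoplasm_iu = 30,
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  nr <- size[1]; nc <- size[2]
  depth <- (seq_len(nr) - 0.5) * pixel_size        # um from the top edge
  depth_m <- matrix(depth, nr, nc)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rowm <- matrix(seq_len(nr), nr, nc)

  sdh <- depth_m >= wm_depth
  kcc2 <- ifelse(sdh, kcc2_base + kcc2_gradient * (depth_m - wm_depth), 0)

  mid <- nc / 2
  axis_row <- function(col)
    ib4_centre_depth / pixel_size + ib4_tilt * (col - mid) +
      ib4_curv * (col - mid)^2
  ib4 <- ib4_amp * exp(-(rowm - axis_row(colm))^2 /
                         (2 * (ib4_sigma / pixel_size)^2))
  cgrp_row <- cgrp_centre_depth / pixel_size
  cgrp <- cgrp_amp * exp(-(rowm - cgrp_row)^2 /
                           (2 * (cgrp_sigma / pixel_size)^2))

  r_px <- cell_radius / pixel_size
  intracellular <- matrix(FALSE, nr, nc)
  polylines <- list()
  cells <- NULL
  if (n_cells > 0) {
    margin <- ceiling(r_px) + 2
    lo <- wm_depth / pixel_size + margin
    hi <- min(nr - margin, 90 / pixel_size)
    if (hi <= lo)
      stop("image too small for the requested cells; reduce cell_radius ",
           "or set n_cells = 0")
    cr <- round(stats::runif(n_cells, lo, hi))
    cc <- round(stats::runif(n_cells, margin, nc - margin))
    cells <- data.frame(row = cr, col = cc, radius_px = r_px)
    for (i in seq_len(n_cells)) {
      d <- sqrt((rowm - cr[i])^2 + (colm - cc[i])^2)
      kcc2[d <= r_px & d > r_px - 1.5] <-
        kcc2[d <= r_px & d > r_px - 1.5] + membrane_iu
      kcc2[d <= r_px - 1.5] <- kcc2[d <= r_px - 1.5] + cytoplasm_iu
      intracellular <- intracellular | (d <= r_px - 3)
      th <- seq(0, 2 * pi, length.out = 49)   # interior on the left
      polylines[[i]] <- cbind(row = cr[i] + r_px * cos(th),
                              col = cc[i] + r_px * sin(th))
    }
  }
  if (noise_sd > 0) {
    kcc2 <- pmax(kcc2 + stats::rnorm(nr * nc, 0, noise_sd), 0)
    ib4 <- pmax(ib4 + stats::rnorm(nr * nc, 0, noise_sd), 0)
    cgrp <- pmax(cgrp + stats::rnorm(nr * nc, 0, noise_sd), 0)
  }
  a0 <- ib4_centre_depth / pixel_size + ib4_tilt * (-mid) + ib4_curv * mid^2
  a1 <- ib4_tilt - 2 * ib4_curv * mid
  a2 <- ib4_curv
  ann <- list(
    background_region = !sdh,
    lamina_masks = list(
      LI = sdh & depth_m < wm_depth + 20,
      LII = depth_m >= wm_depth + 20 & depth_m < wm_depth + 80),
    intracellular_mask = intracellular,
    membrane_polylines = polylines,
    cells = cells,
    axis_coef = c(a0, a1, a2))
  out <- structure(list(channels = list(kcc2 = kcc2, ib4 = ib4,
                                        cgrp = cgrp),
                        pixel_size = pixel_size, annotations = ann),
                   class = "laminar_image")
  attr(out, "truth") <- list(kcc2_gradient = kcc2_gradient,
                             axis_coef = c(a0, a1, a2),
                             wm_depth = wm_depth, seed = seed)
  out
}

#' Synthetic immunogold particle field
#'
#' Mixture of uniformly scattered monomers and Gaussian clusters
#' (oligomers) in a 2D field. The cluster spread is well below half the
#' 65 nm linkage cutoff so that clustered particles link, while the field
#' is kept sparse so that monomers rarely link by chance.
#'
#' @param n total particle count.
#' @param oligomer_fraction fraction of particles placed in clusters.
#' @param cluster_spread Gaussian SD of particle offsets within a
#'   cluster, nm.
#' @param field field side length, nm; by default sized so that the
#'   expected number of chance sub-cutoff pairs among monomers is well
#'   below 1.
#' @param cluster_sizes candidate cluster sizes.
#' @param cutoff linkage cutoff carried by the set, nm.
#' @param seed integer seed.
#' @return a [particle_set] with attribute `truth` (including the per-
#'   particle ground-truth oligomer labels).
#' @export
gen_particles <- function(n = 200, oligomer_fraction = 0.5,
                          cluster_spread = 15, field = NULL,
                          cluster_sizes = 2:4, cutoff = 65, seed = 1) {
  stopifnot(oligomer_fraction >= 0, oligomer_fraction <= 1, n >= 1)
  set.seed(seed)
  if (is.null(field)) field <- sqrt(200 * n * pi * cutoff^2)
  n_olig <- round(oligomer_fraction * n)
  sizes <- integer(0)
  while (sum(sizes) < n_olig)
    sizes <- c(sizes, sample(cluster_sizes, 1))
  if (length(sizes)) sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - n_olig)
  sizes <- sizes[sizes > 0]
  coords <- NULL; truth_olig <- logical(0)
  for (s in sizes) {
    ctr <- stats::runif(2, 3 * cluster_spread, field - 3 * cluster_spread)
    coords <- rbind(coords, cbind(ctr[1] + stats::rnorm(s, 0, cluster_spread),
                                  ctr[2] + stats::rnorm(s, 0, cluster_spread)))
    truth_olig <- c(truth_olig, rep(s >= 2, s))
  }
  n_mono <- n - sum(sizes)
  if (n_mono > 0) {
    coords <- rbind(coords, cbind(stats::runif(n_mono, 0, field),
                                  stats::runif(n_mono, 0, field)))
    truth_olig <- c(truth_olig, rep(FALSE, n_mono))
  }
  out <- particle_set(coords, cutoff = cutoff)
  attr(out, "truth") <- list(oligomer_fraction = oligomer_fraction,
                             oligomeric = truth_olig,
                             cluster_spread = cluster_spread,
                             field = field, seed = seed)
  out
}

#' Synthetic eIPSC depression train
#'
#' 25 peak amplitudes following the one-phase decay
#' a_i = amp1 (plateau + (1 - plateau) exp(-rate (i - 1))) with additive
#' Gaussian noise in relative units.
#'
#' @param plateau asymptotic relative amplitude in [0, 1].
#' @param rate decay constant K, per stimulus.
#' @param noise_sd relative noise SD.
#' @param amp1 first-pulse amplitude, pA.
#' @param n_pulses train length.
#' @param seed integer seed.
#' @return numeric vector of amplitudes with attribute `truth`.
#' @export
gen_eipsc_train <- function(plateau, rate, noise_sd = 0, amp1 = 100,
                            n_pulses = 25, seed = 1) {
  stopifnot(plateau >= 0, plateau <= 1, rate >= 0, noise_sd >= 0)
  set.seed(seed)
  i <- seq_len(n_pulses)
  rel <- plateau + (1 - plateau) * exp(-rate * (i - 1))
  amp <- amp1 * (rel + stats::rnorm(n_pulses, 0, noise_sd))
  attr(amp, "truth") <- list(plateau = plateau, rate = rate,
                             noise_sd = noise_sd, seed = seed)
  amp
}
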