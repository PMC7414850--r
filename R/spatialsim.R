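# Reduced-dimension (axisymmetric 1D finite-volume) model of the
# pipette-imposed chloride load: Fickian axial diffusion along the
# pipette cone -> soma ellipsoid -> merged dendritic cylinder chain, with
# saturating KCC2 efflux on soma/dendrite membrane and a fixed
# concentration at the pipette back boundary.

#' Build the discretized pipette/soma/dendrite chain
#'
#' The pipette is a truncated cone (tip diameter 1.2 um, back diameter
#' 22 um, length 120 um) discretized along its axis; the soma is the
#' laminar prolate ellipsoid (semi-axes 10.75/5.5 um for LI, 7.9/4.58 um
#' for LII) sliced along its long axis, each slice carrying the exact
#' surface-band membrane area; the two dendritic cylinders (1.5 um
#' diameter, `dendrite_length` um) are merged into one equivalent cylinder
#' of doubled cross-section and membrane beyond the distal pole. Membrane
#' area is zero inside the pipette; the dendrite tip is sealed.
#'
#' @param lamina `"LI"` or `"LII"`.
#' @param resolution element length, um (<= 2).
#' @param dendrite_length dendrite length, um.
#' @param n_dendrites number of dendritic cylinders merged.
#' @param pipette list with `length`, `tip_diameter`, `back_diameter` (um).
#' @param diffusion_coef chloride diffusion coefficient, m^2 s^-1
#'   (default 2.03e-9).
#' @param kcc2_regions regions whose membrane carries KCC2.
#' @return a `compartment_chain`: a data frame with columns `region`, `x`
#'   (axial midpoint, um), `dx`, `area` (cross-section, um^2), `volume`
#'   (um^3), `mem_area` (KCC2-bearing membrane, um^2), plus attributes
#'   `diffusion_coef_um2_s` and `lamina`. The first element (pipette back)
#'   is the fixed-concentration boundary.
#' @export
build_geometry <- function(lamina = c("LI", "LII"), resolution = 1,
                           dendrite_length = 80, n_dendrites = 2,
                           pipette = list(length = 120, tip_diameter = 1.2,
                                          back_diameter = 22),
                           diffusion_coef = 2.03e-9,
                           kcc2_regions = c("soma", "dendrite")) {
  lamina <- match.arg(lamina)
  if (resolution > 2) stop("resolution must be <= 2 um")
  ax <- if (lamina == "LI") c(10.75, 5.5) else c(7.9, 4.58)
  a <- ax[1]; b <- ax[2]

  np <- ceiling(pipette$length / resolution)
  xs <- seq(0, pipette$length, length.out = np + 1)
  r_tip <- pipette$tip_diameter / 2
  r_back <- pipette$back_diameter / 2
  r_pip <- function(x) r_back + (r_tip - r_back) * x / pipette$length
  mid_p <- (xs[-1] + xs[-(np + 1)]) / 2
  pip <- data.frame(region = "pipette", x = mid_p, dx = diff(xs),
                    area = pi * r_pip(mid_p)^2, mem_area = 0)

  nsl <- ceiling(2 * a / resolution)
  xs2 <- seq(0, 2 * a, length.out = nsl + 1)
  mid_s <- (xs2[-1] + xs2[-(nsl + 1)]) / 2
  r_soma <- function(x) b * sqrt(pmax(0, 1 - ((x - a) / a)^2))
  band <- vapply(seq_len(nsl), function(i) {
    xq <- seq(xs2[i], xs2[i + 1], length.out = 33)
    r <- r_soma(xq)
    drdx <- (b^2 / a^2) * (a - xq) / pmax(r, 1e-9)
    f <- 2 * pi * r * sqrt(1 + drdx^2)
    sum((f[-1] + f[-33]) / 2) * (xq[2] - xq[1])
  }, numeric(1))
  soma <- data.frame(region = "soma", x = pipette$length + mid_s,
                     dx = diff(xs2), area = pi * r_soma(mid_s)^2,
                     mem_area = band)

  nd <- ceiling(dendrite_length / resolution)
  ddx <- dendrite_length / nd
  rdn <- 0.75  # dendrite radius, um (1.5 um diameter)
  den <- data.frame(region = "dendrite",
                    x = pipette$length + 2 * a + (seq_len(nd) - 0.5) * ddx,
                    dx = ddx, area = n_dendrites * pi * rdn^2,
                    mem_area = n_dendrites * 2 * pi * rdn * ddx)

  ch <- rbind(pip, soma, den)
  ch$volume <- ch$area * ch$dx
  ch$mem_area[!(ch$region %in% kcc2_regions)] <- 0
  structure(ch, class = c("compartment_chain", "data.frame"),
            diffusion_coef_um2_s = diffusion_coef * 1e12, lamina = lamina)
}

# Interface diffusive conductances (um^3/s) between consecutive elements:
# series (harmonic) combination of the half-element conductances, i.e. the
# truncated-cone series-conductance formula at the discrete level.
.chain_conductances <- function(chain) {
  n <- nrow(chain)
  d <- attr(chain, "diffusion_coef_um2_s")
  d / (chain$dx[-n] / (2 * chain$area[-n]) +
       chain$dx[-1] / (2 * chain$area[-1]))
}

#' Steady-state chloride profile under a pipette load
#'
#' Solves the 1D finite-volume balance: Fickian axial fluxes between
#' elements, saturating KCC2 efflux `J * mem_area` as a sink on membrane-
#' bearing elements, and a fixed concentration at the pipette back
#' boundary. A damped Newton iteration on the tridiagonal system is used;
#' the nonlinearity (the saturating flux) is mild and convergence is
#' quadratic.
#'
#' @param chain a `compartment_chain` from [build_geometry].
#' @param kcc2 a [kcc2_params]; the fixed-K form of the flux is used (the
#'   spatial model does not track extracellular K+).
#' @param pipette_cl imposed pipette chloride, mM.
#' @param tol convergence tolerance on the maximal residual flux relative
#'   to the total turnover.
#' @param max_iter Newton iteration cap.
#' @return a `load_solution`: list with `profile` (data frame of `x`,
#'   `region`, `cl`), `somatic_cl` (volume-weighted somatic mean, mM),
#'   `iterations`, `residual` and `pipette_cl`.
#' @export
steady_state_cl <- function(chain, kcc2, pipette_cl = 29, tol = 1e-10,
                            max_iter = 200) {
  stopifnot(inherits(chain, "compartment_chain"),
            inherits(kcc2, "kcc2_params"))
  if (pipette_cl <= kcc2$null_offset)
    stop("pipette concentration must exceed the KCC2 null point")
  n <- nrow(chain)
  g <- .chain_conductances(chain)
  vmax <- kcc2$vmax; k0 <- kcc2$null_offset; ms <- kcc2$michaelis_scale
  sink <- function(c) {
    x <- (c - k0) / ms
    ifelse(x > 0, vmax * x / (1 + x), 0) * chain$mem_area
  }
  dsink <- function(c) {
    x <- (c - k0) / ms
    ifelse(x > 0, vmax / ms / (1 + x)^2, 0) * chain$mem_area
  }
  cl <- rep(pipette_cl, n)
  residual_of <- function(c) {
    fl <- c(0, g * (c[-n] - c[-1]))       # flux entering i from the left
    fr <- c(g * (c[-1] - c[-n]), 0)       # flux entering i from the right
    r <- fl + fr - sink(c)
    r[1] <- 0                              # fixed boundary
    r
  }
  scale <- max(1, vmax * sum(chain$mem_area))
  res <- residual_of(cl)
  resid <- max(abs(res)) / scale
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (resid < tol) break
    lower <- c(0, g)
    upper <- c(g, 0)
    diag_ <- -c(0, g) - c(g, 0) - dsink(cl)
    diag_[1] <- 1; upper[1] <- 0
    dc <- .thomas(lower, diag_, upper, -res)
    # backtracking line search on the residual norm, iterates kept in
    # the physical band (0, pipette_cl]
    lam <- 1; norm0 <- max(abs(res))
    repeat {
      cand <- pmin(pmax(cl + lam * dc, 1e-9), pipette_cl)
      res_c <- residual_of(cand)
      if (max(abs(res_c)) < norm0 || lam < 1e-8) break
      lam <- lam / 2
    }
    cl <- cand; res <- res_c
    resid <- max(abs(res)) / scale
  }
  if (resid >= tol)
    stop("steady-state solve did not converge: relative residual ",
         format(resid), " after ", it, " iterations")
  soma <- chain$region == "soma"
  structure(list(
    profile = data.frame(x = chain$x, region = chain$region, cl = cl),
    somatic_cl = sum(cl[soma] * chain$volume[soma]) / sum(chain$volume[soma]),
    iterations = it, residual = resid, pipette_cl = pipette_cl,
    chain = chain, kcc2 = kcc2), class = "load_solution")
}

# Thomas algorithm for a tridiagonal system; lower/upper padded to length n.
.thomas <- function(lower, diag_, upper, rhs) {
  n <- length(rhs)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag_[1]
  dp[1] <- rhs[1] / diag_[1]
  for (i in 2:n) {
    m <- diag_[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Fit the extrusion capacity to a target somatic chloride
#'
#' Bisects Vmax in [0, 200] micromole m^-2 s^-1 until the steady-state
#' volume-weighted somatic mean matches `target_somatic_cl`.
#'
#' @param chain a `compartment_chain`.
#' @param target_somatic_cl target somatic mean, mM; must lie strictly
#'   between the KCC2 null point and `pipette_cl`.
#' @param pipette_cl imposed pipette chloride, mM.
#' @param kcc2_template [kcc2_params] supplying null offset and scale.
#' @param tol bisection tolerance on Vmax, micromole m^-2 s^-1.
#' @param vmax_range search interval.
#' @return fitted Vmax, micromole m^-2 s^-1.
#' @export
fit_vmax <- function(chain, target_somatic_cl, pipette_cl = 29,
                     kcc2_template = kcc2_params(1), tol = 0.1,
                     vmax_range = c(0, 200)) {
  stopifnot(inherits(chain, "compartment_chain"))
  if (target_somatic_cl >= pipette_cl ||
      target_somatic_cl <= kcc2_template$null_offset)
    stop("target somatic chloride must lie strictly between the KCC2 ",
         "null point and the pipette concentration")
  mean_at <- function(v) {
    k <- kcc2_params(v, kcc2_template$null_offset,
                     kcc2_template$michaelis_scale)
    steady_state_cl(chain, k, pipette_cl)$somatic_cl
  }
  lo <- vmax_range[1]; hi <- vmax_range[2]
  if (mean_at(hi) > target_somatic_cl)
    stop("target below the somatic chloride attainable at Vmax = ",
         hi, "; out of range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mean_at(mid) > target_somatic_cl) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Extent of the chloride gradient at the pipette tip
#'
#' Distance from the pipette tip, back into the pipette, at which the
#' profile has recovered to `fraction` of the imposed pipette
#' concentration.
#'
#' @param solution a `load_solution` from [steady_state_cl].
#' @param fraction recovery fraction in (0, 1); default 0.95.
#' @return distance in um. If the profile never reaches the fraction the
#'   pipette length is returned with attribute `censored = TRUE`.
#' @export
tip_gradient_extent <- function(solution, fraction = 0.95) {
  stopifnot(inherits(solution, "load_solution"),
            fraction > 0, fraction < 1)
  prof <- solution$profile
  pip <- prof$region == "pipette"
  x_tip <- max(prof$x[pip]) + solution$chain$dx[sum(pip)] / 2
  dist <- x_tip - prof$x[pip]     # distance from tip, increasing backwards
  cl <- prof$cl[pip]
  thr <- fraction * solution$pipette_cl
  if (cl[length(cl)] >= thr) return(0)
  if (max(cl) < thr) {
    out <- max(dist)
    attr(out, "censored") <- TRUE
    return(out)
  }
  # profile rises with distance from the tip; interpolate the crossing
  stats::approx(rev(cl), rev(dist), xout = thr, ties = "ordered")$y
}
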