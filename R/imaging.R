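# Image- and point-pattern quantification: FLIM lifetime fitting and
# Stern-Volmer conversion, chloride-vs-depth regression, IB4 barycentric
# laminar axis, trans-laminar intensity profiles, membrane indices
# (global index and distance-profile), and immunogold transitive
# clustering.

#' FLIM photon-arrival histogram
#'
#' @param counts photon counts per arrival-time bin.
#' @param bin_width bin width, ns.
#' @param irf optional instrument-response histogram on the same bins
#'   (normalized internally); a delta IRF is assumed when absent.
#' @param ksv Stern-Volmer chloride sensitivity, M^-1 (32 for MQAE).
#' @param tau_zero fluorescence lifetime at 0 mM Cl-, ns (set from the
#'   dye calibration; 5.5 ns is a representative MQAE value).
#' @return a `flim_trace` object.
#' @export
flim_trace <- function(counts, bin_width, irf = NULL, ksv = 32,
                       tau_zero = 5.5) {
  stopifnot(all(counts >= 0), bin_width > 0, ksv > 0, tau_zero > 0)
  if (!is.null(irf)) stopifnot(length(irf) == length(counts), all(irf >= 0))
  structure(list(counts = counts, bin_width = bin_width, irf = irf,
                 ksv = ksv, tau_zero = tau_zero), class = "flim_trace")
}

# causal discrete convolution of a normalized IRF with a decay shape
.irf_convolve <- function(irf, shape) {
  n <- length(shape)
  irf <- irf / sum(irf)
  out <- stats::convolve(c(irf, rep(0, n)), rev(c(shape, rep(0, n))),
                         type = "open")[seq_len(n)]
  pmax(out, 0)
}

#' Fit a mono-exponential fluorescence lifetime
#'
#' Least-squares fit of A exp(-t/tau), convolved with the instrument
#' response when one is present, to the photon histogram. The amplitude is
#' profiled out analytically, leaving a 1-D minimization over tau, so the
#' fit is scale-invariant in the total counts.
#'
#' @param trace a [flim_trace] (total counts must exceed 100).
#' @param poisson_weighted logical; weight residuals by 1/max(y, 1)
#'   (approximate Poisson weighting). Default unweighted.
#' @return fitted lifetime tau, ns, with the fitted amplitude and residual
#'   sum of squares as attributes.
#' @export
fit_lifetime <- function(trace, poisson_weighted = FALSE) {
  stopifnot(inherits(trace, "flim_trace"))
  y <- trace$counts
  if (sum(y) <= 100) stop("too few photons (<= 100) to fit a lifetime")
  n <- length(y)
  tt <- (seq_len(n) - 0.5) * trace$bin_width
  w <- if (poisson_weighted) 1 / pmax(y, 1) else rep(1, n)
  shape_of <- function(tau) {
    s <- exp(-tt / tau)
    if (!is.null(trace$irf)) s <- .irf_convolve(trace$irf, s)
    s
  }
  rss <- function(tau) {
    s <- shape_of(tau)
    a <- sum(w * y * s) / sum(w * s^2)
    sum(w * (y - a * s)^2)
  }
  opt <- stats::optimize(rss, interval = c(trace$bin_width / 5,
                                           5 * max(tt)), tol = 1e-10)
  tau <- opt$minimum
  s <- shape_of(tau)
  a <- sum(w * y * s) / sum(w * s^2)
  structure(tau, amplitude = a, residual_ss = opt$objective)
}

#' Stern-Volmer chloride concentration from a lifetime
#'
#' [Cl-] = (tau_0/tau - 1) / Ksv, converted to mM.
#'
#' @param tau fitted lifetime, ns.
#' @param trace the [flim_trace] supplying `tau_zero` and `ksv`.
#' @return chloride concentration, mM (negative values, arising when
#'   tau > tau_0, are clipped to 0 with a warning).
#' @export
stern_volmer_cl <- function(tau, trace) {
  stopifnot(inherits(trace, "flim_trace"), tau > 0)
  cl <- (trace$tau_zero / tau - 1) / trace$ksv * 1000
  if (any(cl < 0)) {
    warning("lifetime exceeds tau_zero; negative [Cl-] clipped to 0")
    cl <- pmax(cl, 0)
  }
  cl
}

#' Chloride-versus-depth regression
#'
#' Per-cell chloride estimates are binned by depth (bin means plotted at
#' bin centres) and an ordinary least-squares line is fit through the bin
#' means.
#'
#' @param depth distance of each soma from the dorsal white matter, um.
#' @param cl estimated [Cl-]_i, mM.
#' @param bin bin width, um (default 20).
#' @return list with `slope` (mM/um), `intercept`, `bins` (data frame of
#'   centre/mean/n) and the `lm` fit.
#' @export
cl_depth_regression <- function(depth, cl, bin = 20) {
  stopifnot(length(depth) == length(cl), bin > 0)
  idx <- floor(depth / bin)
  centre <- (as.numeric(names(table(idx))) + 0.5) * bin
  mu <- as.numeric(tapply(cl, idx, mean))
  nn <- as.integer(table(idx))
  if (length(mu) < 2) stop("need at least two occupied depth bins")
  fit <- stats::lm(mu ~ centre)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       bins = data.frame(centre = centre, mean = mu, n = nn), fit = fit)
}

#' Barycentric IB4 laminar axis
#'
#' For each image column, the IB4 band centre is the order-`order`
#' intensity-weighted barycentre sum_r r I(r,c)^order / sum_r I(r,c)^order;
#' columns whose weight total falls below `floor_frac` of the image-wide
#' column median are excluded, and a quadratic row(col) curve is fit
#' through the remaining centres by least squares.
#'
#' @param ib4 IB4 channel matrix (rows x cols).
#' @param order barycentre exponent (default 4).
#' @param floor_frac exclusion floor as a fraction of the median column
#'   weight.
#' @return an `ib4_axis` object: list with `coef` (quadratic coefficients
#'   `c(intercept, linear, quadratic)` of row as a function of column),
#'   `centres` (data frame of the retained per-column centres) and
#'   `predict` (function of column).
#' @export
ib4_axis <- function(ib4, order = 4, floor_frac = 0.01) {
  stopifnot(is.matrix(ib4), order > 0)
  w <- ib4^order
  tot <- colSums(w)
  keep <- tot > floor_frac * stats::median(tot)
  if (!any(keep)) stop("all columns excluded: no IB4 signal")
  rows <- seq_len(nrow(ib4))
  centre <- colSums(rows * w) / tot
  col <- which(keep)
  fit <- stats::lm(centre[keep] ~ col + I(col^2))
  cf <- unname(stats::coef(fit))
  structure(list(coef = cf,
                 centres = data.frame(col = col, row = centre[keep]),
                 predict = function(column)
                   cf[1] + cf[2] * column + cf[3] * column^2),
            class = "ib4_axis")
}

# signed min distance (px) of every pixel to the axis curve sampled at
# column centres; positive towards the dorsal side
.axis_distance_map <- function(dim_img, axis, dorsal = "top") {
  nr <- dim_img[1]; nc <- dim_img[2]
  ycurve <- axis$predict(seq_len(nc))
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  mind2 <- matrix(Inf, nr, nc)
  for (j in seq_len(nc)) {
    d2 <- (rowm - ycurve[j])^2 + (colm - j)^2
    mind2 <- pmin(mind2, d2)
  }
  side <- rowm < ycurve[colm]     # above the curve (smaller row)
  sgn <- if (dorsal == "top") ifelse(side, 1, -1) else ifelse(side, -1, 1)
  sgn * sqrt(mind2)
}

#' Trans-laminar intensity profile
#'
#' For every pixel, the signed minimum Euclidean distance to the IB4 axis
#' curve is computed (pixels on the superficial/dorsal side positive), and
#' each channel's mean intensity is binned against that distance.
#'
#' @param channels named list of channel matrices (or one matrix).
#' @param axis an [ib4_axis].
#' @param pixel_size pixel size, um.
#' @param bin bin width, um.
#' @param dorsal which image edge is dorsal (`"top"` or `"bottom"`).
#' @return list with `profile` (data frame: `distance` bin centre in um
#'   and one mean-intensity column per channel) and `distance_map` (signed
#'   distances, um).
#' @export
translaminar_profile <- function(channels, axis, pixel_size = 0.103,
                                 bin = 5, dorsal = c("top", "bottom")) {
  dorsal <- match.arg(dorsal)
  if (is.matrix(channels)) channels <- list(intensity = channels)
  stopifnot(inherits(axis, "ib4_axis"), length(channels) >= 1)
  dm <- .axis_distance_map(dim(channels[[1]]), axis, dorsal) * pixel_size
  idx <- floor(dm / bin)
  lev <- sort(unique(as.vector(idx)))
  prof <- data.frame(distance = (lev + 0.5) * bin)
  for (nm in names(channels)) {
    stopifnot(all(dim(channels[[nm]]) == dim(channels[[1]])))
    prof[[nm]] <- as.numeric(tapply(as.vector(channels[[nm]]),
                                    factor(as.vector(idx), levels = lev),
                                    mean))
  }
  list(profile = prof, distance_map = dm)
}

#' Membrane analysis by global index (MAGI)
#'
#' M = mean intensity over the lamina region minus the mean intensity over
#' the identified intracellular regions; because intracellular
#' contamination is common to both terms, the difference indexes the
#' membrane-associated signal without manual cell selection. The image
#' should already be background-subtracted (see [subtract_background]).
#'
#' @param image channel matrix.
#' @param lamina_mask logical matrix selecting the lamina region.
#' @param intracellular_mask logical matrix selecting cytoplasmic regions.
#' @return the global membrane intensity index M (intensity units).
#' @export
magi_index <- function(image, lamina_mask, intracellular_mask) {
  stopifnot(is.matrix(image), all(dim(lamina_mask) == dim(image)),
            all(dim(intracellular_mask) == dim(image)))
  if (!any(lamina_mask)) stop("empty lamina mask")
  if (!any(intracellular_mask)) stop("empty intracellular mask")
  mean(image[lamina_mask]) - mean(image[intracellular_mask])
}

# distance (px) from points (r, c) to segment p1-p2 (rows of (row, col)),
# plus the side sign (+1 = left of traversal p1 -> p2)
.segment_distance <- function(r, c, p1, p2) {
  vr <- p2[1] - p1[1]; vc <- p2[2] - p1[2]
  len2 <- vr^2 + vc^2
  if (len2 == 0) stop("degenerate polyline segment (repeated vertex)")
  or <- r - p1[1]; oc <- c - p1[2]
  t <- pmin(1, pmax(0, (or * vr + oc * vc) / len2))
  dr <- or - t * vr; dc <- oc - t * vc
  list(dist = sqrt(dr^2 + dc^2), side = sign(vr * oc - vc * or))
}

#' Membrane distance-profile analysis (MASC-pi)
#'
#' For each pixel, the distance to the closest membrane polyline segment
#' is computed; the sign is positive on the intracellular side, defined as
#' the left of the traversal direction of the polyline. Channel intensity
#' is then binned in pixel-width distance shells.
#'
#' @param image channel matrix.
#' @param polylines list of polylines, each a matrix with columns
#'   (row, col) in pixel coordinates (>= 2 vertices).
#' @param pixel_size pixel size, um.
#' @param max_distance maximal |distance| retained, um.
#' @return list with `profile` (data frame: `distance` shell centre in um,
#'   `mean`, `sd`, `n`) and `distance_map` (signed distances, um).
#' @export
masc_profile <- function(image, polylines, pixel_size = 0.103,
                         max_distance = 5) {
  stopifnot(is.matrix(image), is.list(polylines), length(polylines) >= 1)
  nr <- nrow(image); nc <- ncol(image)
  r <- as.vector(matrix(seq_len(nr), nr, nc))
  c <- as.vector(matrix(rep(seq_len(nc), each = nr), nr, nc))
  best <- rep(Inf, nr * nc); bsign <- rep(1, nr * nc)
  for (pl in polylines) {
    if (!is.matrix(pl) || nrow(pl) < 2)
      stop("each polyline needs at least 2 vertices")
    for (k in seq_len(nrow(pl) - 1)) {
      sd_ <- .segment_distance(r, c, pl[k, ], pl[k + 1, ])
      upd <- sd_$dist < best
      best[upd] <- sd_$dist[upd]
      bsign[upd] <- ifelse(sd_$side[upd] == 0, 1, sd_$side[upd])
    }
  }
  dm <- matrix(bsign * best * pixel_size, nr, nc)
  sel <- abs(dm) <= max_distance
  idx <- floor(dm[sel] / pixel_size)
  vals <- image[sel]
  lev <- sort(unique(idx))
  f <- factor(idx, levels = lev)
  prof <- data.frame(
    distance = (lev + 0.5) * pixel_size,
    mean = as.numeric(tapply(vals, f, mean)),
    sd = as.numeric(tapply(vals, f, stats::sd)),
    n = as.integer(table(f)))
  list(profile = prof, distance_map = dm)
}

#' Subtract a background region's mean intensity
#'
#' The mean intensity of a region known to lack signal (e.g. dorsal white
#' matter for KCC2) is subtracted from the whole channel, clipping at 0.
#'
#' @param image channel matrix.
#' @param region logical matrix selecting the background region.
#' @return background-subtracted matrix.
#' @export
subtract_background <- function(image, region) {
  stopifnot(is.matrix(image), all(dim(region) == dim(image)))
  if (!any(region)) stop("empty background region")
  pmax(image - mean(image[region]), 0)
}

#' Immunogold particle set
#'
#' @param coords n x 2 matrix of particle centroid coordinates, nm.
#' @param lamina optional lamina label.
#' @param cutoff linkage cutoff distance, nm (default 65).
#' @return a `particle_set` object.
#' @export
particle_set <- function(coords, lamina = NA_character_, cutoff = 65) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 1, all(is.finite(coords)),
            cutoff > 0)
  structure(list(coords = coords, lamina = lamina, cutoff = cutoff),
            class = "particle_set")
}

#' Transitive clustering of immunogold particles
#'
#' Particles closer than the cutoff are linked, and linkage is transitive:
#' if A-B and B-C are both under the cutoff, A, B and C belong to one
#' group even if A-C is not (single-linkage connected components,
#' implemented by union-find). Particles in components of size >= 2 are
#' classified oligomeric, singletons monomeric; the percentage counts
#' particles, not groups.
#'
#' @param particles a [particle_set] (or an n x 2 coordinate matrix).
#' @param cutoff linkage cutoff, nm (defaults to the set's).
#' @return list with `labels` (component id per particle), `sizes`
#'   (component sizes), `oligomeric` (logical per particle),
#'   `oligomeric_pct`, `n_oligomeric`, `n_monomeric`.
#' @export
cluster_particles <- function(particles, cutoff = NULL) {
  if (!inherits(particles, "particle_set"))
    particles <- particle_set(particles)
  if (is.null(cutoff)) cutoff <- particles$cutoff
  xy <- particles$coords
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    d <- as.matrix(stats::dist(xy))
    edges <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  labels <- match(root, unique(root))
  sizes <- tabulate(labels)
  olig <- sizes[labels] >= 2
  list(labels = labels, sizes = sizes, oligomeric = olig,
       oligomeric_pct = 100 * sum(olig) / n,
       n_oligomeric = sum(olig), n_monomeric = sum(!olig))
}

#' All-pairs interparticle distance histogram
#'
#' Histogram of all n(n-1)/2 pairwise distances between particles of one
#' cell body.
#'
#' @param particles a [particle_set] (>= 2 particles).
#' @param bin bin width, nm.
#' @return data frame with `mid` (bin centre, nm) and `count`.
#' @export
interparticle_histogram <- function(particles, bin = 10) {
  if (!inherits(particles, "particle_set"))
    particles <- particle_set(particles)
  stopifnot(nrow(particles$coords) >= 2, bin > 0)
  d <- as.numeric(stats::dist(particles$coords))
  breaks <- seq(0, (max(d) %/% bin + 1) * bin, by = bin)
  idx <- cut(d, breaks, include.lowest = TRUE)
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             count = as.integer(table(idx)))
}

#' Oligomeric percentage from category counts
#'
#' Convenience for published per-category particle counts: the percentage
#' of particles classified oligomeric.
#'
#' @param n_oligomeric,n_monomeric particle counts.
#' @return percentage of oligomeric particles.
#' @export
oligomer_percentage <- function(n_oligomeric, n_monomeric) {
  stopifnot(n_oligomeric >= 0, n_monomeric >= 0,
            n_oligomeric + n_monomeric > 0)
  100 * n_oligomeric / (n_oligomeric + n_monomeric)
}
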