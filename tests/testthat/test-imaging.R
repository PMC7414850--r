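# FLIM fitting, Stern-Volmer conversion, laminar image quantification,
# membrane profiles and immunogold clustering.

test_that("fit_lifetime recovers a noiseless exponential and is scale-invariant", {
  tt <- (1:256 - 0.5) * 0.05
  y <- 1e4 * exp(-tt / 5)
  tr <- flim_trace(y, 0.05)
  expect_equal(as.numeric(fit_lifetime(tr)), 5, tolerance = 1e-6)
  tr2 <- flim_trace(y * 17, 0.05)
  expect_equal(as.numeric(fit_lifetime(tr2)),
               as.numeric(fit_lifetime(tr)), tolerance = 1e-9)
  expect_error(fit_lifetime(flim_trace(c(10, 20, 30), 0.05)), "photons")
})

test_that("lifetime recovery from Poisson-noise decays is within 2%", {
  taus <- vapply(1:200, function(s)
    as.numeric(fit_lifetime(gen_flim(3, counts = 1e5, seed = s))),
    numeric(1))
  expect_lt(abs(mean(taus) - 3) / 3, 0.02)
  expect_lt(max(abs(taus - 3) / 3), 0.06)
})

test_that("lifetime is recovered through a Gaussian instrument response", {
  tr <- gen_flim(4, counts = 5e5, irf_sigma = 0.2, seed = 11)
  expect_equal(as.numeric(fit_lifetime(tr)), 4, tolerance = 0.03 * 4)
  # ignoring the IRF would bias the fit; the convolved fit must do better
  tr_noirf <- flim_trace(tr$counts, tr$bin_width)
  biased <- as.numeric(fit_lifetime(tr_noirf))
  expect_gt(abs(biased - 4), abs(as.numeric(fit_lifetime(tr)) - 4))
})

test_that("Stern-Volmer conversion matches its closed form and round-trips", {
  tr <- flim_trace(rep(1, 10), 0.05, ksv = 32, tau_zero = 5.5)
  expect_equal(stern_volmer_cl(5.5, tr), 0)
  expect_equal(stern_volmer_cl(5.5 / 1.32, tr), 0.32 / 32 * 1000)
  cl_true <- 12
  tau_fwd <- 5.5 / (1 + 32 * cl_true / 1000)
  expect_equal(stern_volmer_cl(tau_fwd, tr), cl_true, tolerance = 1e-9)
  expect_warning(out <- stern_volmer_cl(6, tr), "clipped")
  expect_equal(out, 0)
})

test_that("chloride-depth regression recovers slopes and is binning-invariant", {
  depth <- seq(0.25, 99.75, by = 0.5)      # uniform cover of every bin
  cl <- 10 - 0.027 * depth
  r10 <- cl_depth_regression(depth, cl, bin = 10)
  r20 <- cl_depth_regression(depth, cl, bin = 20)
  expect_equal(r10$slope, -0.027, tolerance = 1e-9)
  expect_equal(r20$slope, -0.027, tolerance = 1e-9)
  flat <- cl_depth_regression(depth, rep(7, 200), bin = 20)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(cl_depth_regression(rep(5, 10), rnorm(10), bin = 20),
               "two occupied")
  # noisy Monte-Carlo recovery of the activity-gradient slope
  set.seed(99)
  slopes <- vapply(1:500, function(s) {
    cl_n <- 10 - 0.027 * depth + stats::rnorm(200, 0, 2)
    cl_depth_regression(depth, cl_n, bin = 20)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.027), 0.005)
  expect_lt(abs(mean(slopes) + 0.027), 0.010)
})

test_that("ib4_axis finds a uniform band centre with zero curvature", {
  img <- matrix(0, 64, 64)
  img[30:34, ] <- 100
  ax <- ib4_axis(img)
  expect_equal(ax$coef[1], 32, tolerance = 1e-6)
  expect_equal(ax$coef[2], 0, tolerance = 1e-9)
  expect_equal(ax$coef[3], 0, tolerance = 1e-9)
})

test_that("ib4_axis order-4 weighting matches the brute-force barycentre", {
  img <- matrix(0, 40, 3)
  img[10, ] <- 100       # bright blob
  img[30, ] <- 50        # dim blob, intensity ratio 2 -> weight ratio 16
  ax <- ib4_axis(img)
  w <- c(100^4, 50^4)
  expect_equal(ax$centres$row[1], (10 * w[1] + 30 * w[2]) / sum(w))
  # pulled 16:1 towards the bright blob
  expect_lt(ax$centres$row[1], 10 + (30 - 10) / 16)
})

test_that("ib4_axis recovers a generated parabolic band", {
  img <- gen_laminar_image(size = c(200, 200), ib4_tilt = 0.08,
                           ib4_curv = 0.002, noise_sd = 2, seed = 4)
  ax <- ib4_axis(img$channels$ib4)
  truth <- attr(img, "truth")$axis_coef
  expect_equal(ax$coef[1], truth[1], tolerance = 0.02 * abs(truth[1]))
  # the recovered curve tracks the generating parabola within 2% of its
  # intercept everywhere in the image
  cols <- 1:200
  truth_row <- truth[1] + truth[2] * cols + truth[3] * cols^2
  expect_lt(max(abs(ax$predict(cols) - truth_row)), 0.02 * truth[1])
})

test_that("translaminar distances match the exhaustive per-pixel oracle", {
  img <- gen_laminar_image(size = c(48, 48), pixel_size = 1,
                           ib4_centre_depth = 24, wm_depth = 6,
                           cgrp_centre_depth = 12, ib4_curv = 0.004,
                           seed = 2, n_cells = 0)
  ax <- ib4_axis(img$channels$ib4)
  prof <- translaminar_profile(img$channels, ax, pixel_size = 1, bin = 2)
  oracle <- oracle_curve_distance(48, 48, ax$predict(1:48))
  expect_identical(abs(prof$distance_map), oracle)
  # pixels on the curve are at distance ~0; sign splits the two sides
  ycurve <- ax$predict(24)
  expect_lt(abs(prof$distance_map[round(ycurve), 24]), 1)
  expect_gt(prof$distance_map[5, 24], 0)      # dorsal side positive
  expect_lt(prof$distance_map[45, 24], 0)
})

test_that("translaminar profile is flat for uniform images and recovers gradients", {
  ax <- ib4_axis(matrix(rep(c(0, 0, 100, 0, 0), each = 8), 40, 40))
  uni <- translaminar_profile(matrix(7, 40, 40), ax, pixel_size = 1, bin = 5)
  expect_true(all(abs(uni$profile$intensity - 7) < 1e-12))
  # KCC2 ramp: slope against signed distance ~ -gradient (dorsal positive)
  img <- gen_laminar_image(size = c(220, 64), pixel_size = 0.5,
                           kcc2_gradient = 3.4, n_cells = 0, noise_sd = 0,
                           seed = 3)
  ax2 <- ib4_axis(img$channels$ib4)
  pr <- translaminar_profile(img$channels["kcc2"], ax2,
                             pixel_size = 0.5, bin = 2)
  p <- pr$profile
  sel <- p$distance > -30 & p$distance < 20    # inside the graded region
  fit <- stats::lm(kcc2 ~ distance, data = p[sel, ])
  expect_equal(unname(stats::coef(fit)[2]), -3.4, tolerance = 0.05 * 3.4)
})

test_that("magi_index equals the analytic mixture difference and shifts cancel", {
  img <- matrix(10, 60, 60)
  lam <- matrix(FALSE, 60, 60); lam[10:50, ] <- TRUE
  intra <- matrix(FALSE, 60, 60)
  img[20:30, 20:30] <- 40                       # cytoplasm
  intra[20:30, 20:30] <- TRUE
  img[19, 19:31] <- 100; img[31, 19:31] <- 100  # membrane rim
  img[19:31, 19] <- 100; img[19:31, 31] <- 100
  m <- magi_index(img, lam, intra)
  expect_equal(m, mean(img[lam]) - 40)
  expect_equal(magi_index(img + 13, lam, intra), m)   # shift invariance
  expect_equal(magi_index(img, lam, lam), 0)
  expect_error(magi_index(img, lam & FALSE, intra), "empty")
})

test_that("masc_profile matches the exhaustive segment-distance oracle", {
  set.seed(5)
  img <- matrix(stats::rnorm(32 * 32, 50, 5), 32, 32)
  pl <- list(cbind(row = c(8, 16, 25), col = c(10, 20, 12)))
  res <- masc_profile(img, pl, pixel_size = 1, max_distance = 40)
  oracle <- oracle_polyline_distance(32, 32, pl)
  expect_identical(abs(res$distance_map), oracle$dist)
  expect_identical(sign(res$distance_map), oracle$sign * (oracle$dist > 0))
  expect_error(masc_profile(img, list(cbind(1, 1))), "2 vertices")
})

test_that("masc_profile of a ring cell peaks at the membrane", {
  img <- gen_laminar_image(size = c(96, 96), n_cells = 1, noise_sd = 0,
                           membrane_iu = 200, cytoplasm_iu = 20, seed = 6)
  pl <- img$annotations$membrane_polylines
  res <- masc_profile(img$channels$kcc2, pl, pixel_size = img$pixel_size,
                      max_distance = 4)
  p <- res$profile
  peak <- p$distance[which.max(p$mean)]
  expect_lt(abs(peak), 1)                       # peak at the membrane shell
  # intracellular side positive: the generated circles put inside left
  ctr <- img$annotations$cells
  expect_gt(res$distance_map[ctr$row[1], ctr$col[1]], 0)
})

test_that("subtract_background zeroes its own region and clips at 0", {
  img <- matrix(c(5, 5, 20, 40), 2, 2)
  reg <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  out <- subtract_background(img, reg)
  expect_equal(mean(out[reg]), 0)
  expect_equal(out[1, 2], 15)
  expect_equal(subtract_background(matrix(7, 3, 3),
                                   matrix(TRUE, 3, 3)),
               matrix(0, 3, 3))
  big <- matrix(c(100, 100, 10, 100), 2, 2)
  expect_true(all(subtract_background(big, matrix(c(TRUE, TRUE, FALSE, TRUE),
                                                  2, 2)) >= 0))
})

test_that("cluster_particles applies the transitive 65-nm rule", {
  # chain A-B 50, B-C 50, A-C 100: one oligomeric group of 3
  xy <- rbind(c(0, 0), c(50, 0), c(100, 0))
  cl <- cluster_particles(particle_set(xy))
  expect_equal(length(unique(cl$labels)), 1)
  expect_true(all(cl$oligomeric))
  expect_equal(cl$oligomeric_pct, 100)
  # two particles 70 nm apart stay monomeric
  cl2 <- cluster_particles(particle_set(rbind(c(0, 0), c(70, 0))))
  expect_equal(cl2$n_monomeric, 2)
  expect_equal(cl2$oligomeric_pct, 0)
})

test_that("clustering is invariant to ordering and rigid motion", {
  ps <- gen_particles(120, 0.5, seed = 21)
  base <- cluster_particles(ps)
  perm <- sample(nrow(ps$coords))
  permed <- cluster_particles(particle_set(ps$coords[perm, ]))
  expect_identical(canonical_labels(base$labels[perm]),
                   canonical_labels(permed$labels))
  expect_equal(sort(base$sizes), sort(permed$sizes))
  th <- 0.7
  rot <- ps$coords %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sweep(rot, 2, c(500, -200), "+")
  expect_identical(canonical_labels(base$labels),
                   canonical_labels(cluster_particles(particle_set(rot))$labels))
})

test_that("cluster labels equal the brute-force single-linkage oracle", {
  for (s in 1:25) {
    ps <- gen_particles(300, 0.5, seed = s)
    lab <- cluster_particles(ps)$labels
    olab <- oracle_components(ps$coords, 65)
    expect_identical(canonical_labels(lab), canonical_labels(olab))
  }
})

test_that("interparticle_histogram enumerates all pairs", {
  tri <- particle_set(rbind(c(0, 0), c(60, 0), c(30, 30 * sqrt(3))))
  h <- interparticle_histogram(tri, bin = 10)
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$mid == 55], 3)    # equilateral side 60 -> one bin
  ps <- gen_particles(40, 0.3, seed = 2)
  h2 <- interparticle_histogram(ps, bin = 25)
  expect_equal(sum(h2$count), 40 * 39 / 2)
  d <- as.numeric(stats::dist(ps$coords))
  expect_equal(h2$count[1], sum(d <= 25))
})

test_that("oligomer_percentage reproduces published category arithmetic", {
  expect_equal(oligomer_percentage(506, 320), 100 * 506 / 826)
  expect_equal(round(oligomer_percentage(506, 320)), 61)
  expect_equal(round(oligomer_percentage(133, 568)), 19)
})
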