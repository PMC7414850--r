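# Independent oracles used across tests.

# single-linkage components under a distance cutoff via hclust/cutree
oracle_components <- function(xy, cutoff) {
  n <- nrow(xy)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(xy), method = "single")
  stats::cutree(hc, h = cutoff * (1 - 1e-12))
}

# canonical form of a partition: relabel by order of first appearance
canonical_labels <- function(lab) match(lab, unique(lab))

# exhaustive per-pixel distance to a curve sampled at column centres
oracle_curve_distance <- function(nr, nc, ycurve) {
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best <- Inf
    for (j in seq_len(nc)) {
      d2 <- (r - ycurve[j])^2 + (c - j)^2
      if (d2 < best) best <- d2
    }
    out[r, c] <- sqrt(best)
  }
  out
}

# exhaustive per-pixel point-to-segment distances over all polylines
oracle_polyline_distance <- function(nr, nc, polylines) {
  dist <- matrix(Inf, nr, nc)
  sgn <- matrix(1, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (pl in polylines) {
      for (k in seq_len(nrow(pl) - 1)) {
        vr <- pl[k + 1, 1] - pl[k, 1]; vc <- pl[k + 1, 2] - pl[k, 2]
        len2 <- vr^2 + vc^2
        or <- r - pl[k, 1]; oc <- c - pl[k, 2]
        t <- pmin(1, pmax(0, (or * vr + oc * vc) / len2))
        dr <- or - t * vr; dc <- oc - t * vc
        d <- sqrt(dr^2 + dc^2)
        if (d < dist[r, c]) {
          dist[r, c] <- d
          s <- sign(vr * oc - vc * or)
          sgn[r, c] <- if (s == 0) 1 else s
        }
      }
    }
  }
  list(dist = dist, sign = sgn)
}

# recording-ACSF conditions used throughout
acsf <- function(cl_in = 29) ion_preset("recording_acsf", cl_in = cl_in)
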