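# Independent oracles, kept free of the package's own code paths.

# Potential in a homogeneous sphere (radius R mm, conductivity sigma S/m,
# insulated boundary) from a point current source at `a` and sink at `b` on
# the surface: truncated Legendre series
#   V(r, gamma) = I/(4 pi sigma R) sum_n (2n+1)/n (r/R)^n Pn(cos gamma),
# superposed for the two electrodes. Points strictly inside the sphere.
sphere_series_potential <- function(pts, a, b, R, sigma, I_amp,
                                    n_terms = 3000) {
  r <- sqrt(rowSums(pts^2))
  rr <- pmin(r / R, 1)
  ca <- as.numeric(pts %*% a) / (pmax(r, 1e-12) * R)
  cb <- as.numeric(pts %*% b) / (pmax(r, 1e-12) * R)
  Pa0 <- rep(1, nrow(pts)); Pa1 <- ca
  Pb0 <- rep(1, nrow(pts)); Pb1 <- cb
  tpow <- rr
  V <- 3 * tpow * (Pa1 - Pb1)
  for (n in 2:n_terms) {
    Pa2 <- ((2 * n - 1) * ca * Pa1 - (n - 1) * Pa0) / n
    Pb2 <- ((2 * n - 1) * cb * Pb1 - (n - 1) * Pb0) / n
    tpow <- tpow * rr
    V <- V + (2 * n + 1) / n * tpow * (Pa2 - Pb2)
    Pa0 <- Pa1; Pa1 <- Pa2; Pb0 <- Pb1; Pb1 <- Pb2
  }
  I_amp / (4 * pi * sigma * (R / 1000)) * V
}

# Closed-form envelope of a1*sin(w1 t + p1) + a2*sin(w2 t + p2).
two_tone_envelope_oracle <- function(a1, a2, f1, f2, ph1, ph2, t) {
  sqrt(a1^2 + a2^2 + 2 * a1 * a2 * cos(2 * pi * (f2 - f1) * t + (ph2 - ph1)))
}

# Brute-force two-pair montage search, written as plain loops independent of
# the package's vectorized enumeration. Same selection rule: max target MD,
# then min focality, then lexicographic key; anode is the smaller label.
brute_force_pairs <- function(lf, target_coord, total, ratios,
                              direction = "radial_in") {
  labs <- sort(c(lf$electrode_labels, lf$reference_label))
  n <- length(labs)
  coords <- lf$coords
  d2 <- rowSums((coords - matrix(target_coord, nrow(coords), 3,
                                 byrow = TRUE))^2)
  tnode <- which.min(d2)
  dvec <- if (direction == "radial_in") {
    nr <- sqrt(rowSums(coords^2))
    -coords / ifelse(nr > 0, nr, 1)
  } else matrix(rep(c(0, 1, 0), each = nrow(coords)), ncol = 3)
  proj <- function(lab) {
    if (lab == lf$reference_label) return(numeric(nrow(coords)))
    e <- which(lf$electrode_labels == lab)
    lf$entries[e, , 1] * dvec[, 1] +
      lf$entries[e, , 2] * dvec[, 2] +
      lf$entries[e, , 3] * dvec[, 3]
  }
  pcol <- sapply(labs, proj)
  best <- NULL
  for (i1 in 1:(n - 1)) for (j1 in (i1 + 1):n)
    for (i2 in 1:(n - 1)) for (j2 in (i2 + 1):n) {
      if (length(unique(c(i1, j1, i2, j2))) < 4) next
      if (i1 > i2 || (i1 == i2 && j1 > j2)) next   # pair1 < pair2
      for (r in ratios) {
        I1 <- r * total; I2 <- (1 - r) * total
        p1 <- I1 * (pcol[, i1] - pcol[, j1])
        p2 <- I2 * (pcol[, i2] - pcol[, j2])
        md <- 2 * pmin(abs(p1), abs(p2))
        md_t <- md[tnode]
        foc <- if (md_t > 0)
          (sum(lf$grid_spacing^3 * (md > 0.5 * md_t)) / 1000)^(1/3) else Inf
        key <- paste(labs[i1], labs[j1], labs[i2], labs[j2], format(r))
        cand <- list(md = md_t, foc = foc, key = key,
                     m1 = stats::setNames(c(I1, -I1), labs[c(i1, j1)]),
                     m2 = stats::setNames(c(I2, -I2), labs[c(i2, j2)]))
        if (is.null(best) ||
            cand$md > best$md * (1 + 1e-9) ||
            (abs(cand$md - best$md) <= best$md * 1e-9 &&
             (cand$foc < best$foc - 1e-12 ||
              (abs(cand$foc - best$foc) <= 1e-12 && cand$key < best$key))))
          best <- cand
      }
    }
  best
}
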