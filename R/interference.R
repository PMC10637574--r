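#' Stimulation montage
#'
#' Signed currents (mA) on named electrodes for one stimulation frequency.
#' Positive current flows into the head, negative out. All injected current
#' must return: the currents must sum to zero (to 1e-9 mA). When a montage is
#' applied to a lead field, the lead field's reference electrode acts as the
#' balance electrode.
#'
#' @param currents named numeric vector, mA per electrode label.
#' @param frequency stimulation frequency in Hz.
#' @param phase phase offset in radians.
#' @return a `ti_montage`.
#' @export
#' @examples
#' montage(c(E1 = 1, E3 = -1), frequency = 10)
montage <- function(currents, frequency, phase = 0) {
  if (is.null(names(currents)) || any(names(currents) == ""))
    stop("currents must be a fully named vector")
  if (anyDuplicated(names(currents))) stop("duplicate electrode labels")
  if (abs(sum(currents)) > 1e-9)
    stop("montage currents must sum to zero (net ", sum(currents), " mA)")
  if (frequency <= 0) stop("frequency must be positive")
  structure(list(currents = currents, frequency = frequency, phase = phase),
            class = "ti_montage")
}

#' @export
print.ti_montage <- function(x, ...) {
  cat("<ti_montage> ", x$frequency, " Hz, phase ", signif(x$phase, 3), ": ",
      paste0(names(x$currents), " (", signif(x$currents, 3), ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Two-frequency stimulation protocol
#'
#' Pairs the two montages with a time grid. Defaults follow the illustrative
#' regime of slow carriers: the second montage is conventionally pi out of
#' phase, the sample rate is 100 x the faster carrier, and the record must
#' hold at least two beat cycles so the envelope is identifiable.
#'
#' @param montage_a,montage_b `ti_montage` objects (one per frequency).
#' @param duration record length in seconds.
#' @param sample_rate samples per second; default `100 * max(frequency)`.
#'   Must be at least 50 x the faster carrier.
#' @return a `ti_protocol` with the sampled time grid.
#' @export
stim_protocol <- function(montage_a, montage_b, duration = 1,
                          sample_rate = NULL) {
  stopifnot(inherits(montage_a, "ti_montage"), inherits(montage_b, "ti_montage"))
  fmax <- max(montage_a$frequency, montage_b$frequency)
  if (is.null(sample_rate)) sample_rate <- 100 * fmax
  if (sample_rate < 50 * fmax)
    stop("sample_rate must be >= 50 x the faster carrier (",
         50 * fmax, " Hz)")
  df <- abs(montage_a$frequency - montage_b$frequency)
  if (df > 0 && duration < 2 / df - 1e-12)
    stop("duration must cover at least two beat cycles (",
         signif(2 / df, 4), " s)")
  times <- (seq_len(round(duration * sample_rate)) - 1) / sample_rate
  structure(list(montage_a = montage_a, montage_b = montage_b,
                 duration = duration, sample_rate = sample_rate,
                 times = times),
            class = "ti_protocol")
}

#' @export
print.ti_protocol <- function(x, ...) {
  cat("<ti_protocol> ", x$montage_a$frequency, " + ", x$montage_b$frequency,
      " Hz, ", x$duration, " s at ", x$sample_rate, " Hz (",
      length(x$times), " samples)\n", sep = "")
  invisible(x)
}

#' Direction field over brain nodes
#'
#' Unit vectors d(r) onto which the field is projected. `radial_in` points
#' from each node toward the head centre at the origin; `posterior_anterior`
#' is the constant +y axis (toward the front of the head).
#'
#' @param lf a `ti_leadfield` (supplies the node coordinates), or a numeric
#'   matrix of coordinates.
#' @param mode `"radial_in"`, `"posterior_anterior"`, or `"custom"` (then
#'   `vectors` must be given).
#' @param vectors for `mode = "custom"`: matrix (nodes x 3), normalized
#'   internally.
#' @return a `ti_direction`: unit vectors (nodes x 3) and the mode tag.
#' @export
direction_field <- function(lf, mode = c("radial_in", "posterior_anterior",
                                         "custom"), vectors = NULL) {
  mode <- match.arg(mode)
  coords <- if (inherits(lf, "ti_leadfield")) lf$coords else as.matrix(lf)
  n <- nrow(coords)
  d <- switch(mode,
    radial_in = {
      nr <- sqrt(rowSums(coords^2))
      v <- -coords / ifelse(nr > 0, nr, 1)
      v[nr == 0, ] <- rep(c(0, 0, 1), each = sum(nr == 0))  # centre: arbitrary unit
      v
    },
    posterior_anterior = matrix(rep(c(0, 1, 0), each = n), ncol = 3),
    custom = {
      if (is.null(vectors)) stop("mode 'custom' needs vectors")
      v <- as.matrix(vectors)
      if (!all(dim(v) == c(n, 3))) stop("vectors must be nodes x 3")
      nv <- sqrt(rowSums(v^2))
      if (any(nv == 0)) stop("custom direction vectors must be nonzero")
      v / nv
    })
  structure(list(vectors = d, mode = mode), class = "ti_direction")
}

#' Superposed two-frequency field
#'
#' Evaluates E(r,t) = sin(w1 t + phi1) A(r) s1 + sin(w2 t + phi2) A(r) s2.
#' The object stores the two per-montage static field maps and the time grid;
#' the full space-time array is materialized lazily (via [field_at()] or
#' [project_field()]) because it can be large.
#'
#' @param lf a `ti_leadfield`.
#' @param proto a `ti_protocol`.
#' @param nodes optional integer subset of brain nodes to restrict to.
#' @return a `ti_field`: per-montage field maps `F1`, `F2` (nodes x 3, V/m),
#'   frequencies, phases, and the time grid.
#' @export
total_field <- function(lf, proto, nodes = NULL) {
  stopifnot(inherits(lf, "ti_leadfield"), inherits(proto, "ti_protocol"))
  F1 <- leadfield_field(lf, proto$montage_a$currents)
  F2 <- leadfield_field(lf, proto$montage_b$currents)
  coords <- lf$coords
  if (!is.null(nodes)) {
    F1 <- F1[nodes, , drop = FALSE]
    F2 <- F2[nodes, , drop = FALSE]
    coords <- coords[nodes, , drop = FALSE]
  }
  structure(list(F1 = F1, F2 = F2, coords = coords, nodes = nodes,
                 omega = 2 * pi * c(proto$montage_a$frequency,
                                    proto$montage_b$frequency),
                 phase = c(proto$montage_a$phase, proto$montage_b$phase),
                 times = proto$times, sample_rate = proto$sample_rate),
            class = "ti_field")
}

#' E-field vectors at one time instant
#'
#' @param field a `ti_field`.
#' @param t time in seconds (need not lie on the sample grid).
#' @return matrix (nodes x 3) in V/m.
#' @export
field_at <- function(field, t) {
  stopifnot(inherits(field, "ti_field"))
  sin(field$omega[1] * t + field$phase[1]) * field$F1 +
    sin(field$omega[2] * t + field$phase[2]) * field$F2
}

#' Project the field onto a direction field
#'
#' Per-node scalar time series d(r)^T E(r,t) on the protocol time grid.
#'
#' @param field a `ti_field`.
#' @param d a `ti_direction` over the same nodes.
#' @return a `ti_scalar_field`: matrix `x` (nodes x time, V/m), the two
#'   per-montage projected amplitudes `p1`, `p2` (signed), and the time grid.
#' @export
project_field <- function(field, d) {
  stopifnot(inherits(field, "ti_field"), inherits(d, "ti_direction"))
  if (nrow(d$vectors) != nrow(field$F1))
    stop("direction field has ", nrow(d$vectors), " nodes, field has ",
         nrow(field$F1))
  p1 <- rowSums(field$F1 * d$vectors)
  p2 <- rowSums(field$F2 * d$vectors)
  x <- outer(p1, sin(field$omega[1] * field$times + field$phase[1])) +
       outer(p2, sin(field$omega[2] * field$times + field$phase[2]))
  structure(list(x = x, p1 = p1, p2 = p2, times = field$times,
                 sample_rate = field$sample_rate, omega = field$omega,
                 phase = field$phase, mode = d$mode),
            class = "ti_scalar_field")
}

# Analytic signal x + j H[x] of each row of a real matrix, by FFT
# half-spectrum doubling.
analytic_signal <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
}

#' Amplitude-modulation envelope via the analytic signal
#'
#' Computes |x(t) + j H[x(t)]| per node, where H is the Hilbert transform.
#' Records that already wrap around smoothly (e.g. an integer number of
#' carrier and beat cycles) are transformed as-is, where the FFT Hilbert
#' transform is most accurate. Otherwise the record is mirror-padded by one
#' beat period on each side, with the padding tapered smoothly to zero by a
#' cosine ramp, and cropped afterwards: the taper removes the wrap-around
#' discontinuity that otherwise leaks across DC and rings through the
#' record. The first and last 5% of samples are flagged as untrusted in
#' either case.
#'
#' @param signal a `ti_scalar_field`, or a numeric vector/matrix
#'   (nodes x time) with `sample_rate` given.
#' @param sample_rate samples per second (taken from the object if omitted).
#' @param beat_hz envelope (beat) frequency used to size the mirror padding;
#'   inferred from the protocol frequencies when available, else one tenth of
#'   the record is used.
#' @return a `ti_envelope`: matrix `env` (nodes x time, V/m >= 0), logical
#'   `trusted` over time samples, and the time grid.
#' @export
envelope <- function(signal, sample_rate = NULL, beat_hz = NULL) {
  if (inherits(signal, "ti_scalar_field")) {
    x <- signal$x
    sample_rate <- signal$sample_rate
    times <- signal$times
    if (is.null(beat_hz))
      beat_hz <- abs(diff(signal$omega)) / (2 * pi)
  } else {
    x <- if (is.vector(signal)) matrix(signal, nrow = 1) else as.matrix(signal)
    if (is.null(sample_rate)) stop("sample_rate required for raw input")
    times <- (seq_len(ncol(x)) - 1) / sample_rate
  }
  n <- ncol(x)
  if (n < 4) stop("record too short")
  rng <- apply(x, 1, function(r) diff(range(r)))
  if (all(rng < .Machine$double.eps * 100))
    warning("constant signal: envelope is the absolute constant")
  pad <- if (!is.null(beat_hz) && beat_hz > 0)
    min(n - 1, ceiling(sample_rate / beat_hz)) else ceiling(n / 10)
  # wrap-around discontinuity per row: first sample vs. the linear
  # extrapolation of the last two (a periodic record continues smoothly)
  jump <- abs(x[, 1] - (2 * x[, n] - x[, n - 1]))
  scale <- pmax(apply(abs(x), 1, max), .Machine$double.xmin)
  smooth_wrap <- jump <= 0.03 * scale
  env <- matrix(0, nrow(x), n)
  if (any(smooth_wrap))
    env[smooth_wrap, ] <-
      abs(analytic_signal(x[smooth_wrap, , drop = FALSE]))
  if (any(!smooth_wrap)) {
    xr <- x[!smooth_wrap, , drop = FALSE]
    ramp <- 0.5 * (1 - cos(pi * seq_len(pad) / (pad + 1)))  # 0 -> 1
    left <- xr[, (pad + 1):2, drop = FALSE] * rep(ramp, each = nrow(xr))
    right <- xr[, (n - 1):(n - pad), drop = FALSE] *
      rep(ramp[pad:1], each = nrow(xr))
    env[!smooth_wrap, ] <-
      abs(analytic_signal(cbind(left, xr, right)))[, pad + seq_len(n),
                                                   drop = FALSE]
  }
  edge <- ceiling(0.05 * n)
  trusted <- rep(TRUE, n)
  trusted[seq_len(edge)] <- FALSE
  trusted[n - seq_len(edge) + 1] <- FALSE
  structure(list(env = env, trusted = trusted, times = times,
                 sample_rate = sample_rate),
            class = "ti_envelope")
}

#' Static modulation depth from per-montage projected amplitudes
#'
#' MD(r) = 2 min(|p1|, |p2|): the peak-to-trough depth of the envelope of a
#' two-tone signal is twice the weaker tone's amplitude, so the modulation is
#' determined by the weaker of the two projected fields. Symmetric and
#' nonnegative; a static quantity that does not change with time.
#'
#' @param p1,p2 numeric vectors of signed projected amplitudes (V/m), one per
#'   node, for the two montages.
#' @return numeric vector of MD values (V/m).
#' @export
#' @examples
#' md_static(0.33, 0.01)  # 0.02
md_static <- function(p1, p2) {
  2 * pmin(abs(p1), abs(p2))
}

#' Instantaneous modulation depth
#'
#' The envelope minus its per-node temporal minimum (over the trusted
#' region): a time-varying visualization quantity whose minimum over time is
#' exactly zero and whose temporal maximum equals the static MD.
#'
#' @param env a `ti_envelope`.
#' @return matrix (nodes x time, V/m), zero-minimum per node over the trusted
#'   region.
#' @export
md_instant <- function(env) {
  stopifnot(inherits(env, "ti_envelope"))
  e <- env$env[, env$trusted, drop = FALSE]
  mins <- apply(e, 1, min)
  sweep(env$env, 1, mins, `-`)
}

#' Lissajous trace of the total field at a node
#'
#' The total field at any node is a time-varying combination of the two
#' static per-montage field vectors, so it stays in the plane they span; its
#' tip traces a Lissajous curve there. Returns an orthonormal basis of that
#' plane and the 2-D coordinates of E(r,t) over the time grid.
#'
#' @param lf a `ti_leadfield`.
#' @param proto a `ti_protocol`.
#' @param node brain-node index.
#' @param collinear_tol relative tolerance below which the two field vectors
#'   are treated as collinear (degenerate 1-D trace).
#' @return a `ti_lissajous`: `basis` (3 x 2 orthonormal), `curve`
#'   (time x 2), the out-of-plane residual, and a `degenerate` flag.
#' @export
lissajous <- function(lf, proto, node, collinear_tol = 1e-9) {
  field <- total_field(lf, proto, nodes = node)
  v1 <- field$F1[1, ]; v2 <- field$F2[1, ]
  n1 <- sqrt(sum(v1^2))
  if (n1 == 0) { tmp <- v1; v1 <- v2; v2 <- tmp; n1 <- sqrt(sum(v1^2)) }
  if (n1 == 0) stop("zero field at node: no Lissajous plane")
  u1 <- v1 / n1
  w <- v2 - sum(v2 * u1) * u1
  degenerate <- sqrt(sum(w^2)) <= collinear_tol * sqrt(sum(v2^2))
  u2 <- if (degenerate) {
    # any unit vector orthogonal to u1
    a <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w2 <- a - sum(a * u1) * u1
    w2 / sqrt(sum(w2^2))
  } else w / sqrt(sum(w^2))
  basis <- cbind(u1, u2)
  s1 <- sin(field$omega[1] * field$times + field$phase[1])
  s2 <- sin(field$omega[2] * field$times + field$phase[2])
  E <- outer(s1, v1) + outer(s2, v2)   # time x 3
  curve <- E %*% basis
  resid <- sqrt(rowSums((E - curve %*% t(basis))^2))
  rel_resid <- max(resid) / max(sqrt(rowSums(E^2)), .Machine$double.eps)
  structure(list(basis = basis, curve = curve, times = field$times,
                 residual = rel_resid, degenerate = degenerate),
            class = "ti_lissajous")
}

#' Static modulation-depth map over the brain
#'
#' Evaluates MD(r) = 2 min(|d^T A s1|, |d^T A s2|) at every brain node via
#' the closed form (no time series needed).
#'
#' @param lf a `ti_leadfield`.
#' @param montage_a,montage_b `ti_montage` objects.
#' @param direction a `ti_direction` or a mode string passed to
#'   [direction_field()].
#' @return a `ti_mdmap`: per-node MD values (V/m), node volume (mm^3), node
#'   coordinates, grid metadata and the direction mode.
#' @export
md_map <- function(lf, montage_a, montage_b, direction = "radial_in") {
  stopifnot(inherits(lf, "ti_leadfield"))
  if (is.character(direction)) direction <- direction_field(lf, direction)
  dv <- direction$vectors
  p1 <- rowSums(leadfield_field(lf, montage_a$currents) * dv)
  p2 <- rowSums(leadfield_field(lf, montage_b$currents) * dv)
  new_mdmap(md_static(p1, p2), lf, direction$mode, p1 = p1, p2 = p2)
}

new_mdmap <- function(values, lf, mode, p1 = NULL, p2 = NULL) {
  structure(list(values = values, coords = lf$coords,
                 brain_idx = lf$brain_idx, dim = lf$dim, axes = lf$axes,
                 node_volume = lf$grid_spacing^3,
                 grid_spacing = lf$grid_spacing,
                 direction = mode, p1 = p1, p2 = p2),
            class = "ti_mdmap")
}

#' @export
print.ti_mdmap <- function(x, ...) {
  cat("<ti_mdmap> ", length(x$values), " brain nodes, direction ",
      x$direction, "; max MD ", signif(max(x$values), 4), " V/m\n", sep = "")
  invisible(x)
}
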