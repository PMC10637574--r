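test_that("montage and protocol invariants are enforced", {
  expect_error(montage(c(E1 = 1, E2 = -0.5), 10), "sum to zero")
  expect_error(montage(c(1, -1), 10), "named")
  expect_error(montage(c(E1 = 1, E1 = -1), 10), "duplicate")
  m1 <- montage(c(E1 = 1, E3 = -1), 10)
  m2 <- montage(c(E2 = 1, E4 = -1), 12, pi)
  expect_error(stim_protocol(m1, m2, duration = 0.5), "beat cycles")
  expect_error(stim_protocol(m1, m2, duration = 1, sample_rate = 100),
               "50 x")
  proto <- stim_protocol(m1, m2, duration = 1)
  expect_equal(proto$sample_rate, 1200)
  expect_length(proto$times, 1200)
  # exactly two beat cycles (the canonical 10/12 Hz, 1 s record) is allowed
  expect_s3_class(stim_protocol(m1, m2, duration = 1), "ti_protocol")
})

test_that("direction fields are unit vectors with the stated geometry", {
  coords <- rbind(c(0, 50, 0), c(30, 0, 0), c(0, 0, -20), c(0, 0, 0))
  d <- direction_field(coords, "radial_in")
  expect_equal(rowSums(d$vectors^2), rep(1, 4), tolerance = 1e-12)
  expect_equal(d$vectors[1, ], c(0, -1, 0))
  expect_equal(d$vectors[2, ], c(-1, 0, 0))
  expect_equal(d$vectors[3, ], c(0, 0, 1))
  pa <- direction_field(coords, "posterior_anterior")
  expect_true(all(pa$vectors == rep(c(0, 1, 0), each = 4)))
  cust <- direction_field(coords, "custom", vectors = coords + 1)
  expect_equal(rowSums(cust$vectors^2), rep(1, 4), tolerance = 1e-12)
})

test_that("total field superposes the two montage fields on the time grid", {
  lf <- phantom_lf6()
  m1 <- montage(c(E1 = 1, E3 = -1), 10)
  m0 <- montage(c(E2 = 0, E4 = 0), 12, pi)
  proto0 <- stim_protocol(m1, m0, duration = 1, sample_rate = 1200)
  f0 <- total_field(lf, proto0)
  # single source: time-max of |E| equals the static field magnitude
  normF1 <- sqrt(rowSums(f0$F1^2))
  tmax <- f0$times[which.max(abs(sin(f0$omega[1] * f0$times)))]
  expect_equal(sqrt(rowSums(field_at(f0, tmax)^2)),
               normF1 * abs(sin(f0$omega[1] * tmax)), tolerance = 1e-12)
  expect_true(all(abs(f0$F2) == 0))

  m2 <- montage(c(E2 = 1, E4 = -1), 12, pi)
  proto <- stim_protocol(m1, m2, duration = 1)
  fld <- total_field(lf, proto)
  # t = 0 with phases (0, pi): both sines vanish
  expect_equal(max(abs(field_at(fld, 0))), 0, tolerance = 1e-12)
  # doubling s1 doubles the first summand exactly
  m1x2 <- montage(c(E1 = 2, E3 = -2), 10)
  fld2 <- total_field(lf, stim_protocol(m1x2, m2, duration = 1))
  expect_equal(fld2$F1, 2 * fld$F1, tolerance = 1e-12)
})

test_that("projection is the per-node dot product with the direction", {
  lf <- phantom_lf6()
  proto <- default_protocol()
  fld <- total_field(lf, proto)
  # aligned with the montage-1 field: projection equals its magnitude
  d_aligned <- direction_field(lf$coords, "custom",
                               vectors = fld$F1 + 1e-30)
  sf <- project_field(fld, d_aligned)
  expect_equal(sf$p1, sqrt(rowSums(fld$F1^2)), tolerance = 1e-9)
  # orthogonal direction: zero projection
  v <- cbind(-fld$F1[, 2], fld$F1[, 1], 0)
  ok <- rowSums(v^2) > 0
  d_orth <- direction_field(lf$coords[ok, ], "custom", vectors = v[ok, ])
  fld_ok <- total_field(lf, proto, nodes = which(ok))
  sf_orth <- project_field(fld_ok, d_orth)
  expect_lt(max(abs(sf_orth$p1) / sqrt(rowSums(fld$F1[ok, ]^2))), 1e-9)
  expect_error(project_field(fld, direction_field(lf$coords[1:3, ],
                                                  "radial_in")),
               "nodes")
})

test_that("envelope of a pure tone is flat at the amplitude", {
  # one record wrapping smoothly (integer cycles), one that needs padding
  cases <- list(c(f = 20, fs = 1000, dur = 1.3),
                c(f = 500.3, fs = 50000, dur = 1))
  for (cs in cases) {
    t <- (0:(cs[["fs"]] * cs[["dur"]] - 1)) / cs[["fs"]]
    x <- 0.7 * sin(2 * pi * cs[["f"]] * t + 1.1)
    env <- envelope(x, sample_rate = cs[["fs"]], beat_hz = cs[["f"]] / 20)
    tr <- env$trusted
    expect_lt(max(abs(env$env[1, tr] - 0.7)) / 0.7, 0.01)
  }
  expect_warning(envelope(rep(2, 100), sample_rate = 100), "constant")
})

test_that("envelope matches the closed-form two-tone oracle", {
  set.seed(11)
  for (i in 1:20) {
    a1 <- runif(1, 0.05, 1); a2 <- runif(1, 0.05, 1)
    f1 <- exp(runif(1, log(10), log(500)))
    df <- f1 * runif(1, 0.05, 0.2); f2 <- f1 + df
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    dur <- max(2.5 / df, 100 / f1)
    fs <- ceiling(100 * f2)
    t <- (0:(round(dur * fs) - 1)) / fs
    x <- a1 * sin(2 * pi * f1 * t + ph1) + a2 * sin(2 * pi * f2 * t + ph2)
    env <- envelope(x, sample_rate = fs, beat_hz = df)
    closed <- two_tone_envelope_oracle(a1, a2, f1, f2, ph1, ph2, t)
    tr <- env$trusted
    rel <- sqrt(mean((env$env[1, tr] - closed[tr])^2) / mean(closed[tr]^2))
    expect_lt(rel, 0.01)
  }
})

test_that("envelope dominates the projected signal and beats at |f1 - f2|", {
  fs <- 1200
  t <- (0:(fs - 1)) / fs
  x <- 0.2 * sin(2 * pi * 10 * t) + 0.15 * sin(2 * pi * 12 * t + pi)
  env <- envelope(x, sample_rate = fs, beat_hz = 2)
  expect_true(all(env$env[1, ] >= abs(x) - 1e-6))
  # dominant nonzero spectral peak of env - mean is the beat frequency
  e <- env$env[1, ] - mean(env$env[1, ])
  spec <- Mod(fft(e))[2:(length(e) / 2)]
  expect_equal(which.max(spec), 2)  # 2 Hz bin of a 1 s record
})

test_that("static MD is twice the weaker projected amplitude", {
  expect_identical(md_static(0.33, 0.01), 0.02)
  expect_equal(md_static(-0.4, 0.4), 0.8)
  expect_equal(md_static(0.5, 0), 0)
  expect_equal(md_static(0.2, 0.7), md_static(0.7, 0.2))
  # vectorized and sign invariant
  p1 <- c(-0.1, 0.3); p2 <- c(0.2, -0.05)
  expect_equal(md_static(p1, p2), c(0.2, 0.1))
  expect_equal(md_static(-p1, p2), md_static(p1, p2))
})

test_that("static MD equals max - min of the numeric envelope (dual route)", {
  set.seed(21)
  fs <- 1200
  t <- (0:(fs - 1)) / fs
  for (i in 1:25) {
    p1 <- runif(1, -0.5, 0.5); p2 <- runif(1, -0.5, 0.5)
    x <- p1 * sin(2 * pi * 10 * t) + p2 * sin(2 * pi * 12 * t + pi)
    env <- envelope(x, sample_rate = fs, beat_hz = 2)
    tr <- env$trusted
    md_env <- max(env$env[1, tr]) - min(env$env[1, tr])
    expect_equal(md_env, md_static(p1, p2),
                 tolerance = 0.02 + 1e-12)
  }
})

test_that("instantaneous MD is the envelope above its temporal minimum", {
  fs <- 1200
  t <- (0:(fs - 1)) / fs
  x <- rbind(0.33 * sin(2 * pi * 10 * t) - 0.01 * sin(2 * pi * 12 * t),
             0.5 * sin(2 * pi * 10 * t))
  env <- envelope(x, sample_rate = fs, beat_hz = 2)
  mdt <- md_instant(env)
  expect_equal(min(mdt[1, env$trusted]), 0)
  expect_equal(max(mdt[1, env$trusted]), md_static(0.33, 0.01),
               tolerance = 0.002 / 0.02)
  # pure tone: flat envelope, MD(t) ~ 0
  expect_lt(max(abs(mdt[2, env$trusted])), 0.01 * 0.5)
  # adding a constant to the envelope leaves MD(r,t) unchanged
  env_shift <- env
  env_shift$env <- env$env + 3
  expect_equal(md_instant(env_shift), mdt, tolerance = 1e-12)
})

test_that("MD is invariant to direction sign and frequency ordering", {
  lf <- phantom_lf6()
  m1 <- montage(c(E1 = 1, E3 = -1), 10)
  m2 <- montage(c(E2 = 1, E4 = -1), 12, pi)
  d <- direction_field(lf, "radial_in")
  dneg <- direction_field(lf$coords, "custom", vectors = -d$vectors)
  md_a <- md_map(lf, m1, m2, d)
  md_b <- md_map(lf, m1, m2, dneg)
  expect_equal(md_a$values, md_b$values, tolerance = 1e-12)
  md_sw <- md_map(lf, m2, m1, d)
  expect_equal(md_a$values, md_sw$values, tolerance = 1e-12)
})

test_that("the total field stays in the plane of the two montage fields", {
  lf <- phantom_lf6()
  proto <- default_protocol()
  fld <- total_field(lf, proto)
  set.seed(5)
  for (nd in sample(nrow(lf$coords), 10)) {
    E <- sapply(seq(0, 1, by = 0.05),
                function(t) field_at(fld, t)[nd, ])
    expect_lte(qr(E)$rank, 2)
  }
})

test_that("Lissajous traces close, collapse when degenerate, and stay in-plane", {
  lf <- phantom_lf6()
  proto <- default_protocol()
  nd <- which.max(rowSums(leadfield_field(lf, proto$montage_a$currents)^2))
  li <- lissajous(lf, proto, nd)
  expect_false(li$degenerate)
  expect_lt(li$residual, 1e-9)
  # 10:12 Hz closes after 0.5 s (period 1/gcd = 1/2 s)
  half <- length(li$times) / 2
  expect_equal(li$curve[1:half, ], li$curve[half + 1:half, ],
               tolerance = 1e-9)
  # same frequency, antiphase: the curve is a line segment (rank-1 cloud)
  m1 <- proto$montage_a
  m2same <- montage(proto$montage_b$currents, m1$frequency, pi)
  proto_s <- stim_protocol(m1, m2same, duration = 0.5)
  li_s <- lissajous(lf, proto_s, nd)
  sv <- svd(scale(li_s$curve, scale = FALSE))$d
  expect_lt(sv[2], 1e-9 * sv[1])
})
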