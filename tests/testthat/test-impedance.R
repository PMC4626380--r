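naive_dft_coef <- function(x, n_harm) {
  n <- length(x)
  j <- 0:(n - 1)
  coef <- complex(length.out = n_harm + 1)
  coef[1] <- mean(x)
  for (k in 1:n_harm)
    coef[k + 1] <- 2 / n * sum(x * exp(-2i * pi * j * k / n))
  coef
}

test_that("harmonic decomposition matches a brute-force DFT sum", {
  # constant signal: only coefficient 0
  b <- pressure_beat(rep(4.2, 64), 0.01)
  sp <- harmonic_decompose(b, 10)
  expect_equal(Re(sp$coefficients[1]), 4.2)
  expect_equal(max(Mod(sp$coefficients[-1])), 0, tolerance = 1e-12)

  # pure cos(2*pi*3 t/T) of amplitude 2: only harmonic 3, modulus 2
  t <- (0:127) / 128
  sp <- harmonic_decompose(pressure_beat(2 * cos(2 * pi * 3 * t) + 90, 1 / 128), 10)
  expect_equal(Mod(sp$coefficients[4]), 2, tolerance = 1e-12)
  expect_equal(max(Mod(sp$coefficients[-c(1, 4)])), 0, tolerance = 1e-12)

  # random smooth beats against the O(n^2) oracle
  set.seed(5)
  for (rep in 1:5) {
    x <- 80 + 10 * make_lobe(96, 1, runif(1, 0.25, 0.4)) + rnorm(96, 0, 0.5)
    sp <- harmonic_decompose(pressure_beat(x, 1 / 96), 12)
    expect_equal(sp$coefficients, naive_dft_coef(x, 12), tolerance = 1e-9)
  }

  expect_error(harmonic_decompose(b, 32), class = "hemowave_validation")
})

test_that("Parseval's identity holds and reconstruction is faithful", {
  cfg <- pinned_config(gamma = 0.3)
  p <- resample_beat(simulate_subject(cfg, 1)$subject$pressure, 128)
  sp <- harmonic_decompose(p, 40)
  # power in harmonics 1..40 accounts for (nearly) all pulsatile power
  pulsatile_power <- mean((p$samples - mean(p$samples))^2)
  expect_equal(sum(Mod(sp$coefficients[-1])^2) / 2, pulsatile_power,
               tolerance = 1e-4)
  rec <- harmonic_reconstruct(harmonic_decompose(p, 10), 128)
  expect_gt(cor(rec, p$samples), 0.99)
})

test_that("input impedance is the harmonic ratio with Z0 = MAP / mean flow", {
  # proportional signals: Z_n = 0.1 everywhere
  q <- make_half_sine_flow(sv = 77, per = 1)
  pz <- pressure_beat(q$samples * 0.1 + 80, q$dt)
  z <- input_impedance(harmonic_decompose(pz, 10), harmonic_decompose(q, 10))
  expect_equal(unname(z$modulus[-1]), rep(0.1, 10), tolerance = 1e-10)

  # Z0 is exactly the ratio of means
  expect_equal(z$z[1], complex(real = mean(pz$samples) / mean(q$samples)))
  expect_equal(svr(93, 77.5), 1.2)
  expect_equal(svr(99, 99), 1.0)
  expect_equal(svr(120, 80 * 60 / 60), 1.5)  # MAP 120, SV 80 ml, HR 60
  expect_error(svr(90, 0), class = "hemowave_validation")

  # near-zero flow harmonics are flagged, not divided through
  t <- (0:127) / 128
  qf <- flow_beat(50 + 10 * cos(2 * pi * t), 1 / 128)   # harmonics >= 2 empty
  pf <- pressure_beat(90 + cos(2 * pi * t) + 0.5 * cos(2 * pi * 3 * t), 1 / 128)
  z <- input_impedance(harmonic_decompose(pf, 10), harmonic_decompose(qf, 10))
  expect_true(all(2:10 %in% z$flagged))
  expect_false(1 %in% z$flagged)
})

test_that("characteristic impedance averages harmonics 3-10 with outlier exclusion", {
  fake_z <- function(mods) {
    structure(list(z = complex(modulus = c(1, rep(0.1, 2), mods), argument = 0),
                   modulus = c(1, rep(0.1, 2), mods),
                   phase = rep(0, 11), flagged = integer(0), f0 = 1,
                   n_harm = 10L), class = "impedance_spectrum")
  }
  # all equal: Zc is that value, nothing excluded
  r <- characteristic_impedance(fake_z(rep(0.1, 8)))
  expect_equal(r$zc, 0.1)
  expect_length(r$excluded, 0)

  # one gross outlier is excluded by the MAD rule
  r <- characteristic_impedance(fake_z(c(rep(0.1, 7), 1.0)))
  expect_equal(r$zc, 0.1)
  expect_equal(r$excluded, 10L)

  # uniform draws: Zc equals the arithmetic mean of retained moduli
  set.seed(9)
  mods <- runif(8, 0.09, 0.11)
  r <- characteristic_impedance(fake_z(mods))
  expect_equal(r$zc, mean(mods[r$used - 2]))

  # too many unusable harmonics in the band is a quality error
  bad <- fake_z(rep(0.1, 8))
  bad$modulus[4:9] <- NA; bad$z[4:9] <- NA
  expect_error(characteristic_impedance(bad), class = "hemowave_quality")
})

test_that("a purely resistive load yields Z_n = R at every harmonic and Zc = R", {
  q <- make_half_sine_flow(sv = 70, per = 0.85)
  p <- pressure_beat(1.3 * q$samples, q$dt)  # P = R Q, R = 1.3
  z <- input_impedance(harmonic_decompose(p, 10), harmonic_decompose(q, 10))
  expect_equal(unname(z$modulus), rep(1.3, 11), tolerance = 1e-10)
  expect_equal(characteristic_impedance(z)$zc, 1.3, tolerance = 1e-10)
})

test_that("measured Zc recovers the generator value for echo-free Windkessel pairs", {
  # pure 3-element Windkessel forward pairs (no reflection): the impedance
  # modulus converges to Zc at high harmonics, within 5%
  for (zc_true in c(0.08, 0.12)) {
    cfg <- pinned_config(zc = zc_true, ca = 1.7, gamma = 0)
    s <- simulate_subject(cfg, 1)$subject
    row <- analyze_measured(s)
    expect_equal(row$zc, zc_true, tolerance = 0.05)
    expect_equal(row$svr, s$map_mmHg / (row$sv / (60 / row$hr)),
                 tolerance = 1e-8)
  }
})

test_that("Zc is invariant to a pure heart-rate rescaling of the time axis", {
  # same impedances, stretched time axis: harmonics shift in Hz but the
  # ratio spectrum (and so Zc) is unchanged
  q1 <- make_half_sine_flow(sv = 77, per = 0.8, ed = 0.30)
  q2 <- make_half_sine_flow(sv = 77, per = 1.0, ed = 0.375)
  p1 <- pressure_beat(0.11 * q1$samples + 70, q1$dt)
  p2 <- pressure_beat(0.11 * q2$samples + 70, q2$dt)
  z1 <- characteristic_impedance(
    input_impedance(harmonic_decompose(p1, 10), harmonic_decompose(q1, 10)))
  z2 <- characteristic_impedance(
    input_impedance(harmonic_decompose(p2, 10), harmonic_decompose(q2, 10)))
  expect_equal(z1$zc, z2$zc, tolerance = 1e-9)
})
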