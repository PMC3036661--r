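test_that("sine spec validates harmonics and sampling adequacy", {
  expect_error(sine_beat_spec(omega1 = 350.5), "integer multiples")
  expect_error(sine_beat_spec(rate = 10), "rate too low")
  expect_error(sine_beat_spec(Omega = -1), "positive")
  spec <- sine_beat_spec(hb_count = 4)
  ens <- generate_sine_ensemble(spec)
  expect_equal(nrow(ens$beats), 4)
  expect_equal(ncol(ens$beats), 2^16)
  # odd beats share omega1, even beats omega2
  expect_equal(ens$beats[1, ], ens$beats[3, ])
  expect_equal(ens$beats[2, ], ens$beats[4, ])
  expect_false(isTRUE(all.equal(ens$beats[1, ], ens$beats[2, ])))
})

test_that("zero cavitation amplitude collapses the ensemble to one beat", {
  ens <- generate_sine_ensemble(sine_beat_spec(C = 0))
  expect_equal(ens$beats[1, ], ens$beats[2, ])
  expect_equal(energy_summary(ens)$e_nondet, 0,
               tolerance = 1e-12 * energy_summary(ens)$e_total)
})

test_that("apply_misalignment implements step and wrap cases", {
  b <- c(1, 2, 3, 4, 5)
  expect_identical(apply_misalignment(b, 0, "step"), b)
  expect_equal(apply_misalignment(b, 3, "step"), c(0, 0, 0, 1, 2))
  expect_equal(apply_misalignment(b, 2, "wrap"), c(4, 5, 1, 2, 3))
  set.seed(41)
  x <- rnorm(100)
  expect_equal(sum(apply_misalignment(x, 37, "wrap")^2), sum(x^2))
  expect_error(apply_misalignment(b, 5), "eps")
})

test_that("wrap misalignment injects more heart-beat energy than step", {
  # pure heart-beat sine, no cavitation: compare the two truncation fates of
  # a right-shifted beat, with the silent step prefix excluded (as overlap
  # cropping would do)
  spec <- sine_beat_spec(C = 0, omega1 = 10, omega2 = 10,
                         rate = 2^12 / (2 * pi))
  y <- generate_sine_ensemble(spec)$beats[1, ]
  for (A in c(0.5, 1, 2)) {
    ya <- A * y
    eps <- 200
    wrap <- time_domain_nondet_oracle(beat_ensemble(
      rbind(ya, apply_misalignment(ya, eps, "wrap"), deparse.level = 0), 100))
    stepped <- apply_misalignment(ya, eps, "step")
    keep <- (eps + 1):length(ya)
    step <- time_domain_nondet_oracle(beat_ensemble(
      rbind(ya[keep], stepped[keep], deparse.level = 0), 100))
    expect_gt(wrap, step)
  }
})

test_that("add_component injects at the onset and checks bounds", {
  b <- rep(0, 10)
  expect_identical(add_component(b, rep(0, 4), 2), b)
  out <- add_component(b, c(1, 2), 3)
  expect_equal(out, c(0, 0, 0, 1, 2, 0, 0, 0, 0, 0))
  expect_error(add_component(b, c(1, 2), 9), "overruns")
})

test_that("synthetic PCG is deterministic and matches its spec", {
  spec <- pcg_fixture_spec(rate = 4000, hb_count = 6, seed = 77)
  a <- generate_synthetic_pcg(spec)
  b <- generate_synthetic_pcg(spec)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$onsets, b$onsets)
  expect_length(a$onsets, 6)
  expect_equal(length(a$boundaries), 6)
})

test_that("realized period jitter matches the requested spread", {
  spec <- pcg_fixture_spec(rate = 1000, hb_count = 50, period_jitter_sd = 0.02,
                           noise_sd = 0, seed = 8)
  g <- generate_synthetic_pcg(spec)
  expect_lt(abs(sd(g$periods) - 0.02) / 0.02, 0.3)
})

test_that("continuous energy oracle integrates squared waveforms", {
  expect_equal(continuous_energy_oracle(sin, 0, 2 * pi, 1e-4), pi,
               tolerance = 1e-6)
  expect_equal(continuous_energy_oracle(function(t) 2 * sin(t), 0, 2 * pi,
                                        1e-4), 4 * pi, tolerance = 1e-6)
  # second-order convergence: halving dt shrinks the error ~4x
  f <- function(t) sin(3 * t) + 0.5 * cos(t)
  exact <- continuous_energy_oracle(f, 0, 2, 1e-6)
  e1 <- abs(continuous_energy_oracle(f, 0, 2, 2e-3) - exact)
  e2 <- abs(continuous_energy_oracle(f, 0, 2, 1e-3) - exact)
  expect_equal(e1 / e2, 4, tolerance = 0.2)
  expect_error(continuous_energy_oracle(sin, 1, 0, 0.1), "t1 > t0")
})

test_that("discrete pipeline and continuous oracle agree on sine beats", {
  spec <- sine_beat_spec(rate = 2^14 / (2 * pi))   # smaller n for the oracle
  es <- energy_summary(generate_sine_ensemble(spec))
  dt <- spec$T / 2^14
  o_det <- continuous_energy_oracle(function(t) {
    spec$A * sin(spec$Omega * t) +
      (spec$C / 2) * (sin(spec$omega1 * t) + sin(spec$omega2 * t))
  }, 0, spec$T, dt / 4)
  o_tot <- (continuous_energy_oracle(function(t)
    spec$A * sin(spec$Omega * t) + spec$C * sin(spec$omega1 * t),
    0, spec$T, dt / 4) +
    continuous_energy_oracle(function(t)
      spec$A * sin(spec$Omega * t) + spec$C * sin(spec$omega2 * t),
      0, spec$T, dt / 4)) / 2
  expect_equal(es$e_det / spec$rate, o_det, tolerance = 1e-3)
  expect_equal(es$e_total / spec$rate, o_tot, tolerance = 1e-3)
  expect_equal(es$e_nondet / spec$rate, o_tot - o_det, tolerance = 1e-2)
})
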