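test_that("ensemble_average is the sample-wise mean", {
  e <- beat_ensemble(rbind(c(2, 4), c(4, 8)), rate = 10)
  expect_equal(ensemble_average(e)$samples, c(3, 6))

  row <- c(1, -2, 3, 0.5)
  same <- beat_ensemble(matrix(rep(row, 3), 3, byrow = TRUE), rate = 10)
  expect_equal(ensemble_average(same)$samples, row)

  single <- beat_ensemble(matrix(row, 1), rate = 10)
  expect_equal(ensemble_average(single)$samples, row)
})

test_that("beat_energy satisfies Parseval on analytic and random inputs", {
  expect_equal(beat_energy(c(1, 0, 0, 0)), 1)
  expect_equal(beat_energy(c(1, 1, 1, 1)), 4)
  set.seed(99)
  x <- rnorm(1024)
  expect_equal(beat_energy(x), sum(x^2), tolerance = 1e-9)
  for (n in c(3, 17, 256, 1000)) {
    x <- rnorm(n)
    expect_equal(beat_energy(x), sum(x^2), tolerance = 1e-9)
  }
  expect_error(beat_energy(numeric(0)), "non-empty")
})

test_that("identical superimposed beats carry zero non-deterministic energy", {
  set.seed(4)
  beat <- rnorm(512)
  ens <- beat_ensemble(matrix(rep(beat, 6), 6, byrow = TRUE), rate = 1000)
  es <- energy_summary(ens)
  expect_equal(es$e_nondet, 0, tolerance = 1e-12 * es$e_total)
  expect_equal(es$percent_nondet, 0, tolerance = 1e-10)
  expect_equal(time_domain_nondet_oracle(ens), 0)
})

test_that("two orthogonal unit beats split energy 50/50", {
  ens <- beat_ensemble(rbind(c(1, 0), c(0, 1)), rate = 10)
  es <- energy_summary(ens)
  expect_equal(es$e_det, 0.5)
  expect_equal(es$e_total, 1)
  expect_equal(es$e_nondet, 0.5)
  expect_equal(es$percent_nondet, 50)
  expect_equal(time_domain_nondet_oracle(ens), 0.5)
})

test_that("frequency route and pairwise time-domain oracle agree", {
  set.seed(123)
  for (i in 1:30) {
    hb <- sample(2:10, 1)
    n <- sample(c(8, 33, 128, 1024), 1)
    ens <- beat_ensemble(matrix(rnorm(hb * n), hb), rate = 1000)
    es <- energy_summary(ens)
    expect_equal(es$e_nondet, time_domain_nondet_oracle(ens),
                 tolerance = 1e-9)
    expect_gte(es$e_total, es$e_det * (1 - 1e-12))   # Jensen
  }
})

test_that("waveforms common to every beat cancel from e_nondet", {
  set.seed(17)
  n <- 256
  base <- matrix(rnorm(4 * n), 4)
  common <- 5 * sin(2 * pi * 3 * seq_len(n) / n)
  a <- beat_ensemble(base, rate = 100)
  b <- beat_ensemble(sweep(base, 2, -common), rate = 100)
  expect_equal(energy_summary(a)$e_nondet, energy_summary(b)$e_nondet,
               tolerance = 1e-9)
})

test_that("a transient added to one of two beats contributes ||eta||^2/4", {
  # integer-valued beats keep the arithmetic exact
  y <- c(3, -1, 4, 1, -5, 9, 2, -6)
  eta <- c(0, 0, 2, -3, 1, 0, 0, 0)
  ens <- beat_ensemble(rbind(y, y + eta, deparse.level = 0), rate = 10)
  expect_equal(time_domain_nondet_oracle(ens), sum(eta^2) / 4,
               tolerance = 1e-14)
  expect_equal(energy_summary(ens)$e_nondet, sum(eta^2) / 4,
               tolerance = 1e-12)
})

test_that("three-beat transient identity holds", {
  y <- c(2, -3, 5, 1, -2, 4, 0, -1)
  eta1 <- c(1, 0, -2, 0, 3, 0, 0, 1)
  eta2 <- c(0, 2, 0, -1, 0, 0, 4, -2)
  ens <- beat_ensemble(rbind(y, y + eta1, y + eta2, deparse.level = 0),
                       rate = 10)
  expected <- (2 / 9) * (sum(eta1^2) + sum(eta2^2) - sum(eta1 * eta2))
  expect_equal(time_domain_nondet_oracle(ens), expected, tolerance = 1e-12)
  expect_equal(energy_summary(ens)$e_nondet, expected, tolerance = 1e-10)
})

test_that("sine-ensemble energies match the closed forms within 0.1%", {
  spec <- sine_beat_spec()             # A=1, C=0.2, Omega=1, 2^16 samples
  es <- energy_summary(generate_sine_ensemble(spec))
  dt <- 1 / spec$rate                  # discrete -> continuous units
  expect_equal(es$e_det * dt, pi * (spec$C^2 + 2 * spec$A^2) / (2 * spec$Omega),
               tolerance = 1e-3)
  expect_equal(es$e_total * dt, pi * (spec$A^2 + spec$C^2) / spec$Omega,
               tolerance = 1e-3)
  expect_equal(es$e_nondet * dt, pi * spec$C^2 / (2 * spec$Omega),
               tolerance = 1e-3)
})

test_that("deterministic energy is invariant to the cavitation harmonics", {
  base <- energy_summary(generate_sine_ensemble(sine_beat_spec()))
  alt <- energy_summary(generate_sine_ensemble(sine_beat_spec(omega1 = 351,
                                                              omega2 = 417)))
  expect_equal(alt$e_det, base$e_det, tolerance = 1e-3)
})

test_that("misalignment inflates e_nondet monotonically over a half period", {
  # two beats: y and a circularly rotated copy; no transient at all
  spec <- sine_beat_spec(C = 0, rate = 2^12 / (2 * pi), omega1 = 10,
                         omega2 = 10)
  y <- generate_sine_ensemble(spec)$beats[1, ]
  eps <- round(seq(0.05, 0.95, length.out = 8) * pi / (2 * pi) * length(y))
  vals <- vapply(eps, function(e) {
    shifted <- apply_misalignment(y, e, "wrap")
    time_domain_nondet_oracle(beat_ensemble(rbind(y, shifted,
                                                  deparse.level = 0), 100))
  }, numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))     # growing with eps over (0, pi)
})

test_that("silent ensembles are rejected", {
  ens <- beat_ensemble(matrix(0, 2, 8), rate = 10)
  expect_error(energy_summary(ens), "silent")
})

test_that("energy report export round-trips values", {
  ens <- beat_ensemble(rbind(c(1, 0), c(0, 1)), rate = 10)
  es <- energy_summary(ens)
  f <- tempfile(fileext = ".csv")
  write_energy_report(es, f, format = "csv", signal = "toy")
  tab <- read.csv(f)
  expect_equal(tab$percent_nondet, 50.00)
  expect_equal(tab$e_total, 1)
  fj <- tempfile(fileext = ".json")
  write_energy_report(es, fj, format = "json", signal = "toy")
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$percent_nondet, 50)
})
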