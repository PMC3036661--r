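test_that("extract_beats truncates every beat to the shortest length", {
  s <- acoustic_signal(as.numeric(1:200), rate = 100)
  b <- beat_boundaries(c(0, 100), c(100, 198), rate = 100)
  ens <- extract_beats(s, b)
  expect_equal(dim(ens), c(2L, 98L))
  expect_equal(ens$beats[1, ], as.numeric(1:98))     # first N samples kept
  expect_equal(ens$beats[2, ], as.numeric(101:198))

  one <- extract_beats(s, beat_boundaries(0, 200, 100))
  expect_equal(dim(one), c(1L, 200L))

  eq <- extract_beats(s, beat_boundaries(c(0, 100), c(100, 200), 100))
  expect_equal(eq$beats[2, ], as.numeric(101:200))   # equal lengths unchanged
})

test_that("S1 peak search is windowed, absolute-valued, earliest-tie-broken", {
  b <- rep(0, 100); b[11] <- 0.9
  expect_equal(find_s1_peak(b), 10)                  # 0-based

  # S2-like taller peak outside the first-quarter window is ignored
  b2 <- rep(0, 100); b2[13] <- 1; b2[81] <- 2
  expect_equal(find_s1_peak(b2), 12)

  b3 <- rep(0, 100); b3[6] <- -1; b3[21] <- 1        # tie in |x|
  expect_equal(find_s1_peak(b3), 5)

  expect_equal(find_s1_peak(rep(0.3, 100)), 0)       # degenerate flat beat
})

test_that("S2 peak search covers the last three quarters", {
  b <- rep(0, 100); b[61] <- -0.7
  expect_equal(find_s2_peak(b), 60)

  b2 <- rep(0, 100); b2[6] <- 1; b2[71] <- 0.5       # S1 excluded from window
  expect_equal(find_s2_peak(b2), 70)

  expect_equal(find_s2_peak(rep(0.3, 100)), 25)      # tie-break: window start
})

test_that("align_beats recovers injected integer shifts exactly", {
  tmpl <- peaked_beat(400)
  for (seed in 1:3) {
    set.seed(seed)
    shifts_in <- c(0, sample(-20:20, 4))
    rows <- t(vapply(shifts_in, function(s) delay_beat(tmpl, s), numeric(400)))
    ens <- beat_ensemble(rows, rate = 400)
    al <- align_beats(ens, "S1")
    expect_identical(al$report$shifts, as.integer(-shifts_in))
    # peaks coincide after alignment: rows identical over the overlap
    expect_equal(al$ensemble$beats[2, ], al$ensemble$beats[1, ],
                 tolerance = 1e-12)
  }
})

test_that("S2 alignment recovers shifts from the late peak", {
  tmpl <- peaked_beat(400)
  rows <- rbind(tmpl, delay_beat(tmpl, 7), delay_beat(tmpl, -9))
  al <- align_beats(beat_ensemble(rows, 400), "S2")
  expect_identical(al$report$shifts, c(0L, -7L, 9L))
})

test_that("aligning an already aligned ensemble is the identity", {
  ens <- template_ensemble(5, 300, noise_sd = 0.01, seed = 9)
  al <- align_beats(ens, "S1")
  al2 <- align_beats(al$ensemble, "S1")
  expect_true(all(al2$report$shifts == 0))
  expect_identical(al2$ensemble$beats, al$ensemble$beats)
})

test_that("alignment report statistics follow the stated conventions", {
  tmpl <- peaked_beat(400)
  rows <- rbind(tmpl, delay_beat(tmpl, 4), delay_beat(tmpl, -2))
  al <- align_beats(beat_ensemble(rows, 400), "S1")
  expect_identical(al$report$shifts, c(0L, -4L, 2L))
  expect_equal(al$report$mean_shift_magnitude, 2)
  expect_equal(al$report$std_shift, sd(c(0, -4, 2)))   # ~3.055, signed sd
  expect_equal(al$report$reference_beat, 1L)
})

test_that("remove_misaligned_beats drops only beats beyond the cutoff", {
  # shifts like a real shift audit: {0, -679, 102, -1018}, cutoff 1000
  n <- 16384
  tmpl <- peaked_beat(n, s1_pos = 0.12)
  injected <- c(0, -679, 102, -1018)
  rows <- t(vapply(injected, function(s) delay_beat(tmpl, -s), numeric(n)))
  ens <- beat_ensemble(rows, rate = 4000)
  al <- align_beats(ens, "S1")
  expect_identical(al$report$shifts, as.integer(injected))

  rem <- remove_misaligned_beats(ens, al$report, cutoff = 1000)
  expect_identical(rem$report$removed, 4L)
  expect_identical(rem$report$shifts, c(0L, -679L, 102L))

  # cutoff above every |shift|: nothing removed
  rem2 <- remove_misaligned_beats(ens, al$report, cutoff = 2000)
  expect_length(rem2$report$removed, 0)
  expect_equal(nrow(rem2$ensemble$beats), 4L)

  # degenerate: cutoff below all nonzero shifts with 2 beats
  two <- beat_ensemble(rows[c(1, 2), ], rate = 4000)
  al2 <- align_beats(two, "S1")
  expect_error(remove_misaligned_beats(two, al2$report, cutoff = 10),
               "fewer than 2")
})

test_that("tightening the cutoff never increases mean |shift| retained", {
  n <- 2048
  tmpl <- peaked_beat(n, s1_pos = 0.12)
  set.seed(13)
  injected <- c(0, sample(-150:150, 7))
  rows <- t(vapply(injected, function(s) delay_beat(tmpl, -s), numeric(n)))
  ens <- beat_ensemble(rows, rate = 4000)
  al <- align_beats(ens, "S1")
  cutoffs <- sort(abs(injected[injected != 0]), decreasing = TRUE)
  prev <- Inf
  for (cut in cutoffs[1:4]) {
    rem <- remove_misaligned_beats(ens, al$report, cutoff = cut)
    expect_lte(rem$report$mean_shift_magnitude, prev)
    prev <- rem$report$mean_shift_magnitude
  }
})

test_that("pathologically large shifts abort instead of zero-padding", {
  # peaks at opposite ends with a wide search window: overlap < 4 samples
  s1 <- c(1, rep(0, 7)); s2 <- c(rep(0, 6), 1, 0)
  expect_error(align_beats(beat_ensemble(rbind(s1, s2, deparse.level = 0),
                                         100), "S1", search_fraction = 0.95),
               "overlap")
  expect_error(align_beats(beat_ensemble(matrix(1:8, 1), 100), "S1"),
               "at least 2")
})

test_that("alignment report CSV mirrors the shift-table layout", {
  tmpl <- peaked_beat(400)
  rows <- rbind(tmpl, delay_beat(tmpl, 4), delay_beat(tmpl, -2))
  al <- align_beats(beat_ensemble(rows, 400), "S1")
  f <- tempfile(fileext = ".csv")
  write_alignment_report(al$report, f)
  tab <- read.csv(f)
  expect_named(tab, c("beat", "shift_samples"))
  expect_equal(tab$shift_samples, c(0, -4, 2))
})
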