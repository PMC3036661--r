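#' Specification of an analytic two-tone test ensemble
#'
#' Each synthetic beat is a low-frequency sine (the "heart beat", amplitude
#' `A`, angular frequency `Omega` rad/s) plus a much higher-frequency sine
#' (the "cavitation" signal, amplitude `C`), sampled over exactly one beat
#' period `T = 2*pi/Omega`:
#' `y_m(t) = A*sin(Omega*t) + C*sin(omega_m*t + phi_m)`.
#' Odd-numbered beats use `omega1/phi1`, even-numbered beats `omega2/phi2`,
#' emulating beat-to-beat variation in the high-frequency content. The
#' cavitation frequencies must be integer multiples of `Omega` so every beat
#' is exactly periodic over `T`; the closed-form energies then do not depend
#' on which integer harmonics are chosen, so desk-scale harmonics (hundreds
#' rather than the tens of thousands suggested by the 35-350 kHz cavitation
#' band at ~1 Hz heart rate) give identical results with far fewer samples.
#'
#' With these defaults the continuous-time energies have closed forms:
#' `E_det = pi*(C^2 + 2*A^2)/(2*Omega)`, `E_total = pi*(A^2 + C^2)/Omega`,
#' `E_nondet = pi*C^2/(2*Omega)` — note the non-deterministic energy depends
#' only on the cavitation amplitude `C`.
#'
#' @param A Heart-beat amplitude (default 1).
#' @param C Cavitation amplitude (default 0.2).
#' @param Omega Heart-beat angular frequency in rad/s (default 1).
#' @param omega1,omega2 Cavitation angular frequencies (rad/s), integer
#'   multiples of `Omega`; defaults `350*Omega` and `360*Omega`.
#' @param phi1,phi2 Cavitation phases in rad (default 0).
#' @param rate Sampling rate in Hz; default gives 2^16 samples per period.
#' @param hb_count Number of beats (default 2).
#' @return An object of class `sine_beat_spec`.
#' @export
sine_beat_spec <- function(A = 1, C = 0.2, Omega = 1,
                           omega1 = 350 * Omega, omega2 = 360 * Omega,
                           phi1 = 0, phi2 = 0,
                           rate = 2^16 * Omega / (2 * pi), hb_count = 2L) {
  if (Omega <= 0) stop("`Omega` must be positive", call. = FALSE)
  for (w in c(omega1, omega2)) {
    k <- w / Omega
    if (k <= 0 || abs(k - round(k)) > 1e-9) {
      stop("cavitation frequencies must be positive integer multiples of Omega",
           call. = FALSE)
    }
  }
  if (rate <= max(omega1, omega2) / pi) {
    stop("sampling rate too low for the chosen cavitation frequencies",
         call. = FALSE)
  }
  if (hb_count < 1L) stop("`hb_count` must be >= 1", call. = FALSE)
  structure(list(A = A, C = C, Omega = Omega, omega1 = omega1,
                 omega2 = omega2, phi1 = phi1, phi2 = phi2,
                 T = 2 * pi / Omega, rate = rate,
                 hb_count = as.integer(hb_count)),
            class = "sine_beat_spec")
}

#' Generate the analytic two-tone beat ensemble
#'
#' @param spec A [sine_beat_spec()].
#' @return A [beat_ensemble()] of `hb_count` beats, each sampled over one
#'   full period.
#' @seealso [sine_beat_spec()] for the model and its closed-form energies.
#' @export
generate_sine_ensemble <- function(spec) {
  stopifnot(inherits(spec, "sine_beat_spec"))
  n <- round(spec$T * spec$rate)
  t <- (seq_len(n) - 1L) / spec$rate
  hb <- spec$hb_count
  rows <- t(vapply(seq_len(hb), function(m) {
    if (m %% 2L == 1L) {
      spec$A * sin(spec$Omega * t) + spec$C * sin(spec$omega1 * t + spec$phi1)
    } else {
      spec$A * sin(spec$Omega * t) + spec$C * sin(spec$omega2 * t + spec$phi2)
    }
  }, numeric(n)))
  beat_ensemble(rows, rate = spec$rate)
}

#' Misalign a beat by an integer number of samples
#'
#' Emulates the two ways a right-shifted beat can appear after truncation to
#' a fixed length: `"step"` — the first `epsilon_samples` samples are zero
#' (the shifted-in region before the beat is silent) and the tail is cut;
#' `"wrap"` — the beat is rotated circularly, so its head is the material
#' that truncation cut from the tail. Rotation preserves energy exactly;
#' the step case does not.
#'
#' @param beat Numeric vector.
#' @param epsilon_samples Integer shift, `0 <= epsilon_samples < length(beat)`.
#' @param case `"step"` or `"wrap"`.
#' @return The misaligned beat (same length).
#' @export
apply_misalignment <- function(beat, epsilon_samples, case = c("step", "wrap")) {
  case <- match.arg(case)
  n <- length(beat)
  eps <- as.integer(epsilon_samples)
  if (eps < 0L || eps >= n) {
    stop("`epsilon_samples` must satisfy 0 <= eps < length(beat)",
         call. = FALSE)
  }
  if (eps == 0L) return(beat)
  if (case == "step") {
    c(rep(0, eps), beat[seq_len(n - eps)])
  } else {
    c(beat[(n - eps + 1L):n], beat[seq_len(n - eps)])
  }
}

#' Add a transient component to a beat
#'
#' Element-wise addition of a waveform `eta` (cavitation burst, murmur,
#' noise, ...) starting at a given onset; the rest of the beat is unchanged.
#' Two beats `{y, y + eta}` have non-deterministic energy `||eta||^2 / 4`
#' exactly, which is the cleanest demonstration that the decomposition
#' measures only the non-repeating part.
#'
#' @param beat Numeric vector of length N.
#' @param eta Numeric vector, `onset + length(eta) <= N`.
#' @param onset 0-based sample index at which `eta` starts. Default 0.
#' @return The modified beat.
#' @export
add_component <- function(beat, eta, onset = 0L) {
  n <- length(beat)
  onset <- as.integer(onset)
  if (onset < 0L || onset + length(eta) > n) {
    stop("`eta` overruns the beat (onset ", onset, ", length ", length(eta),
         ", beat length ", n, ")", call. = FALSE)
  }
  idx <- onset + seq_along(eta)
  beat[idx] <- beat[idx] + eta
  beat
}

#' Default cavitation-like burst
#'
#' Gaussian-windowed high-frequency tone burst: a desk-scale stand-in for
#' the short broadband transients produced by cavitation bubble collapse.
#'
#' @param n Length in samples.
#' @param frequency Tone frequency in Hz.
#' @param rate Sampling rate in Hz.
#' @param amplitude Peak amplitude.
#' @return Numeric vector of length `n`.
#' @export
cavitation_burst <- function(n = 256L, frequency = 0.2 * rate, rate = 4000,
                             amplitude = 0.1) {
  t <- (seq_len(n) - 1L) / rate
  mid <- t[length(t) %/% 2L + 1L]
  amplitude * exp(-((t - mid) / (0.15 * max(t)))^2) * sin(2 * pi * frequency * t)
}

#' Specification of a realistic synthetic phonocardiogram
#'
#' Each beat consists of two exponentially decaying tone bursts — S1 at
#' `s1_time` and a quieter S2 at `s2_time` after the beat start — plus white
#' Gaussian noise; beat periods are drawn with Gaussian jitter around
#' `beat_period`. Defaults emulate typical resting recordings: ~1 s beats
#' with 20 ms period jitter, S1 at 0.1 s and S2 at 0.45 s (a ~0.35 s
#' systole), 60 Hz bursts with a 20 ms decay constant, 44.1 kHz sampling,
#' and 18 beats per recording. All randomness is controlled by `seed`.
#'
#' An optional non-repeating component can be injected into selected beats
#' via `injected_component`.
#'
#' @param beat_period Mean beat period in seconds (default 1).
#' @param period_jitter_sd SD of the beat period in seconds (default 0.02).
#' @param s1_time,s2_time Burst onset times within the beat (s); must satisfy
#'   `s1_time < s2_time < beat_period`.
#' @param burst_frequency Tone frequency of S1/S2 bursts in Hz (default 60).
#' @param burst_decay Exponential decay time constant in seconds (default 0.02).
#' @param s1_amp,s2_amp Burst amplitudes (defaults 1 and 0.6).
#' @param noise_sd SD of additive white noise (default 0.01).
#' @param hb_count Number of beats (default 18).
#' @param rate Sampling rate in Hz (default 44100).
#' @param injected_component Optional `list(waveform =, beats =, offset_time =)`:
#'   a waveform added `offset_time` seconds after the S1 onset of each listed
#'   beat.
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `pcg_fixture_spec`.
#' @export
pcg_fixture_spec <- function(beat_period = 1, period_jitter_sd = 0.02,
                             s1_time = 0.1, s2_time = 0.45,
                             burst_frequency = 60, burst_decay = 0.02,
                             s1_amp = 1, s2_amp = 0.6,
                             noise_sd = 0.01, hb_count = 18L, rate = 44100,
                             injected_component = NULL, seed = 1L) {
  if (!(s1_time < s2_time && s2_time < beat_period)) {
    stop("need s1_time < s2_time < beat_period", call. = FALSE)
  }
  if (period_jitter_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (hb_count < 2L) stop("`hb_count` must be >= 2", call. = FALSE)
  structure(list(beat_period = beat_period,
                 period_jitter_sd = period_jitter_sd,
                 s1_time = s1_time, s2_time = s2_time,
                 burst_frequency = burst_frequency,
                 burst_decay = burst_decay,
                 s1_amp = s1_amp, s2_amp = s2_amp,
                 noise_sd = noise_sd, hb_count = as.integer(hb_count),
                 rate = rate, injected_component = injected_component,
                 seed = as.integer(seed)),
            class = "pcg_fixture_spec")
}

#' Generate a synthetic phonocardiogram with ground truth
#'
#' Deterministic for a fixed spec (the seed is part of the spec): running the
#' generator twice yields bit-identical output. The returned ground truth is
#' the S1-onset segmentation — beat `m` spans from its S1 onset to the next
#' beat's S1 onset (the last beat ends at the signal end).
#'
#' @param spec A [pcg_fixture_spec()].
#' @return A list with elements `signal` (an [acoustic_signal()], not
#'   normalized), `boundaries` (ground-truth [beat_boundaries()]), `onsets`
#'   (0-based S1-onset samples) and `periods` (realized beat periods, s).
#' @export
generate_synthetic_pcg <- function(spec) {
  stopifnot(inherits(spec, "pcg_fixture_spec"))
  set.seed(spec$seed)
  hb <- spec$hb_count
  periods <- stats::rnorm(hb, spec$beat_period, spec$period_jitter_sd)
  periods <- pmax(periods, 0.5 * spec$beat_period)
  beat_starts <- cumsum(c(0, periods[-hb]))
  n <- round(sum(periods) * spec$rate)
  x <- stats::rnorm(n, 0, spec$noise_sd)

  add_burst <- function(x, t0, amp) {
    i0 <- round(t0 * spec$rate)                 # 0-based onset sample
    len <- min(round(6 * spec$burst_decay * spec$rate), n - i0)
    if (len <= 0L) return(x)
    tl <- (seq_len(len) - 1L) / spec$rate
    idx <- i0 + seq_len(len)
    x[idx] <- x[idx] + amp * exp(-tl / spec$burst_decay) *
      sin(2 * pi * spec$burst_frequency * tl)
    x
  }
  for (m in seq_len(hb)) {
    x <- add_burst(x, beat_starts[m] + spec$s1_time, spec$s1_amp)
    x <- add_burst(x, beat_starts[m] + spec$s2_time, spec$s2_amp)
  }

  onsets <- round((beat_starts + spec$s1_time) * spec$rate)
  inj <- spec$injected_component
  if (!is.null(inj)) {
    off <- round((inj$offset_time %||% 0) * spec$rate)
    for (m in inj$beats) {
      i0 <- onsets[m] + off
      idx <- i0 + seq_along(inj$waveform)
      idx <- idx[idx <= n]
      x[idx] <- x[idx] + inj$waveform[seq_along(idx)]
    }
  }

  sig <- acoustic_signal(x, rate = spec$rate, source_label = "synthetic PCG")
  list(signal = sig,
       boundaries = boundaries_from_onsets(onsets, n, pre_roll = 0,
                                           rate = spec$rate),
       onsets = as.integer(onsets),
       periods = periods)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brute-force continuous-time energy oracle
#'
#' Trapezoidal approximation of the energy integral of
#' an arbitrary waveform, `int_{t0}^{t1} f(t)^2 dt`, used as an independent
#' numerical check of closed-form energy expressions and of the discrete
#' pipeline (discrete energies divided by the sampling rate converge to this
#' integral). Error decreases as `O(dt^2)` for smooth integrands.
#'
#' @param waveform Function of time returning amplitude (vectorized).
#' @param t0,t1 Integration limits in seconds, `t1 > t0`.
#' @param dt Time step in seconds.
#' @return Energy in amplitude^2 * seconds.
#' @export
continuous_energy_oracle <- function(waveform, t0, t1, dt) {
  if (dt <= 0 || t1 <= t0) stop("need dt > 0 and t1 > t0", call. = FALSE)
  t <- seq(t0, t1, by = dt)
  if (t[length(t)] < t1) t <- c(t, t1)
  pracma::trapz(t, waveform(t)^2)
}
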