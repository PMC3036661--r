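#' Equal-length heart-beat ensemble
#'
#' Matrix of superimposed heart beats: row `m` holds the `m`-th truncated
#' beat, so the element `[m, n]` is the `n`-th sample of beat `m`. All
#' ensemble-level statistics (ensemble average, energy decomposition) operate
#' on this container.
#'
#' @param beats Numeric matrix, one beat per row, all rows the same length.
#' @param rate Sampling rate in Hz.
#' @param alignment_mode `"none"`, `"S1"` or `"S2"`.
#' @param retained_indices Original beat numbers for each row (bookkeeping
#'   across truncation and bad-beat removal).
#' @return An object of class `beat_ensemble`.
#' @export
beat_ensemble <- function(beats, rate, alignment_mode = "none",
                          retained_indices = seq_len(nrow(beats))) {
  if (!is.matrix(beats) || !is.numeric(beats)) {
    stop("`beats` must be a numeric matrix (one beat per row)", call. = FALSE)
  }
  if (nrow(beats) < 1L || ncol(beats) < 1L) {
    stop("ensemble must contain at least one beat and one sample", call. = FALSE)
  }
  if (!all(is.finite(beats))) stop("beats must be finite", call. = FALSE)
  alignment_mode <- match.arg(alignment_mode, c("none", "S1", "S2"))
  structure(list(beats = beats, rate = as.numeric(rate),
                 alignment_mode = alignment_mode,
                 retained_indices = as.integer(retained_indices)),
            class = "beat_ensemble")
}

#' @export
print.beat_ensemble <- function(x, ...) {
  cat(sprintf("<beat_ensemble> %d beats x %d samples @ %g Hz, alignment: %s\n",
              nrow(x$beats), ncol(x$beats), x$rate, x$alignment_mode))
  invisible(x)
}

#' @export
dim.beat_ensemble <- function(x) dim(x$beats)

#' Extract and truncate beats into an ensemble
#'
#' Slices the signal at the beat boundaries and truncates every beat to the
#' length of the shortest one, keeping each beat's first `N` samples (the end
#' of a beat is quiet diastole, so the tail carries the least information and
#' is the part that is dropped).
#'
#' @param signal An [acoustic_signal()].
#' @param boundaries A [beat_boundaries()] object valid for `signal`.
#' @return A [beat_ensemble()] with `alignment_mode = "none"`.
#' @export
extract_beats <- function(signal, boundaries) {
  stopifnot(inherits(signal, "acoustic_signal"),
            inherits(boundaries, "beat_boundaries"))
  if (length(boundaries) < 1L) stop("empty boundaries", call. = FALSE)
  if (max(boundaries$end) > length(signal$samples)) {
    stop("boundaries extend beyond the signal", call. = FALSE)
  }
  lens <- boundaries$end - boundaries$start
  n <- min(lens)
  rows <- t(vapply(seq_along(boundaries$start), function(i) {
    s <- boundaries$start[i]          # 0-based
    signal$samples[(s + 1):(s + n)]
  }, numeric(n)))
  beat_ensemble(rows, rate = signal$rate)
}

#' Locate the S1 peak of a beat
#'
#' Index (0-based) of the maximum absolute amplitude within the first
#' `search_fraction` of the beat. S1 normally falls in the first quarter of
#' the beat; restricting the search window prevents an S2 that happens to be
#' taller than S1 from being picked up. Maximum *absolute* amplitude is used
#' because the polarity of the recorded sound is transducer-dependent. Ties
#' are broken toward the earliest index.
#'
#' @param beat Numeric vector (one ensemble row), length >= 4.
#' @param search_fraction Fraction of the beat searched from the start;
#'   default 0.25.
#' @return 0-based sample index of the peak.
#' @export
find_s1_peak <- function(beat, search_fraction = 0.25) {
  n <- length(beat)
  if (n < 4L) stop("beat too short", call. = FALSE)
  k <- max(1L, floor(search_fraction * n))
  which.max(abs(beat[seq_len(k)])) - 1L
}

#' Locate the S2 peak of a beat
#'
#' Index (0-based) of the maximum absolute amplitude within the last
#' `1 - search_fraction_start` of the beat (by default the last three
#' quarters, where S2 normally falls). Earliest-index tie-break.
#'
#' @param beat Numeric vector (one ensemble row), length >= 4.
#' @param search_fraction_start Fraction of the beat where the search window
#'   begins; default 0.25.
#' @return 0-based sample index of the peak.
#' @export
find_s2_peak <- function(beat, search_fraction_start = 0.25) {
  n <- length(beat)
  if (n < 4L) stop("beat too short", call. = FALSE)
  k0 <- floor(search_fraction_start * n)        # 0-based window start
  k0 + which.max(abs(beat[(k0 + 1):n])) - 1L
}

.shift_stats <- function(shifts) {
  list(mean_shift_magnitude = mean(abs(shifts)),
       sd_shift_magnitude = if (length(shifts) > 1L) stats::sd(abs(shifts)) else 0,
       std_shift = if (length(shifts) > 1L) stats::sd(shifts) else 0)
}

#' Align the beats of an ensemble on their S1 or S2 peaks
#'
#' Finds the chosen peak in every beat, then shifts each beat left or right
#' so that its peak lines up with the peak of the first (reference) beat.
#' The per-beat shift is `reference peak index - beat peak index` (negative =
#' left shift). After shifting, all beats are cropped to the sample range
#' covered by *every* shifted beat — no zero padding ever enters the energy
#' computation, because padded prefixes would masquerade as misplaced beats
#' and corrupt the decomposition. The larger a beat's shift, the more of the
#' ensemble is truncated.
#'
#' @param ensemble A [beat_ensemble()] with at least 2 beats.
#' @param mode `"S1"` or `"S2"`.
#' @param search_fraction Peak search window (see [find_s1_peak()] /
#'   [find_s2_peak()]).
#' @return A list with elements `ensemble` (the aligned, re-truncated
#'   [beat_ensemble()]) and `report` (class `alignment_report`: per-beat
#'   `shifts`, `reference_beat`, `search_window`, `mean_shift_magnitude`,
#'   `sd_shift_magnitude`, `std_shift` (signed sample sd), `removed`,
#'   `cutoff`, `mode`).
#' @export
align_beats <- function(ensemble, mode = c("S1", "S2"),
                        search_fraction = 0.25) {
  stopifnot(inherits(ensemble, "beat_ensemble"))
  mode <- match.arg(mode)
  hb <- nrow(ensemble$beats)
  if (hb < 2L) stop("alignment needs at least 2 beats", call. = FALSE)
  n <- ncol(ensemble$beats)
  peak_fun <- if (mode == "S1") {
    function(b) find_s1_peak(b, search_fraction)
  } else {
    function(b) find_s2_peak(b, search_fraction)
  }
  peaks <- apply(ensemble$beats, 1L, peak_fun)
  shifts <- peaks[1L] - peaks                     # 0 for the reference beat

  lo <- max(0L, max(shifts))                      # common overlap, 0-based
  hi <- n + min(0L, min(shifts))
  if (hi - lo < 4L) {
    stop("shifts are so large that fewer than 4 samples overlap; ",
         "check segmentation quality", call. = FALSE)
  }
  rows <- t(vapply(seq_len(hb), function(m) {
    s <- shifts[m]
    ensemble$beats[m, (lo - s + 1):(hi - s)]
  }, numeric(hi - lo)))

  out <- beat_ensemble(rows, rate = ensemble$rate, alignment_mode = mode,
                       retained_indices = ensemble$retained_indices)
  st <- .shift_stats(shifts)
  report <- structure(
    c(list(shifts = as.integer(shifts),
           beat_numbers = ensemble$retained_indices,
           reference_beat = ensemble$retained_indices[1L],
           search_window = search_fraction, mode = mode),
      st,
      list(removed = integer(0), cutoff = NA_real_)),
    class = "alignment_report"
  )
  list(ensemble = out, report = report)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> %s alignment, %d beats (reference beat %d)\n",
              x$mode, length(x$shifts), x$reference_beat))
  cat(sprintf("  mean |shift| %.2f, sd |shift| %.2f, sd shift %.2f samples\n",
              x$mean_shift_magnitude, x$sd_shift_magnitude, x$std_shift))
  if (length(x$removed)) {
    cat("  removed beats:", paste(x$removed, collapse = ", "),
        sprintf("(cutoff %g)\n", x$cutoff))
  }
  invisible(x)
}

#' Remove badly shifted beats and re-align
#'
#' Beats whose alignment shift exceeds `cutoff` in magnitude are "bad" beats:
#' either the recording or the initial segmentation was poor there, and
#' shifting them into place would truncate away too much of every beat.
#' They are dropped before any energy is computed, and the surviving beats
#' are re-aligned and re-cropped. The reference beat (shift 0) always
#' survives, so shift statistics over the retained set can only improve as
#' the cutoff tightens.
#'
#' The cutoff is signal-dependent and should be chosen by inspecting the
#' shift table (e.g. via [write_alignment_report()]); [shift_cutoff_heuristic()]
#' offers `mean(|shift|) + 2*sd(shift)` as a starting point.
#'
#' @param ensemble The *pre-alignment* [beat_ensemble()] that was passed to
#'   [align_beats()] (its rows correspond one-to-one to `report$shifts`).
#' @param report The `alignment_report` produced by [align_beats()].
#' @param cutoff Positive shift magnitude in samples above which a beat is
#'   removed.
#' @return As [align_beats()]: list of re-aligned `ensemble` and updated
#'   `report` (with `removed` and `cutoff` filled in, statistics recomputed
#'   over retained beats).
#' @export
remove_misaligned_beats <- function(ensemble, report, cutoff) {
  stopifnot(inherits(ensemble, "beat_ensemble"),
            inherits(report, "alignment_report"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("`cutoff` must be a positive number of samples", call. = FALSE)
  }
  if (length(report$shifts) != nrow(ensemble$beats)) {
    stop("`report` does not match `ensemble` (give the pre-alignment ensemble)",
         call. = FALSE)
  }
  keep <- abs(report$shifts) <= cutoff
  if (sum(keep) < 2L) {
    stop("fewer than 2 beats would remain below this cutoff", call. = FALSE)
  }
  removed <- ensemble$retained_indices[!keep]
  sub <- beat_ensemble(ensemble$beats[keep, , drop = FALSE],
                       rate = ensemble$rate,
                       retained_indices = ensemble$retained_indices[keep])
  res <- align_beats(sub, mode = report$mode,
                     search_fraction = report$search_window)
  res$report$removed <- as.integer(removed)
  res$report$cutoff <- as.numeric(cutoff)
  res
}

#' Heuristic shift cutoff
#'
#' `mean(|shift|) + 2 * sd(shift)` over the reported shifts: a starting point
#' for the bad-beat cutoff when no value has been chosen by inspection.
#'
#' @param report An `alignment_report`.
#' @return Cutoff in samples.
#' @export
shift_cutoff_heuristic <- function(report) {
  stopifnot(inherits(report, "alignment_report"))
  report$mean_shift_magnitude + 2 * report$std_shift
}

#' Export an alignment report as CSV
#'
#' Writes a two-column table (`beat`, `shift_samples`), one row per beat, the
#' same layout used for shift audit tables; removed beats are flagged in a
#' third column when a cutoff was applied.
#'
#' @param report An `alignment_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(report, path) {
  stopifnot(inherits(report, "alignment_report"))
  df <- data.frame(beat = report$beat_numbers,
                   shift_samples = report$shifts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
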