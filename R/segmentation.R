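#' Beat boundaries over a recording
#'
#' Ordered, non-overlapping beat intervals. All sample coordinates in this
#' package are 0-based and half-open: a beat `[start, end)` covers samples
#' `start, ..., end - 1`. This convention is used in the in-memory objects
#' and in the CSV interchange format alike so that slicing arithmetic is
#' unambiguous.
#'
#' @param starts,ends Integer vectors of interval starts/ends (0-based,
#'   half-open), same length, strictly increasing starts.
#' @param rate Sampling rate in Hz.
#' @param signal_length Optional signal length (samples) for bounds checking.
#' @return An object of class `beat_boundaries` with elements `start`, `end`
#'   (numeric vectors) and `rate`.
#' @export
beat_boundaries <- function(starts, ends, rate, signal_length = NULL) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("`starts` and `ends` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(ends <= starts)) stop("every interval needs end > start", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("interval starts must be strictly increasing", call. = FALSE)
  }
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    stop("intervals must not overlap", call. = FALSE)
  }
  if (any(starts < 0)) stop("negative start index", call. = FALSE)
  if (!is.null(signal_length) && any(ends > signal_length)) {
    stop("interval extends beyond the signal (length ", signal_length, ")",
         call. = FALSE)
  }
  structure(list(start = starts, end = ends, rate = as.numeric(rate)),
            class = "beat_boundaries")
}

#' @export
print.beat_boundaries <- function(x, ...) {
  cat(sprintf("<beat_boundaries> %d beats, %g-%g samples long @ %g Hz\n",
              length(x$start), min(x$end - x$start), max(x$end - x$start),
              x$rate))
  invisible(x)
}

#' @export
length.beat_boundaries <- function(x) length(x$start)

#' Shannon-energy envelope of a heart-sound signal
#'
#' Computes the per-sample Shannon energy `SE(x) = -x^2 * log(x^2)` (with
#' `SE(0) = 0`) and averages it over sliding frames. For a peak-normalized
#' signal (`|x| <= 1`) the envelope is non-negative and emphasizes
#' medium-intensity bursts such as S1/S2 while suppressing both low-level
#' noise and the extreme peak, which makes it a robust detection envelope.
#'
#' @param signal A peak-normalized [acoustic_signal()].
#' @param frame_length Frame length in samples (default: 20 ms worth).
#' @param hop Hop between frame starts in samples (default: 10 ms worth).
#' @return An object of class `envelope_series`: list with `values`
#'   (one mean Shannon energy per frame), `frame_length`, `hop`, `rate`.
#'   The number of frames is `floor((L - frame_length)/hop) + 1`.
#' @export
shannon_envelope <- function(signal,
                             frame_length = round(0.02 * signal$rate),
                             hop = round(0.01 * signal$rate)) {
  stopifnot(inherits(signal, "acoustic_signal"))
  frame_length <- as.integer(frame_length); hop <- as.integer(hop)
  if (frame_length < 1L || hop < 1L) {
    stop("`frame_length` and `hop` must be >= 1 sample", call. = FALSE)
  }
  x <- signal$samples
  if (frame_length > length(x)) {
    stop("`frame_length` exceeds the signal length", call. = FALSE)
  }
  x2 <- x^2
  se <- ifelse(x2 > 0, -x2 * log(x2), 0)
  n_frames <- (length(x) - frame_length) %/% hop + 1L
  # cumulative sum gives O(L) frame means
  cs <- c(0, cumsum(se))
  starts <- (seq_len(n_frames) - 1L) * hop
  vals <- (cs[starts + frame_length + 1L] - cs[starts + 1L]) / frame_length
  structure(list(values = pmax(vals, 0), frame_length = frame_length,
                 hop = hop, rate = signal$rate),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d frames (frame %d, hop %d samples) @ %g Hz\n",
              length(x$values), x$frame_length, x$hop, x$rate))
  invisible(x)
}

#' Detect beat onsets from a Shannon-energy envelope
#'
#' Frames exceeding `threshold_fraction * max(envelope)` are grouped into
#' contiguous bursts; each burst start (converted to a 0-based sample index)
#' is an onset candidate. A refractory rule then discards any candidate
#' closer than `min_beat_period` to the previously accepted one — this is
#' what separates S1 onsets from the S2 burst of the same beat, since the
#' S1-S2 spacing (systole) is much shorter than a full beat. If both S1 and
#' S2 survive the refractory pass, a second pass estimates the beat period as
#' the median of accepted inter-onset gaps and drops, from any pair of onsets
#' closer than 70% of that period, the one with the weaker envelope burst.
#'
#' This detector is a deliberately simple stand-in for full-featured PCG
#' segmenters; externally computed segmentation points can be supplied via
#' [load_segmentation()] instead.
#'
#' @param envelope An `envelope_series` from [shannon_envelope()].
#' @param threshold_fraction Burst threshold as a fraction of the envelope
#'   maximum, in (0, 1). Default 0.2.
#' @param min_beat_period Refractory period in seconds; onsets closer than
#'   this are merged. Default 0.4 s (a 150 bpm upper bound on heart rate).
#' @return Integer vector of onset sample indices (0-based).
#' @export
detect_beat_onsets <- function(envelope, threshold_fraction = 0.2,
                               min_beat_period = 0.4) {
  stopifnot(inherits(envelope, "envelope_series"))
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (min_beat_period <= 0) stop("`min_beat_period` must be > 0", call. = FALSE)
  v <- envelope$values
  mx <- max(v)
  above <- v > threshold_fraction * mx
  if (mx <= 0 || !any(above)) {
    stop("no burst exceeds the threshold: signal cannot be segmented",
         call. = FALSE)
  }
  runs <- rle(above)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  burst_frames <- run_starts[runs$values]            # 1-based frame index
  burst_peaks <- vapply(seq_along(burst_frames), function(i) {
    max(v[run_starts[runs$values][i]:run_ends[runs$values][i]])
  }, numeric(1))
  onset_samples <- (burst_frames - 1L) * envelope$hop  # 0-based samples
  min_gap <- min_beat_period * envelope$rate

  keep_refractory <- function(onsets, peaks, gap) {
    keep <- logical(length(onsets))
    last <- -Inf
    for (i in seq_along(onsets)) {
      if (onsets[i] - last >= gap) {
        keep[i] <- TRUE
        last <- onsets[i]
      }
    }
    list(onsets = onsets[keep], peaks = peaks[keep])
  }

  acc <- keep_refractory(onset_samples, burst_peaks, min_gap)
  # resolve residual S1/S2 alternation by the spacing pattern
  if (length(acc$onsets) >= 3L) {
    gaps <- diff(acc$onsets)
    period <- stats::median(gaps[gaps >= min_gap])
    if (is.finite(period)) {
      onsets <- acc$onsets; peaks <- acc$peaks
      keep <- rep(TRUE, length(onsets))
      i <- 1L
      while (i < length(onsets)) {
        j <- i + 1L
        while (j <= length(onsets) && !keep[j]) j <- j + 1L
        if (j > length(onsets)) break
        if (onsets[j] - onsets[i] < 0.7 * period) {
          drop <- if (peaks[j] < peaks[i]) j else i
          keep[drop] <- FALSE
          if (drop == i) i <- j
        } else {
          i <- j
        }
      }
      acc$onsets <- onsets[keep]
    }
  }
  as.integer(acc$onsets)
}

#' Build beat boundaries from onset indices
#'
#' Beat `i` spans `[onset_i - pre_roll, onset_{i+1} - pre_roll)`; the last
#' beat ends at the signal end. `pre_roll` expresses where a "beat" begins
#' relative to the detected S1 onset; a negative resulting start is clipped
#' to 0.
#'
#' @param onsets Strictly increasing 0-based onset sample indices (>= 2).
#' @param signal_length Total signal length in samples.
#' @param pre_roll Samples to include before each onset. Default 0.
#' @param rate Sampling rate in Hz (stored on the result).
#' @return A [beat_boundaries()] object.
#' @export
boundaries_from_onsets <- function(onsets, signal_length, pre_roll = 0,
                                   rate = NA_real_) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2L) {
    stop("need at least 2 onsets to delimit beats", call. = FALSE)
  }
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  starts <- pmax(onsets - pre_roll, 0)
  ends <- c(starts[-1L], signal_length)
  beat_boundaries(starts, ends, rate = rate, signal_length = signal_length)
}

#' Load externally computed segmentation points
#'
#' Reads a headerless CSV of either one column (onset sample indices, one per
#' row) or two columns (`start,end` pairs), 0-based. One-column files are
#' converted to boundaries exactly as [boundaries_from_onsets()] does, which
#' requires `signal_length` to close the final beat.
#'
#' @param path CSV file path.
#' @param rate Sampling rate in Hz of the signal the points refer to.
#' @param signal_length Signal length in samples (required for one-column
#'   onset files; used for validation otherwise).
#' @param pre_roll Passed to [boundaries_from_onsets()] for onset files.
#' @return A [beat_boundaries()] object.
#' @export
load_segmentation <- function(path, rate, signal_length = NULL, pre_roll = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("could not parse segmentation CSV: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tab) == 0L) stop("empty segmentation file", call. = FALSE)
  if (ncol(tab) == 1L) {
    if (is.null(signal_length)) {
      stop("`signal_length` is required for onset-only segmentation files",
           call. = FALSE)
    }
    boundaries_from_onsets(tab[[1L]], signal_length, pre_roll = pre_roll,
                           rate = rate)
  } else {
    beat_boundaries(tab[[1L]], tab[[2L]], rate = rate,
                    signal_length = signal_length)
  }
}

#' Write beat boundaries to CSV
#'
#' @param boundaries A [beat_boundaries()] object.
#' @param path Output CSV path; two headerless columns `start,end` (0-based).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "beat_boundaries"))
  utils::write.table(data.frame(boundaries$start, boundaries$end), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
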