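## Event detection: band-pass -> automatic gain control -> adaptive
## sharpness thresholding -> refractory + burst-context false-positive
## rejection -> per-minute counts.

#' Detector configuration
#'
#' @param band Length-2 numeric, pass band in Hz (default 0.2--40, the band
#'   in which the biosensor output correlates with fish movement).
#' @param agc_window_s Window (seconds) over which the running robust scale
#'   is estimated for gain control and thresholding. Default 10.
#' @param sharpness_threshold Detection threshold as a multiple of the robust
#'   local scale (MAD) of the first-difference signal. Default 6.
#' @param refractory_s Minimum separation between accepted events, seconds.
#'   Default 0.15, just below the 0.2 s implied by the 5 flips/s maximum
#'   within-burst rate.
#' @param burst_context_s Window within which an accepted event must have at
#'   least one other candidate (bursts have >= 2 flips); isolated candidates
#'   below `strong_factor` times the threshold are rejected as artifacts.
#'   Default 1.
#' @param strong_factor Isolated candidates at or above
#'   `strong_factor * threshold` are kept regardless of context. Default 2.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(band = c(0.2, 40), agc_window_s = 10,
                            sharpness_threshold = 6, refractory_s = 0.15,
                            burst_context_s = 1, strong_factor = 2) {
  if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop_tf("tailflip_parameter_error", "`band` must satisfy 0 < low < high")
  }
  check_number(agc_window_s, "agc_window_s", lower = 1)
  check_number(sharpness_threshold, "sharpness_threshold", lower = 0)
  check_number(refractory_s, "refractory_s", lower = 0, upper = 0.2)
  check_number(burst_context_s, "burst_context_s", lower = 0)
  check_number(strong_factor, "strong_factor", lower = 1)
  structure(list(band = band, agc_window_s = agc_window_s,
                 sharpness_threshold = sharpness_threshold,
                 refractory_s = refractory_s,
                 burst_context_s = burst_context_s,
                 strong_factor = strong_factor),
            class = "detector_config")
}

#' Zero-phase band-pass filter
#'
#' Restricts a trace to the 0.2--40 Hz band in which the biosensor signal
#' carries movement information. Filtering is zero-phase (forward-backward),
#' so event times are not shifted: a second-order Butterworth high-pass at
#' the lower edge cascaded with an eighth-order Butterworth low-pass at the
#' upper edge, each applied with `signal::filtfilt`.
#'
#' @param trace A [biosensor_trace()].
#' @param band Length-2 numeric pass band in Hz; `band[2]` must be below the
#'   Nyquist frequency.
#' @return A filtered [biosensor_trace()] (truth metadata preserved).
#' @export
bandpass <- function(trace, band = c(0.2, 40)) {
  fs <- trace$sample_rate
  if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 ||
      band[1] >= band[2] || band[2] >= fs / 2) {
    stop_tf("tailflip_parameter_error",
            "band must satisfy 0 < low < high < sample_rate/2")
  }
  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(8, band[2] / (fs / 2), type = "low")
  x <- trace$samples
  n <- length(x)
  ## zero-phase filtering applied in the frequency domain: the spectrum is
  ## multiplied by |H|^2 of the Butterworth cascade, the forward-backward
  ## (filtfilt) response, with zero-padding against circular wrap-around
  nfft <- stats::nextn(n + as.integer(10 * fs), c(2, 3, 5))
  w <- 2 * pi * seq_len(nfft %/% 2 + 1L) - 2 * pi  # 0 .. pi rad/sample grid
  w <- w / nfft
  z <- exp(-1i * w)
  horner <- function(coef, z) {      # sum coef[k] z^(k-1), highest first
    acc <- rep(coef[length(coef)] + 0i, length(z))
    for (j in seq(length(coef) - 1L, 1L)) acc <- acc * z + coef[j]
    acc
  }
  hresp <- function(flt) horner(flt$b, z) / horner(flt$a, z)
  H2 <- Mod(hresp(hp))^2 * Mod(hresp(lp))^2
  H2full <- c(H2, rev(H2[2:(nfft - length(H2) + 1L)]))
  x <- x - mean(x)    # the pass band excludes DC; also tames edge steps
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * H2full, inverse = TRUE))[seq_len(n)] / nfft
  out <- trace
  out$samples <- y
  out
}

## running robust scale: MAD over non-overlapping blocks, linearly
## interpolated to per-sample resolution. O(n).
## running robust statistic over non-overlapping blocks, linearly
## interpolated to per-sample resolution; O(n)
running_stat <- function(x, fs, window_s, fun) {
  n <- length(x)
  block <- max(2L, round(window_s * fs))
  nb <- max(1L, n %/% block)
  m <- matrix(x[seq_len(nb * block)], block, nb)
  v <- apply(m, 2L, fun)
  if (nb == 1L) return(rep(v, n))
  centers <- (seq_len(nb) - 0.5) * block
  approx(centers, v, xout = seq_len(n), rule = 2)$y
}

running_mad <- function(x, fs, window_s) {
  running_stat(x, fs, window_s, function(v) median(abs(v - median(v))))
}

#' Automatic gain control
#'
#' Normalizes the running robust amplitude (MAD over `window_s` blocks) of a
#' trace to 1, making downstream thresholds invariant to constant and slow
#' multiplicative gain changes in the measurement channel. An all-zero trace
#' is returned unchanged (no division blow-up).
#'
#' @param trace A [biosensor_trace()] (typically already band-passed).
#' @param window_s Window in seconds (>= 1). Default 10.
#' @return A gain-normalized [biosensor_trace()].
#' @export
agc <- function(trace, window_s = 10) {
  check_number(window_s, "window_s", lower = 1)
  x <- trace$samples
  g <- running_mad(x, trace$sample_rate, window_s)
  ## the gain is floored at a fixed fraction of the loudest block, capping
  ## the correction range at 4x: ample for instrument gain drift, while
  ## quiet or noise-free stretches -- whose robust scale collapses to the
  ## filter-ripple level -- are not amplified without bound; the floor
  ## scales with the trace, so constant rescaling cancels exactly
  gmax <- max(g)
  out <- trace
  if (gmax == 0) {             # all-zero trace
    out$samples <- x
    return(out)
  }
  out$samples <- x / pmax(g, 0.25 * gmax)
  out
}

#' Detect tail-flip events in a trace
#'
#' Sharpness functional: absolute first difference of the band-passed,
#' gain-controlled signal. Candidate events are local maxima of sharpness
#' exceeding `sharpness_threshold` times the running MAD of the differenced
#' signal; accepted events are separated by at least the refractory period
#' (larger peaks win), and isolated sub-strong candidates (no other
#' candidate within `burst_context_s`) are rejected as artifacts, since real
#' swimming comes in bursts of several flips.
#'
#' @param trace A [biosensor_trace()].
#' @param cfg A [detector_config()].
#' @param preprocess If `TRUE` (default) the trace is band-passed and
#'   gain-controlled first; set `FALSE` if already done.
#' @return A [flip_train()] with `source = "detected"`.
#' @export
detect_flips <- function(trace, cfg = detector_config(), preprocess = TRUE) {
  fs <- trace$sample_rate
  if (length(trace$samples) < cfg$agc_window_s * fs) {
    stop_tf("tailflip_input_error", "trace shorter than the AGC window")
  }
  if (preprocess) {
    trace <- agc(bandpass(trace, cfg$band), cfg$agc_window_s)
  }
  x <- trace$samples
  d <- abs(diff(x))
  scale <- running_mad(diff(x), fs, cfg$agc_window_s)
  ## two floors keep noise-free traces exact: a local one at 15% of the
  ## running high quantile of sharpness (rejects filter ringing next to
  ## events without penalizing quieter stretches of the recording) and a
  ## small global one against numerical ripple far from any event; in noisy
  ## traces the MAD term sits above both
  q_local <- running_stat(d, fs, cfg$agc_window_s,
                          function(v) quantile(v, 0.995, names = FALSE))
  thr <- pmax(cfg$sharpness_threshold * scale, 0.15 * q_local, 0.01 * max(d))
  over <- d > thr & d > 0
  ## local maxima of d among threshold crossings
  loc <- which(over)
  loc <- loc[d[loc] >= c(0, d)[loc] & d[loc] >= c(d, 0)[loc + 1L]]
  if (!length(loc)) {
    return(flip_train(numeric(0), length(x) / fs / 60, trace$phase,
                      trace$fish_id, "detected"))
  }
  ## refractory: greedy by sharpness, larger peaks win
  o <- loc[order(d[loc], decreasing = TRUE)]
  keep <- logical(length(x))
  blocked <- logical(length(x))
  r <- max(1L, round(cfg$refractory_s * fs))
  for (i in o) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      blocked[max(1L, i - r):min(length(x), i + r)] <- TRUE
    }
  }
  ev <- which(keep)
  ## burst context: candidates (pre-refractory) within +/- window
  if (cfg$burst_context_s > 0 && length(ev)) {
    w <- round(cfg$burst_context_s * fs)
    ## candidates (pre-refractory) within +/- w of each event, self included
    n_near <- findInterval(ev + w, loc) - findInterval(ev - w - 1L, loc)
    strong <- d[ev] >= cfg$strong_factor * thr[ev]
    ev <- ev[n_near >= 2L | strong]
  }
  ## event time at the centre of the differenced pair
  times <- (ev - 0.5) / fs
  flip_train(times, length(x) / fs / 60, trace$phase, trace$fish_id, "detected")
}

#' Bin a flip train into counts per minute
#'
#' @param train A [flip_train()].
#' @param span_min Number of minutes to cover (defaults to the train's
#'   duration); all events must fall inside it.
#' @return An [activity_series()] of non-negative integer counts whose sum
#'   equals the number of events.
#' @export
counts_per_minute <- function(train, span_min = ceiling(train$duration_min)) {
  check_number(span_min, "span_min", lower = 1)
  span_min <- as.integer(ceiling(span_min))
  if (length(train$times_s) && max(train$times_s) > span_min * 60) {
    stop_tf("tailflip_input_error", "events outside the requested span")
  }
  m <- floor(train$times_s / 60)
  counts <- tabulate(m + 1L, nbins = span_min)
  activity_series(counts, phase = train$phase, fish_id = train$fish_id,
                  metric = "flips")
}

#' Detect events for every fish of a trace-level study
#'
#' Runs [detect_flips()] and [counts_per_minute()] on each fish's pre- and
#' post-treatment traces, returning records ready for [normalize_study()].
#' Ground-truth trains (when present) are carried along for benchmarking.
#'
#' @param study A `study_data` simulated with `level = "trace"`.
#' @param cfg A [detector_config()].
#' @return List of per-fish records with `fish_id`, `group`, detected
#'   `pre`/`post` [activity_series()], and `truth_pre`/`truth_post` trains.
#' @export
detect_study <- function(study, cfg = detector_config()) {
  stopifnot(inherits(study, "study_data"))
  lapply(study$fish, function(r) {
    out <- list(fish_id = r$fish_id, group = r$group)
    for (ph in c("pre", "post")) {
      tr <- r[[ph]]
      if (is.null(tr)) next
      if (!inherits(tr, "biosensor_trace")) {
        stop_tf("tailflip_input_error", "detect_study needs trace-level data")
      }
      det <- detect_flips(tr, cfg)
      out[[ph]] <- counts_per_minute(det)
      out[[paste0("truth_", ph)]] <- tr$truth
    }
    out
  })
}
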