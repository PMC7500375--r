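#' Zero-phase second-order Butterworth low-pass filter
#'
#' Designs a digital second-order Butterworth low-pass filter (bilinear
#' transform with frequency prewarping) and applies it forwards and backwards
#' (zero phase, so event timings are not lagged; the effective attenuation
#' order doubles).  Edge transients are controlled with odd reflection
#' padding and steady-state initial conditions, so a constant series passes
#' through unchanged (unit DC gain).
#'
#' @param series numeric force samples.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 15).
#' @return filtered series, same length.
#' @export
lowpass_filter <- function(series, fs, cutoff = 15) {
  stopifnot(fs > 2 * cutoff)
  n <- length(series)
  padlen <- 9L   # 3 x (number of coefficients)
  if (n <= padlen) stop("series too short to filter (need > ", padlen,
                        " samples)")
  co <- butter2_coef(cutoff, fs)
  # odd reflection padding at both ends
  pre <- 2 * series[1] - series[seq(padlen + 1L, 2L)]
  post <- 2 * series[n] - series[seq(n - 1L, n - padlen)]
  x <- c(pre, series, post)
  y <- lfilter2(co, x, x[1])
  y <- rev(lfilter2(co, rev(y), y[length(y)]))
  y[seq(padlen + 1L, padlen + n)]
}

# biquad coefficients for a 2nd-order Butterworth low-pass (DC gain 1)
butter2_coef <- function(cutoff, fs) {
  K <- tan(pi * cutoff / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  list(b = c(K^2, 2 * K^2, K^2) * norm,
       a = c(2 * (K^2 - 1), (1 - sqrt(2) * K + K^2)) * norm)
}

# single-pass biquad, assuming the signal sat at x0 before the first sample
# (unit DC gain, so a constant series is a fixed point); vectorised via the
# FIR + recursive decomposition in stats::filter
lfilter2 <- function(co, x, x0) {
  n <- length(x)
  z <- stats::filter(c(x0, x0, x), co$b, sides = 1)[seq(3L, n + 2L)]
  as.numeric(stats::filter(z, -co$a, method = "recursive", init = c(x0, x0)))
}

#' Compose grip and load force from a two-sensor trace
#'
#' Grip force is the mean of the absolute horizontal (grip-normal) channels
#' of the two sensors; load force is the sum of the vertical channels.
#'
#' @param trace an `ll_force_trace` (or any list with `samples` containing
#'   `fyA`, `fyB` for horizontal and `fzA`, `fzB` for vertical forces).
#' @return list with numeric vectors `gf` and `lf` and the time vector `t`.
#' @export
compose_gf_lf <- function(trace) {
  s <- trace$samples
  need <- c("fyA", "fyB", "fzA", "fzB")
  stopifnot(all(need %in% names(s)))
  lens <- vapply(s[need], length, integer(1))
  if (length(unique(lens)) != 1L) stop("channel-length mismatch")
  list(gf = (abs(s$fyA) + abs(s$fyB)) / 2,
       lf = s$fzA + s$fzB,
       t = s$t)
}

# first index where x >= threshold and stays there for >= debounce samples
# (runs truncated by the end of the series count as sustained)
sustained_crossing <- function(x, threshold, debounce) {
  above <- x >= threshold
  if (!any(above)) return(NA_integer_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths >= debounce | ends == length(x))
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1L]]
}

#' Detect lift events from grip and load force series
#'
#' Onsets are the first samples at which the (filtered) force reaches 0.1 N
#' and stays there for at least the debounce window; the contact trigger is
#' the first sustained grip-force crossing of 0.4 N (the threshold used to
#' trigger dynamic-phase stimulation, chosen above the onset threshold to
#' avoid responses to small initial bumps); liftoff is the first sustained
#' sample at which load force reaches the object weight.
#'
#' @param gf,lf filtered force series (same length), N.
#' @param fs sampling rate, Hz.
#' @param object_weight total object weight, N.
#' @param onset_threshold,trigger_threshold thresholds in N (0.1 and 0.4).
#' @param debounce sustain requirement in seconds (0.010).
#' @return list of class `ll_lift_events`: `t_gf_onset`, `t_lf_onset`,
#'   `t_contact_trigger`, `t_liftoff` (seconds from the start of the series;
#'   `NA` when never crossed) and `lifted`.
#' @export
detect_events <- function(gf, lf, fs, object_weight,
                          onset_threshold = 0.1, trigger_threshold = 0.4,
                          debounce = 0.010) {
  stopifnot(length(gf) == length(lf), object_weight > 0)
  db <- max(1L, as.integer(round(debounce * fs)))
  idx_t <- function(i) if (is.na(i)) NA_real_ else (i - 1L) / fs
  i_gf <- sustained_crossing(gf, onset_threshold, db)
  i_lf <- sustained_crossing(lf, onset_threshold, db)
  i_tr <- sustained_crossing(gf, trigger_threshold, db)
  i_lo <- sustained_crossing(lf, object_weight, db)
  structure(list(
    t_gf_onset = idx_t(i_gf),
    t_lf_onset = idx_t(i_lf),
    t_contact_trigger = idx_t(i_tr),
    t_liftoff = idx_t(i_lo),
    lifted = !is.na(i_lo)
  ), class = "ll_lift_events")
}

#' Force rates by central differences
#'
#' First time derivative of the (filtered) force series: central differences
#' scaled by the sampling rate on interior samples, one-sided differences at
#' the endpoints.
#'
#' @param gf,lf force series, N.
#' @param fs sampling rate, Hz.
#' @return list with `gfr` and `lfr` in N/s.
#' @export
compute_rates <- function(gf, lf, fs) {
  list(gfr = deriv_central(gf, fs), lfr = deriv_central(lf, fs))
}

deriv_central <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# indices of local maxima: strictly greater than both neighbours; a plateau
# (flat top) takes its first sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Extract per-trial force parameters
#'
#' Within the analysis window from grip-force onset to 50 ms after liftoff:
#' the peak force rates (global maxima; earliest sample on ties), the first
#' peaks (earliest local maximum at least 30% of the global peak, guarding
#' against small noise peaks; falls back to the global peak when the rate has
#' no interior local maximum), and times to peak (global peak time minus
#' grip-force onset).  Static grip force is the mean grip force 600--800 ms
#' after liftoff, i.e. a stimulation-length window starting 100 ms after a
#' static-phase TMS burst would begin.
#'
#' @param gf,lf filtered force series, N.
#' @param gfr,lfr force-rate series, N/s (see [compute_rates()]).
#' @param events an [detect_events()] result with `lifted = TRUE`.
#' @param fs sampling rate, Hz.
#' @param peak_window time after liftoff closing the rate window, s (0.050).
#' @param static_window start/end of the static grip window after liftoff,
#'   s (`c(0.600, 0.800)`).
#' @param first_peak_frac minimum height of the first peak relative to the
#'   global peak (0.3).
#' @return list of class `ll_lift_metrics`: `peak_LFR`, `peak_GFR`,
#'   `peak1_LFR`, `peak1_GFR`, `tp_LFR`, `tp_GFR`, `gf_static`.
#' @export
extract_metrics <- function(gf, lf, gfr, lfr, events, fs,
                            peak_window = 0.050,
                            static_window = c(0.600, 0.800),
                            first_peak_frac = 0.3) {
  stopifnot(isTRUE(events$lifted))
  n <- length(lf)
  t_end_need <- events$t_liftoff + static_window[2]
  if ((n - 1) / fs < t_end_need) {
    stop("trace ends before liftoff + ", static_window[2], " s")
  }
  i0 <- as.integer(round(events$t_gf_onset * fs)) + 1L
  i1 <- min(n, as.integer(round((events$t_liftoff + peak_window) * fs)) + 1L)
  stopifnot(i1 > i0)

  peaks_of <- function(rate) {
    w <- rate[i0:i1]
    gmax_rel <- which.max(w)                       # earliest tie wins
    peak <- w[gmax_rel]
    lm <- local_maxima(w)
    cand <- lm[w[lm] >= first_peak_frac * peak]
    first <- if (length(cand)) w[cand[1L]] else peak
    list(peak = peak, first = first,
         tp = (i0 + gmax_rel - 2L) / fs - events$t_gf_onset)
  }
  pl <- peaks_of(lfr)
  pg <- peaks_of(gfr)

  j0 <- as.integer(round((events$t_liftoff + static_window[1]) * fs)) + 1L
  j1 <- as.integer(round((events$t_liftoff + static_window[2]) * fs))
  gf_static <- mean(gf[j0:j1])                     # half-open [start, end)

  structure(list(
    peak_LFR = pl$peak, peak_GFR = pg$peak,
    peak1_LFR = pl$first, peak1_GFR = pg$first,
    tp_LFR = pl$tp, tp_GFR = pg$tp,
    gf_static = gf_static
  ), class = "ll_lift_metrics")
}

#' Scheduled TMS pulse times for a trial
#'
#' A burst of three pulses at 10 Hz (100 ms apart, 200 ms span).  In the
#' dynamic condition the first pulse is at the 0.4 N contact trigger; in the
#' static condition 500 ms after liftoff; no stimulation yields an empty
#' schedule.
#'
#' @param events an [detect_events()] result.
#' @param condition `"dynamic"`, `"static"` or `"none"`.
#' @return numeric vector of pulse times, s.
#' @export
schedule_tms <- function(events, condition) {
  burst <- c(0, 0.1, 0.2)
  switch(condition,
    dynamic = {
      if (is.na(events$t_contact_trigger))
        stop("dynamic TMS requires a contact trigger")
      events$t_contact_trigger + burst
    },
    static = {
      if (is.na(events$t_liftoff))
        stop("static TMS requires a liftoff")
      events$t_liftoff + 0.5 + burst
    },
    none = numeric(0),
    stop("unknown TMS condition: ", condition)
  )
}

#' Apply trial exclusion rules
#'
#' The perceptual analysis set drops trials where TMS failed or the object
#' was not lifted; the force analysis set additionally drops trials with
#' multiple lifts, drops, or failed force recording.  Non-analyzable trials
#' (undefined order pair) are removed from both sets.
#'
#' @param trials data frame with logical columns `analyzable`, `tms_failed`,
#'   `not_lifted`, `multiple_lifts`, `dropped`, `data_failure` (missing flag
#'   columns are treated as all-`FALSE`).
#' @return list with logical vectors `perceptual` and `force` marking rows
#'   retained in each set (`force` is always a subset of `perceptual`).
#' @export
apply_exclusions <- function(trials) {
  flag <- function(nm) {
    if (nm %in% names(trials)) as.logical(trials[[nm]])
    else rep(FALSE, nrow(trials))
  }
  base_ok <- as.logical(trials$analyzable) & !flag("tms_failed") &
    !flag("not_lifted")
  force_ok <- base_ok & !flag("multiple_lifts") & !flag("dropped") &
    !flag("data_failure")
  list(perceptual = base_ok, force = force_ok)
}

#' Run the full metric extraction on one simulated trial
#'
#' Convenience wrapper: composes GF/LF, filters both at 15 Hz, detects
#' events, differentiates, and extracts the force parameters.
#'
#' @param trace an `ll_force_trace`.
#' @param object_weight object weight in N (defaults to the weight of the
#'   object recorded in the trace metadata under default physical constants).
#' @param cutoff filter cutoff, Hz.
#' @return list with `events` and `metrics` (`metrics` is `NULL` when the
#'   object was never lifted).
#' @export
analyze_trace <- function(trace, object_weight = NULL, cutoff = 15) {
  if (is.null(object_weight)) {
    object_weight <- object_weight(trace$meta$object)
  }
  comp <- compose_gf_lf(trace)
  gf <- lowpass_filter(comp$gf, trace$fs, cutoff)
  lf <- lowpass_filter(comp$lf, trace$fs, cutoff)
  ev <- detect_events(gf, lf, trace$fs, object_weight)
  if (!ev$lifted) return(list(events = ev, metrics = NULL))
  rates <- compute_rates(gf, lf, trace$fs)
  m <- extract_metrics(gf, lf, rates$gfr, rates$lfr, ev, trace$fs)
  list(events = ev, metrics = m)
}
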