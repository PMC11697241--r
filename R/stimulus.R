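# Frozen pink-noise stimulation protocol.
#
# The protocol mirrors the current-clamp noise stimulation used for in-vitro
# cell-type characterization: a 1 s pink-noise template (sum of sines, 1-100 Hz,
# amplitudes proportional to 1/sqrt(f), random phases) is mean-removed, scaled
# to a coefficient of variation of 0.2 relative to a unit DC offset, replicated
# three times into a 3 s stimulus template, and delivered at 75, 100 and 150 %
# of the cell's rheobase with 5 s recovery windows in between. The same seed
# always reproduces the same waveform ("frozen noise").

#' Generate a frozen pink-noise template
#'
#' Builds a 1/f-power noise trace by summing sine waves at random phases,
#' each with amplitude proportional to the reciprocal square root of its
#' frequency, so spectral power falls as 1/f (equal energy per octave). The
#' mean is removed and the trace is rescaled so that, once the unit DC offset
#' is added by [stimulus_protocol()], the coefficient of variation
#' (sd / mean) equals `cv` exactly.
#'
#' @param seed integer; the frozen-noise seed. Identical seeds give
#'   bit-identical templates.
#' @param duration_s template duration in seconds (default 1).
#' @param f_min_hz,f_max_hz,f_step_hz frequency band of the sine components
#'   in Hz (defaults 1 to 100 in steps of 1).
#' @param cv target coefficient of variation of the stimulus relative to the
#'   unit DC level (default 0.2).
#' @param sampling_rate_hz sampling rate in Hz (default 25000). Must satisfy
#'   `sampling_rate_hz >= 2 * f_max_hz`.
#' @return an object of class `noise_template`: a list with `samples`
#'   (zero-mean, sd = `cv`, dimensionless rheobase-relative current),
#'   `time_s`, and the generating parameters.
#' @examples
#' tpl <- noise_template(seed = 1, sampling_rate_hz = 2000)
#' sd(tpl$samples) / (mean(tpl$samples) + 1) # = cv
#' @export
noise_template <- function(seed, duration_s = 1, f_min_hz = 1, f_max_hz = 100,
                           f_step_hz = 1, cv = 0.2, sampling_rate_hz = 25000) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(cv, "cv", positive = TRUE)
  check_scalar(f_min_hz, "f_min_hz", positive = TRUE)
  check_scalar(f_max_hz, "f_max_hz", positive = TRUE)
  check_scalar(f_step_hz, "f_step_hz", positive = TRUE)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  if (f_min_hz < 1) stop("`f_min_hz` must be >= 1", call. = FALSE)
  if (f_max_hz > sampling_rate_hz / 2) {
    stop("`f_max_hz` exceeds the Nyquist frequency", call. = FALSE)
  }
  if (f_max_hz < f_min_hz) stop("`f_max_hz` must be >= `f_min_hz`", call. = FALSE)

  n <- round(duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  freqs <- seq(f_min_hz, f_max_hz, by = f_step_hz)
  phases <- with_seed(seed, stats::runif(length(freqs), 0, 2 * pi))
  amps <- 1 / sqrt(freqs)

  # rows: frequencies, columns: time; column-major recycling adds phases[i]
  # to row i.
  x <- drop(amps %*% sin(outer(2 * pi * freqs, t) + phases))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate template: zero variance", call. = FALSE)
  x <- x * (cv / s)

  structure(
    list(samples = x, time_s = t, seed = as.integer(seed),
         duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         cv = cv, f_min_hz = f_min_hz, f_max_hz = f_max_hz,
         f_step_hz = f_step_hz),
    class = "noise_template"
  )
}

#' @export
print.noise_template <- function(x, ...) {
  cat(sprintf(
    "<noise_template> seed %d: %.3g s at %g Hz, band %g-%g Hz, CV %.3g\n",
    x$seed, x$duration_s, x$sampling_rate_hz, x$f_min_hz, x$f_max_hz, x$cv))
  invisible(x)
}

#' Assemble the full stimulation protocol for one neuron
#'
#' Replicates the 1 s noise template three times, adds the unit DC offset
#' (the 3 s "stimulus template"), scales copies of it to each requested
#' fraction of the neuron's rheobase, sorts them in increasing intensity and
#' concatenates them separated by zero-current recovery windows.
#'
#' @param template a [noise_template()].
#' @param rheobase_pa neuron rheobase in pA (> 0); the whole trace scales
#'   with it so mean segment current equals `intensity * rheobase_pa`.
#' @param intensities fractions of rheobase, default `c(0.75, 1, 1.5)`.
#' @param recovery_s recovery window between segments in seconds (default 5).
#' @param lead_s,trail_s optional zero-current padding before the first and
#'   after the last segment (default 0).
#' @param noise_id label for the template ("Noise1" or "Noise2").
#' @return an object of class `stimulus_protocol`: `trace` (pA), `time_s`,
#'   `segment_table` (data.frame with `label` = intensity in percent,
#'   `start_s`, `end_s`, `scale_pa`), plus metadata.
#' @examples
#' tpl <- noise_template(seed = 1, sampling_rate_hz = 2000)
#' prot <- stimulus_protocol(tpl, rheobase_pa = 100)
#' prot$segment_table
#' @export
stimulus_protocol <- function(template, rheobase_pa,
                              intensities = c(0.75, 1, 1.5),
                              recovery_s = 5, lead_s = 0, trail_s = 0,
                              noise_id = "Noise1") {
  stopifnot(inherits(template, "noise_template"))
  check_scalar(rheobase_pa, "rheobase_pa", positive = TRUE)
  check_scalar(recovery_s, "recovery_s", nonneg = TRUE)
  check_scalar(lead_s, "lead_s", nonneg = TRUE)
  check_scalar(trail_s, "trail_s", nonneg = TRUE)
  if (length(intensities) == 0L || any(!is.finite(intensities)) ||
      any(intensities <= 0)) {
    stop("`intensities` must be a non-empty vector of positive fractions",
         call. = FALSE)
  }
  intensities <- sort(intensities)

  fs <- template$sampling_rate_hz
  stim <- rep(template$samples, 3L) + 1  # 3 s stimulus template, mean 1
  seg_len <- length(stim)
  rec <- numeric(round(recovery_s * fs))

  pieces <- list(numeric(round(lead_s * fs)))
  starts <- numeric(length(intensities))
  cursor <- lead_s
  for (i in seq_along(intensities)) {
    starts[i] <- cursor
    pieces[[length(pieces) + 1L]] <- stim * (intensities[i] * rheobase_pa)
    cursor <- cursor + seg_len / fs
    if (i < length(intensities)) {
      pieces[[length(pieces) + 1L]] <- rec
      cursor <- cursor + recovery_s
    }
  }
  pieces[[length(pieces) + 1L]] <- numeric(round(trail_s * fs))
  trace <- unlist(pieces, use.names = FALSE)

  segment_table <- data.frame(
    label = round(intensities * 100),
    start_s = starts,
    end_s = starts + seg_len / fs,
    scale_pa = intensities * rheobase_pa
  )

  structure(
    list(trace = trace,
         time_s = (seq_along(trace) - 1) / fs,
         segment_table = segment_table,
         rheobase_pa = rheobase_pa,
         recovery_s = recovery_s,
         sampling_rate_hz = fs,
         noise_id = noise_id,
         seed = template$seed,
         cv = template$cv,
         template_duration_s = template$duration_s),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s (seed %d), rheobase %g pA, %g Hz\n",
              x$noise_id, x$seed, x$rheobase_pa, x$sampling_rate_hz))
  print(x$segment_table, row.names = FALSE)
  invisible(x)
}

#' Total stimulus-segment duration of a protocol (seconds)
#' @param protocol a [stimulus_protocol()].
#' @return numeric scalar.
#' @keywords internal
#' @noRd
stimulus_duration <- function(protocol) {
  sum(protocol$segment_table$end_s - protocol$segment_table$start_s)
}

#' Normalized autocorrelation of a current trace
#'
#' FFT-based autocorrelation of the mean-removed trace, normalized so the
#' zero-lag value is exactly 1. The 3x-concatenated stimulus template has a
#' local maximum at a lag of one template duration (1 s).
#'
#' @param trace numeric vector.
#' @param max_lag_s maximum lag in seconds; must be shorter than the trace.
#' @param sampling_rate_hz sampling rate of `trace` in Hz.
#' @return data.frame with columns `lag_s` and `acf`.
#' @export
trace_autocorrelation <- function(trace, max_lag_s, sampling_rate_hz) {
  if (length(trace) == 0L) stop("`trace` must be non-empty", call. = FALSE)
  check_scalar(max_lag_s, "max_lag_s", positive = TRUE)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  n <- length(trace)
  lag_max <- round(max_lag_s * sampling_rate_hz)
  if (lag_max >= n) {
    stop("`max_lag_s` exceeds the trace duration", call. = FALSE)
  }
  x <- trace - mean(trace)
  if (all(x == 0)) {
    stop("autocorrelation undefined for a constant trace (zero variance)",
         call. = FALSE)
  }
  nfft <- 2^ceiling(log2(2 * n))
  sp <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[seq_len(lag_max + 1L)]
  data.frame(lag_s = (0:lag_max) / sampling_rate_hz, acf = ac / ac[1L])
}

#' Log-log spectral slope of a noise template
#'
#' Regresses log periodogram power on log frequency over the template's
#' frequency band; 1/f power gives a slope of -1.
#'
#' @param template a [noise_template()].
#' @return numeric scalar, the fitted slope.
#' @export
spectral_slope <- function(template) {
  stopifnot(inherits(template, "noise_template"))
  x <- template$samples
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * template$sampling_rate_hz / n
  keep <- f >= template$f_min_hz & f <= template$f_max_hz & p > 0
  unname(stats::coef(stats::lm(log(p[keep]) ~ log(f[keep])))[2L])
}
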