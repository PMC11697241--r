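# Electrophysiological and transcriptomic cell typing.
#
# Cells are classed as fast or regular spiking from the half-amplitude width
# of their averaged action potential (fast iff width < 400 us), and
# transgenic line labels are grouped into PV / non-PV inhibitory / mixed /
# excitatory via a user-editable mapping table.

#' Construct a spike waveform
#'
#' @param samples numeric voltage samples (mV).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param aligned logical; TRUE when waveforms are peak-aligned (required
#'   for averaging).
#' @return object of class `spike_waveform`.
#' @export
spike_waveform <- function(samples, sampling_rate_hz, aligned = TRUE) {
  stopifnot(is.numeric(samples), length(samples) > 2L)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 aligned = isTRUE(aligned)),
            class = "spike_waveform")
}

#' Average peak-aligned spike waveforms
#'
#' Element-wise mean of all spikes a neuron fired during noise stimulation;
#' the resulting "average spike" is the basis of the width measurement.
#'
#' @param waveforms list of [spike_waveform()]s, equal length, peak-aligned.
#' @return a [spike_waveform()].
#' @export
average_spike <- function(waveforms) {
  stopifnot(is.list(waveforms), length(waveforms) >= 1L,
            all(vapply(waveforms, inherits, logical(1), "spike_waveform")))
  if (!all(vapply(waveforms, function(w) w$aligned, logical(1)))) {
    stop("all waveforms must be peak-aligned before averaging",
         call. = FALSE)
  }
  lens <- vapply(waveforms, function(w) length(w$samples), 1L)
  if (length(unique(lens)) != 1L) {
    stop("waveforms must have equal lengths", call. = FALSE)
  }
  fs <- unique(vapply(waveforms, function(w) w$sampling_rate_hz, 1))
  if (length(fs) != 1L) {
    stop("waveforms must share one sampling rate", call. = FALSE)
  }
  m <- rowMeans(do.call(cbind, lapply(waveforms, `[[`, "samples")))
  spike_waveform(m, fs, aligned = TRUE)
}

#' Spike width at half amplitude (microseconds)
#'
#' Duration of the averaged spike at half of the spike amplitude: the time
#' between the first upward and the last downward crossing of
#' `baseline + (peak - baseline) / 2`, with linear interpolation between
#' samples.
#'
#' @param waveform a [spike_waveform()].
#' @param baseline baseline voltage (mV); e.g. the pre-spike median. Must be
#'   below the peak.
#' @return width in microseconds.
#' @export
spike_half_width <- function(waveform, baseline) {
  stopifnot(inherits(waveform, "spike_waveform"))
  check_scalar(baseline, "baseline")
  v <- waveform$samples
  fs <- waveform$sampling_rate_hz
  peak <- max(v)
  if (peak <= baseline) {
    stop("waveform peak must exceed the baseline", call. = FALSE)
  }
  half <- baseline + (peak - baseline) / 2
  above <- v >= half
  if (!any(above) || all(above)) {
    stop("malformed waveform: no half-amplitude crossing found",
         call. = FALSE)
  }
  i_up <- which(above)[1L]
  i_dn <- which(above)[sum(above)]
  # linear interpolation to the crossing on each flank
  t_up <- if (i_up == 1L) i_up - 1 else {
    (i_up - 2) + (half - v[i_up - 1L]) / (v[i_up] - v[i_up - 1L])
  }
  t_dn <- if (i_dn == length(v)) i_dn - 1 else {
    (i_dn - 1) + (v[i_dn] - half) / (v[i_dn] - v[i_dn + 1L])
  }
  (t_dn - t_up) / fs * 1e6
}

#' Classify a neuron as fast or regular spiking
#'
#' Fast spiking iff the average-spike half-amplitude width is strictly below
#' the threshold (default 400 us); a width exactly at the threshold is
#' regular.
#'
#' @param width_us spike width in microseconds (> 0); vectorized.
#' @param threshold_us classification threshold (default 400).
#' @return character vector, `"fast"` or `"regular"`.
#' @export
classify_ephys <- function(width_us, threshold_us = 400) {
  if (any(!is.finite(width_us)) || any(width_us <= 0)) {
    stop("`width_us` must be positive and finite", call. = FALSE)
  }
  check_scalar(threshold_us, "threshold_us", positive = TRUE)
  ifelse(width_us < threshold_us, "fast", "regular")
}

#' Default transgenic-line grouping table
#'
#' Reads the mapping shipped with the package (a plain CSV under
#' `extdata/`, editable or replaceable by the user). Entries are gene
#' prefixes of transgenic driver lines; [group_transcriptomic()] matches a
#' full line label by its gene prefix.
#'
#' @return data.frame with columns `line_label`, `group`.
#' @export
default_line_groups <- function() {
  path <- system.file("extdata", "transcriptomic_groups.csv",
                      package = "spikerel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Group a transgenic line label into a transcriptomic class
#'
#' Matches the label exactly against the mapping table, or failing that by
#' its gene prefix (the part before the first `-`). Unknown labels raise an
#' error naming the label rather than defaulting silently.
#'
#' @param line_label character vector of line labels (e.g.
#'   `"Pvalb-IRES-Cre"`).
#' @param mapping data.frame with columns `line_label`, `group`; default
#'   [default_line_groups()].
#' @return character vector of groups: `"PV"`, `"non-PV inhibitory"`,
#'   `"mixed"`, or `"excitatory"`.
#' @export
group_transcriptomic <- function(line_label, mapping = default_line_groups()) {
  stopifnot(is.data.frame(mapping),
            all(c("line_label", "group") %in% names(mapping)))
  vapply(as.character(line_label), function(lab) {
    hit <- match(lab, mapping$line_label)
    if (is.na(hit)) {
      prefix <- sub("-.*$", "", lab)
      hit <- match(prefix, mapping$line_label)
    }
    if (is.na(hit)) {
      stop(sprintf("unmapped transgenic line label: '%s'", lab),
           call. = FALSE)
    }
    mapping$group[hit]
  }, character(1), USE.NAMES = FALSE)
}
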