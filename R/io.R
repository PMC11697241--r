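# Plain-text readers/writers: stimulation protocols (CSV + JSON sidecar)
# and synthetic populations (JSON index + per-neuron spike CSV, optional
# voltage CSV). Numeric values are written with 17 significant digits so
# round trips are bit-exact for doubles.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a stimulation protocol to disk
#'
#' Writes `<prefix>.csv` (`time_s`, `current_pa`, full double precision)
#' and `<prefix>.json` (segment table, seed, CV, rheobase, sampling rate).
#'
#' @param protocol a [stimulus_protocol()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_protocol <- function(protocol, prefix) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  con <- file(csv, "w")
  on.exit(close(con))
  writeLines("time_s,current_pa", con)
  writeLines(paste(fmt_num(protocol$time_s), fmt_num(protocol$trace),
                   sep = ","), con)
  meta <- list(segment_table = protocol$segment_table,
               rheobase_pa = protocol$rheobase_pa,
               recovery_s = protocol$recovery_s,
               sampling_rate_hz = protocol$sampling_rate_hz,
               noise_id = protocol$noise_id, seed = protocol$seed,
               cv = protocol$cv,
               template_duration_s = protocol$template_duration_s)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a stimulation protocol written by [write_protocol()]
#'
#' @param prefix path prefix used when writing.
#' @return a [stimulus_protocol()]; round-trips bit-exactly.
#' @export
read_protocol <- function(prefix) {
  tab <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  structure(
    list(trace = tab$current_pa, time_s = tab$time_s,
         segment_table = as.data.frame(meta$segment_table),
         rheobase_pa = meta$rheobase_pa, recovery_s = meta$recovery_s,
         sampling_rate_hz = meta$sampling_rate_hz,
         noise_id = meta$noise_id, seed = meta$seed, cv = meta$cv,
         template_duration_s = meta$template_duration_s),
    class = "stimulus_protocol")
}

#' Write a synthetic population to a directory
#'
#' Layout: `population.json` (per-neuron annotations, intrinsic features
#' and file pointers) plus one `<neuron_id>_spikes.csv` per neuron with
#' columns `sweep_id`, `noise_id`, `intensity`, `spike_time_s`. Voltage
#' traces, when present, go to `<neuron_id>_voltage_<noise>_<intensity>.csv`
#' with one column per sweep.
#'
#' @param population a `neuron_population`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_population <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  index <- lapply(population, function(nr) {
    spike_file <- paste0(nr$neuron_id, "_spikes.csv")
    con <- file(file.path(dir, spike_file), "w")
    writeLines("sweep_id,noise_id,intensity,spike_time_s", con)
    volt_files <- character(0)
    for (s in nr$sweep_sets) {
      for (k in seq_along(s$sweeps)) {
        tr <- s$sweeps[[k]]
        if (length(tr)) {
          writeLines(paste(k, s$noise_id, s$intensity_pct, fmt_num(tr),
                           sep = ","), con)
        } else {
          # keep empty sweeps visible so the reader restores sweep counts
          writeLines(paste(k, s$noise_id, s$intensity_pct, "NA",
                           sep = ","), con)
        }
      }
      if (!is.null(s$voltage)) {
        vf <- sprintf("%s_voltage_%s_%g.csv", nr$neuron_id, s$noise_id,
                      s$intensity_pct)
        vm <- do.call(cbind, s$voltage)
        colnames(vm) <- paste0("sweep_", seq_len(ncol(vm)))
        vcon <- file(file.path(dir, vf), "w")
        writeLines(paste(colnames(vm), collapse = ","), vcon)
        writeLines(apply(vm, 1L, function(r)
          paste(fmt_num(r), collapse = ",")), vcon)
        close(vcon)
        volt_files <- c(volt_files, vf)
      }
    }
    close(con)
    list(neuron_id = nr$neuron_id, species = nr$species,
         morpho_type = nr$morpho_type, ephys_type = nr$ephys_type,
         transcriptomic_group = nr$transcriptomic_group,
         class_name = nr$class_name, jitter_sd_ms = nr$jitter_sd_ms,
         intrinsic_features = nr$intrinsic_features,
         sweep_windows = lapply(nr$sweep_sets, function(s)
           list(noise_id = s$noise_id, intensity = s$intensity_pct,
                window = s$stimulus_window_s, n_sweeps = length(s$sweeps),
                sampling_rate_hz = s$sampling_rate_hz)),
         spike_file = spike_file, voltage_files = volt_files)
  })
  jsonlite::write_json(index, file.path(dir, "population.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir directory written by [write_population()].
#' @return a `neuron_population`; spike times round-trip bit-exactly.
#' @export
read_population <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "population.json"),
                               simplifyVector = FALSE)
  pop <- lapply(index, function(e) {
    tab <- utils::read.csv(file.path(dir, e$spike_file))
    sweep_sets <- lapply(e$sweep_windows, function(w) {
      sel <- tab$noise_id == w$noise_id & tab$intensity == w$intensity
      sub <- tab[sel, , drop = FALSE]
      sweeps <- lapply(seq_len(w$n_sweeps), function(k) {
        v <- sub$spike_time_s[sub$sweep_id == k]
        sort(v[!is.na(v)])
      })
      volt <- NULL
      vf <- sprintf("%s_voltage_%s_%g.csv", e$neuron_id, w$noise_id,
                    w$intensity)
      if (file.exists(file.path(dir, vf))) {
        vm <- utils::read.csv(file.path(dir, vf))
        volt <- lapply(seq_len(ncol(vm)), function(k) vm[[k]])
      }
      sweep_set(e$neuron_id, w$noise_id, w$intensity, sweeps,
                stimulus_window_s = unlist(w$window), voltage = volt,
                sampling_rate_hz = w$sampling_rate_hz)
    })
    structure(
      list(neuron_id = e$neuron_id, species = e$species,
           morpho_type = e$morpho_type, ephys_type = e$ephys_type,
           transcriptomic_group = e$transcriptomic_group,
           class_name = e$class_name, jitter_sd_ms = e$jitter_sd_ms,
           intrinsic_features = e$intrinsic_features,
           sweep_sets = sweep_sets),
      class = "neuron_record")
  })
  structure(pop, class = "neuron_population")
}

#' Write an izh_sweep table with its run manifest
#'
#' CSV of the sweep rows plus a JSON manifest recording polarity, measure
#' and all sweep parameters.
#'
#' @param sweep an `izh_sweep` from [sweep_sigma()] or [sweep_n_inputs()].
#' @param prefix output path prefix.
#' @param manifest named list of run parameters to record.
#' @return invisibly, the two file paths.
#' @export
write_sweep <- function(sweep, prefix, manifest = list()) {
  stopifnot(inherits(sweep, "izh_sweep"))
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  utils::write.csv(as.data.frame(sweep), csv, row.names = FALSE)
  jsonlite::write_json(
    c(list(measure = attr(sweep, "measure"),
           polarity = attr(sweep, "polarity")), manifest),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
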