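#' Write a time series as delimited text
#'
#' Canonical interchange format: a CSV with header `time,value`, time in
#' seconds and `.` as the decimal separator.
#'
#' @param ts A [time_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "eeg_ts"))
  df <- as.data.frame(ts)
  # 17 significant digits so the values survive the text round trip exactly
  out <- data.frame(time = sprintf("%.17g", df$time),
                    value = sprintf("%.17g", df$value))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series
#'
#' Reads the delimited-text interchange format (header `time,value...`,
#' sampling rate inferred from the time column) or a single channel of an
#' EDF recording selected by label.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @param channel Channel label for EDF input (e.g. `"Cz"`); ignored for
#'   CSV.
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, format = c("csv", "edf"),
                            channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- read.csv(path)
    if (nrow(df) < 2L || ncol(df) < 2L)
      stop("empty or malformed series file: ", path)
    if (!identical(names(df)[1], "time"))
      stop("malformed series file (first column must be `time`): ", path)
    dt <- diff(df$time)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt))
      stop("time column is not uniformly increasing: ", path)
    time_series(df[[2]], sampling_rate = 1 / mean(dt), t0 = df$time[1])
  } else {
    if (is.null(channel)) stop("`channel` is required for EDF input")
    read_edf_channel(path, channel)
  }
}

# Minimal EDF (European Data Format) reader: fixed 256-byte ASCII header,
# one 256-byte header block per signal, then data records of 2-byte
# little-endian integers, scaled from digital to physical units.
read_edf_channel <- function(path, channel) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("malformed EDF file: ", path)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(field(hdr, 237, 8))
  record_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF file: ", path)
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  sfield <- function(from, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, from + (i - 1) * len, from + i * len - 1)),
      character(1))
  }
  # layout within the signal header block: labels(16), transducer(80),
  # unit(8), phys min/max(8+8), dig min/max(8+8), prefilter(80),
  # samples per record(8)
  off <- 0
  labels <- sfield(off + 1, 16); off <- off + 16 * ns
  off <- off + 80 * ns + 8 * ns             # transducer, unit
  phys_min <- as.numeric(sfield(off + 1, 8)); off <- off + 8 * ns
  phys_max <- as.numeric(sfield(off + 1, 8)); off <- off + 8 * ns
  dig_min <- as.numeric(sfield(off + 1, 8)); off <- off + 8 * ns
  dig_max <- as.numeric(sfield(off + 1, 8)); off <- off + 8 * ns
  off <- off + 80 * ns                      # prefilter
  spr <- as.integer(sfield(off + 1, 8))
  k <- which(labels == channel)
  if (length(k) != 1L)
    stop("channel '", channel, "' not found; available: ",
         paste(labels, collapse = ", "))
  out <- numeric(n_records * spr[k])
  pos <- 1L
  for (rec in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2,
                      endian = "little", signed = TRUE)
      if (s == k) {
        out[pos:(pos + spr[s] - 1L)] <- vals
        pos <- pos + spr[s]
      }
    }
  }
  scale <- (phys_max[k] - phys_min[k]) / (dig_max[k] - dig_min[k])
  phys <- phys_min[k] + (out - dig_min[k]) * scale
  time_series(phys, sampling_rate = spr[k] / record_dur, t0 = 0)
}

#' Default run configuration
#'
#' The full nested configuration consumed by [run_full()] and the command
#' line, with every tunable of the generative cascade and the feature
#' pipeline at its documented default.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    oscillator = list(lambda = 1, p_hz = 10, forcing_gain = 1),
    nmm = as.list(unclass(nmm_params())),
    condition = list(
      stim_freq = 10, stim_amplitude = 0.5, stim_onset = -2,
      visual_weight = 1, pain_weight = 1, input_range = 0.5,
      vr_overrides = vr_default_overrides()
    ),
    protocol = list(n_sessions = 5, trials_per_session = 10,
                    pre_still = 5, movement = 4, rest = 4.5,
                    sampling_rate = 1000, epoch_window = c(-5, 2)),
    sim = list(dt = 1e-3, burn_in = 2),
    features = list(stft_window = 1, stft_hop = 0.05,
                    erd_threshold_db = -20),
    compare = list(folds = 10)
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration and merges it over [default_config()].
#' Unknown keys (at the top level or within a section) are rejected by
#' name.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      badk <- setdiff(names(user[[k]]), c(names(cfg[[k]]), "vr_overrides"))
      if (k == "condition") badk <- setdiff(badk, "vr_overrides")
      if (length(badk))
        stop("unknown config key(s) in `", k, "`: ",
             paste(badk, collapse = ", "))
      cfg[[k]] <- modifyList(cfg[[k]], user[[k]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

# internal: materialise spec objects from a config list
config_objects <- function(cfg, label) {
  cc <- cfg$condition
  cond <- condition_spec(
    label = label,
    stim_freq = cc$stim_freq,
    stim_amplitude = if (label == "vr") cc$stim_amplitude else 0,
    stim_onset = cc$stim_onset,
    connectivity_overrides = if (label == "vr") cc$vr_overrides else list(),
    visual_weight = cc$visual_weight, pain_weight = cc$pain_weight,
    input_range = cc$input_range)
  pp <- cfg$protocol
  proto <- protocol_spec(pp$n_sessions, pp$trials_per_session,
                         pp$pre_still, pp$movement, pp$rest,
                         pp$sampling_rate, unlist(pp$epoch_window))
  osc <- oscillator_params(lam = cfg$oscillator$lambda,
                           p = 2 * pi * cfg$oscillator$p_hz,
                           forcing_gain = cfg$oscillator$forcing_gain)
  nmm <- do.call(nmm_params, cfg$nmm)
  list(cond = cond, proto = proto, osc = osc, nmm = nmm)
}

#' Run the full simulate-extract-compare pipeline
#'
#' Simulates trial ensembles for both conditions, extracts the feature
#' table and per-trial detectability features for each, compares the
#' conditions, and writes everything (trial series, feature tables,
#' comparison report, resolved configuration and seed manifest) under
#' `out_dir`. Idempotent for a fixed `(config, seed)`.
#'
#' @param config Configuration list from [read_config()] /
#'   [default_config()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of the written file paths, invisibly.
#' @export
run_full <- function(config = default_config(), out_dir) {
  stopifnot(is.list(config), !missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  feats <- list(); det <- list()
  for (label in c("normal", "vr")) {
    obj <- config_objects(config, label)
    ens <- generate_dataset(obj$cond, obj$proto, seed = config$seed,
                            burn_in = config$sim$burn_in,
                            osc = obj$osc, nmm = obj$nmm)
    cond_dir <- file.path(out_dir, label)
    dir.create(cond_dir, showWarnings = FALSE)
    for (i in seq_along(ens$trials))
      write_timeseries(ens$trials[[i]],
                       file.path(cond_dir, sprintf("trial_%03d.csv", i)))
    ep <- epoch_signal(ens, window = obj$proto$epoch_window)
    feats[[label]] <- feature_table(
      ep, hop_sec = config$features$stft_hop,
      window_sec = config$features$stft_window)
    # rest window is taken from the interior of the baseline, away from the
    # epoch edge where zero-phase filter transients would inflate band power
    det[[label]] <- detectability_score(
      trial_band_features(ep, window = c(ep$baseline_window[1] + 1,
                                         ep$baseline_window[1] + 2)),
      trial_band_features(ep, window = c(0, 1)),
      folds = config$compare$folds, seed = config$seed)
    fpath <- file.path(out_dir, paste0("features_", label, ".csv"))
    write.csv(feats[[label]], fpath, row.names = FALSE)
    paths[[paste0("features_", label)]] <- fpath
  }

  report <- list(
    features = feats,
    detectability = det,
    vr_minus_normal = list(
      erd_peak = feats$vr$erd_peak - feats$normal$erd_peak,
      mrcp_peak = feats$vr$mrcp_peak - feats$normal$mrcp_peak,
      accuracy = det$vr$accuracy - det$normal$accuracy
    ),
    seed = config$seed
  )
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$config <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
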