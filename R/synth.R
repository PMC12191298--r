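# Synthetic 12-lead ECG records with ground-truth R peaks.
#
# Beats are sums of Gaussian bumps (P, Q, R, S, T) on a per-lead amplitude
# template; MI-like classes perturb the template (ST-segment shift, T-wave
# inversion, pathological Q) on configurable lead subsets. Noise = baseline
# wander sinusoid + powerline sinusoid + white broadband noise.

STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

# Per-lead projection of the lead-II reference morphology (dimensionless).
.lead_template <- c(I = 0.7, II = 1.0, III = 0.5, aVR = -0.8, aVL = 0.35,
                    aVF = 0.75, V1 = -0.5, V2 = 0.8, V3 = 1.05, V4 = 1.25,
                    V5 = 1.1, V6 = 0.9)

# Reference single-beat morphology on lead II: amplitude (mV), centre and
# width (ms, relative to the R peak) of each Gaussian component.
.wave_params <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  amp  = c(0.15, -0.10, 1.20, -0.25, 0.35),
  mu   = c(-170, -28, 0, 32, 280),
  sd   = c(25, 8, 12, 9, 60)
)

# Lead subsets carrying ST/T/Q changes for each MI-like class. "MI" is the
# generic label used by the two-class detection fixtures; region-named classes
# follow conventional infarct-to-lead mappings.
.mi_lead_map <- list(
  MI   = list(st = c("II", "III", "aVF"), t = c("V1", "V2", "V3"), q = c("II", "III", "aVF")),
  AMI  = list(st = c("V1", "V2", "V3", "V4"), t = c("V2", "V3", "V4"), q = c("V1", "V2", "V3")),
  IMI  = list(st = c("II", "III", "aVF"), t = c("II", "III", "aVF"), q = c("II", "III", "aVF")),
  ALMI = list(st = c("I", "aVL", "V5", "V6"), t = c("I", "aVL", "V6"), q = c("V5", "V6", "I")),
  ASMI = list(st = c("V1", "V2", "V3"), t = c("V1", "V2", "V3"), q = c("V1", "V2", "V3")),
  ILMI = list(st = c("II", "III", "aVF", "V5", "V6"), t = c("III", "aVF", "V6"), q = c("III", "aVF", "V6"))
)

#' Configuration for the synthetic ECG generator
#'
#' Bundles every knob of the generator: sampling rate, duration, heart rate
#' (with multiplicative RR jitter), lead count, class label, per-class
#' morphological perturbations and the three noise components.
#'
#' @param sampling_rate Sampling rate in Hz (default 1000, as in the PTB-style
#'   records the pipeline targets).
#' @param duration Record duration in seconds; must allow at least 3 beats.
#' @param heart_rate Mean heart rate in beats/min.
#' @param hr_jitter Fractional standard deviation of the RR interval
#'   (0 = perfectly periodic).
#' @param n_leads Number of leads (default 12; the first `n_leads` standard
#'   lead names are used).
#' @param class_label `"HC"` (healthy control) or one of the MI-like labels
#'   (`"MI"`, `"AMI"`, `"IMI"`, `"ALMI"`, `"ASMI"`, `"ILMI"`).
#' @param morph_params Optional override of the per-class perturbation list
#'   with elements `st_offset` (mV, ST-segment shift), `t_invert` (logical),
#'   `q_deepen` (mV added to the Q amplitude, negative = pathological Q),
#'   `st_leads`, `t_leads`, `q_leads` (lead-name subsets).
#' @param noise List with `baseline_amp` (mV), `baseline_freq` (Hz),
#'   `powerline_amp` (mV), `powerline_freq` (Hz), `broadband_sd` (mV).
#' @param seed Integer seed; identical configs (including seed) generate
#'   bit-identical records.
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(duration = 10, heart_rate = 60, seed = 1)
#' rec <- generate_record(cfg)
#' length(rec$r_peaks)
synth_config <- function(sampling_rate = 1000, duration = 10, heart_rate = 72,
                         hr_jitter = 0.03, n_leads = 12, class_label = "HC",
                         morph_params = NULL,
                         noise = list(baseline_amp = 0.10, baseline_freq = 0.30,
                                      powerline_amp = 0.03, powerline_freq = 50,
                                      broadband_sd = 0.02),
                         seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (!is.numeric(heart_rate) || heart_rate <= 0) stop("heart_rate must be positive")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) stop("sampling_rate must be positive")
  if (duration * heart_rate / 60 < 3) stop("duration too short for 3 beats at this heart rate")
  n_leads <- as.integer(n_leads)
  if (n_leads < 1 || n_leads > 12) stop("n_leads must be in 1..12")
  defaults <- list(baseline_amp = 0.10, baseline_freq = 0.30,
                   powerline_amp = 0.03, powerline_freq = 50,
                   broadband_sd = 0.02)
  noise <- utils::modifyList(defaults, as.list(noise))
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 heart_rate = heart_rate, hr_jitter = hr_jitter,
                 n_leads = n_leads, class_label = class_label,
                 morph_params = morph_params, noise = noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Default morphological perturbation for a class label.
.class_morph <- function(class_label, override = NULL) {
  if (identical(class_label, "HC")) {
    morph <- list(st_offset = 0, t_invert = FALSE, q_deepen = 0,
                  st_leads = character(), t_leads = character(), q_leads = character())
  } else {
    leads <- .mi_lead_map[[class_label]]
    if (is.null(leads)) leads <- .mi_lead_map[["MI"]]
    morph <- list(st_offset = 0.2, t_invert = TRUE, q_deepen = -0.15,
                  st_leads = leads$st, t_leads = leads$t, q_leads = leads$q)
  }
  if (!is.null(override)) morph <- utils::modifyList(morph, override)
  morph
}

# Clean single-beat waveform for one lead: sum of Gaussian bumps evaluated at
# offsets `t_ms` (ms relative to the R peak).
.beat_wave <- function(t_ms, lead, morph) {
  scale <- .lead_template[[lead]]
  wp <- .wave_params
  y <- numeric(length(t_ms))
  for (i in seq_len(nrow(wp))) {
    amp <- wp$amp[i] * scale
    if (wp$wave[i] == "T" && isTRUE(morph$t_invert) && lead %in% morph$t_leads)
      amp <- -amp
    if (wp$wave[i] == "Q" && lead %in% morph$q_leads)
      amp <- amp + morph$q_deepen
    y <- y + amp * exp(-0.5 * ((t_ms - wp$mu[i]) / wp$sd[i])^2)
  }
  # ST-segment shift: broad plateau bridging the J point and the T onset.
  if (morph$st_offset != 0 && lead %in% morph$st_leads)
    y <- y + morph$st_offset * exp(-0.5 * ((t_ms - 120) / 45)^2)
  y
}

#' Generate a synthetic multi-lead ECG record
#'
#' Produces an [ecg_record] at `config$sampling_rate` with ground-truth R-peak
#' sample indices stored in `$r_peaks`. Class-dependent morphology (ST shift,
#' T inversion, pathological Q) is applied on the class's lead subsets, and
#' the configured noise components are added on top of the clean signal.
#' Adding noise never changes the ground-truth peak metadata.
#'
#' @param config A [synth_config()].
#' @param patient_id,record_id Identifiers attached to the record.
#' @return An `ecg_record`.
#' @export
generate_record <- function(config, patient_id = "P000", record_id = "R000") {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  period <- 60 / config$heart_rate                     # seconds per beat
  r_times <- numeric(0)
  t_cur <- 0.45                                        # first R at ~0.45 s
  while (t_cur < config$duration) {
    r_times <- c(r_times, t_cur)
    gap <- period * (1 + config$hr_jitter * stats::rnorm(1))
    t_cur <- t_cur + max(gap, 0.3)                     # refractory floor
  }
  r_idx <- round(r_times * fs) + 1L
  r_idx <- r_idx[r_idx >= 1 & r_idx <= n]

  morph <- .class_morph(config$class_label, config$morph_params)
  leads <- STANDARD_LEADS[seq_len(config$n_leads)]
  sig <- matrix(0, nrow = config$n_leads, ncol = n, dimnames = list(leads, NULL))
  t_ms_all <- (seq_len(n) - 1) / fs * 1000
  for (r in r_idx) {
    lo <- max(1L, r - round(0.40 * fs)); hi <- min(n, r + round(0.55 * fs))
    span <- lo:hi
    t_rel <- t_ms_all[span] - t_ms_all[r]
    for (ld in seq_along(leads))
      sig[ld, span] <- sig[ld, span] + .beat_wave(t_rel, leads[ld], morph)
  }

  tt <- (seq_len(n) - 1) / fs
  nz <- utils::modifyList(list(baseline_amp = 0, baseline_freq = 0.3,
                               powerline_amp = 0, powerline_freq = 50,
                               broadband_sd = 0),
                          as.list(config$noise))
  for (ld in seq_len(config$n_leads)) {
    w <- numeric(n)
    if (nz$baseline_amp > 0)
      w <- w + nz$baseline_amp * sin(2 * pi * nz$baseline_freq * tt + stats::runif(1, 0, 2 * pi))
    if (nz$powerline_amp > 0)
      w <- w + nz$powerline_amp * sin(2 * pi * nz$powerline_freq * tt + stats::runif(1, 0, 2 * pi))
    if (nz$broadband_sd > 0)
      w <- w + stats::rnorm(n, sd = nz$broadband_sd)
    sig[ld, ] <- sig[ld, ] + w
  }

  ecg_record(signal = sig, sampling_rate = fs, lead_names = leads,
             patient_id = patient_id, record_id = record_id,
             label = config$class_label, r_peaks = r_idx)
}

#' Construct an ECG record object
#'
#' @param signal leads x samples numeric matrix in mV.
#' @param sampling_rate Hz.
#' @param lead_names Character vector, one name per row of `signal`.
#' @param patient_id,record_id Identifiers.
#' @param label Class label (or `NA`).
#' @param r_peaks Optional integer vector of ground-truth/detected R-peak
#'   sample indices.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, sampling_rate, lead_names = rownames(signal),
                       patient_id = NA_character_, record_id = NA_character_,
                       label = NA_character_, r_peaks = NULL) {
  signal <- as.matrix(signal)
  if (is.null(lead_names)) stop("lead_names required")
  stopifnot(length(lead_names) == nrow(signal), sampling_rate > 0)
  rownames(signal) <- lead_names
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 lead_names = lead_names, patient_id = patient_id,
                 record_id = record_id, label = label,
                 r_peaks = if (is.null(r_peaks)) NULL else as.integer(r_peaks)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s/%s: %d leads x %d samples @ %g Hz, label=%s%s>\n",
              x$patient_id, x$record_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate, x$label,
              if (!is.null(x$r_peaks)) sprintf(", %d R peaks", length(x$r_peaks)) else ""))
  invisible(x)
}

#' Generate a class-balanced labelled collection of synthetic records
#'
#' Every record gets a distinct synthetic patient id; patient ids are never
#' shared across classes, so the collection supports both intra- and
#' inter-patient splitting.
#'
#' @param n_records_per_class Records per class (>= 1).
#' @param class_list Character vector of class labels, e.g. `c("HC", "MI")`.
#' @param config_template A [synth_config()] whose fields (other than
#'   `class_label` and `seed`) are shared by all records.
#' @param seed Master seed; per-record seeds are derived from it.
#' @return List of `ecg_record` objects.
#' @export
generate_dataset <- function(n_records_per_class, class_list,
                             config_template = synth_config(), seed = 1L) {
  if (length(class_list) == 0) stop("class_list must be non-empty")
  n_records_per_class <- as.integer(n_records_per_class)
  if (n_records_per_class < 1) stop("n_records_per_class must be >= 1")
  records <- list()
  pid <- 0L
  for (ci in seq_along(class_list)) {
    for (ri in seq_len(n_records_per_class)) {
      pid <- pid + 1L
      cfg <- config_template
      cfg$class_label <- class_list[ci]
      cfg$seed <- as.integer((seed * 10007L + pid * 131L) %% .Machine$integer.max)
      records[[pid]] <- generate_record(cfg,
                                        patient_id = sprintf("P%04d", pid),
                                        record_id = sprintf("R%04d", pid))
    }
  }
  records
}

#' Write a label manifest for a record collection
#'
#' Plain-text tab-separated manifest with one row per record
#' (patient id, record id, class label).
#'
#' @param records List of `ecg_record`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  df <- data.frame(patient_id = vapply(records, `[[`, "", "patient_id"),
                   record_id = vapply(records, `[[`, "", "record_id"),
                   label = vapply(records, `[[`, "", "label"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
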