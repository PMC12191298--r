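# Shared fixtures: all synthetic, generated in code at test time.

quiet_noise <- list(baseline_amp = 0, baseline_freq = 0.3,
                    powerline_amp = 0, powerline_freq = 50, broadband_sd = 0)

clean_config <- function(duration = 10, heart_rate = 60, seed = 1, ...) {
  synth_config(duration = duration, heart_rate = heart_rate, hr_jitter = 0,
               noise = quiet_noise, seed = seed, ...)
}

# fraction of true peaks matched by a detection within tol samples
peak_match_rate <- function(detected, truth, tol = 50) {
  if (length(truth) == 0) return(NA_real_)
  if (length(detected) == 0) return(0)
  d <- outer(detected, truth, function(a, b) abs(a - b))
  mean(apply(d, 2, min) <= tol)
}

# single-lead record wrapper around a plain vector (lead II)
vec_record <- function(x, fs = 1000, label = "HC") {
  ecg_record(matrix(x, nrow = 1, dimnames = list("II", NULL)),
             sampling_rate = fs, lead_names = "II",
             patient_id = "P1", record_id = "R1", label = label)
}

# small labelled beat dataset with separable classes, via the full
# generator + preprocessing chain
small_beat_dataset <- function(n_per_class = 2, duration = 6, seed = 1) {
  recs <- generate_dataset(n_per_class, c("HC", "MI"),
                           synth_config(duration = duration, heart_rate = 72,
                                        noise = list(broadband_sd = 0.02,
                                                     baseline_amp = 0.05,
                                                     powerline_amp = 0.02)),
                           seed = seed)
  bind_beats(lapply(recs, preprocess_record))
}
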