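# Preprocessing: baseline removal, improved-threshold wavelet denoising,
# Pan-Tompkins R-peak detection, fixed-window beat segmentation, resampling.

#' Remove baseline wander by cascaded median filtering
#'
#' Estimates the baseline per lead with a two-stage running-median cascade
#' (a short window that preserves the P-QRS complex followed by a long window
#' spanning the T wave) and subtracts it, zero-centering the isoelectric line.
#'
#' @param record An `ecg_record`.
#' @param windows_ms Two median-filter window lengths in ms (default 200 and
#'   600).
#' @return The record with the baseline estimate removed from every lead.
#' @export
remove_baseline <- function(record, windows_ms = c(200, 600)) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate
  ks <- round(windows_ms * fs / 1000)
  ks <- ifelse(ks %% 2 == 0, ks + 1, ks)          # runmed needs odd windows
  if (ncol(record$signal) < max(ks))
    stop("record shorter than the largest median-filter window")
  out <- record
  for (i in seq_len(nrow(record$signal))) {
    base <- record$signal[i, ]
    for (k in ks) base <- stats::runmed(base, k, endrule = "median")
    out$signal[i, ] <- record$signal[i, ] - base
  }
  out
}

#' Wavelet denoising configuration
#'
#' @param wavelet Wavelet basis name (default `"db6"`, whose morphology
#'   resembles the QRS complex).
#' @param n_levels Decomposition depth `b = 1..n_levels` (default 5,
#'   maximum 9).
#' @return An object of class `wavelet_denoise_config`.
#' @export
wavelet_denoise_config <- function(wavelet = "db6", n_levels = 5) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 1 || n_levels > 9) stop("n_levels must be in 1..9")
  structure(list(wavelet = wavelet, n_levels = n_levels),
            class = "wavelet_denoise_config")
}

#' Improved-threshold shrinkage rule
#'
#' The level-wise shrinkage applied to detail coefficients: coefficients with
#' magnitude above the threshold are shrunk toward zero by the threshold with
#' their sign preserved; coefficients at or below it are zeroed.
#'
#' @param d Numeric vector of detail coefficients.
#' @param te Non-negative threshold.
#' @return Shrunk coefficients, same length as `d`.
#' @export
threshold_shrink <- function(d, te) {
  stopifnot(te >= 0)
  ifelse(abs(d) > te, sign(d) * (abs(d) - te), 0)
}

# Level threshold: TE_b = sigma_b * sqrt(2 log ||d_b|| / log(b + 1)),
# sigma_b = median(|d_b|) / 0.6745; radicand clamped at 0 so TE_b >= 0.
.level_threshold <- function(d, b) {
  sigma <- stats::median(abs(d)) / 0.6745
  nrm <- sqrt(sum(d^2))
  if (nrm <= 0) return(0)
  rad <- 2 * log(nrm) / log(b + 1)
  sigma * sqrt(max(rad, 0))
}

#' Denoise an ECG record by improved-threshold wavelet shrinkage
#'
#' Per lead: decompose to `n_levels` with the configured wavelet; for each
#' detail level `b` estimate the noise scale from the median absolute detail
#' coefficient divided by 0.6745 (the upper-quartile point of the standard
#' normal), set the level threshold
#' `TE_b = sigma_b * sqrt(2 log ||d_b|| / log(b+1))` where `||d_b||` is the
#' level's Euclidean coefficient norm, shrink the detail coefficients by
#' [threshold_shrink()], leave the approximation coefficients untouched, and
#' reconstruct.
#'
#' @param record An `ecg_record` (baseline already removed).
#' @param config A [wavelet_denoise_config()].
#' @return The denoised record.
#' @export
denoise_wavelet <- function(record, config = wavelet_denoise_config()) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "wavelet_denoise_config"))
  if (ncol(record$signal) < 2^config$n_levels)
    stop("record shorter than 2^n_levels samples")
  out <- record
  for (i in seq_len(nrow(record$signal))) {
    w <- dwt_periodic(record$signal[i, ], config$wavelet, config$n_levels)
    for (b in seq_len(config$n_levels)) {
      te <- .level_threshold(w$details[[b]], b)
      w$details[[b]] <- threshold_shrink(w$details[[b]], te)
    }
    out$signal[i, ] <- idwt_periodic(w)
  }
  out
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic chain: band-pass 5-15 Hz, five-point differentiation, squaring,
#' 150 ms moving-window integration, adaptive dual thresholds with search-back
#' and a 200 ms refractory period. Band-pass and integration are applied
#' zero-phase, and every detected index is refined to the local extremum of
#' the band-passed signal within +/- 50 ms.
#'
#' @param record An `ecg_record` (ideally denoised).
#' @param lead Lead name to run detection on (default `"II"`; indices are
#'   shared by all leads).
#' @return An object of class `r_peak_list` with sorted `$indices` and
#'   `$sampling_rate`.
#' @export
detect_r_peaks <- function(record, lead = "II") {
  stopifnot(inherits(record, "ecg_record"))
  if (!lead %in% record$lead_names) stop("lead not present: ", lead)
  fs <- record$sampling_rate
  x <- record$signal[lead, ]
  n <- length(x)
  if (n < 2 * fs) stop("record shorter than 2 s; cannot adapt thresholds")

  bp_filt <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bp_filt, x))
  # five-point derivative (1/8T)(-x[n-2] - 2x[n-1] + 2x[n+1] + x[n+2])
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  wlen <- max(3, round(0.150 * fs)); if (wlen %% 2 == 0) wlen <- wlen + 1
  mwi <- stats::filter(sq, rep(1 / wlen, wlen), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks: local maxima of the integrated signal, >= 200 ms apart
  refr <- round(0.2 * fs)
  is_peak <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE) & mwi > 0
  cand <- which(is_peak)
  if (length(cand) == 0)
    return(structure(list(indices = integer(0), sampling_rate = fs),
                     class = "r_peak_list"))
  keep <- logical(length(cand))
  last <- -Inf
  o <- order(-mwi[cand])                 # strongest-first non-max suppression
  taken <- integer(0)
  for (j in o) {
    if (all(abs(cand[j] - taken) >= refr)) { keep[j] <- TRUE; taken <- c(taken, cand[j]) }
  }
  cand <- sort(cand[keep])

  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- 0.5 * max(init); npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_avg <- fs * 60 / 75                 # prior RR until 2 beats seen
  last_qrs <- -Inf
  for (ci in seq_along(cand)) {
    i <- cand[ci]; v <- mwi[i]
    if (v > thr() && (i - last_qrs) >= refr) {
      peaks <- c(peaks, i); spki <- 0.125 * v + 0.875 * spki; last_qrs <- i
      if (length(peaks) >= 2) rr_avg <- mean(diff(utils::tail(peaks, 8)))
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: no QRS within 1.66 x average RR -> retake the largest
      # candidate in the gap at half threshold
      if (length(peaks) > 0 && (i - last_qrs) > 1.66 * rr_avg) {
        gap <- cand[cand > last_qrs + refr & cand <= i]
        if (length(gap) > 0) {
          g <- gap[which.max(mwi[gap])]
          if (mwi[g] > 0.5 * thr()) {
            peaks <- c(peaks, g); spki <- 0.25 * mwi[g] + 0.75 * spki; last_qrs <- g
          }
        }
      }
    }
  }
  peaks <- sort(unique(peaks))

  # refine to the local extremum of the band-passed signal within +/- 50 ms
  half <- round(0.05 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p - half)); hi <- min(n, as.integer(p + half))
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  refined <- refined[c(TRUE, diff(refined) >= refr)]
  structure(list(indices = as.integer(refined), sampling_rate = fs),
            class = "r_peak_list")
}

#' Segment fixed-length heartbeats around R peaks
#'
#' Extracts one beat per peak whose full window `[r - pre, r + post]` lies
#' inside the record; out-of-bounds beats are dropped, not padded. At a
#' 1000 Hz sampling rate the default windows give 250 + 1 + 400 = 651 samples
#' per beat across all leads.
#'
#' @param record An `ecg_record`.
#' @param peaks An `r_peak_list` or integer vector of R-peak sample indices.
#' @param pre,post Samples before/after the R peak (defaults 250 / 400).
#' @return A [beat_dataset] with one slice per retained beat; its
#'   `dropped` attribute counts the out-of-bounds beats.
#' @export
segment_beats <- function(record, peaks, pre = 250, post = 400) {
  stopifnot(inherits(record, "ecg_record"))
  idx <- if (inherits(peaks, "r_peak_list")) peaks$indices else as.integer(peaks)
  n <- ncol(record$signal); L <- pre + post + 1
  ok <- idx - pre >= 1 & idx + post <= n
  kept <- idx[ok]
  x <- array(0, dim = c(nrow(record$signal), L, length(kept)))
  for (j in seq_along(kept))
    x[, , j] <- record$signal[, (kept[j] - pre):(kept[j] + post)]
  ds <- beat_dataset(x,
                     label = rep(record$label, length(kept)),
                     patient_id = rep(record$patient_id, length(kept)),
                     record_id = rep(record$record_id, length(kept)),
                     r_index = kept,
                     lead_names = record$lead_names)
  attr(ds, "dropped") <- sum(!ok)
  ds
}

#' Beat dataset container
#'
#' Holds segmented heartbeats as a `leads x samples x beats` array together
#' with per-beat labels, patient ids, record ids and R-peak indices.
#'
#' @param x Numeric array `leads x samples x n`.
#' @param label,patient_id,record_id Character vectors of length `n`.
#' @param r_index Integer vector of R positions in the source records.
#' @param lead_names Lead names for the first dimension.
#' @return An object of class `beat_dataset`.
#' @export
beat_dataset <- function(x, label, patient_id, record_id = NULL,
                         r_index = NULL, lead_names = NULL) {
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[3]
  structure(list(x = x, label = as.character(label),
                 patient_id = as.character(patient_id),
                 record_id = if (is.null(record_id)) rep(NA_character_, n) else as.character(record_id),
                 r_index = if (is.null(r_index)) rep(NA_integer_, n) else as.integer(r_index),
                 lead_names = lead_names),
            class = "beat_dataset")
}

#' @export
length.beat_dataset <- function(x) dim(x$x)[3]

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset: %d beats of %d leads x %d samples; classes: %s>\n",
              length(x), dim(x$x)[1], dim(x$x)[2],
              paste(names(table(x$label)), table(x$label), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Combine beat datasets
#'
#' @param datasets List of `beat_dataset`s with identical lead/sample
#'   dimensions.
#' @return A single `beat_dataset`.
#' @export
bind_beats <- function(datasets) {
  datasets <- datasets[vapply(datasets, length, 0L) > 0]
  if (length(datasets) == 0) stop("no non-empty datasets to bind")
  d1 <- dim(datasets[[1]]$x)
  n <- sum(vapply(datasets, length, 0L))
  x <- array(0, dim = c(d1[1], d1[2], n))
  at <- 0
  for (ds in datasets) {
    k <- length(ds)
    x[, , at + seq_len(k)] <- ds$x
    at <- at + k
  }
  beat_dataset(x,
               label = unlist(lapply(datasets, `[[`, "label")),
               patient_id = unlist(lapply(datasets, `[[`, "patient_id")),
               record_id = unlist(lapply(datasets, `[[`, "record_id")),
               r_index = unlist(lapply(datasets, `[[`, "r_index")),
               lead_names = datasets[[1]]$lead_names)
}

#' Subset a beat dataset
#'
#' @param ds A `beat_dataset`.
#' @param i Integer or logical index over beats.
#' @return The subsetted `beat_dataset`.
#' @export
subset_beats <- function(ds, i) {
  beat_dataset(ds$x[, , i, drop = FALSE], ds$label[i], ds$patient_id[i],
               ds$record_id[i], ds$r_index[i], ds$lead_names)
}

#' Resample a record to a new rate
#'
#' Band-limited polyphase resampling of every lead; output length is
#' `round(n * target / source)` and the metadata is updated. Ground-truth
#' R-peak indices, when present, are rescaled to the new rate.
#'
#' @param record An `ecg_record`.
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return The resampled record.
#' @export
resample_record <- function(record, target_rate) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(target_rate) || target_rate <= 0) stop("target_rate must be positive")
  src <- record$sampling_rate
  if (target_rate == src) return(record)
  # rational factor p/q in lowest terms
  scale <- 1e6
  p <- round(target_rate * scale); q <- round(src * scale)
  g <- .gcd(p, q); p <- p / g; q <- q / g
  n_in <- ncol(record$signal)
  n_out <- round(n_in * target_rate / src)
  out <- matrix(0, nrow = nrow(record$signal), ncol = n_out)
  for (i in seq_len(nrow(record$signal))) {
    y <- signal::resample(record$signal[i, ], p, q)
    if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, rep(y[length(y)], n_out - length(y)))
    out[i, ] <- y
  }
  rec <- ecg_record(out, target_rate, record$lead_names, record$patient_id,
                    record$record_id, record$label,
                    r_peaks = if (!is.null(record$r_peaks))
                      pmax(1L, round((record$r_peaks - 1) * target_rate / src) + 1L))
  rec
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
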