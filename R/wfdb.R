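# Minimal WFDB (header + format-16 signal) reader/writer, sufficient for
# PTB-style records: one .hea text header plus one interleaved little-endian
# 16-bit .dat file shared by all channels.

#' Write an ECG record in WFDB format
#'
#' Writes `<record_id>.hea` (text header) and `<record_id>.dat` (interleaved
#' little-endian int16, format 16) under `dir`. Amplitudes are quantized with
#' the given ADC gain (units/mV).
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if needed).
#' @param gain ADC gain in units per mV (default 2000).
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 2000) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rid <- record$record_id
  if (is.na(rid) || !nzchar(rid)) rid <- "record"
  n_sig <- nrow(record$signal); n <- ncol(record$signal)
  hea <- file.path(dir, paste0(rid, ".hea"))
  dat <- paste0(rid, ".dat")
  lines <- sprintf("%s %d %g %d", rid, n_sig, record$sampling_rate, n)
  for (i in seq_len(n_sig))
    lines <- c(lines, sprintf("%s 16 %d/mV 16 0 0 0 0 %s", dat, gain, record$lead_names[i]))
  lines <- c(lines,
             sprintf("# patient_id: %s", record$patient_id),
             sprintf("# label: %s", record$label))
  writeLines(lines, hea)
  q <- round(record$signal * gain)
  q <- pmax(pmin(q, 32767), -32768)
  # interleave: sample-major, channel-minor (WFDB layout)
  writeBin(as.integer(as.vector(q)), file.path(dir, dat), size = 2, endian = "little")
  invisible(hea)
}

#' Read a WFDB record
#'
#' Parses the text header and the format-16 signal file, converts to mV using
#' each channel's ADC gain, reorders channels to the canonical 12-lead order
#' (I, II, III, aVR, aVL, aVF, V1-V6) and drops any extra channels (e.g. the
#' Frank leads vx/vy/vz). Lead II must be present.
#'
#' @param path Path to the `.hea` header (with or without the extension).
#' @return An `ecg_record` (no resampling is performed; `sampling_rate` is
#'   whatever the header declares).
#' @export
read_wfdb_record <- function(path) {
  if (!grepl("\\.hea$", path)) path <- paste0(path, ".hea")
  if (!file.exists(path)) stop("header not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  meta <- lines[startsWith(lines, "#")]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  top <- strsplit(lines[1], "[ \t]+")[[1]]
  if (length(top) < 4) stop("unreadable header: ", path)
  rid <- top[1]; n_sig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  if (is.na(n_sig) || is.na(fs) || is.na(n)) stop("unreadable header: ", path)
  sig_lines <- lines[1 + seq_len(n_sig)]
  fields <- lapply(sig_lines, function(l) strsplit(l, "[ \t]+")[[1]])
  dat_file <- fields[[1]][1]
  fmt <- fields[[1]][2]
  if (!identical(sub("x.*", "", fmt), "16")) stop("only format 16 supported, got ", fmt)
  gains <- vapply(fields, function(f) {
    g <- sub("\\(.*\\)", "", sub("/.*", "", f[3]))   # "2000(0)/mV" -> "2000"
    v <- suppressWarnings(as.numeric(g))
    if (is.na(v) || v == 0) 200 else v               # WFDB default gain
  }, numeric(1))
  lead_names <- vapply(fields, function(f) f[length(f)], character(1))

  raw <- readBin(file.path(dirname(path), dat_file), integer(), n = n_sig * n,
                 size = 2, endian = "little", signed = TRUE)
  if (length(raw) < n_sig * n) stop("signal file shorter than header declares")
  sig <- matrix(as.numeric(raw), nrow = n_sig)       # channels x samples
  sig <- sig / gains
  rownames(sig) <- lead_names

  canon <- STANDARD_LEADS
  norm <- tolower(lead_names)
  keep <- match(tolower(canon), norm)
  if (is.na(keep[2])) stop("lead II missing from record ", rid)
  present <- !is.na(keep)
  sig <- sig[keep[present], , drop = FALSE]
  rownames(sig) <- canon[present]

  pid <- sub("^# patient_id:\\s*", "", grep("^# patient_id:", meta, value = TRUE)[1])
  lab <- sub("^# label:\\s*", "", grep("^# label:", meta, value = TRUE)[1])
  ecg_record(signal = sig, sampling_rate = fs, lead_names = canon[present],
             patient_id = if (is.na(pid)) NA_character_ else pid,
             record_id = rid,
             label = if (is.na(lab)) NA_character_ else lab)
}
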