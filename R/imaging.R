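# Imaging: Gramian Angular Field of the lead-II beat spectrum and discrete
# Stockwell (S-) transform time-frequency images.

#' Min-max rescaling to [-1, 1]
#'
#' `x_i -> ((x_i - max) + (x_i - min)) / (max - min)`: the minimum maps to -1
#' and the maximum to +1.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Rescaled vector in `[-1, 1]`.
#' @export
rescale_minmax <- function(x) {
  mx <- max(x); mn <- min(x)
  if (mx == mn) stop("constant series cannot be rescaled to [-1, 1]")
  ((x - mx) + (x - mn)) / (mx - mn)
}

#' Piecewise aggregation approximation (PAA)
#'
#' Partitions the series into `target_length` contiguous near-equal frames
#' and returns the frame means. With `target_length` equal to the input
#' length this is the identity.
#'
#' @param x Numeric vector.
#' @param target_length Output length (1..length(x)).
#' @return Numeric vector of length `target_length`.
#' @export
paa_smooth <- function(x, target_length) {
  n <- length(x)
  m <- as.integer(target_length)
  if (m <= 0) stop("target_length must be positive")
  if (m > n) stop("target_length exceeds input length")
  frame <- floor((seq_len(n) - 1) * m / n) + 1L
  as.vector(tapply(x, frame, mean))
}

#' Gramian Angular Field (difference variant)
#'
#' Encodes a rescaled series via polar angles `phi_i = arccos(x_i)` and
#' returns the matrix `G[i, j] = sin(phi_i - phi_j)`, computed in closed
#' matrix form `sqrt(1 - x^2) x' - x sqrt(1 - x^2)'`. The result has a zero
#' diagonal, is antisymmetric and has all entries in `[-1, 1]`. The polar
#' radius `r_i = t_i / N` is attached as the `"radius"` attribute for
#' completeness; it does not enter `G`.
#'
#' @param x Numeric vector already rescaled to `[-1, 1]`.
#' @return `n x n` GAF matrix with attribute `"radius"`.
#' @export
gaf_transform <- function(x) {
  if (any(x < -1 | x > 1)) stop("input must lie in [-1, 1]")
  s <- sqrt(pmax(1 - x^2, 0))          # sin(arccos(x)), guarded for rounding
  g <- outer(s, x) - outer(x, s)       # sin(phi_i - phi_j)
  attr(g, "radius") <- seq_along(x) / length(x)
  g
}

# One-sided DFT magnitude spectrum of a vector: bins 0..floor(n/2).
spectrum_magnitude <- function(x) {
  n <- length(x)
  Mod(stats::fft(x))[seq_len(n %/% 2 + 1)]
}

#' GAF spectrum image of a heartbeat
#'
#' Chain for the lead-II row of a beat: one-sided DFT magnitude spectrum ->
#' PAA smoothing to `image_size` -> min-max rescaling to `[-1, 1]` -> GAF.
#' The DC bin is retained.
#'
#' @param beat A `leads x samples` matrix (with lead names), a
#'   [beat_dataset] slice, or a plain numeric vector treated as lead II.
#' @param image_size Side length of the square output (default 224; must not
#'   exceed the number of one-sided spectrum bins).
#' @return `image_size x image_size` GAF matrix.
#' @export
beat_to_spectrum_image <- function(beat, image_size = 224) {
  if (image_size < 2) stop("image_size must be >= 2")
  x <- .lead2_of(beat)
  spec <- spectrum_magnitude(x)
  gaf_transform(rescale_minmax(paa_smooth(spec, image_size)))
}

# Extract the lead-II row from whatever carries a beat.
.lead2_of <- function(beat) {
  if (is.numeric(beat) && is.null(dim(beat))) return(as.numeric(beat))
  if (is.matrix(beat)) {
    if (!is.null(rownames(beat)) && "II" %in% rownames(beat)) return(beat["II", ])
    if (nrow(beat) >= 2) return(beat[2, ])      # canonical order: II is row 2
    stop("lead II not present in beat")
  }
  stop("unsupported beat input")
}

#' Discrete Stockwell (S-) transform
#'
#' Frequency-domain implementation: for each frequency bin `k > 0` the voice
#' is the inverse DFT over `m` of `X[k + m] * exp(-2 pi^2 m^2 / k^2)`, the
#' Gaussian window whose width scales inversely with frequency. The `f = 0`
#' row, where the analysis window degenerates, is set to the signal mean.
#' Summing the transform over time recovers the DFT coefficient at each
#' positive frequency exactly.
#'
#' @param x Numeric signal (non-empty).
#' @param freq_bins Integer DFT bin indices to compute (default
#'   `0:(n %/% 2)`); must lie in `0..n %/% 2`.
#' @return Object of class `st_image`: list with complex matrix `S`
#'   (`length(freq_bins)` rows x `n` time columns) and `freq_bins`.
#' @export
s_transform <- function(x, freq_bins = NULL) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  if (is.null(freq_bins)) freq_bins <- 0:(n %/% 2)
  freq_bins <- as.integer(freq_bins)
  if (any(freq_bins < 0 | freq_bins > n %/% 2))
    stop("freq_bins must lie in 0..floor(n/2)")
  X <- stats::fft(x)
  # m wrapped to (-n/2, n/2]: distance of each DFT offset from zero frequency
  m <- ((0:(n - 1) + floor(n / 2)) %% n) - floor(n / 2)
  S <- matrix(0 + 0i, nrow = length(freq_bins), ncol = n)
  for (r in seq_along(freq_bins)) {
    k <- freq_bins[r]
    if (k == 0) { S[r, ] <- mean(x); next }
    g <- exp(-2 * pi^2 * m^2 / k^2)
    shifted <- X[(((0:(n - 1)) + k) %% n) + 1]
    S[r, ] <- stats::fft(shifted * g, inverse = TRUE) / n
  }
  structure(list(S = S, freq_bins = freq_bins, n = n), class = "st_image")
}

#' @export
print.st_image <- function(x, ...) {
  cat(sprintf("<st_image: %d frequency bins x %d time samples>\n",
              nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' S-transform time-frequency image of a heartbeat
#'
#' S-transform of the lead-II row restricted to frequencies in `(0, f_max]`,
#' magnitude taken, resized to `image_size x image_size` by area
#' interpolation and scaled to `[0, 1]` (an all-zero beat stays all-zero).
#'
#' @param beat As in [beat_to_spectrum_image()].
#' @param image_size Side length of the square output.
#' @param f_max Upper frequency bound in Hz (default 45, covering the ECG
#'   diagnostic band); must not exceed the Nyquist frequency.
#' @param sampling_rate Sampling rate of the beat in Hz (default 1000).
#' @return `image_size x image_size` matrix in `[0, 1]`.
#' @export
beat_to_st_image <- function(beat, image_size = 224, f_max = 45,
                             sampling_rate = 1000) {
  x <- .lead2_of(beat)
  n <- length(x)
  if (f_max > sampling_rate / 2) stop("f_max exceeds the Nyquist frequency")
  kmax <- floor(f_max * n / sampling_rate)
  if (kmax < 1) stop("f_max below the first positive frequency bin")
  st <- s_transform(x, freq_bins = seq_len(kmax))
  mag <- Mod(st$S)
  img <- resize_area(mag, image_size, image_size)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  img
}

#' Area-interpolation resize of a matrix
#'
#' Each output pixel is the area-weighted mean of the input pixels its cell
#' overlaps (exact box average; no aliasing for downsizing).
#'
#' @param mat Numeric matrix.
#' @param out_rows,out_cols Output dimensions.
#' @return `out_rows x out_cols` matrix.
#' @export
resize_area <- function(mat, out_rows, out_cols) {
  A <- .overlap_weights(nrow(mat), out_rows)
  B <- .overlap_weights(ncol(mat), out_cols)
  A %*% mat %*% t(B)
}

# out x in matrix of normalized interval overlaps between output cell i
# (covering [ (i-1), i ) * n_in/n_out ) and input cell j (covering [j-1, j)).
.overlap_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale; hi <- i * scale
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Write a matrix as a grayscale PNG
#'
#' Rendering writer for documentation parity: min-max scales the matrix to
#' `[0, 1]` and writes an 8-bit grayscale PNG. The raw matrices, not these
#' renderings, feed the networks.
#'
#' @param mat Numeric matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(mat, path) {
  rng <- range(mat)
  img <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
  png::writePNG(img, path)
  invisible(path)
}

#' Compute GAF and ST image stacks for a beat dataset
#'
#' @param ds A [beat_dataset].
#' @param image_size Side length of both image types.
#' @param f_max S-transform frequency cap in Hz.
#' @param sampling_rate Beat sampling rate in Hz.
#' @return List with arrays `gaf` and `st`, each
#'   `image_size x image_size x n`.
#' @export
dataset_images <- function(ds, image_size = 224, f_max = 45,
                           sampling_rate = 1000) {
  stopifnot(inherits(ds, "beat_dataset"))
  n <- length(ds)
  gaf <- array(0, c(image_size, image_size, n))
  st <- array(0, c(image_size, image_size, n))
  for (j in seq_len(n)) {
    beat <- ds$x[, , j]
    rownames(beat) <- ds$lead_names
    gaf[, , j] <- beat_to_spectrum_image(beat, image_size)
    st[, , j] <- beat_to_st_image(beat, image_size, f_max, sampling_rate)
  }
  list(gaf = gaf, st = st)
}
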