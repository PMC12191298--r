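# Periodized orthogonal discrete wavelet transform (Mallat cascade with
# circular extension). Only what the denoiser needs: analysis, synthesis,
# and the db-family filters used for ECG.

# Daubechies-6 (12-tap) scaling filter; standard published constants.
.db6_lo <- c(-0.0010773010853084796, 0.0047772575109455108,
             0.00055384220116149613, -0.03158203931748603,
             0.027522865530305727, 0.097501605587323043,
             -0.12976686756726194, -0.22626469396543983,
             0.31525035170919763, 0.75113390802109536,
             0.49462389039845306, 0.11154074335010947)

.wavelet_filter <- function(name) {
  lo <- switch(tolower(name),
               "db6" = .db6_lo,
               "haar" = , "db1" = c(1, 1) / sqrt(2),
               "db2" = c(-0.12940952255092145, 0.22414386804185735,
                         0.836516303737469, 0.48296291314469025),
               stop("unsupported wavelet: ", name))
  # quadrature mirror: hi[k] = (-1)^(k+1) lo[L-1-k] (0-based k)
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)
  list(lo = lo, hi = hi, length = L)
}

# One analysis step with circular extension, standard periodization layout:
# a[k] = sum_j rev(f)[j] * x[(2k + j - (L/2 - 1)) mod n]  (0-based k and j).
.dwt_step <- function(x, filt) {
  n <- length(x)
  L <- filt$length
  half <- n %/% 2
  k <- seq_len(half)
  idx <- outer(2 * (k - 1), seq_len(L) - 1 - (L %/% 2 - 1), `+`) %% n + 1  # half x L
  xm <- matrix(x[idx], nrow = half)
  list(a = as.vector(xm %*% rev(filt$lo)),
       d = as.vector(xm %*% rev(filt$hi)))
}

# Synthesis step = transpose of analysis (orthogonal transform).
.idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2 * half
  L <- filt$length
  x <- numeric(n)
  lo <- rev(filt$lo); hi <- rev(filt$hi)
  for (j in seq_len(L)) {
    pos <- (2 * (seq_len(half) - 1) + j - 1 - (L %/% 2 - 1)) %% n + 1
    x[pos] <- x[pos] + lo[j] * a + hi[j] * d
  }
  x
}

# Multi-level periodized DWT. Pads x (periodic wrap) to a multiple of
# 2^levels, returns coefficients plus bookkeeping for exact inversion.
dwt_periodic <- function(x, wavelet = "db6", levels = 5) {
  stopifnot(levels >= 1)
  filt <- .wavelet_filter(wavelet)
  n0 <- length(x)
  block <- 2^levels
  if (n0 < block) stop("signal too short for ", levels, " decomposition levels")
  n <- ceiling(n0 / block) * block
  if (n > n0) x <- c(x, x[seq_len(n - n0)])   # periodic pad
  details <- vector("list", levels)
  a <- x
  for (b in seq_len(levels)) {
    s <- .dwt_step(a, filt)
    details[[b]] <- s$d       # level b = finest scale first
    a <- s$a
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 levels = levels, n_orig = n0), class = "dwt")
}

idwt_periodic <- function(w) {
  stopifnot(inherits(w, "dwt"))
  filt <- .wavelet_filter(w$wavelet)
  a <- w$approx
  for (b in rev(seq_len(w$levels)))
    a <- .idwt_step(a, w$details[[b]], filt)
  a[seq_len(w$n_orig)]
}
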