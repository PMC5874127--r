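# Internal helpers shared across modules.

# Deterministic half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

#' DFT frequency axis in cycles/mm
#'
#' Frequencies of the unshifted DFT bins of an `n`-point axis with sample
#' spacing `delta` mm: bin k (0-based) maps to `k/(n*delta)` for `k <= n/2`
#' and `(k - n)/(n*delta)` above, so the vector runs
#' `0, df, ..., f_Nyq, -f_Nyq + df, ..., -df` with `df = 1/(n*delta)`.
#'
#' @param n number of bins (pixels along the axis).
#' @param delta sample spacing in mm.
#' @return numeric vector of length `n`, signed frequencies in 1/mm.
#' @export
dft_freq <- function(n, delta) {
  stopifnot(n >= 1, delta > 0)
  k <- 0:(n - 1)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / (n * delta)
}

# One-sided axis 0 .. Nyquist for even n: n/2 + 1 frequencies.
one_sided_freq <- function(n, delta) (0:(n %/% 2)) / (n * delta)

# Fold a two-sided DFT-ordered vector to one-sided 0..Nyquist.
# Bin at -f equals bin at +f for the spectra handled here, so the fold
# averages the two (no doubling); DC and the Nyquist bin appear once.
fold_one_sided <- function(v) {
  n <- length(v)
  if (n %% 2 != 0) {
    stop("one-sided folding implemented for even-length axes only, got ", n)
  }
  half <- n %/% 2
  out <- numeric(half + 1)
  out[1] <- v[1]
  if (half > 1) {
    j <- seq_len(half - 1)
    out[j + 1] <- (v[j + 1] + v[n - j + 1]) / 2
  }
  out[half + 1] <- v[half + 1]
  out
}

# Accept a bare matrix or an roi_patch and return the pixel matrix.
patch_values <- function(x) {
  if (inherits(x, "roi_patch")) x$values else if (is.matrix(x)) x else
    stop("expected a matrix or an roi_patch, got ", class(x)[1])
}

# Normalise pixel spacing to a length-2 (dx, dy) vector.
as_spacing <- function(pixel_spacing_mm) {
  s <- as.numeric(pixel_spacing_mm)
  if (length(s) == 1) s <- c(s, s)
  if (length(s) != 2 || any(!is.finite(s)) || any(s <= 0)) {
    stop("pixel_spacing_mm must be one or two strictly positive values")
  }
  s
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
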