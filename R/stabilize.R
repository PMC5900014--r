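#' @include AllClasses.R
NULL

## FFT cross-correlation of two equal-size matrices; returns the integer
## shift (dy, dx) that, applied to `frame`, best aligns it to `ref`.
.bestShift <- function(ref, frame) {
  nr <- nrow(ref); nc <- ncol(ref)
  cc <- Re(fft(fft(ref) * Conj(fft(frame)), inverse = TRUE))
  k <- which.max(cc)
  dy <- (k - 1L) %% nr
  dx <- (k - 1L) %/% nr
  if (dy > nr %/% 2) dy <- dy - nr
  if (dx > nc %/% 2) dx <- dx - nc
  c(dy = dy, dx = dx)
}

#' Rigid motion stabilization of a movie
#'
#' Registers every frame to a reference frame by integer-pixel rigid
#' translation maximizing the (FFT-based, full-search) cross-correlation.
#' Border pixels exposed by shifting are filled with the shifted frame's
#' median intensity. Frames whose best shift exceeds 20% of the frame
#' dimension are flagged unstable, left untranslated and reported in the
#' shift table so downstream analysis can exclude them.
#'
#' Stabilization is idempotent: running it on an already-stabilized movie
#' yields all-zero shifts.
#'
#' @param movie a [CalciumMovie()].
#' @param reference 1-based index of the reference frame (with an EFS
#'   protocol, use a pre-stimulus frame; default the first frame).
#' @param maxShiftFrac shifts beyond this fraction of each dimension flag
#'   the frame as unstable (default 0.2).
#' @return A list: `movie` (stabilized [CalciumMovie()]) and `shifts`
#'   (data.frame with `frame`, `dy`, `dx`, `unstable`). `dy`/`dx` are the
#'   applied corrections (rows/columns).
#' @examples
#' sim <- simulateRecording(GeneratorConfig(duration = 2, nSites = 1,
#'                                          noiseSd = 0, seed = 1))
#' st <- stabilizeMovie(sim$movie)
#' all(st$shifts$dy == 0)
#' @export
stabilizeMovie <- function(movie, reference = 1L, maxShiftFrac = 0.2) {
  A <- movie@intensity
  nr <- dim(A)[1]; nc <- dim(A)[2]; nT <- dim(A)[3]
  stopifnot(reference >= 1L, reference <= nT)
  ref <- A[, , reference]
  refC <- ref - mean(ref)
  fftRef <- fft(refC)
  shifts <- data.frame(frame = seq_len(nT), dy = 0L, dx = 0L,
                       unstable = FALSE)
  out <- A
  for (f in seq_len(nT)) {
    if (f == reference) next
    fr <- A[, , f]
    frC <- fr - mean(fr)
    cc <- Re(fft(fftRef * Conj(fft(frC)), inverse = TRUE))
    k <- which.max(cc)
    dy <- (k - 1L) %% nr
    dx <- (k - 1L) %/% nr
    if (dy > nr %/% 2) dy <- dy - nr
    if (dx > nc %/% 2) dx <- dx - nc
    if (abs(dy) > maxShiftFrac * nr || abs(dx) > maxShiftFrac * nc) {
      shifts$unstable[f] <- TRUE
      next
    }
    shifts$dy[f] <- dy
    shifts$dx[f] <- dx
    if (dy != 0 || dx != 0)
      out[, , f] <- .translateMatrix(fr, dy, dx, stats::median(fr))
  }
  list(movie = CalciumMovie(out, frameRate = movie@frameRate,
                            pixelSize = movie@pixelSize),
       shifts = shifts)
}
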