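#' Convert a resampled suture curve to a 1D deviation signal
#'
#' Rigidly transforms the curve so its endpoint chord lies on the horizontal
#' axis with the first point at the origin; the signal is the sequence of
#' signed vertical coordinates (perpendicular deviations from the chord). A
#' perfectly straight suture maps to the zero signal, and the endpoints are
#' exactly zero by construction. This is the waveform consumed by the
#' short-time Fourier analysis.
#'
#' @param curve A [resample_equidistant()] output (or any `curve2d` with at
#'   least 3 points and distinct endpoints).
#' @return An object of class `suture_signal`: `specimen_id`, `values`
#'   (length-n numeric) and `spacing` (chord length / (n - 1)).
#' @export
suture_signal <- function(curve) {
  stopifnot(inherits(curve, "curve2d"))
  p <- curve$points
  n <- nrow(p)
  if (n < 3L) stop_validation("signal extraction needs at least 3 points")
  chord <- p[n, ] - p[1, ]
  L <- sqrt(sum(chord^2))
  if (L == 0) {
    stop_validation(sprintf("curve '%s': endpoints coincide", curve$specimen_id))
  }
  tangent <- chord / L
  normal <- c(-tangent[2], tangent[1])
  values <- as.numeric((sweep(p, 2, p[1, ])) %*% normal)
  values[c(1L, n)] <- 0
  structure(list(specimen_id = curve$specimen_id,
                 values = values,
                 spacing = L / (n - 1)),
            class = "suture_signal")
}

#' Sinuosity index of a suture curve
#'
#' The ratio of the suture's total path length (summed over all curves and
#' interdigitations) to the straight-line distance between its endpoints.
#' Always >= 1, with 1 for a perfectly straight suture; invariant under
#' rotation, translation, uniform scaling and point-order reversal. SI is
#' most sensitive to the amount of interdigitation.
#'
#' @param curve A `curve2d` with distinct endpoints.
#' @return A scalar >= 1.
#' @examples
#' sinuosity_index(curve2d("s", cbind(c(0, 1, 2), c(0, 1, 0))))  # sqrt(2)
#' @export
sinuosity_index <- function(curve) {
  stopifnot(inherits(curve, "curve2d"))
  p <- curve$points
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord == 0) {
    stop_validation(sprintf("curve '%s': endpoints coincide, SI undefined",
                            curve$specimen_id))
  }
  sum(segment_lengths(p)) / chord
}

taper_window <- function(taper, window) {
  switch(taper,
         hann = {
           k <- seq_len(window) - 1L
           0.5 * (1 - cos(2 * pi * k / (window - 1)))
         },
         boxcar = rep(1, window),
         stop_validation(sprintf("unknown taper '%s'", taper)))
}

#' Short-time Fourier power-spectral-density complexity score
#'
#' Slides a tapered window along the suture deviation signal, computes the
#' discrete Fourier power spectrum of each windowed segment (normalised by the
#' window energy, Welch style), sums the power over all non-zero frequency
#' bins (the DC bin is excluded so placement carries no power), and averages
#' across windows. The score is >= 0, quadratic in signal amplitude, and
#' sensitive to irregularity as well as interdigitation — a complementary
#' complexity axis to the sinuosity index.
#'
#' @param signal A [suture_signal()] result (or bare numeric vector).
#' @param window Window length in samples (default 50; must satisfy
#'   `8 <= window <= length(signal)`).
#' @param overlap_fraction Fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param taper `"hann"` (default) or `"boxcar"`.
#' @return A non-negative scalar.
#' @export
psd_complexity <- function(signal, window = 50L, overlap_fraction = 0.5,
                           taper = c("hann", "boxcar")) {
  taper <- match.arg(taper)
  values <- if (inherits(signal, "suture_signal")) signal$values else as.numeric(signal)
  n <- length(values)
  if (!all(is.finite(values))) stop_validation("signal contains non-finite values")
  if (!is.numeric(window) || length(window) != 1L || window != round(window) ||
      window < 8L) {
    stop_validation("`window` must be a single integer >= 8")
  }
  window <- as.integer(window)
  if (window > n) {
    stop_validation(sprintf("`window` (%d) exceeds signal length (%d)", window, n))
  }
  assert_scalar_number(overlap_fraction, "overlap_fraction", 0, 1 - 1e-12)
  w <- taper_window(taper, window)
  hop <- max(1L, as.integer(round(window * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - window + 1L, by = hop)
  powers <- vapply(starts, function(s) {
    seg <- values[s:(s + window - 1L)] * w
    spec <- Mod(stats::fft(seg))^2 / (window * sum(w^2))
    sum(spec[-1L])  # all non-DC bins (two-sided)
  }, numeric(1))
  mean(powers)
}

#' Per-specimen complexity table
#'
#' Computes the sinuosity index and the STFT power-spectral-density score for
#' each curve. Scores are meant to be computed on Procrustes-aligned,
#' equidistantly resampled semi-landmarks, making both metrics dimensionless.
#'
#' @param curves List of resampled `curve2d` objects (typically
#'   `align_curves(...)$aligned` converted back to curves, or the resampled
#'   curves directly — both metrics are similarity-invariant).
#' @param window,overlap_fraction,taper Passed to [psd_complexity()].
#' @return A `data.frame` with columns `specimen_id`, `SI`, `PSD`.
#' @export
complexity_scores <- function(curves, window = 50L, overlap_fraction = 0.5,
                              taper = "hann") {
  stopifnot(is.list(curves), length(curves) > 0L)
  recs <- lapply(curves, function(cv) {
    si <- sinuosity_index(cv)
    psd <- psd_complexity(suture_signal(cv), window = window,
                          overlap_fraction = overlap_fraction, taper = taper)
    data.frame(specimen_id = cv$specimen_id, SI = si, PSD = psd)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (any(out$SI < 1 - 1e-12) || any(out$PSD < 0) || !all(is.finite(out$SI)) ||
      !all(is.finite(out$PSD))) {
    stop("internal error: complexity invariants violated")  # nocov
  }
  out
}

#' Convert aligned shapes back to curves
#'
#' Rebuilds `curve2d` objects from a 2D [gpa_align()] result so the
#' complexity metrics can be computed on the Procrustes-superimposed
#' semi-landmarks.
#'
#' @param aligned An `aligned_shapes` object with 2-column shapes.
#' @return A list of [curve2d] objects.
#' @export
aligned_to_curves <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  lapply(seq_along(aligned$shapes), function(i) {
    curve2d(aligned$specimen_ids[i], aligned$shapes[[i]])
  })
}
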