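#' Stick spectrum of one frame
#'
#' @param ex an `excitation_set` with oscillator strengths
#' @param frame_id frame identifier
#' @return object of class `stick_spectrum`: `frame_id`, `energy_ev`
#'   (ascending), `f`
#' @export
stick_spectrum <- function(ex, frame_id = 0L) {
  if (is.null(ex$f)) stop("excitation set has no oscillator strengths; run oscillator_strengths()")
  ord <- order(ex$omega_ev)
  structure(list(frame_id = as.integer(frame_id),
                 energy_ev = ex$omega_ev[ord], f = ex$f[ord]),
            class = "stick_spectrum")
}

#' Uniform spectral grid (eV)
#'
#' @param from,to,by grid range and step in eV
#' @return numeric vector of grid energies
#' @export
spectral_grid <- function(from = 1.0, to = 8.0, by = 0.005) {
  seq(from, to, by = by)
}

#' Gaussian convolution of a stick spectrum
#'
#' Each stick becomes an area-normalized Gaussian of the given full width at
#' half-maximum, scaled by its oscillator strength
#' (`sigma = fwhm / (2 sqrt(2 ln 2))`), so the integral of the profile over
#' a wide-enough grid equals the summed oscillator strength. Intensity units
#' are oscillator strength per eV. A warning is issued when the grid does
#' not cover every stick by at least 3 sigma.
#'
#' @param sticks a [stick_spectrum()]
#' @param fwhm_ev full width at half-maximum in eV, > 0
#' @param grid energy grid in eV (see [spectral_grid()])
#' @return object of class `spectrum`: `grid_ev`, `intensity`, `fwhm_ev`,
#'   `n_frames` (= 1), `normalized` (= FALSE)
#' @export
convolve_sticks <- function(sticks, fwhm_ev = 0.3, grid = spectral_grid()) {
  stopifnot(fwhm_ev > 0)
  sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
  e <- sticks$energy_ev; f <- sticks$f
  if (length(e) > 0 &&
      (min(e) - 3 * sigma < grid[1] || max(e) + 3 * sigma > grid[length(grid)])) {
    warning("spectral grid does not cover all sticks +/- 3 sigma; area is truncated")
  }
  intensity <- numeric(length(grid))
  for (k in seq_along(e)) {
    intensity <- intensity +
      f[k] / (sigma * sqrt(2 * pi)) * exp(-(grid - e[k])^2 / (2 * sigma^2))
  }
  structure(list(grid_ev = grid, intensity = intensity, fwhm_ev = fwhm_ev,
                 n_frames = 1L, normalized = FALSE),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  imax <- which.max(x$intensity)
  cat(sprintf("<spectrum> grid %.2f-%.2f eV (%d pts), fwhm %.2f eV, %d frame(s); max at %.3f eV\n",
              x$grid_ev[1], x$grid_ev[length(x$grid_ev)], length(x$grid_ev),
              x$fwhm_ev, x$n_frames, x$grid_ev[imax]))
  invisible(x)
}

#' Average spectra over frames
#'
#' Pointwise mean of raw (un-normalized) per-frame spectra on a common grid;
#' optional max-normalization is applied after averaging (average first,
#' normalize last).
#'
#' @param spectra list of `spectrum` objects with identical grids and fwhm
#' @param normalize if `TRUE`, scale the averaged profile to unit maximum
#' @return a `spectrum`
#' @export
average_spectra <- function(spectra, normalize = FALSE) {
  stopifnot(length(spectra) >= 1L)
  g0 <- spectra[[1]]$grid_ev
  for (s in spectra) {
    if (length(s$grid_ev) != length(g0) || any(s$grid_ev != g0)) {
      stop("spectra must share a common grid to be averaged")
    }
  }
  intensity <- Reduce(`+`, lapply(spectra, `[[`, "intensity")) / length(spectra)
  out <- spectra[[1]]
  out$intensity <- intensity
  out$n_frames <- sum(vapply(spectra, `[[`, 1L, "n_frames"))
  out$normalized <- FALSE
  if (normalize) out <- normalize_spectrum(out)
  out
}

#' Scale a spectrum to unit maximum
#' @param sp a `spectrum`
#' @return the normalized `spectrum`
#' @export
normalize_spectrum <- function(sp) {
  m <- max(sp$intensity)
  if (m > 0) sp$intensity <- sp$intensity / m
  sp$normalized <- TRUE
  sp
}

#' Running-mean convergence diagnostics with confidence intervals
#'
#' For each prefix length `n >= 2` of a per-frame scalar series (for
#' example, the first excitation energy of each snapshot), the running mean
#' and the Student-t confidence-interval half-width
#' `t_{(1+level)/2, n-1} * sd / sqrt(n)` at the given level.
#'
#' @param values numeric vector of per-frame scalars (length >= 2)
#' @param level confidence level, default 0.99
#' @return data.frame with columns `n`, `mean`, `ci_half_width`
#' @export
convergence_ci <- function(values, level = 0.99) {
  n_tot <- length(values)
  if (n_tot < 2L) stop("convergence diagnostics need at least 2 frames")
  cmean <- cumsum(values) / seq_len(n_tot)
  cm2 <- cumsum(values^2)
  n <- 2:n_tot
  varn <- (cm2[n] - n * cmean[n]^2) / (n - 1)
  varn[varn < 0] <- 0
  hw <- stats::qt((1 + level) / 2, df = n - 1) * sqrt(varn / n)
  data.frame(n = n, mean = cmean[n], ci_half_width = hw)
}

#' Write a stick spectrum as CSV
#' @param sticks a `stick_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sticks_csv <- function(sticks, path) {
  utils::write.csv(data.frame(energy_ev = sticks$energy_ev,
                              oscillator_strength = sticks$f),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a convolved spectrum as CSV
#' @param sp a `spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(sp, path) {
  utils::write.csv(data.frame(energy_ev = sp$grid_ev,
                              intensity = sp$intensity),
                   path, row.names = FALSE)
  invisible(path)
}
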