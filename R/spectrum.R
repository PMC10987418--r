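## Parametric model of the Ho-166 energy-spectrum components per window.

## Relative component intensities (%) per acquisition window, from the
## Monte-Carlo spectrum decomposition of a Ho-166 source in a water
## cylinder: columns are photopeak(+scatter), high-energy scatter, X-ray
## peak, bremsstrahlung. Rows are renormalized to sum to 1 (the published
## percentages carry rounding).
SPECTRUM_TABLE <- matrix(
  c(41.5, 54.4, 0.0, 4.4,   # W1
    48.3, 48.7, 0.0, 3.0,   # W2
     6.5, 88.9, 0.0, 4.4,   # W3
     0.0, 96.9, 0.0, 3.1),  # W4
  nrow = 4, byrow = TRUE,
  dimnames = list(WINDOW_LABELS, COMPONENT_NAMES))

#' Spectrum component model
#'
#' Builds a [SpectrumComponentModel-class]. The default fractions are the
#' Monte-Carlo decomposition of the Ho-166 spectrum in a water cylinder:
#' in the main window W2 the counts split roughly evenly between the
#' 80.6 keV photopeak with its associated scatter (48.3%) and high-energy
#' scattered gamma rays (48.7%), with a small bremsstrahlung tail (3%) and a
#' negligible X-ray contribution; the downscatter window W4 is almost purely
#' high-energy scatter (96.9%).
#'
#' Total count rates per window relative to W2 (`rateScale`) are not pinned
#' down by the published decomposition; the defaults (W1 0.30, W3 0.25,
#' W4 0.25) reflect the narrower side windows and the downscatter continuum.
#'
#' @param fractions matrix of per-window component fractions (rows = windows,
#'   columns = the four components); rows are renormalized to sum to 1.
#' @param rateScale named numeric of per-window total-rate multipliers
#'   relative to W2.
#' @return A [SpectrumComponentModel-class].
#' @export
spectrumComponentModel <- function(fractions = SPECTRUM_TABLE,
                                   rateScale = c(W1 = 0.30, W2 = 1.0,
                                                 W3 = 0.25, W4 = 0.25)) {
  f <- as.matrix(fractions)
  rs <- rowSums(f)
  if (any(rs <= 0)) stop("each window needs a positive fraction total",
                         call. = FALSE)
  f <- sweep(f, 1, rs, "/")
  new("SpectrumComponentModel", fractions = f, rateScale = rateScale)
}

#' Draw per-component event tallies for one window
#'
#' Multinomial draw of `nEvents` detected counts over the window's component
#' fractions; the tallies always sum exactly to `nEvents`.
#'
#' @param model a [SpectrumComponentModel-class].
#' @param window window label, e.g. "W2".
#' @param nEvents number of events to classify (>= 0).
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return named integer vector of per-component tallies.
#' @export
sampleWindowComponents <- function(model, window, nEvents, seed = NULL) {
  stopifnot(is(model, "SpectrumComponentModel"))
  if (!window %in% rownames(model@fractions))
    stop("unknown window '", window, "'", call. = FALSE)
  if (nEvents < 0) stop("'nEvents' must be >= 0", call. = FALSE)
  p <- model@fractions[window, ]
  tall <- withSeed(seed, {
    if (nEvents == 0) rep(0L, length(p)) else
      as.integer(rmultinom(1, size = nEvents, prob = p))
  })
  setNames(tall, colnames(model@fractions))
}
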