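## Energy-window arithmetic and the DEW / TEW scatter-correction operators.

#' Symmetric energy-window bounds
#'
#' Converts a window centre and a width expressed as a percentage of the
#' centre into lower/upper bounds:
#' lower = center (1 - width/200), upper = center (1 + width/200).
#' No rounding is applied; round only for display.
#'
#' @param center keV (> 0).
#' @param widthPercent full width as % of the centre (>= 0).
#' @return named numeric c(lower, upper) in keV.
#' @export
windowBounds <- function(center, widthPercent) {
  stopifnot(center > 0, widthPercent >= 0)
  c(lower = center * (1 - widthPercent / 200),
    upper = center * (1 + widthPercent / 200))
}

#' Construct an energy-window record
#'
#' @param label window label ("W1".."W4").
#' @param center keV.
#' @param widthPercent full width as % of the centre.
#' @return one-row data.frame with `label`, `center`, `widthPercent`,
#'   `lower`, `upper` and the absolute `width` in keV.
#' @export
energyWindow <- function(label, center, widthPercent) {
  b <- windowBounds(center, widthPercent)
  data.frame(label = label, center = center, widthPercent = widthPercent,
             lower = b[["lower"]], upper = b[["upper"]],
             width = b[["upper"]] - b[["lower"]])
}

#' The acquisition energy-window table
#'
#' The four windows of the Ho-166 acquisition protocol: the 80.6 keV main
#' window W2 (15% wide, 12 keV), the two 6 keV TEW side windows W1
#' (71.56 keV, 8.39%) and W3 (89.65 keV, 6.69%), and the 118 keV downscatter
#' window W4 (10.2%, 12 keV) used by the DEW method.
#'
#' @return data.frame with one row per window (see [energyWindow()]).
#' @export
defaultWindows <- function() {
  rbind(energyWindow("W1", 71.56, 8.39),
        energyWindow("W2", 80.60, 15.0),
        energyWindow("W3", 89.65, 6.69),
        energyWindow("W4", 118.0, 10.2))
}

#' Dual-energy-window (DEW) scatter correction
#'
#' Subtracts the downscatter-window projections, scaled by a constant k,
#' from the main-window projections: `out = pMain - k * pDown`. With the
#' established k = 1 for Ho-166 this removes, in expectation, a count total
#' equal to the downscatter-window total.
#'
#' @param pMain 3D array, main-window (W2) projections.
#' @param pDown 3D array of identical shape, downscatter-window (W4)
#'   projections.
#' @param params a [DewParams-class] (default k = 1).
#' @param clamp clamp negative pixels to zero (default TRUE; reconstruction
#'   requires non-negative data).
#' @return corrected projection array.
#' @export
dewCorrect <- function(pMain, pDown, params = dewParams(), clamp = TRUE) {
  stopifnot(is(params, "DewParams"))
  stopifnot_same_dim(pMain, pDown)
  out <- pMain - params@k * pDown
  if (clamp) out[out < 0] <- 0
  out
}

#' Triple-energy-window (TEW) scatter correction
#'
#' Estimates the scatter inside the main window by trapezoidal interpolation
#' of the count rates in two narrow side windows:
#' `scatter = (pLow/wLow + pHigh/wHigh) * wMain / 2`, then subtracts it from
#' the main window. With the protocol's 6 / 12 / 6 keV widths the estimate
#' reduces exactly to `pLow + pHigh`, i.e. direct subtraction of the summed
#' side windows.
#'
#' @param pMain,pLow,pHigh 3D arrays of identical shape: main (W2), lower
#'   side (W1) and upper side (W3) window projections.
#' @param widths numeric(3), keV widths c(low, main, high); default the
#'   protocol's c(6, 12, 6).
#' @param clamp clamp negative pixels to zero (default TRUE).
#' @return corrected projection array.
#' @export
tewCorrect <- function(pMain, pLow, pHigh, widths = c(6, 12, 6),
                       clamp = TRUE) {
  if (length(widths) != 3L || any(widths <= 0))
    stop("'widths' must be 3 positive keV widths c(low, main, high)",
         call. = FALSE)
  stopifnot_same_dim(pMain, pLow, pHigh)
  ## trapezoid written so equal side/main widths give exact unit factors
  est <- pLow * (widths[2] / (2 * widths[1])) +
    pHigh * (widths[2] / (2 * widths[3]))
  out <- pMain - est
  if (clamp) out[out < 0] <- 0
  out
}

#' Sum the two TEW side windows into one stack
#'
#' Cameras limited in concurrent images store W1 + W3 as a single acquisition
#' window; this reproduces that summation.
#'
#' @param pLow,pHigh 3D arrays of identical shape.
#' @return elementwise sum.
#' @export
combineSideWindows <- function(pLow, pHigh) {
  stopifnot_same_dim(pLow, pHigh)
  pLow + pHigh
}

#' Apply a scatter correction to a ProjectionSet
#'
#' Window-level driver for [dewCorrect()] / [tewCorrect()]: picks the right
#' window stacks, applies the correction to every projection and returns a
#' single-window ProjectionSet (label "W2") carrying a provenance record of
#' the method and parameters.
#'
#' @param ps a [ProjectionSet-class] containing W2 plus W4 (dew) or W1 and W3
#'   (tew).
#' @param method "dew", "tew" or "none".
#' @param params a [DewParams-class] for method "dew".
#' @param widths keV widths for method "tew" (see [tewCorrect()]); defaults
#'   to the widths recorded in the set's window table.
#' @param clamp clamp negatives to zero.
#' @return a corrected [ProjectionSet-class] holding only the corrected main
#'   window.
#' @export
correctProjections <- function(ps, method = c("tew", "dew", "none"),
                               params = dewParams(), widths = NULL,
                               clamp = TRUE) {
  stopifnot(is(ps, "ProjectionSet"))
  method <- match.arg(method)
  need <- switch(method, none = "W2", dew = c("W2", "W4"),
                 tew = c("W2", "W1", "W3"))
  miss <- setdiff(need, names(ps@counts))
  if (length(miss))
    stop("ProjectionSet lacks window(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- switch(method,
    none = ps@counts[["W2"]],
    dew = dewCorrect(ps@counts[["W2"]], ps@counts[["W4"]], params, clamp),
    tew = {
      if (is.null(widths)) {
        wt <- ps@windows
        widths <- c(wt$width[wt$label == "W1"], wt$width[wt$label == "W2"],
                    wt$width[wt$label == "W3"])
        if (length(widths) != 3L) widths <- c(6, 12, 6)
      }
      tewCorrect(ps@counts[["W2"]], ps@counts[["W1"]], ps@counts[["W3"]],
                 widths, clamp)
    })
  prov <- c(ps@provenance,
            list(list(step = "scatter_correction", method = method,
                      k = if (method == "dew") params@k else NA_real_,
                      widths = if (method == "tew") widths else NULL,
                      clamp = clamp,
                      upstream = objectHash(ps@counts))))
  new("ProjectionSet", counts = list(W2 = out), geometry = ps@geometry,
      windows = ps@windows[ps@windows$label == "W2", , drop = FALSE],
      tallies = ps@tallies, provenance = prov)
}
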