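#' Default haemoglobin extinction coefficients
#'
#' Specific extinction coefficients of oxy- and deoxyhaemoglobin at the two
#' wavelengths of a typical continuous-wave NIRS device (760 and 850 nm),
#' expressed per µM per mm of optical path so that the product with
#' pathlength-scaled concentration changes (µM·mm) is a dimensionless
#' optical-density change. Values are the widely used compilation of Gratzer
#' and Kollias (as distributed with the Homer analysis environments),
#' converted from cm^-1/mM. These are configuration, not ground truth:
#' override them when your device or conversion software uses another table.
#'
#' @param wavelengths_nm Two wavelengths; only 760/850 are tabulated here.
#' @return A 2x2 matrix, rows = wavelengths, columns = `c("oxy", "deoxy")`,
#'   units 1/(µM·mm).
#' @export
default_extinction <- function(wavelengths_nm = c(760, 850)) {
  tab <- rbind(
    `760` = c(oxy = 1.4866, deoxy = 3.8437),  # cm^-1 / mM
    `850` = c(oxy = 2.5264, deoxy = 1.7986)
  )
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(tab))) {
    abort("Only 760 and 850 nm are tabulated; supply `extinction` explicitly.")
  }
  m <- tab[key, , drop = FALSE] * 1e-4  # -> 1/(uM*mm)
  rownames(m) <- key
  m
}

check_extinction <- function(extinction, dpf) {
  if (!is.matrix(extinction) || !all(dim(extinction) == c(2, 2))) {
    abort("`extinction` must be a 2x2 matrix (wavelengths x chromophores).")
  }
  if (any(dpf <= 0)) abort("`dpf` values must be positive.")
  E <- extinction * dpf
  if (abs(det(E)) < 1e-12 * max(abs(E))^2) {
    abort("Singular extinction matrix: wavelength rows are proportional.")
  }
  E
}

#' Forward modified Beer-Lambert model
#'
#' Generates optical-density changes at two wavelengths from known oxy- and
#' deoxyhaemoglobin concentration changes:
#' \eqn{\Delta OD(\lambda) = DPF(\lambda)\,[\epsilon_{oxy}(\lambda)\Delta HbO +
#' \epsilon_{deoxy}(\lambda)\Delta HbR]}. Used to build test inputs and to
#' emulate raw-device output from the synthetic generator's OxyHb signals.
#'
#' @param data Data frame with a time column and the chromophore columns.
#' @param oxy,deoxy Column names (strings) holding ΔHbO and ΔHbR in µM·mm.
#' @param extinction 2x2 extinction matrix, see [default_extinction()].
#' @param dpf Differential pathlength factor per wavelength (length 2).
#' @param time Name of the time column.
#' @return A tibble `time_s`, `od1`, `od2` with wavelengths recorded in the
#'   `wavelengths_nm` attribute.
#' @export
forward_mbll <- function(data, oxy = "oxyhb", deoxy = "deoxyhb",
                         extinction = default_extinction(),
                         dpf = c(1, 1), time = "time_s") {
  E <- check_extinction(extinction, dpf)
  C <- rbind(data[[oxy]], data[[deoxy]])
  OD <- E %*% C
  out <- tibble(time_s = data[[time]], od1 = OD[1, ], od2 = OD[2, ])
  attr(out, "wavelengths_nm") <- as.numeric(rownames(extinction))
  out
}

#' Convert optical-density changes to haemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per sample for two wavelengths and
#' two chromophores. Output stays in pathlength-scaled units (µM·mm), i.e. it
#' is not divided by the source-detector separation, avoiding an unstated
#' partial-pathlength assumption and matching how band-averaged OxyHb
#' results are usually tabulated for this kind of montage.
#'
#' @param data Data frame with a time column and two optical-density columns.
#' @param od Character vector of the two ΔOD column names.
#' @param extinction,dpf See [forward_mbll()]; the extinction matrix must be
#'   invertible and `dpf` positive.
#' @param time Name of the time column.
#' @return A tibble `time_s`, `oxyhb`, `deoxyhb` (µM·mm).
#' @examples
#' hb <- tibble::tibble(time_s = 0:9 / 10, oxyhb = sin(0:9), deoxyhb = cos(0:9))
#' od <- forward_mbll(hb)
#' rec <- mbll_convert(od)
#' max(abs(rec$oxyhb - hb$oxyhb))
#' @export
mbll_convert <- function(data, od = c("od1", "od2"),
                         extinction = default_extinction(),
                         dpf = c(1, 1), time = "time_s") {
  if (length(od) != 2) abort("Exactly two optical-density columns required.")
  E <- check_extinction(extinction, dpf)
  OD <- rbind(data[[od[1]]], data[[od[2]]])
  if (any(!is.finite(OD))) abort("Optical-density samples must be finite.")
  C <- solve(E, OD)
  tibble(time_s = data[[time]], oxyhb = C[1, ], deoxyhb = C[2, ])
}
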