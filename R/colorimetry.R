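# CIE colorimetry: SPD -> XYZ -> CIE 1976 u'v' chromaticity.
#
# All downstream statistics of the pipeline live in the u'v' plane; luminance
# is carried through where available but never enters a distance.

# CIE 1931 2-degree standard observer color-matching functions, 380-780 nm at
# 5 nm steps. Embedded as a constant so SPD conversion has no external data
# dependency; linear interpolation maps it onto a measurement grid.
.cie1931_cmf <- local({
  m <- matrix(c(
    380, 0.001368, 0.000039, 0.006450,
    385, 0.002236, 0.000064, 0.010550,
    390, 0.004243, 0.000120, 0.020050,
    395, 0.007650, 0.000217, 0.036210,
    400, 0.014310, 0.000396, 0.067850,
    405, 0.023190, 0.000640, 0.110200,
    410, 0.043510, 0.001210, 0.207400,
    415, 0.077630, 0.002180, 0.371300,
    420, 0.134380, 0.004000, 0.645600,
    425, 0.214770, 0.007300, 1.039050,
    430, 0.283900, 0.011600, 1.385600,
    435, 0.328500, 0.016840, 1.622960,
    440, 0.348280, 0.023000, 1.747060,
    445, 0.348060, 0.029800, 1.782600,
    450, 0.336200, 0.038000, 1.772110,
    455, 0.318700, 0.048000, 1.744100,
    460, 0.290800, 0.060000, 1.669200,
    465, 0.251100, 0.073900, 1.528100,
    470, 0.195360, 0.090980, 1.287640,
    475, 0.142100, 0.112600, 1.041900,
    480, 0.095640, 0.139020, 0.812950,
    485, 0.057950, 0.169300, 0.616200,
    490, 0.032010, 0.208020, 0.465180,
    495, 0.014700, 0.258600, 0.353300,
    500, 0.004900, 0.323000, 0.272000,
    505, 0.002400, 0.407300, 0.212300,
    510, 0.009300, 0.503000, 0.158200,
    515, 0.029100, 0.608200, 0.111700,
    520, 0.063270, 0.710000, 0.078250,
    525, 0.109600, 0.793200, 0.057250,
    530, 0.165500, 0.862000, 0.042160,
    535, 0.225750, 0.914850, 0.029840,
    540, 0.290400, 0.954000, 0.020300,
    545, 0.359700, 0.980300, 0.013400,
    550, 0.433450, 0.994950, 0.008750,
    555, 0.512050, 1.000000, 0.005750,
    560, 0.594500, 0.995000, 0.003900,
    565, 0.678400, 0.978600, 0.002750,
    570, 0.762100, 0.952000, 0.002100,
    575, 0.842500, 0.915400, 0.001800,
    580, 0.916300, 0.870000, 0.001650,
    585, 0.978600, 0.816300, 0.001400,
    590, 1.026300, 0.757000, 0.001100,
    595, 1.056700, 0.694900, 0.001000,
    600, 1.062200, 0.631000, 0.000800,
    605, 1.045600, 0.566800, 0.000600,
    610, 1.002600, 0.503000, 0.000340,
    615, 0.938400, 0.441200, 0.000240,
    620, 0.854450, 0.381000, 0.000190,
    625, 0.751400, 0.321000, 0.000100,
    630, 0.642400, 0.265000, 0.000050,
    635, 0.541900, 0.217000, 0.000030,
    640, 0.447900, 0.175000, 0.000020,
    645, 0.360800, 0.138200, 0.000010,
    650, 0.283500, 0.107000, 0.000000,
    655, 0.218700, 0.081600, 0.000000,
    660, 0.164900, 0.061000, 0.000000,
    665, 0.121200, 0.044580, 0.000000,
    670, 0.087400, 0.032000, 0.000000,
    675, 0.063600, 0.023200, 0.000000,
    680, 0.046770, 0.017000, 0.000000,
    685, 0.032900, 0.011920, 0.000000,
    690, 0.022700, 0.008210, 0.000000,
    695, 0.015840, 0.005723, 0.000000,
    700, 0.011359, 0.004102, 0.000000,
    705, 0.008111, 0.002929, 0.000000,
    710, 0.005790, 0.002091, 0.000000,
    715, 0.004109, 0.001484, 0.000000,
    720, 0.002899, 0.001047, 0.000000,
    725, 0.002049, 0.000740, 0.000000,
    730, 0.001440, 0.000520, 0.000000,
    735, 0.001000, 0.000361, 0.000000,
    740, 0.000690, 0.000249, 0.000000,
    745, 0.000476, 0.000172, 0.000000,
    750, 0.000332, 0.000120, 0.000000,
    755, 0.000235, 0.000085, 0.000000,
    760, 0.000166, 0.000060, 0.000000,
    765, 0.000117, 0.000042, 0.000000,
    770, 0.000083, 0.000030, 0.000000,
    775, 0.000059, 0.000021, 0.000000,
    780, 0.000042, 0.000015, 0.000000), ncol = 4, byrow = TRUE)
  colnames(m) <- c("wavelength", "xbar", "ybar", "zbar")
  m
})

#' Construct a spectral power distribution
#'
#' Bundles a sampled radiometric measurement (as produced by a spectral
#' radiometer) into a validated object: wavelengths in nanometres, strictly
#' increasing, paired with non-negative spectral power.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing,
#'   all within \[360, 830\].
#' @param power Numeric vector of non-negative power values, same length.
#' @return An object of class `"spd"`: a list with elements `wavelength` and
#'   `power`.
#' @examples
#' s <- spd(seq(380, 780, by = 5), rep(1, 81))
#' spd_to_tristimulus(s)
#' @export
spd <- function(wavelength, power) {
  wavelength <- as.numeric(wavelength)
  power <- as.numeric(power)
  if (length(wavelength) != length(power))
    stop("wavelength and power must have equal length")
  if (length(wavelength) < 2L)
    stop("an SPD needs at least 2 samples")
  if (anyNA(wavelength) || anyNA(power))
    stop("SPD contains missing values")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(wavelength < 360 | wavelength > 830))
    stop("wavelengths must lie within [360, 830] nm")
  if (any(power < 0))
    stop("spectral power must be non-negative")
  structure(list(wavelength = wavelength, power = power), class = "spd")
}

#' Read an SPD from a two-column delimited text file
#'
#' Expects a header line naming the columns `wavelength_nm` and `power`.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, default comma.
#' @return An `"spd"` object.
#' @export
read_spd <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("wavelength_nm", "power")
  if (!all(need %in% names(d)))
    stop("SPD file must have columns: ", paste(need, collapse = ", "))
  spd(d$wavelength_nm, d$power)
}

#' Integrate an SPD against the CIE 1931 color-matching functions
#'
#' Computes CIE 1931 XYZ tristimulus values by rectangular integration on the
#' SPD's own sampling grid, with the 2-degree color-matching functions
#' linearly interpolated onto that grid. The rectangle width is the SPD's
#' median sampling step, so a radiometer's native discretisation is honoured
#' rather than resampled.
#'
#' @param s An `"spd"` object.
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
spd_to_tristimulus <- function(s) {
  if (!inherits(s, "spd")) s <- spd(s$wavelength, s$power)
  if (all(s$power == 0))
    stop("degenerate measurement: spectral power is zero everywhere")
  cmf <- .cie1931_cmf
  rng <- range(cmf[, "wavelength"])
  if (any(s$wavelength < rng[1] | s$wavelength > rng[2]))
    stop("SPD wavelengths fall outside the CMF support [",
         rng[1], ", ", rng[2], "] nm")
  xb <- stats::approx(cmf[, "wavelength"], cmf[, "xbar"], s$wavelength)$y
  yb <- stats::approx(cmf[, "wavelength"], cmf[, "ybar"], s$wavelength)$y
  zb <- stats::approx(cmf[, "wavelength"], cmf[, "zbar"], s$wavelength)$y
  dl <- stats::median(diff(s$wavelength))
  c(X = sum(s$power * xb) * dl,
    Y = sum(s$power * yb) * dl,
    Z = sum(s$power * zb) * dl)
}

#' CIE 1976 u'v' chromaticity from tristimulus values
#'
#' Uses u' = 4X / (X + 15Y + 3Z) and v' = 9Y / (X + 15Y + 3Z); the luminance
#' Y is carried through unchanged. The result is scale-invariant in (X, Y, Z).
#'
#' @param xyz Named or positional numeric vector `c(X, Y, Z)`.
#' @return Named numeric vector `c(u, v, Y)`.
#' @examples
#' tristimulus_to_chromaticity(c(1, 1, 1))  # u = 4/19, v = 9/19
#' @export
tristimulus_to_chromaticity <- function(xyz) {
  xyz <- as.numeric(xyz)
  if (length(xyz) != 3L || anyNA(xyz) || any(!is.finite(xyz)))
    stop("tristimulus must be three finite numbers")
  den <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  if (den <= 0)
    stop("undefined chromaticity: X + 15Y + 3Z must be positive")
  c(u = 4 * xyz[1] / den, v = 9 * xyz[2] / den, Y = xyz[2])
}

#' Euclidean distance in the u'v' chromaticity plane
#'
#' Luminance, if present, is ignored: the pipeline discards luminance in all
#' analyses.
#'
#' @param a,b Numeric vectors whose first two elements (or elements named
#'   `u`, `v`) are chromaticity coordinates.
#' @return Non-negative scalar distance.
#' @export
uv_distance <- function(a, b) {
  a <- .uv(a); b <- .uv(b)
  sqrt(sum((a - b)^2))
}

# extract the (u, v) pair from a vector, list or one-row data frame
.uv <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(c(x$u, x$v))
  }
  if (is.list(x)) return(c(x$u, x$v))
  x <- as.numeric(if (!is.null(names(x)) && all(c("u", "v") %in% names(x)))
    x[c("u", "v")] else x[1:2])
  if (length(x) != 2L || anyNA(x)) stop("not a chromaticity")
  x
}

#' Planckian (blackbody) spectral power distribution
#'
#' Spectral radiance of an ideal blackbody at temperature `temp_K`, sampled on
#' the given wavelength grid and normalised to unit peak. Used to model
#' incandescent-like booth illuminants by correlated color temperature.
#'
#' @param temp_K Temperature in kelvin.
#' @param wavelength Sampling grid in nm (default 380-780 at 5 nm).
#' @return An `"spd"` object.
#' @export
planck_spd <- function(temp_K, wavelength = seq(380, 780, by = 5)) {
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23
  lam <- wavelength * 1e-9
  rad <- (2 * h * c0^2 / lam^5) / (exp(h * c0 / (lam * kB * temp_K)) - 1)
  spd(wavelength, rad / max(rad))
}
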