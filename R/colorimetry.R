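## CIE 1964 10-degree colour-matching functions, tabulated at 5 nm over
## 400-700 nm from the published two-lobe lognormal-Gaussian analytic fits
## (Wyman, Sloan & Shirley, JCGT 2013); approximation error is a few percent,
## and cancels in the k-normalized tristimulus integrals used here.
cmf_x10 <- function(wl) {
  0.398 * exp(-1250 * log((wl + 570.1) / 1014)^2) +
    1.132 * exp(-234 * log((1338 - wl) / 743.5)^2)
}
cmf_y10 <- function(wl) 1.011 * exp(-0.5 * ((wl - 556.1) / 46.14)^2)
cmf_z10 <- function(wl) 2.060 * exp(-32 * log((wl - 265.8) / 180.4)^2)

## CIE standard illuminant D65 relative spectral power, 10 nm table
## (normalized to 100 at 560 nm), linearly interpolated to the 5 nm grid.
D65_10NM <- data.frame(
  wl = seq(400, 700, by = 10),
  s = c(82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86, 115.92,
        108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05, 100.00,
        96.33, 95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70, 80.03,
        80.21, 82.28, 78.28, 69.72, 71.61)
)

#' CIE observer/illuminant tables on the working grid
#'
#' 1964 10-degree colour-matching functions and D65 spectral power on the
#' 400-700 nm, 5 nm grid used throughout (matching the instrument range).
#'
#' @return Data frame `wavelength`, `xbar`, `ybar`, `zbar`, `d65`.
#' @export
cie_tables <- function() {
  wl <- seq(400, 700, by = 5)
  data.frame(
    wavelength = wl,
    xbar = cmf_x10(wl), ybar = cmf_y10(wl), zbar = cmf_z10(wl),
    d65 = stats::approx(D65_10NM$wl, D65_10NM$s, xout = wl)$y
  )
}

#' Construct a reflectance spectrum
#'
#' @param wavelength ascending wavelengths in nm.
#' @param reflectance reflectance fractions; small sensor negatives are
#'   clipped to 0 and values above 1.05 clipped to 1.05, each with a warning.
#' @return Object of class `spectrum` (data frame).
#' @export
reflectance_spectrum <- function(wavelength, reflectance) {
  stopifnot(length(wavelength) == length(reflectance))
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(reflectance < 0)) {
    warning("negative reflectance values clipped to 0")
    reflectance <- pmax(reflectance, 0)
  }
  if (any(reflectance > 1.05)) {
    warning("reflectance values above 1.05 clipped")
    reflectance <- pmin(reflectance, 1.05)
  }
  structure(data.frame(wavelength = wavelength, reflectance = reflectance),
            class = c("spectrum", "data.frame"))
}

#' Resample a spectrum onto the working grid
#'
#' Linear interpolation onto an evenly spaced grid; extrapolation outside the
#' data support is refused.
#'
#' @param s a [reflectance_spectrum()].
#' @param grid target wavelengths (default 400-700 nm, 5 nm step).
#' @return Resampled `spectrum` on `grid`.
#' @export
resample_spectrum <- function(s, grid = seq(400, 700, by = 5)) {
  stopifnot(inherits(s, "spectrum"))
  if (min(grid) < min(s$wavelength) || max(grid) > max(s$wavelength))
    stop("coverage error: spectrum covers ", min(s$wavelength), "-",
         max(s$wavelength), " nm but grid requires ", min(grid), "-",
         max(grid), " nm")
  vals <- stats::approx(s$wavelength, s$reflectance, xout = grid)$y
  reflectance_spectrum(grid, vals)
}

#' Tristimulus XYZ from spectral reflectance
#'
#' Riemann summation of `S(l) R(l) cmf(l) dl` with the normalization
#' `k = 100 / sum(S ybar dl)`, so the perfect reflector has Y = 100 exactly.
#'
#' @param s a [reflectance_spectrum()] on the 5 nm working grid (use
#'   [resample_spectrum()] first if needed).
#' @param tables observer/illuminant tables, default [cie_tables()].
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
reflectance_to_xyz <- function(s, tables = cie_tables()) {
  stopifnot(inherits(s, "spectrum"))
  if (length(s$wavelength) != length(tables$wavelength) ||
      any(s$wavelength != tables$wavelength))
    stop("grid mismatch: resample the spectrum onto the working grid first")
  k <- 100 / sum(tables$d65 * tables$ybar)
  r <- s$reflectance
  c(X = k * sum(tables$d65 * r * tables$xbar),
    Y = k * sum(tables$d65 * r * tables$ybar),
    Z = k * sum(tables$d65 * r * tables$zbar))
}

#' White point of the observer/illuminant pair
#'
#' @param tables observer/illuminant tables, default [cie_tables()].
#' @return Named vector `c(X, Y, Z)` of the perfect reflector.
#' @export
cie_white_point <- function(tables = cie_tables()) {
  reflectance_to_xyz(
    reflectance_spectrum(tables$wavelength, rep(1, nrow(tables))), tables)
}

#' Convert XYZ tristimulus to CIELAB
#'
#' Standard CIE formulas with the piecewise cube-root companding function.
#'
#' @param xyz named or ordered numeric vector `(X, Y, Z)`.
#' @param white white point `(Xn, Yn, Zn)`, default the embedded D65/10-degree
#'   white point.
#' @return Object of class `lab_color`: named vector `c(L, a, b)`.
#' @export
xyz_to_lab <- function(xyz, white = cie_white_point()) {
  if (any(white <= 0)) stop("white point must be positive")
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz[[1]] / white[[1]])
  fy <- f(xyz[[2]] / white[[2]])
  fz <- f(xyz[[3]] / white[[3]])
  structure(c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz)),
            class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("CIELAB: L* = %.2f, a* = %.2f, b* = %.2f\n",
              x[["L"]], x[["a"]], x[["b"]]))
  invisible(x)
}

#' CIELAB from a raw reflectance spectrum
#'
#' Convenience composition: resample, integrate to XYZ, convert to CIELAB.
#'
#' @param s a [reflectance_spectrum()].
#' @return A `lab_color`.
#' @export
spectrum_to_lab <- function(s) {
  tables <- cie_tables()
  xyz <- reflectance_to_xyz(resample_spectrum(s, tables$wavelength), tables)
  xyz_to_lab(xyz, cie_white_point(tables))
}

## coerce a list of lab_color (or a matrix) to an n x 3 matrix
lab_matrix <- function(measurements) {
  if (is.matrix(measurements)) {
    m <- measurements
  } else {
    m <- do.call(rbind, lapply(measurements, function(x) {
      stopifnot(length(x) == 3)
      as.numeric(x)
    }))
  }
  colnames(m) <- c("L", "a", "b")
  m
}

#' Per-swatch mean and SD of repeated colour measurements
#'
#' @param measurements list of `lab_color` objects (or an n x 3 matrix).
#' @return List `mean` (named L/a/b), `sd` (sample SD, n - 1 denominator; 0
#'   when n = 1), `n`.
#' @export
summarize_swatch <- function(measurements) {
  if (length(measurements) == 0) stop("empty measurement list")
  m <- lab_matrix(measurements)
  sds <- if (nrow(m) > 1) apply(m, 2, stats::sd) else c(L = 0, a = 0, b = 0)
  list(mean = colMeans(m), sd = sds, n = nrow(m))
}

#' Box-plot statistics for a reference colour population
#'
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7, the R plotting convention); whiskers extend to
#' the most extreme points within 1.5 IQR of the quartiles, and points beyond
#' are outliers.
#'
#' @param samples list of `lab_color` objects (or an n x 3 matrix), n >= 4.
#' @return Named list per channel (`L`, `a`, `b`), each with `median`, `p25`,
#'   `p75`, `iqr`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
reference_population_stats <- function(samples) {
  m <- lab_matrix(samples)
  if (nrow(m) < 4)
    stop("insufficient-sample: need >= 4 reference samples")
  out <- lapply(c(L = "L", a = "a", b = "b"), function(ch) {
    x <- m[, ch]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    lo_lim <- qs[1] - 1.5 * iqr
    hi_lim <- qs[3] + 1.5 * iqr
    inside <- x >= lo_lim & x <= hi_lim
    list(median = qs[2], p25 = qs[1], p75 = qs[3], iqr = iqr,
         whisker_low = min(x[inside]), whisker_high = max(x[inside]),
         outliers = x[!inside])
  })
  out
}
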