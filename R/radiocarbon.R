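# Radiocarbon arithmetic: collagen/amino-acid quality-control ratios,
# fraction-modern conversion, and single-date calibration against a
# tabulated curve with highest-posterior-density calendar ranges.

#' Theoretical atomic C:N ratio from a molecular formula
#'
#' Parses a molecular formula (element symbols with optional counts,
#' e.g. `"C5H9NO3"` for hydroxyproline) and returns the carbon-to-
#' nitrogen atom count ratio used as a purity screen for dated material.
#'
#' @param formula Molecular formula string.
#' @return Numeric C:N ratio.
#' @examples
#' atomic_cn_from_formula("C5H9NO3") # hydroxyproline: 5
#' @export
atomic_cn_from_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula))
    stop("formula must be a non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse molecular formula: ", formula)
  elem <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", toks))
  cnt[is.na(cnt)] <- 1L
  counts <- tapply(cnt, elem, sum)
  nC <- counts["C"]
  nN <- counts["N"]
  if (is.na(nC) || is.na(nN))
    stop("formula must contain both carbon and nitrogen: ", formula)
  unname(nC / nN)
}

#' Atomic C:N ratio from mass percentages
#'
#' Converts elemental mass percentages to the atomic (molar) ratio using
#' standard atomic weights (C 12.011, N 14.007). For collagen the
#' acceptable range is 2.9-3.5; for hydroxyproline the theoretical value
#' is 5.0.
#'
#' @param pC,pN Carbon and nitrogen content, percent by mass (> 0).
#' @return Numeric atomic C:N ratio.
#' @export
atomic_cn_from_percent <- function(pC, pN) {
  if (any(pC <= 0) || any(pN <= 0)) stop("pC and pN must be positive")
  (pC / 12.011) / (pN / 14.007)
}

#' Percent yield of extracted material
#'
#' @param extract_mg Extracted mass (mg), >= 0.
#' @param input_mg Starting mass (mg), > 0.
#' @return Yield in percent, reported to one decimal place.
#' @export
percent_yield <- function(extract_mg, input_mg) {
  if (any(input_mg <= 0)) stop("input_mg must be positive")
  if (any(extract_mg < 0)) stop("extract_mg must be non-negative")
  round(100 * extract_mg / input_mg, 1)
}

#' Fraction modern from a conventional radiocarbon age
#'
#' `F14C = exp(-age / 8033)`, using the Libby mean life (8033 years) that
#' defines conventional radiocarbon ages.
#'
#' @param age_bp Conventional radiocarbon age(s) in years BP.
#' @return Fraction-modern value(s).
#' @export
f14c <- function(age_bp) {
  if (any(!is.finite(age_bp))) stop("age_bp must be finite")
  exp(-age_bp / 8033)
}

#' Highest-posterior-density selection on a discrete grid
#'
#' Selects the smallest set of grid points whose total mass reaches `p`,
#' taking points in decreasing density order (ties broken toward older,
#' i.e. larger, grid values), and merges the selection into contiguous
#' ranges.
#'
#' @param density Normalized probability masses (must sum to 1).
#' @param p Target probability in (0, 1).
#' @param grid Grid values (ascending, e.g. cal BP ages); defaults to
#'   indices.
#' @return `data.frame` with one row per contiguous range: `old`
#'   (largest grid value), `young` (smallest), `mass`; rows ordered old
#'   to young.
#' @export
hpd_ranges <- function(density, p, grid = seq_along(density)) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (abs(sum(density) - 1) > 1e-6)
    stop("density must be normalized (sums to ", format(sum(density)), ")")
  ord <- order(density, grid, decreasing = TRUE)
  m <- which(cumsum(density[ord]) >= p - 1e-12)[1]
  sel <- sort(ord[seq_len(m)])
  run_id <- cumsum(c(1L, diff(sel) != 1L))
  ranges <- do.call(rbind, lapply(split(sel, run_id), function(ix) {
    data.frame(old = grid[max(ix)], young = grid[min(ix)],
               mass = sum(density[ix]))
  }))
  ranges <- ranges[order(-ranges$old), , drop = FALSE]
  rownames(ranges) <- NULL
  ranges
}

#' Calibrate a radiocarbon measurement against a curve
#'
#' On a 1-year calendar grid over the curve support, the posterior mass
#' of calendar age `theta` is proportional to
#' `exp(-(age - mu(theta))^2 / (2 * (sigma^2 + tau(theta)^2)))`, with the
#' curve mean `mu` and error `tau` linearly interpolated, under a flat
#' calendar-age prior. The density is normalized on the grid and the HPD
#' ranges at probability `p` are reported with bounds rounded outward to
#' 10 years (older bound up, younger bound down), matching conventional
#' reporting. A warning is issued when non-negligible mass sits at the
#' curve edge (the posterior is then truncated).
#'
#' @param age Conventional radiocarbon age (years BP).
#' @param sigma 1-sigma measurement error (years), > 0.
#' @param curve A `calibration_curve` (see [read_calibration_curve()]).
#' @param p HPD probability (default 0.954, the conventional 2-sigma
#'   level).
#' @return Object of class `calibrated_date`: `grid` (cal BP, ascending),
#'   `density` (normalized), `hpd` (data frame `old`, `young`, `mass`,
#'   rounded outward to 10 years), plus the inputs.
#' @export
calibrate_c14 <- function(age, sigma, curve, p = 0.954) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (sigma <= 0) stop("sigma must be positive")
  if (age > max(curve$c14_bp) || age < min(curve$c14_bp))
    stop("measurement lies outside the calibration curve's 14C range")
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, grid)$y
  tau <- stats::approx(curve$cal_bp, curve$error, grid)$y
  v <- sigma^2 + tau^2
  dens <- exp(-(age - mu)^2 / (2 * v))
  if (sum(dens) == 0) stop("posterior mass underflows on the curve support")
  dens <- dens / sum(dens)
  edge <- max(dens[1], dens[length(dens)])
  if (edge > 1e-6)
    warning("posterior density truncated at the calibration curve edge")
  hpd <- hpd_ranges(dens, p, grid)
  hpd$old <- ceiling(hpd$old / 10) * 10
  hpd$young <- floor(hpd$young / 10) * 10
  structure(list(grid = grid, density = dens, hpd = hpd, p = p,
                 age = age, sigma = sigma),
            class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  cat(sprintf("calibrated date for %s +/- %s BP (%.1f%% HPD):\n",
              format(x$age, big.mark = ","), format(x$sigma), 100 * x$p))
  for (i in seq_len(nrow(x$hpd)))
    cat(sprintf("  %s - %s cal BP (%.1f%%)\n",
                format(x$hpd$old[i], big.mark = ","),
                format(x$hpd$young[i], big.mark = ","),
                100 * x$hpd$mass[i]))
  invisible(x)
}
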