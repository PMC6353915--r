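# Poisson molecular clock: count substitutions private to the specimen's
# lineage and convert them to a divergence time with a fixed per-site
# mutation rate.

#' Count substitutions private to a consensus relative to a root
#'
#' Counts called positions where the consensus differs from the root.
#' When a `panel` is supplied, the count is restricted to positions where
#' the consensus also differs from every panel member (true private
#' substitutions). Positions where either sequence is `N` are
#' uncomparable and excluded; the effective number of comparable sites is
#' returned for use as the clock's site count.
#'
#' @param consensus `consensus_sequence` or character scalar.
#' @param root Root/ancestor sequence of the same length.
#' @param panel Optional named character vector of panel haplotypes.
#' @return List: `k` (count), `positions` (0-based), `L_effective`
#'   (comparable sites), `n_uncomparable`.
#' @export
count_private_substitutions <- function(consensus, root, panel = NULL) {
  cons <- as_consensus_string(consensus)
  rootc <- as_consensus_string(root)
  if (nchar(cons) != nchar(rootc))
    stop("consensus and root differ in length")
  cv <- utf8ToInt(cons)
  rv <- utf8ToInt(rootc)
  if (all(cv == CHR_N)) stop("consensus has no called positions")
  comparable <- cv != CHR_N & rv != CHR_N
  diff <- comparable & cv != rv
  if (!is.null(panel) && length(panel) > 0) {
    L <- nchar(cons)
    if (any(nchar(panel) != L))
      stop("panel haplotypes must have the same length as the consensus")
    pm <- matrix(utf8ToInt(paste(panel, collapse = "")), nrow = L)
    diff <- diff & rowSums(pm == cv) == 0 & rowSums(pm == CHR_N) == 0
  }
  list(k = sum(diff), positions = which(diff) - 1L,
       L_effective = sum(comparable), n_uncomparable = sum(!comparable))
}

#' Divergence time from a private-substitution count
#'
#' Under a Poisson clock with per-site rate `mu` (substitutions per site
#' per year) over `L` comparable sites, the expected number of private
#' substitutions after `t` years is `mu * L * t`. The point estimate is
#' `t = k / (mu * L)`; the interval transforms the exact (Garwood)
#' Poisson confidence bounds on the expected count: `qgamma(a/2, k)` to
#' `qgamma(1 - a/2, k + 1)`, divided by `mu * L`. With `k = 0` the lower
#' bound is 0 and only the upper bound is informative
#' (`-log(a/2) / (mu * L)`). When a rate interval `(mu_lo, mu_hi)` is
#' supplied, the envelope of the count interval over that rate range is
#' also reported.
#'
#' @param k Observed private substitutions (or the list returned by
#'   [count_private_substitutions()], from which `k` and `L` are taken).
#' @param mu Mutation rate in substitutions per site per year.
#' @param L Number of comparable sites.
#' @param conf Confidence level (default 0.95).
#' @param mu_interval Optional length-2 numeric `(mu_lo, mu_hi)`.
#' @return Object of class `divergence_estimate`: `t_hat`, `lower`,
#'   `upper` (years), `k`, `mu`, `L`, `conf`, and `envelope` when a rate
#'   interval was given.
#' @export
divergence_time <- function(k, mu, L = NULL, conf = 0.95, mu_interval = NULL) {
  if (is.list(k)) {
    if (is.null(L)) L <- k$L_effective
    k <- k$k
  }
  if (is.null(L)) stop("L (comparable sites) must be supplied")
  if (mu <= 0 || L <= 0 || k < 0) stop("require mu > 0, L > 0, k >= 0")
  a <- 1 - conf
  rate <- mu * L
  count_lo <- if (k == 0) 0 else stats::qgamma(a / 2, k)
  count_hi <- stats::qgamma(1 - a / 2, k + 1)
  env <- NULL
  if (!is.null(mu_interval)) {
    if (length(mu_interval) != 2 || any(mu_interval <= 0) ||
        mu_interval[1] > mu_interval[2])
      stop("mu_interval must be (mu_lo, mu_hi) with 0 < mu_lo <= mu_hi")
    env <- c(lower = count_lo / (mu_interval[2] * L),
             upper = count_hi / (mu_interval[1] * L))
  }
  structure(list(t_hat = k / rate, lower = count_lo / rate,
                 upper = count_hi / rate, k = k, mu = mu, L = L,
                 conf = conf, envelope = env),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("divergence time: %s years (%d substitutions over %d sites at mu = %.3g)\n",
              format(round(x$t_hat), big.mark = ","), x$k, x$L, x$mu))
  cat(sprintf("  %.0f%% Poisson interval: %s - %s years\n", 100 * x$conf,
              format(round(x$lower), big.mark = ","),
              format(round(x$upper), big.mark = ",")))
  if (!is.null(x$envelope))
    cat(sprintf("  rate-interval envelope: %s - %s years\n",
                format(round(x$envelope["lower"]), big.mark = ","),
                format(round(x$envelope["upper"]), big.mark = ",")))
  invisible(x)
}
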