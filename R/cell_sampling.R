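# Unit-cell volume and length sampling --------------------------------------
#
# Cells are generated volume-first: a volume V is drawn from a configured
# distribution (log-normal fitted to database statistics, or uniform), and
# the three orthorhombic cell lengths are then derived from V under length
# bounds [lmin, lmax] and a maximum adjacent axis ratio r.  This reproduces
# the database volume distribution, which sampling the lengths directly does
# not.

#' Volume distribution specification
#'
#' Describes the distribution the unit-cell volume is drawn from: either
#' log-normal (`V = exp(N(mu, sigma))`, volumes in cubic angstroms) or
#' uniform on `[vmin, vmax]`.
#'
#' @param family `"lognormal"` or `"uniform"`.
#' @param mu,sigma Mean and standard deviation of `ln V` (log-normal family);
#'   `sigma > 0`.
#' @param vmin,vmax Support bounds in cubic angstroms (uniform family);
#'   `0 < vmin < vmax`.
#' @return An object of class `volume_spec`.
#' @export
#' @examples
#' volume_spec("lognormal", mu = 6.04, sigma = 0.394)
#' volume_spec("uniform", vmin = 160, vmax = 1000)
volume_spec <- function(family = c("lognormal", "uniform"),
                        mu = NULL, sigma = NULL, vmin = NULL, vmax = NULL) {
  family <- match.arg(family)
  if (family == "lognormal") {
    check_number(mu, "mu")
    check_number(sigma, "sigma", positive = TRUE)
  } else {
    check_number(vmin, "vmin", positive = TRUE)
    check_number(vmax, "vmax", positive = TRUE)
    if (vmin >= vmax) stop_config("vmin must be < vmax")
  }
  structure(list(family = family, mu = mu, sigma = sigma,
                 vmin = vmin, vmax = vmax),
            class = "volume_spec")
}

#' Cell-length bounds and maximum adjacent ratio
#'
#' @param lmin,lmax Minimum and maximum cell length in angstroms,
#'   `0 < lmin <= lmax`.
#' @param max_ratio Maximum allowed adjacent ratio `r >= 1`: with lengths in
#'   ascending order, `a2/a1 <= r` and `a3/a2 <= r`.
#' @return An object of class `cell_bounds`.
#' @export
#' @examples
#' cell_bounds(4, 10, max_ratio = 3)
cell_bounds <- function(lmin = 4, lmax = 10, max_ratio = 3) {
  check_number(lmin, "lmin", positive = TRUE)
  check_number(lmax, "lmax", positive = TRUE)
  check_number(max_ratio, "max_ratio")
  if (lmin > lmax) stop_config("lmin must be <= lmax")
  if (max_ratio < 1) stop_config("max_ratio must be >= 1")
  structure(list(lmin = lmin, lmax = lmax, max_ratio = max_ratio),
            class = "cell_bounds")
}

#' Sample unit-cell volumes
#'
#' Draws `n` volumes from a [volume_spec()]. Reproducible under
#' [set.seed()].
#'
#' @param spec A [volume_spec()].
#' @param n Number of draws.
#' @return Numeric vector of volumes in cubic angstroms.
#' @export
#' @examples
#' set.seed(1)
#' sample_volume(volume_spec("lognormal", mu = 6.04, sigma = 0.394), 5)
sample_volume <- function(spec, n = 1L) {
  if (!inherits(spec, "volume_spec")) stop_config("spec must be a volume_spec")
  switch(spec$family,
    lognormal = exp(stats::rnorm(n, spec$mu, spec$sigma)),
    uniform = stats::runif(n, spec$vmin, spec$vmax)
  )
}

#' Sample a volume restricted to the feasible range of the cell bounds
#'
#' Resamples from `spec` until the draw lies in `[lmin^3, lmax^3]`
#' (truncated sampling); used by the batch generator so that
#' [cell_from_volume()] never sees an infeasible volume.
#'
#' @inheritParams sample_volume
#' @param bounds A [cell_bounds()].
#' @param max_tries Attempts before giving up (guards against a spec whose
#'   mass lies almost entirely outside the feasible range).
#' @return A single feasible volume.
#' @export
sample_volume_feasible <- function(spec, bounds, max_tries = 10000L) {
  lo <- bounds$lmin^3
  hi <- bounds$lmax^3
  for (i in seq_len(max_tries)) {
    v <- sample_volume(spec, 1L)
    if (v >= lo && v <= hi) return(v)
  }
  stop_domain("no feasible volume drawn in ", max_tries,
              " tries; volume spec barely overlaps [lmin^3, lmax^3]")
}

#' Analytic p.d.f. of the volume of a uniformly sampled orthorhombic cell
#'
#' Density of `V = A1 * A2 * A3` where the `A_i` are independent
#' `U(l, u)` draws. Derived through the log transform: `B_i = ln A_i` has
#' density `e^b / (u - l)` on `[ln l, ln u]`; the sum `C = B1 + B2 + B3`
#' is obtained by convolution, which reduces (after the exponential weights
#' cancel) to the integral of a triangle ("tent") overlap function, so the
#' result here is closed-form:
#' `f_V(v) = Phi(min(2U, c - L)) - Phi(max(2L, c - U))` over `(u - l)^3`,
#' with `c = ln v`, `L = ln l`, `U = ln u` and `Phi` the piecewise
#' antiderivative of the tent of width `U - L` on `[2L, 2U]`.
#'
#' @param v Volume(s), cubic angstroms. Vectorized.
#' @param l,u Cell-length bounds, `0 < l < u`.
#' @return Density values (1 per cubic angstrom cubed, i.e. per unit volume);
#'   zero outside `[l^3, u^3]`.
#' @export
#' @examples
#' pdf_volume_uniform_cells(343, 4, 10)
pdf_volume_uniform_cells <- function(v, l, u) {
  check_number(l, "l", positive = TRUE)
  check_number(u, "u", positive = TRUE)
  if (l >= u) stop_domain("need l < u")
  L <- log(l); U <- log(u); w <- U - L
  mid <- L + U
  # antiderivative of the tent m(s) = w - |s - (L+U)| on [2L, 2U]
  Phi <- function(s) {
    s <- pmin(pmax(s, 2 * L), 2 * U)
    ifelse(s <= mid, (s - 2 * L)^2 / 2, w^2 - (2 * U - s)^2 / 2)
  }
  out <- numeric(length(v))
  ok <- is.finite(v) & v > 0
  cc <- log(pmax(v, .Machine$double.xmin))
  inside <- ok & cc >= 3 * L & cc <= 3 * U
  if (any(inside)) {
    ci <- cc[inside]
    out[inside] <- (Phi(pmin(2 * U, ci - L)) - Phi(pmax(2 * L, ci - U))) /
      (u - l)^3
  }
  pmax(out, 0)
}

#' Analytic c.d.f. matching [pdf_volume_uniform_cells()]
#'
#' Returns a vectorized cumulative distribution function built by
#' high-resolution trapezoidal integration of the closed-form density,
#' suitable for Kolmogorov-Smirnov comparisons against Monte-Carlo samples.
#'
#' @inheritParams pdf_volume_uniform_cells
#' @param n_grid Integration grid size.
#' @return A function `F(v)` returning probabilities.
#' @export
cdf_volume_uniform_cells <- function(l, u, n_grid = 20001L) {
  grid <- seq(l^3, u^3, length.out = n_grid)
  dens <- pdf_volume_uniform_cells(grid, l, u)
  h <- diff(grid)
  cum <- c(0, cumsum(h * (dens[-1] + dens[-n_grid]) / 2))
  cum <- cum / cum[n_grid]   # remove residual quadrature drift (~1e-9)
  function(v) {
    p <- stats::approx(grid, cum, xout = v, yleft = 0, yright = 1,
                       rule = 2)$y
    pmin(pmax(p, 0), 1)
  }
}

#' Derive bounded cell lengths from a sampled volume
#'
#' Produces ascending orthorhombic lengths `(a1, a2, a3)` with
#' `a1*a2*a3 = volume`, each in `[lmin, lmax]`, and adjacent ratios
#' `a2/a1 <= r`, `a3/a2 <= r`. The first two lengths are drawn uniformly
#' within their feasible intervals; the third is fixed by the volume.
#'
#' Bound derivation (ascending order assumed): the largest feasible `a1`
#' is `V^(1/3)` (cube), capped at `lmax`; lower bounds come from
#' `a2 = a3 = lmax` (`V/lmax^2`), the ratio envelope
#' `V <= r^3 a1^3` (`(V/r^3)^(1/3)`), and compatibility of
#' `a2 >= V/(a1 lmax)` with `a2 <= r a1` (`sqrt(V/(r lmax))`, active for
#' volumes between `(lmax/r)^3` and `lmax^3/r`). Given `a1`, `a2` ranges
#' between
#' `max(a1, sqrt(V/(r*a1)), V/(a1*lmax))` and
#' `min(r*a1, lmax, sqrt(V/a1))`; `a3 = V/(a1*a2)` then satisfies all
#' constraints.
#'
#' @param volume Target volume, cubic angstroms; must lie in
#'   `[lmin^3, lmax^3]`.
#' @param bounds A [cell_bounds()].
#' @return Numeric length-3 vector, ascending.
#' @export
#' @examples
#' set.seed(1)
#' cell_from_volume(343, cell_bounds(4, 10, 3))
cell_from_volume <- function(volume, bounds) {
  if (!inherits(bounds, "cell_bounds")) stop_config("bounds must be cell_bounds")
  check_number(volume, "volume", positive = TRUE)
  lmin <- bounds$lmin; lmax <- bounds$lmax; r <- bounds$max_ratio
  if (volume < lmin^3 * (1 - 1e-12))
    stop_domain("volume ", volume, " below lmin^3 = ", lmin^3)
  if (volume > lmax^3 * (1 + 1e-12))
    stop_domain("volume ", volume, " above lmax^3 = ", lmax^3)
  v <- min(max(volume, lmin^3), lmax^3)

  a1_hi <- min(lmax, v^(1 / 3))
  a1_lo <- max(lmin, v / lmax^2, (v / r^3)^(1 / 3), sqrt(v / (r * lmax)))
  if (a1_lo > a1_hi) a1_lo <- a1_hi   # numerically degenerate corner
  a1 <- stats::runif(1, a1_lo, a1_hi)

  a2_lo <- max(a1, sqrt(v / (r * a1)), v / (a1 * lmax))
  a2_hi <- min(r * a1, lmax, sqrt(v / a1))
  if (a2_lo > a2_hi) a2_lo <- a2_hi
  a2 <- stats::runif(1, a2_lo, a2_hi)

  a3 <- v / (a1 * a2)
  out <- c(a1, a2, a3)
  stopifnot(abs(prod(out) / volume - 1) < 1e-9)
  out
}

#' Randomly permute a length triple
#'
#' Ascending order from [cell_from_volume()] would bias any consumer that
#' treats the axes asymmetrically, so lengths are shuffled uniformly over
#' the six permutations.
#'
#' @param lengths Numeric length-3 vector.
#' @return The same multiset in a uniformly random order.
#' @export
permute_lengths <- function(lengths) {
  stopifnot(length(lengths) == 3, all(lengths > 0))
  lengths[sample.int(3L)]
}

#' Sample three independent uniform cell lengths
#'
#' The naive baseline generator: each length an independent
#' `U(lmin, lmax)` draw, no volume or ratio constraint. Used to expose the
#' volume-distribution mismatch against database statistics.
#'
#' @param bounds A [cell_bounds()].
#' @return Numeric length-3 vector.
#' @export
sample_cell_uniform <- function(bounds) {
  stats::runif(3, bounds$lmin, bounds$lmax)
}

#' Fit a log-normal distribution to a sample of volumes
#'
#' Maximum-likelihood estimates: `mu` and `sigma` are the mean and the
#' (population, 1/n) standard deviation of `ln V`.
#'
#' @param volumes Numeric vector of positive volumes, length >= 2, or a
#'   path to a plain-text file with one volume per line.
#' @return Named list `list(mu, sigma)`.
#' @export
#' @examples
#' fit_lognormal(c(100, 120, 400, 380))
fit_lognormal <- function(volumes) {
  if (is.character(volumes) && length(volumes) == 1L) {
    volumes <- scan(volumes, what = numeric(), quiet = TRUE)
  }
  if (!is.numeric(volumes) || length(volumes) < 2L)
    stop_domain("need at least 2 numeric volumes")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop_domain("all volumes must be positive and finite")
  lv <- log(volumes)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))
  list(mu = mu, sigma = sigma)
}
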