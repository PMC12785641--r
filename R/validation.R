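# Ensemble diagnostics: distribution reproduction checks ---------------------
#
# The generator is validated statistically: volume, maximal cell length,
# adjacent axis ratios, monoclinic angle and interatomic-distance histograms
# of a generated ensemble are compared against the target distributions
# (Kolmogorov-Smirnov for continuous marginals, bin-mass contrasts for the
# bonded-peak/trough signature of molecule-like structures).

#' Summarize an ensemble of generated structures
#'
#' @param structures List of `crystal_structure` objects.
#' @param max_dist Radius (angstroms) up to which interatomic distances are
#'   histogrammed (minimum-image convention over expanded cells).
#' @param bin Histogram bin width in angstroms.
#' @return An `ensemble_summary`: volume / max-length / ratio / angle
#'   samples, distance histogram, special-position occupancy counts.
#' @export
summarize_ensemble <- function(structures, max_dist = 5, bin = 0.05) {
  stopifnot(length(structures) >= 1)
  vol <- vapply(structures, function(s) det(s$vectors), numeric(1))
  lens <- t(vapply(structures, function(s) {
    p <- s$parameters
    sort(c(p$a, p$b, p$c))
  }, numeric(3)))
  beta <- vapply(structures, function(s) {
    p <- s$parameters
    max(p$alpha, p$beta, p$gamma)
  }, numeric(1))
  occ <- vapply(structures, function(s) sum(s$atoms$site == "special"),
                numeric(1))
  occ_counts <- c(none = sum(occ == 0), one = sum(occ == 1),
                  more = sum(occ > 1))

  edges <- seq(0, max_dist, by = bin)
  nbins <- length(edges) - 1
  counts <- numeric(nbins)
  for (s in structures) {
    d <- pairwise_min_distances(s, max_dist)
    if (length(d)) {
      idx <- pmin(pmax(ceiling(d / bin), 1L), nbins)
      counts <- counts + tabulate(idx, nbins)
    }
  }
  structure(list(volumes = vol,
                 max_length = lens[, 3],
                 ratio21 = lens[, 2] / lens[, 1],
                 ratio32 = lens[, 3] / lens[, 2],
                 oblique_angle = beta,
                 dist_edges = edges, dist_counts = counts,
                 occupancy = occ_counts,
                 n = length(structures)),
            class = "ensemble_summary")
}

#' All pairwise minimum-image distances of one structure up to a radius
#'
#' Distances between all expanded-cell atom pairs, including each atom's
#' own periodic translates, under the minimum-image convention.
#'
#' @param structure A `crystal_structure`.
#' @param max_dist Cutoff radius, angstroms.
#' @return Numeric vector of distances `<= max_dist`.
#' @export
pairwise_min_distances <- function(structure, max_dist = 5) {
  frac <- expand_to_unit_cell(
    as.matrix(structure$atoms[, c("x", "y", "z")]), structure$group)$frac
  n <- nrow(frac)
  if (n == 0) return(numeric(0))
  tr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- numeric(0)
  for (i in seq_len(n)) {
    js <- i:n
    d0 <- frac[js, , drop = FALSE] - matrix(frac[i, ], length(js), 3,
                                            byrow = TRUE)
    big <- d0[rep(seq_along(js), each = 27), , drop = FALSE] +
      tr[rep(1:27, times = length(js)), , drop = FALSE]
    dd <- sqrt(rowSums((big %*% structure$vectors)^2))
    dd <- dd[dd > 1e-9 & dd <= max_dist]
    out <- c(out, dd)
  }
  out
}

#' Kolmogorov-Smirnov distance
#'
#' Two-sample statistic when `b` is numeric; one-sample when `b` is a
#' vectorized c.d.f. function.
#'
#' @param a Numeric sample.
#' @param b Numeric sample or c.d.f. function.
#' @return Statistic in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  stopifnot(length(a) >= 1)
  if (is.function(b)) ks_stat_cdf(a, b) else ks_stat_two(a, b)
}

#' Check an ensemble's volume distribution against its target spec
#'
#' KS distance between the ensemble volume sample and the target c.d.f.
#' (log-normal or uniform). A uniform-cell-parameter ensemble fails this
#' check against a database-style log-normal spec — the mismatch that
#' motivates volume-first sampling.
#'
#' @param volumes Numeric volume sample (or an `ensemble_summary`).
#' @param spec A [volume_spec()].
#' @param tolerance Pass threshold on the KS statistic.
#' @return List `ks`, `tolerance`, `pass`.
#' @export
check_volume_match <- function(volumes, spec, tolerance = 0.01) {
  if (inherits(volumes, "ensemble_summary")) volumes <- volumes$volumes
  stopifnot(length(volumes) >= 1)
  cdf <- switch(spec$family,
    lognormal = function(v) stats::plnorm(v, spec$mu, spec$sigma),
    uniform = function(v) stats::punif(v, spec$vmin, spec$vmax))
  ks <- ks_distance(volumes, cdf)
  list(ks = ks, tolerance = tolerance, pass = ks < tolerance)
}

#' Bonded-peak / trough contrast of a distance histogram
#'
#' Quantifies the molecule-like signature: mass in the trough window
#' `(1.1 * d_bond, nonbond_factor * d_bond)` relative to the mass in the
#' bonded peak `(0.9 * d_bond, 1.1 * d_bond)`, where `d_bond` defaults to
#' twice the carbon covalent radius.
#'
#' @param summary An `ensemble_summary`.
#' @param d_bond Reference bond length, angstroms.
#' @param nonbond_factor Upper edge factor of the trough window.
#' @return List `peak_mass`, `trough_mass`, `ratio`.
#' @export
trough_contrast <- function(summary, d_bond = 1.52, nonbond_factor = 1.5) {
  mids <- summary$dist_edges[-1] - diff(summary$dist_edges) / 2
  peak <- sum(summary$dist_counts[mids > 0.9 * d_bond &
                                  mids < 1.1 * d_bond])
  trough <- sum(summary$dist_counts[mids > 1.1 * d_bond &
                                    mids < nonbond_factor * d_bond])
  list(peak_mass = peak, trough_mass = trough,
       ratio = if (peak > 0) trough / peak else Inf)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> n = %d structures\n", x$n))
  cat(sprintf("  volume: median %.1f A^3  [%.1f, %.1f]\n",
              stats::median(x$volumes), min(x$volumes), max(x$volumes)))
  cat(sprintf("  max length: median %.2f A; ratios a2/a1 <= %.2f, a3/a2 <= %.2f\n",
              stats::median(x$max_length), max(x$ratio21), max(x$ratio32)))
  cat(sprintf("  oblique angle: median %.2f deg\n",
              stats::median(x$oblique_angle)))
  cat(sprintf("  special-position occupancy: none %d, one %d, >1 %d\n",
              x$occupancy["none"], x$occupancy["one"], x$occupancy["more"]))
  invisible(x)
}
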