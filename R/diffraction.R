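# Structure factors, amplitudes and centrosymmetric phases -------------------
#
# F(hkl) = sum_j f_j(s) T_j(s) exp(2 pi i h.x_j) over the full unit cell.
# With the inversion centre at the origin (P-1) the imaginary part vanishes
# and the phase is exactly 0 or pi, given by the sign of the real part —
# the ground truth a phase-problem solver is trained against.  Dispersion
# corrections are deliberately omitted so phases stay exactly binary.

#' Diffraction configuration
#'
#' @param d_min Resolution cutoff in angstroms (reflections with
#'   `d >= d_min` are kept). Default 1.0.
#' @param completeness Fraction of reflections retained, `(0, 1]`.
#' @param sample_resolution If `TRUE`, each structure draws its own
#'   `d_min ~ U(res_range)` (the original-study mode).
#' @param res_range Range for sampled resolution, angstroms.
#' @param sample_completeness If `TRUE`, each structure draws
#'   `completeness ~ U(comp_range)`.
#' @param comp_range Range for sampled completeness.
#' @param index_cap Maximum absolute Miller index per axis (input-tensor
#'   limit of the downstream network). Default 10.
#' @return An object of class `diffraction_config`.
#' @export
diffraction_config <- function(d_min = 1.0, completeness = 1.0,
                               sample_resolution = FALSE,
                               res_range = c(1.0, 2.0),
                               sample_completeness = FALSE,
                               comp_range = c(0.85, 1.0),
                               index_cap = 10L) {
  check_number(d_min, "d_min", positive = TRUE)
  check_number(completeness, "completeness", positive = TRUE)
  if (completeness > 1) stop_config("completeness must be <= 1")
  structure(list(d_min = d_min, completeness = completeness,
                 sample_resolution = sample_resolution,
                 res_range = res_range,
                 sample_completeness = sample_completeness,
                 comp_range = comp_range,
                 index_cap = as.integer(index_cap)),
            class = "diffraction_config")
}

#' Enumerate the symmetry-unique reflection list
#'
#' All integer triples with `|h|,|k|,|l| <= index_cap` and
#' `d(hkl) >= d_min`, reduced to one Friedel representative per pair
#' (`h > 0`, or `h = 0, k > 0`, or `h = k = 0, l > 0`); (000) excluded.
#' d-spacings come from the reciprocal metric of the (possibly skewed)
#' cell.
#'
#' @param vectors 3x3 cell matrix (rows a, b, c).
#' @param config A [diffraction_config()].
#' @return Data frame with columns `h`, `k`, `l`, `d`.
#' @export
reflection_list <- function(vectors, config = diffraction_config()) {
  cap <- config$index_cap
  g <- expand.grid(h = 0:cap, k = -cap:cap, l = -cap:cap)
  keep <- (g$h > 0) | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0)
  g <- g[keep, ]
  recip <- t(solve(vectors))   # rows a*, b*, c*
  hv <- as.matrix(g) %*% recip
  d <- 1 / sqrt(rowSums(hv^2))
  g$d <- d
  out <- g[g$d >= config$d_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Isotropic Debye-Waller attenuation
#'
#' `exp(-8 pi^2 U (sin(theta)/lambda)^2) = exp(-2 pi^2 U / d^2)`.
#'
#' @param u_iso Isotropic displacement parameter, square angstroms, `>= 0`.
#' @param d d-spacing, angstroms, `> 0`.
#' @return Attenuation factor in `(0, 1]`.
#' @export
#' @examples
#' debye_waller(0.05, 1)
debye_waller <- function(u_iso, d) {
  stopifnot(all(u_iso >= 0), all(d > 0))
  exp(-2 * pi^2 * u_iso / d^2)
}

#' Structure factors with centrosymmetric ground-truth phases
#'
#' Full complex summation over the symmetry-expanded unit cell. For P-1
#' with the inversion at the origin the imaginary part must vanish; this is
#' asserted (tolerance `1e-8` relative to the amplitude scale) and the
#' phase is 0 when `Re F >= 0`, pi otherwise. Amplitudes below `1e-10`
#' get phase 0 by convention.
#'
#' @param structure A `crystal_structure` with `u_iso` assigned.
#' @param reflections Data frame from [reflection_list()]; computed from
#'   the structure's cell when omitted.
#' @param config A [diffraction_config()] (used when `reflections` is
#'   omitted).
#' @param table A [form_factor_table()].
#' @return A `reflection_set` data frame: `h, k, l, d, amplitude, phase`
#'   (phase in radians, 0 or pi).
#' @export
structure_factors <- function(structure, reflections = NULL,
                              config = diffraction_config(),
                              table = form_factor_table()) {
  if (is.null(reflections))
    reflections <- reflection_list(structure$vectors, config)
  atoms <- structure$atoms
  if (any(is.na(atoms$u_iso)))
    stop_config("assign_adps() must run before structure_factors()")
  ex <- expand_to_unit_cell(as.matrix(atoms[, c("x", "y", "z")]),
                            structure$group)
  frac <- ex$frac
  src <- ex$asym_index
  elem <- atoms$element[src]
  u <- atoms$u_iso[src]

  h <- as.matrix(reflections[, c("h", "k", "l")])
  s <- 1 / (2 * reflections$d)            # sin(theta)/lambda
  nr <- nrow(h); na <- nrow(frac)
  re <- numeric(nr); im <- numeric(nr)
  if (na > 0) {
    # per-atom form factor and attenuation on every reflection: build by
    # element to keep it vectorized
    f <- matrix(0, nr, na)
    for (el in unique(elem)) {
      cols <- which(elem == el)
      fe <- scattering_factor(el, s, table)
      f[, cols] <- fe
    }
    tfac <- exp(-2 * pi^2 * outer(1 / reflections$d^2, u))
    phase <- 2 * pi * (h %*% t(frac))
    re <- rowSums(f * tfac * cos(phase))
    im <- rowSums(f * tfac * sin(phase))
  }
  scale <- pmax(1, abs(re))
  if (structure$group$name == "P-1" && any(abs(im) > 1e-8 * scale))
    stop("imaginary part of F did not vanish for a centrosymmetric structure")
  amplitude <- sqrt(re^2 + im^2)
  ph <- ifelse(re >= 0, 0, pi)
  ph[amplitude < 1e-10] <- 0
  out <- data.frame(h = reflections$h, k = reflections$k, l = reflections$l,
                    d = reflections$d, amplitude = amplitude, phase = ph)
  class(out) <- c("reflection_set", "data.frame")
  out
}

#' Randomly thin a reflection set to a target completeness
#'
#' Retains `round(fraction * N)` reflections sampled uniformly without
#' replacement; `fraction = 1` returns the set unchanged (no RNG draw).
#'
#' @param refs A `reflection_set`.
#' @param fraction Completeness in `(0, 1]`.
#' @return Thinned `reflection_set`.
#' @export
apply_completeness <- function(refs, fraction) {
  check_number(fraction, "fraction", positive = TRUE)
  if (fraction > 1) stop_config("fraction must be <= 1")
  if (fraction == 1) return(refs)
  n_keep <- round(fraction * nrow(refs))
  out <- refs[sort(sample.int(nrow(refs), n_keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pack a reflection set into dense amplitude and phase grids
#'
#' Layout over the Friedel hemisphere: arrays of dim
#' `(cap+1, 2*cap+1, 2*cap+1)` indexed `[h+1, k+cap+1, l+cap+1]`.
#' Absent reflections have amplitude 0 (phase 0). Exact inverse:
#' [from_grid()].
#'
#' @param refs A `reflection_set`; all indices must be within the cap.
#' @param config A [diffraction_config()] (supplies `index_cap`).
#' @return List `amplitude`, `phase` of equal-dim arrays.
#' @export
to_grid <- function(refs, config = diffraction_config()) {
  cap <- config$index_cap
  if (nrow(refs) > 0 &&
      (any(refs$h < 0) || any(abs(refs$h) > cap) ||
       any(abs(refs$k) > cap) || any(abs(refs$l) > cap)))
    stop_domain("reflection index outside cap ", cap,
                "; pre-filter the set")
  dims <- c(cap + 1L, 2L * cap + 1L, 2L * cap + 1L)
  amp <- array(0, dims)
  ph <- array(0, dims)
  if (nrow(refs) > 0) {
    idx <- cbind(refs$h + 1L, refs$k + cap + 1L, refs$l + cap + 1L)
    amp[idx] <- refs$amplitude
    ph[idx] <- refs$phase
  }
  list(amplitude = amp, phase = ph)
}

#' Unpack grids back into a reflection record table
#'
#' Inverse of [to_grid()]: cells with nonzero amplitude become records.
#'
#' @param grids List `amplitude`, `phase` as produced by [to_grid()].
#' @param config A [diffraction_config()].
#' @return Data frame `h, k, l, amplitude, phase`.
#' @export
from_grid <- function(grids, config = diffraction_config()) {
  cap <- config$index_cap
  nz <- which(grids$amplitude != 0, arr.ind = TRUE)
  out <- data.frame(h = nz[, 1] - 1L, k = nz[, 2] - cap - 1L,
                    l = nz[, 3] - cap - 1L,
                    amplitude = grids$amplitude[nz],
                    phase = grids$phase[nz])
  out[order(out$h, out$k, out$l), , drop = FALSE]
}
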