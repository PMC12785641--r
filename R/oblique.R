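# Oblique (monoclinic / triclinic) cell transforms ---------------------------
#
# Orthorhombic lengths are embedded as a diagonal cell matrix (rows = a, b, c
# in Cartesian coordinates) and skewed by unimodular shears.  The shear
# parameter t maps to the oblique angle through beta = 90 + atan(t); the sign
# convention is fixed so all oblique angles are obtuse (the database-standard
# setting) and t >= 0.

#' Embed orthorhombic cell lengths as lattice vectors
#'
#' @param lengths Numeric length-3 vector of positive cell lengths.
#' @return 3x3 matrix with rows a, b, c (diagonal; determinant = volume).
#' @export
vectors_from_lengths <- function(lengths) {
  stopifnot(length(lengths) == 3, all(is.finite(lengths)), all(lengths > 0))
  diag(as.numeric(lengths))
}

is_orthorhombic <- function(vectors, tol = 1e-9) {
  off <- vectors
  diag(off) <- 0
  all(abs(off) < tol * max(abs(diag(vectors))))
}

#' Monoclinic shear of an orthorhombic cell (b-unique)
#'
#' Unimodular shear: `b` unchanged, `|a|` unchanged, the `c` vector gains a
#' component of length `t*|c|` along `-x`, so `|c'| = |c| * sqrt(1 + t^2)`,
#' the volume is exactly preserved, and the monoclinic angle becomes
#' `beta = 90 + atan(t)` degrees (obtuse setting) with alpha = gamma = 90.
#'
#' @param vectors Orthorhombic (diagonal) 3x3 cell matrix.
#' @param t Shear parameter, `t >= 0`.
#' @return Skewed 3x3 cell matrix.
#' @export
#' @examples
#' skew_monoclinic(vectors_from_lengths(c(4, 7, 10)), tan(35 * pi / 180))
skew_monoclinic <- function(vectors, t) {
  stopifnot(is_orthorhombic(vectors), t >= 0)
  out <- vectors
  out[3, 1] <- out[3, 1] - t * vectors[3, 3]
  out
}

#' Triclinic shear of an orthorhombic cell
#'
#' Lower-triangular unimodular shear with three parameters:
#' `b' = (-t_ab*|b|, |b|, 0)`, `c' = (-t_ac*|c|, -t_bc*|c|, |c|)`.
#' Volume is preserved; with `t_ab = t_bc = 0` this reduces exactly to
#' [skew_monoclinic()] with `t = t_ac`.
#'
#' @param vectors Orthorhombic (diagonal) 3x3 cell matrix.
#' @param t_ab,t_ac,t_bc Non-negative shear parameters.
#' @return Skewed 3x3 cell matrix.
#' @export
skew_triclinic <- function(vectors, t_ab, t_ac, t_bc) {
  stopifnot(is_orthorhombic(vectors), t_ab >= 0, t_ac >= 0, t_bc >= 0)
  out <- vectors
  out[2, 1] <- -t_ab * vectors[2, 2]
  out[3, 1] <- -t_ac * vectors[3, 3]
  out[3, 2] <- -t_bc * vectors[3, 3]
  out
}

#' Skew-angle sampling configuration
#'
#' @param lattice_kind `"orthorhombic"`, `"monoclinic"` or `"triclinic"`.
#' @param beta_max Upper limit of the oblique angle in degrees,
#'   `90 < beta_max < 180`. Default 125.
#' @param t_mode How the shear parameter t is drawn: `"t_uniform"` (uniform
#'   on the feasible interval, pushes angles high), `"t_uniform_adjusted"`
#'   (reflected uniform concentrating mass near 90 degrees) or
#'   `"t_exponential"` (truncated exponential; best match to database angle
#'   statistics, the default).
#' @param rate Rate of the exponential mode. The default `log(2)/tan(5 deg)`
#'   puts the untruncated median of the induced angle at ~95 degrees.
#' @param kappa Reflection fraction of the adjusted-uniform mode (the lower
#'   sampling bound is `-kappa * t_hi`, negatives mapped to 0).
#' @param length_preserving If `TRUE`, skewed cells keep the orthorhombic
#'   lengths (volume changes) instead of the volume-preserving shear.
#' @return An object of class `skew_config`.
#' @export
skew_config <- function(lattice_kind = c("triclinic", "monoclinic",
                                         "orthorhombic"),
                        beta_max = 125,
                        t_mode = c("t_exponential", "t_uniform",
                                   "t_uniform_adjusted"),
                        rate = log(2) / tan(5 * pi / 180),
                        kappa = 0.5,
                        length_preserving = FALSE) {
  lattice_kind <- match.arg(lattice_kind)
  t_mode <- match.arg(t_mode)
  check_number(beta_max, "beta_max")
  if (beta_max <= 90 || beta_max >= 180)
    stop_config("beta_max must be in (90, 180) degrees")
  check_number(rate, "rate", positive = TRUE)
  check_number(kappa, "kappa")
  structure(list(lattice_kind = lattice_kind, beta_max = beta_max,
                 t_mode = t_mode, rate = rate, kappa = kappa,
                 length_preserving = length_preserving),
            class = "skew_config")
}

#' Sample the shear parameter t
#'
#' The upper limit combines the angle cap and, when the skewed length must
#' stay within bounds, the headroom of the skewed axis:
#' `t_hi = min(tan(beta_max - 90), sqrt((lmax/c_len)^2 - 1))`.
#'
#' @param config A [skew_config()].
#' @param c_len Length of the axis being skewed (angstroms); must not
#'   exceed `bounds$lmax`.
#' @param bounds A [cell_bounds()].
#' @return A single draw `t >= 0`.
#' @export
sample_skew_t <- function(config, c_len, bounds) {
  if (c_len > bounds$lmax * (1 + 1e-12))
    stop_domain("skewed axis length ", c_len, " exceeds lmax = ", bounds$lmax)
  t_angle <- tan((config$beta_max - 90) * pi / 180)
  t_len <- sqrt(max((bounds$lmax / c_len)^2 - 1, 0))
  t_hi <- min(t_angle, t_len)
  if (t_hi <= 0) return(0)
  switch(config$t_mode,
    t_uniform = stats::runif(1, 0, t_hi),
    t_uniform_adjusted = max(stats::runif(1, -config$kappa * t_hi, t_hi), 0),
    t_exponential = {
      # inverse-cdf draw from Exp(rate) truncated to [0, t_hi]
      u <- stats::runif(1)
      -log(1 - u * (1 - exp(-config$rate * t_hi))) / config$rate
    }
  )
}

#' Build lattice vectors from cell parameters (lengths preserved)
#'
#' Standard crystallographic construction: a along x, b in the xy-plane.
#' Output lengths equal the inputs exactly; the volume is
#' `abc * sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param lengths Numeric length-3 vector `(a, b, c)` in angstroms.
#' @param angles Numeric length-3 vector `(alpha, beta, gamma)` in degrees.
#' @return 3x3 cell matrix with rows a, b, c.
#' @export
apply_length_preserving <- function(lengths, angles) {
  stopifnot(length(lengths) == 3, all(lengths > 0), length(angles) == 3,
            all(angles > 0), all(angles < 180))
  ca <- cos(angles[1] * pi / 180)
  cb <- cos(angles[2] * pi / 180)
  cg <- cos(angles[3] * pi / 180)
  sg <- sin(angles[3] * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0)
    stop_domain("angles (", paste(angles, collapse = ", "),
                ") give a non-positive-definite metric")
  a <- lengths[1]; b <- lengths[2]; cl <- lengths[3]
  rbind(c(a, 0, 0),
        c(b * cg, b * sg, 0),
        c(cl * cb, cl * (ca - cb * cg) / sg, cl * sqrt(v2) / sg))
}

#' Cell parameters (lengths and angles) from lattice vectors
#'
#' @param vectors 3x3 cell matrix with rows a, b, c; determinant must be
#'   positive (right-handed).
#' @return Named list `a, b, c` (angstroms) and `alpha, beta, gamma`
#'   (degrees).
#' @export
parameters_from_vectors <- function(vectors) {
  stopifnot(is.matrix(vectors), all(dim(vectors) == c(3, 3)),
            all(is.finite(vectors)))
  if (det(vectors) <= 0) stop_domain("cell matrix must be right-handed")
  n <- sqrt(rowSums(vectors^2))
  ang <- function(i, j)
    acos(sum(vectors[i, ] * vectors[j, ]) / (n[i] * n[j])) * 180 / pi
  list(a = n[1], b = n[2], c = n[3],
       alpha = ang(2, 3), beta = ang(1, 3), gamma = ang(1, 2))
}

#' Apply the configured skew pipeline to orthorhombic lengths
#'
#' Dispatches on `lattice_kind`: orthorhombic returns the diagonal
#' embedding; monoclinic draws one t for the c axis; triclinic draws three
#' independent t parameters (shared `beta_max` interpreted per axis). In
#' `length_preserving` mode the induced angles are recomputed onto the
#' original lengths.
#'
#' @param lengths Numeric length-3 vector (already permuted).
#' @param config A [skew_config()].
#' @param bounds A [cell_bounds()].
#' @return 3x3 cell matrix.
#' @export
apply_skew <- function(lengths, config, bounds) {
  vec <- vectors_from_lengths(lengths)
  skewed <- switch(config$lattice_kind,
    orthorhombic = vec,
    monoclinic = skew_monoclinic(vec, sample_skew_t(config, lengths[3], bounds)),
    triclinic = {
      t_ab <- sample_skew_t(config, lengths[2], bounds)
      t_ac <- sample_skew_t(config, lengths[3], bounds)
      # remaining headroom of the c axis after the first shear component,
      # so |c'| = |c| sqrt(1 + t_ac^2 + t_bc^2) stays within lmax
      c_eff <- lengths[3] * sqrt(1 + t_ac^2)
      t_bc <- sample_skew_t(config, min(c_eff, bounds$lmax), bounds)
      skew_triclinic(vec, t_ab, t_ac, t_bc)
    }
  )
  if (isTRUE(config$length_preserving) &&
      config$lattice_kind != "orthorhombic") {
    p <- parameters_from_vectors(skewed)
    skewed <- apply_length_preserving(lengths, c(p$alpha, p$beta, p$gamma))
  }
  skewed
}
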