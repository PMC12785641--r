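# Space groups P1 and P-1, special positions, periodic distances -------------

#' Construct a space-group object
#'
#' Only the two triclinic groups are first-class: P1 (identity) and P-1
#' (identity + inversion through the origin). Operators are stored as
#' `(W, w)` pairs acting on fractional coordinates as `W x + w (mod 1)`.
#'
#' For P-1 the default ships four inversion-centre special positions,
#' (0,0,0), (1/2,0,0), (0,1/2,0), (0,0,1/2) — the count used by the
#' occupancy statistics this generator is calibrated to. Crystallographically
#' P-1 has eight distinct inversion centres (all 0/1/2 combinations);
#' set `full_centers = TRUE` to get all eight.
#'
#' @param name `"P-1"` (default) or `"P1"`.
#' @param full_centers For P-1, use all eight inversion centres instead of
#'   the default four.
#' @return An object of class `space_group` with fields `name`, `ops`
#'   (list of `list(W, w)`), `special_positions` (matrix, one row per
#'   position) and `n_ops`.
#' @export
#' @examples
#' sg <- space_group("P-1")
#' sg$n_ops
space_group <- function(name = c("P-1", "P1"), full_centers = FALSE) {
  name <- match.arg(name)
  id <- list(W = diag(3), w = c(0, 0, 0))
  if (name == "P1") {
    ops <- list(id)
    sp <- matrix(numeric(0), ncol = 3)
  } else {
    ops <- list(id, list(W = -diag(3), w = c(0, 0, 0)))
    if (full_centers) {
      g <- as.matrix(expand.grid(c(0, .5), c(0, .5), c(0, .5)))
      dimnames(g) <- NULL
      sp <- g
    } else {
      sp <- rbind(c(0, 0, 0), c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5))
    }
  }
  structure(list(name = name, ops = ops, special_positions = sp,
                 n_ops = length(ops)),
            class = "space_group")
}

#' Symmetry operator strings for CIF output
#' @param group A [space_group()].
#' @return Character vector like `c("x,y,z", "-x,-y,-z")`.
#' @export
operator_strings <- function(group) {
  vapply(group$ops, function(op) {
    ax <- c("x", "y", "z")
    parts <- vapply(1:3, function(i) {
      terms <- character(0)
      for (j in 1:3) {
        w <- op$W[i, j]
        if (w == 1) terms <- c(terms, ax[j])
        else if (w == -1) terms <- c(terms, paste0("-", ax[j]))
        else if (w != 0) terms <- c(terms, paste0(w, "*", ax[j]))
      }
      s <- paste(terms, collapse = "+")
      s <- gsub("\\+-", "-", s)
      if (op$w[i] != 0) s <- paste0(s, "+", op$w[i])
      s
    }, character(1))
    paste(parts, collapse = ",")
  }, character(1))
}

#' Sample which special positions are occupied
#'
#' Each listed special position of the group is independently occupied with
#' probability `p`. At `p = 0.05` and four positions this yields roughly
#' 81.4% of structures with no special position occupied, 17.2% with one,
#' and 1.4% with more than one.
#'
#' @param p Occupancy probability in `[0, 1]`.
#' @param group A [space_group()].
#' @return Integer vector of occupied special-position row indices
#'   (possibly empty).
#' @export
sample_special_occupancy <- function(p, group) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_config("p must be a probability in [0, 1]")
  n <- nrow(group$special_positions)
  if (n == 0L) return(integer(0))
  which(stats::runif(n) < p)
}

#' Expand asymmetric-unit atoms over the space group
#'
#' Applies every operator, wraps to `[0, 1)` and removes duplicate images
#' (fixed points of the inversion produce one image, general positions two
#' in P-1).
#'
#' @param frac Matrix of fractional coordinates (one atom per row), values
#'   in `[0, 1)`.
#' @param group A [space_group()].
#' @param tol Duplicate tolerance in fractional units.
#' @return List with `frac` (expanded coordinate matrix) and `asym_index`
#'   (integer vector mapping each image back to its source row).
#' @export
expand_to_unit_cell <- function(frac, group, tol = 1e-6) {
  frac <- rbind(frac)
  n <- nrow(frac)
  out <- vector("list", length(group$ops))
  for (k in seq_along(group$ops)) {
    op <- group$ops[[k]]
    out[[k]] <- wrap_frac(frac %*% t(op$W) +
                          matrix(op$w, n, 3, byrow = TRUE))
  }
  all_frac <- do.call(rbind, out)
  idx <- rep(seq_len(n), times = length(group$ops))
  # drop duplicate images of the same source atom (special positions),
  # comparing on the torus
  keep <- rep(TRUE, nrow(all_frac))
  for (i in seq_len(n)) {
    rows <- which(idx == i)
    if (length(rows) < 2) next
    for (r in rows[-1]) {
      for (q in rows[rows < r]) {
        if (!keep[q]) next
        d <- abs(all_frac[r, ] - all_frac[q, ])
        d <- pmin(d, 1 - d)
        if (all(d < tol)) { keep[r] <- FALSE; break }
      }
    }
  }
  list(frac = all_frac[keep, , drop = FALSE], asym_index = idx[keep])
}

# 27 lattice translations (-1, 0, 1)^3, one row each
.translations27 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

#' Minimum-image distance between two fractional positions
#'
#' Shortest Cartesian distance over the 27 lattice translations of the
#' second position. Sufficient whenever the distances of interest are below
#' half the shortest cell height (see [min_cell_height()]); for extremely
#' oblique cells widen `shells`.
#'
#' @param x1,x2 Fractional coordinate triples.
#' @param vectors 3x3 cell matrix (rows a, b, c).
#' @param shells Search half-width in unit cells (1 = 27 images).
#' @return Distance in angstroms.
#' @export
min_image_distance <- function(x1, x2, vectors, shells = 1L) {
  if (shells == 1L) {
    tr <- .translations27
  } else {
    s <- -shells:shells
    tr <- as.matrix(expand.grid(s, s, s))
  }
  d <- matrix(x2 - x1, nrow(tr), 3, byrow = TRUE) + tr
  cart <- d %*% vectors
  sqrt(min(rowSums(cart^2)))
}

#' Shortest perpendicular height of a unit cell
#'
#' The minimum over the three face-to-face distances `V / |area|`; half of
#' this is the safe radius for the 27-image minimum-distance search.
#'
#' @param vectors 3x3 cell matrix.
#' @return Height in angstroms.
#' @export
min_cell_height <- function(vectors) {
  v <- abs(det(vectors))
  cr <- function(i, j) {
    u <- vectors[i, ]; w <- vectors[j, ]
    c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
      u[1] * w[2] - u[2] * w[1])
  }
  areas <- c(sqrt(sum(cr(2, 3)^2)), sqrt(sum(cr(1, 3)^2)),
             sqrt(sum(cr(1, 2)^2)))
  min(v / areas)
}

# Vectorized candidate-contact helper: minimum-image distances from one
# fractional point to every row of a fractional coordinate matrix.
min_image_distances_to_set <- function(x, set_frac, vectors, shells = 1L) {
  if (nrow(set_frac) == 0L) return(numeric(0))
  if (shells == 1L) {
    tr <- .translations27
  } else {
    s <- -shells:shells
    tr <- as.matrix(expand.grid(s, s, s))
  }
  n <- nrow(set_frac)
  m <- nrow(tr)
  d0 <- set_frac - matrix(x, n, 3, byrow = TRUE)
  # n*m rows: each set atom under each translation
  big <- d0[rep(seq_len(n), each = m), , drop = FALSE] +
    tr[rep(seq_len(m), times = n), , drop = FALSE]
  cart <- big %*% vectors
  dist2 <- rowSums(cart^2)
  sqrt(apply(matrix(dist2, nrow = m), 2, min))
}
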