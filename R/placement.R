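# Filling the unit cell with atoms -------------------------------------------
#
# Two placement algorithms share the same contact bookkeeping:
#
#  * uniform mode — every atom's fractional coordinates are drawn uniformly
#    and rejected unless all periodic/symmetry-image distances to atoms
#    already present are >= d_min_contact (10 coordinate tries, then the
#    atom is discarded);
#
#  * molecule mode — "artificial molecules": after special positions, a seed
#    atom is placed, and every further atom is bonded to a randomly chosen
#    parent at a bond length drawn from a window around the summed covalent
#    radii, subject to the dichotomy that every pairwise distance is either
#    inside that pair's bond window or beyond nonbond_factor times the
#    summed radii (20 tries, then a different element, then discard).
#
# Both checks include each candidate's own periodic translates and (in P-1,
# for general sites) its own inversion image, so an atom cannot sit too
# close to an inversion centre or to a short cell edge for its radius.

#' Contact rules for atom placement
#'
#' @param d_min_contact Minimum interatomic distance in uniform mode
#'   (angstroms). Default 1.2.
#' @param bond_window Multipliers `(low, high)` of the summed covalent radii
#'   defining a covalent bond.
#' @param nonbond_factor Non-bonded atoms must be separated by at least this
#'   multiple of their summed covalent radii (molecule mode).
#' @param max_coord_retries Coordinate draws per atom in uniform mode.
#' @param max_growth_retries Placement attempts per element in molecule mode.
#' @return An object of class `placement_rules`.
#' @export
placement_rules <- function(d_min_contact = 1.2,
                            bond_window = c(0.9, 1.1),
                            nonbond_factor = 1.5,
                            max_coord_retries = 10L,
                            max_growth_retries = 20L) {
  check_number(d_min_contact, "d_min_contact", positive = TRUE)
  stopifnot(length(bond_window) == 2, bond_window[1] > 0,
            bond_window[1] < bond_window[2],
            nonbond_factor > bond_window[2],
            max_coord_retries >= 1, max_growth_retries >= 1)
  structure(list(d_min_contact = d_min_contact,
                 bond_low = bond_window[1], bond_high = bond_window[2],
                 nonbond_factor = nonbond_factor,
                 max_coord_retries = as.integer(max_coord_retries),
                 max_growth_retries = as.integer(max_growth_retries)),
            class = "placement_rules")
}

#' Content budget for one unit cell
#'
#' The non-hydrogen atom count of the asymmetric unit follows from the
#' average available volume per non-hydrogen atom,
#' `n_nonh = round(V / (n_ops * v_atom))` (floored at 1), with
#' `v_atom ~ U(7, 22)` cubic angstroms covering the database density range.
#' The hydrogen count follows from the hydrogen mole fraction
#' `x_h ~ U(0.3, 0.6)`: `n_h = round(n_nonh * x_h / (1 - x_h))`.
#'
#' @param volume Unit-cell volume in cubic angstroms.
#' @param group A [space_group()] (supplies the operator count).
#' @param v_atom_range,x_h_range Uniform sampling ranges.
#' @return List `v_atom`, `x_h`, `n_nonh`, `n_h` of class `content_budget`.
#' @export
#' @examples
#' set.seed(1)
#' sample_budget(800, space_group("P-1"))
sample_budget <- function(volume, group, v_atom_range = c(7, 22),
                          x_h_range = c(0.3, 0.6)) {
  check_number(volume, "volume", positive = TRUE)
  v_atom <- stats::runif(1, v_atom_range[1], v_atom_range[2])
  n_nonh <- max(round(volume / (group$n_ops * v_atom)), 1L)
  x_h <- stats::runif(1, x_h_range[1], x_h_range[2])
  n_h <- round(n_nonh * x_h / (1 - x_h))
  structure(list(v_atom = v_atom, x_h = x_h,
                 n_nonh = as.integer(n_nonh), n_h = as.integer(n_h)),
            class = "content_budget")
}

#' Uniform point on a sphere
#'
#' Direction from a normalized 3-variate standard Gaussian (Muller method),
#' scaled to the requested radius.
#'
#' @param center Cartesian centre (length-3, angstroms).
#' @param radius Sphere radius, `> 0`.
#' @return Cartesian point at exactly `radius` from `center`.
#' @export
sample_sphere_point <- function(center = c(0, 0, 0), radius) {
  check_number(radius, "radius", positive = TRUE)
  repeat {
    g <- stats::rnorm(3)
    n <- sqrt(sum(g^2))
    if (n > 1e-12) break
  }
  center + radius * g / n
}

# --- internal placement state ----------------------------------------------

new_placement_state <- function(vectors, group) {
  e <- new.env(parent = emptyenv())
  e$vectors <- vectors
  e$vinv <- solve(vectors)
  e$group <- group
  e$frac <- matrix(numeric(0), ncol = 3)   # expanded images
  e$rad <- numeric(0)                      # radius per image
  e$elem <- character(0)                   # asymmetric-unit atoms:
  e$asym_frac <- matrix(numeric(0), ncol = 3)
  e$site <- character(0)
  e$spidx <- integer(0)
  tr <- .translations27[rowSums(abs(.translations27)) > 0, , drop = FALSE]
  e$self_dists <- sqrt(rowSums((tr %*% vectors)^2))
  e
}

# all periodic-image distances (27 each) from point x to every stored image;
# returns list(dist, rad) aligned
all_contact_distances <- function(state, x, include_inversion, ri) {
  tr <- .translations27
  dist <- numeric(0); rad <- numeric(0)
  n <- nrow(state$frac)
  if (n > 0) {
    d0 <- state$frac - matrix(x, n, 3, byrow = TRUE)
    big <- d0[rep(seq_len(n), each = 27), , drop = FALSE] +
      tr[rep(1:27, times = n), , drop = FALSE]
    dist <- sqrt(rowSums((big %*% state$vectors)^2))
    rad <- rep(state$rad, each = 27)
  }
  # own periodic translates
  dist <- c(dist, state$self_dists)
  rad <- c(rad, rep(ri, length(state$self_dists)))
  # own inversion image (general sites in centrosymmetric groups)
  if (include_inversion && state$group$name == "P-1") {
    inv <- wrap_frac(-x)
    d0 <- matrix(inv - x, 27, 3, byrow = TRUE) + tr
    dd <- sqrt(rowSums((d0 %*% state$vectors)^2))
    dist <- c(dist, dd)
    rad <- c(rad, rep(ri, 27))
  }
  list(dist = dist, rad = rad)
}

contacts_ok_uniform <- function(state, x, rules, is_special) {
  cd <- all_contact_distances(state, x, include_inversion = !is_special,
                              ri = 0)
  all(cd$dist >= rules$d_min_contact)
}

contacts_ok_molecule <- function(state, x, ri, rules, is_special) {
  cd <- all_contact_distances(state, x, include_inversion = !is_special,
                              ri = ri)
  if (length(cd$dist) == 0) return(TRUE)
  sums <- ri + cd$rad
  bonded <- cd$dist >= rules$bond_low * sums &
    cd$dist <= rules$bond_high * sums
  apart <- cd$dist >= rules$nonbond_factor * sums
  all(bonded | apart)
}

add_atom <- function(state, element, x, site, spidx, radius) {
  state$elem <- c(state$elem, element)
  state$asym_frac <- rbind(state$asym_frac, x)
  state$site <- c(state$site, site)
  state$spidx <- c(state$spidx, spidx)
  img <- expand_to_unit_cell(matrix(x, 1), state$group)$frac
  state$frac <- rbind(state$frac, img)
  state$rad <- c(state$rad, rep(radius, nrow(img)))
  invisible(state)
}

# Place sampled special-position atoms; elements from the special table.
# A special atom whose element cannot satisfy the active contact rules
# (e.g. a large metal in a very short cell) is re-drawn a few times and
# skipped if no element fits; skipped positions are logged as shortfall.
place_special_atoms <- function(state, occupied, table_special, rules, mode,
                                radii) {
  skipped <- 0L
  for (idx in occupied) {
    pos <- state$group$special_positions[idx, ]
    placed <- FALSE
    for (try in seq_len(rules$max_coord_retries)) {
      el <- sample_elements(table_special, 1L)
      ok <- if (mode == "uniform")
        contacts_ok_uniform(state, pos, rules, is_special = TRUE)
      else
        contacts_ok_molecule(state, pos, radii[[el]], rules,
                             is_special = TRUE)
      if (ok) {
        add_atom(state, el, pos, "special", idx, radii[[el]])
        placed <- TRUE
        break
      }
    }
    if (!placed) skipped <- skipped + 1L
  }
  skipped
}

finish_structure <- function(state, shortfall) {
  n <- length(state$elem)
  atoms <- data.frame(
    element = state$elem,
    x = if (n) state$asym_frac[, 1] else numeric(0),
    y = if (n) state$asym_frac[, 2] else numeric(0),
    z = if (n) state$asym_frac[, 3] else numeric(0),
    u_iso = rep(NA_real_, n),
    site = state$site,
    special_index = state$spidx,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  structure(list(vectors = state$vectors,
                 parameters = parameters_from_vectors(state$vectors),
                 group = state$group,
                 atoms = atoms,
                 shortfall = shortfall),
            class = "crystal_structure")
}

#' Fill a cell by uniform rejection sampling
#'
#' Non-hydrogen atoms first (elements from the general-position table), then
#' hydrogens, each drawn uniformly in the cell and accepted only if every
#' symmetry/periodic-image distance to previously placed atoms is at least
#' `d_min_contact`. Ten coordinate draws per atom, then the atom is
#' discarded (counted in `shortfall`).
#'
#' @param vectors 3x3 cell matrix.
#' @param group A [space_group()].
#' @param budget A [sample_budget()] result.
#' @param rules A [placement_rules()].
#' @param table General-position [element_table()].
#' @param table_special Special-position [element_table()].
#' @param special_occupied Integer indices of occupied special positions
#'   (from [sample_special_occupancy()]).
#' @param radii Covalent radii vector (used only for special-atom checks in
#'   molecule mode; ignored here beyond bookkeeping).
#' @return A `crystal_structure` (u_iso unset; see [assign_adps()]).
#' @export
place_uniform <- function(vectors, group, budget, rules,
                          table = element_table("general"),
                          table_special = element_table("special"),
                          special_occupied = integer(0),
                          radii = covalent_radii()) {
  state <- new_placement_state(vectors, group)
  shortfall <- place_special_atoms(state, special_occupied, table_special,
                                   rules, "uniform", radii)
  n_special <- sum(state$site == "special")
  n_general <- max(budget$n_nonh - n_special, 0L)

  place_one <- function(element) {
    for (try in seq_len(rules$max_coord_retries)) {
      x <- stats::runif(3)
      if (contacts_ok_uniform(state, x, rules, is_special = FALSE)) {
        add_atom(state, element, x, "general", NA_integer_,
                 radii[[element]])
        return(TRUE)
      }
    }
    FALSE
  }

  for (i in seq_len(n_general)) {
    el <- sample_elements(table, 1L)
    if (!place_one(el)) shortfall <- shortfall + 1L
  }
  for (i in seq_len(budget$n_h)) {
    if (!place_one("H")) shortfall <- shortfall + 1L
  }
  if (shortfall > 0)
    warning(shortfall, " atom(s) discarded after retry exhaustion",
            call. = FALSE)
  finish_structure(state, shortfall)
}

#' Fill a cell by growing an artificial molecule
#'
#' After the special positions, a seed atom is placed at uniform
#' coordinates; every subsequent atom bonds to a randomly selected parent
#' already in the structure at a length drawn uniformly from the bond
#' window of the pair's covalent radii, at a uniformly random direction.
#' Every pairwise distance (symmetry and periodic images included) must be
#' inside that pair's bond window or beyond the non-bond floor. Twenty
#' placement attempts per element, then one different element, then the
#' atom is discarded. The non-hydrogen skeleton is completed before any
#' hydrogen is attached; hydrogens bond only to non-hydrogen parents.
#'
#' @inheritParams place_uniform
#' @return A `crystal_structure` (u_iso unset; see [assign_adps()]).
#' @export
grow_artificial_molecule <- function(vectors, group, budget, rules,
                                     table = element_table("general"),
                                     table_special = element_table("special"),
                                     special_occupied = integer(0),
                                     radii = covalent_radii()) {
  state <- new_placement_state(vectors, group)
  shortfall <- place_special_atoms(state, special_occupied, table_special,
                                   rules, "molecule", radii)
  n_special <- sum(state$site == "special")
  n_general <- max(budget$n_nonh - n_special, 0L)

  # seed atom Z: uniform coordinates, general element pool
  if (n_general > 0) {
    seeded <- FALSE
    for (try in seq_len(5L * rules$max_growth_retries)) {
      el <- sample_elements(table, 1L)
      x <- stats::runif(3)
      if (contacts_ok_molecule(state, x, radii[[el]], rules,
                               is_special = FALSE)) {
        add_atom(state, el, x, "general", NA_integer_, radii[[el]])
        seeded <- TRUE
        break
      }
    }
    if (!seeded) {
      warning("could not place seed atom; structure left with ",
              nrow(state$asym_frac), " atoms", call. = FALSE)
      return(finish_structure(state, shortfall + n_general + budget$n_h))
    }
  }

  # bond one atom of the given element to some parent; TRUE on success
  try_element <- function(element, parent_pool) {
    ri <- radii[[element]]
    for (try in seq_len(rules$max_growth_retries)) {
      pa <- parent_pool[sample.int(length(parent_pool), 1L)]
      ra <- radii[[state$elem[pa]]]
      blen <- stats::runif(1, rules$bond_low * (ra + ri),
                           rules$bond_high * (ra + ri))
      pcart <- as.numeric(state$asym_frac[pa, ] %*% state$vectors)
      cart <- sample_sphere_point(pcart, blen)
      x <- wrap_frac(as.numeric(cart %*% state$vinv))
      if (contacts_ok_molecule(state, x, ri, rules, is_special = FALSE)) {
        add_atom(state, element, x, "general", NA_integer_, ri)
        return(TRUE)
      }
    }
    FALSE
  }

  place_with_ladder <- function(first_element, parent_pool) {
    if (try_element(first_element, parent_pool)) return(TRUE)
    if (first_element != "H") {
      alt <- sample_elements(table, 1L, exclude = first_element)
      if (try_element(alt, parent_pool)) return(TRUE)
    }
    FALSE
  }

  for (i in seq_len(max(n_general - 1L, 0L))) {
    el <- sample_elements(table, 1L)
    pool <- seq_along(state$elem)          # any atom already present
    if (!place_with_ladder(el, pool)) shortfall <- shortfall + 1L
  }
  for (i in seq_len(budget$n_h)) {
    pool <- which(state$elem != "H")       # hydrogens need a heavy parent
    if (length(pool) == 0) { shortfall <- shortfall + 1L; next }
    if (!place_with_ladder("H", pool)) shortfall <- shortfall + 1L
  }
  if (shortfall > 0)
    warning(shortfall, " atom(s) discarded after retry exhaustion",
            call. = FALSE)
  finish_structure(state, shortfall)
}

#' Assign isotropic atomic displacement parameters
#'
#' One structure-level `U ~ U(0.01, 0.1)` square angstroms, plus an
#' individual deviation `delta ~ U(-0.005, 0.005)` per atom, clamped below
#' at 0.001.
#'
#' @param structure A `crystal_structure`.
#' @param u_range,dev_range Uniform sampling ranges in square angstroms.
#' @return The structure with `atoms$u_iso` filled.
#' @export
assign_adps <- function(structure, u_range = c(0.01, 0.1),
                        dev_range = c(-0.005, 0.005)) {
  n <- nrow(structure$atoms)
  if (n == 0) return(structure)
  u0 <- stats::runif(1, u_range[1], u_range[2])
  dev <- stats::runif(n, dev_range[1], dev_range[2])
  structure$atoms$u_iso <- pmax(u0 + dev, 0.001)
  structure
}

#' Replace every element by a single one (equal-atom variant)
#'
#' Geometry, sites and displacement parameters are unchanged; used to build
#' equal-atom training sets.
#'
#' @param structure A `crystal_structure`.
#' @param element Replacement element symbol (default `"C"`).
#' @return Modified structure.
#' @export
make_equal_atom <- function(structure, element = "C") {
  structure$atoms$element <- rep(element, nrow(structure$atoms))
  structure
}

#' @export
print.crystal_structure <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<crystal_structure> %s  a=%.3f b=%.3f c=%.3f  al=%.2f be=%.2f ga=%.2f\n",
              x$group$name, p$a, p$b, p$c, p$alpha, p$beta, p$gamma))
  cat(sprintf("  volume %.2f A^3, %d asymmetric-unit atoms (%d special)\n",
              det(x$vectors), nrow(x$atoms), sum(x$atoms$site == "special")))
  invisible(x)
}
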