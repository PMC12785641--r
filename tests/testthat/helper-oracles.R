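# Independent oracles used by the test suite.  These deliberately share no
# code with the package implementation: symmetry expansion, supercell scans
# and structure-factor sums are re-derived from first principles here.

# Full-cell fractional coordinates for P1/P-1, coded independently of
# expand_to_unit_cell(): apply identity and (for P-1) inversion, wrap,
# drop coincident images.
oracle_expand <- function(atoms, group_name) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  elem <- atoms$element
  if (group_name == "P-1") {
    inv <- (-xyz) %% 1
    xyz2 <- rbind(xyz, inv)
    elem2 <- c(elem, elem)
    # coincident images of the same source atom collapse to one
    src <- rep(seq_len(nrow(atoms)), 2)
    dup <- duplicated(data.frame(src,
                                 round(xyz2[, 1] %% 1, 6),
                                 round(xyz2[, 2] %% 1, 6),
                                 round(xyz2[, 3] %% 1, 6)))
    list(frac = xyz2[!dup, , drop = FALSE] %% 1, element = elem2[!dup])
  } else {
    list(frac = xyz %% 1, element = elem)
  }
}

# Brute-force all-pairs supercell contact audit. Returns the number of
# rule violations (0 expected).  mode "uniform": every distance >= d_min.
# mode "molecule": every distance either inside the pair's bond window or
# beyond nonbond_factor * (r_i + r_j).
oracle_contact_audit <- function(structure, mode, rules,
                                 radii = covalent_radii(), shells = 2L) {
  ex <- oracle_expand(structure$atoms, structure$group$name)
  n <- nrow(ex$frac)
  if (n < 1) return(0L)
  M <- structure$vectors
  rad <- unname(radii[ex$element])
  s <- -shells:shells
  tr <- as.matrix(expand.grid(s, s, s))
  # pair differences (all ordered pairs incl. self) in fractional coords
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  d0 <- ex$frac[jj, , drop = FALSE] - ex$frac[ii, , drop = FALSE]
  viol <- 0L
  rsum <- rad[ii] + rad[jj]
  for (t in seq_len(nrow(tr))) {
    dd <- sqrt(rowSums((sweep(d0, 2, -tr[t, ]) %*% M)^2))
    sel <- dd > 1e-9   # exclude the self/zero pair
    if (mode == "uniform") {
      viol <- viol + sum(dd[sel] < rules$d_min_contact)
    } else {
      d <- dd[sel]; rs <- rsum[sel]
      ok <- (d >= rules$nonbond_factor * rs) |
        (d >= rules$bond_low * rs & d <= rules$bond_high * rs)
      viol <- viol + sum(!ok)
    }
  }
  viol
}

# Bonded-pair audit for molecule mode: for every general-position
# non-hydrogen-or-hydrogen atom after the first, is there at least one
# neighbour within its bond window (minimum over 27 images)?
oracle_connectivity <- function(structure, rules, radii = covalent_radii()) {
  ex <- oracle_expand(structure$atoms, structure$group$name)
  n <- nrow(ex$frac)
  if (n < 2) return(TRUE)
  M <- structure$vectors
  rad <- unname(radii[ex$element])
  tr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  gen <- which(structure$atoms$site == "general")
  if (length(gen) <= 1) return(TRUE)
  asym <- structure$atoms
  for (i in gen[-1]) {
    x <- as.numeric(asym[i, c("x", "y", "z")])
    ri <- radii[[asym$element[i]]]
    bonded <- FALSE
    for (j in seq_len(n)) {
      d0 <- matrix(ex$frac[j, ] - x, 27, 3, byrow = TRUE) + tr
      dd <- sqrt(rowSums((d0 %*% M)^2))
      dd <- dd[dd > 1e-9]
      rs <- ri + rad[j]
      if (any(dd >= rules$bond_low * rs & dd <= rules$bond_high * rs)) {
        bonded <- TRUE
        break
      }
    }
    if (!bonded) return(FALSE)
  }
  TRUE
}

# Independent centrosymmetric structure-factor route:
# F = sum_asym m_j f_j T_j cos(2 pi h . x_j), m_j = 2 (general) or 1
# (special position).
oracle_cosine_sf <- function(structure, reflections,
                             table = form_factor_table()) {
  atoms <- structure$atoms
  h <- as.matrix(reflections[, c("h", "k", "l")])
  s <- 1 / (2 * reflections$d)
  mult <- ifelse(atoms$site == "special", 1, 2)
  nr <- nrow(h)
  f <- vapply(seq_len(nrow(atoms)), function(j) {
    el <- atoms$element[j]
    row <- table[el, ]
    fj <- row$a1 * exp(-row$b1 * s^2) + row$a2 * exp(-row$b2 * s^2) +
      row$a3 * exp(-row$b3 * s^2) + row$a4 * exp(-row$b4 * s^2) + row$c
    tj <- exp(-8 * pi^2 * atoms$u_iso[j] * s^2)
    arg <- 2 * pi * (h %*% as.numeric(atoms[j, c("x", "y", "z")]))
    mult[j] * fj * tj * cos(arg)
  }, numeric(nr))
  rowSums(matrix(f, nrow = nr))
}

# Minimal independent CIF reader (regex based, shares nothing with
# read_cif): returns cell parameters and the atom table.
oracle_read_cif <- function(path) {
  txt <- readLines(path)
  getnum <- function(tag) {
    ln <- txt[grepl(tag, txt, fixed = TRUE)][1]
    as.numeric(regmatches(ln, regexpr("[0-9]+\\.?[0-9]*$", ln)))
  }
  cell <- c(a = getnum("_cell_length_a"), b = getnum("_cell_length_b"),
            c = getnum("_cell_length_c"), alpha = getnum("_cell_angle_alpha"),
            beta = getnum("_cell_angle_beta"),
            gamma = getnum("_cell_angle_gamma"))
  start <- which(grepl("_atom_site_U_iso_or_equiv", txt, fixed = TRUE)) + 1
  atoms <- NULL
  if (length(start) && start <= length(txt)) {
    rows <- txt[start:length(txt)]
    rows <- rows[grepl("^[A-Za-z]", rows)]
    m <- do.call(rbind, strsplit(trimws(rows), "[[:space:]]+"))
    atoms <- data.frame(element = m[, 2],
                        x = as.numeric(m[, 3]), y = as.numeric(m[, 4]),
                        z = as.numeric(m[, 5]), u = as.numeric(m[, 6]))
  }
  ops <- gsub("^\\s*'|'\\s*$", "",
              txt[grepl("^\\s*'.*,[xyz-]", txt)])
  list(cell = cell, atoms = atoms, ops = ops)
}

# Monte-Carlo sampler for the product of three U(l, u) draws.
oracle_mc_products <- function(n, l, u) {
  runif(n, l, u) * runif(n, l, u) * runif(n, l, u)
}

# Small batch generator shared by placement/acceptance tests.
make_batch <- function(mode, n, seed, ...) {
  cfg <- generator_config(placement_mode = mode, seed = seed, ...)
  lapply(seq_len(n), function(i) generate_structure(cfg, i))
}
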