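# File formats: CIF structures, SHELX-style / TSV reflections, raw grids ----

#' Write a crystal structure as CIF
#'
#' Standard CIF with cell parameters, space-group name and operator
#' strings, and an atom-site loop with fractional coordinates and isotropic
#' U values.
#'
#' @param structure A `crystal_structure`.
#' @param path Destination file.
#' @param data_name CIF data block name.
#' @return The path, invisibly.
#' @export
write_cif <- function(structure, path, data_name = "xtalgen") {
  p <- structure$parameters
  ops <- operator_strings(structure$group)
  lines <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a    %.6f", p$a),
    sprintf("_cell_length_b    %.6f", p$b),
    sprintf("_cell_length_c    %.6f", p$c),
    sprintf("_cell_angle_alpha %.6f", p$alpha),
    sprintf("_cell_angle_beta  %.6f", p$beta),
    sprintf("_cell_angle_gamma %.6f", p$gamma),
    sprintf("_cell_volume      %.6f", det(structure$vectors)),
    sprintf("_space_group_name_H-M_alt '%s'", structure$group$name),
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("  '%s'", ops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_U_iso_or_equiv"
  )
  a <- structure$atoms
  if (nrow(a) > 0) {
    label <- paste0(a$element, seq_len(nrow(a)))
    lines <- c(lines, sprintf("%s %s %.6f %.6f %.6f %.6f",
                              label, a$element, a$x, a$y, a$z, a$u_iso))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a CIF written by [write_cif()]
#'
#' Minimal reader for the subset this package emits (cell, operators, atom
#' loop); not a general CIF parser.
#'
#' @param path CIF file.
#' @return A `crystal_structure` (cell rebuilt from the parameters).
#' @export
read_cif <- function(path) {
  lines <- readLines(path)
  num <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  lens <- c(num("_cell_length_a"), num("_cell_length_b"),
            num("_cell_length_c"))
  angs <- c(num("_cell_angle_alpha"), num("_cell_angle_beta"),
            num("_cell_angle_gamma"))
  sg_line <- grep("_space_group_name_H-M_alt", lines, value = TRUE)[1]
  sg <- gsub(".*'(.*)'.*", "\\1", sg_line)
  vectors <- apply_length_preserving(lens, angs)
  i0 <- grep("_atom_site_U_iso_or_equiv", lines)[1]
  atoms <- data.frame(element = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), u_iso = numeric(0),
                      site = character(0), special_index = integer(0),
                      stringsAsFactors = FALSE)
  if (!is.na(i0) && i0 < length(lines)) {
    rows <- lines[(i0 + 1):length(lines)]
    rows <- rows[nzchar(trimws(rows))]
    parts <- strsplit(trimws(rows), "\\s+")
    atoms <- data.frame(
      element = vapply(parts, `[`, character(1), 2),
      x = as.numeric(vapply(parts, `[`, character(1), 3)),
      y = as.numeric(vapply(parts, `[`, character(1), 4)),
      z = as.numeric(vapply(parts, `[`, character(1), 5)),
      u_iso = as.numeric(vapply(parts, `[`, character(1), 6)),
      site = "general", special_index = NA_integer_,
      stringsAsFactors = FALSE)
  }
  structure(list(vectors = vectors,
                 parameters = parameters_from_vectors(vectors),
                 group = space_group(sg),
                 atoms = atoms, shortfall = NA_integer_),
            class = "crystal_structure")
}

#' Write a reflection set
#'
#' Two dialects: `"shelx"` — fixed-width `%4d%4d%4d%8.2f%8.2f`
#' (h, k, l, amplitude, phase in degrees' place kept in radians here as
#' documented) — and `"tsv"` — tab-separated with a header, full
#' precision.
#'
#' @param refs A `reflection_set`.
#' @param path Destination file.
#' @param dialect `"shelx"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_reflections <- function(refs, path, dialect = c("tsv", "shelx")) {
  dialect <- match.arg(dialect)
  if (dialect == "shelx") {
    if (nrow(refs) > 0 &&
        (any(abs(refs$h) > 999) || any(abs(refs$k) > 999) ||
         any(abs(refs$l) > 999)))
      stop_domain("Miller index exceeds the 4-character SHELX field width")
    lines <- sprintf("%4d%4d%4d%8.2f%8.2f",
                     refs$h, refs$k, refs$l, refs$amplitude, refs$phase)
    writeLines(lines, path)
  } else {
    header <- "h\tk\tl\td\tamplitude\tphase"
    lines <- sprintf("%d\t%d\t%d\t%.17g\t%.17g\t%.17g",
                     refs$h, refs$k, refs$l, refs$d, refs$amplitude,
                     refs$phase)
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

#' Read a reflection file written by [write_reflections()]
#' @param path File path.
#' @param dialect `"tsv"` or `"shelx"`.
#' @return Data frame of reflection records.
#' @export
read_reflections <- function(path, dialect = c("tsv", "shelx")) {
  dialect <- match.arg(dialect)
  if (dialect == "shelx") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    data.frame(
      h = as.integer(substr(lines, 1, 4)),
      k = as.integer(substr(lines, 5, 8)),
      l = as.integer(substr(lines, 9, 12)),
      amplitude = as.numeric(substr(lines, 13, 20)),
      phase = as.numeric(substr(lines, 21, 28)))
  } else {
    utils::read.delim(path)
  }
}

#' Serialize amplitude/phase grids as raw binary with a text header
#'
#' Format: a text header (magic line `xtalgen-grid 1`, `dims` line, `order
#' little-endian float64, amplitude block then phase block`) terminated by
#' a blank line, followed by the two arrays in column-major order as
#' little-endian doubles.
#'
#' @param grids List `amplitude`, `phase` from [to_grid()].
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
write_grid <- function(grids, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0("xtalgen-grid 1\n",
                   "dims ", paste(dim(grids$amplitude), collapse = " "),
                   "\n",
                   "layout column-major float64 little-endian",
                   " amplitude-then-phase\n\n")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(grids$amplitude), con, size = 8, endian = "little")
  writeBin(as.numeric(grids$phase), con, size = 8, endian = "little")
  invisible(path)
}

#' Read grids written by [write_grid()]
#' @param path File path.
#' @return List `amplitude`, `phase`.
#' @export
read_grid <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header ends at the first blank line (double newline)
  nl <- which(raw == as.raw(10))
  blank <- nl[which(diff(nl) == 1)[1] + 1]
  header <- strsplit(rawToChar(raw[1:blank]), "\n")[[1]]
  if (header[1] != "xtalgen-grid 1") stop_domain("not an xtalgen grid file")
  dims <- as.integer(strsplit(header[2], "\\s+")[[1]][-1])
  n <- prod(dims)
  body <- raw[(blank + 1):length(raw)]
  vals <- readBin(body, "numeric", 2 * n, size = 8, endian = "little")
  list(amplitude = array(vals[1:n], dims),
       phase = array(vals[(n + 1):(2 * n)], dims))
}
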