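# Element data: covalent radii, scattering factors, frequency tables --------
#
# All tables ship as plain-text TSV under inst/extdata and can be replaced
# by user files of the same layout.  The frequency tables are documented
# approximations of database statistics: in general positions 89% of
# non-hydrogen atoms are C/N/O, in special positions only 49%, with
# transition metals upweighted there (inversion-symmetric complexes).

.xtalgen_cache <- new.env(parent = emptyenv())

read_two_col <- function(path, value_name) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("element", value_name) %in% names(df)))
    stop_config("table ", path, " must have columns element, ", value_name)
  df
}

#' Covalent radii table (Cordero-style single-bond radii)
#'
#' @param path Optional path to a replacement TSV with columns
#'   `element`, `radius` (angstroms); default uses the bundled table.
#' @return Named numeric vector of radii in angstroms.
#' @export
covalent_radii <- function(path = NULL) {
  if (is.null(path)) {
    key <- "radii_default"
    if (!is.null(.xtalgen_cache[[key]])) return(.xtalgen_cache[[key]])
    path <- system.file("extdata", "covalent_radii.tsv", package = "xtalgen",
                        mustWork = TRUE)
  } else key <- NULL
  df <- read_two_col(path, "radius")
  out <- stats::setNames(df$radius, df$element)
  if (!is.null(key)) .xtalgen_cache[[key]] <- out
  out
}

#' Element frequency table
#'
#' Discrete element distribution for general or special positions.
#' Hydrogen is never listed: hydrogens are budgeted separately and excluded
#' from the skeletal element pool.
#'
#' @param which `"general"` or `"special"`.
#' @param path Optional replacement TSV with columns `element`, `frequency`.
#' @return An object of class `element_table`: list with `elements`,
#'   `probs`.
#' @export
element_table <- function(which = c("general", "special"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    key <- paste0("freq_", which)
    if (!is.null(.xtalgen_cache[[key]])) return(.xtalgen_cache[[key]])
    path <- system.file(
      "extdata", paste0("element_freq_", which, "_synthetic.tsv"),
      package = "xtalgen", mustWork = TRUE)
  } else key <- NULL
  df <- read_two_col(path, "frequency")
  if ("H" %in% df$element)
    stop_config("hydrogen may not appear in an element frequency table")
  if (any(df$frequency < 0)) stop_config("negative frequency")
  if (abs(sum(df$frequency) - 1) > 1e-9)
    stop_config("frequencies must sum to 1 (got ", sum(df$frequency), ")")
  out <- structure(list(elements = df$element, probs = df$frequency),
                   class = "element_table")
  if (!is.null(key)) .xtalgen_cache[[key]] <- out
  out
}

#' Draw elements from a frequency table
#' @param table An [element_table()].
#' @param n Number of draws.
#' @param exclude Elements to exclude (probabilities renormalized).
#' @return Character vector of element symbols.
#' @export
sample_elements <- function(table, n = 1L, exclude = character(0)) {
  keep <- !(table$elements %in% exclude)
  if (!any(keep)) stop_config("exclusion removes every element")
  sample(table$elements[keep], n, replace = TRUE,
         prob = table$probs[keep])
}

#' Four-Gaussian scattering-factor coefficient table
#'
#' International-Tables-style parameterization
#' `f(s) = sum_i a_i exp(-b_i s^2) + c` with `s = sin(theta)/lambda`.
#' `f(0)` equals the element's electron count to within 0.1.
#'
#' @param path Optional replacement TSV (columns `element`,
#'   `a1,b1,...,a4,b4,c`).
#' @return Data frame keyed by element.
#' @export
form_factor_table <- function(path = NULL) {
  if (is.null(path)) {
    key <- "form_factors"
    if (!is.null(.xtalgen_cache[[key]])) return(.xtalgen_cache[[key]])
    path <- system.file("extdata", "form_factors.tsv", package = "xtalgen",
                        mustWork = TRUE)
  } else key <- NULL
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(df) <- df$element
  if (!is.null(key)) .xtalgen_cache[[key]] <- df
  df
}

#' Atomic scattering factor
#'
#' @param element Element symbol (vectorized with `s` of length 1, or a
#'   single element with vector `s`).
#' @param s `sin(theta)/lambda` in inverse angstroms, `s >= 0`.
#' @param table A [form_factor_table()].
#' @return Scattering factor in electrons.
#' @export
#' @examples
#' scattering_factor("C", 0)
scattering_factor <- function(element, s, table = form_factor_table()) {
  if (!all(element %in% rownames(table)))
    stop_config("unknown element(s): ",
                paste(setdiff(element, rownames(table)), collapse = ", "))
  if (any(s < 0)) stop_domain("s must be >= 0")
  row <- table[element, , drop = FALSE]
  s2 <- s^2
  row$a1 * exp(-row$b1 * s2) + row$a2 * exp(-row$b2 * s2) +
    row$a3 * exp(-row$b3 * s2) + row$a4 * exp(-row$b4 * s2) + row$c
}
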