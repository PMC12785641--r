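# Run configuration: every sampled distribution's parameters in one object ---

#' Full generator configuration
#'
#' Aggregates every tunable of the pipeline with the defaults the generator
#' is calibrated to: log-normal volumes LN(6.04, 0.394), cell lengths in
#' [4, 10] angstroms with maximum adjacent ratio 3, triclinic skews with
#' beta_max 125 degrees (exponential t), artificial-molecule placement,
#' special-position probability 0.05, volume-per-atom U(7, 22) cubic
#' angstroms, hydrogen mole fraction U(0.3, 0.6), displacement parameters
#' U(0.01, 0.1) square angstroms with per-atom deviation U(-0.005, 0.005),
#' resolution 1.0 angstroms at 100% completeness.
#'
#' @param volume A [volume_spec()].
#' @param bounds A [cell_bounds()].
#' @param skew A [skew_config()].
#' @param placement_mode `"molecules"`, `"uniform"` or `"equal_atoms"`
#'   (uniform placement then [make_equal_atom()]).
#' @param rules A [placement_rules()].
#' @param space_group_name `"P-1"` or `"P1"`.
#' @param full_centers Use all eight P-1 inversion centres (default four).
#' @param special_p Special-position occupancy probability.
#' @param v_atom_range,x_h_range Content-budget sampling ranges.
#' @param u_range,dev_range Displacement-parameter sampling ranges.
#' @param diffraction A [diffraction_config()].
#' @param equal_element Element used by the equal-atom mode.
#' @param table_paths Named list of optional replacement table paths
#'   (`general`, `special`, `radii`, `form_factors`).
#' @param seed Root seed of the run.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(volume = volume_spec("lognormal", mu = 6.04,
                                                  sigma = 0.394),
                             bounds = cell_bounds(4, 10, 3),
                             skew = skew_config("triclinic"),
                             placement_mode = c("molecules", "uniform",
                                                "equal_atoms"),
                             rules = placement_rules(),
                             space_group_name = "P-1",
                             full_centers = FALSE,
                             special_p = 0.05,
                             v_atom_range = c(7, 22),
                             x_h_range = c(0.3, 0.6),
                             u_range = c(0.01, 0.1),
                             dev_range = c(-0.005, 0.005),
                             diffraction = diffraction_config(),
                             equal_element = "C",
                             table_paths = list(),
                             seed = 1L) {
  placement_mode <- match.arg(placement_mode)
  cfg <- structure(list(volume = volume, bounds = bounds, skew = skew,
                        placement_mode = placement_mode, rules = rules,
                        space_group_name = space_group_name,
                        full_centers = full_centers,
                        special_p = special_p,
                        v_atom_range = v_atom_range, x_h_range = x_h_range,
                        u_range = u_range, dev_range = dev_range,
                        diffraction = diffraction,
                        equal_element = equal_element,
                        table_paths = table_paths,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg$volume, "volume_spec"),
            inherits(cfg$bounds, "cell_bounds"),
            inherits(cfg$skew, "skew_config"),
            inherits(cfg$rules, "placement_rules"),
            inherits(cfg$diffraction, "diffraction_config"))
  if (cfg$special_p < 0 || cfg$special_p > 1)
    stop_config("special_p must be in [0, 1]")
  if (!cfg$space_group_name %in% c("P-1", "P1"))
    stop_config("space_group_name must be 'P-1' or 'P1'")
  invisible(cfg)
}

#' Save a generator configuration as JSON
#' @param cfg A [generator_config()].
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a generator configuration from JSON
#' @param path JSON file produced by [save_config()].
#' @return A `generator_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vs <- x$volume
  volume <- volume_spec(vs$family, mu = vs$mu, sigma = vs$sigma,
                        vmin = vs$vmin, vmax = vs$vmax)
  generator_config(
    volume = volume,
    bounds = cell_bounds(x$bounds$lmin, x$bounds$lmax, x$bounds$max_ratio),
    skew = skew_config(x$skew$lattice_kind, x$skew$beta_max, x$skew$t_mode,
                       x$skew$rate, x$skew$kappa,
                       isTRUE(x$skew$length_preserving)),
    placement_mode = x$placement_mode,
    rules = placement_rules(x$rules$d_min_contact,
                            c(x$rules$bond_low, x$rules$bond_high),
                            x$rules$nonbond_factor,
                            x$rules$max_coord_retries,
                            x$rules$max_growth_retries),
    space_group_name = x$space_group_name,
    full_centers = isTRUE(x$full_centers),
    special_p = x$special_p,
    v_atom_range = x$v_atom_range, x_h_range = x$x_h_range,
    u_range = x$u_range, dev_range = x$dev_range,
    diffraction = diffraction_config(
      x$diffraction$d_min, x$diffraction$completeness,
      isTRUE(x$diffraction$sample_resolution), x$diffraction$res_range,
      isTRUE(x$diffraction$sample_completeness), x$diffraction$comp_range,
      x$diffraction$index_cap),
    equal_element = x$equal_element,
    table_paths = if (length(x$table_paths)) x$table_paths else list(),
    seed = x$seed)
}
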