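## ---------------------------------------------------------------------------
## Simulation configuration: defaults, validation, YAML round-trip.
## Lengths in configs are micrometres (converted to SI on build); all other
## quantities SI.
## ---------------------------------------------------------------------------

#' Reference scenario configuration
#'
#' The default scenario: a 60 x 32 x 42 um channel with the substrate at
#' `y = 0`, the tumor cell (icosphere, radius 4 um) released at
#' (20, 10, 21) um, the PMN (spherical cap, base radius 5 um, height 5 um)
#' fixed with its footprint centred under (30, ., 21) um so its volume
#' centroid sits near (30, 2.5, 21) um, 100 timesteps of 1 ms, and the
#' reference molecular parameter sets: ICAM-1 at 13e12 /m^2 on the TC,
#' LFA-1 (45e12 /m^2) and Mac-1 (5e12 /m^2) on the PMN, both integrin
#' pairs with `kon0 = 3000`, `koff0 = 0.3` (LFA-1) / `0.29` (Mac-1) 1/s,
#' `s = 2e-3` N/m, `s_ts = 1e-3` N/m, `lambda = 0.05` um. Repulsion uses
#' `a = -110e-6` N/m, `b = 600e6` N/m^3, `eps = 1.2` um. Flow, timestep
#' and temperature are model assumptions, configurable here.
#'
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged recursively), e.g. `default_config(modes = list(repulsion = FALSE))`.
#' @return a validated configuration list of class `adhesim_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    domain = list(size_um = c(60, 32, 42)),
    tc = list(shape = "icosphere", radius_um = 4,
              centroid_um = c(20, 10, 21),
              max_element_um = 1.0, density_kg_m3 = 1050),
    pmn = list(shape = "cap", base_radius_um = 5, height_um = 5,
               footprint_um = c(30, 21), max_element_um = 1.0,
               fixed = TRUE),
    species = list(
      list(name = "ICAM1", body = "tc", density_per_m2 = 13e12),
      list(name = "LFA1", body = "pmn", density_per_m2 = 45e12),
      list(name = "MAC1", body = "pmn", density_per_m2 = 5e12)
    ),
    bond_types = list(
      list(name = "ICAM1:LFA1", tc_species = "ICAM1", pmn_species = "LFA1",
           kon0 = 3000, koff0 = 0.3, s = 2e-3, s_ts = 1e-3, lambda_um = 0.05),
      list(name = "ICAM1:MAC1", tc_species = "ICAM1", pmn_species = "MAC1",
           kon0 = 3000, koff0 = 0.29, s = 2e-3, s_ts = 1e-3, lambda_um = 0.05)
    ),
    environment = list(
      temperature_K = 310.15, dt_s = 1e-3, n_steps = 100,
      eps_um = 1.2, eps_mv_um = 1.2,
      a_N_m = -110e-6, b_N_m3 = 600e6,
      shear_rate_s = 100, viscosity_Pa_s = 1e-3, fluid_density_kg_m3 = 1000
    ),
    modes = list(
      repulsion = TRUE, adhesion = TRUE, forced_p = NULL,
      repulsion_mode = "clamped", dynamics = "overdamped",
      external_force_N = c(0, 0, 0)
    ),
    seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named")
    cfg <- modifyList(cfg, ov)
  }
  validate_config(cfg)
}

.known_keys <- list(
  top = c("domain", "tc", "pmn", "species", "bond_types", "environment",
          "modes", "seed"),
  domain = "size_um",
  tc = c("shape", "radius_um", "centroid_um", "max_element_um",
         "subdivisions", "density_kg_m3"),
  pmn = c("shape", "base_radius_um", "height_um", "footprint_um",
          "max_element_um", "resolution", "fixed"),
  environment = c("temperature_K", "dt_s", "n_steps", "eps_um", "eps_mv_um",
                  "a_N_m", "b_N_m3", "shear_rate_s", "viscosity_Pa_s",
                  "fluid_density_kg_m3"),
  modes = c("repulsion", "adhesion", "forced_p", "repulsion_mode",
            "dynamics", "external_force_N")
)

#' Validate a configuration
#'
#' Checks key names (unknown keys are rejected, naming the offender),
#' positivity of all lengths, membership of mode switches, and that the
#' two bodies do not initially overlap.
#'
#' @param cfg a configuration list.
#' @return the configuration, classed `adhesim_config`, invisibly usable.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("config: ", ..., call. = FALSE)
  unknown <- setdiff(names(cfg), .known_keys$top)
  if (length(unknown)) fail("unknown key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("domain", "tc", "pmn", "environment", "modes")) {
    if (is.null(cfg[[sec]])) fail("missing section '", sec, "'")
    unknown <- setdiff(names(cfg[[sec]]), .known_keys[[sec]])
    if (length(unknown))
      fail("unknown key(s) in '", sec, "': ", paste(unknown, collapse = ", "))
  }
  pos <- function(x, name) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      fail("'", name, "' must be positive and finite")
  }
  pos(cfg$domain$size_um, "domain$size_um")
  if (length(cfg$domain$size_um) != 3) fail("'domain$size_um' needs 3 values")
  pos(cfg$tc$radius_um, "tc$radius_um")
  pos(cfg$tc$max_element_um, "tc$max_element_um")
  pos(cfg$tc$density_kg_m3, "tc$density_kg_m3")
  if (length(cfg$tc$centroid_um) != 3) fail("'tc$centroid_um' needs 3 values")
  pos(cfg$pmn$base_radius_um, "pmn$base_radius_um")
  pos(cfg$pmn$height_um, "pmn$height_um")
  pos(cfg$pmn$max_element_um, "pmn$max_element_um")
  if (length(cfg$pmn$footprint_um) != 2)
    fail("'pmn$footprint_um' needs 2 values (x, z)")
  env <- cfg$environment
  for (k in c("temperature_K", "dt_s", "eps_um", "b_N_m3",
              "viscosity_Pa_s", "fluid_density_kg_m3"))
    pos(env[[k]], paste0("environment$", k))
  if (!is.numeric(env$eps_mv_um) || env$eps_mv_um < 0)
    fail("'environment$eps_mv_um' must be >= 0")
  if (!is.numeric(env$shear_rate_s) || env$shear_rate_s < 0)
    fail("'environment$shear_rate_s' must be >= 0")
  if (!is.numeric(env$n_steps) || env$n_steps < 0 ||
      env$n_steps != round(env$n_steps))
    fail("'environment$n_steps' must be a non-negative integer")
  if (!cfg$modes$repulsion_mode %in% c("clamped", "signed"))
    fail("'modes$repulsion_mode' must be 'clamped' or 'signed'")
  if (!cfg$modes$dynamics %in% c("overdamped", "newtonian"))
    fail("'modes$dynamics' must be 'overdamped' or 'newtonian'")
  if (!is.null(cfg$modes$forced_p) &&
      (!is.numeric(cfg$modes$forced_p) || cfg$modes$forced_p < 0 ||
         cfg$modes$forced_p > 1))
    fail("'modes$forced_p' must be NULL or a probability")
  if (length(cfg$modes$external_force_N) != 3)
    fail("'modes$external_force_N' needs 3 components")
  for (sp in cfg$species) {
    if (is.null(sp$name) || is.null(sp$body) || is.null(sp$density_per_m2))
      fail("each species needs 'name', 'body', 'density_per_m2'")
    if (!sp$body %in% c("tc", "pmn")) fail("species body must be tc or pmn")
    if (sp$density_per_m2 < 0) fail("species density must be >= 0")
  }
  for (bt in cfg$bond_types) {
    need <- c("name", "tc_species", "pmn_species", "kon0", "koff0",
              "s", "s_ts", "lambda_um")
    miss <- setdiff(need, names(bt))
    if (length(miss))
      fail("bond type missing: ", paste(miss, collapse = ", "))
  }
  ## initial non-overlap: TC sphere against the PMN's bounding sphere-on-wall
  tcx <- cfg$tc$centroid_um
  apex <- c(cfg$pmn$footprint_um[1], cfg$pmn$height_um, cfg$pmn$footprint_um[2])
  gap <- sqrt(sum((tcx - apex)^2)) # conservative: distance to apex
  if (tcx[2] - cfg$tc$radius_um < 0)
    fail("tumor cell initially intersects the substrate")
  if (gap < cfg$tc$radius_um && cfg$tc$centroid_um[2] < cfg$pmn$height_um)
    fail("bodies initially overlapping")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  ## canonicalize so YAML round trips compare equal (a NULL forced_p is
  ## dropped by list merging)
  if (!("forced_p" %in% names(cfg$modes)))
    cfg$modes <- c(cfg$modes, list(forced_p = NULL))
  cfg$modes <- cfg$modes[c("repulsion", "adhesion", "forced_p",
                           "repulsion_mode", "dynamics",
                           "external_force_N")]
  class(cfg) <- "adhesim_config"
  cfg
}

#' Load / save a configuration as YAML
#'
#' `load_config()` reads a YAML file, merges it over the defaults (an
#' empty file yields the full reference scenario) and validates;
#' `save_config()` writes a configuration back out. The round trip is
#' lossless.
#'
#' @param path file path.
#' @param cfg a configuration list.
#' @return `load_config()`: a validated `adhesim_config`;
#'   `save_config()`: `path`, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ## yaml scalars come back length-1; coerce numeric vectors
  cfg <- modifyList(unclass(default_config()), user)
  validate_config(cfg)
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Short hash identifying a configuration
#' @param cfg a configuration list.
#' @return 8-character hash string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

## ---------------------------------------------------------------------------
## Builders: config -> model objects (SI units)
## ---------------------------------------------------------------------------

build_scene <- function(cfg) {
  cfg <- validate_config(cfg)
  tc_sub <- if (!is.null(cfg$tc$subdivisions)) cfg$tc$subdivisions else
    icosphere_subdivisions_for(um(cfg$tc$radius_um), um(cfg$tc$max_element_um))
  tc_mesh <- make_icosphere(um(cfg$tc$radius_um), tc_sub)
  pm_res <- if (!is.null(cfg$pmn$resolution)) cfg$pmn$resolution else
    cap_resolution_for(um(cfg$pmn$base_radius_um), um(cfg$pmn$height_um),
                       um(cfg$pmn$max_element_um))
  pmn_mesh <- make_pmn_cap(um(cfg$pmn$base_radius_um), um(cfg$pmn$height_um),
                           pm_res)
  tc_state <- rigid_state(x = um(cfg$tc$centroid_um),
                          radius = um(cfg$tc$radius_um),
                          density = cfg$tc$density_kg_m3)
  pmn_pose <- list(x = um(c(cfg$pmn$footprint_um[1], 0,
                            cfg$pmn$footprint_um[2])),
                   q = quat_identity())
  species <- lapply(cfg$species, function(s)
    molecule_species(s$name, s$density_per_m2, s$body))
  bond_types <- lapply(cfg$bond_types, function(b)
    bond_type(b$name, b$tc_species, b$pmn_species, b$kon0, b$koff0,
              b$s, b$s_ts, um(b$lambda_um)))
  kenv <- kinetic_env(cfg$environment$temperature_K, cfg$environment$dt_s,
                      um(cfg$environment$eps_mv_um))
  fenv <- flow_env(cfg$environment$shear_rate_s,
                   cfg$environment$viscosity_Pa_s,
                   cfg$environment$fluid_density_kg_m3)
  rparams <- repulsion_params(cfg$environment$a_N_m, cfg$environment$b_N_m3,
                              um(cfg$environment$eps_um),
                              cfg$modes$repulsion_mode)
  lambda_max <- max(vapply(bond_types, `[[`, 0, "lambda"))
  list(cfg = cfg, tc_mesh = tc_mesh, pmn_mesh = pmn_mesh,
       tc_state = tc_state, pmn_pose = pmn_pose, species = species,
       bond_types = bond_types, kenv = kenv, fenv = fenv,
       rparams = rparams,
       cutoff = max(um(cfg$environment$eps_um),
                    kenv$eps_mv + 2 * lambda_max))
}
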