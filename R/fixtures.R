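## ---------------------------------------------------------------------------
## Verification fixtures and scripted experiments: the planar two-plane
## fixture, forced (P = 1) bonding, the coarse-vs-fine mesh-independence
## experiment, and the repulsion-controlled approach trajectory.
## ---------------------------------------------------------------------------

#' Two parallel planar face grids
#'
#' The planar verification fixture: `n` co-registered square faces per
#' side, laid out in a row along `x` at pitch `sqrt(face_area)`, the PMN
#' plane at `y = 0` and the TC plane at `y = gap`. Directly opposing faces
#' are exactly `gap` apart; the full pair-distance matrix is `n x n`.
#' Fixture kinetics normally run with `eps_mv = 0` so the raw gap feeds
#' the rate expressions.
#'
#' @param n_faces_per_side integer >= 1.
#' @param face_area area of each face \[m^2\].
#' @param gap plane separation \[m\], positive.
#' @return list with `face_set`s `tc` and `pmn`.
#' @export
make_parallel_planes <- function(n_faces_per_side = 8L,
                                 face_area = 2.5e-13, gap = 0.05e-6) {
  if (n_faces_per_side < 1) stop("'n_faces_per_side' must be >= 1")
  check_scalar(face_area, "face_area")
  check_scalar(gap, "gap")
  n <- as.integer(n_faces_per_side)
  side <- sqrt(face_area)
  xs <- (seq_len(n) - (n + 1) / 2) * side
  plane <- function(y, normal_y, body_id) {
    centroids <- cbind(xs, y, 0)
    structure(list(
      body_id = body_id,
      face_ids = seq_len(n),
      centroids = centroids,
      areas = rep(face_area, n),
      normals = matrix(rep(c(0, normal_y, 0), each = n), ncol = 3),
      levers = sweep(centroids, 2, c(0, y, 0), "-"),
      origin = c(0, y, 0)
    ), class = "face_set")
  }
  list(tc = plane(gap, -1, "tc"), pmn = plane(0, 1, "pmn"))
}

#' Deterministic availability-limited bonding (P = 1)
#'
#' Runs one formation sweep with the formation probability forced to 1 for
#' every gated pair, so the bond count is limited only by molecule
#' availability on the two sides -- the verification mode used to confirm
#' that per-face molecule counts actually cap bonding and that a molecule
#' engaged by one partner species cannot be double-booked by another.
#'
#' @param tc_faces,pmn_faces `face_set`s.
#' @param ledger a [molecule_ledger()].
#' @param bond_types list of [bond_type()].
#' @param env a [kinetic_env()] (typically with `eps_mv = 0`).
#' @param cutoff pair gating distance \[m\]; default
#'   `eps_mv + 2 * max(lambda)`.
#' @return list with `n_bonds`, `bonds`, `ledger`, `pairs`.
#' @export
forced_bonding_run <- function(tc_faces, pmn_faces, ledger, bond_types, env,
                               cutoff = NULL) {
  if (is.null(cutoff))
    cutoff <- env$eps_mv + 2 * max(vapply(bond_types, `[[`, 0, "lambda"))
  pairs <- gated_face_pairs(tc_faces, pmn_faces, cutoff)
  res <- formation_step(pairs, tc_faces, pmn_faces, ledger, bond_types, env,
                        forced_p = 1)
  list(n_bonds = nrow(res$bonds), bonds = res$bonds, ledger = res$ledger,
       pairs = pairs)
}

#' Coarse-vs-fine mesh independence of the bond count
#'
#' Builds the same two-cell geometry (icosphere TC hovering a fixed
#' surface gap above the PMN cap apex) meshed at a coarse and a fine
#' maximum element size, runs a single-instant bond-formation sweep per
#' seed on each, and compares the mean total bond counts. Each seed also
#' draws a uniformly random rigid orientation for the TC mesh and a random
#' azimuthal spin for the PMN mesh, so the Monte Carlo mean averages over
#' the arbitrary placement of mesh elements on the *same* geometry --
#' the nuisance a mesh-independence claim is about.
#'
#' The sweep runs the actual kinetics at the study conditions (Table-level
#' densities and rates, the configured timestep), where formation is
#' availability-limited near the equilibrium bond length.
#'
#' @param config scenario configuration (cell shapes/sizes and molecular
#'   parameters are taken from it).
#' @param seeds integer vector of seeds, length >= 2 (>= 50 for the
#'   published-style comparison).
#' @param coarse,fine maximum element sizes \[m\].
#' @param gap surface-to-surface gap between TC sphere and cap apex \[m\];
#'   the default is the separation the repulsion model maintains between
#'   cells in contact, the configuration in which bonding operates.
#' @return a `data.frame` with one row per resolution (`mean`, `se`, `n`)
#'   and attributes `diff` (coarse - fine), `se_diff`, `z`, and `counts`.
#' @export
mesh_independence_experiment <- function(config = default_config(),
                                         seeds = 1:50,
                                         coarse = 1.5e-6, fine = 0.5e-6,
                                         gap = 0.3e-6) {
  if (length(seeds) < 2) stop("need at least 2 seeds")
  sc <- build_scene(config)
  r_tc <- um(sc$cfg$tc$radius_um)
  base <- um(sc$cfg$pmn$base_radius_um)
  height <- um(sc$cfg$pmn$height_um)
  run_res <- function(max_el) {
    tc_mesh <- make_icosphere(r_tc, icosphere_subdivisions_for(r_tc, max_el))
    pm_mesh <- make_pmn_cap(base, height,
                            cap_resolution_for(base, height, max_el))
    tc_x <- c(0, height + gap + r_tc, 0)
    counts <- vapply(seeds, function(sd) {
      set.seed(sd)
      tc_faces <- face_properties(tc_mesh, list(x = tc_x, q = quat_random()),
                                  "tc")
      spin <- quat_from_axis_angle(c(0, 1, 0), runif(1, 0, 2 * pi))
      pm_faces <- face_properties(pm_mesh, list(x = c(0, 0, 0), q = spin),
                                  "pmn")
      ledger <- molecule_ledger(tc_faces, pm_faces, sc$species)
      pairs <- gated_face_pairs(tc_faces, pm_faces, sc$cutoff)
      nrow(formation_step(pairs, tc_faces, pm_faces, ledger, sc$bond_types,
                          sc$kenv)$bonds)
    }, 0)
    counts
  }
  cc <- run_res(coarse)
  cf <- run_res(fine)
  out <- data.frame(
    resolution_m = c(coarse, fine),
    mean = c(mean(cc), mean(cf)),
    se = c(sd(cc), sd(cf)) / sqrt(length(seeds)),
    n = length(seeds)
  )
  attr(out, "diff") <- mean(cc) - mean(cf)
  attr(out, "se_diff") <- sqrt(sum(out$se^2))
  attr(out, "z") <- attr(out, "diff") / attr(out, "se_diff")
  attr(out, "counts") <- list(coarse = cc, fine = cf)
  out
}

#' Overdamped approach of the TC toward the fixed PMN
#'
#' Drives the tumor cell straight down onto the PMN cap apex with a
#' constant wall-ward load, adhesion off and no shear flow, and records
#' the minimum face-pair separation over the trajectory. With repulsion
#' on, the nonlinear spring arrests the approach at a finite separation;
#' with repulsion off the surfaces interpenetrate. Quantities are SI.
#'
#' @param repulsion logical, apply the repulsion model.
#' @param load magnitude of the constant wall-ward driving force \[N\].
#' @param gap initial surface-to-surface gap above the apex \[m\].
#' @param dt timestep \[s\].
#' @param n_steps maximum number of steps.
#' @param tc_subdivisions icosphere subdivision level of the TC.
#' @param cap_resolution PMN cap resolution.
#' @param repulsion_mode `"clamped"` or `"signed"`.
#' @param stop_below terminate early once the minimum separation falls
#'   below this \[m\] (used to detect interpenetration cheaply).
#' @param config base configuration for cell sizes and repulsion constants.
#' @return list with `min_separation` \[m\] (minimum over the whole
#'   trajectory), `final_separation`, `trajectory`, `status`, and `sim`.
#' @export
approach_experiment <- function(repulsion = TRUE, load = 1e-11,
                                gap = 2e-6, dt = 1e-5, n_steps = 2500,
                                tc_subdivisions = 3L, cap_resolution = 12L,
                                repulsion_mode = "clamped",
                                stop_below = 0, config = default_config()) {
  r_tc <- um(config$tc$radius_um)
  height <- um(config$pmn$height_um)
  y0 <- (height + gap + r_tc) * 1e6
  cfg <- default_config(
    tc = modifyList(config$tc, list(centroid_um = c(30, y0, 21),
                                    subdivisions = tc_subdivisions)),
    pmn = modifyList(config$pmn, list(resolution = cap_resolution)),
    environment = modifyList(config$environment,
                             list(shear_rate_s = 0, dt_s = dt,
                                  n_steps = n_steps)),
    modes = list(repulsion = repulsion, adhesion = FALSE,
                 repulsion_mode = repulsion_mode,
                 external_force_N = c(0, -load, 0)),
    seed = config$seed
  )
  sim <- simulate_until(cfg, stop_below)
  tr <- sim$trajectory
  list(min_separation = suppressWarnings(min(tr$min_separation_m)),
       final_separation = tr$min_separation_m[nrow(tr)],
       trajectory = tr, status = sim$status, sim = sim)
}

## simulate() with an early-exit threshold on the minimum separation;
## chunked so the stock loop stays untouched
simulate_until <- function(cfg, stop_below = 0) {
  if (stop_below <= 0) return(simulate(cfg))
  total <- cfg$environment$n_steps
  chunk <- max(25L, ceiling(total / 40))
  done <- 0L
  state_cfg <- cfg
  trajs <- list()
  sim <- NULL
  while (done < total) {
    state_cfg$environment$n_steps <- min(chunk, total - done)
    sim <- simulate(state_cfg)
    tr <- sim$trajectory
    if (!is.null(tr) && nrow(tr)) {
      tr$step <- tr$step + done
      trajs[[length(trajs) + 1L]] <- tr
      done <- done + nrow(tr)
      last <- sim$final_state
      state_cfg$tc$centroid_um <- last$x * 1e6
      if (min(tr$min_separation_m) < stop_below) break
      if (sim$status != "completed") break
    } else {
      break
    }
  }
  sim$trajectory <- do.call(rbind, trajs)
  sim
}
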