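## ---------------------------------------------------------------------------
## The coupled simulation loop.
## ---------------------------------------------------------------------------

#' Run a coupled adhesion / repulsion / 6DOF simulation
#'
#' Per timestep, in order: update the TC face geometry at its current
#' pose, find the gated face pairs, compute repulsion loads, test existing
#' bonds for breakage (the routine first reads the live bond list), test
#' gated pairs for bond formation, compute bond spring loads, compute the
#' surrogate flow loads, aggregate, and advance the 6DOF state. The PMN is
#' fixed; its face set is computed once. Runs are bit-identical for an
#' identical configuration and seed.
#'
#' The run terminates cleanly (with a status) if the TC centroid leaves
#' the domain or reaches wall contact.
#'
#' @param config an `adhesim_config` (see [default_config()]).
#' @param quiet suppress per-run messages.
#' @return an object of class `adhesim_sim`: list with `trajectory`
#'   (one row per completed step), `bonds` (live bonds at the end),
#'   `bond_log` (formation/breakage events), `config`, `status`
#'   (`"completed"`, `"exited_domain"` or `"wall_contact"`), and
#'   `n_correction_underflow`.
#' @export
simulate <- function(config = default_config(), quiet = TRUE) {
  sc <- build_scene(config)
  cfg <- sc$cfg
  set.seed(cfg$seed)
  kenv <- sc$kenv
  dt <- kenv$dt
  pmn_faces <- face_properties(sc$pmn_mesh, sc$pmn_pose, "pmn")
  tc_state <- sc$tc_state
  ledger <- molecule_ledger(face_properties(sc$tc_mesh, tc_state, "tc"),
                            pmn_faces, sc$species)
  bonds <- empty_bonds()
  bonds$d_form <- numeric(0)
  domain <- um(cfg$domain$size_um)
  ext <- list(F = as.numeric(cfg$modes$external_force_N), T = c(0, 0, 0))
  n_steps <- cfg$environment$n_steps
  status <- "completed"
  n_underflow <- 0L
  traj <- vector("list", n_steps)
  events <- list()
  log_event <- function(step, time, what, tab, force = NULL) {
    if (!nrow(tab)) return()
    d_face <- if (!is.null(tab$d_form)) tab$d_form else rep(NA_real_, nrow(tab))
    events[[length(events) + 1L]] <<- data.frame(
      step = step, time_s = time, event = what,
      tc_face = tab$tc_face, pmn_face = tab$pmn_face, bond_type = tab$type,
      d_face_m = d_face, d_kin_m = d_face - kenv$eps_mv,
      force_N = if (is.null(force)) rep(NA_real_, nrow(tab)) else force,
      stringsAsFactors = FALSE)
  }

  step <- 0L
  while (step < n_steps) {
    step <- step + 1L
    time <- step * dt
    tc_faces <- face_properties(sc$tc_mesh, tc_state, "tc")
    pairs <- gated_face_pairs(tc_faces, pmn_faces, sc$cutoff)
    rep_loads <- if (cfg$modes$repulsion) {
      repulsion_loads(pairs, tc_faces, sc$rparams)
    } else {
      c(zero_load(), list(n_active = 0L))
    }
    if (cfg$modes$adhesion) {
      brk <- breakage_step(bonds, tc_faces, pmn_faces, ledger,
                           sc$bond_types, kenv)
      bonds <- brk$bonds
      ledger <- brk$ledger
      log_event(step, time, "break", brk$broken)
      frm <- formation_step(pairs, tc_faces, pmn_faces, ledger,
                            sc$bond_types, kenv, time = time,
                            forced_p = cfg$modes$forced_p)
      ledger <- frm$ledger
      n_underflow <- n_underflow + frm$n_underflow
      f_new <- if (nrow(frm$bonds)) {
        bts <- stats::setNames(sc$bond_types,
                               vapply(sc$bond_types, `[[`, "", "name"))
        vapply(seq_len(nrow(frm$bonds)), function(r) {
          bt <- bts[[frm$bonds$type[r]]]
          bt$s * (frm$bonds$d_form[r] - kenv$eps_mv - bt$lambda)
        }, 0)
      } else NULL
      log_event(step, time, "form", frm$bonds, force = f_new)
      bonds <- rbind(bonds, frm$bonds)
    }
    b_loads <- if (cfg$modes$adhesion) {
      bond_loads(bonds, tc_faces, pmn_faces, sc$bond_types, kenv)
    } else {
      zero_load()
    }
    f_loads <- flow_loads(tc_state, sc$fenv)
    loads <- total_loads(f_loads, b_loads, rep_loads, ext)
    tc_state <- step_6dof(tc_state, loads, dt, cfg$modes$dynamics, sc$fenv)
    min_sep <- if (nrow(pairs)) min(pairs$d) else Inf
    traj[[step]] <- data.frame(
      step = step, time_s = time,
      x = tc_state$x[1], y = tc_state$x[2], z = tc_state$x[3],
      qw = tc_state$q[1], qx = tc_state$q[2], qy = tc_state$q[3],
      qz = tc_state$q[4],
      vx = tc_state$v[1], vy = tc_state$v[2], vz = tc_state$v[3],
      wx = tc_state$w[1], wy = tc_state$w[2], wz = tc_state$w[3],
      Fx_fluid = loads$F_fluid[1], Fy_fluid = loads$F_fluid[2],
      Fz_fluid = loads$F_fluid[3],
      Fx_bonds = loads$F_bonds[1], Fy_bonds = loads$F_bonds[2],
      Fz_bonds = loads$F_bonds[3],
      Fx_rep = loads$F_rep[1], Fy_rep = loads$F_rep[2],
      Fz_rep = loads$F_rep[3],
      Tx = loads$T[1], Ty = loads$T[2], Tz = loads$T[3],
      n_pairs_gated = nrow(pairs),
      n_pairs_repelling = rep_loads$n_active,
      n_bonds = nrow(bonds),
      min_separation_m = min_sep)
    if (any(tc_state$x < 0) || any(tc_state$x > domain)) {
      status <- "exited_domain"
      break
    }
    if (tc_state$x[2] <= tc_state$radius) {
      status <- "wall_contact"
      break
    }
  }
  trajectory <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  if (!quiet)
    message("adhesim: ", status, " after ", step, " steps, ",
            nrow(bonds), " live bonds")
  structure(list(trajectory = trajectory, bonds = bonds,
                 bond_log = if (length(events)) do.call(rbind, events)
                 else NULL,
                 config = cfg, status = status,
                 n_correction_underflow = n_underflow,
                 final_state = tc_state),
            class = "adhesim_sim")
}

#' @export
print.adhesim_sim <- function(x, ...) {
  n <- if (is.null(x$trajectory)) 0L else nrow(x$trajectory)
  cat("adhesim simulation:", x$status, "after", n, "steps;",
      nrow(x$bonds), "live bonds;",
      "min separation",
      format(suppressWarnings(min(x$trajectory$min_separation_m)),
             digits = 4), "m\n")
  invisible(x)
}
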