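## ---------------------------------------------------------------------------
## Rigid-body state, analytic near-wall flow-load surrogate, load
## aggregation, and the 6DOF integrator.
## ---------------------------------------------------------------------------

#' Rigid-body state of a cell
#'
#' Pose (position + unit quaternion), velocities, and the mass properties
#' of a uniform-density sphere (`m = 4/3 pi r^3 rho`, `I = 2/5 m r^2`).
#' Fixed bodies (the substrate-adherent PMN) never move: the net load on
#' them is defined to be zero.
#'
#' @param x centroid position \[m\].
#' @param radius nominal cell radius \[m\] (drag/inertia length scale).
#' @param q orientation unit quaternion (scalar first).
#' @param v linear velocity \[m/s\].
#' @param w angular velocity \[rad/s\] (world frame).
#' @param density cell density \[kg/m^3\].
#' @param fixed logical; fixed bodies cannot be stepped.
#' @return an object of class `rigid_state`.
#' @export
rigid_state <- function(x, radius, q = quat_identity(), v = c(0, 0, 0),
                        w = c(0, 0, 0), density = 1050, fixed = FALSE) {
  check_scalar(radius, "radius")
  check_scalar(density, "density")
  mass <- 4 / 3 * pi * radius^3 * density
  structure(list(x = as.numeric(x), q = quat_normalize(q),
                 v = as.numeric(v), w = as.numeric(w),
                 radius = radius, mass = mass,
                 inertia = 2 / 5 * mass * radius^2,
                 fixed = isTRUE(fixed)),
            class = "rigid_state")
}

#' Near-wall linear shear-flow environment
#'
#' The flow surrogate that replaces the CFD solution: a linear shear
#' profile `u_x(y) = G y` over the substrate plane `y = 0`, quiescent in
#' `y` and `z`, with fluid vorticity `(0, 0, -G)`.
#'
#' @param shear_rate wall shear rate `G` \[1/s\] (>= 0).
#' @param viscosity dynamic viscosity \[Pa s\], positive.
#' @param density fluid density \[kg/m^3\], positive.
#' @return an object of class `flow_env`.
#' @export
flow_env <- function(shear_rate = 100, viscosity = 1e-3, density = 1000) {
  if (!is.numeric(shear_rate) || length(shear_rate) != 1L || shear_rate < 0)
    stop("'shear_rate' must be a single non-negative number")
  check_scalar(viscosity, "viscosity")
  check_scalar(density, "density")
  structure(list(shear_rate = shear_rate, viscosity = viscosity,
                 density = density), class = "flow_env")
}

## Built-in near-wall correction table over h/r in [1.05, 10], from the
## classical method-of-reflections expansions for a sphere translating
## parallel to a plane wall (drag factor C_t) and rotating about an axis
## parallel to the wall (torque factor C_r); piecewise-linear in between,
## constant beyond the table.
.wall_tab <- local({
  hr <- c(1.05, 1.1, 1.2, 1.35, 1.5, 1.75, 2, 2.5, 3, 4, 5, 7, 10)
  b <- 1 / hr
  list(hr = hr,
       Ct = 1 / (1 - 9 / 16 * b + 1 / 8 * b^3 - 45 / 256 * b^4 - 1 / 16 * b^5),
       Cr = 1 / (1 - 5 / 16 * b^3))
})

#' Near-wall mobility correction factors
#'
#' @param h_over_r centroid height over radius, > 1.
#' @return list with translation factor `Ct` and rotation factor `Cr`
#'   (both >= 1, approaching 1 far from the wall).
#' @export
wall_correction <- function(h_over_r) {
  hr <- pmin(pmax(h_over_r, .wall_tab$hr[1]), max(.wall_tab$hr))
  list(Ct = approx(.wall_tab$hr, .wall_tab$Ct, hr, rule = 2)$y,
       Cr = approx(.wall_tab$hr, .wall_tab$Cr, hr, rule = 2)$y)
}

#' Analytic flow loads on the tumor cell
#'
#' Surrogate for the CFD surface-stress integrals: wall-corrected Stokes
#' drag on the slip velocity, `F = 6 pi mu r Ct (u_fluid(h) - v)`, plus the
#' shear-induced torque `T = 8 pi mu r^3 Cr (omega_fluid/2 - w)` with
#' `omega_fluid = (0, 0, -G)`. A force- and torque-free sphere therefore
#' advects with the local fluid velocity and spins at half the vorticity.
#'
#' @param state a [rigid_state()] (sphere, centroid height above radius).
#' @param env a [flow_env()].
#' @return list with `F` \[N\] and `T` \[N m\].
#' @export
flow_loads <- function(state, env) {
  h <- state$x[2]
  r <- state$radius
  if (h <= r)
    stop("sphere centroid height must exceed its radius (wall contact)")
  cc <- wall_correction(h / r)
  uf <- c(env$shear_rate * h, 0, 0)
  whalf <- c(0, 0, -env$shear_rate / 2)
  list(F = 6 * pi * env$viscosity * r * cc$Ct * (uf - state$v),
       T = 8 * pi * env$viscosity * r^3 * cc$Cr * (whalf - state$w))
}

#' A zero load contribution
#' @return list with zero `F` and `T`.
#' @export
zero_load <- function() list(F = c(0, 0, 0), T = c(0, 0, 0))

#' Aggregate load set acting at the body centroid
#'
#' Componentwise, exact: `F = F_fluid + F_bonds + F_rep (+ F_ext)` and the
#' same for torques. `ext` carries any imposed driving load (used by the
#' approach experiments).
#'
#' @param flow,bonds,rep,ext load contributions (lists with `F`, `T`).
#' @return an object of class `load_set` with per-source components and
#'   totals `F`, `T`.
#' @export
total_loads <- function(flow = zero_load(), bonds = zero_load(),
                        rep = zero_load(), ext = zero_load()) {
  structure(list(
    F_fluid = flow$F, T_fluid = flow$T,
    F_bonds = bonds$F, T_bonds = bonds$T,
    F_rep = rep$F, T_rep = rep$T,
    F_ext = ext$F, T_ext = ext$T,
    F = flow$F + bonds$F + rep$F + ext$F,
    T = flow$T + bonds$T + rep$T + ext$T
  ), class = "load_set")
}

#' Advance the 6DOF state by one timestep
#'
#' Two integrators:
#' * `"overdamped"` (default): at cell scale the inertial relaxation time
#'   (`m / 6 pi mu r` ~ microseconds) is far below any useful timestep, so
#'   velocities are set by instantaneous force balance -- the flow drag
#'   balances the bond, repulsion and external loads -- and the pose is
#'   advanced kinematically.
#' * `"newtonian"`: semi-implicit Euler on Newton's second law
#'   `m dv/dt = F`, `I dw/dt = T`, retained for fidelity to the printed
#'   equations of motion.
#'
#' The orientation quaternion is renormalized every step.
#'
#' @param state a non-fixed [rigid_state()].
#' @param loads a [total_loads()] set.
#' @param dt timestep \[s\].
#' @param mode `"overdamped"` or `"newtonian"`.
#' @param fenv a [flow_env()]; required in overdamped mode.
#' @return the advanced [rigid_state()].
#' @export
step_6dof <- function(state, loads, dt, mode = c("overdamped", "newtonian"),
                      fenv = NULL) {
  mode <- match.arg(mode)
  if (state$fixed) stop("cannot step a fixed body")
  check_scalar(dt, "dt")
  if (!all(is.finite(loads$F)) || !all(is.finite(loads$T)))
    stop("non-finite loads: F = ", paste(loads$F, collapse = ", "),
         "; T = ", paste(loads$T, collapse = ", "))
  if (mode == "newtonian") {
    v <- state$v + loads$F / state$mass * dt
    w <- state$w + loads$T / state$inertia * dt
  } else {
    if (is.null(fenv)) stop("overdamped mode needs a flow_env")
    h <- state$x[2]
    r <- state$radius
    if (h <= r) stop("sphere centroid height must exceed its radius")
    cc <- wall_correction(h / r)
    Fn <- loads$F_bonds + loads$F_rep + loads$F_ext
    Tn <- loads$T_bonds + loads$T_rep + loads$T_ext
    v <- c(fenv$shear_rate * h, 0, 0) +
      Fn / (6 * pi * fenv$viscosity * r * cc$Ct)
    w <- c(0, 0, -fenv$shear_rate / 2) +
      Tn / (8 * pi * fenv$viscosity * r^3 * cc$Cr)
  }
  state$x <- state$x + v * dt
  state$q <- quat_integrate(state$q, w, dt)
  state$v <- v
  state$w <- w
  state
}
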