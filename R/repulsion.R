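## ---------------------------------------------------------------------------
## Gated nonlinear-spring cellular repulsion.
## ---------------------------------------------------------------------------

#' Repulsion model parameters
#'
#' The lumped nonspecific repulsion (microvillus pushing, electrostatic
#' repulsion, steric stabilization) between close membrane faces is a
#' nonlinear spring `a d + b d^3` applied to every face pair closer than
#' the critical distance `eps` (the summed microvillus lengths of the two
#' cells). With the reference constants `a = -110e-6` N/m and
#' `b = 600e6` N/m^3 the polynomial has a zero-force root at
#' `d* = sqrt(-a/b) ~ 0.43 um`.
#'
#' Taken literally with `a < 0` the polynomial is negative below `d*` and
#' positive above it, i.e. it *attracts* at short range if its sign is
#' read as "positive = repulsive". The default `"clamped"` convention
#' therefore applies a purely repulsive push `max(0, -(a d + b d^3))`,
#' which is monotone in contact, zero at `d*`, and continuous everywhere;
#' `"signed"` preserves the printed form for fidelity experiments.
#'
#' @param a linear spring constant \[N/m\] (negative in the reference set).
#' @param b cubic spring constant \[N/m^3\], positive.
#' @param eps critical gating distance \[m\], positive.
#' @param mode `"clamped"` (default) or `"signed"`.
#' @return an object of class `repulsion_params`.
#' @export
repulsion_params <- function(a = -110e-6, b = 600e6, eps = 1.2e-6,
                             mode = c("clamped", "signed")) {
  mode <- match.arg(mode)
  check_scalar(b, "b")
  check_scalar(eps, "eps")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("'a' must be a single finite number")
  structure(list(a = a, b = b, eps = eps, mode = mode),
            class = "repulsion_params")
}

#' Repulsive force magnitude at a face separation
#'
#' Zero at and beyond the critical distance. Below it, `"clamped"` mode
#' returns the applied push `max(0, -(a d + b d^3))` (non-negative,
#' directed away from the other face); `"signed"` mode returns the raw
#' polynomial `a d + b d^3`.
#'
#' @param d face separation(s) \[m\], strictly positive (a non-positive
#'   separation means interpenetrating geometry and is an error).
#' @param p a [repulsion_params()].
#' @return force magnitude(s) \[N\].
#' @export
repulsion_magnitude <- function(d, p) {
  if (any(d <= 0))
    stop("non-positive face separation: bodies interpenetrate")
  raw <- p$a * d + p$b * d^3
  out <- if (p$mode == "clamped") pmax(0, -raw) else raw
  out[d >= p$eps] <- 0
  out
}

#' Repulsion forces and torques on the tumor cell
#'
#' Applies [repulsion_magnitude()] to every gated pair along the unit
#' vector from the PMN face to the TC face (pushing the TC away), sums the
#' components, and takes torques about the TC centroid. The equal and
#' opposite share on the PMN is returned for completeness but unused when
#' the PMN is fixed.
#'
#' @param pairs output of [gated_face_pairs()] (pairs with `d >= eps`
#'   contribute exactly zero and may be included freely).
#' @param tc_faces the TC `face_set` the pairs refer to.
#' @param p a [repulsion_params()].
#' @return list with `F`, `T` on the TC, `F_pmn`, `T_pmn` (opposite
#'   share, torque about the PMN-side pair centroids omitted), and
#'   `n_active` (pairs with non-zero force).
#' @export
repulsion_loads <- function(pairs, tc_faces, p) {
  if (!nrow(pairs))
    return(list(F = c(0, 0, 0), T = c(0, 0, 0),
                F_pmn = c(0, 0, 0), n_active = 0L))
  mag <- repulsion_magnitude(pairs$d, p)
  e <- as.matrix(pairs[, c("ex", "ey", "ez")])
  fvec <- mag * e
  it <- match(pairs$tc_face, tc_faces$face_ids)
  levers <- tc_faces$levers[it, , drop = FALSE]
  Fv <- unname(colSums(fvec))
  list(F = Fv,
       T = unname(colSums(vec_cross(levers, fvec))),
       F_pmn = -Fv,
       n_active = sum(mag != 0))
}
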