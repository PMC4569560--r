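## ---------------------------------------------------------------------------
## Localized stochastic bond kinetics: Bell-model rates per face pair, the
## discretization correction factor, the molecule-availability ledger, and
## probabilistic bond formation/breakage.
## ---------------------------------------------------------------------------

#' Kinetic and spring parameters of one receptor-ligand pair
#'
#' Slip-bond (Bell/Dembo) parameters of one molecule-pair type. With the
#' reference values (`s = 2e-3`, `s_ts = 1e-3` N/m) the dissociation rate
#' grows with bond strain while the formation rate decays, so bonds are
#' most likely to form -- and least likely to break -- at the equilibrium
#' spring length `lambda`.
#'
#' `kon0` is the equilibrium formation rate per available partner molecule:
#' `kon0 * (available molecule count)` is a rate in 1/s.
#'
#' @param name label, e.g. `"ICAM1:LFA1"`.
#' @param tc_species,pmn_species names of the participating molecule
#'   species on the tumor cell and the PMN.
#' @param kon0 equilibrium formation rate \[1/s per molecule\].
#' @param koff0 equilibrium dissociation rate \[1/s\].
#' @param s bond spring constant \[N/m\].
#' @param s_ts transition-state spring constant \[N/m\].
#' @param lambda equilibrium spring length \[m\].
#' @return an object of class `bond_type`.
#' @export
bond_type <- function(name, tc_species, pmn_species,
                      kon0 = 3000, koff0 = 0.3,
                      s = 2e-3, s_ts = 1e-3, lambda = 0.05e-6) {
  for (p in c("kon0", "koff0", "s", "s_ts", "lambda"))
    check_scalar(get(p), p)
  structure(list(name = name, tc_species = tc_species,
                 pmn_species = pmn_species, kon0 = kon0, koff0 = koff0,
                 s = s, s_ts = s_ts, lambda = lambda),
            class = "bond_type")
}

#' An adhesion molecule species
#'
#' @param name species name (e.g. `"ICAM1"`).
#' @param density uniform surface density \[molecules/m^2\], >= 0.
#' @param body which cell expresses it: `"tc"` or `"pmn"`.
#' @return an object of class `molecule_species`.
#' @export
molecule_species <- function(name, density, body = c("tc", "pmn")) {
  body <- match.arg(body)
  if (!is.numeric(density) || length(density) != 1L || density < 0)
    stop("'density' must be a single non-negative number")
  structure(list(name = name, density = density, body = body),
            class = "molecule_species")
}

#' Kinetic environment shared by all bond types
#'
#' @param temperature absolute temperature \[K\].
#' @param dt timestep / coupling interval \[s\].
#' @param eps_mv microvilli standoff \[m\]: molecules are assumed to sit at
#'   fully extended microvillus tips, so the bond coordinate is the face
#'   separation minus `eps_mv`. Set 0 in fixture mode so raw gap distances
#'   feed the kinetics directly.
#' @param kb Boltzmann constant \[J/K\].
#' @return an object of class `kinetic_env`.
#' @export
kinetic_env <- function(temperature = 310.15, dt = 1e-3,
                        eps_mv = 1.2e-6, kb = .kB) {
  check_scalar(temperature, "temperature")
  check_scalar(dt, "dt")
  if (!is.numeric(eps_mv) || length(eps_mv) != 1L || eps_mv < 0)
    stop("'eps_mv' must be a single non-negative length")
  structure(list(temperature = temperature, dt = dt, eps_mv = eps_mv,
                 kb = kb), class = "kinetic_env")
}

#' Molecules on each face of a face set
#'
#' Distributes a species uniformly: `count(face) = density * area(face)`.
#' Counts are deliberately *not* rounded -- a face may carry a fractional
#' number of molecules, which keeps the surface-total exact and unbiased at
#' any mesh resolution (rounding would bias bond formation toward faces
#' rounded up).
#'
#' @param species a [molecule_species()].
#' @param faces a `face_set`.
#' @return numeric vector of per-face molecule counts.
#' @export
molecules_per_face <- function(species, faces) {
  species$density * faces$areas
}

#' Bond coordinate from a face separation
#'
#' The signed kinetic distance `d_kin = d_face - eps_mv` fed to the rate
#' expressions: with molecules at microvillus tips, a face separation of
#' `eps_mv + lambda` is an unstrained bond.
#'
#' @param d_face face centroid separation \[m\], >= 0.
#' @param env a [kinetic_env()].
#' @return signed bond coordinate \[m\].
#' @export
bond_coordinate <- function(d_face, env) {
  if (any(d_face < 0)) stop("'d_face' must be non-negative")
  d_face - env$eps_mv
}

#' Local bond formation rate on one face pair
#'
#' `kon = kon0 * n_avail * exp(-s_ts (d_kin - lambda)^2 / (2 kb T))`,
#' where `n_avail` is the currently available molecule count on the partner
#' (PMN) face. The rate is gated to zero outside `0 < d_kin < 2 lambda`:
#' beyond twice the equilibrium length the exponential is negligible and
#' the cutoff only trims useless work.
#'
#' @param d_kin signed bond coordinate(s) \[m\].
#' @param n_avail available partner molecule count(s), >= 0.
#' @param p a [bond_type()].
#' @param env a [kinetic_env()].
#' @return formation rate(s) \[1/s\].
#' @export
local_kon <- function(d_kin, n_avail, p, env) {
  if (any(n_avail < 0)) stop("negative molecule availability: ledger corrupt")
  k <- p$kon0 * n_avail *
    exp(-p$s_ts * (d_kin - p$lambda)^2 / (2 * env$kb * env$temperature))
  k[!(d_kin > 0 & d_kin < 2 * p$lambda)] <- 0
  k
}

#' Bond dissociation rate
#'
#' `koff = koff0 * exp((s - s_ts)(d_kin - lambda)^2 / (2 kb T))`. At the
#' equilibrium length this is exactly `koff0`; with `s > s_ts` it grows
#' with strain (slip bond), and with `s == s_ts` it is strain-independent.
#'
#' @inheritParams local_kon
#' @return dissociation rate(s) \[1/s\].
#' @export
koff <- function(d_kin, p, env) {
  p$koff0 * exp((p$s - p$s_ts) * (d_kin - p$lambda)^2 /
                  (2 * env$kb * env$temperature))
}

#' Probability of at least one event in a timestep
#'
#' `P = 1 - exp(-rate * dt)`, the memoryless (Poisson) event probability.
#'
#' @param rate event rate(s) \[1/s\], >= 0.
#' @param dt interval \[s\], positive.
#' @return probability in \[0, 1\].
#' @export
event_probability <- function(rate, dt) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  check_scalar(dt, "dt")
  -expm1(-rate * dt)
}

#' Discretization correction factor for local formation rates
#'
#' Rescales per-face-pair rates so that their mean over the gated pairs
#' equals the single whole-contact-area rate computed the classical way:
#' `kon_global = (sum of partner molecules) * kon0 *
#' exp(-s_ts (d_centroid - lambda)^2 / (2 kb T))` with `d_centroid` the
#' distance between the two *cell* centroids, `kon_average` the mean of the
#' non-zero local rates, and `factor = kon_global / kon_average`.
#'
#' At whole-cell centroid separations (micrometres against a 0.05 um
#' equilibrium length) the global exponential underflows to exactly zero in
#' double precision; rescaling by 0/`kon_average` would erase the local
#' structure, so the factor is then forced to 1 and flagged. The rescaling
#' identity is meaningful -- and enforced -- whenever the global value is
#' representable.
#'
#' @param local_kons numeric vector of local rates over candidate pairs.
#' @param total_navail total available partner molecules over all faces.
#' @param d_centroid distance between the two cell centroids \[m\].
#' @param p a [bond_type()].
#' @param env a [kinetic_env()].
#' @param warn emit a warning when the factor is forced to 1.
#' @return scalar factor with attributes `kon_global`, `kon_average`,
#'   `degenerate`.
#' @export
correction_factor <- function(local_kons, total_navail, d_centroid, p, env,
                              warn = TRUE) {
  gated <- local_kons[local_kons > 0]
  kon_global <- total_navail * p$kon0 *
    exp(-p$s_ts * (d_centroid - p$lambda)^2 / (2 * env$kb * env$temperature))
  kon_average <- if (length(gated)) mean(gated) else 0
  degenerate <- !is.finite(kon_global) || kon_global <= 0 || kon_average <= 0
  if (degenerate) {
    if (warn)
      warning("correction factor degenerate (global k_on underflow or no ",
              "gated pairs); forcing factor = 1", call. = FALSE)
    factor <- 1
  } else {
    factor <- kon_global / kon_average
  }
  structure(factor, kon_global = kon_global, kon_average = kon_average,
            degenerate = degenerate)
}

## ---------------------------------------------------------------------------
## Molecule ledger and bond bookkeeping
## ---------------------------------------------------------------------------

#' Per-face, per-species molecule availability ledger
#'
#' Two matrices (`tc`, `pmn`) indexed by `[face_id, species]` holding the
#' available -- possibly fractional -- molecule counts, initialized from
#' the species densities and face areas. A forming bond decrements both
#' involved faces; a breaking bond restores exactly what it consumed, so
#' `available + consumed-by-live-bonds == initial` holds per face and
#' species at all times. The two-dimensional indexing is what prevents an
#' ICAM-1 molecule engaged by LFA-1 from being double-booked by Mac-1
#' within the same step.
#'
#' @param tc_faces,pmn_faces `face_set` objects.
#' @param species list of [molecule_species()].
#' @return an object of class `molecule_ledger` with elements `tc`, `pmn`,
#'   `initial`.
#' @export
molecule_ledger <- function(tc_faces, pmn_faces, species) {
  build <- function(faces, body) {
    sp <- Filter(function(s) s$body == body, species)
    if (!length(sp)) stop("no species defined on body '", body, "'")
    m <- vapply(sp, function(s) molecules_per_face(s, faces),
                numeric(length(faces$face_ids)))
    m <- matrix(m, nrow = length(faces$face_ids),
                dimnames = list(NULL, vapply(sp, `[[`, "", "name")))
    m
  }
  tc <- build(tc_faces, "tc")
  pmn <- build(pmn_faces, "pmn")
  structure(list(tc = tc, pmn = pmn, initial = list(tc = tc, pmn = pmn)),
            class = "molecule_ledger")
}

#' Empty bond table
#'
#' Bonds persist across timesteps as rows of a data frame keyed to
#' body-fixed face ids; `tc_used`/`pmn_used` record the (possibly
#' fractional) molecule amount each bond consumed, returned on breakage.
#'
#' @return zero-row bond `data.frame`.
#' @export
empty_bonds <- function() {
  data.frame(tc_face = integer(0), pmn_face = integer(0),
             type = character(0), t_form = numeric(0),
             tc_used = numeric(0), pmn_used = numeric(0),
             stringsAsFactors = FALSE)
}

## availability below this is treated as exhausted
.LEDGER_TOL <- 1e-9

#' One stochastic bond-formation sweep
#'
#' Iterates the bond types (outer loop over TC species, inner over PMN
#' species) and, within each type, the gated face pairs in ascending
#' `(tc_face, pmn_face)` order. For a pair whose TC face currently holds
#' `c = floor(c) + frac` molecules, `floor(c)` uniform draws are compared
#' against the formation probability `P` and one additional draw against
#' `frac * P` (the fractional-molecule rule). Every formed bond consumes
#' one molecule (or the remaining fraction) from each involved face, so
#' partner availability caps formation and depletion within the step is
#' visible to later pairs through the re-read ledger.
#'
#' Pairs whose snapshot probability is below ~1e-14 are skipped without
#' consuming random numbers; availability only decreases within a step, so
#' this cannot drop a feasible event and keeps runs reproducible.
#'
#' @param pairs output of [gated_face_pairs()].
#' @param tc_faces,pmn_faces the `face_set`s the pairs refer to.
#' @param ledger a [molecule_ledger()].
#' @param bond_types list of [bond_type()].
#' @param env a [kinetic_env()].
#' @param time current simulation time \[s\] stamped on new bonds.
#' @param forced_p `NULL` for the kinetic probabilities, or a fixed
#'   probability (e.g. 1 in the verification fixtures) applied to every
#'   gated pair.
#' @return list with `bonds` (new bonds), `ledger` (updated),
#'   `correction` (per-type factors) and `n_underflow` (count of bond types
#'   whose correction factor was forced to 1 this sweep).
#' @export
formation_step <- function(pairs, tc_faces, pmn_faces, ledger, bond_types,
                           env, time = 0, forced_p = NULL) {
  if (!is.null(forced_p) &&
      (!is.numeric(forced_p) || forced_p < 0 || forced_p > 1))
    stop("'forced_p' must be NULL or a probability")
  d_centroid <- vec_norm(tc_faces$origin - pmn_faces$origin)
  rec_t <- integer(0); rec_p <- integer(0); rec_ty <- character(0)
  rec_ut <- numeric(0); rec_up <- numeric(0); rec_d <- numeric(0)
  corr <- list()
  n_underflow <- 0L
  for (bt in bond_types) {
    dk <- pairs$d - env$eps_mv
    g <- which(dk > 0 & dk < 2 * bt$lambda)
    if (!length(g)) next
    n_snap <- ledger$pmn[pairs$pmn_face[g], bt$pmn_species]
    kloc <- local_kon(dk[g], n_snap, bt, env)
    cf <- correction_factor(kloc, sum(ledger$pmn[, bt$pmn_species]),
                            d_centroid, bt, env, warn = FALSE)
    if (attr(cf, "degenerate")) n_underflow <- n_underflow + 1L
    corr[[bt$name]] <- cf
    fac <- as.numeric(cf)
    if (is.null(forced_p)) {
      ## skip pairs that cannot plausibly fire even before depletion
      keep <- kloc * fac * env$dt > 1e-14
      g <- g[keep]
    }
    for (j in g) {
      ti <- pairs$tc_face[j]
      pi <- pairs$pmn_face[j]
      avail_tc <- ledger$tc[ti, bt$tc_species]
      if (avail_tc <= .LEDGER_TOL) next
      if (is.null(forced_p)) {
        np <- ledger$pmn[pi, bt$pmn_species]
        if (np <= .LEDGER_TOL) next
        P <- event_probability(local_kon(dk[j], np, bt, env) * fac, env$dt)
      } else {
        P <- forced_p
      }
      if (P <= 0) next
      n_full <- floor(avail_tc + .LEDGER_TOL)
      frac <- avail_tc - n_full
      if (frac < .LEDGER_TOL) frac <- 0
      ndraw <- n_full + (frac > 0)
      if (ndraw == 0) next
      u <- runif(ndraw)
      thresh <- c(rep.int(P, n_full), if (frac > 0) frac * P)
      for (k in seq_len(ndraw)) {
        if (u[k] >= thresh[k]) next
        a_tc <- ledger$tc[ti, bt$tc_species]
        a_pm <- ledger$pmn[pi, bt$pmn_species]
        if (a_tc <= .LEDGER_TOL || a_pm <= .LEDGER_TOL) break
        use_tc <- min(1, a_tc)
        use_pm <- min(1, a_pm)
        ledger$tc[ti, bt$tc_species] <- a_tc - use_tc
        ledger$pmn[pi, bt$pmn_species] <- a_pm - use_pm
        rec_t <- c(rec_t, ti); rec_p <- c(rec_p, pi)
        rec_ty <- c(rec_ty, bt$name)
        rec_ut <- c(rec_ut, use_tc); rec_up <- c(rec_up, use_pm)
        rec_d <- c(rec_d, pairs$d[j])
      }
    }
  }
  bonds <- if (length(rec_t)) {
    data.frame(tc_face = rec_t, pmn_face = rec_p, type = rec_ty,
               t_form = time, tc_used = rec_ut, pmn_used = rec_up,
               stringsAsFactors = FALSE)
  } else {
    empty_bonds()
  }
  bonds$d_form <- rec_d
  list(bonds = bonds, ledger = ledger, correction = corr,
       n_underflow = n_underflow)
}

#' One stochastic bond-breakage sweep
#'
#' Re-measures every live bond at the bodies' current poses, computes
#' `koff` from the new bond length, and tests each bond independently
#' against `P = 1 - exp(-koff dt)` (memoryless: the model compensates for
#' finite bond lifetimes by giving every bond a fresh chance to break each
#' step). Broken bonds return the molecules they consumed to both faces.
#'
#' @param bonds live bond table.
#' @param tc_faces,pmn_faces current `face_set`s.
#' @param ledger a [molecule_ledger()].
#' @param bond_types list of [bond_type()].
#' @param env a [kinetic_env()].
#' @param forced_p `NULL` or a fixed breakage probability.
#' @return list with `bonds` (survivors), `broken`, `ledger`, and `d`
#'   (per-surviving-bond current separation).
#' @export
breakage_step <- function(bonds, tc_faces, pmn_faces, ledger, bond_types,
                          env, forced_p = NULL) {
  if (!nrow(bonds))
    return(list(bonds = bonds, broken = empty_bonds(), ledger = ledger,
                d = numeric(0)))
  types <- stats::setNames(bond_types,
                           vapply(bond_types, `[[`, "", "name"))
  it <- match(bonds$tc_face, tc_faces$face_ids)
  ip <- match(bonds$pmn_face, pmn_faces$face_ids)
  if (anyNA(it) || anyNA(ip)) stop("bond refers to an unknown face id")
  dvec <- sqrt(rowSums((tc_faces$centroids[it, , drop = FALSE] -
                          pmn_faces$centroids[ip, , drop = FALSE])^2))
  dk <- bond_coordinate(dvec, env)
  P <- if (is.null(forced_p)) {
    rate <- numeric(nrow(bonds))
    for (nm in unique(bonds$type)) {
      sel <- bonds$type == nm
      rate[sel] <- koff(dk[sel], types[[nm]], env)
    }
    event_probability(rate, env$dt)
  } else {
    rep.int(forced_p, nrow(bonds))
  }
  u <- runif(nrow(bonds))
  brk <- u < P
  if (any(brk)) {
    bb <- bonds[brk, , drop = FALSE]
    for (r in seq_len(nrow(bb))) {
      bt <- types[[bb$type[r]]]
      ledger$tc[bb$tc_face[r], bt$tc_species] <-
        ledger$tc[bb$tc_face[r], bt$tc_species] + bb$tc_used[r]
      ledger$pmn[bb$pmn_face[r], bt$pmn_species] <-
        ledger$pmn[bb$pmn_face[r], bt$pmn_species] + bb$pmn_used[r]
    }
  }
  list(bonds = bonds[!brk, , drop = FALSE],
       broken = bonds[brk, , drop = FALSE],
       ledger = ledger,
       d = dvec[!brk])
}

#' Forces and torques from the live bonds
#'
#' Each bond is a Hookean spring of constant `s` and rest length `lambda`
#' acting along the line joining the two bonded face centroids: a bond
#' stretched past `eps_mv + lambda` pulls the tumor cell toward the PMN,
#' a compressed one pushes it away. Forces are summed componentwise and
#' torques taken about the TC centroid with the face lever arms.
#'
#' @inheritParams breakage_step
#' @return list with `F` (3-vector \[N\]), `T` (3-vector \[N m\]) on the
#'   TC, and `force` (per-bond signed spring force, positive = tensile).
#' @export
bond_loads <- function(bonds, tc_faces, pmn_faces, bond_types, env) {
  if (!nrow(bonds))
    return(list(F = c(0, 0, 0), T = c(0, 0, 0), force = numeric(0)))
  types <- stats::setNames(bond_types,
                           vapply(bond_types, `[[`, "", "name"))
  it <- match(bonds$tc_face, tc_faces$face_ids)
  ip <- match(bonds$pmn_face, pmn_faces$face_ids)
  dv <- tc_faces$centroids[it, , drop = FALSE] -
    pmn_faces$centroids[ip, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  e <- dv / ifelse(d > 0, d, 1)
  dk <- bond_coordinate(d, env)
  fmag <- numeric(nrow(bonds))
  for (nm in unique(bonds$type)) {
    sel <- bonds$type == nm
    bt <- types[[nm]]
    fmag[sel] <- bt$s * (dk[sel] - bt$lambda)
  }
  fvec <- -fmag * e   # tensile bonds pull the TC toward the PMN
  levers <- tc_faces$levers[it, , drop = FALSE]
  list(F = colSums(fvec), T = colSums(vec_cross(levers, fvec)), force = fmag)
}

#' Check the molecule-conservation invariant
#'
#' For every face and species: available + amount consumed by live bonds
#' must equal the initial count.
#'
#' @param ledger a [molecule_ledger()].
#' @param bonds live bond table.
#' @param bond_types list of [bond_type()].
#' @return largest absolute deviation from conservation (should be ~1e-12).
#' @export
ledger_conservation_error <- function(ledger, bonds, bond_types) {
  types <- stats::setNames(bond_types,
                           vapply(bond_types, `[[`, "", "name"))
  tc_bound <- ledger$tc * 0
  pm_bound <- ledger$pmn * 0
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bt <- types[[bonds$type[r]]]
      tc_bound[bonds$tc_face[r], bt$tc_species] <-
        tc_bound[bonds$tc_face[r], bt$tc_species] + bonds$tc_used[r]
      pm_bound[bonds$pmn_face[r], bt$pmn_species] <-
        pm_bound[bonds$pmn_face[r], bt$pmn_species] + bonds$pmn_used[r]
    }
  }
  max(abs(ledger$tc + tc_bound - ledger$initial$tc),
      abs(ledger$pmn + pm_bound - ledger$initial$pmn))
}
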