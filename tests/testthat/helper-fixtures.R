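## Shared builders for the test suite. All fixtures are generated in code.

ref_env <- function(dt = 1e-3, eps_mv = 0) {
  kinetic_env(temperature = 310.15, dt = dt, eps_mv = eps_mv)
}

lfa_type <- function() bond_type("ICAM1:LFA1", "ICAM1", "LFA1",
                                 kon0 = 3000, koff0 = 0.3,
                                 s = 2e-3, s_ts = 1e-3, lambda = 0.05e-6)

mac_type <- function() bond_type("ICAM1:MAC1", "ICAM1", "MAC1",
                                 kon0 = 3000, koff0 = 0.29,
                                 s = 2e-3, s_ts = 1e-3, lambda = 0.05e-6)

ref_species <- function() list(
  molecule_species("ICAM1", 13e12, "tc"),
  molecule_species("LFA1", 45e12, "pmn"),
  molecule_species("MAC1", 5e12, "pmn")
)

## planar fixture with a prepared ledger; densities chosen per test
planar_setup <- function(n = 8, face_area = 2.5e-13, gap = 0.05e-6,
                         icam = 13e12, lfa = 45e12, mac = 5e12) {
  pl <- make_parallel_planes(n, face_area, gap)
  sp <- list(molecule_species("ICAM1", icam, "tc"),
             molecule_species("LFA1", lfa, "pmn"),
             molecule_species("MAC1", mac, "pmn"))
  list(tc = pl$tc, pmn = pl$pmn,
       ledger = molecule_ledger(pl$tc, pl$pmn, sp), species = sp)
}

## a face_set with n faces at given centroids (unit areas/normals), for
## ledger-level tests that do not need a real mesh
point_faces <- function(centroids, body_id = "body", area = 1e-13) {
  centroids <- matrix(centroids, ncol = 3)
  n <- nrow(centroids)
  structure(list(
    body_id = body_id, face_ids = seq_len(n), centroids = centroids,
    areas = rep(area, n),
    normals = matrix(rep(c(0, 1, 0), each = n), ncol = 3),
    levers = centroids, origin = c(0, 0, 0)
  ), class = "face_set")
}

## brute-force all-pairs oracle for gated_face_pairs
brute_pairs <- function(tc, pmn, cutoff) {
  d2 <- outer(rowSums(tc$centroids^2), rowSums(pmn$centroids^2), "+") -
    2 * tc$centroids %*% t(pmn$centroids)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d < cutoff, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(tc_face = tc$face_ids[hit[, 1]],
             pmn_face = pmn$face_ids[hit[, 2]],
             d = d[hit])
}

## independent cross-product triangle-area oracle
triangle_areas_oracle <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  vapply(seq_len(nrow(f)), function(i) {
    u <- v[f[i, 2], ] - v[f[i, 1], ]
    w <- v[f[i, 3], ] - v[f[i, 1], ]
    0.5 * sqrt(sum(c(u[2] * w[3] - u[3] * w[2],
                     u[3] * w[1] - u[1] * w[3],
                     u[1] * w[2] - u[2] * w[1])^2))
  }, 0)
}
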