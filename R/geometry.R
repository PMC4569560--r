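## ---------------------------------------------------------------------------
## Discretized cell surfaces: meshes, per-face properties, gated face pairs.
## ---------------------------------------------------------------------------

#' Construct a surface mesh
#'
#' A `surface_mesh` is a triangulated surface: an `n x 3` matrix of vertex
#' positions in metres (body frame), an `m x 3` integer matrix of triangle
#' vertex indices, and stable integer `face_ids` (`1:m`, used as row indices
#' into ledgers and face sets for the lifetime of a simulation).
#'
#' @param vertices numeric `n x 3` matrix, vertex positions \[m\].
#' @param faces integer `m x 3` matrix of vertex indices.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("'vertices' must have three columns")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  mesh <- structure(
    list(vertices = vertices, faces = faces, face_ids = seq_len(nrow(faces))),
    class = "surface_mesh"
  )
  a <- triangle_areas(mesh)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("mesh contains degenerate (zero-area) faces")
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, total area", format(mesh_area(x), digits = 4), "m^2\n")
  invisible(x)
}

triangle_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

triangle_areas <- function(mesh) {
  tc <- triangle_corners(mesh)
  cr <- vec_cross(tc$b - tc$a, tc$c - tc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh \[m^2\]
#' @param mesh a [surface_mesh()].
#' @return total face area in m^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Longest edge of any face \[m\]
#'
#' The mesh resolution convention used throughout the package: a mesh has
#' "maximum element size" `h` when its longest triangle edge is at most `h`.
#'
#' @param mesh a [surface_mesh()].
#' @return maximum edge length in metres.
#' @export
mesh_max_edge <- function(mesh) {
  tc <- triangle_corners(mesh)
  max(sqrt(rowSums((tc$a - tc$b)^2)),
      sqrt(rowSums((tc$b - tc$c)^2)),
      sqrt(rowSums((tc$c - tc$a)^2)))
}

#' Enclosed volume and volume centroid of a closed mesh
#'
#' Divergence-theorem sums over origin-based tetrahedra. The volume is
#' signed: positive for an outward-oriented closed surface.
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_volume`: signed volume \[m^3\]. `mesh_volume_centroid`:
#'   centroid of the enclosed solid \[m\].
#' @export
mesh_volume <- function(mesh) {
  tc <- triangle_corners(mesh)
  sum(rowSums(tc$a * vec_cross(tc$b, tc$c))) / 6
}

#' @rdname mesh_volume
#' @export
mesh_volume_centroid <- function(mesh) {
  tc <- triangle_corners(mesh)
  vt <- rowSums(tc$a * vec_cross(tc$b, tc$c)) / 6
  ct <- (tc$a + tc$b + tc$c) / 4
  colSums(ct * vt) / sum(vt)
}

## flip faces whose normal points toward `interior`, so all normals are
## outward; valid for star-shaped bodies (all meshes built here are convex)
orient_outward <- function(mesh, interior = c(0, 0, 0)) {
  tc <- triangle_corners(mesh)
  nrm <- vec_cross(tc$b - tc$a, tc$c - tc$a)
  cen <- (tc$a + tc$b + tc$c) / 3
  out <- sweep(cen, 2, interior, "-")
  flip <- rowSums(nrm * out) < 0
  if (any(flip))
    mesh$faces[flip, c(2, 3)] <- mesh$faces[flip, c(3, 2)]
  mesh
}

## one loop of 4:1 triangle subdivision with shared-edge midpoint caching
subdivide_mesh <- function(vertices, faces) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vertices
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- env[[key]]
    if (!is.null(idx)) return(idx)
    verts <<- rbind(verts, (vertices[i, ] + vertices[j, ]) / 2)
    idx <- nrow(verts)
    env[[key]] <- idx
    idx
  }
  out <- matrix(0L, nrow = 4L * nrow(faces), ncol = 3)
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    ab <- midpoint(f[1], f[2])
    bc <- midpoint(f[2], f[3])
    ca <- midpoint(f[3], f[1])
    out[4L * k - 3L, ] <- c(f[1], ab, ca)
    out[4L * k - 2L, ] <- c(f[2], bc, ab)
    out[4L * k - 1L, ] <- c(f[3], ca, bc)
    out[4L * k, ]      <- c(ab, bc, ca)
  }
  list(vertices = verts, faces = out)
}

#' Triangulated sphere by icosahedron subdivision
#'
#' Builds a closed sphere mesh with `20 * 4^subdivisions` faces. Vertices
#' are placed slightly outside the nominal radius so that the face
#' *centroids* -- where the model locates all adhesion molecules and
#' measures all face-to-face distances -- lie on the nominal cell surface
#' (the mean centroid radius equals `radius`). Without this, centroids of a
#' coarse mesh sit a chord-sagitta inside the sphere and every centroid
#' distance reads systematically large, an artifact that grows with element
#' size and would contaminate mesh-refinement comparisons.
#'
#' @param radius sphere radius \[m\], positive.
#' @param subdivisions non-negative integer subdivision level.
#' @return a [surface_mesh()] centred on the origin.
#' @export
#' @examples
#' m <- make_icosphere(um(4), 3)
#' nrow(m$faces)              # 1280
#' mesh_area(m) / (4 * pi * um(4)^2)  # ~1
make_icosphere <- function(radius, subdivisions = 3L) {
  check_scalar(radius, "radius")
  if (!is.numeric(subdivisions) || length(subdivisions) != 1L ||
      subdivisions < 0 || subdivisions != round(subdivisions))
    stop("'subdivisions' must be a non-negative integer")
  if (subdivisions > 7) stop("'subdivisions' > 7 is not supported")
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  phi, 0,   1,  phi, 0,   -1, -phi, 0,   1, -phi, 0,
     0, -1,  phi,  0,  1,  phi,   0, -1, -phi,  0,  1, -phi,
     phi, 0, -1,   phi, 0,  1,   -phi, 0, -1,  -phi, 0,  1
  ), ncol = 3, byrow = TRUE)
  f <- matrix(c(
    1, 12, 6,   1, 6, 2,    1, 2, 8,    1, 8, 11,   1, 11, 12,
    2, 6, 10,   6, 12, 5,   12, 11, 3,  11, 8, 7,   8, 2, 9,
    4, 10, 5,   4, 5, 3,    4, 3, 7,    4, 7, 9,    4, 9, 10,
    5, 10, 6,   3, 5, 12,   7, 3, 11,   9, 7, 8,    10, 9, 2
  ), ncol = 3, byrow = TRUE)
  for (i in seq_len(subdivisions)) {
    s <- subdivide_mesh(v, f)
    v <- s$vertices
    f <- s$faces
  }
  ## project to the unit sphere, then inflate so mean centroid radius = 1
  v <- v / sqrt(rowSums(v^2))
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  v <- v / mean(sqrt(rowSums(cen^2)))
  orient_outward(surface_mesh(v * radius, f))
}

#' Smallest icosphere subdivision level meeting a maximum element size
#'
#' @param radius sphere radius \[m\].
#' @param max_element requested maximum edge length \[m\].
#' @return integer subdivision level.
#' @export
icosphere_subdivisions_for <- function(radius, max_element) {
  check_scalar(radius, "radius")
  check_scalar(max_element, "max_element")
  for (s in 0:7) {
    if (mesh_max_edge(make_icosphere(radius, s)) <= max_element) return(s)
  }
  stop("requested 'max_element' needs more than 7 subdivisions")
}

#' Spherical-cap mesh for the adherent PMN
#'
#' A parametric stand-in for the flattened, shear-rate-dependent shape of a
#' substrate-adherent neutrophil: the spherical cap with base radius
#' `base_radius` and apex height `height`, resting on the substrate plane
#' `y = 0` with the apex at `y = height` (a hemisphere when the two are
#' equal). The base disc is triangulated in concentric rings so every face
#' respects the element-size convention. Lateral vertices are inflated so
#' face centroids sit on the nominal spherical surface (see
#' [make_icosphere()]); any vertex pushed below the substrate is clamped
#' back to `y = 0`.
#'
#' @param base_radius radius of the contact disc on the substrate \[m\].
#' @param height apex height above the substrate \[m\].
#' @param resolution integer >= 2: number of latitude rings between apex
#'   and rim; azimuthal segments are `4 * resolution`.
#' @return a closed [surface_mesh()]; body frame has the base centre at the
#'   origin and `y` as the wall-normal axis.
#' @export
make_pmn_cap <- function(base_radius, height, resolution = 8L) {
  check_scalar(base_radius, "base_radius")
  check_scalar(height, "height")
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 2 || resolution != round(resolution))
    stop("'resolution' must be an integer >= 2")
  a <- base_radius
  h <- height
  R <- (a^2 + h^2) / (2 * h)      # radius of the generating sphere
  yc <- h - R                      # its centre on the y axis
  n <- as.integer(resolution)
  m <- 4L * n                      # azimuthal segments
  theta_rim <- acos(pmin(1, pmax(-1, (R - h) / R)))
  phi <- 2 * pi * (seq_len(m) - 1) / m

  verts <- matrix(c(0, h, 0), ncol = 3)              # 1: apex
  ring_idx <- list()
  for (i in seq_len(n)) {                            # lateral rings, apex->rim
    th <- theta_rim * i / n
    ring <- cbind(R * sin(th) * cos(phi), yc + R * cos(th), R * sin(th) * sin(phi))
    ring_idx[[i]] <- nrow(verts) + seq_len(m)
    verts <- rbind(verts, ring)
  }
  n_lateral_vert <- nrow(verts)
  base_idx <- list()
  for (k in seq_len(n - 1)) {                        # base rings, rim->centre
    r_k <- a * (n - k) / n
    ring <- cbind(r_k * cos(phi), 0, r_k * sin(phi))
    base_idx[[k]] <- nrow(verts) + seq_len(m)
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, c(0, 0, 0))                  # base centre
  centre_id <- nrow(verts)

  quad_strip <- function(upper, lower) {
    f <- matrix(0L, nrow = 2L * m, ncol = 3)
    for (j in seq_len(m)) {
      jn <- if (j == m) 1L else j + 1L
      f[2L * j - 1L, ] <- c(upper[j], lower[j], lower[jn])
      f[2L * j, ]      <- c(upper[j], lower[jn], upper[jn])
    }
    f
  }
  faces <- matrix(0L, nrow = 0, ncol = 3)
  fan <- cbind(1L, ring_idx[[1]], c(ring_idx[[1]][-1], ring_idx[[1]][1]))
  faces <- rbind(faces, fan)
  for (i in seq_len(n - 1))
    faces <- rbind(faces, quad_strip(ring_idx[[i]], ring_idx[[i + 1]]))
  rings_down <- c(list(ring_idx[[n]]), base_idx)     # rim then inward rings
  for (k in seq_len(length(rings_down) - 1))
    faces <- rbind(faces, quad_strip(rings_down[[k]], rings_down[[k + 1]]))
  last <- rings_down[[length(rings_down)]]
  faces <- rbind(faces, cbind(centre_id, last, c(last[-1], last[1])))

  ## centroid-on-surface inflation of the lateral (spherical) vertices
  mesh0 <- surface_mesh(verts, faces)
  lat_face <- apply(mesh0$faces <= n_lateral_vert, 1, all)
  tc <- triangle_corners(mesh0)
  cen <- (tc$a + tc$b + tc$c) / 3
  rc <- sqrt(cen[lat_face, 1]^2 + (cen[lat_face, 2] - yc)^2 + cen[lat_face, 3]^2)
  k_inf <- R / mean(rc)
  lat <- seq_len(n_lateral_vert)
  verts[lat, 1] <- verts[lat, 1] * k_inf
  verts[lat, 3] <- verts[lat, 3] * k_inf
  verts[lat, 2] <- yc + (verts[lat, 2] - yc) * k_inf
  verts[verts[, 2] < 0, 2] <- 0
  orient_outward(surface_mesh(verts, faces), interior = c(0, h / 4, 0))
}

#' Smallest cap resolution meeting a maximum element size
#' @inheritParams make_pmn_cap
#' @param max_element requested maximum edge length \[m\].
#' @return integer resolution.
#' @export
cap_resolution_for <- function(base_radius, height, max_element) {
  check_scalar(max_element, "max_element")
  for (res in 2:128) {
    if (mesh_max_edge(make_pmn_cap(base_radius, height, res)) <= max_element)
      return(res)
  }
  stop("requested 'max_element' needs resolution > 128")
}

#' World-frame per-face properties of a posed mesh
#'
#' Applies a rigid pose (rotation then translation) to a mesh and returns
#' the quantities the interaction models consume: face centroids, areas,
#' outward unit normals and lever arms (centroid minus body origin).
#'
#' @param mesh a [surface_mesh()].
#' @param pose `NULL` (identity) or a list/[rigid_state()] with elements
#'   `x` (translation \[m\]) and `q` (unit quaternion, scalar first).
#' @param body_id label carried through to logs.
#' @return an object of class `face_set` with elements `face_ids`,
#'   `centroids` (f x 3), `areas` (f), `normals` (f x 3), `levers` (f x 3)
#'   and `origin`.
#' @export
face_properties <- function(mesh, pose = NULL, body_id = "body") {
  if (is.null(pose)) pose <- list(x = c(0, 0, 0), q = quat_identity())
  q <- quat_normalize(pose$q)
  Rm <- quat_to_matrix(q)
  v <- mesh$vertices %*% t(Rm)
  v <- sweep(v, 2, pose$x, "+")
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  ce <- v[f[, 3], , drop = FALSE]
  cr <- vec_cross(b - a, ce - a)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("posed mesh contains a zero-area face")
  centroids <- (a + b + ce) / 3
  structure(list(
    body_id = body_id,
    face_ids = mesh$face_ids,
    centroids = centroids,
    areas = areas,
    normals = cr / (2 * areas),
    levers = sweep(centroids, 2, pose$x, "-"),
    origin = as.numeric(pose$x)
  ), class = "face_set")
}

#' @export
print.face_set <- function(x, ...) {
  cat("face_set '", x$body_id, "': ", length(x$face_ids), " faces, area ",
      format(sum(x$areas), digits = 4), " m^2\n", sep = "")
  invisible(x)
}

#' All face pairs closer than a cutoff
#'
#' Returns exactly the pairs of (TC face, PMN face) whose centroid
#' separation is strictly below `cutoff`, together with the separation `d`
#' and the unit vector `e` pointing from the PMN face centroid to the TC
#' face centroid. Internally the search bins faces into cells of side
#' `cutoff`; the output is identical (as a set) to brute-force all-pairs
#' filtering, and rows are ordered by `(tc_face, pmn_face)` so downstream
#' stochastic processing is reproducible.
#'
#' @param tc,pmn `face_set` objects for the two bodies.
#' @param cutoff gating distance \[m\], positive.
#' @return a `data.frame` with columns `tc_face`, `pmn_face`, `d`, `ex`,
#'   `ey`, `ez` (possibly zero rows).
#' @export
gated_face_pairs <- function(tc, pmn, cutoff) {
  check_scalar(cutoff, "cutoff")
  ct <- tc$centroids
  cp <- pmn$centroids
  empty <- data.frame(tc_face = integer(0), pmn_face = integer(0),
                      d = numeric(0), ex = numeric(0), ey = numeric(0),
                      ez = numeric(0))
  ## exact bounding-sphere prune: a face farther from the other body's
  ## centroid cloud than (cloud radius + cutoff) cannot gate with anything
  cen_p <- colMeans(cp)
  R_p <- sqrt(max(rowSums(sweep(cp, 2, cen_p, "-")^2)))
  keep_t <- which(sqrt(rowSums(sweep(ct, 2, cen_p, "-")^2)) < R_p + cutoff)
  if (!length(keep_t)) return(empty)
  cen_t <- colMeans(ct)
  R_t <- sqrt(max(rowSums(sweep(ct, 2, cen_t, "-")^2)))
  keep_p <- which(sqrt(rowSums(sweep(cp, 2, cen_t, "-")^2)) < R_t + cutoff)
  if (!length(keep_p)) return(empty)
  ct <- ct[keep_t, , drop = FALSE]
  cp <- cp[keep_p, , drop = FALSE]
  bt <- floor(ct / cutoff)
  bp <- floor(cp / cutoff)
  keys <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  pmn_bins <- split(seq_len(nrow(cp)), keys(bp))
  tc_bins <- split(seq_len(nrow(ct)), keys(bt))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  acc_t <- integer(0); acc_p <- integer(0); acc_d <- numeric(0)
  for (bin in tc_bins) {
    base <- bt[bin[1], ]
    nb <- paste(base[1] + off[, 1], base[2] + off[, 2], base[3] + off[, 3],
                sep = ",")
    cand <- unlist(pmn_bins[nb], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    dx <- outer(ct[bin, 1], cp[cand, 1], "-")
    dy <- outer(ct[bin, 2], cp[cand, 2], "-")
    dz <- outer(ct[bin, 3], cp[cand, 3], "-")
    dm <- sqrt(dx * dx + dy * dy + dz * dz)
    hit <- which(dm < cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    acc_t <- c(acc_t, bin[hit[, 1]])
    acc_p <- c(acc_p, cand[hit[, 2]])
    acc_d <- c(acc_d, dm[hit])
  }
  if (!length(acc_t)) return(empty)
  acc_t <- keep_t[acc_t]
  acc_p <- keep_p[acc_p]
  o <- order(acc_t, acc_p)
  tcf <- tc$face_ids[acc_t[o]]
  pmf <- pmn$face_ids[acc_p[o]]
  d <- acc_d[o]
  ev <- (tc$centroids[acc_t[o], , drop = FALSE] -
           pmn$centroids[acc_p[o], , drop = FALSE])
  safe <- ifelse(d > 0, d, 1)
  ev <- ev / safe
  ev[d == 0, ] <- 0
  data.frame(tc_face = tcf, pmn_face = pmf, d = d,
             ex = ev[, 1], ey = ev[, 2], ez = ev[, 3])
}
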