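## ---------------------------------------------------------------------------
## Output writers: trajectory / bond-log CSV with a provenance header,
## OFF and legacy ASCII VTK mesh snapshots, minimal OBJ import.
## ---------------------------------------------------------------------------

output_header <- function(cfg, extra = character(0)) {
  c(paste0("# adhesim ", as.character(utils::packageVersion("adhesim"))),
    paste0("# config_hash: ", config_hash(cfg)),
    paste0("# seed: ", cfg$seed),
    paste0("# flow model: analytic near-wall shear surrogate ",
           "(Stokes drag + wall corrections), not a CFD solution"),
    extra)
}

write_csv_with_header <- function(df, path, cfg, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(cfg, extra), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write the trajectory / bond-event log of a simulation
#'
#' CSV files prefixed with a `#` comment header carrying the package
#' version, configuration hash, RNG seed and the flow-surrogate
#' disclaimer.
#'
#' @param sim an `adhesim_sim` from [simulate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  write_csv_with_header(sim$trajectory, path, sim$config,
                        paste0("# status: ", sim$status))
}

#' @rdname write_trajectory_csv
#' @export
write_bond_log_csv <- function(sim, path) {
  log <- sim$bond_log
  if (is.null(log)) log <- data.frame(step = integer(0), time_s = numeric(0),
                                      event = character(0),
                                      tc_face = integer(0),
                                      pmn_face = integer(0),
                                      bond_type = character(0),
                                      d_face_m = numeric(0),
                                      d_kin_m = numeric(0),
                                      force_N = numeric(0))
  write_csv_with_header(log, path, sim$config)
}

#' Export a mesh as OFF or legacy ASCII VTK PolyData
#'
#' Plain-text snapshot formats for external visualization. `pose` poses
#' the mesh in the world frame first.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param pose optional pose (list with `x`, `q`).
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path, pose = NULL) {
  v <- posed_vertices(mesh, pose)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(v), nrow(mesh$faces), 0), con)
  writeLines(apply(format(v, digits = 10, scientific = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
write_mesh_vtk <- function(mesh, path, pose = NULL) {
  v <- posed_vertices(mesh, pose)
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "adhesim cell surface", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(v), "double")), con)
  writeLines(apply(format(v, digits = 10, scientific = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(paste("POLYGONS", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

posed_vertices <- function(mesh, pose) {
  if (is.null(pose)) return(mesh$vertices)
  v <- mesh$vertices %*% t(quat_to_matrix(quat_normalize(pose$q)))
  sweep(v, 2, pose$x, "+")
}

#' Minimal Wavefront OBJ import
#'
#' Reads `v` and (triangular) `f` records; enough to bring in a
#' user-supplied cell shape. Polygonal faces are fan-triangulated.
#'
#' @param path OBJ file path.
#' @param scale multiplied into vertex coordinates (e.g. `1e-6` for a
#'   file authored in micrometres).
#' @return a [surface_mesh()].
#' @export
read_obj <- function(path, scale = 1) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("no vertices/faces found in ", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(p) as.numeric(p[1:3]))) * scale
  tris <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
    for (k in seq_len(length(idx) - 2))
      tris[[length(tris) + 1L]] <- c(idx[1], idx[k + 1], idx[k + 2])
  }
  surface_mesh(verts, do.call(rbind, tris))
}
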