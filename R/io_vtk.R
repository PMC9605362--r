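# Legacy-ASCII VTK export for meshes (hexahedron cells) and beam networks
# (line cells), plus a minimal command-line entry point.

#' Write a hexahedral mesh as a legacy VTK unstructured grid
#'
#' Tissue tags are written as integer cell data; node sets as integer point
#' masks.
#'
#' @param mesh a [hex_mesh()].
#' @param file output path (`.vtk`).
#' @export
write_vtk_mesh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  N <- nrow(mesh$nodes); E <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "outflowve hex mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", N)),
             con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", E, E * 9), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(as.character(rep(12L, E)), con)
  writeLines(c(sprintf("CELL_DATA %d", E), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$tissue, TISSUES) - 1L), con)
  if (length(mesh$node_sets)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(mesh$node_sets)) {
      writeLines(c(sprintf("SCALARS %s int 1", nm), "LOOKUP_TABLE default"),
                 con)
      mask <- integer(N)
      mask[mesh$node_sets[[nm]]] <- 1L
      writeLines(as.character(mask), con)
    }
  }
  invisible(file)
}

#' Write a beam network as VTK line cells
#'
#' @param beams a [distribute_beams()] network.
#' @param file output path.
#' @param seg_data optional named list of per-segment numeric scalars (e.g.
#'   axial stress).
#' @export
write_vtk_beams <- function(beams, file, seg_data = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  B <- nrow(beams$control_points); S <- nrow(beams$segments)
  writeLines(c("# vtk DataFile Version 3.0", "outflowve beam network",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", B)), con)
  utils::write.table(beams$control_points, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", S, S * 3), con)
  utils::write.table(cbind(2L, beams$segments - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", S), con)
  writeLines(as.character(rep(3L, S)), con)
  writeLines(c(sprintf("CELL_DATA %d", S), "SCALARS group int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(beams$group))), con)
  if (!is.null(seg_data)) for (nm in names(seg_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(as.character(seg_data[[nm]]), con)
  }
  invisible(file)
}

#' Command-line entry point
#'
#' Subcommands: `synth scene|specimen|trajectory|lumen`, `mesh`, `report`.
#' Example: `Rscript -e 'outflowve::outflowve_cli()' synth scene --seed 1
#' --out scene.csv`.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the output path(s).
#' @export
outflowve_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  out <- getopt("--out", "out")
  cmd <- if (length(args)) args[1] else "help"
  sub <- if (length(args) > 1 && !startsWith(args[2], "--")) args[2] else ""
  if (cmd == "synth" && sub == "scene") {
    sc <- generate_scene(seed)
    b <- do.call(rbind, lapply(names(sc$boundaries), function(nm)
      cbind(boundary = nm, sc$boundaries[[nm]])))
    utils::write.csv(b, out, row.names = FALSE)
  } else if (cmd == "synth" && sub == "specimen") {
    gt <- load_param_tables()$specimen
    curve <- generate_specimen_curve(
      visco_params(gt$G0_MPa[1], gt$Ginf_MPa[1], gt$beta_per_s[1]),
      visco_params(gt$G0_MPa[2], gt$Ginf_MPa[2], gt$beta_per_s[2]))
    utils::write.csv(curve, out, row.names = FALSE)
  } else if (cmd == "synth" && sub == "trajectory") {
    sc <- generate_scene(seed, width_um = 120)
    tr <- generate_boundary_trajectory(sc, load_protocol("sc_pressure_ramp"))
    write_trajectory_csv(tr, out)
  } else if (cmd == "synth" && sub == "lumen") {
    st <- generate_sc_lumen_stack(seed = seed)
    d <- vapply(st, fit_circle_diameter, 1)
    utils::write.csv(data.frame(section = seq_along(d), diameter_um = d),
                     out, row.names = FALSE)
  } else if (cmd == "mesh") {
    sc <- generate_scene(seed)
    pr <- load_protocol("sc_pressure_ramp")
    sm <- build_scene_model(sc, pr,
                            edge_um = as.numeric(getopt("--edge", "10")))
    write_vtk_mesh(sm$mesh, out)
  } else if (cmd == "report") {
    write_report(load_param_tables(), out)
  } else {
    cat("usage: outflowve_cli synth scene|specimen|trajectory|lumen |",
        "mesh | report [--seed i] [--out path] [--edge um]\n")
  }
  invisible(out)
}
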