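# Synthetic-data generators: OCT-like cross-section scenes, forward-simulated
# boundary trajectories with known ground truth, specimen stress-strain
# curves, TM-displacement-vs-IOP curves, and SC-lumen cross-section stacks.
# These stand in for the unpublished experimental recordings so that every
# pipeline stage is exercisable at desk scale with a recoverable truth.

#' Default ground-truth parameter sets (healthy 115LF row group)
#'
#' Tissue and beam-group viscoelastic parameters taken from the shipped
#' fitted-parameter fixtures; the conventional decay constants are 109 1/s
#' for tissues and 450 1/s for beam groups.
#'
#' @param model_id row-group id in the fixtures (default "115LF").
#' @return named list of [visco_params()] for TM, JCT, SC_wall, TM_beam,
#'   JCT_beam.
#' @export
default_ground_truth <- function(model_id = "115LF") {
  tab <- rbind(load_param_tables()$healthy, load_param_tables()$glaucoma)
  rows <- tab[tab$model_id == model_id, ]
  if (nrow(rows) == 0) stop("unknown model_id ", model_id)
  out <- lapply(seq_len(nrow(rows)), function(i)
    visco_params(rows$G0_MPa[i], rows$Ginf_MPa[i], rows$beta_per_s[i]))
  rename <- c("TM" = "TM", "JCT" = "JCT", "SC" = "SC_wall",
              "TM Beam Element" = "TM_beam", "JCT Beam Element" = "JCT_beam")
  names(out) <- rename[rows$group]
  out
}

#' Pressurization / loading protocol
#'
#' @param kind one of `"sc_pressure_ramp"`, `"iop_ramp"`, `"uniaxial_strain"`.
#' @param p_start,p_end pressures in mmHg (or strain for uniaxial).
#' @param duration total protocol time, s.
#' @param t_ramp rise time of the ramp (default `duration/6`); the load is
#'   held at `p_end` afterwards. The synthetic ramp is linear; the original
#'   recordings' pressure profile is not published, so a linear rise with
#'   hold is the package's stated protocol.
#' @return list of class `load_protocol`.
#' @export
load_protocol <- function(kind = c("sc_pressure_ramp", "iop_ramp",
                                   "uniaxial_strain"),
                          p_start = 0, p_end = 30, duration = 0.06,
                          t_ramp = duration / 6) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("duration must be > 0")
  if (t_ramp <= 0 || t_ramp > duration) stop("t_ramp must be in (0, duration]")
  structure(list(kind = kind, p_start = p_start, p_end = p_end,
                 duration = duration, t_ramp = t_ramp),
            class = "load_protocol")
}

protocol_series <- function(protocol) {
  list(times = c(0, protocol$t_ramp, protocol$duration),
       values = c(protocol$p_start, protocol$p_end, protocol$p_end))
}

#' Generate a synthetic TM/JCT/SC cross-section scene
#'
#' Boundaries are ordered anterior to posterior: `TM_anterior`,
#' `TM_posterior` (TM/JCT interface), `JCT_band` (JCT/SC-wall interface),
#' `SC_inner_wall`, and `SC_outer_wall` (far side of the canal lumen, not
#' meshed). The JCT band is 14 um and the SC inner wall 2.2 um thick by
#' construction. Undulation is a smooth seeded sum of three sinusoids with
#' amplitude `waviness` times the TM depth.
#'
#' @param seed integer RNG seed; the same seed gives a bit-identical scene.
#' @param width_um band width (>= 100).
#' @param waviness undulation amplitude fraction in `[0, 0.3]`.
#' @param tm_depth_um mean TM band depth (60-120 um; default 90).
#' @param jct_um,sc_um JCT and SC inner-wall thicknesses (14, 2.2).
#' @param lumen_um SC lumen height below the inner wall (default 25).
#' @param dx_um boundary sampling interval (default 2).
#' @param ground_truth named list of [visco_params()]; default the healthy
#'   115LF fixture set.
#' @param noise_sd displacement noise for trajectories, micrometres.
#' @return object of class `synthetic_scene`.
#' @export
generate_scene <- function(seed, width_um = 400, waviness = 0.1,
                           tm_depth_um = 90, jct_um = 14, sc_um = 2.2,
                           lumen_um = 25, dx_um = 2,
                           ground_truth = NULL, noise_sd = 0) {
  if (width_um < 100) stop("width_um must be >= 100")
  if (waviness < 0 || waviness > 0.3) stop("waviness must be in [0, 0.3]")
  if (is.null(ground_truth)) ground_truth <- default_ground_truth()
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  x <- seq(0, width_um, by = dx_um)
  und <- function(amp) {
    ph <- stats::runif(3, 0, 2 * pi)
    a <- stats::runif(3, 0.3, 1)
    y <- rowSums(sapply(1:3, function(k) a[k] * sin(2 * pi * k * x / width_um + ph[k])))
    if (amp == 0) rep(0, length(x)) else amp * y / max(abs(y), 1e-12)
  }
  top <- 0 + und(waviness * tm_depth_um * 0.5)
  depth <- tm_depth_um * (1 + und(waviness * 0.5) / max(tm_depth_um, 1))
  tm_post <- top + pmax(depth, tm_depth_um * 0.5)
  jct_lower <- tm_post + jct_um
  sc_inner <- jct_lower + sc_um
  sc_outer <- sc_inner + lumen_um * (1 + und(waviness * 0.3) / max(lumen_um, 1))

  boundaries <- list(
    TM_anterior = data.frame(x = x, y = top),
    TM_posterior = data.frame(x = x, y = tm_post),
    JCT_band = data.frame(x = x, y = jct_lower),
    SC_inner_wall = data.frame(x = x, y = sc_inner),
    SC_outer_wall = data.frame(x = x, y = sc_outer))
  structure(list(seed = seed, boundaries = boundaries,
                 ground_truth = ground_truth, noise_sd = noise_sd,
                 width_um = width_um, waviness = waviness,
                 tm_depth_um = tm_depth_um, jct_um = jct_um, sc_um = sc_um),
            class = "synthetic_scene")
}

# save/restore the RNG state so generators are pure given their seed
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: seed %d, %g x ~%g um, waviness %.2f, noise %.2g um\n",
              x$seed, x$width_um, x$tm_depth_um, x$waviness, x$noise_sd))
  invisible(x)
}

#' Build the forward FE model of a scene
#'
#' Pipeline helper: smooths the two meshed boundaries, extrudes and meshes,
#' partitions the tissue layers, distributes and couples beams, and binds the
#' scene's ground-truth materials and boundary conditions (lateral columns
#' fixed, SC pressure faces, plane strain).
#'
#' @param scene a [generate_scene()] scene.
#' @param protocol a [load_protocol()] of kind `sc_pressure_ramp`.
#' @param edge_um planar element edge (default 10; coarse desk scale).
#' @param beam_spacing c(planar, thickness) control point spacings in um.
#'   Coarser than the reference 4 x 2.5 lattice by default; the fiber radius
#'   is scaled to preserve the fiber area fraction.
#' @param materials optional override of the scene ground truth.
#' @param smooth_p boundary smoothing parameter (default 0.999).
#' @return list with `mesh`, `beams`, `coupling`, `model`.
#' @export
build_scene_model <- function(scene, protocol, edge_um = 10,
                              beam_spacing = c(10, 5), materials = NULL,
                              smooth_p = 0.999) {
  b <- scene$boundaries
  sm <- function(df) smooth_boundary(df$x, df$y, p = smooth_p)
  bs <- list(TM_anterior = sm(b$TM_anterior),
             SC_inner_wall = sm(b$SC_inner_wall))
  mesh <- extrude_and_mesh(bs, target_edge_um = edge_um)
  mesh <- partition_layers(mesh, jct_thickness = scene$jct_um,
                           sc_thickness = scene$sc_um)
  beams <- distribute_beams(mesh, planar_spacing = beam_spacing[1],
                            thickness_spacing = beam_spacing[2])
  coupling <- couple_beams_to_solid(beams, mesh)
  if (is.null(materials)) materials <- scene$ground_truth
  ps <- protocol_series(protocol)
  model <- build_fe_model(
    mesh, materials = materials, beams = beams, coupling = coupling,
    fixed_sets = "lateral_fixed",
    pressure = list(times = ps$times, values_mmHg = ps$values))
  list(mesh = mesh, beams = beams, coupling = coupling, model = model)
}

#' Forward-simulate a scene and record boundary trajectories
#'
#' Runs the scene's ground-truth forward model under SC pressurization and
#' records the tracked SC-inner-wall and anterior TM boundary nodes at
#' `n_frames` uniformly spaced times, then adds zero-mean Gaussian noise with
#' standard deviation `scene$noise_sd` (seeded by `scene$seed`).
#'
#' @param scene a [generate_scene()] scene.
#' @param protocol a [load_protocol()] with `kind = "sc_pressure_ramp"`.
#' @param n_frames number of frames (>= 2).
#' @param edge_um,beam_spacing,target_steps forwarded to the model builders.
#' @return object of class `boundary_trajectory`: `times` (s), `ids` (mesh
#'   node indices), `label`, `coords` (frames x nodes x 2, micrometres).
#' @export
generate_boundary_trajectory <- function(scene, protocol, n_frames = 30,
                                         edge_um = 10, beam_spacing = c(10, 5),
                                         target_steps = 2000) {
  if (!inherits(protocol, "load_protocol") || protocol$kind != "sc_pressure_ramp")
    stop("protocol must be an sc_pressure_ramp load_protocol")
  if (n_frames < 2) stop("n_frames must be >= 2")
  sm <- build_scene_model(scene, protocol, edge_um = edge_um,
                          beam_spacing = beam_spacing)
  cfg <- simulation_config(duration = protocol$duration, n_frames = n_frames,
                           target_steps = target_steps)
  res <- run_simulation(sm$model, cfg)

  sets <- sm$mesh$node_sets
  ids <- c(sets$sc_inner_wall_track, sets$floating_boundary)
  label <- rep(c("sc_inner_wall_track", "floating_boundary"),
               c(length(sets$sc_inner_wall_track),
                 length(sets$floating_boundary)))
  ridx <- match(ids, res$node_ids)
  nf <- dim(res$disp)[1]
  coords <- array(0, c(nf, length(ids), 2))
  for (d in 1:2)
    coords[, , d] <- sweep(matrix(res$disp[, ridx, d], nf), 2,
                           sm$mesh$nodes[ids, d], "+")
  if (scene$noise_sd > 0) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(scene$seed + 1L)
    coords <- coords + stats::rnorm(length(coords), sd = scene$noise_sd)
  }
  structure(list(times = res$times, ids = ids, label = label, coords = coords,
                 noise_sd = scene$noise_sd, protocol = protocol,
                 seed = scene$seed, quasi_static = res$quasi_static),
            class = "boundary_trajectory")
}

#' @export
print.boundary_trajectory <- function(x, ...) {
  cat(sprintf("boundary_trajectory: %d frames x %d nodes (%s), noise %.2g um\n",
              length(x$times), length(x$ids),
              paste(names(table(x$label)), table(x$label), sep = ":",
                    collapse = ", "), x$noise_sd))
  invisible(x)
}

# ---- specimen model (uniaxial tension of an excised TM strip) --------------

#' Build the TM specimen FE model (10 x 0.24 x 0.136 mm strip)
#'
#' A coarse hexahedral strip with axial collagen fibers whose bundled
#' cross-section preserves the reference fiber area fraction. The tensile
#' strain is applied by displacing both ends symmetrically (the gauge state
#' is identical to a fixed/pulled protocol but the stress wave only has to
#' travel half the specimen, which halves the dynamic-relaxation settle
#' time).
#'
#' @param params_ecm,params_beam [visco_params()] for matrix and fibers.
#' @param strain_max peak tensile strain (paper protocol: 0.02).
#' @param duration ramp time, s (default 0.02: strain rate 1/s, fast enough
#'   to retain rate content for the viscoelastic fit).
#' @param nx axial element count (default 10).
#' @return list with `mesh`, `model`, `gauge_elems`, `protocol info`.
#' @keywords internal
build_specimen_model <- function(params_ecm, params_beam, strain_max = 0.02,
                                 duration = 0.02, nx = 10) {
  L <- 10e3; W <- 240; Tt <- 136          # um
  ny <- 2; nz <- 1
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, W, length.out = ny + 1)
  zs <- seq(0, Tt, length.out = nz + 1)
  nid <- function(i, j, k) (k - 1) * (nx + 1) * (ny + 1) + (j - 1) * (nx + 1) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))[, 1:3]
  elems <- matrix(0L, nx * ny * nz, 8); e <- 0L
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                    nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  ends <- which(nodes[, 1] %in% c(0, L))
  mesh <- hex_mesh(nodes, elems, tissue = rep("TM", nrow(elems)),
                   node_sets = list(ends = ends),
                   dims = c(nx, ny, nz))
  attr(mesh, "thickness_um") <- Tt
  # axial fiber bundles: 3 x 2 lattice across the section, area-fraction
  # preserving (same composite stiffness as the fine reference lattice)
  frac <- pi * 0.5^2 / (4 * 2.5)
  nfib <- 3 * 2
  afib <- frac * W * Tt / nfib            # um^2 per bundle
  rfib <- sqrt(afib / pi)
  yy <- W * c(1, 3, 5) / 6; zz <- Tt * c(1, 3) / 4
  cp <- list(); sg <- list(); idx <- 0L
  for (z in zz) for (y in yy) {
    id <- idx + seq_along(xs)
    cp[[length(cp) + 1]] <- cbind(xs, y, z)
    sg[[length(sg) + 1]] <- cbind(id[-length(id)], id[-1])
    idx <- idx + length(xs)
  }
  beams <- structure(list(control_points = do.call(rbind, cp),
                          segments = do.call(rbind, sg),
                          section = beam_section(rfib),
                          group = rep("TM_beam", nrow(do.call(rbind, sg))),
                          spacing = c(planar = NA, thickness = NA)),
                     class = "beam_network")
  coupling <- couple_beams_to_solid(beams, mesh)
  ecent <- vapply(seq_len(nrow(elems)),
                  function(e) mean(nodes[elems[e, ], 1]), numeric(1))
  gauge <- which(abs(ecent - L / 2) < L / 6)   # central-third gauge region
  amp <- cbind(strain_max * (nodes[ends, 1] - L / 2), 0, 0)
  model <- build_fe_model(
    mesh, materials = list(TM = params_ecm, TM_beam = params_beam),
    beams = beams, coupling = coupling,
    prescribed = list(set = "ends", amp = amp,
                      times = c(0, duration), factors = c(0, 1)),
    plane_strain = FALSE,
    gauge_elems = gauge)
  list(mesh = mesh, model = model, duration = duration,
       strain_max = strain_max)
}

#' Synthetic uniaxial stress-strain curve of a TM specimen
#'
#' Runs the specimen forward model with the given ground truth and returns the
#' gauge-region (specimen center) axial stress against applied strain.
#'
#' @param params_ecm,params_beam [visco_params()] ground truth.
#' @param strain_max peak strain, in `(0, 0.02]`.
#' @param n_points number of curve samples (>= 2).
#' @param duration strain ramp duration, s.
#' @param target_steps solver steps (desk-scale default 6000; settling of
#'   the long strip requires modest mass scaling).
#' @return data.frame with `strain`, `stress_MPa`, `time_s`.
#' @export
generate_specimen_curve <- function(params_ecm, params_beam, strain_max = 0.02,
                                    n_points = 25, duration = 0.02,
                                    target_steps = 6000) {
  if (strain_max <= 0 || strain_max > 0.02)
    stop("strain_max must be in (0, 0.02]")
  if (n_points < 2) stop("n_points must be >= 2")
  sp <- build_specimen_model(params_ecm, params_beam, strain_max, duration)
  cfg <- simulation_config(duration = duration, n_frames = n_points,
                           target_steps = target_steps)
  res <- run_simulation(sp$model, cfg)
  if (!res$quasi_static)
    warning("specimen run did not meet the quasi-static criterion")
  stress <- res$gauge_stress[, 1]
  strain <- res$times / duration * strain_max
  out <- data.frame(strain = c(0, strain), stress_MPa = c(0, stress),
                    time_s = c(0, res$times))
  if (n_points == 2)
    out <- out[c(1, nrow(out)), ]
  else
    out <- out[round(seq(1, nrow(out), length.out = n_points)), ]
  rownames(out) <- NULL
  out
}

# ---- TM patch under IOP (decay-constant calibration stage) -----------------

#' Build the TM patch model loaded by IOP on its anterior surface
#'
#' Rectangular TM band with embedded beams over a thin elastic scleral base
#' (2.93 MPa, nu = 0.495); IOP acts on the anterior face, the base is fixed.
#' Six seeded probe node sets mimic the randomly selected displacement
#' probes.
#'
#' @param params_ecm,params_beam [visco_params()].
#' @param width_um,depth_um patch size (default 120 x 60).
#' @param edge_um element edge (default 10).
#' @param seed probe-set seed.
#' @return list with `mesh`, `model`, `probe_sets`.
#' @keywords internal
build_tm_patch <- function(params_ecm, params_beam, width_um = 120,
                           depth_um = 60, edge_um = 10, seed = 1) {
  scene <- list(boundaries = list(
    TM_anterior = data.frame(x = c(0, width_um), y = c(0, 0)),
    SC_inner_wall = data.frame(x = c(0, width_um),
                               y = c(depth_um, depth_um))))
  mesh <- extrude_and_mesh(scene$boundaries, target_edge_um = edge_um)
  # bottom row is the scleral anchor, the rest is TM
  cent <- t(vapply(seq_len(nrow(mesh$elems)),
                   function(e) colMeans(mesh$nodes[mesh$elems[e, ], ]),
                   numeric(3)))
  tis <- rep("TM", nrow(mesh$elems))
  tis[cent[, 2] > depth_um - edge_um] <- "SCLERA"
  mesh$tissue <- tis
  attr(mesh, "sc_eff_um") <- edge_um   # keep beams off the scleral row
  beams <- distribute_beams(mesh, planar_spacing = 10, thickness_spacing = 5)
  coupling <- couple_beams_to_solid(beams, mesh)

  # anterior (top) faces carry the IOP load: rebuild the pressure face list
  nx <- mesh$dims[1]
  pf <- attr(mesh, "pressure_faces")      # bottom faces; replace with top
  topf <- matrix(0L, nx, 4)
  nid <- function(i, j, k) (k - 1L) * (nx + 1L) * (mesh$dims[2] + 1L) +
    (j - 1L) * (nx + 1L) + i
  for (i in 1:nx)
    topf[i, ] <- c(nid(i, 1, 1), nid(i + 1, 1, 1), nid(i + 1, 1, 2), nid(i, 1, 2))
  for (i in 1:nx) {   # outward normal is -y at the anterior surface
    v <- mesh$nodes[topf[i, ], ]
    nrm <- pracma_cross(v[3, ] - v[1, ], v[4, ] - v[2, ])
    if (nrm[2] > 0) topf[i, ] <- rev(topf[i, ])
  }
  bottom <- mesh$node_sets$sc_inner_wall_track
  bottom <- c(bottom, bottom + (nx + 1L) * (mesh$dims[2] + 1L))
  mesh$node_sets$base_fixed <- bottom

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  tm_nodes <- setdiff(seq_len(nrow(mesh$nodes)), bottom)
  probe_sets <- lapply(1:6, function(i) sample(tm_nodes, 8))
  mesh$node_sets$probes <- sort(unique(unlist(probe_sets)))

  Gs <- 2.93 / (2 * 1.495)   # elastic sclera: E = 2.93 MPa, nu = 0.495
  sclera <- visco_params(Gs, Gs, beta = 1, nu_vol = 0.495)
  list(mesh = mesh, beams = beams, coupling = coupling, topf = topf,
       probe_sets = probe_sets, sclera = sclera,
       materials = list(TM = params_ecm, SCLERA = sclera,
                        TM_beam = params_beam, JCT_beam = params_beam))
}

#' Synthetic TM-displacement-versus-IOP curve
#'
#' IOP rises 0 to `p_end` mmHg in `duration` seconds on the anterior face of
#' the TM patch and is then held for `hold` seconds (the relaxation phase
#' that makes the decay constants observable: during the pure ramp the
#' response is quasi-equilibrium and beta is nearly flat in the cost). The
#' curve is the pooled average displacement magnitude of six seeded probe
#' node sets, with the IOP and the time of every sample.
#'
#' @param params_ecm,params_beam [visco_params()] ground truth.
#' @param p_end peak IOP, mmHg (default 50).
#' @param duration ramp time, s (default 1).
#' @param hold post-ramp hold, s (default 0.25).
#' @param n_points samples (default 60).
#' @param seed probe seed.
#' @param target_steps solver steps (default 2500).
#' @return data.frame with `iop_mmHg`, `disp_um`, `time_s`.
#' @export
generate_tm_iop_curve <- function(params_ecm, params_beam, p_end = 50,
                                  duration = 1, hold = 0.25, n_points = 60,
                                  seed = 1, target_steps = 2500) {
  patch <- build_tm_patch(params_ecm, params_beam, seed = seed)
  total <- duration + hold
  model <- build_fe_model(
    patch$mesh, materials = patch$materials, beams = patch$beams,
    coupling = patch$coupling,
    fixed_sets = c("base_fixed", "lateral_fixed"),
    pressure = list(faces = patch$topf, times = c(0, duration, total),
                    values_mmHg = c(0, p_end, p_end)))
  cfg <- simulation_config(duration = total, n_frames = n_points,
                           target_steps = target_steps)
  res <- run_simulation(model, cfg)
  pr <- probe_average_displacement(res, patch$probe_sets)
  data.frame(iop_mmHg = pmin(res$times / duration, 1) * p_end,
             disp_um = pr$pooled, time_s = res$times)
}

# ---- SC lumen cross-sections ----------------------------------------------

#' Synthetic SC-lumen cross-section point stacks
#'
#' Each section is a ring of points on a circle of the given radius with
#' radial Gaussian jitter, standing in for segmented lumen cross-sections at
#' different distances from the cannula.
#'
#' @param radius_um circle radius (> 0), micrometres.
#' @param n_sections number of cross-sections.
#' @param jitter_sd radial jitter standard deviation, micrometres.
#' @param n_points points per section (>= 24).
#' @param seed RNG seed.
#' @return list of n x 2 matrices.
#' @export
generate_sc_lumen_stack <- function(radius_um = 63, n_sections = 4,
                                    jitter_sd = 0, n_points = 48, seed = 1) {
  if (radius_um <= 0) stop("radius_um must be > 0")
  n_points <- max(24, n_points)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  lapply(seq_len(n_sections), function(s) {
    th <- seq(0, 2 * pi, length.out = n_points + 1)[-1]
    r <- radius_um + stats::rnorm(n_points, sd = jitter_sd)
    cbind(x = r * cos(th), y = r * sin(th))
  })
}

# ---- serialization ---------------------------------------------------------

#' Write a boundary trajectory to CSV with a sidecar
#'
#' One row per node per frame (`frame, time_s, node_id, label, x_um, y_um`)
#' plus a YAML-style sidecar (`<file>.meta.yaml`) holding seed, protocol and
#' noise level.
#'
#' @param traj a `boundary_trajectory`.
#' @param file output CSV path.
#' @export
write_trajectory_csv <- function(traj, file) {
  nf <- length(traj$times); nn <- length(traj$ids)
  df <- data.frame(
    frame = rep(seq_len(nf), each = nn),
    time_s = rep(traj$times, each = nn),
    node_id = rep(traj$ids, nf),
    label = rep(traj$label, nf),
    x_um = as.vector(t(traj$coords[, , 1])),
    y_um = as.vector(t(traj$coords[, , 2])))
  utils::write.csv(df, file, row.names = FALSE)
  meta <- c(sprintf("seed: %d", traj$seed),
            sprintf("noise_sd_um: %g", traj$noise_sd),
            sprintf("protocol_kind: %s", traj$protocol$kind),
            sprintf("p_end_mmHg: %g", traj$protocol$p_end),
            sprintf("duration_s: %g", traj$protocol$duration))
  writeLines(meta, paste0(file, ".meta.yaml"))
  invisible(file)
}

#' Read a boundary trajectory written by [write_trajectory_csv()]
#' @param file CSV path.
#' @return a `boundary_trajectory` (without protocol/seed unless the sidecar
#'   is present).
#' @export
read_trajectory_csv <- function(file) {
  df <- utils::read.csv(file)
  frames <- sort(unique(df$frame))
  ids <- df$node_id[df$frame == frames[1]]
  label <- df$label[df$frame == frames[1]]
  nf <- length(frames); nn <- length(ids)
  coords <- array(0, c(nf, nn, 2))
  coords[, , 1] <- matrix(df$x_um, nn)[, seq_len(nf)] |> t()
  coords[, , 2] <- matrix(df$y_um, nn)[, seq_len(nf)] |> t()
  times <- df$time_s[match(frames, df$frame)]
  meta_file <- paste0(file, ".meta.yaml")
  seed <- NA_integer_; noise <- NA_real_; protocol <- NULL
  if (file.exists(meta_file)) {
    ml <- readLines(meta_file)
    getv <- function(key) sub(paste0(key, ": "), "", ml[startsWith(ml, key)])
    seed <- as.integer(getv("seed"))
    noise <- as.numeric(getv("noise_sd_um"))
    protocol <- load_protocol(getv("protocol_kind"),
                              p_end = as.numeric(getv("p_end_mmHg")),
                              duration = as.numeric(getv("duration_s")))
  }
  structure(list(times = times, ids = ids, label = label, coords = coords,
                 noise_sd = noise, protocol = protocol, seed = seed),
            class = "boundary_trajectory")
}
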