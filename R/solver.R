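# Explicit quasi-static FE driver: model assembly (unit conversion um -> mm,
# material binding, boundary conditions), configuration, the run wrapper
# around the compiled core, probes, and reference implementations of the
# element-level operations used by the oracle tests.

MMHG_TO_MPA <- 133.322e-6

#' Convert pressure from mmHg to MPa
#' @param p pressure in mmHg.
#' @export
mmhg_to_mpa <- function(p) p * MMHG_TO_MPA

#' Simulation configuration
#'
#' The solver integrates with `dt = dt_scale` times the global critical time
#' step computed from the (mass-scaled) density via [critical_timestep()].
#' Mass scaling is the standard explicit-dynamics device for quasi-static
#' problems: it inflates inertia (not stiffness), and its admissibility is
#' monitored through the kinetic/internal energy ratio, which must stay below
#' `kinetic_tol` at termination.
#'
#' @param duration simulated physical time, s.
#' @param n_frames number of recorded output frames.
#' @param dt_scale fraction of the critical time step used (default 0.9).
#' @param target_steps approximate number of integration steps; sets the mass
#'   scale. More steps = less mass scaling = stricter quasi-statics.
#' @param damping mass-proportional damping coefficient, 1/s; default
#'   5 x the largest material decay constant.
#' @param kinetic_tol quasi-static acceptance ratio (default 0.01).
#' @param mass_floor stiffness-proportional nodal mass floor factor.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(duration, n_frames = 30, dt_scale = 0.9,
                              target_steps = 2000, damping = NULL,
                              kinetic_tol = 0.01, mass_floor = 2) {
  stopifnot(duration > 0, n_frames >= 1, dt_scale > 0, dt_scale <= 1)
  structure(list(duration = duration, n_frames = n_frames,
                 dt_scale = dt_scale, target_steps = target_steps,
                 damping = damping, kinetic_tol = kinetic_tol,
                 mass_floor = mass_floor),
            class = "sim_config")
}

#' Assemble an FE model for the explicit solver
#'
#' Binds a (partitioned) mesh, optional beam network with coupling, per-tissue
#' materials, and boundary conditions into the consistent mm-MPa-s unit system
#' of the solver.
#'
#' @param mesh a [hex_mesh()] (micrometres).
#' @param materials named list of [visco_params()]: one entry per tissue tag
#'   present in the mesh (`TM`, `JCT`, `SC_wall`, `SCLERA`) and per beam group
#'   (`TM_beam`, `JCT_beam`) if beams are given.
#' @param beams optional [distribute_beams()] network.
#' @param coupling optional [couple_beams_to_solid()] (required with beams).
#' @param fixed_sets character names of `mesh$node_sets` whose nodes are fully
#'   fixed.
#' @param pressure optional list: `faces` (F x 4 node ids; default the mesh's
#'   `pressure_faces` attribute), `times` (s), `values_mmHg`.
#' @param floating optional list: `trajectory` (a `boundary_trajectory`),
#'   `set` (name of the node set to drive, default `"floating_boundary"`).
#' @param prescribed optional list: `set`, `amp` (3-vector, micrometres),
#'   `times`, `factors` - nodes move by `amp * factor(t)`.
#' @param plane_strain fix all out-of-plane (z) solid displacements
#'   (default TRUE; the 10-um extruded slab is treated as plane strain).
#' @param rho physical density, tonne/mm^3 (default 1.0e-9, water-like).
#' @param record character names of node sets to record (default all sets).
#' @param gauge_elems element indices for volume-averaged stress recording.
#' @param gauge_segs beam segment indices whose (embedded, superimposed)
#'   stress contribution is added to the gauge average; default: all segments
#'   whose midpoint lies in a gauge element.
#' @return list of class `fe_model`.
#' @export
build_fe_model <- function(mesh, materials, beams = NULL, coupling = NULL,
                           fixed_sets = character(), pressure = NULL,
                           floating = NULL, prescribed = NULL,
                           plane_strain = TRUE, rho = 1e-9,
                           record = NULL, gauge_elems = integer(),
                           gauge_segs = NULL) {
  tset <- unique(mesh$tissue)
  missing_mat <- setdiff(tset, names(materials))
  if (length(missing_mat))
    stop("missing materials for: ", paste(missing_mat, collapse = ", "))

  mat_names <- names(materials)
  mats <- do.call(rbind, lapply(materials, function(p)
    c(p$G0, p$Ginf, p$beta, p$nu_vol)))
  emat <- match(mesh$tissue, mat_names) - 1L

  N <- nrow(mesh$nodes)
  fixed <- matrix(FALSE, N, 3)
  for (s in fixed_sets) fixed[mesh$node_sets[[s]], ] <- TRUE
  if (plane_strain) fixed[, 3] <- TRUE

  pf <- matrix(0L, 0, 4); pt <- 0; pv <- 0
  if (!is.null(pressure)) {
    pf <- if (is.null(pressure$faces)) attr(mesh, "pressure_faces") else pressure$faces
    pt <- pressure$times
    pv <- mmhg_to_mpa(pressure$values_mmHg)
  }

  presc_idx <- integer(); presc_pos <- array(0, c(1, 3, 1)); presc_t <- 0
  presc_ncomp <- 0L
  if (!is.null(floating)) {
    traj <- floating$trajectory
    setn <- if (is.null(floating$set)) "floating_boundary" else floating$set
    sel <- traj$label == setn
    if (!any(sel)) stop("trajectory has no nodes labelled ", setn)
    presc_idx <- traj$ids[sel]
    nf <- length(traj$times)
    presc_pos <- array(0, c(length(presc_idx), 3, nf))
    presc_pos[, 1:2, ] <- aperm(traj$coords[, sel, , drop = FALSE], c(2, 3, 1)) * 1e-3
    presc_t <- traj$times
    presc_ncomp <- 2L
  } else if (!is.null(prescribed)) {
    presc_idx <- mesh$node_sets[[prescribed$set]]
    nf <- length(prescribed$times)
    base <- mesh$nodes[presc_idx, , drop = FALSE] * 1e-3
    amp <- prescribed$amp
    if (!is.matrix(amp)) amp <- matrix(amp, nrow(base), 3, byrow = TRUE)
    presc_pos <- array(0, c(length(presc_idx), 3, nf))
    for (k in seq_len(nf))
      presc_pos[, , k] <- base + amp * 1e-3 * prescribed$factors[k]
    presc_t <- prescribed$times
    presc_ncomp <- 3L
  }

  bl <- NULL
  if (!is.null(beams)) {
    if (is.null(coupling)) coupling <- couple_beams_to_solid(beams, mesh)
    gidx <- match(beams$group, mat_names)
    if (anyNA(gidx))
      stop("missing materials for beam groups: ",
           paste(unique(beams$group[is.na(gidx)]), collapse = ", "))
    cp <- beams$control_points * 1e-3
    # initial fiber vectors: Y_eta normal to the segment axis in-plane,
    # Y_zeta out of plane; averaged over incident segments per node
    B <- nrow(cp)
    Ye <- matrix(0, B, 3); cnt <- numeric(B)
    for (s in seq_len(nrow(beams$segments))) {
      n1 <- beams$segments[s, 1]; n2 <- beams$segments[s, 2]
      ax <- cp[n2, ] - cp[n1, ]
      ax <- ax / sqrt(sum(ax^2))
      yn <- pracma_cross(c(0, 0, 1), ax)     # in-plane normal
      nn <- sqrt(sum(yn^2))
      if (nn < 1e-8) yn <- c(0, 1, 0) else yn <- yn / nn
      Ye[n1, ] <- Ye[n1, ] + yn; Ye[n2, ] <- Ye[n2, ] + yn
      cnt[n1] <- cnt[n1] + 1; cnt[n2] <- cnt[n2] + 1
    }
    Ye <- Ye / pmax(sqrt(rowSums(Ye^2)), 1e-12)
    Yz <- matrix(rep(c(0, 0, 1), each = B), B, 3)
    # host-element shear stiffness estimate for the penalty springs
    Gh <- mats[emat[coupling$host_elem] + 1L, 1]
    h_elem <- (attr(mesh, "thickness_um") %||% 10) * 1e-3
    kpen <- coupling$penalty_scale * Gh * h_elem
    if (is.null(gauge_segs) && length(gauge_elems)) {
      mid <- (beams$control_points[beams$segments[, 1], , drop = FALSE] +
                beams$control_points[beams$segments[, 2], , drop = FALSE]) / 2
      loc <- locate_points(mesh, mid)
      gauge_segs <- which(loc$inside & loc$elem %in% gauge_elems)
    }
    bl <- list(bnodes = cp, bsegs = beams$segments - 1L,
               bmat = gidx - 1L, Ye = Ye, Yz = Yz,
               sec_pts = beams$section$pts * 1e-3,
               sec_wts = beams$section$wts * 1e-6,
               area = beams$section$area * 1e-6,
               host_elem = coupling$host_elem - 1L,
               host_w = coupling$weights, kpen = kpen,
               record_segs = as.integer(gauge_segs %||% integer()) - 1L)
  }

  if (is.null(record)) record <- names(mesh$node_sets)
  rec_nodes <- as.integer(sort(unique(unlist(mesh$node_sets[record],
                                             use.names = FALSE))))

  structure(list(
    nodes = mesh$nodes * 1e-3, elems = mesh$elems - 1L, emat = emat,
    mats = mats, mat_names = mat_names, rho = rho, fixed = fixed,
    press_faces = pf - if (nrow(pf)) 1L else 0L, press_t = pt, press_v = pv,
    presc_idx = presc_idx - if (length(presc_idx)) 1L else 0L,
    presc_pos = presc_pos, presc_t = presc_t, presc_ncomp = presc_ncomp,
    beams = bl, record_nodes = rec_nodes - 1L,
    record_elems = as.integer(gauge_elems) - if (length(gauge_elems)) 1L else 0L,
    rec_node_ids = rec_nodes, mesh = mesh),
    class = "fe_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an explicit quasi-static simulation
#'
#' Central-difference integration with mass-proportional damping until the
#' termination time; raises an instability error on energy blow-up and flags
#' the quasi-static criterion (terminal kinetic energy below `kinetic_tol`
#' of internal energy).
#'
#' @param model a [build_fe_model()].
#' @param config a [simulation_config()].
#' @return object of class `sim_result`: `times`, `disp` (frames x nodes x 3,
#'   micrometres, for the recorded nodes), `node_ids`, `gauge_stress` (MPa),
#'   `energies`, `dt`, `quasi_static` flag.
#' @export
run_simulation <- function(model, config) {
  # dt from the stiffest material through the critical-step formula
  Emax <- max(2 * model$mats[, 1] * (1 + model$mats[, 4]))
  numax <- max(model$mats[, 4])
  mesh_mm <- model$mesh
  ct <- critical_timestep(mesh_mm, E = Emax, nu = numax, rho = model$rho)
  dt_needed <- config$duration / config$target_steps
  mass_scale <- max(1, (dt_needed / (config$dt_scale * ct$dt_min))^2)
  rho_eff <- model$rho * mass_scale
  dt <- config$dt_scale * ct$dt_min * sqrt(mass_scale)
  n_steps <- max(config$n_frames, ceiling(config$duration / dt))
  dt <- config$duration / n_steps
  # dynamic relaxation: damp at ~critical for the fundamental structural mode
  # (estimated from the softest long-time shear modulus, the scaled density,
  # and the largest model extent); heavier damping overdamps the slow modes
  # and the model crawls instead of settling.
  Gmin <- min(model$mats[, 2])
  Lmax <- max(apply(model$nodes, 2, function(v) diff(range(v))))
  omega_est <- pi * sqrt(Gmin / rho_eff) / Lmax
  alpha <- config$damping %||% (2 * omega_est)
  # damping stability: alpha*dt must stay well below 2
  alpha <- min(alpha, 1 / dt)

  rec_steps <- unique(round(seq_len(config$n_frames) / config$n_frames * n_steps)) - 1L
  rec_steps <- rec_steps[rec_steps >= 0]

  cm <- model
  cm$rho <- rho_eff
  res <- cpp_run_explicit(cm, list(dt = dt, n_steps = as.integer(n_steps),
                                   alpha = alpha,
                                   mass_floor = config$mass_floor,
                                   rec_steps = rec_steps))
  if (res$blown_up)
    stop("instability: kinetic energy blow-up; reduce dt_scale or increase target_steps")
  en <- res$energies
  nf <- res$frames_done
  ke_ratio <- if (nf > 0 && en[nf, 2] > 0) en[nf, 1] / en[nf, 2] else 0
  structure(list(times = res$times, disp = res$disp * 1e3,
                 node_ids = model$rec_node_ids,
                 gauge_stress = res$gauge_stress,
                 energies = en, dt = dt, n_steps = n_steps,
                 mass_scale = mass_scale, mass_added = res$mass_added,
                 total_mass = res$total_mass,
                 final_nodes = res$final_nodes * 1e3,
                 quasi_static = ke_ratio <= config$kinetic_tol,
                 ke_ratio = ke_ratio),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d frames, dt = %.3g s (%d steps), KE/W = %.2g (%s)\n",
              length(x$times), x$dt, x$n_steps, x$ke_ratio,
              if (x$quasi_static) "quasi-static" else "NOT quasi-static"))
  invisible(x)
}

#' Nodal forces of a follower pressure load
#'
#' `force = -p * current area * current normal`, distributed equally to the
#' four face nodes. Faces must be ordered so their normals point outward.
#'
#' @param coords N x 3 current nodal coordinates.
#' @param faces F x 4 node indices.
#' @param p pressure (force/area in the coordinate units).
#' @return N x 3 matrix of nodal forces.
#' @export
apply_pressure <- function(coords, faces, p) {
  f <- matrix(0, nrow(coords), 3)
  for (k in seq_len(nrow(faces))) {
    v <- coords[faces[k, ], , drop = FALSE]
    d1 <- v[3, ] - v[1, ]; d2 <- v[4, ] - v[2, ]
    an <- pracma_cross(d1, d2) / 2          # area * normal
    if (sum(an^2) == 0) stop("degenerate pressure face ", k)
    ff <- -p * an / 4
    for (a in 1:4) f[faces[k, a], ] <- f[faces[k, a], ] + ff
  }
  f
}

#' Interpolate a floating displacement boundary at a time
#'
#' @param trajectory a `boundary_trajectory`.
#' @param t time, s; must lie within the recorded range.
#' @return matrix n x 2 of prescribed planar coordinates (micrometres).
#' @export
apply_floating_displacement <- function(trajectory, t) {
  tt <- trajectory$times
  if (t < tt[1] - 1e-12 || t > tt[length(tt)] + 1e-12)
    stop("extrapolation error: t outside the trajectory range")
  t <- min(max(t, tt[1]), tt[length(tt)])
  k <- max(2, which(tt >= t - 1e-15)[1])
  w <- (t - tt[k - 1]) / (tt[k] - tt[k - 1])
  (1 - w) * trajectory$coords[k - 1, , ] + w * trajectory$coords[k, , ]
}

#' Set-averaged displacement magnitude probes
#'
#' For each probe node set, the average over nodes of the displacement
#' magnitude per frame, plus the pooled average over sets.
#'
#' @param result a [run_simulation()] result.
#' @param node_sets list of node-id vectors (mesh numbering).
#' @return list with `per_set` (frames x n_sets) and `pooled` (frames).
#' @export
probe_average_displacement <- function(result, node_sets) {
  if (any(vapply(node_sets, length, 1L) == 0)) stop("empty probe set")
  idx <- lapply(node_sets, function(s) match(s, result$node_ids))
  if (anyNA(unlist(idx))) stop("probe nodes were not recorded")
  nf <- dim(result$disp)[1]
  per <- vapply(idx, function(ii) {
    mag <- sqrt(result$disp[, ii, 1, drop = FALSE]^2 +
                result$disp[, ii, 2, drop = FALSE]^2 +
                result$disp[, ii, 3, drop = FALSE]^2)
    rowMeans(matrix(mag, nf))
  }, numeric(nf))
  per <- matrix(per, nf)
  list(per_set = per, pooled = rowMeans(per))
}

#' Reference hexahedron internal force with state update
#'
#' Pure-R single-element mirror of the solver's fully integrated hexahedron:
#' 2x2x2 Gauss rule, mean-dilatation volumetric strain, Jaumann rotation,
#' viscoelastic update, and accumulation of B^T sigma. Used as the oracle
#' implementation in the element-level tests.
#'
#' @param X_prev,X_cur 8 x 3 nodal coordinates before/after the increment.
#' @param states list of 8 `list(sigma, h)` Voigt states (or NULL).
#' @param material a [visco_params()].
#' @param dt time increment, s.
#' @return list with `force` (8 x 3), updated `states`, `mean_stress`
#'   (Voigt), `volume`.
#' @export
hex_internal_force <- function(X_prev, X_cur, states, material, dt) {
  if (is.null(states))
    states <- replicate(8, list(sigma = numeric(6), h = numeric(6)),
                        simplify = FALSE)
  gp <- hex_gauss_points()
  dU <- X_cur - X_prev
  X_mid <- (X_cur + X_prev) / 2
  tr_all <- numeric(8); det_all <- numeric(8)
  G_all <- vector("list", 8); dn_all <- vector("list", 8)
  for (g in 1:8) {
    sh <- hex8_shape(gp$xi[g], gp$eta[g], gp$zeta[g])
    J <- t(X_cur) %*% sh$dN
    dj <- det(J)
    if (dj <= 0) stop("inverted element")
    dNdy <- sh$dN %*% solve(J)
    # strain/spin increment at the half-step configuration: a finite rigid
    # rotation then produces exactly zero strain (Cayley-transform identity)
    Jm <- t(X_mid) %*% sh$dN
    G <- t(dU) %*% (sh$dN %*% solve(Jm))
    det_all[g] <- dj; G_all[[g]] <- G; dn_all[[g]] <- dNdy
    tr_all[g] <- sum(diag(G))
  }
  trbar <- sum(tr_all * det_all) / sum(det_all)
  f <- matrix(0, 8, 3)
  sbar <- numeric(6)
  for (g in 1:8) {
    ss <- strain_spin_increment(G_all[[g]])
    dE <- tensor_to_voigt(ss$dEps, strain = TRUE)
    # impose the element-mean dilatation (B-bar)
    dE[1:3] <- dE[1:3] + (trbar - sum(dE[1:3])) / 3
    st <- stress_state(states[[g]]$sigma, states[[g]]$h, 0)
    up <- update_stress(st, dE, ss$dOmega, dt, material)
    states[[g]] <- list(sigma = up$sigma, h = up$h)
    S <- voigt_to_tensor(up$sigma)
    f <- f + det_all[g] * dn_all[[g]] %*% S
    sbar <- sbar + up$sigma * det_all[g]
  }
  list(force = f, states = states, mean_stress = sbar / sum(det_all),
       volume = sum(det_all))
}
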