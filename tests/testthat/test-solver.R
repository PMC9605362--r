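# Explicit solver: element oracle equivalence, pressure loads, floating
# boundaries, probes, stability and convergence.

test_that("reference hex force: zero displacement, elastic patch, objectivity", {
  mat <- visco_params(10, 10, 100, nu_vol = 0.3)
  X <- unit_hex_mesh(1)$nodes
  r0 <- hex_internal_force(X, X, NULL, mat, dt = 1e-4)
  expect_equal(r0$force, matrix(0, 8, 3))
  # uniaxial strain with free lateral faces: impose the exact elasticity
  # displacement field and check the stress state is uniaxial E*eps
  eps <- 1e-3; nu <- 0.3
  E <- 2 * 10 * (1 + nu)
  Xc <- X
  Xc[, 1] <- X[, 1] * (1 + eps)
  Xc[, 2] <- X[, 2] * (1 - nu * eps)
  Xc[, 3] <- X[, 3] * (1 - nu * eps)
  r <- hex_internal_force(X, Xc, NULL, mat, dt = 1e-4)
  expect_equal(r$mean_stress[1], E * eps, tolerance = 0.01)
  expect_lt(max(abs(r$mean_stress[2:6])), 0.01 * E * eps)
  # finite rigid rotation of a virgin element produces no stress at all
  R <- oracle_rodrigues(c(0.2, -0.1, 0.15))
  rr <- hex_internal_force(X, t(R %*% t(X)), NULL, mat, dt = 1e-4)
  expect_lt(max(abs(rr$force)), 1e-10 * max(abs(r$force)))
  # rigid rotation of a stressed element: invariants are conserved
  rot <- hex_internal_force(Xc, t(R %*% t(Xc)), r$states, mat, dt = 1e-4)
  expect_equal(oracle_vm(rot$mean_stress), oracle_vm(r$mean_stress),
               tolerance = 0.05)   # one large 0.27-rad Jaumann step
})

test_that("single-hex held shear in the solver tracks G(t) (compiled path)", {
  m <- unit_hex_mesh(1000)              # 1 mm cube, prescribed throughout
  for (s in table1_sets()) {
    p <- visco_params(s[1], s[2], s[3])
    gam <- 2e-3
    amp <- cbind(gam * m$nodes[, 2], 0, 0)   # x-shear proportional to y
    t_step <- 2e-4                           # step applied quickly, then held
    Tend <- 4.5 / s[3]
    model <- build_fe_model(m, materials = list(TM = p),
                            prescribed = list(set = "all", amp = amp,
                                              times = c(0, t_step, Tend),
                                              factors = c(0, 1, 1)),
                            plane_strain = FALSE, gauge_elems = 1)
    cfg <- simulation_config(duration = Tend, n_frames = 40,
                             target_steps = round(Tend / (0.1 / s[3])))
    res <- run_simulation(model, cfg)
    keep <- res$times > 2 * t_step
    sig <- res$gauge_stress[keep, 4]
    Gt <- oracle_G(s[1], s[2], s[3], res$times[keep] - t_step / 2)
    expect_lt(max(abs(sig - Gt * gam) / (Gt * gam)), 0.01)
  }
})

test_that("solver rigid rotation of a free element produces negligible stress", {
  m <- unit_hex_mesh(1000)
  p <- visco_params(10, 5, 200)
  th_end <- 0.5
  nseg <- 400                     # fine rotation snapshots: the prescribed
  ths <- seq(0, th_end, length.out = nseg + 1)   # path is near-exactly rigid
  times <- seq(0, 0.01, length.out = nseg + 1)
  pos <- array(0, c(8, 3, nseg + 1))
  for (k in seq_len(nseg + 1)) {
    R <- oracle_rodrigues(c(0, 0, ths[k]))
    pos[, , k] <- t(R %*% t(m$nodes)) * 1e-3
  }
  model <- build_fe_model(m, materials = list(TM = p),
                          plane_strain = FALSE, gauge_elems = 1)
  model$presc_idx <- 0:7
  model$presc_pos <- pos
  model$presc_t <- times
  model$presc_ncomp <- 3L
  cfg <- simulation_config(duration = 0.01, n_frames = 20,
                           target_steps = 2000)
  res <- run_simulation(model, cfg)
  expect_lt(oracle_vm(res$gauge_stress[20, ]), 1e-6 * p$G0)
})

test_that("apply_pressure: closed forms and closed-surface property", {
  # unit square face (1 mm in um units), 1 MPa -> total force 1 N
  coords <- rbind(c(0, 0, 0), c(1000, 0, 0), c(1000, 1000, 0), c(0, 1000, 0))
  f <- apply_pressure(coords * 1e-3, matrix(1:4, 1), p = 1)
  expect_equal(sum(sqrt(rowSums(f^2))), 1, tolerance = 1e-12)
  expect_equal(colSums(f), c(0, 0, -1), tolerance = 1e-12)  # along -normal
  expect_equal(apply_pressure(coords, matrix(1:4, 1), p = 0),
               matrix(0, 4, 3))
  # pressurizing all faces of a closed cube gives zero net force
  m <- unit_hex_mesh(1)
  faces <- rbind(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                 c(4, 8, 7, 3), c(2, 3, 7, 6), c(1, 5, 8, 4))
  fc <- apply_pressure(m$nodes, faces, p = 2)
  expect_lt(max(abs(colSums(fc))), 1e-12)
})

test_that("floating displacement interpolation and probes behave", {
  tr <- structure(list(
    times = c(0, 1, 2),
    ids = 1:2, label = rep("floating_boundary", 2),
    coords = array(c(0, 1, 2, 0, 1, 2,   # node 1 x over frames, node 2 x
                     0, 2, 4, 0, 2, 4), c(3, 2, 2))),
    class = "boundary_trajectory")
  expect_equal(apply_floating_displacement(tr, 1), tr$coords[2, , ])
  expect_equal(apply_floating_displacement(tr, 0.5),
               (tr$coords[1, , ] + tr$coords[2, , ]) / 2)
  expect_error(apply_floating_displacement(tr, 3), "extrapolation")
  # constant trajectory pins the boundary
  trc <- tr; trc$coords[2, , ] <- trc$coords[1, , ]; trc$coords[3, , ] <- trc$coords[1, , ]
  expect_equal(apply_floating_displacement(trc, 1.7), trc$coords[1, , ])

  res <- list(disp = array(rep(c(3, 4, 0), each = 8),  c(2, 4, 3)),
              node_ids = 1:4)
  pr <- probe_average_displacement(res, list(1:2, 3:4))
  expect_equal(pr$per_set, matrix(5, 2, 2))     # |(3,4,0)| = 5 everywhere
  expect_equal(pr$pooled, c(5, 5))
  res0 <- list(disp = array(0, c(2, 4, 3)), node_ids = 1:4)
  expect_equal(probe_average_displacement(res0, list(1:3))$pooled, c(0, 0))
  expect_error(probe_average_displacement(res, list(integer())), "empty")
})

test_that("quasi-static convergence: halving dt changes the result < 0.5%", {
  sc <- generate_scene(6, width_um = 100, waviness = 0.1)
  pr <- load_protocol("sc_pressure_ramp", p_end = 30, duration = 0.05,
                      t_ramp = 0.005)
  sm <- build_scene_model(sc, pr, edge_um = 12, beam_spacing = c(15, 5))
  term <- sapply(c(2000, 4000), function(ns) {
    cfg <- simulation_config(duration = 0.05, n_frames = 5, target_steps = ns)
    res <- run_simulation(sm$model, cfg)
    ids <- sm$mesh$node_sets$sc_inner_wall_track
    mean(res$disp[5, match(ids, res$node_ids), 2])
  })
  expect_lt(abs(term[2] - term[1]) / abs(term[2]), 0.005)
})

test_that("specimen gauge stress is mesh-insensitive (< 3% on refinement)", {
  p_ecm <- visco_params(24.98, 18.81, 500)
  p_beam <- visco_params(35.2, 20.51, 585)
  g <- sapply(c(10, 20), function(nx) {
    sp <- outflowve:::build_specimen_model(p_ecm, p_beam, strain_max = 0.02,
                                           duration = 0.02, nx = nx)
    cfg <- simulation_config(duration = 0.02, n_frames = 5,
                             target_steps = 16000)
    res <- run_simulation(sp$model, cfg)
    res$gauge_stress[5, 1]
  })
  expect_lt(abs(g[2] - g[1]) / abs(g[2]), 0.03)
})

test_that("energy blow-up is detected and flagged", {
  m <- unit_hex_mesh(1000)
  p <- visco_params(10, 5, 200)
  model <- build_fe_model(m, materials = list(TM = p), plane_strain = FALSE,
                          pressure = list(faces = matrix(c(1, 2, 3, 4), 1),
                                          times = c(0, 1),
                                          values_mmHg = c(0, 30)))
  # deliberately unstable: dt above the critical step, no mass floor;
  # detected either by the kinetic-energy monitor or by element inversion
  ct <- critical_timestep(m, E = 2 * 10 * 1.495, nu = 0.495, rho = 1e-9)
  detected <- tryCatch({
    raw <- outflowve:::cpp_run_explicit(
      model, list(dt = 2.2 * ct$dt_min, n_steps = 2000L, alpha = 0,
                  mass_floor = 0, rec_steps = c(500L, 1999L)))
    raw$blown_up
  }, error = function(e) TRUE)
  expect_true(detected)
})
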