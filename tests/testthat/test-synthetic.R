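# Synthetic-data generators: determinism, geometric invariants, forward
# trajectories, specimen curves, lumen stacks, serialization.

test_that("scenes are deterministic, banded, and ordered in depth", {
  s1 <- generate_scene(1, width_um = 200, waviness = 0.15)
  s2 <- generate_scene(1, width_um = 200, waviness = 0.15)
  expect_identical(s1$boundaries, s2$boundaries)
  s3 <- generate_scene(2, width_um = 200, waviness = 0.15)
  dev <- max(abs(s3$boundaries$TM_anterior$y - s1$boundaries$TM_anterior$y))
  expect_gt(dev, 0)
  b <- s1$boundaries
  # monotone in depth: anterior < posterior < JCT < SC inner < SC outer
  expect_true(all(b$TM_posterior$y > b$TM_anterior$y))
  expect_true(all(b$JCT_band$y > b$TM_posterior$y))
  expect_true(all(b$SC_inner_wall$y > b$JCT_band$y))
  expect_true(all(b$SC_outer_wall$y > b$SC_inner_wall$y))
  # band thicknesses by construction (tolerance 10%)
  jct <- b$JCT_band$y - b$TM_posterior$y
  scw <- b$SC_inner_wall$y - b$JCT_band$y
  expect_true(all(abs(jct - 14) / 14 < 0.1))
  expect_true(all(abs(scw - 2.2) / 2.2 < 0.1))
  # zero waviness degenerates to parallel straight lines
  s0 <- generate_scene(1, width_um = 400, waviness = 0)
  expect_equal(diff(range(s0$boundaries$TM_anterior$y)), 0)
  expect_equal(unique(round(s0$boundaries$JCT_band$y -
                            s0$boundaries$TM_posterior$y, 9)), 14)
  expect_error(generate_scene(1, waviness = 0.5), "waviness")
  expect_error(generate_scene(1, width_um = 50), "width")
})

test_that("ground-truth defaults come from the shipped fixtures", {
  gt <- default_ground_truth("115LF")
  expect_setequal(names(gt), c("TM", "JCT", "SC_wall", "TM_beam", "JCT_beam"))
  expect_equal(gt$TM$G0, 5.10)
  expect_equal(gt$TM_beam$Ginf, 70.59)
  expect_equal(gt$JCT$beta, 109)
  expect_equal(gt$TM_beam$beta, 450)
  gt2 <- default_ground_truth("125LF")
  expect_equal(gt2$TM$G0, 16.11)
  expect_error(default_ground_truth("999"), "unknown")
})

test_that("load protocols validate their fields", {
  p <- load_protocol("sc_pressure_ramp", p_end = 30, duration = 0.05)
  expect_equal(outflowve:::protocol_series(p)$values, c(0, 30, 30))
  expect_error(load_protocol("sc_pressure_ramp", duration = 0), "duration")
  expect_error(load_protocol("nope"), "arg")
})

test_that("boundary trajectories: no load, determinism, pressurization sign", {
  sc0 <- generate_scene(3, width_um = 100, waviness = 0.05)
  pr0 <- load_protocol("sc_pressure_ramp", p_end = 0, duration = 0.02,
                       t_ramp = 0.005)
  tr0 <- generate_boundary_trajectory(sc0, pr0, n_frames = 4, edge_um = 15,
                                      beam_spacing = c(20, 10),
                                      target_steps = 300)
  for (k in 2:4)
    expect_equal(tr0$coords[k, , ], tr0$coords[1, , ], tolerance = 1e-12)

  pr <- load_protocol("sc_pressure_ramp", p_end = 30, duration = 0.03,
                      t_ramp = 0.005)
  tr <- generate_boundary_trajectory(sc0, pr, n_frames = 6, edge_um = 15,
                                     beam_spacing = c(20, 10),
                                     target_steps = 4000)
  tr2 <- generate_boundary_trajectory(sc0, pr, n_frames = 6, edge_um = 15,
                                      beam_spacing = c(20, 10),
                                      target_steps = 4000)
  expect_identical(tr$coords, tr2$coords)          # seed determinism
  sel <- tr$label == "sc_inner_wall_track"
  dy <- tr$coords[6, sel, 2] - tr$coords[1, sel, 2]
  # pressurized SC inner wall displaces toward the TM (negative depth)
  expect_lt(mean(dy), 0)
  expect_gt(max(abs(dy)), 0)
  expect_error(generate_boundary_trajectory(sc0, pr, n_frames = 1),
               "n_frames")
  expect_error(generate_boundary_trajectory(
    sc0, load_protocol("iop_ramp"), n_frames = 4), "sc_pressure_ramp")

  # noise is reproducible and has the requested scale
  scn <- generate_scene(3, width_um = 100, waviness = 0.05, noise_sd = 0.5)
  trn <- generate_boundary_trajectory(scn, pr, n_frames = 6, edge_um = 15,
                                      beam_spacing = c(20, 10),
                                      target_steps = 4000)
  resid <- trn$coords - tr$coords
  expect_equal(stats::sd(resid), 0.5, tolerance = 0.1)
})

test_that("specimen curves: endpoints, monotonicity, elastic equivalence", {
  pe <- visco_params(24.98, 18.81, 500)
  pb <- visco_params(35.2, 20.51, 585)
  cur <- generate_specimen_curve(pe, pb, strain_max = 0.02, n_points = 12,
                                 target_steps = 4000)
  expect_equal(cur$strain[1], 0)
  expect_equal(cur$stress_MPa[1], 0)
  expect_equal(max(cur$strain), 0.02, tolerance = 1e-9)
  expect_true(all(diff(cur$stress_MPa) >= -1e-9))
  c2 <- generate_specimen_curve(pe, pb, strain_max = 0.02, n_points = 2,
                                target_steps = 4000)
  expect_equal(nrow(c2), 2)
  expect_equal(c2$strain, c(0, 0.02), tolerance = 1e-9)
  expect_error(generate_specimen_curve(pe, pb, strain_max = 0.05), "strain_max")

  # relaxation off: the curve equals the purely elastic run
  pe0 <- visco_params(24.98, 24.98, 500)
  pb0 <- visco_params(35.2, 35.2, 585)
  ce <- generate_specimen_curve(pe0, pb0, strain_max = 0.02, n_points = 6,
                                target_steps = 4000)
  ce_slow <- generate_specimen_curve(pe0, pb0, strain_max = 0.02,
                                     n_points = 6, duration = 0.08,
                                     target_steps = 4000)
  expect_equal(ce$stress_MPa[6], ce_slow$stress_MPa[6], tolerance = 0.02)
})

test_that("specimen stress at 2% matches the composite hereditary oracle", {
  # one-element-scale closed form: matrix uniaxial relaxation plus the
  # area-fraction-weighted axial fiber contribution (rule of mixtures)
  pe <- visco_params(24.98, 18.81, 500)
  pb <- visco_params(35.2, 20.51, 585)
  dur <- 0.02
  cur <- generate_specimen_curve(pe, pb, strain_max = 0.02, n_points = 10,
                                 duration = dur, target_steps = 8000)
  rate <- 0.02 / dur
  phi <- pi * 0.5^2 / (4 * 2.5)
  s_ecm <- oracle_uniax_ramp(24.98, 18.81, 500, 0.495, rate, dur, dur)
  s_fib <- phi * oracle_uniax_ramp(35.2, 20.51, 585, 0.495, rate, dur, dur)
  oracle <- s_ecm + s_fib
  expect_equal(cur$stress_MPa[nrow(cur)], oracle, tolerance = 0.05)
})

test_that("SC lumen stacks: exact circles, jitter statistics, sizes", {
  st <- generate_sc_lumen_stack(radius_um = 63, n_sections = 4, jitter_sd = 0)
  expect_length(st, 4)
  d <- vapply(st, fit_circle_diameter, 1)
  expect_equal(d, rep(126, 4), tolerance = 1e-9)
  expect_length(generate_sc_lumen_stack(n_sections = 1), 1)
  expect_true(all(vapply(st, nrow, 1L) >= 24))
  stj <- generate_sc_lumen_stack(radius_um = 63, n_sections = 4,
                                 jitter_sd = 2, seed = 5)
  dj <- vapply(stj, fit_circle_diameter, 1)
  expect_true(all(abs(dj - 126) < 3 * 2))
  expect_error(generate_sc_lumen_stack(radius_um = -1), "radius")
})

test_that("trajectory CSV round trip preserves the data and metadata", {
  sc <- generate_scene(3, width_um = 100, waviness = 0.05)
  pr <- load_protocol("sc_pressure_ramp", p_end = 30, duration = 0.03,
                      t_ramp = 0.005)
  tr <- generate_boundary_trajectory(sc, pr, n_frames = 4, edge_um = 15,
                                     beam_spacing = c(20, 10),
                                     target_steps = 300)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$coords, tr$coords, tolerance = 1e-9)
  expect_equal(back$ids, tr$ids)
  expect_equal(back$label, tr$label)
  expect_equal(back$seed, tr$seed)
  expect_equal(back$protocol$p_end, 30)
  unlink(c(f, paste0(f, ".meta.yaml")))
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(42)
  a <- stats::rnorm(1)
  set.seed(42)
  invisible(generate_scene(7))
  invisible(generate_sc_lumen_stack(seed = 3))
  b <- stats::rnorm(1)
  expect_identical(a, b)
})
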