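# Hughes-Liu beam element: shape functions, rotational update, fiber
# vectors, local basis, B matrix, internal force, distribution and coupling.

test_that("hex8 shape functions: Kronecker, partition of unity, center", {
  crn <- outflowve:::HEX8_SIGNS
  for (a in 1:8) {
    sh <- hex8_shape(crn[a, 1], crn[a, 2], crn[a, 3])
    expect_equal(sh$N, as.numeric(1:8 == a))
  }
  set.seed(1)
  for (i in 1:10) {
    p <- stats::runif(3, -1, 1)
    sh <- hex8_shape(p[1], p[2], p[3])
    expect_equal(sum(sh$N), 1)
    expect_equal(colSums(sh$dN), c(0, 0, 0))
  }
  expect_equal(hex8_shape(0, 0, 0)$N, rep(1 / 8, 8))
})

test_that("rotation update: identity, Rodrigues match, exact orthogonality", {
  expect_equal(rotation_update(c(0, 0, 0)), diag(3))
  th <- c(0, 0, 1e-3)
  expect_lt(max(abs(rotation_update(th) - oracle_rodrigues(th))), 1e-9)
  set.seed(7)
  for (i in 1:25) {
    th <- stats::runif(3, -0.3, 0.3)
    R <- rotation_update(th)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("fiber vectors compose rotations and preserve orthonormality", {
  n <- beam_node(c(0, 0, 0), Y_eta = c(0, 1, 0), Y_zeta = c(0, 0, 1))
  n0 <- update_fiber_vectors(n, c(0, 0, 0))
  expect_equal(n0$Y_eta, n$Y_eta)
  expect_equal(attr(n0, "dU_eta"), c(0, 0, 0))
  # 90 degrees about the beam axis (x) in 90 one-degree steps:
  # Y_eta (y) maps onto the initial Y_zeta direction (z)
  nn <- n
  for (i in 1:90) nn <- update_fiber_vectors(nn, c(pi / 180, 0, 0))
  expect_lt(max(abs(nn$Y_eta - c(0, 0, 1))), 1e-4)
  expect_lt(max(abs(nn$Y_zeta - c(0, -1, 0))), 1e-4)
  # orthogonality drift audit over many random small increments
  set.seed(5)
  nd <- n
  for (i in 1:1000) nd <- update_fiber_vectors(nd, stats::rnorm(3, sd = 1e-3))
  expect_lt(abs(sum(nd$Y_eta * nd$Y_zeta)), 1e-8)
  expect_equal(sqrt(sum(nd$Y_eta^2)), 1, tolerance = 1e-10)
})

test_that("local basis: canonical triad, co-rotation, right-handedness", {
  n1 <- beam_node(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  n2 <- beam_node(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1))
  q <- local_basis(n1, n2)
  expect_equal(q, cbind(e1 = c(1, 0, 0), e2 = c(0, 1, 0), e3 = c(0, 0, 1)))
  # rigid rotation of nodes and fibers rotates the triad identically
  R <- oracle_rodrigues(c(0.3, -0.2, 0.5))
  rot <- function(n) beam_node(as.numeric(R %*% n$x), as.numeric(R %*% n$Y_eta),
                               as.numeric(R %*% n$Y_zeta))
  q2 <- local_basis(rot(n1), rot(n2))
  expect_lt(max(abs(q2 - R %*% q)), 1e-12)
  set.seed(9)
  for (i in 1:20) {
    a <- stats::rnorm(3); b <- a + stats::rnorm(3)
    ye <- pracma_cross_t(stats::rnorm(3), b - a)
    m1 <- beam_node(a, ye, pracma_cross_t(b - a, ye))
    m2 <- beam_node(b, ye, pracma_cross_t(b - a, ye))
    qq <- local_basis(m1, m2)
    expect_lt(max(abs(pracma_cross_t(qq[, 1], qq[, 2]) - qq[, 3])), 1e-12)
  }
  expect_error(local_basis(n1, beam_node(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               "degenerate")
})

test_that("B matrix: rigid translation gives zero strain; FD oracle match", {
  n1 <- beam_node(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  n2 <- beam_node(c(1.7, 0.4, 0.2), c(0, 1, 0), c(0, 0, 1))
  sec <- beam_section(0.05)
  for (k in 1:4) {
    B <- beam_b_matrix(n1, n2, sec, point = k)
    expect_equal(dim(B), c(6, 18))
    d_rigid <- c(rep(c(0.3, -0.2, 0.5), 2), rep(0, 12))
    expect_lt(max(abs(B %*% d_rigid)), 1e-12)
  }
  # unit axial stretch of a straight unit beam: axial strain row = 1
  s1 <- beam_node(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  s2 <- beam_node(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  B <- beam_b_matrix(s1, s2, sec, point = 1)
  d_ax <- c(0, 0, 0, 1, 0, 0, rep(0, 12))
  expect_equal(as.numeric((B %*% d_ax)[1]), 1, tolerance = 1e-12)

  # finite-difference oracle: B d equals the FD gradient of the interpolated
  # displacement field (symmetrized, engineering shears)
  set.seed(13)
  d <- stats::rnorm(18, sd = 0.01)
  off <- sec$pts[2, ]
  interp <- function(xi, ye, zt) {
    N <- c((1 - xi) / 2, (1 + xi) / 2)
    y <- N[1] * n1$x + N[2] * n2$x +
      ye * (N[1] * n1$Y_eta + N[2] * n2$Y_eta) +
      zt * (N[1] * n1$Y_zeta + N[2] * n2$Y_zeta)
    u <- N[1] * d[1:3] + N[2] * d[4:6] +
      ye * (N[1] * d[7:9] + N[2] * d[13:15]) +
      zt * (N[1] * d[10:12] + N[2] * d[16:18])
    list(y = y, u = u)
  }
  h <- 1e-6
  base <- interp(0, off[1], off[2])
  dy <- matrix(0, 3, 3); du <- matrix(0, 3, 3)
  probes <- list(c(h, 0, 0), c(0, h, 0), c(0, 0, h))
  for (k in 1:3) {
    pp <- probes[[k]]
    plus <- interp(pp[1], off[1] + pp[2], off[2] + pp[3])
    minus <- interp(-pp[1], off[1] - pp[2], off[2] - pp[3])
    dy[, k] <- (plus$y - minus$y) / 2
    du[, k] <- (plus$u - minus$u) / 2
  }
  Gfd <- du %*% solve(dy)            # du/dy by chain rule through parameters
  eps_fd <- (Gfd + t(Gfd)) / 2
  Bd <- as.numeric(beam_b_matrix(n1, n2, sec, point = 2) %*% d)
  expect_equal(Bd[1:3], diag(eps_fd), tolerance = 1e-6)
  expect_equal(Bd[4], 2 * eps_fd[1, 2], tolerance = 1e-6)
  expect_equal(Bd[5], 2 * eps_fd[2, 3], tolerance = 1e-6)
  expect_equal(Bd[6], 2 * eps_fd[3, 1], tolerance = 1e-6)
})

test_that("beam internal force: zero state, bar theory, Newton's third law", {
  sec <- beam_section(0.05)
  mat <- visco_params(10, 10, 100, nu_vol = 0.3)   # elastic limit
  n1 <- beam_node(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  n2 <- beam_node(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  z <- beam_internal_force(n1, n2, c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                           c(0, 0, 0), NULL, mat, sec, dt = 1e-4)
  expect_equal(z$force, rep(0, 12))
  # small axial strain: axial force = E A eps with E = 2 G (1 + nu)
  eps <- 1e-4
  r <- beam_internal_force(n1, n2, c(0, 0, 0), c(eps, 0, 0), c(0, 0, 0),
                           c(0, 0, 0), NULL, mat, sec, dt = 1e-4)
  E <- 2 * 10 * 1.3
  expect_equal(r$force[7], E * sec$area * eps, tolerance = 0.01)
  # translational equilibrium for arbitrary deformation states
  set.seed(17)
  st <- NULL; nn1 <- n1; nn2 <- n2
  for (i in 1:5) {
    du1 <- stats::rnorm(3, sd = 1e-3); du2 <- stats::rnorm(3, sd = 1e-3)
    th1 <- stats::rnorm(3, sd = 1e-3); th2 <- stats::rnorm(3, sd = 1e-3)
    r <- beam_internal_force(nn1, nn2, du1, du2, th1, th2, st,
                             visco_params(12, 5, 200), sec, dt = 1e-4)
    st <- r$states; nn1 <- r$node1; nn2 <- r$node2
    f1 <- r$force[1:3]; f2 <- r$force[7:9]
    expect_lt(sqrt(sum((f1 + f2)^2)), 1e-10 * max(sqrt(sum(f1^2)), 1e-300))
  }
  # transverse normal stresses vanish in the local frame by condensation
  qloc <- t(local_basis(nn1, nn2))
  for (k in 1:4) {
    sl <- outflowve:::rotate_voigt(st[[k]]$sigma, qloc)
    expect_lt(max(abs(sl[2:3])), 1e-10 * (1 + max(abs(sl))))
  }
})

test_that("rigid rotation of a beam generates no strain or stress", {
  # the whole element (positions and section vectors) is carried through a
  # full turn by the solver's own exactly-orthogonal rotation operator; an
  # incrementally objective element must see zero strain along the way
  sec <- beam_section(0.05)
  mat <- visco_params(12, 5, 200)
  n1 <- beam_node(c(0.2, -0.1, 0.3), c(0, 1, 0), c(0, 0, 1))
  n2 <- beam_node(c(1.2, 0.2, 0.1), c(0, 1, 0), c(0, 0, 1))
  st <- NULL
  nsteps <- 360
  dth <- c(0, 0, 2 * pi / nsteps)
  Rstep <- rotation_update(dth)
  maxstrain <- 0; maxforce <- 0
  for (i in 1:nsteps) {
    du1 <- as.numeric(Rstep %*% n1$x) - n1$x
    du2 <- as.numeric(Rstep %*% n2$x) - n2$x
    r <- beam_internal_force(n1, n2, du1, du2, dth, dth, st, mat, sec,
                             dt = 1e-4)
    st <- r$states; n1 <- r$node1; n2 <- r$node2
    maxstrain <- max(maxstrain, r$max_abs_strain)
    maxforce <- max(maxforce, max(abs(r$force)))
  }
  expect_lt(maxstrain, 1e-8)
  expect_lt(maxforce, 1e-8 * 12 * sec$area)
  # one full turn returns the element to its start (up to the second-order
  # angle deficit of the rotation operator, ~ n * (dth)^3 / 12)
  expect_lt(max(abs(n2$x - c(1.2, 0.2, 0.1))), 1e-3)
  expect_lt(max(abs(n1$Y_eta - c(0, 1, 0))), 1e-3)
})

test_that("beam distribution: spacing, containment, and tissue confinement", {
  sc <- generate_scene(2, width_um = 120, waviness = 0.05)
  sm <- build_scene_model(sc, load_protocol("sc_pressure_ramp"), edge_um = 6,
                          beam_spacing = c(4, 2.5))
  b <- sm$beams
  # along-curve spacing concentrates at 4 um
  seglen <- sqrt(rowSums((b$control_points[b$segments[, 1], ] -
                          b$control_points[b$segments[, 2], ])^2))
  expect_lt(abs(stats::median(seglen) - 4) / 4, 0.15)
  # z-plane spacing is 2.5 um
  zs <- sort(unique(b$control_points[, 3]))
  expect_true(all(abs(diff(zs) - 2.5) < 1e-9))
  # every control point lies inside some hexahedron
  loc <- locate_points(sm$mesh, b$control_points)
  expect_true(all(loc$inside))
  # number of fiber curves ~ band depth / 4 + 1 (counted per z-plane)
  pts_z1 <- sum(b$control_points[, 3] == zs[1])
  per_curve <- length(unique(b$control_points[, 1]))
  band <- sc$tm_depth_um + sc$jct_um
  expect_lt(abs(pts_z1 / per_curve - (floor(band / 4) + 1)), 3)
  # curve-to-curve spacing across the band also concentrates near 4 um
  ys_col <- sort(b$control_points[b$control_points[, 3] == zs[1] &
                                  b$control_points[, 1] == b$control_points[1, 1], 2])
  expect_lt(abs(stats::median(diff(ys_col)) - 4) / 4, 0.15)
  # no segment crosses into SC wall or sclera
  expect_true(all(b$group %in% c("TM_beam", "JCT_beam")))
  mid <- (b$control_points[b$segments[, 1], ] +
            b$control_points[b$segments[, 2], ]) / 2
  tis <- sm$mesh$tissue[locate_points(sm$mesh, mid)$elem]
  expect_true(all(tis %in% c("TM", "JCT")))
})

test_that("coupling: orphan detection, action-reaction, rigid translation", {
  m <- extrude_and_mesh(list(
    TM_anterior = data.frame(x = c(0, 100), y = c(0, 0)),
    SC_inner_wall = data.frame(x = c(0, 100), y = c(50, 50))),
    target_edge_um = 10)
  pts <- rbind(c(5, 5, 5), c(50, 25, 5), c(95, 45, 5))
  beams <- structure(list(control_points = pts,
                          segments = rbind(c(1, 2), c(2, 3)),
                          section = beam_section(0.5),
                          group = c("TM_beam", "TM_beam")),
                     class = "beam_network")
  cp <- couple_beams_to_solid(beams, m)
  expect_equal(length(cp$host_elem), 3)
  # rigid translation: host interpolation follows, zero penalty residual
  d <- c(3, -2, 1)
  f <- coupling_forces(cp, m, sweep(m$nodes, 2, d, "+"),
                       sweep(pts, 2, d, "+"), k = 10)
  expect_lt(max(abs(f$f_beam)), 1e-9)
  # action-reaction for a stretched state
  f2 <- coupling_forces(cp, m, m$nodes * 1.01, pts, k = 10)
  expect_lt(max(abs(colSums(f2$f_beam) + colSums(f2$f_solid))), 1e-9)
  # a point outside the mesh is reported
  bad <- beams; bad$control_points[2, 2] <- 500
  expect_error(couple_beams_to_solid(bad, m), "outside")
})
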