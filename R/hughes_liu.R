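# Hughes-Liu 2-noded beam element: degenerated-solid kinematics with finite
# transverse shear, co-rotational local frame, second-order rotational update,
# viscoelastic stress update under the zero-transverse-normal-stress
# condition, and internal force/moment assembly. This file is the reference
# implementation used element-by-element; the explicit solver repeats the same
# algorithm in compiled code.

skew3 <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0),
                            3, 3)

#' Second-order accurate incremental rotation operator
#'
#' The Hughes-Winget form
#' \eqn{R = I + (S + S^2/2) / (1 + \|\Delta\theta\|^2/4)} with
#' \eqn{S_{ij} = e_{ikj}\Delta\theta_k}: orthogonal to machine precision and
#' second-order accurate in the rotation increment.
#'
#' @param dtheta incremental rotation vector, rad (norm < pi).
#' @return 3x3 rotation matrix.
#' @export
rotation_update <- function(dtheta) {
  stopifnot(length(dtheta) == 3)
  S <- skew3(dtheta)         # S %*% v = dtheta x v
  D <- 1 + sum(dtheta^2) / 4
  diag(3) + (S + S %*% S / 2) / D
}

#' Create a beam node
#'
#' @param x 3-vector position (reference = current at creation).
#' @param Y_eta,Y_zeta unit section ("fiber") vectors, orthogonal to each
#'   other and typically to the beam axis.
#' @return list of class `beam_node`.
#' @export
beam_node <- function(x, Y_eta, Y_zeta) {
  Y_eta <- Y_eta / sqrt(sum(Y_eta^2))
  Y_zeta <- Y_zeta / sqrt(sum(Y_zeta^2))
  structure(list(x = as.numeric(x), Y_eta = Y_eta, Y_zeta = Y_zeta),
            class = "beam_node")
}

#' Rotate the section vectors of a beam node
#'
#' Applies [rotation_update()] to both fiber vectors and reports the fiber-tip
#' displacement increments (new minus old unit vectors).
#'
#' @param node a [beam_node()].
#' @param dtheta incremental rotation vector, rad.
#' @return the node with rotated vectors plus attributes `dU_eta`, `dU_zeta`.
#' @export
update_fiber_vectors <- function(node, dtheta) {
  R <- rotation_update(dtheta)
  Ye <- as.numeric(R %*% node$Y_eta)
  Yz <- as.numeric(R %*% node$Y_zeta)
  out <- node
  out$Y_eta <- Ye / sqrt(sum(Ye^2))
  out$Y_zeta <- Yz / sqrt(sum(Yz^2))
  attr(out, "dU_eta") <- out$Y_eta - node$Y_eta
  attr(out, "dU_zeta") <- out$Y_zeta - node$Y_zeta
  out
}

#' Co-rotational local basis of a beam element
#'
#' \eqn{e_1} along the current axis, \eqn{e_2'} from the averaged eta-fiber
#' vectors, \eqn{e_3 = e_1 \times e_2'} (normalized), \eqn{e_2 = e_3 \times
#' e_1}: an orthonormal triad that rotates rigidly with the element.
#'
#' @param node1,node2 [beam_node()]s at the two ends.
#' @return 3x3 matrix with columns `e1`, `e2`, `e3`.
#' @export
local_basis <- function(node1, node2) {
  ax <- node2$x - node1$x
  L <- sqrt(sum(ax^2))
  if (L < 1e-14) stop("degenerate beam: coincident nodes")
  e1 <- ax / L
  e2p <- node1$Y_eta + node2$Y_eta
  n2 <- sqrt(sum(e2p^2))
  if (n2 < 1e-14) stop("degenerate beam: opposing section vectors")
  e2p <- e2p / n2
  e3 <- pracma_cross(e1, e2p)
  n3 <- sqrt(sum(e3^2))
  if (n3 < 1e-10) stop("degenerate beam: section vector parallel to axis")
  e3 <- e3 / n3
  e2 <- pracma_cross(e3, e1)
  cbind(e1 = e1, e2 = e2, e3 = e3)
}

# Jacobian and shape-gradient machinery at the mid-axis cross-section.
# Parametric coordinates (xi, y_eta, y_zeta): y_eta/y_zeta are physical
# offsets along the current unit fiber vectors (reference offsets eta_bar =
# zeta_bar = 0).
beam_point_geometry <- function(y1, y2, Ye1, Ye2, Yz1, Yz2, c_eta, c_zeta) {
  J <- cbind((y2 - y1) / 2 + c_eta * (Ye2 - Ye1) / 2 + c_zeta * (Yz2 - Yz1) / 2,
             (Ye1 + Ye2) / 2,
             (Yz1 + Yz2) / 2)
  detJ <- det(J)
  if (abs(detJ) < 1e-18) stop("element-distortion error: singular beam Jacobian")
  invJ <- solve(J)
  # gradients of N_a and of the tip-displacement coefficient functions
  # phi_eta_a = N_a * y_eta, phi_zeta_a = N_a * y_zeta w.r.t. global coords
  Nxi <- c(-0.5, 0.5); Na <- c(0.5, 0.5)
  gN <- lapply(1:2, function(a) as.numeric(c(Nxi[a], 0, 0) %*% invJ))
  gPe <- lapply(1:2, function(a) as.numeric(c(Nxi[a] * c_eta, Na[a], 0) %*% invJ))
  gPz <- lapply(1:2, function(a) as.numeric(c(Nxi[a] * c_zeta, 0, Na[a]) %*% invJ))
  list(J = J, detJ = detJ, invJ = invJ, gN = gN, gPe = gPe, gPz = gPz)
}

#' Strain-displacement (B) matrix of the Hughes-Liu beam
#'
#' The 6 x 18 operator relating the 18 incremental nodal unknowns (3
#' translations per node, then the eta/zeta fiber-tip displacement increments
#' per node) to the 6 global strain components, evaluated at the cross-section
#' at the mid-point of the axis. Column order:
#' `u1, u2, U_eta1, U_zeta1, U_eta2, U_zeta2` (3 components each); row order
#' `e11, e22, e33, g12, g23, g31` (engineering shears).
#'
#' @param node1,node2 [beam_node()]s (current configuration).
#' @param section a [beam_section()].
#' @param point integration-point index into `section$pts`, or a length-2
#'   numeric of physical offsets.
#' @return 6 x 18 matrix.
#' @export
beam_b_matrix <- function(node1, node2, section, point = 1) {
  off <- if (length(point) == 2) point else section$pts[point, ]
  g <- beam_point_geometry(node1$x, node2$x, node1$Y_eta, node2$Y_eta,
                           node1$Y_zeta, node2$Y_zeta, off[1], off[2])
  B <- matrix(0, 6, 18)
  blocks <- list(g$gN[[1]], g$gN[[2]], g$gPe[[1]], g$gPz[[1]],
                 g$gPe[[2]], g$gPz[[2]])
  for (kb in seq_along(blocks)) {
    gr <- blocks[[kb]]            # gradient of the scalar coefficient fn
    cols <- (kb - 1) * 3 + 1:3
    B[1, cols[1]] <- gr[1]
    B[2, cols[2]] <- gr[2]
    B[3, cols[3]] <- gr[3]
    B[4, cols[1]] <- gr[2]; B[4, cols[2]] <- gr[1]
    B[5, cols[2]] <- gr[3]; B[5, cols[3]] <- gr[2]
    B[6, cols[1]] <- gr[3]; B[6, cols[3]] <- gr[1]
  }
  B
}

# local-frame tensor rotation: sig_local = q sig q^T with q rows = basis
rotate_voigt <- function(v, q, strain = FALSE) {
  tensor_to_voigt(q %*% voigt_to_tensor(v, strain) %*% t(q), strain)
}

# zero-transverse-normal-stress viscoelastic update in the local frame.
# Static condensation of the local transverse normal strains: solve the 2x2
# linear system so sigma_22 = sigma_33 = 0 after the update, then redo the
# full update with the amended strain increment (keeps h consistent).
beam_local_update <- function(sigma_l, h_l, dEps_l, dt, params) {
  x <- params$beta * dt
  Geff <- params$Ginf + (params$G0 - params$Ginf) * relax_phi(x)
  K <- bulk_modulus(params)
  a <- K + 4 * Geff / 3
  b <- K - 2 * Geff / 3
  do_update <- function(dE) {
    st <- update_stress(stress_state(sigma_l, h_l, 0), dE,
                        dt = dt, params = params)
    st
  }
  trial <- do_update(dEps_l)
  rhs <- -c(trial$sigma[2], trial$sigma[3])
  den <- a * a - b * b
  d22 <- (a * rhs[1] - b * rhs[2]) / den
  d33 <- (a * rhs[2] - b * rhs[1]) / den
  dE <- dEps_l
  dE[2] <- dE[2] + d22
  dE[3] <- dE[3] + d33
  out <- do_update(dE)
  out$sigma[2:3] <- 0   # exact by construction; clear roundoff
  out
}

#' Internal force of one Hughes-Liu beam element over an increment
#'
#' Advances one viscoelastic beam element by one kinematic increment: rotates
#' the section vectors with the nodal rotation increments, rebuilds the
#' co-rotational basis, forms the incremental strain and spin at each
#' cross-section integration point (one-point axial rule), updates the stress
#' in the local frame under the zero-transverse-normal-stress condition,
#' rotates back, and integrates nodal forces and moments
#' (moments via the fiber-tip transformation \eqn{m_a = h_\eta^T f_{\eta a} +
#' h_\zeta^T f_{\zeta a}}).
#'
#' @param node1,node2 [beam_node()]s in the *previous* configuration.
#' @param du1,du2 translational increments of the two nodes.
#' @param dtheta1,dtheta2 incremental rotation vectors of the two nodes.
#' @param states list of 4 `list(sigma, h)` per integration point (global
#'   frame Voigt), or `NULL` for virgin state.
#' @param material a [visco_params()].
#' @param section a [beam_section()]; offsets in the same length unit as the
#'   node coordinates.
#' @param dt time increment, s.
#' @return list with `force` (12-vector: f1, m1, f2, m2), updated `node1`,
#'   `node2`, `states`, and `max_abs_strain` (increment, for objectivity
#'   audits).
#' @export
beam_internal_force <- function(node1, node2, du1, du2, dtheta1, dtheta2,
                                states, material, section, dt) {
  if (is.null(states))
    states <- replicate(nrow(section$pts),
                        list(sigma = numeric(6), h = numeric(6)),
                        simplify = FALSE)
  n1 <- update_fiber_vectors(node1, dtheta1)
  n2 <- update_fiber_vectors(node2, dtheta2)
  n1$x <- node1$x + du1
  n2$x <- node2$x + du2
  q <- t(local_basis(n1, n2))   # rows = basis vectors

  dUe1 <- attr(n1, "dU_eta"); dUz1 <- attr(n1, "dU_zeta")
  dUe2 <- attr(n2, "dU_eta"); dUz2 <- attr(n2, "dU_zeta")

  f <- matrix(0, 2, 3); fe <- matrix(0, 2, 3); fz <- matrix(0, 2, 3)
  max_strain <- 0
  for (k in seq_len(nrow(section$pts))) {
    ce <- section$pts[k, 1]; cz <- section$pts[k, 2]
    g <- beam_point_geometry(n1$x, n2$x, n1$Y_eta, n2$Y_eta,
                             n1$Y_zeta, n2$Y_zeta, ce, cz)
    # incremental displacement gradient at the half-step configuration
    # (mid positions and mid, unnormalized, section vectors): finite rigid
    # steps then produce exactly zero strain
    gm <- beam_point_geometry(n1$x - du1 / 2, n2$x - du2 / 2,
                              n1$Y_eta - attr(n1, "dU_eta") / 2,
                              n2$Y_eta - attr(n2, "dU_eta") / 2,
                              n1$Y_zeta - attr(n1, "dU_zeta") / 2,
                              n2$Y_zeta - attr(n2, "dU_zeta") / 2, ce, cz)
    dUp <- cbind((du2 - du1) / 2 + ce * (dUe2 - dUe1) / 2 + cz * (dUz2 - dUz1) / 2,
                 (dUe1 + dUe2) / 2,
                 (dUz1 + dUz2) / 2)
    G <- dUp %*% gm$invJ
    ss <- strain_spin_increment(G)
    max_strain <- max(max_strain, max(abs(ss$dEps)))

    st <- states[[k]]
    sig <- jaumann_rotate(st$sigma, ss$dOmega)
    h <- jaumann_rotate(st$h, ss$dOmega)
    sig_l <- rotate_voigt(sig, q)
    h_l <- rotate_voigt(h, q)
    dE_l <- rotate_voigt(tensor_to_voigt(ss$dEps, strain = TRUE), q,
                         strain = TRUE)
    up <- beam_local_update(sig_l, h_l, dE_l, dt, material)
    sig_g <- rotate_voigt(up$sigma, t(q))
    states[[k]] <- list(sigma = sig_g, h = rotate_voigt(up$h, t(q)))

    S <- voigt_to_tensor(sig_g)
    w <- 2 * section$wts[k] * g$detJ   # xi-weight 2 x area weight x detJ
    for (a in 1:2) {
      f[a, ] <- f[a, ] + w * as.numeric(S %*% g$gN[[a]])
      fe[a, ] <- fe[a, ] + w * as.numeric(S %*% g$gPe[[a]])
      fz[a, ] <- fz[a, ] + w * as.numeric(S %*% g$gPz[[a]])
    }
  }
  # m_a = h_eta^T f_eta + h_zeta^T f_zeta = Y_eta x f_eta + Y_zeta x f_zeta
  m1 <- as.numeric(skew3(n1$Y_eta) %*% fe[1, ] + skew3(n1$Y_zeta) %*% fz[1, ])
  m2 <- as.numeric(skew3(n2$Y_eta) %*% fe[2, ] + skew3(n2$Y_zeta) %*% fz[2, ])
  list(force = c(f[1, ], m1, f[2, ], m2), node1 = n1, node2 = n2,
       states = states, max_abs_strain = max_strain)
}
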