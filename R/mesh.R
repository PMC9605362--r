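# Mesh and geometry utilities: smoothing spline for segmented boundaries,
# extrusion to a single-layer hexahedral mesh, tissue-layer partition,
# element quality metrics, explicit-dynamics critical time step, and the
# best-fit-circle diameter of SC lumen cross-sections.
#
# Unit conventions: user-facing geometry is in micrometres; the solver works
# in a consistent mm-MPa-N-tonne/mm^3-s system, converted at its boundary.

TISSUES <- c("TM", "JCT", "SC_wall", "SCLERA")

#' Cubic smoothing spline for segmented tissue boundaries
#'
#' Minimizes \eqn{p \sum_i w_i (y_i - s(x_i))^2 + (1-p) \int s''(x)^2 dx}
#' over natural cubic splines, the classical Reinsch formulation. `p = 1`
#' interpolates the data exactly; `p = 0` returns the weighted least-squares
#' straight line. The default `p = 0.999` removes sharp segmentation vertices
#' while following the boundary closely.
#'
#' @param x,y ordered planar points (same length, >= 4). `x` strictly
#'   increasing (duplicated abscissae are an error).
#' @param p smoothing parameter in `[0, 1]`.
#' @param w positive per-point weights (default all 1).
#' @param xout abscissae of the output grid (default `x`).
#' @return data.frame with columns `x`, `y` of the smoothed curve on `xout`.
#' @export
smooth_boundary <- function(x, y, p = 0.999, w = NULL, xout = x) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n)
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (is.null(w)) w <- rep(1, n)
  if (any(w <= 0)) stop("weights must be > 0")
  if (any(diff(x) <= 0)) {
    if (anyDuplicated(x)) stop("duplicated abscissae in input")
    stop("x must be strictly increasing")
  }

  if (p == 0) {                      # roughness-only limit: LS straight line
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    yy <- fit$coefficients[1] + fit$coefficients[2] * xout
    return(data.frame(x = xout, y = as.numeric(yy)))
  }

  if (p == 1) {
    s <- y                           # penalty term vanishes: interpolation
  } else {
    h <- diff(x)
    # Green & Silverman band matrices: Q (n x n-2), R (n-2 x n-2)
    Q <- matrix(0, n, n - 2)
    R <- matrix(0, n - 2, n - 2)
    for (j in 2:(n - 1)) {
      k <- j - 1
      Q[j - 1, k] <- 1 / h[j - 1]
      Q[j, k] <- -1 / h[j - 1] - 1 / h[j]
      Q[j + 1, k] <- 1 / h[j]
      R[k, k] <- (h[j - 1] + h[j]) / 3
      if (k > 1) {
        R[k - 1, k] <- h[j - 1] / 6
        R[k, k - 1] <- h[j - 1] / 6
      }
    }
    K <- Q %*% solve(R, t(Q))        # roughness penalty: integral of s''^2
    A <- p * diag(w) + (1 - p) * K
    s <- as.numeric(solve(A, p * w * y))
  }
  yy <- stats::spline(x, s, xout = xout, method = "natural")$y
  data.frame(x = xout, y = yy)
}

#' Construct a hexahedral mesh object
#'
#' Low-level constructor; most users obtain meshes from [extrude_and_mesh()].
#'
#' @param nodes N x 3 nodal coordinates, micrometres.
#' @param elems E x 8 node indices (1-based, right-handed ordering).
#' @param tissue character vector of per-element tissue tags.
#' @param node_sets named list of integer node-index vectors.
#' @param dims optional structured dimensions `c(nx, ny, nz)` (element counts).
#' @return object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elems, tissue = rep("TM", nrow(elems)),
                     node_sets = list(), dims = NULL) {
  stopifnot(ncol(nodes) == 3, ncol(elems) == 8, length(tissue) == nrow(elems))
  structure(list(nodes = nodes, elems = elems, tissue = tissue,
                 node_sets = node_sets, dims = dims),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %d nodes, %d elements (%s)\n", nrow(x$nodes),
              nrow(x$elems), paste(names(table(x$tissue)), table(x$tissue),
                                   sep = ":", collapse = ", ")))
  invisible(x)
}

# shape function derivative signs for the standard hex8 ordering
HEX8_SIGNS <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                       -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
                     nrow = 8, byrow = TRUE)

#' Trilinear hexahedron shape functions
#'
#' \eqn{N_a = (1+\xi_a\xi)(1+\eta_a\eta)(1+\zeta_a\zeta)/8} on the biunit cube.
#'
#' @param xi,eta,zeta parametric coordinates in `[-1, 1]`.
#' @return list with `N` (length 8) and `dN` (8 x 3 parametric derivatives).
#' @export
hex8_shape <- function(xi, eta, zeta) {
  a <- HEX8_SIGNS
  N <- (1 + a[, 1] * xi) * (1 + a[, 2] * eta) * (1 + a[, 3] * zeta) / 8
  dN <- cbind(a[, 1] * (1 + a[, 2] * eta) * (1 + a[, 3] * zeta),
              a[, 2] * (1 + a[, 1] * xi) * (1 + a[, 3] * zeta),
              a[, 3] * (1 + a[, 1] * xi) * (1 + a[, 2] * eta)) / 8
  list(N = N, dN = dN)
}

GAUSS2 <- 1 / sqrt(3)
hex_gauss_points <- function() {
  g <- GAUSS2
  expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g))
}

#' Extrude smoothed boundaries into a single-layer hexahedral mesh
#'
#' Builds a structured grid of 8-noded hexahedra between the anterior TM
#' boundary and the SC inner-wall boundary of a cross-section, swept 10 um out
#' of plane (single element through the extrusion). Columns follow the local
#' band depth, so element rows grade between the two curves.
#'
#' @param boundaries list with at least `TM_anterior` and `SC_inner_wall`
#'   data.frames (columns `x`, `y`, micrometres); typically `scene$boundaries`.
#' @param target_edge_um in-plane target element edge, micrometres.
#' @param thickness_um extrusion thickness (default 10).
#' @return a [hex_mesh()] with node sets `sc_inner_wall_track`,
#'   `floating_boundary`, `lateral_fixed` and face set `pressure_faces`
#'   (attribute), plus the generating boundary curves as attributes.
#' @export
extrude_and_mesh <- function(boundaries, target_edge_um, thickness_um = 10) {
  top <- boundaries$TM_anterior
  bot <- boundaries$SC_inner_wall
  if (is.null(top) || is.null(bot))
    stop("boundaries must contain TM_anterior and SC_inner_wall")
  xr <- range(top$x)
  ftop <- stats::approxfun(top$x, top$y, rule = 2)
  fbot <- stats::approxfun(bot$x, bot$y, rule = 2)
  xs_chk <- seq(xr[1], xr[2], length.out = 200)
  if (any(fbot(xs_chk) - ftop(xs_chk) <= 0))
    stop("intersecting boundaries: TM_anterior crosses SC_inner_wall")

  nx <- max(2L, round(diff(xr) / target_edge_um))
  depth <- mean(fbot(xs_chk) - ftop(xs_chk))
  ny <- max(2L, round(depth / target_edge_um))
  nz <- 1L
  xs <- seq(xr[1], xr[2], length.out = nx + 1)
  zs <- c(0, thickness_um)

  nid <- function(i, j, k) (k - 1L) * (nx + 1L) * (ny + 1L) +
    (j - 1L) * (nx + 1L) + i
  nodes <- matrix(0, (nx + 1) * (ny + 1) * 2, 3)
  for (k in 1:2) for (j in 1:(ny + 1)) for (i in 1:(nx + 1)) {
    f <- (j - 1) / ny
    y <- (1 - f) * ftop(xs[i]) + f * fbot(xs[i])
    nodes[nid(i, j, k), ] <- c(xs[i], y, zs[k])
  }
  elems <- matrix(0L, nx * ny, 8)
  e <- 0L
  for (j in 1:ny) for (i in 1:nx) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, 1), nid(i + 1, j, 1), nid(i + 1, j + 1, 1),
                    nid(i, j + 1, 1), nid(i, j, 2), nid(i + 1, j, 2),
                    nid(i + 1, j + 1, 2), nid(i, j + 1, 2))
  }
  # node ordering above is right-handed for xi->x, eta->y, zeta->z; but the
  # corner convention of HEX8_SIGNS maps eta to the second local direction:
  # local (xi,eta) traverse (i,j) so corners 1..4 must be (i,j),(i+1,j),
  # (i+1,j+1),(i,j+1) in (xi,eta) = (--),(+-),(++),(-+): that is satisfied.

  sc_track <- nid(1:(nx + 1), ny + 1, 1)
  floating <- nid(1:(nx + 1), 1, 1)
  lateral <- c(nid(1, 1:(ny + 1), 1), nid(1, 1:(ny + 1), 2),
               nid(nx + 1, 1:(ny + 1), 1), nid(nx + 1, 1:(ny + 1), 2))
  # pressure faces: SC-facing (bottom) faces, ordered for outward (+y) normals
  pf <- matrix(0L, nx, 4)
  for (i in 1:nx)
    pf[i, ] <- c(nid(i, ny + 1, 1), nid(i, ny + 1, 2),
                 nid(i + 1, ny + 1, 2), nid(i + 1, ny + 1, 1))
  for (i in 1:nx) {  # orientation audit: flip if normal points -y
    v <- nodes[pf[i, ], ]
    nrm <- pracma_cross(v[3, ] - v[1, ], v[4, ] - v[2, ])
    if (nrm[2] < 0) pf[i, ] <- rev(pf[i, ])
  }

  m <- hex_mesh(nodes, elems,
                tissue = rep("TM", nrow(elems)),
                node_sets = list(sc_inner_wall_track = sc_track,
                                 floating_boundary = floating,
                                 lateral_fixed = lateral),
                dims = c(nx, ny, nz))
  attr(m, "pressure_faces") <- pf
  attr(m, "thickness_um") <- thickness_um
  attr(m, "boundaries") <- boundaries
  jac <- hex_corner_jacobians(m)
  if (min(jac) <= 0) stop("mesh generation produced non-positive Jacobians")
  m
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Corner Jacobian determinants of every element
#'
#' @param mesh a [hex_mesh()].
#' @return E x 8 matrix of Jacobian determinants at the 8 corners.
#' @export
hex_corner_jacobians <- function(mesh) {
  out <- matrix(0, nrow(mesh$elems), 8)
  for (e in seq_len(nrow(mesh$elems))) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    for (a in 1:8) {
      sh <- hex8_shape(HEX8_SIGNS[a, 1], HEX8_SIGNS[a, 2], HEX8_SIGNS[a, 3])
      out[e, a] <- det(t(X) %*% sh$dN)
    }
  }
  out
}

#' Partition a mesh into SC inner wall, JCT, and TM layers
#'
#' Elements are tagged by the distance of their centroid from the SC-facing
#' boundary: within `sc_thickness` (at least one element row) the tag is
#' `SC_wall`, the next `jct_thickness` band is `JCT`, the remainder `TM`.
#'
#' @param mesh a [hex_mesh()] from [extrude_and_mesh()].
#' @param jct_thickness JCT band thickness, micrometres (default 14).
#' @param sc_thickness SC inner-wall thickness, micrometres (default 2.2).
#' @return the mesh with updated `tissue` tags.
#' @export
partition_layers <- function(mesh, jct_thickness = 14, sc_thickness = 2.2) {
  bnd <- attr(mesh, "boundaries")
  if (is.null(bnd)) stop("mesh has no designated SC-facing boundary")
  fbot <- stats::approxfun(bnd$SC_inner_wall$x, bnd$SC_inner_wall$y, rule = 2)
  ftop <- stats::approxfun(bnd$TM_anterior$x, bnd$TM_anterior$y, rule = 2)
  cent <- t(vapply(seq_len(nrow(mesh$elems)),
                   function(e) colMeans(mesh$nodes[mesh$elems[e, ], ]),
                   numeric(3)))
  d <- fbot(cent[, 1]) - cent[, 2]           # distance below centroid to SC
  row_h <- (fbot(cent[, 1]) - ftop(cent[, 1])) / mesh$dims[2]
  depth <- mean(fbot(cent[, 1]) - ftop(cent[, 1]))
  if (jct_thickness + sc_thickness >= depth)
    stop("layer bands thicker than the tissue depth")
  sc_eff <- pmax(sc_thickness, row_h)        # at least the SC-facing row
  jct_eff <- if (jct_thickness > 0) pmax(jct_thickness, row_h) else 0
  tis <- rep("TM", nrow(mesh$elems))
  tis[d < sc_eff + jct_eff] <- "JCT"
  tis[d < sc_eff] <- "SC_wall"
  mesh$tissue <- tis
  attr(mesh, "sc_eff_um") <- mean(sc_eff)
  mesh
}

#' Per-element quality metrics
#'
#' Corner angles are measured between the three adjacent edges at each of the
#' 8 corners (minimum/maximum over all corners), the aspect ratio is the
#' longest over the shortest edge, and the volume is computed by 2x2x2 Gauss
#' integration of the Jacobian determinant.
#'
#' @param mesh a [hex_mesh()].
#' @return data.frame of class `quality_report` with per-element `min_angle`,
#'   `max_angle` (degrees), `aspect_ratio`, `volume` (um^3).
#' @export
element_quality <- function(mesh) {
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  # for each corner, its three incident edges (as rows of `edges`)
  corner_edges <- list(c(1, 4, 9), c(1, 2, 10), c(2, 3, 11), c(3, 4, 12),
                       c(5, 8, 9), c(5, 6, 10), c(6, 7, 11), c(7, 8, 12))
  gp <- hex_gauss_points()
  E <- nrow(mesh$elems)
  out <- data.frame(min_angle = numeric(E), max_angle = numeric(E),
                    aspect_ratio = numeric(E), volume = numeric(E))
  for (e in seq_len(E)) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    ev <- X[edges[, 2], ] - X[edges[, 1], ]
    el <- sqrt(rowSums(ev^2))
    out$aspect_ratio[e] <- max(el) / min(el)
    angs <- c()
    for (a in 1:8) {
      ce <- corner_edges[[a]]
      # direction of each incident edge pointing away from corner a
      dirs <- lapply(ce, function(k) {
        v <- ev[k, ] / el[k]
        if (edges[k, 1] == a) v else -v
      })
      for (i in 1:2) for (j in (i + 1):3) {
        cosv <- sum(dirs[[i]] * dirs[[j]])
        angs <- c(angs, acos(pmin(1, pmax(-1, cosv))) * 180 / pi)
      }
    }
    out$min_angle[e] <- min(angs)
    out$max_angle[e] <- max(angs)
    vol <- 0
    for (g in seq_len(nrow(gp))) {
      sh <- hex8_shape(gp$xi[g], gp$eta[g], gp$zeta[g])
      vol <- vol + det(t(X) %*% sh$dN)
    }
    out$volume[e] <- vol
  }
  class(out) <- c("quality_report", class(out))
  out
}

#' Critical explicit time step from the dilatational wave speed
#'
#' \eqn{C = \sqrt{E(1-\nu) / ((1+\nu)(1-2\nu)\rho)}}, element characteristic
#' length \eqn{l = V_e / A_{e,max}} (volume over largest face area), and
#' \eqn{\Delta t = l / C}.
#'
#' @param mesh a [hex_mesh()] (coordinates in micrometres).
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio, `0 < nu < 0.5`.
#' @param rho density, tonne/mm^3 (1.0e-9 is water-like soft tissue).
#' @return list with `C` (mm/s), per-element `dt` (s), and `dt_min`.
#' @export
critical_timestep <- function(mesh, E, nu, rho) {
  if (nu >= 0.5 || nu <= 0) stop("nu must be in (0, 0.5): wave speed undefined")
  if (rho <= 0) stop("rho must be > 0")
  C <- sqrt(E * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * rho))
  faces <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                 c(4, 3, 7, 8), c(2, 3, 7, 6), c(1, 4, 8, 5))
  gp <- hex_gauss_points()
  E_n <- nrow(mesh$elems)
  dt <- numeric(E_n)
  for (e in seq_len(E_n)) {
    X <- mesh$nodes[mesh$elems[e, ], ] * 1e-3   # um -> mm
    vol <- 0
    for (g in seq_len(nrow(gp))) {
      sh <- hex8_shape(gp$xi[g], gp$eta[g], gp$zeta[g])
      vol <- vol + det(t(X) %*% sh$dN)
    }
    amax <- max(vapply(seq_len(6), function(f) {
      P <- X[faces[f, ], ]
      0.5 * sqrt(sum(pracma_cross(P[3, ] - P[1, ], P[4, ] - P[2, ])^2))
    }, numeric(1)))
    dt[e] <- (vol / amax) / C
  }
  list(C = C, dt = dt, dt_min = min(dt))
}

#' Plane-stress sound speed
#' @param E Young's modulus, MPa; @param nu Poisson ratio; @param rho density
#'   tonne/mm^3.
#' @return c in mm/s.
#' @export
plane_stress_wave_speed <- function(E, nu, rho) sqrt(E / (rho * (1 - nu^2)))

#' Algebraic least-squares circle fit (diameter)
#'
#' Kasa fit: solves the linear system for circle center and radius; used for
#' the SC-lumen cross-section diameter measurement.
#'
#' @param points n x 2 matrix of planar points (n >= 3, non-collinear).
#' @return the fitted diameter (same units as the input).
#' @export
fit_circle_diameter <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need >= 3 points")
  A <- cbind(points[, 1], points[, 2], 1)
  b <- points[, 1]^2 + points[, 2]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol) || qr(A)$rank < 3) stop("collinear points: circle fit failed")
  r <- sqrt(sol[3] + (sol[1]^2 + sol[2]^2) / 4)
  2 * r
}
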