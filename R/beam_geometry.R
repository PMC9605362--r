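# Collagen-fibril surrogate: control-point lattice, fiber curves parallel to
# the TM edges, and the mesh-free penalty coupling of beam nodes to host
# hexahedra.

#' Distribute beam elements through the TM and JCT
#'
#' Control points are laid on fiber curves that blend linearly between the
#' anterior TM edge and the lower JCT edge (an asymmetric fan parallel to both
#' edges), with in-plane spacing `planar_spacing` along and across the curves
#' and `thickness_spacing` between extrusion planes. Segments connect
#' consecutive points along each curve; the group tag is inherited from the
#' host element tissue. The tubular cross-section radius is either given or
#' derived from the target fiber area fraction so that coarse lattices keep
#' the composite (rule-of-mixtures) stiffness of the default 4 x 2.5 um
#' lattice of 0.5-um fibers.
#'
#' @param mesh a partitioned [hex_mesh()].
#' @param planar_spacing in-plane control-point spacing, micrometres.
#' @param thickness_spacing through-thickness plane spacing, micrometres.
#' @param r_outer fiber outer radius, micrometres, or `NULL` to preserve
#'   `fiber_fraction`.
#' @param fiber_fraction fiber area fraction per lattice cell; default
#'   `pi * 0.5^2 / (4 * 2.5)` (a 0.5-um fiber on the reference lattice).
#' @return object of class `beam_network`.
#' @export
distribute_beams <- function(mesh, planar_spacing = 4, thickness_spacing = 2.5,
                             r_outer = NULL,
                             fiber_fraction = pi * 0.5^2 / (4 * 2.5)) {
  bnd <- attr(mesh, "boundaries")
  if (is.null(bnd)) stop("mesh must carry its generating boundaries")
  thick <- attr(mesh, "thickness_um")
  ftop <- stats::approxfun(bnd$TM_anterior$x, bnd$TM_anterior$y, rule = 2)
  fbot <- stats::approxfun(bnd$SC_inner_wall$x, bnd$SC_inner_wall$y, rule = 2)
  sc_eff <- attr(mesh, "sc_eff_um")
  if (is.null(sc_eff)) sc_eff <- 0
  xr <- range(mesh$nodes[, 1])

  band <- function(x) (fbot(x) - sc_eff) - ftop(x)  # TM + JCT depth
  depth <- mean(band(seq(xr[1], xr[2], length.out = 50)))
  n_curves <- floor(depth / planar_spacing) + 1L
  if (n_curves < 1) stop("beam lattice produced zero points: domain too small")
  n_x <- floor(diff(xr) / planar_spacing) + 1L
  xs <- seq(xr[1], xr[2], length.out = n_x)
  zs <- seq(thickness_spacing / 2, thick - thickness_spacing / 2,
            by = thickness_spacing)
  if (length(zs) == 0) zs <- thick / 2

  # fractions across the band; keep a small margin off both edges
  fr <- (seq_len(n_curves) - 0.5) / n_curves
  pts <- list(); segs <- list(); cp_curve <- list()
  idx <- 0L
  for (z in zs) for (f in fr) {
    ys <- ftop(xs) + f * band(xs)
    id <- idx + seq_along(xs)
    pts[[length(pts) + 1]] <- cbind(xs, ys, z)
    segs[[length(segs) + 1]] <- cbind(id[-length(id)], id[-1])
    idx <- idx + length(xs)
  }
  cp <- do.call(rbind, pts)
  sg <- do.call(rbind, segs)
  colnames(cp) <- c("x", "y", "z")

  if (is.null(r_outer))
    r_outer <- sqrt(fiber_fraction * planar_spacing * thickness_spacing / pi)
  section <- beam_section(r_outer)

  # group tag from host element tissue at segment midpoints
  loc <- locate_points(mesh, (cp[sg[, 1], , drop = FALSE] +
                              cp[sg[, 2], , drop = FALSE]) / 2)
  gtag <- rep(NA_character_, nrow(sg))
  ok <- loc$inside & loc$elem > 0
  gtag[ok] <- paste0(mesh$tissue[loc$elem[ok]], "_beam")
  bad <- !(gtag %in% c("TM_beam", "JCT_beam"))
  if (any(bad)) {  # should not happen: lattice is confined to the TM+JCT band
    keep <- !bad
    sg <- sg[keep, , drop = FALSE]
    gtag <- gtag[keep]
  }
  structure(list(control_points = cp, segments = sg, section = section,
                 group = gtag,
                 spacing = c(planar = planar_spacing,
                             thickness = thickness_spacing)),
            class = "beam_network")
}

#' @export
print.beam_network <- function(x, ...) {
  cat(sprintf("beam_network: %d control points, %d segments (%s), r = %.3g um\n",
              nrow(x$control_points), nrow(x$segments),
              paste(names(table(x$group)), table(x$group), sep = ":",
                    collapse = ", "), x$section$r_outer))
  invisible(x)
}

#' Tubular beam cross-section with a 4-point integration rule
#'
#' One integration point per quadrant at the quadrant area centroid
#' (distance `4 r / (3 pi)` per axis for a solid circular section), each
#' carrying a quarter of the section area.
#'
#' @param r_outer outer radius, micrometres.
#' @param r_inner inner radius (0 = solid).
#' @return list with `r_outer`, `r_inner`, `area`, integration point offsets
#'   `pts` (4 x 2, micrometres) and weights `wts` (sum = area).
#' @export
beam_section <- function(r_outer, r_inner = 0) {
  stopifnot(r_outer > 0, r_inner >= 0, r_inner < r_outer)
  area <- pi * (r_outer^2 - r_inner^2)
  # solid-section quadrant centroid; for a tube, area-weighted difference
  csolid <- function(r) 4 * r / (3 * pi)
  if (r_inner > 0) {
    c0 <- (csolid(r_outer) * r_outer^2 - csolid(r_inner) * r_inner^2) /
      (r_outer^2 - r_inner^2)
  } else c0 <- csolid(r_outer)
  pts <- cbind(c(c0, -c0, -c0, c0), c(c0, c0, -c0, -c0))
  list(r_outer = r_outer, r_inner = r_inner, area = area,
       pts = pts, wts = rep(area / 4, 4))
}

#' Locate points in a structured hexahedral mesh
#'
#' Returns the host element and trilinear shape-function weights of each
#' query point; exact for the single-layer extruded meshes built here.
#'
#' @param mesh a structured [hex_mesh()].
#' @param pts n x 3 query coordinates, micrometres.
#' @return list with `elem` (host indices) and `weights` (n x 8), plus
#'   `inside` logical.
#' @export
locate_points <- function(mesh, pts) {
  if (is.null(mesh$dims)) stop("locate_points requires a structured mesh")
  nx <- mesh$dims[1]; ny <- mesh$dims[2]
  pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  elem <- integer(n); W <- matrix(0, n, 8); inside <- logical(n)
  xr <- range(mesh$nodes[, 1]); zr <- range(mesh$nodes[, 3])
  hx <- diff(xr) / nx
  for (q in seq_len(n)) {
    p <- pts[q, ]
    i <- min(nx, max(1, 1 + floor((p[1] - xr[1]) / hx)))
    # scan column i for the row bracketing y (tie-break: lowest element index)
    found <- FALSE
    for (j in 1:ny) {
      e <- (j - 1) * nx + i
      en <- mesh$elems[e, ]
      x0 <- mesh$nodes[en[1], 1]; x1 <- mesh$nodes[en[2], 1]
      xi <- 2 * (p[1] - x0) / (x1 - x0) - 1
      ytop <- (1 - (xi + 1) / 2) * mesh$nodes[en[1], 2] +
        ((xi + 1) / 2) * mesh$nodes[en[2], 2]
      ybot <- (1 - (xi + 1) / 2) * mesh$nodes[en[4], 2] +
        ((xi + 1) / 2) * mesh$nodes[en[3], 2]
      if (p[2] >= ytop - 1e-9 && p[2] <= ybot + 1e-9) {
        eta <- 2 * (p[2] - ytop) / (ybot - ytop) - 1
        zeta <- 2 * (p[3] - zr[1]) / (zr[2] - zr[1]) - 1
        sh <- hex8_shape(max(-1, min(1, xi)), max(-1, min(1, eta)),
                         max(-1, min(1, zeta)))
        elem[q] <- e; W[q, ] <- sh$N
        inside[q] <- xi >= -1 - 1e-9 && xi <= 1 + 1e-9 &&
          zeta >= -1 - 1e-9 && zeta <= 1 + 1e-9
        found <- TRUE
        break
      }
    }
    if (!found) inside[q] <- FALSE
  }
  list(elem = elem, weights = W, inside = inside)
}

#' Couple a beam network to its host solid mesh
#'
#' Each beam control point is bound to the interpolated material point of its
#' host hexahedron by a penalty spring; forces are applied equal-and-opposite
#' and distributed to the host nodes by trilinear shape-function weights. The
#' spring stiffness is `penalty_scale` times a host-element elastic stiffness
#' estimate (`G0 * element thickness`), evaluated when materials are bound at
#' model assembly.
#'
#' @param beams a [distribute_beams()] network.
#' @param mesh the host [hex_mesh()].
#' @param penalty_scale dimensionless penalty factor (default 100).
#' @return list of class `beam_coupling` with host elements, weights, and the
#'   penalty scale.
#' @export
couple_beams_to_solid <- function(beams, mesh, penalty_scale = 100) {
  loc <- locate_points(mesh, beams$control_points)
  if (any(!loc$inside))
    stop(sprintf("coupling error: %d beam control points outside the mesh (e.g. ids %s)",
                 sum(!loc$inside),
                 paste(utils::head(which(!loc$inside), 5), collapse = ", ")))
  structure(list(host_elem = loc$elem, weights = loc$weights,
                 penalty_scale = penalty_scale),
            class = "beam_coupling")
}

#' Penalty coupling forces (reference implementation)
#'
#' Computes the equal-and-opposite penalty forces between beam nodes and host
#' solid nodes for given configurations; used by the coupling audits. Forces
#' on the solid are the negative shape-function-weighted spreads of the beam
#' node forces, so their sum vanishes identically.
#'
#' @param coupling a [couple_beams_to_solid()] object.
#' @param mesh host mesh (reference connectivity).
#' @param solid_coords current solid nodal coordinates (N x 3).
#' @param beam_coords current beam nodal coordinates (B x 3).
#' @param k penalty stiffness (scalar or per beam node), N/mm units if
#'   coordinates are mm.
#' @return list with `f_beam` (B x 3) and `f_solid` (N x 3).
#' @export
coupling_forces <- function(coupling, mesh, solid_coords, beam_coords, k) {
  B <- nrow(beam_coords)
  k <- rep_len(k, B)
  f_beam <- matrix(0, B, 3)
  f_solid <- matrix(0, nrow(solid_coords), 3)
  for (b in seq_len(B)) {
    en <- mesh$elems[coupling$host_elem[b], ]
    xh <- colSums(coupling$weights[b, ] * solid_coords[en, ])
    f <- k[b] * (xh - beam_coords[b, ])
    f_beam[b, ] <- f_beam[b, ] + f
    f_solid[en, ] <- f_solid[en, ] - outer(coupling$weights[b, ], f)
  }
  list(f_beam = f_beam, f_solid = f_solid)
}
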