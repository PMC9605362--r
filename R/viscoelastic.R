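# Constitutive core: single-term shear relaxation with elastic bulk closure,
# shared by the solid hexahedra and the Hughes-Liu beams.
#
# Voigt storage convention used throughout the package:
#   stress  sigma = (s11, s22, s33, s12, s23, s31)      [MPa]
#   strain  eps   = (e11, e22, e33, g12, g23, g31)      engineering shears
# All moduli in MPa, times in seconds, decay constants in 1/s.

#' Viscoelastic material parameters
#'
#' The quantity estimated by the inverse pipeline: a single-exponential shear
#' relaxation \eqn{G(t) = G_\infty + (G_0 - G_\infty) e^{-\beta t}} together
#' with an elastic volumetric closure. The bulk modulus is derived from the
#' short-time shear modulus and a Poisson ratio,
#' \eqn{K = 2 G_0 (1+\nu) / (3 (1-2\nu))}.
#'
#' @param G0 short-time shear modulus, MPa.
#' @param Ginf long-time shear modulus, MPa. Must satisfy `G0 >= Ginf > 0`.
#' @param beta decay constant, 1/s.
#' @param nu_vol Poisson ratio of the volumetric closure, in `[0, 0.5)`.
#'   Defaults to 0.495 (near-incompressible soft tissue).
#' @return An object of class `visco_params`.
#' @export
visco_params <- function(G0, Ginf, beta, nu_vol = 0.495) {
  stopifnot(is.numeric(G0), is.numeric(Ginf), is.numeric(beta))
  if (!(Ginf > 0)) stop("Ginf must be > 0")
  if (G0 < Ginf) stop("invalid parameters: G0 must be >= Ginf")
  if (!(beta > 0)) stop("beta must be > 0")
  if (nu_vol < 0 || nu_vol >= 0.5) stop("nu_vol must be in [0, 0.5)")
  structure(list(G0 = G0, Ginf = Ginf, beta = beta, nu_vol = nu_vol),
            class = "visco_params")
}

#' @export
print.visco_params <- function(x, ...) {
  cat(sprintf("viscoelastic: G0 = %.4g MPa, Ginf = %.4g MPa, beta = %.4g 1/s, nu = %.3f\n",
              x$G0, x$Ginf, x$beta, x$nu_vol))
  invisible(x)
}

#' Shear relaxation modulus G(t)
#'
#' @param params a [visco_params()] object.
#' @param t time(s) in seconds, non-negative.
#' @return `G(t) = Ginf + (G0 - Ginf) * exp(-beta * t)` in MPa.
#' @export
relaxation_modulus <- function(params, t) {
  if (any(t < 0)) stop("t must be >= 0")
  params$Ginf + (params$G0 - params$Ginf) * exp(-params$beta * t)
}

#' Elastic bulk modulus of the volumetric closure
#' @param params a [visco_params()] object.
#' @return K in MPa.
#' @export
bulk_modulus <- function(params) {
  2 * params$G0 * (1 + params$nu_vol) / (3 * (1 - 2 * params$nu_vol))
}

#' Stress state at a material point
#'
#' Holds the Cauchy stress, the deviatoric memory (overstress) variable of the
#' recursive hereditary integral, and the material-point clock.
#'
#' @param sigma length-6 Voigt stress, MPa.
#' @param h length-6 Voigt deviatoric memory stress, MPa (trace ~ 0).
#' @param t current time, s.
#' @return An object of class `stress_state`.
#' @export
stress_state <- function(sigma = numeric(6), h = numeric(6), t = 0) {
  stopifnot(length(sigma) == 6, length(h) == 6)
  if (abs(sum(h[1:3])) > 1e-8 * (1 + max(abs(h))))
    stop("memory variable h must be deviatoric")
  structure(list(sigma = as.numeric(sigma), h = as.numeric(h), t = t),
            class = "stress_state")
}

voigt_to_tensor <- function(v, strain = FALSE) {
  s <- if (strain) 0.5 else 1
  matrix(c(v[1],     s * v[4], s * v[6],
           s * v[4], v[2],     s * v[5],
           s * v[6], s * v[5], v[3]), 3, 3)
}

tensor_to_voigt <- function(m, strain = FALSE) {
  s <- if (strain) 2 else 1
  c(m[1, 1], m[2, 2], m[3, 3], s * m[1, 2], s * m[2, 3], s * m[3, 1])
}

#' Incremental Jaumann rotation of a stress tensor
#'
#' Rotates a stress with the material spin over one increment,
#' \eqn{\bar\sigma = \sigma + \Delta\omega\,\sigma - \sigma\,\Delta\omega},
#' which matches the exact rotation \eqn{R \sigma R^T} to second order in the
#' spin increment. Applied before the constitutive evaluation.
#'
#' @param sigma length-6 Voigt stress.
#' @param dOmega 3x3 skew-symmetric incremental spin tensor.
#' @param tol skew-symmetry tolerance.
#' @return rotated length-6 Voigt stress.
#' @export
jaumann_rotate <- function(sigma, dOmega, tol = 1e-10) {
  if (max(abs(dOmega + t(dOmega))) > tol * (1 + max(abs(dOmega))))
    stop("dOmega must be skew-symmetric")
  S <- voigt_to_tensor(sigma)
  Sn <- S + dOmega %*% S - S %*% dOmega
  tensor_to_voigt((Sn + t(Sn)) / 2)
}

#' Symmetric/skew split of an incremental displacement gradient
#'
#' @param G 3x3 incremental displacement gradient with respect to the deformed
#'   coordinates.
#' @return list with `dEps` (symmetric part) and `dOmega` (skew part), both 3x3.
#' @export
strain_spin_increment <- function(G) {
  stopifnot(is.matrix(G), all(dim(G) == c(3, 3)))
  list(dEps = (G + t(G)) / 2, dOmega = (G - t(G)) / 2)
}

# (1 - exp(-x))/x, stable for small x
relax_phi <- function(x) {
  ifelse(x < 1e-8, 1 - x / 2, -expm1(-x) / x)
}

#' Incremental viscoelastic stress update
#'
#' One increment of the deviatoric hereditary integral under Jaumann rotation:
#' the stress and memory variable are first rotated with the spin increment,
#' the strain increment is split into deviatoric and volumetric parts, the
#' memory stress is advanced by the exponential-integrator recursion (exact for
#' piecewise-constant strain rate)
#' \deqn{h \leftarrow e^{-\beta dt} h + (G_0-G_\infty)\frac{1-e^{-\beta dt}}{\beta dt} 2\,dE',}
#' and the stress receives the equilibrium deviatoric increment
#' \eqn{2 G_\infty dE'}, the change in \eqn{h}, and the elastic volumetric
#' increment \eqn{K\,\mathrm{tr}(d\varepsilon) I}.
#'
#' @param state a [stress_state()].
#' @param dEps length-6 Voigt incremental strain (engineering shears) or a 3x3
#'   symmetric tensor.
#' @param dOmega 3x3 skew incremental spin (default zero).
#' @param dt time increment, s, > 0.
#' @param params a [visco_params()].
#' @return updated [stress_state()].
#' @export
update_stress <- function(state, dEps, dOmega = matrix(0, 3, 3), dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.matrix(dEps)) dEps <- tensor_to_voigt(dEps, strain = TRUE)
  sig <- jaumann_rotate(state$sigma, dOmega)
  h <- jaumann_rotate(state$h, dOmega)

  tr <- sum(dEps[1:3])
  dEdev <- dEps
  dEdev[1:3] <- dEps[1:3] - tr / 3          # deviatoric normal strains
  # tensor (not engineering) deviatoric strain in Voigt shear slots:
  dEdev_t <- dEdev
  dEdev_t[4:6] <- dEdev[4:6] / 2

  x <- params$beta * dt
  phi <- relax_phi(x)
  hn <- exp(-x) * h + (params$G0 - params$Ginf) * phi * 2 * dEdev_t
  dsig <- 2 * params$Ginf * dEdev_t + (hn - h)
  K <- bulk_modulus(params)
  dsig[1:3] <- dsig[1:3] + K * tr

  stress_state(sigma = sig + dsig, h = hn, t = state$t + dt)
}
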