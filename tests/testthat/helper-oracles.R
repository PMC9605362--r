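# Independent closed-form oracles used across the suite.

# shear relaxation modulus, written out independently of the package
oracle_G <- function(G0, Ginf, beta, t) Ginf + (G0 - Ginf) * exp(-beta * t)

# hereditary-integral response of the shear stress to a strain ramp:
# gamma(t) = rate * t for t <= T, held at rate*T afterwards.
# sigma12(t) = int_0^min(t,T) G(t - tau) * rate dtau  (closed form)
oracle_ramp_shear <- function(G0, Ginf, beta, rate, T, t) {
  ifelse(t <= T,
         rate * (Ginf * t + (G0 - Ginf) * (1 - exp(-beta * t)) / beta),
         rate * (Ginf * T + (G0 - Ginf) *
                   (exp(-beta * (t - T)) - exp(-beta * t)) / beta))
}

# uniaxial relaxation modulus with elastic bulk closure (quasi-elastic):
# E(t) = 9 K G(t) / (3 K + G(t)), K from G0 and nu
oracle_uniax_E <- function(G0, Ginf, beta, nu, t) {
  K <- 2 * G0 * (1 + nu) / (3 * (1 - 2 * nu))
  G <- oracle_G(G0, Ginf, beta, t)
  9 * K * G / (3 * K + G)
}

# hereditary uniaxial stress for a strain ramp (numerical convolution on a
# fine grid; independent of the FE path)
oracle_uniax_ramp <- function(G0, Ginf, beta, nu, rate, T, t_eval) {
  sapply(t_eval, function(t) {
    tt <- seq(0, min(t, T), length.out = 4000)
    Et <- oracle_uniax_E(G0, Ginf, beta, nu, t - tt)
    sum(Et) * rate * (tt[2] - tt[1]) -
      0.5 * (Et[1] + Et[length(Et)]) * rate * (tt[2] - tt[1])
  })
}

# exact Rodrigues rotation matrix
oracle_rodrigues <- function(theta) {
  a <- sqrt(sum(theta^2))
  if (a < 1e-300) return(diag(3))
  k <- theta / a
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  # column-major fill above gives K %*% v = k x v
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

# von Mises invariant of a Voigt stress
oracle_vm <- function(s) {
  sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2 +
                6 * (s[4]^2 + s[5]^2 + s[6]^2)))
}

table1_sets <- function() {
  list(healthy_ecm = c(24.98, 18.81, 500),
       healthy_beam = c(35.2, 20.51, 585),
       glaucoma_ecm = c(8.15, 4.45, 510),
       glaucoma_beam = c(45.88, 19.58, 610))
}

pracma_cross_t <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])

# a unit-cube hex mesh (edge in micrometres) with handy node sets
unit_hex_mesh <- function(edge_um = 1000) {
  nodes <- as.matrix(expand.grid(x = c(0, edge_um), y = c(0, edge_um),
                                 z = c(0, edge_um)))[, 1:3]
  # reorder into the standard hex ordering
  ord <- c(1, 2, 4, 3, 5, 6, 8, 7)
  nodes <- nodes[ord, ]
  elems <- matrix(1:8, 1)
  hex_mesh(nodes, elems, tissue = "TM",
           node_sets = list(all = 1:8), dims = c(1, 1, 1))
}
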