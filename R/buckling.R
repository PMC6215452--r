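#' Torsional buckling of thin-walled cylindrical tubes
#'
#' Closed-form relations for torsion-induced buckling of a thin-walled tube
#' (valid for wall thickness much smaller than the diameter): the critical
#' shear stress `tau_crit = k pi^2 D / (l^2 t)` with flexural stiffness per
#' unit circumference `D = E t^3 / (12 (1 - nu^2))`, the torque-stress
#' relation `tau = T / (2 t A)` (`= 2 T / (pi d^2 t)` for a circular section),
#' and the critical torque `T_crit = K pi^3 d^2 t^3 / (2 l^2)` with
#' `K = k E / (12 (1 - nu^2))`. The propensity to buckle therefore grows with
#' the square of the length and falls with the square of the diameter --
#' slender (small, long) tubular bones are the more buckling-prone. SI units
#' throughout.
#'
#' @name buckling
NULL

#' Flexural stiffness per unit circumference
#' @param E Young's modulus (Pa).
#' @param t wall thickness (m).
#' @param nu Poisson's ratio, in (-1, 1) exclusive of |nu| = 1.
#' @return D in N m.
#' @export
flexural_stiffness <- function(E, t, nu) {
  stopifnot(E > 0, t > 0)
  if (nu^2 >= 1) stop("nu^2 must be < 1")
  E * t^3 / (12 * (1 - nu^2))
}

#' Critical shear stress to initiate torsional buckling
#' @param k empirical constant of the material/boundary conditions.
#' @param D flexural stiffness per unit circumference (N m).
#' @param l tube length (m).
#' @param t wall thickness (m).
#' @return tau_crit in Pa.
#' @export
critical_shear <- function(k, D, l, t) {
  stopifnot(k > 0, D > 0, l > 0, t > 0)
  k * pi^2 * D / (l^2 * t)
}

#' Shear stress in a thin-walled tube under torque
#'
#' General thin-walled section: `tau = T / (2 t A)`; for a circular section
#' (`A = pi d^2 / 4`), `tau = 2 T / (pi d^2 t)`.
#'
#' @param T_ applied torque (N m).
#' @param d tube diameter (m); used when `A` is not given.
#' @param t wall thickness (m).
#' @param A enclosed cross-section area (m^2); overrides `d`.
#' @return tau in Pa.
#' @export
shear_from_torque <- function(T_, d = NULL, t, A = NULL) {
  stopifnot(T_ > 0, t > 0)
  if (is.null(A)) {
    stopifnot(!is.null(d), d > 0)
    A <- pi * d^2 / 4
  }
  stopifnot(A > 0)
  T_ / (2 * t * A)
}

#' Critical torque to initiate torsional buckling
#' @param K lumped material constant, `K = k E / (12 (1 - nu^2))`.
#' @param d tube diameter (m).
#' @param t wall thickness (m).
#' @param l tube length (m).
#' @return T_crit in N m.
#' @export
critical_torque <- function(K, d, t, l) {
  stopifnot(K > 0, d > 0, t > 0, l > 0)
  K * pi^3 * d^2 * t^3 / (2 * l^2)
}

#' Lumped buckling constant from material parameters
#' @inheritParams flexural_stiffness
#' @param k empirical constant.
#' @return K = k E / (12 (1 - nu^2)).
#' @export
buckling_constant <- function(k, E, nu) {
  stopifnot(k > 0, E > 0)
  if (nu^2 >= 1) stop("nu^2 must be < 1")
  k * E / (12 * (1 - nu^2))
}

#' Full torsion-tube summary
#'
#' Evaluates D, tau_crit and T_crit for one tube; `K` is derived from
#' `(k, E, nu)` when not supplied.
#'
#' @param E,nu,t,l,d material and geometry (SI units).
#' @param k empirical constant (required if `K` missing).
#' @param K lumped constant (optional).
#' @return `torsion_tube`: list of inputs plus `D`, `tau_crit`, `T_crit`.
#' @export
torsion_tube <- function(E, nu, t, l, d, k = NULL, K = NULL) {
  if (is.null(K)) {
    if (is.null(k)) stop("supply k or K")
    K <- buckling_constant(k, E, nu)
  } else if (is.null(k)) {
    k <- K * 12 * (1 - nu^2) / E
  }
  D <- flexural_stiffness(E, t, nu)
  structure(list(E = E, nu = nu, t = t, l = l, d = d, k = k, K = K, D = D,
                 tau_crit = critical_shear(k, D, l, t),
                 T_crit = critical_torque(K, d, t, l)),
            class = "torsion_tube")
}
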