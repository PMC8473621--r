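#' Power-law rheology of bone marrow
#'
#' Bone marrow is modelled as a shear-thinning power-law fluid,
#' \eqn{\eta = k \dot\gamma^{n-1} H(T)}, clamped between a minimum and a
#' maximum apparent viscosity.  Defaults are the marrow parameters used for
#' the scaffold filling simulation: consistency index `k = 0.017`
#' (Pa s^n), power-law index `n = 0.708`, viscosity limits 0.01 / 0.001 Pa s
#' and density 1050 kg/m^3.  The temperature factor \eqn{H(T)} (Arrhenius
#' law) is the identity unless Arrhenius parameters are supplied.
#'
#' Note that with these defaults `k` itself exceeds the upper viscosity
#' limit, so at shear rates below about 6.15 1/s the apparent viscosity sits
#' on the upper clamp.  The limits are honoured as stated rather than
#' adjusting `k`.
#'
#' @param k consistency index (Pa s^n), > 0.
#' @param n power-law index (dimensionless), > 0; `n < 1` is shear-thinning.
#' @param eta_max,eta_min upper/lower apparent-viscosity clamps (Pa s).
#' @param rho fluid density (kg/m^3).
#' @param arrhenius optional list with elements `alpha`, `T0`, `Talpha`
#'   enabling the temperature factor \eqn{H(T) = \exp[\alpha(1/(T-T_0) -
#'   1/(T_\alpha-T_0))]}.  `NULL` (default) fixes `H = 1`.
#' @return an object of class `marrow_rheology`.
#' @export
marrow_rheology <- function(k = 0.017, n = 0.708, eta_max = 0.01,
                            eta_min = 0.001, rho = 1050, arrhenius = NULL) {
  stopifnot(k > 0, n > 0, rho > 0, eta_min > 0, eta_min < eta_max)
  if (!is.null(arrhenius)) {
    stopifnot(is.list(arrhenius),
              all(c("alpha", "T0", "Talpha") %in% names(arrhenius)))
  }
  structure(list(k = k, n = n, eta_max = eta_max, eta_min = eta_min,
                 rho = rho, arrhenius = arrhenius),
            class = "marrow_rheology")
}

#' Scalar shear rate from a velocity-gradient tensor
#'
#' Computes \eqn{\dot\gamma = \sqrt{\tfrac12 \bar D : \bar D}} with the
#' rate-of-deformation tensor \eqn{\bar D_{ij} = \partial u_j/\partial x_i +
#' \partial u_i/\partial x_j}.  For simple shear with gradient `G` this
#' returns `G`; for a rigid rotation it returns 0.
#'
#' @param grad_u 3x3 (or 2x2) velocity-gradient matrix, entries in 1/s.
#' @return non-negative scalar shear rate (1/s).
#' @export
deformation_rate <- function(grad_u) {
  if (!is.matrix(grad_u) || nrow(grad_u) != ncol(grad_u))
    stop("grad_u must be a square matrix")
  if (!all(is.finite(grad_u))) stop("grad_u must have finite entries")
  D <- grad_u + t(grad_u)
  sqrt(0.5 * sum(D * D))
}

#' Arrhenius temperature factor H(T)
#'
#' Returns 1 when the rheology carries no Arrhenius parameters (the
#' isothermal setting used throughout the filling simulation); otherwise
#' evaluates \eqn{H(T) = \exp[\alpha(1/(T-T_0) - 1/(T_\alpha-T_0))]}.
#'
#' @param rheo a [marrow_rheology()] object.
#' @param T temperature (same units as `T0`, `Talpha`).
#' @return dimensionless factor.
#' @export
arrhenius_factor <- function(rheo, T = NULL) {
  stopifnot(inherits(rheo, "marrow_rheology"))
  a <- rheo$arrhenius
  if (is.null(a)) return(1.0)
  if (is.null(T)) stop("temperature required when Arrhenius parameters are set")
  if (any(T == a$T0)) stop("H(T) is singular at T = T0")
  exp(a$alpha * (1 / (T - a$T0) - 1 / (a$Talpha - a$T0)))
}

#' Apparent viscosity of the marrow
#'
#' \eqn{\eta = \mathrm{clamp}(k\,\dot\gamma^{n-1} H(T),\ \eta_{min},\
#' \eta_{max})}.  At zero shear rate with `n < 1` the power law diverges and
#' the upper clamp is returned (its limit).  Vectorised over `gamma_dot`.
#'
#' @param rheo a [marrow_rheology()] object.
#' @param gamma_dot shear rate(s), 1/s, >= 0.
#' @param T optional temperature, forwarded to [arrhenius_factor()].
#' @param clamp honour the viscosity limits (default TRUE).
#' @return apparent viscosity (Pa s), same length as `gamma_dot`.
#' @export
apparent_viscosity <- function(rheo, gamma_dot, T = NULL, clamp = TRUE) {
  stopifnot(inherits(rheo, "marrow_rheology"))
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("gamma_dot must be finite and non-negative")
  H <- arrhenius_factor(rheo, T)
  eta <- rheo$k * gamma_dot^(rheo$n - 1) * H
  if (rheo$n < 1) eta[gamma_dot == 0] <- Inf
  if (rheo$n > 1) eta[gamma_dot == 0] <- 0
  if (clamp) eta <- pmin(rheo$eta_max, pmax(rheo$eta_min, eta))
  eta
}

#' Tabulate apparent viscosity over a shear-rate range
#'
#' Diagnostic helper backing the CLI `rheology` table: evaluates
#' [apparent_viscosity()] on a log-spaced grid.
#'
#' @param rheo a [marrow_rheology()] object.
#' @param gamma_min,gamma_max range of shear rates (1/s).
#' @param n_points number of samples.
#' @return data.frame with columns `gamma_dot`, `eta`.
#' @export
viscosity_table <- function(rheo, gamma_min = 1e-2, gamma_max = 1e4,
                            n_points = 50) {
  gd <- 10^seq(log10(gamma_min), log10(gamma_max), length.out = n_points)
  data.frame(gamma_dot = gd, eta = apparent_viscosity(rheo, gd))
}
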