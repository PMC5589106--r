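#' Dimensional cable and membrane constants
#'
#' Construct the full set of dimensional constants describing a cylindrical
#' core-conductor with polarized intracellular microstructure and (optionally)
#' a nonohmic mitochondrial membrane current.  Derived per-length quantities
#' (`ci`, `ri`), per-area conversions (`Rm`, `Cm`, `Ci`), and the classical
#' cable scales (`tau_m`, `tau_rho`, `lambda_e`, `Delta`) are computed from
#' the primary inputs.  Any derived quantity may also be supplied explicitly,
#' in which case it must agree with its conversion formula to a relative
#' tolerance of 1e-9; inconsistent inputs are rejected.
#'
#' Units follow the CGS-flavoured conventions of classical cable theory:
#' cm, ms, mV, S/cm, F/cm.  No unit-conversion layer is provided.
#'
#' The axial capacitance per unit length is `ci = 2*eps0*pi*r^2` (F cm) and
#' the intracellular resistance per unit length is `ri = 1/(pi*r^2*sigma)`
#' (Ohm/cm).  The cable scales are the passive membrane time constant
#' `tau_m = cm*rm` (ms), the Maxwell (charge-relaxation) time constant
#' `tau_rho = ci*ri` (ms), the electrotonic space constant
#' `lambda_e = sqrt(rm/ri)` (cm), and `Delta = ci*rm` (Ohm F).
#'
#' The intracellular resistivity is stored as `Ri = 1/sigma` (Ohm cm), the
#' specific resistance of the intracellular fluid.  (An alternative
#' convention `Ri = 0.5*sigma` appears in parts of the cable literature but
#' is dimensionally inconsistent with a resistivity, so the reciprocal
#' convention is the operative one here.)
#'
#' @param r cable radius (cm), > 0.
#' @param sigma intracellular conductivity (S/cm), > 0.
#' @param rm membrane resistance times unit length (Ohm cm), > 0.
#' @param cm membrane capacitance per unit length (F/cm), > 0.
#' @param alpha charge 'soakage' parameter (1/mV), >= 0.  `alpha = 0` means
#'   the microstructure stores no bound charge.
#' @param gstar maximum mitochondrial membrane conductance (S/cm), >= 0.
#' @param a_carrier dimensionless charged-carrier constant.
#' @param b_carrier charged-carrier constant (1/mV).
#' @param Er resting mitochondrial membrane potential (mV).
#' @param eps0 fluid permittivity (F/cm).
#' @param epsr relative permittivity of water (dimensionless).
#' @param ci,ri,Ri,Rm,Cm,Ci optional redundant quantities, checked against
#'   their conversion formulas.
#' @return An object of class `"cable_params"`: a named list with the
#'   primary fields plus `ci`, `ri`, `Ri`, `Rm`, `Cm`, `Ci`, `tau_m`,
#'   `tau_rho`, `lambda_e`, `Delta`.
#' @seealso [derive_dimensionless()], [membrane_iv()]
#' @examples
#' p <- cable_params(r = 1e-4, sigma = 1/70, rm = 2e4, cm = 3.5e-7)
#' p$tau_m
#' p$lambda_e
#' @export
cable_params <- function(r, sigma, rm, cm,
                         alpha = 0, gstar = 0,
                         a_carrier = 0, b_carrier = 0,
                         Er = -139, eps0 = 7e-12, epsr = 81,
                         ci = NULL, ri = NULL, Ri = NULL,
                         Rm = NULL, Cm = NULL, Ci = NULL) {
  stopifnot(is.numeric(r), is.numeric(sigma), is.numeric(rm), is.numeric(cm))
  if (r <= 0)      stop("cable radius 'r' must be positive")
  if (sigma <= 0)  stop("conductivity 'sigma' must be positive")
  if (rm <= 0)     stop("membrane resistance 'rm' must be positive")
  if (cm <= 0)     stop("membrane capacitance 'cm' must be positive")
  if (alpha < 0)   stop("soakage parameter 'alpha' must be non-negative")
  if (gstar < 0)   stop("maximum conductance 'gstar' must be non-negative")

  derived <- list(
    ci = 2 * eps0 * pi * r^2,
    ri = 1 / (pi * r^2 * sigma),
    Ri = 1 / sigma,
    Rm = 2 * pi * r * rm,
    Cm = cm / (2 * pi * r)
  )
  derived$Ci <- derived$ci / (pi * r^2)

  check <- function(name, given) {
    want <- derived[[name]]
    if (!is.null(given)) {
      rel <- abs(given - want) / max(abs(want), .Machine$double.xmin)
      if (rel > 1e-9)
        stop(sprintf("supplied %s = %g is inconsistent with its conversion formula (expected %g)",
                     name, given, want))
    }
    want
  }
  ci <- check("ci", ci); ri <- check("ri", ri); Ri <- check("Ri", Ri)
  Rm <- check("Rm", Rm); Cm <- check("Cm", Cm); Ci <- check("Ci", Ci)

  p <- list(r = r, sigma = sigma, rm = rm, cm = cm,
            alpha = alpha, gstar = gstar,
            a_carrier = a_carrier, b_carrier = b_carrier,
            Er = Er, eps0 = eps0, epsr = epsr,
            ci = ci, ri = ri, Ri = Ri, Rm = Rm, Cm = Cm, Ci = Ci,
            tau_m = cm * rm,
            tau_rho = ci * ri,
            lambda_e = sqrt(rm * pi * r^2 * sigma),
            Delta = ci * rm)
  class(p) <- "cable_params"
  p
}

#' @export
print.cable_params <- function(x, ...) {
  cat("Dimensional cable parameters\n")
  cat(sprintf("  radius r = %g cm, conductivity sigma = %g S/cm\n", x$r, x$sigma))
  cat(sprintf("  rm = %g Ohm cm, cm = %g F/cm  (tau_m = %g ms)\n",
              x$rm, x$cm, x$tau_m))
  cat(sprintf("  ci = %g F cm, ri = %g Ohm/cm  (tau_rho = %g ms)\n",
              x$ci, x$ri, x$tau_rho))
  cat(sprintf("  lambda_e = %g cm, Delta = ci*rm = %g Ohm F\n",
              x$lambda_e, x$Delta))
  cat(sprintf("  soakage alpha = %g /mV; gstar = %g S/cm, a = %g, b = %g /mV\n",
              x$alpha, x$gstar, x$a_carrier, x$b_carrier))
  invisible(x)
}

#' Dimensionless parameter group of the nonlinear cable equation
#'
#' The dimensionless cable equation is governed by four constants:
#' `gamma = tau_rho / tau_m` (ratio of the Maxwell charge-relaxation time to
#' the membrane time constant; the small dispersion parameter),
#' `kappa = gamma * lambda_e^2 / (pi r^2)` (the soakage coupling entering
#' the voltage scaling `U = alpha * kappa * V`),
#' `eta = a * rm * gstar` (dimensionless mitochondrial drive), and
#' `delta = 3 * gstar * b * rm / (2 * alpha * kappa)` (dimensionless
#' strength of the quadratic membrane nonlinearity).
#'
#' Validity flags: the travelling-wave velocity degenerates at
#' `gamma = 1/4` (a warning is issued for `gamma >= 0.25`) and is positive
#' only for `eta < 3` (a warning is issued for `eta >= 3`).
#'
#' @param gamma dispersion ratio, > 0 (and << 1 for the model's regime).
#' @param eta dimensionless mitochondrial drive, >= 0.
#' @param delta dimensionless membrane nonlinearity, >= 0.
#' @param kappa soakage coupling, > 0 if supplied; optional (`NA`) because
#'   the dimensionless dynamics depend only on `(gamma, eta, delta)`.
#' @return Object of class `"cable_dimensionless"`.
#' @export
dimensionless_params <- function(gamma, eta = 0, delta = 0, kappa = NA_real_) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L)
  if (gamma <= 0) stop("'gamma' must be positive")
  if (eta < 0)    stop("'eta' must be non-negative")
  if (delta < 0)  stop("'delta' must be non-negative")
  if (!is.na(kappa) && kappa <= 0) stop("'kappa' must be positive when given")
  if (gamma >= 0.25)
    warning("gamma >= 0.25: outside the model's dispersive regime; the velocity formula degenerates at gamma = 1/4")
  if (eta >= 3)
    warning("eta >= 3: no positive travelling-wave velocity exists")
  structure(list(gamma = gamma, kappa = kappa, eta = eta, delta = delta),
            class = "cable_dimensionless")
}

#' @export
print.cable_dimensionless <- function(x, ...) {
  cat(sprintf("Dimensionless cable parameters: gamma = %g, kappa = %s, eta = %g, delta = %g\n",
              x$gamma, ifelse(is.na(x$kappa), "NA", format(x$kappa)), x$eta, x$delta))
  invisible(x)
}

#' Derive the dimensionless parameter group from dimensional constants
#'
#' Computes `(gamma, kappa, eta, delta)` from a [cable_params()] object by
#' the defining formulas (see [dimensionless_params()]).  `delta` involves
#' division by `alpha * kappa`, so an active quadratic membrane
#' (`gstar * b_carrier > 0`) requires `alpha > 0`.
#'
#' @param p a `"cable_params"` object.
#' @return A `"cable_dimensionless"` object.
#' @examples
#' p <- cable_params(r = 1e-4, sigma = 1/70, rm = 2e4, cm = 3.5e-7,
#'                   alpha = 0.05)
#' derive_dimensionless(p)
#' @export
derive_dimensionless <- function(p) {
  stopifnot(inherits(p, "cable_params"))
  gamma <- p$tau_rho / p$tau_m
  kappa <- gamma * p$lambda_e^2 / (pi * p$r^2)
  eta   <- p$a_carrier * p$rm * p$gstar
  if (p$gstar * p$b_carrier > 0 && p$alpha == 0)
    stop("soakage absent, delta undefined: alpha = 0 with an active quadratic membrane current")
  delta <- if (p$gstar * p$b_carrier == 0) 0 else
    3 * p$gstar * p$b_carrier * p$rm / (2 * p$alpha * kappa)
  dimensionless_params(gamma = gamma, eta = eta, delta = delta, kappa = kappa)
}

#' Nonohmic mitochondrial membrane current-voltage law
#'
#' The total ionic mitochondrial membrane current per unit length is the
#' quadratic charged-carrier law `i(V) = gstar * (a*V - 1.5*b*V^2)`
#' (outward-positive).  It vanishes at rest (`V = 0`) and at the
#' equilibrium potential `Va = 2a/(3b)`, peaks at `V = Va/2 = a/(3b)` with
#' value `(a/4) * gstar * Va`, and has the negative slope conductance
#' `g(V) = -1.5 * gstar * b * V`.
#'
#' @param gstar maximum membrane conductance (S/cm), >= 0.
#' @param a_carrier dimensionless carrier constant.
#' @param b_carrier carrier constant (1/mV), > 0 for a genuine quadratic law.
#' @param Er resting mitochondrial membrane potential (mV).
#' @return Object of class `"membrane_iv"` with fields `gstar`, `a_carrier`,
#'   `b_carrier`, `Va` (equilibrium potential, mV) and `Vrev = Va - Er`
#'   (reversal potential, mV).
#' @examples
#' iv <- membrane_iv(gstar = 1e-6, a_carrier = 1, b_carrier = 10/3)
#' iv$Va                      # 0.2 mV
#' ionic_current(iv$Va, iv)   # 0 at equilibrium
#' @export
membrane_iv <- function(gstar, a_carrier, b_carrier, Er = -139) {
  if (gstar < 0) stop("'gstar' must be non-negative")
  Va <- if (b_carrier > 0) 2 * a_carrier / (3 * b_carrier) else NA_real_
  structure(list(gstar = gstar, a_carrier = a_carrier, b_carrier = b_carrier,
                 Er = Er, Va = Va, Vrev = Va - Er),
            class = "membrane_iv")
}

#' @export
print.membrane_iv <- function(x, ...) {
  cat(sprintf("Nonohmic membrane I-V: gstar = %g S/cm, a = %g, b = %g /mV\n",
              x$gstar, x$a_carrier, x$b_carrier))
  cat(sprintf("  equilibrium Va = %g mV, reversal Vrev = Va - Er = %g mV\n",
              x$Va, x$Vrev))
  invisible(x)
}

#' @rdname membrane_iv
#' @param V depolarization from rest (mV); may be a vector.
#' @param iv a `"membrane_iv"` object.
#' @return `ionic_current()`: current per unit length (A/cm),
#'   outward-positive.
#' @export
ionic_current <- function(V, iv) {
  stopifnot(inherits(iv, "membrane_iv"))
  iv$gstar * (iv$a_carrier * V - 1.5 * iv$b_carrier * V^2)
}

#' @rdname membrane_iv
#' @return `nonohmic_conductance()`: the slope conductance
#'   `-1.5 * gstar * b * V` (S/cm), negative for depolarizations.
#' @export
nonohmic_conductance <- function(V, iv) {
  stopifnot(inherits(iv, "membrane_iv"))
  -1.5 * iv$gstar * iv$b_carrier * V
}

#' Voltage-dependent polarization capacitance and stored charge
#'
#' The microstructure's polarization capacitance-voltage characteristic is
#' linear in the depolarization: `C(V) = 2*alpha*V` (dimensionless factor).
#' Integrating the corresponding charge transfer gives the stored surface
#' charge per unit length `Q(V) = C(V)*V*Ci = 2*alpha*V^2*Ci` (C/cm), which
#' is quadratic in `V` and vanishes when `alpha = 0` (no microstructure, no
#' bound charge).
#'
#' @param V depolarization (mV); may be a vector.
#' @param alpha soakage parameter (1/mV), >= 0.
#' @param Ci intracellular capacitance per unit length (F/cm), >= 0.
#' @return `soakage_capacitance()`: the dimensionless factor `2*alpha*V`;
#'   `soakage_charge()`: charge per unit length (C/cm).
#' @export
soakage_capacitance <- function(V, alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  2 * alpha * V
}

#' @rdname soakage_capacitance
#' @export
soakage_charge <- function(V, alpha, Ci) {
  if (any(Ci < 0)) stop("'Ci' must be non-negative")
  soakage_capacitance(V, alpha) * V * Ci
}

#' Voltage scaling between dimensional and dimensionless depolarization
#'
#' The dimensionless field of the cable equation is `U = alpha * kappa * V`,
#' with `V` the depolarization in mV.  `unscale_voltage()` inverts the map,
#' which requires `alpha * kappa > 0`.
#'
#' @param V depolarization (mV).
#' @param U dimensionless depolarization.
#' @param alpha soakage parameter (1/mV).
#' @param kappa soakage coupling (dimensionless).
#' @return `scale_voltage()`: U (dimensionless); `unscale_voltage()`: V (mV).
#' @export
scale_voltage <- function(V, alpha, kappa) alpha * kappa * V

#' @rdname scale_voltage
#' @export
unscale_voltage <- function(U, alpha, kappa) {
  if (alpha * kappa == 0)
    stop("voltage scaling not invertible: alpha * kappa = 0")
  U / (alpha * kappa)
}
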