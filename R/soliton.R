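#' Hyperbolic secant helper
#' @noRd
sech <- function(x) 1 / cosh(x)

#' Closed-form travelling-wave velocity
#'
#' Dimensionless conduction velocity of the sech-squared quasi-soliton,
#' obtained from the tanh-expansion boundary balance of the travelling-wave
#' reduction:
#' \deqn{v = \frac{3 - \eta}{2\,(1 - 4\gamma)}.}
#' The velocity is positive for `eta < 3`, vanishes at `eta = 3`, is
#' strictly decreasing in `eta` and strictly increasing in `gamma` on the
#' valid domain, and degenerates at `gamma = 1/4`.
#'
#' @param gamma dispersion ratio (Maxwell time / membrane time), in
#'   `[0, 0.25)`.
#' @param eta dimensionless mitochondrial drive, in `[0, 3]`.
#' @return Dimensionless velocity `v >= 0`.  Vectorized over `gamma` and
#'   `eta`.
#' @examples
#' soliton_velocity(0.001, 0)     # 1.506 (passive membrane)
#' soliton_velocity(0.001, 2.9)   # 0.05
#' @export
soliton_velocity <- function(gamma, eta = 0) {
  if (any(eta > 3))
    stop("negative velocity: eta > 3 (a positive velocity requires eta < 3)")
  if (any(gamma >= 0.25))
    stop("velocity formula degenerates: gamma >= 1/4")
  if (any(gamma < 0)) stop("'gamma' must be non-negative")
  (3 - eta) / (2 * (1 - 4 * gamma))
}

#' Closed-form quasi-soliton amplitude
#'
#' Dimensionless amplitude of the sech-squared quasi-soliton,
#' \deqn{a_0 = \frac{6\,(1 + 4\gamma v)}{\delta + 8 v},}
#' with `v` the closed-form velocity; substituting `v` yields the
#' equivalent explicit form
#' \deqn{a_0 = \frac{6\,(1 + 2\gamma(1-\eta))}{\delta(1 - 4\gamma) - 4\eta + 12}.}
#' Both routes are evaluated and must agree to 1e-12 relative error; the
#' `form` argument selects which is returned (they differ only in
#' floating-point round-off).
#'
#' @inheritParams soliton_velocity
#' @param delta dimensionless membrane nonlinearity, >= 0.
#' @param form `"velocity"` evaluates `6(1+4*gamma*v)/(delta+8v)`;
#'   `"direct"` evaluates the explicit form in `(gamma, eta, delta)`.
#' @return Dimensionless amplitude `a0 > 0`.
#' @examples
#' soliton_amplitude(0.001, 0, 0)      # ~0.501 (passive membrane)
#' soliton_amplitude(0.001, 0.5, 10)   # ~0.301 (mitochondrial membrane)
#' @export
soliton_amplitude <- function(gamma, eta = 0, delta = 0,
                              form = c("velocity", "direct")) {
  form <- match.arg(form)
  if (any(delta < 0)) stop("'delta' must be non-negative")
  v <- soliton_velocity(gamma, eta)
  den1 <- delta + 8 * v
  den2 <- delta * (1 - 4 * gamma) - 4 * eta + 12
  if (any(den1 <= 0) || any(den2 <= 0))
    stop("amplitude undefined: non-positive denominator")
  a1 <- 6 * (1 + 4 * gamma * v) / den1
  a2 <- 6 * (1 + 2 * gamma * (1 - eta)) / den2
  if (any(abs(a1 - a2) > 1e-12 * pmax(abs(a1), abs(a2))))
    stop("internal inconsistency between the two amplitude forms")
  if (form == "velocity") a1 else a2
}

#' Quasi-soliton travelling-wave solution
#'
#' Construct the closed-form quasi-soliton of the dimensionless nonlinear
#' cable equation: a sech-squared pulse
#' `U(X, T) = a0 * sech^2(X - Xp -/+ v*T)` of unit width, launched at `Xp`
#' and travelling rightward (`zeta = X - Xp - v*T`) or leftward
#' (`zeta = X - Xp + v*T`).  Amplitude `a0` and velocity `v` are fully
#' determined by `(gamma, eta, delta)` through [soliton_velocity()] and
#' [soliton_amplitude()].  The pulse is an approximate (not exact) solution
#' of the equation; [residuals.quasi_soliton()] quantifies the imbalance.
#'
#' @param gamma,eta,delta dimensionless parameters, or pass a
#'   `"cable_dimensionless"` object as `params`.
#' @param Xp launch position (dimensionless).
#' @param direction `"rightward"` or `"leftward"`.
#' @param params optional `"cable_dimensionless"` object overriding
#'   `gamma`, `eta`, `delta`.
#' @return Object of class `"quasi_soliton"` with fields `params`, `a0`,
#'   `v`, `Xp`, `direction`.
#' @examples
#' qs <- quasi_soliton(0.001, 0, 0, Xp = 0.5)
#' coef(qs)
#' predict(qs, X = c(0.5, 1.5), T = 0)
#' @export
quasi_soliton <- function(gamma, eta = 0, delta = 0, Xp = 0,
                          direction = c("rightward", "leftward"),
                          params = NULL) {
  direction <- match.arg(direction)
  if (is.null(params)) {
    params <- dimensionless_params(gamma = gamma, eta = eta, delta = delta)
  } else {
    stopifnot(inherits(params, "cable_dimensionless"))
  }
  v  <- soliton_velocity(params$gamma, params$eta)
  a0 <- soliton_amplitude(params$gamma, params$eta, params$delta)
  structure(list(params = params, a0 = a0, v = v, Xp = Xp,
                 direction = direction),
            class = "quasi_soliton")
}

#' @export
print.quasi_soliton <- function(x, ...) {
  cat(sprintf("Quasi-soliton (%s): a0 = %.6g, v = %.6g, Xp = %g\n",
              x$direction, x$a0, x$v, x$Xp))
  cat(sprintf("  gamma = %g, eta = %g, delta = %g\n",
              x$params$gamma, x$params$eta, x$params$delta))
  invisible(x)
}

#' @export
summary.quasi_soliton <- function(object, ...) {
  p <- object$params
  cat("Quasi-soliton travelling-wave solution\n")
  cat(sprintf("  parameters: gamma = %g, eta = %g, delta = %g\n",
              p$gamma, p$eta, p$delta))
  cat(sprintf("  amplitude a0 = %.6g (dimensionless)\n", object$a0))
  cat(sprintf("  velocity  v  = %.6g (dimensionless, %s)\n",
              object$v, object$direction))
  cat(sprintf("  launch position Xp = %g\n", object$Xp))
  r0 <- ode_residual(0, object)
  cat(sprintf("  travelling-wave residual at the core: %.6g (the sech^2 ansatz is approximate)\n", r0))
  invisible(object)
}

#' @export
coef.quasi_soliton <- function(object, ...) {
  c(amplitude = object$a0, velocity = object$v)
}

#' Co-moving travelling-wave coordinate
#'
#' `zeta = X - Xp - v*T` for a rightward pulse, `X - Xp + v*T` for a
#' leftward one.
#' @param object a `"quasi_soliton"`.
#' @param X spatial positions (dimensionless).
#' @param T time (dimensionless scalar).
#' @return zeta values.
#' @export
comoving_coordinate <- function(object, X, T = 0) {
  s <- if (object$direction == "rightward") -1 else 1
  X - object$Xp + s * object$v * T
}

#' @describeIn quasi_soliton evaluate the pulse `a0 * sech^2(zeta)` on a
#'   grid `X` at time `T`.
#' @param object,x a `"quasi_soliton"` object.
#' @param X numeric vector of positions.
#' @param T time (scalar).
#' @param ... unused.
#' @export
predict.quasi_soliton <- function(object, X, T = 0, ...) {
  object$a0 * sech(comoving_coordinate(object, X, T))^2
}

#' @describeIn quasi_soliton evaluate the profile and return a
#'   [field_frame()].
#' @export
soliton_profile <- function(object, X, T = 0) {
  field_frame(X = X, T = T, U = predict(object, X, T))
}

#' @export
plot.quasi_soliton <- function(x, X = NULL, T = 0, ...) {
  if (is.null(X)) {
    c0 <- x$Xp + (if (x$direction == "rightward") 1 else -1) * x$v * T
    X <- seq(c0 - 10, c0 + 10, length.out = 801)
  }
  graphics::plot(X, predict(x, X, T), type = "l",
                 xlab = "X (dimensionless)", ylab = "U",
                 main = sprintf("Quasi-soliton at T = %g", T), ...)
  invisible(x)
}

# Closed-form derivatives of Omega(zeta) = a0 * sech^2(zeta), from the
# identities s' = -2 s t, s'' = 4 s - 6 s^2, s''' = t (24 s^2 - 8 s) with
# s = sech^2, t = tanh.
#' @noRd
sech2_derivatives <- function(zeta, a0) {
  s <- sech(zeta)^2
  t <- tanh(zeta)
  list(Omega = a0 * s,
       d1 = -2 * a0 * s * t,
       d2 = a0 * (4 * s - 6 * s^2),
       d3 = a0 * t * (24 * s^2 - 8 * s))
}

#' Travelling-wave residual of the sech-squared ansatz
#'
#' Evaluates the left-hand side of the travelling-wave ODE
#' \deqn{v\gamma\,\Omega''' - \Omega'' + v(4\Omega - 1)\Omega'
#'       + (1+\eta)\Omega - \delta\Omega^2 = 0}
#' with `Omega = a0 * sech^2(zeta)` and exact closed-form derivatives of
#' `sech^2`.  The residual vanishes in the tails (below 1e-12 for
#' `|zeta| >= 20`) but is generally nonzero at the core — the sech-squared
#' pulse is an approximate solution.  At `zeta = 0` the odd derivatives
#' vanish and the residual reduces to `(3 + eta)*a0 - delta*a0^2`.
#'
#' @param zeta co-moving coordinates (numeric vector).
#' @param object a `"quasi_soliton"`.
#' @return Residual values on `zeta`.
#' @export
ode_residual <- function(zeta, object) {
  stopifnot(inherits(object, "quasi_soliton"))
  p <- object$params
  v <- object$v
  d <- sech2_derivatives(zeta, object$a0)
  v * p$gamma * d$d3 - d$d2 + v * (4 * d$Omega - 1) * d$d1 +
    (1 + p$eta) * d$Omega - p$delta * d$Omega^2
}

#' @describeIn ode_residual `residuals()` method: the ODE residual on a
#'   default zeta grid (attribute `"zeta"` carries the grid).
#' @param zeta_range,n grid extent and size for the `residuals()` method.
#' @param ... unused.
#' @export
residuals.quasi_soliton <- function(object, zeta_range = c(-30, 30),
                                    n = 601, ...) {
  zeta <- seq(zeta_range[1], zeta_range[2], length.out = n)
  r <- ode_residual(zeta, object)
  attr(r, "zeta") <- zeta
  r
}

#' Residual of the tanh-transformed travelling-wave equation
#'
#' The substitution `y = tanh(zeta)`, `Omega(zeta) -> f(y)` turns the
#' travelling-wave ODE into a polynomial balance in `y`.  This evaluates
#' that balance (left side minus right side) with the finite expansion
#' `f(y) = a0 * (1 - y^2)`:
#' \deqn{(1+\eta)f - v(1-y^2)f' \;-\;
#'   \Big[-2y(1-y^2)f' + (1-y^2)^2 f''\Big]
#'   + \gamma v\Big[2(1-y^2)(3y^2-1)f' - 6y(1-y^2)^2 f''\Big]
#'   + 4v(1-y^2) f f' - \delta f^2}
#' (the `f'''` term vanishes identically for the quadratic expansion).
#' Because the change of variables is exact, this equals [ode_residual()]
#' at `zeta = atanh(y)` up to round-off.
#'
#' @param y values in `(-1, 1)`.
#' @param object a `"quasi_soliton"`.
#' @return Residual values on `y`.
#' @export
tanh_transform_residual <- function(y, object) {
  stopifnot(inherits(object, "quasi_soliton"))
  if (any(abs(y) >= 1)) stop("'y' must lie strictly inside (-1, 1)")
  p <- object$params; v <- object$v; a0 <- object$a0
  f   <- a0 * (1 - y^2)
  fp  <- -2 * a0 * y
  fpp <- rep(-2 * a0, length(y))
  w   <- 1 - y^2
  lhs <- (1 + p$eta) * f - v * w * fp
  rhs <- (-2 * y * w * fp + w^2 * fpp) -
    p$gamma * v * (2 * w * (3 * y^2 - 1) * fp - 6 * y * w^2 * fpp) -
    4 * v * w * f * fp + p$delta * f^2
  lhs - rhs
}

#' Expansion coefficient fixed by the y = -1 boundary condition
#'
#' The tanh-expansion of the travelling-wave profile truncates at degree 2:
#' `f(y) = a0 + a0*(a1 - 1)*y - a1*a0*y^2`.  Imposing the decay boundary
#' condition `f(-1) = 0` determines `a1`.  This solves that condition
#' numerically (the equation is linear in `a1`); the root is `a1 = 1`, which
#' collapses the expansion to `f(y) = a0 * (1 - y^2)`.
#'
#' @param a0 amplitude (> 0).
#' @return The coefficient `a1`.
#' @export
tanh_expansion_a1 <- function(a0 = 1) {
  stopifnot(a0 > 0)
  f_m1 <- function(a1) a0 + a0 * (a1 - 1) * (-1) - a1 * a0 * (-1)^2
  stats::uniroot(f_m1, interval = c(-10, 10), tol = 1e-14)$root
}

#' Linearized dispersion relation
#'
#' Substituting a plane-wave mode `U = exp(omega*T + i*k*X)` into the
#' cable equation with the nonlinear terms dropped gives the temporal
#' eigenvalue
#' \deqn{\omega(k) = -\frac{1 + \eta + k^2}{1 + \gamma k^2},}
#' which is strictly negative for every real wavenumber: all linear modes
#' decay, i.e. the linearized pulse dissipates as it propagates, and only
#' the nonlinearity sustains the quasi-soliton.
#'
#' @param k wavenumber (numeric vector).
#' @param gamma dispersion ratio, >= 0.
#' @param eta dimensionless mitochondrial drive, >= 0.
#' @return Decay rates `omega(k) < 0`.
#' @examples
#' linear_dispersion(0, 0.001, 0)   # -1: uniform-mode membrane leak
#' @export
linear_dispersion <- function(k, gamma, eta = 0) {
  if (gamma < 0 || eta < 0) stop("'gamma' and 'eta' must be non-negative")
  -(1 + eta + k^2) / (1 + gamma * k^2)
}

#' Superposed counter-propagating quasi-soliton pair
#'
#' Linear superposition of a rightward pulse launched at `Xp1` and a
#' leftward pulse launched at `Xp2 > Xp1`, both with the shared amplitude
#' and speed determined by `(gamma, eta, delta)`:
#' `U(X,T) = a0 * [sech^2(X - Xp1 - v*T) + sech^2(X - Xp2 + v*T)]`.
#' The peak trajectories cross at `T_cross = (Xp2 - Xp1) / (2*v)`, where
#' the superposed field momentarily shows a single peak of height `2*a0`;
#' the interaction is elastic by construction — the field at
#' `T_cross + s` is identical to the field at `T_cross - s`.
#'
#' @inheritParams quasi_soliton
#' @param Xp1,Xp2 launch positions with `Xp1 < Xp2`.
#' @return Object of class `"soliton_pair"` with fields `right`, `left`
#'   (the two `"quasi_soliton"` components), `a0`, `v`, `T_cross`,
#'   `X_mid`.
#' @examples
#' pair <- two_soliton(0.001, 0.1, 3, Xp1 = 4.4177, Xp2 = 5.5823)
#' pair$T_cross   # 0.4
#' @export
two_soliton <- function(gamma, eta = 0, delta = 0, Xp1, Xp2, params = NULL) {
  if (!is.null(params)) {
    gamma <- params$gamma; eta <- params$eta; delta <- params$delta
  }
  if (!(Xp1 < Xp2)) stop("'Xp1' must be strictly less than 'Xp2'")
  right <- quasi_soliton(gamma, eta, delta, Xp = Xp1, direction = "rightward")
  left  <- quasi_soliton(gamma, eta, delta, Xp = Xp2, direction = "leftward")
  structure(list(right = right, left = left,
                 a0 = right$a0, v = right$v,
                 T_cross = (Xp2 - Xp1) / (2 * right$v),
                 X_mid = (Xp1 + Xp2) / 2,
                 params = right$params),
            class = "soliton_pair")
}

#' @export
print.soliton_pair <- function(x, ...) {
  cat(sprintf("Counter-propagating quasi-soliton pair: a0 = %.6g, v = %.6g\n",
              x$a0, x$v))
  cat(sprintf("  launch positions Xp1 = %g, Xp2 = %g; peaks cross at T = %.6g (X = %g)\n",
              x$right$Xp, x$left$Xp, x$T_cross, x$X_mid))
  invisible(x)
}

#' @describeIn two_soliton evaluate the superposed field on `X` at time
#'   `T`.
#' @param object,x a `"soliton_pair"`.
#' @param X positions; `T` time (scalar).
#' @param ... unused.
#' @export
predict.soliton_pair <- function(object, X, T = 0, ...) {
  predict(object$right, X, T) + predict(object$left, X, T)
}

#' @export
plot.soliton_pair <- function(x, X = NULL, T = 0, ...) {
  if (is.null(X)) {
    pad <- 8 + x$v * abs(T)
    X <- seq(x$right$Xp - pad, x$left$Xp + pad, length.out = 1201)
  }
  graphics::plot(X, predict(x, X, T), type = "l",
                 xlab = "X (dimensionless)", ylab = "U",
                 main = sprintf("Colliding quasi-solitons at T = %g", T), ...)
  invisible(x)
}
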