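#' Spatial field snapshot
#'
#' A space-time snapshot of the dimensionless depolarization: the common
#' currency of analytic evaluation, PDE integration, and wave measurement.
#'
#' @param X spatial grid (strictly increasing numeric vector).
#' @param T time stamp (scalar).
#' @param U field values on `X` (finite).
#' @return Object of class `"field_frame"`.
#' @export
field_frame <- function(X, T, U) {
  stopifnot(is.numeric(X), is.numeric(U), length(X) == length(U),
            length(T) == 1L)
  if (any(!is.finite(U))) stop("field values must be finite")
  if (length(X) > 1L && any(diff(X) <= 0)) stop("'X' must be strictly increasing")
  structure(list(X = X, T = T, U = U), class = "field_frame")
}

#' @export
print.field_frame <- function(x, ...) {
  cat(sprintf("field_frame: %d points on [%g, %g] at T = %g, max |U| = %.4g\n",
              length(x$X), min(x$X), max(x$X), x$T, max(abs(x$U))))
  invisible(x)
}

#' @export
plot.field_frame <- function(x, ...) {
  graphics::plot(x$X, x$U, type = "l", xlab = "X (dimensionless)",
                 ylab = "U", main = sprintf("T = %g", x$T), ...)
  invisible(x)
}

#' Finite-difference grid for the cable equation
#'
#' Uniform spatial grid and fixed time step for the method-of-lines
#' integrator.  The travelling pulses have unit width, so the default
#' domain `[0, 40]` spans 40 pulse widths.  Boundary conditions are
#' `"zero-value"` (the profiles decay as sech^2, default) or
#' `"zero-flux"`.
#'
#' @param X_min,X_max domain bounds (dimensionless).
#' @param nx number of grid points (>= 64).
#' @param dt time step (> 0).
#' @param T_end final time.
#' @param bc boundary condition kind.
#' @return Object of class `"grid_spec"` with the grid `X`, spacing `h`,
#'   and the sparse second-difference operator `D2` (stencil
#'   `(1, -2, 1)/h^2`; boundary rows per `bc`).
#' @export
grid_spec <- function(X_min = 0, X_max = 40, nx = 2048, dt = 1e-4,
                      T_end = 0.1, bc = c("zero-value", "zero-flux")) {
  bc <- match.arg(bc)
  if (nx < 64) stop("'nx' must be at least 64")
  if (dt <= 0) stop("'dt' must be positive")
  if (X_max <= X_min) stop("'X_max' must exceed 'X_min'")
  X <- seq(X_min, X_max, length.out = nx)
  h <- X[2] - X[1]
  D2 <- second_difference(nx, h, bc)
  structure(list(X_min = X_min, X_max = X_max, nx = nx, dt = dt,
                 T_end = T_end, bc = bc, X = X, h = h, D2 = D2),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: [%g, %g], nx = %d (h = %.4g), dt = %g, T_end = %g, bc = %s\n",
              x$X_min, x$X_max, x$nx, x$h, x$dt, x$T_end, x$bc))
  invisible(x)
}

# Sparse second-difference operator.  For zero-value boundaries the
# boundary rows are zero (those unknowns are pinned to 0 in the solver);
# for zero-flux the ghost-point reflection gives rows (-2, 2)/h^2.
#' @noRd
second_difference <- function(nx, h, bc) {
  main <- rep(-2, nx); off <- rep(1, nx - 1)
  D2 <- Matrix::bandSparse(nx, nx, k = c(-1, 0, 1),
                           diagonals = list(off, main, off))
  D2 <- D2 / h^2
  if (bc == "zero-value") {
    D2[1, 1:2] <- 0
    D2[nx, (nx - 1):nx] <- 0
  } else {
    D2[1, 2] <- 2 / h^2
    D2[nx, nx - 1] <- 2 / h^2
  }
  methods::as(D2, "CsparseMatrix")
}

#' Mass operator and forcing of the pseudo-parabolic cable equation
#'
#' The dimensionless cable equation
#' \deqn{(1+\eta)U + U_T - U_{XX} = \gamma U_{TXX} + 2 (U^2)_T + \delta U^2}
#' is pseudo-parabolic: time derivatives act through the nonlinear mass
#' operator.  Collecting them gives the mass-action form
#' \deqn{M(U)\,U_T = F(U), \quad M(U) = (1 - 4U)\,I - \gamma D_2, \quad
#'       F(U) = D_2 U - (1+\eta) U + \delta U^2,}
#' with `D_2` the discrete second difference.  `M` is tridiagonal; it
#' remains positive definite only while `1 - 4U > 0` (up to the small
#' `gamma` diffusion), which bounds the amplitudes the initial-value
#' problem can carry — the well-posedness margin `min(1 - 4U)` is reported
#' by the solver diagnostics.
#'
#' For `"zero-value"` boundaries the boundary rows of `M` are identity
#' rows and the corresponding forcing entries are zero, pinning the
#' boundary values.
#'
#' @param U field values on the grid.
#' @param params a `"cable_dimensionless"` object.
#' @param grid a `"grid_spec"`.
#' @return List with sparse matrix `M`, numeric `F`, and the Gershgorin
#'   margin `margin = min(1 - 4U)`.
#' @export
assemble_mass_action <- function(U, params, grid) {
  stopifnot(inherits(params, "cable_dimensionless"),
            inherits(grid, "grid_spec"), length(U) == grid$nx)
  nx <- grid$nx
  M <- Matrix::Diagonal(x = 1 - 4 * U) - params$gamma * grid$D2
  Fv <- as.numeric(grid$D2 %*% U) - (1 + params$eta) * U + params$delta * U^2
  if (grid$bc == "zero-value") {
    M[1, 1] <- 1; M[nx, nx] <- 1      # D2 rows are zero there already
    Fv[c(1, nx)] <- 0
  }
  list(M = M, F = Fv, margin = min(1 - 4 * U))
}

# Nonlinear "charge" variable A(U) = U - 2U^2 - gamma*D2 U whose time
# derivative is M(U) U_T, and the forcing F(U); linearize drops the
# nonlinear terms of both.
#' @noRd
charge_and_forcing <- function(U, params, grid, linearize = FALSE) {
  U2 <- if (linearize) 0 * U else U^2
  A <- U - 2 * U2 - params$gamma * as.numeric(grid$D2 %*% U)
  Fv <- as.numeric(grid$D2 %*% U) - (1 + params$eta) * U +
    (if (linearize) 0 else params$delta) * U^2
  list(A = A, F = Fv)
}

#' Advance the cable equation by one implicit time step
#'
#' One step of the theta-scheme (default trapezoidal, `theta = 0.5`)
#' applied to the conservative form `d/dT A(U) = F(U)` with
#' `A(U) = U - 2U^2 - gamma*D2 U` (so that `A'(U) = M(U)`, the
#' pseudo-parabolic mass operator).  The nonlinear update is solved by
#' Newton iteration with sparse tridiagonal Jacobian solves.  Before the
#' step the Gershgorin margin `min(1 - 4U)` of `M(U)` is checked against
#' `guard_floor`; the solver halts rather than regularize when the mass
#' operator approaches singularity, because beyond `1 - 4U = 0` the
#' initial-value problem changes character.
#'
#' @param frame a `"field_frame"` on the grid of `grid`.
#' @param params a `"cable_dimensionless"`.
#' @param grid a `"grid_spec"`.
#' @param theta implicitness parameter in `(0, 1]`; 0.5 is second-order.
#' @param newton_tol,newton_max Newton stopping tolerance (max-norm of the
#'   step residual) and iteration cap.
#' @param guard_floor positive-definiteness floor for `min(1 - 4U)`.
#' @param linearize drop the nonlinear terms (independent linear
#'   integrator used for cross-checks).
#' @return The `"field_frame"` at `T + dt`, with attribute
#'   `"diagnostics"`: `list(newton_iters, margin)`.
#' @export
pde_step <- function(frame, params, grid, theta = 0.5,
                     newton_tol = 1e-10, newton_max = 25L,
                     guard_floor = 1e-8, linearize = FALSE) {
  stopifnot(inherits(frame, "field_frame"), inherits(grid, "grid_spec"))
  U0 <- frame$U
  nx <- grid$nx
  dt <- grid$dt
  margin <- min(1 - 4 * U0)
  if (!linearize && margin < guard_floor)
    stop(sprintf("mass operator near-singular: min(1 - 4U) = %.3g below floor %.3g",
                 margin, guard_floor))
  old <- charge_and_forcing(U0, params, grid, linearize)
  rhs_const <- old$A + dt * (1 - theta) * old$F
  pin <- if (grid$bc == "zero-value") c(1L, nx) else integer(0)

  U <- U0
  iters <- 0L
  repeat {
    new <- charge_and_forcing(U, params, grid, linearize)
    G <- new$A - dt * theta * new$F - rhs_const
    if (length(pin)) G[pin] <- U[pin] - U0[pin]
    if (max(abs(G)) <= newton_tol * max(1, max(abs(U)))) break
    if (iters >= newton_max)
      stop(sprintf("Newton iteration failed to converge in %d steps (residual %.3g, T = %g)",
                   newton_max, max(abs(G)), frame$T))
    diagU <- if (linearize) rep(1, nx) else 1 - 4 * U
    J <- Matrix::Diagonal(x = diagU) - params$gamma * grid$D2 -
      dt * theta * (grid$D2 - Matrix::Diagonal(x = rep(1 + params$eta, nx)) +
                      (if (linearize) 0 else 2 * params$delta) * Matrix::Diagonal(x = U))
    if (length(pin)) {
      J[pin, ] <- 0
      J[cbind(pin, pin)] <- 1
    }
    U <- U + as.numeric(Matrix::solve(J, -G))
    iters <- iters + 1L
  }
  out <- field_frame(grid$X, frame$T + dt, U)
  attr(out, "diagnostics") <- list(newton_iters = iters, margin = margin)
  out
}

#' Integrate the cable equation and collect snapshots
#'
#' Fixed-step method-of-lines integration of the pseudo-parabolic cable
#' equation from an initial frame, returning the requested snapshot frames
#' together with per-step solver diagnostics (Newton iterations and the
#' well-posedness margin `min(1 - 4U)`).  If the blow-up guard
#' `max |U| > U_max` trips, integration aborts with a warning and the
#' partial result is flagged (`partial = TRUE`).
#'
#' @inheritParams pde_step
#' @param init initial `"field_frame"`; its `X` must match `grid$X`.
#' @param snapshot_times times in `[init$T, T_end]` at which to keep
#'   frames (each rounded to the nearest step).  Default: 11 evenly
#'   spaced times.
#' @param U_max blow-up guard on `max |U|`.
#' @return Object of class `"pde_solution"`: list with `frames` (list of
#'   `"field_frame"`), `diagnostics` (data frame: `step`, `T`,
#'   `newton_iters`, `margin`), `partial` flag, and the `grid` and
#'   `params` used.
#' @examples
#' \donttest{
#' qs <- quasi_soliton(0.001, 0, 100, Xp = 5)   # small-amplitude regime
#' g  <- grid_spec(0, 20, nx = 512, dt = 5e-4, T_end = 0.05)
#' sol <- pde_simulate(soliton_profile(qs, g$X, 0), qs$params, g)
#' }
#' @export
pde_simulate <- function(init, params, grid, snapshot_times = NULL,
                         theta = 0.5, newton_tol = 1e-10, newton_max = 25L,
                         guard_floor = 1e-8, U_max = 10, linearize = FALSE) {
  stopifnot(inherits(init, "field_frame"), inherits(grid, "grid_spec"))
  if (length(init$X) != grid$nx || max(abs(init$X - grid$X)) > 1e-12)
    stop("initial frame is not on the grid of 'grid'")
  T0 <- init$T
  n_steps <- max(1L, as.integer(round((grid$T_end - T0) / grid$dt)))
  if (is.null(snapshot_times))
    snapshot_times <- seq(T0, grid$T_end, length.out = 11)
  if (any(snapshot_times < T0 - 1e-12 | snapshot_times > grid$T_end + 1e-12))
    stop("'snapshot_times' must lie in [init$T, T_end]")
  snap_steps <- pmin(pmax(as.integer(round((snapshot_times - T0) / grid$dt)), 0L),
                     n_steps)

  frames <- vector("list", length(snapshot_times))
  take <- function(step, fr) {
    hit <- which(snap_steps == step)
    for (i in hit) frames[[i]] <<- fr
  }
  take(0L, init)
  diag_rows <- vector("list", n_steps)
  frame <- init
  partial <- FALSE
  for (s in seq_len(n_steps)) {
    frame <- pde_step(frame, params, grid, theta = theta,
                      newton_tol = newton_tol, newton_max = newton_max,
                      guard_floor = guard_floor, linearize = linearize)
    d <- attr(frame, "diagnostics")
    diag_rows[[s]] <- data.frame(step = s, T = frame$T,
                                 newton_iters = d$newton_iters,
                                 margin = d$margin)
    if (max(abs(frame$U)) > U_max) {
      warning(sprintf("blow-up guard tripped at T = %g (max |U| = %.3g); returning partial results",
                      frame$T, max(abs(frame$U))))
      partial <- TRUE
      diag_rows <- diag_rows[seq_len(s)]
      frames <- frames[snap_steps <= s]
      break
    }
    take(s, frame)
  }
  structure(list(frames = Filter(Negate(is.null), frames),
                 diagnostics = do.call(rbind, diag_rows),
                 partial = partial, grid = grid, params = params),
            class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("pde_solution: %d snapshot(s), %d step(s)%s\n",
              length(x$frames), nrow(x$diagnostics),
              if (isTRUE(x$partial)) " [PARTIAL: blow-up guard tripped]" else ""))
  cat(sprintf("  well-posedness margin min(1-4U): %.4g; max Newton iterations: %d\n",
              min(x$diagnostics$margin), max(x$diagnostics$newton_iters)))
  invisible(x)
}

#' @describeIn pde_simulate `simulate()` method for a quasi-soliton:
#'   launches the analytic profile into the numerical integrator on
#'   `grid`.  The sech-squared pulse is only an approximate solution, so
#'   the simulated pulse adjusts as it propagates; amplitudes must stay
#'   well below the `1 - 4U = 0` well-posedness boundary (use
#'   large-`delta`, small-`a0` regimes).
#' @param object a `"quasi_soliton"`.
#' @param nsim,seed accepted for generic compatibility (the dynamics are
#'   deterministic; `seed` is ignored).
#' @param ... passed on to `pde_simulate()`.
#' @export
simulate.quasi_soliton <- function(object, nsim = 1, seed = NULL,
                                   grid = grid_spec(), snapshot_times = NULL,
                                   ...) {
  init <- soliton_profile(object, grid$X, T = 0)
  pde_simulate(init, object$params, grid, snapshot_times = snapshot_times, ...)
}
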