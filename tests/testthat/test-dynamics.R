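test_that("mass operator and forcing match their defining formulas", {
  p <- dimensionless_params(0.001, 0.5, 10)
  g <- grid_spec(0, 10, nx = 128, dt = 1e-3, T_end = 0.01)

  # U = 0: F = 0 and M = I - gamma*D2 (with pinned boundary rows)
  ma <- assemble_mass_action(rep(0, g$nx), p, g)
  expect_equal(ma$F, rep(0, g$nx))
  Mref <- diag(g$nx) - p$gamma * as.matrix(g$D2)
  Mref[1, ] <- 0; Mref[1, 1] <- 1
  Mref[g$nx, ] <- 0; Mref[g$nx, g$nx] <- 1
  expect_equal(as.matrix(ma$M), Mref, ignore_attr = TRUE)
  expect_equal(ma$margin, 1)

  # interior basis perturbation reproduces the (1, -2, 1)/h^2 stencil
  e <- rep(0, g$nx); e[60] <- 1
  col <- as.numeric(g$D2 %*% e)
  expect_equal(col[59:61], c(1, -2, 1) / g$h^2)
  expect_true(all(col[-(59:61)] == 0))

  # sampled sech^2 field: discrete forcing matches the symbolic-derivative
  # evaluation under h-refinement
  qs <- quasi_soliton(0.001, 0.5, 10, Xp = 5)
  ferr <- function(nx) {
    gf <- grid_spec(0, 10, nx = nx, dt = 1e-3, T_end = 0.01)
    U <- predict(qs, gf$X, 0)
    ma <- assemble_mass_action(U, p, gf)
    s <- 1 / cosh(gf$X - 5)^2
    Uxx <- qs$a0 * (4 * s - 6 * s^2)          # exact second derivative
    Fref <- Uxx - (1 + p$eta) * U + p$delta * U^2
    max(abs(ma$F - Fref)[2:(nx - 1)])
  }
  # O(h^2) refinement down to the 1e-6 level
  expect_gt(ferr(512) / ferr(1024), 3.5)
  expect_lt(ferr(8192), 1e-6)
})

test_that("the zero field is a fixed point over a thousand implicit steps", {
  p <- dimensionless_params(0.001, 0.5, 10)
  g <- grid_spec(0, 10, nx = 128, dt = 1e-3, T_end = 1)
  sol <- pde_simulate(field_frame(g$X, 0, rep(0, g$nx)), p, g,
                      snapshot_times = c(0.5, 1))
  expect_equal(nrow(sol$diagnostics), 1000L)
  for (f in sol$frames) expect_equal(max(abs(f$U)), 0)
  expect_false(sol$partial)
})

test_that("small-amplitude mode decay matches the closed-form dispersion rate within 2 percent", {
  p <- dimensionless_params(0.001, 0.5, 0)
  L <- 20
  k <- 2 * pi / L * 2
  om <- linear_dispersion(k, p$gamma, p$eta)
  Tend <- 1 / abs(om)                       # one e-folding
  g <- grid_spec(0, L, nx = 256, dt = Tend / 400, T_end = Tend)
  init <- field_frame(g$X, 0, 1e-5 * sin(k * g$X))
  sol <- pde_simulate(init, p, g, snapshot_times = c(0, Tend))
  A <- vapply(sol$frames, function(f) max(abs(f$U)), 0)
  rate <- log(A[2] / A[1]) / Tend
  expect_lt(abs(rate - om) / abs(om), 0.02)
})

test_that("the trapezoidal scheme is second order in the time step", {
  qs <- quasi_soliton(0.001, 0, 100, Xp = 10)
  run_dt <- function(dt) {
    g <- grid_spec(0, 20, nx = 256, dt = dt, T_end = 0.02)
    pde_simulate(soliton_profile(qs, g$X, 0), qs$params, g,
                 snapshot_times = 0.02)$frames[[1]]$U
  }
  e1 <- max(abs(run_dt(4e-4) - run_dt(2e-4)))
  e2 <- max(abs(run_dt(2e-4) - run_dt(1e-4)))
  expect_gt(e1 / e2, 3.3)     # O(dt^2): halving dt quarters the change
  expect_lt(e1 / e2, 4.7)
})

test_that("nonlinear and independent linear integrators agree in the linear regime", {
  p <- dimensionless_params(0.001, 0.1, 3)
  g <- grid_spec(0, 20, nx = 256, dt = 2e-4, T_end = 0.02)
  init <- field_frame(g$X, 0, 1e-6 * exp(-(g$X - 10)^2))
  sN <- pde_simulate(init, p, g, snapshot_times = 0.02)
  sL <- pde_simulate(init, p, g, snapshot_times = 0.02, linearize = TRUE)
  rel <- max(abs(sN$frames[[1]]$U - sL$frames[[1]]$U)) /
    max(abs(sL$frames[[1]]$U))
  expect_lt(rel, 1e-6)
})

test_that("parity is conserved: an even initial pulse stays even and its peak does not translate", {
  # every term of the equation preserves evenness in X, so the initial-value
  # dynamics of the (even) sech^2 profile cannot move its peak -- the
  # closed-form pulse's translation is a property of the approximate
  # travelling-wave ansatz, not of the initial-value problem
  qs <- quasi_soliton(0.001, 0, 100, Xp = 10)   # a0 ~ 0.054, well-posed
  g <- grid_spec(0, 20, nx = 512, dt = 5e-4, T_end = 0.05)
  sol <- simulate(qs, grid = g, snapshot_times = c(0, 0.05))
  U <- sol$frames[[2]]$U
  expect_lt(max(abs(U - rev(U))), 1e-10)        # even about the midpoint
  tr <- track_peaks(sol)
  expect_lt(abs(tr$peak_X[2] - tr$peak_X[1]), g$h)
  # the amplitude evolves in place (here the delta*U^2 source feeds it)
  expect_gt(abs(tr$peak_U[2] - tr$peak_U[1]), 1e-4)
})

test_that("well-posedness guard halts on amplitudes beyond the 1 - 4U boundary", {
  qs <- quasi_soliton(0.001, 0, 0, Xp = 10)     # a0 ~ 0.5: 1 - 4*a0 < 0
  g <- grid_spec(0, 20, nx = 128, dt = 1e-3, T_end = 0.01)
  init <- soliton_profile(qs, g$X, 0)
  expect_error(pde_step(init, qs$params, g), "near-singular")
  expect_lt(assemble_mass_action(init$U, qs$params, g)$margin, 0)
})

test_that("blow-up guard aborts with flagged partial results", {
  p <- dimensionless_params(0.001, 0, 100)
  g <- grid_spec(0, 10, nx = 128, dt = 1e-3, T_end = 0.05)
  init <- field_frame(g$X, 0, 0.05 / cosh(g$X - 5)^2)
  expect_warning(
    sol <- pde_simulate(init, p, g, U_max = 1e-9),
    "blow-up guard")
  expect_true(sol$partial)
  expect_lt(nrow(sol$diagnostics), 50L)
})

test_that("interior solution is insensitive to enlarging the domain", {
  qs <- quasi_soliton(0.001, 0, 100, Xp = 10)
  h <- 1 / 16
  run_dom <- function(a, b) {
    nx <- as.integer(round((b - a) / h)) + 1L
    g <- grid_spec(a, b, nx = nx, dt = 1e-3, T_end = 0.02)
    sol <- pde_simulate(soliton_profile(qs, g$X, 0), qs$params, g,
                        snapshot_times = 0.02)
    list(X = g$X, U = sol$frames[[1]]$U)
  }
  small <- run_dom(0, 20)     # pulse decays to ~1e-17 at these boundaries
  big <- run_dom(-5, 25)
  idx <- match(round(small$X, 10), round(big$X, 10))
  expect_lt(max(abs(small$U - big$U[idx])), 1e-8)
})

test_that("solver diagnostics report the Gershgorin margin min(1 - 4U)", {
  qs <- quasi_soliton(0.001, 0, 100, Xp = 5)
  g <- grid_spec(0, 10, nx = 128, dt = 1e-3, T_end = 0.005)
  sol <- simulate(qs, grid = g)
  expect_true(all(c("margin", "newton_iters") %in% names(sol$diagnostics)))
  expect_equal(sol$diagnostics$margin[1],
               min(1 - 4 * predict(qs, g$X, 0)), tolerance = 1e-12)
})
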