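test_that("closed-form velocity reproduces the study's printed values at printed precision", {
  # half-ulp of the last printed digit
  expect_lt(abs(soliton_velocity(0.001, 0)   - 1.506),  5e-4)
  expect_lt(abs(soliton_velocity(0.001, 0.5) - 1.255),  5e-4)
  expect_lt(abs(soliton_velocity(0.001, 2.5) - 0.251),  5e-4)
  expect_lt(abs(soliton_velocity(0.001, 2.9) - 0.05),   5e-3)
  expect_lt(abs(soliton_velocity(0.001, 0.1) - 1.4558), 5e-5)
})

test_that("velocity vanishes at eta = 3 and errors outside the valid domain", {
  expect_equal(soliton_velocity(0.1, 3), 0)
  expect_equal(soliton_velocity(0.001, 3), 0)
  expect_error(soliton_velocity(0.001, 3.1), "negative velocity")
  expect_error(soliton_velocity(0.25, 0), "degenerates")
})

test_that("velocity is monotone decreasing in eta and increasing in gamma", {
  eta <- seq(0, 2.9, by = 0.1)
  expect_true(all(diff(soliton_velocity(0.01, eta)) < 0))
  gam <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(soliton_velocity(gam, 1)) > 0))
})

test_that("amplitude matches its passive limit and the velocity-substituted evaluation", {
  # gamma -> 0 passive limit: 6 * 1 / (8 * 1.5) = 0.5
  expect_equal(soliton_amplitude(0, 0, 0), 0.5)
  # independent evaluation of 6(1+4*gamma*v)/(8v) at gamma = 0.001
  v <- (3 - 0) / (2 * (1 - 4 * 0.001))
  expect_equal(round(soliton_amplitude(0.001, 0, 0), 4),
               round(6 * (1 + 4 * 0.001 * v) / (8 * v), 4))
  expect_equal(round(soliton_amplitude(0.001, 0, 0), 4), 0.5010)
  expect_gt(soliton_amplitude(0.001, 2.99, 0), 0)
})

test_that("the two closed-form amplitude expressions agree to 1e-12 over random draws", {
  set.seed(101)
  n <- 1e4
  gam <- stats::runif(n, 0, 0.1)
  eta <- stats::runif(n, 0, 2.9)
  del <- stats::runif(n, 0, 50)
  a_vel <- mapply(soliton_amplitude, gam, eta, del,
                  MoreArgs = list(form = "velocity"))
  a_dir <- mapply(soliton_amplitude, gam, eta, del,
                  MoreArgs = list(form = "direct"))
  expect_lt(max(abs(a_vel - a_dir) / pmax(a_vel, a_dir)), 1e-12)
})

test_that("mitochondrial drive reduces the amplitude by about 40 percent", {
  red <- 100 * (1 - soliton_amplitude(0.001, 0.5, 10) /
                  soliton_amplitude(0.001, 0, 0))
  expect_equal(round(red), 40)
  expect_lt(abs(red - 39.94), 0.01)
})

test_that("the sech-squared profile peaks at a0 on the moving crest and is even about it", {
  qs <- quasi_soliton(0.001, 0.5, 10, Xp = 0.5)
  expect_equal(predict(qs, X = 0.5, T = 0), qs$a0)
  # independent arithmetic for sech^2(1) = 4 / (e + 1/e)^2
  expect_equal(predict(qs, X = 1.5, T = 0),
               qs$a0 * 4 / (exp(1) + exp(-1))^2)
  expect_equal(predict(qs, X = -0.5, T = 0), predict(qs, X = 1.5, T = 0))
  # crest translates at v: values in (0, a0], max exactly at Xp + v*T
  Tt <- 0.25
  X <- seq(-4, 6, by = 1e-3)
  U <- predict(qs, X, Tt)
  expect_true(all(U > 0 & U <= qs$a0))
  expect_equal(predict(qs, qs$Xp + qs$v * Tt, Tt), qs$a0)
})

test_that("passive crest reaches X = 0.6506 at T = 0.1 from Xp = 0.5", {
  qs <- quasi_soliton(0.001, 0, 0, Xp = 0.5)
  expect_equal(round(qs$Xp + qs$v * 0.1, 4), 0.6506)
})

test_that("leftward pulse is the spatial reflection of the rightward pulse", {
  pr <- quasi_soliton(0.001, 0.5, 10, Xp = 2, direction = "rightward")
  pl <- quasi_soliton(0.001, 0.5, 10, Xp = 2, direction = "leftward")
  X <- seq(-6, 10, by = 0.01)
  for (Tt in c(0, 0.3, 1.2))
    expect_equal(predict(pl, X, Tt), predict(pr, 2 * 2 - X, Tt))
})

test_that("profile mass integrates to 2*a0 independent of time", {
  qs <- quasi_soliton(0.001, 0.5, 10, Xp = 0)
  for (Tt in c(0, 0.5)) {
    m <- stats::integrate(function(x) predict(qs, x, Tt), -Inf, Inf,
                          rel.tol = 1e-10)$value
    expect_equal(m, 2 * qs$a0, tolerance = 1e-8)
  }
})

test_that("superposed pair crosses at (Xp2-Xp1)/(2v) with coincident peaks of height 2*a0", {
  pair <- two_soliton(0.001, 0.1, 3, Xp1 = 4.4177, Xp2 = 5.5823)
  expect_equal(round(pair$T_cross, 4), 0.4)
  # independent arithmetic from the caption values
  expect_equal(pair$T_cross, (5.5823 - 4.4177) / (2 * pair$v))
  expect_equal(predict(pair, pair$X_mid, pair$T_cross), 2 * pair$a0,
               tolerance = 1e-9)
  # boundary decay far from both launch positions
  expect_lt(max(predict(pair, c(-20, 30), 0)), 1e-12)
  expect_error(two_soliton(0.001, 0.1, 3, Xp1 = 2, Xp2 = 1), "strictly less")
})

test_that("pair field is symmetric in time about the crossing instant (elastic by construction)", {
  pair <- two_soliton(0.001, 0.1, 3, Xp1 = 4.4177, Xp2 = 5.5823)
  X <- seq(-2, 12, by = 0.01)
  for (s in c(0.1, 0.25, 0.39)) {
    expect_lt(max(abs(predict(pair, X, pair$T_cross + s) -
                        predict(pair, X, pair$T_cross - s))), 1e-12)
  }
})

test_that("travelling-wave residual decays in the tails and equals (3+eta)*a0 - delta*a0^2 at the core", {
  for (par in list(c(0.001, 0, 0), c(0.001, 0.5, 10), c(0.001, 2.9, 8))) {
    qs <- quasi_soliton(par[1], par[2], par[3])
    expect_lt(max(abs(ode_residual(c(-30, -20, 20, 30), qs))), 1e-12)
    expect_equal(ode_residual(0, qs),
                 (3 + par[2]) * qs$a0 - par[3] * qs$a0^2)
  }
  # passive case: the core residual is exactly 3*a0 (large relative to the
  # pulse itself -- the ansatz is approximate)
  qs <- quasi_soliton(0.001, 0, 0)
  expect_equal(ode_residual(0, qs), 3 * qs$a0)
})

test_that("closed-form residual matches the finite-difference oracle", {
  qs <- quasi_soliton(0.001, 0.5, 10)
  zeta <- seq(-5, 5, by = 0.25)
  expect_lt(max(abs(ode_residual(zeta, qs) - fd_residual_oracle(zeta, qs))),
            1e-6)
})

test_that("tanh-transformed residual agrees with the zeta-space residual", {
  qs <- quasi_soliton(0.001, 0.5, 10)
  zeta <- seq(-3, 3, by = 0.1)
  expect_lt(max(abs(tanh_transform_residual(tanh(zeta), qs) -
                      ode_residual(zeta, qs))), 1e-9)
  # y -> +/-1 limits vanish at the closed-form (a0, v)
  expect_lt(max(abs(tanh_transform_residual(c(-1, 1) * (1 - 1e-9), qs))), 1e-6)
  expect_error(tanh_transform_residual(1, qs), "inside")
})

test_that("the y = -1 boundary condition forces the expansion coefficient a1 = 1", {
  expect_equal(tanh_expansion_a1(), 1, tolerance = 1e-10)
  expect_equal(tanh_expansion_a1(a0 = 0.3), 1, tolerance = 1e-10)
})

test_that("all linearized modes decay: omega(k) < 0 everywhere", {
  expect_equal(linear_dispersion(0, 0.2, 0.7), -(1 + 0.7))
  k <- seq(-4, 4, by = 0.5)
  expect_equal(linear_dispersion(k, 0, 0), -(1 + k^2))
  set.seed(7)
  kk <- 10^seq(-3, 3, length.out = 61)
  for (i in 1:25) {
    g <- stats::runif(1, 0, 0.25); e <- stats::runif(1, 0, 3)
    expect_true(all(linear_dispersion(c(-kk, 0, kk), g, e) < 0))
  }
})

test_that("quasi_soliton object is internally consistent and its methods agree", {
  qs <- quasi_soliton(0.001, 0.5, 10, Xp = 1)
  expect_equal(unname(coef(qs)),
               c(soliton_amplitude(0.001, 0.5, 10),
                 soliton_velocity(0.001, 0.5)))
  r <- residuals(qs)
  expect_equal(as.numeric(r[301]), ode_residual(0, qs))  # grid midpoint
  ff <- soliton_profile(qs, seq(0, 2, by = 0.1), 0)
  expect_s3_class(ff, "field_frame")
  expect_equal(ff$U, predict(qs, seq(0, 2, by = 0.1), 0))
})
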