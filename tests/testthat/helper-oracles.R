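# Shared helpers: analytic frame factories and independent finite-difference
# oracles used to cross-check closed-form derivative evaluations.

# Frames of a single analytic pulse on a measurement grid with `ppu` points
# per unit length, padded beyond the pulse excursion.
make_frames <- function(qs, times, ppu = 1024, pad = 6) {
  reach <- qs$v * max(abs(times))
  X <- seq(qs$Xp - pad - reach, qs$Xp + pad + reach, by = 1 / ppu)
  lapply(times, function(Tt) soliton_profile(qs, X, Tt))
}

# Frames of a superposed pair at times symmetric about its crossing time.
make_pair_frames <- function(pair, n = 41, span = 1, ppu = 512, pad = 8) {
  Tc <- pair$T_cross
  times <- Tc + seq(-span * Tc, span * Tc, length.out = n)
  reach <- pair$v * max(times)
  X <- seq(pair$right$Xp - pad - reach, pair$left$Xp + pad + reach,
           by = 1 / ppu)
  lapply(times, function(Tt) field_frame(X, Tt, predict(pair, X, Tt)))
}

# Independent finite-difference oracle for the travelling-wave residual:
# differentiates the profile Omega(zeta) = a0 sech^2(zeta) numerically
# (Richardson-extrapolated central differences), never reusing the
# closed-form derivative identities under test.
fd_residual_oracle <- function(zeta, qs, h = 0.02) {
  Om <- function(z) qs$a0 / cosh(z)^2
  d1h <- function(z, h) (Om(z + h) - Om(z - h)) / (2 * h)
  d2h <- function(z, h) (Om(z + h) - 2 * Om(z) + Om(z - h)) / h^2
  d3h <- function(z, h)
    (Om(z + 2 * h) - 2 * Om(z + h) + 2 * Om(z - h) - Om(z - 2 * h)) / (2 * h^3)
  rich <- function(f, z) (4 * f(z, h / 2) - f(z, h)) / 3
  d1 <- rich(d1h, zeta); d2 <- rich(d2h, zeta); d3 <- rich(d3h, zeta)
  p <- qs$params; v <- qs$v
  v * p$gamma * d3 - d2 + v * (4 * Om(zeta) - 1) * d1 +
    (1 + p$eta) * Om(zeta) - p$delta * Om(zeta)^2
}
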