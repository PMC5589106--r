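# Quadratic (3-point) peak interpolation through the samples bracketing a
# discrete argmax.  Returns interpolated location and height.  Tie-breaking
# for plateau maxima takes the leftmost bracketing triple (which.max picks
# the first index).
#' @noRd
interp_peak <- function(X, U, j) {
  h <- X[j] - X[j - 1]
  den <- U[j - 1] - 2 * U[j] + U[j + 1]
  off <- if (den == 0) 0 else 0.5 * (U[j - 1] - U[j + 1]) / den
  c(X = X[j] + off * h,
    U = U[j] - 0.25 * (U[j - 1] - U[j + 1]) * off)
}

# All interpolated local maxima above min_height_frac * max(U).
#' @noRd
find_peaks <- function(frame, min_height_frac = 0.2) {
  U <- frame$U; X <- frame$X; n <- length(U)
  thr <- min_height_frac * max(U)
  j <- which(U[2:(n - 1)] >= U[1:(n - 2)] & U[2:(n - 1)] > U[3:n]) + 1L
  j <- j[U[j] >= thr]
  if (!length(j)) return(data.frame(X = numeric(0), U = numeric(0)))
  out <- t(vapply(j, function(i) interp_peak(X, U, i), c(X = 0, U = 0)))
  data.frame(X = out[, "X"], U = out[, "U"])
}

#' Track the peak of a travelling pulse across frames
#'
#' Locates the global maximum of each frame by quadratic interpolation
#' through the three samples bracketing the discrete argmax, giving
#' sub-grid peak locations and heights.  This is the measurement
#' underlying the two-point slope/velocity bookkeeping: reading the peak
#' coordinate off the space-time field at successive times.
#'
#' @param frames a list of `"field_frame"` objects (or a
#'   `"pde_solution"`), with strictly increasing time stamps.
#' @return Object of class `"wave_track"` (a data frame with columns
#'   `T`, `peak_X`, `peak_U`).
#' @examples
#' qs <- quasi_soliton(0.001, 0, 0, Xp = 0.5)
#' X <- seq(-5, 6, by = 1/1024)
#' tr <- track_peaks(list(soliton_profile(qs, X, 0),
#'                        soliton_profile(qs, X, 0.1)))
#' tr$peak_X     # 0.5, then 0.5 + v/10 = 0.6506
#' @export
track_peaks <- function(frames) {
  if (inherits(frames, "pde_solution")) frames <- frames$frames
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, TRUE, "field_frame")))
  times <- vapply(frames, function(f) f$T, 0)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  pk <- t(vapply(frames, function(f) {
    j <- which.max(f$U)
    if (j == 1L || j == length(f$U)) stop("peak left domain")
    interp_peak(f$X, f$U, j)
  }, c(X = 0, U = 0)))
  structure(data.frame(T = times, peak_X = pk[, "X"], peak_U = pk[, "U"]),
            class = c("wave_track", "data.frame"))
}

#' Two-point slope and velocity estimate of a peak trajectory
#'
#' The velocity is read off the space-time density plot as the reciprocal
#' of the slope between two designated points of the peak trajectory:
#' `slope = (T2 - T1) / (X2 - X1)` and `v_est = 1 / slope`.  The default
#' uses the first and last tracked points (the two-point convention used
#' to read density plots); `method = "least-squares"` instead fits
#' `T ~ peak_X` over the full track.
#'
#' @param track a `"wave_track"`.
#' @param first,last indices of the two designated points.
#' @param method `"two-point"` (default) or `"least-squares"`.
#' @return List with `slope` and `v_est` (`v_est * slope = 1`).
#' @examples
#' qs <- quasi_soliton(0.001, 0, 0, Xp = 0.5)
#' X <- seq(-5, 6, by = 1/1024)
#' tr <- track_peaks(list(soliton_profile(qs, X, 0),
#'                        soliton_profile(qs, X, 0.1)))
#' slope_velocity(tr)   # slope 0.664, v_est 1.506
#' @export
slope_velocity <- function(track, first = 1L, last = nrow(track),
                           method = c("two-point", "least-squares")) {
  method <- match.arg(method)
  stopifnot(inherits(track, "wave_track"))
  if (method == "two-point") {
    dX <- track$peak_X[last] - track$peak_X[first]
    if (dX == 0) stop("zero peak displacement between the designated points")
    slope <- (track$T[last] - track$T[first]) / dX
  } else {
    slope <- unname(stats::coef(stats::lm(T ~ peak_X, data = track))[2])
    if (slope == 0) stop("zero fitted slope")
  }
  list(slope = slope, v_est = 1 / slope)
}

#' Percentage amplitude difference between two quasi-solitons
#'
#' Reports by how many percent the amplitude of `specA` is smaller than
#' that of `specB`: `100 * (1 - a0_A / a0_B)`.  Negative values mean
#' `specA` is the larger pulse (membrane amplification).
#'
#' @param specA,specB `"quasi_soliton"` objects.
#' @return Percentage difference.
#' @examples
#' mito    <- quasi_soliton(0.001, 0.5, 10)
#' passive <- quasi_soliton(0.001, 0, 0)
#' amplitude_ratio(mito, passive)   # ~40% smaller
#' @export
amplitude_ratio <- function(specA, specB) {
  stopifnot(inherits(specA, "quasi_soliton"), inherits(specB, "quasi_soliton"))
  100 * (1 - specA$a0 / specB$a0)
}

# Finite-difference derivative of a frame (central differences, one order
# per call).
#' @noRd
fd_derivative <- function(X, U) {
  n <- length(U)
  d <- numeric(n)
  d[2:(n - 1)] <- (U[3:n] - U[1:(n - 2)]) / (X[3:n] - X[1:(n - 2)])
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

#' Elasticity analysis of a head-on quasi-soliton collision
#'
#' Measures whether two counter-propagating pulses pass through one
#' another unchanged.  A head-on collision of equal-speed pulses is
#' elastic precisely when the field is symmetric in time about the
#' crossing instant: the frame at `T_cross + s` must equal the frame at
#' `T_cross - s`.  The primary shape-difference score is therefore the
#' max-norm difference between the frame at `post_T` and the frame at the
#' mirrored pre-collision time `2*T_cross - post_T` (for linearly
#' superposed pulses this is exactly zero).  A secondary per-pulse score
#' translates each incoming pulse, windowed about its peak, to the
#' corresponding outgoing peak position and reports the max-norm
#' mismatch; for pulses launched closer together than a few widths the
#' window necessarily overlaps the partner pulse, so the reflection score
#' is the operative one.
#'
#' The report also records whether a frame with a single peak exists near
#' `T_cross` (the pulses momentarily absorb one another), the pre- and
#' post-collision two-point velocity estimates of each pulse, and a
#' localization check at each post-collision peak: the interpolated first
#' derivative vanishes at the peak and the field and its first three
#' derivatives decay at the domain edges.
#'
#' @param frames list of `"field_frame"` objects (or `"pde_solution"`)
#'   bracketing the collision, at strictly increasing times.
#' @param pre_T,post_T times (before and after the collision) at which to
#'   compare shapes; the nearest frames are used.
#' @param T_cross the crossing time, if known (e.g. from
#'   [two_soliton()]); otherwise estimated as the midpoint of the
#'   single-peak interval.
#' @param min_height_frac peaks below this fraction of the frame maximum
#'   are ignored.
#' @param window half-width of the per-pulse comparison window; default
#'   `min(5, half the pre-collision peak separation)`.
#' @param tol tolerance used for the localization check report (default
#'   1e-6).
#' @return Object of class `"collision_report"`.
#' @export
collision_elasticity <- function(frames, pre_T, post_T, T_cross = NULL,
                                 min_height_frac = 0.2, window = NULL,
                                 tol = 1e-6) {
  if (inherits(frames, "pde_solution")) frames <- frames$frames
  times <- vapply(frames, function(f) f$T, 0)
  if (!(min(times) <= pre_T && post_T <= max(times)) || !(pre_T < post_T))
    stop("frames must bracket the collision: pre_T < post_T within the frame times")
  near <- function(t) which.min(abs(times - t))
  i_pre <- near(pre_T); i_post <- near(post_T)
  pre <- frames[[i_pre]]; post <- frames[[i_post]]

  peaks <- lapply(frames, find_peaks, min_height_frac = min_height_frac)
  npk <- vapply(peaks, nrow, 0L)
  if (npk[i_post] == 0L || npk[i_pre] == 0L)
    stop("peaks unresolvable: no peak found in the pre- or post-collision frame")

  single <- which(npk == 1L & times > pre$T & times < post$T)
  single_peak_times <- times[single]
  if (is.null(T_cross)) {
    # the coincident peaks make the frame of greatest height the crossing
    heights <- vapply(frames, function(f) max(f$U), 0)
    T_cross <- times[which.max(heights)]
  }

  # primary score: time-reflection symmetry about T_cross
  t_mirror <- 2 * T_cross - post$T
  i_mir <- near(t_mirror)
  reflection_diff <- max(abs(post$U - frames[[i_mir]]$U))
  reflection_time_mismatch <- abs(times[i_mir] - t_mirror)

  # secondary score: translated-pulse comparison per direction, available
  # only when both comparison frames resolve the two pulses (pulses
  # launched closer than ~1.32 widths stay merged until well after the
  # crossing)
  pre_pk <- peaks[[i_pre]][order(peaks[[i_pre]]$X), ]
  post_pk <- peaks[[i_post]][order(peaks[[i_post]]$X), ]
  if (npk[i_pre] == 2L && npk[i_post] == 2L) {
    if (is.null(window)) window <- min(5, diff(pre_pk$X) / 2)
    pulse_diff <- function(x_in, x_out) {
      s <- seq(-window, window, length.out = 401)
      f_in  <- stats::approx(pre$X,  pre$U,  xout = x_in + s)$y
      f_out <- stats::approx(post$X, post$U, xout = x_out + s)$y
      max(abs(f_in - f_out), na.rm = TRUE)
    }
    # incoming rightward pulse = left peak before collision, right peak after
    pulse_shape_diff <- c(
      rightward = pulse_diff(pre_pk$X[1], post_pk$X[2]),
      leftward  = pulse_diff(pre_pk$X[2], post_pk$X[1]))
  } else {
    if (is.null(window)) window <- NA_real_
    pulse_shape_diff <- c(rightward = NA_real_, leftward = NA_real_)
  }

  # velocities from two-peak frames before / after the comparison times
  two_track <- function(idx, col) {
    ok <- idx[npk[idx] == 2L]
    if (length(ok) < 2L) return(NA_real_)
    xs <- vapply(ok, function(i) sort(peaks[[i]]$X)[col], 0)
    dX <- xs[length(xs)] - xs[1]
    if (dX == 0) return(NA_real_)
    1 / ((times[ok[length(ok)]] - times[ok[1]]) / dX)
  }
  pre_idx  <- which(times <= pre$T)
  post_idx <- which(times >= post$T)
  v_pre  <- c(rightward = two_track(pre_idx, 1),  leftward = -two_track(pre_idx, 2))
  v_post <- c(rightward = two_track(post_idx, 2), leftward = -two_track(post_idx, 1))

  # localization at each post-collision peak and in the tails
  d1 <- fd_derivative(post$X, post$U)
  d2 <- fd_derivative(post$X, d1)
  d3 <- fd_derivative(post$X, d2)
  peak_d1 <- vapply(post_pk$X, function(x)
    abs(stats::approx(post$X, d1, xout = x)$y), 0)
  edge <- c(1:3, (length(post$X) - 2):length(post$X))
  tail_decay <- max(abs(post$U[edge]), abs(d1[edge]), abs(d2[edge]),
                    abs(d3[edge]))

  structure(list(T_cross = T_cross, pre_T = pre$T, post_T = post$T,
                 reflection_diff = reflection_diff,
                 reflection_time_mismatch = reflection_time_mismatch,
                 pulse_shape_diff = pulse_shape_diff,
                 single_peak = length(single) > 0,
                 single_peak_times = single_peak_times,
                 v_pre = v_pre, v_post = v_post,
                 peak_d1 = peak_d1, tail_decay = tail_decay,
                 localized = all(peak_d1 <= tol) && tail_decay <= tol,
                 tol = tol, window = window),
            class = "collision_report")
}

#' @export
print.collision_report <- function(x, ...) {
  cat("Head-on collision elasticity report\n")
  cat(sprintf("  crossing time T_cross = %.6g; compared frames at T = %.6g and %.6g\n",
              x$T_cross, x$pre_T, x$post_T))
  cat(sprintf("  shape difference (time-reflection, max-norm): %.4g\n",
              x$reflection_diff))
  cat(sprintf("  shape difference (translated pulses): rightward %.4g, leftward %.4g\n",
              x$pulse_shape_diff["rightward"], x$pulse_shape_diff["leftward"]))
  cat(sprintf("  single-peak frame near collision: %s%s\n",
              if (x$single_peak) "yes" else "no",
              if (x$single_peak)
                sprintf(" (T in [%.4g, %.4g])", min(x$single_peak_times),
                        max(x$single_peak_times)) else ""))
  cat(sprintf("  velocity estimates: pre (%.4g, %.4g), post (%.4g, %.4g)\n",
              x$v_pre[1], x$v_pre[2], x$v_post[1], x$v_post[2]))
  cat(sprintf("  post-collision localization (|U'| at peaks %.3g, tail decay %.3g, tol %.1g): %s\n",
              max(x$peak_d1), x$tail_decay, x$tol,
              if (x$localized) "satisfied" else "NOT satisfied"))
  invisible(x)
}

#' Space-time density plot of a frame sequence
#'
#' Renders the field `U(X, T)` of a frame sequence as an image (time on
#' the vertical axis), the standard way travelling pulses are displayed
#' and their slopes read off.
#'
#' @param frames list of `"field_frame"` objects (or `"pde_solution"`).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the `U` matrix (space x time).
#' @export
density_plot <- function(frames, ...) {
  if (inherits(frames, "pde_solution")) frames <- frames$frames
  times <- vapply(frames, function(f) f$T, 0)
  U <- vapply(frames, function(f) f$U, frames[[1]]$U)
  graphics::image(frames[[1]]$X, times, U, xlab = "X (dimensionless)",
                  ylab = "T (dimensionless)", ...)
  invisible(U)
}
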