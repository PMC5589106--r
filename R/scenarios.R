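#' Scenario: a reproducible model run
#'
#' Bundles parameters, mode and initial condition into a named,
#' serializable configuration.  `mode = "analytic"` evaluates the
#' closed-form quasi-soliton (or superposed pair) on a measurement grid;
#' `mode = "pde"` launches the profile into the numerical integrator.
#'
#' @param name scenario name.
#' @param params a `"cable_dimensionless"` object (or a `"cable_params"`,
#'   which is first passed through [derive_dimensionless()]).
#' @param mode `"analytic"` or `"pde"`.
#' @param init initial-condition description: a list with `type`
#'   (`"single"` or `"pair"`), and `Xp` (+ optional `direction`) or
#'   `Xp1`/`Xp2`.
#' @param grid for `mode = "pde"`: a `"grid_spec"` (default
#'   [grid_spec()]).  For `mode = "analytic"`: optional list with `T_end`
#'   and `points_per_unit` controlling the measurement frames.
#' @param outputs character vector of artifacts for [run_scenario()]:
#'   any of `"summary"`, `"track"`, `"profile"`, `"png"`.
#' @return Object of class `"cable_scenario"`.
#' @export
scenario <- function(name, params, mode = c("analytic", "pde"),
                     init = list(type = "single", Xp = 0.5),
                     grid = NULL,
                     outputs = c("summary", "track", "profile")) {
  mode <- match.arg(mode)
  if (inherits(params, "cable_params")) params <- derive_dimensionless(params)
  stopifnot(inherits(params, "cable_dimensionless"), is.character(name))
  if (!is.list(init) || is.null(init$type) ||
      !init$type %in% c("single", "pair"))
    stop("'init' must be a list with type 'single' or 'pair'")
  if (init$type == "single" && is.null(init$Xp))
    stop("'init' of type 'single' needs 'Xp'")
  if (init$type == "pair" && (is.null(init$Xp1) || is.null(init$Xp2)))
    stop("'init' of type 'pair' needs 'Xp1' and 'Xp2'")
  if (mode == "pde" && is.null(grid)) grid <- grid_spec()
  bad <- setdiff(outputs, c("summary", "track", "profile", "png"))
  if (length(bad)) stop("unknown outputs: ", paste(bad, collapse = ", "))
  structure(list(name = name, params = params, mode = mode, init = init,
                 grid = grid, outputs = outputs),
            class = "cable_scenario")
}

#' @export
print.cable_scenario <- function(x, ...) {
  p <- x$params
  cat(sprintf("Scenario '%s' (%s): gamma = %g, eta = %g, delta = %g\n",
              x$name, x$mode, p$gamma, p$eta, p$delta))
  if (x$init$type == "single")
    cat(sprintf("  single pulse at Xp = %g\n", x$init$Xp))
  else
    cat(sprintf("  counter-propagating pair at Xp1 = %g, Xp2 = %g\n",
                x$init$Xp1, x$init$Xp2))
  invisible(x)
}

#' Built-in study scenarios
#'
#' The named parameter sets of the study conditions: four single-pulse
#' scenarios at `gamma = 0.001` spanning the passive membrane (`fig5a`:
#' `eta = 0, delta = 0`) and three mitochondrial membranes of increasing
#' drive (`fig5b`: `eta = 0.5, delta = 10`; `fig5c`: `eta = 2.5,
#' delta = 10`; `fig5d`: `eta = 2.9, delta = 8`), each launched at
#' `Xp = 0.5`; the head-on collision scenario (`fig6`: `eta = 0.1,
#' delta = 3`, pulses at `Xp1 = 4.4177` and `Xp2 = 5.5823`); and a
#' small-amplitude variant (`pde_safe`: `eta = 0, delta = 100`, so
#' `a0 ~ 0.054`) whose amplitude keeps the pseudo-parabolic mass operator
#' safely positive definite for numerical integration.
#'
#' @return Named list of six `"cable_scenario"` objects.
#' @examples
#' fx <- scenario_fixtures()
#' names(fx)
#' soliton_velocity(0.001, fx$fig5c$params$eta)   # 0.251
#' @export
scenario_fixtures <- function() {
  single <- function(name, eta, delta, Xp = 0.5)
    scenario(name, dimensionless_params(0.001, eta, delta),
             mode = "analytic", init = list(type = "single", Xp = Xp))
  list(
    fig5a = single("fig5a", 0, 0),
    fig5b = single("fig5b", 0.5, 10),
    fig5c = single("fig5c", 2.5, 10),
    fig5d = single("fig5d", 2.9, 8),
    fig6 = scenario("fig6", dimensionless_params(0.001, 0.1, 3),
                    mode = "analytic",
                    init = list(type = "pair", Xp1 = 4.4177, Xp2 = 5.5823)),
    pde_safe = scenario("pde_safe", dimensionless_params(0.001, 0, 100),
                        mode = "pde",
                        init = list(type = "single", Xp = 5),
                        grid = grid_spec(0, 20, nx = 1024, dt = 5e-4,
                                         T_end = 0.1))
  )
}

# Analytic measurement frames for a single pulse / a pair.
#' @noRd
analytic_frames <- function(sc, points_per_unit = 1024) {
  p <- sc$params
  if (sc$init$type == "single") {
    qs <- quasi_soliton(params = p, Xp = sc$init$Xp,
                        direction = if (is.null(sc$init$direction))
                          "rightward" else sc$init$direction)
    T_end <- if (is.null(sc$grid$T_end)) 0.1 else sc$grid$T_end
    Ts <- seq(0, T_end, length.out = 11)
    reach <- qs$v * T_end
    X <- seq(sc$init$Xp - 6 - reach, sc$init$Xp + 6 + reach,
             by = 1 / points_per_unit)
    list(object = qs, times = Ts,
         frames = lapply(Ts, function(Tt) soliton_profile(qs, X, Tt)))
  } else {
    pair <- two_soliton(Xp1 = sc$init$Xp1, Xp2 = sc$init$Xp2, params = p)
    Ts <- seq(0, 2 * pair$T_cross, length.out = 41)   # symmetric about T_cross
    reach <- pair$v * max(Ts)
    X <- seq(sc$init$Xp1 - 8 - reach, sc$init$Xp2 + 8 + reach,
             by = 1 / points_per_unit)
    list(object = pair, times = Ts,
         frames = lapply(Ts, function(Tt)
           field_frame(X, Tt, predict(pair, X, Tt))))
  }
}

#' Run a scenario and write its artifact bundle
#'
#' Executes a scenario end to end and writes the requested artifacts to
#' `output_dir`: a config echo (`<name>_config.json`), a summary
#' (`<name>_summary.json`) with the closed-form velocity and amplitude
#' plus the measured slope / velocity estimate (and, for a pair, the
#' crossing time, single-peak detection and elasticity scores), the peak
#' track (`<name>_track.csv`), first/last profiles
#' (`<name>_profile.csv`), and optionally a density plot
#' (`<name>_density.png`).  All computation is deterministic, so repeated
#' runs produce byte-identical CSV/JSON artifacts.
#'
#' @param sc a `"cable_scenario"`.
#' @param output_dir output directory (created if missing).
#' @param points_per_unit measurement-grid density for analytic frames.
#' @return Invisibly, the summary list.
#' @export
run_scenario <- function(sc, output_dir, points_per_unit = 1024) {
  stopifnot(inherits(sc, "cable_scenario"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(suffix) file.path(output_dir, paste0(sc$name, suffix))
  p <- sc$params

  if (sc$mode == "analytic") {
    af <- analytic_frames(sc, points_per_unit)
    frames <- af$frames
    if (sc$init$type == "single") {
      qs <- af$object
      track <- track_peaks(frames)
      sv <- slope_velocity(track)
      summary <- list(scenario = sc$name, mode = sc$mode,
                      gamma = p$gamma, eta = p$eta, delta = p$delta,
                      v = qs$v, a0 = qs$a0,
                      slope = sv$slope, v_est = sv$v_est,
                      peak_X_first = track$peak_X[1],
                      peak_X_last = track$peak_X[nrow(track)])
    } else {
      pair <- af$object
      rep <- collision_elasticity(frames, pre_T = 0.25 * pair$T_cross,
                                  post_T = 1.75 * pair$T_cross,
                                  T_cross = pair$T_cross)
      track <- track_peaks(frames[1:3])   # pre-collision composite peak
      summary <- list(scenario = sc$name, mode = sc$mode,
                      gamma = p$gamma, eta = p$eta, delta = p$delta,
                      v = pair$v, a0 = pair$a0, T_cross = pair$T_cross,
                      single_peak = rep$single_peak,
                      single_peak_T_range = if (rep$single_peak)
                        range(rep$single_peak_times) else NULL,
                      reflection_diff = rep$reflection_diff,
                      elastic = rep$reflection_diff <= 1e-9)
    }
  } else {
    qs <- quasi_soliton(params = p, Xp = sc$init$Xp)
    sol <- simulate(qs, grid = sc$grid)
    frames <- sol$frames
    track <- track_peaks(sol)
    sv <- slope_velocity(track)
    summary <- list(scenario = sc$name, mode = sc$mode,
                    gamma = p$gamma, eta = p$eta, delta = p$delta,
                    v = qs$v, a0 = qs$a0,
                    slope = sv$slope, v_est = sv$v_est,
                    margin_min = min(sol$diagnostics$margin),
                    newton_iters_max = max(sol$diagnostics$newton_iters),
                    partial = sol$partial)
  }

  if ("summary" %in% sc$outputs)
    jsonlite::write_json(summary, path("_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(scenario_to_list(sc), path("_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if ("track" %in% sc$outputs)
    utils::write.csv(as.data.frame(unclass(track)), path("_track.csv"),
                     row.names = FALSE)
  if ("profile" %in% sc$outputs) {
    first <- frames[[1]]; last <- frames[[length(frames)]]
    prof <- rbind(data.frame(X = first$X, T = first$T, U = first$U),
                  data.frame(X = last$X, T = last$T, U = last$U))
    utils::write.csv(prof, path("_profile.csv"), row.names = FALSE)
  }
  if ("png" %in% sc$outputs) {
    grDevices::png(path("_density.png"), width = 900, height = 600)
    density_plot(frames, main = sc$name)
    grDevices::dev.off()
  }
  invisible(summary)
}

# Flat-list representation used for YAML/JSON round-tripping.
#' @noRd
scenario_to_list <- function(sc) {
  list(name = sc$name, mode = sc$mode,
       dimensionless = list(gamma = sc$params$gamma, kappa = sc$params$kappa,
                            eta = sc$params$eta, delta = sc$params$delta),
       init = sc$init,
       grid = if (is.null(sc$grid)) NULL else
         sc$grid[c("X_min", "X_max", "nx", "dt", "T_end", "bc")],
       outputs = sc$outputs)
}

#' Read and write scenario configurations
#'
#' Scenarios serialize to flat YAML (or JSON) key-value files; a
#' `dimensionless` block gives `(gamma, eta, delta)` directly.  The
#' round-trip `read_scenario(write_scenario(sc))` is lossless.
#'
#' @param sc a `"cable_scenario"`.
#' @param path file path; `.json` is written/parsed as JSON, anything
#'   else as YAML.
#' @return `read_scenario()`: a `"cable_scenario"`; `write_scenario()`:
#'   the path, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "cable_scenario"))
  x <- scenario_to_list(sc)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  if (is.null(x$name) || is.null(x$dimensionless))
    stop("malformed scenario config: needs 'name' and a 'dimensionless' block")
  d <- x$dimensionless
  if (is.null(d$gamma)) stop("malformed scenario config: 'gamma' missing")
  params <- dimensionless_params(gamma = d$gamma,
                                 eta = if (is.null(d$eta)) 0 else d$eta,
                                 delta = if (is.null(d$delta)) 0 else d$delta,
                                 kappa = if (is.null(d$kappa) || is.na(d$kappa))
                                   NA_real_ else d$kappa)
  grid <- if (!is.null(x$grid) && !is.null(x$grid$nx))
    grid_spec(x$grid$X_min, x$grid$X_max, x$grid$nx, x$grid$dt,
              x$grid$T_end, x$grid$bc)
  scenario(name = x$name, params = params,
           mode = if (is.null(x$mode)) "analytic" else x$mode,
           init = x$init, grid = grid,
           outputs = if (is.null(x$outputs))
             c("summary", "track", "profile") else x$outputs)
}

#' Read and write dimensional parameter files
#'
#' Dimensional constants serialize to flat YAML (or JSON) key-value
#' files keyed by the field names of [cable_params()].
#'
#' @param p a `"cable_params"` object.
#' @param path file path (`.json` for JSON, else YAML).
#' @return `read_params()`: a `"cable_params"`; `write_params()`: the
#'   path, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "cable_params"))
  x <- unclass(p)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  need <- c("r", "sigma", "rm", "cm")
  if (!all(need %in% names(x)))
    stop("malformed parameter file: needs ", paste(need, collapse = ", "))
  opt <- function(nm, default) if (is.null(x[[nm]])) default else x[[nm]]
  cable_params(r = x$r, sigma = x$sigma, rm = x$rm, cm = x$cm,
               alpha = opt("alpha", 0), gstar = opt("gstar", 0),
               a_carrier = opt("a_carrier", 0),
               b_carrier = opt("b_carrier", 0),
               Er = opt("Er", -139), eps0 = opt("eps0", 7e-12),
               epsr = opt("epsr", 81))
}
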