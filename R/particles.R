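# Lagrangian food-particle phase: drag law, equation of motion, reference
# R integrator (used as the oracle for the compiled tracker), and cohort
# tracking through a converged flow field.

#' Particle specification
#'
#' Passive food particles released at the inlet. The defaults (density
#' 1300 kg/m^3, diameter 50 nm) give a momentum response time of order
#' 1e-10 s, far below any flow time scale, so the particles behave as
#' tracers; a 50 micrometre override is provided since metrics are
#' insensitive to the choice.
#'
#' @param density particle density, kg/m^3
#' @param diameter particle diameter, m
#' @param n number of particles injected
#' @param seed random seed for injection positions
#' @return object of class `particle_spec`
#' @export
particle_spec <- function(density = 1300, diameter = 5e-8, n = 1000, seed = 1) {
  if (density <= 0 || diameter <= 0) stop("density and diameter must be positive")
  if (n < 1) stop("at least one particle is required")
  structure(list(density = density, diameter = diameter, n = as.integer(n),
                 seed = as.integer(seed)), class = "particle_spec")
}

#' Tracking configuration
#'
#' @param drag_law `"schiller_naumann"` (default) or `"stokes"`
#' @param body_force extra acceleration vector, m/s^2 (default none; use
#'   [gravity_preset()] for buoyancy-corrected gravity)
#' @param cfl maximum particle displacement per step, in cells
#' @param dt_max maximum time step, s
#' @param max_time maximum simulated time per particle, s
#' @param dt_out output sampling interval for speed/trajectory records, s
#' @param keep_paths number of particles whose full trajectory is stored
#' @return object of class `tracking_config`
#' @export
tracking_config <- function(drag_law = c("schiller_naumann", "stokes"),
                            body_force = c(0, 0, 0), cfl = 0.2, dt_max = 0.05,
                            max_time = 600, dt_out = 0.1, keep_paths = 20) {
  drag_law <- match.arg(drag_law)
  if (cfl <= 0 || dt_max <= 0 || max_time <= 0 || dt_out <= 0) {
    stop("cfl, dt_max, max_time and dt_out must be positive")
  }
  structure(list(drag_law = drag_law, body_force = as.numeric(body_force),
                 cfl = cfl, dt_max = dt_max, max_time = max_time,
                 dt_out = dt_out, keep_paths = as.integer(keep_paths)),
            class = "tracking_config")
}

#' Buoyancy-corrected gravitational acceleration
#'
#' `g (rho_p - rho) / rho_p` along the given direction: the net body force
#' per unit particle mass for a dense particle in fluid.
#'
#' @param spec a [particle_spec()]
#' @param fluid a [fluid_properties()]
#' @param direction unit vector of gravity
#' @param g gravitational acceleration, m/s^2
#' @return acceleration vector, m/s^2
#' @export
gravity_preset <- function(spec = particle_spec(), fluid = fluid_properties(),
                           direction = c(0, 0, -1), g = 9.81) {
  g * (spec$density - fluid$density) / spec$density * direction
}

#' Particle Reynolds number
#'
#' `Re = rho d_p |u_p - u| / mu`: the slip-velocity Reynolds number that
#' selects the drag regime.
#'
#' @param u fluid velocity (vector or n x 3 matrix), m/s
#' @param u_p particle velocity (same shape), m/s
#' @param spec a [particle_spec()]
#' @param fluid a [fluid_properties()]
#' @return nonnegative Reynolds number(s)
#' @export
particle_reynolds <- function(u, u_p, spec = particle_spec(),
                              fluid = fluid_properties()) {
  u <- matrix(as.numeric(u), ncol = 3)
  u_p <- matrix(as.numeric(u_p), ncol = 3)
  slip <- sqrt(rowSums((u_p - u)^2))
  fluid$density * spec$diameter * slip / fluid$viscosity
}

#' Drag coefficient
#'
#' Stokes law `C_D = 24/Re` or the Schiller-Naumann correlation
#' `C_D = (24/Re)(1 + 0.15 Re^0.687)`, valid to Re = 1000 (clamped above,
#' with a warning).
#'
#' @param Re particle Reynolds number(s), >= 0
#' @param law `"schiller_naumann"` or `"stokes"`
#' @return drag coefficient(s); `Inf` at Re = 0 (the drag *force* limit is
#'   finite: `C_D Re / 24 -> 1`)
#' @export
drag_coefficient <- function(Re, law = c("schiller_naumann", "stokes")) {
  law <- match.arg(law)
  if (any(Re < 0)) stop("Re must be nonnegative")
  if (any(Re > 1000)) {
    warning("particle Reynolds number above 1000: outside the drag ",
            "correlation; clamped")
    Re <- pmin(Re, 1000)
  }
  if (law == "stokes") 24 / Re else (24 / Re) * (1 + 0.15 * Re^0.687)
}

# drag relaxation rate F_D * (C_D Re / 24)  [1/s]
drag_rate <- function(u, u_p, spec, fluid, law) {
  base <- 18 * fluid$viscosity / (spec$density * spec$diameter^2)
  if (law == "stokes") return(rep(base, max(nrow(matrix(u, ncol = 3)), 1)))
  Re <- pmin(particle_reynolds(u, u_p, spec, fluid), 1000)
  base * (1 + 0.15 * Re^0.687)
}

#' Particle acceleration
#'
#' Right-hand side of the particle equation of motion: drag
#' `F_D (u - u_p)` (with `F_D = 18 mu / (rho_p d_p^2) * C_D Re / 24`) plus
#' the optional body force.
#'
#' @param u_p particle velocity, m/s (vector or n x 3)
#' @param u local fluid velocity, m/s
#' @param spec a [particle_spec()]
#' @param fluid a [fluid_properties()]
#' @param cfg a [tracking_config()]
#' @return acceleration (same shape as `u_p`), m/s^2
#' @export
particle_acceleration <- function(u_p, u, spec = particle_spec(),
                                  fluid = fluid_properties(),
                                  cfg = tracking_config()) {
  u <- matrix(as.numeric(u), ncol = 3)
  u_p <- matrix(as.numeric(u_p), ncol = 3)
  fd <- drag_rate(u, u_p, spec, fluid, cfg$drag_law)
  sweep(fd * (u - u_p), 2, cfg$body_force, "+")
}

#' One semi-implicit trapezoidal step of the particle motion
#'
#' Velocity update is implicit in the particle velocity and explicit in the
#' fluid velocity sampled at the old position (unconditionally stable for
#' the linear drag term); the position advances with the trapezoid of old
#' and new particle velocities. This is the reference R implementation used
#' to validate the compiled tracker.
#'
#' @param state list with `position` (m) and `velocity` (m/s)
#' @param dt time step, s
#' @param field a `flow_field` plus `mesh`, or a function `f(position)`
#'   returning the local fluid velocity
#' @param mesh the `volume_mesh` (when `field` is a `flow_field`)
#' @param spec,fluid,cfg particle setup
#' @return updated state
#' @export
step_trapezoidal <- function(state, dt, field, mesh = NULL,
                             spec = particle_spec(), fluid = fluid_properties(),
                             cfg = tracking_config()) {
  if (dt <= 0) stop("dt must be positive")
  u <- if (is.function(field)) field(state$position)
       else interpolate_velocity(field, mesh, rbind(state$position))
  u <- as.numeric(u)
  fd <- drag_rate(rbind(u), rbind(state$velocity), spec, fluid, cfg$drag_law)
  a <- fd * dt / 2
  v_new <- (state$velocity * (1 - a) + dt * (fd * u + cfg$body_force)) / (1 + a)
  list(position = state$position + dt / 2 * (state$velocity + v_new),
       velocity = v_new)
}

#' Specular elastic reflection
#'
#' Reverses the wall-normal velocity component, preserving speed and the
#' tangential components exactly.
#'
#' @param velocity velocity vector, m/s
#' @param normal unit wall normal
#' @return reflected velocity
#' @export
reflect_velocity <- function(velocity, normal) {
  normal <- normal / sqrt(sum(normal^2))
  velocity - 2 * sum(velocity * normal) * normal
}

#' Track a particle cohort through a converged flow field
#'
#' Injects `spec$n` particles uniformly over the inlet disc (deterministic
#' for a given seed), initialized at the local fluid velocity, and
#' integrates the drag equation of motion with the semi-implicit trapezoidal
#' rule. Walls reflect elastically; the inlet and outlet planes are escape
#' boundaries. Instantaneous speeds are sampled on a uniform `dt_out` grid.
#'
#' @param field a converged `flow_field`
#' @param mesh the `volume_mesh` it was solved on
#' @param spec a [particle_spec()]
#' @param cfg a [tracking_config()]
#' @param fluid a [fluid_properties()]
#' @return object of class `particle_cohort`: a tibble `summary` (id,
#'   status, retention_time s, mean_speed m/s, n_samples) plus stored
#'   trajectories for the first `cfg$keep_paths` particles
#' @export
track_cohort <- function(field, mesh, spec = particle_spec(),
                         cfg = tracking_config(), fluid = fluid_properties()) {
  if (!field$converged) stop("flow field is not converged; refusing to track")
  lm <- mesh$geom$landmarks$inlet
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  # uniform sampling over the inlet disc, just inside the inlet plane;
  # positions falling into solid stair-step cells at the disc rim are
  # resampled so every particle starts inside the discrete lumen
  z0 <- (mesh$origin[3] + mesh$dims[3] * mesh$h) / 1000 - 0.3 * field$h_m
  d <- mesh$dims
  sample_disc <- function(n) {
    r <- (lm$radius / 1000) * sqrt(stats::runif(n)) * 0.98
    th <- stats::runif(n, 0, 2 * pi)
    cbind(lm$center[1] / 1000 + r * cos(th),
          lm$center[2] / 1000 + r * sin(th), z0)
  }
  in_lumen <- function(p) {
    i <- floor((p[, 1] * 1000 - mesh$origin[1]) / mesh$h) + 1
    j <- floor((p[, 2] * 1000 - mesh$origin[2]) / mesh$h) + 1
    k <- floor((p[, 3] * 1000 - mesh$origin[3]) / mesh$h) + 1
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    ok[ok] <- mesh$mask[cbind(i[ok], j[ok], k[ok])]
    ok
  }
  pts0 <- sample_disc(spec$n)
  for (round in 1:100) {
    bad <- !in_lumen(pts0)
    if (!any(bad)) break
    pts0[bad, ] <- sample_disc(sum(bad))
  }
  if (any(!in_lumen(pts0))) stop("inlet disc not resolved: cannot place particles")
  up0 <- interp_velocity_cpp(as.integer(mesh$dims), field$h_m, field$origin_m,
                             as.integer(mesh$mask), field$u, field$v, field$w, pts0)
  law <- if (cfg$drag_law == "stokes") 0L else 1L
  res <- track_cohort_cpp(as.integer(mesh$dims), field$h_m, field$origin_m,
                          as.integer(mesh$mask), field$u, field$v, field$w,
                          pts0, up0, fluid$density, fluid$viscosity,
                          spec$density, spec$diameter, law,
                          cfg$body_force, cfg$cfl, cfg$dt_max, cfg$max_time,
                          cfg$dt_out, cfg$keep_paths)
  status <- factor(c("TIMED_OUT", "ESCAPED_OUTLET", "ESCAPED_INLET")[res$status + 1L],
                   levels = c("ESCAPED_OUTLET", "ESCAPED_INLET", "TIMED_OUT"))
  n_timed <- sum(status == "TIMED_OUT")
  if (n_timed > 0.1 * spec$n) {
    warning(n_timed, " of ", spec$n, " particles timed out before escaping; ",
            "consider raising max_time (currently ", cfg$max_time, " s)")
  }
  out <- list(summary = tibble::tibble(id = seq_len(spec$n), status = status,
                                       retention_time = res$retention,
                                       mean_speed = res$mean_speed,
                                       n_samples = res$n_samples),
              paths = res$paths, spec = spec, cfg = cfg)
  class(out) <- "particle_cohort"
  out
}

#' @export
print.particle_cohort <- function(x, ...) {
  s <- x$summary
  esc <- s$status == "ESCAPED_OUTLET"
  cat("Particle cohort:", nrow(s), "injected;", sum(esc), "escaped via outlet,",
      sum(s$status == "ESCAPED_INLET"), "via inlet,",
      sum(s$status == "TIMED_OUT"), "timed out\n")
  if (any(esc)) {
    cat(sprintf("  mean retention %.1f s, mean speed %.1f mm/s (escaped particles)\n",
                mean(s$retention_time[esc]), 1000 * mean(s$mean_speed[esc])))
  }
  invisible(x)
}
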