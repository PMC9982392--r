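# Shared fixtures: heavy solves are computed once per test run and reused
# across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Poiseuille validation tube at 2 mm cells with fully developed inflow
poiseuille_case <- function() {
  cached("poiseuille2", {
    geom <- tube_geometry(12, 100)
    mesh <- discretize(geom, 2)
    field <- solve_steady(mesh, bc = boundary_conditions(0.04, "parabolic"))
    list(geom = geom, mesh = mesh, field = field)
  })
}

# finer tube used for the pressure-gradient accuracy gate
poiseuille_fine_case <- function() {
  cached("poiseuille15", {
    geom <- tube_geometry(12, 100)
    mesh <- discretize(geom, 1.5)
    field <- solve_steady(mesh, bc = boundary_conditions(0.04, "parabolic"))
    list(geom = geom, mesh = mesh, field = field)
  })
}

# analytic Hagen-Poiseuille pressure gradient for the validation tube, Pa/m
poiseuille_gradient <- function(U = 0.04, R = 0.012, mu = 0.001003) {
  Q <- U * pi * R^2
  8 * mu * Q / (pi * R^4)
}

# measured axial pressure gradient (Pa/m) over the tube interior
measured_gradient <- function(case, zmin = -90, zmax = -10) {
  cc <- cell_centers(case$mesh)
  sel <- cc[, 3] > zmin & cc[, 3] < zmax
  p <- case$field$p[case$mesh$cellidx][sel]
  unname(stats::coef(stats::lm(p ~ cc[sel, 3]))[2]) * 1000
}

# coarse CGJ/SPGJ pair with tracked cohorts (acceptance-scale comparison)
anatomy_pair <- function() {
  cached("pair5", {
    out <- list()
    for (variant in c("CGJ", "SPGJ")) {
      geom <- build_lumen(anatomy_params(), variant)
      mesh <- discretize(geom, 5)
      field <- solve_steady(mesh, cfg = solver_config(max_iter = 10000))
      cohort <- track_cohort(field, mesh, particle_spec(n = 1000, seed = 11),
                             tracking_config())
      out[[variant]] <- model_result(variant, field, mesh, cohort)
    }
    out
  })
}

# a minimal synthetic model_result for pure-arithmetic report tests
fake_result <- function(variant, pyl, anast, dp, ret, spd, qin = pyl + anast) {
  structure(list(variant = variant, pyloric_flux = pyl, anastomotic_flux = anast,
                 inlet_flux = qin, flux_closure = 0, pressure_drop = dp,
                 mean_retention = ret, mean_speed = spd, n_escaped = 100),
            class = "model_result")
}

# independent RK4 streamline integrator (transit-time oracle for the tracer
# limit): integrates dx/dt = u(x) until the outlet plane is crossed
streamline_transit <- function(field, mesh, start, dt = 0.01, tmax = 300) {
  x <- as.numeric(start)
  z_out <- mesh$origin[3] / 1000
  t <- 0
  vel <- function(p) as.numeric(interpolate_velocity(field, mesh, rbind(p)))
  while (t < tmax) {
    k1 <- vel(x)
    k2 <- tryCatch(vel(x + dt / 2 * k1), error = function(e) k1)
    k3 <- tryCatch(vel(x + dt / 2 * k2), error = function(e) k2)
    k4 <- tryCatch(vel(x + dt * k3), error = function(e) k3)
    step <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (x[3] + step[3] < z_out + 1e-9) {
      frac <- (x[3] - (z_out + 1e-9)) / max(-step[3], 1e-300)
      return(t + frac * dt)
    }
    x <- x + step
    t <- t + dt
  }
  NA_real_
}
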