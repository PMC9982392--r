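# Discrete-phase physics: drag correlation, equation of motion, trapezoidal
# integrator, elastic boundaries, cohort contracts.

test_that("particle Reynolds number follows its definition", {
  expect_equal(particle_reynolds(c(0.01, 0, 0), c(0.01, 0, 0)), 0)
  # slip 0.01 m/s at default properties
  Re <- particle_reynolds(c(0, 0, 0), c(0.01, 0, 0))
  expect_equal(Re, 998.2 * 5e-8 * 0.01 / 0.001003, tolerance = 1e-12)
  expect_equal(Re, 4.98e-4, tolerance = 0.01)
  # linear in diameter
  Re2 <- particle_reynolds(c(0, 0, 0), c(0.01, 0, 0),
                           particle_spec(diameter = 1e-7))
  expect_equal(Re2, 2 * Re)
})

test_that("drag coefficient matches Stokes and Schiller-Naumann forms", {
  # Stokes limit: C_D Re / 24 -> 1
  for (Re in c(1e-6, 1e-4, 1e-3)) {
    expect_equal(drag_coefficient(Re) * Re / 24, 1, tolerance = 2e-3)
  }
  expect_equal(drag_coefficient(1), 24 * 1.15, tolerance = 1e-12)
  expect_equal(drag_coefficient(10), (24 / 10) * (1 + 0.15 * 10^0.687),
               tolerance = 1e-12)
  expect_equal(drag_coefficient(10), 4.15, tolerance = 0.01)
  expect_equal(drag_coefficient(5, law = "stokes"), 24 / 5)
  expect_warning(drag_coefficient(2000), "1000")
})

test_that("acceleration obeys the drag equation of motion", {
  # equilibrium: zero slip, no body force
  a0 <- particle_acceleration(c(0.02, 0, 0), c(0.02, 0, 0))
  expect_equal(as.numeric(a0), c(0, 0, 0))
  # Stokes-limit relaxation rate 18 mu / (rho_p d_p^2)
  fd <- 18 * 0.001003 / (1300 * (5e-8)^2)
  expect_equal(fd, 5.55e9, tolerance = 0.01)
  a <- particle_acceleration(c(0, 0, 0), c(0.01, 0, 0))
  expect_equal(a[1], fd * 0.01, tolerance = 1e-3)
  # terminal settling velocity matches the Stokes closed form within 1%
  vt <- 9.81 * (1300 - 998.2) * (5e-8)^2 / (18 * 0.001003)
  cfg <- tracking_config(body_force = gravity_preset(), drag_law = "stokes")
  st <- list(position = c(0, 0, 0), velocity = c(0, 0, 0))
  still <- function(p) c(0, 0, 0)
  for (i in 1:60) st <- step_trapezoidal(st, 2e-11, still, cfg = cfg)
  expect_equal(-st$velocity[3], vt, tolerance = 0.01)
})

test_that("trapezoidal integration matches the linear-drag closed form within 1%", {
  fd <- 18 * 0.001003 / (1300 * (5e-8)^2)
  dt <- 0.1 / fd
  cfg <- tracking_config(drag_law = "stokes")
  still <- function(p) c(0, 0, 0)
  st <- list(position = c(0, 0, 0), velocity = c(0.03, 0, 0))
  speeds <- numeric(25)
  for (i in 1:25) {
    st <- step_trapezoidal(st, dt, still, cfg = cfg)
    speeds[i] <- st$velocity[1]
  }
  expect_true(all(diff(abs(speeds)) < 0))  # monotone decay
  expect_equal(speeds, 0.03 * exp(-fd * dt * (1:25)), tolerance = 0.01)
})

test_that("uniform flow advects an equilibrated particle in a straight line", {
  u0 <- c(0.01, -0.02, 0.005)
  field <- function(p) u0
  st <- list(position = c(0, 0, 0), velocity = u0)
  for (i in 1:20) st <- step_trapezoidal(st, 0.01, field)
  expect_equal(st$position, u0 * 0.2, tolerance = 1e-9)
  expect_equal(st$velocity, u0, tolerance = 1e-12)
})

test_that("halving dt reduces the position error at second order", {
  # drag-driven relaxation in still fluid: the trapezoid of the linear drag
  # term is second-order accurate, so the final position converges as dt^2
  spec <- particle_spec(density = 1300, diameter = 2e-4)
  still <- function(p) c(0, 0, 0)
  final_pos <- function(dt) {
    st <- list(position = c(0, 0, 0), velocity = c(0.03, 0, 0))
    for (i in seq_len(round(0.02 / dt))) {
      st <- step_trapezoidal(st, dt, still, spec = spec,
                             cfg = tracking_config(drag_law = "stokes"))
    }
    st$position[1]
  }
  ref <- final_pos(2.5e-5)
  e1 <- abs(final_pos(4e-4) - ref)
  e2 <- abs(final_pos(2e-4) - ref)
  expect_lt(e2 / e1, 0.35)   # ~1/4 for a second-order scheme
})

test_that("elastic reflection preserves speed and tangential velocity", {
  v <- c(0.02, -0.01, 0.005)
  r <- reflect_velocity(v, c(0, 0, 1))
  expect_equal(r, c(0.02, -0.01, -0.005))
  expect_equal(sqrt(sum(r^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  # grazing incidence: tangential components exactly preserved
  g <- reflect_velocity(c(0.03, 0.001, -1e-6), c(0, 0, 1))
  expect_identical(g[1:2], c(0.03, 0.001))
})

test_that("plug flow transits the tube in L/v and cohorts are deterministic", {
  m <- discretize(tube_geometry(12, 100), 2)
  f <- solve_steady(m, bc = boundary_conditions(0))
  f$w[, , ] <- -0.04; f$converged <- TRUE
  co <- track_cohort(f, m, particle_spec(n = 150, seed = 7),
                     tracking_config(max_time = 10, dt_out = 0.02))
  s <- co$summary
  expect_equal(sum(s$status == "ESCAPED_OUTLET") + sum(s$status == "TIMED_OUT") +
               sum(s$status == "ESCAPED_INLET"), 150L)  # count conservation
  expect_true(all(s$status == "ESCAPED_OUTLET"))
  expect_equal(mean(s$retention_time), 2.5, tolerance = 0.01)
  expect_equal(1000 * mean(s$mean_speed), 40, tolerance = 0.01)
  co2 <- track_cohort(f, m, particle_spec(n = 150, seed = 7),
                      tracking_config(max_time = 10, dt_out = 0.02))
  expect_identical(co$summary, co2$summary)
})

test_that("the fastest Poiseuille particle rides the centerline peak", {
  case <- poiseuille_case()
  co <- track_cohort(case$field, case$mesh, particle_spec(n = 300, seed = 3),
                     tracking_config(max_time = 120, dt_out = 0.02))
  s <- co$summary
  esc <- s$status == "ESCAPED_OUTLET"
  expect_gt(mean(esc), 0.95)
  # axis transit time L / (2 u_mean)
  expect_equal(min(s$retention_time[esc]), 0.1 / 0.08, tolerance = 0.05)
})
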