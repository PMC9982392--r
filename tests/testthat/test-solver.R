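# Steady flow solver: null forcing, Hagen-Poiseuille oracle, interpolation
# contracts, conservation, and Stokes-regime linearity.

test_that("zero inflow yields a quiescent field with uniform pressure", {
  m <- discretize(tube_geometry(8, 40), 2)
  f <- solve_steady(m, bc = boundary_conditions(0))
  expect_true(f$converged)
  expect_equal(max(abs(f$cell_velocity)), 0)
  expect_equal(diff(range(f$p)), 0)
  expect_equal(pressure_drop(f, m), 0)
})

test_that("the laminar-regime guard refuses transitional Reynolds numbers", {
  m <- discretize(tube_geometry(12, 40), 3)
  expect_error(solve_steady(m, bc = boundary_conditions(0.12)), "Reynolds")
})

test_that("Poiseuille tube reproduces the analytic pressure gradient and peak", {
  case <- poiseuille_fine_case()
  expect_true(case$field$converged)
  grad <- measured_gradient(case)
  expect_lt(abs(grad / poiseuille_gradient() - 1), 0.03)
  # centerline peak = 2 x mean velocity
  v <- interpolate_velocity(case$field, case$mesh, cbind(0, 0, -0.05))
  expect_lt(abs(-v[3] / 0.08 - 1), 0.03)
  # end-to-end pressure drop matches gradient x length
  dp <- pressure_drop(case$field, case$mesh)
  expect_lt(abs(dp / (poiseuille_gradient() * 0.1) - 1), 0.03)
})

test_that("global mass balance closes to 0.1 percent", {
  case <- poiseuille_case()
  expect_lt(case$field$mass_imbalance, 0.001)
  # any full cut of the tube carries the inlet flow
  m <- case$mesh
  sec <- gastroflow:::section_faces(m, c(0, 0, -50), c(0, 0, -1), 20)
  m2 <- m; m2$face_sets$MID <- sec
  q <- cross_section_flux(case$field, m2, "MID")
  expect_equal(q, case$field$Q_in, tolerance = 0.001)
})

test_that("velocity interpolation honors its exactness contracts", {
  case <- poiseuille_case()
  m <- case$mesh; f <- case$field
  # at a cell centroid: exactly the stored cell-centered velocity
  idx <- round(length(m$cellidx) / 2)
  ctr <- cell_centers(m, m$cellidx[idx]) / 1000
  v <- interpolate_velocity(f, m, ctr)
  expect_equal(as.numeric(v), as.numeric(f$cell_velocity[idx, ]), tolerance = 1e-12)
  # a constant synthetic field is reproduced at arbitrary interior points
  fc <- f
  fc$u[, , ] <- 0.011; fc$v[, , ] <- -0.007; fc$w[, , ] <- 0.003
  set.seed(4)
  pts <- cbind(stats::runif(20, -0.004, 0.004), stats::runif(20, -0.004, 0.004),
               stats::runif(20, -0.08, -0.02))
  vv <- interpolate_velocity(fc, m, pts)
  expect_equal(vv, matrix(rep(c(0.011, -0.007, 0.003), each = 20), ncol = 3),
               tolerance = 1e-12)
  # out-of-lumen points are refused with a wall distance
  expect_error(interpolate_velocity(f, m, cbind(0.05, 0.05, -0.05)), "outside")
})

test_that("doubling viscosity doubles the pressure drop in the Stokes regime", {
  geom <- tube_geometry(8, 60)
  mesh <- discretize(geom, 2)
  bc <- boundary_conditions(0.004, "parabolic")
  f1 <- solve_steady(mesh, fluid_properties(998.2, 0.001003), bc)
  f2 <- solve_steady(mesh, fluid_properties(998.2, 0.002006), bc)
  r <- pressure_drop(f2, mesh) / pressure_drop(f1, mesh)
  expect_lt(abs(r / 2 - 1), 0.05)
})

test_that("identical mesh sizes give zero field difference", {
  mi <- mesh_independence_check(tube_geometry(8, 40), 2, 2,
                                bc = boundary_conditions(0.01, "parabolic"))
  expect_equal(mi$difference, 0)
  expect_true(mi$pass)
})

test_that("pressure drop is positive for nonzero inflow through the anatomy", {
  pair <- anatomy_pair()
  expect_gt(pair$CGJ$pressure_drop, 0)
  expect_gt(pair$SPGJ$pressure_drop, 0)
})
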