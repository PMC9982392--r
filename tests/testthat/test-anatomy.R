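# Parametric lumen construction, virtual surgery, voxel discretization and
# surface export.

test_that("parameter validation names the offending field", {
  expect_error(anatomy_params(esophagus_length = -5), "esophagus_length")
  expect_error(anatomy_params(stenosis_factor = 0), "stenosis_factor")
  expect_error(anatomy_params(stenosis_factor = 1.2), "stenosis_factor")
  expect_error(anatomy_params(anastomosis_length = 400,
                              duodenojejunal_path_length = 350),
               "anastomosis_length")
  expect_error(build_lumen(anatomy_params(partition_channel_width = 80), "SPGJ"),
               "partition_channel_width")
})

test_that("CGJ carries no partition; SPGJ carries the printed channel", {
  cgj <- build_lumen(anatomy_params(), "CGJ")
  expect_false("partition" %in% names(cgj$landmarks))
  expect_null(cgj$partition)
  spgj <- build_lumen(anatomy_params(), "SPGJ")
  expect_true("partition" %in% names(spgj$landmarks))
  expect_equal(measure_partition_channel(spgj), 20, tolerance = 0.02)
  # configurable within the surgical 20-30 mm range
  wide <- build_lumen(anatomy_params(partition_channel_width = 28), "SPGJ")
  expect_equal(measure_partition_channel(wide), 28, tolerance = 0.02)
})

test_that("anastomotic opening length follows the parameter", {
  for (L in c(45, 50)) {
    g <- build_lumen(anatomy_params(anastomosis_length = L), "CGJ")
    expect_equal(measure_anastomosis_opening(g), L, tolerance = 0.01)
  }
})

test_that("variants are identical outside the partition neighborhood", {
  cgj <- build_lumen(anatomy_params(), "CGJ")
  spgj <- build_lumen(anatomy_params(), "SPGJ")
  set.seed(1)
  P <- cbind(stats::runif(6000, -80, 170), stats::runif(6000, -45, 55),
             stats::runif(6000, -420, 5))
  part <- spgj$partition
  dn <- abs((P[, 1] - part$q[1]) * part$n[1] + (P[, 3] - part$q[3]) * part$n[3])
  dc <- sqrt((P[, 1] - part$q[1])^2 + (P[, 2] - part$q[2])^2 +
             (P[, 3] - part$q[3])^2)
  far <- dn > part$thickness / 2 + 8 | dc > part$ball + 12
  expect_identical(sign(sdf_eval(spgj, P[far, ])), sign(sdf_eval(cgj, P[far, ])))
})

test_that("voxel volumes match exact references", {
  cube <- discretize(box_geometry(10), 1)
  expect_equal(cube$volume, 1000, tolerance = 0.01)
  cyl <- discretize(tube_geometry(12, 100), 1)
  expect_equal(cyl$volume, pi * 12^2 * 100, tolerance = 0.02)
  expect_equal(cell_closure_defect(cyl), 0)
})

test_that("voxel volume error against the analytic cylinder shrinks with refinement", {
  vol <- pi * 12^2 * 100
  e3 <- abs(discretize(tube_geometry(12, 100), 3)$volume - vol) / vol
  e1 <- abs(discretize(tube_geometry(12, 100), 1)$volume - vol) / vol
  expect_lt(e1, e3)
  expect_lt(e1, 0.02)
})

test_that("anatomy mesh volume agrees with the surface-integrated volume", {
  g <- build_lumen(anatomy_params(), "CGJ")
  vref <- surface_volume(lumen_surface(g, 1.5))
  m <- discretize(g, 4)
  expect_lt(abs(m$volume - vref) / vref, 0.05)
})

test_that("cross-section face sets are present, disjoint and separating", {
  g <- build_lumen(anatomy_params(), "SPGJ")
  m <- discretize(g, 5)
  pyl <- m$face_sets$PYLORUS
  ana <- m$face_sets$ANASTOMOSIS
  expect_gt(nrow(pyl), 0)
  expect_gt(nrow(ana), 0)
  key <- function(fs) paste(fs[, "ilo"], fs[, "axis"])
  expect_length(intersect(key(pyl), key(ana)), 0)
  # two inlet-outlet routes: blocking either cut leaves the tract connected,
  # blocking both disconnects it
  expect_true(lumen_connected(m))
  expect_true(lumen_connected(m, "PYLORUS"))
  expect_true(lumen_connected(m, "ANASTOMOSIS"))
  expect_false(lumen_connected(m, c("PYLORUS", "ANASTOMOSIS")))
})

test_that("discretize refuses cell sizes above the narrowest channel", {
  g <- build_lumen(anatomy_params(), "CGJ")
  expect_error(discretize(g, 16), "pyloric")
  expect_error(discretize(g, -1), "positive")
})

test_that("surface export round-trips through STL", {
  surf <- lumen_surface(box_geometry(10))
  expect_equal(nrow(surf$v1), 12)       # exact box triangulation
  expect_equal(surface_volume(surf), 1000)
  expect_true(surface_is_watertight(surf))
  path <- tempfile(fileext = ".stl")
  g <- tube_geometry(8, 40)
  export_surface(g, path, cell_size = 2)
  back <- import_surface(path)
  fwd <- lumen_surface(g, cell_size = 2)
  expect_equal(surface_volume(back), surface_volume(fwd), tolerance = 1e-9)
  expect_true(surface_is_watertight(back))
  expect_equal(sort(as.numeric(back$v1)), sort(as.numeric(fwd$v1)),
               tolerance = 1e-9)
})

test_that("CGJ anatomy surface is closed and watertight", {
  g <- build_lumen(anatomy_params(), "CGJ")
  surf <- lumen_surface(g, 4)
  expect_true(surface_is_watertight(surf))
  expect_gt(nrow(surf$v1), 0)
})

test_that("geometry serialization reproduces landmarks exactly", {
  g <- build_lumen(anatomy_params(bowel_inner_diameter = 24), "SPGJ")
  path <- tempfile(fileext = ".json")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2$landmarks, g$landmarks, tolerance = 1e-9)
  expect_equal(g2$variant, "SPGJ")
})
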