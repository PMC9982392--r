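# Steady incompressible laminar flow of gastric contents (modeled as water)
# through the discretized lumen: R-side configuration, wall-distance
# precomputation from the implicit geometry, and wrappers around the
# compiled SIMPLE solver.

#' Fluid properties
#'
#' Gastric contents are modeled as water at body-ish conditions.
#'
#' @param density fluid density, kg/m^3
#' @param viscosity dynamic viscosity, kg/(m s)
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(density = 998.2, viscosity = 0.001003) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary conditions
#'
#' A steady uniform (or fully developed parabolic) inflow is imposed on the
#' inlet disc; the outlet is traction-free (zero gauge pressure, zero normal
#' velocity gradient); all walls are rigid and no-slip. The discrete inlet
#' profile is rescaled so the imposed volumetric inflow equals
#' `inlet_velocity` times the nominal inlet disc area regardless of the
#' stair-step rasterization of the disc.
#'
#' @param inlet_velocity mean inlet speed, m/s
#' @param profile `"uniform"` (plug) or `"parabolic"` (fully developed;
#'   used for straight-tube validation)
#' @return object of class `boundary_conditions`
#' @export
boundary_conditions <- function(inlet_velocity = 0.04,
                                profile = c("uniform", "parabolic")) {
  if (inlet_velocity < 0) stop("inlet_velocity must be nonnegative")
  structure(list(inlet_velocity = inlet_velocity, profile = match.arg(profile)),
            class = "boundary_conditions")
}

#' Solver configuration
#'
#' SIMPLE pressure-velocity coupling on the staggered voxel grid; momentum
#' convection is first-order upwind for the first
#' `first_order_iters` outer iterations and deferred-correction second-order
#' upwind afterwards. Convergence requires all scaled residuals (momentum
#' components and continuity, normalized by their largest early-iteration
#' values) to fall below `tol`.
#'
#' @param tol scaled-residual convergence criterion
#' @param max_iter maximum outer iterations
#' @param alpha_u velocity under-relaxation in (0, 1]
#' @param alpha_p pressure under-relaxation in (0, 1]
#' @param scheme `"second_order_upwind"` or `"upwind"` for momentum
#' @param first_order_iters initial iterations run first-order for stability
#' @param sweeps Gauss-Seidel sweeps per momentum solve
#' @return object of class `solver_config`
#' @export
solver_config <- function(tol = 1e-5, max_iter = 20000,
                          alpha_u = 0.5, alpha_p = 0.2,
                          scheme = c("second_order_upwind", "upwind"),
                          first_order_iters = 150, sweeps = 3) {
  scheme <- match.arg(scheme)
  if (alpha_u <= 0 || alpha_u > 1 || alpha_p <= 0 || alpha_p > 1) {
    stop("under-relaxation factors must lie in (0, 1]")
  }
  if (tol <= 0) stop("tol must be positive")
  structure(list(tol = tol, max_iter = as.integer(max_iter), alpha_u = alpha_u,
                 alpha_p = alpha_p, scheme = scheme,
                 first_order_iters = as.integer(first_order_iters),
                 sweeps = as.integer(sweeps)), class = "solver_config")
}

# staggered activity masks for one component axis (R arrays of logicals)
staggered_active <- function(mask, axis) {
  d <- dim(mask)
  dd <- d; dd[axis] <- d[axis] + 1L
  act <- array(FALSE, dd)
  exist <- array(FALSE, dd)
  # shifted occupancy: act at face i (between cell i-1 and i)
  if (axis == 1) {
    act[2:d[1], , ] <- mask[1:(d[1] - 1), , ] & mask[2:d[1], , ]
    exist[2:d[1], , ] <- mask[1:(d[1] - 1), , ] | mask[2:d[1], , ]
    exist[1, , ] <- mask[1, , ]; exist[d[1] + 1, , ] <- mask[d[1], , ]
  } else if (axis == 2) {
    act[, 2:d[2], ] <- mask[, 1:(d[2] - 1), ] & mask[, 2:d[2], ]
    exist[, 2:d[2], ] <- mask[, 1:(d[2] - 1), ] | mask[, 2:d[2], ]
    exist[, 1, ] <- mask[, 1, ]; exist[, d[2] + 1, ] <- mask[, d[2], ]
  } else {
    act[, , 2:d[3]] <- mask[, , 1:(d[3] - 1)] & mask[, , 2:d[3]]
    exist[, , 2:d[3]] <- mask[, , 1:(d[3] - 1)] | mask[, , 2:d[3]]
    exist[, , 1] <- mask[, , 1]; exist[, , d[3] + 1] <- mask[, , d[3]]
  }
  list(act = act, exist = exist)
}

# wall distances for the lateral diffusion links of one velocity component:
# for every active face whose lateral neighbor slot is empty, the distance
# (m) from the face point to the lumen wall along that grid line, found by
# bisecting the implicit geometry; Inf marks the outlet plane (zero
# gradient). Returned concatenated in the solver's slot order.
component_wall_dists <- function(mesh, axis) {
  d <- mesh$dims; h <- mesh$h
  sa <- staggered_active(mesh$mask, axis)
  act <- sa$act
  dd <- dim(act)
  lat_axes <- setdiff(1:3, axis)
  # face-point coordinates (mm)
  coord <- function(lin) {
    i <- (lin - 1L) %% dd[1]
    j <- ((lin - 1L) %/% dd[1]) %% dd[2]
    k <- (lin - 1L) %/% (dd[1] * dd[2])
    off <- c(0.5, 0.5, 0.5); off[axis] <- 0
    cbind(mesh$origin[1] + (i + off[1]) * h,
          mesh$origin[2] + (j + off[2]) * h,
          mesh$origin[3] + (k + off[3]) * h)
  }
  n <- prod(dd)
  out <- numeric(0)
  for (lat in lat_axes) {
    for (dir in c(-1L, 1L)) {
      dist <- rep(NA_real_, n)      # only read where needed
      # need a wall distance wherever the lateral neighbor is not an active
      # unknown: either no slot at all (both cells solid) or a staircase
      # wall face (one cell solid)
      nb_act <- array(FALSE, dd)
      if (lat == 1) {
        if (dir > 0) nb_act[1:(dd[1] - 1), , ] <- act[2:dd[1], , ]
        else nb_act[2:dd[1], , ] <- act[1:(dd[1] - 1), , ]
      } else if (lat == 2) {
        if (dir > 0) nb_act[, 1:(dd[2] - 1), ] <- act[, 2:dd[2], ]
        else nb_act[, 2:dd[2], ] <- act[, 1:(dd[2] - 1), ]
      } else {
        if (dir > 0) nb_act[, , 1:(dd[3] - 1)] <- act[, , 2:dd[3]]
        else nb_act[, , 2:dd[3]] <- act[, , 1:(dd[3] - 1)]
      }
      need <- which(act & !nb_act)
      if (length(need)) {
        P0 <- coord(need)
        dv <- c(0, 0, 0); dv[lat] <- dir
        tc <- sdf_line_crossing(mesh$geom, P0, dv, 1.6 * h)
        tc[is.na(tc)] <- 0.75 * h
        dist[need] <- pmin(pmax(tc, 0.05 * h), 1.6 * h) / 1000  # -> m
      }
      # port planes: tangential faces see the inlet plane as a no-slip
      # Dirichlet at h/2 and the outlet plane as zero-gradient
      if (lat == 3 && mesh$has_ports && axis != 3) {
        kk <- (seq_len(n) - 1L) %/% (dd[1] * dd[2]) + 1L
        if (dir > 0) dist[kk == dd[3]] <- 0.5 * h / 1000
        else dist[kk == 1L] <- Inf
      }
      dist[is.na(dist)] <- 0.5 * h / 1000
      out <- c(out, dist)
    }
  }
  out
}

# inlet face values of w (m/s, negative = downward inflow), rescaled so the
# discrete flux matches inlet_velocity * nominal disc area
inlet_profile <- function(mesh, bc) {
  d <- mesh$dims; h <- mesh$h
  lm <- mesh$geom$landmarks$inlet
  top <- mesh$mask[, , d[3]]
  iw <- which(top)
  i <- (iw - 1L) %% d[1]; j <- (iw - 1L) %/% d[1]
  xc <- mesh$origin[1] + (i + 0.5) * h
  yc <- mesh$origin[2] + (j + 0.5) * h
  r2 <- ((xc - lm$center[1])^2 + (yc - lm$center[2])^2) / lm$radius^2
  val <- if (bc$profile == "parabolic") 2 * pmax(1 - r2, 0) else rep(1, length(iw))
  A_face <- (h / 1000)^2
  Q_target <- bc$inlet_velocity * pi * (lm$radius / 1000)^2
  q_raw <- sum(val) * A_face
  if (q_raw <= 0) stop("inlet disc not resolved on the mesh")
  wvals <- rep(0, d[1] * d[2])
  wvals[iw] <- -val * (Q_target / q_raw)
  wvals
}

#' Solve steady incompressible flow through the lumen
#'
#' Finite-volume SIMPLE solution of the steady incompressible Navier-Stokes
#' equations (laminar, Newtonian) on the voxel mesh, with fixed inflow,
#' traction-free outflow and no-slip rigid walls. Convergence requires all
#' scaled residuals below `cfg$tol`; the configuration Reynolds number
#' (rho U D / mu on the inlet diameter) must stay in the laminar regime.
#'
#' @param mesh a `volume_mesh` with inlet/outlet ports
#' @param fluid a [fluid_properties()]
#' @param bc a [boundary_conditions()]
#' @param cfg a [solver_config()]
#' @param verbose print residual progress
#' @return object of class `flow_field`: staggered face velocities (m/s),
#'   cell pressures (Pa, gauge, outlet mean = 0), cell-centered velocities,
#'   residual history, and global mass-balance diagnostics
#' @export
solve_steady <- function(mesh, fluid = fluid_properties(),
                         bc = boundary_conditions(), cfg = solver_config(),
                         verbose = FALSE) {
  stopifnot(inherits(mesh, "volume_mesh"))
  if (!mesh$has_ports) stop("mesh has no inlet/outlet ports")
  d <- mesh$dims
  h_m <- mesh$h / 1000
  D <- 2 * mesh$geom$landmarks$inlet$radius / 1000
  Re <- fluid$density * bc$inlet_velocity * D / fluid$viscosity
  if (Re > 2000) {
    stop("configuration Reynolds number ", round(Re), " exceeds the laminar ",
         "bound (2000); reduce the inlet velocity or use a smaller inlet")
  }

  if (bc$inlet_velocity == 0) {
    # null forcing: the exact solution is a quiescent field
    zu <- array(0, d + c(1, 0, 0)); zv <- array(0, d + c(0, 1, 0)); zw <- array(0, d + c(0, 0, 1))
    return(new_flow_field(mesh, zu, zv, zw, array(0, d),
                          residuals = matrix(0, 1, 4), iterations = 0L,
                          converged = TRUE, Q_in = 0, Q_out = 0,
                          fluid = fluid, bc = bc, cfg = cfg))
  }

  dist_u <- component_wall_dists(mesh, 1L)
  dist_v <- component_wall_dists(mesh, 2L)
  dist_w <- component_wall_dists(mesh, 3L)
  sol <- solve_simple_cpp(as.integer(d), h_m, as.integer(mesh$mask),
                          inlet_profile(mesh, bc),
                          dist_u, dist_v, dist_w,
                          fluid$density, fluid$viscosity, cfg$tol, cfg$max_iter,
                          cfg$alpha_u, cfg$alpha_p,
                          if (cfg$scheme == "second_order_upwind") cfg$first_order_iters else .Machine$integer.max,
                          cfg$sweeps, as.integer(verbose))

  res <- sol$residuals
  if (!sol$converged) {
    final <- res[nrow(res), ]
    if (any(!is.finite(final)) || max(final) > 1) {
      cond <- simpleError(paste0("flow solve diverged after ", sol$iterations,
                                 " iterations (final scaled residual ",
                                 signif(max(final), 3), ")"))
      cond$residuals <- res
      stop(cond)
    }
    warning("flow solve stalled above tolerance (final scaled residual ",
            signif(max(final), 3), " after ", sol$iterations, " iterations)")
  }

  new_flow_field(mesh,
                 array(sol$u, d + c(1, 0, 0)),
                 array(sol$v, d + c(0, 1, 0)),
                 array(sol$w, d + c(0, 0, 1)),
                 array(sol$p, d),
                 residuals = res, iterations = sol$iterations,
                 converged = sol$converged, Q_in = sol$Q_in, Q_out = sol$Q_out,
                 fluid = fluid, bc = bc, cfg = cfg)
}

new_flow_field <- function(mesh, u, v, w, p, residuals, iterations, converged,
                           Q_in, Q_out, fluid, bc, cfg) {
  d <- mesh$dims
  # cell-centered velocity = average of the two bounding face values
  uc <- 0.5 * (u[1:d[1], , , drop = FALSE] + u[2:(d[1] + 1), , , drop = FALSE])
  vc <- 0.5 * (v[, 1:d[2], , drop = FALSE] + v[, 2:(d[2] + 1), , drop = FALSE])
  wc <- 0.5 * (w[, , 1:d[3], drop = FALSE] + w[, , 2:(d[3] + 1), drop = FALSE])
  structure(list(u = u, v = v, w = w, p = p,
                 cell_velocity = cbind(uc[mesh$cellidx], vc[mesh$cellidx],
                                       wc[mesh$cellidx]),
                 residuals = residuals, iterations = iterations,
                 converged = converged, Q_in = Q_in, Q_out = Q_out,
                 mass_imbalance = if (Q_in > 0) abs(Q_in - Q_out) / Q_in else 0,
                 fluid = fluid, bc = bc, cfg = cfg, h_m = mesh$h / 1000,
                 dims = d, origin_m = mesh$origin / 1000),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Steady flow field:", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations\n")
  cat(sprintf("  Q_in %.4g m^3/s, Q_out %.4g m^3/s, imbalance %.3g%%\n",
              x$Q_in, x$Q_out, 100 * x$mass_imbalance))
  invisible(x)
}

#' Interpolate the velocity field at arbitrary points
#'
#' Component-wise trilinear interpolation on the staggered grid; at a cell
#' centroid this returns exactly the cell-centered (face-averaged) velocity.
#'
#' @param field a `flow_field`
#' @param mesh the `volume_mesh` the field was solved on
#' @param points n x 3 matrix of positions in meters
#' @return n x 3 matrix of velocities, m/s
#' @export
interpolate_velocity <- function(field, mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  pm <- points * 1000  # mm for the containment check
  d <- mesh$dims
  ii <- floor((pm[, 1] - mesh$origin[1]) / mesh$h) + 1
  jj <- floor((pm[, 2] - mesh$origin[2]) / mesh$h) + 1
  kk <- floor((pm[, 3] - mesh$origin[3]) / mesh$h) + 1
  inside <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
  lin <- pmin(pmax(ii, 1), d[1]) + d[1] * (pmin(pmax(jj, 1), d[2]) - 1) +
    d[1] * d[2] * (pmin(pmax(kk, 1), d[3]) - 1)
  inside[inside] <- mesh$mask[lin[inside]]
  if (any(!inside)) {
    wd <- abs(sdf_eval(mesh$geom, pm[which(!inside)[1], , drop = FALSE]))
    stop("point outside the lumen (nearest wall approximately ",
         signif(wd, 3), " mm away)")
  }
  interp_velocity_cpp(as.integer(d), field$h_m, field$origin_m,
                      as.integer(mesh$mask), field$u, field$v, field$w, points)
}

#' Signed volumetric flow through a named cross-section
#'
#' Sums the face fluxes of the stored staircase cut. Sign convention:
#' positive = flow from the stomach toward the duodenum/jejunum (along the
#' stored section normal).
#'
#' @param field a `flow_field`
#' @param mesh the `volume_mesh` carrying the face sets
#' @param section `"PYLORUS"` or `"ANASTOMOSIS"`
#' @return flow rate, m^3/s
#' @export
cross_section_flux <- function(field, mesh, section) {
  fs <- mesh$face_sets[[section]]
  if (is.null(fs)) stop("unknown cross-section '", section, "'")
  if (nrow(fs) == 0) stop("cross-section '", section, "' has no faces (incomplete cut)")
  d <- mesh$dims
  A <- field$h_m^2
  tot <- 0
  for (r in seq_len(nrow(fs))) {
    lin <- fs[r, "ilo"]; axis <- fs[r, "axis"]; sgn <- fs[r, "sgn"]
    i <- (lin - 1) %% d[1] + 1
    j <- ((lin - 1) %/% d[1]) %% d[2] + 1
    k <- (lin - 1) %/% (d[1] * d[2]) + 1
    f <- switch(axis, field$u[i + 1, j, k], field$v[i, j + 1, k],
                field$w[i, j, k + 1])
    tot <- tot + sgn * f * A
  }
  unname(tot)
}

#' Mesh-independence check
#'
#' Solves the same configuration on a coarse and a fine mesh and reports the
#' relative L2 difference of the interpolated velocity fields on shared
#' probe points (the coarse lumen cell centers that lie inside both
#' lumens). The check passes when the difference is below 5 percent.
#'
#' @param geom a `lumen_geometry`
#' @param coarse_size,fine_size cell sizes, mm (fine < coarse)
#' @param fluid,bc,cfg solver setup
#' @return list with `difference` (fraction), `pass`, and both solutions
#' @export
mesh_independence_check <- function(geom, coarse_size, fine_size,
                                    fluid = fluid_properties(),
                                    bc = boundary_conditions(),
                                    cfg = solver_config()) {
  if (fine_size > coarse_size) stop("fine_size must not exceed coarse_size")
  mc <- discretize(geom, coarse_size)
  fc <- solve_steady(mc, fluid, bc, cfg)
  if (fine_size == coarse_size) {
    return(list(difference = 0, pass = TRUE, coarse = list(mesh = mc, field = fc),
                fine = list(mesh = mc, field = fc)))
  }
  mf <- discretize(geom, fine_size)
  ff <- solve_steady(mf, fluid, bc, cfg)
  # probes: coarse cell centers at least one coarse cell inside both lumens
  cc <- cell_centers(mc)
  f <- sdf_eval(geom, cc)
  probes <- cc[f < -coarse_size, , drop = FALSE] / 1000
  vc <- interp_velocity_cpp(as.integer(mc$dims), fc$h_m, fc$origin_m,
                            as.integer(mc$mask), fc$u, fc$v, fc$w, probes)
  vf <- interp_velocity_cpp(as.integer(mf$dims), ff$h_m, ff$origin_m,
                            as.integer(mf$mask), ff$u, ff$v, ff$w, probes)
  diff <- sqrt(sum((vc - vf)^2)) / sqrt(sum(vf^2))
  list(difference = diff, pass = diff < 0.05,
       coarse = list(mesh = mc, field = fc), fine = list(mesh = mf, field = ff))
}
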