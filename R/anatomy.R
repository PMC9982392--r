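# Parametric upper-gastrointestinal lumen and virtual surgery. The tract is
# assembled in the x-z plane (y = anterior-posterior): a vertical esophagus,
# a J-shaped stomach swept with elliptical cross-sections, a pyloric canal,
# a duodenojejunal loop routed slightly anterior, a side-to-side
# gastrojejunal anastomosis at the lowermost point of the greater curvature,
# and an efferent jejunal limb descending to the outlet. The SPGJ variant
# additionally carries a stapled partition wall just distal to the
# anastomosis, leaving a residual channel along the lesser curvature.
# Coordinates in mm; the inlet disc sits at z = 0 and flow is directed
# downward (-z).

#' Anatomical parameters of the parametric upper-GI model
#'
#' All lengths in mm. Defaults follow the published model dimensions where
#' printed (esophagus 100 x 24 mm, pylorus-to-anastomosis bowel path 350 mm,
#' anastomosis 45 mm, SPGJ partition channel 20 mm from the lesser
#' curvature); stomach body dimensions are not printed and default to a
#' normal-stature adult J-shaped stomach.
#'
#' @param esophagus_length esophageal length, mm
#' @param esophagus_inner_diameter esophageal inner diameter, mm
#' @param stomach_greater_curvature_length arc length of the greater
#'   curvature from cardia to pylorus, mm
#' @param stomach_max_lumen_diameter widest in-plane lumen diameter of the
#'   gastric body, mm
#' @param pylorus_diameter pyloric canal diameter, mm
#' @param stenosis_factor dimensionless in (0, 1]; scales the pyloric and
#'   proximal duodenal lumen (1 = patent)
#' @param duodenojejunal_path_length bowel path from pylorus to the
#'   anastomosis, mm
#' @param bowel_inner_diameter duodenal/jejunal inner diameter, mm
#' @param anastomosis_length length of the side-to-side gastrojejunal
#'   junction opening, mm
#' @param partition_channel_width residual lesser-curvature channel left by
#'   the SPGJ partition, mm
#' @param efferent_limb_length jejunal path from the anastomosis to the
#'   outlet, mm
#' @param partition_thickness thickness of the stapled partition wall, mm
#' @return object of class `anatomy_params`
#' @export
anatomy_params <- function(esophagus_length = 100,
                           esophagus_inner_diameter = 24,
                           stomach_greater_curvature_length = 280,
                           stomach_max_lumen_diameter = 80,
                           pylorus_diameter = 15,
                           stenosis_factor = 1.0,
                           duodenojejunal_path_length = 350,
                           bowel_inner_diameter = 25,
                           anastomosis_length = 45,
                           partition_channel_width = 20,
                           efferent_limb_length = 150,
                           partition_thickness = 10) {
  p <- list(esophagus_length = esophagus_length,
            esophagus_inner_diameter = esophagus_inner_diameter,
            stomach_greater_curvature_length = stomach_greater_curvature_length,
            stomach_max_lumen_diameter = stomach_max_lumen_diameter,
            pylorus_diameter = pylorus_diameter,
            stenosis_factor = stenosis_factor,
            duodenojejunal_path_length = duodenojejunal_path_length,
            bowel_inner_diameter = bowel_inner_diameter,
            anastomosis_length = anastomosis_length,
            partition_channel_width = partition_channel_width,
            efferent_limb_length = efferent_limb_length,
            partition_thickness = partition_thickness)
  lengths <- p[setdiff(names(p), "stenosis_factor")]
  for (nm in names(lengths)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a positive length (mm)")
    }
  }
  if (stenosis_factor <= 0 || stenosis_factor > 1) {
    stop("parameter 'stenosis_factor' must lie in (0, 1]")
  }
  if (anastomosis_length >= duodenojejunal_path_length) {
    stop("parameter 'anastomosis_length' must be smaller than 'duodenojejunal_path_length'")
  }
  if (anastomosis_length <= bowel_inner_diameter) {
    stop("parameter 'anastomosis_length' must exceed 'bowel_inner_diameter' ",
         "(the junction opening is capped by the bowel calibre)")
  }
  if (efferent_limb_length < 100) {
    stop("parameter 'efferent_limb_length' must be at least 100 mm so the outlet clears the junction")
  }
  structure(p, class = "anatomy_params")
}

# densified outer (greater-curvature) offset curve of the stomach sweep:
# positions, and the arc length cardia -> pylorus. Gref is a point inside
# the concavity of the J; the outer normal points away from it.
greater_curvature_curve <- function(pts, radii, Gref, ds = 1.5) {
  out <- NULL
  for (s in seq_len(nrow(pts) - 1L)) {
    A <- pts[s, ]; B <- pts[s + 1L, ]
    L <- sqrt(sum((B - A)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(L / ds)))
    if (s > 1L) tt <- tt[-1L]
    tan <- (B - A) / L
    n1 <- c(-tan[3], 0, tan[1])   # in-plane perpendicular
    for (t in tt) {
      c0 <- A + t * (B - A)
      a <- radii[s] + t * (radii[s + 1L] - radii[s])
      n <- if (sum((c0 + n1 - Gref)^2) > sum((c0 - n1 - Gref)^2)) n1 else -n1
      out <- rbind(out, c0 + a * n)
    }
  }
  list(curve = out, length = polyline_length(out))
}

build_stomach <- function(params, k) {
  cardia <- c(0, 0, -params$esophagus_length)
  rel <- rbind(c(0, 0, -4), c(-14, 0, -48), c(-10, 0, -100), c(22, 0, -148),
               c(62, 0, -135), c(92, 0, -114), c(100, 0, -110))
  pts <- sweep(k * rel, 2, cardia, "+")
  radii <- c(14, 28, 36, 30, 22, 13, 9) * (params$stomach_max_lumen_diameter / 80)
  Gref <- cardia + k * c(45, 0, -100)
  list(pts = pts, r = radii, ecc = 0.7, Gref = Gref)
}

#' Build the parametric upper-GI lumen with virtual surgery
#'
#' Constructs the watertight implicit lumen for the requested reconstruction.
#' Both variants share the same esophagus, stomach, pyloric canal, bowel
#' routing and side-to-side gastrojejunal anastomosis at the lowermost point
#' of the greater curvature; the SPGJ variant additionally inserts the
#' stapled partition wall immediately distal to the anastomosis, leaving the
#' residual channel of width `partition_channel_width` along the lesser
#' curvature, so the two geometries are identical outside the partition
#' region. The stomach sweep is scaled so the greater-curvature arc matches
#' `stomach_greater_curvature_length`, and the duodenal loop is scaled so the
#' pylorus-to-anastomosis path matches `duodenojejunal_path_length`.
#'
#' @param params an [anatomy_params()] object
#' @param variant `"CGJ"` or `"SPGJ"`
#' @return object of class `lumen_geometry`: implicit-surface primitives,
#'   named landmarks (inlet, outlet, pylorus, anastomosis, and for SPGJ the
#'   partition plane) and the bounding box
#' @export
build_lumen <- function(params = anatomy_params(), variant = c("CGJ", "SPGJ")) {
  variant <- match.arg(variant)
  if (!inherits(params, "anatomy_params")) params <- do.call(anatomy_params, params)

  re <- params$esophagus_inner_diameter / 2
  rb <- params$bowel_inner_diameter / 2
  sf <- params$stenosis_factor
  r_can <- params$pylorus_diameter / 2 * sf

  # stomach scaled so the greater-curvature arc hits its target
  gc_of_k <- function(k) {
    st <- build_stomach(params, k)
    greater_curvature_curve(st$pts, st$r, st$Gref)$length -
      params$stomach_greater_curvature_length
  }
  k <- stats::uniroot(gc_of_k, c(0.45, 2.2), tol = 1e-4)$root
  st <- build_stomach(params, k)
  gc <- greater_curvature_curve(st$pts, st$r, st$Gref)

  esoph <- list(pts = rbind(c(0, 0, 16), c(0, 0, -params$esophagus_length)),
                r = c(re, re), ecc = 1)

  # lesser-curvature fill: the capsule-chain sweep leaves a notch on the
  # inside of the J-bend at the incisura; real gastric cross-sections are
  # continuous there. A tube hugging the inner curve restores that lumen.
  u2 <- st$Gref - st$pts[3, ]; u2 <- u2 / sqrt(sum(u2^2))
  u4 <- st$Gref - st$pts[5, ]; u4 <- u4 / sqrt(sum(u4^2))
  fill <- list(pts = rbind(st$pts[3, ] + 0.5 * st$r[3] * u2,
                           st$pts[5, ] + 0.5 * st$r[5] * u4),
               r = 0.45 * c(st$r[3], st$r[5]), ecc = 0.7)

  # pyloric canal continues the antral axis
  s_end <- st$pts[nrow(st$pts), ]
  dirp <- s_end - st$pts[nrow(st$pts) - 1L, ]
  dirp <- dirp / sqrt(sum(dirp^2))
  canal_len <- 14
  canal <- list(pts = rbind(s_end, s_end + canal_len * dirp),
                r = c(r_can, r_can), ecc = 1)
  canal_end <- s_end + canal_len * dirp

  # lowermost point of the greater curvature: anastomosis site. The offset
  # polyline only estimates it; refine by casting rays down through the
  # stomach wall (capsule joints bulge slightly below the offset curve).
  ilow <- which.min(gc$curve[, 3])
  stomach_only <- list(tubes = list(st[c("pts", "r", "ecc")]), boxes = list(),
                       partition = NULL)
  xs <- gc$curve[ilow, 1] + seq(-25, 25, by = 0.5)
  P0 <- cbind(xs, 0, gc$curve[ilow, 3] + 12)
  tc <- sdf_line_crossing(stomach_only, P0, c(0, 0, -1), 30)
  zb <- P0[, 3] - tc
  jlow <- which.min(zb)
  x_low <- xs[jlow]
  z_low <- zb[jlow]

  wall_gap <- 8.5                       # stomach-jejunum wall separation, mm
  z_j <- z_low - wall_gap - rb          # jejunal centerline under the stomach
  z_c <- z_low - wall_gap / 2           # anastomosis capsule axis
  Lcap <- params$anastomosis_length - 2 * rb
  anast <- list(pts = rbind(c(x_low - Lcap / 2, 0, z_c),
                            c(x_low + Lcap / 2, 0, z_c)),
                r = c(rb, rb), ecc = 1)

  # efferent limb: along the contact line, then down to the outlet
  j_turn <- 19
  run1 <- 32; run2 <- 24
  v <- params$efferent_limb_length - (run1 + run2 + sqrt(10^2 + j_turn^2))
  z_out <- z_j - j_turn - v
  jej <- list(pts = rbind(c(x_low - 50, 0, z_j), c(x_low - 40, 0, z_j),
                          c(x_low + run1, 0, z_j), c(x_low + run1 + run2, 0, z_j),
                          c(x_low + run1 + run2 + 10, 0, z_j - j_turn),
                          c(x_low + run1 + run2 + 10, 0, z_out - 20)),
              r = rep(rb, 6), ecc = 1)

  # duodenojejunal loop, scaled to the prescribed path length
  d1 <- canal_end + c(22, 0, -14)
  offs <- rbind(c(14, 10, -44), c(-12, 32, -91), c(-66, 32, -108),
                c(-128, 32, -108), c(-166, 20, -88), c(-178, 0, -62))
  loop_pts <- function(kd) {
    e <- offs
    e[, 1] <- kd * e[, 1]; e[, 3] <- kd * e[, 3]
    sweep(e, 2, d1, "+")
  }
  path_of_kd <- function(kd) {
    path <- rbind(canal_end, d1, loop_pts(kd),
                  c(x_low - 50, 0, z_j), c(x_low - 40, 0, z_j), c(x_low, 0, z_j))
    polyline_length(path) - params$duodenojejunal_path_length
  }
  if (path_of_kd(0.25) > 0) {
    stop("parameter 'duodenojejunal_path_length' too short for the layout")
  }
  kd <- stats::uniroot(path_of_kd, c(0.25, 2.5), tol = 1e-4)$root
  duo <- list(pts = rbind(canal_end, d1, loop_pts(kd),
                          c(x_low - 50, 0, z_j), c(x_low - 40, 0, z_j)),
              r = c(r_can, rb * sf, rep(rb, 8)), ecc = 1)

  geom <- list(tubes = list(esophagus = esoph, stomach = st[c("pts", "r", "ecc")],
                            incisura_fill = fill, pylorus = canal, duodenum = duo,
                            anastomosis = anast, jejunum = jej),
               boxes = list(), partition = NULL, channel = NULL)

  landmarks <- list(
    inlet = list(center = c(0, 0, 0), normal = c(0, 0, -1), radius = re),
    outlet = list(center = c(x_low + run1 + run2 + 10, 0, z_out),
                  normal = c(0, 0, -1), radius = rb),
    pylorus = list(center = s_end + (canal_len / 2) * dirp, normal = dirp,
                   radius = r_can, ball = r_can + 8),
    anastomosis = list(center = c(x_low, 0, z_c), normal = c(0, 0, -1),
                       radius = rb, ball = Lcap / 2 + rb + 5)
  )

  if (variant == "SPGJ") {
    s3 <- st$pts[4, ]; s4 <- st$pts[5, ]
    tanp <- (s4 - s3) / sqrt(sum((s4 - s3)^2))
    q_p <- s3 + 0.7 * (s4 - s3)
    m <- c(-tanp[3], 0, tanp[1])
    if (sum((q_p + m - st$Gref)^2) > sum((q_p - m - st$Gref)^2)) m <- -m
    # lesser- and greater-curvature wall crossings along +/- m
    gtmp <- geom
    t_lc <- sdf_line_crossing(gtmp, q_p, m, params$stomach_max_lumen_diameter)
    t_gc <- sdf_line_crossing(gtmp, q_p, -m, params$stomach_max_lumen_diameter)
    if (is.na(t_lc) || is.na(t_gc)) {
      stop("partition plane does not intersect the stomach lumen")
    }
    width_local <- t_lc + t_gc
    if (params$partition_channel_width >= width_local) {
      stop("geometric infeasibility: 'partition_channel_width' (",
           params$partition_channel_width, " mm) is not smaller than the local ",
           "stomach lumen width at the partition plane (",
           round(width_local, 1), " mm)")
    }
    edge <- q_p + t_lc * m
    # the slab must clear the anastomosis opening
    d_anast <- abs(sum((landmarks$anastomosis$center - q_p) * tanp))
    if (d_anast < params$partition_thickness / 2 + rb + 3) {
      stop("geometric infeasibility: the partition wall overlaps the anastomosis channel")
    }
    geom$partition <- list(q = q_p, n = tanp, m = m, edge = edge,
                           width = params$partition_channel_width,
                           thickness = params$partition_thickness,
                           ball = max(t_lc, t_gc) + 10)
    # explicit residual channel: the stapled passage is a short tube of
    # diameter `partition_channel_width` hugging the lesser curvature,
    # crossing the staple wall
    half_len <- params$partition_thickness / 2 + 6
    q_c <- edge - (params$partition_channel_width / 2) * m
    geom$channel <- list(pts = rbind(q_c - half_len * tanp, q_c + half_len * tanp),
                         r = rep(params$partition_channel_width / 2, 2), ecc = 1)
    landmarks$partition <- list(center = q_p, normal = tanp)
  }

  # bounding box over all primitives (ports clip the z extent)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (tube in geom$tubes) {
    rmax <- max(tube$r)
    lo <- pmin(lo, apply(tube$pts, 2, min) - rmax)
    hi <- pmax(hi, apply(tube$pts, 2, max) + rmax)
  }
  lo[3] <- z_out; hi[3] <- 0

  structure(list(tubes = geom$tubes, boxes = geom$boxes,
                 partition = geom$partition, channel = geom$channel,
                 landmarks = landmarks,
                 bbox = rbind(lo = lo, hi = hi), params = params,
                 variant = variant,
                 scale = list(stomach = k, loop = kd),
                 ports_z = c(inlet = 0, outlet = z_out)),
            class = "lumen_geometry")
}

#' @export
print.lumen_geometry <- function(x, ...) {
  cat("Parametric upper-GI lumen -", x$variant, "reconstruction\n")
  cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  cat(sprintf("  bounding box: x [%.0f, %.0f]  y [%.0f, %.0f]  z [%.0f, %.0f] mm\n",
              x$bbox[1, 1], x$bbox[2, 1], x$bbox[1, 2], x$bbox[2, 2],
              x$bbox[1, 3], x$bbox[2, 3]))
  if (!is.null(x$partition)) {
    cat(sprintf("  partition: %.0f mm channel along the lesser curvature, %.0f mm staple wall\n",
                x$partition$width, x$partition$thickness))
  }
  invisible(x)
}

#' Straight-tube validation geometry
#'
#' A vertical circular tube (inlet disc at z = 0, outlet at z = -length):
#' the canonical Hagen-Poiseuille validation case for the flow solver.
#'
#' @param radius tube radius, mm
#' @param length tube length, mm
#' @return a `lumen_geometry`
#' @export
tube_geometry <- function(radius = 12, length = 100) {
  tube <- list(pts = rbind(c(0, 0, 16), c(0, 0, -length - 16)),
               r = c(radius, radius), ecc = 1)
  structure(list(tubes = list(tube = tube), boxes = list(), partition = NULL,
                 landmarks = list(
                   inlet = list(center = c(0, 0, 0), normal = c(0, 0, -1), radius = radius),
                   outlet = list(center = c(0, 0, -length), normal = c(0, 0, -1), radius = radius)),
                 bbox = rbind(lo = c(-radius, -radius, -length), hi = c(radius, radius, 0)),
                 params = list(radius = radius, length = length),
                 variant = "TUBE", ports_z = c(inlet = 0, outlet = -length)),
            class = "lumen_geometry")
}

#' Axis-aligned box test geometry
#'
#' A closed rectangular cavity (no inlet/outlet), used to validate the
#' voxel discretization and surface export against exact volumes.
#'
#' @param edge edge lengths, mm (recycled to length 3)
#' @param center box center, mm
#' @return a `lumen_geometry`
#' @export
box_geometry <- function(edge = 10, center = c(0, 0, 0)) {
  half <- rep_len(edge, 3) / 2
  structure(list(tubes = list(), boxes = list(list(center = center, half = half)),
                 partition = NULL, landmarks = list(),
                 bbox = rbind(lo = center - half, hi = center + half),
                 params = list(edge = rep_len(edge, 3)), variant = "BOX",
                 ports_z = NULL),
            class = "lumen_geometry")
}

#' Measure the SPGJ partition channel width
#'
#' Scans the partition mid-plane from the lesser-curvature wall toward the
#' greater curvature and reports the extent of open lumen before the stapled
#' wall begins.
#'
#' @param geom an SPGJ `lumen_geometry`
#' @return channel width, mm
#' @export
measure_partition_channel <- function(geom) {
  part <- geom$partition
  if (is.null(part)) stop("geometry has no partition (CGJ variant)")
  s <- seq(0.25, part$ball, by = 0.1)
  P <- cbind(part$edge[1] - s * part$m[1], part$edge[2] - s * part$m[2],
             part$edge[3] - s * part$m[3])
  f <- sdf_eval(geom, P)
  blocked <- which(f >= 0)
  if (!length(blocked)) return(NA_real_)
  s[blocked[1]]
}

#' Measure the anastomotic opening length
#'
#' Extent of open lumen along the stomach-jejunum contact line, sampled at
#' the mid-plane between the two walls.
#'
#' @param geom a `lumen_geometry` with an anastomosis landmark
#' @return opening length, mm
#' @export
measure_anastomosis_opening <- function(geom) {
  lm <- geom$landmarks$anastomosis
  if (is.null(lm)) stop("geometry has no anastomosis landmark")
  x <- seq(lm$center[1] - 60, lm$center[1] + 60, by = 0.05)
  P <- cbind(x, lm$center[2], lm$center[3])
  f <- sdf_eval(geom, P)
  # contiguous open run through the junction itself (other conduits may
  # cross the extended line elsewhere)
  open <- f < 0
  i0 <- which.min(abs(x - lm$center[1]))
  if (!open[i0]) return(0)
  lo <- i0; while (lo > 1L && open[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < length(x) && open[hi + 1L]) hi <- hi + 1L
  x[hi] - x[lo]
}

#' Serialize a lumen geometry to JSON
#'
#' Stores the anatomical parameters and surgical variant; [read_geometry()]
#' rebuilds the identical geometry (the construction is deterministic).
#'
#' @param geom a `lumen_geometry` built by [build_lumen()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_geometry <- function(geom, path) {
  if (!geom$variant %in% c("CGJ", "SPGJ")) {
    stop("only CGJ/SPGJ geometries are serializable from parameters")
  }
  jsonlite::write_json(list(params = unclass(geom$params), variant = geom$variant),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_lumen(do.call(anatomy_params, as.list(spec$params)), spec$variant)
}

#' Millimetres to metres
#'
#' Geometry and meshes are authored in mm; the flow solver and particle
#' tracker work in SI units. This is the single explicit conversion.
#'
#' @param x length(s) in mm
#' @return length(s) in m
#' @export
mm_to_m <- function(x) x / 1000
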