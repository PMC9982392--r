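# Implicit-geometry primitives. The lumen is modeled as the union of swept
# tubes (capsule chains with linearly varying radius and elliptical
# cross-section, flattened in the anterior-posterior y direction) and
# axis-aligned boxes, minus the SPGJ partition slab. All coordinates in mm.
# The implicit function is negative inside the lumen; its zero level set is
# the lumen wall. It need not be a true distance field: surface locations
# are always recovered by bisection along a line, which only requires the
# correct sign.

# implicit value of one capsule chain for a matrix of points (n x 3)
sdf_tube <- function(P, pts, r, ecc = 1) {
  stopifnot(length(r) == nrow(pts))
  n <- nrow(P)
  f <- rep(Inf, n)
  for (s in seq_len(nrow(pts) - 1L)) {
    A <- pts[s, ]; B <- pts[s + 1L, ]
    D <- B - A
    L2 <- sum(D^2)
    t <- ((P[, 1] - A[1]) * D[1] + (P[, 2] - A[2]) * D[2] +
          (P[, 3] - A[3]) * D[3]) / L2
    t <- pmin(1, pmax(0, t))
    wx <- P[, 1] - (A[1] + t * D[1])
    wy <- P[, 2] - (A[2] + t * D[2])
    wz <- P[, 3] - (A[3] + t * D[3])
    rad <- r[s] + t * (r[s + 1L] - r[s])
    # elliptical section: in-plane (x,z) half-axis rad, out-of-plane rad*ecc
    g <- sqrt(wx^2 + wz^2 + (wy / ecc)^2) - rad
    f <- pmin(f, g)
  }
  f
}

sdf_box <- function(P, center, half) {
  dx <- abs(P[, 1] - center[1]) - half[1]
  dy <- abs(P[, 2] - center[2]) - half[2]
  dz <- abs(P[, 3] - center[3]) - half[3]
  pmax(dx, dy, dz)
}

# implicit value of a full lumen geometry at points P (n x 3 matrix, mm)
sdf_eval <- function(geom, P) {
  P <- matrix(as.numeric(P), ncol = 3)
  f <- rep(Inf, nrow(P))
  for (tube in geom$tubes) {
    f <- pmin(f, sdf_tube(P, tube$pts, tube$r, tube$ecc))
  }
  for (box in geom$boxes) {
    f <- pmin(f, sdf_box(P, box$center, box$half))
  }
  part <- geom$partition
  if (!is.null(part)) {
    dn <- abs((P[, 1] - part$q[1]) * part$n[1] + (P[, 2] - part$q[2]) * part$n[2] +
              (P[, 3] - part$q[3]) * part$n[3]) - part$thickness / 2
    # distance from the lesser-curvature edge measured along -m (into lumen)
    s <- (part$edge[1] - P[, 1]) * part$m[1] + (part$edge[2] - P[, 2]) * part$m[2] +
         (part$edge[3] - P[, 3]) * part$m[3]
    ball <- sqrt((P[, 1] - part$q[1])^2 + (P[, 2] - part$q[2])^2 +
                 (P[, 3] - part$q[3])^2) - part$ball
    f_slab <- pmax(dn, part$width - s, ball)   # negative inside the stapled wall
    f <- pmax(f, -f_slab)
  }
  # the residual channel tube is restored after the wall is subtracted
  if (!is.null(geom$channel)) {
    f <- pmin(f, sdf_tube(P, geom$channel$pts, geom$channel$r, geom$channel$ecc))
  }
  f
}

# first zero crossing of the implicit function along P0 + t * dir, t in
# (0, tmax]: coarse forward scan to bracket the first sign change, then
# vectorised bisection. Returns NA where no crossing occurs within tmax.
sdf_line_crossing <- function(geom, P0, dir, tmax, iters = 32L, nscan = 48L) {
  P0 <- matrix(as.numeric(P0), ncol = 3)
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = nrow(P0), ncol = 3, byrow = TRUE)
  n <- nrow(P0)
  lo <- rep(0, n); hi <- rep(NA_real_, n)
  open <- rep(TRUE, n)   # still scanning (no bracket yet)
  ts <- tmax * seq_len(nscan) / nscan
  for (t in ts) {
    idx <- which(open)
    if (!length(idx)) break
    f <- sdf_eval(geom, P0[idx, , drop = FALSE] + t * dir[idx, , drop = FALSE])
    hit <- f >= 0
    hi[idx[hit]] <- t
    open[idx[hit]] <- FALSE
    lo[idx[!hit]] <- t
  }
  out <- rep(NA_real_, n)
  act <- which(!is.na(hi))
  if (!length(act)) return(out)
  alo <- lo[act]; ahi <- hi[act]
  for (it in seq_len(iters)) {
    mid <- (alo + ahi) / 2
    fm <- sdf_eval(geom, P0[act, , drop = FALSE] + mid * dir[act, , drop = FALSE])
    inside <- fm < 0
    alo[inside] <- mid[inside]
    ahi[!inside] <- mid[!inside]
  }
  out[act] <- (alo + ahi) / 2
  out
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}
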