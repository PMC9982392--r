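# Triangulated surface extraction and STL input/output. The surface is the
# boundary of a fine voxelization of the implicit lumen: a closed,
# consistently oriented, non-self-intersecting triangle set whose
# divergence-theorem volume equals the voxel volume exactly. Pure box
# geometries are triangulated exactly (12 facets).

#' Triangulated lumen surface
#'
#' Extracts the closed boundary surface of the lumen at the given voxel
#' resolution (the inlet/outlet discs are capped, so the surface is
#' watertight). A single-box geometry is triangulated exactly with 12
#' facets.
#'
#' @param geom a `lumen_geometry`
#' @param cell_size voxel edge used for surface extraction, mm
#' @return object of class `lumen_surface`: list with `v1`, `v2`, `v3`
#'   (n x 3 vertex matrices, mm) and `normal` (n x 3 outward unit normals)
#' @export
lumen_surface <- function(geom, cell_size = 2) {
  if (length(geom$tubes) == 0L && length(geom$boxes) == 1L &&
      is.null(geom$partition)) {
    return(box_surface(geom$boxes[[1L]]))
  }
  h <- cell_size
  lo <- geom$bbox["lo", ]; hi <- geom$bbox["hi", ]
  dims <- as.integer(ceiling((hi - lo) / h) + 4L)
  origin <- lo - 2 * h
  if (!is.null(geom$ports_z)) {
    dims[3] <- as.integer(ceiling((geom$ports_z[["inlet"]] -
                                   geom$ports_z[["outlet"]]) / h))
    origin[3] <- geom$ports_z[["inlet"]] - dims[3] * h
  }
  mask <- voxelize_mask(geom, origin, dims, h)
  tri <- boundary_triangles(mask, origin, h)
  structure(tri, class = "lumen_surface", cell_size = h)
}

box_surface <- function(box) {
  c0 <- box$center - box$half; c1 <- box$center + box$half
  v <- rbind(c(c0[1], c0[2], c0[3]), c(c1[1], c0[2], c0[3]),
             c(c1[1], c1[2], c0[3]), c(c0[1], c1[2], c0[3]),
             c(c0[1], c0[2], c1[3]), c(c1[1], c0[2], c1[3]),
             c(c1[1], c1[2], c1[3]), c(c0[1], c1[2], c1[3]))
  # outward-oriented faces of the hexahedron
  f <- rbind(c(1, 3, 2), c(1, 4, 3),      # z = lo
             c(5, 6, 7), c(5, 7, 8),      # z = hi
             c(1, 2, 6), c(1, 6, 5),      # y = lo
             c(4, 8, 7), c(4, 7, 3),      # y = hi
             c(1, 5, 8), c(1, 8, 4),      # x = lo
             c(2, 3, 7), c(2, 7, 6))      # x = hi
  tri_from_vf(v, f)
}

tri_from_vf <- function(v, f) {
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  n <- cross3(v2 - v1, v3 - v1)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  list(v1 = v1, v2 = v2, v3 = v3, normal = n / len)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# boundary quads of a voxel mask -> outward-oriented triangles
boundary_triangles <- function(mask, origin, h) {
  dims <- dim(mask)
  V1 <- V2 <- V3 <- NULL
  pad <- function(m, axis, side) {
    # mask shifted with FALSE padding: neighbor occupancy along axis
    d <- dim(m)
    out <- array(FALSE, d)
    if (axis == 1) {
      if (side > 0) out[1:(d[1] - 1), , ] <- m[2:d[1], , ]
      else out[2:d[1], , ] <- m[1:(d[1] - 1), , ]
    } else if (axis == 2) {
      if (side > 0) out[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
      else out[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
    } else {
      if (side > 0) out[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
      else out[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
    }
    out
  }
  for (axis in 1:3) {
    for (side in c(-1, 1)) {
      face_cells <- which(mask & !pad(mask, axis, side))
      if (!length(face_cells)) next
      i <- (face_cells - 1L) %% dims[1]
      j <- ((face_cells - 1L) %/% dims[1]) %% dims[2]
      k <- (face_cells - 1L) %/% (dims[1] * dims[2])
      ctr <- cbind(origin[1] + (i + 0.5) * h, origin[2] + (j + 0.5) * h,
                   origin[3] + (k + 0.5) * h)
      # quad corners of the exposed face, ordered so normals point outward
      a1 <- (axis %% 3) + 1L; a2 <- (a1 %% 3) + 1L
      e0 <- e1 <- e2 <- rep(0, 3)
      e0[axis] <- side * h / 2
      e1[a1] <- h / 2; e2[a2] <- h / 2
      p1 <- sweep(ctr, 2, e0 - e1 - e2, "+")
      p2 <- sweep(ctr, 2, e0 + e1 - e2, "+")
      p3 <- sweep(ctr, 2, e0 + e1 + e2, "+")
      p4 <- sweep(ctr, 2, e0 - e1 + e2, "+")
      if (side > 0) {
        V1 <- rbind(V1, p1, p1); V2 <- rbind(V2, p2, p3); V3 <- rbind(V3, p3, p4)
      } else {
        V1 <- rbind(V1, p1, p1); V2 <- rbind(V2, p3, p4); V3 <- rbind(V3, p2, p3)
      }
    }
  }
  n <- cross3(V2 - V1, V3 - V1)
  len <- sqrt(rowSums(n^2))
  list(v1 = V1, v2 = V2, v3 = V3, normal = n / len)
}

#' Enclosed volume of a closed triangle surface
#'
#' Divergence-theorem (signed tetrahedron) volume; positive for outward
#' orientation.
#'
#' @param surf a `lumen_surface` or any list with `v1`, `v2`, `v3`
#' @return volume, mm^3
#' @export
surface_volume <- function(surf) {
  s <- rowSums(surf$v1 * cross3(surf$v2, surf$v3)) / 6
  abs(sum(s))
}

#' Watertightness check for a triangle surface
#'
#' Verifies that every edge is shared by exactly two facets with opposite
#' orientation.
#'
#' @param surf a surface as returned by [lumen_surface()]
#' @return logical
#' @export
surface_is_watertight <- function(surf) {
  key <- function(p) sprintf("%.6f,%.6f,%.6f", p[, 1], p[, 2], p[, 3])
  k1 <- key(surf$v1); k2 <- key(surf$v2); k3 <- key(surf$v3)
  half <- c(paste(k1, k2), paste(k2, k3), paste(k3, k1))
  rev <- c(paste(k2, k1), paste(k3, k2), paste(k1, k3))
  th <- table(half)
  all(th == 1L) && all(half %in% names(table(rev))) && length(half) == length(rev) &&
    all(sort(half) == sort(rev))
}

#' Export a lumen surface to STL
#'
#' Writes the triangulated boundary surface as ASCII STL (mm units).
#'
#' @param geom a `lumen_geometry`
#' @param path output file
#' @param cell_size voxel edge for surface extraction, mm
#' @return `path`, invisibly
#' @export
export_surface <- function(geom, path, cell_size = 2) {
  surf <- lumen_surface(geom, cell_size)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write STL to '", path, "': ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines("solid lumen", con)
  n <- nrow(surf$v1)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 20000))
  for (idx in chunks) {
    txt <- sprintf(paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                          "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                          "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
                   surf$normal[idx, 1], surf$normal[idx, 2], surf$normal[idx, 3],
                   surf$v1[idx, 1], surf$v1[idx, 2], surf$v1[idx, 3],
                   surf$v2[idx, 1], surf$v2[idx, 2], surf$v2[idx, 3],
                   surf$v3[idx, 1], surf$v3[idx, 2], surf$v3[idx, 3])
    writeLines(txt, con)
  }
  writeLines("endsolid lumen", con)
  invisible(path)
}

#' Import an ASCII STL surface
#'
#' @param path STL file
#' @return a surface list (`v1`, `v2`, `v3`, `normal`), coordinates in the
#'   file's units
#' @export
import_surface <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0) stop("not a valid ASCII STL file")
  m <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                         "\\s+"))), ncol = 3, byrow = TRUE)
  v1 <- m[seq(1, nrow(m), by = 3), , drop = FALSE]
  v2 <- m[seq(2, nrow(m), by = 3), , drop = FALSE]
  v3 <- m[seq(3, nrow(m), by = 3), , drop = FALSE]
  tri_from_vf(rbind(v1, v2, v3),
              cbind(seq_len(nrow(v1)), nrow(v1) + seq_len(nrow(v1)),
                    2 * nrow(v1) + seq_len(nrow(v1))))
}
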