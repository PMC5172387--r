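#' Surface mesh
#'
#' A triangle surface mesh for one subcortical structure. All subjects of a
#' cohort share topology (same vertex count, same faces), so vertex `v` is
#' anatomically corresponded across subjects.
#'
#' @param vertices numeric matrix, `n_vertices x 3`, coordinates in mm.
#' @param faces integer matrix, `n_faces x 3`, 1-based vertex indices.
#' @param structure structure label, e.g. `"hippocampus"`.
#' @param hemisphere `"left"`, `"right"` or `NA`.
#'
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, structure = "structure",
                         hemisphere = NA_character_) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (!all(is.finite(vertices))) stop("mesh vertices must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  structure(
    list(vertices = vertices, faces = faces,
         structure = structure, hemisphere = hemisphere),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s (%s): %d vertices, %d faces\n",
              x$structure, x$hemisphere, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Capped tube mesh
#'
#' Template geometry used by the synthetic shape generator: a cylinder of
#' `n_rings` vertex rings with `n_seg` vertices per ring, closed by triangle
#' fans to two apex points on the axis. The axis lies along x. Elongated,
#' so it has a well-defined medial curve like an elongated subcortical
#' structure (hippocampus, caudate).
#'
#' @param n_rings rings of lateral vertices along the axis (>= 2).
#' @param n_seg vertices per ring (>= 3).
#' @param radius tube radius in mm.
#' @param length tube length in mm.
#' @param structure,hemisphere labels passed to [surface_mesh()].
#' @return A closed `surface_mesh` with `n_rings * n_seg + 2` vertices; the
#'   two cap apexes are the last two vertices.
#' @export
mesh_tube <- function(n_rings = 12, n_seg = 16, radius = 5, length = 40,
                      structure = "tube", hemisphere = NA_character_) {
  stopifnot(n_rings >= 2, n_seg >= 3, radius > 0, length > 0)
  xs <- seq(0, length, length.out = n_rings)
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  v <- do.call(rbind, lapply(xs, function(x) {
    cbind(x, radius * cos(theta), radius * sin(theta))
  }))
  apex1 <- c(0, 0, 0)
  apex2 <- c(length, 0, 0)
  v <- rbind(v, apex1, apex2)
  rownames(v) <- NULL

  idx <- function(ring, seg) (ring - 1L) * n_seg + ((seg - 1L) %% n_seg) + 1L
  f <- list()
  for (r in seq_len(n_rings - 1L)) {
    for (s in seq_len(n_seg)) {
      a <- idx(r, s); b <- idx(r, s + 1L)
      c2 <- idx(r + 1L, s); d <- idx(r + 1L, s + 1L)
      # outward orientation (counter-clockwise seen from outside)
      f[[length(f) + 1L]] <- c(a, b, c2)
      f[[length(f) + 1L]] <- c(b, d, c2)
    }
  }
  a1 <- n_rings * n_seg + 1L
  a2 <- n_rings * n_seg + 2L
  for (s in seq_len(n_seg)) {
    f[[length(f) + 1L]] <- c(a1, idx(1L, s + 1L), idx(1L, s))
    f[[length(f) + 1L]] <- c(a2, idx(n_rings, s), idx(n_rings, s + 1L))
  }
  surface_mesh(v, do.call(rbind, f), structure, hemisphere)
}

#' Unit cube mesh
#'
#' Axis-aligned unit cube triangulated into 12 faces, outward-oriented.
#' Enclosed volume is exactly 1; used as a closed-form geometry check.
#' @export
mesh_unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # vertex order: (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1)
  quads <- rbind(
    c(1, 3, 4, 2),  # z = 0, outward -z
    c(5, 6, 8, 7),  # z = 1
    c(1, 2, 6, 5),  # y = 0
    c(3, 7, 8, 4),  # y = 1
    c(1, 5, 7, 3),  # x = 0
    c(2, 4, 8, 6)   # x = 1
  )
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  surface_mesh(v, f, structure = "cube")
}

#' Icosphere mesh
#'
#' Sphere approximated by recursive subdivision of an icosahedron, vertices
#' projected to radius `r`. Volume converges to `4/3 pi r^3` from below.
#'
#' @param r radius in mm.
#' @param subdivisions subdivision depth (0 = icosahedron).
#' @export
mesh_icosphere <- function(r = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(edge_mid[[key]])) return(edge_mid[[key]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      edge_mid[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c2 <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c2); ca <- midpoint(c2, a)
      newf[(4L * (k - 1L) + 1L):(4L * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c2, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v * (r / sqrt(rowSums(v^2)))
  surface_mesh(v, f, structure = "icosphere")
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# barycentric vertex area: one third of incident triangle areas
one_ring_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  a <- numeric(n_vertices(mesh))
  for (j in 1:3) {
    acc <- tapply(ta, mesh$faces[, j], sum)
    ii <- as.integer(names(acc))
    a[ii] <- a[ii] + acc
  }
  a / 3
}

mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume. Orientation is
#' auto-corrected with a warning when the signed sum is negative.
#'
#' @param mesh a closed, consistently oriented [surface_mesh()].
#' @param units `"mm3"` or `"cm3"` (the reporting convention for gross
#'   subcortical volumes is cm^3).
#' @return Positive volume (scalar).
#' @export
gross_volume <- function(mesh, units = c("mm3", "cm3")) {
  units <- match.arg(units)
  if (!mesh_is_closed(mesh)) stop("gross_volume requires a closed mesh")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c2 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) -
    a[, 2] * (b[, 1] * c2[, 3] - b[, 3] * c2[, 1]) +
    a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])
  vol <- sum(det6) / 6
  if (vol < 0) {
    warning("mesh orientation appears inward; flipping sign of volume")
    vol <- -vol
  }
  if (units == "cm3") vol / 1000 else vol
}

#' Log surface Jacobian determinant
#'
#' Per-vertex log ratio of one-ring (barycentric) vertex areas on the subject
#' versus the template: `ln(area_subject(v) / area_template(v))`. Captures
#' local surface dilation; a subject uniformly scaled by `s` has value
#' `2 ln s` everywhere.
#'
#' @param mesh subject `surface_mesh`.
#' @param template template `surface_mesh`, same topology.
#' @return Numeric vector, one value per vertex (unitless).
#' @export
log_jacobian <- function(mesh, template) {
  if (!identical(dim(mesh$vertices), dim(template$vertices)) ||
      !identical(mesh$faces, template$faces)) {
    stop("subject and template meshes must share topology (correspondence)")
  }
  at <- one_ring_areas(template)
  if (any(at <= 0)) {
    stop(sprintf("zero-area one-ring on template at vertex %d",
                 which(at <= 0)[1]))
  }
  as_ <- one_ring_areas(mesh)
  log(as_ / at)
}

#' Write a mesh as ASCII PLY, optionally with a per-vertex scalar
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param scalar optional per-vertex scalar attribute (e.g. a heritability
#'   map), written as property `quality`.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- n_vertices(mesh); nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment structure %s hemisphere %s",
                   mesh$structure, mesh$hemisphere),
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nv)
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vt <- mesh$vertices
  vl <- if (is.null(scalar)) {
    sprintf("%.8g %.8g %.8g", vt[, 1], vt[, 2], vt[, 3])
  } else {
    sprintf("%.8g %.8g %.8g %.8g", vt[, 1], vt[, 2], vt[, 3], scalar)
  }
  fl <- sprintf("3 %d %d %d",
                mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()]
#'
#' @param path PLY file.
#' @return A `surface_mesh`; a `scalar` attribute holds the per-vertex
#'   quality column when present.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("not a PLY file: no end_header")
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  has_scalar <- any(grepl("^property float quality", hdr))
  vlines <- lines[(endh + 1L):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(vlines, " "), as.numeric))
  flines <- lines[(endh + nv + 1L):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(flines, " "), function(x) as.integer(x[2:4]) + 1L))
  cm <- grep("^comment structure", hdr, value = TRUE)
  struct <- "structure"; hemi <- NA_character_
  if (length(cm)) {
    parts <- strsplit(cm[1], " ")[[1]]
    struct <- parts[3]; hemi <- parts[5]
  }
  m <- surface_mesh(vm[, 1:3, drop = FALSE], fm, struct, hemi)
  if (has_scalar) attr(m, "scalar") <- vm[, 4]
  m
}
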