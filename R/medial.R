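#' Medial curve of an elongated structure
#'
#' Ordered 3D control points with arc-length parameterization. Constructed
#' by [fit_medial_curve()] on the template mesh and held fixed across
#' subjects, so that radial-distance differences between subjects reflect
#' surface change rather than curve refitting.
#'
#' @param points numeric matrix, `n_points x 3`, ordered along the curve.
#' @export
medial_curve <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2, all(is.finite(points)))
  seglen <- sqrt(rowSums(diff(points)^2))
  structure(list(points = points, arclength = c(0, cumsum(seglen))),
            class = "medial_curve")
}

#' @export
print.medial_curve <- function(x, ...) {
  cat(sprintf("<medial_curve> %d points, length %.2f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' Fit a medial curve to an elongated mesh
#'
#' Simplified medial model: vertices are projected onto the mesh's first
#' principal axis, partitioned into `n_points` equal-width bins along that
#' axis, per-bin centroids are computed, and the centroid sequence is
#' smoothed with a moving-average pass. Requires the structure to be
#' elongated (distinct first principal axis); spherical meshes are rejected.
#'
#' After the initial axis-binned pass, the curve is refined: each vertex's
#' axial parameter is re-estimated along the local tangent of its current
#' bin (central differences of the smoothed centroids) and the centroids
#' recomputed. This corrects the oblique cross-section cuts a single global
#' projection makes on bent structures.
#'
#' @param mesh a [surface_mesh()], usually the template.
#' @param n_points number of bins / control points.
#' @param elongation_tol minimum excess of the top-two covariance eigenvalue
#'   ratio over 1 for the first axis to count as unique.
#' @param smooth_window odd moving-average window (1 disables smoothing).
#' @param refine number of arc-length refinement passes.
#' @return A [medial_curve()].
#' @export
fit_medial_curve <- function(mesh, n_points = 10, elongation_tol = 0.05,
                             smooth_window = 3, refine = 2) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  ev <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  if (ev$values[1] / ev$values[2] <= 1 + elongation_tol) {
    stop(sprintf(
      "mesh not elongated: top-two covariance eigenvalue ratio %.3f <= %.3f",
      ev$values[1] / ev$values[2], 1 + elongation_tol))
  }
  axis1 <- ev$vectors[, 1]
  t <- drop(vc %*% axis1)
  bc <- bin_centroids(v, t, n_points)
  for (pass in seq_len(refine)) {
    sm <- smooth_polyline(bc$pts, 3L)        # stabilized centroids for tangents
    arc <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
    nb <- nrow(sm)
    tang <- matrix(0, nb, 3)
    for (b in seq_len(nb)) {
      d <- sm[min(nb, b + 1L), ] - sm[max(1L, b - 1L), ]
      tang[b, ] <- d / sqrt(sum(d^2))
    }
    b_of_v <- pmin(bc$bin, nb)
    t <- arc[b_of_v] +
      rowSums((v - sm[b_of_v, , drop = FALSE]) * tang[b_of_v, , drop = FALSE])
    bc <- bin_centroids(v, t, n_points, quiet = TRUE)
  }
  medial_curve(smooth_polyline(bc$pts, smooth_window))
}

# equal-width bins over the parameter; centroid per bin, empties merged
bin_centroids <- function(v, t, n_points, quiet = FALSE) {
  breaks <- seq(min(t), max(t), length.out = n_points + 1L)
  bin <- findInterval(t, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  pts <- matrix(NA_real_, n_points, 3)
  for (b in seq_len(n_points)) {
    sel <- bin == b
    if (any(sel)) pts[b, ] <- colMeans(v[sel, , drop = FALSE])
  }
  empty <- which(is.na(pts[, 1]))
  if (length(empty)) {
    if (!quiet) {
      message(sprintf("fit_medial_curve: %d empty bin(s) merged with neighbors",
                      length(empty)))
    }
    pts <- pts[-empty, , drop = FALSE]
    kept <- setdiff(seq_len(n_points), empty)
    nearest_kept <- vapply(seq_len(n_points),
                           function(b) which.min(abs(kept - b)), integer(1))
    bin <- nearest_kept[bin]
  }
  list(pts = pts, bin = bin)
}

smooth_polyline <- function(pts, smooth_window) {
  if (smooth_window <= 1 || nrow(pts) < smooth_window) return(pts)
  half <- (smooth_window - 1L) %/% 2L
  sm <- pts
  for (i in seq_len(nrow(pts))) {
    lo <- max(1L, i - half); hi <- min(nrow(pts), i + half)
    sm[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  sm
}

# distance from each row of p to segment (a, b)
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(p, 2, a)^2)))
  }
  t <- pmin(1, pmax(0, (sweep(p, 2, a) %*% ab) / len2))
  proj <- outer(drop(t), ab) + rep(a, each = nrow(p))
  sqrt(rowSums((p - proj)^2))
}

#' Radial distance of mesh vertices to a medial curve
#'
#' Euclidean distance from each vertex to the nearest point of the
#' piecewise-linear medial curve, in mm. The curve is fit on the template
#' of the structure and reused for every subject.
#'
#' @param mesh a [surface_mesh()].
#' @param curve a [medial_curve()].
#' @return Numeric vector of nonnegative distances, one per vertex.
#' @export
radial_distance <- function(mesh, curve) {
  if (!inherits(curve, "medial_curve") || nrow(curve$points) < 2) {
    stop("radial_distance needs a medial_curve with >= 2 points")
  }
  p <- mesh$vertices
  d <- rep(Inf, nrow(p))
  for (s in seq_len(nrow(curve$points) - 1L)) {
    d <- pmin(d, point_segment_distance(p, curve$points[s, ],
                                        curve$points[s + 1L, ]))
  }
  d
}

#' Vertex-wise shape measures for a cohort of corresponded meshes
#'
#' Computes one shape descriptor per vertex for every subject mesh:
#' radial distance (mm, to the template's medial curve) or the log surface
#' Jacobian determinant (unitless, relative to the template).
#'
#' @param meshes list of `surface_mesh`, one per subject, same topology.
#' @param template template `surface_mesh`.
#' @param measure `"radial_distance"` or `"log_jacobian"`.
#' @param curve optional precomputed [medial_curve()]; fitted on the
#'   template when `NULL` and `measure = "radial_distance"`.
#' @return A `shape_measures` object: subjects x vertices matrix with
#'   attributes `measure` and `structure`.
#' @export
shape_measures <- function(meshes, template,
                           measure = c("radial_distance", "log_jacobian"),
                           curve = NULL) {
  measure <- match.arg(measure)
  stopifnot(length(meshes) >= 1)
  if (measure == "radial_distance" && is.null(curve)) {
    curve <- fit_medial_curve(template)
  }
  rows <- lapply(meshes, function(m) {
    if (measure == "radial_distance") radial_distance(m, curve)
    else log_jacobian(m, template)
  })
  y <- do.call(rbind, rows)
  rownames(y) <- names(meshes)
  colnames(y) <- paste0("v", seq_len(ncol(y)))
  structure(y, class = c("shape_measures", "matrix"),
            measure = measure, structure = template$structure)
}
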