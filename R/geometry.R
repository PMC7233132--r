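#' Wrap points in an alpha-shape surface
#'
#' Builds the alpha shape of a point set: the generalization of the convex
#' hull controlled by the scale parameter `alpha` (micrometers), able to
#' represent concavities and holes. A boundary facet is any segment (2D) or
#' triangle (3D) whose endpoints admit an empty circumscribed disk/sphere of
#' radius `alpha`; as `alpha -> Inf` the boundary converges to the convex
#' hull. The surface is used to gate points (e.g. random controls) and to
#' measure signed distances of cells to region borders.
#'
#' @param points A cell table, a neighborhood tibble, or anything with
#'   `x_um`/`y_um`/`z_um` (or `x`/`y`/`z`) columns; a 2- or 3-column matrix
#'   also works.
#' @param alpha Alpha radius in micrometers. When `points` is a
#'   neighborhood tibble the default is twice the raster grid spacing
#'   (= the neighborhood radius), which wraps a grid of centers snugly;
#'   otherwise it must be supplied.
#' @param dim `"auto"` (3D iff the z extent is positive), `2` or `3`.
#' @return A `tissue_surface`: the points, the boundary (`edges` m x 2 in
#'   2D, `faces` m x 3 in 3D), `dim`, and `alpha`.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' s <- make_surface(sq, alpha = 10)
#' surface_contains(s, cbind(0.5, 0.5))
make_surface <- function(points, alpha = NULL, dim = c("auto", "2", "3")) {
  dim <- match.arg(as.character(dim), c("auto", "2", "3"))
  if (is.null(alpha)) {
    sp <- attr(points, "spacing", exact = TRUE)
    if (is.null(sp)) {
      abort("supply alpha (no grid spacing to derive a default from)",
            class = "tissuemap_parameter_error")
    }
    alpha <- 2 * sp
  }
  if (!is.numeric(alpha) || alpha <= 0) {
    abort("alpha must be positive", class = "tissuemap_parameter_error")
  }
  xyz <- point_matrix(points)
  if (dim == "auto") {
    dim <- if (ncol(xyz) == 3L && diff(range(xyz[, 3])) > 0) "3" else "2"
  }
  if (dim == "2") {
    xy <- unique(xyz[, 1:2, drop = FALSE])
    if (nrow(xy) < 3L || all_collinear(xy)) {
      abort("degenerate geometry: need >= 3 non-collinear points for a 2D surface",
            class = "tissuemap_geometry_error")
    }
    edges <- alpha_edges_2d_cpp(xy[, 1], xy[, 2], alpha)
    if (nrow(edges) == 0L) {
      abort("alpha too small: no boundary facets found",
            class = "tissuemap_geometry_error")
    }
    structure(list(dim = 2L, points = xy, edges = edges, alpha = alpha),
              class = "tissue_surface")
  } else {
    p3 <- unique(xyz)
    if (nrow(p3) < 4L || all_coplanar(p3)) {
      abort("degenerate geometry: need >= 4 non-coplanar points for a 3D surface",
            class = "tissuemap_geometry_error")
    }
    faces <- alpha_faces_3d_cpp(p3, alpha)
    if (nrow(faces) == 0L) {
      abort("alpha too small: no boundary facets found",
            class = "tissuemap_geometry_error")
    }
    structure(list(dim = 3L, points = p3, faces = faces, alpha = alpha),
              class = "tissue_surface")
  }
}

#' @export
print.tissue_surface <- function(x, ...) {
  cat("Alpha-shape surface (", x$dim, "D), alpha = ", x$alpha, " um\n",
      sep = "")
  cat("  source points: ", nrow(x$points), "; boundary facets: ",
      nrow(if (x$dim == 2L) x$edges else x$faces), "\n", sep = "")
  invisible(x)
}

point_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
    if (ncol(m) == 2L) m <- cbind(m, 0)
    storage.mode(m) <- "double"
    colnames(m) <- NULL
    return(m[, 1:3, drop = FALSE])
  }
  nm <- names(points)
  xc <- if ("x_um" %in% nm) "x_um" else "x"
  yc <- if ("y_um" %in% nm) "y_um" else "y"
  zc <- if ("z_um" %in% nm) "z_um" else if ("z" %in% nm) "z" else NULL
  cbind(as.numeric(points[[xc]]), as.numeric(points[[yc]]),
        if (is.null(zc)) 0 else as.numeric(points[[zc]]))
}

all_collinear <- function(xy) {
  if (nrow(xy) < 3L) return(TRUE)
  v <- sweep(xy, 2, xy[1, ])
  cr <- v[, 1] * v[2, 2] - v[, 2] * v[2, 1]
  base <- v[2, 1]^2 + v[2, 2]^2
  if (base == 0) {
    # first two points coincide; try another base point
    return(all_collinear(xy[-2, , drop = FALSE]))
  }
  all(abs(cr) < 1e-9 * sqrt(base) * sqrt(rowSums(v^2) + 1))
}

all_coplanar <- function(p) {
  if (nrow(p) < 4L) return(TRUE)
  v <- sweep(p, 2, p[1, ])
  sv <- svd(v)$d
  sv[3] < 1e-9 * max(sv[1], 1)
}

surface_segments <- function(surface) {
  p <- surface$points
  e <- surface$edges
  cbind(p[e[, 1], 1], p[e[, 1], 2], p[e[, 2], 1], p[e[, 2], 2])
}

#' Point-in-surface test
#'
#' Even-odd containment against the surface boundary; points on the
#' boundary (within `tol` micrometers) count as inside.
#'
#' @param surface A `tissue_surface`.
#' @param points Points (same accepted forms as [make_surface()]).
#' @param tol Boundary tolerance in micrometers.
#' @return Logical vector.
#' @export
surface_contains <- function(surface, points, tol = 1e-9) {
  xyz <- point_matrix(points)
  if (surface$dim == 2L) {
    seg <- surface_segments(surface)
    inside <- crossings_inside_2d_cpp(xyz[, 1], xyz[, 2], seg)
    on_b <- dist_segments_2d_cpp(xyz[, 1], xyz[, 2], seg) <= tol
  } else {
    inside <- ray_parity_3d_cpp(xyz, surface$points, surface$faces)
    on_b <- dist_triangles_3d_cpp(xyz, surface$points, surface$faces) <= tol
  }
  inside | on_b
}

#' Signed distance of cells to a surface border
#'
#' The magnitude is the Euclidean distance to the nearest boundary facet
#' (segment in 2D, triangle face in 3D); the sign is negative for cells
#' inside the surface, positive outside, zero on the boundary. Distances to
#' the left of zero therefore represent cells inside the region.
#'
#' @param cells A cell table (or points as in [make_surface()]).
#' @param surface A `tissue_surface`.
#' @return A tibble: the input positions plus `signed_dist_um`.
#' @export
signed_distance <- function(cells, surface) {
  xyz <- point_matrix(cells)
  d <- if (surface$dim == 2L) {
    dist_segments_2d_cpp(xyz[, 1], xyz[, 2], surface_segments(surface))
  } else {
    dist_triangles_3d_cpp(xyz, surface$points, surface$faces)
  }
  inside <- surface_contains(surface, xyz)
  tibble::tibble(x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
                 signed_dist_um = ifelse(inside, -d, d))
}

#' Distance of each cell to the nearest target object
#'
#' Minimum Euclidean distance from every cell to any object of a target set
#' (e.g. myeloid cells to the nearest blood vessel). A proximal summary —
#' the fraction of cells closer than a cutoff, 20 um being the conventional
#' vascular-proximity threshold — is available via [proximal_fraction()].
#'
#' @param cells Cell table (or points).
#' @param targets Nonempty target cell table (or points).
#' @return A tibble: the input positions plus `nearest_dist_um`.
#' @export
nearest_object_distance <- function(cells, targets) {
  tm <- point_matrix(targets)
  if (nrow(tm) == 0L) {
    abort("targets are empty", class = "tissuemap_empty_error")
  }
  cm <- point_matrix(cells)
  nn <- RANN::nn2(tm, cm, k = 1L)
  tibble::tibble(x_um = cm[, 1], y_um = cm[, 2], z_um = cm[, 3],
                 nearest_dist_um = as.vector(nn$nn.dists))
}

#' @rdname nearest_object_distance
#' @param distances Numeric vector of distances (or the tibble returned by
#'   `nearest_object_distance()`).
#' @param cutoff Proximity cutoff in micrometers (default 20).
#' @return `proximal_fraction()`: the fraction of cells with distance below
#'   the cutoff.
#' @export
proximal_fraction <- function(distances, cutoff = 20) {
  if (is.data.frame(distances)) distances <- distances$nearest_dist_um
  mean(distances < cutoff)
}

#' Generate randomly distributed control points
#'
#' Uniform points on the bounding box of a reference point set, used as a
#' null reference for distance analyses. Only the plotted axes are
#' randomized: when the reference is effectively 2D (zero z extent) the z
#' coordinate is copied as a constant. All channel values of the new points
#' are 0 and the phenotype is `"RDP"`. Deterministic per seed.
#'
#' @param reference Nonempty cell table providing the bounds (and channel
#'   columns).
#' @param n Number of points (> 0).
#' @param seed RNG seed.
#' @return A cell-table tibble of `n` RDP records.
#' @export
generate_random_points <- function(reference, n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    abort("n must be a single positive integer",
          class = "tissuemap_parameter_error")
  }
  n <- as.integer(n)
  xyz <- point_matrix(reference)
  if (nrow(xyz) == 0L) {
    abort("reference is empty", class = "tissuemap_empty_error")
  }
  zr <- range(xyz[, 3])
  out <- withr::with_seed(seed, tibble::tibble(
    sample_id = if (is.data.frame(reference) && "sample_id" %in% names(reference))
      reference$sample_id[1] else "RDP",
    phenotype = "RDP",
    x_um = runif(n, min(xyz[, 1]), max(xyz[, 1])),
    y_um = runif(n, min(xyz[, 2]), max(xyz[, 2])),
    z_um = if (diff(zr) > 0) runif(n, zr[1], zr[2]) else zr[1]))
  if (is.data.frame(reference)) {
    for (ch in channel_names(reference)) out[[ch]] <- 0
  }
  out
}

#' Gate points on a surface
#'
#' Retains the points contained in the surface (boundary counts as inside),
#' e.g. to discard random control points that fell outside the tissue.
#'
#' @param points A cell table (rows are kept/dropped as a whole).
#' @param surface A `tissue_surface`.
#' @return The retained subset of `points`.
#' @export
gate_points <- function(points, surface) {
  keep <- surface_contains(surface, points)
  points[keep, , drop = FALSE]
}

#' Area of a 2D surface
#'
#' Shoelace area of the boundary loops with even-odd hole handling (a loop
#' nested inside an odd number of other loops subtracts).
#'
#' @param surface A 2D `tissue_surface`.
#' @return Area in square micrometers.
#' @export
surface_area <- function(surface) {
  if (surface$dim != 2L) {
    abort("surface_area is defined for 2D surfaces",
          class = "tissuemap_parameter_error")
  }
  rings <- assemble_rings(surface$edges)
  p <- surface$points
  signed_area <- function(idx) {
    x <- p[idx, 1]; y <- p[idx, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }
  ring_area <- vapply(rings, function(r) abs(signed_area(r)), numeric(1))
  sign <- vapply(seq_along(rings), function(i) {
    v0 <- p[rings[[i]][1], , drop = FALSE]
    depth <- sum(vapply(seq_along(rings)[-i], function(j) {
      idx <- rings[[j]]
      seg <- cbind(p[idx, 1], p[idx, 2],
                   p[c(idx[-1], idx[1]), 1], p[c(idx[-1], idx[1]), 2])
      as.logical(crossings_inside_2d_cpp(v0[1] + 1e-9, v0[2] + 2e-10, seg))
    }, logical(1)))
    if (depth %% 2 == 1) -1 else 1
  }, numeric(1))
  sum(ring_area * sign)
}

# Walk the boundary edge set into closed loops (each vertex of a valid
# alpha-shape boundary has even degree; simple boundaries have degree 2).
assemble_rings <- function(edges) {
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  used <- matrix(FALSE, nrow(edges), 1)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  remaining <- seq_len(nrow(edges))
  rings <- list()
  while (length(remaining)) {
    e <- remaining[1]
    ring <- c(edges[e, 1], edges[e, 2])
    remaining <- remaining[-1]
    repeat {
      last <- ring[length(ring)]
      nxt_edge <- NULL
      for (r in remaining) {
        if (edges[r, 1] == last || edges[r, 2] == last) {
          nxt_edge <- r
          break
        }
      }
      if (is.null(nxt_edge)) break
      nxt <- if (edges[nxt_edge, 1] == last) edges[nxt_edge, 2]
             else edges[nxt_edge, 1]
      remaining <- setdiff(remaining, nxt_edge)
      if (nxt == ring[1]) break
      ring <- c(ring, nxt)
    }
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}
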