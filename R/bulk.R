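# Tumor-bulk delineation: an alpha shape (concave hull) drawn around the
# segmented tumor-epithelium pixels.
#
# Alpha semantics: Delaunay triangles are kept iff their circumradius is at
# most 1/alpha, with coordinates in pixels at the segmentation spacing
# (default 1.0 um/px, where the conventional alpha = 0.038 applies); alpha
# of 0 keeps everything and reduces to the convex hull.

triangle_circumradius <- function(pts, tris) {
  a <- pts[tris[, 1], , drop = FALSE]
  b <- pts[tris[, 2], , drop = FALSE]
  c <- pts[tris[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - c)^2))
  lb <- sqrt(rowSums((a - c)^2))
  lc <- sqrt(rowSums((a - b)^2))
  K <- abs((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
             (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
  r <- la * lb * lc / (4 * K)
  r[K <= 0] <- Inf
  r
}

#' Delaunay triangulation of a 2-D point set
#'
#' Bowyer-Watson triangulation (the basis of [alpha_shape()]); triangles
#' are returned CCW-oriented and the triangulation's boundary is the
#' convex hull of the points.
#'
#' @param points N x 2 matrix of (x, y) coordinates (deduplicated
#'   internally).
#' @return T x 3 integer matrix of one-based vertex indices into the
#'   deduplicated point set (returned as attribute `points`).
#' @export
delaunay_triangles <- function(points) {
  points <- unique(as.matrix(points))
  tris <- cpp_delaunay(points)
  attr(tris, "points") <- points
  tris
}

empty_bulk_polygon <- function(alpha) {
  structure(list(rings = list(), triangles = matrix(integer(0), 0, 3),
                 points = matrix(numeric(0), 0, 2), alpha = alpha,
                 area = 0, n_polygons = 0L), class = "BulkPolygon")
}

#' Alpha shape of a 2-D point set
#'
#' Delaunay-triangulates the points, keeps triangles whose circumradius is
#' at most 1/alpha, and dissolves the kept triangles into boundary polygons.
#' `alpha = 0` yields the convex hull.
#'
#' @param points N x 2 matrix of (x, y) coordinates.
#' @param alpha nonnegative; triangles kept iff circumradius <= 1/alpha.
#' @return a `BulkPolygon`: `rings` (list of N x 2 rings; outer rings and
#'   holes distinguished by orientation), `triangles` (kept Delaunay
#'   triangles, one-based into `points`), `area` (sum of kept triangle
#'   areas), `alpha`, `n_polygons` (number of outer rings).
#' @export
alpha_shape <- function(points, alpha = 0.038) {
  stopifnot(alpha >= 0)
  points <- unique(as.matrix(points))
  if (nrow(points) < 3) {
    warning("alpha_shape: fewer than 3 distinct points; empty shape")
    return(empty_bulk_polygon(alpha))
  }
  tris <- cpp_delaunay(points)
  if (nrow(tris) == 0) {
    warning("alpha_shape: degenerate (collinear) point set; empty shape")
    return(empty_bulk_polygon(alpha))
  }
  rmax <- if (alpha == 0) Inf else 1 / alpha
  keep <- triangle_circumradius(points, tris) <= rmax
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) {
    warning("alpha_shape: no triangle satisfies the alpha criterion")
    return(empty_bulk_polygon(alpha))
  }
  area <- sum(abs((points[tris[, 2], 1] - points[tris[, 1], 1]) *
                    (points[tris[, 3], 2] - points[tris[, 1], 2]) -
                    (points[tris[, 3], 1] - points[tris[, 1], 1]) *
                    (points[tris[, 2], 2] - points[tris[, 1], 2])) / 2)
  rings <- dissolve_triangles(points, tris)
  n_poly <- sum(vapply(rings, ring_area, numeric(1)) > 0)
  structure(list(rings = rings, triangles = tris, points = points,
                 alpha = alpha, area = area, n_polygons = as.integer(n_poly)),
            class = "BulkPolygon")
}

#' @export
print.BulkPolygon <- function(x, ...) {
  cat(sprintf("BulkPolygon: %d polygon(s), %d ring(s), area %.1f px^2 (alpha %g)\n",
              x$n_polygons, length(x$rings), x$area, x$alpha))
  invisible(x)
}

# Boundary of a triangle union: directed edges used exactly once (triangles
# are CCW-oriented) chained into rings; outer rings come out CCW, holes CW.
dissolve_triangles <- function(pts, tris) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  boundary <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  if (!nrow(boundary)) return(list())
  # adjacency: outgoing boundary edges per start vertex
  out <- split(seq_len(nrow(boundary)), boundary[, 1])
  used <- rep(FALSE, nrow(boundary))
  rings <- list()
  for (start_edge in seq_len(nrow(boundary))) {
    if (used[start_edge]) next
    ring <- integer(0)
    ei <- start_edge
    repeat {
      used[ei] <- TRUE
      v_from <- boundary[ei, 1]; v_to <- boundary[ei, 2]
      ring <- c(ring, v_from)
      cand <- out[[as.character(v_to)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) == 1) ei <- cand[1]
      else {
        # pinch vertex: take the sharpest left turn to stay on this component
        din <- pts[v_to, ] - pts[v_from, ]
        ang <- vapply(cand, function(ci) {
          dout <- pts[boundary[ci, 2], ] - pts[v_to, ]
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        ei <- cand[which.max(ang)]
      }
    }
    if (length(ring) >= 3)
      rings[[length(rings) + 1]] <- pts[ring, , drop = FALSE]
  }
  rings
}

#' Tumor bulk from a tumor-epithelium mask
#'
#' Subsamples foreground pixel centers on a stride grid, draws their alpha
#' shape, rasterizes the kept triangles back to a mask and fills small
#' interior holes.
#'
#' @param tumor_epi binary `LabelMask` or matrix of tumor epithelium.
#' @param alpha alpha parameter in 1/pixels at the mask spacing.
#' @param stride subsampling stride in pixels (default 8).
#' @param fill_hole_frac fill interior holes below this fraction of the bulk
#'   area (default 0.05).
#' @return list with `polygon` (a `BulkPolygon`, coordinates in mask pixels)
#'   and `mask` (binary `LabelMask`).
#' @export
bulk_from_mask <- function(tumor_epi, alpha = 0.038, stride = 8,
                           fill_hole_frac = 0.05) {
  m <- mask_data(tumor_epi)
  spacing <- if (inherits(tumor_epi, "LabelMask")) tumor_epi$spacing_um else 1.0
  cls <- c(background = 0L, tumor_bulk = 1L)
  empty <- function() list(polygon = empty_bulk_polygon(alpha),
                           mask = label_mask(matrix(0L, nrow(m), ncol(m)), spacing, cls))
  if (!any(m != 0)) return(empty())
  s <- max(1L, as.integer(stride))
  repeat {
    idx <- which(m != 0, arr.ind = TRUE) - 1L
    sel <- idx[idx[, 1] %% s == 0 & idx[, 2] %% s == 0, , drop = FALSE]
    if (nrow(sel) >= 3 || s == 1) break
    s <- max(1L, s %/% 2L)
  }
  if (nrow(sel) < 3) return(empty())
  pts <- cbind(x = sel[, 2] + 0.5, y = sel[, 1] + 0.5)
  poly <- suppressWarnings(alpha_shape(pts, alpha))
  if (nrow(poly$triangles) == 0) return(empty())
  bulk <- cpp_fill_triangles(poly$points, poly$triangles, nrow(m), ncol(m))
  bulk <- fill_small_holes(bulk, fill_hole_frac * sum(bulk != 0))
  list(polygon = poly, mask = label_mask(bulk, spacing, cls))
}
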