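# Planar polygon geometry on the degree grid.
#
# Polygons are lists of rings; each ring is a two-column matrix of (lon, lat)
# vertices, not necessarily closed (the closing edge is implicit). The first
# ring is the outer boundary, any further rings are holes. All areas are
# planar shoelace areas in square degrees: the assessment domains sit on the
# equator, where this is an excellent approximation and — more importantly —
# keeps cell-overlap computations exactly reproducible by brute force.

# Signed shoelace area of one ring (positive for counter-clockwise).
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3) return(0)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Unsigned area of a polygon (outer ring minus holes).
polygon_area <- function(rings) {
  if (length(rings) == 0) return(0)
  a <- abs(ring_area_signed(rings[[1]]))
  if (length(rings) > 1) {
    a <- a - sum(vapply(rings[-1], function(r) abs(ring_area_signed(r)), 0))
  }
  max(a, 0)
}

# Sutherland-Hodgman clip of one ring against a half-plane. `inside` and
# `intersect` close over the plane. Returns a matrix (possibly 0-row).
clip_halfplane <- function(ring, inside, intersect) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- vector("list", 2L * n)
  k <- 0L
  prev <- ring[n, ]
  prev_in <- inside(prev)
  for (i in seq_len(n)) {
    cur <- ring[i, ]
    cur_in <- inside(cur)
    if (cur_in) {
      if (!prev_in) {
        k <- k + 1L; out[[k]] <- intersect(prev, cur)
      }
      k <- k + 1L; out[[k]] <- cur
    } else if (prev_in) {
      k <- k + 1L; out[[k]] <- intersect(prev, cur)
    }
    prev <- cur
    prev_in <- cur_in
  }
  if (k == 0L) return(ring[0, , drop = FALSE])
  do.call(rbind, out[seq_len(k)])
}

# Clip a ring to the axis-aligned box [xmin,xmax] x [ymin,ymax].
# The box is convex so Sutherland-Hodgman is exact for any simple ring.
clip_ring_box <- function(ring, xmin, xmax, ymin, ymax) {
  lerp <- function(p, q, t) p + t * (q - p)
  planes <- list(
    list(inside = function(p) p[1] >= xmin,
         intersect = function(p, q) lerp(p, q, (xmin - p[1]) / (q[1] - p[1]))),
    list(inside = function(p) p[1] <= xmax,
         intersect = function(p, q) lerp(p, q, (xmax - p[1]) / (q[1] - p[1]))),
    list(inside = function(p) p[2] >= ymin,
         intersect = function(p, q) lerp(p, q, (ymin - p[2]) / (q[2] - p[2]))),
    list(inside = function(p) p[2] <= ymax,
         intersect = function(p, q) lerp(p, q, (ymax - p[2]) / (q[2] - p[2])))
  )
  for (pl in planes) {
    ring <- clip_halfplane(ring, pl$inside, pl$intersect)
    if (nrow(ring) < 3) return(ring[0, , drop = FALSE])
  }
  ring
}

# Overlap area between a polygon (list of rings, holes allowed) and a box.
polygon_box_overlap <- function(rings, xmin, xmax, ymin, ymax) {
  if (length(rings) == 0) return(0)
  outer <- clip_ring_box(rings[[1]], xmin, xmax, ymin, ymax)
  a <- abs(ring_area_signed(outer))
  if (a == 0) return(0)
  if (length(rings) > 1) {
    for (h in rings[-1]) {
      hc <- clip_ring_box(h, xmin, xmax, ymin, ymax)
      a <- a - abs(ring_area_signed(hc))
    }
  }
  max(a, 0)
}

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2]))
}

# A rectangle polygon helper (single CCW ring).
rect_ring <- function(xmin, xmax, ymin, ymax) {
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
         ncol = 2, byrow = TRUE)
}

#' Read and write named polygon sets as GeoJSON
#'
#' Features must be `Polygon` or `MultiPolygon` geometries carrying a `name`
#' property (additional properties are kept and returned in the `properties`
#' list). Coordinates are geographic degrees. `write_geojson_polygons()` is
#' the exact inverse for polygons produced by this package.
#'
#' @param path File path.
#' @param polys For writing: a named list, each element a list of rings (a
#'   ring is a 2-column lon/lat matrix; first ring outer, rest holes).
#' @param properties Optional named list (per feature) of extra properties.
#' @return `read_geojson_polygons()`: a list with elements `polygons` (named
#'   list of ring lists) and `properties` (named list of property lists).
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  polys <- list(); props <- list()
  for (feat in gj$features) {
    nm <- feat$properties$name
    if (is.null(nm)) stop("every feature needs a `name` property")
    geom <- feat$geometry
    to_ring <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
      # GeoJSON rings repeat the first vertex; our rings do not
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, to_ring),
      MultiPolygon = {
        # flatten: outer rings and holes of every part, in order
        unlist(lapply(geom$coordinates, function(part) lapply(part, to_ring)),
               recursive = FALSE)
      },
      stop("unsupported geometry type: ", geom$type)
    )
    polys[[nm]] <- rings
    props[[nm]] <- feat$properties[setdiff(names(feat$properties), "name")]
  }
  list(polygons = polys, properties = props)
}

#' @rdname read_geojson_polygons
#' @export
write_geojson_polygons <- function(polys, path, properties = NULL) {
  feats <- purrr::imap(polys, function(rings, nm) {
    coords <- lapply(rings, function(r) {
      closed <- rbind(r, r[1, , drop = FALSE])
      lapply(seq_len(nrow(closed)), function(i) as.list(unname(closed[i, ])))
    })
    pr <- c(list(name = nm), properties[[nm]])
    list(type = "Feature",
         properties = pr,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
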