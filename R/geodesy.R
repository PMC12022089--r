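#' Elevation rasters and topographic least-cost distances
#'
#' Distances between languages are least-cost paths over an elevation
#' raster: passable cells form a graph whose 8-neighbour edges are weighted
#' by the 3-D Euclidean length between cell centres,
#' `sqrt(horizontal^2 + delta_elevation^2)`. Water / impassable cells are
#' `NA` and never traversed; maritime routes are deliberately not modelled.
#' Horizontal distance is planar (metre grids) or spherical great-circle
#' (degree grids, authalic radius 6371008.8 m).
#'
#' @name glossarea-geodesy
NULL

#' Construct an elevation raster
#'
#' @param values numeric matrix of elevations (m); row 1 is the northern /
#'   top edge; `NA` marks nodata (water or otherwise impassable).
#' @param cellsize cell edge length: metres if `crs = "planar"`, degrees if
#'   `crs = "lonlat"`.
#' @param origin `c(x, y)` of the lower-left corner (metres or lon/lat).
#' @param crs `"planar"` or `"lonlat"`.
#' @return object of class `elevation_raster`.
#' @export
elevation_raster <- function(values, cellsize, origin = c(0, 0),
                             crs = c("planar", "lonlat")) {
  crs <- match.arg(crs)
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, cellsize = cellsize,
                 origin = as.numeric(origin), crs = crs),
            class = "elevation_raster")
}

#' Read an ESRI ASCII elevation grid
#'
#' Plain-text `.asc` raster: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of elevations from the northern edge down.
#'
#' @param path `.asc` file.
#' @param crs `"planar"` or `"lonlat"` (the format does not record units).
#' @return an `elevation_raster`.
#' @export
read_elevation_asc <- function(path, crs = "lonlat") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  elevation_raster(m, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner), crs)
}

# Cell centre coordinates; rows indexed from the top (north).
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- r$origin[1] + (seq_len(nc) - 0.5) * r$cellsize
  y <- r$origin[2] + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(x = x, y = y)
}

# Horizontal distance between point matrices (2 cols), respecting crs.
horiz_dist <- function(p, q, crs) {
  if (crs == "planar") {
    sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)
  } else {
    geosphere::distHaversine(p, q, r = EARTH_RADIUS_M)
  }
}

#' Build the least-cost graph over passable cells
#'
#' Nodes are the non-`NA` cells; edges connect 8-neighbours; the edge
#' weight is the 3-D distance `sqrt(horizontal^2 + (elev_a - elev_b)^2)`
#' with the horizontal component measured between cell centres.
#'
#' @param raster an [elevation_raster()].
#' @return object of class `cost_graph`: the igraph, the raster, and the
#'   passable-cell index.
#' @export
build_cost_graph <- function(raster) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  pass <- which(!is.na(v))                      # column-major cell ids
  if (!length(pass)) stop("all cells impassable")
  cc <- cell_centers(raster)
  idx <- function(r, c) (c - 1L) * nr + r
  edges_from <- integer(0); edges_to <- integer(0); w <- numeric(0)
  # four forward directions cover all 8-neighbour pairs once
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  rc <- cbind(row = ((pass - 1L) %% nr) + 1L, col = ((pass - 1L) %/% nr) + 1L)
  for (d in dirs) {
    r2 <- rc[, 1] + d[1]; c2 <- rc[, 2] + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- !is.na(v[cbind(r2[ok], c2[ok])])
    if (!any(ok)) next
    a <- pass[ok]; b <- idx(r2[ok], c2[ok])
    p <- cbind(cc$x[rc[ok, 2]], cc$y[rc[ok, 1]])
    q <- cbind(cc$x[c2[ok]], cc$y[r2[ok]])
    h <- horiz_dist(p, q, raster$crs)
    dz <- v[b] - v[a]
    edges_from <- c(edges_from, a); edges_to <- c(edges_to, b)
    w <- c(w, sqrt(h^2 + dz^2))
  }
  vmap <- match(seq_len(nr * nc), pass)         # cell id -> vertex id
  g <- igraph::make_empty_graph(n = length(pass), directed = FALSE)
  g <- igraph::add_edges(g, rbind(vmap[edges_from], vmap[edges_to]))
  igraph::E(g)$weight <- w
  structure(list(graph = g, raster = raster, pass = pass, vmap = vmap),
            class = "cost_graph")
}

#' Snap a point to the nearest passable cell
#'
#' Nearest passable cell centre by (geodesic or planar) distance; ties are
#' broken by (row, col) lexicographic order.
#'
#' @param cg a [build_cost_graph()] result.
#' @param pt `c(x, y)` (planar) or `c(lon, lat)`.
#' @return vertex id within the cost graph.
#' @export
snap_to_cell <- function(cg, pt) {
  r <- cg$raster
  nr <- nrow(r$values)
  cc <- cell_centers(r)
  rc <- cbind(((cg$pass - 1L) %% nr) + 1L, ((cg$pass - 1L) %/% nr) + 1L)
  p <- cbind(cc$x[rc[, 2]], cc$y[rc[, 1]])
  d <- horiz_dist(p, matrix(pt, nrow(p), 2, byrow = TRUE), r$crs)
  cand <- which(d == min(d))
  if (length(cand) > 1) cand <- cand[order(rc[cand, 1], rc[cand, 2])][1]
  cand
}

#' Topographic distance between two points
#'
#' Shortest-path (Dijkstra) cost between the passable cells the two points
#' snap to.
#'
#' @param cg a `cost_graph`.
#' @param a,b points (`c(x, y)` or `c(lon, lat)`).
#' @return distance in metres.
#' @export
topographic_distance <- function(cg, a, b) {
  va <- snap_to_cell(cg, a); vb <- snap_to_cell(cg, b)
  d <- igraph::distances(cg$graph, v = va, to = vb, algorithm = "dijkstra")[1, 1]
  if (!is.finite(d)) stop("no path exists between the two points")
  d
}

#' Pairwise topographic distance matrix
#'
#' @param cg a `cost_graph`.
#' @param pts matrix with one point per row.
#' @return symmetric matrix of metres, zero diagonal.
#' @export
topographic_distance_matrix <- function(cg, pts) {
  v <- apply(pts, 1, function(p) snap_to_cell(cg, p))
  d <- igraph::distances(cg$graph, v = v, to = v, algorithm = "dijkstra")
  dimnames(d) <- list(rownames(pts), rownames(pts))
  if (any(!is.finite(d))) stop("no path exists between some points")
  d
}

#' Assemble a distance set
#'
#' @param pairwise symmetric language-by-language distance matrix (m).
#' @param d_entry optional named per-language distance-to-entry vector (m).
#' @param choke optional choke point `c(x, y)`.
#' @param d_choke optional named per-language distance to the choke (m).
#' @return object of class `distance_set`.
#' @export
distance_set <- function(pairwise, d_entry = NULL, choke = NULL,
                         d_choke = NULL) {
  stopifnot(is.matrix(pairwise), nrow(pairwise) == ncol(pairwise))
  if (max(abs(pairwise - t(pairwise))) > 1e-6) stop("pairwise not symmetric")
  if (any(diag(pairwise) != 0)) stop("pairwise diagonal must be zero")
  if (!is.null(d_entry) && any(d_entry < 0, na.rm = TRUE))
    stop("d_entry must be >= 0")
  structure(list(pairwise = pairwise, d_entry = d_entry, choke = choke,
                 d_choke = d_choke), class = "distance_set")
}

#' Compose two continental distance sets through a choke point
#'
#' Cross-continent distances are routed through a single designated land
#' crossing: `d(a, b) = d(a, choke) + d(choke, b)` for `a` northern and `b`
#' southern; within-continent distances are unchanged.
#'
#' @param d_north,d_south `distance_set`s carrying `d_choke`.
#' @param choke the choke point `c(x, y)`, recorded on the result.
#' @return combined `distance_set` over both language sets.
#' @export
compose_via_choke <- function(d_north, d_south, choke) {
  if (is.null(d_north$d_choke) || is.null(d_south$d_choke))
    stop("both distance sets must carry d_choke (choke unreachable?)")
  if (any(!is.finite(d_north$d_choke)) || any(!is.finite(d_south$d_choke)))
    stop("choke unreachable from some language")
  nn <- nrow(d_north$pairwise); ns <- nrow(d_south$pairwise)
  cross <- outer(d_north$d_choke, d_south$d_choke, `+`)
  pw <- rbind(cbind(d_north$pairwise, cross),
              cbind(t(cross), d_south$pairwise))
  nm <- c(rownames(d_north$pairwise), rownames(d_south$pairwise))
  dimnames(pw) <- list(nm, nm)
  de <- NULL
  if (!is.null(d_north$d_entry)) {
    de_s <- d_south$d_entry
    if (is.null(de_s)) de_s <- rep(NA_real_, ns)
    de <- c(d_north$d_entry, de_s)
    names(de) <- nm
  }
  distance_set(pw, d_entry = de, choke = choke,
               d_choke = c(d_north$d_choke, d_south$d_choke))
}

#' Construct a dispersal path
#'
#' A polyline from the entry point through ordered waypoints, resampled to
#' a dense sequence of points at most `step` metres apart, with cumulative
#' along-path arc length from the entry.
#'
#' @param entry `c(x, y)` or `c(lon, lat)` of the entry point.
#' @param waypoints matrix of points (one per row), ordered from the entry.
#' @param step resampling step (m), default 10 km.
#' @param crs `"planar"` or `"lonlat"`.
#' @return object of class `dispersal_path`: `points` (matrix) and `arc`
#'   (non-decreasing arc lengths, 0 at entry).
#' @export
dispersal_path <- function(entry, waypoints, step = 1e4,
                           crs = c("planar", "lonlat")) {
  crs <- match.arg(crs)
  verts <- rbind(matrix(entry, 1), waypoints)
  pts <- verts[1, , drop = FALSE]
  for (i in seq_len(nrow(verts) - 1)) {
    a <- verts[i, ]; b <- verts[i + 1, ]
    seg <- horiz_dist(matrix(a, 1), matrix(b, 1), crs)
    nseg <- max(1L, ceiling(seg / step))
    tt <- seq_len(nseg) / nseg
    pts <- rbind(pts, cbind(a[1] + tt * (b[1] - a[1]),
                            a[2] + tt * (b[2] - a[2])))
  }
  arc <- c(0, cumsum(horiz_dist(pts[-nrow(pts), , drop = FALSE],
                                pts[-1, , drop = FALSE], crs)))
  structure(list(points = pts, arc = arc, crs = crs),
            class = "dispersal_path")
}

#' Distance to the entry point along a dispersal path
#'
#' For a language location, `D` is the along-path arc length from the entry
#' to the path point minimising the topographic distance to the language,
#' plus that off-path topographic distance. Every resampled path point is
#' evaluated; ties are broken toward the smaller arc length.
#'
#' @param path a [dispersal_path()].
#' @param lang language location (`c(x, y)` or `c(lon, lat)`).
#' @param cg optional `cost_graph`; when `NULL` the off-path leg uses the
#'   straight-line (planar or great-circle) distance, the flat-terrain
#'   limit of the least-cost distance.
#' @return `D` in metres.
#' @export
distance_to_entry <- function(path, lang, cg = NULL) {
  if (!nrow(path$points)) stop("empty dispersal path")
  if (is.null(cg)) {
    off <- horiz_dist(path$points,
                      matrix(lang, nrow(path$points), 2, byrow = TRUE),
                      path$crs)
  } else {
    vl <- snap_to_cell(cg, lang)
    vp <- apply(path$points, 1, function(p) snap_to_cell(cg, p))
    off <- igraph::distances(cg$graph, v = vl, to = vp,
                             algorithm = "dijkstra")[1, ]
    if (all(!is.finite(off))) stop("language unreachable from every path point")
  }
  tot <- path$arc + off
  best <- which(tot == min(tot, na.rm = TRUE))[1]  # smaller arc wins ties
  tot[best]
}

#' Read a GeoJSON geometry
#'
#' Minimal reader for the geometries the pipeline needs: `Point` (entry,
#' choke), `LineString` (dispersal paths) and `Polygon` (regions). Returns
#' coordinates as matrices/vectors in (lon, lat) order.
#'
#' @param path GeoJSON file.
#' @return list of geometries, each `list(type, coordinates)`.
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- if (identical(j$type, "FeatureCollection")) {
    if (is.data.frame(j$features)) {
      lapply(seq_len(nrow(j$features)), function(i)
        list(type = j$features$geometry$type[i],
             coordinates = j$features$geometry$coordinates[[i]]))
    } else j$features
  } else if (identical(j$type, "Feature")) list(j$geometry) else list(j)
  lapply(feats, function(f) {
    co <- f$coordinates
    if (identical(f$type, "Point")) co <- as.numeric(co)
    if (identical(f$type, "LineString")) co <- matrix(unlist(co), ncol = 2, byrow = !is.matrix(co))
    if (identical(f$type, "Polygon")) {
      ring <- if (is.list(co)) co[[1]] else co
      co <- matrix(unlist(ring), ncol = 2, byrow = !is.matrix(ring))
    }
    list(type = f$type, coordinates = co)
  })
}

#' Export a distance set as CSV
#'
#' Writes the pairwise matrix (languages x languages) and, when present,
#' the per-language distance-to-entry as a second file with suffix
#' `_entry.csv`.
#'
#' @param ds a `distance_set`.
#' @param path output CSV for the pairwise matrix.
#' @export
write_distance_set <- function(ds, path) {
  utils::write.csv(ds$pairwise, path, row.names = TRUE)
  if (!is.null(ds$d_entry)) {
    p2 <- sub("\\.csv$", "_entry.csv", path)
    utils::write.csv(data.frame(id = names(ds$d_entry), d_entry = ds$d_entry),
                     p2, row.names = FALSE)
  }
  invisible(path)
}
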