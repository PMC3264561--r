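#' @useDynLib whorlsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils head tail write.csv
NULL

## ---- polygon primitives ----------------------------------------------------

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy two-column matrix of vertex coordinates, one row per vertex.
#' @return signed area (scalar).
#' @keywords internal
polygon_signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area-weighted centroid of a simple polygon
#' @param xy two-column coordinate matrix (any orientation).
#' @return length-2 numeric vector.
#' @keywords internal
polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

## does a simple-polygon ring stay simple? O(k^2) segment test, used on small rings
polygon_is_simple <- function(xy) {
  k <- nrow(xy)
  if (k < 3L) return(FALSE)
  seg <- cbind(xy, rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]))
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      ## skip edges sharing a vertex (consecutive, incl. wrap-around pair)
      if (b == a + 1L || (a == 1L && b == k)) next
      if (segments_cross(seg[a, 1:2], seg[a, 3:4], seg[b, 1:2], seg[b, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

## ---- mesh construction -----------------------------------------------------

#' Construct a planar polygonal tissue mesh
#'
#' The mesh is the cell-complex representation used throughout the package:
#' shared vertices, walls (edges, possibly multi-segment between a cell pair)
#' and polygonal cells. Cell rings are normalized to counter-clockwise
#' orientation on construction. Resting areas default to the current areas and
#' wall resting lengths to the current lengths, so a freshly built tissue is at
#' its mechanical energy minimum.
#'
#' @param pos numeric matrix (n_vertices x 2) of vertex positions.
#' @param rings list of integer vectors; each is a cell's vertex ring.
#' @return an object of class `tissue_mesh`: a list with vertex positions,
#'   cell rings, per-cell mechanical and physiological state (resting area,
#'   area at last division, auxin concentration, endosomal PIN, wall PIN per
#'   directed neighbor pair, differentiation flag/time), the wall table and the
#'   directed cell-adjacency used by the transport equations.
#' @export
tissue_mesh <- function(pos, rings) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  dimnames(pos) <- NULL
  if (ncol(pos) != 2L) stop("pos must have two columns")
  if (any(!is.finite(pos))) stop("vertex positions must be finite")
  rings <- lapply(rings, function(r) {
    r <- as.integer(r)
    if (length(r) < 3L) stop("cell rings need at least 3 vertices")
    if (anyDuplicated(r)) stop("cell ring has repeated vertices")
    if (polygon_signed_area(pos[r, , drop = FALSE]) < 0) r <- rev(r)
    r
  })
  nc <- length(rings)
  mesh <- structure(list(
    pos = pos,
    cells = rings,
    rest_area = numeric(nc),
    area_last_div = numeric(nc),
    auxin = numeric(nc),
    pin_endo = numeric(nc),
    differentiated = logical(nc),
    diff_time = rep(NA_real_, nc),
    epoch = 0
  ), class = "tissue_mesh")
  mesh <- rebuild_topology(mesh)
  a <- cell_areas(mesh)
  if (any(a <= 0)) stop("degenerate cell in input rings")
  mesh$rest_area <- a
  mesh$area_last_div <- a
  mesh$wall_rest <- wall_lengths(mesh)
  mesh
}

#' Rebuild wall table and cell adjacency from the cell rings
#'
#' Called after any topological change (division, wall subdivision). Wall
#' resting lengths and per-pair wall PIN are carried over where the entity
#' persists; new walls get their current length as resting length and new
#' directed pairs start with zero wall PIN.
#' @param mesh a `tissue_mesh`.
#' @return the mesh with `walls`, `wall_cells`, `wall_rest`, `edge_from`,
#'   `edge_to`, `edge_rev`, `edge_walls`, `pin_edge` recomputed.
#' @keywords internal
rebuild_topology <- function(mesh) {
  nc <- length(mesh$cells)
  nv <- nrow(mesh$pos)
  ## enumerate directed ring edges with owning cell
  owner <- rep.int(seq_len(nc), lengths(mesh$cells))
  v1 <- unlist(mesh$cells, use.names = FALSE)
  v2 <- unlist(lapply(mesh$cells, function(r) c(r[-1L], r[1L])), use.names = FALSE)
  lo <- pmin(v1, v2); hi <- pmax(v1, v2)
  key <- as.numeric(lo) * (nv + 1) + hi
  uk <- unique(key)
  wid <- match(key, uk)                 # wall id per ring edge
  nw <- length(uk)
  walls <- cbind(lo[match(uk, key)], hi[match(uk, key)])
  cnt <- tabulate(wid, nw)
  if (any(cnt > 2L)) stop("wall shared by more than two cells")
  wall_cells <- matrix(NA_integer_, nw, 2L)
  first <- match(seq_len(nw), wid)
  wall_cells[, 1L] <- owner[first]
  if (any(cnt == 2L)) {
    dup <- duplicated(wid)
    wall_cells[wid[dup], 2L] <- owner[dup]
  }
  ## carry over resting lengths
  old_rest <- rep(NA_real_, nw)
  if (!is.null(mesh$walls)) {
    old_key <- as.numeric(mesh$walls[, 1L]) * (nv + 1) + mesh$walls[, 2L]
    m <- match(uk, old_key)
    old_rest <- mesh$wall_rest[m]
  }
  len <- sqrt(rowSums((mesh$pos[walls[, 1L], , drop = FALSE] -
                       mesh$pos[walls[, 2L], , drop = FALSE])^2))
  old_rest[is.na(old_rest)] <- len[is.na(old_rest)]

  ## directed cell adjacency from interior walls
  int <- which(!is.na(wall_cells[, 2L]))
  ef <- c(wall_cells[int, 1L], wall_cells[int, 2L])
  et <- c(wall_cells[int, 2L], wall_cells[int, 1L])
  ewall <- c(int, int)
  ekey <- as.numeric(ef) * (nc + 1) + et
  ue <- sort(unique(ekey))
  eid <- match(ekey, ue)
  m_e <- length(ue)
  edge_from <- integer(m_e); edge_to <- integer(m_e)
  f1 <- match(seq_len(m_e), eid)
  edge_from <- ef[f1]; edge_to <- et[f1]
  rkey <- as.numeric(edge_to) * (nc + 1) + edge_from
  edge_rev <- match(rkey, ue)
  edge_walls <- split(ewall, eid)       # wall ids contributing to each pair
  ## carry over wall PIN by (from, to) pair
  pin_edge <- numeric(m_e)
  if (!is.null(mesh$edge_from) && length(mesh$edge_from)) {
    old_ekey <- as.numeric(mesh$edge_from) * (nc + 1) + mesh$edge_to
    m <- match(ue, old_ekey)
    keep <- !is.na(m)
    pin_edge[keep] <- mesh$pin_edge[m[keep]]
  }
  mesh$walls <- walls
  mesh$wall_cells <- wall_cells
  mesh$wall_rest <- old_rest
  mesh$edge_from <- edge_from
  mesh$edge_to <- edge_to
  mesh$edge_rev <- edge_rev
  mesh$edge_walls <- edge_walls
  mesh$pin_edge <- pin_edge
  mesh
}

#' Build the initial compact tissue
#'
#' The simulated meristem starts as a small "callus" of roughly equal-area
#' cells; the default 4-cell tissue is a 2x2 block of unit quadrilaterals (the
#' Monte Carlo relaxation rounds the outline out during the first growth
#' steps). For other `n_cells` a near-square grid is used, dropping surplus
#' cells from the last row.
#'
#' @param n_cells number of starting cells (default 4).
#' @param cell_scale linear size of one cell, in model length units.
#' @return a `tissue_mesh`.
#' @examples
#' m <- build_initial_tissue(4, 1.0)
#' length(m$cells)      # 4
#' nrow(m$pos)          # 9
#' @export
build_initial_tissue <- function(n_cells = 4L, cell_scale = 1.0) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be >= 1")
  if (cell_scale <= 0) stop("cell_scale must be > 0")
  nr <- max(1L, as.integer(floor(sqrt(n_cells))))
  ncg <- as.integer(ceiling(n_cells / nr))
  build_grid_tissue(nr, ncg, cell_scale, keep = n_cells)
}

#' Build an nr x nc block of quadrilateral cells
#' @param nr,nc grid rows and columns.
#' @param cell_scale linear cell size.
#' @param keep keep only the first `keep` cells in row-major order.
#' @return a `tissue_mesh`.
#' @export
build_grid_tissue <- function(nr, nc, cell_scale = 1.0, keep = nr * nc) {
  vid <- function(r, c) r * (nc + 1L) + c + 1L
  gx <- rep(0:nc, times = nr + 1L) * cell_scale
  gy <- rep(0:nr, each = nc + 1L) * cell_scale
  pos <- cbind(gx, gy)
  rings <- vector("list", keep)
  k <- 0L
  for (r in 0:(nr - 1L)) for (c in 0:(nc - 1L)) {
    if (k >= keep) break
    k <- k + 1L
    rings[[k]] <- c(vid(r, c), vid(r, c + 1L), vid(r + 1L, c + 1L), vid(r + 1L, c))
  }
  ## drop unused vertices, reindex
  used <- sort(unique(unlist(rings)))
  remap <- integer(nrow(pos)); remap[used] <- seq_along(used)
  rings <- lapply(rings, function(rg) remap[rg])
  tissue_mesh(pos[used, , drop = FALSE], rings)
}

#' Build a one-dimensional ring of cells (annulus of quadrilaterals)
#'
#' Used for peak-spacing experiments: every cell has exactly two neighbors and
#' the topology is periodic.
#'
#' @param n_cells number of cells around the ring.
#' @param radius mid-line radius; wall depth is chosen so cells are roughly
#'   square if `radius = n_cells / (2*pi)`.
#' @param depth radial cell depth.
#' @return a `tissue_mesh`.
#' @export
build_ring_tissue <- function(n_cells, radius = n_cells / (2 * pi), depth = 1.0) {
  if (n_cells < 3L) stop("ring needs at least 3 cells")
  th <- 2 * pi * (0:(n_cells - 1L)) / n_cells
  r0 <- radius - depth / 2
  r1 <- radius + depth / 2
  inner <- cbind(r0 * cos(th), r0 * sin(th))
  outer <- cbind(r1 * cos(th), r1 * sin(th))
  pos <- rbind(inner, outer)            # inner ids 1..n, outer ids n+1..2n
  rings <- lapply(seq_len(n_cells), function(i) {
    j <- if (i == n_cells) 1L else i + 1L
    c(i, j, n_cells + j, n_cells + i)
  })
  tissue_mesh(pos, rings)
}

## ---- geometric queries -----------------------------------------------------

#' Area of one cell
#' @param mesh a `tissue_mesh`.
#' @param cell cell id.
#' @return polygon (shoelace) area, positive.
#' @export
cell_area <- function(mesh, cell) {
  check_cell(mesh, cell)
  abs(polygon_signed_area(mesh$pos[mesh$cells[[cell]], , drop = FALSE]))
}

#' Areas of all cells
#' @param mesh a `tissue_mesh`.
#' @return numeric vector, one entry per cell.
#' @export
cell_areas <- function(mesh) {
  vapply(mesh$cells, function(r) polygon_signed_area(mesh$pos[r, , drop = FALSE]),
         numeric(1))
}

#' Centroid of one cell (area-weighted)
#' @param mesh a `tissue_mesh`.
#' @param cell cell id.
#' @return length-2 coordinate.
#' @export
cell_centroid <- function(mesh, cell) {
  check_cell(mesh, cell)
  polygon_centroid(mesh$pos[mesh$cells[[cell]], , drop = FALSE])
}

#' Centroids of all cells
#' @param mesh a `tissue_mesh`.
#' @return n_cells x 2 matrix.
#' @export
cell_centroids <- function(mesh) {
  t(vapply(mesh$cells, function(r) polygon_centroid(mesh$pos[r, , drop = FALSE]),
           numeric(2)))
}

check_cell <- function(mesh, cell) {
  if (!(is.numeric(cell) && length(cell) == 1L && cell >= 1 &&
        cell <= length(mesh$cells)))
    stop("unknown cell id: ", cell)
  invisible(TRUE)
}

wall_lengths <- function(mesh) {
  sqrt(rowSums((mesh$pos[mesh$walls[, 1L], , drop = FALSE] -
                mesh$pos[mesh$walls[, 2L], , drop = FALSE])^2))
}

#' Total shared wall length between two adjacent cells
#'
#' The contact surface S_ij of the transport equations; after divisions a cell
#' pair may share several collinear wall segments, whose lengths are summed.
#'
#' @param mesh a `tissue_mesh`.
#' @param i,j adjacent cell ids.
#' @return positive scalar; error if the cells are not adjacent.
#' @export
shared_wall_length <- function(mesh, i, j) {
  check_cell(mesh, i); check_cell(mesh, j)
  e <- which(mesh$edge_from == i & mesh$edge_to == j)
  if (!length(e)) stop("cells ", i, " and ", j, " are not adjacent")
  wl <- wall_lengths(mesh)
  sum(wl[mesh$edge_walls[[e]]])
}

#' Shared wall length for every directed adjacency pair
#' @param mesh a `tissue_mesh`.
#' @return numeric vector aligned with `mesh$edge_from` / `mesh$edge_to`.
#' @keywords internal
edge_contact_lengths <- function(mesh) {
  wl <- wall_lengths(mesh)
  vapply(mesh$edge_walls, function(w) sum(wl[w]), numeric(1))
}

#' Cells on the tissue boundary
#'
#' A cell is a boundary cell iff it owns at least one wall with no cell on the
#' other side; these are the cells that receive the equatorial auxin influx.
#'
#' @param mesh a `tissue_mesh`.
#' @return integer vector of cell ids.
#' @export
boundary_cells <- function(mesh) {
  b <- is.na(mesh$wall_cells[, 2L])
  sort(unique(mesh$wall_cells[b, 1L]))
}

#' Neighbor sets N(i)
#' @param mesh a `tissue_mesh`.
#' @return list: element i is the integer vector of neighbors of cell i.
#' @export
cell_neighbors <- function(mesh) {
  nc <- length(mesh$cells)
  out <- split(mesh$edge_to, factor(mesh$edge_from, levels = seq_len(nc)))
  lapply(out, as.integer)
}

#' Center and radius of the tissue
#'
#' Center is the area-weighted mean of cell centroids; radius the largest
#' vertex distance from it. Used by the whorl-circle organ classification.
#' @param mesh a `tissue_mesh`.
#' @return list with `center` (length 2) and `radius` (scalar).
#' @export
tissue_extent <- function(mesh) {
  a <- cell_areas(mesh)
  cen <- colSums(cell_centroids(mesh) * a) / sum(a)
  r <- sqrt(max(rowSums((mesh$pos - rep(cen, each = nrow(mesh$pos)))^2)))
  list(center = cen, radius = r)
}

## ---- validation ------------------------------------------------------------

#' Check all mesh invariants
#'
#' Reports violations instead of throwing: ring size and simplicity, positive
#' orientation, wall sharing (at most two incident cells), adjacency symmetry,
#' per-cell PIN non-negativity, and the tiling property (sum of cell areas
#' equals the area of the outer boundary polygon).
#'
#' @param mesh a `tissue_mesh`.
#' @param tol relative tolerance of the area bookkeeping check.
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  v <- character(0)
  nc <- length(mesh$cells)
  if (any(!is.finite(mesh$pos)))
    v <- c(v, "non-finite vertex position")
  for (i in seq_len(nc)) {
    r <- mesh$cells[[i]]
    xy <- mesh$pos[r, , drop = FALSE]
    if (length(r) < 3L) { v <- c(v, sprintf("cell %d: ring < 3 vertices", i)); next }
    sa <- polygon_signed_area(xy)
    if (sa <= 0) v <- c(v, sprintf("cell %d: non-positive signed area (not CCW)", i))
    if (!polygon_is_simple(xy)) v <- c(v, sprintf("cell %d: self-intersecting ring", i))
  }
  ## adjacency symmetry
  nc1 <- nc + 1
  ekey <- as.numeric(mesh$edge_from) * nc1 + mesh$edge_to
  rkey <- as.numeric(mesh$edge_to) * nc1 + mesh$edge_from
  bad <- which(is.na(match(rkey, ekey)))
  for (b in bad)
    v <- c(v, sprintf("adjacency asymmetric for pair (%d,%d)",
                      mesh$edge_from[b], mesh$edge_to[b]))
  ## every adjacent pair has positive shared length
  S <- edge_contact_lengths(mesh)
  zero <- which(S <= 0)
  for (z in zero)
    v <- c(v, sprintf("pair (%d,%d): shared wall length not positive",
                      mesh$edge_from[z], mesh$edge_to[z]))
  ## tiling: total cell area equals outer boundary polygon area
  ob <- outer_boundary_ring(mesh)
  if (!is.null(ob)) {
    a_cells <- sum(abs(cell_areas(mesh)))
    a_hull <- abs(polygon_signed_area(mesh$pos[ob, , drop = FALSE]))
    if (abs(a_cells - a_hull) > tol * max(a_hull, 1))
      v <- c(v, sprintf("tiling broken: cell area sum %.12g != boundary area %.12g",
                        a_cells, a_hull))
  }
  if (length(mesh$pin_edge) && any(mesh$pin_edge < 0))
    v <- c(v, "negative wall PIN amount")
  if (any(mesh$pin_endo < 0)) v <- c(v, "negative endosomal PIN amount")
  v
}

## trace the outer boundary as one closed ring of vertex ids (NULL if it is
## not a single closed loop, e.g. for a ring tissue with a hole)
outer_boundary_ring <- function(mesh) {
  b <- which(is.na(mesh$wall_cells[, 2L]))
  if (!length(b)) return(NULL)
  ## orient each boundary wall as traversed by its owning cell (CCW outer loop)
  vmap <- integer(0)
  from <- integer(length(b)); to <- integer(length(b))
  for (k in seq_along(b)) {
    w <- b[k]
    cidx <- mesh$wall_cells[w, 1L]
    r <- mesh$cells[[cidx]]
    a <- mesh$walls[w, 1L]; bb <- mesh$walls[w, 2L]
    ia <- match(a, r); ib <- match(bb, r)
    k2 <- length(r)
    ## wall traversed a->b if b follows a in the ring
    if ((ia %% k2) + 1L == ib) { from[k] <- a; to[k] <- bb } else { from[k] <- bb; to[k] <- a }
  }
  if (anyDuplicated(from)) return(NULL)
  nxt <- setNames(to, as.character(from))
  ring <- integer(length(b))
  cur <- from[1L]
  for (k in seq_along(b)) {
    ring[k] <- cur
    nx <- nxt[as.character(cur)]
    if (is.na(nx)) return(NULL)
    cur <- unname(nx)
    ## closed early: more than one boundary loop (tissue with a hole)
    if (cur == ring[1L] && k < length(b)) return(NULL)
  }
  if (cur != ring[1L]) return(NULL)
  ring
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf(
    "tissue_mesh: %d cells, %d vertices, %d walls, epoch %.3f\n",
    length(x$cells), nrow(x$pos), nrow(x$walls), x$epoch))
  cat(sprintf("  total area %.4f, %d boundary cells, %d differentiated\n",
              sum(cell_areas(x)), length(boundary_cells(x)),
              sum(x$differentiated)))
  invisible(x)
}
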