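## Cell mechanics: vertex-model energy, Metropolis relaxation, target growth,
## division on area doubling.

#' Mechanical and growth parameters
#'
#' Parameters of the vertex-model energy, the Metropolis minimizer, the
#' auxin-dependent target-area growth law and the division rule. All quantities
#' are in dimensionless model units (length unit = initial cell edge).
#'
#' @param lambda_area turgor-resistance coefficient: weight of the quadratic
#'   cell-area deviation in the energy (energy / length^4).
#' @param lambda_wall wall spring constant: weight of the quadratic wall-length
#'   deviation (energy / length^2).
#' @param mc_step maximal vertex displacement per trial move (length).
#' @param mc_temperature Boltzmann acceptance scale; 0 means strict descent.
#' @param mc_sweeps trial moves per relaxation call, in units of the current
#'   vertex count (so one sweep visits each vertex once on average).
#' @param g0 baseline target-area growth rate (area / time).
#' @param gA auxin-dependent growth amplitude (area / time); the paper keeps
#'   this small relative to `g0` so growth is almost uniform.
#' @param hA half-maximum auxin concentration of the growth response.
#' @param division_factor a cell divides once its area reaches this multiple of
#'   its area at the last division (default 2: area doubling).
#' @param wall_length_cap boundary walls longer than this are split by midpoint
#'   vertex insertion so the outline can express curvature.
#' @return a list of class `mechanics_params`.
#' @export
mechanics_params <- function(lambda_area = 50, lambda_wall = 2,
                             mc_step = 0.12, mc_temperature = 0.02,
                             mc_sweeps = 6, g0 = 0.1, gA = 0.02, hA = 1,
                             division_factor = 2, wall_length_cap = 2) {
  stopifnot(lambda_area >= 0, lambda_wall >= 0, mc_step > 0,
            mc_temperature >= 0, mc_sweeps >= 0, g0 >= 0, gA >= 0, hA > 0,
            division_factor > 1, wall_length_cap > 0)
  structure(list(lambda_area = lambda_area, lambda_wall = lambda_wall,
                 mc_step = mc_step, mc_temperature = mc_temperature,
                 mc_sweeps = mc_sweeps, g0 = g0, gA = gA, hA = hA,
                 division_factor = division_factor,
                 wall_length_cap = wall_length_cap),
            class = "mechanics_params")
}

#' Generalized potential energy of the tissue
#'
#' `H = sum_cells lambda_area * (a - A_rest)^2 +
#'      sum_walls lambda_wall * (l - L_rest)^2`
#' where `a` is the current polygon area and `l` the current wall length.
#' Non-negative; zero exactly when every cell is at its resting area and every
#' wall at its resting length.
#'
#' @param mesh a `tissue_mesh`.
#' @param params a [mechanics_params()] list.
#' @return scalar energy.
#' @export
tissue_energy <- function(mesh, params = mechanics_params()) {
  a <- cell_areas(mesh)
  l <- wall_lengths(mesh)
  params$lambda_area * sum((a - mesh$rest_area)^2) +
    params$lambda_wall * sum((l - mesh$wall_rest)^2)
}

#' Metropolis Monte Carlo relaxation of the cell shapes
#'
#' Performs `round(mc_sweeps * n_vertices)` random vertex displacements
#' (uniform in a disc of radius `mc_step`). A move is accepted when it lowers
#' the energy, or with probability `exp(-dH / mc_temperature)` when
#' `mc_temperature > 0`; moves that would invert a cell or make its ring
#' self-intersecting are rejected outright. With `mc_temperature = 0` the
#' energy never increases. Uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param mesh a `tissue_mesh`.
#' @param params a [mechanics_params()] list.
#' @param n_trials override the number of trial moves (default
#'   `mc_sweeps * n_vertices`).
#' @return the relaxed mesh (geometry updated, topology unchanged).
#' @export
relax <- function(mesh, params = mechanics_params(), n_trials = NULL) {
  if (is.null(n_trials))
    n_trials <- as.integer(round(params$mc_sweeps * nrow(mesh$pos)))
  if (n_trials <= 0) return(mesh)
  res <- mc_relax_cpp(mesh$pos, mesh$cells, mesh$rest_area,
                      mesh$walls, mesh$wall_rest,
                      params$lambda_area, params$lambda_wall,
                      params$mc_step, params$mc_temperature,
                      as.integer(n_trials), 1e-9)
  mesh$pos <- res$pos
  attr(mesh, "mc_accepted") <- res$accepted
  mesh
}

#' Auxin-dependent growth of the resting areas
#'
#' Each cell's resting (target) area increases by
#' `dt * (g0 + gA * A / (hA + A))` where `A` is the cell's auxin
#' concentration: growth saturates at `g0 + gA` for large `A` and equals
#' `g0 + gA/2` at `A = hA`. Wall resting lengths are rescaled by the square
#' root of the mean resting-area ratio of their incident cells so that shape
#' targets stay mutually consistent.
#'
#' @param mesh a `tissue_mesh`.
#' @param params a [mechanics_params()] list.
#' @param dt time step (> 0).
#' @return the mesh with updated `rest_area` and `wall_rest`.
#' @export
grow_targets <- function(mesh, params = mechanics_params(), dt) {
  if (dt < 0) stop("dt must be non-negative")
  A <- mesh$auxin
  inc <- dt * (params$g0 + params$gA * A / (params$hA + A))
  new_rest <- mesh$rest_area + inc
  ratio <- sqrt(new_rest / mesh$rest_area)
  ## per-wall factor: mean of incident cells' linear growth factors
  f1 <- ratio[mesh$wall_cells[, 1L]]
  f2 <- ratio[mesh$wall_cells[, 2L]]
  f2[is.na(f2)] <- f1[is.na(f2)]
  mesh$wall_rest <- mesh$wall_rest * (f1 + f2) / 2
  mesh$rest_area <- new_rest
  mesh
}

## split boundary walls longer than the cap by inserting midpoint vertices,
## so the Monte Carlo can curve the outline; resting length is split evenly.
subdivide_boundary_walls <- function(mesh, cap) {
  repeat {
    wl <- wall_lengths(mesh)
    long <- which(is.na(mesh$wall_cells[, 2L]) & wl > cap)
    if (!length(long)) return(mesh)
    w <- long[1L]
    a <- mesh$walls[w, 1L]; b <- mesh$walls[w, 2L]
    mid <- (mesh$pos[a, ] + mesh$pos[b, ]) / 2
    mesh$pos <- rbind(mesh$pos, mid)
    nv <- nrow(mesh$pos)
    ci <- mesh$wall_cells[w, 1L]
    r <- mesh$cells[[ci]]
    mesh$cells[[ci]] <- insert_between(r, a, b, nv)
    half <- mesh$wall_rest[w] / 2
    mesh <- rebuild_topology(mesh)
    ## both halves inherit half the resting length
    nw <- which((mesh$walls[, 1L] == min(a, nv) & mesh$walls[, 2L] == max(a, nv)) |
                (mesh$walls[, 1L] == min(b, nv) & mesh$walls[, 2L] == max(b, nv)))
    mesh$wall_rest[nw] <- half
  }
}

## insert vertex `w` into ring `r` between adjacent ring vertices a and b
insert_between <- function(r, a, b, w) {
  k <- length(r)
  ia <- match(a, r); ib <- match(b, r)
  if (is.na(ia) || is.na(ib)) stop("vertices not in ring")
  if ((ia %% k) + 1L == ib) append(r, w, after = ia)
  else if ((ib %% k) + 1L == ia) append(r, w, after = ib)
  else stop("vertices not adjacent in ring")
}

## principal axis (unit vector) of a polygon from its area moments
polygon_long_axis <- function(xy) {
  cen <- polygon_centroid(xy)
  x <- xy[, 1L] - cen[1L]; y <- xy[, 2L] - cen[2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  if (a < 0) { ixx <- -ixx; iyy <- -iyy; ixy <- -ixy }
  ## covariance-like matrix; leading eigenvector = long axis
  M <- matrix(c(iyy, ixy, ixy, ixx), 2L)
  ev <- eigen(M, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  v / sqrt(sum(v^2))
}

#' Divide a cell if its area has doubled
#'
#' Division fires once the cell's area reaches `division_factor` times its
#' area at the last division. The polygon is cut by a straight line through
#' its centroid perpendicular to its longest principal axis (shortest-axis
#' split); new vertices are inserted where the line crosses the ring, also
#' into any neighboring cell sharing the crossed wall. Both daughters inherit
#' the parent's auxin concentration unchanged; endosomal PIN is split in
#' proportion to daughter area and wall PIN follows the walls (split walls
#' share their PIN in proportion to segment length); the new shared wall
#' starts with zero PIN. Under the default `pin_mode = "renormalize"` each
#' daughter's PIN amounts are then rescaled so its total equals `pin_total`
#' (the fixed per-cell PIN pool); `pin_mode = "conserve"` skips the rescaling
#' so the daughters' totals sum exactly to the parent's. Daughter resting
#' areas are set to their current areas and the division counter is reset.
#'
#' @param mesh a `tissue_mesh`.
#' @param cell cell id.
#' @param params a [mechanics_params()] list.
#' @param pin_mode `"renormalize"` (fixed per-cell PIN pool) or `"conserve"`.
#' @param pin_total per-cell PIN pool used by `"renormalize"`.
#' @param max_retries attempts with jittered cut angle before giving up on a
#'   degenerate split (cell stays undivided this step).
#' @return the mesh, with one extra cell if division occurred.
#' @export
divide_if_ready <- function(mesh, cell, params = mechanics_params(),
                            pin_mode = c("renormalize", "conserve"),
                            pin_total = 1, max_retries = 10L) {
  check_cell(mesh, cell)
  pin_mode <- match.arg(pin_mode)
  a <- cell_area(mesh, cell)
  if (a < params$division_factor * mesh$area_last_div[cell]) return(mesh)
  divide_cell(mesh, cell, pin_mode, pin_total, max_retries)
}

## unconditional division; returns mesh unchanged if all cut attempts degenerate
divide_cell <- function(mesh, cell, pin_mode, pin_total, max_retries = 10L) {
  ring <- mesh$cells[[cell]]
  xy <- mesh$pos[ring, , drop = FALSE]
  cen <- polygon_centroid(xy)
  axis <- polygon_long_axis(xy)
  normal <- axis  # cut line perpendicular to long axis => line normal = axis
  for (try in seq_len(max_retries)) {
    sdist <- (xy[, 1L] - cen[1L]) * normal[1L] + (xy[, 2L] - cen[2L]) * normal[2L]
    k <- length(ring)
    nxt <- c(2:k, 1L)
    eps <- 1e-9 * max(sqrt(sum((apply(xy, 2, max) - apply(xy, 2, min))^2)), 1)
    crossings <- which(sdist * sdist[nxt] < 0 & abs(sdist) > eps & abs(sdist[nxt]) > eps)
    if (length(crossings) == 2L) {
      res <- try_split(mesh, cell, ring, xy, sdist, crossings,
                       pin_mode, pin_total)
      if (!is.null(res)) return(res)
    }
    ## degenerate: jitter the cut angle and retry
    th <- runif(1, -0.35, 0.35)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    normal <- as.vector(rot %*% normal)
  }
  mesh
}

try_split <- function(mesh, cell, ring, xy, sdist, crossings,
                      pin_mode, pin_total) {
  k <- length(ring)
  nxt <- c(2:k, 1L)
  nv0 <- nrow(mesh$pos)
  new_ids <- integer(2)
  pos <- mesh$pos
  for (m in 1:2) {
    e <- crossings[m]
    t <- sdist[e] / (sdist[e] - sdist[nxt[e]])
    p <- xy[e, ] + t * (xy[nxt[e], ] - xy[e, ])
    pos <- rbind(pos, p)
    new_ids[m] <- nv0 + m
  }
  ## record old wall info for PIN reassignment and resting-length split
  parent_edges <- which(mesh$edge_from == cell)
  pin_out <- mesh$pin_edge[parent_edges]
  names(pin_out) <- mesh$edge_to[parent_edges]
  parent_rev <- mesh$edge_rev[parent_edges]
  pin_in <- mesh$pin_edge[parent_rev]
  names(pin_in) <- mesh$edge_to[parent_edges]
  wall_rest_of <- function(v1, v2) {
    w <- which(mesh$walls[, 1L] == min(v1, v2) & mesh$walls[, 2L] == max(v1, v2))
    mesh$wall_rest[w]
  }
  crossed_rest <- vapply(1:2, function(m) {
    e <- crossings[m]
    wall_rest_of(ring[e], ring[nxt[e]])
  }, numeric(1))
  crossed_t <- vapply(1:2, function(m) {
    e <- crossings[m]
    sdist[e] / (sdist[e] - sdist[nxt[e]])
  }, numeric(1))

  mesh$pos <- pos
  ## split the ring at the two new vertices
  e1 <- crossings[1L]; e2 <- crossings[2L]
  ## walk ring positions from nxt[e1] to e2 inclusive (cyclically)
  walk <- function(from, to) {
    if (from <= to) seq.int(from, to) else c(seq.int(from, k), seq.int(1L, to))
  }
  part1 <- ring[walk(nxt[e1], e2)]
  part2 <- ring[walk(nxt[e2], e1)]
  ring_a <- c(new_ids[1L], part1, new_ids[2L])
  ring_b <- c(new_ids[2L], part2, new_ids[1L])
  if (length(ring_a) < 3L || length(ring_b) < 3L) return(NULL)

  ## insert the new vertices into neighbor rings sharing the crossed walls
  for (m in 1:2) {
    e <- crossings[m]
    v1 <- ring[e]; v2 <- ring[nxt[e]]
    w <- which(mesh$walls[, 1L] == min(v1, v2) & mesh$walls[, 2L] == max(v1, v2))
    other <- setdiff(stats::na.omit(mesh$wall_cells[w, ]), cell)
    if (length(other) == 1L)
      mesh$cells[[other]] <- insert_between(mesh$cells[[other]], v1, v2, new_ids[m])
  }

  a1 <- polygon_signed_area(mesh$pos[ring_a, , drop = FALSE])
  a2 <- polygon_signed_area(mesh$pos[ring_b, , drop = FALSE])
  ## degenerate sliver: abandon this local copy, caller retries jittered
  if (a1 < 1e-12 || a2 < 1e-12) return(NULL)
  daughter2 <- length(mesh$cells) + 1L
  mesh$cells[[cell]] <- ring_a
  mesh$cells[[daughter2]] <- ring_b

  ## state inheritance
  mesh$rest_area <- c(mesh$rest_area, 0)
  mesh$area_last_div <- c(mesh$area_last_div, 0)
  mesh$auxin <- c(mesh$auxin, mesh$auxin[cell])        # concentration inherited
  endo <- mesh$pin_endo[cell]
  mesh$pin_endo[cell] <- endo * a1 / (a1 + a2)
  mesh$pin_endo <- c(mesh$pin_endo, endo * a2 / (a1 + a2))
  mesh$differentiated <- c(mesh$differentiated, mesh$differentiated[cell])
  mesh$diff_time <- c(mesh$diff_time, mesh$diff_time[cell])
  mesh$rest_area[cell] <- a1
  mesh$rest_area[daughter2] <- a2
  mesh$area_last_div[cell] <- a1
  mesh$area_last_div[daughter2] <- a2

  mesh <- rebuild_topology(mesh)

  ## resting lengths: crossed wall halves split by the cut fraction,
  ## the new shared wall rests at its current length
  for (m in 1:2) {
    e <- crossings[m]
    v1 <- ring[e]; v2 <- ring[nxt[e]]
    w1 <- which(mesh$walls[, 1L] == min(v1, new_ids[m]) &
                mesh$walls[, 2L] == max(v1, new_ids[m]))
    w2 <- which(mesh$walls[, 1L] == min(v2, new_ids[m]) &
                mesh$walls[, 2L] == max(v2, new_ids[m]))
    if (length(w1)) mesh$wall_rest[w1] <- crossed_rest[m] * crossed_t[m]
    if (length(w2)) mesh$wall_rest[w2] <- crossed_rest[m] * (1 - crossed_t[m])
  }

  ## PIN reassignment: for each former neighbor j of the parent, distribute
  ## P_parent,j (and j's P_j,parent) over the daughters by contact length
  S <- edge_contact_lengths(mesh)
  for (j_chr in names(pin_out)) {
    j <- as.integer(j_chr)
    e1j <- which(mesh$edge_from == cell & mesh$edge_to == j)
    e2j <- which(mesh$edge_from == daughter2 & mesh$edge_to == j)
    s1 <- if (length(e1j)) S[e1j] else 0
    s2 <- if (length(e2j)) S[e2j] else 0
    tot <- s1 + s2
    if (tot <= 0) next
    if (length(e1j)) {
      mesh$pin_edge[e1j] <- pin_out[[j_chr]] * s1 / tot
      mesh$pin_edge[mesh$edge_rev[e1j]] <- pin_in[[j_chr]] * s1 / tot
    }
    if (length(e2j)) {
      mesh$pin_edge[e2j] <- pin_out[[j_chr]] * s2 / tot
      mesh$pin_edge[mesh$edge_rev[e2j]] <- pin_in[[j_chr]] * s2 / tot
    }
  }
  ## new shared wall between the daughters starts PIN-free
  e_new <- which((mesh$edge_from == cell & mesh$edge_to == daughter2) |
                 (mesh$edge_from == daughter2 & mesh$edge_to == cell))
  mesh$pin_edge[e_new] <- 0

  if (pin_mode == "renormalize") {
    for (d in c(cell, daughter2)) {
      eo <- which(mesh$edge_from == d)
      tot <- mesh$pin_endo[d] + sum(mesh$pin_edge[eo])
      if (tot > 0) {
        f <- pin_total / tot
        mesh$pin_endo[d] <- mesh$pin_endo[d] * f
        mesh$pin_edge[eo] <- mesh$pin_edge[eo] * f
      } else {
        mesh$pin_endo[d] <- pin_total
      }
    }
  }
  attr(mesh, "divided") <- TRUE
  mesh
}

#' Division sweep over all cells
#'
#' Applies [divide_if_ready()] to every cell that has reached the
#' area-doubling criterion (one pass; cells created during the pass are not
#' re-examined until the next sweep).
#'
#' @inheritParams divide_if_ready
#' @return the updated mesh.
#' @export
divide_ready <- function(mesh, params = mechanics_params(),
                         pin_mode = "renormalize", pin_total = 1) {
  a <- cell_areas(mesh)
  ready <- which(a >= params$division_factor * mesh$area_last_div)
  for (cell in ready)
    mesh <- divide_if_ready(mesh, cell, params, pin_mode, pin_total)
  mesh
}
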