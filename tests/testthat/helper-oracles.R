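## Independent oracles used by the tests. These re-derive quantities with
## deliberately different (slow, loop-based) code paths than the package.

## brute-force shoelace area by triangle fan from the first vertex
oracle_polygon_area <- function(xy) {
  a <- 0
  for (k in 2:(nrow(xy) - 1L)) {
    v1 <- xy[k, ] - xy[1L, ]
    v2 <- xy[k + 1L, ] - xy[1L, ]
    a <- a + (v1[1L] * v2[2L] - v1[2L] * v2[1L]) / 2
  }
  abs(a)
}

## centroid by the same triangle-fan decomposition
oracle_polygon_centroid <- function(xy) {
  atot <- 0; cx <- 0; cy <- 0
  for (k in 2:(nrow(xy) - 1L)) {
    v1 <- xy[k, ] - xy[1L, ]
    v2 <- xy[k + 1L, ] - xy[1L, ]
    a <- (v1[1L] * v2[2L] - v1[2L] * v2[1L]) / 2
    cen <- (xy[1L, ] + xy[k, ] + xy[k + 1L, ]) / 3
    atot <- atot + a; cx <- cx + a * cen[1L]; cy <- cy + a * cen[2L]
  }
  c(cx, cy) / atot
}

## term-by-term vertex-model energy
oracle_energy <- function(mesh, la, lm) {
  h <- 0
  for (i in seq_along(mesh$cells)) {
    xy <- mesh$pos[mesh$cells[[i]], , drop = FALSE]
    h <- h + la * (oracle_polygon_area(xy) - mesh$rest_area[i])^2
  }
  for (w in seq_len(nrow(mesh$walls))) {
    p <- mesh$pos[mesh$walls[w, 1L], ]; q <- mesh$pos[mesh$walls[w, 2L], ]
    h <- h + lm * (sqrt(sum((p - q)^2)) - mesh$wall_rest[w])^2
  }
  h
}

## transport state in dense-matrix form for the oracle
oracle_state <- function(mesh) {
  n <- length(mesh$cells)
  P <- matrix(0, n, n)
  for (e in seq_along(mesh$edge_from))
    P[mesh$edge_from[e], mesh$edge_to[e]] <- mesh$pin_edge[e]
  list(A = mesh$auxin, Pe = mesh$pin_endo, P = P)
}

## hand-coded term-by-term evaluation of the transport right-hand side;
## loops over cells and neighbors, never touching the package's vectorized path
oracle_derivs <- function(mesh, st, tp, n_cells = length(mesh$cells)) {
  n <- length(mesh$cells)
  nb <- cell_neighbors(mesh)
  bc <- boundary_cells(mesh)
  on <- n_cells >= tp$influx_window[1] && n_cells <= tp$influx_window[2]
  h <- function(x) x / (tp$K_mm + x)
  g <- if (tp$saturating_export) h else identity
  dA <- numeric(n); dPe <- numeric(n); dP <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d_eff <- tp$d_decay + if (mesh$differentiated[i]) tp$d_depletion else 0
    dA[i] <- tp$p_production - d_eff * st$A[i] +
      if (i %in% bc && on) tp$f_influx else 0
    for (j in nb[[i]]) {
      S <- shared_wall_length(mesh, i, j)
      dA[i] <- dA[i] + tp$T_active * (st$P[j, i] * g(st$A[j]) -
                                      st$P[i, j] * g(st$A[i])) +
        tp$D_passive * S * (st$A[j] - st$A[i])
      dP[i, j] <- tp$k1 * st$Pe[i] * h(st$A[j]) - tp$k2 * st$P[i, j]
      dPe[i] <- dPe[i] - dP[i, j]
    }
  }
  list(dA = dA, dPe = dPe, dP = dP)
}

## independent classical RK4 reference integrator at a fixed fine step,
## operating on the dense oracle state
oracle_integrate_rk4 <- function(mesh, tp, t_total, h, n_cells = length(mesh$cells)) {
  st <- oracle_state(mesh)
  nstep <- round(t_total / h)
  add <- function(s, d, f) list(A = s$A + f * d$dA, Pe = s$Pe + f * d$dPe,
                                P = s$P + f * d$dP)
  for (k in seq_len(nstep)) {
    k1 <- oracle_derivs(mesh, st, tp, n_cells)
    k2 <- oracle_derivs(mesh, add(st, k1, h / 2), tp, n_cells)
    k3 <- oracle_derivs(mesh, add(st, k2, h / 2), tp, n_cells)
    k4 <- oracle_derivs(mesh, add(st, k3, h), tp, n_cells)
    st <- list(A = st$A + h / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA),
               Pe = st$Pe + h / 6 * (k1$dPe + 2 * k2$dPe + 2 * k3$dPe + k4$dPe),
               P = st$P + h / 6 * (k1$dP + 2 * k2$dP + 2 * k3$dP + k4$dP))
  }
  st
}

## put a dense-matrix PIN state onto a mesh
set_pin_state <- function(mesh, Pe, P) {
  mesh$pin_endo <- Pe
  for (e in seq_along(mesh$edge_from))
    mesh$pin_edge[e] <- P[mesh$edge_from[e], mesh$edge_to[e]]
  mesh
}

## total PIN held by one cell (endosome + all its walls)
cell_pin_total <- function(mesh, i) {
  mesh$pin_endo[i] + sum(mesh$pin_edge[mesh$edge_from == i])
}

## random small mesh with randomized physiological state
random_state_mesh <- function(nr, nc, seed, tp) {
  set.seed(seed)
  m <- build_grid_tissue(nr, nc)
  m <- init_state(m, tp)
  m$auxin <- runif(length(m$cells), 0, 3)
  m$pin_endo <- runif(length(m$cells), 0.5, 2)
  m$pin_edge <- runif(length(m$pin_edge), 0, 0.5)
  m
}
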