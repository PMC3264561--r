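## Tissue snapshot serialization: a documented JSON structure holding the
## complete mesh and physiological state; write -> read is lossless.
##
## Doubles are stored as "%.17g" strings (17 significant digits round-trip
## IEEE doubles exactly; plain JSON numbers are re-printed by most emitters at
## 15 digits and lose the last bits).

fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' Write a tissue snapshot to JSON
#'
#' Serializes vertices, cell rings, per-cell state (resting area, area at last
#' division, auxin, endosomal PIN, differentiation flag and time), wall
#' resting lengths (keyed by vertex pair) and wall PIN (keyed by directed cell
#' pair), and the epoch. Floating-point values are stored as 17-significant-
#' digit strings so that [read_tissue_json()] restores the mesh bit-exactly.
#'
#' @param mesh a `tissue_mesh`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_tissue_json <- function(mesh, path) {
  obj <- list(
    format = "whorlsim-tissue",
    version = 1L,
    epoch = fmt_num(mesh$epoch),
    vertices = lapply(seq_len(nrow(mesh$pos)), function(v)
      list(x = fmt_num(mesh$pos[v, 1L]), y = fmt_num(mesh$pos[v, 2L]))),
    cells = lapply(seq_along(mesh$cells), function(i) list(
      ring = mesh$cells[[i]],
      rest_area = fmt_num(mesh$rest_area[i]),
      area_last_div = fmt_num(mesh$area_last_div[i]),
      auxin = fmt_num(mesh$auxin[i]),
      pin_endosome = fmt_num(mesh$pin_endo[i]),
      differentiated = mesh$differentiated[i],
      diff_time = fmt_num(mesh$diff_time[i]))),
    walls = lapply(seq_len(nrow(mesh$walls)), function(w) list(
      v1 = mesh$walls[w, 1L], v2 = mesh$walls[w, 2L],
      rest_length = fmt_num(mesh$wall_rest[w]))),
    pin_walls = lapply(seq_along(mesh$edge_from), function(e) list(
      from = mesh$edge_from[e], to = mesh$edge_to[e],
      pin = fmt_num(mesh$pin_edge[e]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a tissue snapshot written by [write_tissue_json()]
#'
#' @param path JSON file path.
#' @return the restored `tissue_mesh`, identical in all fields (the topology
#'   ordering is deterministic given the cell rings).
#' @export
read_tissue_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "whorlsim-tissue"))
    stop("not a whorlsim tissue snapshot: ", path)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  pos <- t(vapply(obj$vertices, function(v) c(num(v$x), num(v$y)), numeric(2)))
  rings <- lapply(obj$cells, function(cl) as.integer(unlist(cl$ring)))
  mesh <- tissue_mesh(pos, rings)
  mesh$epoch <- num(obj$epoch)
  mesh$rest_area <- vapply(obj$cells, function(cl) num(cl$rest_area), numeric(1))
  mesh$area_last_div <- vapply(obj$cells, function(cl) num(cl$area_last_div),
                               numeric(1))
  mesh$auxin <- vapply(obj$cells, function(cl) num(cl$auxin), numeric(1))
  mesh$pin_endo <- vapply(obj$cells, function(cl) num(cl$pin_endosome), numeric(1))
  mesh$differentiated <- vapply(obj$cells, function(cl) isTRUE(cl$differentiated),
                                logical(1))
  mesh$diff_time <- vapply(obj$cells, function(cl) num(cl$diff_time), numeric(1))
  ## wall resting lengths by vertex-pair key
  nv <- nrow(pos)
  wk <- as.numeric(mesh$walls[, 1L]) * (nv + 1) + mesh$walls[, 2L]
  for (w in obj$walls) {
    key <- as.numeric(min(w$v1, w$v2)) * (nv + 1) + max(w$v1, w$v2)
    i <- match(key, wk)
    if (is.na(i)) stop("snapshot wall (", w$v1, ",", w$v2, ") not in mesh")
    mesh$wall_rest[i] <- num(w$rest_length)
  }
  ## wall PIN by directed cell-pair key
  nc <- length(rings)
  ek <- as.numeric(mesh$edge_from) * (nc + 1) + mesh$edge_to
  for (e in obj$pin_walls) {
    key <- as.numeric(e$from) * (nc + 1) + e$to
    i <- match(key, ek)
    if (is.na(i)) stop("snapshot pin pair (", e$from, ",", e$to, ") not in mesh")
    mesh$pin_edge[i] <- num(e$pin)
  }
  mesh
}
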