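## Pattern analysis: detection of auxin-maximum clusters from simulation
## traces, whorl/stage classification into organ classes, batch statistics.

#' Snapshot of a tissue for trace recording
#'
#' @param mesh a `tissue_mesh`.
#' @param time simulation time of the snapshot.
#' @return list with time, cell count, per-cell auxin / differentiation /
#'   centroids, and the undirected adjacency edge list.
#' @keywords internal
trace_snapshot <- function(mesh, time) {
  keep <- mesh$edge_from < mesh$edge_to
  list(time = time,
       n_cells = length(mesh$cells),
       auxin = mesh$auxin,
       pin_endo = mesh$pin_endo,
       differentiated = mesh$differentiated,
       area = cell_areas(mesh),
       centroid = cell_centroids(mesh),
       edge_a = mesh$edge_from[keep],
       edge_b = mesh$edge_to[keep])
}

new_trace <- function() structure(list(snapshots = list()), class = "tissue_trace")

#' @export
print.tissue_trace <- function(x, ...) {
  ns <- length(x$snapshots)
  if (ns) {
    last <- x$snapshots[[ns]]
    cat(sprintf("tissue_trace: %d snapshots, t in [%.3g, %.3g], final %d cells\n",
                ns, x$snapshots[[1]]$time, last$time, last$n_cells))
  } else cat("tissue_trace: empty\n")
  invisible(x)
}

## connected components of the super-threshold cells of one snapshot;
## returns an integer component label per cell (NA if below threshold)
super_components <- function(snap, threshold) {
  super <- which(snap$auxin > threshold)
  lab <- rep(NA_integer_, length(snap$auxin))
  if (!length(super)) return(lab)
  keep <- snap$edge_a %in% super & snap$edge_b %in% super
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(snap$edge_a[keep]),
               to = as.character(snap$edge_b[keep])),
    directed = FALSE,
    vertices = data.frame(name = as.character(super)))
  comp <- igraph::components(g)
  lab[super] <- comp$membership[as.character(super)]
  lab
}

#' Detect auxin-maximum clusters in a simulation trace
#'
#' At every sampled time the super-threshold cells are grouped into connected
#' components of the cell-adjacency graph. Components are tracked through time
#' by cell-id overlap: a component overlapping the live cells of an existing
#' cluster extends that cluster (two clusters meeting in one component records
#' a fusion event, resolved later by [merge_fused()]); a component with no
#' live overlap re-attaches to a cluster that fell silent less than `t_gap`
#' ago at the same cells, and otherwise founds a new cluster whose onset time
#' is the current sample. Two spatially contiguous groups therefore count as
#' distinct organs when their onsets are separated by more than `t_gap`, and
#' groups separated by at least one sub-threshold cell are always distinct,
#' mirroring the organ-identity rules of the model.
#'
#' @param trace a `tissue_trace`.
#' @param A_threshold concentration threshold defining a maximum.
#' @param t_gap temporal separation beyond which a re-emerging maximum at the
#'   same site counts as a new organ.
#' @return list of `organ_cluster` objects (fields: `id`, `members`,
#'   `onset_time`, `last_active`); fusion events are attached as the
#'   `"fusions"` attribute.
#' @export
detect_clusters <- function(trace, A_threshold, t_gap = 5) {
  if (!length(trace$snapshots)) stop("empty trace")
  clusters <- list()        # each: onset, last_active
  owner <- integer(0)       # cell id -> owning cluster (0 = none yet)
  own_start <- numeric(0)   # time current ownership began
  log <- list()             # closed ownership intervals (cell, cluster, from, to)
  fusions <- list()
  for (snap in trace$snapshots) {
    lab <- super_components(snap, A_threshold)
    if (length(owner) < length(snap$auxin)) {
      pad <- length(snap$auxin) - length(owner)
      owner <- c(owner, integer(pad))
      own_start <- c(own_start, numeric(pad))
    }
    comps <- split(which(!is.na(lab)), lab[!is.na(lab)])
    active_now <- integer(0)
    for (cells in comps) {
      own <- unique(owner[cells])
      own <- own[own > 0L]
      ## owners count only while fresh: a cluster silent for more than t_gap
      ## does not re-capture a maximum re-emerging at its old site
      fresh <- own[vapply(own, function(o)
        (snap$time - clusters[[o]]$last_active) <= t_gap, logical(1))]
      if (length(fresh) == 0L) {
        clusters[[length(clusters) + 1L]] <-
          list(onset = snap$time, last_active = snap$time,
               members = cells)
        for (c0 in cells[owner[cells] > 0L])
          log[[length(log) + 1L]] <- c(c0, owner[c0], own_start[c0], snap$time)
        owner[cells] <- length(clusters)
        own_start[cells] <- snap$time
        active_now <- c(active_now, length(clusters))
      } else {
        if (length(fresh) > 1L)
          fusions[[length(fusions) + 1L]] <- list(time = snap$time, ids = fresh)
        tgt <- fresh[which.min(vapply(clusters[fresh], `[[`, numeric(1),
                                      "onset"))]
        ## unowned or stale-owned cells join the oldest fresh cluster;
        ## cells of fresh clusters keep their permanent owner
        reassign <- cells[!(owner[cells] %in% fresh)]
        for (c0 in reassign[owner[reassign] > 0L])
          log[[length(log) + 1L]] <- c(c0, owner[c0], own_start[c0], snap$time)
        owner[reassign] <- tgt
        own_start[reassign] <- snap$time
        clusters[[tgt]]$members <- union(clusters[[tgt]]$members, reassign)
        active_now <- c(active_now, unique(owner[cells]))
      }
    }
    for (o in unique(active_now)) clusters[[o]]$last_active <- snap$time
  }
  for (c0 in which(owner > 0L))
    log[[length(log) + 1L]] <- c(c0, owner[c0], own_start[c0], Inf)
  out <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    structure(list(id = i, members = sort(cl$members), onset_time = cl$onset,
                   last_active = cl$last_active), class = "organ_cluster")
  })
  ownership <- if (length(log)) {
    m <- do.call(rbind, log)
    data.frame(cell = m[, 1L], cluster = m[, 2L], from = m[, 3L], to = m[, 4L])
  } else data.frame(cell = numeric(0), cluster = numeric(0),
                    from = numeric(0), to = numeric(0))
  attr(out, "fusions") <- fusions
  attr(out, "ownership") <- ownership
  out
}

#' Merge clusters whose maxima fuse and stay fused
#'
#' Two separate maxima that become one connected super-threshold component at
#' some sampled time, and remain one component at every later sample where
#' either is above threshold, are counted as one presumed organ with the
#' earlier onset time. A transient touch followed by re-separation leaves them
#' distinct.
#'
#' @param clusters output of [detect_clusters()].
#' @param trace the `tissue_trace` the clusters came from.
#' @param A_threshold the threshold used for detection.
#' @return a reduced list of `organ_cluster` objects.
#' @export
merge_fused <- function(clusters, trace, A_threshold) {
  if (length(clusters) < 2L) return(clusters)
  times <- vapply(trace$snapshots, `[[`, numeric(1), "time")
  labs <- lapply(trace$snapshots, super_components, threshold = A_threshold)
  n <- length(clusters)
  own <- attr(clusters, "ownership")
  ## cells owned by cluster i at time t (falls back to static membership for
  ## cluster lists built without the tracking log)
  owned_at <- function(i, t) {
    if (is.null(own)) return(clusters[[i]]$members)
    o <- own[own$cluster == clusters[[i]]$id & own$from <= t & t < own$to, ]
    o$cell
  }
  ## same-component indicator per snapshot for a cluster pair
  joined_at <- function(i, j, s) {
    li <- labs[[s]][intersect(owned_at(i, times[s]), seq_along(labs[[s]]))]
    lj <- labs[[s]][intersect(owned_at(j, times[s]), seq_along(labs[[s]]))]
    li <- unique(li[!is.na(li)]); lj <- unique(lj[!is.na(lj)])
    if (!length(li) || !length(lj)) return(NA)   # one of them silent
    length(intersect(li, lj)) > 0
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    jt <- vapply(seq_along(times), function(s) joined_at(i, j, s), NA)
    first <- which(jt %in% TRUE)[1L]
    if (is.na(first)) next
    later <- jt[seq.int(first, length(jt))]
    if (all(later %in% c(TRUE, NA))) parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    grp <- which(roots == r)
    structure(list(
      id = min(grp),
      members = sort(unique(unlist(lapply(clusters[grp], `[[`, "members")))),
      onset_time = min(vapply(clusters[grp], `[[`, numeric(1), "onset_time")),
      last_active = max(vapply(clusters[grp], `[[`, numeric(1), "last_active"))),
      class = "organ_cluster")
  })
  out
}

#' Classify clusters into sepal, petal and reproductive organs
#'
#' A circle of radius `whorl_radius_fraction` times the tissue radius,
#' centered on the tissue, separates the outer two whorls from the
#' reproductive center: clusters whose centroid lies at a radial fraction of
#' at least `whorl_radius_fraction` are outer-whorl organs — sepals if their
#' onset precedes `stage2_time`, petals otherwise — and all inner clusters are
#' reproductive (stamens and carpels). Each cluster is located in the tissue
#' frame of the snapshot nearest its own onset: the vertex-model growth is not
#' perfectly homothetic (expansion is biased toward the free boundary), so the
#' initiation-time frame, not the final frame, preserves whorl membership.
#'
#' @param clusters list of `organ_cluster` objects.
#' @param trace the `tissue_trace` (supplies cell positions over time).
#' @param whorl_radius_fraction whorl-circle radius as a fraction of the
#'   tissue radius (in (0,1)).
#' @param stage2_time simulation time at which floral stage 2 begins.
#' @return the clusters with `centroid`, `radial_fraction` and `organ_class`
#'   fields filled in.
#' @export
classify_organs <- function(clusters, trace, whorl_radius_fraction = 0.5,
                            stage2_time) {
  stopifnot(whorl_radius_fraction > 0, whorl_radius_fraction < 1)
  times <- vapply(trace$snapshots, `[[`, numeric(1), "time")
  lapply(clusters, function(cl) {
    snap <- trace$snapshots[[which.min(abs(times - cl$onset_time))]]
    a_center <- colMeans(snap$centroid)
    radii <- sqrt(rowSums((snap$centroid -
                           rep(a_center, each = nrow(snap$centroid)))^2))
    t_radius <- max(radii)
    mem <- cl$members[cl$members <= nrow(snap$centroid)]
    cen <- colMeans(snap$centroid[mem, , drop = FALSE])
    rf <- sqrt(sum((cen - a_center)^2)) / t_radius
    cl$centroid <- cen
    cl$radial_fraction <- min(rf, 1)
    cl$organ_class <- if (rf >= whorl_radius_fraction) {
      if (cl$onset_time < stage2_time) "sepal" else "petal"
    } else "reproductive"
    cl
  })
}

#' Organ report for one simulation run
#'
#' @param clusters classified clusters (from [classify_organs()]).
#' @param run_seed seed of the run, recorded for provenance.
#' @return an `organ_report`: counts per organ class and the ordered
#'   (sepal, petal, reproductive) pattern.
#' @export
organ_report <- function(clusters, run_seed = NA_integer_) {
  cls <- vapply(clusters, `[[`, character(1), "organ_class")
  counts <- c(sepal = sum(cls == "sepal"),
              petal = sum(cls == "petal"),
              reproductive = sum(cls == "reproductive"))
  structure(list(counts = counts,
                 pattern = unname(counts),
                 run_seed = run_seed),
            class = "organ_report")
}

#' Summarize a batch of organ reports
#'
#' Computes the frequency of each (sepal, petal, reproductive) pattern and,
#' per organ class, the mean, sample standard deviation and coefficient of
#' variation (`100 * sd / mean`) of the counts over runs. With a single run
#' the standard deviation is reported as 0 and flagged (`sd_defined = FALSE`).
#'
#' @param reports list of `organ_report` objects (at least one).
#' @return a `batch_summary` list with `pattern_frequency` (named counts,
#'   names like `"4-4-5"`), `per_class` (data frame: mean, sd, cv_percent),
#'   `n_runs` and `sd_defined`.
#' @export
summarize_batch <- function(reports) {
  if (!length(reports)) stop("summarize_batch needs at least one report")
  pat <- vapply(reports, function(r) paste(r$pattern, collapse = "-"), character(1))
  freq <- table(pat)
  cm <- t(vapply(reports, function(r) r$counts, numeric(3)))
  colnames(cm) <- c("sepal", "petal", "reproductive")
  mu <- colMeans(cm)
  sdv <- if (nrow(cm) > 1L) apply(cm, 2L, sd) else c(sepal = 0, petal = 0,
                                                     reproductive = 0)
  cv <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  structure(list(
    pattern_frequency = setNames(as.integer(freq), names(freq)),
    per_class = data.frame(class = colnames(cm), mean = unname(mu),
                           sd = unname(sdv), cv_percent = unname(cv)),
    n_runs = length(reports),
    sd_defined = length(reports) > 1L), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("batch_summary over %d runs\n", x$n_runs))
  pf <- sort(x$pattern_frequency, decreasing = TRUE)
  cat("  patterns:", paste(sprintf("%s (%d)", names(pf), pf), collapse = ", "), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Synthetic trace with planted auxin-maximum clusters
#'
#' Builds a trace on a static rectangular grid of cells in which specified
#' groups of cells exceed the threshold over specified time windows, with all
#' other cells held at a low baseline. Used as a ground-truth oracle for the
#' detection pipeline.
#'
#' @param nr,nc grid dimensions.
#' @param plants list of planted clusters; each element is a list with
#'   `cells` (ids on the grid), `t_on`, `t_off`, and optional `level`.
#' @param times sampled times.
#' @param threshold the detection threshold the trace is built against.
#' @param baseline sub-threshold auxin level of unplanted cells.
#' @return a `tissue_trace`; the planted truth is attached as attribute
#'   `"truth"`.
#' @export
planted_trace <- function(nr, nc, plants, times, threshold = 1,
                          baseline = 0.1) {
  mesh <- build_grid_tissue(nr, nc)
  tr <- new_trace()
  for (t in times) {
    mesh$auxin <- rep(baseline, length(mesh$cells))
    for (p in plants) {
      lev <- if (is.null(p$level)) 2 * threshold else p$level
      if (t >= p$t_on && t <= p$t_off) mesh$auxin[p$cells] <- lev
    }
    tr$snapshots[[length(tr$snapshots) + 1L]] <- trace_snapshot(mesh, t)
  }
  attr(tr, "truth") <- plants
  tr
}
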