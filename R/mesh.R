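#' Construct a triangulated surface mesh
#'
#' Builds adjacency and per-node areas from a vertex/triangle description.
#' Node areas apportion each triangle's area equally to its three corners
#' (barycentric one-third rule), so node areas sum exactly to the total
#' surface area.
#'
#' @param vertices numeric matrix, `n_nodes` x 3, coordinates in mm.
#' @param triangles integer matrix, `n_triangles` x 3, 1-based vertex
#'   indices.
#' @return An object of class `surface_mesh`: `vertices`, `triangles`,
#'   `edges` (unique undirected edge list), `adjacency` (list of neighbour
#'   index vectors), `node_area_mm2`, `n_nodes`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  n <- nrow(vertices)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(triangles) != 3L) stop("triangles must be n x 3")
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range")

  # triangle areas via cross product
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c3 - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))

  node_area <- numeric(n)
  for (k in 1:3) {
    s <- rowsum(tri_area / 3, triangles[, k])
    idx <- as.integer(rownames(s))
    node_area[idx] <- node_area[idx] + s[, 1]
  }

  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)],
             triangles[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  both <- rbind(e, e[, 2:1, drop = FALSE])
  adjacency <- split(both[, 2], factor(both[, 1], levels = seq_len(n)))
  adjacency <- lapply(adjacency, function(x) sort(unname(x)))

  structure(
    list(vertices = vertices, triangles = triangles, edges = e,
         adjacency = adjacency, node_area_mm2 = node_area, n_nodes = n),
    class = "surface_mesh")
}

#' Regular planar grid mesh
#'
#' A flat `nx` x `ny` grid of vertices at `spacing` mm, each cell split into
#' two triangles. Used for smoothing calibration and as a toy substrate in
#' tests and simulations.
#'
#' @param nx,ny grid dimensions (vertices per side).
#' @param spacing vertex spacing in mm.
#' @return a [surface_mesh()].
#' @export
grid_mesh <- function(nx, ny, spacing = 1) {
  xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  vertices <- cbind((xy$x - 1) * spacing, (xy$y - 1) * spacing, 0)
  id <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    tris[[length(tris) + 1L]] <- cbind(id(i, j), id(i + 1L, j), id(i, j + 1L))
    tris[[length(tris) + 1L]] <- cbind(id(i + 1L, j), id(i + 1L, j + 1L),
                                       id(i, j + 1L))
  }
  surface_mesh(vertices, do.call(rbind, tris))
}

#' Connected components of a mesh (or of a node subset)
#'
#' Breadth-first labelling over edge adjacency. With `subset` given, the
#' components of the induced subgraph are returned.
#'
#' @param mesh a [surface_mesh()].
#' @param subset optional logical or integer vector selecting nodes.
#' @return integer vector over all mesh nodes: component label, or 0 for
#'   nodes outside `subset`.
#' @export
mesh_components <- function(mesh, subset = NULL) {
  n <- mesh$n_nodes
  inset <- rep(TRUE, n)
  if (!is.null(subset)) {
    if (is.logical(subset)) inset <- subset
    else { inset <- rep(FALSE, n); inset[subset] <- TRUE }
  }
  labels <- integer(n)
  comp <- 0L
  adj <- mesh$adjacency
  for (start in which(inset)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      nb <- nb[inset[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- comp
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

# One averaging step: x_v <- (x_v + sum over neighbours) / (1 + degree).
# Row weights sum to 1, so constants are preserved exactly.
smoothing_step_matrix <- function(mesh) {
  n <- mesh$n_nodes
  S <- diag(n)
  e <- mesh$edges
  S[cbind(e[, 1], e[, 2])] <- 1
  S[cbind(e[, 2], e[, 1])] <- 1
  S / rowSums(S)
}

#' Calibrate smoothing iterations for a target FWHM
#'
#' The smoothing operator is iterated nearest-neighbour averaging; each
#' application spreads a point source a little further. This routine applies
#' the step operator to probe deltas and measures the spatial variance of
#' the spread (for a surface the point response is a two-dimensional bump,
#' so the per-axis variance is half the total squared spread). Iteration
#' stops at the step count whose measured width is closest to the requested
#' Gaussian FWHM (`fwhm = sqrt(8 log 2) * sigma`).
#'
#' @param mesh a [surface_mesh()].
#' @param fwhm_mm target full width at half maximum, mm.
#' @param n_probes number of probe nodes (interior-weighted sample).
#' @param max_steps safety cap on iterations.
#' @return integer number of steps (0 when `fwhm_mm == 0`).
#' @export
calibrate_smoothing_steps <- function(mesh, fwhm_mm, n_probes = 12,
                                      max_steps = 2000) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(0L)
  target_var <- 2 * (fwhm_mm / sqrt(8 * log(2)))^2   # 2D total variance
  n <- mesh$n_nodes
  # favour interior nodes: sample proportional to degree
  deg <- lengths(mesh$adjacency)
  probes <- order(deg, decreasing = TRUE)[seq_len(min(n_probes, n))]
  S <- smoothing_step_matrix(mesh)
  X <- matrix(0, n, length(probes))
  X[cbind(probes, seq_along(probes))] <- 1
  pos <- mesh$vertices
  prev_gap <- target_var
  for (k in seq_len(max_steps)) {
    X <- S %*% X
    v <- vapply(seq_along(probes), function(m) {
      w <- X[, m]
      mu <- colSums(w * pos)
      sum(w * rowSums((pos - rep(mu, each = n))^2))
    }, numeric(1))
    vbar <- mean(v)
    if (vbar >= target_var) {
      # choose k or k-1, whichever variance is closer to the target
      return(if (vbar - target_var <= prev_gap) k else max(k - 1L, 1L))
    }
    prev_gap <- target_var - vbar
  }
  warning("smoothing calibration hit max_steps; FWHM may be under-achieved")
  max_steps
}

#' Smooth per-node data on a surface mesh
#'
#' Iterative nearest-neighbour diffusion calibrated so the point-source
#' spread matches a Gaussian of the requested FWHM (see
#' [calibrate_smoothing_steps()]). Each step is mean-preserving for
#' constants (row weights sum to 1) and the whole operator is linear.
#' `fwhm_mm = 0` returns the input unchanged. On a disconnected mesh,
#' smoothing proceeds independently per component, with a warning.
#'
#' @param values numeric vector (one value per node) or matrix
#'   (`n_nodes` x k, columns smoothed independently).
#' @param mesh a [surface_mesh()].
#' @param fwhm_mm target FWHM in mm.
#' @param n_steps optional precomputed step count; bypasses calibration
#'   (useful when smoothing many maps on the same mesh).
#' @return smoothed data, same shape as `values`.
#' @export
smooth_on_mesh <- function(values, mesh, fwhm_mm, n_steps = NULL) {
  vec <- is.null(dim(values))
  X <- if (vec) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(X) != mesh$n_nodes)
    stop("values must have one row per mesh node")
  if (is.null(n_steps)) {
    if (max(mesh_components(mesh)) > 1L)
      warning("mesh is disconnected; smoothing proceeds per component")
    n_steps <- calibrate_smoothing_steps(mesh, fwhm_mm)
  }
  if (n_steps > 0L) {
    S <- smoothing_step_matrix(mesh)
    for (k in seq_len(n_steps)) X <- S %*% X
  }
  if (vec) drop(X) else X
}

#' Supra-threshold clusters on a mesh
#'
#' Connected components (edge adjacency) of the node set with `p <
#' p_threshold` (strict). Cluster area is the sum of member node areas;
#' clusters with area below `extent_mm2` are discarded.
#'
#' @param stat per-node statistic (signed; peak is the largest `|stat|`).
#' @param p per-node p-values.
#' @param mesh a [surface_mesh()].
#' @param p_threshold nodewise primary threshold.
#' @param extent_mm2 minimum cluster area, mm^2; 0 keeps all clusters.
#' @return An object of class `cluster_set`: `clusters` (data.frame with
#'   `cluster_id`, `n_nodes`, `area_mm2`, `peak_stat`, `peak_node`),
#'   `membership` (per-node cluster id, 0 if none), `nodewise_p_threshold`,
#'   `extent_threshold_mm2`, and `nodes` (list of member index vectors).
#' @export
find_clusters <- function(stat, p, mesh, p_threshold, extent_mm2 = 0) {
  stopifnot(length(stat) == mesh$n_nodes, length(p) == mesh$n_nodes)
  supra <- !is.na(p) & p < p_threshold
  labels <- mesh_components(mesh, subset = supra)
  ids <- setdiff(unique(labels), 0L)
  rows <- list(); nodes <- list(); membership <- integer(mesh$n_nodes)
  kept <- 0L
  for (id in ids) {
    members <- which(labels == id)
    area <- sum(mesh$node_area_mm2[members])
    if (area < extent_mm2) next
    kept <- kept + 1L
    pk <- members[which.max(abs(stat[members]))]
    rows[[kept]] <- data.frame(cluster_id = kept, n_nodes = length(members),
                               area_mm2 = area, peak_stat = stat[pk],
                               peak_node = pk)
    nodes[[kept]] <- members
    membership[members] <- kept
  }
  clusters <- if (kept) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), n_nodes = integer(),
               area_mm2 = numeric(), peak_stat = numeric(),
               peak_node = integer())
  # largest first
  if (kept > 1L) {
    ord <- order(clusters$area_mm2, decreasing = TRUE)
    clusters <- clusters[ord, ]
    nodes <- nodes[ord]
    relabel <- integer(kept); relabel[clusters$cluster_id] <- seq_len(kept)
    clusters$cluster_id <- seq_len(kept)
    membership[membership > 0L] <- relabel[membership[membership > 0L]]
    rownames(clusters) <- NULL
  }
  structure(
    list(clusters = clusters, membership = membership, nodes = nodes,
         nodewise_p_threshold = p_threshold,
         extent_threshold_mm2 = extent_mm2),
    class = "cluster_set")
}

#' Read a FreeSurfer ASCII surface
#'
#' The `.asc` dialect: an optional leading `#` comment line, a line with
#' vertex and triangle counts, then one line per vertex (x y z flag) and one
#' per triangle (three 0-based indices plus flag).
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_freesurfer_ascii <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  counts <- scan(text = lines[1], quiet = TRUE)
  nv <- as.integer(counts[1]); nt <- as.integer(counts[2])
  vert <- matrix(scan(text = lines[2:(1 + nv)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)[, 1:3, drop = FALSE]
  tri <- matrix(scan(text = lines[(2 + nv):(1 + nv + nt)], quiet = TRUE),
                ncol = 4, byrow = TRUE)[, 1:3, drop = FALSE] + 1L
  surface_mesh(vert, tri)
}

#' Write a FreeSurfer ASCII surface
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freesurfer_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#!ascii surface written by crossisc", con)
  writeLines(sprintf("%d %d", mesh$n_nodes, nrow(mesh$triangles)), con)
  writeLines(sprintf("%.6f %.6f %.6f 0", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("%d %d %d 0", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L),
             con)
  invisible(path)
}

#' Write a cluster table as CSV
#'
#' @param clusters a [find_clusters()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  utils::write.csv(clusters$clusters, path, row.names = FALSE)
  invisible(path)
}
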