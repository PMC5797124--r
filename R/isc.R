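#' Fisher z-transform and its inverse
#'
#' `fisher_z()` maps correlations to the variance-stabilized scale
#' `z = atanh(r)`; `inverse_fisher()` maps back with `tanh`. Correlations
#' with `|r| >= 1 - 1e-12` are clipped to that bound before the transform
#' (an infinite z would be unusable as a mixed-model response); clipping is
#' reported in the `clipped` attribute.
#'
#' @param r correlations.
#' @param clip_bound clipping bound; default `1 - 1e-12`.
#' @return `fisher_z`: z values, with logical attribute `clipped` when any
#'   input was clipped. `inverse_fisher`: correlations.
#' @export
fisher_z <- function(r, clip_bound = 1 - 1e-12) {
  clipped <- !is.na(r) & abs(r) >= clip_bound
  r[clipped] <- sign(r[clipped]) * clip_bound
  z <- atanh(r)
  if (any(clipped)) attr(z, "clipped") <- clipped
  z
}

#' @rdname fisher_z
#' @param z Fisher z values.
#' @export
inverse_fisher <- function(z) tanh(z)

# rowwise Pearson correlation of two node x time matrices over given columns
rowwise_cor <- function(A, B, cols) {
  a <- A[, cols, drop = FALSE]; b <- B[, cols, drop = FALSE]
  a <- a - rowMeans(a); b <- b - rowMeans(b)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  num / den
}

#' Per-node pairwise inter-subject correlation matrix
#'
#' For every node, the Pearson correlation between each pair of subjects'
#' residual time series, computed over the volumes uncensored in *both*
#' subjects of the pair (pairwise-complete), then Fisher z-transformed into
#' a symmetric N x N matrix with an undefined diagonal. Pairs with fewer
#' mutually usable volumes than `min_volumes` are flagged and excluded
#' downstream (propagated as missing, never as zeros).
#'
#' @param residuals named list of residual [subject_time_series()] (censored
#'   volumes `NA`, as produced by [regress_nuisance()]). All subjects must
#'   share the node count and volume count.
#' @param min_volumes minimum mutually uncensored volumes per pair;
#'   default 100.
#' @return An object of class `cohort_isc`: `z` (array `n_nodes` x N x N,
#'   `NA` diagonal), `subjects` (data.frame: subject_id, group,
#'   age_months), `pair_counts` (N x N), `flagged` (N x N logical: too few
#'   volumes), `clipped` (N x N logical: any node's `|r|` hit the clipping
#'   bound), `n_subjects`, `n_nodes`, `min_volumes`.
#' @export
pairwise_isc <- function(residuals, min_volumes = 100) {
  N <- length(residuals)
  if (N < 2L) stop("need at least 2 subjects")
  nV <- residuals[[1]]$n_nodes
  nT <- residuals[[1]]$n_volumes
  for (r in residuals)
    if (r$n_nodes != nV || r$n_volumes != nT)
      stop("all subjects must share node and volume counts")
  ids <- vapply(residuals, function(r) r$subject_id, character(1))
  keep <- vapply(residuals, function(r) !is.na(r$data[1, ]), logical(nT))

  z <- array(NA_real_, c(nV, N, N))
  pair_counts <- matrix(0L, N, N, dimnames = list(ids, ids))
  flagged <- matrix(FALSE, N, N, dimnames = list(ids, ids))
  clipped <- matrix(FALSE, N, N, dimnames = list(ids, ids))
  bound <- 1 - 1e-12
  for (i in seq_len(N - 1L)) {
    Ai <- residuals[[i]]$data
    for (j in (i + 1L):N) {
      cols <- which(keep[, i] & keep[, j])
      pair_counts[i, j] <- pair_counts[j, i] <- length(cols)
      if (length(cols) < min_volumes) {
        flagged[i, j] <- flagged[j, i] <- TRUE
        next
      }
      r <- rowwise_cor(Ai, residuals[[j]]$data, cols)
      cl <- !is.na(r) & abs(r) >= bound
      if (any(cl)) {
        r[cl] <- sign(r[cl]) * bound
        clipped[i, j] <- clipped[j, i] <- TRUE
      }
      zz <- atanh(r)
      z[, i, j] <- z[, j, i] <- zz
    }
  }
  subjects <- data.frame(
    subject_id = ids,
    group = vapply(residuals, function(r) r$group, character(1)),
    age_months = vapply(residuals, function(r) r$age_months, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  out <- structure(
    list(z = z, subjects = subjects, pair_counts = pair_counts,
         flagged = flagged, clipped = clipped, n_subjects = N,
         n_nodes = nV, min_volumes = min_volumes),
    class = "cohort_isc")
  validate_isc(out)
  out
}

# structural invariants asserted on every build
validate_isc <- function(m) {
  for (v in seq_len(m$n_nodes)) {
    zv <- m$z[v, , ]
    if (!all(is.na(diag(zv)))) stop("ISC diagonal must be undefined")
    off <- !is.na(zv)
    if (!isTRUE(all.equal(zv[off], t(zv)[off], tolerance = 0)) ||
        !identical(off, t(off)))
      stop("ISC matrix must be symmetric at every node")
  }
  invisible(m)
}

resolve_selector <- function(m, sel) {
  if (is.logical(sel)) return(which(sel))
  if (is.numeric(sel)) return(as.integer(sel))
  idx <- which(m$subjects$group %in% sel)
  if (!length(idx)) idx <- which(m$subjects$subject_id %in% sel)
  if (!length(idx)) stop("selector matches no subjects: ",
                         paste(sel, collapse = ", "))
  idx
}

#' Extract a block of the pairwise ISC matrix as a pair table
#'
#' With identical row and column selectors (a within-group block), each
#' unordered pair appears once; `doubled = TRUE` additionally returns the
#' both-triangles listing (each pair in both orders) used to build balanced
#' crossed random-effects designs. With disjoint selectors (a between-group
#' block, e.g. child x adult), each (row, col) pair appears once.
#'
#' @param m a [pairwise_isc()] result.
#' @param rows,cols group names, subject ids, indices, or logical vectors.
#' @param doubled list both triangles of a within-group block; ignored for
#'   between-group blocks.
#' @return An object of class `isc_pairs`: `pairs` (data.frame with i, j
#'   indices, subject ids, groups, ages, `pair_count`, `flagged`) and `z`
#'   (matrix `n_pairs` x `n_nodes`).
#' @export
extract_block <- function(m, rows, cols, doubled = FALSE) {
  stopifnot(inherits(m, "cohort_isc"))
  ri <- resolve_selector(m, rows)
  ci <- resolve_selector(m, cols)
  if (!length(ri) || !length(ci)) stop("empty selector")
  same <- setequal(ri, ci)
  if (!same && length(intersect(ri, ci)))
    stop("selectors must be disjoint or identical")
  if (same) {
    ri <- sort(ri)
    idx <- if (length(ri) < 2L) matrix(integer(0), 0, 2)
           else t(utils::combn(ri, 2L))
    if (doubled) idx <- rbind(idx, idx[, 2:1, drop = FALSE])
  } else {
    idx <- as.matrix(expand.grid(i = ri, j = ci))
  }
  i <- idx[, 1]; j <- idx[, 2]
  s <- m$subjects
  pairs <- data.frame(
    i = i, j = j,
    subject_i = s$subject_id[i], subject_j = s$subject_id[j],
    group_i = s$group[i], group_j = s$group[j],
    age_i = s$age_months[i], age_j = s$age_months[j],
    pair_count = m$pair_counts[cbind(i, j)],
    flagged = m$flagged[cbind(i, j)],
    stringsAsFactors = FALSE)
  zmat <- vapply(seq_len(m$n_nodes),
                 function(v) m$z[v, , ][cbind(i, j)],
                 numeric(length(i)))
  zmat <- matrix(zmat, nrow = length(i))
  structure(list(pairs = pairs, z = zmat, n_nodes = m$n_nodes,
                 doubled = same && doubled),
            class = "isc_pairs")
}

#' Neural maturity: a child's average Fisher-z ISC with the adult group
#'
#' Per node, the mean of the z entries between each child and every
#' non-flagged adult — an index of how adult-like the child's
#' stimulus-evoked response is. `maturity_age_regression()` pairs this with
#' an ordinary per-node linear regression of the average on child age, the
#' traditional (non-crossed) analysis of age-related synchrony change.
#'
#' @param m a [pairwise_isc()] result.
#' @param children,adults selectors as in [extract_block()]; defaults pick
#'   groups named other than / equal to `"adult"`.
#' @return matrix `n_children` x `n_nodes` of average z values (rownames =
#'   child subject ids); `NA` where every adult pair was flagged.
#' @export
neural_maturity <- function(m, children = NULL, adults = "adult") {
  stopifnot(inherits(m, "cohort_isc"))
  ai <- resolve_selector(m, adults)
  ci <- if (is.null(children)) setdiff(seq_len(m$n_subjects), ai)
        else resolve_selector(m, children)
  if (!length(ai)) stop("no adults present")
  out <- matrix(NA_real_, length(ci), m$n_nodes,
                dimnames = list(m$subjects$subject_id[ci], NULL))
  for (k in seq_along(ci)) {
    ok <- ai[!m$flagged[ci[k], ai]]
    if (!length(ok)) next
    block <- m$z[, ci[k], ok, drop = FALSE]   # n_nodes x 1 x n_ok
    out[k, ] <- apply(block, 1, mean)
  }
  out
}

#' @rdname neural_maturity
#' @param maturity a [neural_maturity()] matrix.
#' @param age_months child ages aligned with the maturity rows.
#' @return `maturity_age_regression`: data.frame per node with `slope`
#'   (z per month), `se`, `t`, `df`, `p`.
#' @export
maturity_age_regression <- function(maturity, age_months) {
  stopifnot(nrow(maturity) == length(age_months))
  rows <- lapply(seq_len(ncol(maturity)), function(v) {
    y <- maturity[, v]
    ok <- !is.na(y)
    fit <- summary(stats::lm(y[ok] ~ age_months[ok]))
    co <- fit$coefficients
    data.frame(node = v, slope = co[2, 1], se = co[2, 2], t = co[2, 3],
               df = fit$df[2], p = co[2, 4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a cohort ISC matrix as long-format CSV
#'
#' One row per (node, unordered subject pair): `node, subject_i, subject_j,
#' z, pair_count`.
#'
#' @param m a [pairwise_isc()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isc_long <- function(m, path) {
  stopifnot(inherits(m, "cohort_isc"))
  idx <- t(utils::combn(m$n_subjects, 2L))
  rows <- lapply(seq_len(m$n_nodes), function(v) {
    zv <- m$z[v, , ]
    data.frame(node = v,
               subject_i = m$subjects$subject_id[idx[, 1]],
               subject_j = m$subjects$subject_id[idx[, 2]],
               z = zv[idx],
               pair_count = m$pair_counts[idx])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
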