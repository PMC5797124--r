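#' Scale each node's time series to a temporal mean of 100
#'
#' Standard BOLD intensity normalization: every node is multiplied by
#' `100 / mean(node)`, so percent signal change is comparable across nodes
#' and subjects. Nodes with (near-)zero temporal mean cannot be scaled; they
#' are set to all-zero, recorded in the `zero_mean_nodes` attribute, and a
#' warning is raised.
#'
#' @param ts a [subject_time_series()].
#' @param tol absolute mean below which a node counts as zero-mean.
#' @return the scaled `subject_ts`; attribute `zero_mean_nodes` holds the
#'   indices of flagged nodes (if any).
#' @export
scale_to_mean_100 <- function(ts, tol = 1e-12) {
  stopifnot(inherits(ts, "subject_ts"))
  mu <- rowMeans(ts$data)
  bad <- which(abs(mu) < tol)
  out <- ts$data * (100 / mu)
  if (length(bad)) {
    out[bad, ] <- 0
    warning(sprintf("%d zero-mean node(s) set to zero: %s", length(bad),
                    paste(utils::head(bad, 5), collapse = ", ")))
  }
  ts$data <- out
  attr(ts, "zero_mean_nodes") <- bad
  ts
}

# sine/cosine regressors at all DFT frequencies of the run that fall
# OUTSIDE the retention band; regressing them out band-stops the data while
# letting censored volumes simply be dropped from the fit
bandstop_regressors <- function(n_volumes, tr_seconds,
                                band_hz = c(0.01, 0.1)) {
  t_idx <- seq_len(n_volumes) - 1
  total <- n_volumes * tr_seconds
  cols <- list(); nm <- character(0)
  for (k in seq_len(floor(n_volumes / 2))) {
    f <- k / total
    if (f >= band_hz[1] && f <= band_hz[2]) next
    ang <- 2 * pi * k * t_idx / n_volumes
    cols[[length(cols) + 1L]] <- cos(ang)
    nm <- c(nm, sprintf("bs_cos_%d", k))
    if (k < n_volumes / 2) {           # sine at Nyquist is identically 0
      cols[[length(cols) + 1L]] <- sin(ang)
      nm <- c(nm, sprintf("bs_sin_%d", k))
    }
  }
  if (!length(cols)) return(matrix(0, n_volumes, 0))
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Build the single nuisance regression design
#'
#' One design holding every signal of no interest, regressed out in a single
#' pass: an intercept plus orthogonal polynomial trends (orders 1-3),
#' band-stop sine/cosine pairs at all run-length DFT frequencies outside the
#' retention band (default 0.01-0.1 Hz) so that censored volumes can be
#' omitted from the regression rather than interpolated, demeaned motion
#' parameters (6) and their backward-difference derivatives (6, first
#' element 0), tissue means (white matter, ventricle), and optionally the
#' mean FEF signal as an attention-control regressor.
#'
#' @param n_volumes run length.
#' @param tr_seconds sampling interval, s.
#' @param motion optional [motion_trace()]; adds 12 columns.
#' @param tissue optional named list of tissue nuisance vectors (e.g.
#'   `white_matter`, `ventricle`, and `fef`); each adds one column. The
#'   `fef` entry is only used when `include_fef = TRUE`.
#' @param censor optional [make_censor_mask()]; stored on the design and
#'   honoured by [regress_nuisance()].
#' @param include_fef add the `fef` tissue column; default `FALSE`.
#' @param band_hz retention band in Hz; frequencies outside it are removed.
#' @param poly_order highest polynomial trend order; default 3.
#' @return An object of class `nuisance_design`: `X` (n_volumes x p, named
#'   columns), `censor`, `n_volumes`, `condition_number` (of the
#'   column-scaled design on kept volumes).
#' @export
build_nuisance_design <- function(n_volumes, tr_seconds, motion = NULL,
                                  tissue = NULL, censor = NULL,
                                  include_fef = FALSE,
                                  band_hz = c(0.01, 0.1), poly_order = 3) {
  parts <- list(intercept = matrix(1, n_volumes, 1))
  colnames(parts$intercept) <- "intercept"
  if (poly_order > 0) {
    tp <- stats::poly(seq_len(n_volumes), degree = poly_order)
    colnames(tp) <- sprintf("poly%d", seq_len(poly_order))
    parts$trends <- unclass(tp)
  }
  parts$bandstop <- bandstop_regressors(n_volumes, tr_seconds, band_hz)
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "motion_trace"))
    if (motion$n_volumes != n_volumes)
      stop("motion trace length does not match n_volumes")
    mp <- cbind(motion$translations, motion$rotations)
    mp <- scale(mp, center = TRUE, scale = FALSE)
    dmp <- rbind(0, diff(mp))
    colnames(mp) <- sprintf("mot%d", 1:6)
    colnames(dmp) <- sprintf("dmot%d", 1:6)
    parts$motion <- cbind(mp, dmp)
  }
  if (!is.null(tissue)) {
    keep_names <- setdiff(names(tissue), "fef")
    if (include_fef) {
      if (is.null(tissue$fef))
        stop("include_fef = TRUE but tissue$fef is missing")
      keep_names <- c(keep_names, "fef")
    }
    for (nmv in keep_names) {
      v <- tissue[[nmv]]
      if (length(v) != n_volumes)
        stop("tissue signal '", nmv, "' length does not match n_volumes")
      m <- matrix(v - mean(v), ncol = 1)
      colnames(m) <- nmv
      parts[[paste0("tissue_", nmv)]] <- m
    }
  } else if (include_fef) {
    stop("include_fef = TRUE but no tissue signals supplied")
  }
  X <- do.call(cbind, parts)

  keep <- if (is.null(censor)) rep(TRUE, n_volumes) else censor$keep
  if (!is.null(censor) && length(censor$keep) != n_volumes)
    stop("censor mask length does not match n_volumes")
  n_keep <- sum(keep)
  if (ncol(X) >= n_keep)
    stop(sprintf("design not estimable: %d columns >= %d usable volumes",
                 ncol(X), n_keep))
  Xk <- X[keep, , drop = FALSE]
  qr_k <- qr(Xk)
  if (qr_k$rank < ncol(X)) {
    dropped <- colnames(X)[qr_k$pivot[(qr_k$rank + 1):ncol(X)]]
    stop("design rank-deficient after censoring; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  sc <- sqrt(colSums(Xk^2))
  cond <- kappa(Xk %*% diag(1 / sc, ncol(Xk)), exact = TRUE)
  structure(
    list(X = X, censor = censor, n_volumes = n_volumes,
         condition_number = cond),
    class = "nuisance_design")
}

#' Regress the nuisance design out of a subject's time series
#'
#' Per node, an ordinary least-squares fit of the signal on the design using
#' uncensored volumes only; the returned series holds the residuals.
#' Censored volumes do not influence the fit; their positions are kept as
#' `NA` gaps (flagged, never interpolated) and downstream pairwise ISC
#' drops them pairwise.
#'
#' @param ts a [subject_time_series()] (typically after
#'   [scale_to_mean_100()]).
#' @param design a [build_nuisance_design()].
#' @return the residual `subject_ts`; censored columns are `NA` and the
#'   `censored_volumes` attribute lists their indices.
#' @export
regress_nuisance <- function(ts, design) {
  stopifnot(inherits(ts, "subject_ts"), inherits(design, "nuisance_design"))
  if (ts$n_volumes != design$n_volumes)
    stop("time series and design disagree on n_volumes")
  keep <- if (is.null(design$censor)) rep(TRUE, ts$n_volumes)
          else design$censor$keep
  Xk <- design$X[keep, , drop = FALSE]
  Yk <- t(ts$data[, keep, drop = FALSE])      # volumes x nodes
  fit <- stats::lm.fit(Xk, Yk)
  res <- matrix(NA_real_, ts$n_nodes, ts$n_volumes)
  res[, keep] <- t(fit$residuals)
  ts$data <- res
  attr(ts, "censored_volumes") <- which(!keep)
  ts
}

#' End-to-end preprocessing of one subject
#'
#' Chains the per-subject pipeline: FD + censor mask from the motion trace,
#' run-level exclusion check, mean-100 scaling, single nuisance regression,
#' and optional surface smoothing of the residuals.
#'
#' @param ts a [subject_time_series()].
#' @param motion a [motion_trace()].
#' @param tissue named list of nuisance signals (see
#'   [build_nuisance_design()]).
#' @param tr_seconds sampling interval, s.
#' @param mesh optional [surface_mesh()] for residual smoothing.
#' @param fwhm_mm smoothing FWHM when `mesh` is given; default 7.
#' @param smooth_steps optional precomputed step count for the mesh.
#' @param include_fef include the FEF attention-control regressor.
#' @param fd_threshold_mm censor threshold; default 0.5.
#' @param rotation_radius_mm FD rotation conversion radius; default 50.
#' @param max_censor_fraction run-exclusion bound; default 0.09.
#' @return list with `residuals` (a `subject_ts`, `NA` at censored
#'   volumes), `fd`, `censor`, `exclusion` (from [run_exclusion()]), and
#'   `design_condition_number`.
#' @export
preprocess_subject <- function(ts, motion, tissue = NULL, tr_seconds = 2,
                               mesh = NULL, fwhm_mm = 7,
                               smooth_steps = NULL, include_fef = FALSE,
                               fd_threshold_mm = 0.5,
                               rotation_radius_mm = 50,
                               max_censor_fraction = 0.09) {
  fd <- compute_fd(motion, rotation_radius_mm)
  censor <- make_censor_mask(fd, fd_threshold_mm)
  excl <- run_exclusion(censor, ts$n_volumes, max_censor_fraction)
  scaled <- scale_to_mean_100(ts)
  design <- build_nuisance_design(ts$n_volumes, tr_seconds, motion = motion,
                                  tissue = tissue, censor = censor,
                                  include_fef = include_fef)
  resid <- regress_nuisance(scaled, design)
  if (!is.null(mesh)) {
    keep <- censor$keep
    sm <- resid$data
    sm[, keep] <- smooth_on_mesh(resid$data[, keep, drop = FALSE], mesh,
                                 fwhm_mm, n_steps = smooth_steps)
    resid$data <- sm
  }
  list(residuals = resid, fd = fd, censor = censor, exclusion = excl,
       design_condition_number = design$condition_number)
}

#' Preprocess every subject of a cohort
#'
#' Applies [preprocess_subject()] across a [simulate_cohort()] result (or
#' any list with the same shape), dropping runs that fail the motion
#' exclusion rule.
#'
#' @param cohort a `synthetic_cohort`.
#' @param mesh optional [surface_mesh()] for residual smoothing.
#' @param fwhm_mm smoothing FWHM; default 7.
#' @param include_fef include the FEF regressor; default `FALSE`.
#' @param ... further arguments to [preprocess_subject()].
#' @return list with `residuals` (named list of residual `subject_ts` for
#'   included runs), `excluded` (ids of dropped runs), and `summary`
#'   (per-subject data.frame: mean FD, censored count, included flag).
#' @export
preprocess_cohort <- function(cohort, mesh = NULL, fwhm_mm = 7,
                              include_fef = FALSE, ...) {
  smooth_steps <- if (!is.null(mesh))
    calibrate_smoothing_steps(mesh, fwhm_mm) else NULL
  ids <- cohort$metadata$subject_id
  residuals <- list(); rows <- list(); excluded <- character(0)
  for (id in ids) {
    pp <- preprocess_subject(cohort$subjects[[id]], cohort$motion[[id]],
                             tissue = cohort$nuisance_signals[[id]],
                             tr_seconds = cohort$config$tr_seconds %||% 2,
                             mesh = mesh, fwhm_mm = fwhm_mm,
                             smooth_steps = smooth_steps,
                             include_fef = include_fef, ...)
    rows[[id]] <- data.frame(subject_id = id, mean_fd = mean(pp$fd),
                             n_censored = pp$censor$n_censored,
                             included = pp$exclusion$include)
    if (pp$exclusion$include) residuals[[id]] <- pp$residuals
    else excluded <- c(excluded, id)
  }
  list(residuals = residuals, excluded = excluded,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write residual time series with a censored-volume sidecar
#'
#' @param ts a residual `subject_ts` from [regress_nuisance()].
#' @param path output path for the tab-delimited node x time matrix;
#'   censored volume indices go to `<path>.censored`.
#' @return `path`, invisibly.
#' @export
write_residuals <- function(ts, path) {
  utils::write.table(ts$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  cens <- attr(ts, "censored_volumes")
  writeLines(as.character(cens %||% integer(0)),
             paste0(path, ".censored"))
  invisible(path)
}
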