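# per-node model drivers over a cohort ISC matrix

fit_row <- function(node, effect, fit, which_coef, r_scale = FALSE) {
  b <- fit$beta[which_coef]
  data.frame(node = node, effect = effect, beta_z = unname(b),
             beta_r = if (r_scale) unname(tanh(b)) else NA_real_,
             se = unname(fit$se[which_coef]),
             t = unname(fit$t[which_coef]),
             df = unname(fit$df[which_coef]),
             p = unname(fit$p_value[which_coef]),
             var_resid = fit$var_resid,
             var_subject = unname(fit$var_subject[1]),
             converged = fit$converged, boundary = fit$boundary,
             n_pairs = fit$n_pairs, stringsAsFactors = FALSE)
}

na_row <- function(node, effect) {
  data.frame(node = node, effect = effect, beta_z = NA_real_,
             beta_r = NA_real_, se = NA_real_, t = NA_real_, df = NA_real_,
             p = NA_real_, var_resid = NA_real_, var_subject = NA_real_,
             converged = FALSE, boundary = NA, n_pairs = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Per-node within-group synchrony model
#'
#' Intercept-only crossed random-effects fit of all within-group pairwise z
#' values at each node; the intercept is the group-average ISC, reported
#' both on the z scale and back-transformed to a Pearson r (`tanh`).
#'
#' @param m a [pairwise_isc()] result.
#' @param group group selector (see [extract_block()]).
#' @param min_pairs minimum non-missing pairs per node; nodes below it are
#'   returned as `NA` rows with `converged = FALSE`.
#' @param nodes node indices to fit; default all.
#' @return data.frame, one row per node: `node`, `effect = "intercept"`,
#'   `beta_z`, `beta_r`, `se`, `t`, `df`, `p`, variance components,
#'   convergence flags, `n_pairs`.
#' @export
within_group_model <- function(m, group, min_pairs = 6, nodes = NULL) {
  blk <- extract_block(m, group, group)
  if (is.null(nodes)) nodes <- seq_len(blk$n_nodes)
  X <- matrix(1, nrow(blk$pairs), 1, dimnames = list(NULL, "intercept"))
  out <- lapply(nodes, function(v) {
    zv <- blk$z[, v]
    if (sum(!is.na(zv)) < min_pairs) return(na_row(v, "intercept"))
    fit <- fit_crossed_lmm(zv, X, blk$pairs$subject_i, blk$pairs$subject_j)
    fit_row(v, "intercept", fit, "intercept", r_scale = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-node between-group synchrony contrast
#'
#' Compares within-group synchrony levels between two groups: the model is
#' fit over the within-A plus within-B pairs with a group-affiliation fixed
#' effect (`beta` = A minus B) and a shared subject random intercept.
#' Mixed (A, B) pairs are excluded by default — the contrast asks whether
#' one group synchronizes more strongly within itself, not whether the
#' groups synchronize with each other; `include_mixed = TRUE` adds them as
#' a third affiliation level.
#'
#' @param m a [pairwise_isc()] result.
#' @param groupA,groupB group selectors; the reported effect is A - B.
#' @param include_mixed add between-group pairs as a third level.
#' @inheritParams within_group_model
#' @return data.frame, one row per node, `effect = "affiliation"`.
#' @export
group_contrast_model <- function(m, groupA, groupB, include_mixed = FALSE,
                                 min_pairs = 10, nodes = NULL) {
  blkA <- extract_block(m, groupA, groupA)
  blkB <- extract_block(m, groupB, groupB)
  pairs <- rbind(blkA$pairs, blkB$pairs)
  zmat <- rbind(blkA$z, blkB$z)
  lev <- c(rep("A", nrow(blkA$pairs)), rep("B", nrow(blkB$pairs)))
  if (include_mixed) {
    blkM <- extract_block(m, groupA, groupB)
    pairs <- rbind(pairs, blkM$pairs)
    zmat <- rbind(zmat, blkM$z)
    lev <- c(lev, rep("mixed", nrow(blkM$pairs)))
  }
  X <- cbind(intercept = 1, affiliation = as.numeric(lev == "A"))
  if (include_mixed) X <- cbind(X, mixed = as.numeric(lev == "mixed"))
  if (is.null(nodes)) nodes <- seq_len(blkA$n_nodes)
  out <- lapply(nodes, function(v) {
    zv <- zmat[, v]
    if (sum(!is.na(zv)) < min_pairs) return(na_row(v, "affiliation"))
    fit <- fit_crossed_lmm(zv, X, pairs$subject_i, pairs$subject_j)
    fit_row(v, "affiliation", fit, "affiliation")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-node child-to-adult age model
#'
#' Fits the child x adult block of the ISC matrix with crossed child and
#' adult random intercepts and fixed effects intercept + centered child age
#' (months). The age slope tests whether a child's synchrony with the adult
#' group — neural maturity — increases with age.
#'
#' @param m a [pairwise_isc()] result.
#' @param children,adults selectors (see [neural_maturity()]).
#' @inheritParams within_group_model
#' @return data.frame, one row per node, `effect = "age_months"`; `beta_z`
#'   is the slope in z units per month.
#' @export
child_to_adult_age_model <- function(m, children = NULL, adults = "adult",
                                     min_pairs = 10, nodes = NULL) {
  ai <- resolve_selector(m, adults)
  ci <- if (is.null(children)) setdiff(seq_len(m$n_subjects), ai)
        else resolve_selector(m, children)
  blk <- extract_block(m, ci, ai)
  age <- blk$pairs$age_i
  if (stats::sd(age) == 0)
    stop("age covariate is constant; slope not estimable")
  X <- cbind(intercept = 1, age_months = age - mean(age))
  if (is.null(nodes)) nodes <- seq_len(blk$n_nodes)
  out <- lapply(nodes, function(v) {
    zv <- blk$z[, v]
    if (sum(!is.na(zv)) < min_pairs) return(na_row(v, "age_months"))
    fit <- fit_crossed_lmm(zv, X, blk$pairs$subject_i, blk$pairs$subject_j,
                           crossed_factors = TRUE)
    fit_row(v, "age_months", fit, "age_months")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export per-node fit tables as CSV
#'
#' @param fits a data.frame from [within_group_model()],
#'   [group_contrast_model()], or [child_to_adult_age_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}
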