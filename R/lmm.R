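# ---- crossed random-effects REML for pairwise Fisher-z ISC -----------------
#
# Model over pairs p:
#   z_p = x_p' beta + a_{i(p)} + a_{j(p)} + e_p,
#   a ~ N(0, tau^2) iid over subjects, e ~ N(0, sigma^2) iid over pairs.
# For child-to-adult blocks the two memberships come from different subject
# pools and carry separate variance components (crossed child and adult
# random intercepts).
#
# Marginally V = sigma^2 I + sum_k tau_k^2 Z_k Z_k', with Z_k the pair ->
# subject incidence. Estimation profiles sigma^2 out of the REML criterion
# and optimizes the low-dimensional variance ratio(s) gamma_k =
# tau_k^2/sigma^2; all V^{-1} products use the Woodbury identity, so the
# cost per evaluation is O(n N^2) rather than O(n^3).

# W = I + sum_k gamma_k Z_k Z_k'. Returns W^{-1} %*% A and log|W|.
woodbury_solve <- function(Zs, gamma, A) {
  act <- which(gamma > 0)
  if (!length(act)) return(list(WiA = A, logdet = 0))
  Zg <- do.call(cbind, lapply(act, function(k) sqrt(gamma[k]) * Zs[[k]]))
  M <- diag(ncol(Zg)) + crossprod(Zg)
  R <- chol(M)
  ZtA <- crossprod(Zg, A)
  WiA <- A - Zg %*% backsolve(R, forwardsolve(t(R), ZtA))
  list(WiA = WiA, logdet = 2 * sum(log(diag(R))))
}

# profiled REML criterion and GLS pieces at a given gamma
reml_pieces <- function(gamma, z, X, Zs) {
  n <- length(z); p <- ncol(X)
  w <- woodbury_solve(Zs, gamma, cbind(X, z))
  WiX <- w$WiA[, seq_len(p), drop = FALSE]
  Wiz <- w$WiA[, p + 1L]
  XtWiX <- crossprod(X, WiX)
  R <- chol(XtWiX)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, Wiz)))
  r <- z - X %*% beta
  # r'W^{-1}r = z'W^{-1}z - 2 beta'X'W^{-1}z + beta'X'W^{-1}X beta
  rWr <- drop(crossprod(z, Wiz) - 2 * crossprod(beta, crossprod(X, Wiz)) +
              crossprod(beta, XtWiX %*% beta))
  rWr <- max(rWr, 0)
  logdet_XtWiX <- 2 * sum(log(diag(R)))
  list(beta = drop(beta), rWr = rWr, logdetW = w$logdet,
       logdet_XtWiX = logdet_XtWiX, XtWiX = XtWiX, n = n, p = p)
}

reml_criterion <- function(gamma, z, X, Zs) {
  pc <- reml_pieces(gamma, z, X, Zs)
  if (pc$rWr < 1e-300) return(-Inf)  # degenerate: perfect fit
  (pc$n - pc$p) * log(pc$rWr) + pc$logdetW + pc$logdet_XtWiX
}

# full REML log-likelihood on the variance scale theta = (tau^2_k, sigma^2)
reml_loglik_theta <- function(theta, z, X, Zs) {
  K <- length(Zs)
  sigma2 <- theta[K + 1L]
  gamma <- theta[seq_len(K)] / sigma2
  pc <- reml_pieces(gamma, z, X, Zs)
  n <- pc$n; p <- pc$p
  -0.5 * ((n - p) * log(2 * pi * sigma2) + pc$logdetW +
            pc$logdet_XtWiX + pc$rWr / sigma2)
}

#' Fit a crossed random-effects linear mixed model to pairwise z values
#'
#' Restricted maximum likelihood for
#' \deqn{z_p = x_p'\beta + a_{i(p)} + a_{j(p)} + e_p,}
#' where each pairwise observation carries random intercepts for both
#' contributing subjects (`a ~ N(0, tau^2)` over subjects, shared variance
#' when both memberships come from one pool, separate `tau_i^2`, `tau_j^2`
#' when `crossed_factors = TRUE`, e.g. child x adult blocks) and
#' `e ~ N(0, sigma^2)` captures pair-level residual.
#'
#' The profile-REML criterion is optimized over the variance ratio(s); all
#' covariance algebra runs through the Woodbury identity on the pair ->
#' subject incidence, so fits scale with the subject count rather than the
#' pair count. Standard errors come from the GLS information; per-effect
#' degrees of freedom use the Satterthwaite approximation (see
#' [satterthwaite_df()]).
#'
#' A table listing both triangles of a within-group correlation block
#' (`doubled = TRUE`) duplicates each unordered pair; the duplicates carry
#' no additional information, so the fit deduplicates to the single
#' triangle and models its exact pair covariance. Estimates and standard
#' errors are therefore identical between doubled and single-triangle
#' inputs by construction.
#'
#' @param z numeric response vector of Fisher-z ISC values (rows with `NA`
#'   are dropped).
#' @param X fixed-effects design matrix (full rank, named columns).
#' @param id_i,id_j subject identifiers of the two members of each pair.
#' @param crossed_factors `FALSE` (default): one subject pool, one shared
#'   `tau^2`, incidence with two 1s per row. `TRUE`: `id_i` and `id_j`
#'   index different pools (two variance components).
#' @param doubled input lists both triangles; deduplicate first.
#' @return An object of class `crossed_lmm_fit`: `beta`, `se`, `t`, `df`,
#'   `p` (per fixed effect), `var_subject` (named variance component(s)),
#'   `var_resid`, `reml_loglik`, `converged`, `boundary` (any variance
#'   pinned at 0), `degenerate` (zero residual variance), `n_pairs`,
#'   `n_subjects`.
#' @export
fit_crossed_lmm <- function(z, X, id_i, id_j, crossed_factors = FALSE,
                            doubled = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  id_i <- as.character(id_i); id_j <- as.character(id_j)
  stopifnot(length(z) == nrow(X), length(id_i) == length(z),
            length(id_j) == length(z))
  if (any(!is.na(z) & id_i == id_j))
    stop("self-pairs (i == j) are not allowed")

  ok <- !is.na(z) & stats::complete.cases(X)
  z <- z[ok]; X <- X[ok, , drop = FALSE]
  id_i <- id_i[ok]; id_j <- id_j[ok]

  if (doubled) {
    key <- paste(pmin(id_i, id_j), pmax(id_i, id_j))
    first <- !duplicated(key)
    dup_of <- match(key, key[first])
    if (any(abs(z - z[first][dup_of]) > 1e-10))
      stop("doubled = TRUE but triangles disagree; matrix not symmetric")
    z <- z[first]; X <- X[first, , drop = FALSE]
    id_i <- id_i[first]; id_j <- id_j[first]
  }
  n <- length(z); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("fixed-effects design is rank deficient (estimability error)")

  if (crossed_factors) {
    lev_i <- sort(unique(id_i)); lev_j <- sort(unique(id_j))
    if (length(lev_i) < 4L || length(lev_j) < 4L)
      stop("need >= 4 subjects per random factor")
    Zi <- matrix(0, n, length(lev_i)); Zi[cbind(seq_len(n), match(id_i, lev_i))] <- 1
    Zj <- matrix(0, n, length(lev_j)); Zj[cbind(seq_len(n), match(id_j, lev_j))] <- 1
    Zs <- list(subject_i = Zi, subject_j = Zj)
    n_subjects <- c(subject_i = length(lev_i), subject_j = length(lev_j))
  } else {
    lev <- sort(unique(c(id_i, id_j)))
    if (length(lev) < 4L) stop("need >= 4 subjects per random factor")
    Z <- matrix(0, n, length(lev))
    Z[cbind(seq_len(n), match(id_i, lev))] <- 1
    Z[cbind(seq_len(n), match(id_j, lev))] <- Z[cbind(seq_len(n), match(id_j, lev))] + 1
    Zs <- list(subject = Z)
    n_subjects <- c(subject = length(lev))
  }
  K <- length(Zs)
  if (n <= p) stop("more fixed effects than usable pairs")

  # degenerate input: response perfectly explained (e.g. constant z)
  ols <- stats::lm.fit(X, z)
  if (sum(ols$residuals^2) < 1e-24 * max(1, sum(z^2))) {
    beta <- stats::setNames(ols$coefficients, colnames(X))
    return(structure(
      list(beta = beta, se = stats::setNames(rep(0, p), colnames(X)),
           t = stats::setNames(rep(NA_real_, p), colnames(X)),
           df = stats::setNames(rep(NA_real_, p), colnames(X)),
           p_value = stats::setNames(rep(NA_real_, p), colnames(X)),
           var_subject = stats::setNames(rep(0, K), names(Zs)),
           var_resid = 0, reml_loglik = Inf, converged = TRUE,
           boundary = TRUE, degenerate = TRUE, n_pairs = n,
           n_subjects = n_subjects, X = X, Zs = Zs, z = z),
      class = "crossed_lmm_fit"))
  }

  lo <- log(1e-10); hi <- log(1e6)
  converged <- TRUE
  if (K == 1L) {
    opt <- stats::optimize(function(lg) reml_criterion(exp(lg), z, X, Zs),
                           c(lo, hi), tol = 1e-10)
    log_gamma <- opt$minimum
  } else {
    opt <- stats::optim(rep(log(0.5), K),
                        function(lg) reml_criterion(exp(lg), z, X, Zs),
                        method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(factr = 1e4, maxit = 500))
    converged <- opt$convergence == 0
    log_gamma <- opt$par
  }
  gamma <- exp(log_gamma)
  boundary <- gamma < 1e-7
  gamma[boundary] <- 0

  pc <- reml_pieces(gamma, z, X, Zs)
  sigma2 <- pc$rWr / (n - p)
  tau2 <- gamma * sigma2
  Vbeta <- sigma2 * solve(pc$XtWiX)
  se <- sqrt(diag(Vbeta))
  beta <- stats::setNames(pc$beta, colnames(X))
  tval <- beta / se
  loglik <- -0.5 * ((n - p) * (log(sigma2) + 1 + log(2 * pi)) +
                      pc$logdetW + pc$logdet_XtWiX)

  fit <- structure(
    list(beta = beta, se = stats::setNames(se, colnames(X)),
         t = stats::setNames(tval, colnames(X)),
         df = NULL, p_value = NULL,
         var_subject = stats::setNames(tau2, names(Zs)),
         var_resid = sigma2, reml_loglik = loglik, converged = converged,
         boundary = any(boundary), degenerate = FALSE, n_pairs = n,
         n_subjects = n_subjects, X = X, Zs = Zs, z = z),
    class = "crossed_lmm_fit")
  dfv <- vapply(seq_len(p), function(k) {
    cc <- numeric(p); cc[k] <- 1
    satterthwaite_df(fit, cc)
  }, numeric(1))
  fit$df <- stats::setNames(dfv, colnames(X))
  fit$p_value <- stats::setNames(2 * stats::pt(-abs(tval), dfv),
                                 colnames(X))
  fit
}

#' Satterthwaite denominator degrees of freedom for a contrast
#'
#' Approximate df for `t = c'beta / se(c'beta)`:
#' `df = 2 f^2 / (g' A g)` with `f = c'(X'V^{-1}X)^{-1}c` evaluated at the
#' REML estimates, `g` its gradient with respect to the variance components
#' `theta = (tau^2_k, sigma^2)` (central finite differences), and `A` the
#' inverse of the observed REML information (numerical Hessian of the REML
#' log-likelihood). The result is clamped to `[1, n_pairs - rank(X)]`.
#'
#' When a subject variance sits on the 0 boundary the approximation is
#' unreliable; the df then falls back to the conservative
#' `n_subjects - rank(X)` (the smallest subject pool when factors are
#' crossed).
#'
#' @param fit a [fit_crossed_lmm()] result.
#' @param contrast numeric contrast vector over the fixed effects.
#' @return degrees of freedom (scalar).
#' @export
satterthwaite_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "crossed_lmm_fit"))
  if (!fit$converged || fit$degenerate) return(NA_real_)
  cc <- as.numeric(contrast)
  p <- ncol(fit$X)
  stopifnot(length(cc) == p)
  n <- fit$n_pairs
  resid_df <- n - p
  fallback <- max(min(fit$n_subjects) - p, 1)
  if (fit$boundary) return(fallback)

  theta <- c(fit$var_subject, fit$var_resid)
  K <- length(fit$var_subject)
  f_c <- function(th) {
    sigma2 <- th[K + 1L]
    pc <- reml_pieces(th[seq_len(K)] / sigma2, fit$z, fit$X, fit$Zs)
    drop(t(cc) %*% (sigma2 * solve(pc$XtWiX)) %*% cc)
  }
  ll <- function(th) reml_loglik_theta(th, fit$z, fit$X, fit$Zs)

  h <- pmax(1e-8, 1e-4 * theta)
  d <- length(theta)
  grad <- vapply(seq_len(d), function(k) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h[k]; tm[k] <- max(tm[k] - h[k], 1e-12)
    (f_c(tp) - f_c(tm)) / (tp[k] - tm[k])
  }, numeric(1))

  H <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in a:d) {
    if (a == b) {
      tp <- theta; tm <- theta
      tp[a] <- tp[a] + h[a]; tm[a] <- max(tm[a] - h[a], 1e-12)
      H[a, a] <- (ll(tp) - 2 * ll(theta) + ll(tm)) /
        ((tp[a] - theta[a]) * (theta[a] - tm[a]))
    } else {
      tpp <- theta; tpm <- theta; tmp <- theta; tmm <- theta
      tpp[a] <- tpp[a] + h[a]; tpp[b] <- tpp[b] + h[b]
      tpm[a] <- tpm[a] + h[a]; tpm[b] <- max(tpm[b] - h[b], 1e-12)
      tmp[a] <- max(tmp[a] - h[a], 1e-12); tmp[b] <- tmp[b] + h[b]
      tmm[a] <- max(tmm[a] - h[a], 1e-12); tmm[b] <- max(tmm[b] - h[b], 1e-12)
      H[a, b] <- H[b, a] <- (ll(tpp) - ll(tpm) - ll(tmp) + ll(tmm)) /
        ((tpp[a] - tmm[a]) * (tpp[b] - tmm[b]))
    }
  }
  info <- -H
  A <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(A)) return(fallback)
  denom <- drop(t(grad) %*% A %*% grad)
  f0 <- f_c(theta)
  if (!is.finite(denom) || denom <= 0) return(fallback)
  df <- 2 * f0^2 / denom
  min(max(df, 1), resid_df)
}

#' @export
print.crossed_lmm_fit <- function(x, ...) {
  cat("Crossed random-effects REML fit\n")
  cat(sprintf("  pairs: %d; subjects: %s\n", x$n_pairs,
              paste(sprintf("%s=%d", names(x$n_subjects), x$n_subjects),
                    collapse = ", ")))
  tab <- data.frame(beta = x$beta, se = x$se, t = x$t, df = x$df,
                    p = x$p_value)
  print(tab, digits = 4)
  cat(sprintf("  var components: %s; residual %.5g\n",
              paste(sprintf("%s=%.5g", names(x$var_subject),
                            x$var_subject), collapse = ", "),
              x$var_resid))
  if (x$boundary) cat("  note: variance component at 0 boundary\n")
  invisible(x)
}
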