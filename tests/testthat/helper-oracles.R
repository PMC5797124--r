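# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: dense covariance + generic optimizer
# for the mixed model, union-find for cluster labels, plain loops elsewhere.

# Dense-covariance REML oracle for the crossed random-effects model.
# Builds V = sigma2 I + sum_k tau2_k Z_k Z_k' explicitly and maximizes the
# REML log-likelihood with a generic optimizer. Same likelihood definition
# as the package: ll = -0.5 (log|V| + log|X'V^-1 X| + r'V^-1 r
#                            + (n - p) log 2pi).
dense_reml_oracle <- function(z, X, id_i, id_j, crossed = FALSE) {
  X <- as.matrix(X)
  n <- length(z); p <- ncol(X)
  if (crossed) {
    lev_i <- sort(unique(id_i)); lev_j <- sort(unique(id_j))
    Zs <- list(outer(id_i, lev_i, "==") * 1,
               outer(id_j, lev_j, "==") * 1)
  } else {
    lev <- sort(unique(c(id_i, id_j)))
    Zs <- list(outer(id_i, lev, "==") * 1 + outer(id_j, lev, "==") * 1)
  }
  loglik <- function(log_theta) {
    th <- exp(log_theta)
    sigma2 <- th[length(th)]
    V <- diag(sigma2, n)
    for (k in seq_along(Zs)) V <- V + th[k] * tcrossprod(Zs[[k]])
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% z)
    r <- z - X %*% beta
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              drop(t(r) %*% Vi %*% r) + (n - p) * log(2 * pi))
  }
  K <- length(Zs)
  start <- log(rep(stats::var(z) / 2, K + 1))
  opt <- stats::optim(start, function(lt) -loglik(lt),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, function(lt) -loglik(lt),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  th <- exp(opt$par)
  sigma2 <- th[K + 1]
  V <- diag(sigma2, n)
  for (k in seq_len(K)) V <- V + th[k] * tcrossprod(Zs[[k]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- drop(solve(XtViX, t(X) %*% Vi %*% z))
  list(beta = beta, se = sqrt(diag(solve(XtViX))),
       tau2 = th[seq_len(K)], sigma2 = sigma2, loglik = -opt$value)
}

# union-find component labelling over a mesh's edge list, restricted to a
# logical supra-threshold node set
union_find_clusters <- function(mesh, supra) {
  n <- mesh$n_nodes
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(mesh$edges))) {
    a <- mesh$edges[r, 1]; b <- mesh$edges[r, 2]
    if (supra[a] && supra[b]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  labels <- integer(n)
  roots <- vapply(which(supra), find, integer(1))
  labels[supra] <- as.integer(factor(roots))
  labels
}

# random perturbed-grid toy mesh (irregular geometry, valid triangulation)
random_toy_mesh <- function(seed, max_side = 12) {
  set.seed(seed)
  nx <- sample(4:max_side, 1); ny <- sample(4:max_side, 1)
  base <- grid_mesh(nx, ny, spacing = 1)
  v <- base$vertices
  v[, 1:2] <- v[, 1:2] + matrix(runif(2 * nrow(v), -0.3, 0.3), ncol = 2)
  tri <- base$triangles
  # drop a few triangles to make adjacency irregular (possibly disconnected)
  drop_n <- sample(0:floor(nrow(tri) / 4), 1)
  if (drop_n > 0) tri <- tri[-sample(nrow(tri), drop_n), , drop = FALSE]
  surface_mesh(v, tri)
}

# direct simulation from the pair-level crossed model (no time series):
# z_ij = x'beta + a_i + a_j + e_ij over two groups' within-group pairs
sim_contrast_pairs <- function(nA, nB, beta0, effect, tau2, sigma2) {
  ids_A <- sprintf("A%02d", seq_len(nA))
  ids_B <- sprintf("B%02d", seq_len(nB))
  a <- stats::setNames(stats::rnorm(nA + nB, 0, sqrt(tau2)),
                       c(ids_A, ids_B))
  pw <- function(ids) t(utils::combn(ids, 2))
  pA <- pw(ids_A); pB <- pw(ids_B)
  id_i <- c(pA[, 1], pB[, 1]); id_j <- c(pA[, 2], pB[, 2])
  grpA <- c(rep(1, nrow(pA)), rep(0, nrow(pB)))
  z <- beta0 + effect * grpA + a[id_i] + a[id_j] +
    stats::rnorm(length(id_i), 0, sqrt(sigma2))
  list(z = unname(z), X = cbind(intercept = 1, affiliation = grpA),
       id_i = id_i, id_j = id_j)
}

# small helper: cohort residuals without any nuisance filtering (the
# closed-form expected-ISC oracle applies to raw generator output)
raw_isc <- function(cohort, min_volumes = 50) {
  pairwise_isc(cohort$subjects, min_volumes = min_volumes)
}
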