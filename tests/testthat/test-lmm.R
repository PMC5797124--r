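# direct simulation from the single-factor pair model
sim_pairs <- function(N, beta0, tau2, sigma2, ids = sprintf("s%02d", 1:N)) {
  a <- stats::setNames(rnorm(N, 0, sqrt(tau2)), ids)
  pw <- t(utils::combn(ids, 2))
  z <- beta0 + a[pw[, 1]] + a[pw[, 2]] + rnorm(nrow(pw), 0, sqrt(sigma2))
  list(z = unname(z), id_i = pw[, 1], id_j = pw[, 2],
       X = matrix(1, nrow(pw), 1, dimnames = list(NULL, "intercept")))
}

test_that("REML fit matches the dense-covariance oracle on small instances", {
  for (seed in 1:4) {
    set.seed(seed)
    N <- sample(6:8, 1)
    d <- sim_pairs(N, beta0 = 0.3, tau2 = 0.02, sigma2 = 0.05)
    fit <- fit_crossed_lmm(d$z, d$X, d$id_i, d$id_j)
    oracle <- dense_reml_oracle(d$z, d$X, d$id_i, d$id_j)
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-6)
    expect_equal(fit$reml_loglik, unname(oracle$loglik), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-4)
  }
})

test_that("crossed two-factor fit matches the dense oracle", {
  set.seed(9)
  nc <- 6; na <- 5
  cid <- sprintf("c%d", 1:nc); aid <- sprintf("a%d", 1:na)
  ac <- stats::setNames(rnorm(nc, 0, sqrt(0.03)), cid)
  aa <- stats::setNames(rnorm(na, 0, sqrt(0.01)), aid)
  g <- expand.grid(i = cid, j = aid, stringsAsFactors = FALSE)
  age <- stats::setNames(runif(nc, 48, 84), cid)
  X <- cbind(intercept = 1, age = age[g$i] - mean(age))
  z <- 0.2 + 0.003 * X[, "age"] + ac[g$i] + aa[g$j] +
    rnorm(nrow(g), 0, sqrt(0.04))
  fit <- fit_crossed_lmm(unname(z), X, g$i, g$j, crossed_factors = TRUE)
  oracle <- dense_reml_oracle(unname(z), X, g$i, g$j, crossed = TRUE)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-5)
  expect_equal(fit$reml_loglik, unname(oracle$loglik), tolerance = 1e-6)
})

test_that("with subject effects off the fit collapses to OLS", {
  set.seed(10)
  d <- sim_pairs(12, beta0 = 0.25, tau2 = 0, sigma2 = 0.05)
  fit <- fit_crossed_lmm(d$z, d$X, d$id_i, d$id_j)
  expect_equal(unname(fit$beta["intercept"]), mean(d$z), tolerance = 1e-6)
  expect_lt(unname(fit$var_subject), unname(fit$var_resid))
})

test_that("doubled-triangle input reproduces the single-triangle fit exactly", {
  set.seed(11)
  d <- sim_pairs(9, beta0 = 0.3, tau2 = 0.02, sigma2 = 0.05)
  single <- fit_crossed_lmm(d$z, d$X, d$id_i, d$id_j)
  dz <- c(d$z, d$z)
  dX <- rbind(d$X, d$X)
  doubled <- fit_crossed_lmm(dz, dX, c(d$id_i, d$id_j), c(d$id_j, d$id_i),
                             doubled = TRUE)
  expect_equal(doubled$beta, single$beta)
  expect_equal(doubled$se, single$se)
  expect_equal(doubled$df, single$df)
  expect_equal(doubled$n_pairs, single$n_pairs)
  # asymmetric duplicates are rejected
  dz2 <- dz; dz2[length(dz2)] <- dz2[length(dz2)] + 0.5
  expect_error(fit_crossed_lmm(dz2, dX, c(d$id_i, d$id_j),
                               c(d$id_j, d$id_i), doubled = TRUE),
               "not symmetric")
})

test_that("intercept recovery is unbiased over repeated simulation", {
  set.seed(12)
  est <- vapply(1:200, function(k) {
    d <- sim_pairs(6, beta0 = 0.3, tau2 = 0.02, sigma2 = 0.05)
    unname(fit_crossed_lmm(d$z, d$X, d$id_i, d$id_j)$beta["intercept"])
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.3), 3 * se)
})

test_that("permuting subject labels leaves the estimates unchanged", {
  set.seed(13)
  d <- sim_pairs(8, beta0 = 0.3, tau2 = 0.02, sigma2 = 0.05)
  fit <- fit_crossed_lmm(d$z, d$X, d$id_i, d$id_j)
  perm <- stats::setNames(sample(sprintf("t%02d", 1:8)),
                          sprintf("s%02d", 1:8))
  fit2 <- fit_crossed_lmm(d$z, d$X, perm[d$id_i], perm[d$id_j])
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-6)
  expect_equal(unname(fit2$se), unname(fit$se), tolerance = 1e-6)
})

test_that("constant response yields the exact degenerate fit", {
  ids <- sprintf("s%d", 1:4)
  pw <- t(utils::combn(ids, 2))
  z <- rep(0.2, nrow(pw))
  fit <- fit_crossed_lmm(z, matrix(1, nrow(pw), 1,
                                   dimnames = list(NULL, "intercept")),
                         pw[, 1], pw[, 2])
  expect_equal(unname(fit$beta), 0.2)
  expect_true(fit$degenerate)
})

test_that("Satterthwaite df is deterministic, bracketed, and falls to OLS df", {
  set.seed(14)
  d <- sim_pairs(21, beta0 = 0.35, tau2 = 0.03, sigma2 = 0.01)
  fit <- fit_crossed_lmm(d$z, d$X, d$id_i, d$id_j)
  df1 <- satterthwaite_df(fit, 1)
  df2 <- satterthwaite_df(fit, 1)
  expect_identical(df1, df2)
  # balanced 21-subject intercept model: df between N-1 and n_pairs - 1
  expect_gte(df1, 21 - 1 - 2)  # small numerical slack below N-1
  expect_lte(df1, choose(21, 2) - 1)
  # strong subject variance pushes df toward the subject count, far below
  # the pair count
  expect_lt(df1, 60)

  # tau2 -> 0 limit: df approaches the OLS residual df
  d0 <- sim_pairs(12, beta0 = 0.2, tau2 = 0, sigma2 = 0.05)
  fit0 <- fit_crossed_lmm(d0$z, d0$X, d0$id_i, d0$id_j)
  if (fit0$boundary) {
    expect_equal(unname(fit0$df["intercept"]), 12 - 1)  # documented fallback
  } else {
    expect_gt(unname(fit0$df["intercept"]), 0.5 * (choose(12, 2) - 1))
  }
})

test_that("per-node model drivers recover generator structure", {
  co <- simulate_cohort(cohort_config(
    n_per_group = c(child4 = 8, child6 = 8, adult = 8),
    n_nodes = 2, seed = 15))
  m <- raw_isc(co)
  wg <- within_group_model(m, "adult")
  expect_equal(nrow(wg), 2L)
  expect_equal(wg$beta_r, tanh(wg$beta_z))
  # adult coupling 0.6 -> within-group r near 0.36
  expect_lt(max(abs(wg$beta_r - 0.36)), 0.12)

  gc <- group_contrast_model(m, "adult", c("child4", "child6"))
  expect_equal(gc$effect, rep("affiliation", 2))
  # adults couple more strongly -> positive contrast
  expect_true(all(gc$beta_z > 0))

  ca <- child_to_adult_age_model(m)
  expect_equal(nrow(ca), 2L)
  expect_true(all(is.finite(ca$t)))

  # constant age -> estimability error
  m2 <- m
  m2$subjects$age_months[m2$subjects$group != "adult"] <- 60
  expect_error(child_to_adult_age_model(m2), "constant")
})

test_that("within-group intercept converges to the coupling product with run length", {
  co <- simulate_cohort(cohort_config(n_per_group = c(adult = 6),
                                      n_volumes = 2000, n_nodes = 1,
                                      seed = 16))
  m <- pairwise_isc(co$subjects)
  wg <- within_group_model(m, "adult")
  expect_lt(abs(wg$beta_r - 0.36), 0.03)
})

test_that("a random partition of one group gives a null affiliation effect", {
  est <- vapply(1:10, function(seed) {
    co <- simulate_cohort(cohort_config(n_per_group = c(adult = 12),
                                        n_nodes = 1, seed = seed + 30))
    m <- pairwise_isc(co$subjects)
    set.seed(seed)
    m$subjects$group <- sample(rep(c("g1", "g2"), each = 6))
    group_contrast_model(m, "g1", "g2")$beta_z
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)) + 0.01)
})

test_that("self-pairs and rank-deficient designs are rejected", {
  ids <- sprintf("s%d", 1:5)
  pw <- t(utils::combn(ids, 2))
  z <- rnorm(nrow(pw))
  expect_error(fit_crossed_lmm(z, matrix(1, nrow(pw), 1), pw[, 1],
                               pw[, 1]),
               "self-pairs")
  X <- cbind(rep(1, nrow(pw)), rep(1, nrow(pw)))
  expect_error(fit_crossed_lmm(z, X, pw[, 1], pw[, 2]), "rank deficient")
})
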