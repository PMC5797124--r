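mk_ts <- function(data, id = "s1") {
  subject_time_series(data, id, "adult", 260)
}

test_that("mean-100 scaling multiplies each node by 100 over its mean", {
  ts <- mk_ts(rbind(rep(5, 10),               # constant 5 -> constant 100
                    rep(100, 10),             # already mean 100 -> unchanged
                    c(rep(1, 5), rep(3, 5)))) # mean 2 -> (50, 150)
  out <- scale_to_mean_100(ts)
  expect_equal(out$data[1, ], rep(100, 10))
  expect_equal(out$data[2, ], rep(100, 10))
  expect_equal(out$data[3, ], c(rep(50, 5), rep(150, 5)))
  # a node already spanning (50, 150) with mean 100 is a fixed point
  ts2 <- mk_ts(matrix(c(50, 150), 1))
  expect_equal(scale_to_mean_100(ts2)$data[1, ], c(50, 150))
})

test_that("zero-mean nodes are flagged, zeroed, and warned about", {
  ts <- mk_ts(rbind(rep(10, 6), c(-1, 1, -1, 1, -1, 1)))
  expect_warning(out <- scale_to_mean_100(ts), "zero-mean")
  expect_equal(attr(out, "zero_mean_nodes"), 2L)
  expect_equal(out$data[2, ], rep(0, 6))
  expect_equal(out$data[1, ], rep(100, 6))
})

test_that("band-stop regressor count matches brute-force DFT enumeration", {
  n <- 176; tr <- 2
  d <- build_nuisance_design(n, tr)
  bs_cols <- grep("^bs_", colnames(d$X))
  # independent enumeration of removed frequencies k/(n*tr)
  n_cols <- 0L
  for (k in seq_len(floor(n / 2))) {
    f <- k / (n * tr)
    if (f < 0.01 || f > 0.1) {
      n_cols <- n_cols + 1L                   # cosine
      if (k < n / 2) n_cols <- n_cols + 1L    # sine except at Nyquist
    }
  }
  expect_equal(length(bs_cols), n_cols)
  # with TR 2 s and 176 volumes: k = 1..3 low, k = 36..88 high
  expect_equal(n_cols, 2 * 3 + 2 * 52 + 1)
})

test_that("design composition: trends-only baseline, FEF adds one column", {
  d0 <- build_nuisance_design(176, 2)
  expect_true(all(grepl("^(intercept|poly|bs_)", colnames(d0$X))))

  tissue <- list(white_matter = rnorm(176), ventricle = rnorm(176),
                 fef = rnorm(176))
  d1 <- build_nuisance_design(176, 2, tissue = tissue, include_fef = FALSE)
  d2 <- build_nuisance_design(176, 2, tissue = tissue, include_fef = TRUE)
  expect_equal(ncol(d2$X) - ncol(d1$X), 1L)
  expect_setdiff <- setdiff(colnames(d2$X), colnames(d1$X))
  expect_equal(expect_setdiff, "fef")
  expect_error(build_nuisance_design(176, 2, include_fef = TRUE), "fef")
  expect_true(is.finite(d1$condition_number))
})

test_that("residuals are orthogonal to every design column on kept volumes", {
  set.seed(31)
  n <- 176
  tr <- motion_trace(matrix(cumsum(rnorm(3 * n, sd = 0.02)), n, 3),
                     matrix(cumsum(rnorm(3 * n, sd = 4e-4)), n, 3))
  fd <- compute_fd(tr)
  cens <- make_censor_mask(fd, 0.2)  # force some censoring
  tissue <- list(white_matter = rnorm(n), ventricle = rnorm(n))
  d <- build_nuisance_design(n, 2, motion = tr, tissue = tissue,
                             censor = cens)
  ts <- mk_ts(matrix(rnorm(4 * n, mean = 1000, sd = 10), 4))
  res <- regress_nuisance(scale_to_mean_100(ts), d)
  keep <- cens$keep
  Xk <- d$X[keep, ]
  for (v in 1:4) {
    dots <- abs(crossprod(Xk, res$data[v, keep]))
    rel <- dots / (sqrt(colSums(Xk^2)) * sqrt(sum(res$data[v, keep]^2)))
    expect_true(all(rel < 1e-8))
  }
  expect_true(all(is.na(res$data[, !keep])))
})

test_that("regression matches an independent least-squares oracle", {
  set.seed(32)
  n <- 120
  d <- build_nuisance_design(n, 2)
  y <- rnorm(n, 100, 5)
  res <- regress_nuisance(mk_ts(matrix(y, 1)), d)
  # normal-equations oracle (different algebra than the qr fit)
  X <- d$X
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(res$data[1, ], as.numeric(y - X %*% beta), tolerance = 1e-10)

  # a series equal to a design column leaves ~zero residuals
  ycol <- X[, "poly2"] * 7
  res2 <- regress_nuisance(mk_ts(matrix(ycol, 1)), d)
  expect_lt(max(abs(res2$data)), 1e-10)

  # a series orthogonal to all columns is only demeaned
  qx <- qr.Q(qr(X))
  yo <- rnorm(n)
  yo <- yo - qx %*% crossprod(qx, yo)
  res3 <- regress_nuisance(mk_ts(matrix(yo, 1)), d)
  expect_equal(res3$data[1, ], as.numeric(yo), tolerance = 1e-10)
})

test_that("one-step regression equals sequential regression of the same span", {
  set.seed(33)
  n <- 100
  d <- build_nuisance_design(n, 2, band_hz = c(0.02, 0.08))
  X <- d$X
  y <- rnorm(n)
  part1 <- 1:4; part2 <- 5:ncol(X)
  # two-stage oracle: regress y and the second block on the first block,
  # then regress stage-1 residuals on residualized second block
  p1 <- function(m) m - X[, part1] %*%
    solve(crossprod(X[, part1]), crossprod(X[, part1], m))
  y1 <- p1(matrix(y)); X2 <- p1(X[, part2])
  two_stage <- y1 - X2 %*% qr.coef(qr(X2), y1)
  res <- regress_nuisance(mk_ts(matrix(y, 1)), d)
  expect_equal(res$data[1, ], as.numeric(two_stage), tolerance = 1e-8)
})

test_that("censored volumes have zero influence on the fit", {
  set.seed(34)
  n <- 150
  keep <- rep(TRUE, n); keep[c(10, 50, 90)] <- FALSE
  cens <- structure(list(keep = keep, n_censored = 3L,
                         fd_threshold_mm = 0.5), class = "censor_mask")
  d <- build_nuisance_design(n, 2, censor = cens)
  y <- rnorm(n, 100, 3)
  y2 <- y; y2[!keep] <- y2[!keep] + 1e6   # corrupt censored volumes
  r1 <- regress_nuisance(mk_ts(matrix(y, 1)), d)
  r2 <- regress_nuisance(mk_ts(matrix(y2, 1)), d)
  expect_equal(r1$data[1, keep], r2$data[1, keep], tolerance = 1e-9)
})

test_that("adding the FEF column never increases residual variance", {
  set.seed(35)
  n <- 150
  tissue <- list(white_matter = rnorm(n), ventricle = rnorm(n),
                 fef = rnorm(n))
  d0 <- build_nuisance_design(n, 2, tissue = tissue, include_fef = FALSE)
  d1 <- build_nuisance_design(n, 2, tissue = tissue, include_fef = TRUE)
  ts <- mk_ts(matrix(rnorm(5 * n, 100, 4), 5))
  r0 <- regress_nuisance(ts, d0)
  r1 <- regress_nuisance(ts, d1)
  for (v in 1:5)
    expect_lte(sum(r1$data[v, ]^2), sum(r0$data[v, ]^2) + 1e-12)
})

test_that("estimability violations are reported with offending columns", {
  # duplicated tissue columns -> rank deficiency
  x <- rnorm(100)
  tissue <- list(white_matter = x, ventricle = x)
  expect_error(build_nuisance_design(100, 2, tissue = tissue),
               "rank-deficient")
  # too few usable volumes
  cens <- structure(list(keep = c(rep(TRUE, 40), rep(FALSE, 60)),
                         n_censored = 60L, fd_threshold_mm = 0.5),
                    class = "censor_mask")
  expect_error(build_nuisance_design(100, 2, censor = cens),
               "not estimable")
})

test_that("full subject preprocessing flags exclusion and writes residuals", {
  co <- simulate_cohort(cohort_config(n_per_group = c(adult = 2),
                                      n_nodes = 2, seed = 91,
                                      motion_spike_rate = 0.3))
  pp <- preprocess_subject(co$subjects[[1]], co$motion[[1]],
                           tissue = co$nuisance_signals[[1]])
  expect_false(pp$exclusion$include)  # 30% spikes blows the 9% bound
  expect_equal(pp$censor$n_censored,
               sum(!is.na(pp$fd) & pp$fd > 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_residuals(pp$residuals, f)
  expect_true(file.exists(paste0(f, ".censored")))
  cens_idx <- as.integer(readLines(paste0(f, ".censored")))
  expect_equal(cens_idx, which(!pp$censor$keep))
})
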