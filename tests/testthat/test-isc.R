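mk_ts <- function(data, id, group = "adult", age = 260) {
  subject_time_series(data, id, group, age)
}

test_that("Fisher transform round-trips and matches the closed form", {
  expect_equal(fisher_z(0), 0)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(inverse_fisher(fisher_z(r)), r, tolerance = 1e-14)
  # atanh(0.5) via the independent log form
  expect_equal(fisher_z(0.5), 0.5 * log((1 + 0.5) / (1 - 0.5)),
               tolerance = 1e-15)
  # |r| = 1 is clipped and flagged, stays finite
  z <- fisher_z(c(0.2, 1, -1))
  expect_true(all(is.finite(z)))
  expect_equal(attr(z, "clipped"), c(FALSE, TRUE, TRUE))
})

test_that("pairwise ISC matches a brute-force correlation oracle", {
  set.seed(21)
  n_nodes <- 4; n_vol <- 120
  res <- lapply(1:5, function(i)
    mk_ts(matrix(rnorm(n_nodes * n_vol), n_nodes), paste0("s", i)))
  m <- pairwise_isc(res, min_volumes = 50)
  for (v in seq_len(n_nodes)) for (i in 1:4) for (j in (i + 1):5) {
    x <- res[[i]]$data[v, ]; y <- res[[j]]$data[v, ]
    # textbook covariance / variance computation
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(m$z[v, i, j], atanh(r_oracle), tolerance = 1e-12)
  }
})

test_that("ISC is invariant to affine rescaling and clips perfect correlation", {
  set.seed(22)
  base <- matrix(rnorm(3 * 150), 3)
  res <- list(mk_ts(base, "a"),
              mk_ts(base * 2 + 3, "b"),        # affine copy -> r = 1
              mk_ts(matrix(rnorm(3 * 150), 3), "c"))
  m <- pairwise_isc(res)
  expect_true(all(is.finite(m$z[, 1, 2])))
  expect_true(m$clipped[1, 2])
  expect_equal(tanh(m$z[1, 1, 2]), 1, tolerance = 1e-9)
  # rescaling subject c leaves every correlation unchanged
  res2 <- res
  res2[[3]] <- mk_ts(res[[3]]$data * -5 + 100, "c")
  m2 <- pairwise_isc(res2)
  expect_equal(abs(m2$z[, 1, 3]), abs(m$z[, 1, 3]), tolerance = 1e-10)
})

test_that("censored volumes are dropped pairwise and short pairs flagged", {
  set.seed(23)
  A <- matrix(rnorm(2 * 120), 2); B <- matrix(rnorm(2 * 120), 2)
  Acens <- A; Acens[, 1:15] <- NA      # censored in subject a
  Bcens <- B; Bcens[, 110:120] <- NA   # censored in subject b
  m <- pairwise_isc(list(mk_ts(Acens, "a"), mk_ts(Bcens, "b")),
                    min_volumes = 50)
  cols <- 16:109
  r_oracle <- cor(A[1, cols], B[1, cols])
  expect_equal(m$z[1, 1, 2], atanh(r_oracle), tolerance = 1e-12)
  expect_equal(m$pair_counts[1, 2], length(cols))

  # below the usable-volume floor: flagged missing, never zero
  m2 <- pairwise_isc(list(mk_ts(Acens, "a"), mk_ts(Bcens, "b")),
                     min_volumes = 100)
  expect_true(m2$flagged[1, 2])
  expect_true(all(is.na(m2$z[, 1, 2])))
})

test_that("matrix structure invariants hold: symmetry, NA diagonal", {
  co <- simulate_cohort(cohort_config(n_per_group = c(child4 = 4,
                                                      adult = 4),
                                      n_nodes = 2, seed = 44))
  m <- raw_isc(co)
  for (v in 1:2) {
    zv <- m$z[v, , ]
    expect_true(all(is.na(diag(zv))))
    expect_equal(zv, t(zv))
  }
})

test_that("block extraction yields the documented pair counts", {
  co <- simulate_cohort(cohort_config(
    n_per_group = c(child4 = 23, child6 = 23, adult = 21),
    n_nodes = 1, n_volumes = 60, seed = 50))
  m <- raw_isc(co, min_volumes = 40)
  adult <- extract_block(m, "adult", "adult")
  expect_equal(nrow(adult$pairs), 21 * 20 / 2)      # 210 unordered
  doubled <- extract_block(m, "adult", "adult", doubled = TRUE)
  expect_equal(nrow(doubled$pairs), 21 * 20)        # 420 both triangles
  ca <- extract_block(m, c("child4", "child6"), "adult")
  expect_equal(nrow(ca$pairs), 46 * 21)             # 966 child-adult
  expect_error(extract_block(m, "adult", "child4", doubled = FALSE), NA)
  # one subject vs itself: diagonal excluded -> no pairs
  one <- extract_block(m, 1, 1)
  expect_equal(nrow(one$pairs), 0L)
  # overlapping but non-identical selectors are rejected
  expect_error(extract_block(m, 1:5, 3:8), "disjoint or identical")
})

test_that("neural maturity equals the loop-oracle mean over adults", {
  co <- simulate_cohort(cohort_config(n_per_group = c(child4 = 5,
                                                      adult = 4),
                                      n_nodes = 3, seed = 61))
  m <- raw_isc(co)
  nm <- neural_maturity(m)
  adults <- which(m$subjects$group == "adult")
  children <- which(m$subjects$group != "adult")
  for (k in seq_along(children)) for (v in 1:3) {
    acc <- 0
    for (a in adults) acc <- acc + m$z[v, children[k], a]
    expect_equal(unname(nm[k, v]), acc / length(adults), tolerance = 1e-12)
  }
  # single adult: maturity equals that pair's z
  m1 <- raw_isc(co)
  nm1 <- neural_maturity(m1, adults = adults[1])
  expect_equal(unname(nm1[1, 2]),
               m$z[2, setdiff(1:9, adults[1])[1], adults[1]])
  # constant block: all z = 0.3 -> maturity 0.3
  mz <- m
  mz$z[1, children, adults] <- 0.3
  mz$z[1, adults, children] <- 0.3
  expect_equal(unname(neural_maturity(mz)[, 1]), rep(0.3, 5))
})

test_that("mean within-group z is monotone in the coupling parameter", {
  means <- vapply(c(0, 0.3, 0.6), function(cpl) {
    zs <- vapply(1:12, function(seed) {
      co <- simulate_cohort(cohort_config(
        n_per_group = c(adult = 8), n_nodes = 1,
        coupling = c(adult = cpl), seed = seed))
      mean(raw_isc(co)$z, na.rm = TRUE)
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("long-format CSV export has one row per node and pair", {
  co <- simulate_cohort(cohort_config(n_per_group = c(adult = 5),
                                      n_nodes = 2, seed = 70))
  m <- raw_isc(co)
  f <- withr::local_tempfile(fileext = ".csv")
  write_isc_long(m, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 2 * choose(5, 2))
  expect_equal(tab$z[tab$node == 1 & tab$subject_i == "sub001" &
                       tab$subject_j == "sub002"],
               m$z[1, 1, 2], tolerance = 1e-12)
})
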