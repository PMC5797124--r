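#' Configuration for a synthetic naturalistic-viewing cohort
#'
#' Describes the statistical structure the ISC analysis assumes: a
#' time-locked shared stimulus signal per node, group- and age-dependent
#' coupling of each subject to that signal, an optional subject-idiosyncratic
#' signal, autocorrelated noise, head-motion traces with spikes, and
#' nuisance signals (white matter, ventricle, and an attention/FEF proxy).
#'
#' At every node, subject `i`'s series is
#' \deqn{y_{iv}(t) = c_{iv} s_v(t) + b\, u_{iv}(t)
#'   + \sqrt{1 - c_{iv}^2 - b^2}\, \epsilon_{iv}(t),}
#' where `s_v` is a unit-variance shared signal, `u_iv` a unit-variance
#' subject-specific smooth signal, and `eps` unit-variance AR(1) noise. The
#' expected Pearson correlation between subjects `i` and `j` at node `v` is
#' then the closed form `c_iv * c_jv` (see [expected_isc()]).
#'
#' The coupling `c_iv` equals `coupling[group]` at every node; inside
#' `effect_nodes` it is `effect_coupling[group]` plus, for children,
#' `age_slope * (age_months - age_center)`.
#'
#' @param n_per_group named integer vector: subjects per group. Default
#'   `c(child4 = 23, child6 = 23, adult = 21)` (a 67-subject cohort).
#' @param n_volumes time points per run; default 176 (180 acquired minus 4
#'   discarded at a 2 s TR gives a 6-minute run).
#' @param tr_seconds sampling interval, s; default 2.
#' @param n_nodes number of surface nodes to simulate; default 8.
#' @param coupling named numeric vector in `[0, 1)`: baseline shared-signal
#'   coupling per group. Default `c(child4 = 0.4, child6 = 0.4, adult =
#'   0.6)`.
#' @param effect_nodes integer node indices where group differences / age
#'   slopes apply; default none.
#' @param effect_coupling per-group coupling inside `effect_nodes`; default
#'   `coupling`.
#' @param age_slope per-month coupling increment for children inside
#'   `effect_nodes`; default 0.
#' @param age_range_months sampling range for child ages; default
#'   `c(48, 84)`.
#' @param age_center month at which a child's effect-node coupling equals
#'   `effect_coupling[group]`; default `mean(age_range_months)`.
#' @param age_two_clusters draw child ages from two narrow bands (means
#'   53.3 and 78.6 months, sd 3.5) instead of the uniform range; default
#'   `FALSE`.
#' @param adult_group name of the adult group; default `"adult"`.
#' @param idio_coupling coupling `b` in `[0, 1)` to a subject-idiosyncratic
#'   smooth signal; default 0 (no field value constrains it).
#' @param noise_ar1 lag-1 autocorrelation of the noise, in `[0, 1)`;
#'   default 0.3.
#' @param signal_fwhm_tr temporal smoothness (FWHM in TRs) of the shared and
#'   idiosyncratic signals; default 3.
#' @param motion_spike_rate expected fraction of high-motion (FD > 0.5 mm)
#'   volumes; default 0.05.
#' @param spikes_affect_signal also inject signal artifacts at spike
#'   volumes (for scrubbing-efficacy experiments); default `FALSE`.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = c(child4 = 23, child6 = 23,
                                          adult = 21),
                          n_volumes = 176, tr_seconds = 2, n_nodes = 8,
                          coupling = c(child4 = 0.4, child6 = 0.4,
                                       adult = 0.6),
                          effect_nodes = integer(0),
                          effect_coupling = NULL,
                          age_slope = 0,
                          age_range_months = c(48, 84),
                          age_center = mean(age_range_months),
                          age_two_clusters = FALSE,
                          adult_group = "adult",
                          idio_coupling = 0,
                          noise_ar1 = 0.3,
                          signal_fwhm_tr = 3,
                          motion_spike_rate = 0.05,
                          spikes_affect_signal = FALSE,
                          seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(groups == ""))
    stop("n_per_group must be a named vector")
  if (is.null(effect_coupling)) effect_coupling <- coupling
  if (!all(groups %in% names(coupling)) ||
      !all(groups %in% names(effect_coupling)))
    stop("coupling must be named for every group")
  if (any(coupling < 0 | coupling >= 1) ||
      any(effect_coupling < 0 | effect_coupling >= 1))
    stop("couplings must lie in [0, 1)")
  if (idio_coupling < 0 || idio_coupling >= 1)
    stop("idio_coupling must lie in [0, 1)")
  if (noise_ar1 < 0 || noise_ar1 >= 1)
    stop("noise_ar1 must lie in [0, 1)")
  if (motion_spike_rate < 0 || motion_spike_rate >= 1)
    stop("motion_spike_rate must lie in [0, 1)")
  # worst-case child coupling at the range ends must stay in [0, 1)
  half <- max(abs(age_range_months - age_center))
  child_groups <- setdiff(groups, adult_group)
  worst <- effect_coupling[child_groups] + abs(age_slope) * half
  if (length(effect_nodes) &&
      any(worst >= 1 |
          effect_coupling[child_groups] - abs(age_slope) * half < 0))
    stop("coupling + age contribution leaves [0, 1) over age_range_months")
  if (any(pmax(coupling, effect_coupling)^2 + idio_coupling^2 >= 1) ||
      length(effect_nodes) && any(worst^2 + idio_coupling^2 >= 1))
    stop("coupling^2 + idio_coupling^2 must stay below 1")
  # non-frequency nuisance regressors of the default design
  # (intercept + 3 trends + 12 motion + 2 tissue + FEF)
  if (n_volumes < 2 * 19)
    stop("n_volumes too small for the default nuisance design")
  if (length(effect_nodes) && (min(effect_nodes) < 1 ||
                               max(effect_nodes) > n_nodes))
    stop("effect_nodes out of range")
  structure(
    list(n_per_group = n_per_group, n_volumes = as.integer(n_volumes),
         tr_seconds = tr_seconds, n_nodes = as.integer(n_nodes),
         coupling = coupling, effect_nodes = as.integer(effect_nodes),
         effect_coupling = effect_coupling, age_slope = age_slope,
         age_range_months = age_range_months, age_center = age_center,
         age_two_clusters = age_two_clusters, adult_group = adult_group,
         idio_coupling = idio_coupling, noise_ar1 = noise_ar1,
         signal_fwhm_tr = signal_fwhm_tr,
         motion_spike_rate = motion_spike_rate,
         spikes_affect_signal = spikes_affect_signal,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' Keys mirror the arguments of [cohort_config()]; named vectors
#' (`n_per_group`, `coupling`, `effect_coupling`) are YAML maps.
#'
#' @param path YAML file path.
#' @return a [cohort_config()].
#' @export
cohort_config_from_file <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("n_per_group", "coupling", "effect_coupling"))
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(cohort_config, raw)
}

#' Per-subject node x time series with metadata
#'
#' @param data numeric matrix, `n_nodes` x `n_volumes`.
#' @param subject_id character id.
#' @param group group label.
#' @param age_months age in months.
#' @return an object of class `subject_ts`.
#' @export
subject_time_series <- function(data, subject_id, group, age_months) {
  data <- as.matrix(data)
  structure(
    list(data = data, subject_id = as.character(subject_id),
         group = as.character(group), age_months = age_months,
         n_nodes = nrow(data), n_volumes = ncol(data)),
    class = "subject_ts")
}

# unit-variance smooth Gaussian signal: white noise convolved with a
# Gaussian kernel (FWHM in samples), then standardized to mean 0, sd 1
smooth_gaussian_signal <- function(n, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  w <- stats::rnorm(n + 2L * half)
  s <- stats::convolve(w, rev(kern), type = "filter")  # valid part, length n
  as.numeric(scale(s))
}

# unit-variance AR(1) noise (standardized sample)
ar1_noise <- function(n, ar) {
  x <- if (ar == 0) stats::rnorm(n)
       else as.numeric(stats::filter(stats::rnorm(n), ar,
                                     method = "recursive"))
  as.numeric(scale(x))
}

#' Simulate a synthetic cohort
#'
#' Generates per-subject node x time BOLD-like matrices, motion traces with
#' FD spikes, and nuisance signals, under the generative model documented in
#' [cohort_config()]. The returned `truth` record (per-subject, per-node
#' couplings plus ages and groups) is sufficient to compute the expected
#' pairwise correlation at every node via [expected_isc()].
#'
#' Deterministic given `config$seed`; the caller's RNG state is restored on
#' exit.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: `subjects` (list of
#'   [subject_time_series()]), `motion` (list of [motion_trace()]),
#'   `nuisance_signals` (per-subject list with `white_matter`, `ventricle`,
#'   `fef`), `metadata` (data.frame: subject_id, group, age_months, sex),
#'   `truth`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  nT <- config$n_volumes
  nV <- config$n_nodes
  groups <- rep(names(config$n_per_group), config$n_per_group)
  nS <- length(groups)
  ids <- sprintf("sub%03d", seq_len(nS))
  is_child <- groups != config$adult_group

  # ages: children over the configured range; adults nominal young-adult
  ages <- numeric(nS)
  rng <- config$age_range_months
  if (config$age_two_clusters) {
    child_groups <- unique(groups[is_child])
    band_means <- seq(rng[1] + 5, rng[2] - 5,
                      length.out = max(length(child_groups), 1L))
    names(band_means) <- child_groups
    # conventional bands: ~4.44 y and ~6.55 y when two child groups exist
    if (length(child_groups) == 2L) band_means[] <- c(53.3, 78.6)
    for (g in child_groups) {
      sel <- groups == g
      ages[sel] <- pmin(pmax(stats::rnorm(sum(sel), band_means[g], 3.5),
                             rng[1]), rng[2])
    }
  } else {
    ages[is_child] <- stats::runif(sum(is_child), rng[1], rng[2])
  }
  ages[!is_child] <- stats::rnorm(sum(!is_child), 21.6 * 12, 2.94 * 12)
  sex <- sample(c("M", "F"), nS, replace = TRUE)

  # coupling matrix: subjects x nodes
  couplings <- matrix(config$coupling[groups], nS, nV)
  if (length(config$effect_nodes)) {
    base <- config$effect_coupling[groups]
    base[is_child] <- base[is_child] +
      config$age_slope * (ages[is_child] - config$age_center)
    couplings[, config$effect_nodes] <- base
  }
  if (any(couplings < 0 | couplings >= 1))
    stop("realized couplings left [0, 1); adjust config")
  rownames(couplings) <- ids

  shared <- vapply(seq_len(nV), function(v)
    smooth_gaussian_signal(nT, config$signal_fwhm_tr), numeric(nT))

  b <- config$idio_coupling
  # sample-orthogonalize x against ref columns, then restandardize; keeps
  # component sample variances exactly 1 so var(y) = 1 by construction
  orth_scale <- function(x, refs) {
    for (ref in refs) {
      coef <- colSums(ref * x) / colSums(ref^2)
      x <- x - t(t(ref) * coef)
    }
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    x
  }
  subjects <- vector("list", nS)
  motion <- vector("list", nS)
  nuisance <- vector("list", nS)
  spike_record <- vector("list", nS)

  for (i in seq_len(nS)) {
    ci <- couplings[i, ]
    eps <- vapply(seq_len(nV), function(v) ar1_noise(nT, config$noise_ar1),
                  numeric(nT))
    if (b > 0) {
      u <- orth_scale(vapply(seq_len(nV), function(v)
        smooth_gaussian_signal(nT, config$signal_fwhm_tr), numeric(nT)),
        list(shared))
      eps <- orth_scale(eps, list(shared, u))
      y <- t(shared) * ci + b * t(u) + sqrt(1 - ci^2 - b^2) * t(eps)
    } else {
      eps <- orth_scale(eps, list(shared))
      y <- t(shared) * ci + sqrt(1 - ci^2) * t(eps)
    }

    # motion: random-walk drift plus step-change spikes on one axis
    dtr <- matrix(stats::rnorm(3 * nT, sd = 0.025), nT, 3)
    dro <- matrix(stats::rnorm(3 * nT, sd = 0.0005), nT, 3)
    dtr[1, ] <- 0; dro[1, ] <- 0
    spikes <- which(stats::runif(nT) < config$motion_spike_rate)
    spikes <- setdiff(spikes, 1L)
    for (s in spikes) {
      axis <- sample(3L, 1L)
      dtr[s, axis] <- dtr[s, axis] +
        sample(c(-1, 1), 1L) * stats::runif(1, 0.55, 1.2)
    }
    motion[[i]] <- motion_trace(apply(dtr, 2, cumsum),
                                apply(dro, 2, cumsum))
    spike_record[[i]] <- spikes

    if (config$spikes_affect_signal && length(spikes))
      y[, spikes] <- y[, spikes] +
        matrix(stats::rnorm(nV * length(spikes), sd = 8), nV)

    # arbitrary-unit BOLD: mean 1000, unit fluctuation scale
    subjects[[i]] <- subject_time_series(1000 + 10 * y, ids[i], groups[i],
                                         ages[i])
    nuisance[[i]] <- list(white_matter = ar1_noise(nT, 0.5),
                          ventricle = ar1_noise(nT, 0.5),
                          fef = ar1_noise(nT, 0.5))
  }
  names(subjects) <- names(motion) <- names(nuisance) <- ids

  metadata <- data.frame(subject_id = ids, group = groups,
                         age_months = ages, sex = sex,
                         stringsAsFactors = FALSE)
  truth <- list(couplings = couplings, groups = stats::setNames(groups, ids),
                age_months = stats::setNames(ages, ids),
                age_slope = config$age_slope,
                effect_nodes = config$effect_nodes,
                spike_volumes = stats::setNames(spike_record, ids),
                seed = config$seed)
  structure(
    list(subjects = subjects, motion = motion, nuisance_signals = nuisance,
         metadata = metadata, truth = truth, config = config),
    class = "synthetic_cohort")
}

#' Expected pairwise ISC from the generating truth
#'
#' Closed-form oracle: under the generative model the expected Pearson
#' correlation between subjects `i` and `j` at node `v` is the product of
#' their shared-signal couplings, `c_iv * c_jv`.
#'
#' @param truth the `truth` record of a [simulate_cohort()] result.
#' @param i,j subject ids (character) or indices.
#' @param v node index.
#' @return expected correlation (numeric scalar).
#' @export
expected_isc <- function(truth, i, j, v) {
  cm <- truth$couplings
  resolve <- function(s) {
    if (is.character(s)) {
      if (!s %in% rownames(cm)) stop("unknown subject: ", s)
      return(s)
    }
    if (s < 1 || s > nrow(cm)) stop("unknown subject index: ", s)
    s
  }
  if (v < 1 || v > ncol(cm)) stop("unknown node: ", v)
  unname(cm[resolve(i), v] * cm[resolve(j), v])
}

#' Write a synthetic cohort to disk as plain text
#'
#' One tab-delimited node x time matrix per subject
#' (`<id>_bold.tsv`), AFNI-style 6-column motion files (`<id>_motion.1D`),
#' per-subject nuisance signal CSVs (`<id>_nuisance.csv`), a cohort
#' metadata table (`participants.csv`), and the generating configuration
#' including the seed (`config.yml`).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$metadata, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  for (id in cohort$metadata$subject_id) {
    utils::write.table(cohort$subjects[[id]]$data,
                       file.path(dir, paste0(id, "_bold.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    write_motion_1d(cohort$motion[[id]],
                    file.path(dir, paste0(id, "_motion.1D")))
    utils::write.csv(as.data.frame(cohort$nuisance_signals[[id]]),
                     file.path(dir, paste0(id, "_nuisance.csv")),
                     row.names = FALSE)
  }
  cfg <- cohort$config
  cfg_out <- lapply(unclass(cfg), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `participants.csv` and per-subject
#'   files.
#' @return a `synthetic_cohort`-shaped list (without `truth`).
#' @export
read_cohort <- function(dir) {
  metadata <- utils::read.csv(file.path(dir, "participants.csv"),
                              stringsAsFactors = FALSE)
  subjects <- list(); motion <- list(); nuisance <- list()
  for (k in seq_len(nrow(metadata))) {
    id <- metadata$subject_id[k]
    dat <- as.matrix(utils::read.table(
      file.path(dir, paste0(id, "_bold.tsv")), sep = "\t"))
    dimnames(dat) <- NULL
    subjects[[id]] <- subject_time_series(dat, id, metadata$group[k],
                                          metadata$age_months[k])
    motion[[id]] <- read_motion_1d(file.path(dir, paste0(id, "_motion.1D")))
    nuisance[[id]] <- as.list(utils::read.csv(
      file.path(dir, paste0(id, "_nuisance.csv"))))
  }
  cfg_path <- file.path(dir, "config.yml")
  config <- if (file.exists(cfg_path)) cohort_config_from_file(cfg_path)
            else NULL
  structure(
    list(subjects = subjects, motion = motion, nuisance_signals = nuisance,
         metadata = metadata, truth = NULL, config = config),
    class = "synthetic_cohort")
}
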