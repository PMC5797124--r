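#' Construct a motion trace
#'
#' Bundles the six rigid-body realignment parameters of one functional run:
#' three translations (mm) and three rotations (radians). These are the
#' inputs to framewise displacement; the package never performs realignment
#' itself.
#'
#' @param translations numeric matrix, `n_volumes` x 3, in mm.
#' @param rotations numeric matrix, `n_volumes` x 3, in radians.
#' @return An object of class `motion_trace` with fields `translations`,
#'   `rotations` and `n_volumes`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    stop("translations and rotations must each have 3 columns")
  if (nrow(translations) != nrow(rotations))
    stop("translations and rotations must have equal length")
  if (!all(is.finite(translations)) || !all(is.finite(rotations)))
    stop("motion parameters must be finite")
  structure(
    list(translations = translations, rotations = rotations,
         n_volumes = nrow(translations)),
    class = "motion_trace")
}

#' Framewise displacement
#'
#' Per-volume head-motion scalar: the sum of absolute backward differences of
#' the six rigid-body parameters,
#' \deqn{FD_i = |\Delta d_{ix}| + |\Delta d_{iy}| + |\Delta d_{iz}|
#'   + |\Delta \alpha_i| + |\Delta \beta_i| + |\Delta \gamma_i|,}
#' with the rotation terms expressed as arc length on a sphere of radius
#' `rotation_radius_mm` (the convention of Power-style scrubbing; 50 mm
#' approximates the distance from the centre of the head to the cortex).
#' `rotation_radius_mm = 0` is accepted and reproduces the literal sum of
#' raw angular differences, for pipelines that report FD without the
#' conversion.
#'
#' The first volume has no predecessor; its FD is defined as 0 so the series
#' aligns with the run.
#'
#' @param motion a [motion_trace()].
#' @param rotation_radius_mm sphere radius for the rotation-to-mm
#'   conversion; default 50. Use 0 to sum raw angular values.
#' @return numeric vector of length `n_volumes`, in mm; first element 0.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  if (motion$n_volumes < 2L)
    stop("compute_fd() needs at least 2 volumes")
  if (rotation_radius_mm < 0) stop("rotation_radius_mm must be >= 0")
  dtr <- abs(diff(motion$translations))
  dro <- abs(diff(motion$rotations))
  rot_scale <- if (rotation_radius_mm == 0) 1 else rotation_radius_mm
  fd <- rowSums(dtr) + rot_scale * rowSums(dro)
  c(0, fd)
}

#' Censor mask from framewise displacement
#'
#' Volumes whose FD strictly exceeds the threshold are censored (scrubbed).
#' The boundary value itself is kept: "exceeded 0.5 mm" is a strict
#' inequality.
#'
#' @param fd numeric FD series (mm), as from [compute_fd()].
#' @param fd_threshold_mm censoring threshold in mm; default 0.5.
#' @return An object of class `censor_mask`: list with `keep` (logical per
#'   volume, `FALSE` = censored), `n_censored`, and `fd_threshold_mm`.
#' @export
make_censor_mask <- function(fd, fd_threshold_mm = 0.5) {
  if (fd_threshold_mm <= 0) stop("fd_threshold_mm must be > 0")
  if (!all(is.finite(fd))) stop("fd must be finite")
  keep <- !(fd > fd_threshold_mm)
  structure(
    list(keep = keep, n_censored = sum(!keep),
         fd_threshold_mm = fd_threshold_mm),
    class = "censor_mask")
}

#' Run-level motion exclusion
#'
#' A run is excluded when more than `max_fraction` of its volumes were
#' censored. The volume limit is the smallest integer strictly greater than
#' `max_fraction * n_volumes`; with 176 volumes and a 9% bound this is 16
#' volumes, i.e. a run with 16 or more censored volumes is excluded.
#'
#' @param mask a [make_censor_mask()] result (or a plain censored count via
#'   `n_censored`).
#' @param n_volumes number of volumes in the run.
#' @param max_fraction maximum tolerated censored fraction, in (0, 1);
#'   default 0.09.
#' @return list with `include` (logical), `volume_limit` (integer), and
#'   `n_censored`.
#' @export
run_exclusion <- function(mask, n_volumes, max_fraction = 0.09) {
  if (max_fraction <= 0 || max_fraction >= 1)
    stop("max_fraction must be in (0, 1)")
  n_censored <- if (inherits(mask, "censor_mask")) mask$n_censored
                else as.integer(mask)
  volume_limit <- floor(max_fraction * n_volumes) + 1L
  list(include = n_censored < volume_limit,
       volume_limit = as.integer(volume_limit),
       n_censored = as.integer(n_censored))
}

#' Read AFNI-style 6-column motion parameters
#'
#' Whitespace-delimited text, one row per volume, six columns. The default
#' dialect is the 3dvolreg output order (roll, pitch, yaw in degrees, then
#' dS, dL, dP in mm); `order = "trans_first"` reads translations in columns
#' 1-3 instead. Angles are converted to radians when `rotation_units =
#' "degrees"`.
#'
#' @param path file path.
#' @param order `"rot_first"` (default, 3dvolreg) or `"trans_first"`.
#' @param rotation_units `"degrees"` (default) or `"radians"`.
#' @return a [motion_trace()].
#' @export
read_motion_1d <- function(path, order = c("rot_first", "trans_first"),
                           rotation_units = c("degrees", "radians")) {
  order <- match.arg(order)
  rotation_units <- match.arg(rotation_units)
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   comment.char = "#"))
  if (ncol(m) != 6L) stop("motion file must have exactly 6 columns")
  if (order == "rot_first") {
    rot <- m[, 1:3, drop = FALSE]; trans <- m[, 4:6, drop = FALSE]
  } else {
    trans <- m[, 1:3, drop = FALSE]; rot <- m[, 4:6, drop = FALSE]
  }
  if (rotation_units == "degrees") rot <- rot * pi / 180
  motion_trace(trans, rot)
}

#' Write a motion trace in AFNI 6-column format
#'
#' @param motion a [motion_trace()].
#' @param path output path.
#' @param order column order, as in [read_motion_1d()].
#' @param rotation_units angle units to write.
#' @return `path`, invisibly.
#' @export
write_motion_1d <- function(motion, path,
                            order = c("rot_first", "trans_first"),
                            rotation_units = c("degrees", "radians")) {
  order <- match.arg(order)
  rotation_units <- match.arg(rotation_units)
  rot <- motion$rotations
  if (rotation_units == "degrees") rot <- rot * 180 / pi
  m <- if (order == "rot_first") cbind(rot, motion$translations)
       else cbind(motion$translations, rot)
  utils::write.table(format(m, scientific = FALSE, digits = 10), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an AFNI-dialect censor file
#'
#' One value per line: 1 = keep, 0 = censored.
#'
#' @param mask a [make_censor_mask()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_censor_1d <- function(mask, path) {
  stopifnot(inherits(mask, "censor_mask"))
  writeLines(as.character(as.integer(mask$keep)), path)
  invisible(path)
}

#' Read an AFNI-dialect censor file
#'
#' @param path file path.
#' @param fd_threshold_mm threshold recorded on the returned mask (the file
#'   itself does not store it).
#' @return a `censor_mask`.
#' @export
read_censor_1d <- function(path, fd_threshold_mm = 0.5) {
  keep <- as.integer(readLines(path))
  if (!all(keep %in% c(0L, 1L))) stop("censor file must contain only 0/1")
  structure(
    list(keep = keep == 1L, n_censored = sum(keep == 0L),
         fd_threshold_mm = fd_threshold_mm),
    class = "censor_mask")
}
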