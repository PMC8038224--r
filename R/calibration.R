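# Sensor-to-segment calibration from functional calibration movements.
#
# The fixed rotation from each sensor casing frame to its body-segment
# anatomical frame is estimated from two cues: the mean accelerometer
# direction during quiet neutral stance (gravity fixes the segment
# longitudinal axis) and the dominant angular-velocity direction during a
# sagittal movement (the rotation axis fixes the mediolateral axis).  The
# anterior axis completes the right-handed triad; Gram-Schmidt
# orthogonalization keeps the gravity axis exact.

CALIB_RATE_THRESHOLD <- 0.3   # rad/s; samples below this are "not moving"

# which calibration movement supplies the rotation-axis cue per site
calib_movement_for_site <- function(site) {
  if (site %in% c("sternum", "sacrum")) "bending" else "shoulder_flexion"
}

#' Estimate sensor-to-segment rotations from calibration trials
#'
#' Requires at least one neutral-stance trial (gravity cue, all sites) and,
#' per site, one sagittal movement trial: trunk bending for the sternum and
#' sacrum sensors, shoulder flexion for the four arm sensors.  Within the
#' movement trial, gyroscope samples above 0.3 rad/s are pooled across all
#' repetitions and their first principal direction taken as the mediolateral
#' axis; its sign is fixed by the rotation direction at movement onset
#' (forward flexion is a rotation about the negative mediolateral axis in
#' the package frame convention).
#'
#' @param calib_trials list of segment-calibration [trial()]s.
#' @param sites sites to calibrate; default all six.
#' @return object of class `segment_calibration`: named list `rotations` of
#'   casing-to-segment unit quaternions, per-site `residual_deg` (angle
#'   between the raw principal axis and the orthogonalized mediolateral
#'   axis) and `source_trials`.
#' @export
estimate_segment_frames <- function(calib_trials, sites = immu_sites()) {
  movements <- vapply(calib_trials, function(tr) tr$movement, character(1))
  neutral <- calib_trials[movements == "neutral"]
  if (!length(neutral))
    stop("calibration requires a neutral-stance trial")

  rotations <- list()
  residual <- numeric(0)
  src <- character(0)
  for (site in sites) {
    mv <- calib_movement_for_site(site)
    move <- calib_trials[movements == mv]
    if (!length(move))
      stop(sprintf("calibration for site '%s' requires a '%s' trial",
                   site, mv))
    ntr <- neutral[[1]]; mtr <- move[[1]]
    if (is.null(ntr$immu[[site]]) || is.null(mtr$immu[[site]]))
      stop(sprintf("calibration trials carry no stream for site '%s'", site))

    # gravity cue: specific force during quiet stance points opposite
    # gravity; reject moving or transient samples
    ns <- ntr$immu[[site]]
    fn <- sqrt(rowSums(ns$linacc^2))
    wn <- sqrt(rowSums(ns$angvel^2))
    keep <- abs(fn - GRAVITY) < 1 & wn < 0.1
    if (sum(keep) < 10L)
      stop(sprintf("site '%s': too few quiet stance samples", site))
    up <- colMeans(ns$linacc[keep, , drop = FALSE])
    up <- up / sqrt(sum(up^2))
    z_seg <- -up                       # longitudinal axis, caudal

    ms <- mtr$immu[[site]]
    wmag <- sqrt(rowSums(ms$angvel^2))
    active <- which(wmag > CALIB_RATE_THRESHOLD)
    if (length(active) < 10L)
      stop(sprintf(
        "site '%s': no samples above the %.1f rad/s movement threshold",
        site, CALIB_RATE_THRESHOLD))
    W <- ms$angvel[active, , drop = FALSE]
    v <- svd(W, nu = 0, nv = 1)$v[, 1]
    cosg <- abs(sum(v * z_seg))
    if (cosg > cos(15 * pi / 180))
      stop(sprintf(
        "site '%s': rotation axis within 15 degrees of gravity, degenerate calibration geometry",
        site))
    # sign: at onset the movement proceeds in its named (positive)
    # direction, a rotation about the negative mediolateral axis
    onset <- W[1, ]
    v <- -sign(sum(onset * v)) * v

    y_raw <- v
    y_seg <- y_raw - sum(y_raw * z_seg) * z_seg
    y_seg <- y_seg / sqrt(sum(y_seg^2))
    x_seg <- cross3(matrix(y_seg, 1), matrix(z_seg, 1))[1, ]
    A <- cbind(x_seg, y_seg, z_seg)    # segment axes in casing coords
    rotations[[site]] <- rotmat_to_quat(A)
    residual[site] <- acos(pmin(1, abs(sum(y_raw * y_seg)))) * 180 / pi
    src <- unique(c(src, ntr$id, mtr$id))
  }
  structure(list(rotations = rotations, residual_deg = residual,
                 source_trials = src),
            class = "segment_calibration")
}

#' Re-express a sensor stream in its segment frame
#'
#' Applies the calibration rotation to the orientation, angular-velocity and
#' linear-acceleration channels.  Vector channel norms are preserved sample
#' by sample.
#'
#' @param stream an [immu_stream()] in casing coordinates.
#' @param calib a [estimate_segment_frames()] result containing the
#'   stream's site.
#' @return the stream re-expressed in the segment anatomical frame.
#' @export
apply_calibration <- function(stream, calib) {
  stopifnot(inherits(stream, "immu_stream"),
            inherits(calib, "segment_calibration"))
  q_cal <- calib$rotations[[stream$site]]
  if (is.null(q_cal))
    stop(sprintf("no calibration for site '%s'", stream$site))
  qc <- quat_conjugate(q_cal)
  immu_stream(stream$site, stream$t,
              quat_normalize(quat_multiply(stream$quat, q_cal)),
              quat_rotate(qc, stream$angvel),
              quat_rotate(qc, stream$linacc))
}

# apply the calibration to every inertial stream of every trial
calibrate_session <- function(ses, calib = NULL) {
  if (is.null(calib)) {
    calib <- estimate_segment_frames(
      session_trials(ses, kind = "segment_calibration"))
  }
  ses$trials <- lapply(ses$trials, function(tr) {
    tr$immu <- lapply(tr$immu, apply_calibration, calib = calib)
    tr
  })
  ses$calibration <- calib
  ses
}
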