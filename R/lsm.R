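# Top-down linked segment model: 3D net moment at L5/S1.
#
# The upper body (trunk incl. head, both upper arms, both forearm+hand
# segments, plus any handheld load) is treated as a chain rooted at the
# L5/S1 joint centre.  The net reaction moment about L5/S1 is
#
#   M = sum_i [ r_i x m_i (a_i - g) ] + sum_i dH_i/dt,
#
# with r_i the COM position relative to L5/S1, a_i the COM acceleration, g
# the gravitational acceleration vector and H_i the segment angular
# momentum.  In the package frame (x anterior, y right, z down) this yields
# positive My in forward flexion, positive Mx in left lateroflexion and
# positive Mz in left rotation, the usual reporting convention.  Moments are
# expressed in the trunk anatomical frame.

# zero-phase 2nd-order Butterworth low-pass on the 50 Hz grid; used for all
# numerical differentiation (suppresses noise amplification)
lowpass50 <- function(x, cutoff = 3, rate = SAMPLE_RATE) {
  x <- as.matrix(x)
  if (nrow(x) < 12L) return(x)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  apply(x, 2, function(col) as.numeric(signal::filtfilt(bf, col)))
}

# central-difference time derivative of an n x k track
numderiv <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) return(matrix(0, n, ncol(x)))
  d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) /
    (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

# Shared moment engine operating on a segment pose set:
#   poses = list(t, segments = list(<name> = list(quat, angvel)), root_acc)
# with quat the segment-to-global track, angvel the body-frame angular
# velocity and root_acc an optional n x 3 global acceleration of the L5/S1
# root.  Used both for ground-truth generation (noise-free poses) and for
# the sensor-driven LSM, so the two differ only in their inputs.
moment_engine <- function(poses, body_model, load, smooth_cutoff = 3) {
  t <- poses$t
  n <- length(t)
  g <- matrix(rep(c(0, 0, GRAVITY), each = n), ncol = 3)
  wsh <- attr(body_model, "shoulder_halfwidth")

  trunk <- body_segment(body_model, "trunk")
  head <- body_segment(body_model, "head_neck")
  q_tr <- poses$segments$trunk$quat

  com <- list()   # COM positions, global, relative to L5/S1
  mass <- list()
  com$trunk <- quat_rotate(q_tr, c(0, 0, -trunk$com))
  mass$trunk <- trunk$mass
  com$head_neck <- quat_rotate(q_tr, c(0, 0, -(trunk$length + head$com)))
  mass$head_neck <- head$mass

  sh <- list(L = quat_rotate(q_tr, c(0, -wsh, -trunk$length)),
             R = quat_rotate(q_tr, c(0, wsh, -trunk$length)))
  hands <- list()
  for (side in c("L", "R")) {
    ua <- body_segment(body_model, paste0("upper_arm_", side))
    fa <- body_segment(body_model, paste0("lower_arm_", side))
    q_ua <- poses$segments[[paste0("upper_arm_", side)]]$quat
    q_fa <- poses$segments[[paste0("lower_arm_", side)]]$quat
    com[[paste0("upper_arm_", side)]] <-
      sh[[side]] + quat_rotate(q_ua, c(0, 0, ua$com))
    mass[[paste0("upper_arm_", side)]] <- ua$mass
    elbow <- sh[[side]] + quat_rotate(q_ua, c(0, 0, ua$length))
    com[[paste0("lower_arm_", side)]] <-
      elbow + quat_rotate(q_fa, c(0, 0, fa$com))
    mass[[paste0("lower_arm_", side)]] <- fa$mass
    hands[[side]] <- elbow + quat_rotate(q_fa, c(0, 0, fa$length))
  }

  if (load$mass > 0) {
    mid <- (hands$L + hands$R) / 2
    com$load <- mid + quat_rotate(q_tr, load$position)
    mass$load <- load$mass
  }

  root_acc <- poses$root_acc
  if (!is.null(root_acc)) root_acc <- lowpass50(root_acc, smooth_cutoff)

  M <- matrix(0, n, 3)
  dt <- SAMPLE_DT
  for (nm in names(com)) {
    p <- com[[nm]]
    ps <- lowpass50(p, smooth_cutoff)
    a <- numderiv(numderiv(ps, dt), dt)
    if (!is.null(root_acc)) a <- a + root_acc
    M <- M + cross3(p, mass[[nm]] * (a - g))
  }

  # segment rotational terms dH/dt (small relative to the gravitational and
  # translational-inertia terms, but kept for completeness)
  for (nm in c("trunk", "upper_arm_L", "upper_arm_R",
               "lower_arm_L", "lower_arm_R")) {
    seg <- body_segment(body_model,
                        if (nm == "trunk") "trunk" else nm)
    pose <- poses$segments[[nm]]
    if (is.null(pose$angvel)) next
    Ib <- c(seg$I_trans, seg$I_trans, seg$I_long)
    H <- quat_rotate(pose$quat, sweep(pose$angvel, 2, Ib, `*`))
    M <- M + numderiv(lowpass50(H, smooth_cutoff), dt)
  }

  M_trunk <- quat_rotate(quat_conjugate(q_tr), M)
  net_moment_series(t, M_trunk)
}

# convert calibrated segment-frame immu streams into a pose set
streams_to_poses <- function(streams, use_linacc = TRUE) {
  need <- c("sternum", "upper_arm_L", "upper_arm_R",
            "lower_arm_L", "lower_arm_R")
  for (s in need)
    if (is.null(streams[[s]]))
      stop(sprintf("linked segment model: missing stream for segment '%s'",
                   if (s == "sternum") "trunk" else s))
  segs <- list(trunk = list(quat = streams$sternum$quat,
                            angvel = streams$sternum$angvel))
  for (s in setdiff(need, "sternum"))
    segs[[s]] <- list(quat = streams[[s]]$quat,
                      angvel = streams[[s]]$angvel)
  root_acc <- NULL
  if (use_linacc && !is.null(streams$sacrum)) {
    # specific force f = a - g measured at the pelvis root; recover the
    # global root acceleration a = R f + g
    n <- length(streams$sacrum$t)
    g <- matrix(rep(c(0, 0, GRAVITY), each = n), ncol = 3)
    root_acc <- quat_rotate(streams$sacrum$quat, streams$sacrum$linacc) + g
  }
  list(t = streams$sternum$t, segments = segs, root_acc = root_acc)
}

#' Net L5/S1 moment from segment kinematics (linked segment model)
#'
#' Computes the 3D net moment about the L5/S1 joint centre from calibrated
#' segment-frame kinematics of the trunk (sternum sensor) and both arms,
#' the subject-scaled body model and a known handheld load.  This is the
#' supervised-training target generator for the network estimator.
#'
#' Segment COM accelerations are obtained by double central differences of
#' the reconstructed COM trajectories after zero-phase 3 Hz smoothing;
#' when `use_linacc` is `TRUE` (controlled environments) the pelvis-sensor
#' specific force supplies the root translation acceleration.
#'
#' @param streams named list of segment-frame [immu_stream()]s; must contain
#'   `sternum`, `upper_arm_L`, `upper_arm_R`, `lower_arm_L`, `lower_arm_R`;
#'   `sacrum` is used for the root acceleration when present.
#' @param body_model a [scale_body_model()] result.
#' @param load a [load_spec()]; load kinematics are derived from the hand
#'   kinematics of the chain.
#' @param use_linacc logical; include the measured root linear acceleration.
#' @param smooth_cutoff low-pass cutoff (Hz) used before numerical
#'   differentiation.
#' @return a [net_moment_series()] in the trunk anatomical frame.
#' @export
lsm_net_moment <- function(streams, body_model, load = load_spec(0),
                           use_linacc = TRUE, smooth_cutoff = 3) {
  stopifnot(inherits(body_model, "body_model"), inherits(load, "load_spec"))
  poses <- streams_to_poses(streams, use_linacc = use_linacc)
  moment_engine(poses, body_model, load, smooth_cutoff = smooth_cutoff)
}
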