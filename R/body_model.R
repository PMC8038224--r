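# Anthropometric scaling of the upper-body linked segment model.

#' Default anthropometric fractions
#'
#' Segment mass fractions (of body mass), segment length fractions (of
#' stature), centre-of-mass position as a fraction of segment length from the
#' proximal end, and transverse radius of gyration about the COM as a
#' fraction of segment length.  Values follow the standard adult cadaver
#' tables used in occupational biomechanics (Dempster-derived, as tabulated
#' by Winter); the trunk row pools thorax, abdomen and pelvis, and the
#' head+neck row is treated as rigidly attached to the trunk because the
#' sensor layout carries no head sensor.  The modeled upper body sums to
#' 0.678 of body mass.
#'
#' All fractions can be overridden by passing a modified table to
#' [scale_body_model()].
#'
#' @return data.frame with one row per modeled segment.
#' @export
anthropometric_table <- function() {
  data.frame(
    segment = c("trunk", "head_neck", "upper_arm_L", "upper_arm_R",
                "lower_arm_L", "lower_arm_R"),
    mass_fraction = c(0.497, 0.081, 0.028, 0.028, 0.022, 0.022),
    length_fraction = c(0.300, 0.090, 0.186, 0.186, 0.200, 0.200),
    com_fraction = c(0.45, 0.50, 0.436, 0.436, 0.530, 0.530),
    rg_fraction = c(0.350, 0.300, 0.322, 0.322, 0.365, 0.365),
    stringsAsFactors = FALSE
  )
}

# geometry fractions of stature that are not per-segment
SHOULDER_HALFWIDTH_FRACTION <- 0.129

#' Scale the upper-body segment model to a subject
#'
#' Builds the rigid-segment parameter set driving the top-down linked
#' segment model: per-segment mass, length, COM position and principal
#' inertia, scaled linearly by body mass and stature.  The trunk segment
#' spans L5/S1 to the shoulder line; head+neck is a point mass rigidly fixed
#' above the trunk; forearm and hand are pooled into one distal segment per
#' side.
#'
#' @param subject a [subject_info()].
#' @param table anthropometric fraction table, default
#'   [anthropometric_table()].
#' @return object of class `body_model`: data.frame of segment parameters
#'   (`mass` kg, `length` m, `com` m from proximal end, `I_trans`, `I_long`
#'   kg m^2) plus attributes `shoulder_halfwidth` (m), `subject`.
#' @export
scale_body_model <- function(subject, table = anthropometric_table()) {
  stopifnot(inherits(subject, "subject_info"))
  seg <- table
  seg$mass <- seg$mass_fraction * subject$mass
  seg$length <- seg$length_fraction * subject$height
  seg$com <- seg$com_fraction * seg$length
  rg <- seg$rg_fraction * seg$length
  seg$I_trans <- seg$mass * rg^2
  seg$I_long <- 0.3 * seg$I_trans
  bm <- structure(seg, class = c("body_model", "data.frame"),
                  shoulder_halfwidth = SHOULDER_HALFWIDTH_FRACTION *
                    subject$height,
                  subject = subject)
  validate_body_model(bm)
  bm
}

validate_body_model <- function(bm) {
  if (any(bm$mass <= 0)) stop("body model: segment masses must be positive")
  if (any(bm$com_fraction <= 0 | bm$com_fraction >= 1))
    stop("body model: COM fractions must lie in (0, 1)")
  frac <- sum(bm$mass) / attr(bm, "subject")$mass
  if (abs(frac - 0.678) > 0.01)
    stop(sprintf(
      "body model: upper-body mass fraction %.3f outside 0.678 +/- 0.01",
      frac))
  invisible(bm)
}

body_segment <- function(bm, name) {
  i <- match(name, bm$segment)
  if (is.na(i)) stop(sprintf("body model has no segment '%s'", name))
  bm[i, ]
}

#' Handheld load specification
#'
#' @param mass load mass in kg (>= 0).
#' @param position load position relative to the mid-hands point, m, in the
#'   trunk frame.
#' @param known whether the load properties are known (training trials).
#' @return object of class `load_spec`.
#' @export
load_spec <- function(mass = 0, position = c(0.10, 0, 0), known = TRUE) {
  if (!is.numeric(mass) || length(mass) != 1L || mass < 0)
    stop("load mass must be a single nonnegative number")
  stopifnot(length(position) == 3L)
  structure(list(mass = mass, position = as.numeric(position), known = known),
            class = "load_spec")
}
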