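# Construction of the two competing grasp predictions. Both hypotheses keep
# the bias magnitude measured at a reference orientation and place the
# predicted grasp centre on one side of the object midline; they differ only
# in which side. Contacts are idealised: perpendicular to, and in contact
# with, the cylinder surface.

#' Side of the midline favoured by the object-visibility hypothesis
#'
#' Grasping on the side of the acting hand leaves less of the object occluded
#' by the hand. For a right hand this is the side of the long axis whose
#' endpoint has the larger x coordinate; for a left hand, the smaller.
#' No occlusion raycasting is performed -- the prediction is purely
#' side-of-midline.
#'
#' @param pose an [object_pose()]; its axis must not be perpendicular to x
#'   (theta = 90 is degenerate: the two ends have equal x).
#' @param hand `"right"` (default) or `"left"`.
#' @return `+1` or `-1`: the sign `s` such that the axis endpoint
#'   `s * (cos theta, sin theta)` lies on the acting-hand side.
#' @export
visibility_side <- function(pose, hand = c("right", "left")) {
  hand <- match.arg(hand)
  ct <- cos(.deg2rad(pose$theta))
  if (abs(ct) < 1e-9) {
    stop("theta = 90: both axis ends have equal x, visibility side undefined",
         call. = FALSE)
  }
  s <- if (ct > 0) 1 else -1
  if (hand == "left") -s else s
}

#' Side of the midline favoured by the minimum-reach hypothesis
#'
#' Of the two candidate grasp centres at `+/- bias` along the long axis,
#' returns the sign of the one closer to the hand's start location. Computed
#' from the actual candidate-to-start distances rather than hard-coded sides,
#' so it generalises to any layout.
#'
#' @inheritParams visibility_side
#' @param start length-3 start location of the hand (cm, table frame).
#' @param bias bias magnitude in cm, `> 0`.
#' @return `+1` or `-1`.
#' @export
reach_side <- function(pose, start, bias) {
  stopifnot(is.numeric(bias), length(bias) == 1)
  if (!(bias > 0)) stop("reach_side requires a positive bias", call. = FALSE)
  a <- axis_unit(pose$theta)
  d_plus <- reach_distance(start, pose$center + bias * a)
  d_minus <- reach_distance(start, pose$center - bias * a)
  if (abs(d_plus - d_minus) < 1e-9) {
    stop("candidate grasp centres are equidistant from the start location",
         call. = FALSE)
  }
  if (d_plus < d_minus) 1 else -1
}

#' Bias estimate container
#'
#' The bias is the deviation of the grasp centre from the object midline,
#' measured from medoid grasps at a reference orientation. `source` records
#' whether the magnitude is one participant's own medoid deviation
#' (`per_participant`) or the absolute mean of all participants' medoid
#' deviations (`group`).
#'
#' @param magnitude non-negative bias magnitude (cm).
#' @param reference_theta orientation (degrees) the bias was measured at.
#' @param source `"per_participant"` or `"group"`.
#' @return a `bias_estimate` list.
#' @export
bias_estimate <- function(magnitude, reference_theta,
                          source = c("per_participant", "group")) {
  source <- match.arg(source)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, magnitude >= 0)
  structure(list(magnitude = magnitude, reference_theta = reference_theta,
                 source = source),
            class = "bias_estimate")
}

#' Build a hypothesis prediction at a target orientation
#'
#' Transfers a bias magnitude measured at a reference orientation to a
#' target pose: the predicted grasp centre sits at `side * magnitude` along
#' the target long axis, with `side` from [visibility_side()] or
#' [reach_side()], and idealised contacts from [surface_contacts()]. A zero
#' bias places both predictions at the object centre.
#'
#' @param hypothesis `"visibility"` or `"reach"`.
#' @param bias a [bias_estimate()] or a plain non-negative magnitude (cm).
#' @param pose the target [object_pose()].
#' @param start hand start location (cm); used by the reach hypothesis.
#' @param hand handedness for the visibility hypothesis.
#' @param thumb_side passed to [surface_contacts()].
#' @return a `hypothesis_prediction` list: `hypothesis`, `pose`, `u_offset`
#'   (signed cm), `center`, `thumb`, `index` (table-frame points).
#' @export
build_prediction <- function(hypothesis = c("visibility", "reach"), bias, pose,
                             start, hand = "right", thumb_side = "near") {
  hypothesis <- match.arg(hypothesis)
  magnitude <- if (inherits(bias, "bias_estimate")) bias$magnitude else bias
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, magnitude >= 0)
  u_offset <- if (magnitude == 0) {
    0
  } else if (hypothesis == "visibility") {
    visibility_side(pose, hand = hand) * magnitude
  } else {
    reach_side(pose, start, magnitude) * magnitude
  }
  contacts <- surface_contacts(pose, u_offset, thumb_side = thumb_side)
  structure(
    list(hypothesis = hypothesis, pose = pose, u_offset = u_offset,
         center = pose$center + u_offset * axis_unit(pose$theta),
         thumb = contacts$thumb, index = contacts$index),
    class = "hypothesis_prediction")
}

#' @export
print.hypothesis_prediction <- function(x, ...) {
  cat(sprintf(
    "<%s prediction> theta %.1f deg, u_offset %+.3f cm, centre (%.3f, %.3f, %.3f)\n",
    x$hypothesis, x$pose$theta, x$u_offset, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}
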