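# Experiment layout constants, encoded once. In the table frame (origin at
# the object centre, x right, y away from the participant, z up): the object
# sits 36 cm from the table edge; the hand starts 11 cm from the edge and
# 26 cm to the right of the object, i.e. at (26, -25, 0); the transport goal
# is 28.5 cm to the right, elevated 3.7 cm.

#' Study layout constants
#'
#' @return list with `start` (hand start location) and `goal_center`, both
#'   length-3 table-frame points in cm.
#' @export
study_layout <- function() {
  list(start = c(26, -25, 0), goal_center = c(28.5, 0, 3.7))
}

#' Analysis configuration
#'
#' Bundles every tunable of [run_analysis()]. The defaults reproduce the
#' study conditions: bias measured at 150 degrees, predictions tested at 60
#' degrees, centre metric, 45-degree long-axis exclusion threshold,
#' 10 x 2.5 cm cylinder at the origin, right hand starting at (26, -25, 0).
#'
#' @param reference_theta orientation (deg) whose grasps define the bias.
#' @param target_theta orientation (deg) at which the hypotheses are tested.
#' @param metric grasp-distance metric, see [grasp_distance()].
#' @param exclusion_threshold_deg long-axis exclusion threshold (deg).
#' @param object_length,object_radius cylinder dimensions (cm).
#' @param object_center cylinder centre (cm, table frame).
#' @param start_location hand start location (cm, table frame).
#' @param bias_source `"per_participant"`: each participant's predictions use
#'   their own reference-orientation medoid deviation; `"group"`: all use the
#'   absolute mean of the per-participant deviations.
#' @param hand `"right"` or `"left"`, for the visibility side.
#' @param thumb_side digit assignment for predicted contacts.
#' @param alpha significance level for declaring a winner.
#' @param column_mapping named character vector mapping the canonical record
#'   fields to the input file's column names, see [default_column_mapping()].
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(reference_theta = 150,
                            target_theta = 60,
                            metric = c("center", "mean_digit"),
                            exclusion_threshold_deg = 45,
                            object_length = 10,
                            object_radius = 1.25,
                            object_center = c(0, 0, 0),
                            start_location = study_layout()$start,
                            bias_source = c("per_participant", "group"),
                            hand = c("right", "left"),
                            thumb_side = c("near", "far"),
                            alpha = 0.05,
                            column_mapping = default_column_mapping()) {
  metric <- match.arg(metric)
  bias_source <- match.arg(bias_source)
  hand <- match.arg(hand)
  thumb_side <- match.arg(thumb_side)
  stopifnot(object_length > 0, object_radius > 0,
            exclusion_threshold_deg > 0, exclusion_threshold_deg <= 90,
            alpha > 0, alpha < 1)
  structure(
    list(reference_theta = reference_theta, target_theta = target_theta,
         metric = metric, exclusion_threshold_deg = exclusion_threshold_deg,
         object_length = object_length, object_radius = object_radius,
         object_center = as.numeric(object_center),
         start_location = as.numeric(start_location),
         bias_source = bias_source, hand = hand, thumb_side = thumb_side,
         alpha = alpha, column_mapping = column_mapping),
    class = "analysis_config")
}

# pose of the study cylinder at a given orientation under a config
.config_pose <- function(config, theta) {
  object_pose(center = config$object_center, theta = theta,
              length = config$object_length, radius = config$object_radius)
}
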