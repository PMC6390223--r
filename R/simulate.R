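# Synthetic grasp-record generator. Emulates the study design: 14
# participants x 4 materials x 5 repetitions at each of two orientations,
# a participant-level grasp-centre bias along the long axis drawn from a
# truncated-normal population, idealised surface contacts with isotropic
# motor noise on each digit, and a small fraction of degenerate long-axis
# grasps at the cylinder ends.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions and design counts: N = 14
#' participants, 4 materials, 5 repetitions, orientations 150 and 60
#' degrees, a 4% long-axis-grasp rate, and a visibility-driven bias with
#' population mean 1.5 cm and sd 0.5 cm. Motor noise (sd 0.5 cm, isotropic)
#' is applied independently to each digit, not to the grasp centre, so the
#' grasp-axis angle is noisy too and the exclusion filter is exercised
#' realistically. Material labels never affect the generated geometry (the
#' analysis pools across materials).
#'
#' @param n_participants number of participants.
#' @param materials character vector of material labels.
#' @param n_repetitions trial repetitions per material and orientation.
#' @param orientations orientations (deg) to generate.
#' @param generating_hypothesis `"visibility"`, `"reach"` or `"null"`; which
#'   side of the midline the intended grasp centre falls on (`"null"`: no
#'   bias, centre on the midline).
#' @param bias_mean,bias_sd population mean and sd of the participant-level
#'   bias magnitude (cm); draws are truncated below at 0.
#' @param noise_sd isotropic motor-noise sd per contact point (cm).
#' @param long_axis_prob probability a trial is a degenerate long-axis grasp.
#' @param object_length,object_radius,object_center cylinder geometry (cm).
#' @param start_location hand start location (cm, table frame).
#' @param hand handedness, for the visibility side.
#' @param thumb_side digit assignment for the idealised contacts.
#' @param seed optional integer; when set, [generate_dataset()] is fully
#'   reproducible (same seed, byte-identical output).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 14,
                       materials = c("styrofoam", "wood", "brass", "brass_vaseline"),
                       n_repetitions = 5,
                       orientations = c(150, 60),
                       generating_hypothesis = c("visibility", "reach", "null"),
                       bias_mean = 1.5,
                       bias_sd = 0.5,
                       noise_sd = 0.5,
                       long_axis_prob = 0.04,
                       object_length = 10,
                       object_radius = 1.25,
                       object_center = c(0, 0, 0),
                       start_location = study_layout()$start,
                       hand = c("right", "left"),
                       thumb_side = c("near", "far"),
                       seed = NULL) {
  generating_hypothesis <- match.arg(generating_hypothesis)
  hand <- match.arg(hand)
  thumb_side <- match.arg(thumb_side)
  stopifnot(n_participants >= 1, length(materials) >= 1, n_repetitions >= 1,
            length(orientations) >= 1,
            bias_sd >= 0, noise_sd >= 0,
            long_axis_prob >= 0, long_axis_prob <= 1,
            object_length > 2 * object_radius)
  if (bias_mean < 0) stop("bias_mean must be non-negative", call. = FALSE)
  structure(
    list(n_participants = n_participants, materials = materials,
         n_repetitions = n_repetitions, orientations = orientations,
         generating_hypothesis = generating_hypothesis,
         bias_mean = bias_mean, bias_sd = bias_sd, noise_sd = noise_sd,
         long_axis_prob = long_axis_prob,
         object_length = object_length, object_radius = object_radius,
         object_center = as.numeric(object_center),
         start_location = as.numeric(start_location),
         hand = hand, thumb_side = thumb_side, seed = seed),
    class = "sim_config")
}

#' Draw participant-level bias magnitudes
#'
#' Draws from a normal population (`bias_mean`, `bias_sd`) truncated below
#' at 0, by inverse-CDF sampling (one uniform draw per participant, so the
#' random stream is easy to reason about). With `bias_sd = 0` every
#' participant gets the mean.
#'
#' @param config a [sim_config()].
#' @param n number of draws; defaults to the configured participant count.
#' @return numeric vector of non-negative bias magnitudes (cm).
#' @export
sample_participant_bias <- function(config, n = config$n_participants) {
  if (config$bias_sd == 0) return(rep(config$bias_mean, n))
  lo <- stats::pnorm(0, mean = config$bias_mean, sd = config$bias_sd)
  u <- stats::runif(n, min = lo, max = 1)
  stats::qnorm(u, mean = config$bias_mean, sd = config$bias_sd)
}

# intended side of the midline for one participant at one orientation
.generating_side <- function(config, pose, bias) {
  switch(config$generating_hypothesis,
    null = 0,
    visibility = visibility_side(pose, hand = config$hand),
    reach = reach_side(pose, config$start_location, bias))
}

#' Generate a synthetic grasp-record dataset
#'
#' For every participant x orientation x material x repetition cell, places
#' the intended grasp centre at `side * bias` along the long axis (side from
#' the generating hypothesis), constructs idealised surface contacts, and
#' perturbs each contact with isotropic Gaussian motor noise. With
#' probability `long_axis_prob` the trial is replaced by a degenerate
#' long-axis grasp: both contacts near a randomly chosen cylinder end, the
#' grasp axis parallel to the long axis, then the same noise.
#'
#' @param config a [sim_config()]; if `config$seed` is set the RNG is seeded
#'   first.
#' @return a grasp-record tibble with
#'   `n_participants * length(orientations) * length(materials) *
#'   n_repetitions` rows, ordered by participant, orientation, material,
#'   repetition. Passes [validate_records()] by construction.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  poses <- lapply(config$orientations, function(th)
    object_pose(center = config$object_center, theta = th,
                length = config$object_length, radius = config$object_radius))
  names(poses) <- as.character(config$orientations)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  biases <- sample_participant_bias(config)

  n_rows <- config$n_participants * length(config$orientations) *
    length(config$materials) * config$n_repetitions
  participant <- material <- character(n_rows)
  orientation_deg <- numeric(n_rows)
  repetition <- integer(n_rows)
  contacts <- matrix(NA_real_, n_rows, 6)  # thumb xyz, index xyz
  k <- 0L
  for (i in seq_along(ids)) {
    for (th in as.character(config$orientations)) {
      pose <- poses[[th]]
      side <- .generating_side(config, pose, biases[i])
      ideal <- surface_contacts(pose, side * biases[i],
                                thumb_side = config$thumb_side)
      for (mat in config$materials) {
        for (rep_i in seq_len(config$n_repetitions)) {
          if (stats::runif(1) < config$long_axis_prob) {
            # degenerate grasp at a random end, digits along the axis
            end <- sample(c(-1, 1), 1)
            a <- axis_unit(pose$theta)
            thumb <- pose$center + end * (config$object_length / 2) * a
            index <- thumb - end * 2 * config$object_radius * a
          } else {
            thumb <- ideal$thumb
            index <- ideal$index
          }
          thumb <- thumb + stats::rnorm(3, sd = config$noise_sd)
          index <- index + stats::rnorm(3, sd = config$noise_sd)
          k <- k + 1L
          participant[k] <- ids[i]; material[k] <- mat
          orientation_deg[k] <- as.numeric(th); repetition[k] <- rep_i
          contacts[k, ] <- c(thumb, index)
        }
      }
    }
  }
  tibble::tibble(
    participant = participant, material = material,
    orientation_deg = orientation_deg, repetition = repetition,
    thumb_x = contacts[, 1], thumb_y = contacts[, 2], thumb_z = contacts[, 3],
    index_x = contacts[, 4], index_y = contacts[, 5], index_z = contacts[, 6])
}
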