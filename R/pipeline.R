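#' Run the full grasp-bias analysis
#'
#' End-to-end reanalysis: (1) restrict to the reference and target
#' orientations and exclude long-axis grasps; (2) compute each participant's
#' medoid grasp at each orientation across materials and repetitions; (3)
#' compute the group medoid across participants; (4) measure the bias (signed
#' long-axis deviation of the medoid grasp centre from the object midline) at
#' the reference orientation; (5) build the visibility and reach predictions
#' at the target orientation from that bias; (6) measure each participant's
#' distance from their target-orientation medoid to each prediction; (7) run
#' a paired t-test on the two distance vectors; (8) declare the winner.
#'
#' The target-orientation grasps are never used to fit anything -- only the
#' reference-orientation bias feeds the predictions -- so the comparison is
#' not circular. Medoid ties are broken on records sorted by (participant,
#' orientation, material, repetition), making every reported number
#' independent of input row order.
#'
#' @param records grasp-record tibble (see [load_records()]); must contain
#'   grasps at both configured orientations for every participant.
#' @param config an [analysis_config()].
#' @param verbose print per-stage counts.
#' @return a `comparison_result` list: `n_participants`, `excluded_fraction`,
#'   `bias` (per-participant signed deviations, their mean, and the source in
#'   use), `per_participant` (tibble of signed bias, d_visibility, d_reach),
#'   `group_medoid` (per-orientation group medoid summaries), `predictions`
#'   (group-level prediction objects), `test` (a `paired_test_result`),
#'   `winner` (`"visibility"`, `"reach"` or `"inconclusive"`), `alpha`,
#'   `config`.
#' @export
run_analysis <- function(records, config = analysis_config(), verbose = FALSE) {
  records <- validate_records(records)
  thetas <- c(reference = config$reference_theta, target = config$target_theta)
  recs <- records[records$orientation_deg %in% thetas, , drop = FALSE]
  if (!nrow(recs)) stop("no records at the configured orientations", call. = FALSE)
  recs <- recs[order(recs$participant, recs$orientation_deg,
                     recs$material, recs$repetition), , drop = FALSE]
  participants <- sort(unique(recs$participant))
  poses <- lapply(thetas, function(th) .config_pose(config, th))

  # long-axis exclusion, per orientation pose
  flag <- rep(FALSE, nrow(recs))
  for (th in thetas) {
    sel <- recs$orientation_deg == th
    flag[sel] <- is_long_axis_grasp(recs[sel, ], .config_pose(config, th),
                                    config$exclusion_threshold_deg)
  }
  excluded_fraction <- mean(flag)
  retained <- recs[!flag, , drop = FALSE]
  if (verbose) {
    message(nrow(recs), " records at the analyzed orientations; ",
            sum(flag), " long-axis grasps excluded (",
            sprintf("%.1f%%", 100 * excluded_fraction), ")")
  }

  # every participant needs retained grasps at both orientations
  have <- table(retained$participant, retained$orientation_deg)
  need <- as.character(thetas)
  incomplete <- participants[
    !vapply(participants, function(p)
      all(need %in% colnames(have)) && all(have[p, need] > 0), logical(1))]
  if (length(incomplete)) {
    stop("participant(s) with no retained grasps at a required orientation: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }

  # per-participant medoids at each orientation
  medoid_of <- function(p, th) {
    medoid(retained[retained$participant == p & retained$orientation_deg == th, ],
           metric = config$metric)
  }
  med_ref <- dplyr::bind_rows(lapply(participants, medoid_of, th = thetas["reference"]))
  med_tgt <- dplyr::bind_rows(lapply(participants, medoid_of, th = thetas["target"]))
  if (verbose) {
    cnt <- table(retained$participant)
    message("retained trials per participant: ",
            paste(range(cnt), collapse = "-"))
  }

  # group medoid across participants (same metric)
  group_med <- list(
    reference = medoid(med_ref, metric = config$metric),
    target = medoid(med_tgt, metric = config$metric))

  # signed bias at the reference orientation
  bias_u <- grasp_summary(med_ref, poses$reference)$u
  group_mean_u <- mean(bias_u)
  magnitudes <- switch(config$bias_source,
    per_participant = abs(bias_u),
    group = rep(abs(group_mean_u), length(participants)))

  # predictions at the target orientation and per-participant distances
  tgt_summary <- grasp_summary(med_tgt, poses$target)
  predict_center <- function(hyp, mag) {
    build_prediction(hyp, mag, poses$target, start = config$start_location,
                     hand = config$hand, thumb_side = config$thumb_side)
  }
  dist_to <- function(i, hyp) {
    pred <- predict_center(hyp, magnitudes[i])
    if (config$metric == "center") {
      ctr <- c(tgt_summary$center_x[i], tgt_summary$center_y[i], tgt_summary$center_z[i])
      reach_distance(ctr, pred$center)
    } else {
      thumb <- c(med_tgt$thumb_x[i], med_tgt$thumb_y[i], med_tgt$thumb_z[i])
      index <- c(med_tgt$index_x[i], med_tgt$index_y[i], med_tgt$index_z[i])
      (reach_distance(thumb, pred$thumb) + reach_distance(index, pred$index)) / 2
    }
  }
  np <- length(participants)
  d_vis <- vapply(seq_len(np), dist_to, numeric(1), hyp = "visibility")
  d_reach <- vapply(seq_len(np), dist_to, numeric(1), hyp = "reach")

  test <- paired_t_test(d_vis, d_reach)
  winner <- if (test$p < config$alpha && mean(d_vis) < mean(d_reach)) {
    "visibility"
  } else if (test$p < config$alpha && mean(d_reach) < mean(d_vis)) {
    "reach"
  } else {
    "inconclusive"
  }

  group_bias <- bias_estimate(abs(group_mean_u), thetas[["reference"]], "group")
  structure(
    list(
      n_participants = np,
      excluded_fraction = excluded_fraction,
      bias = list(per_participant_u = stats::setNames(bias_u, participants),
                  group_mean_u = group_mean_u, source = config$bias_source),
      per_participant = tibble::tibble(
        participant = participants, bias_u_reference = bias_u,
        d_visibility = d_vis, d_reach = d_reach),
      group_medoid = list(
        reference = grasp_summary(group_med$reference, poses$reference),
        target = grasp_summary(group_med$target, poses$target)),
      predictions = list(
        visibility = predict_center("visibility", group_bias$magnitude),
        reach = predict_center("reach", group_bias$magnitude)),
      test = test, winner = winner, alpha = config$alpha, config = config),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Grasp-bias hypothesis comparison (%d participants)\n", x$n_participants))
  cat(sprintf("  long-axis grasps excluded: %.1f%%\n", 100 * x$excluded_fraction))
  cat(sprintf("  bias at %g deg (mean signed deviation): %+.3f cm [source: %s]\n",
              x$config$reference_theta, x$bias$group_mean_u, x$bias$source))
  cat(sprintf("  mean distance to visibility prediction: %.3f cm\n",
              mean(x$per_participant$d_visibility)))
  cat(sprintf("  mean distance to reach prediction:      %.3f cm\n",
              mean(x$per_participant$d_reach)))
  cat(sprintf("  t(%d) = %.3f, p = %.3g (alpha = %g)\n",
              x$test$df, x$test$t, x$test$p, x$alpha))
  cat(sprintf("  winner: %s\n", x$winner))
  invisible(x)
}

#' Write an analysis report
#'
#' Writes a machine-readable JSON summary of a [run_analysis()] result plus a
#' human-readable text block (same path with `.txt` appended).
#'
#' @param result a `comparison_result`.
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
report <- function(result, path) {
  stopifnot(inherits(result, "comparison_result"))
  payload <- list(
    n_participants = result$n_participants,
    excluded_fraction = result$excluded_fraction,
    bias_group_mean_u = result$bias$group_mean_u,
    bias_source = result$bias$source,
    per_participant = result$per_participant,
    mean_d_visibility = mean(result$per_participant$d_visibility),
    mean_d_reach = mean(result$per_participant$d_reach),
    t = result$test$t, df = result$test$df, p = result$test$p,
    mean_difference = result$test$mean_difference,
    alpha = result$alpha, winner = result$winner)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(result))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path path written by [report()].
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path)
}
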