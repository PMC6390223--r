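# Medoid statistics over sets of grasps. The medoid -- the element of a set
# minimising its summed distance to all other elements -- is preferred to the
# mean here because it is always an actually observed grasp, so it cannot lie
# inside the object or between two disjoint grasp clusters.

.grasp_metrics <- c("center", "mean_digit")

# full pairwise distance matrix among the grasps in `records`
.pairwise_grasp_dist <- function(records, metric) {
  thumb <- .thumb_mat(records)
  index <- .index_mat(records)
  if (metric == "center") {
    as.matrix(stats::dist((thumb + index) / 2))
  } else {
    (as.matrix(stats::dist(thumb)) + as.matrix(stats::dist(index))) / 2
  }
}

#' Distance between two grasps
#'
#' Two metrics are available. `"center"` (default throughout the package) is
#' the Euclidean distance between the two grasp centres; digit-correspondence
#' errors cannot affect it. `"mean_digit"` is the mean of the thumb-thumb and
#' index-index Euclidean distances, retained for sensitivity analyses. Both
#' are true metrics (non-negative, symmetric, triangle inequality).
#'
#' @param a,b single grasp records (one-row tibbles or lists with the
#'   standard `thumb_*` / `index_*` fields, cm).
#' @param metric `"center"` or `"mean_digit"`.
#' @return distance in cm.
#' @export
grasp_distance <- function(a, b, metric = c("center", "mean_digit")) {
  metric <- match.arg(metric)
  ta <- c(a$thumb_x, a$thumb_y, a$thumb_z); ia <- c(a$index_x, a$index_y, a$index_z)
  tb <- c(b$thumb_x, b$thumb_y, b$thumb_z); ib <- c(b$index_x, b$index_y, b$index_z)
  if (metric == "center") {
    sqrt(sum(((ta + ia) / 2 - (tb + ib) / 2)^2))
  } else {
    (sqrt(sum((ta - tb)^2)) + sqrt(sum((ia - ib)^2))) / 2
  }
}

#' Medoid of a set of grasps
#'
#' Returns the grasp minimising the sum of distances to all grasps in the
#' set, under the chosen metric. Ties are broken by the earliest position in
#' the input, so callers that need file-order independence should sort the
#' records by stable identifiers first (as [run_analysis()] does).
#'
#' @param records grasp-record tibble, at least one row.
#' @inheritParams grasp_distance
#' @return the medoid row (a one-row tibble) with attribute `medoid_index`,
#'   its position in the input.
#' @export
medoid <- function(records, metric = c("center", "mean_digit")) {
  metric <- match.arg(metric)
  n <- nrow(records)
  if (is.null(n) || n < 1) stop("medoid of an empty set is undefined", call. = FALSE)
  if (n == 1) {
    out <- records[1, ]
    attr(out, "medoid_index") <- 1L
    return(out)
  }
  d <- .pairwise_grasp_dist(records, metric)
  i <- unname(which.min(rowSums(d)))  # first minimum: stable tie-break
  out <- records[i, ]
  attr(out, "medoid_index") <- i
  out
}

#' Paired-samples t-test on two distance vectors
#'
#' Standard two-sided paired t-test on `d1 - d2`, as used to compare each
#' participant's grasp distance to the two hypothesis predictions. The fully
#' degenerate case `d1 == d2` elementwise (every difference exactly zero)
#' returns `t = 0`, `p = 1`; any other zero-variance difference vector is an
#' error, since the t statistic is undefined.
#'
#' @param d1,d2 numeric vectors of equal length `n >= 2` (cm).
#' @return a `paired_test_result` list: `t`, `df` (`n - 1`), `p` (two-sided),
#'   `mean_difference` (`mean(d1 - d2)`, cm).
#' @export
paired_t_test <- function(d1, d2) {
  stopifnot(is.numeric(d1), is.numeric(d2))
  if (length(d1) != length(d2)) stop("d1 and d2 must have equal length", call. = FALSE)
  n <- length(d1)
  if (n < 2) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  diffs <- d1 - d2
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) {
      return(structure(
        list(t = 0, df = n - 1L, p = 1, mean_difference = 0),
        class = "paired_test_result"))
    }
    stop("degenerate paired t-test: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(d1, d2, paired = TRUE, alternative = "two.sided")
  structure(
    list(t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
         p = tt$p.value, mean_difference = mean(diffs)),
    class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.3g, mean difference = %.3f cm\n",
              x$df, x$t, x$p, x$mean_difference))
  invisible(x)
}
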