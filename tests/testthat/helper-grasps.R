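# Shared fixtures, built in code.

# n random grasp records in a cube of half-width `range` around the origin
random_records <- function(n, range = 5) {
  tibble::tibble(
    participant = "P01", material = "wood",
    orientation_deg = 150, repetition = seq_len(n),
    thumb_x = stats::runif(n, -range, range),
    thumb_y = stats::runif(n, -range, range),
    thumb_z = stats::runif(n, 0, range),
    index_x = stats::runif(n, -range, range),
    index_y = stats::runif(n, -range, range),
    index_z = stats::runif(n, 0, range))
}

# a single record from explicit contact points
record_from_contacts <- function(thumb, index, participant = "P01",
                                 material = "wood", orientation_deg = 150,
                                 repetition = 1L) {
  tibble::tibble(
    participant = participant, material = material,
    orientation_deg = orientation_deg, repetition = repetition,
    thumb_x = thumb[1], thumb_y = thumb[2], thumb_z = thumb[3],
    index_x = index[1], index_y = index[2], index_z = index[3])
}

random_pose <- function(avoid_90 = FALSE) {
  theta <- stats::runif(1, 0, 180)
  if (avoid_90) while (abs(theta - 90) < 5) theta <- stats::runif(1, 0, 180)
  object_pose(center = stats::runif(3, -10, 10), theta = theta,
              length = stats::runif(1, 6, 14), radius = stats::runif(1, 0.5, 2))
}

# independent medoid oracle: exhaustive pairwise-distance summation over
# per-row lists, no distance matrix
brute_medoid_index <- function(records, metric) {
  rows <- lapply(seq_len(nrow(records)), function(i) as.list(records[i, ]))
  sums <- vapply(rows, function(a)
    sum(vapply(rows, function(b) grasp_distance(a, b, metric), numeric(1))),
    numeric(1))
  which.min(sums)
}
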