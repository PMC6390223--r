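# Table-frame convention used throughout: origin at the object centre on the
# table surface, x toward the participant's right, y away from the
# participant, z up. Right-handed, all coordinates in cm. The hand start
# location therefore has positive x and negative y.

.deg2rad <- function(deg) deg * pi / 180

#' Unit vector along a cylinder's long axis
#'
#' @param theta orientation angle in degrees, counterclockwise from the +x
#'   axis viewed from above.
#' @return length-3 unit vector in the table plane.
#' @keywords internal
axis_unit <- function(theta) {
  t <- .deg2rad(theta)
  c(cos(t), sin(t), 0)
}

# in-plane unit normal to the long axis (90 deg counterclockwise from it)
normal_unit <- function(theta) {
  t <- .deg2rad(theta)
  c(-sin(t), cos(t), 0)
}

#' Cylinder pose in the table frame
#'
#' Describes the grasped cylinder: its centre, the orientation of its long
#' axis, and its dimensions. The long axis is undirected, so `theta` is
#' normalised into \[0, 180); `theta` and `theta + 180` describe the same
#' pose.
#'
#' @param center length-3 numeric, cylinder centre in table coordinates (cm).
#' @param theta long-axis orientation in degrees, counterclockwise from the
#'   +x axis viewed from above.
#' @param length cylinder length (cm); must exceed the diameter.
#' @param radius cylinder radius (cm).
#' @return an `object_pose` list with fields `center`, `theta`, `length`,
#'   `radius`.
#' @examples
#' object_pose(theta = 150)
#' @export
object_pose <- function(center = c(0, 0, 0), theta, length = 10, radius = 1.25) {
  stopifnot(is.numeric(center), length(center) == 3, all(is.finite(center)))
  stopifnot(is.numeric(theta), length(theta) == 1, is.finite(theta))
  if (!(length > 0 && radius > 0)) {
    stop("cylinder dimensions must be positive", call. = FALSE)
  }
  if (length <= 2 * radius) {
    stop("cylinder length must exceed its diameter (length > 2 * radius)",
         call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), theta = theta %% 180,
         length = length, radius = radius),
    class = "object_pose"
  )
}

#' @export
print.object_pose <- function(x, ...) {
  cat(sprintf(
    "<object_pose> centre (%.2f, %.2f, %.2f) cm, theta %.1f deg, length %.2f cm, radius %.2f cm\n",
    x$center[1], x$center[2], x$center[3], x$theta, x$length, x$radius))
  invisible(x)
}

# coerce a length-3 vector or an n x 3 matrix/data frame to an n x 3 matrix;
# remembers whether the input was a single point
.as_points <- function(p) {
  if (is.numeric(p) && is.null(dim(p))) {
    stopifnot(length(p) == 3)
    m <- matrix(p, nrow = 1)
    attr(m, "single") <- TRUE
    return(m)
  }
  m <- as.matrix(p)
  stopifnot(ncol(m) == 3)
  m
}

#' Transform table-frame points into the object frame
#'
#' The object frame has its origin at the cylinder centre; `u` is the signed
#' coordinate along the long axis (so the object midline is the plane
#' `u = 0`), `v` the transverse in-plane coordinate, `w` the vertical one.
#'
#' @param p a length-3 point or an n x 3 matrix of points (cm, table frame).
#' @param pose an [object_pose()].
#' @return for a single point, a named numeric `c(u, v, w)`; for a matrix of
#'   points, an n x 3 matrix with columns `u`, `v`, `w`.
#' @seealso [from_object_frame()] for the inverse.
#' @export
to_object_frame <- function(p, pose) {
  m <- .as_points(p)
  centered <- sweep(m, 2, pose$center)
  basis <- rbind(axis_unit(pose$theta), normal_unit(pose$theta), c(0, 0, 1))
  out <- centered %*% t(basis)
  colnames(out) <- c("u", "v", "w")
  if (isTRUE(attr(m, "single"))) return(drop(out)[c("u", "v", "w")])
  out
}

#' Inverse of [to_object_frame()]
#'
#' @param q a length-3 `(u, v, w)` point or an n x 3 matrix.
#' @inheritParams to_object_frame
#' @return table-frame coordinates, same shape convention as the input.
#' @export
from_object_frame <- function(q, pose) {
  m <- .as_points(q)
  basis <- rbind(axis_unit(pose$theta), normal_unit(pose$theta), c(0, 0, 1))
  out <- m %*% basis
  out <- sweep(out, 2, pose$center, `+`)
  colnames(out) <- c("x", "y", "z")
  if (isTRUE(attr(m, "single"))) return(drop(out)[c("x", "y", "z")])
  out
}

.thumb_mat <- function(records) {
  as.matrix(records[, c("thumb_x", "thumb_y", "thumb_z")])
}

.index_mat <- function(records) {
  as.matrix(records[, c("index_x", "index_y", "index_z")])
}

#' Per-grasp summary quantities
#'
#' For each grasp record, computes the grasp centre (midpoint of the thumb
#' and index contacts), its signed long-axis deviation `u` from the object
#' midline, and the grasp-axis angle: the acute angle between the undirected
#' thumb-index line and the cylinder's long axis.
#'
#' @param records a grasp-record tibble (see [load_records()] for columns).
#' @param pose an [object_pose()].
#' @return a tibble with one row per record: `center_x/y/z`, `u`, `v`, `w`
#'   (object-frame coordinates of the centre, cm) and `grasp_axis_angle`
#'   (degrees in \[0, 90\]).
#' @export
grasp_summary <- function(records, pose) {
  thumb <- .thumb_mat(records)
  index <- .index_mat(records)
  d <- thumb - index
  dn <- sqrt(rowSums(d^2))
  if (any(dn == 0)) {
    stop("degenerate grasp (thumb == index) in row(s): ",
         paste(which(dn == 0), collapse = ", "), call. = FALSE)
  }
  center <- (thumb + index) / 2
  obj <- to_object_frame(center, pose)
  a <- axis_unit(pose$theta)
  cosang <- pmin(1, abs(d %*% a) / dn)
  tibble::tibble(
    center_x = as.numeric(center[, 1]), center_y = as.numeric(center[, 2]),
    center_z = as.numeric(center[, 3]),
    u = as.numeric(obj[, "u"]), v = as.numeric(obj[, "v"]),
    w = as.numeric(obj[, "w"]),
    grasp_axis_angle = as.numeric(acos(cosang)) * 180 / pi
  )
}

#' Flag grasps that fall along the object's long axis
#'
#' A long-axis grasp grips the cylinder near its ends, with the thumb-index
#' axis (near-)parallel to the long axis; such grasps are excluded from the
#' bias analysis. The flag is `grasp_axis_angle < angle_threshold`, which at
#' the default 45 degrees partitions grasps into "across the axis" versus
#' "along the axis" with no gap.
#'
#' @inheritParams grasp_summary
#' @param angle_threshold degrees; default 45.
#' @return logical vector, `TRUE` for long-axis grasps.
#' @export
is_long_axis_grasp <- function(records, pose, angle_threshold = 45) {
  grasp_summary(records, pose)$grasp_axis_angle < angle_threshold
}

#' Idealised surface contact points at a given long-axis offset
#'
#' Places thumb and index contacts on the cylinder's curved surface,
#' diametrically opposite in the table plane, so that the grasp axis is
#' perpendicular to the long axis, the contacts are `2 * radius` apart, and
#' the grasp centre sits at long-axis coordinate `u_offset`.
#'
#' @inheritParams grasp_summary
#' @param u_offset signed long-axis coordinate of the grasp centre (cm);
#'   must satisfy `|u_offset| <= length / 2`.
#' @param thumb_side `"near"` (default) puts the thumb on the participant's
#'   near side (smaller y; ties broken toward smaller x, which arises only
#'   when the axis is parallel to y), as for a right-hand precision grip
#'   approaching from the right. `"far"` swaps the digits.
#' @return list with `thumb` and `index`, each a length-3 table-frame point.
#' @export
surface_contacts <- function(pose, u_offset, thumb_side = c("near", "far")) {
  thumb_side <- match.arg(thumb_side)
  if (abs(u_offset) > pose$length / 2) {
    stop(sprintf("u_offset %.3f cm is off the object (half-length %.3f cm)",
                 u_offset, pose$length / 2), call. = FALSE)
  }
  base <- pose$center + u_offset * axis_unit(pose$theta)
  n <- normal_unit(pose$theta)
  c1 <- base + pose$radius * n
  c2 <- base - pose$radius * n
  dy <- c1[2] - c2[2]
  near_first <- if (abs(dy) > 1e-9) dy < 0 else c1[1] < c2[1]
  thumb <- if (near_first) c1 else c2
  index <- if (near_first) c2 else c1
  if (thumb_side == "far") {
    tmp <- thumb; thumb <- index; index <- tmp
  }
  list(thumb = thumb, index = index)
}

#' Euclidean reach distance between two points
#'
#' @param start,p length-3 points (cm).
#' @return distance in cm.
#' @examples
#' reach_distance(c(26, -25, 0), c(0, 0, 0))  # start location to object centre
#' @export
reach_distance <- function(start, p) {
  stopifnot(length(start) == 3, length(p) == 3)
  sqrt(sum((start - p)^2))
}

#' Reflect grasp contacts across the object midline
#'
#' Maps every contact point's long-axis coordinate `u` to `-u`, leaving the
#' transverse and vertical coordinates unchanged. Useful for constructing
#' mirror datasets in which the two hypotheses swap roles.
#'
#' @inheritParams grasp_summary
#' @return the records tibble with reflected contact coordinates.
#' @export
reflect_across_midline <- function(records, pose) {
  refl <- function(m) {
    q <- to_object_frame(m, pose)
    q[, "u"] <- -q[, "u"]
    from_object_frame(q, pose)
  }
  thumb <- refl(.thumb_mat(records))
  index <- refl(.index_mat(records))
  records$thumb_x <- thumb[, 1]; records$thumb_y <- thumb[, 2]; records$thumb_z <- thumb[, 3]
  records$index_x <- index[, 1]; records$index_y <- index[, 2]; records$index_z <- index[, 3]
  records
}
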