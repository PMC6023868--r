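#' Y-maze geometry
#'
#' Constructs the geometry of the Y-maze used in the virtual-shoal assay:
#' a circular central decision zone onto which the silhouettes are projected,
#' two destination arms, and a holding area from which the fish is released.
#' The coordinate system has its origin at the decision-zone centre, units in
#' cm, the holding area extending along the negative y axis, and the two
#' destination arms at +/-120 degrees from the holding direction (Y-maze
#' symmetry). Analysis is two-dimensional; maze depth is ignored, matching
#' overhead video tracking.
#'
#' @param arm_length Length of each destination arm, cm.
#' @param arm_width Width of each arm (and of the holding channel), cm.
#' @param decision_zone_diameter Diameter of the central decision zone, cm.
#' @param holding_length Length of the rectangular holding area, cm. The
#'   holding area abuts the decision zone along the negative y axis; its exact
#'   shape is a modelling choice, as only the release gate position matters
#'   for the analyses.
#' @param leader_boundary_extension Distance, cm, by which the effective
#'   boundary for *leader* silhouettes is extended back towards the holding
#'   area (0 in the solitary experiment; 13.8 in the group experiment, where
#'   it reduces the visual disturbance of many stimuli vanishing at an arm
#'   entrance).
#'
#' @return An object of class `maze_geometry`: a list with the dimensions,
#'   the zone radius, and unit axis vectors for the left arm, right arm and
#'   holding channel.
#' @examples
#' geom <- maze_geometry()
#' classify_zone(0, 0, geom) # centre of the decision zone
#' @export
maze_geometry <- function(arm_length = 46,
                          arm_width = 23,
                          decision_zone_diameter = 46,
                          holding_length = 23,
                          leader_boundary_extension = 0) {
  stopifnot(
    arm_length > 0, arm_width > 0, decision_zone_diameter > 0,
    holding_length > 0, leader_boundary_extension >= 0
  )
  # holding channel points down (-y); arms at +/-120 degrees from it
  rot <- function(v, theta) {
    c(cos(theta) * v[1] - sin(theta) * v[2],
      sin(theta) * v[1] + cos(theta) * v[2])
  }
  holding_axis <- c(0, -1)
  structure(
    list(
      arm_length = arm_length,
      arm_width = arm_width,
      zone_radius = decision_zone_diameter / 2,
      decision_zone_diameter = decision_zone_diameter,
      holding_length = holding_length,
      leader_boundary_extension = leader_boundary_extension,
      holding_axis = holding_axis,
      arm_axis_left = rot(holding_axis, -2 * pi / 3),
      arm_axis_right = rot(holding_axis, 2 * pi / 3)
    ),
    class = "maze_geometry"
  )
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat("Y-maze geometry (cm):\n")
  cat(sprintf("  decision zone diameter %.1f, arms %.1f x %.1f, holding %.1f x %.1f\n",
              x$decision_zone_diameter, x$arm_length, x$arm_width,
              x$holding_length, x$arm_width))
  if (x$leader_boundary_extension > 0) {
    cat(sprintf("  leader boundary extended by %.1f towards holding\n",
                x$leader_boundary_extension))
  }
  invisible(x)
}

zone_levels <- c("HOLDING", "DECISION", "ARM_LEFT", "ARM_RIGHT", "OUTSIDE")

# axial/perpendicular coordinates of points relative to a channel axis
.channel_member <- function(x, y, axis, from, to, half_width) {
  axial <- x * axis[1] + y * axis[2]
  perp <- abs(x * -axis[2] + y * axis[1])
  axial >= from & axial <= to & perp <= half_width
}

#' Classify points into maze zones
#'
#' Assigns each 2D point one of the labels `DECISION`, `ARM_LEFT`,
#' `ARM_RIGHT`, `HOLDING` or `OUTSIDE`. Any point within the decision-zone
#' radius of the centre is `DECISION`; arm and holding membership is decided
#' by the channel rectangles extending from the centre; overlaps are broken
#' in the order DECISION > ARM > HOLDING. The classification is total:
#' unclassifiable points are `OUTSIDE`.
#'
#' @param x,y Coordinates in cm (vectors of equal length).
#' @param geom A [maze_geometry()].
#' @return A character vector of zone labels (one of [zone_levels]).
#' @export
classify_zone <- function(x, y, geom) {
  stopifnot(inherits(geom, "maze_geometry"), length(x) == length(y))
  r <- sqrt(x^2 + y^2)
  reach <- geom$zone_radius + geom$arm_length
  hw <- geom$arm_width / 2
  out <- rep("OUTSIDE", length(x))
  out[.channel_member(x, y, geom$holding_axis, 0,
                      geom$zone_radius + geom$holding_length, hw)] <- "HOLDING"
  out[.channel_member(x, y, geom$arm_axis_left, 0, reach, hw)] <- "ARM_LEFT"
  out[.channel_member(x, y, geom$arm_axis_right, 0, reach, hw)] <- "ARM_RIGHT"
  out[r <= geom$zone_radius] <- "DECISION"
  out
}

#' First decision-zone-to-arm crossing of a trajectory
#'
#' Scans a time-ordered track for the first frame at which the fish's
#' position passes from the decision zone into one of the destination arms.
#' Later re-entries are ignored (a single choice is scored per trial).
#'
#' @param track A data frame with columns `t`, `x`, `y`, sorted by `t`.
#' @param geom A [maze_geometry()].
#' @return A list with `arm` (`"ARM_LEFT"` or `"ARM_RIGHT"`) and `frame`
#'   (row index of the first in-arm frame), or `NULL` if the track never
#'   crosses from the zone into an arm.
#' @export
arm_entrance_crossing <- function(track, geom) {
  stopifnot(is.data.frame(track), all(c("t", "x", "y") %in% names(track)))
  if (nrow(track) == 0) {
    stop("empty track: no frames to classify", call. = FALSE)
  }
  if (is.unsorted(track$t, strictly = FALSE)) {
    stop("track must be sorted by time", call. = FALSE)
  }
  z <- classify_zone(track$x, track$y, geom)
  if (length(z) < 2) return(NULL)
  hit <- which(z[-length(z)] == "DECISION" &
                 z[-1] %in% c("ARM_LEFT", "ARM_RIGHT"))
  if (length(hit) == 0) return(NULL)
  i <- hit[1] + 1L
  list(arm = z[i], frame = i)
}

#' Point at which an arm meets the decision zone
#'
#' @param arm `"ARM_LEFT"` or `"ARM_RIGHT"`.
#' @param geom A [maze_geometry()].
#' @return Length-2 numeric, cm.
#' @export
arm_entrance_point <- function(arm, geom) {
  axis <- switch(arm,
    ARM_LEFT = geom$arm_axis_left,
    ARM_RIGHT = geom$arm_axis_right,
    stop("arm must be ARM_LEFT or ARM_RIGHT", call. = FALSE)
  )
  axis * geom$zone_radius
}
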