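#' The 25-landmark skeletal hand model
#'
#' The hand is represented by 25 named landmarks: four thumb joints
#' (CMC, MCP, IP, TIP), five per remaining finger (BASE, MCP, PIP, DIP,
#' TIP for index, middle, ring and pinky) and the palm center. The order
#' returned here (thumb to pinky, proximal to distal, palm last) is the
#' canonical serialization order used throughout the package.
#'
#' @return Character vector of the 25 landmark identifiers, in canonical
#'   order.
#' @examples
#' joint_ids()
#' @export
joint_ids <- function() .JOINT_IDS

.FINGERS <- list(
  thumb  = paste0("THUMB_", c("CMC", "MCP", "IP", "TIP")),
  index  = paste0("INDEX_", c("BASE", "MCP", "PIP", "DIP", "TIP")),
  middle = paste0("MIDDLE_", c("BASE", "MCP", "PIP", "DIP", "TIP")),
  ring   = paste0("RING_", c("BASE", "MCP", "PIP", "DIP", "TIP")),
  pinky  = paste0("PINKY_", c("BASE", "MCP", "PIP", "DIP", "TIP"))
)

.JOINT_IDS <- c(unlist(.FINGERS, use.names = FALSE), "PALM_CENTER")

#' Finger membership of each landmark
#'
#' @return Named character vector mapping each of the 25 landmark ids to
#'   its digit (`"thumb"`, `"index"`, `"middle"`, `"ring"`, `"pinky"`) or
#'   `"palm"` for the palm center.
#' @examples
#' table(joint_fingers())
#' @export
joint_fingers <- function() {
  f <- rep(names(.FINGERS), times = lengths(.FINGERS))
  names(f) <- unlist(.FINGERS, use.names = FALSE)
  c(f, PALM_CENTER = "palm")[.JOINT_IDS]
}

.SOURCES <- c("vertical", "horizontal", "fused", "truth")
.HANDEDNESS <- c("left", "right")
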