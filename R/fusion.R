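#' Fusion configuration
#'
#' Parameters of the two sensor-fusion strategies. The binary switch
#' activates the horizontal sensor whenever the palm-normal projection
#' angle falls inside one of two closed windows -- by default
#' \[45, 135\] degrees (palm facing up) and \[225, 315\] degrees (palm
#' facing down) -- and the vertical sensor otherwise. The joint-wise
#' switch compares per-joint frame-to-frame speeds between the sensors
#' and moves a joint to the other sensor when the active sensor's joint
#' moves more than `switch_margin` times faster (slower-tracked motion
#' is taken as the more robust datum).
#'
#' @param strategy `"binary_switch"` or `"jointwise_switch"`.
#' @param windows_horizontal List of two closed angle intervals
#'   (degrees, within \[0, 360)) in which the horizontal sensor is
#'   active under the binary switch.
#' @param projection_epsilon Minimum XY-projection norm of the palm
#'   normal below which the projection angle is undefined.
#' @param initial_sensor Sensor assumed active at stream start and held
#'   while the angle is undefined.
#' @param switch_margin Speed-ratio margin kappa (>= 1) of the
#'   joint-wise switch; ties and within-margin cases keep the current
#'   sensor.
#' @param pairing_tolerance_ms Maximum timestamp difference when pairing
#'   records of the two streams (default half the nominal 25 ms frame
#'   interval at 40 fps).
#' @param angle_tolerance_deg Numerical slack at the window boundaries:
#'   an angle within this distance of a closed boundary counts as
#'   inside. The default (1e-9 degrees) is far below sensor resolution
#'   and only guards boundary membership against floating-point
#'   round-off in angles recomputed from unit normals.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(strategy = c("binary_switch", "jointwise_switch"),
                          windows_horizontal = list(c(45, 135), c(225, 315)),
                          projection_epsilon = 1e-6,
                          initial_sensor = "horizontal",
                          switch_margin = 1,
                          pairing_tolerance_ms = 12.5,
                          angle_tolerance_deg = 1e-9) {
  strategy <- match.arg(strategy)
  for (w in windows_horizontal) {
    if (length(w) != 2L || any(w < 0) || any(w >= 360) || w[1] > w[2])
      stop("each horizontal window must be an interval within [0, 360)")
  }
  if (switch_margin < 1) stop("switch_margin must be >= 1")
  if (!initial_sensor %in% c("vertical", "horizontal"))
    stop("initial_sensor must be 'vertical' or 'horizontal'")
  structure(list(strategy = strategy,
                 windows_horizontal = windows_horizontal,
                 projection_epsilon = projection_epsilon,
                 initial_sensor = initial_sensor,
                 switch_margin = switch_margin,
                 pairing_tolerance_ms = pairing_tolerance_ms,
                 angle_tolerance_deg = angle_tolerance_deg),
            class = "fusion_config")
}

#' Palm-normal projection angle
#'
#' Counterclockwise angle, in degrees within \[0, 360), between the
#' X-axis of the horizontal sensor's reference system and the projection
#' of the palm normal onto its X-Y plane. The angle is undefined
#' (`NA`) when the projection norm falls below `epsilon` (palm normal
#' nearly parallel to the Z-axis).
#'
#' @param normal Unit 3-vector (checked to within 1e-6).
#' @param epsilon Minimum XY-projection norm; see [fusion_config()].
#' @return Angle in degrees, or `NA_real_` when undefined.
#' @export
palm_projection_angle <- function(normal, epsilon = 1e-6) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || abs(sqrt(sum(normal^2)) - 1) > 1e-6)
    stop("palm normal must be a unit 3-vector")
  h <- sqrt(normal[1]^2 + normal[2]^2)
  if (h < epsilon) return(NA_real_)
  (atan2(normal[2], normal[1]) * 180 / pi) %% 360
}

#' Binary-switch sensor selection
#'
#' Selects the horizontal sensor iff the palm-normal projection angle
#' lies in one of the configured closed windows (default palm-up
#' \[45, 135\] or palm-down \[225, 315\] degrees); the vertical sensor
#' otherwise. When the angle is undefined the previous decision is held
#' (or the configured initial sensor at stream start). The test is
#' memoryless for defined angles: no hysteresis.
#'
#' @param angle Projection angle in degrees, or `NA` when undefined.
#' @param previous Previously active sensor, or `NULL` at stream start.
#' @param config A [fusion_config()].
#' @return `"horizontal"` or `"vertical"`.
#' @export
binary_switch_select <- function(angle, previous = NULL,
                                 config = fusion_config()) {
  if (is.na(angle)) {
    if (!is.null(previous)) return(previous)
    return(config$initial_sensor)
  }
  tol <- config$angle_tolerance_deg
  for (w in config$windows_horizontal)
    if (angle >= w[1] - tol && angle <= w[2] + tol) return("horizontal")
  "vertical"
}

# per-joint euclidean frame-to-frame distances for a landmarks pair
.joint_displacements <- function(lm_t, lm_prev) {
  sqrt(rowSums((lm_t - lm_prev)^2))
}

#' Joint-wise sensor selection for one frame transition
#'
#' For each of the 25 joints, intra-sensor speeds
#' `v_s = ||p_s(t) - p_s(t-1)|| / dt` are computed for both sensors (in
#' the common reference frame). A joint currently assigned to the active
#' sensor switches to the other sensor iff
#' `v_active > kappa * v_other`; ties and within-margin cases keep the
#' current assignment.
#'
#' @param vertical_t,vertical_prev,horizontal_t,horizontal_prev
#'   [hand_frame()]s at `t` and `t-1`, vertical already mapped into the
#'   horizontal (reference) frame.
#' @param active Named character vector over [joint_ids()] giving the
#'   currently active sensor per joint.
#' @param dt_ms Positive time step in milliseconds.
#' @param config A [fusion_config()].
#' @return Named character vector: the updated active sensor per joint.
#' @export
jointwise_select <- function(vertical_t, vertical_prev,
                             horizontal_t, horizontal_prev,
                             active, dt_ms, config = fusion_config()) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  v_v <- .joint_displacements(vertical_t$landmarks, vertical_prev$landmarks) / dt_ms
  v_h <- .joint_displacements(horizontal_t$landmarks, horizontal_prev$landmarks) / dt_ms
  k <- config$switch_margin
  out <- active
  for (j in .JOINT_IDS) {
    va <- if (active[[j]] == "vertical") v_v[[j]] else v_h[[j]]
    vo <- if (active[[j]] == "vertical") v_h[[j]] else v_v[[j]]
    if (va > k * vo)
      out[[j]] <- if (active[[j]] == "vertical") "horizontal" else "vertical"
  }
  out
}

#' Intra- and inter-sensor joint speeds for one frame transition
#'
#' Diagnostic companion to the joint-wise switch: per joint, the
#' frame-to-frame speed within each sensor and the inter-sensor speed
#' `||p_other(t) - p_active(t-1)|| / dt` for each sensor taken as
#' active.
#'
#' @inheritParams jointwise_select
#' @return Data frame with one row per joint and columns
#'   `intra_vertical`, `intra_horizontal`, `inter_from_vertical`,
#'   `inter_from_horizontal` (mm/ms).
#' @export
speed_metrics <- function(vertical_t, vertical_prev,
                          horizontal_t, horizontal_prev, dt_ms) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  data.frame(
    joint = .JOINT_IDS,
    intra_vertical =
      .joint_displacements(vertical_t$landmarks, vertical_prev$landmarks) / dt_ms,
    intra_horizontal =
      .joint_displacements(horizontal_t$landmarks, horizontal_prev$landmarks) / dt_ms,
    inter_from_vertical =
      .joint_displacements(horizontal_t$landmarks, vertical_prev$landmarks) / dt_ms,
    inter_from_horizontal =
      .joint_displacements(vertical_t$landmarks, horizontal_prev$landmarks) / dt_ms,
    row.names = NULL)
}

# nearest-timestamp pairing of two sorted timestamp vectors, injective,
# within tol; returns 2-column index matrix
.pair_timestamps <- function(tv, th, tol) {
  i <- 1L; j <- 1L
  out <- matrix(integer(0), ncol = 2L)
  while (i <= length(tv) && j <= length(th)) {
    d <- tv[i] - th[j]
    if (abs(d) <= tol) {
      # candidate match; prefer a closer later record on either side
      if (i < length(tv) && abs(tv[i + 1L] - th[j]) < abs(d)) {
        i <- i + 1L; next
      }
      if (j < length(th) && abs(tv[i] - th[j + 1L]) < abs(d)) {
        j <- j + 1L; next
      }
      out <- rbind(out, c(i, j))
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  out
}

#' Fuse the two sensor streams into the three-model session stream
#'
#' The vertical stream is first mapped into the horizontal (reference)
#' frame through the calibration transform, records are paired by
#' nearest timestamp within `pairing_tolerance_ms` (unmatched records
#' are dropped), and the configured strategy then selects, per frame
#' (binary switch) or per joint (joint-wise switch), which sensor's data
#' feed the fused model. Both strategies are switches, never blends:
#' every fused landmark is bit-identical to one source model's landmark.
#' Output records carry all three models -- `vertical` (transformed),
#' `horizontal` and `fused` -- and the per-record decisions are attached
#' (retrievable via [fusion_decisions()]).
#'
#' Under the binary switch the palm-normal projection angle is computed
#' from the horizontal (reference) sensor's reported normal.
#'
#' @param vertical,horizontal Valid [session_stream()]s.
#' @param transform [rigid_transform()] mapping vertical-sensor
#'   coordinates into the horizontal frame.
#' @param config A [fusion_config()].
#' @return A [session_stream()] whose records hold the three models;
#'   the header is the horizontal stream's. The fusion is a pure
#'   function of its arguments.
#' @export
fuse_streams <- function(vertical, horizontal, transform,
                         config = fusion_config()) {
  stopifnot(inherits(vertical, "session_stream"),
            inherits(horizontal, "session_stream"))
  if (!inherits(transform, "rigid_transform"))
    stop("missing calibration: transform must be a rigid_transform")
  vertical <- apply_transform(transform, vertical)
  tv <- .timestamps(vertical); th <- .timestamps(horizontal)
  pairs <- .pair_timestamps(tv, th, config$pairing_tolerance_ms)
  if (!nrow(pairs))
    stop("no overlapping records between the two streams within ",
         config$pairing_tolerance_ms, " ms")

  records <- vector("list", nrow(pairs))
  decisions <- vector("list", nrow(pairs))
  previous <- NULL
  active <- stats::setNames(rep(config$initial_sensor, 25L), .JOINT_IDS)
  prev_vf <- NULL; prev_hf <- NULL; prev_t <- NULL

  for (k in seq_len(nrow(pairs))) {
    vf <- vertical$records[[pairs[k, 1L]]]$models[["vertical"]]
    hf <- horizontal$records[[pairs[k, 2L]]]$models[["horizontal"]]
    if (is.null(vf) || is.null(hf))
      stop("input streams must carry their own sensor model in every record")
    t <- th[pairs[k, 2L]]                  # reference timestamps
    vf$timestamp <- t; hf$timestamp <- t

    if (config$strategy == "binary_switch") {
      angle <- palm_projection_angle(hf$palm_normal, config$projection_epsilon)
      sel <- binary_switch_select(angle, previous, config)
      previous <- sel
      fused <- if (sel == "vertical") vf else hf
      fused$source <- "fused"; fused$reliability <- NULL
      decisions[[k]] <- list(timestamp = t, strategy = "binary_switch",
                             angle = angle, active = sel)
    } else {
      if (k > 1L)
        active <- jointwise_select(vf, prev_vf, hf, prev_hf,
                                   active, t - prev_t, config)
      lm <- hf$landmarks
      vj <- active == "vertical"
      lm[vj, ] <- vf$landmarks[vj, ]
      fused <- hand_frame(t, lm, hf$palm_normal,
                          handedness = hf$handedness, source = "fused")
      decisions[[k]] <- list(timestamp = t, strategy = "jointwise_switch",
                             active = active)
      prev_vf <- vf; prev_hf <- hf; prev_t <- t
    }
    records[[k]] <- frame_record(t, list(vertical = vf, horizontal = hf,
                                         fused = fused))
  }
  out <- session_stream(horizontal$header, records)
  attr(out, "decisions") <- decisions
  out
}

#' Fusion decision log of a fused stream
#'
#' @param stream A stream returned by [fuse_streams()].
#' @return List with one entry per record: timestamp, strategy, the
#'   projection angle (binary switch) and the active sensor (per frame)
#'   or per-joint active map (joint-wise).
#' @export
fusion_decisions <- function(stream) attr(stream, "decisions")
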