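#' Canonical right-hand geometry
#'
#' Representative adult landmark offsets (mm) in the canonical pose:
#' palm center at the origin, palm normal along +X, fingers extending
#' along +Y, the mediolateral axis along Z. Segment lengths are in the
#' anatomical 20-90 mm range; realism beyond landmark topology is not
#' attempted -- the pipeline is geometry-agnostic.
#'
#' @return 25 x 3 matrix with [joint_ids()] rownames.
#' @export
canonical_hand <- function() {
  m <- rbind(
    THUMB_CMC   = c(0,   5,  40),
    THUMB_MCP   = c(0,  35,  52),
    THUMB_IP    = c(0,  55,  60),
    THUMB_TIP   = c(0,  70,  66),
    INDEX_BASE  = c(0,  10,  25),
    INDEX_MCP   = c(0,  55,  25),
    INDEX_PIP   = c(0,  85,  25),
    INDEX_DIP   = c(0, 105,  25),
    INDEX_TIP   = c(0, 125,  25),
    MIDDLE_BASE = c(0,  10,   8),
    MIDDLE_MCP  = c(0,  58,   8),
    MIDDLE_PIP  = c(0,  90,   8),
    MIDDLE_DIP  = c(0, 111,   8),
    MIDDLE_TIP  = c(0, 132,   8),
    RING_BASE   = c(0,  10,  -8),
    RING_MCP    = c(0,  55,  -8),
    RING_PIP    = c(0,  86,  -8),
    RING_DIP    = c(0, 106,  -8),
    RING_TIP    = c(0, 124,  -8),
    PINKY_BASE  = c(0,  10, -25),
    PINKY_MCP   = c(0,  48, -25),
    PINKY_PIP   = c(0,  73, -25),
    PINKY_DIP   = c(0,  89, -25),
    PINKY_TIP   = c(0, 103, -25),
    PALM_CENTER = c(0,   0,   0))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Parametric hand-motion model
#'
#' Ground-truth generator: each finger flexes rigidly about its pivot
#' joint (BASE; CMC for the thumb) by a sinusoidal angle
#' `A sin(2 pi f t + phase)`, and the whole hand follows a global
#' palm-orientation trajectory theta(t) (rotation about the Z axis, so
#' theta is exactly the palm-normal projection angle) plus a constant
#' translation. Because flexion is a rigid rotation, every joint's
#' analytic speed is `2 pi f A r` at the peak, with `r` its distance
#' from the pivot -- the oracle used by the kinematics tests.
#'
#' @param flexion Named list per finger (`thumb`, `index`, `middle`,
#'   `ring`, `pinky`), each `list(amplitude_deg, frequency_hz, phase)`.
#'   Missing fingers stay static.
#' @param orientation Palm-normal angle profile: `list(type =
#'   "constant", value_deg = )`, `list(type = "sweep", from_deg = ,
#'   to_deg = )` (linear over the session) or `list(type = "sine",
#'   center_deg = , amplitude_deg = , frequency_hz = )`.
#' @param translation Constant hand position offset (mm) in the
#'   reference frame.
#' @param handedness `"right"` (default) or `"left"` (mirrored).
#' @return An object of class `hand_pose_model`.
#' @export
hand_pose_model <- function(flexion = list(index = list(amplitude_deg = 40,
                                                        frequency_hz = 1,
                                                        phase = 0)),
                            orientation = list(type = "constant",
                                               value_deg = 270),
                            translation = c(0, 200, 0),
                            handedness = "right") {
  for (f in flexion) {
    if (f$frequency_hz < 0) stop("flexion frequency must be >= 0")
    if (f$amplitude_deg < 0) stop("flexion amplitude must be >= 0")
  }
  geom <- canonical_hand()
  segs <- diff(geom[c("INDEX_BASE", "INDEX_MCP", "INDEX_PIP",
                      "INDEX_DIP", "INDEX_TIP"), 2])
  stopifnot(all(segs > 0))                # anatomically ordered geometry
  structure(list(geometry = geom, flexion = flexion,
                 orientation = orientation,
                 translation = as.numeric(translation),
                 handedness = handedness),
            class = "hand_pose_model")
}

.PIVOTS <- c(thumb = "THUMB_CMC", index = "INDEX_BASE",
             middle = "MIDDLE_BASE", ring = "RING_BASE",
             pinky = "PINKY_BASE")

.orientation_angle <- function(profile, t_s, duration_s) {
  switch(profile$type,
         constant = rep(profile$value_deg, length(t_s)),
         sweep = profile$from_deg + (profile$to_deg - profile$from_deg) *
           t_s / duration_s,
         sine = profile$center_deg + profile$amplitude_deg *
           sin(2 * pi * profile$frequency_hz * t_s),
         stop("unknown orientation profile type: ", profile$type))
}

.rz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate a ground-truth session stream
#'
#' Evaluates a [hand_pose_model()] at `duration * fps` uniformly spaced
#' instants and returns a stream with a single `"truth"` model per
#' record. The generator is deterministic (the `seed` argument is
#' accepted for interface uniformity with the observation stage but no
#' randomness is used). The analytic per-joint speed profile (peak and
#' mean speed, valid for constant-orientation sessions) is attached as
#' attribute `"analytic"` for use as a test oracle.
#'
#' @param pose A [hand_pose_model()].
#' @param duration_s Session length in seconds.
#' @param fps Frame rate, default 40 (25 ms steps).
#' @param seed Unused; kept for a uniform generator interface.
#' @param header Optional [session_header()]; a simulator default is
#'   built when omitted.
#' @return A [session_stream()] with `attr(, "analytic")`.
#' @export
generate_ground_truth <- function(pose, duration_s, fps = 40, seed = NULL,
                                  header = NULL) {
  stopifnot(inherits(pose, "hand_pose_model"), duration_s > 0, fps > 0)
  n <- round(duration_s * fps)
  t_ms <- (seq_len(n) - 1L) * 1000 / fps
  t_s <- t_ms / 1000
  theta <- .orientation_angle(pose$orientation, t_s, duration_s)
  if (is.null(header))
    header <- session_header("sim-patient", "sim-therapist", "sim-rig",
                             task = list(type = "simulated", difficulty = 1,
                                         duration = duration_s,
                                         repetitions = 1,
                                         start_date = "2023-03-25"))
  geom <- pose$geometry
  records <- vector("list", n)
  for (i in seq_len(n)) {
    lm <- geom
    for (fn in names(pose$flexion)) {
      f <- pose$flexion[[fn]]
      phi <- f$amplitude_deg * pi / 180 *
        sin(2 * pi * f$frequency_hz * t_s[i] + (f$phase %||% 0))
      pivot <- geom[.PIVOTS[[fn]], ]
      moving <- setdiff(.FINGERS[[fn]], .PIVOTS[[fn]])
      rel <- sweep(geom[moving, , drop = FALSE], 2L, pivot)
      rot <- rel
      rot[, 1] <- rel[, 1] * cos(phi) - rel[, 2] * sin(phi)
      rot[, 2] <- rel[, 1] * sin(phi) + rel[, 2] * cos(phi)
      lm[moving, ] <- sweep(rot, 2L, pivot, `+`)
    }
    Rz <- .rz(theta[i])
    lm <- sweep(lm %*% t(Rz), 2L, pose$translation, `+`)
    rownames(lm) <- rownames(geom)
    normal <- as.numeric(Rz %*% c(1, 0, 0))
    frame <- hand_frame(t_ms[i], lm, normal,
                        handedness = "right", source = "truth")
    if (pose$handedness == "left") frame <- mirror_frame(frame)
    records[[i]] <- frame_record(t_ms[i], list(truth = frame))
  }
  out <- session_stream(header, records)
  attr(out, "analytic") <- .analytic_speeds(pose)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic per-joint speed profile for rigid sinusoidal flexion
.analytic_speeds <- function(pose) {
  geom <- pose$geometry
  radius <- stats::setNames(rep(0, 25L), .JOINT_IDS)
  peak <- radius
  for (fn in names(pose$flexion)) {
    f <- pose$flexion[[fn]]
    pivot <- geom[.PIVOTS[[fn]], ]
    moving <- setdiff(.FINGERS[[fn]], .PIVOTS[[fn]])
    r <- sqrt(rowSums(sweep(geom[moving, c(1, 2), drop = FALSE], 2L,
                            pivot[c(1, 2)])^2))
    radius[moving] <- r
    peak[moving] <- 2 * pi * f$frequency_hz * (f$amplitude_deg * pi / 180) * r
  }
  data.frame(joint = .JOINT_IDS,
             radius_mm = radius,
             peak_speed_mm_s = peak,
             mean_speed_mm_s = peak * 2 / pi,
             orientation_constant = pose$orientation$type == "constant",
             row.names = NULL)
}

#' Sensor observation model
#'
#' One tracking sensor: a pose (rigid transform from the reference/world
#' frame into the sensor frame), i.i.d. Gaussian position noise, and an
#' occlusion rule -- when the palm normal comes within `alpha_occ_deg`
#' of perpendicular to the sensor's viewing axis the per-joint jitter
#' inflates to `sigma_occ_mm` and each joint freezes (holds its last
#' value, as real trackers repeat stale estimates) with probability
#' `p_drop`. Occlusion defaults (30 degrees, 10x jitter, 0.2 dropout)
#' are free parameters chosen to make fusion benefits visible at desk
#' scale; the hardware this emulates publishes no such magnitudes.
#'
#' @param id `"vertical"` or `"horizontal"`.
#' @param pose [rigid_transform()] world -> sensor frame.
#' @param view_axis Unit vector (world frame) the sensor looks along.
#' @param sigma_mm Baseline additive noise SD per axis (mm).
#' @param fps Nominal frame rate (default 40).
#' @param alpha_occ_deg Occlusion half-width around perpendicularity.
#' @param sigma_occ_mm Occluded-frame jitter SD (mm).
#' @param p_drop Per-joint hold-last-value probability on occluded
#'   frames, in \[0, 1\].
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(id, pose = rigid_transform(),
                         view_axis = c(0, 1, 0),
                         sigma_mm = 0.5, fps = 40,
                         alpha_occ_deg = 30, sigma_occ_mm = 10 * sigma_mm,
                         p_drop = 0.2) {
  stopifnot(sigma_mm >= 0, sigma_occ_mm >= 0, p_drop >= 0, p_drop <= 1)
  view_axis <- as.numeric(view_axis)
  view_axis <- view_axis / sqrt(sum(view_axis^2))
  structure(list(id = id, pose = pose, view_axis = view_axis,
                 sigma_mm = sigma_mm, fps = fps,
                 alpha_occ_deg = alpha_occ_deg,
                 sigma_occ_mm = sigma_occ_mm, p_drop = p_drop),
            class = "sensor_model")
}

#' Observe a ground-truth stream through a sensor
#'
#' Maps the truth into the sensor frame via the sensor pose, adds
#' Gaussian noise (inflated on occluded frames), applies hold-last-value
#' dropouts on occluded frames, and emits per-joint reliability scores
#' (0.95 normally, 0.4 while occluded). Deterministic given `seed`.
#'
#' @param truth Stream from [generate_ground_truth()].
#' @param sensor A [sensor_model()].
#' @param seed Integer RNG seed.
#' @return A [session_stream()] whose records hold one model named after
#'   `sensor$id`; occlusion flags per record are attached as attribute
#'   `"occluded"`.
#' @export
observe <- function(truth, sensor, seed = 1L) {
  stopifnot(inherits(truth, "session_stream"), inherits(sensor, "sensor_model"))
  set.seed(seed)
  n <- length(truth$records)
  records <- vector("list", n)
  occluded <- logical(n)
  prev_lm <- NULL
  for (i in seq_len(n)) {
    tf <- truth$records[[i]]$models[["truth"]]
    if (is.null(tf)) stop("truth stream must carry a 'truth' model")
    nw <- tf$palm_normal
    ang <- acos(pmin(1, pmax(-1, sum(nw * sensor$view_axis)))) * 180 / pi
    occ <- abs(ang - 90) < sensor$alpha_occ_deg
    occluded[i] <- occ
    obs <- apply_transform(sensor$pose, tf)
    sd <- if (occ) sensor$sigma_occ_mm else sensor$sigma_mm
    lm <- obs$landmarks + matrix(stats::rnorm(75L, sd = sd), 25L, 3L)
    if (occ && sensor$p_drop > 0 && !is.null(prev_lm)) {
      drop <- stats::runif(25L) < sensor$p_drop
      lm[drop, ] <- prev_lm[drop, ]
    }
    rownames(lm) <- rownames(obs$landmarks)
    rel <- stats::setNames(rep(if (occ) 0.4 else 0.95, 25L), .JOINT_IDS)
    frame <- hand_frame(tf$timestamp, lm, obs$palm_normal,
                        handedness = tf$handedness, source = sensor$id,
                        reliability = rel)
    records[[i]] <- frame_record(tf$timestamp,
                                 stats::setNames(list(frame), sensor$id))
    prev_lm <- lm
  }
  hdr <- truth$header
  hdr$device_id <- paste0(hdr$device_id, "-", sensor$id)
  out <- session_stream(hdr, records)
  attr(out, "occluded") <- occluded
  out
}

#' Default orthogonal two-sensor rig
#'
#' The horizontal sensor defines the reference frame (identity pose,
#' looking along +Y, i.e. up at the hand); the vertical sensor is
#' mounted orthogonally, looking along +X, with its own rotated and
#' translated frame. The returned `calibration` element is the true
#' vertical -> horizontal transform a calibration should recover.
#'
#' @param sigma_mm Baseline noise SD for both sensors.
#' @param ... Further arguments passed to both [sensor_model()] calls.
#' @return List with `vertical`, `horizontal` ([sensor_model()]s) and
#'   `calibration` (the true [rigid_transform()]).
#' @export
default_sensor_rig <- function(sigma_mm = 0.5, ...) {
  # vertical sensor frame: world rotated -90 deg about Z then offset
  pose_v <- rigid_transform(.rz(-90), c(40, -260, 15))
  list(vertical = sensor_model("vertical", pose = pose_v,
                               view_axis = c(1, 0, 0),
                               sigma_mm = sigma_mm, ...),
       horizontal = sensor_model("horizontal",
                                 view_axis = c(0, 1, 0),
                                 sigma_mm = sigma_mm, ...),
       calibration = invert_transform(pose_v))
}

#' Synthesize a calibration point cloud
#'
#' Emulates the stick-on-a-mill protocol: `n` positions drawn uniformly
#' in the shared working volume are measured by sensor A directly and by
#' sensor B as `T(a) + noise`.
#'
#' @param true_transform The [rigid_transform()] from A to B.
#' @param n Number of stick positions (>= 3).
#' @param sigma_mm Measurement noise SD per axis (mm).
#' @param seed Integer RNG seed.
#' @param box Half-width of the sampling cube (mm).
#' @return A [calibration_cloud()]; deterministic given `seed`.
#' @export
make_calibration_cloud <- function(true_transform, n, sigma_mm = 0,
                                   seed = 1L, box = 150) {
  if (n < 3L) stop("need at least 3 stick positions")
  set.seed(seed)
  a <- matrix(stats::runif(n * 3L, -box, box), ncol = 3L)
  b <- transform_points(true_transform, a) +
    matrix(stats::rnorm(n * 3L, sd = sigma_mm), ncol = 3L)
  calibration_cloud(a, b)
}

#' Rehabilitation task specification
#'
#' A virtual-keyboard style task: targets light up on a schedule and
#' must be touched by a designated joint while lit.
#'
#' @param type Task name.
#' @param difficulty Difficulty level.
#' @param duration_s Task duration per repetition in seconds (> 0).
#' @param repetitions Number of repetitions (>= 1).
#' @param radius_mm Activation radius around each target (> 0).
#' @param targets Data frame with columns `x`, `y`, `z` (mm), `joint`
#'   (designated landmark id), `lit_from_ms`, `lit_until_ms`; may be
#'   empty.
#' @param start_date Session start date.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(type = "virtual_keyboard", difficulty = 1,
                      duration_s = 30, repetitions = 1, radius_mm = 15,
                      targets = NULL, start_date = "2023-03-25") {
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (is.null(targets))
    targets <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          joint = character(), lit_from_ms = numeric(),
                          lit_until_ms = numeric())
  structure(list(type = type, difficulty = difficulty,
                 duration_s = duration_s, repetitions = repetitions,
                 radius_mm = radius_mm, targets = targets,
                 start_date = as.character(start_date)),
            class = "task_spec")
}

#' Score a stream against a toy task
#'
#' A target counts as hit when its designated joint enters the
#' activation radius while the target is lit; each target scores at most
#' once. The score is the hit count.
#'
#' @param stream A [session_stream()] carrying the chosen model.
#' @param task A [task_spec()].
#' @param model Model to score against, default `"fused"`.
#' @return List with `score` (hit count) and `events` (data frame of hit
#'   timestamps and target indices).
#' @export
run_toy_task <- function(stream, task, model = "fused") {
  stopifnot(inherits(task, "task_spec"))
  tg <- task$targets
  events <- data.frame(t_ms = numeric(), target = integer())
  if (nrow(tg)) {
    t_ms <- .timestamps(stream)
    for (k in seq_len(nrow(tg))) {
      P <- .joint_track(stream, model, tg$joint[k])
      d <- sqrt(rowSums(sweep(P, 2L, c(tg$x[k], tg$y[k], tg$z[k]))^2))
      lit <- t_ms >= tg$lit_from_ms[k] & t_ms <= tg$lit_until_ms[k]
      hit <- which(lit & d <= task$radius_mm)
      if (length(hit))
        events <- rbind(events,
                        data.frame(t_ms = t_ms[hit[1L]], target = k))
    }
  }
  list(score = nrow(events), events = events)
}

#' Run a headless rehabilitation session
#'
#' The session-lifecycle state machine on a simulated clock (tests run
#' instantly): INFO screen, hand detection, a pre-task countdown
#' (default ten seconds, letting the sensors lock onto the hand), the
#' RUNNING task phase, then -- while repetitions remain -- a REST phase
#' before the next countdown; finally a SUMMARY phase. One stream is
#' produced per repetition and scored against the task when targets are
#' defined.
#'
#' @param task A [task_spec()].
#' @param stream_provider Function `(repetition, duration_s)` returning
#'   the [session_stream()] recorded during that repetition's RUNNING
#'   phase.
#' @param countdown_s Pre-task countdown duration (seconds), default 10.
#' @param rest_s Rest-phase duration between repetitions (seconds).
#' @param info_s INFO-screen duration (seconds).
#' @param hand_detected Was a hand detected within the timeout? When
#'   `FALSE` the session aborts.
#' @param detect_timeout_s Detection timeout used for the aborted
#'   outcome's timing.
#' @param model Model scored by the toy task.
#' @return List with `status` (`"completed"` or `"aborted"`), `phases`
#'   (data frame: phase, repetition, start/end on the simulated clock),
#'   `streams` (one per repetition), `scores`, `total_score` and
#'   `countdown_s`.
#' @export
run_session <- function(task, stream_provider, countdown_s = 10,
                        rest_s = 15, info_s = 2, hand_detected = TRUE,
                        detect_timeout_s = 30, model = "fused") {
  stopifnot(inherits(task, "task_spec"), is.function(stream_provider))
  clock <- 0
  phases <- data.frame(phase = character(), repetition = integer(),
                       start_s = numeric(), end_s = numeric())
  push <- function(phase, rep, dur) {
    phases <<- rbind(phases, data.frame(phase = phase, repetition = rep,
                                        start_s = clock,
                                        end_s = clock + dur))
    clock <<- clock + dur
  }
  push("INFO", NA_integer_, info_s)
  if (!hand_detected) {
    push("ABORTED", NA_integer_, detect_timeout_s)
    return(list(status = "aborted", phases = phases, streams = list(),
                scores = numeric(), total_score = NA_real_,
                countdown_s = countdown_s))
  }
  push("HAND_DETECTED", NA_integer_, 0)
  streams <- vector("list", task$repetitions)
  scores <- numeric(task$repetitions)
  for (r in seq_len(task$repetitions)) {
    push("COUNTDOWN", r, countdown_s)
    streams[[r]] <- stream_provider(r, task$duration_s)
    push("RUNNING", r, task$duration_s)
    scores[r] <- if (nrow(task$targets))
      run_toy_task(streams[[r]], task, model)$score else NA_real_
    if (r < task$repetitions) push("REST", r, rest_s)
  }
  push("SUMMARY", NA_integer_, 0)
  list(status = "completed", phases = phases, streams = streams,
       scores = scores, total_score = sum(scores, na.rm = TRUE),
       countdown_s = countdown_s)
}
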