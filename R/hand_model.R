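#' Construct a single-instant skeletal hand frame
#'
#' A hand frame is one sensor's (or the fused) snapshot of the hand at
#' one time instant: 25 landmark positions in millimetres, the palm
#' normal (the unit vector orthogonal to the palm, used by the fusion
#' switch to infer hand orientation), handedness, and an optional
#' per-joint tracking-reliability score. Sensor-collected frames may
#' carry reliability scores; fused frames usually do not.
#'
#' @param timestamp Time of the frame in milliseconds.
#' @param landmarks Numeric 25 x 3 matrix of landmark positions (mm)
#'   whose rownames are the ids from [joint_ids()] (any order; rows are
#'   reordered canonically).
#' @param palm_normal Numeric length-3 unit vector orthogonal to the palm.
#' @param handedness `"left"` or `"right"`.
#' @param source Which model this frame belongs to: `"vertical"`,
#'   `"horizontal"`, `"fused"` or `"truth"` (simulator ground truth).
#' @param reliability Optional named numeric vector of per-joint scores
#'   in \[0, 1\]; `NA` marks joints without a score.
#' @return An object of class `hand_frame`.
#' @seealso [validate_frame()], [mirror_frame()]
#' @export
hand_frame <- function(timestamp, landmarks, palm_normal,
                       handedness = "right", source = "truth",
                       reliability = NULL) {
  stopifnot(is.numeric(timestamp), length(timestamp) == 1L)
  landmarks <- as.matrix(landmarks)
  if (is.null(rownames(landmarks)))
    stop("landmarks must have the 25 joint ids as rownames")
  missing <- setdiff(.JOINT_IDS, rownames(landmarks))
  if (length(missing))
    stop("landmarks missing joints: ", paste(missing, collapse = ", "))
  landmarks <- landmarks[.JOINT_IDS, , drop = FALSE]
  colnames(landmarks) <- c("x", "y", "z")
  if (!is.null(reliability)) {
    r <- rep(NA_real_, 25L)
    names(r) <- .JOINT_IDS
    r[names(reliability)] <- reliability
    reliability <- r
  }
  structure(
    list(timestamp = as.numeric(timestamp),
         source = source,
         handedness = handedness,
         palm_normal = as.numeric(palm_normal),
         landmarks = landmarks,
         reliability = reliability),
    class = "hand_frame")
}

#' Validate a hand frame against the data-model invariants
#'
#' Checks the structural invariants of the 25-landmark model: all 25
#' joints present with finite coordinates, a unit palm normal (within
#' 1e-9), a recognised source and handedness, and reliability scores in
#' \[0, 1\] where present. The validator reports; it never throws.
#'
#' @param frame A [hand_frame()].
#' @return Character vector of violations, empty when the frame is valid.
#'   Each entry names the offending field.
#' @export
validate_frame <- function(frame) {
  v <- character()
  if (!inherits(frame, "hand_frame"))
    return("frame: not a hand_frame object")
  lm <- frame$landmarks
  if (!is.matrix(lm) || ncol(lm) != 3L) {
    v <- c(v, "landmarks: not a 25 x 3 matrix")
  } else {
    missing <- setdiff(.JOINT_IDS, rownames(lm))
    for (m in missing) v <- c(v, paste0("landmarks: ", m, " absent"))
    extra <- setdiff(rownames(lm), .JOINT_IDS)
    for (m in extra) v <- c(v, paste0("landmarks: unknown joint ", m))
    if (!all(is.finite(lm)))
      v <- c(v, "landmarks: non-finite position component")
  }
  pn <- frame$palm_normal
  if (!is.numeric(pn) || length(pn) != 3L || !all(is.finite(pn))) {
    v <- c(v, "palm_normal: not a finite 3-vector")
  } else if (abs(sqrt(sum(pn^2)) - 1) > 1e-9) {
    v <- c(v, sprintf("palm_normal: norm %.6g is not 1 within 1e-9",
                      sqrt(sum(pn^2))))
  }
  if (!frame$source %in% .SOURCES)
    v <- c(v, paste0("source: unknown value ", frame$source))
  if (!frame$handedness %in% .HANDEDNESS)
    v <- c(v, paste0("handedness: unknown value ", frame$handedness))
  if (!is.null(frame$reliability)) {
    r <- frame$reliability[!is.na(frame$reliability)]
    if (length(r) && (any(r < 0) || any(r > 1)))
      v <- c(v, "reliability: score outside [0, 1]")
  }
  if (!is.numeric(frame$timestamp) || !is.finite(frame$timestamp))
    v <- c(v, "timestamp: not finite")
  v
}

#' Mirror a hand frame for user-facing presentation
#'
#' Raw sensor frames show the hand from the sensor's point of view, so a
#' right hand reads as a left hand. The mirror transformation flips the
#' presentation: by default the X coordinate of every landmark and of the
#' palm normal is negated (reflection across the Y-Z plane) and the
#' handedness label is swapped. The alternative reading -- reflection
#' about the X axis line, negating Y and Z instead -- is available via
#' `mode`.
#'
#' Mirroring is an involution and preserves all inter-landmark distances.
#'
#' @param frame A [hand_frame()].
#' @param mode `"negate_x"` (default) or `"about_x_axis"`.
#' @return The mirrored `hand_frame`; timestamp and source are preserved.
#' @export
mirror_frame <- function(frame, mode = c("negate_x", "about_x_axis")) {
  mode <- match.arg(mode)
  sgn <- if (mode == "negate_x") c(-1, 1, 1) else c(1, -1, -1)
  frame$landmarks <- sweep(frame$landmarks, 2L, sgn, `*`)
  frame$palm_normal <- frame$palm_normal * sgn
  frame$handedness <- if (frame$handedness == "right") "left" else "right"
  frame
}

#' @export
print.hand_frame <- function(x, ...) {
  cat(sprintf("<hand_frame> %s %s hand @ %g ms\n",
              x$source, x$handedness, x$timestamp))
  cat(sprintf("  palm normal: [%s]\n",
              paste(signif(x$palm_normal, 4), collapse = ", ")))
  cat(sprintf("  25 landmarks, bounding box %s mm\n",
              paste(signif(apply(x$landmarks, 2, function(c) diff(range(c))), 4),
                    collapse = " x ")))
  invisible(x)
}

#' Construct a session header
#'
#' The header of a session stream carries the person- and task-specific
#' information saved alongside the tracking data: who performed the
#' session, on which device, under which therapist, and the parameters
#' of the assigned task.
#'
#' @param patient_id,therapist_id,device_id Non-empty identifier strings.
#' @param task List with elements `type`, `difficulty`, `duration`
#'   (seconds, > 0), `repetitions` (>= 1), `start_date` (`"YYYY-MM-DD"`
#'   or Date); optional `params_id` (reference into the task-parameters
#'   collection) and `score`.
#' @param calibration_ref Identifier of the calibration transform in use.
#' @param schema_version Stream schema version string.
#' @return An object of class `session_header`.
#' @export
session_header <- function(patient_id, therapist_id, device_id,
                           task = list(type = "keyboard", difficulty = 1,
                                       duration = 60, repetitions = 1,
                                       start_date = "2023-03-25"),
                           calibration_ref = "uncalibrated",
                           schema_version = "1.0") {
  for (id in c(patient_id, therapist_id, device_id))
    if (!is.character(id) || !nzchar(id)) stop("header ids must be non-empty")
  if (is.null(task$duration) || task$duration <= 0)
    stop("task duration must be > 0")
  if (is.null(task$repetitions) || task$repetitions < 1)
    stop("task repetitions must be >= 1")
  task$start_date <- as.character(task$start_date)
  structure(
    list(patient_id = patient_id, therapist_id = therapist_id,
         device_id = device_id, task = task,
         calibration_ref = calibration_ref,
         schema_version = schema_version),
    class = "session_header")
}

#' Bundle the hand models observed at one time instant
#'
#' Each stored record carries up to three hand models for the instant:
#' one from the vertical sensor, one from the horizontal sensor, and one
#' produced by their fusion. Before fusion the fused model may be absent;
#' simulator ground truth uses a single `"truth"` model.
#'
#' @param timestamp Record time in milliseconds; all contained frames
#'   must share it.
#' @param models Named list of [hand_frame()]s keyed by source.
#' @return An object of class `frame_record`.
#' @export
frame_record <- function(timestamp, models) {
  if (!length(models) || is.null(names(models)))
    stop("models must be a non-empty named list")
  bad <- setdiff(names(models), .SOURCES)
  if (length(bad)) stop("unknown model source: ", paste(bad, collapse = ", "))
  for (m in models)
    if (abs(m$timestamp - timestamp) > 1e-9)
      stop("contained hand frame timestamp disagrees with record timestamp")
  structure(list(timestamp = as.numeric(timestamp), models = models),
            class = "frame_record")
}

#' Construct a session stream
#'
#' A session stream is the streaming file in memory: a header followed by
#' the ordered per-instant records. Record timestamps must be strictly
#' increasing.
#'
#' @param header A [session_header()].
#' @param records List of [frame_record()]s in time order.
#' @return An object of class `session_stream`.
#' @export
session_stream <- function(header, records = list()) {
  if (!inherits(header, "session_header")) stop("header must be a session_header")
  ts <- vapply(records, `[[`, numeric(1), "timestamp")
  if (length(ts) > 1L && any(diff(ts) <= 0))
    stop("record timestamps must be strictly increasing")
  structure(list(header = header, records = records),
            class = "session_stream")
}

#' @export
print.session_stream <- function(x, ...) {
  n <- length(x$records)
  cat(sprintf("<session_stream> patient %s, task %s: %d records\n",
              x$header$patient_id, x$header$task$type, n))
  if (n) {
    ts <- range(vapply(x$records, `[[`, numeric(1), "timestamp"))
    cat(sprintf("  %g .. %g ms; models per record: %s\n", ts[1], ts[2],
                paste(names(x$records[[1]]$models), collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.session_stream <- function(x) length(x$records)

## --- JSON (de)serialization -------------------------------------------

# 17 significant digits: doubles survive the decimal round trip bit-exactly
.tojson <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null")
}

.frame_to_list <- function(frame) {
  lms <- lapply(seq_len(25L), function(i) {
    l <- list(p = unname(frame$landmarks[i, ]))
    r <- frame$reliability[[.JOINT_IDS[i]]]
    if (!is.null(r) && !is.na(r)) l$r <- r
    l
  })
  names(lms) <- .JOINT_IDS
  list(handedness = frame$handedness,
       palm_normal = frame$palm_normal,
       landmarks = lms)
}

.frame_from_list <- function(l, timestamp, source) {
  lm <- t(vapply(l$landmarks[.JOINT_IDS], function(j) as.numeric(j$p),
                 numeric(3)))
  rel <- vapply(l$landmarks[.JOINT_IDS],
                function(j) if (is.null(j$r)) NA_real_ else as.numeric(j$r),
                numeric(1))
  if (all(is.na(rel))) rel <- NULL
  hand_frame(timestamp, lm, as.numeric(l$palm_normal),
             handedness = l$handedness, source = source,
             reliability = rel)
}

#' Write a session stream as a JSON-Lines file
#'
#' Line 1 holds the header object; each subsequent line holds one frame
#' record (`{"t": <ms>, "models": {...}}`). Numbers are serialized at
#' full precision so that [read_stream()] reproduces the stream exactly.
#' The schema is published in `inst/extdata/stream.schema.json`.
#'
#' @param stream A [session_stream()].
#' @param path Output file path (conventionally `*.vgs.jsonl`).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "session_stream"))
  lines <- character(1L + length(stream$records))
  lines[1L] <- .tojson(list(header = unclass(stream$header)))
  for (i in seq_along(stream$records)) {
    rec <- stream$records[[i]]
    lines[i + 1L] <- .tojson(list(
      t = rec$timestamp,
      models = lapply(rec$models, .frame_to_list)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a session stream from a JSON-Lines file
#'
#' @param path File written by [write_stream()].
#' @return A [session_stream()].
#' @details Malformed lines raise a parse error naming the line number;
#'   non-increasing timestamps raise a validation error.
#' @export
read_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty stream file: ", path)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
             error = function(e)
               stop(sprintf("parse error at line %d of %s: %s",
                            i, path, conditionMessage(e)), call. = FALSE))
  }
  hdr <- parse_line(1L)
  if (is.null(hdr$header)) stop("line 1 of ", path, " is not a header object")
  h <- hdr$header
  header <- session_header(h$patient_id, h$therapist_id, h$device_id,
                           task = h$task,
                           calibration_ref = h$calibration_ref,
                           schema_version = h$schema_version)
  records <- vector("list", length(lines) - 1L)
  last_t <- -Inf
  for (i in seq_along(records)) {
    obj <- parse_line(i + 1L)
    t <- as.numeric(obj$t)
    if (t <= last_t)
      stop(sprintf("non-increasing timestamp at line %d of %s", i + 1L, path))
    last_t <- t
    models <- lapply(names(obj$models), function(s)
      .frame_from_list(obj$models[[s]], t, s))
    names(models) <- names(obj$models)
    records[[i]] <- frame_record(t, models)
  }
  session_stream(header, records)
}

# matrix of one model's landmark positions across a stream (n x 3)
.joint_track <- function(stream, model, joint) {
  t(vapply(stream$records, function(r) r$models[[model]]$landmarks[joint, ],
           numeric(3)))
}

.timestamps <- function(stream)
  vapply(stream$records, `[[`, numeric(1), "timestamp")
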