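#' Per-joint position, speed and acceleration series
#'
#' Differentiates one model of a session stream joint by joint using
#' finite differences on the actual timestamps (non-uniform safe):
#' central differences on interior samples, one-sided at the ends.
#' Acceleration is obtained by applying the same operator to the
#' velocity vectors. Speed and acceleration are reported as vector
#' magnitudes in mm/s and mm/s^2; per-axis components are kept in the
#' series for plotting. Central differences are exact on linear and
#' quadratic trajectories at uniform spacing and second-order accurate
#' otherwise. No smoothing is applied by default; a moving-average
#' pre-filter is available for noisy real data.
#'
#' @param stream A [session_stream()] with at least 3 records.
#' @param model Which model to analyze: `"fused"` (default),
#'   `"vertical"`, `"horizontal"` or `"truth"`.
#' @param smooth_window Optional odd integer; moving-average window (in
#'   samples) applied to positions before differentiation.
#' @return Named list over [joint_ids()]; each element a data frame with
#'   columns `t_ms`, `x`, `y`, `z` (mm), `vx`, `vy`, `vz`, `speed`
#'   (mm/s), `ax`, `ay`, `az`, `accel` (mm/s^2).
#' @export
differentiate <- function(stream, model = "fused", smooth_window = NULL) {
  stopifnot(inherits(stream, "session_stream"))
  n <- length(stream$records)
  if (n < 3L) stop("need at least 3 records to differentiate")
  for (i in seq_len(n))
    if (is.null(stream$records[[i]]$models[[model]]))
      stop(sprintf("model '%s' absent in record %d", model, i))
  t_ms <- .timestamps(stream)
  ts <- t_ms / 1000                        # seconds
  out <- vector("list", 25L)
  names(out) <- .JOINT_IDS
  for (j in .JOINT_IDS) {
    P <- .joint_track(stream, model, j)
    if (!is.null(smooth_window) && smooth_window > 1L)
      P <- apply(P, 2L, .moving_average, w = smooth_window)
    V <- .fd_derivative(P, ts)
    A <- .fd_derivative(V, ts)
    out[[j]] <- data.frame(
      t_ms = t_ms,
      x = P[, 1], y = P[, 2], z = P[, 3],
      vx = V[, 1], vy = V[, 2], vz = V[, 3],
      speed = sqrt(rowSums(V^2)),
      ax = A[, 1], ay = A[, 2], az = A[, 3],
      accel = sqrt(rowSums(A^2)))
  }
  out
}

# central differences inside, one-sided at the ends; columns independent
.fd_derivative <- function(M, ts) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M))
  D[1L, ] <- (M[2L, ] - M[1L, ]) / (ts[2L] - ts[1L])
  D[n, ] <- (M[n, ] - M[n - 1L, ]) / (ts[n] - ts[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    D[i, ] <- (M[i + 1L, , drop = FALSE] - M[i - 1L, , drop = FALSE]) /
      (ts[i + 1L] - ts[i - 1L])
  }
  D
}

.moving_average <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Per-joint session summary statistics
#'
#' Summarizes a session for therapist review: per joint, mean and
#' maximum speed over interior samples (the one-sided end estimates are
#' first-order only and are excluded), total path length and per-axis
#' range of motion, plus session metadata (identifier components, task
#' score when present, frame count and effective frame rate).
#'
#' @inheritParams differentiate
#' @return An object of class `session_summary`: list with `session_id`,
#'   `task_score`, `n_frames`, `frame_rate_fps`, `model` and `joints`, a
#'   data frame with one row per joint and columns `mean_speed`,
#'   `max_speed` (mm/s), `path_length`, `range_x`, `range_y`, `range_z`
#'   (mm).
#' @export
joint_statistics <- function(stream, model = "fused") {
  series <- differentiate(stream, model)
  n <- length(stream$records)
  interior <- 2:(n - 1L)
  rows <- lapply(.JOINT_IDS, function(j) {
    s <- series[[j]]
    P <- as.matrix(s[, c("x", "y", "z")])
    data.frame(
      joint = j,
      mean_speed = mean(s$speed[interior]),
      max_speed = max(s$speed[interior]),
      path_length = sum(sqrt(rowSums(diff(P)^2))),
      range_x = diff(range(P[, 1])),
      range_y = diff(range(P[, 2])),
      range_z = diff(range(P[, 3])))
  })
  h <- stream$header
  t_ms <- .timestamps(stream)
  structure(
    list(session_id = paste(h$patient_id, h$therapist_id,
                            gsub("-", "", h$task$start_date), sep = "_"),
         task_score = if (is.null(h$task$score)) NA_real_ else h$task$score,
         n_frames = n,
         frame_rate_fps = 1000 * (n - 1) / (t_ms[n] - t_ms[1]),
         model = model,
         joints = do.call(rbind, rows)),
    class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %s (%s model): %d frames @ %.1f fps\n",
              x$session_id, x$model, x$n_frames, x$frame_rate_fps))
  cat(sprintf("  task score: %s\n", format(x$task_score)))
  j <- x$joints
  cat(sprintf("  mean speed %.1f mm/s (max %.1f), mean path %.1f mm over 25 joints\n",
              mean(j$mean_speed), max(j$max_speed), mean(j$path_length)))
  invisible(x)
}

#' Compare summaries across rehabilitation sessions
#'
#' Computes per-joint, per-statistic differences between consecutive
#' session summaries, plus a sign-of-trend per joint and statistic (the
#' sign of the mean consecutive delta), so progress of hand mobility
#' across a therapy plan can be monitored.
#'
#' @param summaries List of >= 2 [joint_statistics()] results sharing
#'   the same joint set, in session order.
#' @return An object of class `session_comparison`: list with
#'   `session_ids`, `deltas` (list of data frames, one per consecutive
#'   pair) and `trend` (data frame of signs per joint and statistic).
#' @export
compare_sessions <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 summaries to compare")
  stats_cols <- c("mean_speed", "max_speed", "path_length",
                  "range_x", "range_y", "range_z")
  base_joints <- summaries[[1]]$joints$joint
  for (s in summaries)
    if (!identical(s$joints$joint, base_joints))
      stop("summaries have mismatched joint sets")
  deltas <- lapply(seq_len(length(summaries) - 1L), function(i) {
    d <- summaries[[i + 1L]]$joints[stats_cols] -
      summaries[[i]]$joints[stats_cols]
    cbind(data.frame(joint = base_joints,
                     from = summaries[[i]]$session_id,
                     to = summaries[[i + 1L]]$session_id), d)
  })
  mean_delta <- Reduce(`+`, lapply(deltas, function(d) d[stats_cols])) /
    length(deltas)
  trend <- cbind(data.frame(joint = base_joints), sign(mean_delta))
  structure(list(session_ids = vapply(summaries, `[[`, "", "session_id"),
                 deltas = deltas, trend = trend),
            class = "session_comparison")
}

#' Export a structured report
#'
#' Writes a report directory for a session summary (JSON document,
#' per-joint CSV table, per-joint max-speed plot) or for a session
#' comparison (JSON, delta CSVs, trend plot). The input stream data are
#' never modified: reports are derived artifacts and re-exporting from
#' the same data yields identical JSON/CSV content.
#'
#' @param x A `session_summary` or `session_comparison`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_report <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (inherits(x, "session_summary")) {
    jf <- file.path(outdir, "summary.json")
    writeLines(.tojson(list(
      session_id = x$session_id, task_score = x$task_score,
      n_frames = x$n_frames, frame_rate_fps = x$frame_rate_fps,
      model = x$model, joints = x$joints)), jf, useBytes = TRUE)
    cf <- file.path(outdir, "joints.csv")
    utils::write.csv(x$joints, cf, row.names = FALSE)
    pf <- file.path(outdir, "max_speed.png")
    grDevices::png(pf, width = 900, height = 500)
    graphics::par(mar = c(9, 4, 2, 1))
    graphics::barplot(x$joints$max_speed, names.arg = x$joints$joint,
                      las = 2, ylab = "max speed [mm/s]",
                      main = paste("Session", x$session_id))
    grDevices::dev.off()
    files <- c(jf, cf, pf)
  } else if (inherits(x, "session_comparison")) {
    jf <- file.path(outdir, "comparison.json")
    writeLines(.tojson(list(session_ids = x$session_ids,
                            trend = x$trend)), jf, useBytes = TRUE)
    files <- jf
    for (i in seq_along(x$deltas)) {
      cf <- file.path(outdir, sprintf("deltas_%d.csv", i))
      utils::write.csv(x$deltas[[i]], cf, row.names = FALSE)
      files <- c(files, cf)
    }
    pf <- file.path(outdir, "trend.png")
    grDevices::png(pf, width = 900, height = 500)
    graphics::par(mar = c(9, 4, 2, 1))
    graphics::barplot(x$trend$path_length, names.arg = x$trend$joint,
                      las = 2, ylab = "path-length trend sign",
                      main = "Across-session trend")
    grDevices::dev.off()
    files <- c(files, pf)
  } else stop("x must be a session_summary or session_comparison")
  invisible(files)
}
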