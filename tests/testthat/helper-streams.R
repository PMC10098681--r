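# Shared fixture builders: everything is generated in code at test time.

# one valid frame at a given palm-orientation angle (deg) and time
make_frame <- function(t_ms = 0, theta_deg = 270, source = "truth",
                       offset = c(0, 0, 0)) {
  a <- theta_deg * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  lm <- sweep(canonical_hand() %*% t(Rz), 2L, offset, `+`)
  rownames(lm) <- rownames(canonical_hand())
  hand_frame(t_ms, lm, as.numeric(Rz %*% c(1, 0, 0)), source = source)
}

# whole-hand translation along a prescribed path; offsets is n x 3 [mm]
make_path_stream <- function(offsets, dt_ms = 25, source = "fused",
                             theta_deg = 270, t0_ms = 0) {
  offsets <- as.matrix(offsets)
  recs <- lapply(seq_len(nrow(offsets)), function(i) {
    t <- t0_ms + (i - 1) * dt_ms
    f <- make_frame(t, theta_deg, source, offsets[i, ])
    frame_record(t, stats::setNames(list(f), source))
  })
  session_stream(sim_header(), recs)
}

sim_header <- function(params_id = NULL) {
  task <- list(type = "simulated", difficulty = 1, duration = 30,
               repetitions = 1, start_date = "2023-03-25")
  if (!is.null(params_id)) task$params_id <- params_id
  session_header("p1", "t1", "vg1", task = task)
}

# random but valid stream for serialization property tests
random_stream <- function(n_records = 3, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(n_records), function(i) {
    t <- (i - 1) * 25 + runif(1, 0, 10)
    models <- lapply(c(vertical = "vertical", horizontal = "horizontal"),
                     function(src) {
      lm <- matrix(rnorm(75, sd = 50), 25, 3,
                   dimnames = list(joint_ids(), c("x", "y", "z")))
      pn <- rnorm(3); pn <- pn / sqrt(sum(pn^2))
      rel <- stats::setNames(round(runif(25), 3), joint_ids())
      rel[sample(25, 5)] <- NA            # some joints unscored
      hand_frame(t, lm, pn, handedness = sample(c("left", "right"), 1),
                 source = src, reliability = rel)
    })
    frame_record(t, models)
  })
  session_stream(sim_header(), recs)
}

# random proper rotation (QR of a Gaussian matrix, det-corrected)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_transform <- function(max_shift = 100) {
  rigid_transform(random_rotation(), runif(3, -max_shift, max_shift))
}

rotation_error_deg <- function(R_est, R_true) {
  c_ang <- (sum(diag(R_est %*% t(R_true))) - 1) / 2
  acos(pmin(1, pmax(-1, c_ang))) * 180 / pi
}

# RMSE of one model's landmarks to the truth stream, all joints x frames
stream_rmse <- function(stream, truth, model) {
  stopifnot(length(stream) == length(truth))
  se <- 0; n <- 0
  for (i in seq_along(stream$records)) {
    d <- stream$records[[i]]$models[[model]]$landmarks -
      truth$records[[i]]$models[["truth"]]$landmarks
    se <- se + sum(d^2); n <- n + length(d)
  }
  sqrt(se / n)
}
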