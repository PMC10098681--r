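test_that("the generator honours frame counts and degenerate profiles", {
  static_pose <- hand_pose_model(flexion = list(), orientation =
                                   list(type = "constant", value_deg = 270))
  s <- generate_ground_truth(static_pose, duration_s = 5, fps = 40)
  expect_length(s, 200)                       # 5 s at 40 fps
  expect_equal(diff(vapply(s$records, `[[`, numeric(1), "timestamp")),
               rep(25, 199))
  first <- s$records[[1]]$models$truth$landmarks
  for (rec in s$records)
    expect_identical(rec$models$truth$landmarks, first)
  expect_identical(validate_frame(s$records[[1]]$models$truth), character())
})

test_that("ground truth is deterministic and left hands are mirrored", {
  pose <- hand_pose_model()
  a <- generate_ground_truth(pose, duration_s = 1, fps = 40)
  b <- generate_ground_truth(pose, duration_s = 1, fps = 40)
  expect_identical(a$records, b$records)

  left <- hand_pose_model(handedness = "left")
  l <- generate_ground_truth(left, duration_s = 0.25, fps = 40)
  expect_identical(l$records[[1]]$models$truth$handedness, "left")
  expect_equal(l$records[[1]]$models$truth$landmarks[, "x"],
               -a$records[[1]]$models$truth$landmarks[, "x"])
})

test_that("a noiseless identity sensor reproduces the truth", {
  pose <- hand_pose_model()
  truth <- generate_ground_truth(pose, duration_s = 0.5, fps = 40)
  sensor <- sensor_model("horizontal", sigma_mm = 0, alpha_occ_deg = 0,
                         p_drop = 0)
  obs <- observe(truth, sensor, seed = 1)
  for (i in seq_along(obs$records))
    expect_equal(obs$records[[i]]$models$horizontal$landmarks,
                 truth$records[[i]]$models$truth$landmarks,
                 tolerance = 1e-12)
  expect_false(any(attr(obs, "occluded")))
})

test_that("observation noise matches its nominal sigma", {
  static_pose <- hand_pose_model(flexion = list())
  truth <- generate_ground_truth(static_pose, duration_s = 25, fps = 40)
  sensor <- sensor_model("horizontal", sigma_mm = 0.5, alpha_occ_deg = 0,
                         p_drop = 0)
  obs <- observe(truth, sensor, seed = 42)     # 1000 static frames
  tip <- t(vapply(obs$records,
                  function(r) r$models$horizontal$landmarks["INDEX_TIP", ],
                  numeric(3)))
  for (axis in 1:3) {
    sd_axis <- sd(tip[, axis])
    expect_gt(sd_axis, 0.45)
    expect_lt(sd_axis, 0.55)
  }
})

test_that("observation is seed-deterministic", {
  pose <- hand_pose_model()
  truth <- generate_ground_truth(pose, duration_s = 0.5, fps = 40)
  sensor <- sensor_model("vertical", sigma_mm = 0.5)
  a <- observe(truth, sensor, seed = 7)
  b <- observe(truth, sensor, seed = 7)
  c <- observe(truth, sensor, seed = 8)
  expect_identical(a$records, b$records)
  expect_false(identical(a$records, c$records))
})

test_that("occlusion windows inflate empirical jitter", {
  # palm sweeping the full circle: the horizontal sensor (view axis +Y)
  # is occluded near 0 and 180 degrees where the normal is perpendicular
  # to its view axis
  pose <- hand_pose_model(flexion = list(),
                          orientation = list(type = "sweep", from_deg = 0,
                                             to_deg = 360))
  truth <- generate_ground_truth(pose, duration_s = 10, fps = 40)
  sensor <- sensor_model("horizontal", sigma_mm = 0.3, alpha_occ_deg = 30,
                         sigma_occ_mm = 3, p_drop = 0)
  obs <- observe(truth, sensor, seed = 9)
  occ <- attr(obs, "occluded")
  expect_gt(sum(occ), 50)
  expect_gt(sum(!occ), 50)
  resid <- vapply(seq_along(obs$records), function(i)
    obs$records[[i]]$models$horizontal$landmarks["PALM_CENTER", 1] -
      truth$records[[i]]$models$truth$landmarks["PALM_CENTER", 1],
    numeric(1))
  expect_gt(sd(resid[occ]), 4 * sd(resid[!occ]))
  # reliability marks the occluded frames
  rel <- vapply(obs$records, function(r)
    r$models$horizontal$reliability[["PALM_CENTER"]], numeric(1))
  expect_true(all(rel[occ] == 0.4) && all(rel[!occ] == 0.95))
})

test_that("dropout holds the last value on occluded frames", {
  pose <- hand_pose_model(orientation = list(type = "constant",
                                             value_deg = 270))
  truth <- generate_ground_truth(pose, duration_s = 2, fps = 40)
  # vertical sensor (view axis +X) is fully occluded at 270 degrees
  sensor <- sensor_model("vertical", sigma_mm = 0, alpha_occ_deg = 30,
                         sigma_occ_mm = 0, p_drop = 0.5,
                         view_axis = c(1, 0, 0))
  obs <- observe(truth, sensor, seed = 10)
  expect_true(all(attr(obs, "occluded")))
  tip <- t(vapply(obs$records,
                  function(r) r$models$vertical$landmarks["INDEX_TIP", ],
                  numeric(3)))
  frozen <- rowSums(abs(diff(tip))) == 0
  expect_gt(mean(frozen), 0.3)       # roughly p_drop of transitions freeze
  expect_lt(mean(frozen), 0.7)
})

test_that("synthetic calibration clouds drive exact and noisy recovery", {
  set.seed(11)
  truth_tf <- random_transform()
  exact <- make_calibration_cloud(truth_tf, 20, sigma_mm = 0, seed = 1)
  est <- estimate_rigid_transform(exact)
  expect_lt(norm(est$rotation - truth_tf$rotation, "F"), 1e-9)
  expect_lt(max(abs(est$translation - truth_tf$translation)), 1e-9)

  cube <- calibration_cloud(
    as.matrix(expand.grid(c(-75, 75), c(-75, 75), c(-75, 75))),
    transform_points(truth_tf,
                     as.matrix(expand.grid(c(-75, 75), c(-75, 75), c(-75, 75)))) +
      matrix(rnorm(24, sd = 0.5), 8, 3))
  est2 <- estimate_rigid_transform(cube)
  expect_lt(registration_residual(est2, cube), 3 * 0.5 * sqrt(3))

  expect_error(make_calibration_cloud(truth_tf, 2, seed = 1), "at least 3")
  expect_identical(make_calibration_cloud(truth_tf, 10, 0.1, seed = 5)$a,
                   make_calibration_cloud(truth_tf, 10, 0.1, seed = 5)$a)
})

test_that("the toy task scores hits inside the activation radius while lit", {
  pose <- hand_pose_model()
  truth <- generate_ground_truth(pose, duration_s = 2, fps = 40)
  empty <- task_spec(duration_s = 2)
  expect_equal(run_toy_task(truth, empty, model = "truth")$score, 0)

  # place one target exactly on the fingertip's position mid-session
  on_path <- truth$records[[40]]$models$truth$landmarks["INDEX_TIP", ]
  hit_task <- task_spec(duration_s = 2, radius_mm = 5, targets = data.frame(
    x = on_path[1], y = on_path[2], z = on_path[3],
    joint = "INDEX_TIP", lit_from_ms = 900, lit_until_ms = 1100))
  res <- run_toy_task(truth, hit_task, model = "truth")
  expect_equal(res$score, 1)
  expect_equal(res$events$t_ms, 975)        # frame 40 at 40 fps

  # vanishing radius on a non-intersecting path scores zero
  off_task <- task_spec(duration_s = 2, radius_mm = 1e-6, targets = data.frame(
    x = on_path[1] + 500, y = on_path[2], z = on_path[3],
    joint = "INDEX_TIP", lit_from_ms = 0, lit_until_ms = 2000))
  expect_equal(run_toy_task(truth, off_task, model = "truth")$score, 0)
})

test_that("the session state machine sequences countdowns, runs and rests", {
  provider <- function(rep, duration_s) {
    pose <- hand_pose_model()
    s <- generate_ground_truth(pose, duration_s, fps = 40)
    for (i in seq_along(s$records)) {
      s$records[[i]]$models <- list(fused = s$records[[i]]$models$truth)
      s$records[[i]]$models$fused$source <- "fused"
    }
    s
  }
  one <- run_session(task_spec(duration_s = 1, repetitions = 1), provider)
  expect_identical(one$status, "completed")
  expect_equal(sum(one$phases$phase == "RUNNING"), 1)
  expect_equal(one$countdown_s, 10)          # default pre-task counter

  three <- run_session(task_spec(duration_s = 1, repetitions = 3), provider)
  expect_length(three$streams, 3)
  expect_equal(sum(three$phases$phase == "REST"), 2)
  expect_equal(sum(three$phases$phase == "COUNTDOWN"), 3)
  # phases tile the simulated clock in order
  expect_true(all(diff(three$phases$start_s) >= 0))
  expect_equal(three$phases$start_s[-1],
               three$phases$end_s[-nrow(three$phases)])

  aborted <- run_session(task_spec(duration_s = 1), provider,
                         hand_detected = FALSE)
  expect_identical(aborted$status, "aborted")
  expect_length(aborted$streams, 0)
})
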