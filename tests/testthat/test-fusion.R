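test_that("palm projection angle follows the atan2 definition", {
  expect_equal(palm_projection_angle(c(1, 0, 0)), 0)
  expect_equal(palm_projection_angle(c(0, 1, 0)), 90)
  expect_equal(palm_projection_angle(c(0, -1, 0)), 270)
  expect_equal(palm_projection_angle(c(-1, 0, 0)), 180)
  expect_true(is.na(palm_projection_angle(c(0, 0, 1))))
  expect_error(palm_projection_angle(c(1, 1, 0)), "unit")
})

test_that("binary switch activates the horizontal sensor in the closed windows", {
  expect_identical(binary_switch_select(270), "horizontal")  # palm down
  expect_identical(binary_switch_select(90), "horizontal")   # palm up
  expect_identical(binary_switch_select(0), "vertical")
  expect_identical(binary_switch_select(180), "vertical")
  # the printed thresholds themselves activate the horizontal sensor
  for (edge in c(45, 135, 225, 315))
    expect_identical(binary_switch_select(edge), "horizontal")
  expect_identical(binary_switch_select(44.999), "vertical")
  expect_identical(binary_switch_select(135.001), "vertical")
  # undefined angle: hold the previous decision, or the initial sensor
  expect_identical(binary_switch_select(NA, previous = "vertical"), "vertical")
  expect_identical(binary_switch_select(NA, previous = NULL), "horizontal")
})

test_that("the angle windows partition every defined angle", {
  sel <- vapply(0:359, function(a) binary_switch_select(a), "")
  expect_true(all(sel %in% c("vertical", "horizontal")))
  expect_equal(sum(sel == "horizontal"), 2 * 91)   # two closed 91-deg windows
  expect_equal(min(which(sel == "horizontal")) - 1, 45)
})

test_that("joint-wise selection switches only on faster active-sensor motion", {
  cfg <- fusion_config("jointwise_switch")
  active <- stats::setNames(rep("horizontal", 25), joint_ids())
  f0v <- make_frame(0, source = "vertical")
  f0h <- make_frame(0, source = "horizontal")

  # both sensors static: equal zero speeds keep the active sensor
  upd <- jointwise_select(f0v, f0v, f0h, f0h, active, 25, cfg)
  expect_identical(upd, active)

  # active (horizontal) joint jumps 50 mm while vertical moves 1 mm
  f1h <- f0h; f1h$landmarks["INDEX_TIP", ] <-
    f1h$landmarks["INDEX_TIP", ] + c(50, 0, 0)
  f1v <- f0v; f1v$landmarks["INDEX_TIP", ] <-
    f1v$landmarks["INDEX_TIP", ] + c(1, 0, 0)
  upd <- jointwise_select(f1v, f0v, f1h, f0h, active, 25, cfg)
  expect_identical(unname(upd[["INDEX_TIP"]]), "vertical")
  expect_identical(upd[names(upd) != "INDEX_TIP"],
                   active[names(active) != "INDEX_TIP"])

  expect_error(jointwise_select(f1v, f0v, f1h, f0h, active, 0, cfg),
               "positive")
})

test_that("smooth identical motion in both sensors never switches", {
  pose <- hand_pose_model()    # sinusoidal index flexion, palm down
  truth <- generate_ground_truth(pose, duration_s = 2.5, fps = 40)
  # both sensors see bit-identical motion: speeds tie at every joint and
  # the margin rule must hold the current assignment
  v <- observe(truth, sensor_model("vertical", sigma_mm = 0,
                                   alpha_occ_deg = 0), seed = 1)
  h <- observe(truth, sensor_model("horizontal", sigma_mm = 0,
                                   alpha_occ_deg = 0), seed = 2)
  fj <- fuse_streams(v, h, rigid_transform(), fusion_config("jointwise_switch"))
  active <- t(vapply(fusion_decisions(fj), function(d) d$active,
                     character(25)))
  expect_length(fj, 100)
  expect_true(all(active == "horizontal"))   # initial sensor, zero switches
})

test_that("palm-down sequences are served entirely by the horizontal sensor", {
  pose <- hand_pose_model(orientation = list(type = "constant",
                                             value_deg = 270))
  truth <- generate_ground_truth(pose, duration_s = 1, fps = 40)
  rig <- default_sensor_rig(sigma_mm = 0.5)
  v <- observe(truth, rig$vertical, seed = 3)
  h <- observe(truth, rig$horizontal, seed = 4)
  fused <- fuse_streams(v, h, rig$calibration)
  for (rec in fused$records) {
    expect_identical(rec$models$fused$landmarks, rec$models$horizontal$landmarks)
    expect_identical(rec$models$fused$source, "fused")
    expect_setequal(names(rec$models), c("vertical", "horizontal", "fused"))
  }
  expect_true(all(vapply(fusion_decisions(fused), `[[`, "", "active") ==
                    "horizontal"))
})

test_that("binary fusion matches a brute-force per-frame reselection oracle", {
  pose <- hand_pose_model(orientation = list(type = "sweep", from_deg = 0,
                                             to_deg = 360))
  truth <- generate_ground_truth(pose, duration_s = 5, fps = 40)   # 200 frames
  rig <- default_sensor_rig(sigma_mm = 0.5)
  v <- observe(truth, rig$vertical, seed = 5)
  h <- observe(truth, rig$horizontal, seed = 6)
  cfg <- fusion_config()
  fused <- fuse_streams(v, h, rig$calibration, cfg)
  expect_length(fused, 200)

  v_ref <- apply_transform(rig$calibration, v)   # oracle works from scratch
  previous <- NULL
  used_both <- c(vertical = FALSE, horizontal = FALSE)
  for (i in seq_along(fused$records)) {
    hf <- h$records[[i]]$models$horizontal
    nxy <- sqrt(sum(hf$palm_normal[1:2]^2))
    ang <- if (nxy < cfg$projection_epsilon) NA_real_ else
      (atan2(hf$palm_normal[2], hf$palm_normal[1]) * 180 / pi) %% 360
    tol <- 1e-9     # documented closed-boundary slack of the window rule
    sel <- if (is.na(ang)) (if (is.null(previous)) "horizontal" else previous)
    else if ((ang >= 45 - tol && ang <= 135 + tol) ||
               (ang >= 225 - tol && ang <= 315 + tol))
      "horizontal" else "vertical"
    previous <- sel
    expected <- if (sel == "vertical")
      v_ref$records[[i]]$models$vertical$landmarks else hf$landmarks
    expect_identical(fused$records[[i]]$models$fused$landmarks, expected)
    expect_identical(fusion_decisions(fused)[[i]]$active, sel)
    used_both[sel] <- TRUE
  }
  expect_true(all(used_both))    # the sweep exercises both sensors
})

test_that("jointwise fusion matches a brute-force per-joint oracle", {
  pose <- hand_pose_model(orientation = list(type = "sweep", from_deg = 0,
                                             to_deg = 360))
  truth <- generate_ground_truth(pose, duration_s = 5, fps = 40)
  rig <- default_sensor_rig(sigma_mm = 0.5, p_drop = 0)
  v <- observe(truth, rig$vertical, seed = 7)
  h <- observe(truth, rig$horizontal, seed = 8)
  cfg <- fusion_config("jointwise_switch")
  fused <- fuse_streams(v, h, rig$calibration, cfg)

  v_ref <- apply_transform(rig$calibration, v)
  active <- stats::setNames(rep("horizontal", 25), joint_ids())
  for (i in seq_along(fused$records)) {
    vl <- v_ref$records[[i]]$models$vertical$landmarks
    hl <- h$records[[i]]$models$horizontal$landmarks
    if (i > 1) {
      vp <- v_ref$records[[i - 1]]$models$vertical$landmarks
      hp <- h$records[[i - 1]]$models$horizontal$landmarks
      sv <- sqrt(rowSums((vl - vp)^2)); sh <- sqrt(rowSums((hl - hp)^2))
      for (j in joint_ids()) {
        va <- if (active[[j]] == "vertical") sv[[j]] else sh[[j]]
        vo <- if (active[[j]] == "vertical") sh[[j]] else sv[[j]]
        if (va > vo)
          active[[j]] <- if (active[[j]] == "vertical") "horizontal" else "vertical"
      }
    }
    expected <- hl
    expected[active == "vertical", ] <- vl[active == "vertical", ]
    expect_identical(fused$records[[i]]$models$fused$landmarks, expected)
  }
})

test_that("fused output is a switch, never a blend, under both strategies", {
  pose <- hand_pose_model(orientation = list(type = "sweep", from_deg = 0,
                                             to_deg = 360))
  truth <- generate_ground_truth(pose, duration_s = 1.5, fps = 40)
  rig <- default_sensor_rig(sigma_mm = 1)
  v <- observe(truth, rig$vertical, seed = 9)
  h <- observe(truth, rig$horizontal, seed = 10)
  for (strategy in c("binary_switch", "jointwise_switch")) {
    fused <- fuse_streams(v, h, rig$calibration, fusion_config(strategy))
    for (rec in fused$records) {
      fl <- rec$models$fused$landmarks
      vl <- rec$models$vertical$landmarks
      hl <- rec$models$horizontal$landmarks
      from_one_source <- vapply(seq_len(25), function(j)
        identical(fl[j, ], vl[j, ]) || identical(fl[j, ], hl[j, ]),
        logical(1))
      expect_true(all(from_one_source))
    }
  }
})

test_that("identical streams fuse back to the ground truth", {
  pose <- hand_pose_model()
  truth <- generate_ground_truth(pose, duration_s = 1, fps = 40)
  noiseless <- sensor_model("horizontal", sigma_mm = 0, alpha_occ_deg = 0)
  h <- observe(truth, noiseless, seed = 1)
  v <- observe(truth, sensor_model("vertical", sigma_mm = 0,
                                   alpha_occ_deg = 0), seed = 2)
  for (strategy in c("binary_switch", "jointwise_switch")) {
    fused <- fuse_streams(v, h, rigid_transform(), fusion_config(strategy))
    for (i in seq_along(fused$records))
      expect_equal(fused$records[[i]]$models$fused$landmarks,
                   truth$records[[i]]$models$truth$landmarks,
                   tolerance = 1e-12)
  }
})

test_that("jointwise fusion rejects injected jump artifacts", {
  # clean motion in both sensors, then one 60 mm jump artifact injected
  # into the horizontal sensor at a single frame
  pose <- hand_pose_model()
  truth <- generate_ground_truth(pose, duration_s = 2, fps = 40)
  rig <- default_sensor_rig(sigma_mm = 0, p_drop = 0)
  v <- observe(truth, rig$vertical, seed = 11)
  h <- observe(truth, rig$horizontal, seed = 12)
  k <- 40
  h$records[[k]]$models$horizontal$landmarks["RING_TIP", ] <-
    h$records[[k]]$models$horizontal$landmarks["RING_TIP", ] + c(0, 0, 60)

  fused <- fuse_streams(v, h, rig$calibration, fusion_config("jointwise_switch"))
  v_ref <- apply_transform(rig$calibration, v)
  # at the corrupted frame the joint is served by the clean sensor
  expect_identical(fused$records[[k]]$models$fused$landmarks["RING_TIP", ],
                   v_ref$records[[k]]$models$vertical$landmarks["RING_TIP", ])

  max_step <- function(stream, model) {
    steps <- vapply(2:length(stream), function(i)
      max(sqrt(rowSums((stream$records[[i]]$models[[model]]$landmarks -
                          stream$records[[i - 1]]$models[[model]]$landmarks)^2))),
      numeric(1))
    max(steps)
  }
  expect_lte(max_step(fused, "fused"), max_step(fused, "horizontal"))
})

test_that("fusion is deterministic and fails cleanly on disjoint streams", {
  pose <- hand_pose_model()
  truth <- generate_ground_truth(pose, duration_s = 1, fps = 40)
  rig <- default_sensor_rig(sigma_mm = 0.5)
  v <- observe(truth, rig$vertical, seed = 13)
  h <- observe(truth, rig$horizontal, seed = 14)
  f1 <- fuse_streams(v, h, rig$calibration)
  f2 <- fuse_streams(v, h, rig$calibration)
  expect_identical(f1$records, f2$records)
  expect_identical(fusion_decisions(f1), fusion_decisions(f2))

  late <- generate_ground_truth(pose, duration_s = 1, fps = 40)
  for (i in seq_along(late$records)) {
    late$records[[i]]$timestamp <- late$records[[i]]$timestamp + 1e6
    late$records[[i]]$models$truth$timestamp <-
      late$records[[i]]$models$truth$timestamp + 1e6
  }
  v_late <- observe(late, rig$vertical, seed = 15)
  expect_error(fuse_streams(v_late, h, rig$calibration), "no overlapping")
  expect_error(fuse_streams(v, h, transform = NULL), "missing calibration")
})
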