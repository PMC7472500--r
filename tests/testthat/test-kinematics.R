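test_that("a single rigid body has no relative joint motion", {
  set.seed(5)
  Rs <- lapply(1:6, function(i) random_rotation())
  traj <- make_traj(neutral_foot_markers(), n = 6, R = Rs,
                    t = lapply(1:6, function(i) stats::rnorm(3, sd = 30)))
  for (id in c("new", "new_2", "rizzoli")) {
    ang <- joint_angles(traj, register_model(id))
    base <- static_baseline(ang)
    for (a in ang) {
      # the inter-segment orientation is frozen: angles constant over frames
      expect_lt(max(apply(a$angles, 2, function(x) diff(range(x)))), 1e-7)
      # and identically zero once the static posture is subtracted
      expect_lt(max(abs(subtract_baseline(a, base)$angles)), 1e-7)
    }
  }
})

test_that("an imposed 45-degree plate rotation appears at Cal_Met only", {
  g <- dummy_geometry()
  sw <- simulate_sweep(g, "rearfoot", "sagittal", grid = c(0, 45))
  m <- register_model("new")
  ang <- joint_angles(sw$traj, m, joints = c("Met_Hal", "Cal_Met"))
  expect_equal(unname(ang$Cal_Met$angles[2, "dfpf"]), 45, tolerance = 1e-6)
  expect_lt(max(abs(ang$Cal_Met$angles[1, ])), 1e-6)
  expect_lt(max(abs(ang$Met_Hal$angles)), 1e-6)
})

test_that("a missing marker only fails joints that need it", {
  traj0 <- make_traj(neutral_foot_markers(), n = 2)
  traj <- trajectory_set(traj0$markers[setdiff(marker_names(traj0), "P1")],
                         traj0$rate)
  m <- register_model("new")
  expect_silent(joint_angles(traj, m, joints = "Cal_Met"))
  expect_error(joint_angles(traj, m, joints = "Met_Hal"), "P1 not found")
  expect_error(joint_angles(traj, m, joints = "Nope"), "unknown joint")
})

test_that("baseline subtraction is exact component-wise arithmetic", {
  ang <- joint_angle_series("Met_Hal",
                            matrix(c(10, 0, 0), 1, 3, byrow = TRUE), 100)
  base <- structure(list(Met_Hal = c(dfpf = 2, evinv = -1, abdadd = 0.5)),
                    class = "static_baseline")
  out <- subtract_baseline(ang, base)
  expect_equal(unname(out$angles[1, ]), c(8, 1, -0.5))
  expect_true(out$baseline_subtracted)
  # subtracting a series from its own baseline zeroes it
  ang2 <- joint_angle_series("Met_Hal",
                             matrix(c(2, -1, 0.5), 5, 3, byrow = TRUE), 100)
  b2 <- static_baseline(list(ang2))
  expect_equal(max(abs(subtract_baseline(ang2, b2)$angles)), 0)
  expect_error(subtract_baseline(ang, structure(list(), class = "static_baseline")),
               "does not contain joint")
})

test_that("baseline estimated from a noisy static window is unbiased", {
  set.seed(91)
  n <- 1500  # 15 s at 100 Hz
  sigma <- 0.1
  true_mean <- c(5, -2, 1)
  noisy <- sweep(matrix(stats::rnorm(3 * n, sd = sigma), n, 3), 2,
                 true_mean, "+")
  ang <- joint_angle_series("Sha_Cal", noisy, 100)
  base <- static_baseline(list(ang))
  out <- subtract_baseline(ang, base)
  expect_lt(max(abs(colMeans(out$angles))), 1e-12)  # mean removed exactly
  expect_lt(max(abs(base$Sha_Cal - true_mean)), 3 * sigma / sqrt(n) * 3)
})

test_that("peak extraction equals brute-force order statistics", {
  n <- 201  # odd length so the grid contains the exact peak of the ramp
  dfpf <- 37.6 * sin(seq(0, pi, length.out = n))
  ang <- joint_angle_series("Met_Hal", cbind(dfpf, 0, 0), 100)
  pk <- extract_peaks(ang, task = "calf_raise")
  expect_equal(pk$max[pk$component == "dfpf"], 37.6)
  expect_equal(pk$min[pk$component == "dfpf"], 0)
  # constant series: max == min
  flat <- joint_angle_series("Cal_Met", matrix(2, 5, 3), 100)
  pkf <- extract_peaks(flat)
  expect_equal(pkf$max, pkf$min)
  # window restriction, against brute force on the same window
  w <- c(20, 60)
  pkw <- extract_peaks(ang, window = w)
  expect_equal(pkw$max[pkw$component == "dfpf"], max(dfpf[w[1]:w[2]]))
  expect_error(extract_peaks(ang, window = c(50, 20)), "empty")
  expect_error(extract_peaks(ang, window = c(1, 400)), "outside")
})

test_that("multi-trial peak aggregation recovers injected values", {
  set.seed(17)
  injected <- c(24.1, 26.7, 22.9, 25.3, 27.8, 23.4, 26.0)  # 7 trials
  peaks <- vapply(injected, function(p) {
    n <- 121
    ser <- p * sin(seq(0, pi, length.out = n))
    ang <- joint_angle_series("Sha_Cal", cbind(ser, 0, 0), 100)
    pk <- extract_peaks(ang, task = "drop_jump")
    pk$max[pk$component == "dfpf"]
  }, numeric(1))
  expect_equal(mean(peaks), mean(injected), tolerance = 1e-12)
  expect_equal(stats::sd(peaks), stats::sd(injected), tolerance = 1e-12)
})

test_that("angle invariants are enforced on raw series", {
  expect_error(joint_angle_series("J", matrix(c(0, 95, 0), 1, 3), 100),
               "out of range")
  expect_silent(joint_angle_series("J", matrix(c(0, 95, 0), 1, 3), 100,
                                   baseline_subtracted = TRUE))
  expect_error(joint_angle_series("J", matrix(c(NA, 0, 0), 1, 3), 100),
               "non-finite")
})

test_that("tidy export reproduces the series", {
  ang <- joint_angle_series("Met_Hal", matrix(1:9 / 10, 3, 3), 50)
  df <- angles_to_df(ang, trial = "t1")
  expect_equal(nrow(df), 9)
  expect_setequal(unique(df$component), c("dfpf", "evinv", "abdadd"))
  expect_equal(df$angle_deg[df$component == "dfpf"], ang$angles[, 1])
  expect_equal(df$time_s[df$frame == 3][1], 2 / 50)
})
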