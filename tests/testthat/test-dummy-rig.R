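test_that("the rig geometry satisfies the physical invariants", {
  g <- dummy_geometry()
  expect_equal(nrow(g$markers), 17)  # 12 unique + 5 duplicated landmarks
  dup <- names(which(table(g$markers$name) > 1))
  expect_setequal(dup, c("H1", "H2", "H5", "B5", "NV"))
  for (i in seq_len(nrow(g$markers))) {
    b <- g$boxes[[g$markers$box[i]]]
    expect_true(g$markers$x[i] >= b$x_min - 10 &&
                  g$markers$x[i] <= b$x_max + 10)
  }
  expect_setequal(names(g$plates), c("A", "B", "C"))
})

test_that("plate frames follow the o-x-z construction", {
  p <- plate_pose(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_lt(max_matdiff(p$R[, , 1], diag(3)), 1e-12)
  expect_equal(unname(p$origin[1, ]), c(0, 0, 0))
  # rigid-motion oracle: rotating the three points rotates the frame
  set.seed(31)
  for (k in 1:15) {
    R0 <- random_rotation()
    p2 <- plate_pose(as.vector(R0 %*% c(0, 0, 0)),
                     as.vector(R0 %*% c(1, 0, 0)),
                     as.vector(R0 %*% c(0, 0, 1)))
    expect_lt(max_matdiff(p2$R[, , 1], R0), 1e-9)
  }
  expect_error(plate_pose(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               "degenerate")
  expect_error(plate_pose(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("imposed rotations define the ground truth exactly", {
  g <- dummy_geometry()
  for (plane in c("frontal", "transverse", "sagittal")) {
    comp <- switch(plane, frontal = "evinv", transverse = "abdadd",
                   sagittal = "dfpf")
    for (end in c("toe", "rearfoot")) {
      sw <- simulate_sweep(g, end, plane, grid = seq(-90, 90, 5))
      expect_equal(sw$truth[[comp]], seq(-90, 90, 5))
      other <- setdiff(c("dfpf", "evinv", "abdadd"), comp)
      expect_lt(max(abs(as.matrix(sw$truth[other]))), 1e-9)
    }
  }
  expect_error(simulate_sweep(g, "toe", "sagittal", grid = c(0, 95)),
               "within")
})

test_that("plate-derived angles reproduce the imposed grid", {
  g <- dummy_geometry()
  for (plane in c("frontal", "transverse", "sagittal")) {
    comp <- switch(plane, frontal = "evinv", transverse = "abdadd",
                   sagittal = "dfpf")
    sw <- simulate_sweep(g, "toe", plane)
    pa <- plate_angles(sw$traj, "A_rel_B")
    expect_lt(max(abs(pa[, comp] - sw$truth[[comp]])), 1e-9)
    sw <- simulate_sweep(g, "rearfoot", plane)
    pa <- plate_angles(sw$traj, "B_rel_C")
    expect_lt(max(abs(pa[, comp] - sw$truth[[comp]])), 1e-9)
  }
})

test_that("ground truth is independent of noise and seed", {
  g <- dummy_geometry()
  a <- simulate_sweep(g, "toe", "sagittal", noise_sd = 0)
  b <- simulate_sweep(g, "toe", "sagittal", noise_sd = 2, seed = 1)
  d <- simulate_sweep(g, "toe", "sagittal", noise_sd = 2, seed = 99)
  expect_identical(a$truth, b$truth)
  expect_identical(b$truth, d$truth)
  # but the markers do differ
  expect_gt(max(abs(b$traj$markers$P1 - a$traj$markers$P1)), 0)
})

test_that("the neutral grid position matches the static reference", {
  g <- dummy_geometry()
  sw <- simulate_sweep(g, "toe", "sagittal", grid = 0)
  ang <- joint_angles(sw$traj, register_model("new"),
                      joints = c("Met_Hal", "Cal_Met"))
  expect_lt(max(abs(ang$Met_Hal$angles)), 1e-9)
  expect_lt(max(abs(ang$Cal_Met$angles)), 1e-9)
})

test_that("static simulation is stationary, seeded and calibrated", {
  g <- dummy_geometry()
  s0 <- simulate_static(g, duration_s = 0.05, rate_hz = 100)
  expect_equal(n_frames(s0), 5)
  for (m in s0$markers) expect_equal(max(apply(m, 2, stats::sd)), 0)
  s1 <- simulate_static(g, 0.1, 100, noise_sd = 0.5, seed = 4)
  s2 <- simulate_static(g, 0.1, 100, noise_sd = 0.5, seed = 4)
  expect_identical(s1$markers, s2$markers)
  # sample SD of the noise within 10% of sigma at n = 1500
  s3 <- simulate_static(g, 15, 100, noise_sd = 0.5, seed = 8)
  sds <- apply(s3$markers$P1, 2, stats::sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.1))
})

test_that("a mounting offset produces a constant measured-true offset", {
  g <- dummy_geometry()
  sw <- simulate_sweep(g, "toe", "sagittal", placement_offset_deg = 5)
  ang <- joint_angles(sw$traj, register_model("new"), joints = "Met_Hal")
  d <- ang$Met_Hal$angles[, "dfpf"] - sw$truth$dfpf
  expect_lt(stats::sd(d), 1e-6)
  expect_equal(mean(d), 5, tolerance = 1e-6)
})
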