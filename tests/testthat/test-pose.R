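aligned_hallux_traj <- function(n = 1) {
  # long axis along lab +X, plane horizontal: segment frame = identity
  make_traj(list(H1 = c(0, 10, -20), P1 = c(50, 10, -20),
                 H5 = c(0, 10, 30)), n = n)
}

test_that("an aligned marker layout yields the identity pose", {
  seg <- register_model("new")$segments$Hallux
  pose <- build_segment_pose(aligned_hallux_traj(3), seg)
  for (i in 1:3) expect_lt(max_matdiff(pose$R[, , i], diag(3)), 1e-12)
  expect_equal(unname(pose$origin[1, ]), c(0, 10, -20))
})

test_that("poses are equivariant under rigid motions and scale invariant", {
  set.seed(42)
  seg <- register_model("new")$segments$Hallux
  base <- aligned_hallux_traj(1)
  p0 <- build_segment_pose(base, seg)
  for (k in 1:20) {
    R0 <- random_rotation()
    t0 <- stats::rnorm(3, sd = 100)
    moved <- trajectory_set(lapply(base$markers, function(m) {
      sweep(m %*% t(R0), 2, t0, "+")
    }), base$rate)
    p1 <- build_segment_pose(moved, seg)
    expect_lt(max_matdiff(p1$R[, , 1], R0 %*% p0$R[, , 1]), 1e-9)
    expect_lt(max(abs(p1$origin[1, ] -
                        (as.vector(R0 %*% p0$origin[1, ]) + t0))), 1e-9)
  }
  scaled <- trajectory_set(lapply(base$markers, function(m) m * 3.7),
                           base$rate)
  expect_lt(max_matdiff(build_segment_pose(scaled, seg)$R[, , 1],
                        p0$R[, , 1]), 1e-12)
})

test_that("all returned frames are orthonormal right-handed", {
  set.seed(7)
  m <- register_model("new")
  for (k in 1:10) {
    R0 <- random_rotation()
    traj <- make_traj(neutral_foot_markers(), n = 1, R = R0,
                      t = stats::rnorm(3, sd = 50))
    traj <- derive_virtual_markers(traj, m)
    for (seg in m$segments) {
      pose <- build_segment_pose(traj, seg)
      Ri <- pose$R[, , 1]
      expect_lt(max_matdiff(crossprod(Ri), diag(3)), 1e-9)
      expect_equal(det(Ri), 1, tolerance = 1e-9)
    }
  }
})

test_that("collinear plane markers raise a degenerate-frame error", {
  seg <- register_model("new")$segments$Hallux
  traj <- make_traj(list(H1 = c(0, 0, 0), P1 = c(50, 0, 0),
                         H5 = c(25, 0, 0)), n = 2)
  expect_error(build_segment_pose(traj, seg), "collinear.*frame 1")
})

test_that("missing markers are reported with the requesting segment", {
  seg <- register_model("new")$segments$Hallux
  traj <- make_traj(list(H1 = c(0, 0, 0), P1 = c(50, 0, 0)), n = 1)
  expect_error(build_segment_pose(traj, seg), "H5 not found")
})

test_that("shared segments of new and new_2 produce identical poses", {
  traj <- make_traj(neutral_foot_markers(), n = 2)
  a <- register_model("new")
  b <- register_model("new_2")
  ta <- derive_virtual_markers(traj, a)
  for (seg in c("Hallux", "Forefoot", "Shank")) {
    expect_identical(build_segment_pose(ta, a$segments[[seg]])$R,
                     build_segment_pose(ta, b$segments[[seg]])$R)
  }
})

test_that("relative rotation expresses the child in the parent frame", {
  # child equal to parent: identity
  set.seed(11)
  R <- array(0, c(3, 3, 5))
  for (i in 1:5) R[, , i] <- random_rotation()
  rel <- relative_rotation(R, R)
  for (i in 1:5) expect_lt(max_matdiff(rel[, , i], diag(3)), 1e-12)
  # identity parent passes the child through
  child <- array(rot_z(30), c(3, 3, 1))
  rel <- relative_rotation(child, array(diag(3), c(3, 3, 1)))
  expect_lt(max_matdiff(rel[, , 1], rot_z(30)), 1e-12)
  # reconstruction oracle: R_parent %*% R_rel == R_child
  for (k in 1:25) {
    Rc <- random_rotation(); Rp <- random_rotation()
    rel <- relative_rotation(array(Rc, c(3, 3, 1)), array(Rp, c(3, 3, 1)))
    expect_lt(max_matdiff(Rp %*% rel[, , 1], Rc), 1e-12)
    # inverse symmetry: (A rel B) %*% (B rel A) = I
    rel2 <- relative_rotation(array(Rp, c(3, 3, 1)), array(Rc, c(3, 3, 1)))
    expect_lt(max_matdiff(rel[, , 1] %*% rel2[, , 1], diag(3)), 1e-12)
  }
  expect_error(relative_rotation(R, R[, , 1:2]), "mismatch")
})
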