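test_that("kabsch_align recovers exact transforms and rejects degeneracy", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  id <- kabsch_align(src, src)
  expect_equal(id$R, diag(3), tolerance = 1e-12)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-12)

  R <- rotation_axis_angle(c(0, 0, 1), 90)
  dst <- src %*% t(R) + rep(c(1, 2, 3), each = 4)
  tf <- kabsch_align(src, dst)
  expect_equal(tf$R, R, tolerance = 1e-9)
  expect_equal(tf$t, c(1, 2, 3), tolerance = 1e-9)

  expect_error(kabsch_align(src[1:2, ], src[1:2, ]), "at least 3")
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(kabsch_align(line, line), "collinear")
})

test_that("kabsch on a mirrored set stays a proper rotation with residual", {
  # a planar (3-point) mirror is achievable by a proper rotation, so a
  # tetrahedron is needed for a genuinely chiral configuration
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  dst <- src
  dst[, 1] <- -dst[, 1]  # reflection
  tf <- kabsch_align(src, dst)
  expect_equal(det(tf$R), 1, tolerance = 1e-9)
  res <- sum((transform_points(tf, src) - dst)^2)
  expect_gt(res, 1e-6)
  # optimal proper-rotation residual equals the brute-force minimum
  expect_equal(res, brute_kabsch_rss_o(src, dst), tolerance = 1e-6)
})

test_that("kabsch matches brute-force axis-angle minimization (property)", {
  set.seed(7)
  for (rep in 1:5) {
    src <- matrix(rnorm(12, sd = 10), 4, 3)
    dst <- matrix(rnorm(12, sd = 10), 4, 3)
    tf <- kabsch_align(src, dst)
    rss <- sum((transform_points(tf, src) - dst)^2)
    expect_equal(rss, brute_kabsch_rss_o(src, dst), tolerance = 1e-6)
  }
})

test_that("icp_refine is a fixed point on identical meshes, log monotone", {
  f <- small_face(28)
  out <- icp_refine(f$mesh, f$mesh, rigid_transform(),
                    icp_params(min_iter = 5))
  expect_lt(out$rms, 1e-12)
  expect_equal(out$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(out$transform$t, c(0, 0, 0), tolerance = 1e-9)
  expect_true(all(diff(out$log$rms) <= 1e-12))
  expect_gte(nrow(out$log), 5)
})

test_that("icp_refine rejects outlier spikes beyond the tolerance", {
  f <- small_face(36)
  ref <- f$mesh
  # spike: push one interior vertex 10 mm anterior on a copy of the reference
  spike <- ref
  vi <- which.min(rowSums(sweep(ref$vertices, 2, c(20, 30, 20))^2))
  spike$vertices[vi, 2] <- spike$vertices[vi, 2] + 10
  init <- rigid_transform(rotation_axis_angle(c(0, 0, 1), 1), c(0.5, 0, 0))
  test <- transform_object(invert_transform(init), ref)
  with_spike <- icp_refine(test, spike, init, icp_params(tolerance = 2))
  without <- icp_refine(test, ref, init, icp_params(tolerance = 2))
  expect_equal(with_spike$transform$t, without$transform$t,
               tolerance = 1e-3)
  expect_equal(rotation_angle_deg(t(with_spike$transform$R) %*%
                                    without$transform$R), 0,
               tolerance = 1e-3)
})

test_that("icp_refine errors when every correspondence is rejected", {
  f <- small_face(24)
  far <- transform_object(rigid_transform(diag(3), c(0, 500, 0)), f$mesh)
  expect_error(icp_refine(far, f$mesh, rigid_transform(),
                          icp_params(tolerance = 2)),
               "no-overlap.*iteration 1")
})

test_that("two_step_register recovers a rigid perturbation exactly", {
  pair <- generate_face_pair(
    synthetic_face_spec(resolution = 40),
    deformation_spec(rigid = list(axis = c(1, 2, 0.5), angle_deg = 5,
                                  translation = c(3, -1, 2)),
                     noise_sd = 0))
  reg <- two_step_register(pair$test, pair$reference, pair$test_landmarks,
                           pair$reference_landmarks)
  comp <- compose_transforms(reg$transform, pair$rigid)
  expect_lt(rotation_angle_deg(comp$R), 0.05)
  expect_lt(sqrt(sum(comp$t^2)), 0.02)
  # and a deviation field over the registered mesh is at the noise floor
  reg_mesh <- transform_object(reg$transform, pair$test)
  expect_lt(rmse(deviation_field(reg_mesh, pair$reference))$rmse, 1e-3)
})

test_that("two_step_register errors name the missing registration landmark", {
  pair <- generate_face_pair(synthetic_face_spec(resolution = 24),
                             deformation_spec(noise_sd = 0))
  lms <- pair$test_landmarks
  drop <- unclass(lms)[setdiff(rownames(lms), "NoseTip"), ]
  expect_error(two_step_register(pair$test, pair$reference,
                                 landmark_set(drop),
                                 pair$reference_landmarks),
               "NoseTip")
})

test_that("two_step_register is equivariant under a common rigid motion", {
  pair <- generate_face_pair(
    synthetic_face_spec(resolution = 32),
    deformation_spec(rigid = list(axis = c(0, 1, 0), angle_deg = 3,
                                  translation = c(1, 2, -1)),
                     noise_sd = 0))
  base <- two_step_register(pair$test, pair$reference, pair$test_landmarks,
                            pair$reference_landmarks)$transform
  Q <- rigid_transform(rotation_axis_angle(c(1, 1, 1), 25), c(10, -5, 8))
  conj <- two_step_register(
    transform_object(Q, pair$test), transform_object(Q, pair$reference),
    transform_object(Q, pair$test_landmarks),
    transform_object(Q, pair$reference_landmarks))$transform
  expected <- compose_transforms(Q, compose_transforms(base,
                                                       invert_transform(Q)))
  expect_equal(conj$R, expected$R, tolerance = 1e-6)
  expect_equal(conj$t, expected$t, tolerance = 1e-6)
})
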