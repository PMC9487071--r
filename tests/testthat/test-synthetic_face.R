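test_that("generation is deterministic and anatomically symmetric", {
  a <- generate_face(synthetic_face_spec(resolution = 32, seed = 1))
  b <- generate_face(synthetic_face_spec(resolution = 32, seed = 1))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(unclass(a$landmarks), unclass(b$landmarks))

  tl <- landmark_point(a$landmarks, "TragionL")
  tr <- landmark_point(a$landmarks, "TragionR")
  expect_equal(tl * c(-1, 1, 1), tr, tolerance = 1e-12)
  expect_lt(abs(tl[1] + tr[1]), 1e-9)

  # featureless dome: nose tip and nasion rows are symmetric about the dome
  flat <- generate_face(synthetic_face_spec(resolution = 32, nose_amp = 0,
                                            brow_amp = 0, lip_amp = 0,
                                            chin_amp = 0))
  expect_equal(landmark_point(flat$landmarks, "Prn")[2],
               landmark_point(flat$landmarks, "NasionSoft")[2],
               tolerance = 1e-12)
  expect_error(synthetic_face_spec(resolution = 10), "resolution")
})

test_that("landmarks lie on the generated surface", {
  f <- generate_face()  # default resolution
  cp <- closest_on_mesh(unclass(f$landmarks), f$mesh)
  # analytic landmark positions vs the piecewise-linear mesh: within the
  # chord error of the default grid (worst at the steep lateral boundary)
  expect_lt(max(cp$dist), 0.3)
})

test_that("empty deformation is the identity with zero ground truth", {
  f <- small_face(32)
  out <- apply_deformation(f$mesh, f$landmarks,
                           deformation_spec(noise_sd = 0))
  expect_equal(out$mesh$vertices, f$mesh$vertices, tolerance = 0)
  expect_identical(out$truth, rep(0, nrow(f$mesh$vertices)))
  expect_equal(unclass(out$landmarks), unclass(f$landmarks), tolerance = 0)
})

test_that("a single bump displaces its anchor vertex by the amplitude", {
  f <- small_face(32)
  vi <- 200L
  anchor <- f$mesh$vertices[vi, ]
  out <- apply_deformation(
    f$mesh, f$landmarks,
    deformation_spec(bumps = list(list(center = anchor, width = 8,
                                       amplitude = 1.25,
                                       direction = "normal")),
                     noise_sd = 0))
  expect_equal(out$truth[vi], 1.25, tolerance = 1e-9)
  expect_equal(sqrt(sum((out$mesh$vertices[vi, ] - anchor)^2)), 1.25,
               tolerance = 1e-9)
  expect_error(
    apply_deformation(f$mesh, f$landmarks,
                      deformation_spec(bumps = list(
                        list(center = c(0, NA, 0), width = 5,
                             amplitude = 1)))),
    "unresolvable")
})

test_that("rigid-only deformation is an isometry with zero truth", {
  f <- small_face(32)
  d <- deformation_spec(rigid = list(axis = c(0, 0, 1), angle_deg = 10,
                                     translation = c(5, 0, 0)),
                        noise_sd = 0)
  out <- apply_deformation(f$mesh, f$landmarks, d)
  expect_identical(out$truth, rep(0, nrow(f$mesh$vertices)))
  L0 <- unclass(f$landmarks)
  L1 <- unclass(out$landmarks)
  expect_equal(as.numeric(dist(L1)), as.numeric(dist(L0)),
               tolerance = 1e-9)
  # vertex pairwise distances preserved (sampled)
  set.seed(1)
  i <- sample(nrow(f$mesh$vertices), 50)
  expect_equal(as.numeric(dist(out$mesh$vertices[i, ])),
               as.numeric(dist(f$mesh$vertices[i, ])), tolerance = 1e-9)
})

test_that("noise is seed-deterministic and leaves landmarks untouched", {
  f <- small_face(32)
  d <- deformation_spec(noise_sd = 0.05, seed = 42)
  a <- apply_deformation(f$mesh, f$landmarks, d)
  b <- apply_deformation(f$mesh, f$landmarks, d)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_equal(unclass(a$landmarks), unclass(f$landmarks), tolerance = 0)
  rms_noise <- sqrt(mean(rowSums((a$mesh$vertices - f$mesh$vertices)^2)))
  expect_gt(rms_noise, 0.02)
  expect_lt(rms_noise, 0.1)
})
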