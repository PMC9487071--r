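canonical_frame_lms <- function() {
  landmark_set(list(TragionL = c(60, 0, 0), TragionR = c(-60, 0, 0),
                    SuborbitalR = c(-40, 70, 0), Prn = c(0, 90, -20)))
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("facial frame: canonical configuration and equivariance", {
  fr <- build_facial_frame(canonical_frame_lms())
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fr$x, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$z, c(0, 0, 1), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:3) {
    Q <- random_rigid()
    fr2 <- build_facial_frame(transform_object(Q, canonical_frame_lms()))
    expect_equal(fr2$x, as.numeric(Q$R %*% fr$x), tolerance = 1e-9)
    expect_equal(fr2$y, as.numeric(Q$R %*% fr$y), tolerance = 1e-9)
    expect_equal(fr2$z, as.numeric(Q$R %*% fr$z), tolerance = 1e-9)
    expect_equal(fr2$origin, transform_points(Q, fr$origin),
                 tolerance = 1e-9)
  }
  # right-handed orthonormal axes
  expect_equal(cross3_test(fr$x, fr$y), fr$z, tolerance = 1e-9)

  bad <- landmark_set(list(TragionL = c(1, 0, 0), TragionR = c(1, 0, 0),
                           SuborbitalR = c(0, 1, 0), Prn = c(0, 2, 0)))
  expect_error(build_facial_frame(bad), "tragions coincide")
  flat <- landmark_set(list(TragionL = c(60, 0, 0), TragionR = c(-60, 0, 0),
                            SuborbitalR = c(0, 0, 0), Prn = c(0, 2, 0)))
  expect_error(build_facial_frame(flat), "tragion line")
})

test_that("region crops are nontrivial and perioral is nested in facial", {
  f <- small_face(40)
  fr <- build_facial_frame(f$landmarks)
  fa <- crop_region(f$mesh, f$landmarks, fr, "facial")
  pe <- crop_region(f$mesh, f$landmarks, fr, "perioral")
  n <- nrow(f$mesh$vertices)
  expect_gt(nrow(fa$vertices), 0)
  expect_lt(nrow(fa$vertices), n)
  expect_true(all(attr(pe, "orig_index") %in% attr(fa, "orig_index")))

  # degenerate: menton above subnasale -> empty perioral band
  lms <- unclass(f$landmarks)
  lms["Me'", ] <- lms["Sn", ] + c(0, 0, 5)
  expect_error(crop_region(f$mesh, landmark_set(lms), fr, "perioral"),
               "empty crop")
})

test_that("deviation field: zero on identity, exact on offset plane", {
  f <- small_face(28)
  fld <- deviation_field(f$mesh, f$mesh)
  expect_equal(max(abs(fld$signed)), 0, tolerance = 1e-12)

  # plane z = 0 with +z normals vs the same grid lifted by +0.5
  g <- expand.grid(x = 0:6, y = 0:6)
  V <- cbind(g$x, g$y, 0)
  idx <- function(i, j) i + 7L * (j - 1L)
  F <- do.call(rbind, lapply(1:6, function(j) do.call(rbind, lapply(1:6,
    function(i) rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                      c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  plane <- triangle_mesh(V, F)
  lifted <- triangle_mesh(cbind(g$x, g$y, 0.5), F)
  fld2 <- deviation_field(lifted, plane)
  expect_equal(fld2$signed, rep(0.5, nrow(V)), tolerance = 1e-12)

  expect_error(deviation_field(plane, triangle_mesh(V, matrix(integer(),
                                                              0, 3))),
               "no faces")
})

test_that("closest-point queries match the exhaustive oracle", {
  mesh <- decimate_faces(small_face(20)$mesh, stride = 4L)
  expect_lte(nrow(mesh$faces), 200)
  set.seed(3)
  n <- 250
  Q <- cbind(runif(n, -80, 80), runif(n, -20, 90), runif(n, -95, 95))
  res <- closest_on_mesh(Q, mesh)
  for (i in seq_len(n)) {
    o <- brute_closest_o(Q[i, ], mesh)
    expect_equal(res$dist[i], o$dist, tolerance = 1e-9)
  }
})

test_that("deviation distances are invariant to a common rigid motion", {
  f <- small_face(24)
  d <- deformation_spec(bumps = list(list(center = "Gl", width = 15,
                                          amplitude = 1.5,
                                          direction = "normal")),
                        noise_sd = 0)
  out <- apply_deformation(f$mesh, f$landmarks, d)
  base <- deviation_field(out$mesh, f$mesh)$signed
  set.seed(5)
  Q <- random_rigid()
  moved <- deviation_field(transform_object(Q, out$mesh),
                           transform_object(Q, f$mesh))$signed
  expect_equal(abs(moved), abs(base), tolerance = 1e-9)
})

test_that("rmse implements the printed formula", {
  expect_equal(rmse(c(0, 0, 0))$rmse, 0)
  expect_equal(rmse(c(1, 2, 2))$rmse, sqrt(3), tolerance = 1e-12)
  expect_equal(rmse(rep(-0.7, 10))$rmse, 0.7, tolerance = 1e-12)
  s <- rmse(c(1, -2, 2))
  expect_equal(s$rmse^2, mean(c(1, 4, 4)), tolerance = 1e-12)
  expect_error(rmse(numeric()), "empty")
})

test_that("cohort summary uses the t-based confidence interval", {
  s <- cohort_summary(c(1, 1, 1, 1))
  expect_equal(s$ci, c(1, 1))
  s2 <- cohort_summary(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s2$ci, 1 + c(-1, 1) * qt(0.975, 1) * 1, tolerance = 1e-12)
  expect_error(cohort_summary(1.5), "at least 2")
})

test_that("landmark deviation decomposes in frame axes with Pythagoras", {
  fr <- build_facial_frame(canonical_frame_lms())
  ref <- landmark_set(list(Prn = c(0, 90, -20), `Me'` = c(0, 60, -70)))
  tst <- landmark_set(list(Prn = c(0.3, 90.4, -20), `Me'` = c(0, 60, -70)))
  d <- landmark_deviation(tst, ref, fr)
  prn <- d[d$landmark == "Prn", ]
  expect_equal(prn$Dx, 0.3, tolerance = 1e-12)
  expect_equal(prn$Dy, 0.4, tolerance = 1e-12)
  expect_equal(prn$Dz, 0, tolerance = 1e-12)
  expect_equal(prn$D, 0.5, tolerance = 1e-12)
  me <- d[d$landmark == "Me'", ]
  expect_equal(me$D, 0)

  set.seed(9)
  for (rep in 1:10) {
    delta <- rnorm(3)
    t2 <- landmark_set(list(Prn = c(0, 90, -20) + delta))
    r2 <- landmark_set(list(Prn = c(0, 90, -20)))
    dd <- landmark_deviation(t2, r2, fr)
    expect_equal(dd$D^2, dd$Dx^2 + dd$Dy^2 + dd$Dz^2, tolerance = 1e-12)
  }
  expect_error(landmark_deviation(ref, ref, fr, names = "Sto"), "Sto")
})

test_that("colorize maps the diverging palette with clamping", {
  f <- small_face(24)
  n <- nrow(f$mesh$vertices)
  mkfield <- function(vals) structure(list(points = f$mesh$vertices,
                                           signed = vals, region = "facial",
                                           n = n),
                                      class = "deviation_field")
  green <- colorize(mkfield(rep(0, n)), f$mesh, limit = 2)
  expect_true(all(green$colors[, 2] == 1 & green$colors[, 1] == 0 &
                    green$colors[, 3] == 0))
  red <- colorize(mkfield(rep(2, n)), f$mesh, limit = 2)
  expect_true(all(red$colors[, 1] == 1 & red$colors[, 2] == 0))
  clamped <- colorize(mkfield(rep(-4, n)), f$mesh, limit = 2)
  at_limit <- colorize(mkfield(rep(-2, n)), f$mesh, limit = 2)
  expect_identical(clamped$colors, at_limit$colors)
  expect_error(colorize(mkfield(rep(0, n)), f$mesh, limit = 0), "limit")
})
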