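#' ICP parameter set
#'
#' Controls the best-fit (ICP) refinement stage. Defaults honor the study
#' protocol: at least 50 iterations, convergence precision well below 0.1 mm
#' (threshold 1e-3 mm on the RMS change), correspondence rejection tolerance
#' 2 mm, and all test vertices used (sampling fraction 1 = "100%").
#'
#' @param min_iter minimum number of iterations (default 50).
#' @param max_iter maximum number of iterations (default 500).
#' @param threshold convergence threshold on |change in RMS| (mm).
#' @param tolerance correspondence rejection distance (mm).
#' @param fraction fraction of test vertices used, in (0, 1]; sub-sampling is
#'   a deterministic stride.
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(min_iter = 50L, max_iter = 500L, threshold = 1e-3,
                       tolerance = 2, fraction = 1) {
  stopifnot(min_iter <= max_iter, threshold > 0, tolerance > 0,
            fraction > 0, fraction <= 1)
  structure(list(min_iter = as.integer(min_iter),
                 max_iter = as.integer(max_iter),
                 threshold = threshold, tolerance = tolerance,
                 fraction = fraction),
            class = "icp_params")
}

#' Least-squares rigid alignment of paired points (Kabsch)
#'
#' Returns the proper rigid transform `T` minimizing
#' `sum_i || T(src_i) - dst_i ||^2` over rotations and translations, via SVD
#' of the cross-covariance with determinant correction (reflections are
#' excluded).
#'
#' @param src,dst n x 3 matrices of corresponding points, n >= 3, not
#'   collinear.
#' @return A [rigid_transform()].
#' @export
kabsch_align <- function(src, dst) {
  src <- as.matrix(src)
  dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must have equal point counts")
  if (nrow(src) < 3L) stop("at least 3 point pairs are required")
  cs <- colMeans(src)
  cd <- colMeans(dst)
  X <- sweep(src, 2, cs)
  Y <- sweep(dst, 2, cd)
  # collinearity check: second singular value of the centered source cloud
  sv <- svd(X)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("degenerate configuration: points are collinear")
  H <- crossprod(X, Y)  # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' ICP refinement against a reference surface
#'
#' Point-to-surface iterative closest point: at each iteration the (possibly
#' sub-sampled) test vertices are transformed by the current estimate, paired
#' with their exact closest points on the reference surface, pairs farther
#' than `tolerance` are rejected, and a Kabsch update is estimated from the
#' survivors. An update that would increase the RMS is not accepted (the
#' iteration log is therefore monotone non-increasing). The convergence test
#' |change in RMS| < `threshold` is applied only after `min_iter` iterations.
#'
#' @param test a [triangle_mesh()] to align.
#' @param reference the fixed reference [triangle_mesh()].
#' @param init initial [rigid_transform()] (e.g. from [kabsch_align()]).
#' @param params an [icp_params()].
#' @return List with `transform` (composite [rigid_transform()]), `rms`
#'   (final RMS over accepted correspondences, mm), and `log` (data frame of
#'   per-iteration RMS and pair counts).
#' @export
icp_refine <- function(test, reference, init = rigid_transform(),
                       params = icp_params()) {
  stopifnot(inherits(test, "triangle_mesh"),
            inherits(reference, "triangle_mesh"),
            inherits(init, "rigid_transform"),
            inherits(params, "icp_params"))
  if (nrow(test$vertices) == 0L || nrow(reference$vertices) == 0L)
    stop("empty mesh")
  n <- nrow(test$vertices)
  if (params$fraction < 1) {
    stride <- max(1L, floor(1 / params$fraction))
    pts0 <- test$vertices[seq(1L, n, by = stride), , drop = FALSE]
  } else pts0 <- test$vertices

  tf <- init
  p <- transform_points(tf, pts0)
  cp <- closest_on_mesh(p, reference)
  rms_prev <- Inf
  log_rms <- numeric(0)
  log_n <- integer(0)
  for (it in seq_len(params$max_iter)) {
    keep <- cp$dist <= params$tolerance
    if (!any(keep))
      stop("no-overlap: all correspondences rejected at iteration ", it)
    rms <- sqrt(mean(cp$dist[keep]^2))
    cand <- kabsch_align(p[keep, , drop = FALSE],
                         cp$point[keep, , drop = FALSE])
    tf_cand <- compose_transforms(cand, tf)
    # accept only non-increasing RMS (point-to-surface updates carry no
    # point-to-point monotonicity guarantee, so verify before accepting)
    p2 <- transform_points(tf_cand, pts0)
    cp2 <- closest_on_mesh(p2, reference)
    keep2 <- cp2$dist <= params$tolerance
    rms_new <- if (any(keep2)) sqrt(mean(cp2$dist[keep2]^2)) else Inf
    if (rms_new <= rms + 1e-15) {
      tf <- tf_cand
      p <- p2
      cp <- cp2
      rms_acc <- rms_new
    } else rms_acc <- rms
    log_rms <- c(log_rms, rms_acc)
    log_n <- c(log_n, sum(keep))
    if (it >= params$min_iter && abs(rms_prev - rms_acc) < params$threshold)
      break
    rms_prev <- rms_acc
  }
  list(transform = tf, rms = log_rms[length(log_rms)],
       log = data.frame(iteration = seq_along(log_rms), rms = log_rms,
                        pairs = log_n))
}

#' Two-step registration: landmark alignment then best-fit ICP
#'
#' Stage 1 is a Kabsch alignment on the four registration landmarks
#' (bilateral lateral canthus, nose tip, soft-tissue nasion); stage 2 refines
#' with point-to-surface ICP over the whole test mesh seeded with the stage-1
#' transform.
#'
#' @param test,reference [triangle_mesh()] objects (test is moved onto
#'   reference).
#' @param test_lms,reference_lms [landmark_set()] objects; both must contain
#'   CanthusL, CanthusR, NoseTip, NasionSoft.
#' @param params an [icp_params()].
#' @return List with `transform` (composite), `landmark_rms` (stage-1 RMS on
#'   the 4 landmarks), `surface_rms` (final ICP RMS) and `log`.
#' @export
two_step_register <- function(test, reference, test_lms, reference_lms,
                              params = icp_params()) {
  reg_names <- c("CanthusL", "CanthusR", "NoseTip", "NasionSoft")
  require_landmarks(test_lms, reg_names)
  require_landmarks(reference_lms, reg_names)
  src <- unclass(test_lms)[reg_names, , drop = FALSE]
  dst <- unclass(reference_lms)[reg_names, , drop = FALSE]
  init <- kabsch_align(src, dst)
  lm_rms <- sqrt(mean(rowSums((transform_points(init, src) - dst)^2)))
  ref <- icp_refine(test, reference, init, params)
  list(transform = ref$transform, landmark_rms = lm_rms,
       surface_rms = ref$rms, log = ref$log)
}
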