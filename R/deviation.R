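#' Build the anatomical facial coordinate frame
#'
#' Origin at the midpoint of the bilateral tragions; x axis along the
#' tragion line (toward the subject's left); the soft-tissue Frankfort
#' horizontal plane through both tragions and the right suborbital point is
#' the x-y plane; z completes a right-handed frame pointing superior. The
#' sign of z is fixed by requiring the anterior (y) axis to point toward the
#' pronasale. Left, superior and anterior are the positive directions.
#'
#' @param lms a [landmark_set()] containing TragionL, TragionR, SuborbitalR
#'   and Prn.
#' @return An object of class `facial_frame`: list with `origin` and unit
#'   `x`, `y`, `z` axes.
#' @export
build_facial_frame <- function(lms) {
  require_landmarks(lms, c("TragionL", "TragionR", "SuborbitalR", "Prn"))
  tl <- landmark_point(lms, "TragionL")
  tr <- landmark_point(lms, "TragionR")
  so <- landmark_point(lms, "SuborbitalR")
  prn <- landmark_point(lms, "Prn")
  origin <- (tl + tr) / 2
  xv <- tl - tr
  if (sqrt(sum(xv^2)) < 1e-9) stop("degenerate plane: tragions coincide")
  xhat <- xv / sqrt(sum(xv^2))
  nrm <- cross3(xv, so - tr)
  if (sqrt(sum(nrm^2)) < 1e-9 * sqrt(sum(xv^2)) * sqrt(sum((so - tr)^2)) ||
      sqrt(sum(nrm^2)) == 0)
    stop("degenerate plane: SuborbitalR lies on the tragion line")
  zhat <- nrm / sqrt(sum(nrm^2))
  yhat <- cross3(zhat, xhat)
  if (sum(yhat * (prn - origin)) < 0) {
    zhat <- -zhat
    yhat <- -yhat
  }
  structure(list(origin = origin, x = xhat, y = yhat, z = zhat),
            class = "facial_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Express points in a facial frame
#'
#' @param frame a `facial_frame`.
#' @param pts n x 3 matrix or length-3 vector of world points.
#' @return Coordinates relative to the frame (x transverse-left, y anterior,
#'   z superior).
#' @export
frame_coordinates <- function(frame, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L) else as.matrix(pts)
  B <- cbind(frame$x, frame$y, frame$z)
  out <- sweep(p, 2, frame$origin) %*% B
  if (vec) as.numeric(out) else out
}

#' Crop a landmark-defined facial region
#'
#' Replaces interactive segmentation with reproducible landmark-driven
#' bounds in the anatomical frame. `facial`: frame-z between z(Me') - 5 mm
#' and z(Gl) + 10 mm, frame-x between the tragions. `perioral`: frame-z in
#' [z(Me'), z(Sn)], |frame-x| <= 1.2 * max(|x(Lch)|, |x(Rch)|). Faces are
#' kept iff all three vertices are kept. The returned mesh carries an
#' `orig_index` attribute mapping kept vertices to input vertex indices.
#'
#' @param mesh a [triangle_mesh()].
#' @param lms a [landmark_set()] (reference-side landmarks).
#' @param frame a `facial_frame` built from `lms`.
#' @param region `"facial"` or `"perioral"`.
#' @return The cropped [triangle_mesh()].
#' @export
crop_region <- function(mesh, lms, frame, region = c("facial", "perioral")) {
  region <- match.arg(region)
  fc <- frame_coordinates(frame, mesh$vertices)
  if (region == "facial") {
    require_landmarks(lms, c("TragionL", "TragionR", "Me'", "Gl"))
    zlo <- frame_coordinates(frame, landmark_point(lms, "Me'"))[3] - 5
    zhi <- frame_coordinates(frame, landmark_point(lms, "Gl"))[3] + 10
    xlo <- frame_coordinates(frame, landmark_point(lms, "TragionR"))[1]
    xhi <- frame_coordinates(frame, landmark_point(lms, "TragionL"))[1]
    keep <- fc[, 3] >= zlo & fc[, 3] <= zhi & fc[, 1] >= xlo & fc[, 1] <= xhi
  } else {
    require_landmarks(lms, c("Sn", "Me'", "Lch", "Rch"))
    zlo <- frame_coordinates(frame, landmark_point(lms, "Me'"))[3]
    zhi <- frame_coordinates(frame, landmark_point(lms, "Sn"))[3]
    halfw <- 1.2 * max(abs(frame_coordinates(frame,
                                             landmark_point(lms, "Lch"))[1]),
                       abs(frame_coordinates(frame,
                                             landmark_point(lms, "Rch"))[1]))
    keep <- fc[, 3] >= zlo & fc[, 3] <= zhi & abs(fc[, 1]) <= halfw
  }
  if (!any(keep)) stop("empty crop: no vertex inside the ", region, " region")
  newid <- cumsum(keep)
  fkeep <- keep[mesh$faces[, 1]] & keep[mesh$faces[, 2]] & keep[mesh$faces[, 3]]
  faces <- matrix(newid[mesh$faces[fkeep, , drop = FALSE]], ncol = 3L)
  out <- triangle_mesh(mesh$vertices[keep, , drop = FALSE], faces,
                       if (!is.null(mesh$colors))
                         mesh$colors[keep, , drop = FALSE])
  attr(out, "orig_index") <- which(keep)
  out
}

#' Signed point-to-surface deviation field
#'
#' For every test vertex, the exact closest point on the reference surface;
#' the sign is taken from the outward reference face normal at the closest
#' point (positive = test lies anterior/outside the reference). The test
#' mesh must already be registered to the reference.
#'
#' @param test a [triangle_mesh()] (already registered).
#' @param reference a [triangle_mesh()] with consistently oriented faces;
#'   orientation is normalized with [orient_outward()].
#' @param region optional region label carried in the result.
#' @return An object of class `deviation_field`: list with `points` (test
#'   vertices), `signed` (signed distances, mm), `closest`, `region`, `n`.
#' @export
deviation_field <- function(test, reference, region = "facial") {
  stopifnot(inherits(test, "triangle_mesh"),
            inherits(reference, "triangle_mesh"))
  if (nrow(reference$faces) == 0L) stop("reference mesh has no faces")
  if (nrow(test$vertices) == 0L) stop("empty test mesh")
  reference <- orient_outward(reference)
  cp <- closest_on_mesh(test$vertices, reference)
  fn <- face_normals(reference)$normal
  s <- sign(rowSums((test$vertices - cp$point) * fn[cp$tri, , drop = FALSE]))
  s[s == 0] <- 1
  structure(list(points = test$vertices, signed = s * cp$dist,
                 closest = cp$point, region = region,
                 n = nrow(test$vertices)),
            class = "deviation_field")
}

#' RMSE summary of a deviation field
#'
#' RMS = sqrt(mean(d_i^2)) over the signed point-to-surface distances; the
#' mean signed deviation and its SD are reported alongside.
#'
#' @param field a [deviation_field()] (or a bare numeric vector of
#'   distances).
#' @return An object of class `deviation_summary`: list with `rmse`, `mean`,
#'   `sd`, `n`.
#' @export
rmse <- function(field) {
  d <- if (inherits(field, "deviation_field")) field$signed
  else as.numeric(field)
  if (!length(d)) stop("empty deviation field")
  structure(list(rmse = sqrt(mean(d^2)), mean = mean(d),
                 sd = if (length(d) > 1L) sd(d) else NA_real_,
                 n = length(d)),
            class = "deviation_summary")
}

#' Cohort summary of per-model RMSEs
#'
#' Mean, SD (n-1 denominator) and the t-based 95% confidence interval
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)` of a cohort of per-model RMSE
#' values.
#'
#' @param per_model_rmse numeric vector of per-model RMSEs (mm), length >= 2.
#' @param conf confidence level (default 0.95).
#' @return List with `mean`, `sd`, `ci` (length-2), `n`.
#' @export
cohort_summary <- function(per_model_rmse, conf = 0.95) {
  x <- as.numeric(per_model_rmse)
  n <- length(x)
  if (n < 2L) stop("cohort summary needs at least 2 values")
  m <- mean(x)
  s <- sd(x)
  hw <- qt(1 - (1 - conf) / 2, n - 1L) * s / sqrt(n)
  list(mean = m, sd = s, ci = c(m - hw, m + hw), n = n)
}

#' Landmark deviation decomposition
#'
#' Test-minus-reference landmark displacement expressed in the anatomical
#' frame: D is the total deviation, Dx/Dy/Dz the absolute per-axis components
#' (x transverse, y sagittal/anteroposterior, z vertical). D^2 =
#' Dx^2 + Dy^2 + Dz^2.
#'
#' @param test_lms,ref_lms [landmark_set()] objects.
#' @param frame a `facial_frame`.
#' @param names landmarks to evaluate (default: those present in both sets).
#' @return Data frame with columns landmark, D, Dx, Dy, Dz (mm).
#' @export
landmark_deviation <- function(test_lms, ref_lms, frame, names = NULL) {
  if (is.null(names))
    names <- intersect(rownames(ref_lms), rownames(test_lms))
  require_landmarks(test_lms, names)
  require_landmarks(ref_lms, names)
  B <- cbind(frame$x, frame$y, frame$z)
  delta <- (unclass(test_lms)[names, , drop = FALSE] -
              unclass(ref_lms)[names, , drop = FALSE]) %*% B
  data.frame(landmark = names,
             D = sqrt(rowSums(delta^2)),
             Dx = abs(delta[, 1]), Dy = abs(delta[, 2]),
             Dz = abs(delta[, 3]), row.names = NULL)
}

#' Color-code a deviation field onto a mesh
#'
#' Symmetric diverging blue-green-red palette over [-limit, +limit], clamped
#' beyond: negative (inside the reference) shades toward blue, zero is green,
#' positive (outside) shades toward red.
#'
#' @param field a [deviation_field()] sampled at the test vertices.
#' @param test the test [triangle_mesh()].
#' @param limit color range half-width (mm), > 0.
#' @return The test mesh with per-vertex colors.
#' @export
colorize <- function(field, test, limit = 2) {
  stopifnot(inherits(field, "deviation_field"),
            inherits(test, "triangle_mesh"))
  if (limit <= 0) stop("limit must be > 0")
  if (length(field$signed) != nrow(test$vertices))
    stop("field is not sampled at the test vertices")
  t <- pmin(1, pmax(0, (field$signed + limit) / (2 * limit)))
  col <- matrix(0, length(t), 3L)
  lo <- t < 0.5  # blue -> green
  col[lo, 3] <- 1 - 2 * t[lo]
  col[lo, 2] <- 2 * t[lo]
  col[!lo, 1] <- 2 * t[!lo] - 1
  col[!lo, 2] <- 2 - 2 * t[!lo]
  triangle_mesh(test$vertices, test$faces, col)
}
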