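#' Construct a rigid transform
#'
#' A proper rigid-body transform `x -> R x + t` (rotation plus translation,
#' millimetres). The rotation must be orthonormal with determinant +1.
#'
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    stop("rotation has determinant != +1 (reflection?)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle",
      format(rotation_angle_deg(x$R), digits = 6), "deg, translation",
      paste(format(x$t, digits = 6), collapse = " "), "mm\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(tf, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1L) else as.matrix(pts)
  out <- p %*% t(tf$R) + rep(tf$t, each = nrow(p))
  if (vec) as.numeric(out) else out
}

#' Apply a rigid transform to a mesh or landmark set
#'
#' @param tf a [rigid_transform()].
#' @param x a [triangle_mesh()] or [landmark_set()].
#' @return The transformed object.
#' @export
transform_object <- function(tf, x) {
  if (inherits(x, "triangle_mesh"))
    triangle_mesh(transform_points(tf, x$vertices), x$faces, x$colors)
  else if (inherits(x, "landmark_set")) {
    out <- transform_points(tf, unclass(x))
    rownames(out) <- rownames(x)
    landmark_set(out, attr(x, "units"))
  } else stop("unsupported object")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is "apply `b` first, then `a`".
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composite [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Rotation matrix from axis and angle
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#' @param R 3 x 3 rotation matrix.
#' @return Angle in degrees, in [0, 180].
#' @export
rotation_angle_deg <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c))) * 180 / pi
}

# internal: per-face unit normals and areas
face_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  list(normal = n / pmax(len, .Machine$double.xmin), area = len / 2)
}

#' Area-weighted per-vertex normals
#'
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normal * fn$area
  # accumulate area-weighted face normals onto the three corner vertices
  idx <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  acc <- rowsum(rbind(w, w, w), group = idx)
  out <- matrix(0, nrow(mesh$vertices), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  out / pmax(len, .Machine$double.xmin)
}

#' Orient all faces consistently outward
#'
#' Flips the winding of every face if the average face normal points toward
#' the mesh centroid rather than away from it. Intended for star-shaped /
#' height-field surfaces where "outward" is well defined.
#'
#' @param mesh a [triangle_mesh()].
#' @return The mesh, possibly with all faces rewound.
#' @export
orient_outward <- function(mesh) {
  fn <- face_normals(mesh)
  cen <- colMeans(mesh$vertices)
  fcen <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  outward <- rowSums(fn$normal * (fcen - rep(cen, each = nrow(fcen))))
  if (sum(outward * fn$area) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Closest points on a mesh surface
#'
#' Exact closest point on the triangulated surface for each query point,
#' accelerated by a uniform spatial grid. Distance ties between triangles are
#' broken toward the lowest triangle index.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a [triangle_mesh()] with at least one face.
#' @return List with `point` (n x 3 closest points), `dist` (n unsigned
#'   distances, mm) and `tri` (1-based index of the closest triangle).
#' @export
closest_on_mesh <- function(points, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("reference mesh has no faces")
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  res <- cpp_closest_points(p, mesh$vertices, mesh$faces - 1L)
  res$tri <- res$tri + 1L
  res
}
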