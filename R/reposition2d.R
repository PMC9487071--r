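#' 2D photo landmarks
#'
#' Named pixel coordinates on a clinical photograph, raster convention
#' (y axis points down). Rotation angles throughout this module are
#' counterclockwise-positive as seen on screen.
#'
#' @param points named list of length-2 numeric vectors or an n x 2 matrix
#'   with row names; names are free-form (e.g. CanthusL, CanthusR, Cheilion,
#'   Trichion, Prn, Me').
#' @param pixel_mm optional pixel pitch (mm per pixel).
#' @return An object of class `photo_landmarks`.
#' @export
photo_landmarks <- function(points, pixel_mm = NULL) {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("photo landmarks must be 2-vectors")
  if (is.null(rownames(points))) stop("photo landmarks must be named")
  if (!all(is.finite(points))) stop("non-finite pixel coordinates")
  structure(points, class = "photo_landmarks", pixel_mm = pixel_mm)
}

photo_point <- function(lms, name) {
  if (!name %in% rownames(lms)) stop("missing photo landmark: ", name)
  as.numeric(lms[name, ])
}

#' Rotate a 2D point (raster convention)
#'
#' Screen-counterclockwise rotation by `angle_deg` about `center`, with the
#' image y axis pointing down.
#'
#' @param p length-2 point or n x 2 matrix.
#' @param center rotation center.
#' @param angle_deg screen-CCW angle in degrees.
#' @return Rotated point(s).
#' @export
rotate_point2d <- function(p, center, angle_deg) {
  th <- angle_deg * pi / 180
  # y-down raster: screen CCW corresponds to [c, s; -s, c]
  Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(p, 1L) else as.matrix(p)
  out <- sweep(pm, 2, center) %*% t(Rm) + rep(center, each = nrow(pm))
  if (vec) as.numeric(out) else out
}

#' Leveling angle for a front photo
#'
#' The screen-CCW rotation (about the image center) that makes the lateral
#' canthus line horizontal, reported in (-90, 90] degrees.
#'
#' @param lms a [photo_landmarks()] with CanthusL and CanthusR.
#' @return Angle in degrees.
#' @export
front_leveling_angle <- function(lms) {
  cl <- photo_point(lms, "CanthusL")
  cr <- photo_point(lms, "CanthusR")
  d <- cl - cr
  if (sqrt(sum(d^2)) == 0) stop("coincident canthi")
  ang <- atan2(d[2], d[1]) * 180 / pi  # raster-frame line angle
  # reduce the line (not vector) angle to (-90, 90]
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Vertical canthus-to-cheilion distance H1 (pixels)
#'
#' The vertical drop from the lateral canthus (of the given side) to the
#' cheilion, measured on a leveled photo.
#'
#' @param lms a [photo_landmarks()].
#' @param side `"L"` or `"R"`: which lateral canthus anchors H1.
#' @param level if `TRUE` (default), the front leveling rotation is applied
#'   before measuring.
#' @return H1 in pixels.
#' @export
h1 <- function(lms, side = c("L", "R"), level = TRUE) {
  side <- match.arg(side)
  canthus_name <- paste0("Canthus", side)
  ch <- photo_point(lms, "Cheilion")
  ca <- photo_point(lms, canthus_name)
  if (level && all(c("CanthusL", "CanthusR") %in% rownames(lms))) {
    ang <- front_leveling_angle(lms)
    ch <- rotate_point2d(ch, c(0, 0), ang)
    ca <- rotate_point2d(ca, c(0, 0), ang)
  }
  abs(ch[2] - ca[2])
}

#' Rotation aligning the lateral photo to the target H1
#'
#' The smallest-magnitude screen-CCW rotation about the canthus that makes
#' the vertical drop of the cheilion equal `target_h1`; of the two solutions,
#' those keeping the cheilion below the canthus (raster y larger) are
#' preferred.
#'
#' @param canthus,cheilion 2D pixel points.
#' @param target_h1 target vertical drop (pixels), at most the
#'   canthus-cheilion distance.
#' @return Angle in degrees.
#' @export
lateral_rotation_angle <- function(canthus, cheilion, target_h1) {
  v <- as.numeric(cheilion) - as.numeric(canthus)
  L <- sqrt(sum(v^2))
  if (target_h1 > L + 1e-12)
    stop("infeasible: target H1 exceeds the canthus-cheilion distance ",
         format(L))
  target_h1 <- min(target_h1, L)
  phi <- atan2(v[2], v[1])
  alpha <- asin(target_h1 / L)
  cand <- (c(phi - alpha, phi - (pi - alpha),
             phi + alpha, phi + (pi - alpha))) * 180 / pi
  cand <- ((cand + 180) %% 360) - 180
  drop_after <- vapply(cand, function(a)
    rotate_point2d(v + c(0, 0), c(0, 0), a)[2], numeric(1))
  below <- abs(drop_after - target_h1) < 1e-9  # cheilion below canthus
  pool <- if (any(below)) cand[below] else
    cand[abs(abs(drop_after) - target_h1) < 1e-9]
  pool[which.min(abs(pool))]
}
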