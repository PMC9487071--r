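#' Inter-landmark distance (mm)
#'
#' 3D Euclidean distance between two named landmarks. All "height"
#' measurements are direct inter-landmark distances (Farkas-style
#' anthropometry), not vertical projections.
#'
#' @param lms a [landmark_set()].
#' @param a,b landmark names.
#' @return Distance in mm.
#' @export
linear_measure <- function(lms, a, b) {
  require_landmarks(lms, c(a, b))
  sqrt(sum((landmark_point(lms, a) - landmark_point(lms, b))^2))
}

#' Angle at a vertex landmark (degrees)
#'
#' Angle between the rays vertex->a and vertex->b, via the arccosine of the
#' normalized dot product (clamped to [-1, 1]). Exactly opposite rays yield
#' 180 degrees with a warning (outside the open (0, 180) range expected of
#' anatomical angles).
#'
#' @param lms a [landmark_set()].
#' @param a,vertex,b landmark names; the angle is measured at `vertex`.
#' @return Angle in decimal degrees.
#' @export
angle_measure <- function(lms, a, vertex, b) {
  require_landmarks(lms, c(a, vertex, b))
  u <- landmark_point(lms, a) - landmark_point(lms, vertex)
  v <- landmark_point(lms, b) - landmark_point(lms, vertex)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate ray: endpoint coincides with the vertex landmark")
  cth <- min(1, max(-1, sum(u * v) / (nu * nv)))
  ang <- acos(cth) * 180 / pi
  if (ang >= 180) warning("collinear opposite rays: angle is 180 degrees")
  ang
}

# the 12 standard soft-tissue measurements: landmark assignments
measurement_table <- function() {
  list(
    linear = list(
      UpperLipHeight      = c("Sn", "Sto"),
      LowerLipHeight      = c("Sl", "Li"),
      UpperVermilionHeight = c("Ls", "Sto"),
      LowerVermilionHeight = c("Li", "Sto"),
      PhiltralLength      = c("Sn", "Ls"),
      PhiltralWidth       = c("CphR", "CphL"),
      LabialFissureWidth  = c("Lch", "Rch"),
      FacialHeight        = c("N'", "Gn'")),
    angular = list(
      NasolabialAngle  = c("Prn", "Sn", "Ls"),
      FacialConvexity  = c("Gl", "Sn", "Pg'"),
      NasalAngle       = c("N'", "Prn", "Sn"),
      NasofrontalAngle = c("Gl", "N'", "Prn")))
}

#' All twelve soft-tissue measurements
#'
#' Eight linear (mm): upper/lower lip height (Sn-Sto, Sl-Li), upper/lower
#' vermilion height (Ls-Sto, Li-Sto), philtral length and width (Sn-Ls,
#' CphR-CphL), labial fissure width (Lch-Rch), facial height (N'-Gn').
#' Four angular (degrees): nasolabial (Prn-Sn-Ls), facial convexity
#' (Gl-Sn-Pg'), nasal (N'-Prn-Sn), nasofrontal (Gl-N'-Prn). Angles are
#' measured at the middle landmark of each triple.
#'
#' @param lms a [landmark_set()] containing the 14 referenced landmarks.
#' @return Named list of 12 numeric values (mm / decimal degrees).
#' @export
measure_all <- function(lms) {
  tab <- measurement_table()
  needed <- unique(c(unlist(tab$linear), unlist(tab$angular)))
  require_landmarks(lms, needed)
  out <- c(
    lapply(tab$linear, function(ab) linear_measure(lms, ab[1], ab[2])),
    lapply(tab$angular, function(avb)
      angle_measure(lms, avb[1], avb[2], avb[3])))
  out
}
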