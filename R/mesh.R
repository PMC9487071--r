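#' Landmark name vocabulary
#'
#' Controlled vocabulary of facial soft-tissue landmark names accepted by
#' landmark sets: pronasale (Prn), labrale superius/inferius (Ls/Li), left and
#' right cheilion (Lch/Rch), pogonion/gnathion/menton of soft tissue
#' (Pg'/Gn'/Me'), subnasale (Sn), stomion (Sto), sublabial (Sl), crista
#' philtri (CphL/CphR), glabella (Gl), soft-tissue nasion (N', NasionSoft),
#' tragions, right suborbital point, lateral canthi, and nose tip.
#'
#' @return Character vector of allowed landmark names.
#' @export
landmark_vocabulary <- function() {
  c("Prn", "Ls", "Li", "Lch", "Rch", "Pg'", "Gn'", "Me'", "Sn", "Sto", "Sl",
    "CphL", "CphR", "Gl", "N'", "TragionL", "TragionR", "SuborbitalR",
    "CanthusL", "CanthusR", "NoseTip", "NasionSoft")
}

#' Construct a triangle mesh
#'
#' A triangulated surface in millimetres. Faces are stored 1-based (R
#' convention); the OBJ reader/writer converts to/from the format's 1-based
#' indices transparently.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param colors optional n x 3 matrix of per-vertex RGB in [0, 1].
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L)
    stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range [1, vertex count]")
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop("degenerate face (repeated vertex index) at face ",
           which(degen)[1])
  }
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "double"
    if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
      stop("colors must be an n x 3 matrix matching the vertices")
    if (any(colors < 0 | colors > 1)) stop("colors must lie in [0, 1]")
  }
  structure(list(vertices = vertices, faces = faces, colors = colors),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", per-vertex colors"))
  invisible(x)
}

#' Construct a landmark set
#'
#' Named anatomical 3D points in millimetres. Names must come from
#' [landmark_vocabulary()].
#'
#' @param points named list of length-3 numeric vectors, or an n x 3 matrix
#'   with row names.
#' @param units unit tag; only "mm" is supported.
#' @return An object of class `landmark_set` (a named k x 3 matrix plus a
#'   units attribute).
#' @export
landmark_set <- function(points, units = "mm") {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("landmark points must be 3-vectors")
  colnames(points) <- NULL
  nm <- rownames(points)
  if (is.null(nm) || any(!nzchar(nm))) stop("landmarks must be named")
  if (anyDuplicated(nm)) stop("duplicate landmark name: ",
                              nm[duplicated(nm)][1])
  bad <- setdiff(nm, landmark_vocabulary())
  if (length(bad))
    stop("unknown landmark name(s): ", paste(bad, collapse = ", "),
         "; allowed names: ", paste(landmark_vocabulary(), collapse = ", "))
  if (!all(is.finite(points))) stop("non-finite landmark coordinates")
  if (!identical(units, "mm")) stop("only units = \"mm\" is supported")
  structure(points, class = "landmark_set", units = units)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set (%s): %d landmarks\n", attr(x, "units"), nrow(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Look up one landmark
#'
#' @param lms a `landmark_set`.
#' @param name landmark name.
#' @return Length-3 numeric vector.
#' @export
landmark_point <- function(lms, name) {
  if (!name %in% rownames(lms)) stop("missing landmark: ", name)
  as.numeric(lms[name, ])
}

# internal: require a set of names, error listing all missing at once
require_landmarks <- function(lms, names) {
  missing <- setdiff(names, rownames(lms))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
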