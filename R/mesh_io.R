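#' Read a Wavefront OBJ mesh
#'
#' Permissive reader for scanner exports: `v` and `f` records are parsed,
#' `vt`/`vn`/material and all other record types are ignored (a note is
#' emitted once per type). Face records may carry `/`-separated texture and
#' normal sub-indices, which are dropped. Polygons with more than three
#' vertices are fan-triangulated around their first vertex. Vertex order is
#' preserved exactly (downstream color maps rely on index stability).
#' Negative (relative) OBJ indices are rejected.
#'
#' @param path path to an OBJ file.
#' @return A [triangle_mesh()].
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  verts <- list()
  faces <- list()
  seen_other <- character()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s) || startsWith(s, "#")) next
    tok <- strsplit(s, "[ \t]+")[[1]]
    key <- tok[1]
    if (key == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4L || any(is.na(xyz)))
        stop("malformed vertex record at line ", ln)
      verts[[length(verts) + 1L]] <- xyz
    } else if (key == "f") {
      if (length(tok) < 4L) stop("malformed face record at line ", ln)
      ref <- vapply(tok[-1], function(t) {
        first <- strsplit(t, "/", fixed = TRUE)[[1]][1]
        v <- suppressWarnings(as.integer(first))
        if (is.na(v)) stop("malformed face record at line ", ln)
        if (v < 0L) stop("negative (relative) OBJ index at line ", ln,
                         " is not supported")
        v
      }, integer(1), USE.NAMES = FALSE)
      # fan triangulation around the first polygon vertex
      for (k in seq_len(length(ref) - 2L))
        faces[[length(faces) + 1L]] <- c(ref[1], ref[k + 1L], ref[k + 2L])
    } else {
      if (!key %in% seen_other) {
        seen_other <- c(seen_other, key)
        message("read_obj: ignoring '", key, "' records")
      }
    }
  }
  if (!length(verts)) stop("no vertex records in ", path)
  if (!length(faces)) stop("no face records in ", path)
  V <- do.call(rbind, verts)
  F <- do.call(rbind, faces)
  if (max(F) > nrow(V) || min(F) < 1L)
    stop("face index out of range [1, ", nrow(V), "]")
  triangle_mesh(V, F)
}

#' Write a Wavefront OBJ mesh
#'
#' Coordinates are written with 17 significant digits so that a
#' read-after-write round trip is lossless at double precision. OBJ has no
#' portable per-vertex color; if the mesh carries colors they are dropped
#' with a warning (use [write_ply_colored()] for color maps).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("refusing to write a mesh with no faces")
  if (!is.null(mesh$colors))
    warning("OBJ cannot carry per-vertex colors; colors dropped")
  vl <- sprintf("v %.17g %.17g %.17g",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  fl <- sprintf("f %d %d %d",
                mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(vl, fl), con)
  invisible(path)
}

#' Write a color mesh as ASCII PLY
#'
#' Export vehicle for color-coded deviation maps: ASCII PLY 1.0 with
#' `x y z red green blue` vertex properties, colors quantized to 8 bits with
#' round-half-up.
#'
#' @param mesh a [triangle_mesh()] with per-vertex colors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ply_colored <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(mesh$colors)) stop("mesh has no per-vertex colors")
  if (nrow(mesh$faces) == 0L) stop("refusing to write a mesh with no faces")
  bytes <- floor(mesh$colors * 255 + 0.5)  # round half up
  bytes[bytes > 255] <- 255
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    "property uchar red", "property uchar green", "property uchar blue",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.17g %.17g %.17g %d %d %d",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                bytes[, 1], bytes[, 2], bytes[, 3])
  fl <- sprintf("3 %d %d %d",
                mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, vl, fl), con)
  invisible(path)
}

#' Read an ASCII PLY mesh (colors supported)
#'
#' Minimal reader for the files produced by [write_ply_colored()], used for
#' round-trip checks.
#'
#' @param path path to an ASCII PLY file.
#' @return A [triangle_mesh()] with colors when present.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file: ", path)
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "",
               grep("^property (double|float|uchar) ",
                    lines[seq_len(endh)], value = TRUE))
  vrows <- lines[(endh + 1):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(vrows, " "), as.numeric))
  colors <- NULL
  if (all(c("red", "green", "blue") %in% props)) {
    ci <- match(c("red", "green", "blue"), props)
    colors <- vm[, ci, drop = FALSE] / 255
  }
  xyz <- vm[, match(c("x", "y", "z"), props), drop = FALSE]
  frows <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(frows, " "), function(t)
    as.integer(t[2:4]) + 1L))
  triangle_mesh(xyz, fm, colors)
}

#' Read a landmark annotation file
#'
#' JSON schema: `{"units": "mm", "landmarks": {"Prn": [x, y, z], ...}}`.
#' Names outside [landmark_vocabulary()] are rejected.
#'
#' @param path path to a landmark JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$units) || is.null(obj$landmarks))
    stop("landmark file must have 'units' and 'landmarks' fields: ", path)
  pts <- obj$landmarks
  bad <- names(pts)[vapply(pts, function(p) length(p) != 3L ||
                             !is.numeric(p), logical(1))]
  if (length(bad))
    stop("landmark(s) not 3-vectors: ", paste(bad, collapse = ", "))
  landmark_set(pts, units = obj$units)
}

#' Write a landmark annotation file
#'
#' @param lms a [landmark_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  pts <- lapply(seq_len(nrow(lms)), function(i) as.numeric(lms[i, ]))
  names(pts) <- rownames(lms)
  obj <- list(units = attr(lms, "units"), landmarks = pts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
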