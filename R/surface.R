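#' Voxel-boundary face set
#'
#' The surface representation used for all area measurements: the exact set
#' of axis-aligned unit faces between voxels of different materials, with no
#' smoothing or decimation, so measured areas reflect the segmentation
#' verbatim. Each row is one face, identified by the 0-based index of its
#' owning voxel, the face axis (1 = x, 2 = y, 3 = z) and orientation (+1 if
#' the face looks towards increasing index). `nb` is the label of the voxel
#' on the other side (`NA` at the volume border).
#'
#' @param df Data frame with columns `i`, `j`, `k`, `axis`, `orient`, `nb`.
#' @param spacing Voxel edge in µm.
#' @param material Label owning the faces.
#' @return An object of class `face_set`.
#' @keywords internal
face_set <- function(df, spacing, material) {
  structure(df, spacing = spacing, material = material,
            class = c("face_set", "data.frame"))
}

#' @export
print.face_set <- function(x, ...) {
  cat(sprintf("<face_set> %d faces of material %d, spacing %.4g um, area %.6g um^2\n",
              nrow(x), attr(x, "material"), attr(x, "spacing"), area_of(x)))
  invisible(x)
}

#' Extract all boundary faces of a material
#'
#' Every face between a voxel of `material` and a 6-neighbour of any other
#' label, plus faces on the volume border.
#'
#' @param labels A [label_volume()].
#' @param material Label whose boundary is wanted (default: implant, 2).
#' @return A [face_set()].
#' @export
extract_boundary_faces <- function(labels, material = 2L) {
  stopifnot(inherits(labels, "label_volume"))
  a <- labels$data
  if (!any(a == material)) stop("material absent from label volume")
  rows <- vector("list", 6)
  n <- 0L
  for (axis in 1:3) for (orient in c(1L, -1L)) {
    nb <- shift_array(a, axis, orient, fill = NA_integer_)
    face <- a == material & (is.na(nb) | nb != material)
    idx <- which(face, arr.ind = TRUE)
    n <- n + 1L
    rows[[n]] <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                            k = idx[, 3] - 1L, axis = axis, orient = orient,
                            nb = nb[face])
  }
  face_set(do.call(rbind, rows), spacing = labels$spacing, material = material)
}

#' Faces at the interface of two materials
#'
#' The subset of boundary faces separating a voxel of label `a` from a
#' 6-neighbouring voxel of label `b`. May be empty.
#'
#' @param labels A [label_volume()].
#' @param a,b Material labels; faces are owned by the `a` voxel.
#' @return A [face_set()].
#' @export
interface_faces <- function(labels, a, b) {
  stopifnot(inherits(labels, "label_volume"))
  if (!any(labels$data == a) || !any(labels$data == b))
    stop("both labels must be present")
  fs <- extract_boundary_faces(labels, a)
  face_set(fs[!is.na(fs$nb) & fs$nb == b, , drop = FALSE],
           spacing = attr(fs, "spacing"), material = a)
}

#' Reduce implant boundary faces to the lateral shell
#'
#' Removes the flat end caps: z-oriented faces whose plane lies within one
#' voxel of the implant's global z-minimum (downward-facing) or z-maximum
#' (upward-facing) slice. All other faces — including the z-oriented terrace
#' faces that a cone's staircase surface legitimately contains at
#' intermediate heights — are retained.
#'
#' @param faces A [face_set()] of implant boundary faces.
#' @param labels The [label_volume()] the faces came from.
#' @return The shell [face_set()].
#' @export
classify_shell <- function(faces, labels) {
  stopifnot(inherits(faces, "face_set"), inherits(labels, "label_volume"))
  imp <- labels$data == attr(faces, "material")
  kz <- which(apply(imp, 3, any)) - 1L        # 0-based slice indices
  zmin <- min(kz); zmax <- max(kz)
  drop <- faces$axis == 3L &
    ((faces$orient == -1L & faces$k <= zmin + 1L) |
     (faces$orient == 1L & faces$k >= zmax - 1L))
  face_set(faces[!drop, , drop = FALSE], spacing = attr(faces, "spacing"),
           material = attr(faces, "material"))
}

#' Physical area of a face set
#'
#' Face count times the squared voxel spacing. Each square face corresponds
#' to two mesh triangles.
#'
#' @param faces A [face_set()].
#' @return Area in µm².
#' @export
area_of <- function(faces) {
  stopifnot(inherits(faces, "face_set"))
  nrow(faces) * attr(faces, "spacing")^2
}

#' Bone-to-implant contact from a label volume
#'
#' Computes, on the voxel-boundary shell of the implant:
#' * `pBIC_area` — possible contact: shell faces adjacent to bone or to
#'   background/marrow (any face a bone voxel could occupy);
#' * `eBIC_area` — effective contact: shell faces adjacent to bone;
#' * `excluded_area` — shell faces adjacent to `excluded` voxels, removed
#'   from the pBIC so the percentage is computed only over the analysable
#'   shell (the denominator correction that accompanies plane cropping);
#' * `pVA = 100 * eBIC / pBIC`.
#'
#' Both areas carry the same staircase (aliasing) overestimation of the
#' smooth shell, which therefore cancels in pVA. Faces on the volume border
#' are not counted.
#'
#' @param labels A [label_volume()] containing an implant and bone and/or
#'   background.
#' @return An object of class `interface_result`.
#' @export
compute_bic3d <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  shell <- classify_shell(extract_boundary_faces(labels, LBL_IMPLANT), labels)
  nb <- shell$nb
  s2 <- attr(shell, "spacing")^2
  n_e <- sum(!is.na(nb) & nb == LBL_BONE)
  n_p <- n_e + sum(!is.na(nb) & nb == LBL_BACKGROUND)
  n_x <- sum(!is.na(nb) & nb == LBL_EXCLUDED)
  if (n_p == 0)
    stop("pBIC is zero: implant shell fully excluded or absent")
  structure(list(
    pBIC_area = n_p * s2, eBIC_area = n_e * s2,
    pVA = 100 * n_e / n_p,
    triangle_count_pBIC = 2L * n_p, triangle_count_eBIC = 2L * n_e,
    excluded_area = n_x * s2, spacing = attr(shell, "spacing")),
    class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf("bone-to-implant contact (voxel-boundary surface, spacing %.4g um)\n",
              x$spacing))
  cat(sprintf("  pBIC %.6g um^2 (%d triangles)\n", x$pBIC_area,
              x$triangle_count_pBIC))
  cat(sprintf("  eBIC %.6g um^2 (%d triangles)\n", x$eBIC_area,
              x$triangle_count_eBIC))
  cat(sprintf("  excluded %.6g um^2\n", x$excluded_area))
  cat(sprintf("  pVA %.2f %%\n", x$pVA))
  invisible(x)
}

#' Staircase-area overestimation of the implant shell
#'
#' Ratio of the voxel-face shell area to a known analytic lateral area of
#' the same geometry. For any curved surface digitized on an axis-aligned
#' grid the ratio exceeds 1 (a right circular cylinder tends to 4/pi as
#' resolution grows); it is exactly 1 for axis-aligned flat faces. The same
#' factor inflates pBIC and eBIC, which is why their ratio pVA remains
#' meaningful.
#'
#' @param labels A [label_volume()] with an implant.
#' @param analytic_area True lateral area of the implant, µm².
#' @return The ratio (dimensionless).
#' @export
aliasing_report <- function(labels, analytic_area) {
  stopifnot(analytic_area > 0)
  shell <- classify_shell(extract_boundary_faces(labels, LBL_IMPLANT), labels)
  area_of(shell) / analytic_area
}

# Quad corners of each face in physical µm. Returns n x 4 x 3 array, corners
# ordered so the right-hand rule gives the outward (orient) normal.
face_quads <- function(faces, origin = c(0, 0, 0)) {
  s <- attr(faces, "spacing")
  n <- nrow(faces)
  quads <- array(0, dim = c(n, 4, 3))
  if (n == 0) return(quads)
  ctr <- cbind(faces$i, faces$j, faces$k) * s +
    matrix(origin, n, 3, byrow = TRUE)
  for (r in seq_len(n)) {
    ax <- faces$axis[r]; o <- faces$orient[r]
    u <- c(1, 2, 3)[-ax]
    ctr_r <- ctr[r, ]
    ctr_r[ax] <- ctr_r[ax] + o * s / 2
    off <- matrix(0, 4, 3)
    du <- c(-1, 1, 1, -1) * s / 2
    dv <- c(-1, -1, 1, 1) * s / 2
    off[, u[1]] <- du; off[, u[2]] <- dv
    if ((ax == 2 && o == 1) || (ax != 2 && o == -1))
      off <- off[c(1, 4, 3, 2), ]  # flip winding for outward normal
    quads[r, , ] <- matrix(ctr_r, 4, 3, byrow = TRUE) + off
  }
  quads
}

#' Export a face set as a triangle mesh
#'
#' Writes each square face as two triangles to binary STL or ASCII PLY
#' (chosen by file extension). Reading the file back recovers the triangle
#' count and total area exactly.
#'
#' @param faces A [face_set()].
#' @param path Output path ending in `.stl` or `.ply`.
#' @param origin Physical position of voxel (0,0,0), µm.
#' @return `path`, invisibly.
#' @export
export_surface <- function(faces, path, origin = c(0, 0, 0)) {
  stopifnot(inherits(faces, "face_set"))
  ext <- tolower(tools::file_ext(path))
  quads <- face_quads(faces, origin)
  n <- nrow(faces)
  # two triangles per quad: (1,2,3) and (1,3,4)
  tri <- array(0, dim = c(2 * max(n, 0), 3, 3))
  if (n > 0) {
    tri[seq_len(n) * 2 - 1, , ] <- quads[, c(1, 2, 3), , drop = FALSE]
    tri[seq_len(n) * 2, , ] <- quads[, c(1, 3, 4), , drop = FALSE]
  }
  if (ext == "stl") write_stl_binary(tri, path)
  else if (ext == "ply") write_ply_ascii(tri, path)
  else stop("unsupported surface format: ", ext)
  invisible(path)
}

write_stl_binary <- function(tri, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "osseoquant voxel-boundary surface"))
  writeBin(header[1:80], con)
  nt <- dim(tri)[1]
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  for (t in seq_len(nt)) {
    v <- tri[t, , ]
    nrm <- pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, t(v))), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

write_ply_ascii <- function(tri, path) {
  nt <- dim(tri)[1]
  verts <- matrix(aperm(tri, c(2, 1, 3)), ncol = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nt),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(verts) > 0)
    writeLines(apply(verts, 1, function(v) paste(format(v, trim = TRUE),
                                                 collapse = " ")), con)
  if (nt > 0)
    writeLines(sprintf("3 %d %d %d", (seq_len(nt) - 1) * 3,
                       (seq_len(nt) - 1) * 3 + 1, (seq_len(nt) - 1) * 3 + 2),
               con)
  invisible(path)
}

#' Read a triangle mesh written by [export_surface()]
#'
#' @param path `.stl` (binary) or `.ply` (ASCII) file.
#' @return List with `triangles` (n x 3 x 3 vertex array) and `area` (sum of
#'   triangle areas, µm²).
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tri <- if (ext == "stl") read_stl_binary(path)
  else if (ext == "ply") read_ply_ascii(path)
  else stop("unsupported surface format: ", ext)
  nt <- dim(tri)[1]
  area <- 0
  for (t in seq_len(nt)) {
    v <- tri[t, , ]
    area <- area + 0.5 * sqrt(sum(pracma_cross(v[2, ] - v[1, ],
                                               v[3, ] - v[1, ])^2))
  }
  list(triangles = tri, area = area)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- array(0, dim = c(nt, 3, 3))
  for (t in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    tri[t, , ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "integer", 1, size = 2, endian = "little")
  }
  tri
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines, value = TRUE)))
  verts <- if (nv > 0)
    matrix(scan(text = lines[(end + 1):(end + nv)], quiet = TRUE),
           ncol = 3, byrow = TRUE) else matrix(0, 0, 3)
  tri <- array(0, dim = c(nf, 3, 3))
  for (f in seq_len(nf)) {
    idx <- as.integer(strsplit(lines[end + nv + f], " ")[[1]][-1]) + 1L
    tri[f, , ] <- verts[idx, ]
  }
  tri
}

#' Serialize an interface result
#'
#' @param x An `interface_result`.
#' @param path Output path; `.json` or `.csv` by extension.
#' @return `path`, invisibly.
#' @export
write_interface_result <- function(x, path) {
  stopifnot(inherits(x, "interface_result"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  } else stop("unsupported result format: ", ext)
  invisible(path)
}
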