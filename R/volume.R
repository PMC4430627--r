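#' @useDynLib osseoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Label codes used throughout: 0 background/marrow, 1 bone, 2 implant,
# 3 excluded-from-analysis. Face adjacency is always 6-neighbourhood;
# island detection uses 26-connectivity.
LBL_BACKGROUND <- 0L
LBL_BONE <- 1L
LBL_IMPLANT <- 2L
LBL_EXCLUDED <- 3L

#' Grey-value volume
#'
#' A reconstructed micro-CT scalar volume on an isotropic voxel grid. Values
#' are in arbitrary grey units; all linear dimensions are micrometres.
#'
#' @param data 3D numeric array of grey values.
#' @param spacing Isotropic voxel edge length in micrometres (single positive
#'   number).
#' @param origin Physical position of the centre of voxel (1,1,1), in
#'   micrometres (length-3 numeric).
#' @return An object of class `grey_volume`.
#' @export
grey_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 1 || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number (µm)")
  if (!all(is.finite(data))) stop("grey volume must contain finite values only")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = c("grey_volume", "ct_volume"))
}

#' Label volume
#'
#' A material map on the same grid as a [grey_volume()]: 0 background/marrow,
#' 1 bone, 2 implant, 3 excluded.
#'
#' @param data 3D integer array of labels in \{0, 1, 2, 3\}.
#' @inheritParams grey_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  if (!all(data %in% 0:3)) stop("labels must be in {0, 1, 2, 3}")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 1 || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number (µm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = c("label_volume", "ct_volume"))
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.4g um, origin (%s) um\n",
              class(x)[1], d[1], d[2], d[3], x$spacing,
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "label_volume")) {
    tb <- tabulate(as.integer(x$data) + 1L, 4L)
    cat(sprintf("  background/marrow %d | bone %d | implant %d | excluded %d\n",
                tb[1], tb[2], tb[3], tb[4]))
  } else {
    cat(sprintf("  grey range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# Voxel-centre physical coordinates along one axis (1-based index i maps to
# origin + (i-1)*spacing).
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
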