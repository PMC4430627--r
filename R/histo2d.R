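#' Extract a longitudinal section through the implant axis
#'
#' Virtual counterpart of a histological thin section: a single-pixel-thick
#' plane containing the implant axis (z by construction), at a chosen
#' in-plane angle, sampled with nearest-neighbour labels. The in-plane
#' sampling step can be refined with `supersample` to mimic the finer pixel
#' size of real histomorphometry.
#'
#' @param labels A [label_volume()] containing an implant.
#' @param angle In-plane angle of the section, degrees.
#' @param supersample Sampling refinement factor (pixel size = spacing /
#'   supersample).
#' @return A `section_image`: list with `data` (matrix, radial position x
#'   z-slice), `pixel_size` (µm) and `angle`.
#' @export
extract_section <- function(labels, angle = 0, supersample = 1) {
  stopifnot(inherits(labels, "label_volume"))
  a <- labels$data
  d <- dim(a)
  imp <- which(a == LBL_IMPLANT, arr.ind = TRUE)
  if (nrow(imp) == 0) stop("implant axis undeterminable: no implant voxels")
  s <- labels$spacing
  cx <- (mean(imp[, 1]) - 1) * s
  cy <- (mean(imp[, 2]) - 1) * s
  th <- angle * pi / 180
  ext <- max(d[1], d[2]) * s
  step <- s / supersample
  nhalf <- floor(ext / 2 / step)
  t <- (-nhalf:nhalf) * step   # symmetric grid so opposite angles mirror exactly
  px <- cx + t * cos(th)
  py <- cy + t * sin(th)
  ii <- round(px / s) + 1L
  jj <- round(py / s) + 1L
  ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2]
  sec <- matrix(LBL_BACKGROUND, nrow = length(t), ncol = d[3])
  for (k in seq_len(d[3])) {
    col <- rep(LBL_BACKGROUND, length(t))
    col[ok] <- a[cbind(ii[ok], jj[ok], k)]
    sec[, k] <- col
  }
  structure(list(data = sec, pixel_size = step, angle = angle),
            class = "section_image")
}

# Moore-neighbour contour tracing (8-connected, clockwise) of a binary mask.
# Returns the ordered closed sequence of boundary pixel (row, col) pairs.
trace_contour <- function(mask) {
  d <- dim(mask)
  at <- function(p) p[1] >= 1 && p[1] <= d[1] && p[2] >= 1 && p[2] <= d[2] &&
    mask[p[1], p[2]]
  # clockwise Moore neighbourhood starting west
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  lin <- which(mask)
  if (length(lin) == 0) stop("empty mask")
  start <- c((lin[1] - 1) %% d[1] + 1, (lin[1] - 1) %/% d[1] + 1)
  if (sum(mask) == 1) return(matrix(start, 1, 2))
  # backtrack is the (empty) pixel west of the start (column-major scan
  # guarantees it is outside the mask)
  b_off <- 1L
  contour <- list(start)
  cur <- start
  prev_off <- b_off
  repeat {
    found <- FALSE
    for (step in 0:7) {
      o <- (prev_off - 1L + step) %% 8L + 1L
      cand <- cur + offs[o, ]
      if (at(cand)) {
        # next backtrack: the offset just before the found neighbour,
        # re-expressed relative to the new pixel
        prev_o <- (o - 2L) %% 8L + 1L
        back_pix <- cur + offs[prev_o, ]
        rel <- back_pix - cand
        prev_off <- which(offs[, 1] == rel[1] & offs[, 2] == rel[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && prev_off == b_off) break
    contour[[length(contour) + 1L]] <- cur
    if (length(contour) > 8L * length(lin)) break  # safety
  }
  do.call(rbind, contour)
}

#' 2D bone-to-implant contact of a section
#'
#' Traces the implant profile (8-connected Moore contour of the largest
#' implant component), measures its length with the Freeman chain-code
#' convention (1 pixel per axial step, sqrt(2) per diagonal step), and
#' reports the fraction of that length in contact with bone. End-cap
#' segments (contour pixels within one pixel of the implant's extreme
#' z-columns) and segments adjacent to `excluded` pixels are dropped from
#' the evaluated shell length, mirroring the 3D shell/exclusion semantics.
#'
#' @param section A `section_image` from [extract_section()].
#' @return A `histo2d_result`: list with `total_shell_length` (µm),
#'   `bone_contact_length` (µm), `BIC2D` (percent) and `section_angle`.
#' @export
compute_bic2d <- function(section) {
  stopifnot(inherits(section, "section_image"))
  img <- section$data
  d <- dim(img)
  imp <- img == LBL_IMPLANT
  if (!any(imp)) stop("implant absent from section")
  cc <- .cc_label_3d(array(imp, dim = c(d, 1L)), c(d, 1L), 26L)[, , 1]
  main <- which.max(tabulate(cc[cc > 0L]))
  imp <- cc == main
  contour <- trace_contour(imp)
  n <- nrow(contour)
  if (n < 2) stop("implant profile too small to trace")

  # per-pixel weight: half of each incident chain step
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  step_len <- sqrt(rowSums((nxt - contour)^2))   # 1 or sqrt(2)
  w <- (step_len + c(step_len[n], step_len[-n])) / 2

  # 8-neighbourhood adjacency of each contour pixel
  pad <- matrix(LBL_BACKGROUND, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- img
  adj <- function(lbl) {
    res <- logical(n)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      res <- res | pad[cbind(contour[, 1] + 1 + dr, contour[, 2] + 1 + dc)] == lbl
    }
    res
  }
  near_bone <- adj(LBL_BONE)
  near_excl <- adj(LBL_EXCLUDED)

  zc <- which(apply(imp, 2, any))
  endcap <- contour[, 2] <= min(zc) + 1L | contour[, 2] >= max(zc) - 1L
  keep <- !endcap & !near_excl
  total <- sum(w[keep]) * section$pixel_size
  bone <- sum(w[keep & near_bone]) * section$pixel_size
  if (total == 0) stop("no evaluable shell length in section")
  structure(list(total_shell_length = total, bone_contact_length = bone,
                 BIC2D = 100 * bone / total, section_angle = section$angle),
            class = "histo2d_result")
}

#' @export
print.histo2d_result <- function(x, ...) {
  cat(sprintf("virtual histomorphometry @ %.1f deg: BIC2D %.2f %% (%.5g / %.5g um)\n",
              x$section_angle, x$BIC2D, x$bone_contact_length,
              x$total_shell_length))
  invisible(x)
}

#' Sweep section angles
#'
#' Computes single-section BIC2D at `n_angles` equally spaced angles in
#' \[0°, 180°). The spread across angles quantifies how strongly a
#' histomorphometric estimate depends on the (single) chosen section plane,
#' whereas the 3D pVA of the same volume is plane-independent.
#'
#' @param labels A [label_volume()].
#' @param n_angles Number of angles (>= 2).
#' @param supersample Passed to [extract_section()].
#' @return A list with `results` (data frame of angle and BIC2D), `mean` and
#'   `sd` across angles.
#' @export
section_sweep <- function(labels, n_angles = 18L, supersample = 1) {
  stopifnot(n_angles >= 2)
  angles <- seq(0, 180, length.out = n_angles + 1L)[seq_len(n_angles)]
  bic <- vapply(angles, function(a)
    compute_bic2d(extract_section(labels, a, supersample))$BIC2D, numeric(1))
  list(results = data.frame(angle = angles, BIC2D = bic),
       mean = mean(bic), sd = stats::sd(bic))
}
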