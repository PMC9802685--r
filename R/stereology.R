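# Stereological quantification on serial sections: point-counting Cavalieri
# volume estimation and cycloid-probe intersection counting on vertical
# sections (mean cisternae per stack as I[cist] / I[stack face]).

#' Point lattice for Cavalieri point counting
#'
#' A regular square lattice of test points with a uniform random offset; the
#' area represented by each point is `a_p = (spacing * pixel_size)^2`.
#'
#' @param spacing_px Lattice spacing in pixels.
#' @param offset Offset `c(u, v)` in pixels, each in `[0, spacing_px)`.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A `point_lattice` list with `a_p_um2`.
#' @export
point_lattice <- function(spacing_px, offset = c(0, 0), pixel_size_um = 1) {
  stopifnot(spacing_px > 0, all(offset >= 0), all(offset < spacing_px))
  structure(list(spacing_px = spacing_px, offset = offset,
                 pixel_size_um = pixel_size_um,
                 a_p_um2 = (spacing_px * pixel_size_um)^2),
            class = "point_lattice")
}

#' Count lattice points hitting a mask
#'
#' Test points sit at `(offset + i * spacing)` in continuous pixel
#' coordinates (0-based, pixel `k` covering `[k-1, k)`); a point hits when
#' the pixel under it is foreground.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param lattice A [point_lattice()].
#' @return Integer point count.
#' @export
point_count <- function(mask, lattice) {
  stopifnot(inherits(lattice, "point_lattice"))
  h <- nrow(mask); w <- ncol(mask)
  xs <- seq(lattice$offset[1], w - 1e-9, by = lattice$spacing_px)
  ys <- seq(lattice$offset[2], h - 1e-9, by = lattice$spacing_px)
  if (!length(xs) || !length(ys)) return(0L)
  xi <- floor(xs) + 1L; yi <- floor(ys) + 1L
  sum(mask[yi, xi, drop = FALSE] > 0)
}

#' Serial-section stack
#'
#' @param masks List of equal-size section masks, ordered by depth.
#' @param spacing_um Section spacing `t`, micrometres.
#' @param pixel_size_um In-plane pixel size, micrometres.
#' @param start_offset_um Depth of the first section relative to the random
#'   starting point (recorded for provenance).
#' @return A `section_stack` list.
#' @export
section_stack <- function(masks, spacing_um = 0.2, pixel_size_um = 1,
                          start_offset_um = 0) {
  stopifnot(length(masks) >= 1, spacing_um > 0, pixel_size_um > 0)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1)))) {
    rlang::abort("inconsistent mask shapes in section stack")
  }
  structure(list(masks = masks, spacing_um = spacing_um,
                 pixel_size_um = pixel_size_um,
                 start_offset_um = start_offset_um),
            class = "section_stack")
}

#' Cavalieri volume estimate
#'
#' `V = t * a_p * sum(P)`: section spacing times area-per-point times the
#' total point count over all sections. Unbiased over uniform random lattice
#' offsets and section starting points.
#'
#' @param stack A [section_stack()] (or list of masks plus `spacing_um`).
#' @param lattice A [point_lattice()] whose `pixel_size_um` matches the
#'   stack.
#' @return List with `volume_um3`, `total_points` and `per_section` tibble.
#' @export
cavalieri_volume <- function(stack, lattice) {
  stopifnot(inherits(stack, "section_stack"), inherits(lattice, "point_lattice"))
  if (length(stack$masks) < 2) rlang::abort("at least 2 sections required")
  counts <- vapply(stack$masks, point_count, integer(1), lattice = lattice)
  v <- stack$spacing_um * lattice$a_p_um2 * sum(counts)
  list(volume_um3 = v, total_points = sum(counts),
       per_section = tibble::tibble(section = seq_along(counts), points = counts))
}

#' Cycloid probe grid
#'
#' An array of cycloid arcs tiling the section plane, minor axis aligned with
#' the section's vertical axis (the axis orthogonal to the substratum, which
#' is the y axis of our vertical sections). Each arch spans `pi * r`
#' horizontally and `2 * r` vertically; arch rows repeat with the given
#' spacings and a uniform random phase.
#'
#' @param r_px Cycloid parameter r in pixels.
#' @param spacing_x_px,spacing_y_px Horizontal/vertical tiling period
#'   (defaults: one arch width / `4 r`).
#' @param phase Offset `c(x, y)` in pixels.
#' @param step_px Arc sampling step (<= 0.25 px for intersection counting).
#' @return A `cycloid_grid` list.
#' @export
cycloid_grid <- function(r_px, spacing_x_px = NULL, spacing_y_px = NULL,
                         phase = c(0, 0), step_px = 0.25) {
  stopifnot(r_px > 0)
  structure(list(r_px = r_px,
                 spacing_x_px = spacing_x_px %||% (pi * r_px),
                 spacing_y_px = spacing_y_px %||% (4 * r_px),
                 phase = phase, step_px = step_px),
            class = "cycloid_grid")
}

# All cycloid arcs of a grid intersecting a width x height window, as dense
# polylines (list of n x 2 matrices, columns x, y). Alternate arches are
# mirrored so each row forms a continuous wave.
cycloid_curves <- function(grid, width, height) {
  r <- grid$r_px
  n_th <- max(8, ceiling(pi * r / grid$step_px))
  th <- seq(0, pi, length.out = n_th)
  bx <- r * (th - sin(th))   # 0 .. pi r
  by <- r * (1 - cos(th))    # 0 .. 2 r
  curves <- list()
  y0s <- seq(grid$phase[2] - grid$spacing_y_px, height + grid$spacing_y_px,
             by = grid$spacing_y_px)
  x0s <- seq(grid$phase[1] - 2 * grid$spacing_x_px, width + grid$spacing_x_px,
             by = grid$spacing_x_px)
  for (y0 in y0s) {
    flip <- FALSE
    for (x0 in x0s) {
      yy <- if (flip) y0 + 2 * r - by else y0 + by
      curves[[length(curves) + 1]] <- cbind(x0 + bx, yy)
      flip <- !flip
    }
  }
  curves
}

# Count transversal crossings between two sets of polylines.
count_polyline_crossings <- function(curves_a, curves_b) {
  total <- 0L
  for (A in curves_a) {
    ax0 <- A[-nrow(A), 1]; ay0 <- A[-nrow(A), 2]
    ax1 <- A[-1, 1]; ay1 <- A[-1, 2]
    abb <- c(min(A[, 1]), max(A[, 1]), min(A[, 2]), max(A[, 2]))
    for (B in curves_b) {
      if (min(B[, 1]) > abb[2] || max(B[, 1]) < abb[1] ||
          min(B[, 2]) > abb[4] || max(B[, 2]) < abb[3]) next
      for (s in seq_len(nrow(B) - 1)) {
        total <- total + sum(segments_intersect(
          ax0, ay0, ax1, ay1, B[s, 1], B[s, 2], B[s + 1, 1], B[s + 1, 2]))
      }
    }
  }
  total
}

# Vectorized proper-intersection test of many segments (a) vs one segment (b).
segments_intersect <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  d1 <- (bx1 - bx0) * (ay0 - by0) - (by1 - by0) * (ax0 - bx0)
  d2 <- (bx1 - bx0) * (ay1 - by0) - (by1 - by0) * (ax1 - bx0)
  d3 <- (ax1 - ax0) * (by0 - ay0) - (ay1 - ay0) * (bx0 - ax0)
  d4 <- (ax1 - ax0) * (by1 - ay0) - (ay1 - ay0) * (bx1 - ax0)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Count cycloid-probe intersections
#'
#' Counts transversal crossings between the cycloid arcs and the target
#' curves: cisterna midlines (`target = "cisterna"`, polylines) or the stack
#' profile boundary (`target = "stack_face"`, a mask whose outline is
#' extracted; every boundary crossing — entering and exiting — is counted).
#'
#' @param x For `"cisterna"`: list of polylines (n x 2 matrices). For
#'   `"stack_face"`: a logical mask.
#' @param grid A [cycloid_grid()].
#' @param target `"cisterna"` or `"stack_face"`.
#' @param dim_px Section size `c(width, height)` (required for polyline
#'   input; inferred from the mask otherwise).
#' @return Integer intersection count.
#' @export
cycloid_intersections <- function(x, grid, target = c("cisterna", "stack_face"),
                                  dim_px = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(grid, "cycloid_grid"))
  if (target == "stack_face") {
    mask <- x
    dim_px <- c(ncol(mask), nrow(mask))
    oc <- EBImage::ocontour(as_eb(mask * 1))
    curves <- lapply(oc, function(p) {
      # ocontour returns 0-based (x, y) in EBImage frame == our (x, y)
      rbind(p, p[1, ]) + 1
    })
  } else {
    curves <- x
    if (is.null(dim_px)) rlang::abort("dim_px required for polyline targets")
    curves <- lapply(curves, function(p) as.matrix(p))
  }
  if (!length(curves)) return(0L)
  arcs <- cycloid_curves(grid, dim_px[1], dim_px[2])
  count_polyline_crossings(arcs, curves)
}

#' Mean cisternae per stack
#'
#' Ratio of cisterna-midline intersections to stack-face intersections.
#'
#' @param i_cist,i_face Intersection counts (`i_face > 0`).
#' @return `i_cist / i_face`.
#' @export
mean_cisternae <- function(i_cist, i_face) {
  if (i_face <= 0) rlang::abort("stack-face intersection count must be positive")
  i_cist / i_face
}

#' Classify a profile component as cisterna or other
#'
#' A membranous profile counts as a cisterna when its length-to-breadth
#' ratio is at least 3. Length and breadth are the extents of the component
#' along its principal axes (projection range + 1 px, so a 30 x 10 px
#' rectangle sits exactly on the 3:1 boundary).
#'
#' @param mask Logical matrix of the component.
#' @return `"cisterna"` or `"other"`.
#' @export
classify_cisterna_profile <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) rlang::abort("empty component")
  h <- nrow(mask)
  ys <- (idx - 1L) %% h + 1L; xs <- (idx - 1L) %/% h + 1L
  P <- cbind(xs - mean(xs), ys - mean(ys))
  if (nrow(P) < 2) return("other")
  ev <- eigen(stats::cov(P), symmetric = TRUE)$vectors
  proj1 <- P %*% ev[, 1]; proj2 <- P %*% ev[, 2]
  len <- diff(range(proj1)) + 1
  breadth <- diff(range(proj2)) + 1
  if (len / breadth >= 3) "cisterna" else "other"
}

#' Extract cisterna midlines from a labelled section
#'
#' For each cisterna label in a section of a labelled volume, the midline is
#' the principal-axis segment through the component centroid spanning its
#' extent — the single line bisecting the cisternal profile.
#'
#' @param section Integer label matrix (labels > 1 are cisternae).
#' @return List of 2 x 2 polylines (segment endpoints).
#' @export
cisterna_midlines <- function(section) {
  labs <- setdiff(sort(unique(as.vector(section))), c(0L, 1L))
  out <- list()
  h <- nrow(section)
  for (L in labs) {
    idx <- which(section == L)
    if (length(idx) < 4) next
    ys <- (idx - 1L) %% h + 1L; xs <- (idx - 1L) %/% h + 1L
    cx <- mean(xs); cy <- mean(ys)
    P <- cbind(xs - cx, ys - cy)
    ax <- eigen(stats::cov(P), symmetric = TRUE)$vectors[, 1]
    t_ <- P %*% ax
    out[[length(out) + 1]] <- rbind(
      c(cx + min(t_) * ax[1], cy + min(t_) * ax[2]),
      c(cx + max(t_) * ax[1], cy + max(t_) * ax[2]))
  }
  out
}

#' Sample sections from a labelled volume
#'
#' Takes z-slices at uniform spacing with a random starting point, the
#' sampling design behind the Cavalieri estimator.
#'
#' @param volume 3-D label array `[y, x, z]`.
#' @param voxel_size_um Isotropic voxel size.
#' @param spacing_um Section spacing `t`.
#' @param start_frac Starting offset as a fraction of the spacing in
#'   `[0, 1)`.
#' @return List of label matrices (the sampled z-slices).
#' @export
sample_sections <- function(volume, voxel_size_um, spacing_um = 0.2,
                            start_frac = 0) {
  nz <- dim(volume)[3]
  step <- spacing_um / voxel_size_um
  zs <- seq(1 + start_frac * step, nz, by = step)
  lapply(round(zs), function(z) volume[, , min(max(z, 1), nz)])
}

#' Full stereology of a synthetic Golgi volume
#'
#' Runs the Cavalieri estimator (stack-label mask, point lattice) and the
#' cycloid pipeline (cisterna midlines vs stack-face outline) on sections
#' sampled from a labelled volume.
#'
#' @param volume A labelled volume as from [gen_golgi_volume()] (the list or
#'   the bare array).
#' @param voxel_size_um Voxel size (taken from the generator truth when a
#'   full object is passed).
#' @param spacing_um Section spacing.
#' @param lattice_spacing_px Point-lattice spacing.
#' @param cycloid_r_px Cycloid parameter.
#' @param seed Seed for the random lattice offset, section start and cycloid
#'   phase.
#' @return List with `volume_um3`, `total_points`, `i_cist`, `i_face`,
#'   `mean_cisternae`, `n_sections`.
#' @export
golgi_stereology <- function(volume, voxel_size_um = NULL, spacing_um = 0.2,
                             lattice_spacing_px = 4, cycloid_r_px = 6,
                             seed = 1) {
  if (is.list(volume)) {
    voxel_size_um <- voxel_size_um %||% volume$truth$voxel_size_um
    volume <- volume$volume
  }
  stopifnot(!is.null(voxel_size_um))
  rnd <- with_seed(seed, stats::runif(5))
  sections <- sample_sections(volume, voxel_size_um, spacing_um,
                              start_frac = rnd[1])
  lat <- point_lattice(lattice_spacing_px,
                       offset = rnd[2:3] * lattice_spacing_px,
                       pixel_size_um = voxel_size_um)
  stack_masks <- lapply(sections, function(s) s >= 1)
  st <- section_stack(stack_masks, spacing_um, voxel_size_um)
  cav <- cavalieri_volume(st, lat)
  grid <- cycloid_grid(cycloid_r_px,
                       phase = rnd[4:5] * c(pi, 4) * cycloid_r_px)
  i_cist <- 0L; i_face <- 0L
  for (s in sections) {
    ml <- cisterna_midlines(s)
    if (length(ml)) {
      i_cist <- i_cist + cycloid_intersections(ml, grid, "cisterna",
                                               dim_px = c(ncol(s), nrow(s)))
    }
    if (any(s >= 1)) {
      i_face <- i_face + cycloid_intersections(s >= 1, grid, "stack_face")
    }
  }
  list(volume_um3 = cav$volume_um3, total_points = cav$total_points,
       i_cist = i_cist, i_face = i_face,
       mean_cisternae = if (i_face > 0) i_cist / i_face else NA_real_,
       n_sections = length(sections))
}
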