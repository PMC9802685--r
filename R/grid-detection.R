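# Line-orientation detection (LOD) and crossing/landmark extraction.
#
# The detector follows the classic recipe for finding a gridded fiducial
# pattern: edge detection, suppression of edge pixels that do not lie on long
# straight strokes, then an angular projection (Radon/Hough-style accumulator
# over line angle 0-180 deg and signed offset from the image center) whose
# 2-D local maxima are the detected lines. Crossings are the intersections of
# paired bar-edge lines; each candidate is re-validated on a cropped patch.

#' Line-orientation detector parameters
#'
#' @param k_neighbors Half-width (in accumulator bins) of the non-maxima
#'   suppression neighbourhood used during peak finding.
#' @param stroke Stroke length in pixels: an edge pixel is kept only when it
#'   lies on a straight run of at least this length.
#' @param canny_low,canny_high Hysteresis edge thresholds as fractions of the
#'   maximum gradient magnitude.
#' @param angular_resolution Angular step of the projection, degrees; must
#'   divide 180.
#' @param use_clahe Apply adaptive histogram equalization first (unbalanced
#'   brightness/contrast).
#' @param use_laplacian_prefilter Apply a Laplacian prefilter first (regular
#'   interference patterns).
#' @param noise_floor_nsd Peak acceptance threshold in accumulator standard
#'   deviations above the mean.
#' @param spacing_tol Relative tolerance on expected grid spacings (bar
#'   width / square size) in the layout test.
#' @param max_lines Maximum number of lines returned.
#' @return A `lod_params` list.
#' @export
lod_params <- function(k_neighbors = 12, stroke = 15,
                       canny_low = 0.06, canny_high = 0.075,
                       angular_resolution = 1,
                       use_clahe = FALSE, use_laplacian_prefilter = FALSE,
                       noise_floor_nsd = 5, spacing_tol = 0.15,
                       max_lines = 40) {
  stopifnot(k_neighbors >= 1, stroke >= 1,
            canny_low > 0, canny_low < 1, canny_high > 0, canny_high < 1,
            180 %% angular_resolution == 0)
  structure(list(k_neighbors = k_neighbors, stroke = stroke,
                 canny_low = canny_low, canny_high = canny_high,
                 angular_resolution = angular_resolution,
                 use_clahe = use_clahe,
                 use_laplacian_prefilter = use_laplacian_prefilter,
                 noise_floor_nsd = noise_floor_nsd,
                 spacing_tol = spacing_tol, max_lines = max_lines),
            class = "lod_params")
}

# Canny-style hysteresis edge mask + gradient magnitude.
edge_map <- function(img, params) {
  if (params$use_clahe) {
    img <- tryCatch(from_eb(EBImage::clahe(as_eb(img), nx = 8, ny = 8)),
                    error = function(e) img)
  }
  if (params$use_laplacian_prefilter) {
    lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    img <- abs(conv2_same(img, lap))
  }
  img <- img_gblur(img, 1)
  g <- sobel_gradients(img)
  mx <- max(g$mag)
  if (mx < 1e-9) return(list(mask = matrix(FALSE, nrow(img), ncol(img)), mag = g$mag))
  strong <- g$mag > params$canny_high * mx
  weak <- g$mag > params$canny_low * mx
  if (!any(strong)) return(list(mask = strong, mag = g$mag))
  lab <- label_components(weak)
  keep <- unique(lab[strong])
  mask <- weak & (lab %in% keep[keep > 0])
  dim(mask) <- dim(weak)
  list(mask = mask, mag = g$mag)
}

# Stroke-support response: fraction of an oriented line kernel covered by
# (dilated) edge pixels, maximized over orientations.
stroke_support <- function(edge_mask, stroke, step_deg = 15, len = NULL) {
  len <- len %||% stroke
  dil <- from_eb(EBImage::dilate(as_eb(edge_mask * 1), disc_brush(2)))
  best <- matrix(0, nrow(edge_mask), ncol(edge_mask))
  for (a in seq(0, 180 - step_deg, by = step_deg)) {
    k <- line_brush(len, a)
    resp <- conv2_fft(dil, k / sum(k))
    best <- pmax(best, resp)
  }
  clamp01(best)
}

#' Detect lines by angular projection
#'
#' Runs the line-orientation detector on a grayscale image: Canny-style edge
#' detection with hysteresis, stroke-support filtering (edge pixels must lie
#' on a straight run of at least `stroke` pixels), and a weighted
#' angle-offset accumulator over 0-180 degrees whose local maxima (2-D
#' non-maxima suppression, sub-pixel offset interpolation) are the detected
#' lines. When a `layout` and `pixel_size` are supplied, lines are
#' additionally tested against the expected grid spacings and unsupported
#' lines dropped.
#'
#' A detected line with angle `theta` (degrees, direction of the line) and
#' offset `t` (pixels) is the locus of points `p` with
#' `(p - center) . (cos(theta+90), sin(theta+90)) = t`.
#'
#' @param image Grayscale image matrix.
#' @param params A [lod_params()].
#' @param layout Optional [grid_layout()] for the spacing test.
#' @param pixel_size Pixel size in micrometres (required with `layout`).
#' @return A tibble of class `clem_lines` with columns `angle`, `offset`,
#'   `score`, sorted by score; attributes `center` and `image_dim`.
#' @export
detect_lines <- function(image, params = lod_params(), layout = NULL,
                         pixel_size = NULL) {
  assert_image(image)
  if (min(dim(image)) < 32) rlang::abort("image too small for line detection")
  em <- edge_map(image, params)
  if (!any(em$mask)) rlang::abort("no lines found")
  sup <- stroke_support(em$mask, params$stroke)
  w_mat <- em$mag * em$mask * (sup >= 0.6)
  idx <- which(w_mat > 0)
  if (length(idx) < params$stroke) rlang::abort("no lines found")
  H <- nrow(image); W <- ncol(image)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  ys <- (idx - 1L) %% H + 1L; xs <- (idx - 1L) %/% H + 1L
  dx <- xs - cx; dy <- ys - cy
  wts <- w_mat[idx]
  D <- ceiling(sqrt((W / 2)^2 + (H / 2)^2)) + 1L
  nb <- 2L * D + 1L
  angles <- seq(0, 180 - params$angular_resolution, by = params$angular_resolution)
  acc <- matrix(0, length(angles), nb)
  for (ai in seq_along(angles)) {
    phi <- (angles[ai] + 90) * pi / 180
    tv <- round(dx * cos(phi) + dy * sin(phi)) + D + 1L
    s <- rowsum(wts, tv)
    acc[ai, as.integer(rownames(s))] <- s
  }
  # slight smoothing along the offset axis stabilizes the peaks
  accs <- acc
  accs[, 2:(nb - 1)] <- 0.25 * acc[, 1:(nb - 2)] + 0.5 * acc[, 2:(nb - 1)] +
    0.25 * acc[, 3:nb]
  thr <- mean(accs) + params$noise_floor_nsd * stats::sd(accs)
  # non-maxima suppression in (angle, offset)
  ka <- max(3L, as.integer(params$k_neighbors %/% 2))
  peaks <- local_maxima_2d(accs, thr, win_r = ka, win_c = params$k_neighbors)
  if (!nrow(peaks)) rlang::abort("no lines found")
  # sub-pixel offset by parabolic interpolation
  off <- vapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks$row[i]; c <- peaks$col[i]
    if (c <= 1 || c >= nb) return(c - D - 1)
    y0 <- accs[r, c - 1]; y1 <- accs[r, c]; y2 <- accs[r, c + 1]
    d <- y0 - 2 * y1 + y2
    (c - D - 1) + if (abs(d) > 1e-12) 0.5 * (y0 - y2) / d else 0
  }, numeric(1))
  lines <- tibble::tibble(angle = angles[peaks$row], offset = off,
                          score = peaks$value)
  lines <- dedupe_wrapped_lines(lines, params$angular_resolution)
  lines <- lines[order(-lines$score), ]
  if (nrow(lines) > params$max_lines) lines <- lines[seq_len(params$max_lines), ]
  if (!is.null(layout)) {
    if (is.null(pixel_size)) rlang::abort("pixel_size required for the layout spacing test")
    lines <- spacing_filter(lines, layout, pixel_size, params$spacing_tol)
    if (!nrow(lines)) rlang::abort("no lines found")
  }
  structure(lines, class = c("clem_lines", class(lines)),
            center = c(cx, cy), image_dim = c(W, H))
}

local_maxima_2d <- function(m, thr, win_r = 3L, win_c = 7L) {
  nr <- nrow(m); nc <- ncol(m)
  cand <- which(m > thr)
  if (!length(cand)) return(tibble::tibble(row = integer(), col = integer(), value = numeric()))
  rows <- (cand - 1L) %% nr + 1L; cols <- (cand - 1L) %/% nr + 1L
  ok <- logical(length(cand))
  for (i in seq_along(cand)) {
    r0 <- max(1L, rows[i] - win_r); r1 <- min(nr, rows[i] + win_r)
    c0 <- max(1L, cols[i] - win_c); c1 <- min(nc, cols[i] + win_c)
    ok[i] <- m[rows[i], cols[i]] >= max(m[r0:r1, c0:c1])
  }
  out <- tibble::tibble(row = rows[ok], col = cols[ok], value = m[cand[ok]])
  out[order(-out$value), ]
}

# Lines near angle 0 and 180 are the same line with negated offset.
dedupe_wrapped_lines <- function(lines, res) {
  if (nrow(lines) < 2) return(lines)
  drop <- rep(FALSE, nrow(lines))
  for (i in seq_len(nrow(lines) - 1)) {
    if (drop[i]) next
    for (j in (i + 1):nrow(lines)) {
      if (drop[j]) next
      da <- abs(lines$angle[i] - lines$angle[j])
      da <- min(da, 180 - da)
      wrapped <- abs(lines$angle[i] - lines$angle[j]) > 90
      doff <- if (wrapped) abs(lines$offset[i] + lines$offset[j]) else
        abs(lines$offset[i] - lines$offset[j])
      if (da <= 2 * res && doff <= 3) {
        drop[if (lines$score[i] >= lines$score[j]) j else i] <- TRUE
      }
    }
  }
  lines[!drop, ]
}

# Keep only lines having a same-family partner at an expected grid spacing.
spacing_filter <- function(lines, layout, pixel_size, tol) {
  if (nrow(lines) < 2) return(lines[0, ])
  exp_sp <- c(layout$bar_width, layout$square_size, layout$pitch) / pixel_size
  keep <- rep(FALSE, nrow(lines))
  for (i in seq_len(nrow(lines))) {
    for (j in seq_len(nrow(lines))) {
      if (i == j) next
      da <- abs(lines$angle[i] - lines$angle[j]); da <- min(da, 180 - da)
      if (da > 3) next
      doff <- abs(lines$offset[i] - lines$offset[j])
      if (any(abs(doff - exp_sp) <= tol * exp_sp)) { keep[i] <- TRUE; break }
    }
  }
  lines[keep, ]
}

line_direction <- function(angle) c(cos(angle * pi / 180), sin(angle * pi / 180))
line_normal <- function(angle) {
  phi <- (angle + 90) * pi / 180
  c(cos(phi), sin(phi))
}

# Intersection of two (angle, offset) lines, in centered coordinates.
line_intersection <- function(a1, t1, a2, t2) {
  n1 <- line_normal(a1); n2 <- line_normal(a2)
  M <- rbind(n1, n2)
  if (abs(det(M)) < 1e-9) return(NULL)
  as.numeric(solve(M, c(t1, t2)))
}

#' Find grid-bar crossings from detected lines
#'
#' Groups the detected lines into two orientation families, pairs lines
#' within a family whose separation matches the bar width (each bar
#' contributes its two edge lines), and intersects the edge-line pairs of the
#' two families: the four pairwise intersections of a horizontal pair with a
#' vertical pair are a crossing's corners and their centroid its center.
#' Candidate centers closer than half a bar width are merged.
#'
#' @param lines A `clem_lines` tibble from [detect_lines()].
#' @param layout A [grid_layout()].
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param tol Relative tolerance on the bar-width separation.
#' @return A tibble of class `clem_crossings`: `center_x`, `center_y`
#'   (absolute pixel coordinates), `corners` (list of 4 x 2 matrices),
#'   `angle_a`, `angle_b`, `sep_a`, `sep_b`, `score`, `status`. Empty when
#'   all lines are parallel or no pairing fits the layout.
#' @export
find_crossings <- function(lines, layout, pixel_size, tol = 0.15) {
  stopifnot(inherits(lines, "clem_lines"))
  ctr <- attr(lines, "center")
  empty <- tibble::tibble(center_x = numeric(), center_y = numeric(),
                          corners = list(), angle_a = numeric(),
                          angle_b = numeric(), sep_a = numeric(),
                          sep_b = numeric(), score = numeric(),
                          status = character())
  class(empty) <- c("clem_crossings", class(empty))
  if (nrow(lines) < 4) return(empty)
  ang_dist <- function(a, b) pmin(abs(a - b), 180 - abs(a - b))
  a0 <- lines$angle[1]
  famA <- which(ang_dist(lines$angle, a0) < 30)
  famB <- which(ang_dist(lines$angle, (a0 + 90) %% 180) < 30)
  if (length(famA) < 2 || length(famB) < 2) return(empty)
  bw_px <- layout$bar_width / pixel_size
  pair_up <- function(fam) {
    prs <- list()
    if (length(fam) < 2) return(prs)
    cmb <- utils::combn(fam, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      # separation measured along the common normal (offsets may be signed
      # against nearly opposite normals when angles straddle 0/180)
      doff <- abs(lines$offset[i] - lines$offset[j])
      if (abs(lines$angle[i] - lines$angle[j]) > 90) {
        doff <- abs(lines$offset[i] + lines$offset[j])
      }
      if (abs(doff - bw_px) <= tol * bw_px) prs[[length(prs) + 1]] <- c(i, j)
    }
    prs
  }
  pairsA <- pair_up(famA); pairsB <- pair_up(famB)
  if (!length(pairsA) || !length(pairsB)) return(empty)
  cand <- list()
  for (pa in pairsA) {
    for (pb in pairsB) {
      pts <- list()
      for (i in pa) for (j in pb) {
        p <- line_intersection(lines$angle[i], lines$offset[i],
                               lines$angle[j], lines$offset[j])
        if (is.null(p)) next
        pts[[length(pts) + 1]] <- p
      }
      if (length(pts) != 4) next
      P <- do.call(rbind, pts)
      ctr_pt <- colMeans(P)
      cand[[length(cand) + 1]] <- list(
        center = ctr_pt + ctr, corners = sweep(P, 2, -ctr),
        angle_a = mean(lines$angle[pa]), angle_b = mean(lines$angle[pb]),
        sep_a = abs(diff(lines$offset[pa])), sep_b = abs(diff(lines$offset[pb])),
        score = sum(lines$score[c(pa, pb)]))
    }
  }
  if (!length(cand)) return(empty)
  centers <- t(vapply(cand, function(z) z$center, numeric(2)))
  used <- rep(FALSE, length(cand))
  rows <- list()
  ord <- order(-vapply(cand, function(z) z$score, numeric(1)))
  for (i in ord) {
    if (used[i]) next
    d <- sqrt((centers[, 1] - centers[i, 1])^2 + (centers[, 2] - centers[i, 2])^2)
    grp <- which(!used & d <= bw_px / 2)
    used[grp] <- TRUE
    cm <- colMeans(centers[grp, , drop = FALSE])
    z <- cand[[i]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      center_x = cm[1], center_y = cm[2], corners = list(z$corners),
      angle_a = z$angle_a, angle_b = z$angle_b,
      sep_a = z$sep_a, sep_b = z$sep_b, score = z$score,
      status = "candidate")
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("clem_crossings", class(out))
  attr(out, "center") <- ctr
  out
}

#' Refine and validate a crossing candidate
#'
#' Crops the neighbourhood of a candidate crossing and re-runs the line
#' detector on the patch. The candidate is accepted only when the patch
#' yields a crossing near the patch center whose edge separations fit the
#' expected bar width, and when the expected bar-edge lines are actually
#' supported by edge pixels around the center (occlusions by cracks,
#' scratches or dirt fail this check). Accepted crossings get a sub-pixel
#' refined center.
#'
#' @param image The full image the candidate came from.
#' @param crossing One row of a `clem_crossings` tibble (or a list with
#'   `center_x`, `center_y`).
#' @param params A [lod_params()].
#' @param layout A [grid_layout()].
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param crop_half Patch half-size in pixels (default fits ~3 bar widths).
#' @param min_edge_fraction Minimum fraction of expected edge-line samples
#'   supported by detected edges.
#' @return A one-row tibble: refined `center_x`, `center_y`, `status`
#'   (`"accepted"` or `"rejected"`), `reason` (NA, or one of
#'   `out_of_bounds`, `no_lines`, `spacing_mismatch`, `occluded`).
#' @export
refine_crossing <- function(image, crossing, params = lod_params(),
                            layout = grid_layout(), pixel_size = 1.7,
                            crop_half = NULL, min_edge_fraction = 0.45,
                            max_sector_deviation = 0.5) {
  assert_image(image)
  bw_px <- layout$bar_width / pixel_size
  crop_half <- crop_half %||% as.integer(round(1.6 * bw_px) + 24)
  cxp <- round(crossing$center_x); cyp <- round(crossing$center_y)
  H <- nrow(image); W <- ncol(image)
  reject <- function(reason) tibble::tibble(
    center_x = crossing$center_x, center_y = crossing$center_y,
    status = "rejected", reason = reason)
  if (cxp - crop_half < 1 || cxp + crop_half > W ||
      cyp - crop_half < 1 || cyp + crop_half > H) {
    return(reject("out_of_bounds"))
  }
  patch <- image[(cyp - crop_half):(cyp + crop_half),
                 (cxp - crop_half):(cxp + crop_half)]
  lines <- tryCatch(detect_lines(patch, params), error = function(e) NULL)
  if (is.null(lines)) return(reject("no_lines"))
  cr <- find_crossings(lines, layout, pixel_size)
  if (!nrow(cr)) return(reject("spacing_mismatch"))
  pc <- crop_half + 1
  d <- sqrt((cr$center_x - pc)^2 + (cr$center_y - pc)^2)
  best <- which.min(d)
  if (d[best] > 0.75 * bw_px) return(reject("spacing_mismatch"))
  # strict re-validation of the edge separations on the patch: a pairing that
  # mixes a defect edge with a bar edge makes the two families disagree, and
  # a grossly wrong pair falls outside the layout band altogether (a small
  # symmetric bias is allowed — ridge-style SEM edges sit slightly inward)
  sep <- c(cr$sep_a[best], cr$sep_b[best])
  if (abs(sep[1] - sep[2]) > 0.1 * bw_px ||
      abs(mean(sep) - bw_px) > 0.15 * bw_px) {
    return(reject("spacing_mismatch"))
  }
  # local edge-support check around the crossing: the four bar-edge lines
  # must be visible in the immediate neighbourhood
  em <- edge_map(patch, params)
  # only stroke-supported edges count: speckle inside cracks/dirt forms no
  # long straight runs and must not masquerade as bar edges
  straight <- em$mask & (stroke_support(em$mask, params$stroke) >= 0.6)
  dil <- from_eb(EBImage::dilate(as_eb(straight * 1), disc_brush(2))) > 0
  ctr_rel <- c(cr$center_x[best] - pc, cr$center_y[best] - pc)
  sup <- edge_line_support(dil, ctr_rel, pc,
                           cr$angle_a[best], cr$angle_b[best], bw_px)
  if (sup < min_edge_fraction) return(reject("occluded"))
  # model-consistency: the four background quadrants must agree with each
  # other, and the four bar arms likewise; a defect overlapping the crossing
  # core pulls at least one sector off its group level
  q <- sector_consistency(patch, ctr_rel, pc,
                          cr$angle_a[best], cr$angle_b[best], bw_px)
  if (!is.na(q$dev) && q$dev > max_sector_deviation) return(reject("occluded"))
  if (!is.na(q$periph) && q$periph > max_sector_deviation / 2) {
    return(reject("occluded"))
  }
  tibble::tibble(
    center_x = cr$center_x[best] + cxp - pc,
    center_y = cr$center_y[best] + cyp - pc,
    status = "accepted", reason = NA_character_)
}

# Support of the 4 expected bar-edge lines by detected edge pixels, sampled
# near the crossing but excluding the central area where edges genuinely
# vanish. Returns the minimum per-line fraction: occluding any one bar edge
# (crack, scratch, dirt) fails the crossing.
edge_line_support <- function(edge_dil, ctr_rel, pc, angle_a, angle_b, bw_px) {
  H <- nrow(edge_dil); W <- ncol(edge_dil)
  svals <- c(-seq(0.8 * bw_px, 2 * bw_px, by = 1), seq(0.8 * bw_px, 2 * bw_px, by = 1))
  fracs <- numeric(0)
  for (ang in c(angle_a, angle_b)) {
    d <- line_direction(ang); nrm <- line_normal(ang)
    for (side in c(-1, 1)) {
      base <- ctr_rel + side * (bw_px / 2) * nrm
      px <- round(pc + base[1] + svals * d[1])
      py <- round(pc + base[2] + svals * d[2])
      ok <- px >= 1 & px <= W & py >= 1 & py <= H
      if (sum(ok) < 4) next
      fracs <- c(fracs, sum(edge_dil[cbind(py[ok], px[ok])]) / sum(ok))
    }
  }
  if (!length(fracs)) return(0)
  min(fracs)
}

# Intensity-model consistency of a crossing neighbourhood. Sectors: 4
# background quadrants (between the bars) and 4 bar arms in an annulus around
# the crossing, compared as 20%-trimmed means. Returns `dev`, the maximum
# normalized deviation of any sector from its group median (a localized
# defect pulls one sector off), and `periph`, the deviation of the central
# quadrant/arm levels from the same levels measured on a peripheral annulus
# (a defect covering the whole crossing core shifts the center levels
# together, which `dev` alone cannot see). Both are normalized by the
# bar/background contrast; NA when the geometry leaves too few pixels or the
# contrast is negligible.
sector_consistency <- function(patch, ctr_rel, pc, angle_a, angle_b, bw_px) {
  H <- nrow(patch); W <- ncol(patch)
  xs <- outer(rep(1, H), seq_len(W)) - (pc + ctr_rel[1])
  ys <- outer(seq_len(H), rep(1, W)) - (pc + ctr_rel[2])
  na <- line_normal(angle_a); nb <- line_normal(angle_b)
  da <- line_direction(angle_a); db <- line_direction(angle_b)
  pa <- xs * na[1] + ys * na[2]   # signed distance to bar a centerline
  pb <- xs * nb[1] + ys * nb[2]
  ta <- xs * da[1] + ys * da[2]   # position along bar a
  tb <- xs * db[1] + ys * db[2]
  r2 <- xs^2 + ys^2
  tm <- function(sel) {
    v <- patch[sel]
    if (length(v) < 12) return(NA_real_)
    mean(v, trim = 0.2)
  }
  is_quad <- abs(pa) > 0.55 * bw_px & abs(pb) > 0.55 * bw_px
  is_arm <- (abs(pa) < 0.35 * bw_px & abs(ta) > 0.7 * bw_px) |
    (abs(pb) < 0.35 * bw_px & abs(tb) > 0.7 * bw_px)
  core <- r2 < (1.8 * bw_px)^2
  quads <- c(tm(pa > 0.55 * bw_px & pb > 0.55 * bw_px & core),
             tm(pa > 0.55 * bw_px & pb < -0.55 * bw_px & core),
             tm(pa < -0.55 * bw_px & pb > 0.55 * bw_px & core),
             tm(pa < -0.55 * bw_px & pb < -0.55 * bw_px & core))
  arms <- c(tm(abs(pa) < 0.35 * bw_px & ta > 0.7 * bw_px & ta < 1.7 * bw_px),
            tm(abs(pa) < 0.35 * bw_px & ta < -0.7 * bw_px & ta > -1.7 * bw_px),
            tm(abs(pb) < 0.35 * bw_px & tb > 0.7 * bw_px & tb < 1.7 * bw_px),
            tm(abs(pb) < 0.35 * bw_px & tb < -0.7 * bw_px & tb > -1.7 * bw_px))
  out <- list(dev = NA_real_, periph = NA_real_)
  if (sum(!is.na(quads)) < 3 || sum(!is.na(arms)) < 3) return(out)
  B <- stats::median(quads, na.rm = TRUE); A <- stats::median(arms, na.rm = TRUE)
  ring <- r2 >= (2.1 * bw_px)^2 & r2 < (2.9 * bw_px)^2
  B_out <- tm(is_quad & ring); A_out <- tm(is_arm & ring)
  contrast <- if (!is.na(B_out) && !is.na(A_out)) abs(B_out - A_out) else abs(B - A)
  if (contrast < 0.05) return(out)
  out$dev <- max(c(abs(quads - B), abs(arms - A)), na.rm = TRUE) / contrast
  if (!is.na(B_out) && !is.na(A_out)) {
    out$periph <- max(abs(B - B_out), abs(A - A_out)) / contrast
  }
  out
}

#' Per-pixel grid-bar-edge probability for SEM images
#'
#' Scores each pixel's likelihood of lying on a grid-bar edge. The
#' `"classical"` backend is the normalized oriented-edge response: gradient
#' magnitude masked by the edge map and convolved with line kernels at the
#' stroke length and at three times the stroke length (long scratches score
#' lower than full-length bar edges under the longer kernel — the
#' stroke-length test). The `"model"` backend is a logistic-regression pixel
#' classifier over the same filter-bank features, trained once per session on
#' an internally generated synthetic SEM grid with known edge mask.
#'
#' @param image SEM-style grayscale image.
#' @param backend `"classical"` or `"model"`.
#' @param params A [lod_params()].
#' @return Matrix of probabilities in \[0, 1\], same size as `image`.
#' @export
sem_edge_probability <- function(image, backend = c("classical", "model"),
                                 params = lod_params()) {
  backend <- match.arg(backend)
  assert_image(image)
  f <- edge_feature_stack(image, params)
  if (backend == "classical") {
    pos <- f$mag[f$mag > 0]
    if (!length(pos)) return(matrix(0, nrow(image), ncol(image)))
    M <- clamp01(f$mag / stats::quantile(pos, 0.99))
    Md <- from_eb(EBImage::dilate(as_eb(M), disc_brush(1)))
    Md * (0.5 * f$short + 0.5 * f$long)
  } else {
    model <- get_sem_edge_model(params)
    eta <- model$b0 + model$b1 * f$mag + model$b2 * f$short + model$b3 * f$long
    matrix(1 / (1 + exp(-eta)), nrow(image), ncol(image))
  }
}

edge_feature_stack <- function(image, params) {
  em <- edge_map(image, params)
  M <- em$mag * em$mask
  mx <- max(M)
  if (mx > 0) M <- M / mx
  short <- stroke_support(em$mask, params$stroke)
  long <- stroke_support(em$mask, params$stroke, len = 3L * params$stroke)
  list(mag = M, short = short, long = long)
}

.clemtarget_env <- new.env(parent = emptyenv())

get_sem_edge_model <- function(params) {
  if (!is.null(.clemtarget_env$sem_edge_model)) return(.clemtarget_env$sem_edge_model)
  sc <- gen_grid_image(layout = grid_layout(), frame = frame_transform(angle_deg = 45),
                       pixel_size = 1.7, image_size = 384, style = "sem",
                       noise_sd = 0.02, seed = 424242)
  truth <- scene_edge_mask(sc)
  f <- edge_feature_stack(sc$image, params)
  df <- data.frame(y = as.integer(as.vector(truth)),
                   mag = as.vector(f$mag), short = as.vector(f$short),
                   long = as.vector(f$long))
  # balance classes by subsampling the background
  pos <- which(df$y == 1); neg <- which(df$y == 0)
  neg <- neg[seq(1, length(neg), length.out = min(length(neg), 4 * length(pos)))]
  fit <- stats::glm(y ~ mag + short + long, family = stats::binomial(),
                    data = df[c(pos, neg), ])
  cf <- stats::coef(fit)
  model <- list(b0 = cf[1], b1 = cf[2], b2 = cf[3], b3 = cf[4])
  .clemtarget_env$sem_edge_model <- model
  model
}

#' Ground-truth bar-edge mask of a synthetic scene
#'
#' Recomputes, from a `clem_scene`'s parameter echo, which pixels lie within
#' `tol_px` of a visible grid-bar edge (edges are hidden where they run
#' through a crossing).
#'
#' @param scene A `clem_scene` from [gen_grid_image()].
#' @param tol_px Distance tolerance in pixels.
#' @return Logical matrix.
#' @export
scene_edge_mask <- function(scene, tol_px = 1.5) {
  p <- scene$truth$params
  layout <- p$layout; frame <- p$frame
  W <- p$image_size[1]; H <- p$image_size[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  sx <- outer(rep(1, H), seq_len(W) - cx) * p$pixel_size + p$stage_center[1]
  sy <- outer(seq_len(H) - cy, rep(1, W)) * p$pixel_size + p$stage_center[2]
  Ainv <- solve(frame$A)
  gx <- Ainv[1, 1] * (sx - frame$t[1]) + Ainv[1, 2] * (sy - frame$t[2])
  gy <- Ainv[2, 1] * (sx - frame$t[1]) + Ainv[2, 2] * (sy - frame$t[2])
  pitch <- layout$pitch; bw <- layout$bar_width
  ux <- abs(((gx + pitch / 2) %% pitch) - pitch / 2)
  uy <- abs(((gy + pitch / 2) %% pitch) - pitch / 2)
  tol_um <- tol_px * p$pixel_size
  (abs(ux - bw / 2) <= tol_um & uy >= bw / 2) |
    (abs(uy - bw / 2) <= tol_um & ux >= bw / 2)
}

#' Detect and refine all crossings in one image
#'
#' Convenience wrapper: [detect_lines()] with the layout spacing test,
#' [find_crossings()], then [refine_crossing()] on every candidate.
#'
#' @inheritParams detect_lines
#' @inheritParams refine_crossing
#' @return A tibble with refined centers and statuses (one row per
#'   candidate crossing).
#' @export
detect_grid_crossings <- function(image, layout = grid_layout(),
                                  pixel_size = 1.7, params = lod_params()) {
  lines <- detect_lines(image, params, layout = layout, pixel_size = pixel_size)
  cands <- find_crossings(lines, layout, pixel_size)
  if (!nrow(cands)) return(cands)
  out <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
    refine_crossing(image, cands[i, ], params, layout, pixel_size)
  })
  dplyr::bind_cols(out, cands[, c("angle_a", "angle_b", "score")])
}

#' Build a landmark map over a simulated or real dish surface
#'
#' Visits a uniformly sampled subset of the layout's grid crossings (fraction
#' `sampling_fraction`, at least `min_landmarks`), acquiring an image at each
#' predicted stage position via `image_source`, detecting and refining the
#' central crossing. A failed detection is retried once after a simulated
#' refocus (a second image request); a second failure flags the landmark
#' `blocked`. After every valid addition the lattice model mapping label
#' indices to stage coordinates is refitted and used to predict subsequent
#' positions.
#'
#' @param image_source `function(stage_xy)` returning a grayscale image
#'   centered at that stage position.
#' @param layout A [grid_layout()].
#' @param frame Initial [frame_transform()] guess (grid to stage), used until
#'   four landmarks are available to fit the lattice model.
#' @param sampling_fraction Fraction of grid crossings to visit.
#' @param min_landmarks Minimum number of valid landmarks required.
#' @param pixel_size,params Detection settings for the acquired images.
#' @param frame_label Frame tag stored in the map (`"LM"` or `"EM"`).
#' @param seed Integer seed for the uniform sampling order.
#' @return A `clem_landmark_map` tibble: `label`, `frame`, `stage_x_um`,
#'   `stage_y_um`, `status` (`valid`/`blocked`); attribute `lattice` holds
#'   the final lattice model.
#' @export
build_landmark_map <- function(image_source, layout, frame,
                               sampling_fraction = 0.30, min_landmarks = 20,
                               pixel_size = 1.7, params = lod_params(),
                               frame_label = "EM", seed = 1) {
  labs <- grid_labels(layout)
  order_idx <- with_seed(seed, sample.int(nrow(labs)))
  n_target <- max(ceiling(sampling_fraction * nrow(labs)), min_landmarks)
  lattice <- NULL
  map <- tibble::tibble(label = character(), frame = character(),
                        stage_x_um = numeric(), stage_y_um = numeric(),
                        status = character())
  n_valid <- 0L
  for (i in order_idx) {
    if (n_valid >= n_target) break
    lab <- labs[i, ]
    pred <- if (!is.null(lattice)) {
      as.numeric(predict(lattice, tibble::tibble(row = lab$row, col = lab$col)))
    } else {
      as.numeric(apply_frame(frame, c(lab$x_um, lab$y_um)))
    }
    res <- try_landmark(image_source, pred, layout, pixel_size, params)
    if (is.null(res)) {  # refocus once and retry
      res <- try_landmark(image_source, pred, layout, pixel_size, params)
    }
    if (is.null(res)) {
      map <- dplyr::bind_rows(map, tibble::tibble(
        label = lab$label, frame = frame_label,
        stage_x_um = pred[1], stage_y_um = pred[2], status = "blocked"))
      next
    }
    map <- dplyr::bind_rows(map, tibble::tibble(
      label = lab$label, frame = frame_label,
      stage_x_um = res[1], stage_y_um = res[2], status = "valid"))
    n_valid <- n_valid + 1L
    valid <- map[map$status == "valid", ]
    if (n_valid >= 4) {
      lm_tbl <- dplyr::inner_join(valid, labs[, c("label", "row", "col")],
                                  by = "label")
      lattice <- tryCatch(fit_lattice(lm_tbl, layout), error = function(e) lattice)
    }
  }
  if (n_valid < min_landmarks) {
    rlang::abort(sprintf("only %d of the required %d landmarks were valid",
                         n_valid, min_landmarks),
                 class = "clemtarget_partial_map", map = map)
  }
  structure(map, class = c("clem_landmark_map", class(map)), lattice = lattice)
}

try_landmark <- function(image_source, stage_xy, layout, pixel_size, params) {
  img <- image_source(stage_xy)
  cr <- tryCatch(detect_grid_crossings(img, layout, pixel_size, params),
                 error = function(e) NULL)
  if (is.null(cr) || !nrow(cr)) return(NULL)
  cr <- cr[cr$status == "accepted", ]
  if (!nrow(cr)) return(NULL)
  ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
  d <- sqrt((cr$center_x - ctr[1])^2 + (cr$center_y - ctr[2])^2)
  best <- which.min(d)
  if (d[best] > layout$bar_width / pixel_size * 2) return(NULL)
  c(stage_xy[1] + (cr$center_x[best] - ctr[1]) * pixel_size,
    stage_xy[2] + (cr$center_y[best] - ctr[2]) * pixel_size)
}
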