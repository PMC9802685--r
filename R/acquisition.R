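# FIB-SEM acquisition-setup heuristics as pure functions: coincidence-point
# z-offset, beam-shift refinement by cross-correlation, trench detection, and
# autofocus/autostigmation (AFAS) site selection.

#' FIB/SEM beam geometry
#'
#' @param beam_angle_deg Angle between the FIB and SEM axes, degrees
#'   (Crossbeam-style stages sit at 54).
#' @param pixel_size Image pixel size, micrometres per pixel.
#' @param mark_size_um Side of the sputtered square fiducial mark.
#' @param shift_protect_um Lateral stage shift applied before sputtering so
#'   the mark does not burn the target.
#' @param dz_sign Sign convention of the stage z correction (+1: positive dy
#'   means the stage must move up).
#' @return A `beam_geometry` list.
#' @export
beam_geometry <- function(beam_angle_deg = 54, pixel_size = 0.25,
                          mark_size_um = 20, shift_protect_um = 50,
                          dz_sign = 1) {
  stopifnot(beam_angle_deg > 0, beam_angle_deg < 90, pixel_size > 0)
  structure(list(beam_angle_deg = beam_angle_deg, pixel_size = pixel_size,
                 mark_size_um = mark_size_um,
                 shift_protect_um = shift_protect_um, dz_sign = dz_sign),
            class = "beam_geometry")
}

#' Coincidence-point z correction from the mark offset
#'
#' Converts the measured y-offset between the sputtered-mark centers in the
#' SEM and FIB views into the stage z correction that brings both beams onto
#' the same surface point: `dz = dy / tan(beam_angle)`, an odd (linear)
#' function of `dy`. The sign convention is configurable through
#' `geometry$dz_sign`.
#'
#' @param dy_um Signed SEM-vs-FIB mark center offset, micrometres.
#' @param geometry A [beam_geometry()].
#' @return Stage z correction `dz` in micrometres.
#' @export
coincidence_z_offset <- function(dy_um, geometry = beam_geometry()) {
  geometry$dz_sign * dy_um / tan(geometry$beam_angle_deg * pi / 180)
}

#' Beam-shift refinement by mark cross-correlation
#'
#' Measures the residual translation between the sputtered fiducial mark as
#' imaged by the FIB and by the SEM, by phase correlation with sub-pixel peak
#' interpolation, converted to micrometres via the pixel size. The result is
#' applied to the SEM beam shift.
#'
#' @param mark_img_fib,mark_img_sem Equal-size grayscale images containing
#'   the mark.
#' @param geometry A [beam_geometry()].
#' @param min_peak Correlation-peak confidence floor; below it the mark is
#'   declared not found.
#' @return List with `dx_um`, `dy_um`, `peak`.
#' @export
beamshift_refine <- function(mark_img_fib, mark_img_sem,
                             geometry = beam_geometry(), min_peak = 0.1) {
  assert_image(mark_img_fib); assert_image(mark_img_sem)
  pc <- phase_correlation(mark_img_fib, mark_img_sem)
  if (pc$peak < min_peak) rlang::abort("mark not found")
  # second pass on the coarsely aligned pair removes the window-induced
  # proportional bias, leaving only the sub-pixel residual to interpolate
  int_shift <- round(c(pc$dx, pc$dy))
  realigned <- img_translate(mark_img_sem, -int_shift[1], -int_shift[2])
  pc2 <- phase_correlation(mark_img_fib, realigned)
  dx <- int_shift[1] + pc2$dx
  dy <- int_shift[2] + pc2$dy
  list(dx_um = dx * geometry$pixel_size, dy_um = dy * geometry$pixel_size,
       peak = max(pc$peak, pc2$peak))
}

#' Detect the milled trench as a trapezoid
#'
#' Applies a slight blur and three-level (two-threshold Otsu) intensity
#' classification; the darkest class is segmented into connected components,
#' each tested for a trapezoid shape (convex quadrilateral, horizontal-ish
#' top edge longer than the bottom edge — the FIB-perspective signature of a
#' milled trench). Among passing components the largest is returned, or the
#' one nearest the image center when `expect_near_center` and several
#' qualify. The procedure depends only on intensity ranks, so it is invariant
#' to global offset and gain changes.
#'
#' @param image Grayscale image.
#' @param expect_near_center Prefer the trapezoid nearest the image center
#'   when several are present (re-acquisitions leave old trenches).
#' @param min_area_frac Minimum component area as a fraction of the image.
#' @param top_bottom_ratio Allowed top/bottom edge length ratio range.
#' @param max_top_tilt_deg Maximum tilt of the top edge from horizontal.
#' @return A `clem_trapezoid`: list with `corners` (tibble: position, x, y),
#'   `top_center`, `centroid`, `area_px`.
#' @export
detect_trench <- function(image, expect_near_center = TRUE,
                          min_area_frac = 0.002,
                          top_bottom_ratio = c(1.05, 4),
                          max_top_tilt_deg = 10) {
  assert_image(image)
  img <- img_gblur(image, 1)
  th <- multiotsu_thresholds(img)
  dark <- img <= th[1]
  if (!any(dark)) rlang::abort("trench not found")
  # the darkest class must be genuinely separated from the brightest one;
  # a unimodal texture split into thirds scores ~2.5 on this (gain- and
  # offset-invariant) contrast, a milled trench >= 6
  bright <- img[img > th[2]]
  contrast <- (mean(bright) - mean(img[dark])) /
    max(stats::sd(img[dark]) + stats::sd(bright), 1e-9)
  if (!is.finite(contrast) || contrast < 3.5) rlang::abort("trench not found")
  lab <- label_components(dark)
  sizes <- tabulate(lab[lab > 0])
  H <- nrow(image); W <- ncol(image)
  cands <- list()
  for (k in which(sizes >= min_area_frac * H * W)) {
    px <- which(lab == k)
    ys <- (px - 1L) %% H + 1L; xs <- (px - 1L) %/% H + 1L
    tz <- fit_trapezoid(xs, ys, top_bottom_ratio, max_top_tilt_deg)
    if (!is.null(tz)) cands[[length(cands) + 1]] <- tz
  }
  if (!length(cands)) rlang::abort("trench not found")
  if (length(cands) > 1 && expect_near_center) {
    d <- vapply(cands, function(z) {
      sqrt((z$centroid[1] - (W + 1) / 2)^2 + (z$centroid[2] - (H + 1) / 2)^2)
    }, numeric(1))
    cands[[which.min(d)]]
  } else {
    areas <- vapply(cands, function(z) z$area_px, numeric(1))
    cands[[which.max(areas)]]
  }
}

fit_trapezoid <- function(xs, ys, ratio_rng, max_tilt) {
  # ignore stray rows (blur fringes): keep rows carrying real width
  cnt <- table(ys)
  solid <- as.integer(names(cnt))[cnt >= max(3, 0.25 * stats::median(cnt))]
  if (!length(solid)) return(NULL)
  keep <- ys %in% solid
  xs <- xs[keep]; ys <- ys[keep]
  ymin <- min(ys); ymax <- max(ys)
  if (ymax - ymin < 8) return(NULL)
  top <- xs[ys <= ymin + 2]; bot <- xs[ys >= ymax - 2]
  tl <- c(min(top), ymin); tr <- c(max(top), ymin)
  bl <- c(min(bot), ymax); br <- c(max(bot), ymax)
  top_w <- tr[1] - tl[1]; bot_w <- br[1] - bl[1]
  if (bot_w < 2 || top_w < 8) return(NULL)
  ratio <- top_w / bot_w
  if (ratio < ratio_rng[1] || ratio > ratio_rng[2]) return(NULL)
  # fill ratio: component area must match the quadrilateral's area
  quad_x <- c(tl[1], tr[1], br[1], bl[1]); quad_y <- c(tl[2], tr[2], br[2], bl[2])
  quad_area <- abs(sum(quad_x * c(quad_y[-1], quad_y[1]) -
                         c(quad_x[-1], quad_x[1]) * quad_y)) / 2
  if (quad_area <= 0) return(NULL)
  fill <- length(xs) / quad_area
  if (fill < 0.8 || fill > 1.3) return(NULL)
  # top-edge tilt estimated from the upper boundary profile
  ord <- order(xs)
  upper <- tapply(ys, xs, min)
  ux <- as.numeric(names(upper)); uy <- as.numeric(upper)
  mid <- ux > tl[1] + 0.1 * top_w & ux < tr[1] - 0.1 * top_w
  if (sum(mid) >= 5) {
    slope <- stats::coef(stats::lm(uy[mid] ~ ux[mid]))[2]
    if (abs(atan(slope) * 180 / pi) > max_tilt) return(NULL)
  }
  structure(list(
    corners = tibble::tibble(
      position = c("top_left", "top_right", "bottom_right", "bottom_left"),
      x = c(tl[1], tr[1], br[1], bl[1]),
      y = c(tl[2], tr[2], br[2], bl[2])),
    top_center = c((tl[1] + tr[1]) / 2, ymin),
    centroid = c(mean(xs), mean(ys)),
    area_px = length(xs)),
    class = "clem_trapezoid")
}

#' @export
print.clem_trapezoid <- function(x, ...) {
  cat(sprintf("<clem_trapezoid> centroid (%.1f, %.1f), area %d px\n",
              x$centroid[1], x$centroid[2], as.integer(x$area_px)))
  invisible(x)
}

#' Select autofocus/autostigmation sites on a cross-section
#'
#' Finds Harris corners below the coating exclusion band, clusters them with
#' k-means, and ranks the cluster centroids by a weighted score of local
#' intensity variance, local entropy and proximity to the image center. On a
#' featureless image the fallback site is the edge between the cross-section
#' and the block surface (the detected coating boundary).
#'
#' @param image Grayscale cross-section image.
#' @param coating_row Last row of the exclusion band (sites must lie below
#'   it); detected via [detect_coating_edge()] when `NULL`.
#' @param k_sites Maximum number of sites returned.
#' @param margin_px Extra margin below the coating and from image borders.
#' @param weights Score weights `c(variance, entropy, proximity)`.
#' @param patch Half-size of the local statistics patch.
#' @param seed Seed for the k-means initialization.
#' @return Tibble of class `clem_afas_sites`: `x`, `y`, `variance`,
#'   `entropy`, `proximity`, `score`, `rank`, `method`
#'   (`"features"`/`"fallback"`).
#' @export
select_afas_sites <- function(image, coating_row = NULL, k_sites = 6,
                              margin_px = 8, weights = c(0.5, 0.3, 0.2),
                              patch = 7, seed = 1) {
  assert_image(image)
  H <- nrow(image); W <- ncol(image)
  if (is.null(coating_row)) {
    coating_row <- tryCatch(detect_coating_edge(image), error = function(e) 0L)
  }
  if (H <= coating_row + margin_px + 2 * patch) {
    rlang::abort("image height does not exceed the exclusion band")
  }
  fallback <- function() {
    row <- max(coating_row + margin_px, 1L)
    tibble::tibble(x = (W + 1) / 2, y = row, variance = NA_real_,
                   entropy = NA_real_, proximity = NA_real_, score = NA_real_,
                   rank = 1L, method = "fallback")
  }
  R <- harris_response(img_gblur(image, 1))
  thr <- 0.01 * max(R)
  if (max(R) <= 1e-12) return(structure(fallback(), class = c("clem_afas_sites", class(fallback()))))
  corners <- local_maxima(R, thr, min_sep = 5)
  corners <- corners[corners$y > coating_row + margin_px + patch &
                       corners$y < H - patch &
                       corners$x > patch & corners$x < W - patch, ]
  if (nrow(corners) < 3) {
    out <- fallback()
    return(structure(out, class = c("clem_afas_sites", class(out))))
  }
  k <- min(max(6, nrow(corners) %/% 50), 12, nrow(corners))
  # corner clouds can make Lloyd's algorithm cycle; the assignment it stops
  # on is still a fine clustering for site ranking
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(cbind(corners$x, corners$y), centers = k, nstart = 3,
                  iter.max = 30)))
  ctrs <- km$centers
  stats_at <- function(cx, cy) {
    cx <- round(pmin(pmax(cx, patch + 1), W - patch))
    cy <- round(pmin(pmax(cy, coating_row + margin_px + patch + 1), H - patch))
    p <- image[(cy - patch):(cy + patch), (cx - patch):(cx + patch)]
    c(cx, cy, stats::var(as.vector(p)), intensity_entropy(as.vector(p)))
  }
  st <- t(vapply(seq_len(k), function(i) stats_at(ctrs[i, 1], ctrs[i, 2]),
                 numeric(4)))
  prox <- 1 - sqrt((st[, 1] - (W + 1) / 2)^2 + (st[, 2] - (H + 1) / 2)^2) /
    sqrt(((W - 1) / 2)^2 + ((H - 1) / 2)^2)
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  }
  score <- weights[1] * norm01(st[, 3]) + weights[2] * norm01(st[, 4]) +
    weights[3] * norm01(prox)
  ord <- order(-score)
  out <- tibble::tibble(
    x = st[ord, 1], y = st[ord, 2],
    variance = st[ord, 3], entropy = st[ord, 4], proximity = prox[ord],
    score = score[ord], rank = seq_along(ord), method = "features")
  out <- out[seq_len(min(k_sites, nrow(out))), ]
  stopifnot(all(out$y > coating_row + margin_px))
  structure(out, class = c("clem_afas_sites", class(out)))
}
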