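# Per-slice supervision of a running slice-and-view acquisition: drift
# tracking with a coating-band fallback, focus/stigmatism quality metrics,
# the 25%-change warning rule, FOV-shift decisions and autotune-box placement.

#' Run-monitor configuration
#'
#' @param quality_change_threshold Relative metric change between consecutive
#'   slices that triggers a warning.
#' @param drift_tolerance_fraction Allowed cumulative y-drift as a fraction
#'   of the image height before the FOV is shifted.
#' @param fov_step_um FOV correction quantum, micrometres.
#' @param afas_interval_min Interval between autofocus/autostigmation runs,
#'   minutes (recorded with the run; nothing sleeps on it).
#' @param min_feature_inliers RANSAC inlier floor below which drift
#'   estimation falls back to coating-band alignment.
#' @return A `monitor_config` list.
#' @export
monitor_config <- function(quality_change_threshold = 0.25,
                           drift_tolerance_fraction = 0.25,
                           fov_step_um = 0.5, afas_interval_min = 45,
                           min_feature_inliers = 8) {
  stopifnot(quality_change_threshold > 0, quality_change_threshold < 1,
            drift_tolerance_fraction > 0, drift_tolerance_fraction < 1,
            fov_step_um > 0, afas_interval_min > 0)
  structure(list(quality_change_threshold = quality_change_threshold,
                 drift_tolerance_fraction = drift_tolerance_fraction,
                 fov_step_um = fov_step_um,
                 afas_interval_min = afas_interval_min,
                 min_feature_inliers = min_feature_inliers),
            class = "monitor_config")
}

#' Estimate inter-slice drift
#'
#' Detects corner features on the previous slice, matches each by normalized
#' cross-correlation of its local patch within a search window on the current
#' slice, and estimates the translation as the RANSAC consensus of the match
#' displacements (sub-pixel via parabolic interpolation of each correlation
#' surface). When fewer than `min_feature_inliers` matches agree, the
#' estimate falls back to aligning the bright coating band (y only).
#'
#' @param img_prev,img_cur Consecutive slices, equal size.
#' @param cfg A [monitor_config()].
#' @param search_px Search half-window, pixels.
#' @param patch_px Feature patch half-size, pixels.
#' @param max_features Number of corner features used.
#' @return List with `dx`, `dy` (pixels; content of `img_cur` = content of
#'   `img_prev` shifted by +dx, +dy), `method` (`"features"`/`"coating"`),
#'   `n_inliers`.
#' @export
estimate_drift <- function(img_prev, img_cur, cfg = monitor_config(),
                           search_px = 24, patch_px = 7, max_features = 60) {
  assert_image(img_prev); assert_image(img_cur)
  stopifnot(all(dim(img_prev) == dim(img_cur)))
  H <- nrow(img_prev); W <- ncol(img_prev)
  R <- harris_response(img_gblur(img_prev, 1))
  margin <- search_px + patch_px + 1
  disp <- NULL
  if (max(R) > 1e-12) {
    corners <- local_maxima(R, 0.01 * max(R), min_sep = 2 * patch_px)
    corners <- corners[corners$x > margin & corners$x < W - margin &
                         corners$y > margin & corners$y < H - margin, ]
    if (nrow(corners) > max_features) corners <- corners[seq_len(max_features), ]
    if (nrow(corners) >= 3) {
      disp <- purrr::map_dfr(seq_len(nrow(corners)), function(i) {
        match_patch(img_prev, img_cur, corners$x[i], corners$y[i],
                    patch_px, search_px)
      })
      disp <- disp[!is.na(disp$dx) & disp$ncc > 0.5, ]
    }
  }
  if (!is.null(disp) && nrow(disp) >= cfg$min_feature_inliers) {
    est <- ransac_translation(disp, tol = 1.5)
    if (est$n_inliers >= cfg$min_feature_inliers) {
      return(list(dx = est$dx, dy = est$dy, method = "features",
                  n_inliers = est$n_inliers))
    }
  }
  # coating fallback: align the bright band rows
  r1 <- tryCatch(detect_coating_edge(img_prev), error = function(e) NULL)
  r2 <- tryCatch(detect_coating_edge(img_cur), error = function(e) NULL)
  if (is.null(r1) || is.null(r2)) rlang::abort("untrackable slice")
  list(dx = 0, dy = r2 - r1, method = "coating", n_inliers = 0L)
}

match_patch <- function(prev, cur, cx, cy, p, s) {
  tpl <- prev[(cy - p):(cy + p), (cx - p):(cx + p)]
  tpl <- tpl - mean(tpl)
  tn <- sqrt(sum(tpl^2))
  if (tn < 1e-9) return(tibble::tibble(dx = NA_real_, dy = NA_real_, ncc = 0))
  win <- cur[(cy - p - s):(cy + p + s), (cx - p - s):(cx + p + s)]
  n <- 2 * s + 1
  ncc <- matrix(-Inf, n, n)
  for (iy in seq_len(n)) {
    for (ix in seq_len(n)) {
      sub <- win[(iy):(iy + 2 * p), (ix):(ix + 2 * p)]
      sub <- sub - mean(sub)
      sn <- sqrt(sum(sub^2))
      if (sn < 1e-9) next
      ncc[iy, ix] <- sum(sub * tpl) / (sn * tn)
    }
  }
  pk <- arrayInd(which.max(ncc), dim(ncc))
  sub1 <- function(v, i) {
    if (i <= 1 || i >= length(v) || !all(is.finite(v[(i - 1):(i + 1)]))) return(0)
    d <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (abs(d) < 1e-12) 0 else 0.5 * (v[i - 1] - v[i + 1]) / d
  }
  tibble::tibble(dx = pk[2] - s - 1 + sub1(ncc[pk[1], ], pk[2]),
                 dy = pk[1] - s - 1 + sub1(ncc[, pk[2]], pk[1]),
                 ncc = max(ncc))
}

ransac_translation <- function(disp, tol = 1.5) {
  best <- integer()
  for (i in seq_len(nrow(disp))) {
    inl <- which(abs(disp$dx - disp$dx[i]) <= tol &
                   abs(disp$dy - disp$dy[i]) <= tol)
    if (length(inl) > length(best)) best <- inl
  }
  list(dx = mean(disp$dx[best]), dy = mean(disp$dy[best]),
       n_inliers = length(best))
}

#' Detect the coating band edge row
#'
#' Locates the top of the resin block (gold coating) as the row of maximal
#' change in the row-wise intensity-entropy profile, searched over the top
#' half of the image.
#'
#' @param img Grayscale image with at least 32 rows.
#' @param min_change Minimum entropy-profile change considered significant.
#' @return Row index (integer).
#' @export
detect_coating_edge <- function(img, min_change = 0.3) {
  assert_image(img)
  if (nrow(img) < 32) rlang::abort("image too small for coating detection")
  ent <- apply(img, 1, intensity_entropy, n_bins = 16)
  # the coating band is bright and homogeneous (low entropy) relative to the
  # textured cross-section below and the dark vacuum above
  bright <- rowMeans(img)
  score <- bright - 0.1 * ent
  h <- nrow(img)
  half <- seq_len(max(16, h %/% 2))
  s <- score[half]
  if (max(s) - stats::median(s) < min_change) rlang::abort("no coating")
  pk <- max(s)
  band <- which(s >= stats::median(s) + 0.9 * (pk - stats::median(s)))
  # contiguous run around the peak
  peak_row <- which.max(s)
  run <- band[cumsum(c(1, diff(band) > 1)) ==
                cumsum(c(1, diff(band) > 1))[match(peak_row, band)]]
  as.integer(round(mean(run)))
}

#' Vollath F4 focus metric
#'
#' Vollath's autocorrelation sharpness measure, normalized by pixel count so
#' thresholds are resolution independent:
#' `F4 = (sum I(x,y) I(x+1,y) - sum I(x,y) I(x+2,y)) / n_pixels`. Zero for a
#' constant image; decreases monotonically with defocus blur.
#'
#' @param img Grayscale image.
#' @return Non-negative focus score.
#' @export
focus_metric <- function(img) {
  assert_image(img)
  W <- ncol(img)
  if (W < 3) return(0)
  s1 <- sum(img[, 1:(W - 1)] * img[, 2:W])
  s2 <- sum(img[, 1:(W - 2)] * img[, 3:W])
  max(0, (s1 - s2 * (W - 1) / (W - 2)) / length(img))
}

#' Laplacian stigmatism metric
#'
#' Normalized variance of the Laplacian-filtered image; anisotropic
#' (astigmatic) blur changes it relative to isotropic blur of comparable
#' strength. Invariant to a global intensity offset.
#'
#' @param img Grayscale image.
#' @return Non-negative score.
#' @export
astig_metric <- function(img) {
  assert_image(img)
  lap <- conv2_same(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  stats::var(as.vector(lap)) * 1e4
}

#' Consecutive-slice quality check
#'
#' Warns when a quality metric changes by more than
#' `quality_change_threshold` (default 25%) relative to the previous slice.
#'
#' @param prev_score,cur_score Metric values (previous must be > 0).
#' @param cfg A [monitor_config()].
#' @return `"ok"` or `"warn"`.
#' @export
check_quality <- function(prev_score, cur_score, cfg = monitor_config()) {
  stopifnot(prev_score > 0)
  if (abs(cur_score - prev_score) / prev_score > cfg$quality_change_threshold)
    "warn" else "ok"
}

#' FOV shift decision from cumulative drift
#'
#' No action while the cumulative y-drift stays within a quarter (by default)
#' of the image height; beyond it, a shift opposing the drift is emitted,
#' quantized upward to whole `fov_step_um` increments so the reference is
#' brought back within tolerance.
#'
#' @param cumulative_dy_px Cumulative y drift, pixels (positive = down).
#' @param image_height_px Image height, pixels.
#' @param pixel_size_um Pixel size, micrometres.
#' @param cfg A [monitor_config()].
#' @return List with `shift_um` (0 when no action), `steps` (signed number of
#'   `fov_step_um` increments) and `action` (`"none"`/`"shift"`).
#' @export
decide_fov_shift <- function(cumulative_dy_px, image_height_px, pixel_size_um,
                             cfg = monitor_config()) {
  stopifnot(image_height_px > 0, pixel_size_um > 0)
  tol <- cfg$drift_tolerance_fraction * image_height_px
  if (abs(cumulative_dy_px) <= tol) {
    return(list(shift_um = 0, steps = 0L, action = "none"))
  }
  steps <- ceiling(abs(cumulative_dy_px) * pixel_size_um / cfg$fov_step_um)
  list(shift_um = -sign(cumulative_dy_px) * steps * cfg$fov_step_um,
       steps = as.integer(-sign(cumulative_dy_px) * steps), action = "shift")
}

#' Place the autotune box
#'
#' Best autofocus site (reusing the AFAS scoring) under the hard constraints
#' that the box lies fully inside the image, fully below the upper coating,
#' and fully within the upper half of the image.
#'
#' @param img Grayscale image.
#' @param coating_row Coating band row.
#' @param box_size_px Side of the square autotune box.
#' @param seed Seed for the site clustering.
#' @return `c(x, y)` of the box top-left corner.
#' @export
place_autotune_box <- function(img, coating_row, box_size_px, seed = 1) {
  assert_image(img)
  H <- nrow(img); W <- ncol(img)
  y_min <- coating_row + 1
  y_max <- floor(H / 2) - box_size_px
  if (y_max < y_min || box_size_px > W) {
    rlang::abort("no feasible autotune-box position")
  }
  sites <- tryCatch(
    select_afas_sites(img, coating_row = coating_row, k_sites = 6,
                      margin_px = 1, seed = seed),
    error = function(e) NULL)
  center_for <- function(x, y) {
    tlx <- min(max(round(x - box_size_px / 2), 1), W - box_size_px + 1)
    tly <- min(max(round(y - box_size_px / 2), y_min), y_max + 1)
    c(tlx, tly)
  }
  if (!is.null(sites) && sites$method[1] == "features") {
    cand <- sites[sites$y <= floor(H / 2), , drop = FALSE]
    if (nrow(cand)) return(center_for(cand$x[1], cand$y[1]))
  }
  # featureless: center of the feasible band
  c(max(1, round((W - box_size_px) / 2)), round((y_min + y_max) / 2))
}

#' Monitor a slice stack
#'
#' Sequentially applies drift estimation, the focus and stigmatism metrics,
#' the consecutive-slice quality rule and the FOV-shift decision to a stack.
#' Emitted FOV shifts are applied to the tracked reference, so a shift is
#' followed by quiet slices until the drift accumulates again (hysteresis).
#'
#' @param stack 3-D array `[y, x, slice]` (or list of matrices).
#' @param cfg A [monitor_config()].
#' @param pixel_size_um Pixel size for the FOV-shift quantization.
#' @return A tibble of class `clem_slice_reports`: per slice, `slice`,
#'   `dx`, `dy`, `dx_cum`, `dy_cum`, `method`, `focus`, `astig`,
#'   `focus_status`, `astig_status`, `fov_shift_um`, `warnings`.
#' @export
monitor_stack <- function(stack, cfg = monitor_config(), pixel_size_um = 0.008) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 2)
  n <- dim(stack)[3]
  H <- dim(stack)[1]
  reports <- vector("list", n)
  cum <- c(0, 0)
  ref_dy <- 0  # tracked reference offset after applied FOV shifts
  prev_focus <- NA_real_; prev_astig <- NA_real_
  for (i in seq_len(n)) {
    img <- stack[, , i]
    f <- focus_metric(img); a <- astig_metric(img)
    if (i == 1) {
      reports[[i]] <- tibble::tibble(
        slice = 0L, dx = 0, dy = 0, dx_cum = 0, dy_cum = 0,
        method = "reference", focus = f, astig = a,
        focus_status = "ok", astig_status = "ok",
        fov_shift_um = 0, warnings = "")
    } else {
      dr <- estimate_drift(stack[, , i - 1], img, cfg)
      cum <- cum + c(dr$dx, dr$dy)
      fs <- if (prev_focus > 0) check_quality(prev_focus, f, cfg) else "ok"
      as_ <- if (prev_astig > 0) check_quality(prev_astig, a, cfg) else "ok"
      dec <- decide_fov_shift(cum[2] - ref_dy, H, pixel_size_um, cfg)
      if (dec$action == "shift") {
        ref_dy <- cum[2]  # reference re-centered by the applied shift
      }
      warn <- c(if (fs == "warn") "focus_change", if (as_ == "warn") "astig_change")
      reports[[i]] <- tibble::tibble(
        slice = i - 1L, dx = dr$dx, dy = dr$dy,
        dx_cum = cum[1], dy_cum = cum[2], method = dr$method,
        focus = f, astig = a, focus_status = fs, astig_status = as_,
        fov_shift_um = dec$shift_um,
        warnings = paste(warn, collapse = ";"))
    }
    prev_focus <- f; prev_astig <- a
  }
  out <- dplyr::bind_rows(reports)
  structure(out, class = c("clem_slice_reports", class(out)))
}
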