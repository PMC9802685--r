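# Golgi-morphology phenotype features and cell-selection quality control.
#
# Four intensity-independent morphology scores computed on the GFP (Golgi
# marker) channel within each segmented cell cytoplasm: diffuseness
# (grayscale-opening energy ratio), fragmentation (component count after
# top-hat + Otsu), tubularity (orientation anisotropy of line-SE openings)
# and condensation (shape factor 4*pi*A/P^2 of the binarized signal).

#' Feature-extraction configuration
#'
#' Structuring-element sizes default to a 1.7 um/px acquisition scale and
#' scale linearly with pixel size.
#'
#' @param opening_radius_px Disc radius of the diffuseness opening.
#' @param tophat_radius_px Disc radius of the top-hat filter.
#' @param line_length_px Length of the line structuring elements.
#' @param angle_step_deg Orientation step of the line-opening sweep over
#'   0-180 degrees.
#' @param condensation_mode `"area_weighted"` (mean shape factor weighted by
#'   component area) or `"largest"` (largest component only).
#' @param min_fragment_px Minimum component size counted by fragmentation
#'   (0 = no floor).
#' @return A `feature_config` list.
#' @export
feature_config <- function(opening_radius_px = 10, tophat_radius_px = 15,
                           line_length_px = 21, angle_step_deg = 1,
                           condensation_mode = c("area_weighted", "largest"),
                           min_fragment_px = 0) {
  stopifnot(opening_radius_px > 0, tophat_radius_px > 0, line_length_px > 0,
            angle_step_deg > 0)
  structure(list(opening_radius_px = opening_radius_px,
                 tophat_radius_px = tophat_radius_px,
                 line_length_px = line_length_px,
                 angle_step_deg = angle_step_deg,
                 condensation_mode = match.arg(condensation_mode),
                 min_fragment_px = min_fragment_px),
            class = "feature_config")
}

#' Segment cells from DAPI and GFP channels
#'
#' Segments nuclei from the DAPI signal (blur, Otsu, hole filling, small
#' objects dropped) and delimits each cell's cytoplasmic region by radial
#' dilation of its nucleus, partitioning contested pixels to the nearest
#' nucleus so cytoplasm masks are disjoint.
#'
#' @param dapi_img,gfp_img Equal-size grayscale images.
#' @param dilation_radius_px Radial dilation of each nuclear region.
#' @param min_nucleus_px Minimum nucleus size kept.
#' @return List of per-cell records: `nucleus_mask`, `cytoplasm_mask`
#'   (logical matrices; nucleus subset of cytoplasm).
#' @export
segment_cells <- function(dapi_img, gfp_img, dilation_radius_px = 40,
                          min_nucleus_px = 60) {
  assert_image(dapi_img); assert_image(gfp_img)
  stopifnot(all(dim(dapi_img) == dim(gfp_img)))
  sm <- img_gblur(dapi_img, 2)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask)) rlang::abort("no nuclei found")
  mask <- from_eb(EBImage::fillHull(as_eb(mask * 1))) > 0
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_nucleus_px)
  if (!length(keep)) rlang::abort("no nuclei found")
  dmaps <- lapply(keep, function(k) {
    # distance of every pixel to nucleus k
    from_eb(EBImage::distmap(as_eb((lab != k) * 1)))
  })
  D <- simplify2array(dmaps)
  nearest <- apply(D, c(1, 2), which.min)
  lapply(seq_along(keep), function(i) {
    nuc <- lab == keep[i]
    cyto <- D[, , i] <= dilation_radius_px & nearest == i
    list(nucleus_mask = nuc, cytoplasm_mask = cyto | nuc)
  })
}

#' Diffuseness of the GFP signal
#'
#' Sum of the cytoplasm pixel values after a grayscale opening, divided by
#' the raw sum: close to 1 when the signal is homogeneously spread over the
#' cell body, small when it is concentrated in structures smaller than the
#' structuring element. Always in \[0, 1\] since an opening never increases
#' values.
#'
#' @param gfp_img Grayscale GFP image.
#' @param cytoplasm_mask Logical mask of the cell cytoplasm.
#' @param cfg A [feature_config()].
#' @return Scalar in \[0, 1\].
#' @export
diffuseness <- function(gfp_img, cytoplasm_mask, cfg = feature_config()) {
  check_cell_inputs(gfp_img, cytoplasm_mask)
  tot <- sum(gfp_img[cytoplasm_mask])
  if (tot <= 0) rlang::abort("zero total signal in the cytoplasm")
  op <- img_opening(gfp_img, disc_brush(cfg$opening_radius_px))
  sum(op[cytoplasm_mask]) / tot
}

#' Fragmentation of the GFP signal
#'
#' Number of separate 8-connected components of the binarized signal
#' (top-hat filter then Otsu threshold) within the cytoplasm.
#'
#' @inheritParams diffuseness
#' @return Non-negative integer count.
#' @export
fragmentation <- function(gfp_img, cytoplasm_mask, cfg = feature_config()) {
  check_cell_inputs(gfp_img, cytoplasm_mask)
  mask <- binarize_signal(gfp_img, cytoplasm_mask, cfg)
  if (!any(mask)) return(0L)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= max(1, cfg$min_fragment_px))
}

#' Tubularity of the GFP signal
#'
#' Grayscale openings with line structuring elements swept over 0-180
#' degrees; for each pixel the difference between the maximum and minimum
#' response over orientations is accumulated and normalized by the total GFP
#' intensity. Isotropic structures larger than the line score near zero;
#' elongated tubules score high.
#'
#' @inheritParams diffuseness
#' @return Non-negative scalar.
#' @export
tubularity <- function(gfp_img, cytoplasm_mask, cfg = feature_config()) {
  check_cell_inputs(gfp_img, cytoplasm_mask)
  tot <- sum(gfp_img[cytoplasm_mask])
  if (tot <= 0) rlang::abort("zero total signal in the cytoplasm")
  angles <- seq(0, 180 - cfg$angle_step_deg, by = cfg$angle_step_deg)
  mx <- NULL; mn <- NULL
  for (a in angles) {
    op <- img_opening(gfp_img, line_brush(cfg$line_length_px, a))
    if (is.null(mx)) { mx <- op; mn <- op } else {
      mx <- pmax(mx, op); mn <- pmin(mn, op)
    }
  }
  sum((mx - mn)[cytoplasm_mask]) / tot
}

#' Condensation of the GFP signal
#'
#' Shape factor `4 * pi * Area / Perimeter^2` of the binarized signal
#' (top-hat + Otsu) within the cytoplasm, aggregated over connected
#' components (area-weighted mean by default). The perimeter uses a
#' Crofton-style multi-directional estimator so a digital circle approaches
#' the analytic maximum of 1; the result is clipped to \[0, 1\].
#'
#' @inheritParams diffuseness
#' @return Scalar in \[0, 1\].
#' @export
condensation <- function(gfp_img, cytoplasm_mask, cfg = feature_config()) {
  check_cell_inputs(gfp_img, cytoplasm_mask)
  mask <- binarize_signal(gfp_img, cytoplasm_mask, cfg)
  if (!any(mask)) rlang::abort("no component after binarization")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  sf <- vapply(seq_along(sizes), function(k) shape_factor(lab == k), numeric(1))
  v <- if (cfg$condensation_mode == "largest") {
    sf[which.max(sizes)]
  } else {
    sum(sf * sizes) / sum(sizes)
  }
  min(max(v, 0), 1)
}

binarize_signal <- function(gfp_img, cytoplasm_mask, cfg) {
  th <- img_tophat(gfp_img, disc_brush(cfg$tophat_radius_px))
  vals <- th[cytoplasm_mask]
  if (max(vals) - min(vals) < 1e-6) return(matrix(FALSE, nrow(gfp_img), ncol(gfp_img)))
  thr <- otsu_threshold(vals)
  th > thr & cytoplasm_mask
}

#' Shape-factor formula
#'
#' `4 * pi * Area / Perimeter^2` evaluated from given (analytic) area and
#' perimeter: 1 for a circle (`A = pi r^2`, `P = 2 pi r`), `pi/4` for a
#' square, `40 pi / 484` for a 10:1 rectangle.
#'
#' @param area,perimeter Analytic area and perimeter of the shape.
#' @return The shape factor.
#' @export
shape_factor_formula <- function(area, perimeter) 4 * pi * area / perimeter^2

#' Shape factor of a binary component
#'
#' `4 * pi * Area / Perimeter^2` with area = pixel count and perimeter from
#' the Cauchy-Crofton estimator over four directions
#' (`P = pi/8 * (C0 + C90 + (C45 + C135)/sqrt(2))`, where `C` counts
#' boundary crossings along each line family). Equals 1 for a circle in the
#' continuum; rasterized circles converge to 1 as the radius grows.
#'
#' @param mask Logical matrix (single component).
#' @return Shape factor (uncapped; rasterization can push it a few percent
#'   above 1 for small discs).
#' @export
shape_factor <- function(mask) {
  A <- sum(mask)
  if (A == 0) return(NA_real_)
  P <- crofton_perimeter(mask)
  if (P <= 0) return(NA_real_)
  4 * pi * A / P^2
}

crofton_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- mask * 1L
  H <- h + 2L; W <- w + 2L
  c0 <- sum(abs(p[, -1] - p[, -W]))          # crossings along rows
  c90 <- sum(abs(p[-1, ] - p[-H, ]))         # crossings along columns
  c45 <- sum(abs(p[-1, -1] - p[-H, -W]))     # crossings along main diagonals
  c135 <- sum(abs(p[-1, -W] - p[-H, -1]))    # crossings along anti-diagonals
  pi / 8 * (c0 + c90 + (c45 + c135) / sqrt(2))
}

check_cell_inputs <- function(gfp_img, mask) {
  assert_image(gfp_img)
  if (!is.logical(mask)) rlang::abort("mask must be logical")
  if (!any(mask)) rlang::abort("empty mask")
  stopifnot(all(dim(gfp_img) == dim(mask)))
}

#' Log-log power-spectrum slope
#'
#' Slope of the least-squares line fitted to the log radially averaged power
#' spectrum against log spatial frequency (DC excluded). White noise gives a
#' slope near zero; blur makes the slope more negative, which flags
#' out-of-focus acquisitions.
#'
#' @param img Grayscale image, at least 64 px per side.
#' @return Slope (dimensionless).
#' @export
power_log_log_slope <- function(img) {
  assert_image(img)
  if (min(dim(img)) < 64) rlang::abort("image too small (need >= 64 px per side)")
  x <- img - mean(img)
  P <- Mod(stats::fft(x))^2
  h <- nrow(img); w <- ncol(img)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  FR <- sqrt(outer(fy^2, fx^2, "+"))
  rmax <- 0.5
  nb <- 32L
  bins <- cut(as.vector(FR), breaks = seq(0, rmax, length.out = nb + 1),
              include.lowest = FALSE)
  pw <- tapply(as.vector(P), bins, mean)
  fr <- tapply(as.vector(FR), bins, mean)
  ok <- !is.na(pw) & pw > 0
  stats::coef(stats::lm(log(pw[ok]) ~ log(fr[ok])))[[2]]
}

#' Score all cells of an image pair
#'
#' Segments cells and computes the four morphology features plus the QC
#' covariates (integrated GFP signal, DAPI coefficient of variation within
#' the nucleus, and the log-log power-spectrum slope of the cell crop).
#'
#' @param gfp_img,dapi_img Grayscale channel images.
#' @param cfg A [feature_config()].
#' @param dilation_radius_px Cytoplasm dilation radius.
#' @return A tibble, one row per cell: `cell_id`, `diffuseness`,
#'   `fragmentation`, `tubularity`, `condensation`, `gfp_integral`,
#'   `dapi_cov`, `power_slope`.
#' @export
score_cells <- function(gfp_img, dapi_img, cfg = feature_config(),
                        dilation_radius_px = 40) {
  cells <- segment_cells(dapi_img, gfp_img, dilation_radius_px)
  purrr::map_dfr(seq_along(cells), function(i) {
    cell <- cells[[i]]
    cm <- cell$cytoplasm_mask; nm <- cell$nucleus_mask
    slope <- tryCatch(power_log_log_slope(crop_to_mask(gfp_img, cm, 64)),
                      error = function(e) NA_real_)
    tibble::tibble(
      cell_id = i,
      diffuseness = diffuseness(gfp_img, cm, cfg),
      fragmentation = fragmentation(gfp_img, cm, cfg),
      tubularity = tubularity(gfp_img, cm, cfg),
      condensation = tryCatch(condensation(gfp_img, cm, cfg),
                              error = function(e) NA_real_),
      gfp_integral = sum(gfp_img[cm]),
      dapi_cov = stats::sd(dapi_img[nm]) / mean(dapi_img[nm]),
      power_slope = slope)
  })
}

crop_to_mask <- function(img, mask, min_side) {
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  grow <- function(r, n, lim) {
    need <- max(0, min_side - (r[2] - r[1] + 1))
    c(max(1, r[1] - ceiling(need / 2)), min(lim, r[2] + ceiling(need / 2)))
  }
  rr <- grow(rr, min_side, nrow(img)); cc <- grow(cc, min_side, ncol(img))
  img[rr[1]:rr[2], cc[1]:cc[2]]
}

#' Quality-control filter for cell records
#'
#' Three sequential filters mirroring the screening workflow: cells with too
#' little integrated GFP signal are rejected as dim, cells whose DAPI
#' coefficient of variation is too high are rejected as mitotic (chromosome
#' condensation raises the CoV), and cells whose power-spectrum slope is too
#' negative are rejected as out of focus. Each rejection records the first
#' failing reason.
#'
#' @param records Tibble from [score_cells()].
#' @param min_gfp_integral,max_dapi_cov,min_power_slope Thresholds.
#' @return `records` with columns `qc_status` (`"kept"`/`"rejected"`) and
#'   `qc_reason` (`NA`, `"dim"`, `"mitotic"` or `"out_of_focus"`).
#' @export
qc_filter <- function(records, min_gfp_integral = 0, max_dapi_cov = Inf,
                      min_power_slope = -Inf) {
  records <- tibble::as_tibble(records)
  reason <- dplyr::case_when(
    records$gfp_integral < min_gfp_integral ~ "dim",
    records$dapi_cov > max_dapi_cov ~ "mitotic",
    !is.na(records$power_slope) & records$power_slope < min_power_slope ~ "out_of_focus",
    TRUE ~ NA_character_)
  records$qc_status <- ifelse(is.na(reason), "kept", "rejected")
  records$qc_reason <- reason
  records
}

#' Select cells by a feature value
#'
#' Deterministic selection rules used for picking phenotype cells:
#' `above_control_mean` keeps cells whose feature exceeds the mean of a
#' control population, `top_n` keeps the n highest, `threshold` keeps values
#' at or above a cutoff. Ties are broken by `cell_id`.
#'
#' @param records Scored (and typically QC-kept) cell tibble.
#' @param feature Feature column name.
#' @param rule `"above_control_mean"`, `"top_n"` or `"threshold"`.
#' @param control Control-population records (required for
#'   `above_control_mean`).
#' @param n,threshold Rule parameters.
#' @return The selected rows, ordered by decreasing feature then `cell_id`.
#' @export
select_by_feature <- function(records, feature,
                              rule = c("above_control_mean", "top_n", "threshold"),
                              control = NULL, n = NULL, threshold = NULL) {
  rule <- match.arg(rule)
  records <- tibble::as_tibble(records)
  v <- records[[feature]]
  sel <- switch(rule,
    above_control_mean = {
      if (is.null(control)) rlang::abort("control records required")
      v > mean(control[[feature]])
    },
    top_n = {
      if (is.null(n)) rlang::abort("n required")
      ord <- order(-v, records$cell_id)
      seq_along(v) %in% ord[seq_len(min(n, length(v)))]
    },
    threshold = {
      if (is.null(threshold)) rlang::abort("threshold required")
      v >= threshold
    })
  out <- records[sel, ]
  out[order(-out[[feature]], out$cell_id), ]
}
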