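# Synthetic fixture generators: every image/volume the pipeline consumes,
# produced deterministically with exact ground truth. These are first-class,
# tested package code — the study conditions for all downstream validation.

#' Surface defect specifications
#'
#' Polygonal defect models for the synthetic grid surfaces, following the
#' common failure taxonomy on resin blocks: cracks, scratches and dirt.
#' Vertices are in stage coordinates (micrometres).
#'
#' @param from,to Endpoints `c(x, y)` in micrometres (crack/scratch axis).
#' @param width Band width in micrometres.
#' @param center,radius Dirt blob center and radius in micrometres.
#' @param seed Integer seed for the jagged crack outline / dirt blob shape.
#' @return A `clem_defect` list with fields `kind` and `polygon` (n x 2).
#' @name defects
NULL

#' @rdname defects
#' @export
defect_crack <- function(from, to, width = 30, seed = 1) {
  n <- 12
  tt <- seq(0, 1, length.out = n)
  d <- c(to[1] - from[1], to[2] - from[2])
  L <- sqrt(sum(d^2)); u <- d / L
  nrm <- c(-u[2], u[1])
  jig <- with_seed(seed, {
    raw <- stats::rnorm(n, 0, width * 0.5)
    as.numeric(stats::filter(raw, rep(1 / 3, 3), sides = 2, circular = TRUE))
  })
  jig[c(1, n)] <- 0
  cx <- from[1] + tt * d[1] + jig * nrm[1]
  cy <- from[2] + tt * d[2] + jig * nrm[2]
  poly <- rbind(cbind(cx + nrm[1] * width / 2, cy + nrm[2] * width / 2),
                cbind(rev(cx - nrm[1] * width / 2), rev(cy - nrm[2] * width / 2)))
  structure(list(kind = "crack", polygon = poly), class = "clem_defect")
}

#' @rdname defects
#' @export
defect_scratch <- function(from, to, width = 6) {
  d <- c(to[1] - from[1], to[2] - from[2])
  u <- d / sqrt(sum(d^2)); nrm <- c(-u[2], u[1])
  poly <- rbind(from + nrm * width / 2, to + nrm * width / 2,
                to - nrm * width / 2, from - nrm * width / 2)
  structure(list(kind = "scratch", polygon = poly), class = "clem_defect")
}

#' @rdname defects
#' @export
defect_dirt <- function(center, radius = 50, seed = 1) {
  n <- 14
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- with_seed(seed, radius * stats::runif(n, 0.6, 1.25))
  poly <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  structure(list(kind = "dirt", polygon = poly), class = "clem_defect")
}

#' Synthetic grid-substrate image with ground truth
#'
#' Renders the gridded substrate under an arbitrary frame transform in either
#' reflected-light style (dark bars and alphanumeric glyphs on a bright
#' background) or SEM style (topographic ridges along the bar edges on a
#' mid-gray background), with optional polygonal surface defects and Gaussian
#' pixel noise. The scene truth records every bar-crossing center in grid,
#' stage and pixel coordinates together with its square label and occlusion
#' status.
#'
#' The image center maps to `stage_center` (stage-coordinate metadata refers
#' to the image center); pixel centers sit at integer coordinates.
#'
#' @param layout A [grid_layout()].
#' @param frame A [frame_transform()] mapping grid to stage micrometres.
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param image_size Image size in pixels, scalar or `c(width, height)`.
#' @param style `"reflected_light"` or `"sem"`.
#' @param defects List of defect objects (see [defect_crack()]).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param stage_center Stage position of the image center, micrometres.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A `clem_scene`: list with `image` (matrix) and `truth` (list with
#'   `crossings` tibble, `defects`, and a full parameter echo).
#' @examples
#' sc <- gen_grid_image(image_size = 384, seed = 1)
#' dim(sc$image)
#' sc$truth$crossings
#' @export
gen_grid_image <- function(layout = grid_layout(), frame = frame_transform(),
                           pixel_size = 1.7, image_size = 1024,
                           style = c("reflected_light", "sem"),
                           defects = list(), noise_sd = 0,
                           stage_center = c(0, 0), seed = 1) {
  style <- match.arg(style)
  stopifnot(pixel_size > 0)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  if (min(W, H) * pixel_size < layout$bar_width) {
    rlang::abort("degenerate FOV: field of view smaller than one bar width")
  }
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  # stage coordinates of every pixel
  sx <- outer(rep(1, H), seq_len(W) - cx) * pixel_size + stage_center[1]
  sy <- outer(seq_len(H) - cy, rep(1, W)) * pixel_size + stage_center[2]
  Ainv <- solve(frame$A)
  gx <- Ainv[1, 1] * (sx - frame$t[1]) + Ainv[1, 2] * (sy - frame$t[2])
  gy <- Ainv[2, 1] * (sx - frame$t[1]) + Ainv[2, 2] * (sy - frame$t[2])

  pitch <- layout$pitch; bw <- layout$bar_width
  e <- pixel_size  # edge softening, ~1 px
  ux <- abs(((gx + pitch / 2) %% pitch) - pitch / 2)  # distance to lattice line
  uy <- abs(((gy + pitch / 2) %% pitch) - pitch / 2)
  covx <- clamp01((bw / 2 + e / 2 - ux) / e)
  covy <- clamp01((bw / 2 + e / 2 - uy) / e)
  barcov <- pmax(covx, covy)

  if (style == "reflected_light") {
    img <- 0.85 - 0.55 * barcov
  } else {
    # topographic appearance: bright ridge along each bar edge
    dx_ <- ux - bw / 2; dy_ <- uy - bw / 2
    srd <- 1.2  # ridge sigma, um
    ridge <- pmax(exp(-dx_^2 / (2 * srd^2)), exp(-dy_^2 / (2 * srd^2)))
    img <- 0.5 - 0.08 * barcov + 0.35 * ridge
  }

  # square glyphs (reflected-light style only)
  if (style == "reflected_light") {
    jr <- range(floor(gx / pitch)); ir <- range(floor(gy / pitch))
    vis_rows <- intersect(seq(ir[1] + 1, ir[2] + 2), seq_len(layout$rows))
    vis_cols <- intersect(seq(jr[1] + 1, jr[2] + 2), seq_len(layout$cols))
    for (i in vis_rows) {
      for (j in vis_cols) {
        lab <- paste0(layout$row_labels[i], layout$col_labels[j])
        g_h <- 0.40 * layout$square_size
        ras <- render_text_raster(lab, height_px = 48)
        g_w <- g_h * ncol(ras) / nrow(ras)
        cxs <- (j - 0.5) * pitch; cys <- (i - 0.5) * pitch
        sel <- which(gx >= cxs - g_w / 2 & gx < cxs + g_w / 2 &
                       gy >= cys - g_h / 2 & gy < cys + g_h / 2)
        if (!length(sel)) next
        ri <- pmin(pmax(floor((gy[sel] - (cys - g_h / 2)) / g_h * nrow(ras)) + 1L, 1L), nrow(ras))
        ci <- pmin(pmax(floor((gx[sel] - (cxs - g_w / 2)) / g_w * ncol(ras)) + 1L, 1L), ncol(ras))
        img[sel] <- img[sel] - 0.5 * ras[cbind(ri, ci)]
      }
    }
  }

  # defects (rendered over everything, seeded textures)
  if (length(defects)) {
    for (k in seq_along(defects)) {
      df <- defects[[k]]
      poly <- df$polygon
      inside <- which(points_in_polygon(as.vector(sx), as.vector(sy),
                                        poly[, 1], poly[, 2]))
      if (!length(inside)) next
      tex <- with_seed(seed + 1000L + k,
                       stats::rnorm(length(inside), 0, 0.08))
      img[inside] <- switch(df$kind,
        crack = 0.18 + tex,
        scratch = 0.30 + tex * 0.5,
        dirt = 0.55 + tex,
        0.3 + tex)
    }
  }

  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(H * W, 0, noise_sd), H, W))
  }
  img <- clamp01(img)

  # ground truth: all lattice nodes within two pitches of the FOV
  grng_x <- range(gx); grng_y <- range(gy)
  jj <- seq(floor(grng_x[1] / pitch) - 1, ceiling(grng_x[2] / pitch) + 1)
  ii <- seq(floor(grng_y[1] / pitch) - 1, ceiling(grng_y[2] / pitch) + 1)
  nodes <- expand.grid(j = jj, i = ii)
  gxy <- cbind(nodes$j * pitch, nodes$i * pitch)
  sxy <- apply_frame(frame, gxy)
  px <- (sxy[, 1] - stage_center[1]) / pixel_size + cx
  py <- (sxy[, 2] - stage_center[2]) / pixel_size + cy
  row_i <- nodes$i + 1L; col_j <- nodes$j + 1L
  has_label <- row_i >= 1 & row_i <= layout$rows & col_j >= 1 & col_j <= layout$cols
  labels <- rep(NA_character_, nrow(nodes))
  labels[has_label] <- paste0(layout$row_labels[row_i[has_label]],
                              layout$col_labels[col_j[has_label]])
  # occlusion truth: a crossing is occluded when defects cover >= 15% of its
  # core disc (radius 1.5 bar widths), estimated on a sample grid
  occluded <- rep(FALSE, nrow(nodes))
  if (length(defects)) {
    rr <- 1.5 * layout$bar_width
    gg <- seq(-rr, rr, length.out = 15)
    dx_s <- rep(gg, times = 15); dy_s <- rep(gg, each = 15)
    in_disc <- dx_s^2 + dy_s^2 <= rr^2
    dx_s <- dx_s[in_disc]; dy_s <- dy_s[in_disc]
    for (q in seq_len(nrow(nodes))) {
      covered <- rep(FALSE, length(dx_s))
      for (df in defects) {
        covered <- covered | points_in_polygon(sxy[q, 1] + dx_s, sxy[q, 2] + dy_s,
                                               df$polygon[, 1], df$polygon[, 2])
      }
      occluded[q] <- mean(covered) >= 0.15
    }
  }
  crossings <- tibble::tibble(
    label = labels, row = row_i, col = col_j,
    grid_x_um = gxy[, 1], grid_y_um = gxy[, 2],
    stage_x_um = sxy[, 1], stage_y_um = sxy[, 2],
    px_x = px, px_y = py,
    inside_fov = px >= 1 & px <= W & py >= 1 & py <= H,
    occluded = occluded)
  crossings <- crossings[crossings$px_x > -W & crossings$px_x < 2 * W &
                           crossings$px_y > -H & crossings$px_y < 2 * H, ]
  structure(list(
    image = img,
    truth = list(crossings = crossings, defects = defects,
                 params = list(layout = layout, frame = frame,
                               pixel_size = pixel_size,
                               image_size = c(W, H), style = style,
                               noise_sd = noise_sd,
                               stage_center = stage_center, seed = seed))),
    class = "clem_scene")
}

#' Synthetic alphanumeric glyph image
#'
#' Renders a square-identifier glyph (digit+letter, e.g. `"8Q"`) as a binary
#' 128 x 128 image, with optional augmentation by rotation, scaling,
#' translation and intensity variation. Ranged augmentation parameters
#' (length-2 vectors) are sampled from the given seed.
#'
#' @param label Two-character square label.
#' @param size Output image side in pixels.
#' @param augment List with optional entries `rotation_deg`, `scale`,
#'   `translate_px` (each a scalar for a fixed value or a length-2 range),
#'   `intensity` (foreground level) and `noise_sd`.
#' @param seed Integer seed.
#' @return List with `image` (matrix in \[0,1\]) and `label`.
#' @export
gen_glyph_image <- function(label, size = 128, augment = list(), seed = 1) {
  chars <- strsplit(label, "")[[1]]
  if (length(chars) != 2 || !all(chars %in% names(.font5x7))) {
    rlang::abort(sprintf("unknown label '%s'", label))
  }
  draw <- function(par, default) {
    v <- augment[[par]] %||% default
    if (length(v) == 2) stats::runif(1, v[1], v[2]) else v
  }
  with_seed(seed, {
    rot <- draw("rotation_deg", 0)
    scl <- draw("scale", 1)
    trx <- draw("translate_px", 0)
    try_ <- draw("translate_px", 0)
    inten <- draw("intensity", 1)
    nsd <- augment$noise_sd %||% 0
    ras <- render_text_raster(label, height_px = round(0.45 * size))
    canvas <- matrix(0, size, size)
    oy <- round((size - nrow(ras)) / 2); ox <- round((size - ncol(ras)) / 2)
    canvas[oy + seq_len(nrow(ras)), ox + seq_len(ncol(ras))] <- ras
    # inverse-map output pixels through translate -> rotate -> scale
    c0 <- (size + 1) / 2
    xs <- rep(seq_len(size), each = size) - c0 - trx
    ys <- rep(seq_len(size), times = size) - c0 - try_
    th <- -rot * pi / 180
    xr <- (cos(th) * xs - sin(th) * ys) / scl + c0
    yr <- (sin(th) * xs + cos(th) * ys) / scl + c0
    xi <- round(xr); yi <- round(yr)
    ok <- xi >= 1 & xi <= size & yi >= 1 & yi <= size
    out <- numeric(size * size)
    out[ok] <- canvas[cbind(yi[ok], xi[ok])]
    img <- matrix(out, size, size) * inten
    if (nsd > 0) img <- clamp01(img + matrix(stats::rnorm(size^2, 0, nsd), size, size))
    list(image = img, label = label)
  })
}

#' Synthetic milled-trench image
#'
#' A dark trapezoid (the FIB-milled trench seen top-down) over a textured
#' block surface, optionally with additional off-center trapezoids emulating
#' previous acquisitions. Truth marks which trapezoid is nearest the image
#' center.
#'
#' @param corners 4 x 2 matrix of pixel corner coordinates in order top-left,
#'   top-right, bottom-right, bottom-left, or `NULL` for a texture-only image
#'   (flagged "no trench").
#' @param image_size Image size in pixels, scalar or `c(width, height)`.
#' @param background_texture List with `mean`, `sd`, `smooth_sigma`.
#' @param n_extra Number of additional off-center trapezoids.
#' @param seed Integer seed.
#' @return List with `image` and `truth` (tibble of trapezoids with corner
#'   list-column, centers, and `nearest_center` flag; zero rows when no
#'   trench was requested).
#' @export
gen_trench_image <- function(corners, image_size = 256,
                             background_texture = list(mean = 0.6, sd = 0.1,
                                                       smooth_sigma = 2),
                             n_extra = 0, seed = 1) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  img <- with_seed(seed, {
    base <- matrix(stats::rnorm(H * W, 0, 1), H, W)
    base <- img_gblur(base, background_texture$smooth_sigma %||% 2)
    background_texture$mean + background_texture$sd * base / max(stats::sd(base), 1e-9)
  })
  polys <- list()
  if (!is.null(corners)) {
    corners <- as.matrix(corners)
    stopifnot(nrow(corners) == 4, ncol(corners) == 2)
    v <- rbind(corners, corners[1, ])
    cr <- sapply(1:4, function(i) {
      a <- v[i + 1, ] - v[i, ]; b <- v[(i %% 4) + 2, ] - v[i + 1, ]
      a[1] * b[2] - a[2] * b[1]
    })
    if (!(all(cr > 0) || all(cr < 0))) rlang::abort("non-convex corner set")
    top_w <- abs(corners[2, 1] - corners[1, 1])
    bot_w <- abs(corners[3, 1] - corners[4, 1])
    if (top_w < bot_w) rlang::abort("top edge must be at least as long as bottom edge")
    polys[[1]] <- corners
    if (n_extra > 0) {
      ctr <- colMeans(corners)
      shp <- sweep(corners, 2, ctr) * 0.5
      placed <- 0L
      with_seed(seed + 7L, {
        tries <- 0L
        while (placed < n_extra && tries < 400L) {
          tries <- tries + 1L
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0.3, 0.46) * min(W, H)
          cand <- sweep(shp, 2, c(W / 2 + rad * cos(ang), H / 2 + rad * sin(ang)), "+")
          if (min(cand[, 1]) < 4 || max(cand[, 1]) > W - 4 ||
              min(cand[, 2]) < 4 || max(cand[, 2]) > H - 4) next
          clash <- any(vapply(polys, function(p) {
            !(max(cand[, 1]) + 6 < min(p[, 1]) || min(cand[, 1]) - 6 > max(p[, 1]) ||
                max(cand[, 2]) + 6 < min(p[, 2]) || min(cand[, 2]) - 6 > max(p[, 2]))
          }, logical(1)))
          if (clash) next
          polys[[length(polys) + 1]] <- cand
          placed <- placed + 1L
        }
      })
    }
  }
  px <- rep(seq_len(W), each = H); py <- rep(seq_len(H), times = W)
  for (k in seq_along(polys)) {
    p <- polys[[k]]
    inside <- points_in_polygon(px, py, p[, 1], p[, 2])
    dark <- with_seed(seed + 20L + k, stats::rnorm(sum(inside), 0.08, 0.02))
    img[cbind(py[inside], px[inside])] <- dark
  }
  img <- clamp01(img)
  if (length(polys)) {
    centers <- t(vapply(polys, polygon_centroid, numeric(2)))
    d <- sqrt((centers[, 1] - (W + 1) / 2)^2 + (centers[, 2] - (H + 1) / 2)^2)
    truth <- tibble::tibble(
      id = seq_along(polys),
      corners = lapply(polys, function(p) p),
      center_x = centers[, 1], center_y = centers[, 2],
      nearest_center = seq_along(polys) == which.min(d))
  } else {
    truth <- tibble::tibble(id = integer(), corners = list(),
                            center_x = numeric(), center_y = numeric(),
                            nearest_center = logical())
    attr(truth, "no_trench") <- TRUE
  }
  list(image = img, truth = truth)
}

#' Synthetic drifting / defocusing slice stack
#'
#' Emulates a slice-and-view acquisition: slice `i` is slice 0 translated by
#' `i * drift_per_slice` and blurred per `blur_schedule`, with a bright
#' coating band (the gold-coated block top) and either a textured or a
#' textureless cross-section interior (the latter exercises the coating-only
#' drift fallback). Positive `dy` moves content down.
#'
#' @param n_slices Number of slices (>= 2).
#' @param drift_per_slice `c(dx, dy)` pixel drift per slice.
#' @param blur_schedule Gaussian sigma per slice (length 1 or `n_slices`).
#' @param coating_row Row of the coating band center in slice 0.
#' @param image_size Scalar or `c(width, height)` pixels.
#' @param style `"textured"` or `"textureless"`.
#' @param noise_sd Per-slice independent Gaussian noise sd.
#' @param seed Integer seed.
#' @return List with `stack` (H x W x n array) and `truth` tibble
#'   (`slice`, `dx_cum`, `dy_cum`, `blur_sigma`, `coating_row`).
#' @export
gen_drift_stack <- function(n_slices, drift_per_slice = c(0, 0.5),
                            blur_schedule = 0, coating_row = 40,
                            image_size = 256,
                            style = c("textured", "textureless"),
                            noise_sd = 0.01, seed = 1) {
  style <- match.arg(style)
  stopifnot(n_slices >= 2)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  blur_schedule <- rep(blur_schedule, length.out = n_slices)
  base <- with_seed(seed, {
    img <- matrix(0.35, H, W)
    rows <- seq_len(H)
    img[rows < coating_row - 3, ] <- 0.06  # vacuum above the block
    band <- abs(rows - coating_row) <= 3
    img[band, ] <- 0.95
    if (style == "textured") {
      tex <- img_gblur(matrix(stats::rnorm(H * W), H, W), 1.5)
      tex <- 0.12 * tex / max(stats::sd(tex), 1e-9)
      below <- rows > coating_row + 3
      img[below, ] <- 0.4 + tex[below, ]
      # a few organelle-like blobs for feature matching
      nb <- 25
      bx <- stats::runif(nb, 10, W - 10)
      by <- stats::runif(nb, coating_row + 15, H - 10)
      br <- stats::runif(nb, 3, 9)
      xs <- matrix(rep(seq_len(W), each = H), H, W)
      ys <- matrix(rep(seq_len(H), times = W), H, W)
      for (k in seq_len(nb)) {
        img <- img + 0.35 * exp(-((xs - bx[k])^2 + (ys - by[k])^2) / (2 * br[k]^2)) *
          (ys > coating_row + 4)
      }
    }
    clamp01(img)
  })
  stack <- array(0, dim = c(H, W, n_slices))
  for (i in seq_len(n_slices)) {
    sl <- img_translate(base, (i - 1) * drift_per_slice[1],
                        (i - 1) * drift_per_slice[2])
    if (blur_schedule[i] > 0) sl <- img_gblur(sl, blur_schedule[i])
    if (noise_sd > 0) {
      sl <- sl + with_seed(seed + i, matrix(stats::rnorm(H * W, 0, noise_sd), H, W))
    }
    stack[, , i] <- clamp01(sl)
  }
  truth <- tibble::tibble(
    slice = seq_len(n_slices) - 1L,
    dx_cum = (seq_len(n_slices) - 1L) * drift_per_slice[1],
    dy_cum = (seq_len(n_slices) - 1L) * drift_per_slice[2],
    blur_sigma = blur_schedule,
    coating_row = coating_row + (seq_len(n_slices) - 1L) * drift_per_slice[2])
  list(stack = stack, truth = truth)
}

#' Synthetic phenotype-controllable cell images
#'
#' Generates a GFP (Golgi marker) / DAPI (nucleus) image pair plus truth
#' masks for one cell rendered as one of five Golgi-morphology archetypes.
#' `strength` monotonically increases the archetype's geometric parameter:
#' cytoplasmic spread for `diffuse`, fragment count for `fragmented`,
#' elongation for `tubular` and compactness for `condensed`.
#'
#' @param phenotype One of `"control"`, `"diffuse"`, `"fragmented"`,
#'   `"tubular"`, `"condensed"`.
#' @param strength Archetype strength in \[0, 1\].
#' @param image_size Image side in pixels.
#' @param gfp_scale Multiplies the GFP signal (QC fixtures).
#' @param dapi_cov_boost Adds chromatin-condensation texture to DAPI
#'   (mitotic-cell fixtures).
#' @param defocus_sigma Gaussian blur applied to both channels (out-of-focus
#'   fixtures).
#' @param seed Integer seed.
#' @return List with `gfp`, `dapi`, `cytoplasm_mask`, `nucleus_mask`
#'   (logical matrices) and `truth` (phenotype, strength, archetype
#'   parameter).
#' @export
gen_phenotype_cell <- function(phenotype = c("control", "diffuse", "fragmented",
                                             "tubular", "condensed"),
                               strength = 0.7, image_size = 192,
                               gfp_scale = 1, dapi_cov_boost = 0,
                               defocus_sigma = 0, seed = 1) {
  phenotype <- match.arg(phenotype)
  stopifnot(strength >= 0, strength <= 1)
  n <- as.integer(image_size)
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  nucleus <- ((xs - c0)^2 / 24^2 + (ys - c0)^2 / 19^2) <= 1
  cyto <- ((xs - c0)^2 / (0.42 * n)^2 + (ys - c0)^2 / (0.36 * n)^2) <= 1
  gauss <- function(cx, cy, s) exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))

  res <- with_seed(seed, {
    ribbon <- function() {
      # compact juxtanuclear Golgi ribbon: short chain of blobs
      a0 <- stats::runif(1, 0, 2 * pi)
      r0 <- 27
      cxs <- c0 + r0 * cos(a0 + c(-0.55, 0, 0.55))
      cys <- c0 + r0 * sin(a0 + c(-0.55, 0, 0.55))
      0.85 * (gauss(cxs[1], cys[1], 7) + gauss(cxs[2], cys[2], 8) +
                gauss(cxs[3], cys[3], 7))
    }
    param <- NA_real_
    gfp <- switch(phenotype,
      control = { param <- 0; ribbon() },
      diffuse = {
        param <- strength
        (1 - strength) * ribbon() + strength * 0.5 * cyto
      },
      fragmented = {
        k <- 2L + as.integer(round(strength * 8))
        param <- k
        sig <- matrix(0, n, n)
        placed <- matrix(numeric(0), ncol = 2)
        tries <- 0L
        min_sep <- 20
        while (nrow(placed) < k) {
          tries <- tries + 1L
          if (tries %% 500L == 0L) min_sep <- min_sep * 0.8  # relax if crowded
          a <- stats::runif(1, 0, 2 * pi); r <- stats::runif(1, 20, 0.38 * n)
          p <- c(c0 + r * cos(a), c0 + r * sin(a))
          if (!cyto[round(p[2]), round(p[1])] || nucleus[round(p[2]), round(p[1])]) next
          if (nrow(placed) && min(sqrt(rowSums(sweep(placed, 2, p)^2))) < min_sep) next
          placed <- rbind(placed, p)
          sig <- sig + 0.9 * gauss(p[1], p[2], 3.5)
        }
        sig
      },
      tubular = {
        L <- 40 + strength * 0.45 * n
        wdt <- 3
        param <- L / (2 * wdt)
        a <- stats::runif(1, 0, pi)
        u <- c(cos(a), sin(a))
        t_ <- (xs - c0) * u[1] + (ys - c0) * u[2]
        d_ <- -(xs - c0) * u[2] + (ys - c0) * u[1]
        0.9 * exp(-d_^2 / (2 * wdt^2)) * (abs(t_) <= L / 2)
      },
      condensed = {
        rad <- 14 - 6 * strength
        param <- 1 / rad
        a0 <- stats::runif(1, 0, 2 * pi)
        px <- c0 + 30 * cos(a0); py <- c0 + 30 * sin(a0)
        d2 <- (xs - px)^2 + (ys - py)^2
        0.95 * clamp01((rad + 1 - sqrt(d2)))
      })
    gfp <- gfp * ifelse(cyto, 1, 0)
    gfp <- clamp01(gfp + 0.02) * gfp_scale
    gfp <- clamp01(gfp + matrix(stats::rnorm(n^2, 0, 0.012), n, n))
    dapi <- 0.55 * nucleus
    chrom <- img_gblur(matrix(stats::rnorm(n^2), n, n), 1.2)
    dapi <- dapi + (0.05 + dapi_cov_boost) * (chrom / max(stats::sd(chrom), 1e-9)) * nucleus
    dapi <- clamp01(dapi + matrix(stats::rnorm(n^2, 0, 0.01), n, n))
    list(gfp = gfp, dapi = dapi, param = param)
  })
  gfp <- res$gfp; dapi <- res$dapi
  if (defocus_sigma > 0) {
    gfp <- img_gblur(gfp, defocus_sigma)
    dapi <- img_gblur(dapi, defocus_sigma)
  }
  list(gfp = gfp, dapi = dapi,
       cytoplasm_mask = cyto, nucleus_mask = nucleus,
       truth = list(phenotype = phenotype, strength = strength,
                    param = res$param, seed = seed))
}

#' Synthetic labelled Golgi volume
#'
#' A labelled voxel volume containing a Golgi-stack region (sphere by
#' default) with `n_cisternae` parallel plate cisternae spanning it, for
#' validating the stereology estimators. Voxel labels: 0 background, 1 stack,
#' `1 + k` cisterna `k`. The truth volume is the analytic volume of the stack
#' region; with `n_cisternae = 0` the stack label is absent and the truth
#' volume is 0.
#'
#' @param n_cisternae Number of cisternae (>= 0).
#' @param radius_um Stack sphere radius, micrometres.
#' @param voxel_size_um Isotropic voxel size, micrometres.
#' @param margin_um Empty margin around the stack, micrometres.
#' @param seed Integer seed (reserved; the construction is deterministic).
#' @return List with `volume` (integer array `[y, x, z]`) and `truth`
#'   (`volume_um3`, `n_cisternae`, `voxel_size_um`, `radius_um`).
#' @export
gen_golgi_volume <- function(n_cisternae = 4, radius_um = 1.5,
                             voxel_size_um = 0.05, margin_um = 0.3, seed = 1) {
  stopifnot(n_cisternae >= 0)
  half <- radius_um + margin_um
  n <- as.integer(ceiling(2 * half / voxel_size_um))
  coord <- (seq_len(n) - (n + 1) / 2) * voxel_size_um
  vol <- array(0L, dim = c(n, n, n))
  if (n_cisternae > 0) {
    d2y <- coord^2
    inside2 <- radius_um^2
    plate_y <- seq(-0.6 * radius_um, 0.6 * radius_um, length.out = n_cisternae)
    half_th <- voxel_size_um  # plate half-thickness
    for (z in seq_len(n)) {
      r2 <- outer(d2y, d2y, "+") + coord[z]^2  # [y, x] + z
      sl <- matrix(0L, n, n)
      sl[r2 <= inside2] <- 1L
      for (k in seq_len(n_cisternae)) {
        rows <- which(abs(coord - plate_y[k]) <= half_th)
        if (length(rows)) {
          sub <- sl[rows, , drop = FALSE]
          sub[sub == 1L] <- 1L + k
          sl[rows, ] <- sub
        }
      }
      vol[, , z] <- sl
    }
  }
  truth_vol <- if (n_cisternae > 0) 4 / 3 * pi * radius_um^3 else 0
  list(volume = vol,
       truth = list(volume_um3 = truth_vol, n_cisternae = as.integer(n_cisternae),
                    voxel_size_um = voxel_size_um, radius_um = radius_um))
}

#' Two-beam coincidence-point measurement simulator
#'
#' Geometric simulator of the coincidence-point routine: the SEM axis looks
#' straight down at the nominal coincidence point, the FIB axis passes through
#' the same point at `beam_angle_deg` from the SEM axis. With the sample
#' surface displaced by `dz_um` from the coincidence height, the FIB sputters
#' its fiducial mark where its axis meets the actual surface; the simulator
#' projects that mark into both views (orthographic projection along each
#' beam axis) and reports the y-offset between the mark centers measured in
#' the two images.
#'
#' @param dz_um True surface height offset from the coincidence point,
#'   micrometres (positive = surface above).
#' @param geometry A [beam_geometry()].
#' @return List with `dy_um` (measured SEM-vs-FIB mark offset),
#'   `mark_surface_um` (mark position on the surface) and `dz_um` echo.
#' @export
simulate_coincidence <- function(dz_um, geometry = beam_geometry()) {
  alpha <- geometry$beam_angle_deg * pi / 180
  # FIB axis through the origin, tilted in the y-z plane
  d_fib <- c(0, sin(alpha), cos(alpha))
  # intersection with the plane z = dz: t * cos(alpha) = dz
  t_ <- dz_um / d_fib[3]
  mark <- t_ * d_fib                      # mark sputtered here
  y_sem <- mark[2]                        # SEM: orthographic along z
  # FIB view: coordinates in the plane orthogonal to the FIB axis; the mark
  # lies on the axis, so it is centered
  y_fib <- sum(mark * c(0, cos(alpha), -sin(alpha)))
  list(dy_um = y_sem - y_fib, mark_surface_um = mark, dz_um = dz_um)
}
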