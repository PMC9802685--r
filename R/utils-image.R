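# Internal image utilities.
#
# Convention used throughout the package: a grayscale image is a plain numeric
# matrix with intensities in [0, 1], indexed img[y, x] (row = y, pointing down;
# column = x, pointing right), matching what tiff::readTIFF() returns. Pixel
# centers sit at integer coordinates (1-based).

#' @importFrom rlang abort warn %||%
NULL

assert_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix (grayscale image)", arg))
  }
  invisible(img)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `expr` under a local RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# EBImage stores images as [x, y]; our matrices are [y, x].
as_eb <- function(img) EBImage::Image(t(img))
from_eb <- function(eb) t(EBImage::imageData(eb))

img_gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  from_eb(EBImage::gblur(as_eb(img), sigma = sigma))
}

# Grayscale morphology on the full image with a flat structuring element.
img_opening <- function(img, brush) from_eb(EBImage::opening(as_eb(img), brush))
img_tophat <- function(img, brush) from_eb(EBImage::whiteTopHat(as_eb(img), brush))

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

# Line structuring element of given length (px) and angle (degrees) in image
# coordinates (angle measured from +x towards +y), rasterized directly into
# the [y, x] frame.
line_brush <- function(length, angle_deg) {
  L <- as.integer(length)
  if (L <= 1) return(matrix(1, 1, 1))
  th <- angle_deg * pi / 180
  t <- seq(-(L - 1) / 2, (L - 1) / 2, by = 0.5)
  xs <- round(t * cos(th)); ys <- round(t * sin(th))
  rx <- max(abs(xs)); ry <- max(abs(ys))
  k <- matrix(0, 2 * ry + 1, 2 * rx + 1)
  k[cbind(ys + ry + 1, xs + rx + 1)] <- 1
  k
}

# Separable translation by integer or fractional pixels, bilinear, edge
# replicated. Positive dx moves content right, positive dy moves it down.
img_translate <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  xs <- seq_len(w) - dx
  ys <- seq_len(h) - dy
  bilinear_sample(img, xs = rep(xs, each = h), ys = rep(ys, times = w),
                  out_dim = c(h, w))
}

# Sample image at continuous coordinates (1-based), bilinear, clamped at edges.
bilinear_sample <- function(img, xs, ys, out_dim = NULL) {
  h <- nrow(img); w <- ncol(img)
  xs <- pmin(pmax(xs, 1), w)
  ys <- pmin(pmax(ys, 1), h)
  x0 <- pmin(floor(xs), w - 1L); y0 <- pmin(floor(ys), h - 1L)
  fx <- xs - x0; fy <- ys - y0
  v <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
  if (!is.null(out_dim)) dim(v) <- out_dim
  v
}

# Sobel gradients; returns list(gx, gy, mag).
sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  gx <- conv2_same(img, kx)
  gy <- conv2_same(img, t(kx))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# 2-D convolution, output same size, edges replicated. Small kernels only.
conv2_same <- function(img, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  pad <- pad_replicate(img, ph, pw)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] *
        pad[(i - 1) + seq_len(nrow(img)), (j - 1) + seq_len(ncol(img))]
    }
  }
  out
}

pad_replicate <- function(img, ph, pw) {
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep(1L, ph), seq_len(h), rep(h, ph))
  ci <- c(rep(1L, pw), seq_len(w), rep(w, pw))
  img[ri, ci, drop = FALSE]
}

# FFT convolution with an arbitrary (possibly large) kernel, 'same' output,
# zero-padded borders. Used for oriented line-kernel responses.
conv2_fft <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(k); kw <- ncol(k)
  H <- h + kh - 1L; W <- w + kw - 1L
  A <- matrix(0, H, W); A[seq_len(h), seq_len(w)] <- img
  B <- matrix(0, H, W); B[seq_len(kh), seq_len(kw)] <- k
  C <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (H * W)
  r0 <- (kh - 1L) %/% 2; c0 <- (kw - 1L) %/% 2
  C[r0 + seq_len(h), c0 + seq_len(w)]
}

# Otsu threshold on values in [0, 1] (returns threshold).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(rng[1])
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Two-threshold (three-class) Otsu: maximizes between-class variance over all
# threshold pairs on a binned histogram. Returns sorted c(t1, t2).
multiotsu_thresholds <- function(x, n_bins = 64L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(c(rng[1], rng[1]))
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins),
                n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  P <- c(0, cumsum(p))
  S <- c(0, cumsum(p * mids))
  best <- -Inf; bi <- c(1L, 2L)
  for (i in seq_len(n_bins - 2L)) {
    w0 <- P[i + 1]; s0 <- S[i + 1]
    if (w0 <= 0) next
    j <- seq.int(i + 1L, n_bins - 1L)
    w1 <- P[j + 1] - w0
    w2 <- 1 - w0 - w1
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    s1 <- S[j + 1] - s0
    s2 <- S[n_bins + 1] - s0 - s1
    v <- s0^2 / w0 + ifelse(ok, s1^2 / w1 + s2^2 / w2, -Inf)
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; bi <- c(i, j[k]) }
  }
  sort(mids[bi])
}

# 8-connectivity labeling: EBImage::bwlabel (4-connectivity) plus union-find
# merge of diagonally adjacent labels.
label_components <- function(mask) {
  lab <- from_eb(EBImage::bwlabel(as_eb(mask * 1)))
  n <- max(lab)
  if (n < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

# Shannon entropy (bits) of an intensity sample, fixed-width histogram.
intensity_entropy <- function(x, n_bins = 32L, rng = c(0, 1)) {
  if (!length(x)) return(0)
  b <- tabulate(pmin(pmax(floor((x - rng[1]) / max(diff(rng), 1e-12) * n_bins) + 1L,
                          1L), n_bins), n_bins)
  p <- b / sum(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Windowed, normalized cross-correlation between two equal-size images.
# Returns the translation (dx, dy) that maps `a` onto `b` (content of b =
# content of a shifted by +dx, +dy), with sub-pixel parabolic interpolation,
# and the normalized peak height (~1 for a perfect match, ~0 for unrelated
# content).
phase_correlation <- function(a, b, window = TRUE) {
  stopifnot(all(dim(a) == dim(b)))
  h <- nrow(a); w <- ncol(a)
  if (window) {
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
    win <- outer(wy, wx)
    a <- (a - mean(a)) * win
    b <- (b - mean(b)) * win
  } else {
    a <- a - mean(a); b <- b - mean(b)
  }
  FA <- stats::fft(a); FB <- stats::fft(b)
  r <- Re(stats::fft(FB * Conj(FA), inverse = TRUE)) / (h * w)
  r <- r / max(sqrt(sum(a^2)) * sqrt(sum(b^2)), 1e-12)
  pk <- arrayInd(which.max(r), dim(r))
  peak <- r[pk[1], pk[2]]
  sub <- function(m, i, n) {
    im <- ((i - 2) %% n) + 1L; ip <- (i %% n) + 1L
    y0 <- m[im]; y1 <- m[i]; y2 <- m[ip]
    if (y0 > 0 && y1 > 0 && y2 > 0) {
      # log-parabola: exact for Gaussian-shaped correlation peaks
      y0 <- log(y0); y1 <- log(y1); y2 <- log(y2)
    }
    d <- (y0 - 2 * y1 + y2)
    if (abs(d) < 1e-12) 0 else 0.5 * (y0 - y2) / d
  }
  dyf <- sub(r[, pk[2]], pk[1], h)
  dxf <- sub(r[pk[1], ], pk[2], w)
  dy <- pk[1] - 1 + dyf; dx <- pk[2] - 1 + dxf
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  list(dx = dx, dy = dy, peak = peak)
}

# Harris corner response.
harris_response <- function(img, sigma = 2, kappa = 0.04) {
  g <- sobel_gradients(img)
  sxx <- img_gblur(g$gx^2, sigma)
  syy <- img_gblur(g$gy^2, sigma)
  sxy <- img_gblur(g$gx * g$gy, sigma)
  det <- sxx * syy - sxy^2
  tr <- sxx + syy
  det - kappa * tr^2
}

# Local maxima of a matrix above a threshold, min separation in px.
local_maxima <- function(m, threshold, min_sep = 5L) {
  h <- nrow(m); w <- ncol(m)
  cand <- which(m > threshold)
  if (!length(cand)) return(tibble::tibble(x = numeric(), y = numeric(), value = numeric()))
  cand <- cand[order(m[cand], decreasing = TRUE)]
  ys <- (cand - 1L) %% h + 1L
  xs <- (cand - 1L) %/% h + 1L
  vals <- m[cand]
  keep_x <- numeric(); keep_y <- numeric(); keep_v <- numeric()
  for (i in seq_along(cand)) {
    if (!length(keep_x) ||
        all((keep_x - xs[i])^2 + (keep_y - ys[i])^2 >= min_sep^2)) {
      keep_x <- c(keep_x, xs[i]); keep_y <- c(keep_y, ys[i]); keep_v <- c(keep_v, vals[i])
    }
  }
  tibble::tibble(x = keep_x, y = keep_y, value = keep_v)
}

# Nearest-neighbour resize to given dims (used for glyph feature extraction).
resize_nn <- function(img, h, w) {
  ys <- pmin(pmax(round(seq(1, nrow(img), length.out = h)), 1), nrow(img))
  xs <- pmin(pmax(round(seq(1, ncol(img), length.out = w)), 1), ncol(img))
  img[ys, xs, drop = FALSE]
}

# Point-in-polygon (even-odd rule), vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i] + 1e-300) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Area centroid of a simple polygon (n x 2 matrix).
polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Min distance from a point to a closed polygon outline.
point_polygon_distance <- function(x, y, vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  ax <- vx[j]; ay <- vy[j]; bx <- vx; by <- vy
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  t <- pmin(pmax(((x - ax) * dx + (y - ay) * dy) / pmax(L2, 1e-300), 0), 1)
  min(sqrt((ax + t * dx - x)^2 + (ay + t * dy - y)^2))
}
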