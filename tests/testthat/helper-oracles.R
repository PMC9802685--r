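# Independent brute-force oracles used to validate the implementation paths.

# Grayscale erosion/dilation by explicit offset minimum/maximum (independent
# of the EBImage implementation). SE given as logical matrix with odd dims.
oracle_erode <- function(img, se) {
  ry <- (nrow(se) - 1) / 2; rx <- (ncol(se) - 1) / 2
  out <- matrix(Inf, nrow(img), ncol(img))
  pad <- matrix(Inf, nrow(img) + 2 * ry, ncol(img) + 2 * rx)
  pad[ry + seq_len(nrow(img)), rx + seq_len(ncol(img))] <- img
  for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
    if (!se[i, j]) next
    out <- pmin(out, pad[(i - 1) + seq_len(nrow(img)), (j - 1) + seq_len(ncol(img))])
  }
  out
}

oracle_dilate <- function(img, se) {
  ry <- (nrow(se) - 1) / 2; rx <- (ncol(se) - 1) / 2
  out <- matrix(-Inf, nrow(img), ncol(img))
  pad <- matrix(-Inf, nrow(img) + 2 * ry, ncol(img) + 2 * rx)
  pad[ry + seq_len(nrow(img)), rx + seq_len(ncol(img))] <- img
  se_flip <- se[rev(seq_len(nrow(se))), rev(seq_len(ncol(se))), drop = FALSE]
  for (i in seq_len(nrow(se))) for (j in seq_len(ncol(se))) {
    if (!se_flip[i, j]) next
    out <- pmax(out, pad[(i - 1) + seq_len(nrow(img)), (j - 1) + seq_len(ncol(img))])
  }
  out
}

oracle_opening <- function(img, se) oracle_dilate(oracle_erode(img, se), se)

disc_se <- function(r) {
  d <- 2 * r + 1
  outer(seq_len(d) - r - 1, seq_len(d) - r - 1,
        function(y, x) x^2 + y^2 <= r^2)
}

# Least-squares affine fit by explicit normal equations (independent of the
# lm.fit-based implementation path).
oracle_affine <- function(X, Y) {
  Z <- cbind(1, X)
  B <- solve(t(Z) %*% Z, t(Z) %*% Y)
  list(predict = function(P) cbind(1, P) %*% B)
}

# Analytic count of intersections between the cycloid arch tiling of a
# cycloid_grid and a horizontal segment y = h, x in [x0, x1]. Uses the
# monotonicity of the arch height y(theta) = r (1 - cos theta).
oracle_cycloid_hline <- function(grid, width, height, h, x0, x1) {
  r <- grid$r_px
  count <- 0L
  y0s <- seq(grid$phase[2] - grid$spacing_y_px, height + grid$spacing_y_px,
             by = grid$spacing_y_px)
  x0s <- seq(grid$phase[1] - 2 * grid$spacing_x_px, width + grid$spacing_x_px,
             by = grid$spacing_x_px)
  for (yb in y0s) {
    flip <- FALSE
    for (xb in x0s) {
      # arch height at parameter theta: yb + (1-cos) r, or mirrored
      hh <- if (flip) yb + 2 * r - h else h - yb
      flip <- !flip
      if (hh <= 0 || hh >= 2 * r) next
      th <- acos(1 - hh / r)
      xc <- xb + r * (th - sin(th))
      if (xc > x0 && xc < x1) count <- count + 1L
    }
  }
  count
}
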