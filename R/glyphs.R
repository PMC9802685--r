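# Alphanumeric square-identifier classification.
#
# Each square label is a digit+letter pair rendered into the glass. The
# classifier segments the cleaned glyph patch into its two characters,
# normalizes each to a 12x12 crop, and scores them with per-character random
# forests trained on the synthetic glyph generator.

glyph_cell <- 12L

# Binarize, despeckle and split a glyph patch into two normalized character
# crops. Returns list(digit = vec, letter = vec) or NULL for a blank patch.
glyph_features <- function(img) {
  assert_image(img)
  thr <- otsu_threshold(img)
  mask <- img > thr
  if (sum(mask) < 20 || mean(mask) > 0.6) return(NULL)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= max(10, 0.02 * sum(sizes)))
  if (!length(keep)) return(NULL)
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  colsum <- colSums(mask)
  occ <- which(colsum > 0)
  if (length(occ) < 4) return(NULL)
  # split at the widest interior gap of the column occupancy profile
  inner <- occ[1]:occ[length(occ)]
  gaps <- rle(colsum[inner] == 0)
  split_col <- NULL
  if (any(gaps$values)) {
    ends <- cumsum(gaps$lengths)
    starts <- ends - gaps$lengths + 1
    gi <- which(gaps$values)
    gi <- gi[which.max(gaps$lengths[gi])]
    split_col <- inner[1] + as.integer((starts[gi] + ends[gi]) / 2) - 1L
  }
  if (is.null(split_col)) {
    # characters touching: split at the column occupancy midpoint
    split_col <- as.integer(round(stats::weighted.mean(seq_along(colsum), colsum)))
  }
  left <- mask[, seq_len(split_col), drop = FALSE]
  right <- mask[, (split_col + 1):ncol(mask), drop = FALSE]
  f <- function(m) {
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    crop <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    side <- max(dim(crop))
    sq <- matrix(0, side, side)
    oy <- (side - nrow(crop)) %/% 2; ox <- (side - ncol(crop)) %/% 2
    sq[oy + seq_len(nrow(crop)), ox + seq_len(ncol(crop))] <- crop
    as.numeric(resize_nn(sq, glyph_cell, glyph_cell))
  }
  if (!any(left) || !any(right)) return(NULL)
  list(digit = f(left), letter = f(right))
}

#' Train the square-identifier glyph classifier
#'
#' Generates augmented synthetic glyph images for every label of the layout
#' and trains two random forests (one for the digit, one for the letter) on
#' normalized 12 x 12 character crops.
#'
#' @param layout A [grid_layout()] defining the label alphabet.
#' @param n_per_label Training images generated per label.
#' @param augment Augmentation ranges passed to [gen_glyph_image()].
#' @param num_trees Trees per forest.
#' @param seed Integer seed.
#' @return A `glyph_classifier` object.
#' @export
train_glyph_classifier <- function(layout = grid_layout(), n_per_label = 12,
                                   augment = list(rotation_deg = c(-6, 6),
                                                  scale = c(0.85, 1.15),
                                                  translate_px = c(-5, 5),
                                                  intensity = c(0.7, 1),
                                                  noise_sd = 0.02),
                                   num_trees = 300, seed = 1) {
  labs <- grid_labels(layout)$label
  feats <- list(); digs <- character(); lets <- character()
  si <- 0L
  for (lab in labs) {
    for (r in seq_len(n_per_label)) {
      si <- si + 1L
      g <- gen_glyph_image(lab, augment = augment, seed = seed * 100000L + si)
      f <- glyph_features(g$image)
      if (is.null(f)) next
      feats[[length(feats) + 1]] <- c(f$digit, f$letter)
      digs <- c(digs, substr(lab, 1, 1))
      lets <- c(lets, substr(lab, 2, 2))
    }
  }
  X <- do.call(rbind, feats)
  nd <- glyph_cell^2
  colnames(X) <- paste0("p", seq_len(2 * nd))
  dd <- data.frame(X[, seq_len(nd)], y = factor(digs))
  dl <- data.frame(X[, nd + seq_len(nd)], y = factor(lets))
  names(dl)[seq_len(nd)] <- paste0("p", seq_len(nd))
  fit <- function(df, s) ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                                        probability = TRUE, seed = s,
                                        num.threads = 1)
  structure(list(digit_model = fit(dd, seed), letter_model = fit(dl, seed + 1),
                 layout = layout, n_train = nrow(X)),
            class = "glyph_classifier")
}

#' Classify a square-identifier glyph patch
#'
#' @param glyph_image Cleaned glyph patch (grayscale matrix; binarization is
#'   applied internally).
#' @param model A `glyph_classifier` from [train_glyph_classifier()].
#' @param threshold Confidence below which the label is reported `"unknown"`.
#' @return A list with `label` and `confidence` in \[0, 1\].
#' @export
classify_square_id <- function(glyph_image, model, threshold = 0.5) {
  stopifnot(inherits(model, "glyph_classifier"))
  f <- glyph_features(glyph_image)
  if (is.null(f)) return(list(label = "unknown", confidence = 0))
  nd <- glyph_cell^2
  newd <- function(v) stats::setNames(as.data.frame(matrix(v, 1, nd)),
                                      paste0("p", seq_len(nd)))
  pd <- stats::predict(model$digit_model, data = newd(f$digit),
                       num.threads = 1)$predictions
  pl <- stats::predict(model$letter_model, data = newd(f$letter),
                       num.threads = 1)$predictions
  cd <- max(pd); cl <- max(pl)
  conf <- min(cd, cl)
  lab <- paste0(colnames(pd)[which.max(pd)], colnames(pl)[which.max(pl)])
  if (conf < threshold) return(list(label = "unknown", confidence = conf))
  list(label = lab, confidence = conf)
}
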