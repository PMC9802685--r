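# LM -> EM registration: lattice prediction from few landmarks, global affine
# on all matched pairs, locally refined affine near each target.

#' Registration parameters
#'
#' @param local_radius_um Radius around a target within which landmarks feed
#'   the local transform (micrometres).
#' @param local_k Maximum number of in-radius neighbours used locally.
#' @param min_pairs_global Pairs below this count trigger a warning for the
#'   global fit.
#' @param min_separation_um Minimum allowed distance between kept targets
#'   (closer targets interfere through trench milling).
#' @return A `registration_params` list.
#' @export
registration_params <- function(local_radius_um = 1200, local_k = 8,
                                min_pairs_global = 4, min_separation_um = 150) {
  stopifnot(local_radius_um > 0, local_k > 0, min_pairs_global > 0,
            min_separation_um > 0)
  structure(list(local_radius_um = local_radius_um, local_k = local_k,
                 min_pairs_global = min_pairs_global,
                 min_separation_um = min_separation_um),
            class = "registration_params")
}

rank2_ok <- function(X) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  sv <- svd(Xc)$d
  length(sv) >= 2 && sv[2] > 1e-9 * max(sv[1], 1)
}

new_affine <- function(A, t, residuals = NULL, n_pairs = NA_integer_,
                       fallback = FALSE) {
  rmse <- if (is.null(residuals)) NA_real_ else
    sqrt(mean(rowSums(residuals^2)))
  structure(list(A = A, t = as.numeric(t), rmse_um = rmse,
                 n_pairs = n_pairs, residuals = residuals,
                 det = det(A), fallback = fallback),
            class = "clem_affine")
}

#' @export
print.clem_affine <- function(x, ...) {
  cat(sprintf("<clem_affine> n_pairs = %s, rmse = %s um, det = %.4g%s\n",
              x$n_pairs, format(x$rmse_um, digits = 4), x$det,
              if (isTRUE(x$fallback)) " (global fallback)" else ""))
  invisible(x)
}

solve_affine <- function(X, Y) {
  # least squares Y ~ A X + t (columns are x, y)
  fit <- stats::lm.fit(cbind(1, X), Y)
  B <- fit$coefficients
  list(A = t(B[2:3, , drop = FALSE]), t = as.numeric(B[1, ]),
       residuals = as.matrix(fit$residuals))
}

#' Fit the lattice model from labelled landmarks
#'
#' Least-squares affine map from integer lattice indices (row, col, decoded
#' from the square labels) to stage coordinates. With four exact landmarks on
#' a regular lattice the model predicts every other crossing exactly,
#' including under rotated, scaled or mirrored stage frames.
#'
#' @param landmarks Tibble with `stage_x_um`, `stage_y_um` and either
#'   `row`/`col` indices or a `label` column.
#' @param layout A [grid_layout()] (used to decode labels).
#' @return A `clem_lattice` object with a `predict()` method taking a tibble
#'   of `row`/`col` (or `label`).
#' @export
fit_lattice <- function(landmarks, layout = grid_layout()) {
  lm_tbl <- tibble::as_tibble(landmarks)
  if (!all(c("row", "col") %in% names(lm_tbl))) {
    idx <- label_indices(lm_tbl$label, layout)
    lm_tbl$row <- idx$row; lm_tbl$col <- idx$col
  }
  if (nrow(lm_tbl) < 4) rlang::abort("at least 4 landmarks required")
  X <- cbind(lm_tbl$col, lm_tbl$row)
  if (!rank2_ok(X)) rlang::abort("degenerate index configuration (collinear labels)")
  Y <- cbind(lm_tbl$stage_x_um, lm_tbl$stage_y_um)
  s <- solve_affine(X, Y)
  structure(list(A = s$A, t = s$t,
                 rmse_um = sqrt(mean(rowSums(s$residuals^2))),
                 n = nrow(lm_tbl), layout = layout),
            class = "clem_lattice")
}

#' @export
predict.clem_lattice <- function(object, newdata, ...) {
  nd <- tibble::as_tibble(newdata)
  if (!all(c("row", "col") %in% names(nd))) {
    idx <- label_indices(nd$label, object$layout)
    nd$row <- idx$row; nd$col <- idx$col
  }
  P <- cbind(nd$col, nd$row) %*% t(object$A)
  tibble::tibble(stage_x_um = P[, 1] + object$t[1],
                 stage_y_um = P[, 2] + object$t[2])
}

#' @export
print.clem_lattice <- function(x, ...) {
  cat(sprintf("<clem_lattice> fitted on %d landmarks, rmse = %s um\n",
              x$n, format(x$rmse_um, digits = 4)))
  invisible(x)
}

#' Match landmarks of two frames by label
#'
#' @param lm_map,em_map Landmark tibbles with `label`, `stage_x_um`,
#'   `stage_y_um` (and optionally `status`; only `valid` rows are used).
#' @return Pair tibble with `label`, `lm_x_um`, `lm_y_um`, `em_x_um`,
#'   `em_y_um`.
#' @export
match_landmarks <- function(lm_map, em_map) {
  pick <- function(m) {
    m <- tibble::as_tibble(m)
    if ("status" %in% names(m)) m <- m[m$status == "valid", ]
    m[, c("label", "stage_x_um", "stage_y_um")]
  }
  a <- pick(lm_map); b <- pick(em_map)
  names(a) <- c("label", "lm_x_um", "lm_y_um")
  names(b) <- c("label", "em_x_um", "em_y_um")
  dplyr::inner_join(a, b, by = "label")
}

#' Fit the global affine transform between stage frames
#'
#' Least-squares 2-D affine registration of matched (LM, EM) landmark pairs.
#' Reflections are permitted — the LM and EM views of the substrate are
#' mirrored after coverslip removal — and show up as a negative determinant.
#' Residual outliers beyond 3x the median absolute deviation are flagged but
#' kept (landmarks are already validated upstream).
#'
#' @param pairs Pair tibble as from [match_landmarks()], or any tibble with
#'   `lm_x_um`, `lm_y_um`, `em_x_um`, `em_y_um`.
#' @param params A [registration_params()].
#' @return A `clem_affine` with elements `A`, `t`, `rmse_um`, `n_pairs`,
#'   `residuals`, `det`, and an `outlier` attribute.
#' @export
fit_global_affine <- function(pairs, params = registration_params()) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 3) rlang::abort("at least 3 landmark pairs required")
  X <- cbind(pairs$lm_x_um, pairs$lm_y_um)
  if (!rank2_ok(X)) rlang::abort("landmark pairs are collinear")
  if (nrow(pairs) < params$min_pairs_global) {
    rlang::warn(sprintf("only %d pairs (fewer than %d); transform may be unstable",
                        nrow(pairs), params$min_pairs_global))
  }
  Y <- cbind(pairs$em_x_um, pairs$em_y_um)
  s <- solve_affine(X, Y)
  out <- new_affine(s$A, s$t, s$residuals, n_pairs = nrow(pairs))
  r <- sqrt(rowSums(s$residuals^2))
  madr <- stats::mad(r, center = stats::median(r))
  attr(out, "outlier") <- if (madr > 0) r > stats::median(r) + 3 * madr else
    rep(FALSE, length(r))
  out
}

#' Fit a locally refined affine transform near a target
#'
#' Uses only the matched landmarks within `local_radius_um` of the target (in
#' the LM frame), capped at the `local_k` nearest. With fewer than three
#' usable (non-collinear) neighbours the global transform is returned,
#' flagged as a fallback.
#'
#' @param pairs Matched pair tibble (see [match_landmarks()]).
#' @param target_lm_xy Target position `c(x, y)` in LM micrometres.
#' @param params A [registration_params()].
#' @param global Optional precomputed global `clem_affine` used as fallback
#'   (computed from all pairs when omitted).
#' @return A `clem_affine`; `$fallback` is `TRUE` when the global transform
#'   was substituted.
#' @export
fit_local_affine <- function(pairs, target_lm_xy,
                             params = registration_params(), global = NULL) {
  pairs <- tibble::as_tibble(pairs)
  d <- sqrt((pairs$lm_x_um - target_lm_xy[1])^2 +
              (pairs$lm_y_um - target_lm_xy[2])^2)
  sel <- which(d <= params$local_radius_um)
  sel <- sel[order(d[sel])][seq_len(min(length(sel), params$local_k))]
  loc <- pairs[sel, ]
  usable <- nrow(loc) >= 3 &&
    rank2_ok(cbind(loc$lm_x_um, loc$lm_y_um))
  if (!usable) {
    g <- global %||% fit_global_affine(pairs, params)
    g$fallback <- TRUE
    return(g)
  }
  s <- solve_affine(cbind(loc$lm_x_um, loc$lm_y_um),
                    cbind(loc$em_x_um, loc$em_y_um))
  new_affine(s$A, s$t, s$residuals, n_pairs = nrow(loc))
}

#' Apply a transform to target positions
#'
#' Elementwise affine application, order preserved.
#'
#' @param transform A `clem_affine`.
#' @param targets Tibble with `x_um`, `y_um` (or an n x 2 matrix).
#' @return Tibble with `em_x_um`, `em_y_um`.
#' @export
predict_targets <- function(transform, targets) {
  stopifnot(inherits(transform, "clem_affine"))
  if (is.matrix(targets)) {
    X <- targets
  } else {
    targets <- tibble::as_tibble(targets)
    X <- cbind(targets$x_um, targets$y_um)
  }
  P <- X %*% t(transform$A)
  tibble::tibble(em_x_um = P[, 1] + transform$t[1],
                 em_y_um = P[, 2] + transform$t[2])
}

#' Invert an affine transform
#'
#' @param transform A `clem_affine`.
#' @return The inverse `clem_affine`.
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  new_affine(Ai, -Ai %*% transform$t, n_pairs = transform$n_pairs)
}

#' Targeting error between predicted and true positions
#'
#' @param predicted,truth Tibbles with matching coordinate columns (first two
#'   numeric columns are used), or n x 2 matrices, equal lengths.
#' @return List with `distances_um` (per-point Euclidean distances) and
#'   `rmsd_um` (their root mean square).
#' @export
targeting_error <- function(predicted, truth) {
  P <- coord_matrix(predicted); Q <- coord_matrix(truth)
  if (nrow(P) != nrow(Q)) rlang::abort("predicted and truth lengths differ")
  d <- sqrt(rowSums((P - Q)^2))
  list(distances_um = d, rmsd_um = sqrt(mean(d^2)))
}

coord_matrix <- function(x) {
  if (is.matrix(x)) return(x[, 1:2, drop = FALSE])
  x <- tibble::as_tibble(x)
  num <- which(vapply(x, is.numeric, logical(1)))[1:2]
  as.matrix(x[, num])
}

#' Filter targets by minimum separation and surface status
#'
#' Removes targets on blocked or damaged regions first, then greedily removes
#' targets (those in conflict with the most others first) until all pairwise
#' distances are at least `min_separation_um` — two trenches closer than that
#' would interfere.
#'
#' @param targets Tibble with `x_um`, `y_um`, optional `status` column
#'   (`"blocked"`/`"defect"` rows are dropped first) and optional `id`.
#' @param params A [registration_params()].
#' @return The kept rows of `targets`.
#' @export
filter_targets <- function(targets, params = registration_params()) {
  targets <- tibble::as_tibble(targets)
  if ("status" %in% names(targets)) {
    targets <- targets[!(targets$status %in% c("blocked", "defect")), ]
  }
  if (nrow(targets) < 2) return(targets)
  keep <- rep(TRUE, nrow(targets))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    D <- as.matrix(stats::dist(cbind(targets$x_um[idx], targets$y_um[idx])))
    conf <- rowSums(D < params$min_separation_um) - 1
    if (max(conf) == 0) break
    worst <- idx[which.max(conf)]  # ties: earliest index removed last -> max picks first
    # remove the target with the most conflicts; on ties prefer removing the
    # later one so earlier-listed targets survive
    mx <- which(conf == max(conf))
    worst <- idx[mx[length(mx)]]
    keep[worst] <- FALSE
  }
  targets[keep, ]
}
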