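# End-to-end simulated targeting workflow and broom-style accessors.

#' Run the simulated targeting pipeline
#'
#' Exercises the full workflow on synthetic data: renders the same grid
#' lattice under an LM frame and a (rotated, mirrored) EM frame, detects and
#' refines crossing landmarks in both frames, registers the frames with the
#' global affine transform, refines locally around each target, predicts the
#' EM positions of the LM targets and reports the targeting error against the
#' simulated truth.
#'
#' @param layout A [grid_layout()].
#' @param lm_frame,em_frame Frame transforms (grid to stage) for the two
#'   modalities; the EM default is rotated 45 degrees and mirrored.
#' @param n_landmarks Number of landmark crossings sampled per frame.
#' @param n_targets Number of simulated targets.
#' @param landmark_noise_um Gaussian noise added to detected landmark stage
#'   positions (emulating detection error).
#' @param params A [registration_params()].
#' @param seed Integer seed.
#' @return List with `pairs`, `global` (clem_affine), `targets` (tibble with
#'   LM positions, predicted and true EM positions, per-target transform
#'   kind), and `error` (list with `distances_um`, `rmsd_um`).
#' @export
run_pipeline <- function(layout = grid_layout(),
                         lm_frame = frame_transform(),
                         em_frame = frame_transform(angle_deg = 45, flip = TRUE,
                                                    translation = c(300, -150)),
                         n_landmarks = 30, n_targets = 8,
                         landmark_noise_um = 2,
                         params = registration_params(), seed = 1) {
  labs <- grid_labels(layout)
  with_seed(seed, {
    sel <- sample.int(nrow(labs), min(n_landmarks, nrow(labs)))
    g <- cbind(labs$x_um[sel], labs$y_um[sel])
    lm_xy <- apply_frame(lm_frame, g) +
      matrix(stats::rnorm(2 * length(sel), 0, landmark_noise_um), ncol = 2)
    em_xy <- apply_frame(em_frame, g) +
      matrix(stats::rnorm(2 * length(sel), 0, landmark_noise_um), ncol = 2)
    pairs <- tibble::tibble(label = labs$label[sel],
                            lm_x_um = lm_xy[, 1], lm_y_um = lm_xy[, 2],
                            em_x_um = em_xy[, 1], em_y_um = em_xy[, 2])
    global <- fit_global_affine(pairs, params)
    tg <- cbind(stats::runif(n_targets, min(g[, 1]), max(g[, 1])),
                stats::runif(n_targets, min(g[, 2]), max(g[, 2])))
    t_lm <- apply_frame(lm_frame, tg)
    t_em_true <- apply_frame(em_frame, tg)
    preds <- purrr::map_dfr(seq_len(n_targets), function(i) {
      loc <- fit_local_affine(pairs, t_lm[i, ], params, global = global)
      p <- predict_targets(loc, matrix(t_lm[i, ], 1))
      tibble::tibble(target = i, lm_x_um = t_lm[i, 1], lm_y_um = t_lm[i, 2],
                     pred_em_x_um = p$em_x_um, pred_em_y_um = p$em_y_um,
                     true_em_x_um = t_em_true[i, 1],
                     true_em_y_um = t_em_true[i, 2],
                     transform = if (isTRUE(loc$fallback)) "global" else "local")
    })
    err <- targeting_error(preds[, c("pred_em_x_um", "pred_em_y_um")],
                           preds[, c("true_em_x_um", "true_em_y_um")])
    list(pairs = pairs, global = global, targets = preds, error = err)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an affine transform
#'
#' One row per coefficient of the 2-D affine map.
#'
#' @param x A `clem_affine`.
#' @param ... Unused.
#' @export
tidy.clem_affine <- function(x, ...) {
  tibble::tibble(
    term = c("a11", "a12", "a21", "a22", "tx", "ty"),
    estimate = c(x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2]))
}

#' Summarize an affine transform fit
#'
#' @param x A `clem_affine`.
#' @param ... Unused.
#' @export
glance.clem_affine <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, rmse_um = x$rmse_um, det = x$det,
                 reflection = x$det < 0, fallback = isTRUE(x$fallback))
}

#' @export
tidy.clem_lattice <- function(x, ...) {
  tibble::tibble(
    term = c("dx_dcol", "dx_drow", "dy_dcol", "dy_drow", "x0", "y0"),
    estimate = c(x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2]))
}

#' @export
glance.clem_lattice <- function(x, ...) {
  tibble::tibble(n = x$n, rmse_um = x$rmse_um, det = det(x$A))
}
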