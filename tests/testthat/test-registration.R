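make_pairs <- function(n, A, t, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- cbind(stats::runif(n, -3000, 3000), stats::runif(n, -3000, 3000))
    Y <- X %*% t(A) + matrix(t, n, 2, byrow = TRUE) +
      matrix(stats::rnorm(2 * n, 0, noise), n, 2)
    tibble::tibble(label = as.character(seq_len(n)),
                   lm_x_um = X[, 1], lm_y_um = X[, 2],
                   em_x_um = Y[, 1], em_y_um = Y[, 2])
  })
}

rot_mat <- function(deg, flip = FALSE, scale = 1) {
  th <- deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) * scale
  if (flip) R %*% diag(c(-1, 1)) else R
}

test_that("noiseless affines are recovered exactly, including reflections", {
  for (case in list(list(A = rot_mat(33), t = c(100, -50)),
                    list(A = rot_mat(45, flip = TRUE, scale = 1.04),
                         t = c(-310, 220)))) {
    pairs <- make_pairs(12, case$A, case$t)
    fit <- fit_global_affine(pairs)
    expect_lt(max(abs(fit$A - case$A)), 1e-9)
    expect_lt(max(abs(fit$t - case$t)), 1e-7)
    expect_lt(fit$rmse_um, 1e-8)
  }
  refl <- fit_global_affine(make_pairs(10, rot_mat(10, flip = TRUE), c(0, 0)))
  expect_lt(refl$det, 0)
  expect_error(fit_global_affine(make_pairs(2, rot_mat(0), c(0, 0))), "3")
  col <- tibble::tibble(lm_x_um = 1:5, lm_y_um = 2 * (1:5),
                        em_x_um = 1:5, em_y_um = 2 * (1:5))
  expect_error(fit_global_affine(col), "collinear")
})

test_that("the lattice model predicts all crossings from four corners", {
  layout <- grid_layout()
  labs <- grid_labels(layout)
  corners <- labs[labs$label %in% c("1A", "1B", "2A", "2B"), ]
  for (fr in list(frame_transform(),
                  frame_transform(angle_deg = 45, flip = TRUE,
                                  translation = c(777, -333)))) {
    st <- clemtarget:::apply_frame(fr, cbind(corners$x_um, corners$y_um))
    lm_tbl <- tibble::tibble(label = corners$label,
                             stage_x_um = st[, 1], stage_y_um = st[, 2])
    lat <- fit_lattice(lm_tbl, layout)
    probe <- labs[labs$label == "9T", ]
    pred <- predict(lat, probe)
    truth <- clemtarget:::apply_frame(fr, c(probe$x_um, probe$y_um))
    expect_lt(abs(pred$stage_x_um - truth[1]), 1e-6)
    expect_lt(abs(pred$stage_y_um - truth[2]), 1e-6)
  }
  expect_error(fit_lattice(tibble::tibble(label = c("1A", "1B", "1C", "1D"),
                                          stage_x_um = c(0, 600, 1200, 1800),
                                          stage_y_um = rep(0, 4)), layout),
               "degenerate")
})

test_that("lattice prediction error under landmark noise matches Monte Carlo", {
  layout <- grid_layout()
  labs <- grid_labels(layout)
  seeds4 <- labs[labs$label %in% c("1A", "1T", "9A", "9T"), ]
  probe <- labs[labs$label == "5J", ]
  n_rep <- 100
  err_impl <- err_oracle <- numeric(n_rep)
  withr::with_seed(42, {
    for (r in seq_len(n_rep)) {
      noise <- matrix(stats::rnorm(8, 0, 5), 4, 2)
      lm_tbl <- tibble::tibble(label = seeds4$label,
                               stage_x_um = seeds4$x_um + noise[, 1],
                               stage_y_um = seeds4$y_um + noise[, 2])
      lat <- fit_lattice(lm_tbl, layout)
      p <- predict(lat, probe)
      err_impl[r] <- sqrt((p$stage_x_um - probe$x_um)^2 +
                            (p$stage_y_um - probe$y_um)^2)
      o <- oracle_affine(cbind(seeds4$col, seeds4$row),
                         cbind(lm_tbl$stage_x_um, lm_tbl$stage_y_um))
      po <- o$predict(cbind(probe$col, probe$row))
      err_oracle[r] <- sqrt(sum((po - c(probe$x_um, probe$y_um))^2))
    }
  })
  rmse_impl <- sqrt(mean(err_impl^2)); rmse_oracle <- sqrt(mean(err_oracle^2))
  expect_lt(rmse_impl, 3 * rmse_oracle)
  expect_lt(abs(rmse_impl - rmse_oracle) / rmse_oracle, 0.01)
})

test_that("target prediction error under noise matches the Monte-Carlo oracle", {
  A <- rot_mat(25, flip = TRUE); tt <- c(150, -80)
  targets <- cbind(c(-1000, 0, 1500), c(800, -500, 200))
  truth <- targets %*% t(A) + matrix(tt, 3, 2, byrow = TRUE)
  n_rep <- 500
  rmse_o <- numeric(n_rep)
  impl_idx <- seq(1, n_rep, by = 5)
  rmse_i <- numeric(length(impl_idx)); ii <- 0
  for (r in seq_len(n_rep)) {
    pairs <- make_pairs(30, A, tt, noise = 3, seed = 1000 + r)
    o <- oracle_affine(cbind(pairs$lm_x_um, pairs$lm_y_um),
                       cbind(pairs$em_x_um, pairs$em_y_um))
    rmse_o[r] <- sqrt(mean(rowSums((o$predict(targets) - truth)^2)))
    if (r %in% impl_idx) {
      ii <- ii + 1
      fit <- fit_global_affine(pairs)
      pred <- predict_targets(fit, targets)
      rmse_i[ii] <- targeting_error(pred, truth)$rmsd_um
    }
  }
  mo <- mean(rmse_o); se <- stats::sd(rmse_o) / sqrt(length(impl_idx))
  expect_lt(abs(mean(rmse_i) - mo), 4 * se + 0.02 * mo)
})

test_that("prediction error scales linearly with landmark noise", {
  A <- rot_mat(15); tt <- c(0, 0)
  targets <- cbind(c(500, -500), c(500, -500))
  truth <- targets %*% t(A)
  rmse_at <- function(sig) {
    errs <- vapply(1:120, function(r) {
      pairs <- make_pairs(25, A, tt, noise = sig, seed = 7000 + r)
      fit <- fit_global_affine(pairs)
      targeting_error(predict_targets(fit, targets), truth)$rmsd_um
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r1 <- rmse_at(1); r3 <- rmse_at(3); r5 <- rmse_at(5)
  expect_lt(abs(r3 / r1 - 3), 0.75)
  expect_lt(abs(r5 / r1 - 5), 1.25)
})

test_that("local refinement agrees with global on uniform fields and beats it under distortion", {
  A <- rot_mat(40, flip = TRUE); tt <- c(300, 100)
  pairs <- make_pairs(40, A, tt, seed = 5)
  g <- fit_global_affine(pairs)
  loc <- fit_local_affine(pairs, c(0, 0), registration_params(local_radius_um = 1e5))
  p1 <- predict_targets(loc, cbind(10, 20))
  p2 <- predict_targets(g, cbind(10, 20))
  expect_lt(abs(p1$em_x_um - p2$em_x_um), 1e-6)
  expect_lt(abs(p1$em_y_um - p2$em_y_um), 1e-6)
  # smooth quadratic distortion: local neighbourhoods out-predict the global fit
  warp <- function(X) X %*% t(A) + 2e-5 * cbind(X[, 1]^2, X[, 1] * X[, 2])
  withr::with_seed(9, {
    Xl <- cbind(stats::runif(120, -4000, 4000), stats::runif(120, -4000, 4000))
    pw <- tibble::tibble(lm_x_um = Xl[, 1], lm_y_um = Xl[, 2],
                         em_x_um = warp(Xl)[, 1], em_y_um = warp(Xl)[, 2])
    Tg <- cbind(stats::runif(100, -3000, 3000), stats::runif(100, -3000, 3000))
  })
  truth <- warp(Tg)
  gw <- fit_global_affine(pw)
  params <- registration_params()
  e_loc <- e_glob <- numeric(nrow(Tg))
  for (i in seq_len(nrow(Tg))) {
    loc <- fit_local_affine(pw, Tg[i, ], params, global = gw)
    e_loc[i] <- targeting_error(predict_targets(loc, Tg[i, , drop = FALSE]),
                                truth[i, , drop = FALSE])$rmsd_um
    e_glob[i] <- targeting_error(predict_targets(gw, Tg[i, , drop = FALSE]),
                                 truth[i, , drop = FALSE])$rmsd_um
  }
  expect_lt(mean(e_loc), mean(e_glob))
  # isolated target with too few neighbours falls back to the global transform
  iso <- fit_local_affine(pw[1:2, ], c(0, 0), params, global = gw)
  expect_true(iso$fallback)
})

test_that("predict_targets is exactly affine and invertible", {
  fit <- fit_global_affine(make_pairs(8, rot_mat(70, scale = 0.9), c(5, -5)))
  a <- c(100, 200); b <- c(-300, 50); al <- 0.3
  pa <- as.numeric(predict_targets(fit, rbind(a))[1, ])
  pb <- as.numeric(predict_targets(fit, rbind(b))[1, ])
  pm <- as.numeric(predict_targets(fit, rbind(al * a + (1 - al) * b))[1, ])
  expect_lt(max(abs(pm - (al * pa + (1 - al) * pb))), 1e-9)
  inv <- invert_affine(fit)
  back <- predict_targets(inv, as.matrix(predict_targets(fit, rbind(a, b))))
  expect_lt(max(abs(as.matrix(back) - rbind(a, b))), 1e-9)
  idp <- fit_global_affine(make_pairs(5, diag(2), c(0, 0)))
  expect_equal(as.numeric(predict_targets(idp, rbind(c(3, 4)))[1, ]), c(3, 4))
})

test_that("targeting error reports distances and RMSD", {
  e0 <- targeting_error(rbind(c(1, 2), c(3, 4)), rbind(c(1, 2), c(3, 4)))
  expect_equal(e0$distances_um, c(0, 0))
  e1 <- targeting_error(rbind(c(3, 4)), rbind(c(0, 0)))
  expect_equal(e1$distances_um, 5)
  expect_equal(e1$rmsd_um, 5)
  expect_error(targeting_error(rbind(c(1, 1)), rbind(c(1, 1), c(2, 2))),
               "lengths differ")
})

test_that("target filtering enforces the minimum separation", {
  p <- registration_params()
  two_close <- tibble::tibble(x_um = c(0, 100), y_um = c(0, 0))
  expect_equal(nrow(filter_targets(two_close, p)), 1)
  two_far <- tibble::tibble(x_um = c(0, 200), y_um = c(0, 0))
  expect_equal(nrow(filter_targets(two_far, p)), 2)
  # chain A-B-C: removing the middle target maximizes the kept count
  chain <- tibble::tibble(x_um = c(0, 100, 200), y_um = 0)
  kept <- filter_targets(chain, p)
  expect_equal(kept$x_um, c(0, 200))
  # brute-force confirmation: no larger valid subset exists
  valid_subsets <- Filter(function(s) {
    if (length(s) < 2) return(TRUE)
    all(stats::dist(cbind(chain$x_um[s], chain$y_um[s])) >= 150)
  }, unlist(lapply(1:3, function(k) utils::combn(3, k, simplify = FALSE)),
            recursive = FALSE))
  expect_equal(max(lengths(valid_subsets)), nrow(kept))
  # blocked targets go first
  bl <- tibble::tibble(x_um = c(0, 100), y_um = 0, status = c("blocked", "ok"))
  expect_equal(filter_targets(bl, p)$x_um, 100)
})
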