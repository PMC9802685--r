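test_that("cell segmentation partitions cytoplasm around each nucleus", {
  n <- 200
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  dapi <- matrix(0, n, n)
  centers <- rbind(c(50, 60), c(150, 60), c(100, 150))
  for (k in 1:3) {
    dapi <- dapi + 0.6 * exp(-((xs - centers[k, 1])^2 +
                                 (ys - centers[k, 2])^2) / (2 * 8^2))
  }
  gfp <- matrix(0.1, n, n)
  cells <- segment_cells(dapi, gfp, dilation_radius_px = 30)
  expect_length(cells, 3)
  for (cell in cells) {
    expect_true(all(cell$cytoplasm_mask[cell$nucleus_mask]))
  }
  # cytoplasm masks are pairwise disjoint
  overlap <- cells[[1]]$cytoplasm_mask & cells[[2]]$cytoplasm_mask
  expect_false(any(overlap))
  expect_error(segment_cells(matrix(0, 64, 64), matrix(0, 64, 64)), "no nuclei")
})

test_that("diffuseness matches the brute-force opening oracle", {
  cfg <- feature_config(opening_radius_px = 6)
  n <- 48
  b <- 0.2
  img <- matrix(b, n, n)
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  spot <- (xs - 24)^2 + (ys - 24)^2 <= 2^2   # smaller than the SE
  img[spot] <- b + 0.6
  mask <- matrix(FALSE, n, n); mask[8:41, 8:41] <- TRUE
  d <- diffuseness(img, mask, cfg)
  # oracle 1: independent grayscale opening
  opened <- oracle_opening(img, disc_se(6))
  expect_equal(d, sum(opened[mask]) / sum(img[mask]), tolerance = 1e-9)
  # oracle 2: closed form — the opening removes the spot entirely
  s <- sum(img[spot & mask] - b)
  expect_equal(d, sum(b * mask) / (sum(b * mask) + s), tolerance = 1e-9)
  # constant signal scores exactly 1
  expect_equal(diffuseness(matrix(0.37, 64, 64), matrix(TRUE, 64, 64), cfg), 1)
  expect_error(diffuseness(matrix(0, 32, 32), matrix(TRUE, 32, 32), cfg),
               "zero total signal")
})

test_that("diffuse archetypes score above controls", {
  cfg <- test_feature_config()
  withr::with_seed(5, {
    d_diff <- vapply(1:8, function(i) {
      cell <- gen_phenotype_cell("diffuse", strength = stats::runif(1, 0.6, 1),
                                 seed = 40 + i)
      diffuseness(cell$gfp, cell$cytoplasm_mask, cfg)
    }, numeric(1))
    d_ctrl <- vapply(1:8, function(i) {
      cell <- gen_phenotype_cell("control", seed = 80 + i)
      diffuseness(cell$gfp, cell$cytoplasm_mask, cfg)
    }, numeric(1))
  })
  expect_true(all(outer(d_diff, d_ctrl, ">")))
})

test_that("fragmentation counts constructed components exactly", {
  cfg <- test_feature_config()
  n <- 128
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  mask <- matrix(TRUE, n, n)
  one <- 0.02 + 0.8 * exp(-((xs - 64)^2 + (ys - 64)^2) / 18)
  expect_equal(fragmentation(one, mask, cfg), 1)
  seven <- matrix(0.02, n, n)
  pos <- rbind(c(20, 20), c(20, 64), c(20, 108), c(64, 20), c(64, 108),
               c(108, 40), c(108, 90))
  for (k in 1:7) {
    seven <- seven + 0.8 * exp(-((xs - pos[k, 1])^2 + (ys - pos[k, 2])^2) / 14)
  }
  expect_equal(fragmentation(seven, mask, cfg), 7)
  expect_equal(fragmentation(matrix(0.25, n, n), mask, cfg), 0)
})

test_that("tubularity separates bars from discs and matches its oracle", {
  cfg <- feature_config(line_length_px = 15, angle_step_deg = 30)
  n <- 96
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  mask <- matrix(TRUE, n, n)
  disc <- 0.02 + 0.8 * ((xs - 48)^2 + (ys - 48)^2 <= 30^2)
  bar <- 0.02 + 0.8 * (abs(ys - 48) <= 3.5 & abs(xs - 48) <= 45)
  t_disc <- tubularity(disc, mask, cfg)
  t_bar <- tubularity(bar, mask, cfg)
  expect_lt(t_disc, 0.08)      # isotropic structure, all orientations equal
  expect_gt(t_bar, t_disc)
  # independent oracle: explicit line openings over the same sweep
  oracle_tub <- function(img) {
    angles <- seq(0, 150, by = 30)
    ops <- lapply(angles, function(a) {
      oracle_opening(img, clemtarget:::line_brush(15, a) > 0)
    })
    mx <- Reduce(pmax, ops); mn <- Reduce(pmin, ops)
    sum(mx - mn) / sum(img)
  }
  expect_equal(t_bar, oracle_tub(bar), tolerance = 0.05)
  expect_gt(oracle_tub(bar), oracle_tub(disc))
})

test_that("tubularity is invariant to a 90-degree rotation", {
  cfg <- test_feature_config()
  cell <- gen_phenotype_cell("tubular", strength = 0.7, seed = 51)
  t1 <- tubularity(cell$gfp, cell$cytoplasm_mask, cfg)
  rot <- t(cell$gfp)[ncol(cell$gfp):1, ]
  rot_mask <- t(cell$cytoplasm_mask)[ncol(cell$cytoplasm_mask):1, ]
  t2 <- tubularity(rot, rot_mask, cfg)
  expect_lt(abs(t1 - t2) / t1, 0.02)
})

test_that("the shape factor formula and its rasterized estimate behave", {
  r <- 7.3
  expect_equal(shape_factor_formula(pi * r^2, 2 * pi * r), 1)
  expect_equal(shape_factor_formula(1, 4), pi / 4)              # unit square
  expect_equal(shape_factor_formula(10, 22), 40 * pi / 484)     # 10:1 rectangle
  n <- 221
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  circ <- (xs - 111)^2 + (ys - 111)^2 <= 100^2
  expect_lt(abs(shape_factor(circ) - 1), 0.02)
})

test_that("condensation scores compact shapes near 1 and respects its config", {
  cfg <- test_feature_config()
  n <- 160
  xs <- outer(rep(1, n), seq_len(n)); ys <- outer(seq_len(n), rep(1, n))
  mask <- matrix(TRUE, n, n)
  blob <- 0.02 + 0.8 * ((xs - 80)^2 + (ys - 80)^2 <= 25^2)
  v <- condensation(blob, mask, cfg)
  expect_gt(v, 0.9); expect_lte(v, 1)
  expect_error(condensation(matrix(0.3, n, n), mask, cfg), "no component")
})

test_that("all four features are invariant to positive intensity scaling", {
  cfg <- test_feature_config()
  cell <- gen_phenotype_cell("fragmented", strength = 0.5, seed = 61)
  g <- cell$gfp; m <- cell$cytoplasm_mask
  for (fn in list(diffuseness, fragmentation, tubularity, condensation)) {
    v1 <- fn(g, m, cfg)
    v2 <- fn(g * 3.7, m, cfg)
    expect_lt(abs(v2 - v1) / max(abs(v1), 1e-12), 1e-9)
  }
})

test_that("the power log-log slope flags blur and is flat for white noise", {
  withr::with_seed(21, {
    slopes <- vapply(1:20, function(i) {
      power_log_log_slope(matrix(stats::runif(128^2), 128))
    }, numeric(1))
  })
  expect_lt(max(abs(slopes)), 0.2)
  st <- gen_drift_stack(2, drift_per_slice = c(0, 0), seed = 22)
  img <- st$stack[, , 1]
  s0 <- power_log_log_slope(img)
  s1 <- power_log_log_slope(clemtarget:::img_gblur(img, 2))
  expect_lt(s1, s0)
  expect_identical(power_log_log_slope(img), power_log_log_slope(img))
  expect_error(power_log_log_slope(matrix(0.1, 32, 32)), "too small")
})

test_that("QC filtering applies the three sequential rules with reasons", {
  rec <- tibble::tibble(
    cell_id = 1:4,
    gfp_integral = c(100, 5, 100, 100),
    dapi_cov = c(0.1, 0.1, 0.9, 0.1),
    power_slope = c(-1, -1, -1, -4))
  out <- qc_filter(rec, min_gfp_integral = 50, max_dapi_cov = 0.5,
                   min_power_slope = -3)
  expect_equal(out$qc_status, c("kept", "rejected", "rejected", "rejected"))
  expect_equal(out$qc_reason, c(NA, "dim", "mitotic", "out_of_focus"))
  all_kept <- qc_filter(rec)
  expect_true(all(all_kept$qc_status == "kept"))
  # constructed population: rejected fraction equals the constructed fraction
  pop <- tibble::tibble(cell_id = 1:10,
                        gfp_integral = c(rep(100, 7), rep(1, 3)),
                        dapi_cov = 0.1, power_slope = -1)
  expect_equal(mean(qc_filter(pop, min_gfp_integral = 50)$qc_status == "rejected"),
               0.3)
})

test_that("feature-based selection rules are deterministic", {
  rec <- tibble::tibble(cell_id = 1:6,
                        diffuseness = c(0.9, 0.3, 0.7, 0.5, 0.95, 0.2))
  ctrl <- tibble::tibble(cell_id = 1:4, diffuseness = c(0.4, 0.5, 0.45, 0.55))
  sel <- select_by_feature(rec, "diffuseness", "above_control_mean",
                           control = ctrl)
  expect_setequal(sel$cell_id, c(1, 3, 4, 5))
  expect_equal(nrow(select_by_feature(rec, "diffuseness", "top_n", n = 6)), 6)
  expect_equal(nrow(select_by_feature(rec, "diffuseness", "threshold",
                                      threshold = 0.95 + 1e-9)), 0)
})

test_that("cell scoring produces one tidy row per cell", {
  cell <- gen_phenotype_cell("control", seed = 71)
  tbl <- score_cells(cell$gfp, cell$dapi, test_feature_config())
  expect_equal(nrow(tbl), 1)
  expect_true(all(c("diffuseness", "fragmentation", "tubularity",
                    "condensation", "gfp_integral", "dapi_cov",
                    "power_slope") %in% names(tbl)))
  expect_true(tbl$diffuseness >= 0 && tbl$diffuseness <= 1)
})
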