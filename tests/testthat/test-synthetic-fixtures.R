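test_that("grid scenes are deterministic and carry exact truth", {
  a <- gen_grid_image(image_size = 256, noise_sd = 0.05, seed = 11)
  b <- gen_grid_image(image_size = 256, noise_sd = 0.05, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$crossings, b$truth$crossings)
  c <- gen_grid_image(image_size = 256, noise_sd = 0.05, seed = 12)
  expect_false(identical(a$image, c$image))
  expect_identical(a$truth$crossings, c$truth$crossings)  # truth is seed-free
})

test_that("identity-frame scene places the 600 um pitch lattice correctly", {
  layout <- grid_layout()
  sc <- gen_grid_image(layout = layout, image_size = 1024, pixel_size = 1.7,
                       seed = 1)
  tr <- sc$truth$crossings
  # stage positions are exact lattice multiples of the pitch
  expect_true(all(abs(tr$stage_x_um %% layout$pitch) < 1e-9 |
                    abs(tr$stage_x_um %% layout$pitch - layout$pitch) < 1e-9))
  ctr <- tr[abs(tr$stage_x_um) < 1e-9 & abs(tr$stage_y_um) < 1e-9, ]
  expect_equal(c(ctr$px_x, ctr$px_y), c(512.5, 512.5))
  # neighbouring crossings are one pitch apart in pixels
  nx <- tr[abs(tr$stage_x_um - layout$pitch) < 1e-9 & abs(tr$stage_y_um) < 1e-9, ]
  expect_equal(nx$px_x - ctr$px_x, layout$pitch / 1.7)
})

test_that("degenerate fields of view are refused", {
  expect_error(gen_grid_image(image_size = 16, pixel_size = 1.7),
               "degenerate FOV")
})

test_that("rendered crossing centers agree with truth when re-measured", {
  sc <- gen_grid_image(image_size = 384, seed = 4,
                       frame = frame_transform(angle_deg = 30,
                                               translation = c(40, -25)))
  tr <- sc$truth$crossings[sc$truth$crossings$inside_fov, ]
  bw_px <- 40 / 1.7
  for (k in seq_len(nrow(tr))) {
    cx <- tr$px_x[k]; cy <- tr$px_y[k]
    if (cx < 2 * bw_px || cy < 2 * bw_px ||
        cx > 384 - 2 * bw_px || cy > 384 - 2 * bw_px) next
    win <- round(1.2 * bw_px)
    ys <- (round(cy) - win):(round(cy) + win)
    xs <- (round(cx) - win):(round(cx) + win)
    w <- pmax(0.85 - sc$image[ys, xs], 0)  # darkness of the bar cross
    mx <- sum(w * outer(rep(1, length(ys)), xs)) / sum(w)
    my <- sum(w * outer(ys, rep(1, length(xs)))) / sum(w)
    expect_lt(sqrt((mx - cx)^2 + (my - cy)^2), 0.5)
  }
})

test_that("crossings covered by a crack are flagged occluded", {
  sc <- gen_grid_image(
    image_size = 384, style = "sem", frame = frame_transform(angle_deg = 45),
    defects = list(defect_crack(c(-200, -150), c(200, 150), width = 60,
                                seed = 2)),
    seed = 5)
  tr <- sc$truth$crossings
  hit <- tr[abs(tr$stage_x_um) < 1 & abs(tr$stage_y_um) < 1, ]
  expect_true(hit$occluded)
  far <- tr[tr$stage_x_um > 500, ]
  expect_false(any(far$occluded))
})

test_that("glyph images honour label, augmentation and seed contracts", {
  g <- gen_glyph_image("8Q", seed = 1)
  expect_equal(g$label, "8Q")
  expect_equal(dim(g$image), c(128, 128))
  expect_gt(sum(g$image > 0.5), 500)  # the text is actually rendered
  rot <- gen_glyph_image("8Q", augment = list(rotation_deg = 5), seed = 1)
  expect_equal(rot$label, "8Q")
  expect_false(identical(g$image, rot$image))
  # seed contract: a batch regenerates byte-identically
  aug <- list(rotation_deg = c(-6, 6), scale = c(0.9, 1.1),
              translate_px = c(-4, 4), noise_sd = 0.02)
  batch1 <- lapply(1:20, function(i) gen_glyph_image("3K", augment = aug,
                                                     seed = i)$image)
  batch2 <- lapply(1:20, function(i) gen_glyph_image("3K", augment = aug,
                                                     seed = i)$image)
  expect_identical(batch1, batch2)
  expect_error(gen_glyph_image("~!"), "unknown label")
})

test_that("trench scenes validate geometry and mark the center-nearest", {
  corners <- rbind(c(60, 90), c(200, 90), c(170, 170), c(90, 170))
  sc <- gen_trench_image(corners, seed = 1)
  expect_equal(sc$truth$corners[[1]], corners)
  bad <- rbind(c(60, 90), c(200, 90), c(90, 170), c(170, 170))  # crossed
  expect_error(gen_trench_image(bad, seed = 1), "non-convex")
  blank <- gen_trench_image(NULL, seed = 2)
  expect_equal(nrow(blank$truth), 0)
  expect_true(isTRUE(attr(blank$truth, "no_trench")))
  multi <- gen_trench_image(corners, n_extra = 2, seed = 5)
  expect_equal(nrow(multi$truth), 3)
  d <- sqrt((multi$truth$center_x - 128.5)^2 + (multi$truth$center_y - 128.5)^2)
  expect_equal(which(multi$truth$nearest_center), which.min(d))
})

test_that("drift stacks follow the requested schedule exactly", {
  st <- gen_drift_stack(10, drift_per_slice = c(0, 0.5), seed = 3)
  expect_equal(st$truth$dy_cum[10], 4.5)
  expect_equal(st$truth$dx_cum, rep(0, 10))
  # with zero blur and integer drift, slices are pure translations
  st2 <- gen_drift_stack(4, drift_per_slice = c(3, 2), blur_schedule = 0,
                         noise_sd = 0, seed = 4)
  a <- st2$stack[20:200, 20:200, 1]
  b <- st2$stack[(20 + 2):(200 + 2), (20 + 3):(200 + 3), 2]
  expect_lt(max(abs(a - b)), 1e-9)
  # textureless interior is uninformative below the coating band
  st3 <- gen_drift_stack(3, drift_per_slice = c(0, 1), style = "textureless",
                         noise_sd = 0, seed = 5)
  interior <- st3$stack[60:250, , 1]
  expect_lt(stats::sd(interior), 1e-9)
})

test_that("phenotype cells realize their archetype parameters", {
  fr <- gen_phenotype_cell("fragmented", strength = 0.6, seed = 7)
  k <- fr$truth$param
  lab <- clemtarget:::label_components(fr$gfp > 0.3)
  expect_equal(max(lab), k)
  dif <- gen_phenotype_cell("diffuse", strength = 1, seed = 8)
  v <- dif$gfp[dif$cytoplasm_mask & !dif$nucleus_mask]
  expect_lt(stats::sd(v) / mean(v), 0.25)  # near-uniform over the cytoplasm
  tub <- gen_phenotype_cell("tubular", strength = 0.8, seed = 9)
  expect_gte(tub$truth$param, 3)
  expect_equal(classify_cisterna_profile(tub$gfp > 0.4), "cisterna")
})

test_that("golgi volumes have analytic truth", {
  empty <- gen_golgi_volume(n_cisternae = 0)
  expect_equal(empty$truth$volume_um3, 0)
  expect_equal(sort(unique(as.vector(empty$volume))), 0L)
  gv <- gen_golgi_volume(n_cisternae = 4, radius_um = 1.5, voxel_size_um = 0.05)
  expect_equal(gv$truth$volume_um3, 4 / 3 * pi * 1.5^3)
  labs <- sort(unique(as.vector(gv$volume)))
  expect_true(all(c(0L, 1L, 2L, 3L, 4L, 5L) %in% labs))
  # voxelized stack volume approximates the analytic sphere
  vox <- sum(gv$volume >= 1) * 0.05^3
  expect_lt(abs(vox - gv$truth$volume_um3) / gv$truth$volume_um3, 0.05)
})
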