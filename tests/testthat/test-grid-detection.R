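test_that("lod_params validates its ranges", {
  expect_error(lod_params(k_neighbors = 0))
  expect_error(lod_params(canny_low = 0))
  expect_error(lod_params(angular_resolution = 7))
  expect_s3_class(lod_params(), "lod_params")
})

test_that("a single rendered line yields one dominant peak at its parameters", {
  W <- 320; ctr <- (W + 1) / 2
  ang <- 30; off <- -120
  nrm <- clemtarget:::line_normal(ang)
  xs <- outer(rep(1, W), seq_len(W)) - ctr
  ys <- outer(seq_len(W), rep(1, W)) - ctr
  d <- abs(xs * nrm[1] + ys * nrm[2] - off)
  img <- matrix(0.8 - 0.5 * pmax(0, pmin(1.5 - d, 1)), W, W)
  lines <- detect_lines(img)
  expect_lt(min(abs(lines$angle[1] - ang), 180 - abs(lines$angle[1] - ang)), 1.01)
  expect_lt(abs(abs(lines$offset[1]) - abs(off)), 2)
  # dominant: any other peak is far weaker
  if (nrow(lines) > 1) expect_gt(lines$score[1], 2 * lines$score[2])
})

test_that("constant images contain no lines", {
  expect_error(detect_lines(matrix(0.5, 256, 256)), "no lines found")
})

test_that("a 45-degree grid is detected at 45/135 with true edge offsets", {
  sc <- scene_45()
  lines <- detect_lines(sc$image)
  top <- lines[1:4, ]
  angs <- sort(unique(top$angle))
  expect_true(all(pmin(abs(top$angle - 45), abs(top$angle - 135)) <= 1))
  # bar centerlines pass through the image center: edges at +- bar_width/2
  expect_lt(max(abs(abs(top$offset) - (40 / 1.7) / 2)), 2)
})

test_that("detected angles are equivariant under scene rotation", {
  base <- gen_grid_image(image_size = 320, frame = frame_transform(angle_deg = 10),
                         seed = 21)
  rot <- gen_grid_image(image_size = 320, frame = frame_transform(angle_deg = 55),
                        seed = 21)
  a1 <- sort(unique(detect_lines(base$image)$angle[1:4]))
  a2 <- sort(unique(detect_lines(rot$image)$angle[1:4]))
  shifted <- sort((a1 + 45) %% 180)
  expect_true(all(pmin(abs(sort(a2) - shifted),
                       180 - abs(sort(a2) - shifted)) <= 1.01))
})

test_that("two perpendicular edge pairs intersect at the exact center", {
  layout <- grid_layout()
  bw_px <- layout$bar_width / 1.7
  x0 <- 5; y0 <- -7  # crossing center relative to image center
  lines <- tibble::tibble(
    angle = c(0, 0, 90, 90),
    offset = c(y0 - bw_px / 2, y0 + bw_px / 2, -x0 - bw_px / 2, -x0 + bw_px / 2),
    score = c(1, 1, 1, 1))
  class(lines) <- c("clem_lines", class(lines))
  attr(lines, "center") <- c(160.5, 160.5)
  cr <- find_crossings(lines, layout, 1.7)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$center_x, 160.5 + x0)
  expect_equal(cr$center_y, 160.5 + y0)
})

test_that("edge pairs violating the bar-width spacing yield no crossing", {
  layout <- grid_layout()
  bw_px <- layout$bar_width / 1.7
  lines <- tibble::tibble(
    angle = c(0, 0, 90, 90),
    offset = c(-bw_px * 0.75, bw_px * 0.75, -bw_px / 2, bw_px / 2),
    score = 1)
  class(lines) <- c("clem_lines", class(lines))
  attr(lines, "center") <- c(160.5, 160.5)
  cr <- find_crossings(lines, layout, 1.7)  # first family 50% off
  expect_equal(nrow(cr), 0)
  par <- lines; par$angle <- c(0, 0, 0, 0)
  cr2 <- find_crossings(par, layout, 1.7)   # all parallel
  expect_equal(nrow(cr2), 0)
})

test_that("every truth crossing in a full scene is matched within 2 px", {
  sc <- scene_45()
  lines <- detect_lines(sc$image, layout = grid_layout(), pixel_size = 1.7)
  cr <- find_crossings(lines, grid_layout(), 1.7)
  tr <- sc$truth$crossings[sc$truth$crossings$inside_fov, ]
  for (k in seq_len(nrow(tr))) {
    d <- min(sqrt((cr$center_x - tr$px_x[k])^2 + (cr$center_y - tr$px_y[k])^2))
    expect_lt(d, 2)
  }
})

test_that("refinement accepts clean crossings, corrects offsets, rejects occlusions", {
  layout <- grid_layout()
  sc <- scene_45()
  tr <- sc$truth$crossings[sc$truth$crossings$inside_fov, ]
  clean <- refine_crossing(sc$image,
                           list(center_x = tr$px_x[1], center_y = tr$px_y[1]),
                           layout = layout, pixel_size = 1.7)
  expect_equal(clean$status, "accepted")
  expect_lt(sqrt((clean$center_x - tr$px_x[1])^2 + (clean$center_y - tr$px_y[1])^2), 1)
  # candidate 3 px off truth is pulled back
  off <- refine_crossing(sc$image,
                         list(center_x = tr$px_x[1] + 2.1, center_y = tr$px_y[1] - 2.1),
                         layout = layout, pixel_size = 1.7)
  expect_equal(off$status, "accepted")
  expect_lt(sqrt((off$center_x - tr$px_x[1])^2 + (off$center_y - tr$px_y[1])^2), 1)
  # crossing occluded by a crack is rejected
  occ_sc <- gen_grid_image(layout = layout, frame = frame_transform(angle_deg = 45),
                           image_size = 384,
                           defects = list(defect_crack(c(-250, 30), c(250, -40),
                                                       width = 55, seed = 3)),
                           seed = 33)
  occ_tr <- occ_sc$truth$crossings[occ_sc$truth$crossings$inside_fov, ]
  expect_true(any(occ_tr$occluded))
  res <- refine_crossing(occ_sc$image,
                         list(center_x = occ_tr$px_x[1], center_y = occ_tr$px_y[1]),
                         layout = layout, pixel_size = 1.7)
  expect_equal(res$status, "rejected")
  # out-of-bounds crop
  oob <- refine_crossing(sc$image, list(center_x = 5, center_y = 5),
                         layout = layout, pixel_size = 1.7)
  expect_equal(oob$reason, "out_of_bounds")
})

test_that("no accepted crossing ever sits on occluded truth", {
  layout <- grid_layout()
  n_occluded <- 0L
  n_false_accept <- 0L
  for (i in c(2, 4)) {
    a2 <- (i * 29) %% 180
    d <- c(cos(a2 * pi / 180), sin(a2 * pi / 180)) * 250
    sc <- gen_grid_image(layout = layout, frame = frame_transform(angle_deg = 45),
                         image_size = 384,
                         defects = list(defect_crack(-d, d, width = 50, seed = i)),
                         seed = 60 + i)
    occ <- sc$truth$crossings[sc$truth$crossings$occluded, ]
    n_occluded <- n_occluded + nrow(occ)
    res <- tryCatch(detect_grid_crossings(sc$image, layout, 1.7),
                    error = function(e) NULL)
    if (is.null(res)) next
    acc <- res[res$status == "accepted", ]
    if (!nrow(acc) || !nrow(occ)) next
    dmin <- min(sqrt(outer(acc$center_x, occ$px_x, "-")^2 +
                       outer(acc$center_y, occ$px_y, "-")^2))
    if (dmin <= 40 / 1.7 / 2) n_false_accept <- n_false_accept + 1L
  }
  expect_gt(n_occluded, 0)          # the fixtures do occlude crossings
  expect_equal(n_false_accept, 0L)  # and none of them is ever accepted
})

test_that("glyph classification identifies labels and flags blanks", {
  model <- glyph_model_small()
  g <- gen_glyph_image("8Q", seed = 2)
  res <- classify_square_id(g$image, model)
  expect_equal(res$label, "8Q")
  expect_gte(res$confidence, 0.5)
  blank <- classify_square_id(matrix(0.02, 128, 128), model)
  expect_equal(blank$label, "unknown")
  # held-out accuracy on the small alphabet
  labs <- grid_labels(model$layout)$label
  aug <- list(rotation_deg = c(-6, 6), scale = c(0.85, 1.15),
              translate_px = c(-5, 5), intensity = c(0.7, 1), noise_sd = 0.02)
  set.seed(17)
  test_labs <- sample(labs, 60, replace = TRUE)
  hits <- vapply(seq_along(test_labs), function(i) {
    g <- gen_glyph_image(test_labs[i], augment = aug, seed = 500000 + i)
    classify_square_id(g$image, model)$label == test_labs[i]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("neighbour labels validate against lattice adjacency", {
  layout <- grid_layout()
  nb <- tibble::tibble(label = "1B", x_um = layout$pitch, y_um = 0)
  expect_equal(validate_neighbor_label("1A", nb, layout, position = c(0, 0)),
               "consistent")
  nb2 <- tibble::tibble(label = "1A", x_um = 0, y_um = 0)
  expect_equal(validate_neighbor_label("8B", nb2, layout,
                                       position = c(layout$pitch, 0)),
               "inconsistent")
  expect_equal(validate_neighbor_label("1A", tibble::tibble(), layout),
               "consistent")
})

test_that("sem edge probability separates bar edges from background and scratches", {
  layout <- grid_layout()
  sc <- gen_grid_image(layout = layout, frame = frame_transform(angle_deg = 45),
                       image_size = 384, style = "sem", noise_sd = 0.03, seed = 11)
  truth <- scene_edge_mask(sc)
  for (backend in c("classical", "model")) {
    p <- suppressWarnings(sem_edge_probability(sc$image, backend))
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(mean(p[truth]) - mean(p[!truth]), 0.3)
  }
  flat <- sem_edge_probability(matrix(0.5, 256, 256), "classical")
  expect_lt(max(flat), 0.05)
  # short scratch parallel to a bar scores below true bar edges
  u <- c(1, 1) / sqrt(2)
  sc2 <- gen_grid_image(layout = layout, frame = frame_transform(angle_deg = 45),
                        image_size = 384, style = "sem",
                        defects = list(defect_scratch(100 * u - 20 * u,
                                                      100 * u + 20 * u, width = 5)),
                        seed = 12)
  p2 <- sem_edge_probability(sc2$image, "classical")
  W <- 384; cx <- (W + 1) / 2
  sx <- outer(rep(1, W), seq_len(W) - cx) * 1.7
  sy <- outer(seq_len(W) - cx, rep(1, W)) * 1.7
  poly <- sc2$truth$defects[[1]]$polygon
  scr <- matrix(clemtarget:::points_in_polygon(as.vector(sx), as.vector(sy),
                                              poly[, 1], poly[, 2]), W, W)
  edges2 <- scene_edge_mask(sc2)
  expect_lt(mean(p2[scr]), mean(p2[edges2 & !scr]))
})

test_that("landmark maps sample, refine, block failures and stay deterministic", {
  layout <- grid_layout(rows = 9, cols = 11)
  fr <- frame_transform(angle_deg = 45, flip = TRUE, translation = c(120, -80))
  src <- function(stage_xy) {
    gen_grid_image(layout = layout, frame = fr, pixel_size = 1.7,
                   image_size = 128, style = "sem", stage_center = stage_xy,
                   seed = as.integer(sum(round(abs(stage_xy))) %% 100000))$image
  }
  map <- build_landmark_map(src, layout, fr, sampling_fraction = 0.30,
                            min_landmarks = 20, pixel_size = 1.7,
                            frame_label = "EM", seed = 7)
  expect_gte(nrow(map), 30)                      # >= 30% of 99 attempted
  expect_gte(sum(map$status == "valid"), 20)
  expect_false(anyDuplicated(map[, c("label", "frame")]) > 0)
  # stage accuracy against the simulated frame
  labs <- grid_labels(layout)
  valid <- dplyr::inner_join(map[map$status == "valid", ], labs, by = "label")
  truth <- clemtarget:::apply_frame(fr, cbind(valid$x_um, valid$y_um))
  err <- sqrt((valid$stage_x_um - truth[, 1])^2 + (valid$stage_y_um - truth[, 2])^2)
  expect_lt(max(err), 1.7)  # within one pixel in stage units
  map2 <- build_landmark_map(src, layout, fr, sampling_fraction = 0.30,
                             min_landmarks = 20, pixel_size = 1.7,
                             frame_label = "EM", seed = 7)
  expect_identical(map$label, map2$label)        # identical visit order
})

test_that("landmark maps block occluded crossings but still complete", {
  layout <- grid_layout(rows = 5, cols = 5)
  fr <- frame_transform()
  defect <- defect_dirt(c(layout$pitch, layout$pitch), radius = 70, seed = 2)
  src <- function(stage_xy) {
    gen_grid_image(layout = layout, frame = fr, pixel_size = 1.7,
                   image_size = 128, stage_center = stage_xy,
                   defects = list(defect),
                   seed = as.integer(sum(round(abs(stage_xy))) %% 100000))$image
  }
  map <- build_landmark_map(src, layout, fr, sampling_fraction = 0.9,
                            min_landmarks = 10, pixel_size = 1.7, seed = 3)
  expect_gte(sum(map$status == "valid"), 10)
  blocked <- map[map$status == "blocked", ]
  if (nrow(blocked)) {
    d <- sqrt((blocked$stage_x_um - layout$pitch)^2 +
                (blocked$stage_y_um - layout$pitch)^2)
    expect_lt(min(d), 120)  # the blocked landmark is the occluded one
  }
})
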