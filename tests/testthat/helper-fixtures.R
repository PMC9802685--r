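# Shared fixtures: cached small models and frequently used scenes.

.test_cache <- new.env(parent = emptyenv())

# Small-alphabet glyph classifier, trained once per test run.
glyph_model_small <- function() {
  if (is.null(.test_cache$glyph_small)) {
    layout <- grid_layout(rows = 2, cols = 2,
                          row_labels = c("7", "8"), col_labels = c("P", "Q"))
    .test_cache$glyph_small <- train_glyph_classifier(layout, n_per_label = 14,
                                                      seed = 3)
  }
  .test_cache$glyph_small
}

# One clean reflected-light scene at 45 degrees with its central crossing.
scene_45 <- function() {
  if (is.null(.test_cache$scene45)) {
    .test_cache$scene45 <- gen_grid_image(
      layout = grid_layout(), frame = frame_transform(angle_deg = 45),
      image_size = 384, seed = 1)
  }
  .test_cache$scene45
}

# Standard phenotype feature config used in tests (coarser angle sweep keeps
# the line-opening sweep quick; the orientation statistics are unchanged).
test_feature_config <- function() feature_config(angle_step_deg = 15)

expect_scene_match <- function(detections, scene, tol_px) {
  acc <- detections[detections$status == "accepted", ]
  tr <- scene$truth$crossings
  for (k in seq_len(nrow(acc))) {
    d <- min(sqrt((tr$px_x - acc$center_x[k])^2 + (tr$px_y - acc$center_y[k])^2))
    expect_lt(d, tol_px)
  }
  invisible(acc)
}
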