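# 5x7 bitmap glyph font for the digit+letter square identifiers.
# A plain sans-serif raster is all the generator needs: glyphs must be unique
# and legible to the classifier, not typographically faithful.

.font5x7 <- local({
  def <- list(
    "0" = c(" ### ", "#   #", "#  ##", "# # #", "##  #", "#   #", " ### "),
    "1" = c("  #  ", " ##  ", "  #  ", "  #  ", "  #  ", "  #  ", " ### "),
    "2" = c(" ### ", "#   #", "    #", "   # ", "  #  ", " #   ", "#####"),
    "3" = c(" ### ", "#   #", "    #", "  ## ", "    #", "#   #", " ### "),
    "4" = c("   # ", "  ## ", " # # ", "#  # ", "#####", "   # ", "   # "),
    "5" = c("#####", "#    ", "#### ", "    #", "    #", "#   #", " ### "),
    "6" = c(" ### ", "#    ", "#    ", "#### ", "#   #", "#   #", " ### "),
    "7" = c("#####", "    #", "   # ", "  #  ", "  #  ", "  #  ", "  #  "),
    "8" = c(" ### ", "#   #", "#   #", " ### ", "#   #", "#   #", " ### "),
    "9" = c(" ### ", "#   #", "#   #", " ####", "    #", "    #", " ### "),
    "A" = c(" ### ", "#   #", "#   #", "#####", "#   #", "#   #", "#   #"),
    "B" = c("#### ", "#   #", "#   #", "#### ", "#   #", "#   #", "#### "),
    "C" = c(" ### ", "#   #", "#    ", "#    ", "#    ", "#   #", " ### "),
    "D" = c("#### ", "#   #", "#   #", "#   #", "#   #", "#   #", "#### "),
    "E" = c("#####", "#    ", "#    ", "#### ", "#    ", "#    ", "#####"),
    "F" = c("#####", "#    ", "#    ", "#### ", "#    ", "#    ", "#    "),
    "G" = c(" ### ", "#   #", "#    ", "# ###", "#   #", "#   #", " ### "),
    "H" = c("#   #", "#   #", "#   #", "#####", "#   #", "#   #", "#   #"),
    "I" = c(" ### ", "  #  ", "  #  ", "  #  ", "  #  ", "  #  ", " ### "),
    "J" = c("  ###", "   # ", "   # ", "   # ", "   # ", "#  # ", " ##  "),
    "K" = c("#   #", "#  # ", "# #  ", "##   ", "# #  ", "#  # ", "#   #"),
    "L" = c("#    ", "#    ", "#    ", "#    ", "#    ", "#    ", "#####"),
    "M" = c("#   #", "## ##", "# # #", "# # #", "#   #", "#   #", "#   #"),
    "N" = c("#   #", "##  #", "# # #", "#  ##", "#   #", "#   #", "#   #"),
    "O" = c(" ### ", "#   #", "#   #", "#   #", "#   #", "#   #", " ### "),
    "P" = c("#### ", "#   #", "#   #", "#### ", "#    ", "#    ", "#    "),
    "Q" = c(" ### ", "#   #", "#   #", "#   #", "# # #", "#  # ", " ## #"),
    "R" = c("#### ", "#   #", "#   #", "#### ", "# #  ", "#  # ", "#   #"),
    "S" = c(" ####", "#    ", "#    ", " ### ", "    #", "    #", "#### "),
    "T" = c("#####", "  #  ", "  #  ", "  #  ", "  #  ", "  #  ", "  #  "),
    "U" = c("#   #", "#   #", "#   #", "#   #", "#   #", "#   #", " ### "),
    "V" = c("#   #", "#   #", "#   #", "#   #", "#   #", " # # ", "  #  "),
    "W" = c("#   #", "#   #", "#   #", "# # #", "# # #", "## ##", "#   #"),
    "X" = c("#   #", "#   #", " # # ", "  #  ", " # # ", "#   #", "#   #"),
    "Y" = c("#   #", "#   #", " # # ", "  #  ", "  #  ", "  #  ", "  #  "),
    "Z" = c("#####", "    #", "   # ", "  #  ", " #   ", "#    ", "#####")
  )
  lapply(def, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
    storage.mode(m) <- "double"
    m
  })
})

# Rasterize a character string (side-by-side glyphs) into a binary matrix of
# the requested pixel height; width follows from the 5x7 aspect.
render_text_raster <- function(text, height_px, spacing_frac = 0.25) {
  chars <- strsplit(text, "")[[1]]
  bitmaps <- lapply(chars, function(ch) {
    bm <- .font5x7[[ch]]
    if (is.null(bm)) rlang::abort(sprintf("no glyph for character '%s'", ch))
    bm
  })
  cell_h <- 7L; cell_w <- 5L
  sp <- max(1L, round(cell_w * spacing_frac))
  total_w <- length(chars) * cell_w + (length(chars) - 1L) * sp
  canvas <- matrix(0, cell_h, total_w)
  x <- 1L
  for (bm in bitmaps) {
    canvas[, x:(x + cell_w - 1L)] <- bm
    x <- x + cell_w + sp
  }
  scale <- height_px / cell_h
  out_h <- as.integer(round(cell_h * scale))
  out_w <- as.integer(round(total_w * scale))
  resize_nn(canvas, out_h, out_w)
}
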