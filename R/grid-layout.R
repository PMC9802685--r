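#' Gridded-substrate layout
#'
#' Geometry of the alphanumeric grid imprinted on gridded glass-bottom culture
#' dishes: a square lattice of bars of width `bar_width` enclosing squares of
#' side `square_size` (pitch = `square_size + bar_width`), each square carrying
#' a unique digit+letter identifier (e.g. `"8Q"`). The layout is shared by the
#' synthetic generators and the detectors so that ground truth and detection
#' speak the same coordinate language.
#'
#' Grid coordinates are in micrometres with bar centerlines at integer
#' multiples of the pitch; the crossing named after square `(row, col)` is the
#' square's top-left bar crossing, at `((col-1)*pitch, (row-1)*pitch)`.
#'
#' @param square_size Side of the open square, in micrometres.
#' @param bar_width Width of the grid bars, in micrometres.
#' @param rows,cols Number of labelled squares in each direction.
#' @param row_labels,col_labels Ordered label alphabets; defaults are digits
#'   `1..9` for rows and `A..Z` for columns, composed as `"8Q"`.
#' @return An object of class `grid_layout`.
#' @examples
#' layout <- grid_layout()
#' layout$pitch
#' head(grid_labels(layout))
#' @export
grid_layout <- function(square_size = 560, bar_width = 40,
                        rows = 9, cols = 20,
                        row_labels = as.character(1:9),
                        col_labels = LETTERS) {
  stopifnot(square_size > 0, bar_width > 0, rows >= 1, cols >= 1)
  if (rows > length(row_labels) || cols > length(col_labels)) {
    rlang::abort("layout alphabet too small for requested rows/cols")
  }
  structure(
    list(square_size = square_size, bar_width = bar_width,
         pitch = square_size + bar_width,
         rows = as.integer(rows), cols = as.integer(cols),
         row_labels = row_labels[seq_len(rows)],
         col_labels = col_labels[seq_len(cols)]),
    class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout> %g um squares, %g um bars (pitch %g um), %d x %d squares\n",
              x$square_size, x$bar_width, x$pitch, x$rows, x$cols))
  invisible(x)
}

#' Square labels and crossing positions of a layout
#'
#' One row per labelled square; `x_um`/`y_um` give the grid-frame position of
#' the square's top-left bar crossing (the landmark named after the square).
#'
#' @param layout A [grid_layout()].
#' @return A tibble with columns `label`, `row`, `col`, `x_um`, `y_um`.
#' @export
grid_labels <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  g <- expand.grid(row = seq_len(layout$rows), col = seq_len(layout$cols))
  tibble::tibble(
    label = paste0(layout$row_labels[g$row], layout$col_labels[g$col]),
    row = g$row, col = g$col,
    x_um = (g$col - 1) * layout$pitch,
    y_um = (g$row - 1) * layout$pitch)
}

#' Split a square label into lattice indices
#'
#' @param label Character vector of square labels (e.g. `"8Q"`).
#' @param layout A [grid_layout()].
#' @return A tibble with columns `label`, `row`, `col` (NA when not in the
#'   layout alphabet).
#' @export
label_indices <- function(label, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  r <- match(substr(label, 1, 1), layout$row_labels)
  c <- match(substr(label, 2, 2), layout$col_labels)
  tibble::tibble(label = label, row = r, col = c)
}

#' Frame transform between grid and stage coordinates
#'
#' A 2-D affine map `stage = A %*% grid + t` (micrometres to micrometres),
#' optionally including a reflection (as produced by imaging the imprinted
#' pattern from the opposite side after coverslip removal).
#'
#' @param angle_deg Rotation angle, degrees.
#' @param scale Isotropic scale factor (or length-2 for anisotropic).
#' @param flip If `TRUE`, mirror the x axis before rotating (det < 0).
#' @param translation Length-2 translation in micrometres.
#' @param matrix Optionally, a full 2x2 linear part overriding
#'   angle/scale/flip.
#' @return An object of class `frame_transform` with elements `A` (2x2) and
#'   `t` (length 2).
#' @export
frame_transform <- function(angle_deg = 0, scale = 1, flip = FALSE,
                            translation = c(0, 0), matrix = NULL) {
  if (is.null(matrix)) {
    th <- angle_deg * pi / 180
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    S <- diag(rep(scale, length.out = 2))
    F <- diag(c(if (flip) -1 else 1, 1))
    A <- R %*% S %*% F
  } else {
    A <- base::matrix(as.numeric(matrix), 2, 2)
  }
  if (abs(det(A)) < 1e-12) rlang::abort("frame transform linear part is singular")
  structure(list(A = A, t = as.numeric(translation)), class = "frame_transform")
}

apply_frame <- function(frame, xy) {
  # xy: n x 2 matrix of grid coords -> stage coords
  xy <- rbind_matrix(xy)
  sweep(xy %*% t(frame$A), 2, -frame$t)
}

invert_frame <- function(frame, xy) {
  xy <- rbind_matrix(xy)
  sweep(xy, 2, frame$t) %*% t(solve(frame$A))
}

rbind_matrix <- function(xy) {
  if (is.null(dim(xy))) matrix(xy, ncol = 2) else as.matrix(xy)
}

#' Lattice adjacency check for square labels
#'
#' Validates a freshly classified square label against already accepted
#' neighbouring landmarks: a label is consistent when, for every neighbour,
#' the difference of lattice indices implied by the two labels matches the
#' difference of their positions on the lattice (e.g. `"1A"` can sit next to
#' `"1B"`, but not next to `"8B"`).
#'
#' @param label Candidate square label.
#' @param neighbors A tibble of accepted landmarks with columns `label` and
#'   grid positions `x_um`, `y_um` (grid frame), or `row`/`col` indices.
#' @param layout A [grid_layout()].
#' @param position Optional `c(x_um, y_um)` grid-frame position of the
#'   candidate; when neighbours carry positions the index offset implied by
#'   geometry is compared against the label offset.
#' @param tolerance Index tolerance (lattice units) for the geometric check.
#' @return `"consistent"` or `"inconsistent"`. An empty neighbour set is
#'   vacuously consistent.
#' @export
validate_neighbor_label <- function(label, neighbors, layout,
                                    position = NULL, tolerance = 0.25) {
  stopifnot(inherits(layout, "grid_layout"))
  if (is.null(neighbors) || !nrow(neighbors)) return("consistent")
  idx <- label_indices(label, layout)
  if (is.na(idx$row) || is.na(idx$col)) return("inconsistent")
  nidx <- label_indices(neighbors$label, layout)
  if (anyNA(nidx$row) || anyNA(nidx$col)) return("inconsistent")
  if (!is.null(position) && all(c("x_um", "y_um") %in% names(neighbors))) {
    dcol <- (position[1] - neighbors$x_um) / layout$pitch
    drow <- (position[2] - neighbors$y_um) / layout$pitch
    ok <- abs((idx$col - nidx$col) - dcol) <= tolerance &
      abs((idx$row - nidx$row) - drow) <= tolerance
    if (all(ok)) "consistent" else "inconsistent"
  } else {
    # Without geometry, require plain lattice adjacency (chebyshev distance
    # <= 1) to every accepted neighbour.
    ok <- pmax(abs(idx$row - nidx$row), abs(idx$col - nidx$col)) <= 1
    if (all(ok)) "consistent" else "inconsistent"
  }
}
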