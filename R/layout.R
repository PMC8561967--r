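#' Superpool layout: plates in a grid, row pools and column pools
#'
#' In clone-array pooled shotgun sequencing (CAPSS) the 384-well plates of a
#' BAC library are arranged in a two-dimensional grid (the superpool). Every
#' physical row of wells across the plate-grid row is pooled into one "row
#' pool" and every physical column across the plate-grid column into one
#' "column pool"; each well then lies at the intersection of exactly one row
#' pool and one column pool, which is what lets a sequence shared by one row
#' pool and one column pool be assigned back to a single well.
#'
#' The shipped default is the 24-plate configuration (6 plate-grid rows by 4
#' plate-grid columns of 16 x 24-well plates), giving 96 row pools, 96 column
#' pools (192 secondary pools) and 9216 wells, but any dimensions are
#' accepted so tiny superpools can be exercised in tests.
#'
#' @param plate_grid_rows,plate_grid_cols plate-grid dimensions.
#' @param well_rows,well_cols wells per plate (rows x columns).
#' @param plate_ids plate labels, row-major across the plate grid; defaults
#'   to `"P1"..` in order.
#' @return an object of class `superpool_layout` with derived counts
#'   `n_plates`, `n_row_pools`, `n_col_pools`, `n_wells`.
#' @examples
#' build_layout()            # the 24-plate, 9216-well default
#' build_layout(2, 2, 4, 6)  # a 96-well toy superpool
#' @export
build_layout <- function(plate_grid_rows = 6L, plate_grid_cols = 4L,
                         well_rows = 16L, well_cols = 24L,
                         plate_ids = NULL) {
  dims <- c(plate_grid_rows, plate_grid_cols, well_rows, well_cols)
  if (any(dims < 1L) || any(dims != as.integer(dims)))
    stop("layout dimensions must be positive integers")
  plate_grid_rows <- as.integer(plate_grid_rows)
  plate_grid_cols <- as.integer(plate_grid_cols)
  well_rows <- as.integer(well_rows)
  well_cols <- as.integer(well_cols)
  n_plates <- plate_grid_rows * plate_grid_cols
  if (is.null(plate_ids)) plate_ids <- paste0("P", seq_len(n_plates))
  if (length(plate_ids) != n_plates)
    stop("plate_ids must have length plate_grid_rows * plate_grid_cols (",
         n_plates, "), got ", length(plate_ids))
  structure(list(
    plate_grid_rows = as.integer(plate_grid_rows),
    plate_grid_cols = as.integer(plate_grid_cols),
    well_rows = as.integer(well_rows),
    well_cols = as.integer(well_cols),
    plate_ids = as.character(plate_ids),
    n_plates = n_plates,
    n_row_pools = plate_grid_rows * well_rows,
    n_col_pools = plate_grid_cols * well_cols,
    n_wells = n_plates * well_rows * well_cols
  ), class = "superpool_layout")
}

#' @export
print.superpool_layout <- function(x, ...) {
  cat("Superpool layout: ", x$n_plates, " plates (",
      x$plate_grid_rows, "x", x$plate_grid_cols, " grid) of ",
      x$well_rows, "x", x$well_cols, " wells\n",
      "  ", x$n_row_pools, " row pools + ", x$n_col_pools,
      " column pools = ", x$n_row_pools + x$n_col_pools,
      " secondary pools; ", x$n_wells, " wells\n", sep = "")
  invisible(x)
}

#' Construct a well address
#'
#' All internal coordinates are 0-based: `plate` indexes `plate_ids`
#' row-major over the plate grid, `row`/`col` index wells within the plate.
#'
#' @param plate,row,col 0-based indices (vectorised).
#' @return a `data.frame` with columns `plate`, `row`, `col`.
#' @export
well_address <- function(plate, row, col) {
  data.frame(plate = as.integer(plate), row = as.integer(row),
             col = as.integer(col))
}

check_wells <- function(layout, wells) {
  bad <- wells$plate < 0L | wells$plate >= layout$n_plates |
    wells$row < 0L | wells$row >= layout$well_rows |
    wells$col < 0L | wells$col >= layout$well_cols
  if (any(bad)) stop("well address out of range for layout")
  invisible(wells)
}

#' Row pool and column pool containing a well
#'
#' The row-pool index is `plate_grid_row * well_rows + row` and the
#' column-pool index is `plate_grid_col * well_cols + col`, where the plate's
#' grid coordinates come from its row-major position in the plate grid.
#' Inverse of [well_at_intersection()].
#'
#' @param layout a [build_layout()] object.
#' @param wells a well-address data.frame (vectorised).
#' @return a `data.frame` with columns `row_pool`, `col_pool` (0-based).
#' @export
pools_for_well <- function(layout, wells) {
  check_wells(layout, wells)
  grid_row <- wells$plate %/% layout$plate_grid_cols
  grid_col <- wells$plate %% layout$plate_grid_cols
  data.frame(row_pool = grid_row * layout$well_rows + wells$row,
             col_pool = grid_col * layout$well_cols + wells$col)
}

#' The unique well at the intersection of a row pool and a column pool
#'
#' @param layout a [build_layout()] object.
#' @param row_pool,col_pool 0-based pool indices (vectorised).
#' @return a well-address `data.frame`; inverse of [pools_for_well()].
#' @export
well_at_intersection <- function(layout, row_pool, col_pool) {
  row_pool <- as.integer(row_pool); col_pool <- as.integer(col_pool)
  if (any(row_pool < 0L) || any(row_pool >= layout$n_row_pools) ||
      any(col_pool < 0L) || any(col_pool >= layout$n_col_pools))
    stop("pool index out of range for layout")
  grid_row <- row_pool %/% layout$well_rows
  grid_col <- col_pool %/% layout$well_cols
  well_address(plate = grid_row * layout$plate_grid_cols + grid_col,
               row = row_pool %% layout$well_rows,
               col = col_pool %% layout$well_cols)
}

#' All wells belonging to one secondary pool
#'
#' A row pool spans one well row across every plate in its plate-grid row
#' (`well_cols * plate_grid_cols` wells); a column pool spans one well column
#' across every plate in its plate-grid column (`well_rows * plate_grid_rows`
#' wells). In the 24-plate default both sizes are 96.
#'
#' @param layout a [build_layout()] object.
#' @param axis `"ROW"` or `"COL"`.
#' @param index 0-based pool index.
#' @return a well-address `data.frame`.
#' @export
member_wells <- function(layout, axis, index) {
  axis <- match.arg(axis, c("ROW", "COL"))
  index <- as.integer(index)
  if (axis == "ROW") {
    if (index < 0L || index >= layout$n_row_pools) stop("row pool out of range")
    grid_row <- index %/% layout$well_rows
    plates <- grid_row * layout$plate_grid_cols + seq_len(layout$plate_grid_cols) - 1L
    well_address(plate = rep(plates, each = layout$well_cols),
                 row = index %% layout$well_rows,
                 col = rep(seq_len(layout$well_cols) - 1L, length(plates)))
  } else {
    if (index < 0L || index >= layout$n_col_pools) stop("column pool out of range")
    grid_col <- index %/% layout$well_cols
    plates <- (seq_len(layout$plate_grid_rows) - 1L) * layout$plate_grid_cols + grid_col
    well_address(plate = rep(plates, each = layout$well_rows),
                 row = rep(seq_len(layout$well_rows) - 1L, length(plates)),
                 col = index %% layout$well_cols)
  }
}

#' Every well of a layout
#'
#' @param layout a [build_layout()] object.
#' @return a well-address `data.frame` with one row per well, in
#'   (plate, row, col) lexicographic order.
#' @export
all_wells <- function(layout) {
  g <- expand.grid(col = seq_len(layout$well_cols) - 1L,
                   row = seq_len(layout$well_rows) - 1L,
                   plate = seq_len(layout$n_plates) - 1L)
  well_address(g$plate, g$row, g$col)
}

#' Human-readable well labels
#'
#' Formats addresses the way BAC plates are labelled: plate number, then the
#' well row as a letter run (`A`..) and the 1-based column, e.g. plate 4 row
#' G column 16 prints as `4G16`. Internal indices stay 0-based; letters and
#' 1-based numbers exist only at this presentation surface.
#'
#' @param layout a [build_layout()] object.
#' @param wells a well-address data.frame.
#' @return character vector of labels.
#' @export
well_label <- function(layout, wells) {
  check_wells(layout, wells)
  row_letters <- if (layout$well_rows <= 26L) LETTERS[wells$row + 1L] else
    paste0(LETTERS[wells$row %/% 26L + 1L], LETTERS[wells$row %% 26L + 1L])
  paste0(wells$plate + 1L, row_letters, wells$col + 1L)
}

## Compact scalar key for a well (used as a map key in assignment tables).
well_key <- function(wells) paste(wells$plate, wells$row, wells$col, sep = ":")
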