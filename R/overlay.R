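#' Map test points to thickness grid cells
#'
#' Inverse-rotates each point by the grid rotation about the grid centre,
#' then bins the unrotated coordinates into the uniform
#' `n_rows` x `n_cols` partition of the scan area. For points produced by
#' [generate_pp_grid()] the result equals the point's own `(row, col)`.
#'
#' Tie-break convention: a point lying exactly on an interior cell boundary
#' belongs to the lower-indexed column (and lower-indexed row); the outer
#' edges of the scan area belong to the nearest cell. Points outside the
#' scan area are flagged (`in_area = FALSE`), never silently clamped.
#'
#' @param points A data.frame with rotated coordinates `x`, `y` (degrees),
#'   e.g. a grid from [generate_pp_grid()].
#' @param spec The [grid_spec()] describing the thickness grid.
#' @return A data.frame with columns `row`, `col`, `in_area`.
#' @export
#' @examples
#' g <- generate_pp_grid()
#' all(point_to_cell(g)$row == g$row)  # TRUE
point_to_cell <- function(points, spec = grid_spec()) {
  stopifnot(inherits(spec, "pp_grid_spec"))
  rel <- rotate_point(cbind(points$x - spec$center[1],
                            points$y - spec$center[2]), -spec$rotation)
  x0 <- rel[, 1]; y0 <- rel[, 2]
  cw <- spec$width / spec$n_cols
  ch <- spec$height / spec$n_rows
  hw <- spec$width / 2; hh <- spec$height / 2
  tol <- 1e-9
  in_area <- x0 >= -hw - tol & x0 <= hw + tol &
             y0 >= -hh - tol & y0 <= hh + tol
  # (low, high] cells: exact interior boundaries go to the lower index.
  col <- ceiling((x0 + hw) / cw - tol)
  row <- ceiling((hh - y0) / ch - tol)
  col <- pmin(pmax(col, 1L), spec$n_cols)
  row <- pmin(pmax(row, 1L), spec$n_rows)
  col[!in_area] <- NA_integer_
  row[!in_area] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             in_area = in_area)
}

#' Superimpose a sensitivity map onto layer-thickness grids
#'
#' Produces the combined morpho-functional map: each of the 64 sensitivity
#' test points is assigned to its thickness grid cell via [point_to_cell()],
#' and the requested layer thicknesses of that cell are attached to the
#' point. The pairing must be bijective (a permutation of the 64 cells);
#' colliding or out-of-area points raise an error listing the offending
#' point ids. No value is altered, and the output is ordered by point id.
#'
#' Both inputs must be laterality-normalized to the same (right-eye)
#' orientation; use [normalize_laterality()] first for left eyes.
#'
#' @param thickness_maps A named list of length-64 numeric vectors (one per
#'   layer, cell-id order: `(row - 1) * n_cols + col`), or a 64 x n_layers
#'   matrix with column names.
#' @param sensitivity_map A length-64 vector of point sensitivities (dB) in
#'   point-id order.
#' @param points The grid data.frame of the sensitivity pattern.
#' @param spec The [grid_spec()] of the thickness grid.
#' @param layers Which layers to attach (default: all supplied).
#' @return A data.frame of class `pp_combined_map` with columns `point_id`,
#'   `row`, `col`, `x_deg`, `y_deg`, `quadrant`, `sensitivity_db`, and one
#'   `<layer>_um` column per layer.
#' @export
#' @examples
#' g <- generate_pp_grid()
#' m <- overlay(list(GCL = rep(30, 64)), rep(20, 64), g)
#' head(m)
overlay <- function(thickness_maps, sensitivity_map, points,
                    spec = grid_spec(), layers = NULL) {
  if (is.matrix(thickness_maps))
    thickness_maps <- as.list(as.data.frame(thickness_maps))
  if (is.null(layers)) layers <- names(thickness_maps)
  if (is.null(layers) || !length(layers) || is.null(names(thickness_maps)))
    stop("thickness_maps must be a named list of layer vectors")
  missing_l <- setdiff(layers, names(thickness_maps))
  if (length(missing_l))
    stop("layers not present in thickness_maps: ",
         paste(missing_l, collapse = ", "))
  n_cells <- spec$n_rows * spec$n_cols
  if (length(sensitivity_map) != n_cells)
    stop("sensitivity_map must have ", n_cells, " entries")
  for (l in layers)
    if (length(thickness_maps[[l]]) != n_cells)
      stop("thickness map for layer ", l, " must have ", n_cells, " entries")
  if (nrow(points) != n_cells)
    stop("points must have ", n_cells, " rows")

  cells <- point_to_cell(points, spec)
  if (any(!cells$in_area))
    stop("points outside the scan area: id ",
         paste(points$id[!cells$in_area], collapse = ", "))
  cell_id <- (cells$row - 1L) * spec$n_cols + cells$col
  if (anyDuplicated(cell_id)) {
    dup <- cell_id[duplicated(cell_id)]
    stop("degenerate geometry: points mapping to the same cell, ids ",
         paste(points$id[cell_id %in% dup], collapse = ", "))
  }
  out <- data.frame(
    point_id = points$id,
    row = cells$row, col = cells$col,
    x_deg = points$x, y_deg = points$y,
    quadrant = if ("quadrant" %in% names(points)) points$quadrant else
      assign_quadrant(data.frame(row = cells$row, col = cells$col),
                      spec)$quadrant,
    sensitivity_db = sensitivity_map,
    stringsAsFactors = FALSE
  )
  for (l in layers)
    out[[paste0(l, "_um")]] <- thickness_maps[[l]][cell_id]
  out <- out[order(out$point_id), ]
  rownames(out) <- NULL
  class(out) <- c("pp_combined_map", "data.frame")
  out
}

#' Combined morpho-functional map of one simulated eye
#'
#' Convenience wrapper: extracts one eye's sensitivity map and layer maps
#' from a cohort and overlays them.
#'
#' @param cohort A `pp_cohort`.
#' @param eye_index Row index into `cohort$eyes`.
#' @param layers Layer names to attach (default `c("Retina", "GCL")`, the
#'   two layers shown on the published combination maps).
#' @return A `pp_combined_map` data.frame.
#' @export
combined_map <- function(cohort, eye_index, layers = c("Retina", "GCL")) {
  stopifnot(inherits(cohort, "pp_cohort"))
  if (eye_index < 1 || eye_index > nrow(cohort$eyes))
    stop("eye_index out of range")
  tm <- lapply(layers, function(l) {
    li <- match(l, dimnames(cohort$thickness)[[2]])
    if (is.na(li)) stop("unknown layer: ", l)
    cohort$thickness[eye_index, li, ]
  })
  names(tm) <- layers
  overlay(tm, cohort$sensitivity[eye_index, ], cohort$grid,
          cohort$grid_spec, layers)
}

#' Write or read a combined map CSV
#'
#' @param map A `pp_combined_map`.
#' @param file Path to a CSV file.
#' @return `read_map_csv` returns the map data.frame. Files written with a
#'   decimal comma (European convention, semicolon-separated) are
#'   normalized on ingest.
#' @export
write_map_csv <- function(map, file) {
  utils::write.csv(map, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(file) {
  df <- read_numeric_csv(
    file, non_numeric_cols = c("quadrant", "vertical", "horizontal"))
  need <- c("point_id", "sensitivity_db")
  if (!all(need %in% names(df)))
    stop("map CSV must contain columns: ", paste(need, collapse = ", "))
  df
}

#' Render an 8 x 8 numeric map
#'
#' Draws a posterior-pole map in the layout of the device printouts: a
#' colour-coded 8 x 8 grid with the cell values printed, row 1 (superior)
#' on top and column 1 (nasal) on the left.
#'
#' @param values A length-64 vector in row-major point-id order, or an
#'   8 x 8 matrix.
#' @param main Plot title.
#' @param digits Digits for the printed values.
#' @return Invisibly, the plotted matrix.
#' @export
plot_pp_map <- function(values, main = "", digits = 0) {
  m <- if (is.matrix(values)) values else matrix(values, 8, 8, byrow = TRUE)
  # image() draws row 1 at the bottom; flip so superior is on top
  graphics::image(1:8, 1:8, t(m[8:1, ]), axes = FALSE, xlab = "N <- -> T",
                  ylab = "I <- -> S", main = main,
                  col = grDevices::hcl.colors(64, "viridis"))
  for (r in 1:8) for (cc in 1:8)
    graphics::text(cc, 9 - r, format(round(m[r, cc], digits), nsmall = digits),
                   cex = 0.7, col = "white")
  invisible(m)
}
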