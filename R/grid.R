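#' Posterior-pole grid specification
#'
#' Describes the geometry of the posterior-pole test pattern: an
#' `n_rows` x `n_cols` partition of a `width` x `height` degree scan area
#' centred on the fovea, rotated by the fovea-to-disc inclination.
#' Defaults give the standard 8 x 8 grid over 30 x 25 degrees with a
#' 7 degree rotation.
#'
#' Coordinate convention: degrees of visual angle, fovea at the origin,
#' x positive temporal and y positive superior in right-eye orientation.
#' A positive rotation is counterclockwise about the grid centre.
#'
#' @param n_cols,n_rows Grid dimensions (default 8 x 8 = 64 points).
#' @param width,height Scan area extents in degrees (default 30 x 25).
#' @param rotation Fovea-to-disc inclination in degrees (default 7).
#' @param center Grid centre `(x, y)` in degrees (default the fovea, (0,0)).
#' @return An object of class `pp_grid_spec`.
#' @export
#' @examples
#' grid_spec()
grid_spec <- function(n_cols = 8L, n_rows = 8L, width = 30, height = 25,
                      rotation = 7, center = c(0, 0)) {
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || is.na(n_rows) || n_cols < 1L || n_rows < 1L)
    stop("n_cols and n_rows must be positive integers")
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("width and height must be positive and finite")
  if (!is.finite(rotation))
    stop("rotation must be finite")
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be a finite (x, y) pair")
  structure(list(n_cols = n_cols, n_rows = n_rows, width = width,
                 height = height, rotation = rotation,
                 center = as.numeric(center)),
            class = "pp_grid_spec")
}

#' @export
print.pp_grid_spec <- function(x, ...) {
  cat(sprintf("Posterior-pole grid: %d x %d cells over %g x %g deg, rotation %g deg\n",
              x$n_rows, x$n_cols, x$width, x$height, x$rotation))
  invisible(x)
}

#' Rotate points in the visual-field plane
#'
#' Applies the planar rotation `x' = x cos(theta) - y sin(theta)`,
#' `y' = x sin(theta) + y cos(theta)` (counterclockwise for positive
#' `theta`) about the origin.
#'
#' @param p A length-2 numeric `(x, y)` or an n x 2 matrix of points,
#'   in degrees.
#' @param theta Rotation angle in degrees.
#' @return Rotated coordinates with the same shape as `p`.
#' @export
#' @examples
#' rotate_point(c(10, 0), 7)
rotate_point <- function(p, theta) {
  if (!is.finite(theta)) stop("theta must be finite")
  vec <- is.null(dim(p))
  m <- if (vec) matrix(as.numeric(p), ncol = 2) else as.matrix(p)
  if (ncol(m) != 2L) stop("p must be an (x, y) pair or an n x 2 matrix")
  if (!all(is.finite(m))) stop("non-finite point coordinates")
  th <- theta * pi / 180
  out <- cbind(m[, 1] * cos(th) - m[, 2] * sin(th),
               m[, 1] * sin(th) + m[, 2] * cos(th))
  if (vec) c(out) else { colnames(out) <- c("x", "y"); out }
}

#' Generate the posterior-pole test pattern
#'
#' Places one test point at the centre of each cell of the uniform
#' `n_rows` x `n_cols` partition of the scan area (row 1 superior,
#' column 1 nasal in right-eye orientation), then rotates every centre by
#' `spec$rotation` about the grid centre, mirroring the fovea-to-disc
#' inclination of the acquisition protocol. Points carry both the
#' pre-rotation (`x0`, `y0`) and rotated (`x`, `y`) coordinates, and
#' quadrant labels.
#'
#' @param spec A [grid_spec()].
#' @return A data.frame with `n_rows * n_cols` rows and columns `id`
#'   (0-based, row-major), `row`, `col`, `x0`, `y0`, `x`, `y`, `vertical`,
#'   `horizontal`, `quadrant`.
#' @export
#' @examples
#' g <- generate_pp_grid()
#' nrow(g)  # 64
generate_pp_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "pp_grid_spec"))
  row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  cw <- spec$width / spec$n_cols
  ch <- spec$height / spec$n_rows
  x0 <- spec$center[1] + cw * (col - (spec$n_cols + 1) / 2)
  y0 <- spec$center[2] - ch * (row - (spec$n_rows + 1) / 2)
  rel <- rotate_point(cbind(x0 - spec$center[1], y0 - spec$center[2]),
                      spec$rotation)
  pts <- data.frame(
    id = (row - 1L) * spec$n_cols + (col - 1L),
    row = row, col = col,
    x0 = x0, y0 = y0,
    x = rel[, 1] + spec$center[1],
    y = rel[, 2] + spec$center[2]
  )
  cbind(pts, assign_quadrant(pts, spec))
}

#' Assign quadrant labels to grid points
#'
#' Labels each point superior/inferior by row and nasal/temporal by column
#' in right-eye orientation: superior iff `row <= n_rows / 2`, nasal iff
#' `col <= n_cols / 2`. Deterministic; for the default 8 x 8 grid this
#' partitions the 64 points into four groups of 16.
#'
#' @param points A data.frame with `row` and `col` columns
#'   (laterality-normalized, right-eye orientation).
#' @param spec The [grid_spec()] the points came from.
#' @return A data.frame with columns `vertical`, `horizontal`, `quadrant`.
#' @export
assign_quadrant <- function(points, spec = grid_spec()) {
  stopifnot(inherits(spec, "pp_grid_spec"))
  vertical <- ifelse(points$row <= spec$n_rows / 2, "superior", "inferior")
  horizontal <- ifelse(points$col <= spec$n_cols / 2, "nasal", "temporal")
  data.frame(vertical = vertical, horizontal = horizontal,
             quadrant = paste(vertical, horizontal, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Normalize grid laterality to right-eye orientation
#'
#' Right eyes (`OD`) are returned unchanged. Left eyes (`OS`) are mirrored
#' about the vertical midline (`x -> -x`, both pre- and post-rotation) and
#' their column indices re-labelled (`col -> n_cols + 1 - col`) so that
#' column 1 is nasal in both eyes; the rotation sign is implicitly flipped
#' by the mirroring, keeping the fovea-to-disc inclination pointing toward
#' the disc. The operation is an involution: applying it twice with `OS`
#' recovers the input.
#'
#' @param points A grid data.frame from [generate_pp_grid()].
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param spec The [grid_spec()] used to build `points`.
#' @return The normalized grid data.frame, sorted by `id`.
#' @export
normalize_laterality <- function(points, eye, spec = grid_spec()) {
  eye <- match.arg(eye, c("OD", "OS"))
  if (eye == "OD") return(points)
  out <- points
  out$x0 <- 2 * spec$center[1] - out$x0
  out$x <- 2 * spec$center[1] - out$x
  out$col <- spec$n_cols + 1L - out$col
  out$id <- (out$row - 1L) * spec$n_cols + (out$col - 1L)
  q <- assign_quadrant(out, spec)
  out$vertical <- q$vertical
  out$horizontal <- q$horizontal
  out$quadrant <- q$quadrant
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  out
}

#' Export or import a grid as CSV
#'
#' @param points A grid data.frame.
#' @param file Path to a CSV file.
#' @return `read_grid_csv` returns the grid data.frame.
#' @export
write_grid_csv <- function(points, file) {
  utils::write.csv(points, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(file) {
  g <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "row", "col", "x", "y")
  if (!all(need %in% names(g)))
    stop("grid CSV must contain columns: ", paste(need, collapse = ", "))
  g
}

#' Serialize a grid specification to JSON
#'
#' @param spec A [grid_spec()].
#' @param file Path to a JSON file.
#' @return `read_grid_spec_json` returns a `pp_grid_spec`.
#' @export
write_grid_spec_json <- function(spec, file) {
  stopifnot(inherits(spec, "pp_grid_spec"))
  jsonlite::write_json(unclass(spec), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_grid_spec_json
#' @export
read_grid_spec_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  grid_spec(n_cols = x$n_cols, n_rows = x$n_rows, width = x$width,
            height = x$height, rotation = x$rotation, center = x$center)
}
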