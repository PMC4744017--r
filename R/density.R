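#' Grid specification for density maps
#'
#' Defines the pixel raster of the aligned reference frame. Pixel `(row j,
#' col i)` covers the half-open cell
#' `[origin_x + (i-1)*pixel_size, origin_x + i*pixel_size)` x
#' `[origin_y + (j-1)*pixel_size, origin_y + j*pixel_size)` in degrees;
#' rows index y (downward), columns x (rightward). The default covers
#' 16 x 16 degrees at 256 x 256 pixels (0.0625 deg/px), which samples a
#' 0.3-degree Gaussian kernel with about five pixels per standard
#' deviation; tests and simulation studies typically use a 64 x 64 grid of
#' the same extent.
#'
#' @param width,height Grid size in pixels.
#' @param pixel_size Pixel edge length in degrees.
#' @param origin Degree coordinates of the top-left corner of pixel (1, 1).
#' @return A `gc_grid` object.
#' @export
grid_spec <- function(width = 256, height = 256, pixel_size = 0.0625,
                      origin = c(0, 0)) {
  stopifnot_scalar_number(pixel_size, "pixel_size", 1e-12, Inf)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 origin = c(x = origin[1], y = origin[2])),
            class = "gc_grid")
}

#' @rdname grid_spec
#' @export
default_grid <- function() grid_spec(256, 256, 0.0625)

#' @rdname grid_spec
#' @export
coarse_grid <- function() grid_spec(64, 64, 0.25)

same_grid <- function(a, b) {
  a$width == b$width && a$height == b$height &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(unname(a$origin), unname(b$origin)))
}

grid_centers <- function(grid) {
  list(x = grid$origin["x"] + (seq_len(grid$width) - 0.5) * grid$pixel_size,
       y = grid$origin["y"] + (seq_len(grid$height) - 0.5) * grid$pixel_size)
}

#' Locate a degree coordinate on the grid
#'
#' @param grid A `gc_grid`.
#' @param x,y Degree coordinates.
#' @return Integer `c(row, col)` of the containing pixel (clamped to the
#'   grid).
#' @export
grid_locate <- function(grid, x, y) {
  col <- pmin(pmax(floor((x - grid$origin["x"]) / grid$pixel_size) + 1, 1),
              grid$width)
  row <- pmin(pmax(floor((y - grid$origin["y"]) / grid$pixel_size) + 1, 1),
              grid$height)
  c(row = as.integer(row), col = as.integer(col))
}

# per-pixel mass of one unit-mass isotropic Gaussian, as a column vector of
# length height*width (column-major). `exact` integrates the Gaussian over
# each pixel cell via CDF differences; otherwise the density at the pixel
# center times the pixel area is used.
fixation_cell_mass <- function(x, y, grid, sigma, exact = TRUE) {
  if (exact) {
    ex <- grid$origin["x"] + (0:grid$width) * grid$pixel_size
    ey <- grid$origin["y"] + (0:grid$height) * grid$pixel_size
    px <- diff(pnorm(ex, mean = x, sd = sigma))
    py <- diff(pnorm(ey, mean = y, sd = sigma))
  } else {
    ctr <- grid_centers(grid)
    px <- stats::dnorm(ctr$x, x, sigma) * grid$pixel_size
    py <- stats::dnorm(ctr$y, y, sigma) * grid$pixel_size
  }
  as.vector(outer(py, px))
}

#' Optimal translation aligning a face layout to reference AOI centers
#'
#' Returns the translation `t` minimizing the sum of squared differences
#' between the layout's AOI centers shifted by `t` and the reference
#' centers (the mean AOI centers across all faces); in closed form `t` is
#' the mean over AOIs of (reference center - layout center).
#'
#' @param layout A `gc_layout` with all 7 AOIs.
#' @param ref_centers 7 x 2 matrix as returned by [reference_centers()].
#' @return Numeric `c(dx, dy)`.
#' @export
align_translation <- function(layout, ref_centers) {
  cen <- aoi_centers(layout)
  if (!all(rownames(ref_centers) %in% rownames(cen)))
    stop("layout is missing AOIs present in the reference")
  d <- ref_centers[rownames(cen), , drop = FALSE] - cen
  c(dx = mean(d[, "x"]), dy = mean(d[, "y"]))
}

#' @rdname align_translation
#' @param layouts Named list of `gc_layout` objects.
#' @export
reference_centers <- function(layouts) {
  acc <- Reduce(`+`, lapply(layouts, aoi_centers))
  acc / length(layouts)
}

#' @rdname align_translation
#' @export
alignment_offsets <- function(layouts, ref_centers = reference_centers(layouts)) {
  m <- t(vapply(layouts, align_translation, numeric(2), ref_centers))
  colnames(m) <- c("dx", "dy")
  m
}

#' Render a Gaussian fixation-density map
#'
#' Each fixation contributes an isotropic Gaussian of unit mass (standard
#' deviation `sigma` in both dimensions) centered at its location after
#' applying its face's alignment translation; contributions are integrated
#' exactly over each pixel cell by default. Mass falling outside the grid
#' is simply lost (never renormalized) and shows up as
#' `mass_in_grid < n_fixations`. With `weight_by_duration` each fixation's
#' mass is its duration divided by the mean duration, preserving the total
#' nominal mass.
#'
#' @param fixations Fixation table with `x_deg`, `y_deg`, `face_id` (and
#'   `duration_ms` if weighting).
#' @param offsets Matrix from [alignment_offsets()] (rows named by face),
#'   or `NULL` for no alignment.
#' @param grid A [grid_spec()].
#' @param sigma Gaussian SD in degrees (default 0.3).
#' @param weight_by_duration Weight fixations by relative duration.
#' @param exact Exact per-cell integration (default) vs pixel-center
#'   approximation.
#' @return A `gc_density` with `values` (height x width matrix),
#'   `n_fixations`, `mass_in_grid`, `grid`.
#' @export
render_density <- function(fixations, offsets = NULL, grid = default_grid(),
                           sigma = 0.3, weight_by_duration = FALSE,
                           exact = TRUE) {
  n <- nrow(fixations)
  v <- matrix(0, grid$height, grid$width)
  if (n > 0) {
    dx <- rep(0, n); dy <- rep(0, n)
    if (!is.null(offsets)) {
      dx <- offsets[fixations$face_id, "dx"]
      dy <- offsets[fixations$face_id, "dy"]
    }
    w <- rep(1, n)
    if (weight_by_duration)
      w <- fixations$duration_ms / mean(fixations$duration_ms)
    for (i in seq_len(n)) {
      v <- v + w[i] * fixation_cell_mass(fixations$x_deg[i] + dx[i],
                                         fixations$y_deg[i] + dy[i],
                                         grid, sigma, exact)
    }
  }
  density_map(v, grid, n_fixations = n)
}

density_map <- function(values, grid, n_fixations = NA_integer_) {
  structure(list(values = matrix(values, grid$height, grid$width),
                 grid = grid, n_fixations = n_fixations,
                 mass_in_grid = sum(values)),
            class = "gc_density")
}

#' @export
print.gc_density <- function(x, ...) {
  cat(sprintf("<gc_density> %d x %d px (%.4g deg/px), n_fix = %s, mass = %.6g\n",
              x$grid$height, x$grid$width, x$grid$pixel_size,
              format(x$n_fixations), x$mass_in_grid))
  invisible(x)
}

#' Combine density maps
#'
#' `average_maps()` is the element-wise mean of maps on one grid;
#' `difference_map()` the signed element-wise difference `a - b`;
#' `group_difference_map()` forms the per-participant difference and then
#' averages across participants (numerically identical to the difference
#' of the group means when participants are equally weighted, but kept as
#' the primitive because the permutation test resamples per participant).
#'
#' @param maps List of `gc_density` on identical grids.
#' @return A `gc_density` (signed for differences).
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps) if (!same_grid(m$grid, g)) stop("grid mismatch across maps")
  v <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  density_map(v, g, n_fixations = mean(vapply(maps, `[[`, 0, "n_fixations")))
}

#' @rdname average_maps
#' @param a,b `gc_density` maps on identical grids.
#' @export
difference_map <- function(a, b) {
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch between maps")
  density_map(a$values - b$values, a$grid, NA_integer_)
}

#' @rdname average_maps
#' @param maps_a,maps_b Per-participant map lists, matched by position or
#'   name.
#' @export
group_difference_map <- function(maps_a, maps_b) {
  if (length(maps_a) != length(maps_b))
    stop("need one map per participant in each condition")
  if (!is.null(names(maps_a)) && !is.null(names(maps_b))) {
    if (!setequal(names(maps_a), names(maps_b)))
      stop("participant names differ between conditions")
    maps_b <- maps_b[names(maps_a)]
  }
  diffs <- Map(difference_map, maps_a, maps_b)
  average_maps(diffs)
}

#' Marginal profile of a density map
#'
#' Collapses a 2-D (possibly signed) density map to one dimension by
#' summation: the y profile sums along the horizontal dimension and is a
#' curve over vertical position (one value per pixel row, visualizing
#' density over facial features); the x profile sums along the vertical
#' dimension. Profiles conserve total map mass.
#'
#' @param map A `gc_density`.
#' @param axis `"y"` (default) or `"x"`.
#' @return A `gc_profile` with `values`, `axis`, `grid`.
#' @export
profile_curve <- function(map, axis = c("y", "x")) {
  axis <- match.arg(axis)
  v <- if (axis == "y") rowSums(map$values) else colSums(map$values)
  structure(list(axis = axis, values = v, grid = map$grid,
                 n_fixations = map$n_fixations), class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("<gc_profile> %s profile, %d bins, mass = %.6g\n",
              x$axis, length(x$values), sum(x$values)))
  invisible(x)
}

#' Face-region analysis mask
#'
#' Boolean pixel mask of the face region in the aligned frame: a pixel is
#' in-face when its center falls inside the aligned image frame of at
#' least `coverage` of the faces. Used to ignore non-face pixels in the
#' FDR correction of spatial statistical maps.
#'
#' @param layouts Named list of `gc_layout`.
#' @param offsets [alignment_offsets()] matrix.
#' @param grid A [grid_spec()].
#' @param coverage Minimum fraction of faces covering a pixel.
#' @return Logical height x width matrix.
#' @export
face_mask <- function(layouts, offsets, grid, coverage = 0.5) {
  ctr <- grid_centers(grid)
  acc <- matrix(0, grid$height, grid$width)
  for (fid in names(layouts)) {
    fr <- shift_rect(layouts[[fid]]$frame, offsets[fid, "dx"], offsets[fid, "dy"])
    inx <- ctr$x >= fr["x0"] & ctr$x < fr["x1"]
    iny <- ctr$y >= fr["y0"] & ctr$y < fr["y1"]
    acc <- acc + outer(iny, inx)
  }
  acc / length(layouts) >= coverage
}
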