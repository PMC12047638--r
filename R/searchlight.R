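#' Integer voxel offsets of a searchlight sphere
#'
#' Enumerates every integer voxel offset whose physical Euclidean distance
#' from the origin (given the voxel size in mm) is at most `radius_mm`. The
#' center `(0,0,0)` is always included, so a sphere is never empty; the offset
#' set is symmetric under negation. Offsets are returned in a canonical order
#' (sorted by z, then y, then x).
#'
#' The reference analysis used a 6 mm radius, equivalently a 3-voxel sphere on
#' a 2 mm isotropic grid; the radius here is specified in millimeters and
#' converted through the voxel size, which honors both phrasings.
#'
#' @param radius_mm sphere radius in millimeters (> 0).
#' @param voxel_size_mm physical voxel size, length-3 (default 2 mm isotropic).
#' @return integer matrix with 3 columns (dx, dy, dz), one row per offset.
#' @examples
#' nrow(sphere_offsets(3, c(1, 1, 1)))  # 123
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm = c(2, 2, 2)) {
  radius_mm <- check_scalar(radius_mm, "radius_mm")
  if (radius_mm <= 0) abort_config("radius_mm must be > 0")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    abort_config("voxel_size_mm must be 3 positive sizes")
  }
  rv <- floor(radius_mm / voxel_size_mm)
  g <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  d2 <- (g$dx * voxel_size_mm[1])^2 + (g$dy * voxel_size_mm[2])^2 +
    (g$dz * voxel_size_mm[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  g <- g[order(g$dz, g$dy, g$dx), , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(m) <- "integer"
  m
}

#' Searchlight sphere specification
#'
#' @param radius_mm sphere radius in millimeters (default 6).
#' @param voxel_size_mm physical voxel size (default 2 mm isotropic; 6 mm at
#'   2 mm voxels gives the classic 3-voxel sphere).
#' @param min_voxels minimum in-mask voxels a sphere must contain for its
#'   center to be evaluated (default 1, i.e. no thresholding; spheres are
#'   truncated at the mask boundary, never padded).
#' @return object of class `sphere_spec` with the derived `offsets`.
#' @export
sphere_spec <- function(radius_mm = 6, voxel_size_mm = c(2, 2, 2),
                        min_voxels = 1L) {
  offs <- sphere_offsets(radius_mm, voxel_size_mm)
  structure(list(radius_mm = radius_mm,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 min_voxels = check_count(min_voxels, "min_voxels", 1L),
                 offsets = offs),
            class = "sphere_spec")
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf("Searchlight sphere: radius %.3g mm at (%s) mm voxels -> %d offsets\n",
              x$radius_mm, paste(x$voxel_size_mm, collapse = ", "),
              nrow(x$offsets)))
  invisible(x)
}

## For every in-mask voxel (column of the data matrix), the data-column
## indices of the sphere's in-mask voxels. Returns a list; entry order is the
## canonical offset order restricted to in-mask members.
sphere_neighbourhoods <- function(mask, sphere) {
  dims <- dim(mask)
  vol_index <- array(NA_integer_, dim = dims)
  vol_index[mask] <- seq_len(sum(mask))
  centers <- which(mask, arr.ind = TRUE)
  offs <- sphere$offsets
  n_off <- nrow(offs)
  ## neighbour matrix: centers x offsets, NA where off-grid or out-of-mask
  nb <- matrix(NA_integer_, nrow(centers), n_off)
  for (o in seq_len(n_off)) {
    x <- centers[, 1] + offs[o, 1]
    y <- centers[, 2] + offs[o, 2]
    z <- centers[, 3] + offs[o, 3]
    ok <- x >= 1L & x <= dims[1] & y >= 1L & y <= dims[2] & z >= 1L & z <= dims[3]
    idx <- rep(NA_integer_, nrow(centers))
    idx[ok] <- vol_index[cbind(x[ok], y[ok], z[ok])]
    nb[, o] <- idx
  }
  nb
}

#' Run a searchlight over all in-mask voxels
#'
#' Sweeps the sphere across every in-mask voxel; at each center, the statistic
#' callback is applied to the data restricted to the sphere's in-mask voxels
#' and its scalar value is assigned to the center. Centers are processed
#' independently, so the output is identical regardless of iteration order or
#' chunking. A callback error at one sphere records `NA` at that center (with
#' one summary warning) rather than aborting the map.
#'
#' @param data either a numeric matrix (observations x in-mask voxels) or a
#'   list of such matrices sharing the voxel axis; the callback receives the
#'   same structure restricted to the sphere's columns.
#' @param mask logical 3D array; `sum(mask)` must equal the voxel count.
#' @param statistic function of the sphere-restricted data returning a scalar.
#' @param sphere a [sphere_spec()].
#' @param chunks split centers into this many consecutive chunks (results are
#'   bit-identical for any value; exposed to make that contract testable).
#' @param statistic_name label stored in the result.
#' @return a `stat_map`: list with 3D `values` (NA at unevaluated centers,
#'   `NA` outside the mask), `mask`, `validity` (3D logical: callback
#'   succeeded), and `statistic_name`.
#' @export
run_searchlight <- function(data, mask, statistic, sphere = sphere_spec(),
                            chunks = 1L, statistic_name = "statistic") {
  mask <- mask > 0
  v <- sum(mask)
  mats <- if (is.list(data) && !is.data.frame(data)) data else list(data)
  for (m in mats) {
    if (!is.matrix(m) || ncol(m) != v) {
      abort_data("each data matrix must have one column per in-mask voxel (%d)", v)
    }
  }
  single <- !is.list(data) || is.data.frame(data)
  nb <- sphere_neighbourhoods(mask, sphere)
  n_centers <- nrow(nb)
  chunks <- check_count(chunks, "chunks", 1L)
  bounds <- chunk_bounds(n_centers, chunks)
  values <- rep(NA_real_, n_centers)
  ok <- rep(TRUE, n_centers)
  n_fail <- 0L
  for (ch in seq_len(nrow(bounds))) {
    for (ci in seq(bounds[ch, 1], bounds[ch, 2])) {
      cols <- nb[ci, ]
      cols <- cols[!is.na(cols)]
      if (length(cols) < sphere$min_voxels) {
        ok[ci] <- FALSE
        next
      }
      sub <- if (single) mats[[1]][, cols, drop = FALSE] else
        lapply(mats, function(m) m[, cols, drop = FALSE])
      res <- tryCatch(statistic(sub), error = function(e) e)
      if (inherits(res, "error")) {
        ok[ci] <- FALSE
        n_fail <- n_fail + 1L
      } else {
        values[ci] <- as.numeric(res)[1]
      }
    }
  }
  if (n_fail > 0L) {
    warning(sprintf("searchlight statistic failed at %d of %d centers; recorded as NA",
                    n_fail, n_centers), call. = FALSE)
  }
  vol <- array(NA_real_, dim = dim(mask))
  vol[mask] <- values
  valid <- array(FALSE, dim = dim(mask))
  valid[mask] <- ok & !is.na(values)
  stat_map(vol, mask, statistic_name, validity = valid)
}

chunk_bounds <- function(n, chunks) {
  chunks <- min(chunks, max(n, 1L))
  starts <- floor(seq(1L, n + 1L, length.out = chunks + 1L))
  cbind(starts[-length(starts)], starts[-1] - 1L)[starts[-length(starts)] <=
                                                    starts[-1] - 1L, , drop = FALSE]
}

#' Construct a statistic map
#'
#' @param values 3D numeric array on the grid (NA outside the mask or at
#'   unevaluated centers).
#' @param mask logical 3D array.
#' @param statistic_name label.
#' @param validity optional logical 3D array marking evaluated centers.
#' @return object of class `stat_map`.
#' @export
stat_map <- function(values, mask, statistic_name = "statistic",
                     validity = NULL) {
  mask <- mask > 0
  if (!all(dim(values) == dim(mask))) abort_data("values and mask grids differ")
  if (any(!is.finite(values[mask]) & !is.na(values[mask]))) {
    abort_data("non-finite statistic values inside the mask")
  }
  if (is.null(validity)) validity <- mask & !is.na(values)
  structure(list(values = values, mask = mask, validity = validity,
                 statistic_name = statistic_name),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  inm <- x$values[x$validity]
  cat(sprintf("Stat map '%s' on %s grid: %d evaluated voxels, range [%.4f, %.4f]\n",
              x$statistic_name, paste(dim(x$values), collapse = "x"),
              length(inm),
              if (length(inm)) min(inm) else NA, if (length(inm)) max(inm) else NA))
  invisible(x)
}
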