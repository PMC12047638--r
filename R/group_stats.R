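#' TFCE parameters
#'
#' Threshold-free cluster enhancement integrates, at every voxel, cluster
#' extent and height over all suprathreshold levels:
#' `TFCE(p) = sum over h of e(h)^E * h^H * dh`, where `e(h)` is the size of
#' the connected suprathreshold component containing `p`. Defaults are the
#' field-standard constants: `H = 2`, `E = 0.5`, 100 integration steps
#' (`dh = max/100`), 26-connectivity.
#'
#' @param height_exponent height exponent `H`.
#' @param extent_exponent extent exponent `E`.
#' @param n_steps number of integration steps when `dh` is `NULL`.
#' @param dh explicit step height; `NULL` selects `max(map)/n_steps`.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @return object of class `tfce_params`.
#' @export
tfce_params <- function(height_exponent = 2, extent_exponent = 0.5,
                        n_steps = 100L, dh = NULL, connectivity = 26L) {
  if (!is.null(dh)) {
    dh <- check_scalar(dh, "dh")
    if (dh <= 0) abort_config("dh must be positive")
  }
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort_config("connectivity must be 6, 18 or 26")
  }
  structure(list(height_exponent = check_scalar(height_exponent, "height_exponent"),
                 extent_exponent = check_scalar(extent_exponent, "extent_exponent"),
                 n_steps = check_count(n_steps, "n_steps", 1L),
                 dh = dh,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

## neighbour offsets for a connectivity scheme
connectivity_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  n2 <- g$dx^2 + g$dy^2 + g$dz^2
  keep <- switch(as.character(connectivity),
                 "6" = n2 == 1, "18" = n2 >= 1 & n2 <= 2, "26" = n2 >= 1)
  as.matrix(g[keep, , drop = FALSE])
}

## CSR adjacency over in-mask voxels (0-based, for the C++ core)
mask_adjacency <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  vol_index <- array(NA_integer_, dim = dims)
  vol_index[mask] <- seq_len(sum(mask))
  centers <- which(mask, arr.ind = TRUE)
  offs <- connectivity_offsets(connectivity)
  neigh <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    x <- centers[, 1] + offs[o, 1]
    y <- centers[, 2] + offs[o, 2]
    z <- centers[, 3] + offs[o, 3]
    ok <- x >= 1L & x <= dims[1] & y >= 1L & y <= dims[2] &
      z >= 1L & z <= dims[3]
    idx <- rep(NA_integer_, nrow(centers))
    idx[ok] <- vol_index[cbind(x[ok], y[ok], z[ok])]
    neigh[[o]] <- idx
  }
  nb <- do.call(cbind, neigh)
  counts <- rowSums(!is.na(nb))
  ptr <- c(0L, cumsum(counts))
  idx <- t(nb)[!is.na(t(nb))] - 1L  # row-major flatten keeps per-voxel groups
  list(ptr = as.integer(ptr), idx = as.integer(idx))
}

#' TFCE transform of a statistic map
#'
#' Applies threshold-free cluster enhancement to the positive part of a map
#' (negative values contribute nothing, matching the one-sided group test).
#' Connected components are computed per discrete threshold step, the
#' standard staircase approximation of the TFCE integral. The transform is
#' monotone: raising any voxel's value never lowers any voxel's score.
#'
#' @param map a `stat_map`, or a 3D numeric array (then `mask` is required).
#' @param params a [tfce_params()].
#' @param mask logical 3D array when `map` is a plain array.
#' @return 3D numeric array of TFCE scores (0 outside the mask).
#' @export
tfce_transform <- function(map, params = tfce_params(), mask = NULL) {
  if (inherits(map, "stat_map")) {
    mask <- map$mask
    vol <- map$values
  } else {
    if (is.null(mask)) abort_config("mask is required for a plain array map")
    vol <- map
  }
  mask <- mask > 0
  vals <- vol[mask]
  vals[is.na(vals)] <- 0
  if (any(!is.finite(vals))) abort_data("non-finite values inside the mask")
  adj <- mask_adjacency(mask, params$connectivity)
  scores <- .tfce_graph(pmax(vals, 0), adj$ptr, adj$idx,
                        params$height_exponent, params$extent_exponent,
                        params$n_steps, params$dh %||% -1)
  out <- array(0, dim = dim(mask))
  out[mask] <- scores
  out
}

#' One-sample sign-flip permutation test with TFCE
#'
#' Group-level inference over a stack of per-pair statistic maps: tests, one
#' sided, whether the mean map exceeds `null_value` (0 for RSA correlations,
#' 0.5 for decoding AUC). The statistic is the TFCE transform of the mean of
#' the null-centred maps; the null distribution is built by randomly flipping
#' the sign of each map (the one-sample permutation scheme of FSL Randomise),
#' and each voxel's familywise-corrected p-value compares its observed TFCE
#' score to the permutation distribution of the image-wide maximum.
#'
#' When `2^n_maps - 1 <= n_permutations` all distinct non-identity sign
#' patterns are enumerated instead of sampled, making the test exact.
#' p-values are `(1 + #(max_perm >= t_voxel)) / (n_used + 1)`, so the
#' smallest attainable p is `1/(n_used + 1)`.
#'
#' Voxels not validly evaluated in every map are excluded from inference
#' (their p is `NA`).
#'
#' @param maps a `stat_map_stack`, or a list of `stat_map`s on one grid.
#' @param null_value chance level subtracted from every map (defaults to the
#'   stack's own).
#' @param params a [tfce_params()].
#' @param n_permutations requested number of permutations (default 5000).
#' @param seed integer seed for the sign draws.
#' @return an object of class `group_result` with `mean_map`, `tfce_map`,
#'   `p_map` (3D arrays), `null_max` (the permutation maxima),
#'   `n_permutations` (actually used), `exhaustive`, `null_value`, `seed`.
#' @export
permutation_test <- function(maps, null_value = NULL, params = tfce_params(),
                             n_permutations = 5000L, seed = 1L) {
  if (inherits(maps, "stat_map_stack")) {
    null_value <- null_value %||% maps$null_value
    maps <- maps$maps
  }
  null_value <- null_value %||% 0
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  n <- length(maps)
  if (n < 2L) abort_config("need >= 2 maps, got %d", n)
  dims <- dim(maps[[1]]$values)
  mask <- maps[[1]]$mask
  for (m in maps) {
    if (!all(dim(m$values) == dims)) abort_data("maps are not on a shared grid")
  }
  analysis_mask <- Reduce(`&`, lapply(maps, function(m) m$validity), mask)
  v <- sum(analysis_mask)
  if (v == 0L) abort_data("no voxel is valid in every map")
  mat <- do.call(rbind, lapply(maps, function(m) m$values[analysis_mask]))
  mat <- mat - null_value

  adj <- mask_adjacency(analysis_mask, params$connectivity)
  obs_mean <- colMeans(mat)
  obs_tfce <- .tfce_graph(pmax(obs_mean, 0), adj$ptr, adj$idx,
                          params$height_exponent, params$extent_exponent,
                          params$n_steps, params$dh %||% -1)

  exhaustive <- (2^n - 1) <= n_permutations
  signs <- if (exhaustive) {
    s <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    s[-1L, , drop = FALSE]  # drop the identity pattern
  } else {
    with_seed(derive_seed(seed, 91L), {
      matrix(sample(c(1, -1), n_permutations * n, replace = TRUE),
             n_permutations, n)
    })
  }
  n_used <- nrow(signs)
  ## permutations processed in blocks to bound the n_perm x n_voxel buffer
  null_max <- numeric(n_used)
  block <- 256L
  for (start in seq(1L, n_used, by = block)) {
    rows <- start:min(start + block - 1L, n_used)
    perm_means <- (signs[rows, , drop = FALSE] %*% mat) / n
    null_max[rows] <- .tfce_max_rows(perm_means, adj$ptr, adj$idx,
                                     params$height_exponent,
                                     params$extent_exponent,
                                     params$n_steps, params$dh %||% -1)
  }
  exceed <- vapply(obs_tfce, function(t) sum(null_max >= t), numeric(1))
  p <- (1 + exceed) / (n_used + 1)

  to_vol <- function(x, fill = NA_real_) {
    out <- array(fill, dim = dims)
    out[analysis_mask] <- x
    out
  }
  structure(list(mean_map = to_vol(obs_mean + null_value),
                 tfce_map = to_vol(obs_tfce, fill = 0),
                 p_map = to_vol(p),
                 mask = analysis_mask,
                 null_max = null_max,
                 n_maps = n,
                 n_permutations = n_used,
                 exhaustive = exhaustive,
                 null_value = null_value,
                 params = params,
                 seed = seed),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("One-sample sign-flip TFCE permutation test (null value %.2g)\n",
              x$null_value))
  cat(sprintf("%d maps, %d permutations%s, %d voxels analysed\n", x$n_maps,
              x$n_permutations, if (x$exhaustive) " (exhaustive)" else "",
              sum(x$mask)))
  cat(sprintf("significant voxels at p < 0.05: %d (min p = %.4g)\n",
              sum(x$p_map < 0.05, na.rm = TRUE), min(x$p_map, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.group_result <- function(object, alpha = 0.05, ...) {
  p <- object$p_map
  sig <- !is.na(p) & p < alpha
  out <- list(alpha = alpha,
              n_significant = sum(sig),
              n_voxels = sum(object$mask),
              min_p = min(p, na.rm = TRUE),
              max_mean = if (any(object$mask)) max(object$mean_map, na.rm = TRUE) else NA,
              n_permutations = object$n_permutations)
  class(out) <- "summary.group_result"
  out
}

#' @export
print.summary.group_result <- function(x, ...) {
  cat(sprintf("%d of %d voxels significant at p < %.3g (min p %.4g, %d permutations)\n",
              x$n_significant, x$n_voxels, x$alpha, x$min_p, x$n_permutations))
  invisible(x)
}

#' Significant-voxel mask of a group result
#'
#' @param result a `group_result`.
#' @param alpha familywise threshold (default 0.05).
#' @return logical 3D array.
#' @export
significant_voxels <- function(result, alpha = 0.05) {
  !is.na(result$p_map) & result$p_map < alpha
}
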