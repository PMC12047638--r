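#' Ellipsoidal brain mask on a small grid
#'
#' Builds a binary mask shaped as the ellipsoid inscribed in the grid (scaled
#' by `fill`), a desk-scale stand-in for a brain mask in standardized space.
#'
#' @param dims integer length-3 grid extents (default `c(24, 24, 24)`).
#' @param fill fraction of each half-extent covered by the ellipsoid.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(dims = c(24L, 24L, 24L), fill = 0.9) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) abort_config("dims must be 3 positive extents")
  c0 <- (dims + 1) / 2
  r <- fill * (dims - 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  inside <- ((idx[, 1] - c0[1]) / r[1])^2 + ((idx[, 2] - c0[2]) / r[2])^2 +
    ((idx[, 3] - c0[3]) / r[3])^2 <= 1
  array(inside, dim = dims)
}

#' Cuboid region inside a grid
#'
#' @param dims grid extents.
#' @param from,to inclusive 1-based corner voxel indices (length-3).
#' @return logical 3D array marking the cuboid.
#' @export
cuboid_region <- function(dims, from, to) {
  dims <- as.integer(dims)
  if (any(from < 1) || any(to > dims) || any(from > to)) {
    abort_config("cuboid corners must satisfy 1 <= from <= to <= dims")
  }
  m <- array(FALSE, dim = dims)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

#' Ground truth for synthetic BOLD generation
#'
#' Encodes the planted representational structure of a synthetic study: which
#' voxels carry stimulus information (`signal_mask`), the per-subject linear
#' maps from item features to those voxels, and the noise level. Voxels inside
#' the signal mask respond as `weights %*% features + noise`; all other
#' in-mask voxels carry pure Gaussian noise. Per-subject weight maps mix a
#' common component with subject-specific ones,
#' `W_s = sqrt(f) W_common + sqrt(1 - f) W_subject`, so `shared_fraction = 1`
#' yields identical encoding across subjects (a fully shared representational
#' blueprint) and `0` makes every subject idiosyncratic.
#'
#' @param mask logical 3D brain mask.
#' @param signal_mask logical 3D array, subset of `mask`, marking responsive
#'   voxels. Defaults to a cuboid in one hemisphere of an ellipsoidal mask.
#' @param n_subjects number of subjects to draw weight maps for.
#' @param feature_dim stimulus feature dimensionality (default 300).
#' @param noise_sd standard deviation of additive Gaussian noise, applied to
#'   every in-mask voxel.
#' @param shared_fraction mixing weight `f` in `[0, 1]` above.
#' @param signal_scale multiplier on all weight maps; `0` plants no signal
#'   anywhere (null model).
#' @param seed integer seed for the weight draws.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(mask,
                         signal_mask = NULL,
                         n_subjects = 7L,
                         feature_dim = 300L,
                         noise_sd = 0.5,
                         shared_fraction = 1,
                         signal_scale = 1,
                         seed = 1L) {
  if (!is.array(mask) || length(dim(mask)) != 3L) abort_config("mask must be a 3D array")
  mask <- mask > 0
  dims <- dim(mask)
  if (is.null(signal_mask)) {
    mid <- round(dims / 2)
    signal_mask <- cuboid_region(dims, pmax(round(dims * 0.25), 1), mid)
  }
  signal_mask <- (signal_mask > 0) & mask
  n_subjects <- check_count(n_subjects, "n_subjects", 1L)
  feature_dim <- check_count(feature_dim, "feature_dim", 1L)
  noise_sd <- check_scalar(noise_sd, "noise_sd", lower = 0)
  shared_fraction <- check_scalar(shared_fraction, "shared_fraction", 0, 1)
  signal_scale <- check_scalar(signal_scale, "signal_scale")
  v_sig <- sum(signal_mask)

  ## weight entries ~ N(0, 1/feature_dim): unit-variance voxel responses for
  ## unit-variance features, so noise_sd is interpretable as 1/SNR
  weights <- with_seed(derive_seed(seed, 77L), {
    w0 <- matrix(rnorm(v_sig * feature_dim, sd = 1 / sqrt(feature_dim)),
                 v_sig, feature_dim)
    lapply(seq_len(n_subjects), function(s) {
      ws <- matrix(rnorm(v_sig * feature_dim, sd = 1 / sqrt(feature_dim)),
                   v_sig, feature_dim)
      signal_scale * (sqrt(shared_fraction) * w0 +
                        sqrt(1 - shared_fraction) * ws)
    })
  })
  structure(list(mask = mask, signal_mask = signal_mask, weights = weights,
                 noise_sd = noise_sd, shared_fraction = shared_fraction,
                 signal_scale = signal_scale, feature_dim = feature_dim,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", paste(dim(x$mask), collapse = "x"), "grid,",
      sum(x$mask), "in-mask voxels,", sum(x$signal_mask), "signal voxels\n")
  cat(sprintf("%d subjects, %d features, noise_sd=%.3g, shared_fraction=%.2f, scale=%.2f\n",
              length(x$weights), x$feature_dim, x$noise_sd, x$shared_fraction,
              x$signal_scale))
  invisible(x)
}

#' Generate item feature vectors with planted category structure
#'
#' Samples an `n_items x dim` feature matrix in which rows (items) of the same
#' category are equicorrelated: animate pairs correlate at
#' `within_animate_corr`, inanimate pairs at `within_inanimate_corr`, and
#' across categories the expected correlation is zero. This emulates the
#' category-cluster structure of item representations from a fine-tuned
#' convolutional network, where the model dissimilarity matrix shows clear
#' animate/inanimate blocks and one category can be more internally consistent
#' than the other.
#'
#' @param n_items number of items; `item ids 1..n_animate` are animate.
#' @param dim feature dimensionality (>= 2; default 300).
#' @param within_animate_corr,within_inanimate_corr within-category row
#'   correlations, each in (-1, 1) and above the equicorrelation
#'   positive-definiteness bound `-1/(n_c - 1)`.
#' @param n_animate animate item count (default `n_items / 2`).
#' @param seed integer seed.
#' @return numeric matrix with item ids as row names.
#' @export
generate_item_features <- function(n_items, dim = 300L,
                                   within_animate_corr = 0.5,
                                   within_inanimate_corr = 0.3,
                                   n_animate = NULL,
                                   seed = 1L) {
  n_items <- check_count(n_items, "n_items", 2L)
  dim <- check_count(dim, "dim", 2L)
  n_animate <- if (is.null(n_animate)) n_items %/% 2L else
    check_count(n_animate, "n_animate", 0L)
  sizes <- c(animate = n_animate, inanimate = n_items - n_animate)
  rhos <- c(within_animate_corr, within_inanimate_corr)
  if (any(rhos <= -1) || any(rhos >= 1)) {
    abort_config("within-category correlations must lie in (-1, 1)")
  }
  with_seed(derive_seed(seed, 7L), {
    blocks <- lapply(1:2, function(b) {
      n_c <- sizes[b]
      if (n_c == 0L) return(matrix(numeric(0), 0, dim))
      sigma <- matrix(rhos[b], n_c, n_c)
      diag(sigma) <- 1
      ch <- tryCatch(chol(sigma), error = function(e) {
        abort_config(
          "within-category correlation %.3f implies a non-positive-definite covariance for %d items",
          rhos[b], n_c)
      })
      t(ch) %*% matrix(rnorm(n_c * dim), n_c, dim)
    })
  })
  out <- rbind(blocks[[1]], blocks[[2]])
  rownames(out) <- as.character(seq_len(n_items))
  colnames(out) <- paste0("f", seq_len(dim))
  out
}

#' Generate trial-level BOLD response volumes for every subject
#'
#' Realizes the encoding premise of the synthetic study: inside the planted
#' signal region each voxel's trial response is a linear map of that trial's
#' item features plus Gaussian noise; outside it, in-mask voxels carry pure
#' noise. Volumes are trial-level response maps on a shared grid (no
#' hemodynamic model), deterministic given the seed.
#'
#' @param design a trial table from [generate_design()].
#' @param features item feature matrix; row names must cover every `item_id`
#'   in `design`.
#' @param truth a [ground_truth()] whose subject count covers the design.
#' @param seed integer seed for the noise draws.
#' @return named list (one element per subject) of `volume_set` objects; each
#'   holds `data` (trials x in-mask voxels), the `mask`, and the subject's
#'   trial rows.
#' @export
generate_bold <- function(design, features, truth, seed = 1L) {
  validate_trial_table(design)
  if (!inherits(truth, "ground_truth")) abort_config("truth must be a ground_truth")
  need <- as.character(sort(unique(design$item_id)))
  have <- rownames(features)
  if (is.null(have) || !all(need %in% have)) {
    abort_data("design items with no feature row: %s",
               paste(setdiff(need, have), collapse = ", "))
  }
  if (ncol(features) != truth$feature_dim) {
    abort_config("feature dim (%d) does not match ground truth (%d)",
                 ncol(features), truth$feature_dim)
  }
  subjects <- sort(unique(design$subject))
  if (length(truth$weights) < max(subjects)) {
    abort_config("ground truth has weights for %d subjects; design needs %d",
                 length(truth$weights), max(subjects))
  }
  mask_idx <- which(truth$mask)
  sig_in_mask <- which(truth$signal_mask[truth$mask])
  vols <- lapply(subjects, function(s) {
    rows <- design[design$subject == s, , drop = FALSE]
    n_tr <- nrow(rows)
    x <- features[as.character(rows$item_id), , drop = FALSE]
    data <- with_seed(derive_seed(seed, 3000L + s), {
      matrix(rnorm(n_tr * length(mask_idx), sd = truth$noise_sd),
             n_tr, length(mask_idx))
    })
    if (length(sig_in_mask)) {
      data[, sig_in_mask] <- data[, sig_in_mask] +
        x %*% t(truth$weights[[s]])
    }
    volume_set(data, truth$mask, subject = s, trials = rows)
  })
  names(vols) <- as.character(subjects)
  vols
}

#' Construct a volume set
#'
#' A `volume_set` couples a trials-by-voxels response matrix to the 3D mask
#' defining which grid voxels the columns correspond to (column `j` is the
#' `j`-th `TRUE` voxel of `mask` in column-major order), plus the matching
#' trial metadata.
#'
#' @param data numeric matrix, trials x in-mask voxels.
#' @param mask logical 3D array with `sum(mask) == ncol(data)`.
#' @param subject subject identifier.
#' @param trials optional trial table aligned with the rows of `data`.
#' @return object of class `volume_set`.
#' @export
volume_set <- function(data, mask, subject = NA, trials = NULL) {
  mask <- mask > 0
  if (!is.matrix(data) || ncol(data) != sum(mask)) {
    abort_data("data must be a matrix with one column per in-mask voxel (%d)",
               sum(mask))
  }
  if (!is.null(trials) && nrow(trials) != nrow(data)) {
    abort_data("trial table rows (%d) do not match data rows (%d)",
               nrow(trials), nrow(data))
  }
  structure(list(data = data, mask = mask, subject = subject, trials = trials),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat("Volume set: subject", x$subject, "-", nrow(x$data), "volumes on",
      paste(dim(x$mask), collapse = "x"), "grid (", ncol(x$data),
      "in-mask voxels )\n")
  invisible(x)
}
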