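#' Fit a voxelwise linear encoding model
#'
#' Regresses every voxel's response on the stimulus feature vector with a
#' shared L2 (ridge) penalty, solved in closed form. Features are standardized
#' to zero mean and unit variance using training-set statistics only; the
#' standardizer is frozen in the returned model and re-applied at prediction
#' time. Voxel responses are not standardized. With the penalty applied to
#' standardized features and an unpenalized intercept (the per-voxel training
#' mean), predictions shrink toward the training mean as
#' `regularization_strength` grows, and the fit is deterministic.
#'
#' @param features numeric matrix, trials x feature dimensions.
#' @param responses numeric matrix, trials x voxels (same row count).
#' @param regularization_strength nonnegative ridge penalty (default 1).
#' @return an object of class `encoding_model` with elements `weights`
#'   (features x voxels), `intercepts`, `center`, `scale`,
#'   `regularization_strength`.
#' @seealso [predict.encoding_model()]
#' @export
fit_encoding <- function(features, responses, regularization_strength = 1) {
  features <- as.matrix(features)
  responses <- as.matrix(responses)
  if (nrow(features) != nrow(responses)) {
    abort_data("features (%d rows) and responses (%d rows) do not align",
               nrow(features), nrow(responses))
  }
  if (nrow(features) < 2L) abort_data("need >= 2 trials to fit an encoding model")
  if (any(!is.finite(features)) || any(!is.finite(responses))) {
    abort_data("non-finite values in features or responses")
  }
  lambda <- check_scalar(regularization_strength, "regularization_strength",
                         lower = 0)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, sd)
  scl[scl < 1e-12] <- 1  # constant features carry no signal; leave centered
  z <- sweep(sweep(features, 2L, ctr), 2L, scl, `/`)
  yc <- sweep(responses, 2L, colMeans(responses))
  d <- ncol(z)
  gram <- crossprod(z) + diag(lambda, d)
  ## tiny jitter keeps the unpenalized limit solvable when features are
  ## collinear; dominated by any real lambda
  w <- solve(gram + diag(1e-10, d), crossprod(z, yc))
  structure(list(weights = w,
                 intercepts = colMeans(responses),
                 center = ctr, scale = scl,
                 regularization_strength = lambda,
                 n_trials = nrow(features)),
            class = "encoding_model")
}

#' Predict voxel responses for new stimuli
#'
#' Applies the frozen feature standardizer and the fitted linear map:
#' `prediction = standardized features %*% weights + intercepts`.
#'
#' @param object an `encoding_model`.
#' @param features numeric matrix, items (or trials) x feature dimensions,
#'   matching the training dimensionality.
#' @param ... ignored.
#' @return numeric matrix, rows x voxels, preserving `features` row names.
#' @export
predict.encoding_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(object$weights)) {
    abort_config("feature dim (%d) does not match model (%d)",
                 ncol(features), nrow(object$weights))
  }
  z <- sweep(sweep(features, 2L, object$center), 2L, object$scale, `/`)
  out <- z %*% object$weights
  sweep(out, 2L, object$intercepts, `+`)
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("Voxelwise ridge encoding model: %d features -> %d voxels (lambda=%.3g, %d trials)\n",
              nrow(x$weights), ncol(x$weights), x$regularization_strength,
              x$n_trials))
  invisible(x)
}

#' @export
coef.encoding_model <- function(object, ...) object$weights
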