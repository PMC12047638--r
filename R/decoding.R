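#' Fit a sparse linear decoder (standardizer + L1 linear SVM)
#'
#' Fits the two-part decoding model used within each searchlight sphere: a
#' per-feature standardizer (mean and standard deviation learned from the
#' training data and locked thereafter) followed by an L1-regularized linear
#' support vector machine. The SVM minimizes the squared-hinge loss
#' `mean(max(0, 1 - y f(x))^2) + (1/C) * ||w||_1` with an unpenalized
#' intercept, the standard convex formulation admitting an L1 penalty, solved
#' by accelerated proximal gradient descent (FISTA) with soft-thresholding to
#' a fixed tolerance. The L1 penalty drives uninformative feature weights to
#' exactly zero, performing feature selection. The solver is deterministic;
#' `seed` is accepted for interface compatibility but no randomness is used.
#'
#' @param patterns numeric matrix, trials x voxels (features).
#' @param labels binary class labels; the first level in sorted order is coded
#'   -1, the second +1 (for `animate`/`inanimate` this puts `animate` at -1).
#' @param penalty_strength inverse regularization C > 0 (default 1); smaller
#'   values penalize more heavily.
#' @param seed unused (deterministic solver); kept in the signature.
#' @param max_iter,tol solver iteration cap and relative-change tolerance.
#' @return an object of class `svm_decoder` with `weights`, `intercept`,
#'   `center`, `scale`, `classes`, `penalty_strength`.
#' @export
fit_decoder <- function(patterns, labels, penalty_strength = 1, seed = 1L,
                        max_iter = 500L, tol = 1e-4) {
  patterns <- as.matrix(patterns)
  labels <- as.character(labels)
  if (nrow(patterns) != length(labels)) {
    abort_data("labels length (%d) does not match pattern rows (%d)",
               length(labels), nrow(patterns))
  }
  if (nrow(patterns) < 2L) abort_data("need >= 2 trials to fit a decoder")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    abort_data("decoder training requires exactly 2 classes, got: %s",
               paste(classes, collapse = ", "))
  }
  cc <- check_scalar(penalty_strength, "penalty_strength")
  if (cc <= 0) abort_config("penalty_strength must be > 0")
  y <- ifelse(labels == classes[2L], 1, -1)

  ## standardizer: fit on training data, locked at test time
  ctr <- colMeans(patterns)
  scl <- apply(patterns, 2L, sd)
  scl[scl < 1e-12] <- 1  # zero-variance features pass through centered
  z <- sweep(sweep(patterns, 2L, ctr), 2L, scl, `/`)

  fit <- l1_svm_fista(z, y, lambda = 1 / cc, max_iter = max_iter, tol = tol)
  structure(list(weights = fit$w, intercept = fit$b, center = ctr, scale = scl,
                 classes = classes, penalty_strength = cc,
                 iterations = fit$iterations),
            class = "svm_decoder")
}

## FISTA on f(w,b) = mean(max(0, 1 - y*(Zw + b))^2) + lambda*||w||_1
## (intercept unpenalized). Lipschitz constant of the smooth part is bounded
## by 2 * smax^2 / n for the augmented [Z 1] matrix.
l1_svm_fista <- function(z, y, lambda, max_iter, tol) {
  n <- nrow(z); p <- ncol(z)
  za <- cbind(z, 1)
  ## top singular value by a few deterministic power iterations (upper-bounded
  ## with a safety factor); Frobenius bound would slow FISTA ~p-fold
  v <- rep(1 / sqrt(p + 1), p + 1)
  smax2 <- 0
  for (i in 1:15) {
    u <- za %*% v
    smax2 <- sum(u * u)                # ||A v||^2 -> sigma_max^2 for unit v
    v <- crossprod(za, u)
    v <- v / sqrt(sum(v * v) + 1e-300)
  }
  lip <- 2 * 1.25 * smax2 / n
  step <- 1 / lip
  w <- numeric(p); b <- 0
  wv <- w; bv <- b                     # momentum point
  t_k <- 1
  obj_old <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    f <- z %*% wv + bv
    slack <- pmax(0, 1 - y * f)
    grad_f <- as.vector(crossprod(z, -2 * y * slack) / n)
    grad_b <- sum(-2 * y * slack) / n
    w_new <- soft_threshold(wv - step * grad_f, step * lambda)
    b_new <- bv - step * grad_b
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    wv <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    bv <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    w <- w_new; b <- b_new; t_k <- t_new
    if (it %% 10L == 0L) {
      s <- pmax(0, 1 - y * (z %*% w + b))
      obj <- mean(s * s) + lambda * sum(abs(w))
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(1, abs(obj_old))) break
      obj_old <- obj
    }
  }
  list(w = as.numeric(w), b = b, iterations = it)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Decision values of a fitted decoder
#'
#' Applies the locked standardizer and the linear decision function
#' `f(x) = w' z + b`; positive values favor the second class in
#' `object$classes`.
#'
#' @param object an `svm_decoder`.
#' @param patterns numeric matrix, trials x voxels.
#' @param ... ignored.
#' @return numeric vector of decision values.
#' @export
predict.svm_decoder <- function(object, patterns, ...) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != length(object$weights)) {
    abort_config("pattern voxel count (%d) does not match decoder (%d)",
                 ncol(patterns), length(object$weights))
  }
  z <- sweep(sweep(patterns, 2L, object$center), 2L, object$scale, `/`)
  as.numeric(z %*% object$weights + object$intercept)
}

#' @export
print.svm_decoder <- function(x, ...) {
  cat(sprintf("L1 linear SVM decoder: %d features, %d nonzero weights (C=%.3g), classes %s vs %s\n",
              length(x$weights), sum(x$weights != 0), x$penalty_strength,
              x$classes[1], x$classes[2]))
  invisible(x)
}

#' @export
coef.svm_decoder <- function(object, ...) {
  c(intercept = object$intercept, setNames(object$weights,
                                           paste0("v", seq_along(object$weights))))
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive-class score exceeds a randomly
#' chosen negative-class score, with ties counted one half (the Mann-Whitney
#' formulation). Invariant under strictly increasing transforms of the
#' scores; 0.5 is chance.
#'
#' @param scores continuous decision values.
#' @param labels binary labels; `positive` names the class scored as positive.
#' @param positive positive class (default: last of the sorted unique labels,
#'   matching the decoder's +1 coding).
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class is present.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) {
    abort_data("scores and labels lengths differ")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    warning("single-class labels: ROC AUC undefined", call. = FALSE)
    return(NA_real_)
  }
  if (length(classes) > 2L) abort_data("ROC AUC requires binary labels")
  positive <- positive %||% classes[2L]
  pos <- labels == positive
  r <- rank(scores)  # average ranks handle ties as 1/2
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score a decoder on held-out trials
#'
#' Computes ROC AUC from the decoder's continuous decision values on a test
#' set (decision values rather than thresholded labels, so the AUC does not
#' degenerate to a two-point curve).
#'
#' @param decoder an `svm_decoder`.
#' @param patterns test trials x voxels.
#' @param labels test labels.
#' @return AUC in `[0, 1]`, `NA` (with a warning) for single-class test sets.
#' @export
score_decoder <- function(decoder, patterns, labels) {
  scores <- predict(decoder, patterns)
  roc_auc(scores, labels, positive = decoder$classes[2L])
}
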