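#' Average trial-level features by item
#'
#' Collapses a trials-by-dimensions matrix to one row per distinct item (the
#' arithmetic mean of that item's trials), in canonical sorted item order.
#' This is the summarization applied both to network hidden representations
#' and to voxel response patterns before RDM construction.
#'
#' @param trial_features numeric matrix, trials x dimensions.
#' @param item_labels per-trial item identifiers (length `nrow(trial_features)`).
#' @param items optional full item set that must be covered; an item with no
#'   trials then raises a data error.
#' @return matrix, items x dimensions, row names the sorted item labels.
#' @export
average_by_item <- function(trial_features, item_labels, items = NULL) {
  trial_features <- as.matrix(trial_features)
  if (nrow(trial_features) != length(item_labels)) {
    abort_data("item_labels length (%d) does not match trial rows (%d)",
               length(item_labels), nrow(trial_features))
  }
  labs <- as.character(item_labels)
  present <- sort_items(unique(labs))
  if (!is.null(items)) {
    items <- sort_items(as.character(items))
    missing <- setdiff(items, present)
    if (length(missing)) {
      abort_data("item(s) with zero trials: %s", paste(missing, collapse = ", "))
    }
    present <- items
  }
  grp <- factor(labs, levels = present)
  sums <- rowsum(trial_features, grp)
  out <- sums / as.vector(table(grp))
  rownames(out) <- present
  out
}

## numeric item ids sort numerically, anything else lexicographically
sort_items <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x)
}

#' Summarize voxel responses by item
#'
#' Identical contract to [average_by_item()]: mean response pattern per item,
#' canonical item order. Provided under the name used in the encoding
#' pipeline.
#'
#' @inheritParams average_by_item
#' @param responses numeric matrix, trials x voxels.
#' @return matrix, items x voxels.
#' @export
summarize_by_item <- function(responses, item_labels, items = NULL) {
  average_by_item(responses, item_labels, items)
}

#' Scaled exponential linear unit
#'
#' `selu(x) = lambda * x` for positive `x` and
#' `lambda * alpha * (exp(x) - 1)` otherwise, with the self-normalizing
#' constants of Klambauer et al.
#'
#' @param x numeric vector or array.
#' @return transformed values, same shape.
#' @export
selu <- function(x) {
  lambda <- 1.0507009873554805
  alpha <- 1.6732632423543772
  ifelse(x > 0, lambda * x, lambda * alpha * (expm1(x)))
}

#' Specify a feature-extraction backbone and fine-tuning head
#'
#' Describes the architecture used to extract item representations from
#' images: a (frozen) convolutional backbone, adaptive global average pooling
#' to a flat vector, a fully connected hidden layer of `hidden_dim` units with
#' SELU activation whose post-activation outputs are the extracted features,
#' and a classification layer trained with one-vs-all binary cross entropy by
#' stochastic gradient descent, stopping early after `early_stop_patience`
#' epochs without validation improvement. The backbone itself is pluggable
#' (see [register_backbone()]); the built-in `"tiny-test"` backend is a small
#' fixed-weight convolutional network suitable for desk-scale use.
#'
#' @param backbone_name registered backbone identifier.
#' @param hidden_dim hidden layer width (default 300).
#' @param activation activation identifier (only `"selu"` is built in).
#' @param pooling pooling identifier (only `"adaptive_mean"` is built in).
#' @param frozen_backbone are backbone weights frozen during head training?
#' @param loss,optimizer training identifiers (`"bce"`, `"sgd"`).
#' @param early_stop_patience epochs of non-improvement tolerated (default 5).
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(backbone_name = "tiny-test",
                          hidden_dim = 300L,
                          activation = "selu",
                          pooling = "adaptive_mean",
                          frozen_backbone = TRUE,
                          loss = "bce",
                          optimizer = "sgd",
                          early_stop_patience = 5L) {
  structure(list(
    backbone_name = backbone_name,
    hidden_dim = check_count(hidden_dim, "hidden_dim", 1L),
    activation = match.arg(activation, "selu"),
    pooling = match.arg(pooling, "adaptive_mean"),
    frozen_backbone = isTRUE(frozen_backbone),
    loss = match.arg(loss, "bce"),
    optimizer = match.arg(optimizer, "sgd"),
    early_stop_patience = check_count(early_stop_patience, "early_stop_patience", 1L)
  ), class = "backbone_spec")
}

## backbone registry: name -> function(images) returning images x channels
## pooled descriptors
.backbones <- new.env(parent = emptyenv())

#' Register or look up a feature-extraction backbone
#'
#' A backbone is a function taking an image stack (numeric array,
#' `n x height x width x channels`, or a list of `height x width x channels`
#' arrays) and returning an `n x d` matrix of pooled convolutional
#' descriptors. The head defined by [backbone_spec()] is applied on top.
#'
#' @param name backbone identifier.
#' @param fn backbone function as described above.
#' @return `register_backbone` the name invisibly; `get_backbone` the
#'   function (configuration error if unregistered).
#' @export
register_backbone <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .backbones)
  invisible(name)
}

#' @rdname register_backbone
#' @export
get_backbone <- function(name) {
  if (!exists(name, envir = .backbones, inherits = FALSE)) {
    abort_config("no backbone registered under '%s' (available: %s)", name,
                 paste(ls(.backbones), collapse = ", "))
  }
  get(name, envir = .backbones, inherits = FALSE)
}

## ---- tiny-test backbone -------------------------------------------------
## One valid-convolution layer with fixed pseudo-random 3x3 kernels, ReLU,
## then adaptive (global) average pooling per output channel. Deterministic:
## weights depend only on the input channel count and a fixed seed.

tiny_conv_kernels <- function(in_ch, out_ch = 8L, k = 3L) {
  with_seed(20240501L, {
    array(rnorm(k * k * in_ch * out_ch, sd = 1 / sqrt(k * k * in_ch)),
          dim = c(k, k, in_ch, out_ch))
  })
}

conv2d_valid <- function(img, kernels) {
  k <- dim(kernels)[1]
  out_ch <- dim(kernels)[4]
  h <- dim(img)[1] - k + 1L
  w <- dim(img)[2] - k + 1L
  if (h < 1L || w < 1L) abort_data("image smaller than convolution kernel")
  out <- array(0, dim = c(h, w, out_ch))
  for (oc in seq_len(out_ch)) {
    acc <- matrix(0, h, w)
    for (ic in seq_len(dim(img)[3])) {
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        acc <- acc + kernels[di, dj, ic, oc] *
          img[di:(di + h - 1L), dj:(dj + w - 1L), ic]
      }
    }
    out[, , oc] <- acc
  }
  out
}

tiny_test_backbone <- function(images) {
  imgs <- as_image_list(images)
  t(vapply(imgs, function(im) {
    fm <- conv2d_valid(im, tiny_conv_kernels(dim(im)[3]))
    fm[fm < 0] <- 0  # ReLU
    apply(fm, 3L, mean)  # adaptive global average pooling
  }, numeric(8L)))
}

as_image_list <- function(images) {
  if (is.list(images)) {
    imgs <- lapply(images, function(im) {
      im <- as.array(im)
      if (length(dim(im)) == 2L) im <- array(im, dim = c(dim(im), 1L))
      im
    })
  } else {
    images <- as.array(images)
    if (length(dim(images)) == 3L) {
      dim(images) <- c(dim(images), 1L)
    }
    if (length(dim(images)) != 4L) {
      abort_data("images must be n x height x width x channels (or a list)")
    }
    imgs <- lapply(seq_len(dim(images)[1]), function(i) {
      array(images[i, , , ], dim = dim(images)[-1])
    })
  }
  shapes <- vapply(imgs, function(im) paste(dim(im), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1L) {
    abort_data("images differ in shape: %s", paste(unique(shapes), collapse = " vs "))
  }
  imgs
}

#' Extract item feature representations from images
#'
#' Runs the image stack through the registered backbone, then through the
#' fine-tuning head: a fully connected hidden layer followed by SELU. The
#' post-activation hidden outputs are the returned features, one row per
#' image. Head weights are drawn deterministically from `head_seed` unless a
#' trained head (see [train_head()]) is supplied, so extraction is a fixed
#' deterministic map and is invariant to how the stack is batched.
#'
#' @param images image stack (see [register_backbone()] for accepted shapes).
#' @param spec a [backbone_spec()].
#' @param head optional trained head from [train_head()].
#' @param head_seed seed for the untrained head's weights.
#' @return matrix, images x `spec$hidden_dim`.
#' @export
extract_features <- function(images, spec = backbone_spec(), head = NULL,
                             head_seed = 1L) {
  backbone <- get_backbone(spec$backbone_name)
  pooled <- backbone(images)
  if (!is.matrix(pooled)) abort_data("backbone must return a matrix")
  if (is.null(head)) {
    head <- init_head(ncol(pooled), spec$hidden_dim, n_classes = 2L,
                      seed = head_seed)
  }
  if (ncol(pooled) != nrow(head$w1)) {
    abort_config("backbone output dim (%d) does not match head input (%d)",
                 ncol(pooled), nrow(head$w1))
  }
  selu(sweep(pooled %*% head$w1, 2L, head$b1, `+`))
}

init_head <- function(in_dim, hidden_dim, n_classes, seed = 1L) {
  with_seed(derive_seed(seed, 17L), {
    list(w1 = matrix(rnorm(in_dim * hidden_dim, sd = 1 / sqrt(in_dim)),
                     in_dim, hidden_dim),
         b1 = numeric(hidden_dim),
         w2 = matrix(rnorm(hidden_dim * n_classes, sd = 1 / sqrt(hidden_dim)),
                     hidden_dim, n_classes),
         b2 = numeric(n_classes))
  })
}

#' Train the classification head on pooled backbone descriptors
#'
#' Fits the two dense layers of the fine-tuning head (hidden + classification)
#' by full-batch stochastic gradient descent on one-vs-all binary cross
#' entropy over one-hot class targets, with the backbone frozen. Training
#' stops when the validation loss has not improved for
#' `spec$early_stop_patience` consecutive epochs, or at `max_epochs`.
#'
#' @param pooled matrix of backbone descriptors, samples x d.
#' @param classes integer class labels (1-based).
#' @param spec a [backbone_spec()].
#' @param val_fraction fraction of samples held out for early stopping.
#' @param lr SGD learning rate.
#' @param max_epochs hard epoch cap.
#' @param seed seed for initialization and the validation split.
#' @return list with the trained `head`, per-epoch `train_loss` and
#'   `val_loss`, and `epochs_run`.
#' @export
train_head <- function(pooled, classes, spec = backbone_spec(),
                       val_fraction = 0.25, lr = 0.5, max_epochs = 200L,
                       seed = 1L) {
  pooled <- as.matrix(pooled)
  classes <- as.integer(classes)
  n_classes <- max(classes)
  n <- nrow(pooled)
  if (n < 4L) abort_data("need >= 4 samples to split train/validation")
  y <- matrix(0, n, n_classes)
  y[cbind(seq_len(n), classes)] <- 1
  val_idx <- with_seed(derive_seed(seed, 23L), {
    sample(n, max(1L, round(val_fraction * n)))
  })
  head <- init_head(ncol(pooled), spec$hidden_dim, n_classes, seed)
  xt <- pooled[-val_idx, , drop = FALSE]; yt <- y[-val_idx, , drop = FALSE]
  xv <- pooled[val_idx, , drop = FALSE];  yv <- y[val_idx, , drop = FALSE]

  forward <- function(h, x) {
    z1 <- sweep(x %*% h$w1, 2L, h$b1, `+`)
    a1 <- selu(z1)
    p <- plogis(sweep(a1 %*% h$w2, 2L, h$b2, `+`))
    list(z1 = z1, a1 = a1, p = p)
  }
  bce <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                                (1 - y) * log(pmax(1 - p, 1e-12)))
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772

  train_loss <- val_loss <- numeric(0)
  best <- Inf; best_head <- head; since_best <- 0L
  for (epoch in seq_len(max_epochs)) {
    f <- forward(head, xt)
    m <- nrow(xt) * ncol(yt)
    dz2 <- (f$p - yt) / m                       # d BCE / d logits
    gw2 <- crossprod(f$a1, dz2); gb2 <- colSums(dz2)
    da1 <- dz2 %*% t(head$w2)
    dz1 <- da1 * ifelse(f$z1 > 0, lambda, lambda * alpha * exp(f$z1))
    gw1 <- crossprod(xt, dz1); gb1 <- colSums(dz1)
    head$w2 <- head$w2 - lr * gw2; head$b2 <- head$b2 - lr * gb2
    head$w1 <- head$w1 - lr * gw1; head$b1 <- head$b1 - lr * gb1

    train_loss[epoch] <- bce(f$p, yt)
    val_loss[epoch] <- bce(forward(head, xv)$p, yv)
    if (val_loss[epoch] < best - 1e-9) {
      best <- val_loss[epoch]; best_head <- head; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= spec$early_stop_patience) break
    }
  }
  list(head = best_head, train_loss = train_loss, val_loss = val_loss,
       epochs_run = length(train_loss))
}

## register built-ins at load time
.onLoad <- function(libname, pkgname) {
  register_backbone("tiny-test", tiny_test_backbone)
}
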