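# Independent reference implementations used as oracles. These deliberately
# use naive loops / third-party graph code, never the package's own routines.

# Pearson correlation of two vectors from the sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x * x) - sx^2) * sqrt(n * sum(y * y) - sy^2)
  num / den
}

# RDM by per-pair looping.
rdm_oracle <- function(patterns) {
  n <- nrow(patterns)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- 1 - pearson_oracle(patterns[i, ], patterns[j, ])
    }
  }
  d
}

# Average ranks computed by sorting, then Pearson (Spearman oracle).
rank_oracle <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

spearman_oracle <- function(x, y) pearson_oracle(rank_oracle(x), rank_oracle(y))

# ROC AUC by pairwise concordance, ties counted one half.
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Sphere offsets by brute-force lattice enumeration.
sphere_offsets_oracle <- function(radius_mm, voxel_mm) {
  r <- 1 + ceiling(radius_mm / min(voxel_mm))
  out <- NULL
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    d <- sqrt((dx * voxel_mm[1])^2 + (dy * voxel_mm[2])^2 + (dz * voxel_mm[3])^2)
    if (d <= radius_mm + 1e-9) out <- rbind(out, c(dx, dy, dz))
  }
  out[order(out[, 3], out[, 2], out[, 1]), , drop = FALSE]
}

# TFCE by per-threshold connected-component labelling (igraph), staircase sum.
tfce_oracle <- function(vol, mask, H = 2, E = 0.5, n_steps = 100,
                        connectivity = 26) {
  vals <- vol
  vals[!mask] <- 0
  vals[vals < 0] <- 0
  vmax <- max(vals)
  out <- array(0, dim = dim(vol))
  if (vmax <= 0) return(out)
  dh <- vmax / n_steps
  offs <- connectivity_offsets(connectivity)  # package internal, inputs only
  dims <- dim(vol)
  for (k in seq_len(n_steps)) {
    h <- k * dh
    supra <- which(vals >= h)
    if (!length(supra)) break
    pos <- arrayInd(supra, dims)
    id <- setNames(seq_along(supra), supra)
    edges <- NULL
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(pos, 2, offs[o, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- rep(NA_integer_, length(supra))
      lin[ok] <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
        (nb[ok, 3] - 1L) * dims[1] * dims[2]
      hit <- !is.na(lin) & as.character(lin) %in% names(id)
      if (any(hit)) {
        edges <- rbind(edges, cbind(seq_along(supra)[hit],
                                    id[as.character(lin[hit])]))
      }
    }
    g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    out[supra] <- out[supra] + sizes^E * h^H * dh
  }
  out
}
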