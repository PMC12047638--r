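#' Representational dissimilarity matrix (1 - Pearson)
#'
#' Computes the items-by-items RDM of a pattern matrix: entry (i, j) is
#' `1 - cor(pattern_i, pattern_j)` (Pearson), so identical patterns score 0
#' and perfectly anticorrelated ones score 2. This is the standard fMRI RSA
#' dissimilarity; it is invariant to adding a constant to a pattern or
#' positively rescaling it.
#'
#' @param patterns numeric matrix, items x measurement channels (>= 2
#'   columns). Row names, if present, become the RDM's item labels.
#' @return an `rdm` object: a symmetric zero-diagonal numeric matrix.
#' @examples
#' compute_rdm(matrix(rnorm(12), 4, 3))
#' @export
compute_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2L) abort_data("patterns need >= 2 columns to correlate")
  if (any(!is.finite(patterns))) abort_data("patterns contain non-finite values")
  ## centered cross-products (not cor(t(x))): this runs once per searchlight
  ## sphere, so avoid per-call overhead
  ctr <- patterns - rowMeans(patterns)
  ss <- rowSums(ctr * ctr)
  if (any(ss <= 1e-24)) {
    ids <- rownames(patterns) %||% as.character(seq_len(nrow(patterns)))
    abort_data("zero-variance pattern row(s): %s",
               paste(ids[ss <= 1e-24], collapse = ", "))
  }
  nrm <- sqrt(ss)
  r <- tcrossprod(ctr / nrm)
  d <- 1 - r
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2  # kill numeric asymmetry
  as_rdm(d)
}

as_rdm <- function(m) {
  structure(m, class = c("rdm", class(m)))
}

validate_rdm <- function(x, tol = 1e-8) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) abort_data("RDM must be square")
  if (max(abs(x - t(x))) > tol) abort_data("RDM is asymmetric beyond tolerance %g", tol)
  if (max(abs(diag(x))) > tol) abort_data("RDM diagonal must be zero")
  invisible(x)
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM over", nrow(x), "items; dissimilarity range [",
      sprintf("%.3f", min(x[lower.tri(x)])), ",",
      sprintf("%.3f", max(x[lower.tri(x)])), "]\n")
  invisible(x)
}

#' Lower-triangle vector of an RDM
#'
#' Extracts the strictly-below-diagonal entries in a fixed column-major order
#' (the order of `lower.tri`), giving the `n(n-1)/2` unique dissimilarities of
#' a symmetric RDM. For the reference 96-item set this is a length-4560
#' vector.
#'
#' @param rdm a square symmetric matrix (symmetry is checked).
#' @return numeric vector of length `n(n-1)/2`.
#' @export
lower_triangle <- function(rdm) {
  validate_rdm(unclass(rdm))
  rdm[lower.tri(rdm)]
}

#' Compare two RDMs by Spearman correlation (RSA score)
#'
#' The similarity of two representational geometries is the Spearman rank
#' correlation of their lower-triangle dissimilarity vectors, using average
#' ranks for ties. Being rank-based, the score is invariant under any strictly
#' increasing transform of either RDM's entries.
#'
#' @param rdm_a,rdm_b RDMs over the same items in the same order.
#' @return Spearman's rho in `[-1, 1]`; `NA` with a warning if either
#'   lower-triangle vector is constant (undefined correlation).
#' @export
rsa_score <- function(rdm_a, rdm_b) {
  if (!all(dim(rdm_a) == dim(rdm_b))) {
    abort_data("RDMs differ in size: %d vs %d items", nrow(rdm_a), nrow(rdm_b))
  }
  a <- lower_triangle(rdm_a)
  b <- lower_triangle(rdm_b)
  spearman(a, b)
}

## Spearman rho = Pearson on average ranks; NA (flagged) on constant input.
spearman <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant dissimilarity vector: Spearman correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(rank(a), rank(b))
}

#' Write / read an RDM as a tab-separated table
#'
#' Square numeric table with item ids as both header and first column.
#'
#' @param rdm an RDM matrix.
#' @param path file path.
#' @return `read_rdm` returns the RDM; `write_rdm` its path, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  m <- as.matrix(rdm)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- data.frame(item_id = ids, m, check.names = FALSE)
  colnames(df) <- c("item_id", ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_rdm(m)
  as_rdm(m)
}
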