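# Genomic relationship matrix and its principal components, used as
# fixed-effect stratification covariates in the association scan.

#' Build a genomic relationship matrix
#'
#' Per-locus-standardised relationships: entry (j, k) is the mean over
#' usable loci of `(x_j - 2p)(x_k - 2p) / (2p(1 - p))`, with `p` the
#' alternate-allele frequency estimated from the analysis samples
#' themselves. Loci that are monomorphic in the sample are excluded.
#' Missing genotypes are handled by pairwise-complete locus exclusion by
#' default; `complete_cases = TRUE` restricts to loci with no missing call
#' in any sample.
#'
#' @param geno a [genotype_matrix()] with at least two samples.
#' @param loci optional integer vector of map row indices to build from
#'   (e.g. an autosomal subset); default all.
#' @param complete_cases use only fully observed loci instead of
#'   pairwise-complete exclusion.
#' @return an object of class `grm`: list with the symmetric relationship
#'   matrix `G`, `sample_ids` and `n_loci_used`.
#' @export
build_grm <- function(geno, loci = NULL, complete_cases = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosage
  if (nrow(X) < 2L) stop("at least two samples required")
  if (!is.null(loci)) X <- X[, as.integer(loci), drop = FALSE]
  if (complete_cases) {
    X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
  }
  p <- colMeans(X, na.rm = TRUE) / 2
  usable <- !is.na(p) & p > 0 & p < 1
  if (!any(usable)) stop("no polymorphic loci left to build the GRM from")
  X <- X[, usable, drop = FALSE]
  p <- p[usable]

  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  M <- !is.na(Z)
  Z[!M] <- 0
  num <- Z %*% t(Z)
  den <- M %*% t(M)  # loci observed in both members of each pair
  if (any(den == 0)) stop("some sample pair shares no observed locus")
  G <- num / den
  structure(list(G = G, sample_ids = rownames(X), n_loci_used = ncol(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$sample_ids), "samples,", x$n_loci_used, "loci;",
      sprintf("mean diagonal %.3f\n", mean(diag(x$G))))
  invisible(x)
}

#' Top principal components of a genomic relationship matrix
#'
#' Eigendecomposition of the GRM; component scores are the eigenvectors
#' scaled by the square root of their eigenvalues, with the sign of each
#' component fixed by forcing its largest-magnitude loading positive (for
#' reproducibility across platforms).
#'
#' @param grm a [build_grm()] result.
#' @param k number of components (default 10; must be below the sample
#'   count).
#' @return an object of class `pc_set`: list with `scores` (samples x k,
#'   rownames = sample ids), `eigenvalues` (all, non-increasing) and `k`.
#' @export
top_principal_components <- function(grm, k = 10L) {
  stopifnot(inherits(grm, "grm"))
  G <- grm$G
  if (!all(is.finite(G))) stop("GRM contains non-finite entries")
  n <- nrow(G)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1L) stop("k must be positive")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- vec %*% diag(sqrt(pmax(e$values[seq_len(k)], 0)), k, k)
  dimnames(scores) <- list(grm$sample_ids, paste0("PC", seq_len(k)))
  structure(list(scores = scores, eigenvalues = e$values, k = k),
            class = "pc_set")
}

#' @export
print.pc_set <- function(x, ...) {
  tot <- sum(pmax(x$eigenvalues, 0))
  expl <- sum(pmax(x$eigenvalues[seq_len(x$k)], 0)) / tot
  cat(sprintf("pc_set: %d components over %d samples (%.1f%% of variance)\n",
              x$k, nrow(x$scores), 100 * expl))
  invisible(x)
}

#' Write / read a GRM or PC score table as headered TSV
#' @param grm a `grm` object.
#' @param path file path.
#' @export
write_grm <- function(grm, path) {
  df <- as.data.frame(grm$G)
  colnames(df) <- grm$sample_ids
  df <- cbind(sample_id = grm$sample_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @param n_loci_used locus count to record when reading back.
#' @export
read_grm <- function(path, n_loci_used = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$sample_id
  structure(list(G = G, sample_ids = df$sample_id,
                 n_loci_used = n_loci_used), class = "grm")
}
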