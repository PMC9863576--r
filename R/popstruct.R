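#' Genomic kinship matrix
#'
#' Realized-relationship estimate from SNP dosages. Two standard variants:
#' `centered_ibs` column-centers the dosage matrix and scales the cross
#' product by the marker count; `vanraden` centers by twice the allele
#' frequency and scales by `2 * sum(p * (1 - p))`. Missing calls are
#' mean-imputed per marker for this computation only. Both variants are
#' symmetric and positive semi-definite by construction.
#'
#' @param G A [genotype_matrix()].
#' @param method `"centered_ibs"` (default) or `"vanraden"`.
#' @return Accession x accession numeric matrix with attribute `method`.
#' @export
kinship <- function(G, method = c("centered_ibs", "vanraden")) {
  method <- match.arg(method)
  if (ncol(G$calls) == 0) stop("kinship needs at least one marker")
  X <- impute_calls(G$calls)
  p <- colMeans(X) / 2
  if (method == "centered_ibs") {
    Z <- sweep(X, 2, colMeans(X))
    K <- tcrossprod(Z) / ncol(Z)
  } else {
    Z <- sweep(X, 2, 2 * p)
    denom <- 2 * sum(p * (1 - p))
    if (denom == 0) stop("all markers monomorphic; kinship undefined")
    K <- tcrossprod(Z) / denom
  }
  dimnames(K) <- list(accession_ids(G), accession_ids(G))
  attr(K, "method") <- method
  K
}

#' Allele-sharing distance
#'
#' Pairwise dissimilarity `1 - IBS`, where IBS is the proportion of shared
#' alleles (`1 - |g_i - g_j| / 2` per marker) averaged over markers with
#' non-missing calls in both accessions.
#'
#' @param G A [genotype_matrix()].
#' @return Symmetric accession x accession distance matrix.
#' @export
ibs_distance <- function(G) {
  calls <- G$calls
  M <- 1 - is.na(calls)                      # non-missing mask
  X <- calls; X[is.na(X)] <- 0L
  A0 <- (X == 0L & M == 1) * 1.0
  A2 <- (X == 2L & M == 1) * 1.0
  X <- X * M * 1.0
  # |a-b| = (a-b)^2 - 2*[{a,b}={0,2}];  (a-b)^2 = a^2 - 2ab + b^2 over shared markers
  sq <- X^2
  n_shared <- tcrossprod(M * 1.0)
  cross <- tcrossprod(X)
  s1 <- tcrossprod(sq, M * 1.0)              # sum a^2 over shared
  diffsq <- s1 + t(s1) - 2 * cross
  opp <- tcrossprod(A0, A2)
  absdiff <- diffsq - 2 * (opp + t(opp))
  D <- absdiff / (2 * n_shared)
  D[n_shared == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(accession_ids(G), accession_ids(G))
  D
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of the squared allele-sharing distance matrix:
#' double-centering of `-D^2 / 2` followed by eigen-decomposition. Axes are
#' sorted by eigenvalue; the percentage of variance of an axis is its
#' eigenvalue over the sum of positive eigenvalues. Each axis is oriented so
#' that its first non-zero score is non-negative (eigenvectors are defined
#' only up to sign).
#'
#' @param x A [genotype_matrix()] (distance computed via [ibs_distance()])
#'   or a symmetric distance matrix / `dist` object.
#' @return A `pcoa_result` list: `scores` (accession x axis, scaled by
#'   `sqrt(eigenvalue)`), `eigenvalues`, `pct_variance`.
#' @export
pcoa <- function(x) {
  D <- if (inherits(x, "genotype_matrix")) ibs_distance(x)
       else if (inherits(x, "dist")) as.matrix(x)
       else as.matrix(x)
  n <- nrow(D)
  if (n < 2) stop("PCoA needs at least two accessions")
  A <- -0.5 * D^2
  B <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  vals <- e$values
  pos <- vals > max(vals, 0) * 1e-10 & vals > 0
  if (!any(pos)) {
    warning("degenerate input: all eigenvalues are zero")
    return(structure(list(scores = matrix(0, n, 1,
                                          dimnames = list(rownames(D), "axis1")),
                          eigenvalues = 0, pct_variance = 0),
                     class = "pcoa_result"))
  }
  vecs <- e$vectors[, pos, drop = FALSE]
  vals <- vals[pos]
  scores <- sweep(vecs, 2, sqrt(vals), `*`)
  # sign convention: first non-zero score per axis non-negative
  for (k in seq_len(ncol(scores))) {
    nz <- which(abs(scores[, k]) > 1e-12)
    if (length(nz) && scores[nz[1], k] < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(rownames(D), paste0("axis", seq_along(vals)))
  structure(list(scores = scores, eigenvalues = vals,
                 pct_variance = 100 * vals / sum(vals)),
            class = "pcoa_result")
}

#' @export
#' @method print pcoa_result
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d accessions, %d positive axes; axis 1 explains %.1f%%\n",
              nrow(x$scores), length(x$eigenvalues), x$pct_variance[1]))
  invisible(x)
}

#' Eigenvector phenotypes for an eigenGWAS scan
#'
#' Turns the top `k` principal-coordinate axes into traits named
#' `eigen1..eigenk`, so that loci driving population differentiation can be
#' mapped with the same mixed-model engine as any other trait.
#'
#' @param p A [pcoa()] result.
#' @param k Number of axes (default 5).
#' @return Trait table tibble: `accession_id`, `trait`, `value`.
#' @export
eigen_phenotypes <- function(p, k = 5) {
  if (k <= 0) stop("k must be positive")
  if (k > ncol(p$scores)) stop("k exceeds the number of positive axes")
  out <- lapply(seq_len(k), function(i)
    tibble::tibble(accession_id = rownames(p$scores),
                   trait = paste0("eigen", i),
                   value = p$scores[, i]))
  dplyr::bind_rows(out)
}

#' Compute the population-structure bundle for association scans
#'
#' Convenience wrapper producing everything the mixed-model engine needs:
#' the kinship matrix, the fixed-effect principal components (PCA of the
#' mean-imputed, column-centered dosage matrix), the PCoA and the
#' eigenvector trait table.
#'
#' @param G A [genotype_matrix()] (after QC).
#' @param n_pcs Number of fixed-effect principal components (default 6).
#' @param n_eigen Number of eigenvector phenotypes (default 5).
#' @param kinship_method Passed to [kinship()].
#' @return List `K`, `pcs` (n x n_pcs score matrix), `pcoa`,
#'   `eigen_traits`.
#' @export
compute_structure <- function(G, n_pcs = 6, n_eigen = 5,
                              kinship_method = "centered_ibs") {
  K <- kinship(G, kinship_method)
  X <- impute_calls(G$calls)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pcs <- pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
  rownames(pcs) <- accession_ids(G)
  pc <- pcoa(G)
  list(K = K, pcs = pcs, pcoa = pc,
       eigen_traits = eigen_phenotypes(pc, min(n_eigen, ncol(pc$scores))))
}
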