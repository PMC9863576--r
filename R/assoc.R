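#' Association-scan configuration
#'
#' @param n_pcs_fixed Number of principal components used as fixed
#'   covariates (default 6).
#' @param threshold_logp Minimum -log10 p for a marker-trait association to
#'   be reported (default 3).
#' @param p3d Estimate variance components once under the null and reuse
#'   them for every marker test (default); `FALSE` refits REML per marker.
#' @param compression Either `"none"` (default) or an integer number of
#'   kinship groups: accessions are clustered on the kinship matrix and the
#'   model is fitted at group level with averaged phenotypes and kinship.
#' @param drop_collinear_pc_for_eigen When scanning eigenvector phenotypes,
#'   exclude the fixed principal component with the same index as the
#'   eigenvector under test, so a differentiation axis is never regressed on
#'   itself (default `TRUE`).
#' @export
assoc_config <- function(n_pcs_fixed = 6, threshold_logp = 3.0, p3d = TRUE,
                         compression = "none",
                         drop_collinear_pc_for_eigen = TRUE) {
  stopifnot(threshold_logp > 0, n_pcs_fixed >= 0)
  if (!identical(compression, "none")) {
    compression <- as.integer(compression)
    stopifnot(compression >= 1)
  }
  structure(list(n_pcs_fixed = n_pcs_fixed, threshold_logp = threshold_logp,
                 p3d = p3d, compression = compression,
                 drop_collinear_pc_for_eigen = drop_collinear_pc_for_eigen),
            class = "assoc_config")
}

# Restricted log-likelihood of the variance ratio delta = sigma_g^2/sigma_e^2,
# in the eigenbasis of K. yr, Xr are rotated (U'y, U'X); d the eigenvalues.
reml_loglik_delta <- function(log_delta, yr, Xr, d) {
  delta <- exp(log_delta)
  w <- delta * d + 1
  Xw <- Xr / sqrt(w); yw <- yr / sqrt(w)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(yr); p <- ncol(Xr)
  XtX <- crossprod(Xw)
  ld_xtx <- determinant(XtX, logarithm = TRUE)$modulus
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(w)) + ld_xtx)
}

#' Fit the null mixed linear model (variance components)
#'
#' REML estimation of the genetic and residual variance of the model
#' `y = X beta + g + e`, `g ~ N(0, sigma_g^2 K)`, `e ~ N(0, sigma_e^2 I)`,
#' via a single eigen-decomposition of the kinship matrix and profiling of
#' the restricted likelihood over the variance ratio (the EMMA device).
#'
#' @param y Named numeric phenotype vector (names = accession ids).
#' @param X Fixed-effect design matrix (intercept + covariates); rows must
#'   match `y`. `NULL` means intercept only.
#' @param K Kinship matrix over the same accessions; must be positive
#'   semi-definite.
#' @return List `sigma_g2`, `sigma_e2`, `delta`, `loglik`, plus the
#'   eigen-decomposition (`U`, `d`) and `X` for reuse by [scan_markers()].
#' @export
fit_null_mlm <- function(y, X = NULL, K) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- cbind(X)
  if (!all(dim(K) == n) || nrow(X) != n) stop("dimension mismatch")
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("kinship matrix is not positive semi-definite")
  d <- pmax(e$values, 0)
  U <- e$vectors
  yr <- crossprod(U, y)[, 1]
  Xr <- crossprod(U, X)
  grid <- seq(-10, 10, length.out = 41)
  ll <- vapply(grid, reml_loglik_delta, numeric(1), yr = yr, Xr = Xr, d = d)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_loglik_delta, c(lo, hi), maximum = TRUE,
                         yr = yr, Xr = Xr, d = d, tol = 1e-8)
  delta <- exp(opt$maximum)
  # treat boundary solutions as (near-)zero / large ratio; keep the value
  w <- delta * d + 1
  fit <- stats::lm.fit(Xr / sqrt(w), yr / sqrt(w))
  sigma_e2 <- sum(fit$residuals^2) / (n - ncol(X))
  list(sigma_g2 = delta * sigma_e2, sigma_e2 = sigma_e2, delta = delta,
       loglik = opt$objective, U = U, d = d, X = X)
}

#' Mixed-model single-marker scan
#'
#' Tests every marker as a fixed additive term (dosage 0/1/2, missing calls
#' mean-imputed per marker) in the model of [fit_null_mlm()], by
#' generalized least squares after whitening with the estimated covariance
#' `sigma_g^2 K + sigma_e^2 I`. Under P3D the variance components come from
#' the null fit; otherwise REML is refitted per marker. The reported
#' `r2` is the squared partial correlation between the whitened marker and
#' whitened phenotype given the fixed covariates (the marker's incremental
#' variance explained in the transformed model). Markers whose whitened
#' dosage is collinear with the covariates (or constant after imputation)
#' are skipped and counted.
#'
#' @param y Named phenotype vector.
#' @param G A [genotype_matrix()] over the same accessions.
#' @param X Fixed covariate matrix (intercept added automatically).
#' @param K Kinship matrix.
#' @param cfg An [assoc_config()].
#' @param map Optional marker map used to annotate results.
#' @param trait_name,trait_class Annotation carried into the result.
#' @param return_all Return all markers, not only those over the threshold.
#' @return Tibble of marker-trait associations: `marker_id`, `chromosome`,
#'   `cM`, `bp`, `trait`, `trait_class`, `minus_log10_p`, `r2`, `effect`.
#'   Attribute `"n_skipped"` counts untestable markers.
#' @export
scan_markers <- function(y, G, X = NULL, K, cfg = assoc_config(), map = NULL,
                         trait_name = "trait", trait_class = "P",
                         return_all = FALSE) {
  acc <- accession_ids(G)
  if (is.null(names(y))) names(y) <- acc
  if (!all(acc %in% names(y))) stop("dimension mismatch: phenotype vs genotypes")
  y <- y[acc]
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), X)
  if (nrow(X0) != length(y)) stop("dimension mismatch: covariates")
  if (!identical(cfg$compression, "none")) {
    comp <- compress_accessions(y, G, X0, K, cfg$compression)
    y <- comp$y; X0 <- comp$X; K <- comp$K; Gmat <- comp$Gmat
  } else {
    Gmat <- impute_calls(G$calls)
  }
  n <- length(y)
  null <- fit_null_mlm(y, X0, K)
  if (cfg$p3d) {
    res <- gls_marker_tests(null, y, Gmat)
  } else {
    res <- exact_marker_tests(y, X0, K, Gmat)
  }
  p <- ncol(X0)
  out <- tibble::tibble(
    marker_id = colnames(Gmat),
    trait = trait_name, trait_class = trait_class,
    minus_log10_p = unname(-log10(res$pval)), r2 = unname(res$r2),
    effect = unname(res$beta), skipped = unname(res$skipped))
  if (!is.null(map)) {
    idx <- match(out$marker_id, map$marker_id)
    out$chromosome <- map$chromosome[idx]
    out$cM <- map$cM[idx]
    out$bp <- map$bp[idx]
    out <- out[, c("marker_id", "chromosome", "cM", "bp", "trait",
                   "trait_class", "minus_log10_p", "r2", "effect", "skipped")]
  }
  n_skipped <- sum(out$skipped)
  if (!return_all) {
    out <- out[!out$skipped & out$minus_log10_p > cfg$threshold_logp, ]
    if (!nrow(out) && n_skipped == ncol(Gmat))
      warning("all markers skipped")
  }
  out$skipped <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "null_fit") <- null[c("sigma_g2", "sigma_e2", "delta", "loglik")]
  out
}

# Vectorized whitened-GLS marker tests given the null variance components.
gls_marker_tests <- function(null, y, Gmat) {
  w <- null$delta * null$d + 1
  sw <- sqrt(w)
  Ut <- t(null$U)
  yt <- (Ut %*% y)[, 1] / sw
  Xt <- (Ut %*% null$X) / sw
  Gt <- (Ut %*% Gmat) / sw
  qr_x <- qr(Xt)
  Q <- qr.Q(qr_x)
  yr <- yt - Q %*% crossprod(Q, yt)
  Gr <- Gt - Q %*% crossprod(Q, Gt)
  n <- length(yt); p <- qr_x$rank
  df <- n - p - 1
  gss <- colSums(Gr^2)
  tol <- max(colSums(Gt^2), 1) * 1e-10
  skipped <- gss <= tol
  gss[skipped] <- NA_real_
  bnum <- colSums(Gr * as.vector(yr))
  beta <- bnum / gss
  rss0 <- sum(yr^2)
  rss1 <- pmax(rss0 - bnum^2 / gss, 0)
  Fstat <- (bnum^2 / gss) / (rss1 / df)
  pval <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  r2 <- Fstat / (Fstat + df)
  list(pval = pval, beta = beta, r2 = r2, skipped = skipped)
}

# Exact per-marker REML refit (slow path, small problems only).
exact_marker_tests <- function(y, X0, K, Gmat) {
  m <- ncol(Gmat)
  pval <- beta <- r2 <- rep(NA_real_, m)
  skipped <- logical(m)
  for (j in seq_len(m)) {
    g <- Gmat[, j]
    Xj <- cbind(X0, g)
    if (qr(Xj)$rank <= qr(X0)$rank) { skipped[j] <- TRUE; next }
    nullj <- fit_null_mlm(y, Xj, K)
    res <- gls_marker_tests(list(delta = nullj$delta, d = nullj$d,
                                 U = nullj$U, X = X0),
                            y, Gmat[, j, drop = FALSE])
    pval[j] <- res$pval; beta[j] <- res$beta; r2[j] <- res$r2
    skipped[j] <- res$skipped
  }
  list(pval = pval, beta = beta, r2 = r2, skipped = skipped)
}

# Kinship-guided compression: cluster accessions into g groups and average
# phenotype, covariates, dosages and kinship at group level.
compress_accessions <- function(y, G, X0, K, g) {
  hc <- stats::hclust(stats::as.dist(max(K) - K), method = "average")
  grp <- stats::cutree(hc, k = min(g, length(y)))
  M <- sweep(stats::model.matrix(~ 0 + factor(grp)), 2, tabulate(grp), `/`)
  list(y = as.vector(crossprod(M, y)),
       X = crossprod(M, X0),
       K = crossprod(M, K %*% M),
       Gmat = crossprod(M, impute_calls(G$calls)))
}

#' Run one family of association scans
#'
#' Scans every trait of a trait table with the PCA + kinship mixed model and
#' concatenates the marker-trait associations, annotated with the trait
#' class: `"P"` phenology, `"C"` climate, `"E"` eigenvector. For class
#' `"E"`, when `cfg$drop_collinear_pc_for_eigen` is on and the trait is
#' named `eigen<k>`, the k-th fixed principal component is excluded from
#' the covariates of that scan.
#'
#' @param traits Trait table tibble `accession_id`, `trait`, `value`.
#' @param trait_class One of `"P"`, `"C"`, `"E"`.
#' @param G A [genotype_matrix()].
#' @param structure Structure bundle from [compute_structure()].
#' @param cfg An [assoc_config()].
#' @param map Optional marker map for annotation.
#' @return Tibble of associations over the threshold (one row per
#'   marker-trait pair).
#' @export
run_scan_family <- function(traits, trait_class, G, structure,
                            cfg = assoc_config(), map = NULL) {
  if (!trait_class %in% c("P", "C", "E"))
    stop("unknown trait class: ", trait_class)
  if (!nrow(traits)) return(empty_mta())
  pcs_all <- structure$pcs[, seq_len(min(cfg$n_pcs_fixed, ncol(structure$pcs))),
                           drop = FALSE]
  out <- list()
  for (tr in unique(traits$trait)) {
    d <- traits[traits$trait == tr, ]
    y <- stats::setNames(d$value, d$accession_id)
    pcs <- pcs_all
    if (trait_class == "E" && cfg$drop_collinear_pc_for_eigen &&
        grepl("^eigen[0-9]+$", tr)) {
      k <- as.integer(sub("^eigen", "", tr))
      if (k <= ncol(pcs)) pcs <- pcs[, -k, drop = FALSE]
    }
    if (ncol(pcs) == 0) pcs <- NULL
    out[[tr]] <- scan_markers(y, G, pcs, structure$K, cfg, map = map,
                              trait_name = tr, trait_class = trait_class)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_skipped") <- sum(vapply(out, function(x) attr(x, "n_skipped"),
                                       numeric(1)))
  res
}

empty_mta <- function() {
  tibble::tibble(marker_id = character(0), trait = character(0),
                 trait_class = character(0), minus_log10_p = numeric(0),
                 r2 = numeric(0), effect = numeric(0))
}
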