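# Independent oracles used to validate the package implementations.
# These deliberately use the most direct (dense, loop-based) formulations.

# Build a small genotype_matrix from an integer matrix.
toy_geno <- function(calls, acc = NULL, mk = NULL, ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  rownames(calls) <- acc %||% sprintf("a%02d", seq_len(nrow(calls)))
  colnames(calls) <- mk %||% sprintf("m%02d", seq_len(ncol(calls)))
  al <- if (is.null(ref)) NULL else
    tibble::tibble(marker_id = colnames(calls), ref = ref, alt = alt)
  genotype_matrix(calls, al)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weir & Cockerham (1984) multi-population theta estimator, textbook form,
# genotype-based (observed heterozygote frequencies).
wc_fst <- function(calls, pop) {
  pops <- unique(pop)
  r <- length(pops)
  num <- den <- 0
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      gk <- g[pop == pops[k]]
      gk <- gk[!is.na(gk)]
      ni[k] <- length(gk)
      if (ni[k] == 0) next
      pi[k] <- mean(gk) / 2
      hi[k] <- mean(gk == 1)
    }
    if (any(ni < 2)) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force double-loop kinship matching the centered-IBS formula.
brute_kinship_centered <- function(calls) {
  X <- calls * 1.0
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mu
    X[, j] <- X[, j] - mu
  }
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    K[i, k] <- sum(X[i, ] * X[k, ]) / ncol(X)
  K
}

# Brute-force allele-sharing distance (per-pair loop over markers).
brute_ibs_distance <- function(calls) {
  n <- nrow(calls)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[k, ])
    D[i, k] <- mean(abs(calls[i, ok] - calls[k, ok]) / 2)
  }
  D
}

# Exact whitened-GLS marker tests given variance components: builds the full
# covariance, Cholesky-whitens, and runs a textbook F-test per marker.
brute_gls_scan <- function(y, X, Gmat, K, sigma_g2, sigma_e2) {
  n <- length(y)
  V <- sigma_g2 * K + sigma_e2 * diag(n)
  L <- chol(V)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  m <- ncol(Gmat)
  pval <- beta <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    wg <- backsolve(L, Gmat[, j], transpose = TRUE)
    Xf <- cbind(wX, wg)
    fit1 <- stats::lm.fit(Xf, wy)
    fit0 <- stats::lm.fit(wX, wy)
    if (fit1$rank <= fit0$rank) next
    rss1 <- sum(fit1$residuals^2)
    rss0 <- sum(fit0$residuals^2)
    df <- n - fit1$rank
    Fst <- (rss0 - rss1) / (rss1 / df)
    pval[j] <- stats::pf(Fst, 1, df, lower.tail = FALSE)
    beta[j] <- fit1$coefficients[ncol(Xf)]
  }
  list(pval = pval, beta = beta)
}

# Henderson mixed-model-equation solve for the augmented-design model, at
# given variance components; returns accession BLUPs.
henderson_blups <- function(d, trait, vc) {
  # d must carry the same derived factors reml_blup builds internally
  X <- stats::model.matrix(~ check, d)
  Zr <- stats::model.matrix(~ 0 + rowf, d)
  Zc <- stats::model.matrix(~ 0 + colf, d)
  Za <- stats::model.matrix(~ 0 + acc, d)
  Z <- cbind(Zr, Zc, Za)
  lam <- c(rep(vc$sigma_e2 / vc$sigma_row2, ncol(Zr)),
           rep(vc$sigma_e2 / vc$sigma_col2, ncol(Zc)),
           rep(vc$sigma_e2 / vc$sigma_acc2, ncol(Za)))
  y <- d[[trait]]
  A <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lam)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(A, rhs)
  u <- sol[(ncol(X) + 1):length(sol)]
  acc_u <- u[(ncol(Zr) + ncol(Zc) + 1):length(u)]
  names(acc_u) <- sub("^acc", "", colnames(Za))
  acc_u
}

# Rebuild the internal model frame reml_blup uses for one year.
blup_frame <- function(plots, trait, year) {
  checks <- unique(plots$genotype_id[plots$is_check])
  d <- plots[plots$year == year & !is.na(plots[[trait]]), ]
  d$check <- factor(ifelse(d$is_check, d$genotype_id, "none"),
                    levels = c("none", sort(checks)))
  d$rowf <- factor(d$row); d$colf <- factor(d$column)
  d$acc <- factor(d$genotype_id)
  d
}

# Simulated structured panel, small scale.
small_panel <- function(n = 60, m = 400, fst = 0.1, seed = 11, admix = 0.2) {
  cfg <- sim_config(n_accessions = n, n_markers = m, fst = fst,
                    admix_fraction = admix, seed = seed,
                    n_chromosomes = min(21, m))
  simulate_population(cfg)
}

# Mean-imputed dosage matrix (test-side copy of the package's rule).
impute_g <- function(G) {
  X <- G$calls * 1.0
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mu
  }
  X
}
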