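sim_instance <- function(n, m, seed, h2 = 0.4) {
  sim <- small_panel(n = n, m = m, fst = 0.1, seed = seed)
  K <- kinship(sim$geno)
  X <- impute_g(sim$geno)
  withr::with_seed(seed + 1000, {
    g <- as.vector(X %*% stats::rnorm(m, 0, sqrt(1 / m)))
    y <- stats::setNames(sqrt(h2) * scale(g)[, 1] +
                           sqrt(1 - h2) * stats::rnorm(n),
                         accession_ids(sim$geno))
  })
  list(sim = sim, K = K, y = y)
}

test_that("null-model variance components behave in the closed-form limits", {
  inst <- sim_instance(50, 80, 31)
  n <- length(inst$y)
  # K = identity: total variance equals the OLS unbiased residual estimator
  fit <- fit_null_mlm(inst$y, NULL, diag(n))
  s2 <- sum((inst$y - mean(inst$y))^2) / (n - 1)
  expect_equal(fit$sigma_g2 + fit$sigma_e2, s2, tolerance = 1e-6)
  expect_error(fit_null_mlm(rep(1, n), NULL, diag(n)), "zero phenotypic")
  expect_error(fit_null_mlm(inst$y, NULL, -diag(n)), "positive semi-definite")
})

test_that("variance ratio tracks the simulated genetic architecture", {
  # pure-noise phenotype: genetic fraction near zero
  sim <- small_panel(n = 80, m = 400, fst = 0.1, seed = 32)
  K <- kinship(sim$geno)
  y0 <- withr::with_seed(1, stats::rnorm(80))
  f0 <- fit_null_mlm(y0, NULL, K)
  expect_lt(f0$sigma_g2 / (f0$sigma_g2 + f0$sigma_e2), 0.2)
  # phenotype built from K (h2 = 1 construction): large ratio
  L <- chol(K + diag(1e-8, 80))
  y1 <- withr::with_seed(2, as.vector(crossprod(L, stats::rnorm(80))))
  f1 <- fit_null_mlm(y1, NULL, K)
  expect_gt(f1$delta, 10)
})

test_that("scan p-values equal the whitened-GLS brute-force oracle", {
  for (seed in c(41, 42, 43)) {
    n <- sample(25:40, 1)
    inst <- sim_instance(n, 60, seed)
    st_pcs <- stats::prcomp(impute_g(inst$sim$geno))$x[, 1:3]
    res <- scan_markers(inst$y, inst$sim$geno, st_pcs, inst$K,
                        assoc_config(), return_all = TRUE)
    null <- attr(res, "null_fit")
    oracle <- brute_gls_scan(inst$y, cbind(1, st_pcs), impute_g(inst$sim$geno),
                             inst$K, null$sigma_g2, null$sigma_e2)
    p_pkg <- 10^(-res$minus_log10_p)
    ok <- !is.na(oracle$pval)
    expect_lt(max(abs(p_pkg[ok] - oracle$pval[ok]) / oracle$pval[ok]), 1e-8)
    expect_equal(res$effect[ok], oracle$beta[ok], tolerance = 1e-6)
  }
})

test_that("markers collinear with covariates are skipped with a count", {
  inst <- sim_instance(30, 20, 44)
  X <- impute_g(inst$sim$geno)
  cov1 <- X[, 1]  # covariate equal to marker 1
  res <- scan_markers(inst$y, inst$sim$geno, cbind(cov1), inst$K,
                      return_all = TRUE)
  expect_gte(attr(res, "n_skipped"), 1)
  expect_true(is.na(res$minus_log10_p[1]))
})

test_that("r2 decreases monotonically as a marker effect is diluted by noise", {
  sim <- small_panel(n = 100, m = 50, seed = 45, admix = 0)
  K <- kinship(sim$geno)
  g <- impute_g(sim$geno)[, 7]
  r2s <- sapply(c(0.5, 1, 2, 4), function(sd_e) {
    y <- stats::setNames(2 * g + withr::with_seed(3, stats::rnorm(100, 0, 1)) * sd_e,
                         accession_ids(sim$geno))
    res <- scan_markers(y, sim$geno, NULL, K, return_all = TRUE)
    res$r2[7]
  })
  expect_true(all(diff(r2s) < 0))
})

test_that("permuted phenotypes exceed the threshold at the nominal rate", {
  sim <- small_panel(n = 100, m = 300, fst = 0.1, seed = 46)
  K <- kinship(sim$geno)
  pcs <- stats::prcomp(impute_g(sim$geno))$x[, 1:3]
  hits <- 0; total <- 0
  for (s in 1:10) {
    y <- withr::with_seed(s, stats::setNames(stats::rnorm(100),
                                             accession_ids(sim$geno)))
    res <- scan_markers(y, sim$geno, pcs, K, return_all = TRUE)
    hits <- hits + sum(res$minus_log10_p > 3, na.rm = TRUE)
    total <- total + sum(!is.na(res$minus_log10_p))
  }
  expect_lte(hits, stats::qbinom(0.999, total, 1e-3))
})

test_that("scan families wire the eigenvector collinearity guard", {
  sim <- small_panel(n = 50, m = 120, seed = 47)
  st <- compute_structure(sim$geno)
  cfg <- assoc_config(threshold_logp = 0.5)
  res <- run_scan_family(st$eigen_traits[st$eigen_traits$trait == "eigen1", ],
                         "E", sim$geno, st, cfg, map = sim$map)
  expect_true(all(res$trait_class == "E"))
  expect_error(run_scan_family(st$eigen_traits, "X", sim$geno, st),
               "unknown trait class")
  expect_equal(nrow(run_scan_family(st$eigen_traits[0, ], "E", sim$geno, st)), 0)
  # with the guard off, eigen1 regressed with all PCs fixed finds (almost)
  # nothing because the matching PC absorbs the signal
  cfg_on <- assoc_config(threshold_logp = 3)
  res_on <- run_scan_family(st$eigen_traits[st$eigen_traits$trait == "eigen1", ],
                            "E", sim$geno, st, cfg_on, map = sim$map)
  cfg_off <- assoc_config(threshold_logp = 3, drop_collinear_pc_for_eigen = FALSE)
  res_off <- run_scan_family(st$eigen_traits[st$eigen_traits$trait == "eigen1", ],
                             "E", sim$geno, st, cfg_off, map = sim$map)
  expect_gte(nrow(res_on), nrow(res_off))
})

test_that("kinship compression reduces the model to group level", {
  inst <- sim_instance(45, 40, 48)
  res <- scan_markers(inst$y, inst$sim$geno, NULL, inst$K,
                      assoc_config(compression = 15), return_all = TRUE)
  expect_equal(nrow(res), 40)
  expect_true(all(is.finite(res$minus_log10_p[!is.na(res$minus_log10_p)])))
})

test_that("a planted QTL is detected by the full scan family", {
  sim <- small_panel(n = 90, m = 150, seed = 49)
  mk <- marker_ids(sim$geno)[30]
  plots <- simulate_phenology(sim$geno, planted_effect(mk, "D65", 3),
                              h2 = 0.7, years = 1, layout = c(11, 10),
                              sd_row = 0.5, sd_col = 0.5, seed = 50)
  d <- plots[!plots$is_check, ]
  traits <- tibble::tibble(accession_id = d$genotype_id, trait = "D65",
                           value = d$D65)
  st <- compute_structure(sim$geno)
  res <- run_scan_family(traits, "P", sim$geno, st, assoc_config(),
                         map = sim$map)
  expect_true(mk %in% res$marker_id)
})
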