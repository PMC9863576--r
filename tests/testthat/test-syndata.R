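test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config(n_accessions = 20, n_markers = 60, fst = 0.1, seed = 42)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$meta, b$meta)
  expect_identical(a$map, b$map)
  c2 <- simulate_population(sim_config(n_accessions = 20, n_markers = 60,
                                       fst = 0.1, seed = 43))
  expect_false(identical(a$geno$calls, c2$geno$calls))
})

test_that("simulated panels satisfy their structural contracts", {
  cfg <- sim_config(n_accessions = 30, n_markers = 100, fst = 0.2,
                    admix_fraction = 0.3, seed = 5)
  sim <- simulate_population(cfg)
  expect_true(all(sim$geno$calls %in% 0:2))
  expect_true(all(sim$geno$alleles$ref %in% c("A", "C", "G", "T")))
  expect_true(all(sim$geno$alleles$ref != sim$geno$alleles$alt))
  expect_true(all(sim$meta$subpop %in% c("SP1", "SP2", "SP3")))
  # accessions carry countries from their subpopulation's pool
  pools <- cfg$country_pools
  for (i in seq_len(nrow(sim$meta)))
    expect_true(sim$meta$country[i] %in% pools[[sim$meta$subpop[i]]])
  # map strictly increasing within chromosome, both scales
  for (ch in unique(sim$map$chromosome)) {
    mp <- sim$map[sim$map$chromosome == ch, ]
    expect_true(all(diff(mp$cM) > 0))
    expect_true(all(diff(mp$bp) > 0))
  }
  expect_error(simulate_population(sim_config(n_accessions = 5, n_markers = 3,
                                              n_chromosomes = 21)),
               "invalid config")
})

test_that("fst = 0 gives vanishing subpopulation divergence at large n", {
  cfg <- sim_config(n_accessions = 300, n_markers = 200, fst = 0,
                    admix_fraction = 0, seed = 2)
  sim <- simulate_population(cfg)
  f <- sapply(c("SP1", "SP2"), function(sp) {
    colMeans(sim$geno$calls[sim$meta$subpop == sp, ]) / 2
  })
  expect_lt(mean(abs(f[, 1] - f[, 2])), 0.08)
})

test_that("realized Fst matches the Balding-Nichols parameter (W-C oracle)", {
  cfg <- sim_config(n_accessions = 150, n_markers = 5000, fst = 0.10,
                    admix_fraction = 0, seed = 9)
  sim <- simulate_population(cfg)
  theta <- wc_fst(sim$geno$calls, sim$meta$subpop)
  expect_lt(abs(theta - 0.10), 0.02)
})

test_that("phenology plots reduce to the genetic score in the noiseless limit", {
  sim <- small_panel(n = 25, m = 40, seed = 3)
  eff <- planted_effect(marker_ids(sim$geno)[c(2, 7)], "D65", c(2, -1))
  plots <- simulate_phenology(sim$geno, eff, h2 = 1, years = 1,
                              layout = c(6, 6),
                              base = c(D45 = 0, D55 = 0, D65 = 0, D87 = 0),
                              sd_year = 0, sd_row = 0, sd_col = 0,
                              sd_resid_null = 0, seed = 1)
  g <- sim$geno$calls[, c(2, 7)] %*% c(2, -1)
  test <- plots[!plots$is_check, ]
  expect_equal(test$D65, unname(g[test$genotype_id, 1]), tolerance = 1e-12)
  expect_equal(plots$DBA, plots$D65 - plots$D45)
  expect_equal(plots$GFD, plots$D87 - plots$D65)
  # checks at a 1:5 ratio, two replicated check cultivars
  expect_equal(sum(plots$is_check), 2 * ceiling(25 / 10))
  expect_setequal(unique(plots$genotype_id[plots$is_check]),
                  c("Anza", "Soissons"))
  expect_error(simulate_phenology(sim$geno, eff, layout = c(3, 3)),
               "invalid config")
})

test_that("an OLS oracle recovers a planted additive effect", {
  sim <- small_panel(n = 80, m = 30, seed = 4, admix = 0)
  mk <- marker_ids(sim$geno)[5]
  beta_true <- 3
  slopes <- sapply(1:40, function(s) {
    plots <- simulate_phenology(sim$geno, planted_effect(mk, "D65", beta_true),
                                h2 = 0.5, years = 1, layout = c(10, 10),
                                sd_row = 0, sd_col = 0, seed = s)
    d <- plots[!plots$is_check, ]
    stats::coef(stats::lm(d$D65 ~ sim$geno$calls[d$genotype_id, mk]))[2]
  })
  expect_lt(abs(mean(slopes) - beta_true), 3 * stats::sd(slopes) / sqrt(40))
})

test_that("without planted effects the phenotype is uncorrelated with markers", {
  sim <- small_panel(n = 60, m = 50, seed = 6, admix = 0, fst = 0)
  plots <- simulate_phenology(sim$geno, h2 = 0.5, years = 1, layout = c(9, 9),
                              sd_row = 0, sd_col = 0, seed = 8)
  d <- plots[!plots$is_check, ]
  r <- abs(stats::cor(d$D65, sim$geno$calls[d$genotype_id, ]))
  # Bonferroni-style null envelope for 50 independent correlations at n = 60
  crit <- stats::qnorm(1 - 0.025 / 50) / sqrt(nrow(d) - 3)
  expect_lt(max(tanh(atanh(r))), crit * 1.25)
})

test_that("climate simulation shares subpopulation means across countries", {
  sim <- small_panel(n = 40, m = 30, seed = 12)
  clim0 <- simulate_climate(sim$meta, country_noise_sd = 0, seed = 1)
  merged <- merge(clim0, unique(sim$meta[, c("country", "subpop")]))
  spread <- tapply(merged$value,
                   paste(merged$subpop, merged$variable, merged$period),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  expect_identical(simulate_climate(sim$meta, seed = 7),
                   simulate_climate(sim$meta, seed = 7))
  bad <- data.frame(subpop = "SP1", variable = "Tmax", period = "XX", mean = 1)
  expect_error(simulate_climate(sim$meta, bad), "unknown period")
})

test_that("subpopulation climate separation is detectable by ANOVA", {
  sim <- small_panel(n = 60, m = 30, seed = 13)
  sp_means <- data.frame(subpop = c("SP1", "SP2", "SP3"), variable = "Tmax",
                         period = "SA", mean = c(10, 20, 30))
  clim <- simulate_climate(sim$meta, sp_means, country_noise_sd = 1, seed = 2)
  merged <- merge(clim, unique(sim$meta[, c("country", "subpop")]))
  fit <- stats::aov(value ~ subpop, data = merged)
  expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 0.001)
})

test_that("planted expression deltas pass the DEG filter exactly", {
  sim <- small_panel(n = 20, m = 50, seed = 14)
  ae <- simulate_annotation_expression(sim$map, n_genes = 100,
                                       stress_up_fraction = 0.1,
                                       delta_tpm_range = c(5, 5), seed = 3)
  expect_equal(nrow(ae$planted), 10)
  sel <- deg_filter(ae$annotation, ae$expression, 2)
  expect_setequal(paste(sel$gene_id, sel$tissue),
                  paste(ae$planted$gene_id, ae$planted$tissue))
  # no planted upregulation -> nothing selected
  ae0 <- simulate_annotation_expression(sim$map, n_genes = 50,
                                        stress_up_fraction = 0, seed = 4)
  expect_equal(nrow(deg_filter(ae0$annotation, ae0$expression, 2)), 0)
  # gene intervals valid and sorted within chromosome
  expect_true(all(ae$annotation$start <= ae$annotation$end))
  expect_true(all(ae$annotation$start >= 0))
  expect_error(simulate_annotation_expression(sim$map, n_genes = 0), "positive")
})
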