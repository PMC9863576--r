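catalogue <- function() {
  read_hotspot_table(system.file("extdata", "wheat_hotspot_catalogue.tsv",
                                 package = "medscan"))
}

test_that("MTA position standardization follows the 95% Gaussian width", {
  expect_equal(mta_sigma(3.92), 1.0)
  expect_equal(mta_sigma(10), 10 / 3.92, tolerance = 1e-12)
  expect_equal(round(mta_sigma(10), 3), 2.551)
  expect_error(mta_sigma(0), "positive")
  expect_error(mta_sigma(-1), "positive")
})

test_that("overview index evaluates Gaussian densities per experiment", {
  mtas <- tibble::tibble(chromosome = "1A", cM = 50, trait_class = "P")
  ov <- overview_index(mtas, c(`1A` = 100), ld_ci = 3.92, nbE = 1)
  u50 <- ov$profile$U[ov$profile$cM == 50]
  expect_equal(u50, 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(ov$mean_threshold, 1 / 100)
  # linearity: duplicating the MTA doubles the profile
  ov2 <- overview_index(mtas[c(1, 1), ], c(`1A` = 100), 3.92, 1)
  expect_equal(ov2$profile$U, 2 * ov$profile$U)
  # nbE divides
  ov3 <- overview_index(mtas, c(`1A` = 100), 3.92, nbE = 4)
  expect_equal(ov3$profile$U, ov$profile$U / 4)
  expect_warning(overview_index(mtas[0, ], c(`1A` = 100), 3.92, 1), "no MTAs")
})

test_that("overview index conserves MTA mass away from map edges", {
  withr::with_seed(5, {
    mtas <- tibble::tibble(
      chromosome = sample(c("1A", "2B", "3D"), 100, replace = TRUE),
      cM = stats::runif(100, 20, 130), trait_class = "P")
  })
  lens <- c(`1A` = 150, `2B` = 150, `3D` = 150)
  ov <- overview_index(mtas, lens, ld_ci = 8, nbE = 5)
  mass <- sum(ov$profile$U)  # Riemann sum at 1 cM spacing
  expect_lt(abs(mass - 100 / 5) / (100 / 5), 0.01)
})

test_that("peak detection counts runs and positions per the contract", {
  mtas <- tibble::tibble(chromosome = "1A", cM = c(10.5, 11.2, 40),
                         trait_class = "P")
  prof <- overview_index(mtas, c(`1A` = 60), ld_ci = 3.92, nbE = 1)
  # hand-set profile: craft exact over-threshold pattern {10,11,12} and {40}
  prof$profile$U <- 0
  prof$profile$U[prof$profile$cM %in% c(10, 11, 12)] <- c(0.5, 0.9, 0.5)
  prof$profile$U[prof$profile$cM == 40] <- 0.4
  pk <- detect_peaks(prof, 0.3)
  expect_equal(attr(pk, "n_positions"), 4)
  expect_equal(attr(pk, "n_peaks"), 2)
  expect_equal(pk$peak_cM, c(11, 40))
  expect_gte(attr(pk, "n_positions"), attr(pk, "n_peaks"))
  # flat profile below threshold: nothing
  expect_equal(nrow(detect_peaks(prof, 10)), 0)
})

test_that("two Gaussians merge or split depending on the valley depth", {
  sigma <- 1; ld <- sigma * 3.92
  mk2 <- function(gap) {
    tibble::tibble(chromosome = "1A", cM = c(30, 30 + gap), trait_class = "P")
  }
  # 3 sigma apart: valley dips below a threshold cutting both humps
  prof_far <- overview_index(mk2(6), c(`1A` = 60), ld, 1)
  thr <- 0.3  # valley at +/-3 cM from each peak is ~0.013+0.013 << 0.3
  pk_far <- detect_peaks(prof_far, thr)
  expect_equal(attr(pk_far, "n_peaks"), 2)
  # 1 cM apart: single over-threshold run
  prof_near <- overview_index(mk2(1), c(`1A` = 60), ld, 1)
  pk_near <- detect_peaks(prof_near, thr)
  expect_equal(attr(pk_near, "n_peaks"), 1)
})

test_that("hotspot construction merges close peaks and names in cM order", {
  peaks <- tibble::tibble(chromosome = c("1A", "1A", "1A"),
                          peak_cM = c(10, 11, 50),
                          run_start = c(10, 11, 50), run_end = c(10, 11, 50),
                          n_positions = 1L, max_U = 1)
  map <- tibble::tibble(marker_id = sprintf("mk%02d", 1:8),
                        chromosome = "1A",
                        cM = c(7, 9, 11, 13, 47, 49, 51, 53),
                        bp = c(1, 2, 3, 4, 10, 11, 12, 13) * 1e6)
  mtas <- tibble::tibble(chromosome = "1A", cM = c(10, 11, 50),
                         trait_class = c("P", "C", "E"))
  hs <- build_hotspots(peaks, ld_ci = 4, map = map, mtas = mtas)
  expect_equal(hs$name, c("1A.1", "1A.2"))
  expect_equal(hs$cM_lo, c(8, 48))
  expect_equal(hs$cM_hi, c(13, 52))
  expect_equal(hs$trait_classes, c("C,P", "E"))
  expect_equal(hs$left_marker, c("mk02", "mk06"))
  expect_equal(hs$right_marker, c("mk04", "mk07"))
  # two peaks 50 cM apart with small ld stay separate (already shown);
  # 5-peak fixture: {10, 11, 13} chain-merge, {30} and {50} alone
  peaks5 <- tibble::tibble(chromosome = "1A",
                           peak_cM = c(10, 11, 13, 30, 50),
                           run_start = 0, run_end = 0, n_positions = 1L,
                           max_U = 1)
  hs5 <- build_hotspots(peaks5, 4, map, mtas)
  expect_equal(nrow(hs5), 3)
  # no physically mapped marker inside -> flagged, NA interval
  far_map <- dplyr::mutate(map, cM = cM + 1000)
  hs_na <- build_hotspots(peaks, 4, far_map, mtas)
  expect_true(all(hs_na$no_physical))
  expect_true(all(is.na(hs_na$ci_mb)))
})

test_that("physical intervals are order-insensitive and rounded to 2 decimals", {
  hs <- tibble::tibble(name = c("x.1", "x.2", "x.3"), chromosome = "1A",
                       left_bp = c(7643102, 38833829, 5e6),
                       right_bp = c(8296998, 26186242, 5e6))
  out <- physical_interval(hs)
  expect_equal(out$ci_mb, c(0.65, 12.65, 0))
  expect_equal(out$bp_lo[2], 26186242)
  expect_equal(out$bp_hi[2], 38833829)
})

test_that("selection keeps CIs at most 20 Mb and counts genomes", {
  hs <- physical_interval(tibble::tibble(
    name = c("1A.1", "1B.1", "2D.1"), chromosome = c("1A", "1B", "2D"),
    left_bp = c(0, 0, 0), right_bp = c(21e6, 16.37e6, 2e6)))
  sel <- select_hotspots(hs, 20)
  expect_equal(sel$name, c("1B.1", "2D.1"))
  expect_equal(attr(sel, "n_excluded"), 1)
  counts <- attr(sel, "genome_counts")
  expect_equal(unname(counts[c("B", "D")]), c(1L, 1L))
})

test_that("overlap merging unions intersecting intervals only", {
  hs <- physical_interval(tibble::tibble(
    name = c("1B.1", "1B.2", "1B.3", "2A.1"),
    chromosome = c("1B", "1B", "1B", "2A"),
    trait_classes = c("C", "P", "C", "E"),
    left_marker = "l", right_marker = "r",
    left_bp = c(26186242, 28563880, 100e6, 1e6),
    right_bp = c(38833829, 44933589, 101e6, 2e6)))
  merged <- merge_overlapping(hs)
  expect_equal(sort(merged$name), c("1B.1-2", "1B.3", "2A.1"))
  m <- merged[merged$name == "1B.1-2", ]
  expect_equal(m$bp_lo, 26186242)
  expect_equal(m$bp_hi, 44933589)
  expect_equal(m$trait_classes, "C,P")
  expect_equal(attr(merged, "merge_events"), list(c("1B.1", "1B.2")))
  # adjacent but disjoint (gap of 1 bp) stays separate; touching merges
  touch <- physical_interval(tibble::tibble(
    name = c("3B.1", "3B.2"), chromosome = "3B", trait_classes = "P",
    left_marker = "l", right_marker = "r",
    left_bp = c(1e6, 2e6), right_bp = c(2e6, 3e6)))
  expect_equal(nrow(merge_overlapping(touch)), 1)
  gap <- physical_interval(tibble::tibble(
    name = c("3B.1", "3B.2"), chromosome = "3B", trait_classes = "P",
    left_marker = "l", right_marker = "r",
    left_bp = c(1e6, 2e6 + 1), right_bp = c(2e6, 3e6)))
  expect_equal(nrow(merge_overlapping(gap)), 2)
})

test_that("planted MTA clusters surface as hotspots containing the truth", {
  sim <- small_panel(n = 60, m = 300, seed = 61)
  # fake a scan result: 4 MTAs clustered near 80 cM on 2A, 1 stray on 5D
  mtas <- tibble::tibble(
    chromosome = c(rep("2A", 4), "5D"),
    cM = c(79, 80, 80.5, 81.5, 30),
    trait_class = c("P", "P", "C", "P", "E"))
  lens <- stats::setNames(rep(175, 21), paste0(rep(1:7, each = 3), c("A", "B", "D")))
  ov <- overview_index(mtas, lens, ld_ci = 5, nbE = 2)
  pk <- detect_peaks(ov, "mean")
  hs <- build_hotspots(pk, 5, sim$map, mtas)
  on2a <- hs[hs$chromosome == "2A", ]
  expect_gte(nrow(on2a), 1)
  expect_true(any(on2a$cM_lo <= 80 & on2a$cM_hi >= 80))
})
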