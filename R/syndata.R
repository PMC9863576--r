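#' Simulation configuration for a structured landrace collection
#'
#' Defaults emulate a Mediterranean bread-wheat landrace panel: 153
#' accessions from three geographic subpopulations (West, North and East
#' Mediterranean) with a substantial admixed fraction, genotyped at ~10^4
#' biallelic SNPs spread over the 21 wheat chromosomes of a consensus
#' genetic map of ~3675 cM.
#'
#' @param n_accessions Number of accessions.
#' @param n_markers Total number of biallelic markers.
#' @param n_chromosomes Number of chromosomes (default 21, named 1A..7D).
#' @param map_length_cM Genetic length per chromosome (recycled).
#' @param bp_per_cM Physical-to-genetic scale for simulated bp positions.
#' @param n_subpops Number of subpopulations (labels SP1, SP2, ...).
#' @param fst Balding-Nichols divergence parameter, in [0, 1).
#' @param admix_fraction Fraction of accessions drawn as 50/50 two-subpopulation
#'   mixtures.
#' @param country_pools Optional named list of country labels per subpopulation;
#'   defaults to a 23-country Mediterranean split (7/8/8).
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_accessions = 153, n_markers = 10458,
                       n_chromosomes = 21, map_length_cM = 175,
                       bp_per_cM = 4e6, n_subpops = 3, fst = 0.10,
                       admix_fraction = 0.2, country_pools = NULL,
                       seed = 1L) {
  stopifnot(n_subpops >= 1, fst >= 0, fst < 1,
            admix_fraction >= 0, admix_fraction <= 1,
            n_accessions >= 1, n_markers >= 1, n_chromosomes >= 1)
  if (n_markers < n_chromosomes)
    stop("invalid config: n_markers must be >= n_chromosomes")
  if (n_chromosomes == 21) {
    chrom_names <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  } else {
    chrom_names <- paste0("chr", seq_len(n_chromosomes))
  }
  if (is.null(country_pools)) country_pools <- default_country_pools(n_subpops)
  structure(list(
    n_accessions = n_accessions, n_markers = n_markers,
    n_chromosomes = n_chromosomes, chrom_names = chrom_names,
    map_length_cM = rep_len(map_length_cM, n_chromosomes),
    bp_per_cM = bp_per_cM, n_subpops = n_subpops,
    subpop_labels = paste0("SP", seq_len(n_subpops)),
    fst = fst, admix_fraction = admix_fraction,
    country_pools = country_pools, seed = as.integer(seed)),
    class = "sim_config")
}

# 23 Mediterranean countries split into West / North / East pools.
default_country_pools <- function(n_subpops) {
  pools <- list(
    SP1 = c("Spain", "Portugal", "Morocco", "Algeria", "Tunisia", "France", "Italy"),
    SP2 = c("Albania", "Bosnia & Herzegovina", "Bulgaria", "Croatia", "Greece",
            "Macedonia", "Romania", "Serbia"),
    SP3 = c("Cyprus", "Egypt", "Israel", "Jordan", "Lebanon", "Libya", "Syria",
            "Turkey"))
  if (n_subpops <= 3) return(pools[seq_len(n_subpops)])
  extra <- lapply(seq_len(n_subpops - 3), function(i) paste0("Country", i))
  names(extra) <- paste0("SP", 4:n_subpops)
  c(pools, extra)
}

#' Simulate a structured genotype panel
#'
#' Allele frequencies follow the Balding-Nichols construction: an ancestral
#' frequency p ~ Uniform(0.1, 0.9) per marker, and per-subpopulation
#' frequencies Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst) (equal to p exactly when
#' Fst = 0). Genotypes are binomial draws of two alleles from the accession's
#' subpopulation frequency; admixed accessions draw marker-wise from the
#' 50/50 mixture of two subpopulation frequency vectors and are labeled by
#' their first mixture component. Markers are simulated independently.
#'
#' @param cfg A [sim_config()].
#' @return List with `geno` (a [genotype_matrix()]), `meta` (tibble:
#'   `accession_id`, `subpop`, `admixed`, `subpop2` (second mixture
#'   component, `NA` for non-admixed accessions), `country`) and `map`
#'   (tibble: `marker_id`, `chromosome`, `cM`, `bp`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_accessions; m <- cfg$n_markers; ns <- cfg$n_subpops
    p_anc <- stats::runif(m, 0.1, 0.9)
    if (cfg$fst == 0) {
      P <- matrix(rep(p_anc, ns), nrow = ns, byrow = TRUE)
    } else {
      a <- p_anc * (1 - cfg$fst) / cfg$fst
      b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
      P <- t(vapply(seq_len(ns), function(k) stats::rbeta(m, a, b), numeric(m)))
    }
    # subpopulation assignment: balanced, then admixed overlay
    sp <- rep_len(seq_len(ns), n)
    n_admix <- round(cfg$admix_fraction * n)
    admixed <- rep(FALSE, n)
    if (n_admix > 0 && ns >= 2) {
      idx <- sample.int(n, n_admix)
      admixed[idx] <- TRUE
    }
    calls <- matrix(0L, nrow = n, ncol = m)
    sp2 <- integer(n)
    for (i in seq_len(n)) {
      if (admixed[i]) {
        pair <- sample.int(ns, 2)
        sp[i] <- pair[1]; sp2[i] <- pair[2]
        freq <- (P[pair[1], ] + P[pair[2], ]) / 2
      } else {
        freq <- P[sp[i], ]
      }
      calls[i, ] <- stats::rbinom(m, 2L, freq)
    }
    acc_ids <- sprintf("acc%03d", seq_len(n))
    mk_ids <- sprintf("snp%05d", seq_len(m))
    rownames(calls) <- acc_ids; colnames(calls) <- mk_ids

    letters4 <- c("A", "C", "G", "T")
    ref <- sample(letters4, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(letters4, r), 1), character(1))
    alleles <- tibble::tibble(marker_id = mk_ids, ref = unname(ref), alt = unname(alt))

    chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
    cM <- numeric(m); bp <- numeric(m)
    for (c in seq_len(cfg$n_chromosomes)) {
      j <- which(chrom_of == c)
      pos <- sort(stats::runif(length(j), 0, cfg$map_length_cM[c]))
      # enforce strict monotonicity against (improbable) ties
      pos <- pos + seq_along(pos) * 1e-9
      cM[j] <- pos
      b <- round(pos * cfg$bp_per_cM)
      bp[j] <- b + cumsum(duplicated(b))
    }
    map <- tibble::tibble(marker_id = mk_ids,
                          chromosome = cfg$chrom_names[chrom_of],
                          cM = cM, bp = bp)

    countries <- vapply(seq_len(n), function(i) {
      pool <- cfg$country_pools[[sp[i]]]
      pool[sample.int(length(pool), 1)]
    }, character(1))
    meta <- tibble::tibble(accession_id = acc_ids,
                           subpop = cfg$subpop_labels[sp],
                           admixed = admixed,
                           subpop2 = ifelse(admixed, cfg$subpop_labels[pmax(sp2, 1)],
                                            NA_character_),
                           country = countries)
    list(geno = genotype_matrix(calls, alleles), meta = meta, map = map)
  })
}

#' Declare a planted marker effect
#'
#' Ground truth for parameter-recovery experiments: an additive per-allele
#' effect of a named marker on a named trait.
#'
#' @param marker_id Marker carrying the effect.
#' @param trait_name Trait the effect acts on (one of the stage traits
#'   D45/D55/D65/D87).
#' @param effect_size Additive effect per alternate allele, in trait units.
#' @export
planted_effect <- function(marker_id, trait_name = "D65", effect_size = 1) {
  tibble::tibble(marker_id = marker_id, trait_name = trait_name,
                 effect_size = effect_size)
}

#' Simulate augmented-design phenology trials
#'
#' Emulates a non-replicated augmented field design with two replicated check
#' cultivars at a 1:5 check:test ratio. Each test accession appears once per
#' year; plot values are base mean + year effect + row and column effects +
#' additive genetic score from the planted effects + residual, with the
#' residual variance scaled so that the genetic score explains `h2` of the
#' (non-design) phenotypic variance. Stage traits are days from sowing;
#' DBA = D65 - D45 and GFD = D87 - D65 are derived, never simulated
#' independently.
#'
#' @param G A [genotype_matrix()].
#' @param effects Tibble of [planted_effect()] rows (may be empty).
#' @param h2 Heritability of the planted genetic score within a year.
#' @param years Number of trial years.
#' @param layout `c(rows, cols)` of the field grid; must hold all test and
#'   check plots.
#' @param base Named base means (days) for the stage traits.
#' @param sd_year,sd_row,sd_col Standard deviations of year, row and column
#'   effects in days.
#' @param sd_resid_null Residual SD (days) used when a trait has no planted
#'   effects (h2 is undefined there).
#' @param check_names Names of the two replicated checks.
#' @param seed Integer seed.
#' @return Tibble with columns `year`, `row`, `column`, `genotype_id`,
#'   `is_check`, `D45`, `D55`, `D65`, `D87`, `DBA`, `GFD`.
#' @export
simulate_phenology <- function(G, effects = planted_effect(character(0)),
                               h2 = 0.5, years = 3, layout = c(14, 14),
                               base = c(D45 = 145, D55 = 154, D65 = 160, D87 = 192),
                               sd_year = 8, sd_row = 1, sd_col = 1,
                               sd_resid_null = 3,
                               check_names = c("Anza", "Soissons"),
                               seed = 1L) {
  stopifnot(h2 > 0, h2 <= 1)
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) && !all(effects$marker_id %in% marker_ids(G)))
    stop("planted effects reference unknown markers")
  stages <- c("D45", "D55", "D65", "D87")
  if (nrow(effects) && !all(effects$trait_name %in% stages))
    stop("planted effects must act on stage traits (D45/D55/D65/D87)")
  n <- nrow(G$calls)
  n_checks <- 2 * ceiling(n / 10)   # ~1:5 ratio, both checks replicated
  n_plots <- n + n_checks
  if (prod(layout) < n_plots)
    stop(sprintf("invalid config: layout %dx%d cannot hold %d plots",
                 layout[1], layout[2], n_plots))
  withr::with_seed(seed, {
    imp <- impute_calls(G$calls)
    gscore <- matrix(0, nrow = n, ncol = length(stages),
                     dimnames = list(accession_ids(G), stages))
    for (tr in unique(effects$trait_name)) {
      e <- effects[effects$trait_name == tr, ]
      gscore[, tr] <- imp[, e$marker_id, drop = FALSE] %*% e$effect_size
    }
    out <- list()
    for (y in seq_len(years)) {
      # check plots interleaved every 6th position (1:5 ratio)
      ids <- character(n_plots); is_check <- logical(n_plots)
      check_pos <- seq(6, by = 6, length.out = n_checks)
      check_pos <- check_pos[check_pos <= n_plots]
      extra <- n_checks - length(check_pos)
      if (extra > 0) check_pos <- c(check_pos, setdiff(seq_len(n_plots), check_pos)[seq_len(extra)])
      is_check[check_pos] <- TRUE
      ids[check_pos] <- rep_len(check_names, n_checks)
      ids[!is_check] <- sample(accession_ids(G))
      row_i <- ((seq_len(n_plots) - 1) %/% layout[2]) + 1
      col_i <- ((seq_len(n_plots) - 1) %% layout[2]) + 1
      year_eff <- stats::rnorm(1, 0, sd_year)
      row_eff <- stats::rnorm(layout[1], 0, sd_row)
      col_eff <- stats::rnorm(layout[2], 0, sd_col)
      tab <- tibble::tibble(year = y, row = row_i, column = col_i,
                            genotype_id = ids, is_check = is_check)
      for (tr in stages) {
        g <- numeric(n_plots)
        g[!is_check] <- gscore[ids[!is_check], tr]
        vg <- stats::var(gscore[, tr])
        sd_e <- if (vg > 0) sqrt(vg * (1 - h2) / h2) else sd_resid_null
        tab[[tr]] <- base[[tr]] + year_eff + row_eff[row_i] + col_eff[col_i] +
          g + stats::rnorm(n_plots, 0, sd_e)
      }
      out[[y]] <- tab
    }
    plots <- dplyr::bind_rows(out)
    plots$DBA <- plots$D65 - plots$D45
    plots$GFD <- plots$D87 - plots$D65
    plots
  })
}

#' Simulate a structured null phenotype
#'
#' A phenotype with no marker effect but a mean shift that follows each
#' accession's ancestry (admixed accessions receive the 50/50 mixture of
#' their two components' shifts) plus unit Gaussian noise. This is the
#' canonical confounded null for testing that the PCA + kinship correction
#' controls the false-positive rate where a naive scan does not.
#'
#' @param meta Accession metadata from [simulate_population()].
#' @param sp_shift Named numeric vector of subpopulation mean shifts (trait
#'   units / noise SD).
#' @param seed Integer seed.
#' @return Named numeric vector of phenotype values.
#' @export
simulate_structured_null <- function(meta, sp_shift = c(SP1 = 0, SP2 = 0.5,
                                                        SP3 = 1),
                                     seed = 1L) {
  s1 <- sp_shift[meta$subpop]
  s2 <- ifelse(is.na(meta$subpop2), s1, sp_shift[meta$subpop2])
  withr::with_seed(seed, {
    stats::setNames((s1 + s2) / 2 + stats::rnorm(nrow(meta)),
                    meta$accession_id)
  })
}

#' Default subpopulation climate means
#'
#' Plausible subpopulation-level means for the eight climate variables in the
#' two growth windows (sowing-to-anthesis SA, anthesis-to-maturity AM), with
#' the east/south Mediterranean warmer and drier than the north. Units:
#' temperatures in deg C, Rh in %, Sunshine in h, Rad in MJ m^-2 day^-1,
#' ET0 and Rain in mm.
#'
#' @param subpops Subpopulation labels.
#' @return Tibble with columns `subpop`, `variable`, `period`, `mean`.
#' @export
default_sp_climate_means <- function(subpops = c("SP1", "SP2", "SP3")) {
  vars <- c("Tmax", "Tmin", "Tmean", "Rh", "Sunshine", "Rad", "ET0", "Rain")
  sa <- rbind(SP1 = c(15, 5.5, 10.5, 74, 4.8, 10.3, 200, 280),
              SP2 = c(8.8, 0.6, 4.8, 79, 2.5, 6.3, 80, 290),
              SP3 = c(17.5, 7.2, 12.6, 68, 5.8, 11.8, 270, 180))
  am <- rbind(SP1 = c(23.3, 12, 17.7, 64, 8.1, 20.9, 360, 140),
              SP2 = c(21.6, 10.5, 16, 67, 6.5, 18.3, 210, 200),
              SP3 = c(27.9, 14.6, 21.3, 55, 9.2, 23.1, 470, 40))
  colnames(sa) <- colnames(am) <- vars
  base <- dplyr::bind_rows(
    tidyr::pivot_longer(tibble::as_tibble(sa, rownames = "subpop"),
                        -"subpop", names_to = "variable", values_to = "mean") |>
      dplyr::mutate(period = "SA"),
    tidyr::pivot_longer(tibble::as_tibble(am, rownames = "subpop"),
                        -"subpop", names_to = "variable", values_to = "mean") |>
      dplyr::mutate(period = "AM"))
  extra <- setdiff(subpops, c("SP1", "SP2", "SP3"))
  if (length(extra)) {
    add <- dplyr::bind_rows(lapply(extra, function(s)
      dplyr::mutate(base[base$subpop == "SP1", ], subpop = s)))
    base <- dplyr::bind_rows(base, add)
  }
  base[base$subpop %in% subpops, c("subpop", "variable", "period", "mean")]
}

#' Simulate a long-term climate table
#'
#' One value per country x variable x period. Countries belonging to the
#' same subpopulation share the subpopulation mean plus country-level
#' Gaussian noise, emulating the regional coherence of long-term climate
#' normals.
#'
#' @param meta Accession metadata from [simulate_population()].
#' @param sp_means Tibble `subpop`, `variable`, `period`, `mean`
#'   (default [default_sp_climate_means()]). Periods must be "SA" or "AM".
#' @param country_noise_sd SD of country-level noise around the
#'   subpopulation mean (same units as the variable).
#' @param seed Integer seed.
#' @return Tibble `country`, `variable`, `period`, `value`.
#' @export
simulate_climate <- function(meta, sp_means = NULL, country_noise_sd = 1,
                             seed = 1L) {
  if (is.null(sp_means)) sp_means <- default_sp_climate_means(unique(meta$subpop))
  sp_means <- tibble::as_tibble(sp_means)
  bad <- setdiff(unique(sp_means$period), c("SA", "AM"))
  if (length(bad)) stop("unknown period label(s): ", paste(bad, collapse = ", "))
  cm <- unique(meta[, c("country", "subpop")])
  cm <- cm[!duplicated(cm$country), ]
  withr::with_seed(seed, {
    out <- dplyr::inner_join(cm, sp_means, by = "subpop",
                             relationship = "many-to-many")
    out$value <- out$mean + stats::rnorm(nrow(out), 0, country_noise_sd)
    out[, c("country", "variable", "period", "value")]
  })
}

#' Simulate gene annotation and stress-expression data
#'
#' Places gene models on the chromosomes of a marker map and generates tpm
#' values per gene x tissue x condition, with a planted subset upregulated
#' under stress by more than the candidate-filter margin of 2 tpm.
#'
#' @param map Marker map tibble (chromosome bp ranges define where genes go).
#' @param n_genes Number of gene models.
#' @param stress_up_fraction Fraction of genes planted as stress-upregulated.
#' @param delta_tpm_range Range of the planted stress - control tpm delta
#'   (must exceed 2 to pass the downstream filter).
#' @param tissues Tissue panel.
#' @param study Study tag recorded on every expression record.
#' @param seed Integer seed.
#' @return List with `annotation` (tibble `gene_id`, `chromosome`, `start`,
#'   `end`, `description`), `expression` (tibble `gene_id`, `tissue`,
#'   `condition`, `study`, `tpm`) and `planted` (tibble `gene_id`, `tissue`,
#'   `delta`).
#' @export
simulate_annotation_expression <- function(map, n_genes = 100,
                                           stress_up_fraction = 0.1,
                                           delta_tpm_range = c(3, 8),
                                           tissues = c("root", "shoot/leaf", "spike", "grain"),
                                           study = "sim", seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be positive")
  withr::with_seed(seed, {
    chroms <- unique(map$chromosome)
    chrom_of <- sample(chroms, n_genes, replace = TRUE)
    start <- numeric(n_genes); end <- numeric(n_genes)
    for (c in chroms) {
      j <- which(chrom_of == c)
      rng <- range(map$bp[map$chromosome == c], na.rm = TRUE)
      s <- sort(round(stats::runif(length(j), rng[1], rng[2])))
      start[j] <- s
      end[j] <- s + round(stats::runif(length(j), 1500, 5000))
    }
    ids <- sprintf("gene%04d", seq_len(n_genes))
    ann <- tibble::tibble(gene_id = ids, chromosome = chrom_of,
                          start = start, end = end,
                          description = "simulated gene model")
    ann <- dplyr::arrange(ann, match(.data$chromosome, chroms), .data$start)

    n_up <- round(stress_up_fraction * n_genes)
    up_genes <- if (n_up > 0) sample(ids, n_up) else character(0)
    up_tissue <- if (n_up > 0) sample(tissues, n_up, replace = TRUE) else character(0)
    grid <- tidyr::expand_grid(gene_id = ids, tissue = tissues)
    control <- stats::rexp(nrow(grid), rate = 0.2)   # typical tpm scale
    delta <- stats::runif(nrow(grid), -0.5, 0.5)     # null jitter, |delta| <= 2
    planted <- match(paste(grid$gene_id, grid$tissue),
                     paste(up_genes, up_tissue))
    is_up <- !is.na(planted)
    delta[is_up] <- stats::runif(sum(is_up), delta_tpm_range[1], delta_tpm_range[2])
    expr <- dplyr::bind_rows(
      tibble::tibble(grid, condition = "control", study = study, tpm = control),
      tibble::tibble(grid, condition = "stress", study = study,
                     tpm = pmax(control + delta, 0)))
    planted_tab <- tibble::tibble(gene_id = up_genes, tissue = up_tissue,
                                  delta = delta[is_up][order(planted[is_up])])
    list(annotation = ann, expression = expr, planted = planted_tab)
  })
}
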