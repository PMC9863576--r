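#' REML BLUPs from an augmented field design
#'
#' For each year (environment), fits the linear mixed model
#' `y = X beta + Z gamma + epsilon` with the replicated check cultivars as
#' fixed effects and row, column and accession as independent random
#' effects, estimated by REML. The best linear unbiased predictors of the
#' accession effects are returned, averaged across years (configurable to
#' per-year values). BLUPs are shrinkage estimates: they are pulled toward
#' zero relative to raw check-adjusted means whenever the residual variance
#' is non-zero.
#'
#' @param plots Field-plot tibble with columns `year`, `row`, `column`,
#'   `genotype_id`, `is_check` and one column per trait (as produced by
#'   [simulate_phenology()]).
#' @param trait Trait column to analyse.
#' @param combine `"mean"` (average BLUPs across years, the default) or
#'   `"per_year"`.
#' @return Trait table tibble `accession_id`, `trait`, `value`
#'   (plus `year` when `combine = "per_year"`). The fitted `lmerMod`
#'   objects are attached as attribute `"fits"`.
#' @export
reml_blup <- function(plots, trait, combine = c("mean", "per_year")) {
  combine <- match.arg(combine)
  if (!trait %in% names(plots)) stop("unknown trait column: ", trait)
  checks <- unique(plots$genotype_id[plots$is_check])
  if (length(checks) < 2)
    stop("augmented-design fit needs >= 2 replicated check genotypes")
  per_year <- list()
  fits <- list()
  for (y in sort(unique(plots$year))) {
    d <- plots[plots$year == y & !is.na(plots[[trait]]), ]
    reps <- table(d$genotype_id[d$is_check])
    if (any(reps < 2))
      stop(sprintf("year %s: unreplicated check(s): %s", y,
                   paste(names(reps)[reps < 2], collapse = ", ")))
    d$check <- factor(ifelse(d$is_check, d$genotype_id, "none"),
                      levels = c("none", sort(checks)))
    d$rowf <- factor(d$row); d$colf <- factor(d$column)
    d$acc <- factor(d$genotype_id)
    d$.y <- d[[trait]]
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(.y ~ check + (1 | rowf) + (1 | colf) + (1 | acc),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    fits[[as.character(y)]] <- fit
    re <- lme4::ranef(fit)$acc
    blup <- stats::setNames(re[[1]], rownames(re))
    test_acc <- setdiff(unique(d$genotype_id[!d$is_check]), checks)
    per_year[[as.character(y)]] <- tibble::tibble(
      accession_id = test_acc, year = y, trait = trait,
      value = unname(blup[test_acc]))
  }
  out <- dplyr::bind_rows(per_year)
  if (combine == "mean") {
    out <- dplyr::summarise(dplyr::group_by(out, .data$accession_id, .data$trait),
                            value = mean(.data$value), .groups = "drop")
  }
  attr(out, "fits") <- fits
  out
}

#' Average a daily series over a wheat growth window
#'
#' The two windows reflect the Mediterranean wheat cycle: `SA` (sowing to
#' anthesis) spans 20 November-31 March and `AM` (anthesis to maturity)
#' 1 April-30 June. Values are averaged over calendar days in the window,
#' except rainfall, which is accumulated (long-term rain figures are window
#' totals in mm, not daily means).
#'
#' @param daily Tibble with columns `date` (Date) and `value`.
#' @param window `"SA"` or `"AM"`.
#' @param variable Variable name; `"Rain"` switches to the sum convention.
#' @return A single numeric value.
#' @export
window_average <- function(daily, window = c("SA", "AM"), variable = "Tmean") {
  window <- match.arg(window)
  mo <- as.integer(format(daily$date, "%m"))
  dy <- as.integer(format(daily$date, "%d"))
  inside <- if (window == "SA") {
    (mo == 11 & dy >= 20) | mo == 12 | mo <= 3
  } else {
    mo >= 4 & mo <= 6
  }
  v <- daily$value[inside]
  if (!length(v)) stop("no daily records fall inside the ", window, " window")
  if (variable == "Rain") sum(v) else mean(v)
}

#' Read a long-term climate table
#'
#' Long TSV with columns `country`, `variable`, `period`, `value`.
#' The packaged example table (`system.file("extdata",
#' "mediterranean_climate.tsv", package = "medscan")`) holds 15-year climate
#' normals for 23 Mediterranean wheat-growing countries over the SA and AM
#' windows.
#'
#' @param path File path.
#' @export
read_climate_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    country = readr::col_character(), variable = readr::col_character(),
    period = readr::col_character(), value = readr::col_double()))
  dup <- duplicated(tab[, c("country", "variable", "period")])
  if (any(dup)) stop("duplicate country/variable/period rows in climate table")
  tab
}

#' Climate phenotype from country of origin
#'
#' Assigns to each accession the long-term value of a climate variable in
#' its country of origin: the basis of environmental GWAS, where loci
#' associated with the climate of origin mark adaptive variation.
#' Accessions from the same country receive identical values by design.
#'
#' @param meta Accession metadata with `accession_id` and `country`.
#' @param climate Climate table from [read_climate_table()] or
#'   [simulate_climate()].
#' @param variable Climate variable name (e.g. `"Tmax"`).
#' @param period `"SA"` or `"AM"`.
#' @return Trait table tibble `accession_id`, `trait`
#'   (`"<variable>_<period>"`), `value`.
#' @export
climate_phenotype <- function(meta, climate, variable, period) {
  sub <- climate[climate$variable == variable & climate$period == period, ]
  if (!nrow(sub)) stop("no climate rows for ", variable, " / ", period)
  miss <- setdiff(unique(meta$country), sub$country)
  if (length(miss))
    stop("countries missing from the climate table: ",
         paste(miss, collapse = ", "))
  idx <- match(meta$country, sub$country)
  tibble::tibble(accession_id = meta$accession_id,
                 trait = paste(variable, period, sep = "_"),
                 value = sub$value[idx])
}
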