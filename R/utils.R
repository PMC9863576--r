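#' @importFrom rlang .data
#' @importFrom methods is
NULL

# Mean-impute missing calls per marker (used for kinship, PCA and marker
# testing only; never written back to the genotype container).
impute_calls <- function(calls) {
  if (!anyNA(calls)) return(calls * 1.0)
  mu <- colMeans(calls, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(calls), arr.ind = TRUE)
  out <- calls * 1.0
  out[idx] <- mu[idx[, 2]]
  out
}

# Genome letter of a wheat chromosome label ("1A" -> "A").
genome_letter <- function(chromosome) {
  substr(chromosome, nchar(chromosome), nchar(chromosome))
}

# Hotspot ordinal parsing: "1B.1-2" -> c(1, 2); "1B.3" -> 3
hotspot_ordinals <- function(name) {
  suf <- sub("^.*\\.", "", name)
  as.integer(unlist(strsplit(suf, "-", fixed = TRUE)))
}
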