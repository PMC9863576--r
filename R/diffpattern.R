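#' Differentiation-classification configuration
#'
#' A subpopulation pair is differentiated at a marker when the two
#' subpopulations carry opposite majority alleles; the call is "robust"
#' when both majority frequencies reach the robust threshold (default 80%)
#' and "moderate" when both reach the moderate threshold (default 60%)
#' without qualifying as robust.
#'
#' @param robust_threshold Frequency for a robust call, in (0.5, 1].
#' @param moderate_threshold Frequency for a moderate call, in (0.5,
#'   robust_threshold).
#' @export
diff_config <- function(robust_threshold = 0.80, moderate_threshold = 0.60) {
  stopifnot(moderate_threshold > 0.5, moderate_threshold < robust_threshold,
            robust_threshold <= 1)
  structure(list(robust_threshold = robust_threshold,
                 moderate_threshold = moderate_threshold),
            class = "diff_config")
}

#' Classify subpopulation allele-frequency differentiation
#'
#' For every marker and every pair of subpopulations, determines whether
#' the pair is differentiated per [diff_config()]. Classification is
#' symmetric in the pair and invariant to allele labelling. Markers with an
#' undefined frequency in any group (no non-missing calls) are skipped with
#' a warning.
#'
#' @param freqs Frequency table from [group_allele_frequencies()] (biallelic:
#'   two rows per marker x group).
#' @param cfg A [diff_config()].
#' @return Tibble `marker_id`, `sp_a`, `sp_b`, `allele_a`, `freq_a`,
#'   `allele_b`, `freq_b`, `classification` (`"robust"`, `"moderate"` or
#'   `"none"`).
#' @export
classify_differentiation <- function(freqs, cfg = diff_config()) {
  undef <- if ("undefined" %in% names(freqs)) freqs$undefined else FALSE
  undef_mk <- unique(freqs$marker_id[undef])
  if (length(undef_mk)) {
    warning("skipping markers with undefined group frequencies: ",
            paste(undef_mk, collapse = ", "))
    freqs <- freqs[!freqs$marker_id %in% undef_mk, ]
  }
  maj <- dplyr::slice_max(dplyr::group_by(freqs, .data$marker_id, .data$group),
                          .data$freq, n = 1, with_ties = FALSE)
  maj <- dplyr::ungroup(maj)
  out <- list()
  for (mk in unique(maj$marker_id)) {
    sub <- maj[maj$marker_id == mk, ]
    grps <- sort(sub$group)
    if (length(grps) < 2) next
    for (i in seq_len(length(grps) - 1)) for (j in (i + 1):length(grps)) {
      a <- sub[sub$group == grps[i], ]; b <- sub[sub$group == grps[j], ]
      cls <- "none"
      if (a$allele != b$allele) {
        if (a$freq >= cfg$robust_threshold && b$freq >= cfg$robust_threshold)
          cls <- "robust"
        else if (a$freq >= cfg$moderate_threshold &&
                 b$freq >= cfg$moderate_threshold)
          cls <- "moderate"
      }
      out[[length(out) + 1]] <- tibble::tibble(
        marker_id = mk, sp_a = grps[i], sp_b = grps[j],
        allele_a = a$allele, freq_a = a$freq,
        allele_b = b$allele, freq_b = b$freq, classification = cls)
    }
  }
  if (!length(out))
    return(tibble::tibble(marker_id = character(0), sp_a = character(0),
                          sp_b = character(0), allele_a = character(0),
                          freq_a = numeric(0), allele_b = character(0),
                          freq_b = numeric(0), classification = character(0)))
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize differentiation per hotspot
#'
#' Rolls marker-level differentiation calls up to hotspot level: for each
#' hotspot, the strongest classification over its markers
#' (robust > moderate > none) and the subpopulation pairs discriminated at
#' that level.
#'
#' @param patterns Result of [classify_differentiation()].
#' @param marker_hotspot Tibble `marker_id`, `hotspot` assigning markers to
#'   hotspots.
#' @return Tibble `hotspot`, `classification`, `pairs` (comma-separated
#'   `SPi-SPj` labels at the strongest level; empty for `"none"`).
#' @export
hotspot_diff_summary <- function(patterns, marker_hotspot) {
  rank <- c(none = 0, moderate = 1, robust = 2)
  joined <- dplyr::inner_join(patterns, marker_hotspot, by = "marker_id")
  out <- list()
  for (h in unique(marker_hotspot$hotspot)) {
    sub <- joined[joined$hotspot == h, ]
    if (!nrow(sub)) {
      out[[h]] <- tibble::tibble(hotspot = h, classification = "none", pairs = "")
      next
    }
    best <- max(rank[sub$classification])
    cls <- names(rank)[rank == best]
    pairs <- if (best == 0) "" else {
      top <- sub[rank[sub$classification] == best, ]
      paste(sort(unique(paste0(top$sp_a, "-", top$sp_b))), collapse = ",")
    }
    out[[h]] <- tibble::tibble(hotspot = h, classification = cls, pairs = pairs)
  }
  dplyr::bind_rows(out)
}
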