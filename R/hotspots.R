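#' Gaussian standard deviation of an MTA position
#'
#' Marker-trait association positions are standardized as Gaussian densities
#' whose 95% width equals the chromosome's linkage-disequilibrium decay
#' extent (CI, in cM): `sigma = CI / 3.92`, with 3.92 = 2 x 1.96.
#'
#' @param ld_ci_cM Per-chromosome LD-decay extent in cM (positive).
#' @return Gaussian standard deviation(s) in cM.
#' @export
mta_sigma <- function(ld_ci_cM) {
  if (any(ld_ci_cM <= 0)) stop("LD confidence interval must be positive")
  ld_ci_cM / 3.92
}

#' Per-cM QTL overview index
#'
#' The density of marker-trait associations along each chromosome,
#' evaluated at every integer cM: the sum over MTAs of a Gaussian density
#' centered at the MTA position with the chromosome's [mta_sigma()],
#' divided by the number of experiments `nbE` (trait-scan combinations).
#' The mean threshold is `nbQTL / (nbE * total map length)` (the value a
#' uniform spread of the same mass would take everywhere) and the high
#' threshold a configurable multiple of it. The index integrates to
#' `nbQTL / nbE` over the map, up to Gaussian mass lost beyond chromosome
#' ends (not reflected; a documented edge bias).
#'
#' @param mtas Tibble of associations with at least `chromosome` and `cM`.
#' @param chrom_lengths Named vector of chromosome genetic lengths (cM).
#' @param ld_ci Named vector of per-chromosome LD extents (cM), or a single
#'   value recycled to all chromosomes.
#' @param nbE Number of experiments (>= 1).
#' @param high_multiplier High threshold as a multiple of the mean
#'   threshold (default 5).
#' @return An `overview_profile`: list with `profile` (tibble `chromosome`,
#'   `cM`, `U`), `nbQTL`, `nbE`, `map_length_cM`, `mean_threshold`,
#'   `high_threshold`, `sigma` (named per chromosome).
#' @export
overview_index <- function(mtas, chrom_lengths, ld_ci, nbE,
                           high_multiplier = 5) {
  stopifnot(nbE >= 1)
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) stop("chrom_lengths must be named by chromosome")
  if (length(ld_ci) == 1 && is.null(names(ld_ci)))
    ld_ci <- stats::setNames(rep(ld_ci, length(chroms)), chroms)
  if (!all(chroms %in% names(ld_ci)))
    stop("ld_ci must cover every chromosome")
  sigma <- mta_sigma(ld_ci[chroms])
  total_len <- sum(chrom_lengths)
  nbQTL <- nrow(mtas)
  if (nbQTL == 0) warning("no MTAs: overview index is identically zero")
  if (nbQTL > 0 && anyNA(mtas$cM)) stop("every MTA needs a cM position")
  prof <- lapply(chroms, function(ch) {
    grid <- 0:floor(chrom_lengths[[ch]])
    U <- numeric(length(grid))
    pos <- mtas$cM[mtas$chromosome == ch]
    for (x in pos) U <- U + stats::dnorm(grid, x, sigma[[ch]])
    tibble::tibble(chromosome = ch, cM = grid, U = U / nbE)
  })
  mean_thr <- nbQTL / (nbE * total_len)
  structure(list(profile = dplyr::bind_rows(prof), nbQTL = nbQTL, nbE = nbE,
                 map_length_cM = total_len, mean_threshold = mean_thr,
                 high_threshold = high_multiplier * mean_thr,
                 sigma = sigma),
            class = "overview_profile")
}

#' @export
#' @method print overview_profile
print.overview_profile <- function(x, ...) {
  cat(sprintf(paste0("<overview_profile> %d MTAs / %d experiments over %.0f cM;",
                     " mean threshold %.3g, high threshold %.3g\n"),
              x$nbQTL, x$nbE, x$map_length_cM, x$mean_threshold,
              x$high_threshold))
  invisible(x)
}

#' Detect peaks of the overview index
#'
#' A peak is a maximal run of consecutive integer-cM positions with index
#' value strictly above the threshold; each run contributes one peak at its
#' argmax (leftmost position on ties). Both the number of over-threshold
#' positions and the number of peaks are reported.
#'
#' @param profile An [overview_index()] result.
#' @param threshold `"high"`, `"mean"`, or a numeric value.
#' @return Tibble `chromosome`, `peak_cM`, `run_start`, `run_end`,
#'   `n_positions`, `max_U`; attributes `n_positions` (total) and
#'   `n_peaks`.
#' @export
detect_peaks <- function(profile, threshold = "high") {
  thr <- if (is.numeric(threshold)) threshold
         else switch(threshold, high = profile$high_threshold,
                     mean = profile$mean_threshold,
                     stop("unknown threshold: ", threshold))
  out <- list()
  for (ch in unique(profile$profile$chromosome)) {
    p <- profile$profile[profile$profile$chromosome == ch, ]
    over <- p$U > thr
    if (!any(over)) next
    r <- rle(over)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      peak <- idx[which.max(p$U[idx])]   # which.max: leftmost on ties
      out[[length(out) + 1]] <- tibble::tibble(
        chromosome = ch, peak_cM = p$cM[peak],
        run_start = p$cM[starts[k]], run_end = p$cM[ends[k]],
        n_positions = length(idx), max_U = p$U[peak])
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(chromosome = character(0), peak_cM = numeric(0),
                   run_start = numeric(0), run_end = numeric(0),
                   n_positions = integer(0), max_U = numeric(0))
  attr(res, "n_positions") <- sum(res$n_positions)
  attr(res, "n_peaks") <- nrow(res)
  res
}

#' Consolidate peaks into named QTL hotspots
#'
#' Each peak spans the cM interval `peak +/- ld_ci/2` (clipped at 0);
#' same-chromosome peaks with overlapping intervals are merged into a single
#' hotspot whose interval is the union. A hotspot's trait classes are the
#' union of the classes of the MTAs falling inside its interval; its
#' flanking markers are the physically mapped markers (with a bp position)
#' whose cM position lies inside the interval and is nearest to each end.
#' Hotspots are named per chromosome in cM order (`1A.1`, `1A.2`, ...).
#' Hotspots without any physically mapped marker inside the interval are
#' flagged and carry `NA` bp bounds.
#'
#' @param peaks Result of [detect_peaks()].
#' @param ld_ci Named per-chromosome LD extent (cM), or single value.
#' @param map Marker map tibble (`marker_id`, `chromosome`, `cM`, `bp`).
#' @param mtas The MTA tibble used to build the profile (needs
#'   `chromosome`, `cM`, `trait_class`).
#' @return Hotspot tibble: `name`, `chromosome`, `cM_lo`, `cM_hi`,
#'   `trait_classes`, `left_marker`, `left_bp`, `right_marker`, `right_bp`,
#'   `bp_lo`, `bp_hi`, `ci_mb`, `no_physical`.
#' @export
build_hotspots <- function(peaks, ld_ci, map, mtas) {
  if (!nrow(peaks)) return(empty_hotspots())
  chroms <- unique(peaks$chromosome)
  if (length(ld_ci) == 1 && is.null(names(ld_ci)))
    ld_ci <- stats::setNames(rep(ld_ci, length(chroms)), chroms)
  rows <- list()
  for (ch in chroms) {
    pk <- peaks[peaks$chromosome == ch, ]
    half <- ld_ci[[ch]] / 2
    lo <- pmax(pk$peak_cM - half, 0); hi <- pk$peak_cM + half
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    # merge overlapping cM intervals
    m_lo <- lo[1]; m_hi <- hi[1]; iv <- list()
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= m_hi) m_hi <- max(m_hi, hi[i])
      else { iv[[length(iv) + 1]] <- c(m_lo, m_hi); m_lo <- lo[i]; m_hi <- hi[i] }
    }
    iv[[length(iv) + 1]] <- c(m_lo, m_hi)
    mp <- map[map$chromosome == ch & !is.na(map$bp), ]
    mt <- mtas[mtas$chromosome == ch, ]
    for (i in seq_along(iv)) {
      a <- iv[[i]][1]; b <- iv[[i]][2]
      classes <- sort(unique(mt$trait_class[mt$cM >= a & mt$cM <= b]))
      inside <- mp[mp$cM >= a & mp$cM <= b, ]
      if (nrow(inside)) {
        li <- which.min(abs(inside$cM - a))
        ri <- which.min(abs(inside$cM - b))
        rows[[length(rows) + 1]] <- tibble::tibble(
          name = paste0(ch, ".", i), chromosome = ch, cM_lo = a, cM_hi = b,
          trait_classes = paste(classes, collapse = ","),
          left_marker = inside$marker_id[li], left_bp = inside$bp[li],
          right_marker = inside$marker_id[ri], right_bp = inside$bp[ri],
          no_physical = FALSE)
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          name = paste0(ch, ".", i), chromosome = ch, cM_lo = a, cM_hi = b,
          trait_classes = paste(classes, collapse = ","),
          left_marker = NA_character_, left_bp = NA_real_,
          right_marker = NA_character_, right_bp = NA_real_,
          no_physical = TRUE)
      }
    }
  }
  physical_interval(dplyr::bind_rows(rows))
}

empty_hotspots <- function() {
  physical_interval(tibble::tibble(
    name = character(0), chromosome = character(0), cM_lo = numeric(0),
    cM_hi = numeric(0), trait_classes = character(0),
    left_marker = character(0), left_bp = numeric(0),
    right_marker = character(0), right_bp = numeric(0),
    no_physical = logical(0)))
}

#' Physical interval and confidence-interval width of hotspots
#'
#' Sets `bp_lo`/`bp_hi` to the sorted flanking-marker positions (order of
#' the input flanks is irrelevant) and `ci_mb` to the interval width in Mb
#' rounded to two decimals. Hotspots lacking a bp position are flagged via
#' `no_physical` and keep `NA` values.
#'
#' @param hs Hotspot tibble with `left_bp` and `right_bp`.
#' @return The tibble with `bp_lo`, `bp_hi`, `ci_mb` columns (re)computed.
#' @export
physical_interval <- function(hs) {
  hs$bp_lo <- pmin(hs$left_bp, hs$right_bp)
  hs$bp_hi <- pmax(hs$left_bp, hs$right_bp)
  hs$ci_mb <- round((hs$bp_hi - hs$bp_lo) / 1e6, 2)
  if (!"no_physical" %in% names(hs)) hs$no_physical <- is.na(hs$ci_mb)
  hs
}

#' Select hotspots by physical confidence-interval width
#'
#' Retains hotspots whose CI is at most `max_ci_mb` (default 20 Mb), the
#' practical bound for candidate-gene mining. Hotspots without a physical
#' interval are excluded and counted. Per-genome counts (the trailing
#' letter of the chromosome name: A, B or D) are attached as attribute
#' `genome_counts`.
#'
#' @param hs Hotspot tibble with `ci_mb`.
#' @param max_ci_mb Maximum CI in Mb.
#' @return Filtered tibble with attribute `genome_counts`.
#' @export
select_hotspots <- function(hs, max_ci_mb = 20) {
  keep <- !is.na(hs$ci_mb) & hs$ci_mb <= max_ci_mb
  out <- hs[keep, ]
  counts <- c(table(genome_letter(out$chromosome)))
  attr(out, "genome_counts") <- counts
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Merge hotspots with overlapping physical intervals
#'
#' Same-chromosome hotspots whose bp intervals intersect (coordinates are
#' 1-based inclusive, so touching endpoints intersect; a gap of >= 1 bp does
#' not) are unioned into a single region. The merged name concatenates the
#' ordinal range (e.g. `1B.1` + `1B.2` -> `1B.1-2`); trait classes are
#' unioned. All other hotspots pass through unchanged. Merge events are
#' recorded in attribute `merge_events` (list of character vectors of the
#' names merged).
#'
#' @param hs Selected hotspot tibble with `bp_lo`, `bp_hi`.
#' @return Merged tibble with attribute `merge_events`.
#' @export
merge_overlapping <- function(hs) {
  events <- list()
  out <- list()
  if (!nrow(hs)) {
    attr(hs, "merge_events") <- events
    return(hs)
  }
  for (ch in unique(hs$chromosome)) {
    sub <- hs[hs$chromosome == ch, ]
    sub <- sub[order(sub$bp_lo), ]
    i <- 1
    while (i <= nrow(sub)) {
      grp <- i
      hi <- sub$bp_hi[i]
      j <- i + 1
      while (j <= nrow(sub) && !is.na(sub$bp_lo[j]) && !is.na(hi) &&
             sub$bp_lo[j] <= hi) {
        grp <- c(grp, j)
        hi <- max(hi, sub$bp_hi[j])
        j <- j + 1
      }
      if (length(grp) > 1) {
        members <- sub[grp, ]
        ords <- sort(unlist(lapply(members$name, hotspot_ordinals)))
        merged <- members[1, ]
        merged$name <- paste0(ch, ".", min(ords), "-", max(ords))
        if (all(c("cM_lo", "cM_hi") %in% names(members))) {
          merged$cM_lo <- min(members$cM_lo)
          merged$cM_hi <- max(members$cM_hi)
        }
        merged$trait_classes <- paste(
          sort(unique(unlist(strsplit(members$trait_classes, ",")))),
          collapse = ",")
        wl <- which.min(members$bp_lo); wr <- which.max(members$bp_hi)
        lo_is_left <- members$bp_lo[wl] == members$left_bp[wl]
        merged$left_marker <- if (lo_is_left) members$left_marker[wl] else members$right_marker[wl]
        merged$left_bp <- members$bp_lo[wl]
        hi_is_right <- members$bp_hi[wr] == members$right_bp[wr]
        merged$right_marker <- if (hi_is_right) members$right_marker[wr] else members$left_marker[wr]
        merged$right_bp <- members$bp_hi[wr]
        events[[length(events) + 1]] <- members$name
        out[[length(out) + 1]] <- merged
      } else {
        out[[length(out) + 1]] <- sub[grp, ]
      }
      i <- j
    }
  }
  res <- physical_interval(dplyr::bind_rows(out))
  attr(res, "merge_events") <- events
  res
}

#' Read a hotspot catalogue table
#'
#' Tab-separated with columns `name`, `chromosome`, `cM_lo`, `cM_hi`,
#' `trait_classes`, `left_marker`, `left_bp`, `right_marker`, `right_bp`,
#' `ci_mb`, `n_gene_models`. The packaged catalogue
#' (`system.file("extdata", "wheat_hotspot_catalogue.tsv",
#' package = "medscan")`) lists the 33 selected QTL hotspots of a
#' Mediterranean bread-wheat landrace panel with their flanking markers and
#' physical intervals.
#'
#' @param path File path.
#' @export
read_hotspot_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("name", "chromosome", "left_bp", "right_bp")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("hotspot table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("cM_lo", "cM_hi", "left_bp", "right_bp", "ci_mb",
                          "bp_lo", "bp_hi", "n_gene_models"), names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}

#' Write a hotspot report
#'
#' @param hs Hotspot tibble.
#' @param path Output TSV path.
#' @export
write_hotspot_table <- function(hs, path) {
  readr::write_tsv(hs, path)
  invisible(path)
}
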