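#' Construct a genotype matrix object
#'
#' The central container of the pipeline: biallelic SNP calls for a panel of
#' accessions, coded as minor/alternate allele dosage 0/1/2 with `NA` for
#' missing, together with the recorded allele letters per marker.
#'
#' @param calls Integer matrix, accessions in rows, markers in columns.
#'   Row and column names are taken as accession and marker identifiers.
#'   Allowed values are 0, 1, 2 and `NA`.
#' @param alleles Optional tibble with columns `marker_id`, `ref`, `alt`
#'   (single letters from A/C/G/T, or `NA` when unknown). Code 0 means
#'   homozygous `ref`, 2 homozygous `alt`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, alleles = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stop("`calls` must carry accession row names and marker column names")
  if (is.null(dimnames(calls)))
    dimnames(calls) <- list(character(0), character(0))
  if (is.null(colnames(calls))) colnames(calls) <- character(0)
  if (is.null(rownames(calls))) rownames(calls) <- character(0)
  if (anyDuplicated(rownames(calls))) stop("duplicated accession ids")
  if (anyDuplicated(colnames(calls))) stop("duplicated marker ids")
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(alleles)) {
    alleles <- tibble::tibble(marker_id = colnames(calls),
                              ref = NA_character_, alt = NA_character_)
  } else {
    alleles <- tibble::as_tibble(alleles)
    stopifnot(all(c("marker_id", "ref", "alt") %in% names(alleles)))
    if (!setequal(alleles$marker_id, colnames(calls)))
      stop("`alleles` must cover exactly the markers of `calls`")
    alleles <- alleles[match(colnames(calls), alleles$marker_id), ]
  }
  structure(list(calls = calls, alleles = alleles), class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d markers, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Accessor helpers for genotype matrices
#' @param G A [genotype_matrix()].
#' @return Character vector of identifiers.
#' @export
accession_ids <- function(G) rownames(G$calls)

#' @rdname accession_ids
#' @export
marker_ids <- function(G) colnames(G$calls)

#' Read a genotype file
#'
#' Two dialects are supported. `matrix_tsv` is the package's native format:
#' a header row of marker ids, one row per accession with the accession id in
#' the first column and calls coded 0/1/2/NA. `hapmap` is HapMap-like tab
#' text: the 11 standard leading columns (`rs#`, `alleles`, `chrom`, `pos`,
#' `strand`, ...) followed by one column per accession holding diploid
#' letter calls (e.g. `AA`, `AG`, `NN`).
#'
#' @param path File path.
#' @param format `"matrix_tsv"` or `"hapmap"`.
#' @return A list with elements `geno` (a [genotype_matrix()]) and `map`
#'   (a marker-map tibble for hapmap input, `NULL` for matrix_tsv).
#' @export
read_genotypes <- function(path, format = c("matrix_tsv", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix_tsv") read_genotypes_matrix(path) else read_genotypes_hapmap(path)
}

read_genotypes_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix_tsv needs a header and at least one accession row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  m <- length(header) - 1L
  if (m < 1) stop("line 1: no marker columns in header")
  markers <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = length(rows), ncol = m)
  acc <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != m + 1L)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L, m + 1L, length(r)))
    acc[i] <- r[[1]]
    v <- r[-1]
    ok <- v %in% c("0", "1", "2", "NA", "")
    if (!all(ok))
      stop(sprintf("line %d: invalid genotype code '%s'", i + 1L, v[!ok][1]))
    v[v == ""] <- NA_character_
    calls[i, ] <- suppressWarnings(as.integer(v))
  }
  rownames(calls) <- acc
  colnames(calls) <- markers
  list(geno = genotype_matrix(calls), map = NULL)
}

.hapmap_lead <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                  "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

read_genotypes_hapmap <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("hapmap file needs a header and at least one marker row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 12) stop("line 1: hapmap header must have 11 leading columns plus accessions")
  acc <- header[-(1:11)]
  n <- length(acc)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- length(rows)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  markers <- character(m); chrom <- character(m); pos <- numeric(m)
  ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    r <- rows[[j]]
    if (length(r) != n + 11L)
      stop(sprintf("line %d: expected %d fields, found %d", j + 1L, n + 11L, length(r)))
    markers[j] <- r[[1]]
    al <- strsplit(r[[2]], "/", fixed = TRUE)[[1]]
    if (length(al) != 2)
      stop(sprintf("line %d: non-biallelic allele field '%s'", j + 1L, r[[2]]))
    ref[j] <- al[1]; alt[j] <- al[2]
    chrom[j] <- r[[3]]; pos[j] <- as.numeric(r[[4]])
    g <- r[-(1:11)]
    bad <- nchar(g) != 2L
    if (any(bad))
      stop(sprintf("line %d: genotype call '%s' is not a 2-letter diploid call",
                   j + 1L, g[bad][1]))
    a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
    miss <- a1 == "N" | a2 == "N"
    known <- c(ref[j], alt[j])
    foreign <- !miss & (!(a1 %in% known) | !(a2 %in% known))
    if (any(foreign))
      stop(sprintf("line %d: call '%s' does not match alleles %s/%s",
                   j + 1L, g[foreign][1], ref[j], alt[j]))
    dose <- (a1 == alt[j]) + (a2 == alt[j])
    dose[miss] <- NA_integer_
    calls[, j] <- as.integer(dose)
  }
  rownames(calls) <- acc
  colnames(calls) <- markers
  alleles <- tibble::tibble(marker_id = markers, ref = ref, alt = alt)
  map <- tibble::tibble(marker_id = markers, chromosome = chrom,
                        cM = NA_real_, bp = pos)
  list(geno = genotype_matrix(calls, alleles), map = map)
}

#' Write a genotype matrix
#'
#' `matrix_tsv` output round-trips bit-exactly through [read_genotypes()].
#' `hapmap` output requires allele letters and a marker map (for `chrom` and
#' `pos`).
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @param format `"matrix_tsv"` or `"hapmap"`.
#' @param map Marker-map tibble, required for hapmap output.
#' @export
write_genotypes <- function(G, path, format = c("matrix_tsv", "hapmap"), map = NULL) {
  format <- match.arg(format)
  if (format == "matrix_tsv") {
    header <- paste(c("accession", marker_ids(G)), collapse = "\t")
    body <- vapply(seq_len(nrow(G$calls)), function(i) {
      paste(c(rownames(G$calls)[i], ifelse(is.na(G$calls[i, ]), "NA", G$calls[i, ])),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    if (is.null(map)) stop("hapmap output needs a marker map")
    al <- G$alleles
    if (anyNA(al$ref) || anyNA(al$alt)) stop("hapmap output needs allele letters")
    idx <- match(marker_ids(G), map$marker_id)
    if (anyNA(idx)) stop("map does not cover all markers")
    header <- paste(c(.hapmap_lead, accession_ids(G)), collapse = "\t")
    body <- vapply(seq_len(ncol(G$calls)), function(j) {
      dose <- G$calls[, j]
      g <- character(length(dose))
      g[is.na(dose)] <- "NN"
      g[!is.na(dose) & dose == 0L] <- strrep(al$ref[j], 2)
      g[!is.na(dose) & dose == 1L] <- paste0(al$ref[j], al$alt[j])
      g[!is.na(dose) & dose == 2L] <- strrep(al$alt[j], 2)
      paste(c(marker_ids(G)[j], paste0(al$ref[j], "/", al$alt[j]),
              map$chromosome[idx[j]], format(map$bp[idx[j]], scientific = FALSE),
              "+", rep("NA", 6), g), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read / write a marker map
#'
#' Tab-separated with columns `marker_id`, `chromosome`, `cM`, `bp`
#' (`bp` may be `NA` for markers without a physical position).
#'
#' @param path File path.
#' @return Tibble with those four columns.
#' @export
read_marker_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), chromosome = readr::col_character(),
    cM = readr::col_double(), bp = readr::col_double()))
}

#' @rdname read_marker_map
#' @param map Marker-map tibble.
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' Quality-control configuration
#'
#' Defaults follow common SNP-chip practice for landrace panels: markers with
#' more than 25\% missing calls or minor allele frequency below 5\% are
#' dropped, duplicated call patterns are collapsed to one representative, and
#' accessions with more than 25\% missing calls are removed first.
#'
#' @param max_marker_missing Maximum marker missingness fraction.
#' @param min_maf Minimum minor allele frequency.
#' @param drop_duplicate_patterns Collapse identical call patterns?
#' @param max_accession_missing Maximum accession missingness fraction.
#' @export
qc_config <- function(max_marker_missing = 0.25, min_maf = 0.05,
                      drop_duplicate_patterns = TRUE,
                      max_accession_missing = 0.25) {
  stopifnot(max_marker_missing >= 0, max_marker_missing <= 1,
            min_maf >= 0, min_maf <= 1,
            max_accession_missing >= 0, max_accession_missing <= 1)
  structure(list(max_marker_missing = max_marker_missing, min_maf = min_maf,
                 drop_duplicate_patterns = drop_duplicate_patterns,
                 max_accession_missing = max_accession_missing),
            class = "qc_config")
}

marker_maf <- function(calls) {
  # allele counts: 2 per homozygote, 1 per het, over non-missing calls
  alt <- colSums(calls, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(calls))
  f <- ifelse(tot > 0, alt / tot, NA_real_)
  pmin(f, 1 - f)
}

#' Apply marker and accession quality-control filters
#'
#' Filtering order is fixed: (1) accessions above the missingness threshold
#' are dropped; (2) duplicated marker call patterns (identical call vectors
#' including missing positions) are collapsed, keeping the first by input
#' order; (3) markers above the missingness threshold are dropped; (4)
#' markers below the MAF threshold are dropped. The operation is idempotent.
#'
#' @param G A [genotype_matrix()].
#' @param cfg A [qc_config()].
#' @return List with `geno` (filtered matrix) and `report` (tibble of
#'   removal counts per rule).
#' @export
qc_filter <- function(G, cfg = qc_config()) {
  calls <- G$calls
  acc_miss <- rowMeans(is.na(calls))
  drop_acc <- acc_miss > cfg$max_accession_missing
  calls <- calls[!drop_acc, , drop = FALSE]

  dup <- rep(FALSE, ncol(calls))
  if (cfg$drop_duplicate_patterns && ncol(calls) > 0) {
    pat <- apply(calls, 2, function(v) paste(ifelse(is.na(v), ".", v), collapse = ""))
    dup <- duplicated(pat)
  }
  calls2 <- calls[, !dup, drop = FALSE]

  mk_miss <- colMeans(is.na(calls2))
  drop_miss <- mk_miss > cfg$max_marker_missing
  calls3 <- calls2[, !drop_miss, drop = FALSE]

  maf <- marker_maf(calls3)
  drop_maf <- is.na(maf) | maf < cfg$min_maf
  calls4 <- calls3[, !drop_maf, drop = FALSE]

  if (ncol(calls4) == 0) warning("all markers removed by QC filters")

  report <- tibble::tibble(
    rule = c("accession_missing", "duplicate_pattern", "marker_missing", "maf"),
    removed = c(sum(drop_acc), sum(dup), sum(drop_miss), sum(drop_maf)))
  al <- G$alleles[match(colnames(calls4), G$alleles$marker_id), ]
  list(geno = genotype_matrix(calls4, al), report = report)
}

#' Per-group allele frequencies
#'
#' For each requested marker and each accession group, the frequency of the
#' recorded reference and alternate alleles among non-missing calls (allele
#' counting: 2 per homozygote, 1 per heterozygote). Frequencies per marker
#' and group sum to 1. Groups with no non-missing call at a marker are
#' flagged as undefined.
#'
#' @param G A [genotype_matrix()].
#' @param groups Named character vector mapping accession id to group label;
#'   accessions with an `NA` label are excluded.
#' @param marker_ids Markers to tabulate (default: all).
#' @return Tibble with columns `marker_id`, `group`, `allele`, `freq`,
#'   `n_calls`, `undefined`.
#' @export
group_allele_frequencies <- function(G, groups, marker_ids = NULL) {
  if (is.null(marker_ids)) marker_ids <- colnames(G$calls)
  missing_mk <- setdiff(marker_ids, colnames(G$calls))
  if (length(missing_mk)) stop("unknown markers: ", paste(missing_mk, collapse = ", "))
  acc <- accession_ids(G)
  if (!all(acc %in% names(groups)))
    stop("every accession needs a group label (NA allowed to exclude)")
  lab <- groups[acc]
  keep <- !is.na(lab)
  out <- list()
  for (g in unique(lab[keep])) {
    sub <- G$calls[keep & lab == g, marker_ids, drop = FALSE]
    alt_n <- colSums(sub, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(sub))
    undef <- tot == 0
    f_alt <- ifelse(undef, NA_real_, alt_n / tot)
    al <- G$alleles[match(marker_ids, G$alleles$marker_id), ]
    ref_letter <- ifelse(is.na(al$ref), "ref", al$ref)
    alt_letter <- ifelse(is.na(al$alt), "alt", al$alt)
    out[[g]] <- tibble::tibble(
      marker_id = rep(marker_ids, 2L),
      group = g,
      allele = c(ref_letter, alt_letter),
      freq = unname(c(1 - f_alt, f_alt)),
      n_calls = unname(rep(tot, 2L)),
      undefined = unname(rep(undef, 2L)))
  }
  res <- dplyr::arrange(dplyr::bind_rows(out),
                        match(.data$marker_id, marker_ids), .data$group)
  if (any(res$undefined))
    warning("some marker/group cells have no non-missing calls; frequencies undefined")
  res
}
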