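#' Read gene models from a GFF3 annotation
#'
#' Keeps `gene` features only. Coordinates are 1-based inclusive, as in
#' GFF3.
#'
#' @param path GFF3 file.
#' @return Tibble `gene_id`, `chromosome`, `start`, `end`, `description`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  desc <- if (!is.null(gr$description)) gr$description else NA_character_
  tibble::tibble(gene_id = as.character(id),
                 chromosome = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 description = as.character(desc))
}

#' Write gene models as GFF3
#'
#' @param ann Annotation tibble (`gene_id`, `chromosome`, `start`, `end`,
#'   optional `description`).
#' @param path Output file.
#' @export
write_gene_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chromosome,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end))
  gr$type <- "gene"
  gr$source <- "medscan"
  gr$ID <- ann$gene_id
  if (!is.null(ann$description)) gr$description <- ann$description
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Gene models within a hotspot interval
#'
#' Any-overlap rule on 1-based inclusive coordinates: a gene is inside a
#' hotspot when its `[start, end]` interval intersects the hotspot's
#' `[bp_lo, bp_hi]` interval on the same chromosome, including genes that
#' merely abut an interval end.
#'
#' @param ann Annotation tibble from [read_gene_annotation()].
#' @param hotspot One hotspot row (needs `chromosome`, `bp_lo`, `bp_hi`).
#' @return Tibble of overlapping gene models.
#' @export
genes_in_hotspot <- function(ann, hotspot) {
  if (is.na(hotspot$bp_lo) || is.na(hotspot$bp_hi))
    stop("hotspot has no physical interval")
  if (!hotspot$chromosome %in% unique(ann$chromosome))
    stop("annotation has no chromosome label: ", hotspot$chromosome)
  genes <- GenomicRanges::GRanges(ann$chromosome,
                                  IRanges::IRanges(ann$start, ann$end))
  hs <- GenomicRanges::GRanges(hotspot$chromosome,
                               IRanges::IRanges(hotspot$bp_lo, hotspot$bp_hi))
  hit <- GenomicRanges::findOverlaps(genes, hs)
  ann[S4Vectors::queryHits(hit), ]
}

#' Count gene models per hotspot
#'
#' Vectorized [genes_in_hotspot()] over a hotspot table; fills
#' `n_gene_models`. Hotspots without a physical interval get `NA`.
#'
#' @param ann Annotation tibble.
#' @param hs Hotspot tibble.
#' @return `hs` with an `n_gene_models` column.
#' @export
count_gene_models <- function(ann, hs) {
  hs$n_gene_models <- vapply(seq_len(nrow(hs)), function(i) {
    if (is.na(hs$bp_lo[i])) return(NA_integer_)
    nrow(genes_in_hotspot(ann, hs[i, ]))
  }, integer(1))
  hs
}

#' Gene-ontology tally
#'
#' Counts and percentages of genes per GO term within each namespace
#' (molecular function, biological process, cellular component); genes
#' without any term in a namespace are tallied as `"unclassified"`.
#'
#' @param genes Tibble with a `gene_id` column.
#' @param go Optional tibble `gene_id`, `namespace`, `term`.
#' @return Tibble `namespace`, `term`, `n`, `pct` (percentage of the genes
#'   classified in that namespace; `unclassified` percentages are of all
#'   genes).
#' @export
go_summary <- function(genes, go = NULL) {
  ids <- unique(genes$gene_id)
  if (is.null(go) || !nrow(go)) {
    return(tibble::tibble(namespace = "all", term = "unclassified",
                          n = length(ids), pct = 100))
  }
  go <- go[go$gene_id %in% ids, ]
  out <- list()
  for (ns in unique(go$namespace)) {
    sub <- unique(go[go$namespace == ns, c("gene_id", "term")])
    classified <- unique(sub$gene_id)
    tab <- dplyr::count(sub, .data$term, name = "n")
    tab$namespace <- ns
    tab$pct <- 100 * tab$n / length(classified)
    un <- length(setdiff(ids, classified))
    if (un > 0)
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        term = "unclassified", n = un, namespace = ns,
        pct = 100 * un / length(ids)))
    out[[ns]] <- tab[, c("namespace", "term", "n", "pct")]
  }
  dplyr::bind_rows(out)
}

#' Differential-expression candidate filter
#'
#' A gene is selected for a tissue when its stress tpm exceeds its control
#' tpm by strictly more than `min_delta_tpm` (default 2) in that tissue in
#' at least one study. Only upregulation counts; downregulated genes are
#' never selected, and a delta of exactly the threshold is excluded. Genes
#' with a stress record but no matching control record are skipped with a
#' warning.
#'
#' @param genes Tibble with `gene_id` (e.g. from [genes_in_hotspot()]).
#' @param expr Expression tibble `gene_id`, `tissue`, `condition`
#'   (`"control"`/`"stress"`), `study`, `tpm`.
#' @param min_delta_tpm Strict lower bound for stress - control (tpm).
#' @return Tibble `gene_id`, `tissue`, `study`, `delta`, `upregulated`
#'   (one row per selected gene x tissue x study).
#' @export
deg_filter <- function(genes, expr, min_delta_tpm = 2.0) {
  expr <- expr[expr$gene_id %in% unique(genes$gene_id), ]
  wide <- tidyr::pivot_wider(expr, id_cols = c("gene_id", "tissue", "study"),
                             names_from = "condition", values_from = "tpm")
  if (!"control" %in% names(wide)) wide$control <- NA_real_
  if (!"stress" %in% names(wide)) wide$stress <- NA_real_
  orphan <- !is.na(wide$stress) & is.na(wide$control)
  if (any(orphan))
    warning("skipping gene/tissue pairs with stress but no control record: ",
            paste(unique(wide$gene_id[orphan]), collapse = ", "))
  ok <- !is.na(wide$stress) & !is.na(wide$control)
  wide <- wide[ok, ]
  wide$delta <- wide$stress - wide$control
  sel <- wide[wide$delta > min_delta_tpm, ]
  tibble::tibble(gene_id = sel$gene_id, tissue = sel$tissue,
                 study = sel$study, delta = sel$delta, upregulated = TRUE)
}
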