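#' Read gene models from a GFF3 annotation
#'
#' Imports the annotation and keeps `gene` features. Gene identity is keyed on
#' the GFF3 `ID` attribute (falling back to `Name`); duplicated ids are
#' rejected.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates), sorted by coordinate.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    nm <- gr$Name
    if (is.null(ids)) ids <- rep(NA_character_, length(gr))
    ids[is.na(ids)] <- nm[is.na(ids)]
  }
  if (anyNA(ids)) stop("gene feature without ID/Name attribute in ", path, call. = FALSE)
  if (anyDuplicated(ids) > 0) {
    stop("duplicated gene ids in annotation: ",
      paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Genes overlapping candidate intervals
#'
#' Returns genes overlapping any interval by at least 1 bp, strand-agnostic,
#' under 1-based inclusive coordinates (so a gene ending at `start - 1` is
#' excluded). Intervals on chromosomes absent from the annotation are skipped
#' with a warning.
#'
#' @param intervals [call_intervals()] output (or any tibble with `chrom`,
#'   `start`, `end`).
#' @param genes Gene models from [read_gff_genes()] or [make_gene_models()].
#' @param label Optional provenance label (population x marker class) stored
#'   in a `set_label` column.
#' @return A gene-set tibble: `gene_id`, `chrom`, `start`, `end`
#'   (+ `set_label`), deduplicated and sorted by coordinate.
#' @export
genes_in_intervals <- function(intervals, genes, label = NULL) {
  missing_chr <- setdiff(unique(intervals$chrom), unique(genes$chrom))
  if (length(missing_chr) > 0) {
    warning(
      "intervals on chromosome(s) absent from annotation, skipped: ",
      paste(missing_chr, collapse = ", "),
      call. = FALSE
    )
    intervals <- intervals[!intervals$chrom %in% missing_chr, ]
  }
  out <- genes[0, c("gene_id", "chrom", "start", "end")]
  if (nrow(intervals) > 0 && nrow(genes) > 0) {
    g <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end)
    )
    iv <- GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start, intervals$end)
    )
    hits <- GenomicRanges::findOverlaps(g, iv, ignore.strand = TRUE)
    out <- genes[
      sort(unique(S4Vectors::queryHits(hits))),
      c("gene_id", "chrom", "start", "end")
    ]
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  if (!is.null(label)) out$set_label <- label
  out
}

#' Intersect two gene sets (co-localization across populations)
#'
#' @param a,b Gene-set tibbles (must contain `gene_id`).
#' @param label Optional provenance label for the result.
#' @return Gene-set tibble of genes present in both, with `a`'s coordinates.
#' @export
intersect_gene_sets <- function(a, b, label = NULL) {
  out <- dplyr::semi_join(a, b, by = "gene_id")
  out <- dplyr::distinct(out, .data$gene_id, .keep_all = TRUE)
  if (!is.null(label)) out$set_label <- label
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Union of two gene sets (combining marker classes)
#'
#' Deduplicated union, so `nrow(union) = nrow(a) + nrow(b) - |a intersect b|`.
#'
#' @param a,b Gene-set tibbles (must contain `gene_id`).
#' @param label Optional provenance label for the result.
#' @return Gene-set tibble of genes present in either set.
#' @export
union_gene_sets <- function(a, b, label = NULL) {
  keep <- intersect(names(a), names(b))
  out <- dplyr::bind_rows(a[keep], b[keep])
  out <- dplyr::distinct(out, .data$gene_id, .keep_all = TRUE)
  if (!is.null(label)) out$set_label <- label
  if (all(c("chrom", "start") %in% names(out))) {
    out <- dplyr::arrange(out, .data$chrom, .data$start)
  }
  out
}

#' Write a gene set as one-id-per-line text
#'
#' @param genes Gene-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes$gene_id, path)
  invisible(path)
}
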