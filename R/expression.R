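#' Expression pattern labels
#'
#' The seven mutually exclusive stage-pattern classes used to describe FPKM
#' profiles across the four husk/panicle developmental stages (S1 panicle
#' branch differentiation, S2 heading, S3 husk pollination, S4 husk filling).
#'
#' @return Character vector of pattern labels in canonical order.
#' @export
pattern_levels <- function() {
  c(
    "not_expressed_all", "high_all", "high_last_two", "low_first_three",
    "high_first_two", "high_second_only", "other"
  )
}

#' Read a gene x stage FPKM matrix
#'
#' Accepts either one column per stage (`S1`..`S4`) or replicate columns
#' (`S1_r1`, `S1_r2`, ...; any `S<k>` prefix), which are averaged per stage.
#' The first column is taken as the gene id.
#'
#' @param path Path to a tab-delimited FPKM table.
#' @return Tibble: `gene_id`, `S1`, `S2`, `S3`, `S4` (replicate means).
#' @export
read_fpkm <- function(path) {
  if (!file.exists(path)) stop("FPKM file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "gene_id"
  out <- tibble::tibble(gene_id = as.character(raw$gene_id))
  for (s in paste0("S", 1:4)) {
    cols <- grep(paste0("^", s, "($|[^0-9])"), names(raw), value = TRUE)
    if (length(cols) == 0) {
      stop("FPKM table lacks any column for stage ", s, call. = FALSE)
    }
    out[[s]] <- rowMeans(as.matrix(raw[cols]))
  }
  if (any(is.na(out[paste0("S", 1:4)]))) {
    stop("missing FPKM values in ", path, call. = FALSE)
  }
  if (any(out$S1 < 0 | out$S2 < 0 | out$S3 < 0 | out$S4 < 0)) {
    stop("negative FPKM values in ", path, call. = FALSE)
  }
  out
}

# stage state: high (>= high_cut), off (< off_cut), low otherwise
stage_states <- function(x, high_cut, off_cut) {
  ifelse(x >= high_cut, "high", ifelse(x < off_cut, "off", "low"))
}

classify_signature <- function(st) {
  # st: character vector of 4 stage states
  hi <- st == "high"
  off <- st == "off"
  if (all(off)) {
    "not_expressed_all"
  } else if (all(hi)) {
    "high_all"
  } else if (hi[3] && hi[4] && !hi[1] && !hi[2]) {
    "high_last_two"
  } else if (hi[1] && hi[2] && !hi[3] && !hi[4]) {
    "high_first_two"
  } else if (hi[2] && !hi[1] && !hi[3] && !hi[4]) {
    "high_second_only"
  } else if (!hi[1] && !hi[2] && !hi[3] && hi[4]) {
    "low_first_three"
  } else {
    "other"
  }
}

#' Classify stage-wise expression patterns
#'
#' Each stage is scored high (FPKM >= `high_cut`), off (< `off_cut`) or low
#' (in between); the 4-stage state signature maps onto one of
#' [pattern_levels()]. Classification is invariant to rescaling FPKM and both
#' cutoffs by the same positive constant.
#'
#' @param fpkm A [read_fpkm()] tibble (columns `S1`..`S4`), or a bare numeric
#'   vector of 4 stage values for a single gene.
#' @param high_cut FPKM at or above which a stage counts as highly expressed
#'   (default 1).
#' @param off_cut FPKM below which a stage counts as not expressed
#'   (default 0.1); must be `< high_cut`.
#' @return The tibble with a `pattern` factor column appended (or a single
#'   label for vector input).
#' @examples
#' classify_pattern(c(5, 7.2, 0.05, 0))
#' @export
classify_pattern <- function(fpkm, high_cut = 1, off_cut = 0.1) {
  if (off_cut >= high_cut) stop("off_cut must be < high_cut", call. = FALSE)
  if (is.numeric(fpkm) && is.null(dim(fpkm))) {
    stopifnot(length(fpkm) == 4)
    return(classify_signature(stage_states(fpkm, high_cut, off_cut)))
  }
  stopifnot(all(paste0("S", 1:4) %in% names(fpkm)))
  sm <- as.matrix(fpkm[paste0("S", 1:4)])
  labels <- apply(sm, 1, function(v) {
    classify_signature(stage_states(v, high_cut, off_cut))
  })
  fpkm$pattern <- factor(labels, levels = pattern_levels())
  fpkm
}

#' Census of expression patterns over a gene set
#'
#' Counts genes in each pattern class; counts always sum to the gene-set
#' size. Genes absent from the matrix are treated as not expressed, with a
#' warning.
#'
#' @param genes Gene-set tibble (column `gene_id`), e.g. from
#'   [genes_in_intervals()] / [union_gene_sets()].
#' @param fpkm A [read_fpkm()] tibble.
#' @inheritParams classify_pattern
#' @return Tibble `pattern`, `n` with one row per [pattern_levels()] class.
#' @export
pattern_census <- function(genes, fpkm, high_cut = 1, off_cut = 0.1) {
  labels <- gene_set_patterns(genes, fpkm, high_cut, off_cut)
  tibble::tibble(
    pattern = factor(pattern_levels(), levels = pattern_levels()),
    n = as.integer(table(labels)[pattern_levels()])
  ) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Select expression-supported candidate genes
#'
#' Papillae are fully formed by the pollination stage (S3), so genes driving
#' their differentiation should be highly expressed during the first two
#' stages only. Retains genes classified `high_first_two` or
#' `high_second_only` — both signatures are high before S3 and not high in
#' S3/S4.
#'
#' @inheritParams pattern_census
#' @return The gene-set tibble filtered to candidates, with a `pattern`
#'   column appended.
#' @export
select_candidates <- function(genes, fpkm, high_cut = 1, off_cut = 0.1) {
  labels <- gene_set_patterns(genes, fpkm, high_cut, off_cut)
  out <- genes
  out$pattern <- labels
  out[labels %in% c("high_first_two", "high_second_only"), ]
}

gene_set_patterns <- function(genes, fpkm, high_cut, off_cut) {
  classified <- classify_pattern(fpkm, high_cut, off_cut)
  idx <- match(genes$gene_id, classified$gene_id)
  labels <- factor(rep("not_expressed_all", nrow(genes)),
    levels = pattern_levels()
  )
  if (anyNA(idx)) {
    warning(
      sum(is.na(idx)),
      " gene(s) absent from the FPKM matrix; treated as not expressed",
      call. = FALSE
    )
  }
  labels[!is.na(idx)] <- classified$pattern[idx[!is.na(idx)]]
  labels
}
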