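#' Define a simulated genome and marker map
#'
#' Builds the specification object the F2 simulator works from: a set of
#' chromosomes with physical and genetic lengths, an evenly spaced marker map
#' per chromosome (a mix of SNP and InDel markers), and optionally a single
#' biallelic causal locus whose dominant allele is carried by parent P1 (the
#' papilla parent). Physical positions are converted to genetic positions by a
#' constant cM/Mb rate per chromosome.
#'
#' Defaults model a compact nine-chromosome foxtail-millet-like genome:
#' 9 chromosomes of 40 Mb, 2,000 markers each, causal locus mid-chromosome 5.
#'
#' @param chromosomes Tibble or data frame with columns `chrom` (character),
#'   `length_bp` (integer), and optionally `cm_per_mb` (genetic map rate,
#'   recycled from `cm_per_mb` argument when absent).
#' @param markers_per_chrom Number of evenly spaced markers per chromosome.
#' @param cm_per_mb Constant genetic map rate in centimorgan per megabase.
#' @param causal_locus `NULL` for a null genome (phenotype independent of
#'   genotype), or a list/vector `list(chrom =, pos =)`. The locus is snapped
#'   to the nearest marker on its chromosome (with a message if it moves).
#' @param inheritance `"dominant"` (papillae require >= 1 P1 allele) or
#'   `"recessive"` (papillae require P1/P1).
#' @param indel_fraction Fraction of markers designated InDel rather than SNP
#'   (assigned deterministically, evenly interleaved).
#'
#' @return An object of class `genome_spec`: a list with `chromosomes`,
#'   `markers` (tibble: `chrom`, `pos`, `cm`, `marker_class`, `ref`, `alt`),
#'   `causal` (row index into `markers`, or `NA` for a null genome) and
#'   `inheritance`.
#'
#' @examples
#' spec <- genome_spec(markers_per_chrom = 100)
#' spec$markers
#' @export
genome_spec <- function(chromosomes = default_chromosomes(),
                        markers_per_chrom = 2000,
                        cm_per_mb = 3,
                        causal_locus = list(chrom = "chr5", pos = 2e7),
                        inheritance = c("dominant", "recessive"),
                        indel_fraction = 0.15) {
  inheritance <- match.arg(inheritance)
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)))
  if (!"cm_per_mb" %in% names(chromosomes)) {
    chromosomes$cm_per_mb <- cm_per_mb
  }
  if (anyDuplicated(chromosomes$chrom) > 0) {
    stop("duplicated chromosome names in genome spec", call. = FALSE)
  }
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$cm_per_mb <= 0)) {
    stop("chromosome physical and genetic lengths must be positive", call. = FALSE)
  }
  if (markers_per_chrom < 1) stop("markers_per_chrom must be >= 1", call. = FALSE)

  markers <- purrr::pmap_dfr(
    chromosomes,
    function(chrom, length_bp, cm_per_mb) {
      spacing <- length_bp / markers_per_chrom
      pos <- round(spacing / 2 + spacing * (seq_len(markers_per_chrom) - 1))
      pos <- pmin(pmax(pos, 1), length_bp)
      tibble::tibble(
        chrom = chrom,
        pos = as.integer(pos),
        cm = pos / 1e6 * cm_per_mb
      )
    }
  )
  if (any(duplicated(markers[c("chrom", "pos")]))) {
    stop("marker map too dense: duplicated positions", call. = FALSE)
  }
  # deterministic SNP/InDel interleaving; InDels alternate insertion/deletion
  n <- nrow(markers)
  is_indel <- rep(FALSE, n)
  if (indel_fraction > 0) {
    k <- max(1L, round(1 / indel_fraction))
    if (k <= n) is_indel[seq(k, n, by = k)] <- TRUE
  }
  markers$marker_class <- ifelse(is_indel, "InDel", "SNP")
  ins <- is_indel & (cumsum(is_indel) %% 2L == 1L)
  markers$ref <- ifelse(!is_indel, "A", ifelse(ins, "A", "AT"))
  markers$alt <- ifelse(!is_indel, "G", ifelse(ins, "AT", "A"))
  markers$marker_id <- paste0(markers$chrom, "_", markers$pos)

  causal <- NA_integer_
  if (!is.null(causal_locus)) {
    causal_locus <- as.list(causal_locus)
    if (!causal_locus$chrom %in% chromosomes$chrom) {
      stop("causal locus chromosome not declared in the genome", call. = FALSE)
    }
    len <- chromosomes$length_bp[chromosomes$chrom == causal_locus$chrom]
    if (causal_locus$pos < 1 || causal_locus$pos > len) {
      stop("causal locus position outside its chromosome", call. = FALSE)
    }
    on_chrom <- which(markers$chrom == causal_locus$chrom)
    causal <- on_chrom[which.min(abs(markers$pos[on_chrom] - causal_locus$pos))]
    if (markers$pos[causal] != causal_locus$pos) {
      message(sprintf(
        "causal locus snapped to nearest marker: %s:%d -> %s:%d",
        causal_locus$chrom, as.integer(causal_locus$pos),
        markers$chrom[causal], markers$pos[causal]
      ))
    }
  }

  structure(
    list(
      chromosomes = chromosomes,
      markers = markers,
      causal = causal,
      inheritance = inheritance
    ),
    class = "genome_spec"
  )
}

#' Default chromosome table for the simulator
#'
#' Nine 40-Mb chromosomes named `chr1`..`chr9`, 3 cM/Mb.
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp Physical length of each chromosome (bp).
#' @param cm_per_mb Genetic map rate.
#' @return A tibble with columns `chrom`, `length_bp`, `cm_per_mb`.
#' @export
default_chromosomes <- function(n_chrom = 9, length_bp = 4e7, cm_per_mb = 3) {
  tibble::tibble(
    chrom = paste0("chr", seq_len(n_chrom)),
    length_bp = as.integer(length_bp),
    cm_per_mb = cm_per_mb
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %d chromosomes, %d markers (%d SNP / %d InDel)\n",
    nrow(x$chromosomes), nrow(x$markers),
    sum(x$markers$marker_class == "SNP"),
    sum(x$markers$marker_class == "InDel")
  ))
  if (is.na(x$causal)) {
    cat("  causal locus: none (null genome)\n")
  } else {
    cat(sprintf(
      "  causal locus: %s:%d (%s papilla allele on P1)\n",
      x$markers$chrom[x$causal], x$markers$pos[x$causal], x$inheritance
    ))
  }
  invisible(x)
}
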