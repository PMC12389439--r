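#' Write a simulated dataset as standard-format fixture files
#'
#' Emits everything the downstream analysis consumes: two parent VCFs (P1
#' homozygous REF, P2 homozygous ALT at every marker), two bulk VCFs carrying
#' GT and AD, a GFF3 of genes tiled along the genome, and a gene x stage FPKM
#' matrix with planted expression patterns. Genes overlapping the causal
#' window are planted with the "highly expressed in the first two stages"
#' pattern so the full pipeline has a recoverable truth; remaining genes cycle
#' through the other patterns deterministically. All files are plain text and
#' byte-identical under a fixed seed.
#'
#' @param outdir Output directory (created if absent).
#' @param spec The [genome_spec()] used for the simulation.
#' @param papilla_reads,non_papilla_reads [sequence_bulk()] tibbles.
#' @param gene_length,gene_spacing Gene model length and start-to-start
#'   spacing in bp for the tiled annotation.
#' @param causal_halfwidth Half-width (bp) of the window around the causal
#'   marker whose genes receive the candidate expression pattern.
#' @param parent_depth Fixed parental read depth written to parent VCF AD.
#' @param fpkm_replicates Replicate columns per stage in the FPKM matrix
#'   (1 writes S1..S4; 3 writes S1_r1..S4_r3).
#' @param seed Integer seed for FPKM noise.
#' @return Named list of file paths: `parent1`, `parent2`, `bulk_papilla`,
#'   `bulk_non_papilla`, `gff3`, `fpkm`, plus `planted_candidates` (character
#'   vector of causal-window gene ids, not a file).
#' @export
write_fixture_set <- function(outdir, spec, papilla_reads, non_papilla_reads,
                              gene_length = 3000, gene_spacing = 20000,
                              causal_halfwidth = 5e5,
                              parent_depth = 30, fpkm_replicates = 1,
                              seed = 1) {
  stopifnot(inherits(spec, "genome_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir, call. = FALSE)

  paths <- list(
    parent1 = file.path(outdir, "parent1.vcf"),
    parent2 = file.path(outdir, "parent2.vcf"),
    bulk_papilla = file.path(outdir, "bulk_papilla.vcf"),
    bulk_non_papilla = file.path(outdir, "bulk_non_papilla.vcf"),
    gff3 = file.path(outdir, "genes.gff3"),
    fpkm = file.path(outdir, "fpkm.tsv")
  )

  write_parent_vcf(paths$parent1, spec, sample = "P1", parent = 1, depth = parent_depth)
  write_parent_vcf(paths$parent2, spec, sample = "P2", parent = 2, depth = parent_depth)
  write_bulk_vcf(paths$bulk_papilla, spec, papilla_reads, sample = "BULK_PAP")
  write_bulk_vcf(paths$bulk_non_papilla, spec, non_papilla_reads, sample = "BULK_NONPAP")

  genes <- make_gene_models(spec, gene_length = gene_length, spacing = gene_spacing)
  write_gff3(paths$gff3, genes)

  planted <- character()
  if (!is.na(spec$causal)) {
    cc <- spec$markers$chrom[spec$causal]
    cp <- spec$markers$pos[spec$causal]
    planted <- genes$gene_id[
      genes$chrom == cc &
        genes$end >= cp - causal_halfwidth &
        genes$start <= cp + causal_halfwidth
    ]
  }
  fpkm <- make_fpkm_matrix(genes$gene_id,
    planted_first_two = planted, seed = seed
  )
  write_fpkm(paths$fpkm, fpkm, replicates = fpkm_replicates, seed = seed + 1L)

  c(paths, list(planted_candidates = planted))
}

vcf_header <- function(spec, sample) {
  c(
    "##fileformat=VCFv4.2",
    "##source=bsapilla-simulator",
    sprintf(
      "##contig=<ID=%s,length=%d>",
      spec$chromosomes$chrom, spec$chromosomes$length_bp
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample
    ), collapse = "\t")
  )
}

#' Write a fixed-homozygous parent VCF
#'
#' @param path Output path.
#' @param spec A [genome_spec()].
#' @param sample Sample name in the VCF column header.
#' @param parent 1 (homozygous REF at every marker) or 2 (homozygous ALT).
#' @param depth Fixed read depth written into AD.
#' @return `path`, invisibly.
#' @export
write_parent_vcf <- function(path, spec, sample, parent = 1, depth = 30) {
  gt <- if (parent == 1) "0/0" else "1/1"
  ad <- if (parent == 1) sprintf("%d,0", depth) else sprintf("0,%d", depth)
  m <- spec$markers
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%s",
    m$chrom, m$pos, m$marker_id, m$ref, m$alt, gt, ad
  )
  writeLines(c(vcf_header(spec, sample), body), path)
  invisible(path)
}

#' Write a bulk VCF from simulated reads
#'
#' AD holds REF,ALT depths (simulated P1 counts map to REF since P1 is the
#' reference parent in fixtures). GT is a naive call from the ALT frequency
#' (< 0.2 hom-REF, > 0.8 hom-ALT, else het; zero depth missing).
#'
#' @param path Output path.
#' @param spec A [genome_spec()].
#' @param reads A [sequence_bulk()] tibble aligned with `spec$markers`.
#' @param sample Sample name.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(path, spec, reads, sample) {
  m <- spec$markers
  stopifnot(nrow(reads) == nrow(m))
  freq <- ifelse(reads$depth > 0, reads$nonp1_count / reads$depth, NA_real_)
  gt <- dplyr::case_when(
    is.na(freq) ~ "./.",
    freq < 0.2 ~ "0/0",
    freq > 0.8 ~ "1/1",
    TRUE ~ "0/1"
  )
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%d,%d",
    m$chrom, m$pos, m$marker_id, m$ref, m$alt, gt,
    reads$p1_count, reads$nonp1_count
  )
  writeLines(c(vcf_header(spec, sample), body), path)
  invisible(path)
}

#' Tile synthetic gene models along a simulated genome
#'
#' @param spec A [genome_spec()].
#' @param gene_length Gene length in bp.
#' @param spacing Start-to-start spacing in bp.
#' @return Tibble of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (alternating +/-). Ids are `synt.<k>G<nnnnn>` for chromosome k.
#' @export
make_gene_models <- function(spec, gene_length = 3000, spacing = 20000) {
  stopifnot(gene_length >= 1, spacing >= 1)
  purrr::pmap_dfr(
    spec$chromosomes[, c("chrom", "length_bp")],
    function(chrom, length_bp) {
      starts <- seq(1L, as.integer(length_bp) - as.integer(gene_length), by = as.integer(spacing))
      k <- sub("^chr", "", chrom)
      tibble::tibble(
        gene_id = sprintf("synt.%sG%05d", k, seq_along(starts)),
        chrom = chrom,
        start = as.integer(starts),
        end = as.integer(starts + gene_length - 1L),
        strand = rep_len(c("+", "-"), length(starts))
      )
    }
  )
}

#' Write gene models to GFF3
#'
#' @param path Output path.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(path, genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = "gene",
    source = "bsapilla",
    ID = genes$gene_id,
    Name = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# canonical stage-state signatures per expression pattern
pattern_signatures <- function() {
  list(
    not_expressed_all = c("off", "off", "off", "off"),
    high_all = c("high", "high", "high", "high"),
    high_last_two = c("off", "off", "high", "high"),
    low_first_three = c("low", "low", "low", "high"),
    high_first_two = c("high", "high", "off", "off"),
    high_second_only = c("off", "high", "off", "off"),
    other = c("high", "off", "high", "off")
  )
}

draw_state_fpkm <- function(state, n) {
  switch(state,
    off = stats::runif(n, 0, 0.08),
    low = stats::runif(n, 0.15, 0.9),
    high = stats::runif(n, 2, 60)
  )
}

#' Build a synthetic FPKM matrix with planted expression patterns
#'
#' Genes named in `planted_first_two` receive the candidate pattern (high in
#' stages 1-2, off in 3-4); all other genes cycle deterministically through
#' the remaining patterns so every class is represented.
#'
#' @param gene_ids Character vector of gene ids.
#' @param planted_first_two Gene ids to plant with the `high_first_two`
#'   pattern.
#' @param pattern_cycle Patterns assigned round-robin to non-planted genes.
#' @param seed Integer seed for FPKM noise.
#' @return Tibble: `gene_id`, `S1`..`S4`, `true_pattern`.
#' @export
make_fpkm_matrix <- function(gene_ids,
                             planted_first_two = character(),
                             pattern_cycle = c(
                               "not_expressed_all", "high_all",
                               "high_last_two", "low_first_three",
                               "high_second_only", "other"
                             ),
                             seed = 1) {
  set.seed(as.integer(seed))
  pattern <- rep_len(pattern_cycle, length(gene_ids))
  pattern[gene_ids %in% planted_first_two] <- "high_first_two"
  sigs <- pattern_signatures()
  stage_cols <- purrr::map(1:4, function(s) {
    states <- purrr::map_chr(pattern, ~ sigs[[.x]][s])
    vals <- numeric(length(states))
    for (st in c("off", "low", "high")) {
      i <- states == st
      vals[i] <- draw_state_fpkm(st, sum(i))
    }
    round(vals, 3)
  })
  names(stage_cols) <- paste0("S", 1:4)
  tibble::tibble(gene_id = gene_ids, !!!stage_cols, true_pattern = pattern)
}

#' Write an FPKM matrix as TSV
#'
#' With `replicates = 1` columns are `gene_id, S1..S4`; with more, each stage
#' gets jittered replicate columns `S<k>_r<j>` (multiplicative lognormal
#' noise), which [read_fpkm()] averages back per stage.
#'
#' @param path Output path.
#' @param fpkm Tibble with `gene_id` and `S1`..`S4`.
#' @param replicates Replicate columns per stage.
#' @param seed Integer seed for replicate jitter.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(path, fpkm, replicates = 1, seed = 1) {
  stopifnot(all(c("gene_id", paste0("S", 1:4)) %in% names(fpkm)))
  if (replicates == 1) {
    readr::write_tsv(fpkm[, c("gene_id", paste0("S", 1:4))], path)
    return(invisible(path))
  }
  set.seed(as.integer(seed))
  out <- tibble::tibble(gene_id = fpkm$gene_id)
  for (s in paste0("S", 1:4)) {
    for (r in seq_len(replicates)) {
      out[[sprintf("%s_r%d", s, r)]] <-
        round(fpkm[[s]] * stats::rlnorm(nrow(fpkm), 0, 0.05), 3)
    }
  }
  readr::write_tsv(out, path)
  invisible(path)
}
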