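#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML with a mandatory integer `seed`, an `outdir`, and
#' either a `simulate` block (synthetic data) or an `inputs` block (paths to
#' parent/bulk VCFs plus a GFF3). Analysis parameters live under `params`;
#' omitted entries take the package defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated config list (class `bsa_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A config list built in code.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  if (is.null(config$outdir)) stop("config must set an outdir", call. = FALSE)
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop("config needs exactly one of `simulate` or `inputs`", call. = FALSE)
  }
  defaults <- list(
    min_depth = 8, window = 1e6, step = 1e5, threshold = 0.5,
    min_markers = 5, high_cut = 1, off_cut = 0.1, write_plots = TRUE
  )
  config$params <- utils::modifyList(defaults, config$params %||% list())
  thr <- config$params$threshold
  if (thr <= 0 || thr > 1) stop("threshold must lie in (0, 1]", call. = FALSE)
  structure(config, class = c("bsa_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_defaults <- function(sim) {
  defaults <- list(
    n = 300, bulk_size = 30, coverage = 50, error_rate = 0.001,
    markers_per_chrom = 2000, n_chrom = 9, chrom_length = 4e7, cm_per_mb = 3,
    causal = list(chrom = "chr5", pos = 2e7)
  )
  sim <- sim %||% list()
  # YAML 1.1 reads a bare `n:` key as a boolean, so configs use `n_f2`
  if (!is.null(sim$n_f2)) {
    sim$n <- sim$n_f2
    sim$n_f2 <- NULL
  }
  has_causal <- "causal" %in% names(sim)
  out <- utils::modifyList(defaults, sim)
  if (has_causal) out$causal <- sim$causal
  out
}

#' Run the single-population BSA pipeline
#'
#' Orchestrates one mapping population end to end: simulate (or load) parent
#' and bulk variant data, screen homozygous-differential markers, compute
#' SNP- and InDel-index tracks, aggregate sliding windows, call candidate
#' intervals at the |delta| threshold, summarize chromosomes, annotate
#' interval genes, and write every artifact plus a JSON manifest under
#' `config$outdir`.
#'
#' @param config A config list (see [read_run_config()]); validated on entry.
#' @return (Invisibly) a list: `marker_table`, `filter_report`, per-class
#'   `tracks`, `windows`, `intervals`, `summaries`, `gene_sets`, the gene
#'   `annotation`, `fixtures` (paths, synthetic runs only), `files` written,
#'   and the expanded `config`.
#' @export
run_single_population <- function(config) {
  config <- validate_config(unclass(config))
  p <- config$params
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()

  if (!is.null(config$simulate)) {
    sim <- sim_defaults(config$simulate)
    spec <- genome_spec(
      chromosomes = default_chromosomes(
        n_chrom = sim$n_chrom, length_bp = sim$chrom_length,
        cm_per_mb = sim$cm_per_mb
      ),
      markers_per_chrom = sim$markers_per_chrom,
      causal_locus = sim$causal
    )
    pop <- simulate_f2_population(spec, n = sim$n, seed = config$seed)
    bulks <- make_bulks(pop, bulk_size = sim$bulk_size, seed = config$seed + 1L)
    reads_pap <- sequence_bulk(pop, bulks$papilla,
      coverage = sim$coverage, error_rate = sim$error_rate,
      seed = config$seed + 2L
    )
    reads_nonpap <- sequence_bulk(pop, bulks$non_papilla,
      coverage = sim$coverage, error_rate = sim$error_rate,
      seed = config$seed + 3L
    )
    fixtures <- write_fixture_set(
      file.path(outdir, "fixtures"), spec, reads_pap, reads_nonpap,
      seed = config$seed + 4L
    )
    inputs <- list(
      parent1_vcf = fixtures$parent1, parent2_vcf = fixtures$parent2,
      bulk_papilla_vcf = fixtures$bulk_papilla,
      bulk_non_papilla_vcf = fixtures$bulk_non_papilla,
      gff3 = fixtures$gff3
    )
    chrom_lengths <- stats::setNames(
      spec$chromosomes$length_bp, spec$chromosomes$chrom
    )
  } else {
    inputs <- config$inputs
    fixtures <- NULL
    chrom_lengths <- NULL
    if (!is.null(inputs$chrom_lengths)) {
      chrom_lengths <- unlist(inputs$chrom_lengths)
    }
  }

  parent1 <- load_vcf(inputs$parent1_vcf)
  parent2 <- load_vcf(inputs$parent2_vcf)
  bulk_pap <- load_vcf(inputs$bulk_papilla_vcf)
  bulk_nonpap <- load_vcf(inputs$bulk_non_papilla_vcf)

  markers <- screen_homozygous_differential(
    parent1, parent2, bulk_pap, bulk_nonpap,
    min_depth = p$min_depth
  )
  files$marker_table <- write_marker_table(
    markers, file.path(outdir, "marker_table.tsv")
  )
  files$filter_report <- file.path(outdir, "filter_report.json")
  jsonlite::write_json(
    attr(markers, "filter_report"), files$filter_report,
    auto_unbox = TRUE, pretty = TRUE
  )

  annotation <- if (!is.null(inputs$gff3)) read_gff_genes(inputs$gff3) else NULL

  tracks <- windows <- intervals <- summaries <- gene_sets <- list()
  for (cls in c("SNP", "InDel")) {
    sub <- markers[markers$marker_class == cls, ]
    if (nrow(sub) == 0) next
    track <- compute_index(sub)
    wt <- window_track(track,
      window_size = p$window, step = p$step,
      chrom_lengths = chrom_lengths
    )
    iv <- call_intervals(wt, track,
      threshold = p$threshold,
      min_markers = p$min_markers
    )
    tracks[[cls]] <- track
    windows[[cls]] <- wt
    intervals[[cls]] <- iv
    summaries[[cls]] <- summarize_chromosomes(track, threshold = p$threshold)

    files[[paste0("track_", cls)]] <- file.path(outdir, sprintf("track_%s.tsv", cls))
    readr::write_tsv(track, files[[paste0("track_", cls)]])
    files[[paste0("windows_", cls)]] <- file.path(outdir, sprintf("windows_%s.tsv", cls))
    readr::write_tsv(wt, files[[paste0("windows_", cls)]])
    files[[paste0("intervals_", cls)]] <- file.path(outdir, sprintf("intervals_%s.bed", cls))
    write_intervals_bed(iv, files[[paste0("intervals_", cls)]])
    files[[paste0("intervals_json_", cls)]] <- file.path(outdir, sprintf("intervals_%s.json", cls))
    jsonlite::write_json(iv, files[[paste0("intervals_json_", cls)]],
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )

    if (!is.null(annotation)) {
      gs <- genes_in_intervals(iv, annotation,
        label = paste0(config$label %||% "pop", ":", cls)
      )
      gene_sets[[cls]] <- gs
      files[[paste0("genes_", cls)]] <- write_gene_set(
        gs, file.path(outdir, sprintf("genes_%s.txt", cls))
      )
    }

    if (isTRUE(p$write_plots)) {
      plt <- plot_delta_track(track, wt, iv, threshold = p$threshold)
      files[[paste0("plot_", cls)]] <- file.path(outdir, sprintf("delta_%s.png", cls))
      suppressMessages(ggplot2::ggsave(
        files[[paste0("plot_", cls)]], plt,
        width = 9, height = 7, dpi = 120
      ))
    }
  }

  manifest <- list(
    package = "bsapilla",
    version = as.character(utils::packageVersion("bsapilla")),
    seed = config$seed,
    params = p,
    mode = if (!is.null(config$simulate)) "simulate" else "real",
    files = lapply(files, basename),
    filter_report = attr(markers, "filter_report")
  )
  files$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    marker_table = markers,
    filter_report = filter_report(markers),
    tracks = tracks, windows = windows, intervals = intervals,
    summaries = summaries, gene_sets = gene_sets,
    annotation = annotation, fixtures = fixtures,
    files = files, config = config
  ))
}

#' Co-localize candidates across two mapping populations
#'
#' Intersects the SNP-derived and InDel-derived interval gene sets of two
#' independent populations, takes the union across marker classes, runs the
#' expression-pattern census, and applies the first-two-stage candidate
#' filter.
#'
#' @param pop1,pop2 Results of [run_single_population()].
#' @param fpkm_path Path to the gene x stage FPKM matrix.
#' @param outdir Output directory for co-localization artifacts.
#' @param high_cut,off_cut Expression thresholds (see [classify_pattern()]).
#' @return (Invisibly) a list: `snp_common`, `indel_common`, `union`,
#'   `census`, `candidates`, `summary` (one-row tibble with the counts),
#'   `files`.
#' @export
run_colocalization <- function(pop1, pop2, fpkm_path, outdir,
                               high_cut = 1, off_cut = 0.1) {
  if (!file.exists(fpkm_path)) {
    stop("expression stage failed: FPKM file not found: ", fpkm_path,
      call. = FALSE
    )
  }
  for (nm in c("SNP", "InDel")) {
    if (is.null(pop1$gene_sets[[nm]]) || is.null(pop2$gene_sets[[nm]])) {
      stop(
        "co-localization needs annotated gene sets for both populations (",
        nm, " missing)",
        call. = FALSE
      )
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()

  snp_common <- intersect_gene_sets(
    pop1$gene_sets$SNP, pop2$gene_sets$SNP,
    label = "common:SNP"
  )
  indel_common <- intersect_gene_sets(
    pop1$gene_sets$InDel, pop2$gene_sets$InDel,
    label = "common:InDel"
  )
  union_set <- union_gene_sets(snp_common, indel_common, label = "common:union")
  if (nrow(union_set) == 0) {
    warning("populations share no candidate genes", call. = FALSE)
  }

  fpkm <- read_fpkm(fpkm_path)
  census <- pattern_census(union_set, fpkm, high_cut = high_cut, off_cut = off_cut)
  candidates <- select_candidates(union_set, fpkm,
    high_cut = high_cut, off_cut = off_cut
  )

  summary <- tibble::tibble(
    n_snp_common = nrow(snp_common),
    n_indel_common = nrow(indel_common),
    n_shared = nrow(snp_common) + nrow(indel_common) - nrow(union_set),
    n_union = nrow(union_set),
    n_candidates = nrow(candidates)
  )

  files$snp_common <- write_gene_set(snp_common, file.path(outdir, "genes_common_SNP.txt"))
  files$indel_common <- write_gene_set(indel_common, file.path(outdir, "genes_common_InDel.txt"))
  files$union <- write_gene_set(union_set, file.path(outdir, "genes_union.txt"))
  files$candidates <- write_gene_set(candidates, file.path(outdir, "candidates.txt"))
  files$census <- file.path(outdir, "pattern_census.json")
  jsonlite::write_json(
    stats::setNames(as.list(census$n), as.character(census$pattern)),
    files$census,
    auto_unbox = TRUE, pretty = TRUE
  )
  files$summary <- file.path(outdir, "colocalization_summary.json")
  jsonlite::write_json(as.list(summary), files$summary,
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    snp_common = snp_common, indel_common = indel_common,
    union = union_set, census = census, candidates = candidates,
    summary = summary, files = files
  ))
}
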