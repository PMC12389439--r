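#' Load per-sample genotype and allele-depth records from a VCF
#'
#' Reads a VCF (v4.2) and returns one row per retained site per requested
#' sample, carrying the GT and AD FORMAT fields. Multi-allelic and symbolic
#' ALT sites are dropped by default and counted.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param samples Character vector of sample names to extract; `NULL` keeps
#'   all samples in the file.
#' @param drop_multiallelic Drop sites whose ALT holds several alleles or a
#'   symbolic allele (default `TRUE`).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample`, `gt`,
#'   `ad_ref`, `ad_alt`. The number of dropped multi-allelic/symbolic sites is
#'   attached as attribute `"dropped_multiallelic"`.
#' @examples
#' vcf <- system.file("extdata", "toy_parent1.vcf", package = "bsapilla")
#' load_vcf(vcf, samples = "P1")
#' @export
load_vcf <- function(path, samples = NULL, drop_multiallelic = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)

  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    sample = character(), gt = character(),
    ad_ref = integer(), ad_alt = integer()
  )

  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(vcf@fix) == 0) {
    attr(empty, "dropped_multiallelic") <- 0L
    return(empty)
  }

  fix <- tibble::as_tibble(as.data.frame(vcf@fix[, c("CHROM", "POS", "REF", "ALT"),
    drop = FALSE
  ], stringsAsFactors = FALSE))
  names(fix) <- c("chrom", "pos", "ref", "alt")
  fix$pos <- as.integer(fix$pos)

  file_samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- file_samples
  missing_s <- setdiff(samples, file_samples)
  if (length(missing_s) > 0) {
    stop(
      "sample(s) not present in ", path, ": ",
      paste(missing_s, collapse = ", "),
      call. = FALSE
    )
  }

  bad <- rep(FALSE, nrow(fix))
  if (drop_multiallelic) {
    bad <- grepl(",", fix$alt, fixed = TRUE) | grepl("<", fix$alt, fixed = TRUE)
  }
  dropped <- sum(bad)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")

  out <- purrr::map_dfr(samples, function(s) {
    adm <- stringr::str_split_fixed(ad[, s], ",", 2)
    tibble::tibble(
      fix,
      sample = s,
      gt = unname(gt[, s]),
      ad_ref = suppressWarnings(as.integer(adm[, 1])),
      ad_alt = suppressWarnings(as.integer(adm[, 2]))
    )
  })
  out <- out[rep(!bad, length(samples)), ]
  attr(out, "dropped_multiallelic") <- as.integer(dropped)
  out
}

#' Screen homozygous-differential markers and orient bulk depths
#'
#' Retains sites where the two inbred parents are homozygous for different
#' alleles — the informative marker class for bulked-segregant analysis — and
#' orients each bulk's allele depths to the P1 (papilla-parent) allele, which
#' may be either REF or ALT at a given site. Sites are classified SNP when
#' both alleles have length 1, otherwise InDel.
#'
#' Sites are dropped, in order of precedence, when a parental genotype is
#' missing, when a parent is heterozygous (or not a simple diploid call),
#' when the parents carry the same allele, or when either bulk's total depth
#' at the site falls below `min_depth`.
#'
#' @param parent1,parent2 [load_vcf()] tibbles for the papilla (P1) and
#'   non-papilla (P2) parent, each holding a single sample.
#' @param bulk_papilla,bulk_non_papilla [load_vcf()] tibbles for the two
#'   bulks, each holding a single sample.
#' @param min_depth Minimum per-bulk read depth to retain a site (default 8).
#' @return A marker-table tibble sorted by chromosome and position with
#'   columns `marker_class`, `chrom`, `pos`, `ref`, `alt`, `parent1_gt`,
#'   `parent2_gt`, `pap_p1`, `pap_nonp1`, `nonpap_p1`, `nonpap_nonp1`
#'   (per-bulk read counts of the P1 and non-P1 allele). The filter report —
#'   a named list with `input`, `dropped_missing`,
#'   `dropped_heterozygous_parent`, `dropped_nondifferential`,
#'   `dropped_low_depth`, `retained` — is attached as attribute
#'   `"filter_report"` (see [filter_report()]).
#' @export
screen_homozygous_differential <- function(parent1, parent2,
                                           bulk_papilla, bulk_non_papilla,
                                           min_depth = 8) {
  key <- c("chrom", "pos", "ref", "alt")
  p1 <- dplyr::select(parent1, dplyr::all_of(key), p1_gt = "gt")
  p2 <- dplyr::select(parent2, dplyr::all_of(key), p2_gt = "gt")
  bp <- dplyr::select(bulk_papilla, dplyr::all_of(key),
    pap_ad_ref = "ad_ref", pap_ad_alt = "ad_alt"
  )
  bn <- dplyr::select(bulk_non_papilla, dplyr::all_of(key),
    nonpap_ad_ref = "ad_ref", nonpap_ad_alt = "ad_alt"
  )

  sites <- p1 |>
    dplyr::inner_join(p2, by = key) |>
    dplyr::left_join(bp, by = key) |>
    dplyr::left_join(bn, by = key) |>
    dplyr::mutate(dplyr::across(
      c("pap_ad_ref", "pap_ad_alt", "nonpap_ad_ref", "nonpap_ad_alt"),
      ~ tidyr::replace_na(.x, 0L)
    ))

  g1 <- gt_class(sites$p1_gt)
  g2 <- gt_class(sites$p2_gt)
  missing <- g1 == "missing" | g2 == "missing"
  het <- !missing & (g1 == "het" | g2 == "het")
  nondiff <- !missing & !het & g1 == g2
  pap_depth <- sites$pap_ad_ref + sites$pap_ad_alt
  nonpap_depth <- sites$nonpap_ad_ref + sites$nonpap_ad_alt
  low <- !missing & !het & !nondiff &
    (pap_depth < min_depth | nonpap_depth < min_depth)
  keep <- !(missing | het | nondiff | low)

  p1_is_ref <- g1 == "hom_ref"
  out <- tibble::tibble(
    marker_class = ifelse(
      nchar(sites$ref) == 1 & nchar(sites$alt) == 1, "SNP", "InDel"
    ),
    chrom = sites$chrom,
    pos = sites$pos,
    ref = sites$ref,
    alt = sites$alt,
    parent1_gt = sites$p1_gt,
    parent2_gt = sites$p2_gt,
    pap_p1 = ifelse(p1_is_ref, sites$pap_ad_ref, sites$pap_ad_alt),
    pap_nonp1 = ifelse(p1_is_ref, sites$pap_ad_alt, sites$pap_ad_ref),
    nonpap_p1 = ifelse(p1_is_ref, sites$nonpap_ad_ref, sites$nonpap_ad_alt),
    nonpap_nonp1 = ifelse(p1_is_ref, sites$nonpap_ad_alt, sites$nonpap_ad_ref)
  )[keep, ]
  out <- dplyr::arrange(out, .data$chrom, .data$pos)

  attr(out, "filter_report") <- list(
    input = nrow(sites),
    dropped_missing = sum(missing),
    dropped_heterozygous_parent = sum(het),
    dropped_nondifferential = sum(nondiff),
    dropped_low_depth = sum(low),
    retained = sum(keep)
  )
  out
}

# classify a diploid GT string: hom_ref / hom_alt / het / missing
gt_class <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% "1/1"] <- "hom_alt"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out
}

#' Retrieve the filter report attached to a screened marker table
#'
#' @param markers Output of [screen_homozygous_differential()].
#' @return A one-row tibble with the site-count bookkeeping: input, each drop
#'   category, retained.
#' @export
filter_report <- function(markers) {
  rep <- attr(markers, "filter_report")
  if (is.null(rep)) stop("no filter report attached to this table", call. = FALSE)
  tibble::as_tibble(rep)
}

#' Write / read a marker table as TSV
#'
#' Column order is fixed: marker_class, chrom, pos, ref, alt, parent1_gt,
#' parent2_gt, pap_p1, pap_nonp1, nonpap_p1, nonpap_nonp1.
#'
#' @param markers A marker-table tibble.
#' @param path Output (input) file path.
#' @return `write_marker_table()` returns `path` invisibly;
#'   `read_marker_table()` returns the tibble.
#' @export
write_marker_table <- function(markers, path) {
  cols <- c(
    "marker_class", "chrom", "pos", "ref", "alt", "parent1_gt", "parent2_gt",
    "pap_p1", "pap_nonp1", "nonpap_p1", "nonpap_nonp1"
  )
  readr::write_tsv(markers[, cols], path)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_class = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    parent1_gt = readr::col_character(),
    parent2_gt = readr::col_character(),
    pap_p1 = readr::col_integer(),
    pap_nonp1 = readr::col_integer(),
    nonpap_p1 = readr::col_integer(),
    nonpap_nonp1 = readr::col_integer()
  ))
}
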