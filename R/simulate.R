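#' Simulate an F2 population from two inbred parents
#'
#' Each F2 individual is the union of two independent F1 gametes. A gamete is
#' generated marker-to-marker along each chromosome as a first-order Markov
#' chain: the first marker's parental origin is a fair coin, and adjacent
#' markers recombine with Haldane's fraction r = (1 - exp(-2d))/2 for genetic
#' distance d Morgans (no interference). Phenotype is deterministic from the
#' genotype at the causal locus: under the dominant model an individual has
#' papillae iff it carries at least one P1 allele there. For a null genome
#' (no causal locus) phenotypes are drawn independently, papilla with
#' probability 3/4.
#'
#' @param spec A [genome_spec()].
#' @param n Number of F2 individuals (>= 1).
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return An object of class `f2_population`: list with `spec`, `genotype`
#'   (integer matrix, markers x individuals, values 0/1/2 = number of P2
#'   alleles) and `phenotype` (character, `"papilla"`/`"non_papilla"`).
#'
#' @examples
#' spec <- genome_spec(markers_per_chrom = 50)
#' pop <- simulate_f2_population(spec, n = 100, seed = 1)
#' table(pop$phenotype)
#' @export
simulate_f2_population <- function(spec, n, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("population size n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(as.integer(seed))

  m <- nrow(spec$markers)
  geno <- matrix(0L, nrow = m, ncol = n)
  idx <- split(seq_len(m), spec$markers$chrom)
  for (rows in idx) {
    d <- diff(spec$markers$cm[rows]) / 100 # Morgans between adjacent markers
    r <- (1 - exp(-2 * d)) / 2
    geno[rows, ] <- sim_gametes(length(rows), r, n) + sim_gametes(length(rows), r, n)
  }

  if (is.na(spec$causal)) {
    pheno <- ifelse(stats::runif(n) < 0.75, "papilla", "non_papilla")
  } else {
    g <- geno[spec$causal, ] # number of P2 alleles
    has_p1 <- g < 2L
    papilla <- if (spec$inheritance == "dominant") has_p1 else g == 0L
    pheno <- ifelse(papilla, "papilla", "non_papilla")
  }

  structure(
    list(spec = spec, genotype = geno, phenotype = pheno),
    class = "f2_population"
  )
}

# One chromosome's worth of gametes: m markers, n gametes, recombination
# fractions r (length m-1). Returns m x n matrix of 0 (P1) / 1 (P2).
sim_gametes <- function(m, r, n) {
  start <- stats::rbinom(n, 1L, 0.5)
  if (m == 1) {
    return(matrix(as.integer(start), nrow = 1))
  }
  # r (length m-1) recycles down the column-major crossover draw
  xo <- matrix((stats::runif((m - 1) * n) < r) * 1L, nrow = m - 1)
  switches <- apply(xo, 2, cumsum)
  if (!is.matrix(switches)) switches <- matrix(switches, nrow = m - 1)
  state <- sweep(switches, 2, start, "+") %% 2L
  out <- rbind(matrix(start, nrow = 1), state)
  storage.mode(out) <- "integer"
  out
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf(
    "<f2_population> %d individuals x %d markers; %d papilla / %d non-papilla\n",
    ncol(x$genotype), nrow(x$genotype),
    sum(x$phenotype == "papilla"), sum(x$phenotype == "non_papilla")
  ))
  invisible(x)
}

#' Tidy an F2 population into a per-individual tibble
#'
#' @param x An `f2_population`.
#' @param ... Unused.
#' @return Tibble with `individual`, `phenotype`, and (if a causal locus
#'   exists) `causal_genotype` coded `P1/P1`, `P1/P2`, `P2/P2`.
#' @export
tidy.f2_population <- function(x, ...) {
  out <- tibble::tibble(
    individual = seq_along(x$phenotype),
    phenotype = x$phenotype
  )
  if (!is.na(x$spec$causal)) {
    g <- x$genotype[x$spec$causal, ]
    out$causal_genotype <- c("P1/P1", "P1/P2", "P2/P2")[g + 1L]
  }
  out
}

#' Draw phenotype-extreme bulks from an F2 population
#'
#' Samples `bulk_size` individuals uniformly without replacement within each
#' phenotype class, mirroring tail-bulk construction for BSA-Seq.
#'
#' @param pop An [simulate_f2_population()] result.
#' @param bulk_size Individuals per bulk (default 30).
#' @param seed Integer seed.
#' @return List with `papilla` and `non_papilla`, each an integer vector of
#'   individual indices of length `bulk_size`.
#' @examples
#' spec <- genome_spec(markers_per_chrom = 50)
#' pop <- simulate_f2_population(spec, n = 200, seed = 1)
#' bulks <- make_bulks(pop, bulk_size = 30, seed = 2)
#' @export
make_bulks <- function(pop, bulk_size = 30, seed) {
  stopifnot(inherits(pop, "f2_population"))
  set.seed(as.integer(seed))
  classes <- c("papilla", "non_papilla")
  out <- lapply(classes, function(cl) {
    pool <- which(pop$phenotype == cl)
    if (length(pool) < bulk_size) {
      stop(sprintf(
        "cannot form %s bulk: %d individuals available, %d requested",
        cl, length(pool), bulk_size
      ), call. = FALSE)
    }
    sort(sample(pool, bulk_size))
  })
  names(out) <- classes
  out
}

#' Simulate sequencing of a bulk
#'
#' Per marker, read depth is Poisson(`coverage`); each read carries the non-P1
#' allele with probability f(1-e) + (1-f)e, where f is the bulk's true non-P1
#' allele frequency (over 2 x bulk-size allele copies) and e a symmetric
#' per-read error rate.
#'
#' @param pop The `f2_population` the bulk was drawn from.
#' @param bulk Integer vector of individual indices (one element of
#'   [make_bulks()]).
#' @param coverage Mean read depth per marker (lambda > 0).
#' @param error_rate Per-read allele flip probability, in \[0, 0.5).
#' @param seed Integer seed.
#' @return Tibble: `chrom`, `pos`, `marker_class`, `depth`, `p1_count`,
#'   `nonp1_count`.
#' @examples
#' spec <- genome_spec(markers_per_chrom = 50)
#' pop <- simulate_f2_population(spec, n = 200, seed = 1)
#' bulks <- make_bulks(pop, seed = 2)
#' reads <- sequence_bulk(pop, bulks$papilla, coverage = 50, seed = 3)
#' @export
sequence_bulk <- function(pop, bulk, coverage = 50, error_rate = 0.001, seed) {
  stopifnot(inherits(pop, "f2_population"))
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must lie in [0, 0.5)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  m <- nrow(pop$genotype)
  f <- rowMeans(pop$genotype[, bulk, drop = FALSE]) / 2 # non-P1 allele frequency
  p <- f * (1 - error_rate) + (1 - f) * error_rate
  depth <- stats::rpois(m, coverage)
  nonp1 <- stats::rbinom(m, depth, p)
  dplyr::mutate(
    pop$spec$markers[, c("chrom", "pos", "marker_class")],
    depth = depth,
    p1_count = depth - nonp1,
    nonp1_count = nonp1
  )
}

#' Build a marker table directly from simulated bulk reads
#'
#' Convenience constructor that skips the VCF round trip: because simulated
#' parents are fixed homozygous opposite at every marker, the oriented marker
#' table is known by construction. The result is identical in shape to
#' [screen_homozygous_differential()] output and feeds [compute_index()].
#'
#' @param spec The [genome_spec()] used for the simulation.
#' @param papilla_reads,non_papilla_reads [sequence_bulk()] tibbles for the
#'   two bulks.
#' @param min_depth Minimum per-bulk depth to retain a marker.
#' @return A marker-table tibble (see [screen_homozygous_differential()]).
#' @export
marker_table_from_sim <- function(spec, papilla_reads, non_papilla_reads,
                                  min_depth = 8) {
  stopifnot(inherits(spec, "genome_spec"))
  tbl <- tibble::tibble(
    marker_class = spec$markers$marker_class,
    chrom = spec$markers$chrom,
    pos = spec$markers$pos,
    ref = spec$markers$ref,
    alt = spec$markers$alt,
    parent1_gt = "0/0",
    parent2_gt = "1/1",
    pap_p1 = papilla_reads$p1_count,
    pap_nonp1 = papilla_reads$nonp1_count,
    nonpap_p1 = non_papilla_reads$p1_count,
    nonpap_nonp1 = non_papilla_reads$nonp1_count
  )
  tbl <- dplyr::filter(
    tbl,
    (.data$pap_p1 + .data$pap_nonp1) >= min_depth,
    (.data$nonpap_p1 + .data$nonpap_nonp1) >= min_depth
  )
  dplyr::arrange(tbl, .data$chrom, .data$pos)
}
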