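# Shared fixtures and independent oracles for the test suite.

# Exact genotype-frequency oracle for expected bulk allele frequencies.
# Enumerates the F2 genotype classes at the causal marker (P1/P1, P1/P2,
# P2/P2 at 1/4 : 1/2 : 1/4), conditions on the phenotype class, and returns
# the expected non-P1 allele frequency of each bulk and the expected delta.
# Independent of the simulator: pure probability arithmetic.
expected_bulk_freqs <- function(model = "dominant") {
  geno_freq <- c(0.25, 0.5, 0.25) # P1/P1, P1/P2, P2/P2
  nonp1_dose <- c(0, 1, 2) / 2
  papilla <- if (model == "dominant") c(TRUE, TRUE, FALSE) else c(TRUE, FALSE, FALSE)
  f_pap <- sum(geno_freq[papilla] * nonp1_dose[papilla]) / sum(geno_freq[papilla])
  f_non <- sum(geno_freq[!papilla] * nonp1_dose[!papilla]) / sum(geno_freq[!papilla])
  list(papilla = f_pap, non_papilla = f_non, delta = f_non - f_pap)
}

# Reduced two-chromosome map for replicate studies of the delta-index
# sampling distribution: the distribution at a given marker does not depend
# on how many other markers are simulated.
two_chrom_spec <- function(markers_per_chrom = 11, causal = TRUE) {
  suppressMessages(genome_spec(
    chromosomes = tibble::tibble(
      chrom = c("chr1", "chr5"), length_bp = 4e7L, cm_per_mb = 3
    ),
    markers_per_chrom = markers_per_chrom,
    causal_locus = if (causal) list(chrom = "chr5", pos = 2e7) else NULL
  ))
}

# One simulate -> bulk -> sequence -> marker-table pass.
sim_marker_table <- function(spec, seed, n = 300, bulk_size = 30,
                             coverage = 50, error_rate = 0.001) {
  pop <- simulate_f2_population(spec, n = n, seed = seed)
  bulks <- make_bulks(pop, bulk_size = bulk_size, seed = seed + 1L)
  rp <- sequence_bulk(pop, bulks$papilla,
    coverage = coverage,
    error_rate = error_rate, seed = seed + 2L
  )
  rn <- sequence_bulk(pop, bulks$non_papilla,
    coverage = coverage,
    error_rate = error_rate, seed = seed + 3L
  )
  marker_table_from_sim(spec, rp, rn)
}

chrom_lengths_of <- function(spec) {
  stats::setNames(spec$chromosomes$length_bp, spec$chromosomes$chrom)
}

# Random marker table generator for property tests.
random_marker_table <- function(seed, n_markers = 30, n_chrom = 2,
                                max_pos = 5e6, max_depth = 40) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_markers, replace = TRUE))
  tbl <- tibble::tibble(
    marker_class = sample(c("SNP", "InDel"), n_markers, replace = TRUE),
    chrom = chrom,
    pos = NA_integer_,
    ref = "A", alt = "G", parent1_gt = "0/0", parent2_gt = "1/1",
    pap_p1 = rpois(n_markers, max_depth / 2),
    pap_nonp1 = rpois(n_markers, max_depth / 2),
    nonpap_p1 = rpois(n_markers, max_depth / 2),
    nonpap_nonp1 = rpois(n_markers, max_depth / 2)
  )
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    tbl$pos[tbl$chrom == ch] <- sort(sample.int(max_pos, k))
  }
  tbl
}

# Brute-force oracle for window aggregation + interval calling: explicit
# per-window marker scans and a literal merge loop, no shared code with
# window_track()/call_intervals().
brute_intervals <- function(track, chrom_lengths, window_size, step,
                            threshold, min_markers) {
  sel <- list()
  for (ch in sort(unique(track$chrom))) {
    t <- track[track$chrom == ch, ]
    len <- chrom_lengths[[ch]]
    start <- 1
    while (start <= len) {
      end <- min(start + window_size - 1, len)
      inside <- t$delta_index[t$pos >= start & t$pos <= end]
      if (length(inside) >= min_markers &&
        abs(mean(inside)) >= threshold) {
        sel[[length(sel) + 1]] <- list(chrom = ch, start = start, end = end)
      }
      start <- start + step
    }
  }
  if (length(sel) == 0) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric()
    ))
  }
  merged <- list(sel[[1]])
  for (w in sel[-1]) {
    last <- merged[[length(merged)]]
    if (w$chrom == last$chrom && w$start <= last$end + 1) {
      merged[[length(merged)]]$end <- max(last$end, w$end)
    } else {
      merged[[length(merged) + 1]] <- w
    }
  }
  dplyr::bind_rows(lapply(merged, tibble::as_tibble))
}

# Brute-force all-pairs gene/interval overlap oracle (1-based inclusive).
brute_genes_in_intervals <- function(intervals, genes) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(intervals$chrom == genes$chrom[i] &
      intervals$start <= genes$end[i] &
      intervals$end >= genes$start[i])
  }, logical(1))
  out <- genes[hit, c("gene_id", "chrom", "start", "end")]
  out[order(out$chrom, out$start), ]
}

# FPKM fixture whose pattern census is a prescribed partition.
partition_fpkm_fixture <- function(counts = c(
                                     not_expressed_all = 33, high_all = 26,
                                     high_last_two = 6, low_first_three = 2,
                                     high_first_two = 4, high_second_only = 1
                                   ),
                                   seed = 42) {
  patterns <- rep(names(counts), counts)
  ids <- sprintf("fix.5G%05d", seq_along(patterns))
  fpkm <- make_fpkm_matrix(ids, seed = seed)
  # overwrite the round-robin assignment with the prescribed partition
  sigs <- list(
    not_expressed_all = c(0, 0, 0, 0),
    high_all = c(3, 4, 6, 5),
    high_last_two = c(0.02, 0.05, 8, 9),
    low_first_three = c(0.3, 0.5, 0.4, 7),
    high_first_two = c(5, 7.2, 0.05, 0),
    high_second_only = c(0.01, 6, 0.04, 0.02)
  )
  set.seed(seed)
  for (s in 1:4) {
    base <- vapply(patterns, function(p) sigs[[p]][s], numeric(1))
    jitter <- ifelse(base >= 2, runif(length(base), 0.9, 1.1), 1)
    fpkm[[paste0("S", s)]] <- base * jitter
  }
  fpkm$true_pattern <- patterns
  gene_set <- tibble::tibble(
    gene_id = ids, chrom = "chr5",
    start = seq_along(ids) * 1000L, end = seq_along(ids) * 1000L + 500L
  )
  list(fpkm = fpkm, genes = gene_set)
}
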