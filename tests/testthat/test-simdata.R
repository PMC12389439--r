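test_that("genome_spec validates its inputs and snaps the causal locus", {
  spec <- two_chrom_spec(markers_per_chrom = 10)
  expect_s3_class(spec, "genome_spec")
  expect_true(all(diff(spec$markers$pos[spec$markers$chrom == "chr1"]) > 0))
  expect_equal(spec$markers$chrom[spec$causal], "chr5")
  expect_message(
    genome_spec(markers_per_chrom = 10, causal_locus = list(chrom = "chr5", pos = 123)),
    "snapped"
  )
  expect_error(
    genome_spec(causal_locus = list(chrom = "chr99", pos = 1)),
    "not declared"
  )
  expect_error(
    genome_spec(causal_locus = list(chrom = "chr5", pos = 9e9)),
    "outside"
  )
  expect_error(genome_spec(markers_per_chrom = 0), "markers_per_chrom")
})

test_that("F2 genotypes at a marker segregate 1:2:1 and phenotypes 3:1", {
  spec <- two_chrom_spec(markers_per_chrom = 5)
  pop <- simulate_f2_population(spec, n = 10000, seed = 7)
  # genotype law at an arbitrary single marker
  g <- table(factor(pop$genotype[3, ], levels = 0:2))
  gof_geno <- stats::chisq.test(g, p = c(1, 2, 1) / 4)
  expect_gt(gof_geno$p.value, 0.01)
  # dominant phenotype law at the causal locus
  ph <- table(factor(pop$phenotype, levels = c("papilla", "non_papilla")))
  gof_ph <- stats::chisq.test(ph, p = c(3, 1) / 4)
  expect_gt(gof_ph$p.value, 0.01)
  # phenotype is deterministic from the causal genotype under dominance
  expect_equal(
    pop$phenotype == "papilla",
    pop$genotype[spec$causal, ] < 2
  )
})

test_that("phenotype segregation passes a 3:1 chi-square in nearly all replicates", {
  spec <- two_chrom_spec(markers_per_chrom = 3)
  pvals <- vapply(1:100, function(s) {
    pop <- simulate_f2_population(spec, n = 300, seed = 1000 + s)
    ph <- table(factor(pop$phenotype, levels = c("papilla", "non_papilla")))
    stats::chisq.test(ph, p = c(3, 1) / 4)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("zero genetic distance between adjacent markers means zero recombination", {
  spec <- suppressMessages(genome_spec(
    chromosomes = tibble::tibble(chrom = "chr1", length_bp = 4e7L, cm_per_mb = 1e-9),
    markers_per_chrom = 4,
    causal_locus = list(chrom = "chr1", pos = 2e7)
  ))
  pop <- simulate_f2_population(spec, n = 5000, seed = 11)
  for (i in 2:4) {
    expect_equal(pop$genotype[i, ], pop$genotype[1, ])
  }
})

test_that("tidy and glance expose population summaries", {
  spec <- two_chrom_spec(markers_per_chrom = 4)
  pop <- simulate_f2_population(spec, n = 50, seed = 3)
  td <- tidy(pop)
  expect_equal(nrow(td), 50)
  expect_true(all(c("individual", "phenotype", "causal_genotype") %in% names(td)))
  gl <- glance(pop)
  expect_equal(gl$n, 50)
  expect_equal(gl$n_papilla + gl$n_non_papilla, 50)
  expect_equal(gl$causal_chrom, "chr5")
})

test_that("bulk construction samples within phenotype class and is seed-deterministic", {
  spec <- two_chrom_spec(markers_per_chrom = 4)
  pop <- simulate_f2_population(spec, n = 164, seed = 21)
  bulks <- make_bulks(pop, bulk_size = 30, seed = 5)
  expect_length(bulks$papilla, 30)
  expect_length(bulks$non_papilla, 30)
  expect_true(all(pop$phenotype[bulks$papilla] == "papilla"))
  expect_true(all(pop$phenotype[bulks$non_papilla] == "non_papilla"))
  expect_identical(bulks, make_bulks(pop, bulk_size = 30, seed = 5))
  # pigeonhole: cannot draw more individuals than a class holds
  n_nonpap <- sum(pop$phenotype == "non_papilla")
  expect_error(make_bulks(pop, bulk_size = n_nonpap + 1, seed = 5), "cannot form")
})

test_that("sequencing a fixed-genotype bulk hits the 0/1 index endpoints", {
  spec <- two_chrom_spec(markers_per_chrom = 6, causal = FALSE)
  m <- nrow(spec$markers)
  make_pop <- function(dose) {
    structure(
      list(
        spec = spec,
        genotype = matrix(dose, nrow = m, ncol = 10),
        phenotype = rep("papilla", 10)
      ),
      class = "f2_population"
    )
  }
  # all P2/P2, no error: every read carries the non-P1 allele -> index 1
  r2 <- sequence_bulk(make_pop(2L), 1:10, coverage = 30, error_rate = 0, seed = 1)
  expect_true(all(r2$p1_count == 0))
  expect_true(all(r2$nonp1_count == r2$depth))
  # all P1/P1 -> index 0
  r0 <- sequence_bulk(make_pop(0L), 1:10, coverage = 30, error_rate = 0, seed = 2)
  expect_true(all(r0$nonp1_count == 0))
  expect_equal(r0$p1_count, r0$depth)
  expect_error(sequence_bulk(make_pop(0L), 1:10, coverage = 0, seed = 1), "positive")
  expect_error(
    sequence_bulk(make_pop(0L), 1:10, error_rate = 0.7, seed = 1),
    "error_rate"
  )
})

test_that("papilla-bulk allele frequency at the causal marker matches the genotype-frequency oracle", {
  oracle <- expected_bulk_freqs("dominant")
  expect_equal(oracle$papilla, 1 / 3) # (0*1 + 1*2) / (2*3)
  expect_equal(oracle$non_papilla, 1)
  expect_equal(oracle$delta, 2 / 3)
  spec <- two_chrom_spec(markers_per_chrom = 5)
  freqs <- vapply(1:60, function(s) {
    pop <- simulate_f2_population(spec, n = 300, seed = 400 + s)
    bulks <- make_bulks(pop, bulk_size = 30, seed = s)
    mean(pop$genotype[spec$causal, bulks$papilla]) / 2
  }, numeric(1))
  expect_lt(abs(mean(freqs) - oracle$papilla), 0.03)
})

test_that("fixture files are byte-identical under a fixed seed and round-trip", {
  spec <- two_chrom_spec(markers_per_chrom = 30)
  pop <- simulate_f2_population(spec, n = 200, seed = 9)
  bulks <- make_bulks(pop, seed = 10)
  rp <- sequence_bulk(pop, bulks$papilla, seed = 11)
  rn <- sequence_bulk(pop, bulks$non_papilla, seed = 12)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_fixture_set(d1, spec, rp, rn, seed = 13)
  f2 <- write_fixture_set(d2, spec, rp, rn, seed = 13)
  for (nm in c("parent1", "parent2", "bulk_papilla", "bulk_non_papilla", "gff3", "fpkm")) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  }

  # parent construction: P1 hom-REF, P2 hom-ALT at every site
  p1 <- load_vcf(f1$parent1)
  p2 <- load_vcf(f1$parent2)
  expect_true(all(p1$gt == "0/0"))
  expect_true(all(p2$gt == "1/1"))
  expect_equal(nrow(p1), nrow(spec$markers))

  # GFF3 round-trips through the gene reader without warnings
  expect_no_warning(genes <- read_gff_genes(f1$gff3))
  expect_gt(nrow(genes), 0)
  expect_true(all(f1$planted_candidates %in% genes$gene_id))

  # FPKM round-trips and planted candidate genes carry the first-two pattern
  fpkm <- read_fpkm(f1$fpkm)
  cls <- classify_pattern(fpkm)
  planted <- cls[cls$gene_id %in% f1$planted_candidates, ]
  expect_true(all(planted$pattern == "high_first_two"))
})

test_that("replicated FPKM columns are averaged per stage on read", {
  fpkm <- make_fpkm_matrix(sprintf("g%02d", 1:12), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fpkm(path, fpkm, replicates = 3, seed = 6)
  back <- read_fpkm(path)
  expect_equal(names(back), c("gene_id", "S1", "S2", "S3", "S4"))
  # replicate jitter is multiplicative and small: stage means stay close
  expect_true(all(abs(back$S2 - fpkm$S2) <= pmax(0.35 * fpkm$S2, 0.02)))
})
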