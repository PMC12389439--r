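---
title: "Mapping a monogenic dominant trait by bulked-segregant sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a monogenic dominant trait by bulked-segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsapilla)
```

## The mapping problem

Husk papillae — dome-shaped specialized epidermal cells on the foxtail millet
(*Setaria italica*) husk — are associated with faster seed water uptake and
earlier germination. In F2 populations derived from crosses between a
papillate and a smooth-husk inbred, the trait segregates approximately 3:1,
the signature of a single dominant locus. `bsapilla` implements the full
desk-side analysis for mapping such a locus by bulked-segregant sequencing
(BSA-Seq / QTL-seq), together with a synthetic F2 simulator that provides a
ground truth for validating every stage.

## The delta-index statistic

Both inbred parents are sequenced along with two phenotype-extreme bulks (30
papillate and 30 non-papillate F2 individuals each). Analysis uses only
*homozygous-differential* markers: sites where the parents are homozygous for
different alleles, so every F2 allele can be assigned a parental origin.

With the papilla parent P1 as the reference parent, the **SNP-index** of a
bulk at a marker is the fraction of its reads carrying the non-P1 allele: 0
when the bulk matches P1 entirely, 1 when fully mismatched. The
**delta-index** is

$$\Delta = \mathrm{index}_{\text{non-papilla}} - \mathrm{index}_{\text{papilla}}.$$

At a marker unlinked to the trait locus both bulks are random draws from the
F2 allele pool, so both indices have expectation 1/2 and $E[\Delta] = 0$. At
the causal locus of a dominant trait, the non-papilla bulk is entirely P2/P2
($\mathrm{index} = 1$) while the papilla bulk is P1/P1 : P1/P2 = 1 : 2, giving
a non-P1 allele frequency of $(0 \cdot 1 + 1 \cdot 2)/(2 \cdot 3) = 1/3$ and
hence

$$E[\Delta_{\text{causal}}] = 1 - \tfrac{1}{3} = \tfrac{2}{3}.$$

The same computation applies unchanged to small insertion/deletion markers
(the InDel-index); the package processes the two marker classes through
identical machinery.

Candidate regions are screened at $|\Delta| \ge 0.5$, the conventional
threshold line, applied to sliding-window means rather than single markers.

## The analysis pipeline

1. **Screening** (`load_vcf()`, `screen_homozygous_differential()`): parent
   and bulk VCFs are reduced to a marker table of homozygous-differential
   sites. The "P1 allele" at a site is whichever VCF allele parent 1 is
   homozygous for — REF or ALT — so the 0/1 index convention does not depend
   on which parent resembles the genome assembly. Sites with a missing or
   heterozygous parental call, identical parental alleles, or a bulk depth
   below `min_depth` are dropped and itemized in a filter report.
2. **Index tracks** (`compute_index()`): per-bulk indices are read-count
   fractions (depth-weighted within a marker), matching the continuous 0–1
   semantics of the statistic; zero-depth markers are excluded and counted.
3. **Windowing** (`window_track()`): arithmetic mean of marker deltas in
   sliding windows. Defaults are 1 Mb windows advancing by 100 kb — common
   QTL-seq practice; both are configurable.
4. **Interval calling** (`call_intervals()`): windows with
   $|\bar\Delta| \ge$ threshold (boundary included) are merged when
   overlapping or book-ended. Windows holding fewer than `min_markers = 5`
   markers never qualify, which suppresses spurious single-marker calls.
   Selection acts on $|\bar\Delta|$, so swapping bulk labels — which negates
   every delta — leaves the called intervals unchanged.
5. **Chromosome summary** (`summarize_chromosomes()`): per-chromosome counts
   of markers with $|\Delta| \ge$ threshold plus the genome-wide argmax
   marker. Counting *markers* (not windows) is an interpretation; the
   alternative is a documented open question of the underlying study design.
6. **Co-localization** (`genes_in_intervals()`, `intersect_gene_sets()`,
   `union_gene_sets()`): interval genes from two independent F2 populations
   are intersected per marker class and the SNP- and InDel-derived common
   sets are unioned. Overlap is any-bp and strand-agnostic under 1-based
   inclusive coordinates — the most permissive standard rule.
7. **Expression filtering** (`classify_pattern()`, `select_candidates()`):
   papillae are fully differentiated by the pollination stage (S3), so
   candidate regulators should be highly expressed in the first two stages
   only. Each stage is scored high (FPKM $\ge$ `high_cut`), off
   (< `off_cut`) or low, and the 4-stage signature maps to one of seven
   exclusive pattern classes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` | 8 | reads/bulk | marker retention floor at screening |
| `window` | 1e6 | bp | sliding window width |
| `step` | 1e5 | bp | window stride |
| `threshold` | 0.5 | — | screening line on the windowed delta-index |
| `min_markers` | 5 | markers | minimum window support |
| `high_cut` | 1 | FPKM | "highly expressed" stage state |
| `off_cut` | 0.1 | FPKM | "not expressed" stage state |

`min_depth = 8` reflects standard QTL-seq filtering; the source study does
not state its depth filter. `high_cut`/`off_cut` are community-standard
FPKM conventions for expressed/silent calls; the classification is invariant
to rescaling data and cutoffs together. Threshold comparisons use $\ge$,
reading "equal to 0.5 as the threshold line" as boundary-inclusive.

A deliberate design choice in candidate selection: the filter admits
`high_second_only` alongside `high_first_two`. The study's gene-level
listings place one of its five final candidates in a "highly expressed at
the second stage" class while describing all five as first-two-stage
candidates; admitting both signatures — each high before pollination and not
high afterwards — is the only reading consistent with both statements.

## The synthetic F2 generator

`genome_spec()` + `simulate_f2_population()` + `make_bulks()` +
`sequence_bulk()` emulate the data-generating process the statistic assumes:

- **Genome and map**: nine 40 Mb chromosomes, 2,000 evenly spaced markers
  each (~15% InDel), bp→cM by a constant 3 cM/Mb. The real study provides no
  genetic map; a constant rate gives simple, adjustable linkage decay.
- **Meiosis**: gametes follow a first-order Markov chain along each
  chromosome with Haldane's map function $r = \tfrac12(1 - e^{-2d})$ — no
  interference. This is sufficient for the index expectations being tested.
- **Trait**: a single biallelic causal locus, dominant papilla allele on
  parent P1 (mirroring the papillate paternal parents of the crosses);
  phenotype is deterministic from the causal genotype. A null genome
  (no causal locus) assigns phenotypes independently at 3:1.
- **Sequencing**: per-marker depth ~ Poisson($\lambda$ = 50 by default), each
  read flipped to the wrong allele with probability $e$ = 0.001 — the
  simplest depth/error model matching the 0/1 index semantics.
- **Scale**: n = 300 F2 individuals and bulks of 30 (the bulk size of the
  real study; its two F2 populations of 164 and 182 plants are available as
  an obvious preset but the default population is larger for stable bulk
  composition).

`write_fixture_set()` serializes a simulated dataset as parent/bulk VCFs
(v4.2, GT+AD), a tiled-gene GFF3 and a stage-wise FPKM matrix with planted
expression patterns, so the entire pipeline can be exercised through its
file-format surfaces.

What the simulator does *not* emulate: alignment and variant-calling
artefacts, depth heterogeneity beyond Poisson, allele-specific bias,
segregation distortion, interference, and multi-locus or quantitative
architectures. Passing tests therefore demonstrate correctness of the
statistical machinery on data satisfying the model's assumptions, not
robustness to real sequencing pathologies.

## Numerical and degenerate-input conventions

- Indices are undefined at zero depth; such markers are excluded and counted
  rather than imputed.
- Empty windows are flagged and never thresholded; an all-zero track has no
  argmax and is reported as such.
- The causal locus snaps to the nearest marker with a message when it is not
  itself a marker position.
- The segregation $\chi^2$ is uncorrected Pearson with df = 1 — the
  convention under which the published F2 tables reproduce exactly (a Yates
  correction would give 0.659, not 0.813, for 128:36 vs 3:1).
- Determinism: every stochastic step takes an explicit seed, and fixture
  files are byte-identical under a fixed seed. In YAML configurations the
  F2 population size is `n_f2` (a bare `n` key is a YAML 1.1 boolean).

## Validation scale

The test-suite and acceptance studies use: 200 replicates on a reduced
two-chromosome map for the delta-index sampling distribution (the
distribution at a single marker does not depend on how many other markers
are simulated); 50 seeded full-scale runs (9 × 2,000 markers, n = 300) for
locus recovery; and 50 full-scale null-genome runs for false-positive
control. Interval calling and gene-interval annotation are additionally
verified against brute-force enumeration oracles on small random instances,
and bulk allele-frequency expectations against exact F2 genotype-frequency
arithmetic.

## Known limitations

- Single biallelic locus, F2 design only; no multi-locus or quantitative
  phenotype models.
- No statistical confidence envelope for the delta-index: the screening line
  is the fixed 0.5 convention, not a simulation-based band.
- No variant calling, indel normalization or genotype-likelihood handling:
  inputs are taken as called.
- Expression classification is threshold-based; a clustering-based reading
  of stage patterns could assign borderline genes differently.
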