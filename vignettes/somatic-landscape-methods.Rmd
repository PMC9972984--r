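---
title: "Methods: somatic mutation landscape analysis with somascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation landscape analysis with somascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somascape)
```

# Scope and data model

`somascape` starts where variant calling ends. Its atom is the annotated
variant call: one observed tumour (or normal) alteration per sample, with
gene, genomic region and protein consequence, Phred-scaled call quality,
read-depth evidence in tumour and matched normal, population allele
frequencies from up to three reference cohorts, known-variant identifiers
(dbSNP, COSMIC), clinical-significance labels, protein-impact predictions,
and the trinucleotide context of substitutions. Coordinates are 1-based
and fully closed (VCF convention) everywhere; there is no 0-based interop
surface, which removes a whole class of off-by-one defects. Missing
annotations are `NA` — "absent", never a sentinel number — and absence is
deliberately treated as *not* exceeding any threshold, because the filters
exist to remove variants *known* to be common, not variants lacking a
record.

Raw records are stored on the strand they were called on; pyrimidine
strand normalization happens at catalog time (`build_catalog()`), not at
read time, so input files round-trip faithfully.

# Variant prioritization

The chain applies, in a fixed documented order: call quality, population
allele frequency, functional consequence, germline subtraction, and a
novelty flag.

* **Quality**: keep calls with quality strictly above `min_quality`
  (default 30). "Above Q30" is read literally, so 30.0 is removed.
* **Population allele frequency**: a call is removed iff the *maximum*
  frequency over the configured databases, ignoring databases where it is
  absent, is strictly above `max_pop_af` (default 0.05). Whether the
  threshold should apply to the maximum across databases or to any single
  one is genuinely open; maximum-across is the more conservative removal
  rule and is configurable via `af_databases`.
* **Functional**: keep exonic/splicing calls annotated to a gene with a
  consequence other than synonymous/unclassified. Indels flow through the
  same chain as SNVs.
* **Germline subtraction**: remove tumour calls whose (chrom, pos, ref,
  alt) appears in the matched normal call set. When tumour and normal
  tables share sample identifiers (a per-patient-keyed cohort), matching
  is additionally keyed by sample, so one patient's germline variant can
  never subtract another patient's somatic call.
* **Novelty** is a flag, not a removal: a call is novel iff it is absent
  from *both* catalogs and the normal sample shows at least 10 reads with
  at most 0 variant reads at the position — a confident wild-type normal.
  Manual review of alignments, which this criterion replaces in an
  automated pipeline, is out of scope.

Because the four removal predicates read disjoint fields, the surviving
set is invariant under any stage permutation; the per-stage trace
(`FilterTrace`) records counts for the order actually run, and removals
are attributed to the first failing stage.

# Burden, hypermutation and MSI statistics

The mutation rate is `somatic_count / callable_mb`. The callable-genome
denominator is an explicit per-sample metadata field with no hidden
default constant, because published rates depend strongly on it.
Hypermutation is strictly `rate > 12` mutations/Mb, the conventional
threshold for colorectal tumours; the boundary value 12.0 is not
hypermutated.

MSI status (MSI-H / MSI-L / MSS) is input metadata from a wet-lab assay,
never inferred. Group comparisons use deliberately minimal nonparametric
machinery: a two-sided Mann–Whitney rank-sum test for MSI-H versus MSI-L
rates (exact null for small tie-free groups, normal approximation with
continuity correction otherwise) and a two-sided Fisher exact test
(point-probability method) on the 2×2 table of MSI-H membership against
hypermutation. Degenerate inputs (an empty comparison group) yield `NA`
with a warning rather than an error, so a partial cohort still summarizes.
Both tests are verified in the test suite against exhaustive enumeration
oracles for all group sizes up to 8 per side.

# Mutational signatures

Substitutions map to the canonical 96 channels: six pyrimidine-centered
substitution classes × 16 flank combinations, ordered lexicographically
(class, then 5' base, then 3' base) — the order is fixed once in
`channel_labels()` and stored in the signature-matrix fixture, preventing
silent misalignment between catalogs and references. Purine-reference
records are reverse-complemented (ref, alt and context together);
normalization is an involution fixed point on already-normalized input.

Two attribution pathways are provided, and neither is privileged:

* **Refitting** (default): non-negative least squares,
  `min ‖W e − c‖₂` s.t. `e ≥ 0`, solved by Lawson–Hanson. Exposures are
  reported raw and as proportions, with the reconstruction, residual norm
  and per-signature cosines.
* **De novo extraction**: NMF of the samples × 96 matrix by multiplicative
  updates on the Frobenius loss; 10 restarts, at most 2000 iterations per
  restart or relative objective tolerance 1e-6, each restart on its own
  seed stream derived from the user seed, best objective kept. Extracted
  signatures are column-normalized and matched to reference columns by
  best cosine, each reference assigned at most once.

The bundled reference (`reference_signatures()`) contains *synthetic*
stand-ins named Sig1/Sig6/Sig10 with the qualitative features of the
ageing (CpG C>T), mismatch-repair-deficiency (broad non-CpG C>T) and
POLE-exonuclease (TpCpT C>A) processes. They are constructions for
testing and simulation, not the real COSMIC profiles — a genuine
reference matrix can be supplied by path wherever a signature matrix is
accepted.

# Driver tests

Full covariate-based driver callers model per-gene background rates from
replication timing, expression and chromatin; reproducing that here would
pretend to a calibration the package cannot have. Instead two transparent
tests are provided and labelled as simplifications:

* `smg_binomial()`: per gene, the upper-tail binomial probability of the
  observed variant count under a uniform per-bp, per-sample background
  rate, BH-adjusted across genes. Useful within a cohort; not comparable
  across studies.
* `hotspot_driver_score()`: the fraction of a gene's variants at its
  single most-recurrent position, tested against a null scattering the
  same number of variants uniformly over the gene length. The null is
  enumerated exactly whenever the assignment space has at most 1e5
  states and otherwise estimated by seeded permutation (default 2000
  draws, with the add-one estimator). Genes with fewer than two variants
  are excluded — clustering is undefined for singletons.

# Druggability rules

The rule engine replaces a web-based clinical interpretation service with
a versioned TSV shipped in the package: gene, pattern kind (`exact_aa`,
`truncating`, `frameshift`, `any_nonsynonymous`, `position_class`),
payload, drug, predicted effect (responsive/resistant), evidence level
(FDA > NCCN > late trials > early trials > case report > pre-clinical)
and disease label (exact string, default COREAD; no ontology). A variant
may match several rules and all matches are reported, sorted by evidence
strength. The bundled rules transcribe the response/resistance statements
reported for the emulated cohort (KRAS G12D resistance to EGFR/ERBB2
monoclonal antibodies, KRAS variants responsive to MEK combinations,
PIK3CA and PI3K-pathway inhibition plus cetuximab resistance, APC
truncations and tankyrase inhibitors at pre-clinical evidence, RNF43
frameshifts and the porcupine inhibitor LGK974, BRAF V600E combination
therapy, POLE variants and immune checkpoint blockade). They are
illustrative fixtures for a reporting pipeline, not clinical guidance.

# The synthetic cohort generator

`simulate_cohort()` emulates the cohort structure the analysis assumes;
its defaults *are* the study conditions, chosen once:

* 50 samples apportioned 10%/10%/80% to MSI-H/MSI-L/MSS by largest
  remainder (so exactly 5/5/40).
* Per-sample rates log-normal around group medians 57.7/4.1/3.8
  mutations/Mb. Only medians are known for the emulated cohort, so the
  distribution family and its dispersion (sigma 0.6) are stand-ins chosen
  to reproduce a qualitatively wide rate range; both are exposed.
* One MSS sample is planted as a hypermutated outlier at 244/Mb with a
  POLE-like, Sig10-heavy mixture, mirroring the ultramutator phenotype.
* Somatic SNV channels are multinomial draws from the group's signature
  mixture over the bundled reference; half the records are emitted on the
  purine strand so catalog building must really normalize.
* Hotspots are planted in exactly their configured carrier counts
  (defaults: KRAS G12D ×6, ACVR2A K435fs ×4, TP53 R175H ×4).
* Population-common germline variants (expected 20 per sample, Poisson)
  appear with identical evidence in tumour and normal and carry allele
  frequencies drawn from (0.06, 0.5) in all three databases — safely
  above the 5% threshold, so no boundary straddling.
* A configurable fraction (default 10%) of somatic variants is
  uncatalogued with confident normal coverage, i.e. truly novel.

Genomic placement uses an abstract gene panel (name, chromosome, offset,
length) with order-of-magnitude-realistic coding lengths; there is no
reference FASTA, and contexts are emitted directly by the simulator.

Two deliberate idealizations matter for interpreting green tests. First,
every generated somatic variant passes all prioritization thresholds with
margin, and the only contaminants are the germline-common injections;
recovery precision and recall of exactly 1.0 therefore demonstrates the
bookkeeping is correct, not that the thresholds are well-calibrated for
real data — threshold boundary behaviour is pinned separately by unit
fixtures. Second, the generator has no linkage, copy number, subclonality,
indel length spectra or read-level error model, so passing tests say
nothing about caller artefacts upstream of this package's scope.

# Numerical and design choices

* All thresholds are strict inequalities, matching their verbal
  definitions ("above Q30", "more than 5%", ">12/Mb").
* Recurrence is keyed on the genomic change, not the amino-acid label:
  one genomic position can legitimately carry different amino-acid labels
  across transcript annotations.
* Novelty requires absence from *both* catalogs, and is a flag so that
  known/novel accounting never changes the survivor set.
* BH adjustment is `stats::p.adjust`; rank and Fisher tests are
  `stats::wilcox.test` / `stats::fisher.test`; NNLS is
  `pracma::lsqnonneg`. The NMF is implemented in-package (multiplicative
  updates are a few lines and the restart/seeding policy needs to be
  owned for determinism).
* Determinism contract: every stochastic entry point takes an explicit
  seed, and `run_pipeline()` bundles are byte-identical under an
  identical configuration and seed.

Problem sizes in the test suite are chosen to exercise each property at
the smallest scale where it is meaningful: the default 50-sample cohort
(~25k calls) for end-to-end recovery, 600 samples at a reduced 3-Mb
callable genome for median-rate recovery, 30 catalogs of 2000 mutations
across 5 seeds for de novo signature recovery, and 200 genes across 20
seeds for false-discovery control.

# Known limitations

* The uniform-background burden test will flag long, late-replicating
  genes in real data; it is a within-cohort screen, not a calibrated
  driver caller.
* The rules engine does no oncogenicity pre-filtering: any
  non-synonymous match to a gene-level rule is reported.
* Signature attribution at low mutation counts (tens of SNVs) is
  unstable for any method; per-sample refits should be read with the
  residual norm and reconstruction cosine in hand.
* MSI status and the callable-genome size are trusted inputs; errors in
  either propagate directly into the burden statistics.
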