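---
title: "Variant triage for small unmatched leukemia cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant triage for small unmatched leukemia cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alltriage)
```

## The problem

Small, demographically focused leukemia cohorts are usually sequenced
without matched normal tissue, so somatic and germline variants cannot be
separated by tumor/normal comparison. `alltriage` implements the pragmatic
alternative used in such studies: reduce the variant list with population
and control evidence, then rank what remains by curated mutational and
clinical evidence. The package assumes genotyped, *annotated* VCFs — a
pipe-delimited `gene|consequence|protein_change` INFO entry per alternate
allele, the compact form of VEP/SnpEff-style annotation. Annotation itself
(transcript selection, consequence calling) is upstream and out of scope;
when a record carries several transcript annotations, the first is used and
the rest ignored.

## The filter cascade

Three predicates are applied in order, each removing variants and each
audited in a `FilterTrace` (per stage: `n_in`, `n_removed`, `n_out`, with
stages chaining exactly):

1. **Coding restriction.** Keep consequences in a configurable vocabulary;
   the default covers the non-synonymous substitution classes plus
   truncating classes (missense, stop gained/lost, start lost, in-frame
   indels, frameshift, essential splice sites). Unannotated records are
   removed here and counted.
2. **Control subtraction.** A cohort variant is removed when the identical
   allele key `(chrom, pos, ref, alt)` has dosage ≥ 1 in *any* control
   sample. No control-frequency threshold is applied; one carrier
   suffices. A `match_mode = "position"` option removes on site identity
   regardless of allele, for users who read "position" literally — allele
   matching is the default because frequency databases are allelic.
3. **Population-frequency filter.** A variant is removed when its
   catalogued allele frequency in the configured population (default
   `"LAT"`, Latino/Admixed American) is **strictly greater than** the
   threshold (default 0.05). Equality survives — the cut is "more than
   5%", not "at least 5%". Variants absent from the catalogue are kept:
   absence is read as rarity, which is the point of a cascade meant to
   retain rare germline variants of possible relevance in an
   under-represented population.

Because stages 2 and 3 are independent predicates, their order is
immaterial (tested over seeded random cohorts); the cascade is monotone and
idempotent by construction, and the tests pin all three properties.

## Tier classification

Each catalogued amino-acid change carries three boolean evidence factors:
recurrence among driver-gene mutations (f1), a pathogenic ClinVar assertion
(f2), and positive selection by dN/dS (f3). The tier rules:

- **Tier 1** — f1 and f2 both set (checked first, so f1∧f2 combinations
  are never Tier 2; this precedence is the only reading under which the
  "factors 1 and 2" and "any two factors" rules are simultaneously
  satisfiable);
- **Tier 2** — any two factors otherwise;
- **Tier 3** — exactly one factor;
- **Other** — none.

The function is total over the 8 factor combinations and tested
exhaustively. A catalogue record whose label is `"other"` is treated as
Other regardless of its factors — the catalogue's own ranking is taken as
authoritative for that record.

**Tier X** extends the scale to changes without curated evidence of their
own: a query change gets Tier X when (a) it has no exact catalogue match
but its `(gene, position)` holds at least one Tier 1–3 record, or (b) its
exact match is labelled `"other"` while the position carries a Tier 1–3
record. Records ranked Other do **not** confer Tier X on a position — only
tiered locations qualify. Everything else is Unranked. Two deliberate
choices: frameshift changes parse (`"fs"` suffix) but never match exactly,
only positionally, since per-substitution evidence does not apply to them;
and a reference-residue conflict between query and catalogue at the same
position warns and degrades to a position match rather than failing, since
isoform numbering differences are a common benign cause.

Clinical-evidence levels (1–4, OncoKB style) are collapsed across the
diagnostic/prognostic/therapeutic categories; a gene's level is the
strongest (minimum) across categories, with the attaining categories
reported. Pathway membership is a plain lookup returning all memberships.

## Cohort statistics

Carrier statistics are **per individual**, not per allele: a patient
carries a variant when any mapped allele has dosage ≥ 1, and frequencies
are `100 · carriers / total` within a stratum. Samples with no surviving
variants keep all-false rows so denominators stay fixed (a cohort of nine
stays "of nine"). Position aggregation (`aggregate_position`) collapses
every change at one codon into a hotspot group (`KRAS G12X`), counting each
sample once however many changes it carries; nonsense/frameshift changes at
the codon are included. `compare_strata` reports the fold difference of two
strata's percents plus the raw 2×2 counts — no hypothesis test is attached,
because at these cohort sizes a descriptive comparison is what the data
support; the counts are exposed for external testing.

## Ancestry by classical MDS

Genetic distance is `1 − IBS` on dosages: per pair, the mean over
pairwise-complete loci of `(2 − |d_i − d_j|)/2`, giving distances in
`[0, 1]`. This is the conventional metric for genotype MDS; Euclidean
distance on column-standardised dosages is available as an option. Missing
genotypes are handled by pairwise-complete averaging, never imputation; a
pair sharing no complete locus is an error, not a guess.

Classical (Torgerson) scaling double-centres the squared distances,
`B = −½ J D² J`, and embeds with the top-k eigenvectors scaled by square
roots of eigenvalues. `k = 2` by default — assignment happens in the first
two MDS dimensions. Negative eigenvalues among the top k (possible for
non-Euclidean inputs) are truncated at zero with a warning, zeroing that
coordinate. The implementation is checked in the tests against
`stats::cmdscale` on random configurations and against known geometry
(Procrustes residual < 1e-8 on a recovered unit square).

Queries are assigned the nearest reference-population centroid in the
embedding; exact ties break to the lexicographically smallest label and are
flagged ambiguous. Nearest-centroid is deliberately simple — with the
divergence this step is meant to resolve (continental-scale frequency
differences), clusters are well separated and anything fancier adds
parameters without information. Which reference populations, and how many
samples each, are the user's choice; the synthetic panel generator ships a
two-population benchmark.

## The synthetic generator and the packaged fixture

`generate_cohort()` emulates the study design the package targets: nine
patients and seven healthy controls by default, planted clinically relevant
variants (dosage 1, named sample only), and random missense background
variants that are shared with a control with probability 0.3 and common
(catalogue frequency above the 5% threshold) with probability 0.3 — rates
chosen to exercise both removal stages heavily while leaving a meaningful
survivor set. Every draw is seeded; identical specs produce byte-identical
VCFs, and a truth table records exactly which variants must survive the
cascade (survival = coding ∧ not shared ∧ not common). The tests require
the cascade's survivor set to equal the truth table exactly.

What it does *not* emulate: linkage disequilibrium, realistic site-spectrum
or mutation-rate heterogeneity, sequencing/genotyping error, or real
genomic coordinates (each gene gets a pseudo-contig, with codon and residue
encoded in the position). Passing tests therefore demonstrate the logic of
the pipeline, not robustness to real-data noise — on real VCFs the cascade
inherits whatever upstream genotyping got wrong.

`borderland_fixture()` encodes a published nine-patient borderland ALL
cohort: the patient–variant assignments (NOTCH2 C19W in five of nine
patients; KRAS G12A, STAT5B N642H, ROS1 S1109L, WT1 C303\*, ATM E2366\*,
NOTCH2 N7S/E38K, SOCS1 L174D in their respective patients; patient 6 with
no surviving variant), Table-1-style metadata (four new-onset, five
relapse, all Hispanic), and a synthetic catalogue bundle whose factor
combinations reproduce the printed tier/level assignments. Four caveats,
also flagged in the fixture's `MANIFEST.txt`: the exact substitutions for
the DNMT3A, TET2, SUZ12 and PTEN variants are not public, so they are
encoded as placeholder changes `A999G` against a census sibling `A999V`
(classifying Tier X, as published) and excluded from exact-change checks;
the ATM stop change is reconstructed from a reported similar variant; the
per-variant factor values behind each Tier 3 call are reconstructions
consistent with the printed tier; and three decoy variants are added so the
fixture exercises all three cascade stages. The fixture path contains no
randomness.

A worked note on placeholders: an earlier design used `X1X`-style tokens,
but `X` is not a valid one-letter amino-acid code and Tier X matching needs
a parseable position, so placeholders are syntactically valid changes at a
clearly artificial position (999) instead.

## Numerical and interface choices

- Thresholds: allele-frequency cut strictly `> 0.05`; configurable in
  `(0, 1)`.
- Dosages are integers in `{0, 1, 2, NA}`; phased and unphased genotypes
  are treated identically; multi-allelic records are split on read, one
  row per alternate allele.
- Protein-change notation is the compact `<ref><pos><alt>` form with `*`
  for stop and `fs` for frameshift; full HGVS grammar is out of scope.
  Unparseable tokens warn, keep their raw string, and are excluded from
  tier matching.
- Catalogue loading is strict (schema, duplicate keys, value ranges) —
  silent acceptance of a malformed snapshot is worse than a load error.
- All report files are tab-delimited with LF endings; the run manifest
  records an FNV-1a hash of the config and of each catalogue file, so
  byte-identical reruns are checkable and checked.
- External comparison-cohort frequencies (controlled-access consortium
  data) never ship with the package: `read_target_counts()` reads a
  user-exported count table and raises a classed error when it is absent.

## Problem sizes in the tests

The test suite and acceptance script run entirely on synthetic data at
desk scale: cascade property checks over 1,000 random 12-variant cohorts,
truth-table equivalence at 300–500 background variants, and the ancestry
benchmark at 500 loci with 50+50 reference and 20 query samples — sizes at
which the binomial sampling noise is far smaller than the 0.5
allele-frequency gap being detected, so the ≥95% assignment-accuracy check
is a test of correctness rather than of luck.

## Known limitations

- Tier classification matches on amino-acid position and assumes census
  and annotation share a canonical transcript per gene; isoform mismatches
  degrade to position matches with a warning.
- Control subtraction with very few controls removes only what those
  controls happen to carry; it is not a population filter and does not
  pretend to be.
- Nearest-centroid assignment has no admixture model; an admixed sample is
  assigned its nearest single population, with only the tie flag and
  centroid distances to signal ambiguity.
- The G12X-style aggregation counts any change at the codon, including
  truncating ones; users wanting substitutions only can filter keys before
  aggregating.
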