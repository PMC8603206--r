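---
title: "Methods: variant proteome databases, peptide evidence and network drug prioritization"
author: "proteovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant proteome databases, peptide evidence and network drug prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteovar)
```

# Scope and model

`proteovar` connects three layers of tumor-cell data. Called nucleotide
variants (VCF) are expressed at the protein level by injecting them into
transcript coding sequences and translating; tandem-MS peptide evidence is
then read against both the reference and the variant-bearing isoform; and
quantitative (phospho)proteome comparisons plus a filtered protein–protein
interaction network turn the molecular observations into a ranked list of
candidate drugs. The package assumes variant calling, spectral search and
quantification have already happened upstream (GATK-class callers,
MaxQuant-class search engines); it consumes their standard outputs.

# Variant protein databases

## Extraction and translation

CDS segments are read from GFF3/GTF (`rtracklayer`), spliced in
transcription order, reverse-complemented for minus-strand models, and the
annotated phase of the first codon is trimmed. Translation
(`Biostrings::translate`) starts at base 1 and stops at — excluding — the
first stop codon; a trailing incomplete codon is dropped and any codon
containing an ambiguous base becomes `X`, which never matches a motif or a
digestion rule downstream.

All coordinates in the package are 1-based and closed, the GFF3/VCF and
IRanges convention. Interval arithmetic (variant-to-CDS overlap, span
clipping) is delegated to `IRanges`, so no manual base-offset conversion
happens anywhere; this was chosen over a 0-based internal convention
because every container the package uses is natively 1-based closed.

## Injection semantics

All variants of one sample overlapping one transcript are injected together
into a single alternate isoform — one alternate database entry per
(transcript, sample), which reflects how alternate databases stay small
relative to the reference. Phasing is not modeled. Injection rules:

* genomic alleles are complemented for minus-strand transcripts;
* variants are applied in descending transcript coordinate, so an
  insertion or deletion cannot shift the mapped position of a variant
  applied after it;
* a variant whose REF allele disagrees with the extracted CDS is skipped
  and logged (consistency guard), as are variants crossing splice
  junctions, lying outside the CDS or sitting in the phase-trimmed region;
* heterozygous variants are injected exactly like homozygous ones —
  zygosity is carried as annotation only, since injected databases are
  search spaces, not genotype models;
* overlapping variants on one transcript are rejected as an input error;
* if the combined protein equals the reference (all changes synonymous) or
  the start codon is disrupted, no alternate entry is emitted and the
  reason is logged.

## Protein-level naming

Names are produced by diffing the reference protein against the
single-variant-injected protein: substitutions give `<ref><pos><alt>`
(e.g. `F31I`), stop gains `<ref><pos>X` (e.g. `E61X`), and frameshifts
`<ref><pos><alt>fsX<k>` where `k` counts residues from the changed position
to the new stop inclusive (e.g. `V110RfsX24`). A frameshift whose first
shifted codon is itself a stop collapses to the stop-gain form — the
protein-level consequence is a truncation, and the name follows the
consequence rather than the nucleotide mechanism.

# Impact annotation

Two scoring strategies share one code path and differ only in the
configured category list:

* **phospho** (default): `sty_loss`, `sty_gain`, `motif_loss`,
  `motif_gain`, `known_phosphosite_loss`, `known_phosphosite_gain`,
  `known_melanoma_variant`, `cancer_gene` — 8 categories;
* **resistance**: `known_melanoma_variant`, `known_cancer_variant`,
  `cancer_gene`, `resistance_gene` — 4 categories.

Every firing category contributes +1 over the variant's alternate-sequence
span; the maximum per-residue sum is the isoform's score and the scaled
score divides by the category count, making runs with different category
configurations comparable. A category marks a residue at most once, so the
score is bounded by the category count even when several variants' spans
coincide on one residue — which happens when an early stop gain truncates
the alternate protein and downstream variant spans clip onto its last
residue. Scoring accrues on the alternate sequence only.
Gene-level hits (cancer gene membership) attach to the variant span like
positional hits, so a single residue can accumulate positional and
gene-level impacts.

S/T/Y loss/gain compares the counts of each phosphorylatable residue between
the reference and alternate spans, so `S→T` is a loss *and* a gain. Kinase
motifs are deterministic patterns over the 20 amino acids with `x` matching
any residue; matches are enumerated with overlaps, and only matches
overlapping the variant span count, keyed by their offset relative to the
span so substitutions compare position-for-position.

Levenshtein similarity is `1 − editDistance / max(len_ref, len_alt)`; the
max-length denominator penalizes truncations symmetrically (the convention
is not universal, so it is stated here). Isoforms under 0.90 are flagged.
Ranking is scaled score descending, ties broken by similarity ascending
(the more disrupted isoform first), then by isoform id — fully
deterministic.

# Peptide evidence

Digestion follows trypsin/P: cleavage C-terminal to every K and R with no
proline suppression, matching the common search-engine setting; up to 2
missed cleavages by default. Peptide length bounds default to 7–52 residues
to emulate typical search-engine limits; both are configurable. Matching of
observed peptides against the in-silico digest is exact string equality
(no I/L equivalence), because modern search engines report residue-resolved
sequences.

Classification: a peptide matching an alternate-isoform peptide whose span
covers a variant position is *alternate*; matching a reference peptide
covering a variant position is *reference*; a peptide that matches but
covers no variant — or covers it with an identical sequence on both sides,
the synonymous-at-peptide-level edge case — is *unspecific*; a peptide
matching neither digest is an error record excluded from coverage. Coverage
per isoform collapses to `reference_and_alternate` / `reference_only` /
`alternate_only` / `unspecific` / `none`, with variant-spanning classes
taking precedence over unspecific ones.

Phosphosites are mapped from peptide offsets to isoform coordinates;
`phospho_on_variant` is true only when a site lands exactly on a variant
residue, and it counts as localized when its localization probability is at
least 0.99.

# Quantitative statistics

Phosphosite intensities are normalized by subtracting the parent protein's
log2 intensity per sample; sites without a quantified parent are dropped
with a log. Features are complete-case only (no imputation) — entries not
quantified in all tested samples must be filtered out first, and
`filterComplete()` does exactly that.

The test statistic is the SAM-type `d = (meanA − meanB) / (SE_pooled + s0)`
with `s0 = 0.1` by default. The widely used desktop implementation of this
statistic does not publish its exact formulation, so the Tusher-style form
is adopted deliberately and documented here; `s0 = 0` recovers the
classical pooled t statistic exactly. The permutation null relabels group
assignments — exhaustively when at most 100 distinct relabelings exist
(including the identity, as in exact permutation tests), otherwise with a
seeded random sample. Per-feature p-values are exceedance fractions of
|d| under the relabelings; the FDR at a cutoff is the median permuted
exceedance count divided by the observed count, monotonized in the q-value
sense, and a feature is significant when its FDR is at or below the
threshold (0.05 proteome, 0.10 phosphoproteome by convention). Results are
bit-for-bit reproducible given the seed. Features with `d = 0` are never
called.

Overrepresentation uses the one-sided hypergeometric tail per category
against the background of identified entries, BH adjustment, and the
enrichment factor `(k/n)/(K/N)`. SILAC screening averages log2 ratios over
at least three replicates and calls entries with `|mean log2| ≥ 1`
(twofold).

# Network and drugs

Interaction records pass four filters: both organisms human, at least two
experimental evidences (distinct publication/method combinations when raw
interaction rows are aggregated), no self-loops, and — after deduplication
of parallel edges on the undirected simple graph — no degree-0 nodes. The
seeded mode keeps edges strictly between seed entries (significantly
changing (phospho)proteins plus driver-mutation genes); the focus mode
keeps the subgraph induced on a focus protein and its direct interactors,
for single-protein interactome views. Metrics (degree; unnormalized
betweenness, Brandes convention with endpoints excluded) are computed on
the full filtered graph, and top-N truncation happens afterwards — the
order of those two steps is a genuinely open choice, and computing metrics
first keeps them independent of the display cutoff.

Drug prioritization keeps human-acting drugs regardless of category or
approval status. Specificity is defined as the fraction of the drug's
*total reported* targets that are in the network — a drug hitting only
network members is maximally specific — and the priority score sums the
network degree of the in-network targets, favoring drugs aimed at hubs.
Ties break by specificity, then name, so the ranking is a deterministic
function of its inputs.

# Synthetic data: what it does and does not emulate

The generators produce structurally faithful inputs: multi-exon and
minus-strand transcript models whose CDS start with ATG and end with a stop
codon; substitutions constructed codon-wise so a requested fraction
gains/loses S/T/Y; frameshift insertions and deletions placed on dedicated
plus-strand transcripts carrying no other variant, so every variant's
protein consequence is independently predictable (VCF anchor conventions
make minus-strand indel truth bookkeeping error-prone, and nothing in the
indel code path is strand-specific beyond what substitutions already
exercise); MS evidence sampled from the true digests with known labels;
Gaussian log2 matrices with a 5% spike-in at 4 noise SDs in 3-vs-3 design;
interaction tables with known filter outcomes; drug tables with known
in-network target mixes.

They do **not** emulate: realistic MS noise, intensity-dependent missing
values, chromatography or localization ambiguity; mutational signatures;
scale (the defaults run the whole pipeline in seconds on one CPU — fixture
sizes used by the tests and the acceptance script are 10–100 transcripts,
up to 1000 variants, 1000 quantitative features). Passing tests therefore
demonstrate algorithmic correctness against construction-time truth and
independent oracles, not performance on organism-scale data.

The default quantitative noise SD is 0.3 on the log2 scale, a realistic
replicate scatter for label-free protein quantification, and the spike
effect is expressed in units of that SD.

# Known limitations

* With n = 3 per group, per-feature variance estimates carry only 4
  degrees of freedom. Under the default design (1000 features, 5% spiked at
  4 noise SDs, s0 = 0.1, FDR ≤ 0.05) the acceptance script's
  `spike_in_recovery_pct` settles near 73–74%: the null |d| tail of the
  ~950 unshifted features overlaps the weakest spiked features, and even an
  oracle thresholding |d| at a true false-discovery proportion of 0.05
  cannot recover much more. This is a property of small-n moderated
  testing, not of the estimator — the permutation FDR tracks the oracle
  closely — and it is reported honestly rather than hidden behind a larger
  effect size or a quieter generator.
* Variant phasing and overlapping variants are not modeled; multi-variant
  isoforms assume independence.
* Selenocysteine, non-standard codon tables and annotation liftover are out
  of scope; ambiguous bases translate to `X`.
* Kinase motifs are deterministic patterns; no probabilistic
  kinase–substrate scoring.
* The network is undirected and unweighted, as the upstream interaction
  resources provide no direction; betweenness is used for relative ordering
  only.
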