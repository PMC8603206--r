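# proteovar

Proteogenomics toolkit for studying how nonsynonymous nucleotide variants
reshape a cancer cell's proteome and phosphoproteome, and for turning that
information into drug hypotheses. It reimplements, as a reusable R package,
a workflow developed around BRAF-inhibitor resistance in melanoma cells:

1. **Variant protein databases** — transcript coding sequences are extracted
   from a genome + GFF3 annotation, VCF variants are injected (strand-aware,
   applied in descending transcript coordinate), and both reference and
   sample-specific alternate isoforms are translated from the start codon to
   the first stop and written as FASTA, with protein-level variant names in
   the field's nomenclature (`F31I`, `E61X`, `V110RfsX24`).
2. **Impact annotation** — each alternate isoform is scored for loss/gain of
   phosphorylatable S/T/Y residues, loss/gain of kinase motifs (wildcard
   `x`), overlap with known phosphosites, known melanoma/cancer variant
   sites and cancer gene lists, and for Levenshtein similarity to its
   reference (isoforms under 0.90 are flagged as heavily disrupted). Every
   overlapping impact adds +1 to the affected residues; the maximum summed
   score, its scaled form `max_score / n_categories` in [0, 1], and a
   deterministic ranking prioritize isoforms for follow-up.
3. **Peptide evidence** — reference and alternate isoforms are digested in
   silico (trypsin/P, up to two missed cleavages) and observed MS peptides
   are classified as *reference*, *alternate* or *unspecific* variant
   peptides, with per-isoform coverage summaries and flags for
   phosphorylation sitting directly on a variant residue (localized when
   the localization probability is at least 0.99).
4. **Quantitative statistics** — phosphosite intensities are normalized by
   parent protein intensities; group differences are tested with a
   SAM-type moderated statistic `d = Δmean / (SE + s0)` (default s0 = 0.1)
   and a permutation-based FDR (exhaustive relabelings when few, seeded
   random otherwise; FDR ≤ 0.05 for proteome-style and ≤ 0.10 for
   phosphoproteome-style data); Fisher exact overrepresentation with BH
   adjustment and enrichment factors; SILAC ratios averaged over three
   replicates against a twofold cutoff.
5. **Signaling network and drugs** — interaction records are filtered to
   human–human pairs with at least two experimental evidences, self-loops
   and orphan nodes are removed, and the undirected simple graph is built
   either strictly between seed entries (significant (phospho)proteins plus
   driver-mutation genes) or around a focus protein. Nodes carry degree and
   unnormalized betweenness; drugs are kept when human-acting with at least
   one in-network target, scored by specificity (in-network fraction of all
   reported targets) and prioritized by the summed degree of their targets.

A seeded fixtures module generates toy genomes, annotations, VCFs, MS
evidence, quantitative matrices, interaction and drug tables — each with a
construction-time truth table — so the entire pipeline is testable offline.

## Worked example

```r
library(proteovar)
spec <- fixtureSpec(nTranscripts = 10L, nSubstitutions = 15L, nInsertions = 2L,
                    nDeletions = 2L, nObservedPeptides = 40L,
                    nFeatures = 300L, nNodes = 20L, nDrugs = 6L)
res <- runPipeline(seed = 42, spec = spec)
res$db
head(res$impact[, c("isoform", "variant_names", "similarity",
                    "max_score", "scaled_score", "rank")], 5)
table(res$classified$class)
res$network
head(res$drugRanking, 3)
```

```
VariantDB
  reference proteins : 10
  alternate [S1]     : 10
  skipped variants   : 0

  isoform  variant_names similarity max_score scaled_score rank
1  t08|S1 T27S;H28Q;Q31P  0.9387755         5        0.625    1
2  t01|S1 Q22R;V43L;S47T  0.9482759         5        0.625    2
3  t02|S1 C31S;R40Q;F96S  0.9747899         3        0.375    3
4  t07|S1       M48AfsX5  0.6447368         2        0.250    4
5  t03|S1      P31RfsX12  0.7317073         2        0.250    5

 alternate  reference unspecific
        13         12         15

SignalingNetwork (seeded): 15 nodes, 15 edges
  top degree: N08, N02, N11, N05, N06

    drug n_targets in_network_targets specificity priority_score
1 drug05         3                N08   0.3333333              6
2 drug02         1                N11   1.0000000              3
3 drug04         1                N16   1.0000000              2
```

Reading it: 10 transcripts each acquired one alternate isoform; the top
isoform `t08|S1` carries three substitutions whose impacts stack to a
summed score of 5 out of 8 configured categories (scaled 0.625), the
frameshift isoforms (`M48AfsX5`) are flagged by similarity well below 0.90;
of the 40 observed peptides, 13 carry the alternate residue across a variant
position, 12 the reference residue, 15 span no variant; the filtered
interaction network retains 15 of 20 candidate proteins, and `drug05` wins
the ranking because its single in-network target is the hub `N08`
(degree 6), although drugs with full target specificity follow right after.

A shell entry point with the same stages is installed at
`system.file("scripts", "proteovar", package = "proteovar")` — subcommands
`build-db`, `annotate`, `classify`, `network`, `stats`, `fixtures`.

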