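---
title: "Methods: synthetic-community analysis of crAss-like phages"
author: "crasskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-community analysis of crAss-like phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crasskit reimplements a complete crAss-like phage (Crassvirales) analysis
for gut metagenomes — detection, dereplication, taxonomy, genome features,
host linkage, quantification and group association — driven by a synthetic
community generator that plants every piece of ground truth. This vignette
is the package's methodological account: the models and rules each stage
applies, the parameters that matter, the design choices made where the
design was genuinely open, and what passing the test suite does and does
not demonstrate about real data.

## The synthetic community

`community_spec()` fixes the study conditions; `simulate_community()`
realizes them under a single integer seed (all stage generators derive
their seeds from it by fixed offsets, so the fixture is byte-reproducible).
The defaults are the package's standard conditions:

* **20 phage genomes of 70–110 kb** (zeta-family genomes drawn 1.5× longer,
  echoing the much larger replication apparatus of that clade), each a
  random intergenic background carrying the five marker genes in the
  canonical order IHF_54 … MCP … portal … TerL … primase, separated by
  family-specific numbers of filler genes. Marker proteins are drawn from
  synthetic family-level consensi (shipped under `inst/extdata/`, generated
  by `inst/tools/make_extdata.R`; they are random seeded sequences, not
  copies of any database) at 5% amino-acid divergence; the family consensi
  themselves sit ≈30% apart, comfortably above the ≈25% inter-family
  divergence at which MRCA classification is identifiable.
* **Family and code mixes** patterned on the composition reported for pig
  gut crAss-like phages: families alpha 0.26 / beta 0.44 / delta 0.21 /
  zeta 0.09; genetic codes 11 0.70 / 15 0.25 / 4 0.05, with alpha-family
  genomes always standard-code.
* **Recoding model.** A genome assigned code 15 (TAG = Gln) or 4
  (TGA = Trp) recodes a fraction of its genes (default 20% for code 15);
  within a recoded gene every site of the recoded amino acid uses the stop
  codon with probability 0.8 — stop-codon capture is a genome-wide,
  tRNA-mediated property, so the stop codon behaves as the dominant codon
  for its amino acid rather than appearing a fixed number of times.
  Because tryptophan is ~3× rarer than glutamine, the code-4 per-gene
  fraction is scaled 3× so both alternative codes plant a comparable
  recoded-codon density. Every gene starts with ATG and ends with TAA —
  the one stop codon shared by all three candidate codes — and each
  intergenic spacer carries in-frame stop guards at both ends, so gene
  calling under the true code reproduces the planted coordinates and code
  inference rests on the planted recoded stops rather than on terminal
  read-through noise. Alternative-code genomes also receive a suppressor
  tRNA cassette (anticodon CTA for code 15, TCA for code 4) built from the
  packaged template.
* **30 bacterial genomes (30 kb)** with 1–2 CRISPR arrays each: identical
  28–32 bp repeats alternating with 30–35 bp spacers. Half the phages
  receive planted spacer links (exact or one-mismatch copies of phage
  subsequences, either strand); some arrays carry two-mismatch decoys that
  must never be recovered. Spacer boundary bases are kept non-unanimous
  across copies (adjusted only on unlinked random spacers) so array
  boundaries are locally unambiguous and extraction is exact.
* **16 read samples (8 fat / 8 lean), 50,000 × 150 bp reads** at 0.5%
  substitution error (substitution-only: the 90%-identity mapping gate is
  exercised by substitutions alone, and the internal mapper can stay
  gapless and exact). Baseline relative abundances are log-normal
  (sdlog 0.75) with per-sample jitter (sdlog 0.25); the three planted
  fat-vs-lean effects (log2FC +2, +2, −2) are attached to mid-ranked
  phages — abundant enough to clear the coverage gate in most samples, yet
  holding a small share of total mass, so the planted fold-changes do not
  compositionally distort the total-sum-scaled abundances of the
  unaffected community.

What the generator does **not** emulate: real crAssphage sequence
composition and GC skew, indel divergence, sequencing error profiles,
strain mixtures, and partial/fragmented assemblies. Passing the suite
therefore demonstrates that the decision rules, statistics and recovery
logic are implemented correctly at realistic scale — not that the
thresholds themselves are optimal for any particular real dataset.

## Detection

Contigs are first filtered by the four-criterion retention rule on the
virus-predictor score table (score ≥ 0.9; or score ≥ 0.9 with p < 0.01;
or both scores > 0.7 with p < 0.05; or a positive binary prediction), with
missing values failing the criteria that need them, and the printed
boundary semantics (≥ vs >) implemented literally.

Two identification routes follow. The *signature route* calls genes under
the standard code and Smith–Waterman-aligns two signature proteins (a
terminase and a polymerase) against every predicted protein (BLOSUM62,
affine gaps 11/1, ungapped Karlin–Altschul E-values with λ = 0.267,
K = 0.041 and search space |q|·|t| — the 1e-5 decision threshold dominates,
not the exact statistic); a genome passes with ≥1 hit at E < 1e-5 over
≥350 aligned residues *and* length > 70 kb (alignment length is counted
in residues; a nucleotide reading of the same figure is configurable). The *structural route*
six-frame-translates the genome with stops rewritten to X, splits on X
runs into peptides ≥50 aa, and searches each against the TerL/portal/MCP
profiles, so genomes using alternative codes are still found via the
fragments between recoded stops. The final call is the union of the two
routes by default ("combined" read disjunctively); an intersection mode is
available.

**Profile scoring and calibration.** Profiles are log2-odds matrices over
the Robinson–Robinson background built from the shipped seed alignments;
search is gapless (best contiguous window, local in both the peptide and
the profile) — adequate because the generator's divergence model is
substitution-only, and cross-checked against a brute-force window oracle.
The hit threshold is calibrated once per profile from 10,000 seeded
composition-shuffled proteins: a Gumbel tail is fitted to the null
best-score distribution and the 99.9th percentile is extrapolated to the
residue search space of a whole-genome six-frame scan (2×10⁵ residues).
The extrapolation matters: a genome performs thousands of peptide
searches, so a per-protein percentile alone would admit roughly one false
marker hit per 10–20 marker-free genomes, while the scaled threshold keeps
whole decoy genomes clean without touching sensitivity (planted markers
score 400–2300 bits against thresholds near 35).

## Dereplication and taxonomy

Nucleotide alignment between genomes is k-mer anchored and chained
(minimap2, `-c --eqx`, asm20), with chains split at indels ≥50 bp into
blocks; ANI is the column-weighted mean identity over blocks and the
aligned fraction is the merged block span over the **shorter** genome
(the MIUViG-style dereplication convention; a query-based mode is a flag).
Greedy clustering scans genomes longest-first: a genome joins the first
centroid with ANI ≥ 95% and AF ≥ 85%, else founds a new vOTU; the longest
member represents the cluster. The scan order is canonical (length, then
id), so the partition is order-invariant; 2%-divergent mutants co-cluster
with their parents while 10%-divergent genomes never do.

TerL proteins of the representatives are aligned together with the labeled
reference set by a compact progressive aligner (UPGMA guide tree on 3-mer
distances; profile–profile global alignment with expected BLOSUM62 column
scores and a linear gap penalty of 8 — enough to reproduce the
two-sequence Needleman–Wunsch optimum on the small cases the tests pin).
p-distances with pairwise gap deletion feed canonical neighbor joining
(negative branches clamped to zero with the deficit moved to the sibling,
preserving paths through the parent); the tree is midpoint-rooted. NJ
replaces a maximum-likelihood search deliberately: the classification rule
being exercised is MRCA propagation, and NJ recovers additive distances
exactly, which the test suite uses as the module's oracle. Trees may also
be supplied pre-built in Newick.

**MRCA propagation** assigns to every leaf descending from the MRCA of a
family's reference leaves that family's label; leaves under several
labeled MRCAs take the smallest (fewest-leaf) enclosing clade — the
references in this design are disjoint, so the rule only matters for
constructed overlaps — and leaves under none are `unclassified` and are
removed from family-level analyses after assignment (removal follows, not
precedes, MRCA computation). Bootstrap support is available as a seeded
column-resampling option but is not part of the pipeline.

## Genome features

Genetic-code inference calls ORFs (≥60 aa) under codes 11, 4 and 15 and
compares coding densities (union of ORF spans over genome length); the
standard code is kept unless an alternative exceeds it by δ = 0.05 — the
margin guards against the structural advantage alternative codes enjoy
(their stop sets are subsets of code 11's, so their ORF unions are always
at least as large). Suppressor tRNAs are found by ≥90%-identity template
matching on both strands with the anticodon read at the template's fixed
offset; only CTA (reads through TAG) and TCA (TGA) are reported.

Marker annotation labels each called gene with its best profile hit at the
calibrated threshold. For gene *counting* between markers the pipeline
first reduces the overlapping ORF calls to a non-overlapping tiling
(weighted-interval dynamic programming maximizing total coding bases, the
deterministic stand-in for a coding-statistics gene caller); counting then
uses gene midpoints strictly between the marker midpoints, taking the
shorter arc on circular genomes, `NA` when a flanking marker is absent,
and the highest-scoring copy (with a warning) when a marker is duplicated.
Family contrasts of the three blocks use the two-sided Wilcoxon rank-sum
test — exact by full enumeration when n+m ≤ 10 (which also handles ties),
normal approximation with tie and continuity corrections otherwise.

Anti-CRISPR candidates are retained only when both external predictors
agree and the protein is ≤200 aa; CAZyme prevalence is the percentage of
genomes per family carrying ≥1 gene of each type, with absent types kept
as zero rows. Both consume predictor output tables; no predictor is
reimplemented.

## Host linkage

CRISPR arrays are detected CRT-style: exact 16-mer seeds recurring ≥3
times at spacings compatible with repeat (23–47 bp) and spacer (17–50 bp)
bounds; repeat boundaries extend while all copies stay within one interior
mismatch of the first copy and are trimmed back to unanimous columns;
overlapping candidates resolve to the higher repeat count. Spacer-to-phage
matching is an exhaustive Hamming scan on both strands over the full
spacer length with ≤1 mismatch — a whole-spacer mismatch cap is a Hamming
condition, so the exhaustive scan is exact and replaces a heuristic
short-read BLAST. Hits aggregate to (vOTU × bacterial genome), taxonomy is
joined (missing lineages become `unknown` with a warning), and per-vOTU
genus breadth separates single-genus from multi-genus (≥2) phages.

## Quantification and association

The internal read mapper is gapless seed-and-extend (21-mer seeds every
12 bp, both orientations, best placement by matching bases with canonical
tie-breaking); externally produced PAF alignments can be imported instead.
Mappings with identity < 90% or aligned-percent < 95% are dropped. RPKM is
count × 10⁹ / (genome length × total reads). The two printed coverage
clauses are implemented literally and independently: abundance is zeroed
when the covered fraction is **below** 75%, and a vOTU is detected only
**above** 75% — a genome at exactly 75% keeps its abundance but is not
detected; both boundaries are unit-tested. Prevalence is the percentage of
samples with detection; a vOTU is detected in a population if detected in
any of its samples; a family is present in a sample if any member vOTU is
detected there.

Association is a compact MaAsLin-style model: total-sum scaling per
sample, y = log2(x + pseudo) with pseudo = half the smallest nonzero
scaled abundance, a per-vOTU linear model on the group factor, BH
adjustment across tested vOTUs (q < 0.05 by default; the upstream tool's
own 0.25 default is selectable), and the signed significance score
−log10(qval)·sign(coeff), with base 10 as the convention.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally and 1-based in written
tables. N bases translate to X and never act as stops or starts. All
alignment kernels break ties deterministically (first maximum in scan
order; diagonal preferred in traceback), so every result is reproducible
bit-for-bit. Identical samples give a rank-sum p of 1; constant vOTUs get
p = 1 in association; empty alignment sets quantify to all-zero matrices;
a tree whose branch lengths are all zero midpoint-roots at the first leaf
with a warning.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default 20-phage / 30-bacterium / 16-sample community (≈2 Mb of phage
sequence, 800,000 reads), oracle-equivalence sweeps on 500 random small
instances per kernel (≤60-residue alignments, ≤40-column profiles),
clustering trials on 70–80 kb genome triples, and 300 reduced gene-dense
genomes (25 genes each) for the genetic-code confusion matrix — sizes
chosen so a complete run takes a few minutes on one core while leaving
every decision rule exercised at the scale its thresholds assume.

## Known limitations

The gapless mapper and PSSM search assume substitution-only divergence;
real indel-rich data should come in through the PAF import route and
pre-aligned profiles. The progressive aligner is adequate for single-gene
marker sets, not genome-scale MSAs. E-values use ungapped Karlin–Altschul
constants with gapped alignments, so they are decision gates rather than
calibrated significance estimates. CRISPR detection requires near-identical
repeat copies (≤1 interior mismatch) and does not merge arrays across
gaps. The association model fits a single group factor without covariates
or random effects, and compositional alternatives (CLR) are out of scope.
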