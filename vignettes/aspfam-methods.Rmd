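---
title: "Methods: rule-based characterization of plant aspartic-protease families"
author: "aspfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based characterization of plant aspartic-protease families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspfam)
```

# Scope and model

Plant aspartic proteases (APs) are pepsin-like endopeptidases whose
catalytic machinery consists of two aspartate residues, each sitting in a
conserved Asp-Thr/Ser-Gly (`D[TS]G`) triplet. Genome-wide surveys of this
family conventionally proceed through a fixed series of steps: candidate
filtering for complete open reading frames and a complete catalytic
domain; categorization into typical APs (category A, carrying the
~100-residue saposin-like plant-specific insert, PSI), nucellin-like APs
(category B, marked by the cysteine-containing blocks `QCDYE` and
`GCGYDQ`) and atypical APs (category C, everything else); a
neighbor-joining (NJ) phylogeny with bootstrap support; exon/intron
statistics; tandem and segmental duplication analysis with Ka/Ks
estimation and molecular-clock dating; degenerate-motif scanning of
promoters for secondary-cell-wall (SCW) cis-elements; N-glycosylation
sequon analysis; and expression-matrix filtering and clustering.

`aspfam` implements that pipeline as composable, individually tested
functions, plus a synthetic-genome generator that plants every feature
the pipeline is supposed to recover. The package takes a genome FASTA and
a GFF3 annotation (or in-memory equivalents); all coordinates are held
0-based half-open internally and converted at the GFF3/TSV boundary.

# Family identification rules

Profile-HMM scoring of the pepsin domain is out of scope here; the
package instead uses an explicit, tunable sequence rule:

* **Perfect ORF** (`checkOrf`): starts with ATG, ends with a stop, no
  internal stop, length divisible by 3.
* **Domain completeness** (`domainComplete`): at least two `D[TS]G` hits
  whose Asp-to-Asp spacing falls in `[minGap, maxGap]`, defaults 100-350
  residues. The generous upper bound deliberately accommodates the PSI,
  which sits between the two catalytic motifs in category-A proteins and
  inflates their spacing. The first qualifying pair (leftmost first Asp,
  then leftmost partner) is recorded and anchors downstream rules.
* **PSI heuristic** (`hasPsiInsert`): at least 6 cysteines within some
  120-residue window strictly between the chosen catalytic Asp pair. Six
  is the number of conserved cysteines of the saposin-like fold; 120
  gives the ~100-residue insert room to drift. Both are arguments.
* **Nucellin motifs**: `QCDYE` and `GCGYDQ`, each tolerating one
  substitution by default — the blocks are highly conserved but not
  invariant, and a hard exact-match rule would be brittle against single
  substitutions.
* **Category assignment** (`classifyCategory`): PSI present gives A;
  otherwise both nucellin motifs give B; otherwise C. A proteins that
  also carry the nucellin motifs stay A and are flagged as conflicts.
  The assignment is deterministic and total on domain-complete proteins.

Molecular weights use average residue masses plus one water (18.0153
Da), the convention of the standard pI/MW web tools. Subcellular
localization is not predicted; the package only aggregates externally
produced labels by strict majority (`majorityVoteLocalization`), with
ties reported as ambiguous.

# Phylogeny

`proteinDistance` computes pairwise-deletion p-distances with an
optional Poisson correction, `d = -ln(1 - p)`. Poisson-corrected
distances are the default, the common default for protein NJ in the
established desktop tools; the reference analyses this package emulates
state only "default parameters". NJ agglomeration is delegated to
`ape::nj` — the standard Saitou-Nei algorithm — behind the `njTree`
surface; on additive matrices the tree's path metric reproduces the
input to machine precision (this is asserted in the test suite over
random 4-12 taxon additive matrices). Negative branch-length estimates,
a known NJ artifact, are clamped to zero with a warning and recorded in
the tree's `clamped` attribute.

Bootstrap support (`bootstrapSupport`) resamples alignment columns with
replacement, rebuilds each replicate tree, and reports the percentage of
replicates containing each internal bipartition of the full-data tree.
The reference scale is 1000 replicates; examples and the pipeline
default use fewer to keep interactive runs quick — the support
definition is identical at any scale. When a bootstrap replicate drives
a Poisson distance to saturation (p >= 1), that pair's distance is
capped at 1.1x the largest finite distance in the replicate rather than
aborting, so every replicate yields a tree; this only affects extremely
diverged pairs.

The built-in progressive aligner (`progressiveAlign`: k-mer guide
distances, average-linkage guide order, profile-profile global alignment
with BLOSUM62 column scores and a linear gap cost) is a deliberately
simple fallback so the pipeline runs self-contained. It is approximate;
for real-data phylogenies an externally computed multiple alignment is
the recommended input.

# Duplication, Ka/Ks and dating

Tandem duplication uses the conventional rule: family genes on one
chromosome whose nearest gene boundaries lie within 50 kb are chained by
single linkage (`findTandem`). Because the input set is already the
family, no additional similarity threshold is applied. Segmental pairs
(`assignSegmental`) are gene pairs overlapping (>= 1 bp) the two sides
of the same externally supplied duplication block; block derivation
itself is out of scope.

Ka/Ks uses the Nei-Gojobori (1986) counting method with Jukes-Cantor
correction, the classical estimator for such family surveys, written
from first principles in `ng86`:

* synonymous-site fractions are computed per codon over its single
  nucleotide neighbors, **excluding changes to stop codons from both
  numerator and denominator**, so each codon position contributes
  exactly one site and `S + N = 3 x` compared codons holds exactly;
* sites are averaged over the two sequences;
* multi-nucleotide codon differences are resolved by averaging the
  synonymous/nonsynonymous step counts over all minimal mutational
  pathways that avoid stop codons; in the degenerate case where every
  pathway passes through a stop, all pathways are averaged instead of
  returning nothing;
* `Ks = -(3/4) ln(1 - (4/3) ps)` and likewise Ka; estimates with
  `ps` or `pn >= 3/4` are flagged saturated and reported as NA rather
  than extrapolated.

The test suite checks `ng86` against an independent brute-force oracle
(explicit neighbor enumeration and recursive pathway walking with a
different translation backend) to `1e-12` on random codon pairs, and the
synthetic generator validates parameter recovery: synonymous-only
divergence at a known substitution count is recovered exactly as `sd`
and within three binomial standard errors as Ks.

Duplication ages use the molecular clock `T = Ks / (2 lambda)` with the
*Populus* rate `lambda = 9.1e-9` synonymous substitutions per site per
year as the default; the rate is an argument everywhere it appears.
Ka/Ks ratios below 1 are labeled purifying, above 1 positive, exactly 1
neutral, and saturated or zero-Ks cases undefined.

# Promoter cis-element scanning

Promoters are the `lengthBp` (default 3000) bases upstream of the
transcription start — the 5'-most transcript coordinate on the plus
strand, the 3'-most on the minus strand — reported 5' to 3' on the
gene's coding strand. Genes without an annotated 5'-UTR anchor at the
CDS start and carry a flag; windows truncated by a chromosome edge are
flagged too.

The built-in catalog holds the ten SCW-related IUPAC consensus elements
(SNBE `WNNYBTNNNNNNNAMGNHW`, TERE `CTTNAAAGCNA`, M46RE `RKTWGGTR`, ACI
`ACCTACC`, ACII `ACCAACC`, ACIII `ACCTAAC`, SMRE1 `ACCAAAT`, SMRE2
`ACCAACT`, SMRE3 `ACCAAAC`, SMRE5 `ACCTAAT`) and can be replaced from a
two-column TSV. The scanner expands each consensus into per-position
base sets and reports **every** occurrence at every offset, overlaps
included; minus-strand hits are matches of the reverse-complemented
consensus reported at their 5'-most promoter coordinate. Three
deliberate semantic choices:

* both strands are scanned by default (several of these elements act
  orientation-independently); a plus-only mode exists to probe how
  presence calls depend on strand handling;
* an `N` in the subject sequence never matches any consensus code,
  including consensus `N` — masked sequence cannot produce hits;
* presence/absence per promoter is derived from the full hit list
  (`presenceMatrix`), so reporting overlaps costs nothing downstream.

The scanner is validated against a regex-expansion oracle (explicit
character-class alternation with lookahead) for exact hit-set equality
on random 3-kb sequences, and on synthetic promoters every planted
instance must be recovered at its exact position and strand.

# Glycosylation

N-glycosylation uses the canonical sequon rule N-X-S/T with X != P
(`scanNSequons`), overlaps included. This replaces neural-network
acceptor-site scoring, so sequon counts upper-bound predictor "YES"
calls; per-protein counts are therefore not comparable to
predictor-based published counts and are not treated as such anywhere.
For nucellin-like proteins, `conservedSequonNearAnchor` asks whether a
sequon lies within 60 residues upstream of the `GCGYDQ` block — an
operational stand-in for the published anchor "between the invariant
Tyr75 (pepsin numbering) and GCGYDQ", since pepsin-reference numbering
requires a structural alignment this package does not do. The window is
an argument and the approximation is flagged in the output status
vocabulary (`conserved` / `absent` / `anchor-missing` /
`not-applicable`).

# Expression

Expression matrices are genes x tissues, non-negative, with NA allowed
and excluded from statistics. The xylem selection rule is strict:
`value > 1000` (printed threshold; a gene exactly at 1000 is excluded),
then closed under duplication-pair partnership so that the duplicate of
a passing gene is carried along; the closure is idempotent. Heat-map
clustering transforms values as `log2(x + 1)` — the offset handles
zeros, which a bare log cannot — and clusters rows by average-linkage
agglomeration on Euclidean distances, the common default of heat-map
tools. Relative qPCR expression is `2^-(Ct_target - Ct_ref)`, and the
two-sample comparison is a two-sided pooled-variance t-test with the
usual star convention (p < 0.05 `*`, p < 0.01 `**`). Zero variance in
both groups with equal means is defined as p = 1.

# The synthetic study

`simulateFamilyGenome` generates the default study conditions used by
the tests and the acceptance script: a 2-chromosome assembly (450 kb
each) carrying 12 family genes in a 2/2/8 A/B/C mix; one tandem cluster
of 3 genes at 30-kb gaps against a 60-kb background spacing; two
segmental source/copy pairs diverged by exactly 12/3 and 25/6
synonymous/nonsynonymous substitutions inside emitted duplication
blocks; one to four exons per gene with a quarter of genes lacking a
5'-UTR; two planted cis-element instances per 3-kb promoter (one per
strand, drawn uniformly from the consensus expansion over a uniform
A/C/G/T background); and a 6-tissue expression matrix whose planted
xylem-specific genes sit at archetype 1500 against sub-500 background
with Gaussian noise of sd 50 (truncated at zero) — more than ten
standard deviations of margin around the 1000 threshold, so recovery
failures indicate bugs, not noise. All randomness flows from a single
seed and the outputs are byte-identical across runs.

Design choices worth stating: background protein sequence excludes
cysteine and aspartate so that catalytic motifs, PSI cysteine counts and
nucellin motifs occur only where planted (this makes category recovery
an exact, not statistical, test); copies protect the designed motif
region and the start codon from mutation so a planted category cannot be
destroyed by the divergence process; and the background base
composition is uniform, which sets the false-positive rate of the
degenerate elements — extra scanner hits on background are allowed in
recovery tests only when the independent oracle fires too.

What the generator does **not** emulate: indels, rate heterogeneity,
codon-usage bias, repetitive DNA, alternative isoforms, or annotation
noise. Passing the synthetic recovery tests therefore demonstrates
correctness of the implemented rules, not robustness to the messiness of
real annotations; the real-data path exists (`readGenome`,
`readGeneModels` accept any FASTA/GFF3 pair) but its published candidate
counts depend on external BLAST/profile tooling that is out of scope.

# Numerical and degenerate-input choices

* Coordinates: 0-based half-open internally; GFF3 and block TSVs are
  1-based inclusive on disk and converted at the boundary.
* Ambiguity characters other than N in genome input: rejected by
  default, optionally masked to N (`ambiguity = "mask"`).
* Primary transcript: the mRNA whose ID ends `.1`, else the longest
  CDS — the convention of the major plant genome portals; the choice is
  recorded per gene in `primaryRule`.
* NJ ties and negative branches: deterministic agglomeration order from
  the NJ implementation; negatives clamped to zero with a warning.
* Empty inputs: structure summaries of zero genes, promoters with zero
  hits and presence matrices with all-zero rows are all well-defined and
  exercised in tests.
* Problem sizes in the validation suite (1000 random 3-kb promoters for
  the scanner oracle, 200 random 30-codon pairs for the Ka/Ks oracle,
  200 additive matrices for NJ, 100 seeded pairs for Ks recovery) were
  chosen to exercise each estimator across its input space at desk
  scale.

# Known limitations

* Category assignment rests on sequence rules alone; the published
  practice also consults the phylogenetic tree, and where a
  user-supplied tree disagrees both labels should be reported — the
  package does not arbitrate.
* The NG86 estimator is the only Ka/Ks method shipped; maximum-likelihood
  codon models will differ, especially at high divergence.
* The progressive aligner is approximate by design.
* Sequon detection deliberately over-calls relative to trained
  predictors.
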