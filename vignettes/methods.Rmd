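---
title: "Comparative intergenic sRNA discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative intergenic sRNA discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnascout)
```

# The problem

Bacterial small non-coding RNAs (sRNAs, typically 50–500 nt) are hard to
find by annotation alone: they leave no open reading frame, and their
sequence conservation is often weak while their *secondary structure* is
conserved. The classical comparative strategy is a funnel:

1. extract all intergenic regions (IGRs) of a focal genome;
2. keep IGR segments conserved across related genomes (local alignment
   with an E-value cutoff);
3. keep conserved segments whose fold looks like a real RNA — thermodynamic
   stability beyond what base composition explains, plus comparative
   support (consensus structure, compensatory substitutions);
4. annotate the survivors with promoter/terminator signals and known-RNA
   family labels, then confront them with strand-specific RNA-seq coverage
   (transcription units, RPKM, condition ratios) and downstream target /
   GO analysis.

`srnascout` implements this funnel end to end for desk-scale data, plus a
synthetic multi-genome generator with planted ground truth so that every
stage is testable without downloading anything.

# Stage models and the parameters that matter

## IGR extraction (`extract_igrs`)

Coordinates are 1-based and fully inclusive everywhere
(`length = end - start + 1`). "Gene" means any annotated gene-like feature
(CDS, tRNA/rRNA/ncRNA, pseudogenes included), which makes the IGR
definition conservative. IGRs are the maximal gaps in the union of gene
intervals, including the two terminal gaps; the default minimum length is
50 nt, the conventional lower bound for bacterial sRNAs. IGRs are
strandless; strand is assigned later.

## Conservation screen (`local_align`, `evalue`, `find_conserved_blocks`)

Alignment is exact Smith–Waterman–Gotoh (affine gaps; a gap of length $L$
scores `gap_open` $+ L\cdot$`gap_extend`), with the BLASTN-like default
scheme +2/−3, −5/−2. Significance uses Karlin–Altschul statistics,
$E = K m n e^{-\lambda S}$: $\lambda$ is the positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ (solved to $|f| < 10^{-9}$);
$K$ is estimated once per scoring scheme by simulation, matching the Gumbel
location of maximal ungapped segment scores over 200 random 300-nt pairs
($E[S_{max}] = (\ln K m n + \gamma)/\lambda$) under a fixed internal
calibration seed, so E-values are deterministic. Applying ungapped theory
to gapped scores is the standard approximation and is ample for a
$10^{-5}$ cutoff at these scales. The subject database length $n$ is the
total IGR length of the subject genome, matching the IGR-restricted search
space. Hits on the same focal interval (reciprocal overlap ≥ 50%) merge
into a conserved block; blocks need support from at least 2 non-focal
genomes by default.

## Energy model (`energy_model`)

One simplified nearest-neighbour model is shared by MFE folding, terminator
hairpin scoring and sRNA–mRNA duplex energies: a 6×6 stacking table over
{CG, GC, GU, UG, AU, UA} (kcal/mol), linear length penalties for hairpin
(≥ 3 nt), bulge and internal loops, a linear multiloop model
($a + b\cdot\text{branches} + c\cdot\text{unpaired}$), no dangling ends, no
coaxial stacking, no pseudoknots. The table is symmetric under viewing a
stack from the opposite strand ($S(p,q) = S(\bar q,\bar p)$), which makes
duplex energies invariant under exchanging the two molecules. The
constants ship as plain-text files under `inst/extdata`. The point of the
simplification is determinism and oracle-checkability: for sequences up to
22 nt the dynamic program is verified against exhaustive enumeration of
all secondary structures; parity with full Turner-parameter folders is a
non-goal.

## Structure screen (`structure_zscore`, `structure_conservation_index`, `covariation_score`, `classify_structured`)

*Thermodynamic evidence.* The z-score compares the native MFE with MFEs of
dinucleotide-preserving shuffles (Eulerian-walk shuffle, uniform over valid
shuffles, preserving all 16 dinucleotide counts and both terminal bases):
$z = (E_{native} - \bar E_{shuffle})/s_{shuffle}$ with the $n-1$ standard
deviation, and $z = 0$ by convention when the shuffle SD is zero. The
default 100 shuffles put the Monte-Carlo error of $z$ near 0.1.

*Comparative evidence.* The structure conservation index is
$\mathrm{SCI} = E_{consensus} / \overline{E_{single}}$, where the consensus
fold of a pairwise alignment may pair a column pair only if both rows pair
legally there, stacks are averaged over rows, and each compensatory column
pair earns a −1 kcal/mol bonus. An identical-row alignment has SCI exactly
1 by construction. The covariation score adds +1 per compensatory double
substitution, +0.5 per consistent single substitution (e.g. GC→GU), −1 per
pair-breaking substitution over the paired columns of the consensus
structure. Because a conserved block is supported by several genomes, SCI
and covariation are averaged over all supporting pairwise alignments — the
pairwise analogue of scoring one multiple alignment, and considerably more
stable than using a single (often flank-heavy) best hit.

*Decision rule.* A block is "structured" iff all three pass:
$z \le -2$ (thermodynamic), $\mathrm{SCI} \ge 0.6$ **and** covariation
$\ge 0$ (comparative), and at least 20 base pairs in the native MFE
structure. The conjunction mirrors the keep-the-intersection logic of
running a thermodynamic and a comparative screen side by side. The
"minimum stem" rule counts total paired bases across helices, not one
contiguous 20-bp helix — contiguous 20-bp stems are rare in genuine sRNAs,
which favour several shorter stem-loops.

Note that a covariation score computed on the consensus-fold structure is
non-negative by construction (the consensus can only pair columns that
pair in both rows), so with the default `cov_min = 0` the comparative
decision is carried by the SCI; the covariation score remains the
quantitative record of positive compensatory support, and the scoring
table itself is exercised against planted and disrupted stems in the
tests.

## Signal screen (`scan_promoters`, `find_terminators`)

Promoters are σ70 −35/−10 box pairs scored by log-odds PWMs (consensus
TTGACA/TATAAT with 0.85/0.05 pseudocount frequencies against a uniform
background; user-replaceable), spacer 15–19 nt, default score cutoff 14
bits of the maximal ~21. Terminators are enumerated hairpins (stem 4–18 bp,
loop 3–10 nt) scored as
$(-E_{hairpin}) + w_U \cdot \#\mathrm{U}_{8\,nt\ tail}$ with $w_U = 1$ and
cutoff 12; overlapping hits reduce to the best. Search windows: 150 nt
upstream of a candidate's 5′ end for promoters; the candidate's 3′ half
plus 50 nt downstream for terminators. Signal evidence *annotates*
candidates — it never removes one, since many genuine trans-sRNAs lack a
recognisable intrinsic terminator.

## Candidate assembly and family labelling

One candidate per structured block. Strand is the strand with the lower
MFE; energies within 2 kcal/mol count as a tie, because Watson–Crick-dominated
structures fold almost identically on both strands under this model. Ties go
to the terminator evidence — comparing tail U counts first, since a hairpin
reads the same on both strands and only the poly-U tract is
strand-specific — then to the composite terminator score, then "+". This structure-only strand call is a known
weak point whenever a block carries long unstructured flanks; in practice
strand is confirmed by stranded coverage, which the expression stage does.
Family labels come from exact local alignment against a user-supplied
labelled RNA library (identity ≥ 0.6 and E ≤ 10⁻⁵ required; ties broken by
E-value then family name, so record order is irrelevant). Families matching
the riboswitch set {FMN, TPP, cobalamin, glycine, SAM} are flagged
cis-regulatory. Covariance-model (Rfam CM) search is out of scope; the
labelling contract is the same, the sensitivity is not.

## Expression validation (`call_transcription_units`, `expression_table`)

Transcription units are maximal runs of per-base coverage at or above a
threshold (default: `max(5, 0.5 × median nonzero coverage)` — scale-free in
library depth), with runs separated by ≤ 50 nt merged and units < 50 nt
dropped. Candidates match units on the same replicon and strand by maximal
reciprocal overlap ≥ 0.5; start/stop agreement uses a ±20 nt tolerance, the
operational meaning of "approximate" boundary agreement here (configurable;
no published value exists for it). RPKM is
$10^9 \cdot \text{count} / (\text{library size} \times \text{length})$,
counting a read when at least half of it overlaps the interval on the same
strand. Condition ratios are reported against the first condition (the
free-living reference), rounded half-up to 2 decimals for report parity
with the published precision; full precision is kept alongside. bedGraph
input/output is 0-based half-open and converted exactly.

## Target prediction (`predict_interactions`)

A hybridization-only model: gap-free antisense duplexes seeded by ≥ 7
contiguous Watson–Crick pairs, extended while pairing remains possible
(G:U allowed in the extension), scored by the shared stacking table, best
hit per gene, energy cutoff −8 kcal/mol. Target regions are translation
initiation windows, −60…+30 nt around the start codon in sense
orientation. Accessibility ($\Delta G_{open}$) and interior loops are
deliberately omitted so the optimum is verifiable by exhaustive
enumeration; the ranking should be read as candidate generation, not as a
calibrated affinity.

## GO enrichment (`hypergeom_enrichment`, `category_summary`)

Upper-tail hypergeometric tests ($p = P(X \ge k)$, `phyper` in log space)
per term, Benjamini–Hochberg adjusted within each namespace; the universe
is the focal genome's annotated genes, and the annotation table is taken
as already propagated (no GO graph handling). Category summaries follow
the WEGO convention: a gene may count in several classes, percentages are
gene–class assignments over all assignments per namespace, rounded to
integers.

# The synthetic cohort: what it emulates, and what it does not

`simulate_genomes()` builds an ancestor of ~60 kb with 50 gene placeholders
separated by 150–300 nt IGRs (GC 0.6, the rhizobial regime) and plants 8
elements, each two designed 12-bp stem-loops plus an intrinsic terminator
(10-bp GC stem, U₈ tail) behind a σ70 promoter. Four descendant genomes
diverge by per-site substitution and background indels; the focal genome is
the ancestor itself. Defaults:

* background substitution 0.40/site with 0.05/site indels — near alignment
  saturation, so most background IGRs do *not* survive the E ≤ 10⁻⁵ screen.
  This reproduces the shape of the real funnel (a minority of IGRs yield
  cross-species hits) rather than a cohort of near-identical strains;
* element substitution 0.05/site with compensatory probability 1 — stems
  mutate but stay paired, the signature the comparative screen looks for;
* expression log-uniform in 200–2000 RPKM per condition (FC/MN/SN,
  mirroring free-living, mature-nodule and senescent-nodule conditions),
  libraries of 10⁶ mapped 50-nt reads, negative-binomial counts
  (dispersion 0.1), and ~1× background coverage per strand.

What passing on this cohort shows: every stage's logic — interval
arithmetic, alignment statistics, fold/z/SCI discrimination, TU/RPKM
recovery — under a controlled truth. What it does not show: performance on
real inter-species divergence patterns (rate heterogeneity,
rearrangements, horizontally transferred IGRs), real promoter diversity,
RNA processing and degradation (the main cause of predicted-vs-sequenced
length discrepancies in real data), or Rfam-level family sensitivity.

# Numerical choices and degenerate inputs

* Folding ties prefer fewer pairs via a deterministic traceback; energies,
  not structures, are the oracle-checked quantity.
* Interior loops are capped at 30 unpaired nt (standard practice); hairpin
  loops ≥ 3 nt; the MFE is never positive because the empty structure is
  always admissible, so energy 0 ⟺ no pairs.
* `z = 0` when the shuffle SD is 0; `SCI = 0` when the mean single-sequence
  MFE is 0; ratios are `NA` when the reference-condition RPKM is 0.
* A replicon with no genes is one giant IGR (documented, not an error);
  zero structured blocks yield typed empty tables end to end.
* All randomness (generator, shuffles, coverage) flows from explicit seeds;
  the K-calibration uses a fixed internal seed and is cached per scoring
  scheme, so E-values never depend on session state.
* Report rounding is half-up (not banker's) to match printed tables.

# Problem sizes used by the checks

The bundled verification runs were sized to stay comfortable on one CPU:
the full synthetic cohort (5 genomes × ~60 kb) for planted-truth recovery
with 50 coverage replicates; 100 shuffled-background trials of 120 nt for
structure-screen calibration and 50 shuffled-subject search trials (8 focal
IGRs × 2 subject genomes, 150 nt) for the E-value null; oracle batteries of
several hundred cases at ≤ 12 nt (alignment), ≤ 20 nt (duplexes), ≤ 22 nt
(folding) and M ≤ 20 (hypergeometric). The test suite uses a reduced
cohort (4 genomes, 10 genes, 3 elements) for the end-to-end fixtures.

# Known limitations

* The fold model is intentionally coarse; absolute energies are not
  comparable to Turner-parameter folders, only the screen's *relative*
  decisions are meaningful.
* Strand assignment from structure alone is unreliable for symmetric
  structures with flanks; treat it as provisional until coverage confirms.
* Family labelling by sequence alignment misses remote homologs that a
  covariance model would find.
* The E-value calibration (ungapped K on gapped scores, simulation-based)
  is approximate; with the 10⁻⁵ cutoff and desk-scale search spaces the
  approximation has ample margin, as the null-calibration checks verify.
* Hybridization-only target prediction over-ranks accessible-looking sites
  in structured windows; it is a screen, not a binding-affinity model.
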