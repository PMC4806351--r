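---
title: "Methods: surveying an R2R3-MYB gene family with mybkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying an R2R3-MYB gene family with mybkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mybkit` re-implements the standard analysis chain of a genome-wide
R2R3-MYB transcription-factor family survey as composable, tested R
functions. This vignette records the models behind each stage, the
parameters that matter, what the bundled simulator does and does not
emulate, and the numerical and design choices a maintainer would want
explained.

## The NG86 Ka/Ks estimator

Given a pair of gap-free aligned coding sequences, the Nei–Gojobori
(1986) method classifies each codon position fractionally: the synonymous
site content of a position is the fraction of its single-nucleotide
changes that preserve the amino acid. Changes that create a stop codon
are excluded from *both* numerator and denominator, so each position
contributes exactly one site and `S + N = 3 × codons` holds as an exact
invariant (tested to machine precision). Codon pairs differing at 2 or 3
positions are resolved by pathway averaging: all orderings of the single
steps are enumerated, orderings passing through a stop codon are
discarded, and the synonymous/nonsynonymous step counts of the survivors
are averaged with equal weights. (If every ordering is blocked — not
observed for sense–sense pairs in exhaustive enumeration, but guarded —
the average falls back to all orderings.) The proportions `p_S = sd/S`
and `p_N = nd/N` are Jukes–Cantor corrected, `d = -3/4·log(1 - 4p/3)`,
and proportions at or above 3/4 are flagged saturated rather than forced
to a number. The per-codon-pair counts are precomputed into 61×61 lookup
tables, so sequence-level estimates are sums of table entries; the test
suite checks 1000 random codon pairs against an independent recursive
enumerator at 1e-9.

Duplication ages follow the clock `T = Ks/(2λ)` with
`λ = 1.5×10⁻⁸` synonymous substitutions per site per year (the rate used
for *G. raimondii*); λ is a parameter everywhere it appears. Selection
regimes are labelled with the survey's operational cut-offs: Ka/Ks < 0.5
purifying, 0.5–1 candidate positive, > 1 positive.

## The simulator: a family with known history

`simulateFamily()` grows a gene family from a single ancestor on a
multi-chromosome genome of background genes. Each duplication event
copies a current family gene into a new locus and diverges the **new
copy** to the event's target (Ks, Ka/Ks) with `mutateCDS()`. Diverging
only the copy — rather than both copies by half the target — is a
deliberate design choice: NG86 is symmetric, so the pair's estimate
cannot distinguish the two, while mutating a source gene again in a later
event would corrupt the Ks of every earlier pair it belongs to. With
asymmetric divergence, every event's pairwise target holds exactly
regardless of how events chain through the family.

`mutateCDS()` converts the target Ks back through the Jukes–Cantor
correction into an expected proportion of synonymous differences and
multiplies by the NG86 site count to get a substitution budget (the
fractional part resolved by a Bernoulli draw, so the expectation is
exact). Two refinements make the generator the estimator's exact inverse:

* **One hit per codon while possible.** Sites are drawn per-site
  multinomially conditioned on class (transitions weighted 2:1 by
  default), but each codon is touched at most once while untouched codons
  remain. Single-nucleotide codon differences are counted by NG86 without
  any pathway ambiguity, so the planted counts are recovered exactly.
  Only extreme targets reuse codons (at most twice, with the candidate
  catalogue refreshed against the mutated codon); targets beyond that
  capacity raise a saturation error, as do targets implying `p ≥ 3/4`.
* **Site-drift calibration.** NG86 normalizes by the *mean* site count of
  the two sequences, and substitution drifts codon usage toward higher
  synonymy (on the default ancestor, S rises ~12% at Ks = 0.6, which
  would bias pair estimates ~8% low). The substitution budget is
  therefore calibrated against the expected post-mutation site count,
  computed from the class-conditional mean site-count change of the
  candidate catalogue and a scalar fixed-point iteration. Across the
  (Ks ∈ {0.1, 0.3, 0.6}) × (Ka/Ks ∈ {0.2, 0.5}) grid at 500 codons, mean
  recovery error is under 2%.

Stop codons are never created: stop-creating changes are simply not in
the candidate set, and the start codon is held immutable for family
genes.

**Placement semantics.** Tandem copies are inserted adjacent to their
source; segmental copies go to a uniformly chosen location that is not
family-adjacent to the source (another chromosome, or the same chromosome
with at least one family gene intervening — matching the classification
rule's notion of "one following the other" on family ranks). Because the
classifier reads the *final* gene order, insertions protect previously
created tandem pairs: a tandem copy takes the source flank that does not
split an existing pair (so a gene flanked by two earlier partners is not
an eligible tandem source), and segmental insertion slots that would fall
between a recorded tandem pair are excluded. The default event table (4
tandem + 6 segmental, Ks 0.04–0.60) pairs higher Ks with lower Ka/Ks
(0.10–0.25), the purifying regime observed for real duplicated R2R3-MYB
pairs; this also keeps expected protein identity, roughly
`exp(-2.25·p_N(Ka))`, above the 80% detection rule for every event, which
is what makes end-to-end recovery a meaningful test.

Gene structures place introns at fixed CDS offsets (default 133 and 266,
phases 1 and 2 — the typical 3-exon/2-intron MYB layout) shared by all
family genes; background genes get 0–3 introns at random offsets. GFF3 is
emitted 1-based inclusive with CDS phase fields; strands are random and
minus-strand genes are reverse-complemented into the chromosome sequence.

**What the simulator does not emulate:** indels within coding sequence
(family divergence is gap-free, so alignment difficulty is not tested),
codon-usage bias and selection heterogeneity along the gene, transposon
or pseudogene content in the intergenic space, and sequencing or assembly
artifacts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness
to alignment error on diverged real genomes.

## Repeat detection and conservation statistics

The R2/R3 scan replaces the usual BLAST + SMART/Pfam screening with a
self-contained log-odds position-weight model (default width 49 — the
repeat core; the literature's "approximately 53 residues" refers to the
full repeat and is reachable via configuration). Frequencies use
pseudocount 0.5 over a background; window scores are summed log2-odds;
non-overlapping hits are selected greedily by descending score with ties
to the leftmost start. The score threshold is calibrated as the 99.9th
percentile of the per-protein maximum window score over random proteins —
drawn from the *scanned set's own* residue composition, because
codon-usage skew raises null scores noticeably relative to a uniform
background. This gives a per-protein false-positive rate of about 0.1%;
on the default simulated genome, family sensitivity is 11/11 with zero
background hits.

ORF completeness filtering drops proteins lacking an initial Met or
containing an internal stop (reason "incomplete ORF"). Repeat-count
labels are none/1R/R2R3/3R/4R; the R2R3 label additionally requires the
R2 hit to precede a non-overlapping R3 hit within 25 residues (the
repeats are adjacent in genuine R2R3 proteins); two repeats violating
that arrangement get an explicit "2R" label rather than being forced into
another class. Conservation statistics are the sequence-logo quantities:
`I_c = log2(20) + Σ f·log2 f` bits per column (clipped at 0; columns with
more than 50% gaps dropped, gaps excluded from frequencies) and columns
whose modal residue reaches a frequency threshold (default 1.0 = 100%
conserved).

## Alignment, distances, trees, subgroups

Pairwise global alignment is affine-gap Needleman–Wunsch (BLOSUM62, gap
open 10, extend 0.5 — ClustalW-like defaults, since only "default
options" are ever reported for such surveys), computed with Biostrings
and verified against exhaustive enumeration for short sequences. The
progressive MSA builds a UPGMA guide tree from pairwise identity
distances and merges profiles with an Rcpp profile–profile Gotoh aligner
(sum-of-pairs BLOSUM column scores, same gap costs, deterministic
diagonal > up > left tie-break); two sequences reduce exactly to the
pairwise aligner.

Distances are Poisson-corrected, `d = -log(1-p)`, with pairwise deletion
(only the columns gapped in the specific pair are excluded); `p = 1` is
flagged saturated rather than stored. Neighbor joining delegates the
Saitou–Nei agglomeration to `ape::nj` and then clamps negative branch
lengths to zero, transferring the deficit to the sister branch so path
lengths through the parent are preserved (the behavior MEGA users
expect). Additive 4- and 5-taxon matrices are recovered to 1e-9.
Bootstrap resamples alignment columns, rebuilds the NJ tree per
replicate, and counts reference bipartitions via `ape::prop.clades`;
within replicates a saturated pair is capped just below `p = 1` so the
replicate stays usable. The default is 1000 replicates; the test suite
and pipeline use 200, which bounds the support standard error at ~3.5
points — ample for the ≥50% subgroup rule and the ≥90% sibling checks.
Subgroups are the maximal clades whose subtending edge has at least 50%
support, remaining leaves becoming singletons, labels C1… assigned in
preorder.

The sibling-recovery test uses a "cherry" family design — five deeply
diverged lineages (Ks 0.9) each duplicated once shallowly (Ks 0.15) — so
that every shallow pair is a true cherry. The founder itself gets no
shallow partner: it sits at the radiation point on a zero-length branch,
where a cherry bipartition is not statistically identifiable (an early
draft that included it produced an honest ~68% support for an
unidentifiable split, not an algorithmic failure).

## Motif discovery

`zoopsEM()` is a compact MEME-style elicitor under the
zero-or-one-occurrence-per-sequence model: E-step responsibilities over
all window starts plus the "no site" outcome, M-step PWM re-estimation
with a Dirichlet pseudocount (α = 0.1) and occurrence-prior update. The
reported objective is the penalized likelihood the EM actually ascends
(data log-likelihood plus the log-prior term), asserted non-decreasing on
every run. Two practical measures matter: the occurrence prior is kept in
[1e-4, 0.99] so absence remains expressible when decoding new sequences,
and the best-of-restarts fit is refined over column shifts of ±1–2 (EM
readily converges to an off-by-one optimum; restarting from the shifted
PWM and keeping the best likelihood removes it). Significance is the
log-likelihood ratio against the background-only model — a ranking and
stopping statistic, not a calibrated E-value; `discoverMotifs()` defaults
its retention threshold to 1.2× the maximum LLR over column-shuffled
datasets and masks decoded occurrences with background-sampled residues
between rounds. Widths default to 8 in the pipeline (desk-scale; the
width range is configurable).

## Expression analysis

Technical replicates are averaged first; ΔCt subtracts the arithmetic
mean Ct of the reference genes per biological sample (equivalent to the
geometric mean of relative quantities — the combination rule is a
package choice, as surveys list reference genes without stating one);
ΔΔCt differences treated against control within tissue, and
`2^-ΔΔCt` is the fold change. Significance mirrors the field's practice:
one-way ANOVA (classical decomposition via `stats::aov`; zero
within-group variance with equal means is defined as F = 0, p = 1) on
raw p-values at α = 0.05 together with a ≥2-fold (or ≤0.5) change;
Benjamini–Hochberg q-values are provided as an extra column but do not
drive the flag. Ct values at the detection ceiling (40 cycles) are
treated as censored: excluded from ANOVA, with the fold change flagged as
a bound. Profile clustering uses 1 − Pearson distance with average
linkage; constant profiles (undefined correlation) are placed at distance
0 from identical profiles and 2 from everything else, and flagged.

The qPCR simulator inverts the ΔΔCt model exactly: Ct = per-gene baseline
(drawn once around 22 cycles, a typical mid-dynamic-range value) minus
the planted log2 fold change, plus Gaussian technical noise (default
0.25 cycles), clamped to [10, 40]; reference genes have fold change 1
everywhere. The default design is two tissues (leaf, root) × control +
two drought + two salt levels with 3 biological × 3 technical replicates,
matching the usual stress-survey layout. With two reference genes at
default noise, a null gene's fold change lands in [0.8, 1.25] in ≥95% of
simulations, and a planted 226-fold response (the largest reported in the
motivating survey) is recovered with mean estimate ≈ 229 over 300
simulations.

## Duplication detection and the published pair table

Duplicate pairs are called by the survey's rule: aligned region covering
>80% of the longer gene and >80% identity, both strictly, on proteins.
"Similarity" is read as alignment-column identity over non-gap-pair
columns (the rule's source does not define it further). Classification
is tandem iff same chromosome and adjacent family ranks (no intervening
family member), segmental otherwise (intra- or inter-chromosomal).
`inst/extdata/grmyb_duplication_pairs.tsv` ships the published Ka/Ks
table for the 35 duplicated GrMYB pairs (27 segmental, 8 tandem);
re-deriving ages from its Ks column reproduces the reported 6.33 Mya
(Ks = 0.19), 15.68 Mya segmental mean and 7 Mya tandem mean. Counting
selection labels from the table's printed (rounded) ratios gives 9 pairs
in [0.5, 1] where the original text says eight — the text presumably used
unrounded ratios; the report emits the counts as computed and makes no
attempt to force agreement.

## Problem sizes and runtime

The test suite and acceptance script run at desk scale: 500-codon
ancestors, 10-event families on 5 chromosomes with 40 background genes,
100 simulated pairs per (Ks, Ka/Ks) target, 200 bootstrap replicates,
1000-pair NG86 oracle comparisons, 1000 null ANOVA simulations and
300-fold-change Monte-Carlo draws. These sizes put the whole suite at a
few minutes while leaving every estimate's Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

Gap-free family divergence means codon alignment through the protein
alignment is exercised only lightly; NG86 carries its usual biases at
high divergence (saturation flagged, not corrected by γ or
maximum-likelihood models — deliberately out of scope); the motif
significance proxy is not an E-value and should not be compared across
datasets of different size; and the subgroup rule exposes only the
explicit ≥50% support criterion — deeper grouping conventions seen in
published family surveys are editorial, not algorithmic.
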