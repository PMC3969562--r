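---
title: "Methods and models behind popcontent"
author: "popcontent authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind popcontent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`popcontent` implements the computational core of a population-genomics
workflow for budding yeast resequencing panels: linkage-based assembly
scaffolding, presence/absence genome content detection, synteny-guided
annotation transfer, windowed read-depth copy-number analysis,
loss-of-function variant classification with selection statistics, and
copy-number-phenotype association. Every stage can be exercised and
scored against machine-readable ground truth produced by the package's
own synthetic-data generators. This vignette records the models, the
tunable parameters, and the design decisions, in that order of
importance.

## The synthetic study the generators emulate

The generators emulate a panel of haploid (or homozygous diploid) yeast
strains resequenced with short reads: a phylogenetically structured
population whose genomes differ by SNPs, short indels, presence/absence
of multi-kilobase segments, tandem copy-number changes, and
loss-of-function variants; advanced-intercross (F12) segregant panels
derived from pairs of those strains; windowed read-depth tracks; and
copy-number-dependent growth phenotypes. The subtelomeres — by
convention the outermost 33 kb of each chromosome — are the structurally
dynamic compartment: segment gains, losses and copy-number changes are
placed there with a 40-fold rate enrichment by default, the order of
enrichment observed for subtelomeric copy-number variation in natural
yeast populations. Both numbers are parameters
(`subtelomereSpan`, `subtelEnrichment`).

`simulatePopulation()` draws Poisson numbers of events per branch of a
user-supplied phylogeny, with expected counts `rate * branchLength *
genomeLength` per event class. Branch lengths are in substitutions per
bp, so with the default `snp = 1` a branch of length 0.001 contributes
about one SNP per kilobase. Every event records its carriers, so
pairwise SNP distances are proportional to path lengths through the
tree and all downstream detectors can be scored without re-simulation.
Three forms of purifying selection are emulated at generation time:
random SNPs that would create a premature stop are rejected and
resampled; random frame-shifting indels inside ORFs are rejected with
probability `frameshiftRejection` (default 0.9, which produces the
multiple-of-three length enrichment of in-ORF indels); and targeted
loss-of-function events avoid essential and dubious ORFs. Segment
events are kept at least `segmentPadding` (default 1200) bp apart so
that each event remains an individually resolvable region under the
1-kb reporting rule of the content detector.

### The intercross model

The source study states only that segregants are "F12" progeny of a
two-parent cross; the pedigree design (sib-mating versus random
mating) is not recoverable, so the package implements the simplest
scheme with the right LD structure and documents it: each segregant
chromosome is a haploid mosaic whose crossover count is Poisson with
mean `generations * mapDensity` (crossovers accumulate linearly over
generations), crossover positions are uniform, and the parental allele
alternates at each crossover. Under this model the correlation between
markers at distance $d$ is $e^{-2\rho d}$ with $\rho$ the accumulated
per-bp crossover density, hence $r^2 = e^{-4\rho d}$ — exactly the
exponential decay form the scaffolder fits. `mapDensity` defaults to
1 crossover per chromosome per meiosis; with 12 generations and 1-Mb
chromosomes this puts the decay constant near $5\times10^{-5}$ per bp,
so LD falls from ~1 at 1 kb to below 0.5 within a few tens of
kilobases, decaying over a physical scale that makes scaffold linking
informative. The cross defaults to 192 segregants of which 20 emulate
diploid/contaminated DNA ("contaminants"), matching the proportion
excluded in the motivating study.

Genotype emissions are log-likelihood ratios: the true allele draws
LLR from $N(\pm 18, 4)$, a genotyping error (default probability
0.002) flips the sign, and a missing emission (default 0.02) or a
contaminant marker (half of a contaminant's markers) draws from
$N(0, 3)$, which falls inside the no-call band of the threshold rule.
Only the LLR is consumed downstream, so the emission model is internal.

### Coverage and phenotypes

`simulateCoverage()` emits mean depth in non-overlapping windows
(default 500 bp). Expected window depth is `meanDepth` times local
copy number; read counts are negative-binomial with variance
$\mu + \text{noise}\,\mu^2$ assuming 100-bp reads. The default
overdispersion 0.01 gives a per-window depth CV of about 13% at 30x,
in the range seen for real short-read windowed coverage; windows
overlapping repeat annotation are depth-inflated (collapsed-repeat
pile-up) and flagged masked. `simulatePhenotypes()` implements the
additive model $E[y] = \beta_0 + \beta_1 c$ and a saturating mode in
which the effect plateaus at one copy, the pattern seen for growth
efficiency phenotypes where additivity breaks down. Phenotype units
are treated as opaque reals; in the motivating data they are log2
ratios relative to a reference strain.

## Linkage scaffolding

Genotypes are called from LLRs with the strict threshold rule (call at
|LLR| > 10, no-call otherwise); indel genotypes use 5.3. Segregants
whose missing-call fraction exceeds 0.2 are excluded as
diploid/contaminated — the fraction of intermediate calls is the
implemented surrogate for "genome-wide patterns of heterozygosity",
which the source does not further specify.

LD is computed as
$r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)}$
over the segregants non-missing at both markers (pairwise-complete
cases, standard LD practice). Monomorphic or under-observed pairs are
skipped with a reason. The decay model $r^2 = e^{-\lambda d}$ is fit
by least squares over within-scaffold pairs on scaffolds of at least
50 kb; the one-dimensional objective is minimized over
$\log \lambda$ with Brent's method at tolerance $10^{-12}$, which is
deterministic and recovers a noiseless decay constant to machine
precision. Physical gaps are estimated by inversion,
$d = -\ln(r^2)/\lambda$, with $r^2 = 0$ mapping to an infinite-distance
sentinel.

Scaffold pairs are linked by corner LD: the between-scaffold $r^2$
matrix (markers ordered by position) is summarized at its four corners
by the mean over `cornerK` x `cornerK` blocks. The strongest corner
identifies the adjacent scaffold ends and hence the relative
orientation (FF/FR/RF/RR). The literal reading of the source is a
single corner element (`cornerK = 1`); single-SNP corners are noisy,
so the default is 5 with the literal behavior available. An edge is
emitted when the best corner reaches 0.3, and its orientation counts
as resolved when the best corner beats the second best by at least
0.05. These two thresholds are the automated surrogate for path
curation that was partly manual in the source workflow. Paths are
traced greedily: reliably oriented edges are accepted in decreasing
strength when both scaffold ends are free and no cycle would form; a
cycle-closing edge (necessarily the weakest in its component) is
dropped. Scaffolds with fewer than two markers are unplaced with
reason `too_few_snps`; scaffolds whose corner contrast never resolves
an orientation are unplaced with reason `no_orientation`; edge-less
scaffolds form singleton paths. Path direction is fixed canonically so
output does not depend on input order. Scaffold ends whose outermost
5 kb exceed the genome-wide median coverage by more than $2^{0.5}$
(log2 ratio strictly above 0.5, with a $10^{-9}$ epsilon guarding the
exact boundary against floating-point noise) are flagged as collapsed
repeats and excluded from linking.

On simulated crosses (two 1-Mb chromosomes, ~20 scaffolds of at least
20 kb, markers every ~2.5 kb, 170 segregants of which 20
contaminated), ordering concordance is 1.0 and orientation accuracy
1.0 across seeds; accuracy degrades monotonically with genotyping
error, as it must.

## Genome content variation

The detector consumes alignment blocks from any engine that reports
block lengths and identities; the bundled engine is an exact
seed-and-extend matcher (k-mer seeds, per-diagonal maximal extension,
Rcpp) whose same-diagonal blocks separated by at most 200 bp are
chained into mismatch-tolerant blocks with identity equal to the
matched fraction of the span. Using a contract rather than a named
external search tool keeps the algorithmic content — the coverage and
reporting rules — in the package. A query position is covered when
inside any block at least 100 bp long with identity of at least 0.75,
or at least 50 bp at 0.90; maximal uncovered runs of at least 1 kb are
the absent regions. Region edges are trimmed to uncovered-run
boundaries and never merged across covered gaps. Pairwise totals are
reported both per direction and symmetrized (the sum of both
directions is the headline statistic; which one a published scatter
used is ambiguous, so both are kept). On planted segments the
per-region length error is a few bp up to a few tens of bp, well
within the 50-bp slack the acceptance check allows, and sub-kilobase
segments are never reported.

## Annotation transfer

Candidate homolog placements (similarity > 0.90, score within 90% of
the per-query top; `is_top` marks the top 10%) are selected in
priority order: top-scoring with synteny support on both sides; then
top-scoring with synteny on one side and the scaffold edge on the
other; then non-top with synteny on both sides. Synteny support means
the nearest provisionally placed gene on that side is a reference
neighbor within two intervening genes — the source does not quantify
its synteny window, so two is the documented choice. A side with no
placed gene between the candidate and the scaffold end counts as at
the edge. Ties break by score, then gene length, then coordinates, so
assignment is a pure function of the candidate set. Assignments whose
intervals coincide within 100 bp at both ends compete; the survivor is
chosen by tier, then score, then length, and every drop is logged with
its rule. Predicted genes are nonreference when they are at least
300 bp, overlap no assigned homolog, and have no reference hit of at
least 200 bp (or 80% of their length) at identity of at least 0.90.
Ab initio prediction itself is an input; a deliberately naive ORF
finder is bundled for synthetic tests only.

## Copy-number analysis

Mean depth in non-overlapping 500-bp windows is normalized by the
genome-wide median over unmasked windows and log2-transformed;
zero-coverage windows sit at a configurable floor (default -10).
Strains below 8x genome-wide coverage are rejected outright. Windows
overlapping repeat/transposon-similar annotation are masked and never
contribute to normalization, calls or family estimates. The source
called CNV regions by manual inspection of the plots; the package
substitutes deterministic thresholding — maximal runs of at least 3
unmasked windows at |log2| of at least 0.58 (about 1.5-fold), both
configurable — so fidelity is at the procedure level, not
call-by-call. The inter-strain variable-region union keeps windows
covered by a call in at least one strain where at least two strains
differ in call state, so identical copy-number changes in every strain
are not counted as variation between strains. Gene-family copy number
is the sum over member loci of mean unmasked normalized depth times
the reference copy count, the aggregate-depth device that sidesteps
read-mapping ambiguity among close paralogs; at 30x the estimate is
linear in truth (slope within [0.9, 1.1]) with errors well under one
copy for families spanning 1-12 copies. Subtelomeric enrichment reports
the fractions of subtelomeric and core positions inside the variable
union, their fold ratio (an infinite sentinel when no core position is
affected, which is common at desk scale), and a two-proportion test
whose p-value is anti-conservative because neighboring positions are
strongly autocorrelated — it is a summary, not a calibrated
significance level.

## Variant effects and selection

SNP coding effects come from strand-aware codon arithmetic under the
standard nuclear code, validated against an independent whole-ORF
retranslation oracle; a variant overlapping several ORFs is evaluated
against each. The equivalent indel region — the interval of all
placements of an indel that give an identical edited sequence — is
computed by scanning anchors outward from the reported position,
stopping after `len` consecutive non-equivalent anchors (equivalent
placements are spaced by the repeat period, which cannot exceed the
indel length, so the scan is exhaustive); it matches brute-force
enumeration on homopolymer and microsatellite fixtures. An indel
affects an ORF only when its equivalent region is completely contained
in the ORF; contained indels are frameshifts when their length is not
a multiple of three. Loss-of-function calls are premature-stop SNPs
and frameshifting indels in non-dubious ORFs at relative position
below 0.98 (the last 2% of the ORF is excluded, where truncation
usually spares function). Stop-loss variants are classified but not
counted as loss of function, and start-codon-disrupting SNPs are
nonsynonymous, matching the premature-stop/frameshift definition.
Positional enrichment in the 3' tail uses an exact binomial tail;
the frame-preservation spectrum reports the 2x2 sample odds ratio
(in-ORF x multiple-of-three) with a two-sided Fisher exact p. Alleles
are polarized against an outgroup allele that must match one of the
two ingroup alleles, otherwise the site is flagged unpolarized and
excluded from derived-allele-frequency spectra. pN/pS uses pooled
counts per gene set with a two-sided Fisher comparison (a per-gene
table is available from the same inputs); deleteriousness labels are
consumed as an input column, never computed. Paralog counting is a
contract over protein-similarity hits (significant hit covering at
least 80% of the query); the bundled engine uses local BLOSUM62
alignment with an identity-based significance rule standing in for an
E-value threshold.

## Distances, trees and association

Neighbor joining is delegated to the standard agglomeration in `ape`,
behind a surface that pre-sorts taxa for deterministic tie-breaking
and optionally clamps negative branch lengths; tests cross-check it
against a least-squares brute force over quartet topologies. Content
distances may violate the triangle inequality and are used as-is. CNV
profile distance is Euclidean over shared unmasked per-window log2
ratios (the source's metric is unstated). The additive copy-number
model is a single-predictor least-squares regression whose variance
explained equals the squared Pearson correlation; per-copy group means
expose departures from additivity, and the 1-vs-2-copy Welch contrast
distinguishes additive from saturating phenotypes (for degenerate
zero-variance groups with equal means the contrast reports a
difference of 0 with p = 1).

## Numerical choices and degenerate inputs

Threshold rules are strict inequalities, with a single documented
epsilon ($10^{-9}$) on the collapsed-edge log2 cut. The LD decay fit
requires at least 50 usable pairs and rejects all-zero distances. LD
pairs need at least 4 shared non-missing calls. Empty candidate lists
yield unassigned queries, not errors; an `r2` of zero maps to an
infinite gap; a fully subtelomeric CNV load yields an infinite fold
sentinel; zero-coverage windows sit on the log2 floor. Generators are
deterministic for a fixed seed and restore the caller's RNG state.

## What the simulations do and do not show

The generators produce uniform-composition random genomes with planted
ORFs and repeat copies; they do not model read-level sequencing error,
mapping bias, GC effects, diploid heterozygosity, mitochondrial or
rDNA arrays, or real subtelomeric gene families. Passing tests
therefore demonstrate that the algorithms implement their stated rules
and recover planted truth under the stated statistical models — not
that the thresholds are optimal for any particular real data set.
Problem sizes in the tests and the acceptance script (genomes of 0.1-2
Mb, panels of 2-6 strains, 120-192 segregants, 10 or fewer seeds per
property) were chosen as the smallest instances at which the asymptotic
properties under test are comfortably resolved.
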