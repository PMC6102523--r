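---
title: "Models and methods behind burpevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind burpevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`burpevol` packages a complete evolutionary analysis of the
plant-specific BURP domain-containing gene family: member
identification, phylogeny, duplication classification and dating,
codon-model selection tests, functional-divergence estimation, and
promoter element profiling. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and
what the synthetic-data tests do and do not establish.

## Domain model and curation rules

The family is recognized by its conserved C-terminal pattern of four
cysteine–histidine dyads and a terminal tryptophan,

```
C H X10  C H X23–27  C H X23–26  C H X8  W
```

where X is any residue. `scan_burp_domain()` matches this with a
lazily quantified regular expression, so the reported hit is the
leftmost one with minimal spacers; the choice matters only for
pathological sequences with overlapping candidate matches, and making
it deterministic keeps catalogs reproducible. The anchor residues
must be literal C/H/W — the ambiguity code X is accepted only in
spacer positions, because the anchors are what define the domain.
Two additional conserved cysteines are annotated when present inside
the matched span but are not required for a hit: the defining pattern
quotes only the CH repeats and the tryptophan. A sequence without the
full pattern yields no hit; catalogs record such proteins as
domain-incomplete and exclude them.

Curation follows two rules applied in order: one isoform per locus
(the longest protein, ties broken by lexicographically smallest id so
reruns are identical), then a complete-ORF requirement — start codon,
terminal stop, no internal stop, length divisible by three — that
removes pseudogene candidates. Codons containing N are treated as
non-stop and flagged rather than rejected.

## Distances and the NJ tree

Protein distances use pairwise deletion: each pair is compared over
the columns where both rows are ungapped. This is deliberate — BURP
proteins have long, variable N-terminal regions, and complete
deletion would discard most of the alignment for every pair because
of a few ragged rows. The default correction is Poisson,
$d = -\ln(1 - p)$; the raw p-distance is available, and pairs whose
p-distance saturates are flagged. Trees come from Saitou–Nei
neighbor joining (`ape::nj`); negative branch lengths, a known NJ
artifact, are clamped to zero with a log message. Bootstrap supports
resample alignment columns with replacement and report, per internal
edge, the percentage of replicate trees containing the same
bipartition, printed as integer percents as is conventional on
published family trees.

Subfamily labels are seed-driven rather than inferred: the user (or
the simulation truth) names a few known members per subfamily, and
each leaf takes the label of the smallest proper clade containing it
and at least one seed, by majority over the seeds in that clade. The
whole tree never counts as a clade, so leaves that share no proper
clade with any seed stay `unassigned`. A rooted input tree is used
as supplied; the usual unrooted NJ output is midpoint-rooted first,
which on family trees with deep inter-subfamily backbones places the
root between subfamilies. Published subfamily cuts also lean on
motif content, which is outside this package's scope — hence seeds
are configuration, not inference.

## Codon alignments, NG86 and 4DTv

`back_translate()` threads each coding sequence through its aligned
protein (one residue → one codon, one gap → `---`), trimming a
trailing stop and verifying that every codon translates to its
aligned residue. Downstream statistics use pairwise deletion of
codon columns with a gap, an N, or an in-frame stop (the last are
also logged).

The synonymous/nonsynonymous rates are Nei–Gojobori (1986):
synonymous site counts average the per-position synonymous fractions
of the two codons (changes to stop codons are excluded from both
numerator and denominator, so S + N = 3 per codon); difference
counts average equally over all substitution pathways that avoid
stops; and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ maps proportions to
distances, with saturation flagged when the logarithm's argument is
non-positive. NG86 was chosen because the upstream database that
originally supplied Ks values for collinear anchors does not name
its estimator; fixing a simple, fully specified estimator makes the
pipeline reproducible. Its equal-pathway weighting and JC correction
are exact to the published method, which our tests verify against an
independent pathway-enumeration oracle to 1e-9.

4DTv is the proportion of transversions among third positions of
fourfold-degenerate codon columns. A column is eligible only when
both codons share their first two bases and that prefix is one of
the eight fourfold families; columns whose two codons fall in
different degeneracy families are excluded, which is standard
practice. The raw proportion lies in [0, 1] by construction — one
published tandem-pair value of 1.6 therefore cannot be a raw
proportion, and we treat that pair as saturated. An optional
Kimura-style transversion correction $-\ln(1-2Q)/2$ is available
behind a flag (off by default) since a corrected statistic is the
only way such a value can arise; the correction used originally is
unstated, so we do not guess it by default.

## Duplication classification and dating

Tandem duplicates are family genes on one chromosome separated by at
most 10 intervening annotated genes; the bound is inclusive ("no
more than 10") and intervening genes include other family members —
the alternative (excluding them) is not documented anywhere we could
anchor it, and counting all genes makes the rule a pure function of
the annotation. Gene order is by start coordinate, ties broken by
id, strand ignored.

Segmental duplicates come from collinearity anchor blocks supplied
as a file: anchors with Ks > 1.0 are discarded to avoid saturation,
blocks with fewer than three surviving anchors are dropped, and each
family pair in a surviving block is reported with the block's mean ±
SD Ks. Ages use the synonymous molecular clock $T = K_s / (2\lambda)$
with literature clock rates (soybean 6.1e-9, Brassica 1.4e-8,
Arabidopsis 1.5e-8 substitutions/site/year). Printed ages are
rounded half-up to one decimal to match the reporting convention;
the raw value is always carried alongside. One transcribed pair
(Ks = 0.151 at λ = 6.1e-9) computes to 12.4 Mya against a printed
12.3; the recomputation is reported as computed.

## GY94 site and branch-site models

The selection machinery is a Goldman–Yang (1994) codon model over
the 61 sense codons: single-base changes only, rate multipliers κ
for transitions and ω for nonsynonymous changes, target-codon
frequencies π (F3x4 by default, uniform available for controlled
tests), each class generator scaled to one expected substitution per
codon per unit branch length. Likelihoods use Felsenstein pruning
with per-node rescaling; gap and ambiguous codons contribute
all-ones partial likelihoods. The transition matrices come from the
spectral decomposition of the reversible generator, which is exact
and lets decompositions be cached across the many re-evaluations an
optimizer makes.

Site models: M0 (one ω), M3 (three free classes), M7 (beta on
(0,1), K = 10 equal-probability categories represented by their
means), M8 (M7 plus one class with ω ≥ 1). Branch lengths are
optimized once, under M0, and held fixed for every other model; κ is
likewise carried over from M0 by the orchestrator
(`fit_site_models`). This is a deliberate economy: per-model branch
length re-optimization multiplies runtime several-fold while moving
desk-scale log-likelihoods by amounts that do not affect the LRTs,
and the degrees of freedom of the standard tests (M3 vs M0: 4, M8 vs
M7: 2) count only ω-distribution parameters, so the bookkeeping is
unchanged. Each mixture fit uses three random restarts with fixed
seeds by default. The branch-site model A has the standard four
classes with foreground ω2 ≥ 1 on a user-named clade (including its
stem edge); its null fixes ω2 = 1 and the LRT uses the halved
chi-squared mixture.

Site detection offers NEB (class posteriors at the MLEs) and, for
M8, a grid Bayes empirical Bayes: NEB averaged over an 8-point grid
per parameter on (p0, p, q, ωs) — p0 on bin midpoints of (0,1), p
and q log-spaced on [0.1, 50], ωs on (1, 11) — weighted by each grid
point's marginal data likelihood under a uniform prior. The BEB
internals of the reference implementation are unpublished at this
level of detail, so the grid is documented here and NEB remains the
fallback. BEB's averaging makes it conservative on small alignments;
at the 16-taxon scale of our tests NEB calls planted ω = 5 sites at
the 0.95 tier with no false calls, while BEB posteriors shrink
toward the threshold. On alignments of a hundred-plus sequences the
two converge. Calls are reported at the >0.95 and >0.99 tiers, in
alignment coordinates and optionally in the residue numbering of a
chosen reference sequence.

## Functional divergence

Type I follows Gu (1999) in spirit: per-site substitution counts in
each cluster (Fitch parsimony minima on the cluster subtree) are
modeled as Poisson conditional on a gamma-distributed site rate;
with probability θ the two clusters draw independent rates
(divergence), with 1 − θ they share one rate, making the joint count
distribution a two-component mixture of independent negative
binomials and a bivariate negative binomial. θ, the gamma shape
(shared across clusters — separate shapes buy little at these sizes
and destabilize the fit), and the two cluster depths are estimated
by maximum likelihood; the SE comes from the observed information
via the delta method, the test against θ = 0 is a 1-df LRT, and Qk
is the per-site posterior of the divergence state.

Type II is a moment estimator on cluster consensus sequences: among
sites conserved within both clusters (majority residue frequency ≥
0.9 by default), the fraction whose consensus residues differ
radically — crossing a five-class property partition
(positive KRH / negative DE / polar STNQY / hydrophobic AVLIMFW /
special CGP) — is compared with its expectation under the background
residue frequencies, and the excess is rescaled by its maximum. The
estimate is deliberately not clamped: when radical differences fall
below background expectation the estimate is negative, matching how
such coefficients are reported in practice. The SE is a
nonparametric bootstrap over columns (200 replicates). The property
partition is configuration, because the reference tool's internal
partition is not published.

## The synthetic-data generator

`simulate_family()` produces every input the pipeline consumes, with
truth tables. Subfamily gene trees (random topologies scaled to a
crown depth of 0.25 expected substitutions/codon) hang off a star
backbone of length 0.9, which cleanly separates subfamilies the way
deep inter-subfamily branches do on the real family tree. Codon
sequences evolve under the same GY94 machinery the inference uses —
a deliberate model-consistency choice so that recovery tests test
estimation, not model mismatch. Defaults: four subfamilies of six
genes across two species, 150 codons, κ = 2, purifying ω = 0.2.

The domain core (four CH dyads at spacers 10/25/24/8 plus the
terminal W, 76 residues) is held invariant in every non-decoy
protein by fixing those nine anchor codons after simulation; spacers
evolve freely and there are no indels, so the simulated sequences
are their own alignment. Duplications are planted by evolving a
copy of a family gene along a branch calibrated so that the
*expected* NG86 Ks equals the configured depth — the calibration
inverts the exact codon-pair distribution $\pi_i P_{ij}(t)$ rather
than assuming linearity, so realized Ks is unbiased up to sampling
noise (about ±8% SD at 1000 codons, the size used by the end-to-end
age checks). The tandem copy is placed on the same chromosome with a
configurable number of intervening filler genes (default 3);
unrelated family genes are spaced 12 filler genes apart so the ≤10
rule cannot fire between non-duplicates. The segmental copy is
emitted on a separate chromosome together with an anchor block of 5
anchors whose per-anchor Ks scatter (SD 0.05) around the configured
depth, plus one saturated block and one sparse block that the
filters must reject. Decoys exercise each curation rule: proteins
with the terminal W mutated away (domain-incomplete), shorter extra
isoforms sharing a locus, and CDSs with an internal stop
(pseudogene). Promoters are 1500-bp i.i.d. backgrounds at 40% GC
with elements planted at recorded, non-overlapping positions; an
alphabet-restricted background (e.g. A/T only) makes chance matches
impossible for exact planted-vs-scanned comparisons.

What passing these tests shows: the estimators recover what the
model they assume generated. What they do not show: robustness to
indels and alignment error, to rate variation the model lacks, to
collinearity-detection errors upstream of the anchor file, or to the
motif-content signal that real subfamily definitions partly use.

## Numerical choices and scales

Optimization uses `nlminb` on transformed parameters (log for
positive quantities, logit for proportions, softmax for class
weights) with a relative tolerance of 1e-7 and clamped parameter
ranges matching common practice (κ ≤ 100, ω ≤ 50, beta shapes in
[0.005, 99]). Degenerate inputs are first-class: zero comparable
columns, all-gap columns, absent fourfold sites, and models without
an ω > 1 class all return flagged results or informative errors
rather than numbers.

The test-suite problem sizes are chosen as the smallest at which
each property is decisively testable: 3-taxon enumerations for exact
likelihood checks; 8 × 500 codons for M0 recovery; 50 replicates of
4 × 60 codons for the M7-vs-M8 null calibration; 16 × 300 codons
for planted-site detection; 1000-codon families for duplication-age
accuracy. The published full-data fits (125 sequences) are not
reproduced: their exact parameter values depend on the original
tool versions and alignment, which is why the acceptance checks pair
the printed arithmetic (ages, counts, LRT) with property-based
validation on known-truth simulations.

## Known limitations

- NG86 ignores transition/transversion bias in site counting; it is
  the documented estimator, not the most efficient one. The
  calibration of simulated Ks depths accounts for this exactly.
- Branch lengths and κ fixed at M0 estimates differ from per-model
  re-optimization; lnL differences are negligible at desk scale but
  would matter for publication-grade full-family fits.
- Grid BEB is conservative on small alignments (documented above).
- Fitch counts on multifurcating nodes are computed by sequential
  pairwise reduction, exact for binary trees.
- The type-II θ estimator is a moment method on consensus sequences,
  not a likelihood fit; it reproduces the sign and ranking behavior
  of published values but is not numerically interchangeable with
  any specific tool's output.
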