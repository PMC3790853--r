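---
title: "Detecting interlocus gene conversion in segmental duplication families"
author: "igcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interlocus gene conversion in segmental duplication families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igcscan)
```

## The problem

Segmental duplications (SDs) are blocks of genomic sequence, often tens of
kilobases long, present in multiple high-identity copies. Because the copies
are homologous, double-strand break repair can use a paralogous locus as its
template. The non-crossover outcome — interlocus gene conversion (IGC) —
copies a short tract of a donor paralog over the homologous interval of an
acceptor, without any copy-number change. IGC homogenizes paralogs,
invalidates the molecular clock for duplicated loci, and can shuttle variants
(including pathogenic ones) between copies. Its footprint is subtle: no
standard structural-variant assay sees it, and sequence-level methods must
distinguish a conversion tract from recurrent point mutation.

`igcscan` implements a complete, testable pipeline for detecting historical
IGC in families of aligned paralogs, built around two complementary
detectors, plus the supporting machinery: preprocessing filters, tree
inference, a substitution-model simulation null, track and breakpoint
estimation, genomic-context randomization tests, equilibrium rate estimation,
and a synthetic-data generator that provides ground truth for every stage.

## The quartet method

For any four paralogs there are exactly three unrooted tree topologies. A
parsimony-informative column — two distinct bases, each carried by two
sequences — supports exactly one of them. Writing the four sequences in a
fixed order (A, B, C, D):

* a **C site** (concordant) supports the quartet topology induced by the
  family tree, presumed to reflect the duplication history;
* an **R site** (reticulate) supports one of the two alternative topologies —
  the signature of sequence exchange between non-sister paralogs;
* a **B site** (bimutational) shows three or more distinct bases and can only
  arise by multiple independent mutations.

A family of *N* paralogs contributes choose(*N*, 4) quartets; the family-level
statistic is the number of columns reticulate in at least one quartet.
R sites can also arise by coincident parallel mutation, so the observed count
is compared against a no-exchange null: 100 alignments simulated along the
family tree under GTR+Γ4+I with all parameters fitted to the family by
maximum likelihood (`fit_substitution_model()`, which wraps
`phangorn::optim.pml` with empirical base frequencies). Uncertainty on the
observed side comes from 100 column bootstraps. After independent seeded
shuffles, bootstrap and simulated counts are paired and the one-sided p-value
is the fraction of pairs in which the simulated count exceeds the bootstrap
count; with 100 pairs the granularity is 0.01. Ties count toward the null.
Three safeguards bound the mutational explanation: the same test applied to B
sites (which exchange cannot create — conversion only copies existing bases),
replication on CpG-stripped alignments (CpG dinucleotides are the dominant
source of parallel substitutions), and a Wald–Wolfowitz runs test for
clustering of R sites along the alignment, exact below 20 informative sites
and normal-approximated (with continuity correction) above.

```{r quartet-demo}
spec <- family_gen_spec(n_paralogs = 6, length = 5000,
                        target_identity = 0.95, seed = 42)
g <- generate_null_family(spec)
tree <- build_nj_tree(g$fam, n_boot = 50, seed = 7)
scan_family(g$fam, tree)
```

## Track and breakpoint geometry

On quartets clean enough to read individual sites (simulation predicts fewer
than 5 B sites while more than 5 R sites are observed), maximal runs of
consecutive R sites sharing one alternative topology are conversion-track
candidates. The most probable track boundaries are the midpoints between the
outermost R sites and the flanking C sites — with only informative sites to
go on, the switch point is equally likely anywhere between two adjacent
informative sites. A terminal run of five or more R sites reaching the end of
the informative range is instead a crossover candidate, with the breakpoint
resolved to the window between the flanking C site and the first R site of
the run. The same midpoint construction tiles the alignment into topology
blocks, whose discordant fraction measures how much of the alignment sits on
a non-duplication history; three or more topology switches within a 2 kb
window are flagged as possible complex repair (MMBIR-like), with flags near
the alignment edges annotated, since edge alignment quality is usually poor.

Two geometry choices are deliberate. Runs are split when consecutive R sites
support different alternative topologies, because mixing donors in one track
would conflate distinct events; a consequence, visible in the tests, is that
crossover detection in divergent families can be interrupted by homoplasic R
sites of a third topology inside the swapped suffix, so breakpoint recovery
is most reliable above ~98% identity. Clusters separated by a single interior
C site are not merged.

## The identity-fragment (Sawyer) scan

The second detector is insensitive to tree topology: a recent conversion
leaves a tract where donor and acceptor are identical while the family is
polymorphic. Over the ordered polymorphic columns, each pair's maximal runs
of identity are candidate fragments, scored by the number of polymorphic
sites spanned. The null preserves each pair's match/mismatch multiset but
permutes the column order (one shared permutation per replicate across all
pairs, so the alignment-wide maximum is well defined). For a fragment of
score *s*, the global p-value is the fraction of permutations in which any
pair attains *s*; the pairwise p-value is the per-pair tail probability
multiplied by the number of pairs (Bonferroni). A fragment is significant
when either p-value falls below 0.05; monomorphic columns are transparent by
construction. The permutation core is compiled code
(`src/identity_scan.cpp`), making a 1246-family calibration battery at 1000
permutations a matter of minutes on one CPU.

Calibration on no-exchange families, measured by the test suite and the
acceptance script: the global route alone flags about 5% of null families,
the Bonferroni pairwise route alone about 5%, and the two sets barely
overlap, so the union rule runs at roughly 10% of families (about 1.07
significant fragments per flagged family). A scan that couples the two
criteria more tightly — as the original BLAST-style pairwise corrections in
GENECONV appear to — would sit lower. This union behavior is a property of
the scheme as defined here and is reported as such, not adjusted.

Nested SD families report the same event at the same genomic coordinates;
`deduplicate_tracks()` pools both members' genome intervals of every
significant call and merges them (`GenomicRanges::reduce`) into disjoint
unique tracks, each linked back to its supporting calls.

## Genomic context

To ask whether unique tracks avoid or prefer genomic features, each observed
track of length *l* is re-placed at random: an alignment is sampled with
probability proportional to its length (among alignments longer than *l*),
two members are chosen at random, and the start is uniform on (1, *L*−*l*).
One thousand such datasets form the null for any context statistic —
repeat-class overlap, gene/CDS/pseudogene pairings, inter- versus
intrachromosomal exchange, pericentromeric and subtelomeric zone exchange,
intrachromosomal track spacing, and PRDM9 motif content (the degenerate
13-mer CCnCCnTnnCCnC counted on both strands with overlaps allowed; note it
has 8 fixed bases, so uniform background yields 2(len−12)/4^8 expected
matches). P-values are quantile positions of the observed value in the null,
with the same code path computing observed and null statistics. Zone
definitions are explicit BED inputs rather than inherited annotations.

## Equilibrium IGC rates

If mutation (rate μ per site per generation) diversifies paralogs while
conversion homogenizes them, and each paralog is equally likely to be
converted by any of the other *n*−1 family members, divergence reaches a
steady state and the pairwise conversion rate can be read off the observed
divergence *d*:

$$c = \frac{2\mu(n-1)}{d}.$$

At the human germline rate μ = 1.2×10⁻⁸ and the 88%-identity eligibility
floor (d = 0.118, n = 4) this gives 6.1×10⁻⁷ conversions/site/generation.
`converted_site_fraction()` halves the observed-minus-expected discordant
percentage (each exchange relabels one of the two lineages involved), and
`per_generation_loads()` converts rates into expected converted and mutated
sites per generation over a surveyed duplicated length.

The consistency test for this estimator runs the forward simulator
`evolve_family_igc()` to equilibrium. Its conversion parameter is defined on
the estimator's own scale: internally each copy's site is overwritten by a
uniformly chosen donor with per-generation probability *g* = *c*/2. In
mean-field, mutation adds 2μ per generation to a pair's divergence while the
pair's two directed conversion channels each remove *g*/(*n*−1)·*d*, so at
balance *d* = μ(*n*−1)/*g* = 2μ(*n*−1)/*c*, and the estimator recovers *c*
by construction. The test verifies recovery within a factor of two across a
10× rate grid; only the ratio μ/*c* matters, so μ is scaled up (2×10⁻⁴) to
reach equilibrium in a tractable number of generations.

## The synthetic-data generator

All validation rests on `generate_null_family()` and the injection
operators, so their defaults are the study conditions, fixed once:

* profile matched to the analyzed SD dataset: 4–16 paralogs (7–8 in the
  calibration batteries), 18.8 kb alignments, 95.8% mean identity;
* GTR with a 4× transition bias, mildly AT-rich base frequencies
  (0.295/0.205/0.205/0.295), gamma shape 1 over four rate classes, 20%
  invariant sites — values typical of fitted non-coding human alignments and
  consistent with what `fit_substitution_model()` recovers from them;
* tree: a random birth-process topology whose height is scaled analytically
  (via the model's expected pairwise identity as a function of distance) to
  hit the identity target, realized within about one percentage point;
* injections operate on aligned coordinates after simulation, so truth
  intervals are exact; conversions copy donor over acceptor, crossovers swap
  suffixes (an involution); optional CpG hypermutation adds post-hoc C→T/G→A
  hits at CpG contexts so that `strip_cpg()` can be shown to remove the
  induced B-site excess.

What the generator does not emulate: indels (alignments are born gapless;
the preprocessing filters are exercised on separately constructed gapped
fixtures), realistic duplication histories with nested mosaic SDs, selection,
and biased gene conversion. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
alignment error — on real data, alignment quality is the binding constraint,
which is why the preprocessing thresholds (88% identity floor, 0.25
gap-inflation cap, 10 kb / 4-member minima, 88% bootstrap support) are kept
as strict as in the source analysis.

## Numerical and procedural choices

* Coordinates: 0-based half-open genomic intervals (BED convention), 1-based
  inclusive alignment columns in reports.
* Sequence identity for the 88% filter is computed over columns where
  neither sequence is gapped (configurable to gap-penalizing).
* CpG stripping removes both columns of every dinucleotide, unioned over
  members — the strictest reading, configurable upstream of the scan.
* Terminal trimming advances each alignment end to the first window of 20
  consecutive gap-free columns (no published rule exists; 20 columns is small
  against a 10 kb minimum length).
* Gap-inflation removal is iterative, dropping the single worst offender and
  recomputing, to avoid order dependence. Note that only a sequence whose own
  gaps destroy otherwise-alignable columns can inflate: columns gapped in all
  other members die with or without it.
* The family tree is neighbor joining on F84 distances with column-bootstrap
  supports; saturated bootstrap distances are capped rather than discarded.
  Full maximum-likelihood tree search is out of scope — quartet statistics
  depend only on topology, which NJ recovers reliably at these identities —
  but the substitution model used for the null is a full ML fit (GTR+Γ4+I)
  on the NJ topology, and the type-I batteries show the resulting test is
  calibrated (the rejection rate over 200 null families stays within the
  nominal band at α = 0.05).
* The null simulator assigns each site invariant status (probability
  `p_inv`) or a discrete-gamma category (category means), scaling rates by
  1/(1−`p_inv`) so branch lengths mean substitutions per site averaged over
  all sites — the same convention as the fitted model, verified against
  `phangorn::simSeq` and closed-form Jukes–Cantor expectations in the tests.
* Pruning of low-support nodes removes one random (seeded) leaf under the
  worst node per iteration and rebuilds, rejecting families that fall below
  four members.
* Permutation and enrichment p-values are reported at granularity 1/n
  (1/(n+1) with a "less-than" flag when the observed value is beyond every
  simulated one); ties always count toward the null.

## Problem sizes

The shipped suite and acceptance script use: 200-family batteries for the
two calibration checks (quartet type-I at 100 bootstraps/simulations each;
identity-scan null at 1000 permutations each), a 1246-family battery at 1000
permutations in the acceptance script, exhaustive oracles at 7 polymorphic
sites (5040 orderings) and up to 12-site runs-test enumerations, and 20 kb
simulator-fidelity checks. These sizes were chosen so each battery's
Monte-Carlo error is small against the tolerance it is tested at.

## Known limitations

* The quartet method cannot see exchange between sister paralogs (the
  pattern multiset is invariant), and assigns no donor/acceptor direction.
* Power falls as identity approaches 100% (few informative sites) — the
  regime where IGC is most frequent; the identity scan degrades more slowly
  but shares the limit.
* The equilibrium rate estimator inherits its steady-state and
  equal-partner assumptions; on non-equilibrium families it is an
  order-of-magnitude device.
* GENECONV's exact scoring constants and pairwise correction are not ported;
  the permutation scheme here is a documented reconstruction, and its union
  significance rule is somewhat more permissive than GENECONV's joint
  behavior on null data (see the calibration section).
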