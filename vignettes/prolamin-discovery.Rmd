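---
title: "Mining prolamin gene families from shotgun reads and ESTs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining prolamin gene families from shotgun reads and ESTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolaminr)
```

## The problem

Cereal seed storage proteins (prolamins: the gliadins and glutenins of
wheat, hordeins of barley, secalins of rye) form large families of
near-identical gene copies spread across the subgenomes of polyploid
species. Discovering a new prolamin class from survey sequence data means
solving several coupled problems at once: separating reads from gene
copies that differ by only a couple of percent, deciding which copies are
expressed and which are inactivated, classifying sequences against the
known classes, and placing the new sequences on the family tree without
being misled by their fast-evolving internal tandem repeats. `prolaminr`
implements that whole chain as testable, seeded components, together with
a synthetic-locus generator that provides ground truth for every stage.

## The gene model

A prolamin coding sequence is modelled as six ordered domains on the
protein: a signal peptide (SIG, fixed length, 19 residues for the
gamma-type classes), a short non-repetitive domain I, the repetitive
domain II, a cysteine-bearing non-repetitive domain III, a glutamine-rich
domain IV, and a C-terminal domain V carrying the final cysteines.
Domain II is a tandem array of short motifs; each class has its own motif
template in the field's standard shorthand:

| class                        | motif template  |
|------------------------------|-----------------|
| delta-gliadin / gamma-3 hordein | P-L/F-P-Q(2-3) |
| alpha-gliadin                | P-F/Y-P-Q(3-5)  |
| LMW glutenin                 | P-F-P/S-Q(2-5)  |
| gamma-type (gliadin/secalin/hordein) | P-F-(P-Q1-2)-P-Q-Q |
| omega-gliadin                | repeat-rich, cysteine-free |

The delta class carries eight conserved cysteines (six in domain III, two
in domain V); an even count means every cysteine can pair intramolecularly
and none is free for intermolecular gluten-polymer bonds, which is why
`census_cysteines()` flags odd counts as polymer candidates.

Design choices worth knowing about:

* **One canonical scaffold per class.** The non-repetitive domains of a
  class are drawn once from a class-keyed random stream, so all members of
  a class share their protein scaffold, as real class members do. The
  user-facing seed of `build_gene()` controls the synonymous codon draws
  (glutamine biased CAA:CAG at 2:1, matching the CAA bias of prolamin
  polyglutamine runs), so two same-class genes built under different seeds
  encode the same protein through DNA that differs silently by a few
  percent. Divergence beyond that is always modelled explicitly with
  `diverge()`.
* **Identifiable domain boundaries.** Proline is confined to domain II and
  cysteine to its layout positions; domain III ends on its last layout
  cysteine and domain V starts on its first. This is a deliberate
  stylization: it makes `segment_domains()` exactly invertible against the
  generator's ground truth, which in turn lets the tests distinguish
  segmentation errors from generation errors. Real prolamins have
  occasional prolines and cysteines outside these positions; on real data
  the segmentation is approximate rather than exact.
* **Domain II detection** scans for motif matches (window 15, density
  0.6, refined to motif boundaries). The window and threshold are this
  package's calibration, validated against generator ground truth.

## The simulated study systems

`scenario_hexaploid()` builds the bread-wheat situation: three orthologs
(genomes A, B, D) at ~2% pairwise divergence from a common ancestor, with
the A copy inactivated by two tandem in-frame premature stop codons, plus
a ~8%-diverged D-genome paralog that is a pseudogene carrying one in-frame
stop, a 1-bp deletion and an 11-bp deletion (both frameshifts).
`scenario_diploid()` builds the D-genome ancestor's locus (one intact gene
plus the shared pseudogene). Functional orthologs are drawn under
purifying selection: a divergence draw that would create a premature stop
is re-drawn, because an expressed storage-protein gene cannot carry one.
Defect positions sit in the non-repetitive domains at fixed offsets so
that alignment recovers them unambiguously (an indel planted inside a
polyglutamine run can slide under alignment; these cannot).

Reads emulate a filtered pyrosequencing screen: normal lengths
(mean 450, sd 80), 100 bp minimum, starts uniform over the coding region
plus 200 bp flanks, substitution errors at 0.5% per base (filtered
pyrosequencing reads are dominated by short indel errors that upstream
filtering removes; what survives is modelled as substitution noise), all
on the coding strand. ESTs are 5'- or 3'-anchored partial transcripts of
uniform length 200-700 bp, sampled with probability proportional to each
gene's expression weight; premature-stop carriers and pseudogenes have
weight zero (their message is unstable), so they never yield ESTs.

What the generator does **not** model: indel sequencing errors and
homopolymer miscalls, reverse-complement reads (real data must be
pre-oriented), chimeric library artifacts, intron structure (prolamin
genes are intronless, so this costs nothing), and expression noise beyond
multinomial sampling. Tests passing on this generator therefore show the
pipeline's logic is right under a clean substitution-only error model,
not that it is robust to every artifact of a real 454 run.

## Assembly: distinguishable read sets

`cluster_reads()` automates the manual separation of reads into
distinguishable sets. It is a greedy gapless agglomeration (layouts are
gapless because within one copy the model has substitutions only): the
longest unassigned read seeds a cluster; a read joins the cluster where
its best k-mer-seeded placement has at least 40 bp overlap at >= 98%
identity and creates no diagnostic conflict. The numeric choices:

* **Join thresholds** (98% / 40 bp) separate ~2% copy divergence from
  sub-percent noise.
* **Mismatch allowance floor (2).** On a short overlap against a depth-1
  consensus, read + seed errors (~1% combined) routinely produce two
  mismatches, which a flat 98% ratio would reject; the floor is about the
  99th percentile of that noise count. True divergence still separates
  via the ratio on long overlaps and via conflicts.
* **Diagnostic conflict.** A column where two different bases each have
  two or more supporting reads is the signature of two copies collapsed
  together. At join time two such columns are required (a single one can
  be two coincident errors); between matured consensi a single
  established discordant column blocks a merge, because majority
  consensus has already absorbed single-read errors.
* **Short extension joins must be clean.** A read extending the layout
  across an overlap shorter than 150 bp commits the cluster to new
  sequence on thin evidence, so it must match every established column
  exactly -- the two-independent-reads, 100%-match extension standard
  applied to membership.

`assemble()` then iterates (at most 5 rounds): members that no longer
meet the acceptance against their matured consensus, contradict
established columns at three or more positions, or sit with the minority
at two or more established conflict columns are evicted and re-placed;
disconnected remnants are split; clusters whose consensi agree are merged
(with a noise-aware allowance that distinguishes established from
depth-1 columns); a cluster found to be chimeric by a witness cluster --
members siding with discordant columns across a thin junction -- is split
by supporter. Finally, two-read splinters are disbanded and re-placed.
Clusters with a single supporting read are reported as unplaced, not as
contigs: a reported consensus requires multiple overlapping reads.

`build_consensus()` applies the termination rule: inside an anchor span
(an EST-like trusted region) the consensus is the per-column majority
with ties emitted as N; beyond it the consensus extends one column at a
time only while at least two reads support a single base, and the end is
marked `extension_failed` the moment that support ends.

**Known limitation.** At 5x coverage with 450 bp reads over ~1 kb gene
units, Lander-Waterman statistics put a coverage gap somewhere in a
four-copy locus in roughly one simulation in seven; a gapped copy
necessarily yields two contigs, and thin (<150 bp) junctions carrying
zero or one diagnostic site are intrinsically ambiguous. Measured over
50 seeded replicates, the hexaploid locus resolves into exactly four
contigs in about 70% of runs and the diploid into exactly two in about
90%; the per-copy separation (not the fragment count) is what the
remaining runs get wrong, almost always by one extra fragment.

## Classification and annotation

`assign_class()` replaces a database co-assembly screen with its
measurable core: local-alignment identity against one representative per
class, with a floor of 0.85 over at least 60 aligned bases and a 0.05
margin over the runner-up; queries matching two classes within the margin
stay unclassified rather than being arbitrarily assigned. EST-to-gene
counting (`count_ests()`) uses the same machinery with a 0.01 margin,
because orthologous copies differ by only ~2% and the identity gap that
separates them is necessarily small.

`detect_defects()` aligns query coding DNA to an intact reference with
the query ends free in the reference (so a truncated contig maps onto its
window without phantom terminal indels), records indels whose length is
not divisible by three as frameshifts, and translates the query codon by
codon in the reference frame -- each reference codon reads the query
bases aligned to its three positions, so the frame is restored after
every indel and downstream stops are not cascade artifacts. A stop
strictly before the reference's final five codons is premature. Status is
a pure function of the defect list: any frameshift makes a pseudogene,
stops alone make an inactivated gene.

## Repeats, trees and genomes

`tokenize_repeats()` uses one canonical dialect: a token runs from its
start through the last residue of the next maximal glutamine run (run
length >= 1; single-Q ends are flagged as variants rather than merged),
and tokens not beginning with proline are single-substitution variants.
Tokenization is lossless by construction. `align_motif_lists()` finds the
longest order-preserving matching where tokens of equal length differing
by at most one residue match; its traceback breaks ties by token string
order so the result is exactly symmetric under argument swap.

Trees are built on repeat-stripped proteins (domain II removed -- aligned
repeats are unreliable because proline/glutamine prevalence creates false
matches) with p-distances over comparable columns and neighbor joining,
rooted on an alpha-gliadin outgroup; negative branch-length estimates are
clamped to zero with a warning. Pairs with fewer than ten comparable
columns are an error rather than a distance. `assign_genome()` counts
base mismatches of a query against each candidate reference and assigns
the minimum; an in-frame 3-base gap inside a run of three or more
glutamine codons is tallied as a single polyglutamine codon event, not as
three mismatches or a generic gap (with two bases of positional slack,
because repeat context lets the aligner slide a gap off the run's codon
phase). Ties are reported as ambiguous.

## Quantification

The copy-number estimator is the crude screening arithmetic: with N
matching reads of mean length R over a target of L bases at c-fold
coverage, one copy attracts cL/R reads, so the copy total is N/(cL/R),
split across G genomes. The uncorrected L/R form is the default because
it is the form the screening arithmetic uses; the Lander-Waterman
(L+R)/R edge correction is available and always gives a smaller
estimate. The expression test pools the per-cultivar EST counts across
genomes and applies a chi-square goodness-of-fit against uniform
proportions (df = k-1); for three genomes the survival function at df = 2
is exactly exp(-x/2). Pooling across cultivars (rather than a 2x3
independence test) is the reading consistent with testing whether the
total EST distribution across genomes could be uniform by chance.

## Problem sizes used by the tests

The test-suite simulations use the study-scale systems directly: ~1 kb
gene units, 5x read sets (about 45-70 reads per locus), 17 + 14 ESTs,
seven-taxon families for the clade analyses, 20-50 seeded replicates for
the stochastic recovery rates, and exhaustive-enumeration oracles on
inputs small enough to enumerate (alignments of length <= 5, motif lists
of <= 6 tokens, trees of <= 8 leaves).
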