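---
title: "Triangulating wildlife provenance with mtDNA haplotypes"
author: "mtprov authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating wildlife provenance with mtDNA haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtprov)
```

## The problem

Maternally inherited mitochondrial DNA disperses very little in species whose
females are matrilocal: a female stays with her natal herd, so an mtDNA
haplotype is effectively tied to the geographic range of a matriline. African
elephants are the extreme case — males mediate nuclear gene flow while
females do not migrate — so mtDNA haplotypes are strongly structured by
locality even where nuclear markers are not. For wildlife forensics this is
an opportunity: a confiscated sample (ivory, hair, tissue) carrying a
haplotype known only from one locality, or from localities with strongly
different haplotype frequencies, constrains where the animal could have come
from. Because mtDNA and nuclear phylogeography are incongruent in such taxa,
the two marker systems carry close-to-independent information and can be
*triangulated*.

`mtprov` implements that analysis chain over a curated multiple sequence
alignment of mtDNA:

1. collapse aligned sequences into unique haplotypes (`collapseHaplotypes`);
2. derive and apply a hierarchical diagnostic-site key assigning sequences to
   two deep clades (`F`, forest-origin; `S`, savanna-only) and their regional
   subclades (`deriveDiagnosticKey`, `classifyDataset`);
3. quantify geographic specificity of haplotypes and haplotype sharing
   between localities (`haplotypeSpecificity`, `sharingMatrix`);
4. test pairwise differentiation with a permutation F~ST~ test
   (`fstPermutationTest`, `fstMatrix`);
5. visualize haplotype relationships as a median-joining network
   (`buildMJNetwork`);
6. combine an external nuclear assignment table with the mtDNA evidence
   (`triangulate`).

A synthetic-data module (`simConfig`, `simulateMtdna`,
`simulateNuclearAssignments`) generates matrilocal datasets with known ground
truth so every stage can be validated end to end.

## Haplotype collapsing and missing data

Two aligned sequences are the same haplotype when they agree at every
*variable* column. A column is variable when at least two states among
`A, C, G, T, -` occur in the dataset; the alignment gap is a genuine fifth
state (indels distinguish haplotypes — real curated alignments vary by a few
positions in raw length), while `N` never creates variability.

Sequences carrying `N` at variable columns need a policy, and the package
makes it explicit rather than silent:

* `strict` excludes them and reports the count;
* `resolve` (default) merges a partial sequence into a haplotype only when
  exactly **one** haplotype matches all of its non-`N` columns, and excludes
  it otherwise. This keeps partial voucher sequences (e.g. one missing a
  66-bp tail of the control region) usable without inventing resolution.

Haplotype ids are assigned deterministically (descending count, then
lexicographic sequence) so outputs diff cleanly across runs.

## The diagnostic key

The classifier is a two-level decision table over alignment columns, applied
clade-first. Its site types mirror how diagnostic polymorphisms behave in
reference panels:

* **fixed sites** carry a state present in *all* members of the group they
  label and in *no* other group — these decide assignments, and only
  contradictory fixed sites can declare a `conflict`;
* **group-specific polymorphisms** (a non-majority state whose carriers all
  belong to one group, with within-group exceptions) are emitted with
  `fixed = FALSE` and only vote, and only when no fixed site is usable; a
  strict plurality is required, ties abstain.

This asymmetry matters in a forensic setting: a shared (ancestral) state says
little about membership, so it never votes; a derived state confined to one
group votes for that group only. As a consequence, masking diagnostic columns
can only degrade an assignment to `unassigned`, never flip it to a wrong
label — a property the test suite checks both column-by-column and with 10%
random masking. Sequences are classified through reference coordinates, so a
short sequenced window (such as a 316-bp control-region segment) is handled
by treating out-of-window sites as missing.

The key is an input artifact, not a constant: `deriveDiagnosticKey` rebuilds
it from any labeled haplotype table, and it serializes to JSON/TSV.

## Geographic specificity and F~ST~

`haplotypeSpecificity` computes, per haplotype, the number of units
(localities or countries) where it was observed ("spread"), and reports the
fraction of unique haplotypes and of individuals at each spread. Spread-1
(private) haplotypes are the forensically decisive class. Rendered
percentages round half away from zero to whole percent, matching
conventional reporting; full precision is kept internally.

Pairwise differentiation uses the haplotype-frequency F~ST~ with the
haplotype-identity distance (0 same, 1 different):

$$F_{ST} = \frac{d_b - \tfrac{1}{2}\,(d_w(A)+d_w(B))}{d_b},$$

where $d_w$ averages over unordered within-unit pairs and $d_b$ over cross
pairs; $F_{ST} = 0$ when $d_b = 0$. Negative estimates are reported as
computed. Significance comes from permutation: pool the two units, re-split
at the observed sizes, and use the add-one estimator
$p = (1 + \#\{F_{ST}^{perm} \ge F_{ST}^{obs}\})/(1 + n_{perm})$, which is a
valid p-value and never exactly zero. The default is 10 000 permutations per
pair and $\alpha = 0.05$ on raw p-values; no multiple-testing correction is
applied by default (Bonferroni is a one-line change of `alpha`). A
sequence-mismatch distance variant is available behind
`distance = "sequence"`.

The permutation inner loop works on haplotype count vectors, so each
permutation is $O(n + H)$; the type-I error of the test is verified against
the 99% binomial envelope over 500 null replicates in the acceptance suite.

## The median-joining network

`buildMJNetwork` is a from-scratch implementation of the median-joining
algorithm over the variable columns: iteratively (i) compute pairwise
Hamming distances, (ii) form the $\varepsilon$-relaxed minimum spanning
network (at $\varepsilon = 0$, the union of all minimum spanning trees),
(iii) for every feasible triple — two links sharing a node, which covers
mutually connected triples through their cheapest center — propose median
vectors (per-column majority), and (iv) add, as frequency-0 nodes, the
proposals that connect their triple more cheaply than its two existing
links, keeping per pass only proposals within $\varepsilon$ of the best.
When no proposal survives, obsolete medians (removable at equal spanning
cost, lowest degree first) are pruned.

Numerical/tie decisions, all tested against an exhaustive Steiner-tree
oracle (Dreyfus–Wagner over the per-column state product space):

* three-way column ties generate up to three candidates, resolving all tied
  columns toward one parent each — a bounded subset of the full quasi-median
  set;
* feasible triples are *paths as well as triangles*. This is load-bearing:
  with triangles only, a genealogy whose unobserved ancestor sits on a
  spanning path (e.g. `AATAA`, `AAATT`, `TTAAA`) can never recover that
  ancestor, and the network misses the parsimony optimum even on
  homoplasy-free data;
* `networkCost` reports the minimum spanning cost over the final node set —
  the total mutational steps the network requires.

On tree-like (infinite-sites) data the construction is exact: across 200
random genealogical instances with up to 5 haplotypes and 6 variable sites
the network cost equals the Steiner optimum. Under heavy homoplasy
(uniform random sequences) median joining is a greedy heuristic: in our
measurements it stays within the sound bounds (never below the Steiner
optimum, never above the observed-only spanning tree) but exceeds the
optimum on roughly 2–7% of such instances, typically when the optimum needs
two cooperating Steiner points that no single triple can propose. mtDNA
control-region data sit far closer to the tree-like regime, but network
costs on fast-evolving markers should be read as upper bounds, and deep
relationships across haplogroups should not be over-interpreted from
networks of short windows.

`subcladeGroupingCheck` verifies that each subclade's haplotypes occupy a
connected patch of the network (medians attributed to their nearest labeled
neighbor), which is how a classification and a network can cross-validate
each other.

## Triangulation

`triangulate` categorizes each sample of a nuclear assignment table in
priority order: `nuclear_correct` (assignment matches the true locality),
`mtdna_precludes` (the true and assigned localities share zero haplotypes —
sequencing would have excluded the assignment), `mtdna_distinguishes`
(haplotypes are shared, but the pair's permutation F~ST~ is significant at
$\alpha$, so frequencies still separate them), else `unresolved`. The
precludes-before-distinguishes order reflects evidence strength: absence of
sharing is categorical, frequency differentiation is statistical.

`batchFrequencySupport` extends the idea to batches (confiscations often
arrive as multi-sample seizures): per candidate unit it sums log smoothed
haplotype frequencies (add-one smoothing over the unit's counts with the
global haplotype inventory as support) and flags units for which the batch
contains a private haplotype. This scoring is our construction — an
extension built on the haplotype table, not a published procedure — and is
labeled as such in its documentation.

## What the simulator emulates — and what it does not

`simConfig()` defaults encode a realistic continental voucher study: 22
localities grouped into 13 countries, 30 samples per locality (~660 total),
a 4258-column alignment on a reference frame starting at position 11 750,
two clades split into 5 + 3 subclades with 2 fixed diagnostic mutations per
internal branch, 6 observed haplotypes per locality, private-haplotype
fraction 0.72, 4 singleton mutations per haplotype (infinite-sites), a
geometric (ratio 0.5) haplotype frequency skew, and a nuclear
mis-assignment rate of 0.452 applied independently of mtDNA subclade.

Two generator choices deserve emphasis:

* **Private fraction is an inventory property.** Each pool slot creates a
  private haplotype with probability $p$, or a haplotype planted in the
  slot's locality *plus one other locality of the same subclade region*.
  Every pool haplotype receives at least one sampled carrier in each
  locality where it is planted (`haplotypesPerLocality` is *observed*
  richness, as voucher tables report it). Consequently the expected
  spread-1 haplotype fraction equals $p$ exactly, which is what makes the
  parameter-recovery tests meaningful rather than approximately hopeful.
* **Infinite sites by default.** Every mutation hits an unused column, so
  diagnostic sites are unambiguous and the genealogy is homoplasy-free;
  `infiniteSites = FALSE` switches on homoplasy for network stress testing.

The simulator does **not** emulate: coalescent genealogies within
subclades, recombination (absent in mtDNA), mutation-model heterogeneity,
sequencing error beyond uniform `N` masking, hybrid-zone localities mixing
subclades (achievable via a custom `homeSubclade`/weights layout but not a
default), or microsatellite genotypes (only assignment *outcomes* are
simulated). Passing tests on synthetic data therefore demonstrate
correctness of the statistics under the stated structural assumptions, not
robustness to every property of field data — in particular, real voucher
collections under-sample rare haplotypes, so observed spread-1 fractions in
real data are biased upward relative to the underlying inventory.

## Problem sizes and numerical conventions

The test suite exercises: collapsing against an exhaustive pairwise oracle
(≤ 12 samples × 15 columns), F~ST~ against full pair enumeration
(n ≤ 12), permutation calibration (500 replicates of 20 + 20 at 999
permutations), network-vs-Steiner equality (200 genealogical instances,
≤ 5 × ≤ 6), key recovery with and without 10% masking (~190 samples), and
specificity recovery over 20 seeds (10 localities × 5 haplotypes each); the
whole suite runs in a couple of minutes on one core. The acceptance script
runs the full default-sized study. Other conventions: reference and
alignment coordinates are 1-based inclusive; per-pair permutation sub-seeds
derive deterministically from the master seed and the ordered pair, so any
matrix cell can be recomputed in isolation; ties at any voting step abstain
rather than guess.

## Limitations

* The diagnostic key is only as good as its training panel; subclades
  missing from training cannot be assigned and fixed sites can demote to
  voting sites as panels grow.
* Median-joining is a greedy heuristic under homoplasy (bounds above).
* Haplotype-identity F~ST~ ignores sequence distance between haplotypes;
  the `distance = "sequence"` variant is provided but shares the same
  permutation framework.
* Triangulation treats the nuclear assignment table as given; it does not
  model assignment uncertainty beyond the correct/incorrect dichotomy.
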