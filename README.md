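# mtprov

Mitochondrial DNA haplotype analysis for triangulating the geographic
provenance of wildlife samples.

## Why

In matrilocal species — African elephants are the canonical case — females
stay with their natal herd, so maternally inherited mtDNA barely disperses:
haplotypes are tied to localities even where nuclear markers, spread by
males, are not. A confiscated sample (ivory, hair, tissue) carrying a
haplotype private to one locality, or drawn from populations with strongly
different haplotype frequencies, is therefore geographically constrained.
And because mtDNA and nuclear phylogeography are incongruent in such taxa,
mtDNA evidence can be *triangulated* against nuclear (microsatellite)
assignments: where nuclear markers mis-assign a sample, mtDNA can either
preclude the wrong locality (no shared haplotypes) or distinguish the pair
by haplotype frequencies (significant F<sub>ST</sub>).

## What it computes

For an aligned set of mtDNA sequences with locality/country metadata:

- **Haplotypes** — collapse sequences identical at all variable columns
  (gap `-` is a fifth state, `N` handled by an explicit `strict`/`resolve`
  policy), with deterministic ids and per-locality counts.
- **Diagnostic key** — derive a hierarchical decision table of diagnostic
  columns (clade level first, then subclade) from labeled training
  haplotypes; classify new sequences, including short windows, with
  conflicts only ever declared by contradictory *fixed* sites.
- **Geographic specificity** — fraction of haplotypes (and of individuals
  carrying them) observed in exactly *k* localities or countries; the
  locality-by-locality haplotype sharing matrix; units with private
  haplotypes.
- **Differentiation** — pairwise haplotype-frequency
  F<sub>ST</sub> = (d_b − (d_w(A)+d_w(B))/2) / d_b with
  haplotype-identity distances, permutation p-values (add-one estimator,
  default 10 000 permutations), and the all-pairs matrix with
  deterministic per-pair sub-seeds.
- **Median-joining network** — a clean-room implementation over variable
  sites (ε-relaxed minimum spanning network, median vectors from feasible
  triples, cost-equal pruning), exported to GML/DOT; plus a check that
  subclades group contiguously on the network.
- **Triangulation** — categorize every record of a nuclear assignment
  table as `nuclear_correct`, `mtdna_precludes`, `mtdna_distinguishes`, or
  `unresolved`; batch scoring by smoothed haplotype frequencies.
- **Simulation** — a matrilocal voucher-study generator with planted
  clade/subclade diagnostic sites, controlled private-haplotype fraction,
  geometric frequency skew, and nuclear mis-assignment independent of
  mtDNA structure, providing ground truth for every stage.

## Worked example

```r
library(mtprov)

fa  <- system.file("extdata", "toy_alignment.fasta", package = "mtprov")
tsv <- system.file("extdata", "toy_metadata.tsv",   package = "mtprov")
aln <- readMtAlignment(fa, tsv)
aln
#> MtAlignment: 32 sample(s), 80 columns
#>   reference unspecified:1-80
#>   localities: AA AB AC AD

tab <- collapseHaplotypes(aln)
tab
#> HaplotypeTable: 12 haplotype(s) from 32 sample(s) (0 excluded)
#>   32 variable site(s); 4 locality(ies), 2 country(ies)

sp <- haplotypeSpecificity(tab, "locality")
round(sp$hapFractionBySpread, 3)
#>    1    2
#> 0.75 0.25

sharingMatrix(tab)
#>    AA AB AC AD
#> AA  5  2  0  0
#> AB  2  3  0  0
#> AC  0  0  3  1
#> AD  0  0  1  4

fstPermutationTest(tab, "AA", "AB", nPermutations = 999, seed = 7)
#> FstResult AA vs AB: F_ST = 0.1527, p = 0.047 (999 permutations, n = 8 + 8)

net <- buildMJNetwork(tab)
net
#> HaplotypeNetwork: 12 observed + 2 median node(s), 13 edge(s), cost 32 (epsilon 0)
```

75% of this toy collection's haplotypes are private to a single locality
(it was simulated with a private fraction of 0.6 over 12 observed
haplotypes), localities only share haplotypes within their own subclade
region, and the two localities of the `AA`/`AB` region are still separable
by haplotype frequencies (F<sub>ST</sub> ≈ 0.15, permutation p = 0.047).
The network connects the 12 haplotypes with 32 mutational steps — exactly
the number of variable sites, as expected for homoplasy-free data.

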