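---
title: "Melt-curve haplotype screening and chloroplast phylogeography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melt-curve haplotype screening and chloroplast phylogeography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmhap)
```

High-resolution melt (HRM) analysis genotypes PCR products without
sequencing: as a dye-saturated amplicon is heated through its melting
transition, fluorescence falls, and both the temperature of the
fluorescence-loss peak (Tm, the maximum of $-dF/dT$) and the shape of
the curve depend on the amplicon's sequence. Clusters of similar melt
curves are therefore putative haplotypes. This package implements the
full workflow a molecular ecology lab uses to apply HRM to a non-model
organism: screening amplification quality, normalising melt curves and
calling Tm, clustering curves per population, scoring how reliably
clusters track known haplotypes, assigning verified haplotypes to
duplicate-run field samples, and carrying the resulting
population-by-haplotype table through a standard chloroplast
phylogeography analysis. A seeded simulator generates melt curves from
haplotype sequences so every stage is testable without an instrument.

## Melt-curve model and normalisation

A raw melt curve is fluorescence on a uniform temperature grid (the
protocol sweep is 65-95 °C in 0.2 °C increments). `normalize_melt()`
fits straight-line baselines in a pre-melt and a post-melt window and
rescales fluorescence between them, clipping to $[0, 1]$. The windows
default to the first and last 2 °C of the sweep; instruments that place
melt domains automatically do the equivalent, and both windows are
overridable per run for chemistries that need manual placement.

Tm is called as the argmax of the smoothed negative derivative of the
normalised curve. Smoothing is a quadratic Savitzky-Golay filter over a
1 °C window (5 points at the protocol step): wide enough to suppress
dye noise, narrow enough not to shift a logistic melt peak at this
sampling density. The grid argmax is refined by parabolic
interpolation of the three surrounding points, giving sub-grid Tm
resolution; exact ties resolve to the lower temperature so the call is
deterministic. Normalisation is idempotent to $10^{-9}$, and Tm is
invariant under affine transforms of raw fluorescence ($F \mapsto aF +
b$, $a > 0$) because the baselines absorb them — both properties are
enforced by tests.

Amplification screening reflects that only wells with sufficient PCR
product give interpretable melt curves. No quantitative threshold is
published for this step, so the default is explicit and configurable:
a well passes when its amplification plateau reaches at least 10% of
the plate's median plateau *and* a four-parameter logistic fits the
curve with positive, noise-resolvable amplitude
(`minpack.lm::nlsLM`); flat or drifting curves fail with a stated
reason.

## Clustering semantics

The instrument software that motivated this design exposes three
settings — a ΔTm threshold of 0.05 °C, a curve-shape sensitivity of
70%, and a temperature correction of 20 — but its algorithm is
proprietary. `cluster_curves()` gives those settings explicit,
documented semantics:

* **shape similarity** between two normalised curves is one minus their
  mean squared difference over the melt window
  ($[\min T_m - 2, \max T_m + 2]$ °C), after the best horizontal
  alignment of at most 20 grid increments (4 °C), which absorbs
  plate-position temperature bias; set the correction to 0 to disable
  alignment;
* two wells are **mergeable** only if their Tm gap is at most the ΔTm
  threshold *and* their shape similarity is at least the shape
  threshold;
* clustering is **agglomerative with complete linkage** on the combined
  dissimilarity $\max(\Delta T_m / \delta,\ (1 - s) / (1 - s_0))$, cut
  at 1, so *every* pair inside a cluster satisfies both conditions —
  the "share a cluster only if" reading of the settings. Merges use
  canonical tie-breaking (smallest dissimilarity, then smallest member
  ids), so the partition is independent of well input order.

Complete linkage also makes the cluster count non-increasing as the
ΔTm threshold is raised, a property the test suite checks across
seeds. Field screens cluster each population's wells separately
(`cluster_by_group()`), mirroring the well-group practice that keeps
PCR-quality differences between population extractions from
contaminating clusters; labels are local to each group.

## Discrimination scoring

Given a replicate matrix (haplotypes × clusters, cells counting
replicates), each haplotype's confusion counts use its *modal* cluster
(largest count, ties to the lowest label): TP are its replicates in
that cluster, FN its remaining replicates, FP other haplotypes'
replicates in that cluster, TN the rest. Then

$$\mathrm{Sen} = \frac{TP}{TP+FN},\qquad
  \mathrm{Spe} = \frac{TN}{TN+FP},\qquad
  \mathrm{Acc} = \frac{TP+TN}{TP+FP+TN+FN}.$$

Two haplotypes may share a modal cluster; that is precisely the
specificity-below-100 situation and no uniqueness is forced. Published
tables of this design round inconsistently (68.75 → 69 but 94.74 → 94),
so `score_discrimination()` reports exact percentages alongside
round-half-up integers, and comparisons in the test suite allow ±1
point. Where a printed `N` disagrees with the printed cluster counts,
`N` is taken as authoritative and the row is flagged
(`count_mismatch`) rather than silently repaired. The packaged metrics
table additionally flags four printed cells whose values are
arithmetically impossible given their own row (no integer confusion
matrix reproduces them); tests assert the recomputed, internally
consistent values for those cells and the printed values everywhere
else.

## Haplotype assignment and locus concatenation

Field samples run in duplicate. Every per-population cluster must be
verified by sequencing a minimum number of members (default 3, with
smaller clusters sequenced completely) before calls are issued;
requesting calls for an unverified cluster is an error that lists the
clusters needing sequencing. Samples whose duplicates agree inherit
the cluster's verified haplotype (`inferred`, or `confirmed` when the
sample itself was sequenced). Duplicates that map to *different*
verified haplotypes are flagged `conflict` and excluded from
frequency tables until an explicit sequencing override resolves them —
no majority vote, because a split duplicate is evidence of
contamination or mis-pipetting, not of a preference. Note that a
cluster that merely over-split (same verified haplotype twice) does
not conflict.

Chloroplast loci are maternally co-inherited without recombination, so
per-locus calls are concatenated (`concatenate_loci()`); haplotypes
identical at one locus are handled by collapsing that locus to its
distinct alleles (`locus_alleles()`) and labelling concatenated
combinations. For distance-based analyses, every maximal run of
alignment columns with an identical gap pattern collapses to a single
column in which the gap is a fifth character state
(`reduce_indels()`), so a 7 bp indel counts as one mutational event.

## Population-genetic analysis

For each population pair ($k = 2$), with $n_i$ samples and haplotype
frequencies $p_i$:

$$H_S = \tfrac12\sum_i \tfrac{n_i}{n_i-1}\Big(1 - \sum_a p_{ia}^2\Big),
\qquad
H_T = 1 - \sum_a \bar p_a^2 + \frac{H_S}{2\tilde n},$$

with $\tilde n$ the harmonic mean sample size. Then
$G_{ST} = (H_T - H_S)/H_T$,
$G''_{ST} = k(H_T - H_S) / \big((kH_T - H_S)(1 - H_S)\big)$, and
Jost's $D = \tfrac{k}{k-1}(H_T - H_S)/(1 - H_S)$. Three estimator
variants are exposed (`corrected`, the default above; `harmonic`,
which applies a single harmonic-mean correction after averaging; and
`raw`, no corrections); they differ by well under 0.01 on the packaged
data. Pairs of populations fixed for the same haplotype have
$H_S = H_T = 0$ and the ratio measures are undefined; they are
reported as 0 (no differentiation) by default, or `NA` on request.
Small negative estimates from the corrections are truncated to 0.
Prevosti's distance works on the indel-coded alignment: the mean over
polymorphic sites of half the $L_1$ distance between the two
populations' per-site allele frequencies, so a coded indel is one
event.

Geographic distances are haversine great circles on a sphere of mean
radius 6371.0088 km (the data cannot distinguish geodesic conventions
at this scale; a degrees-Euclidean variant exists for sensitivity
checks). `mantel_ibd()` correlates lower triangles and tests the
one-sided positive-association hypothesis by simultaneous row/column
permutation with the add-one estimator $p = (1 + \#\{r^* \ge r\}) /
(n_{perm} + 1)$ (vegan's machinery, 9,999 permutations by default); r
and $r^2$ are both reported because squared values are what
isolation-by-distance studies usually print.

**Convention sensitivity.** On the packaged eight-population table the
squared correlations are 0.51 ($G_{ST}$ vs km), 0.57 (Jost's $D$ vs
km) and 0.40 ($G_{ST}$ vs ln km), and they move by less than 0.01
across the estimator variants and the undefined-pair conventions. The
*un-squared* correlations are 0.71, 0.76 and 0.63. Reference values
reported for data of this structure (0.70-0.77 linear, 0.61-0.67 log)
fall in the range of the un-squared coefficient under every convention
examined and outside the range of any $r^2$ variant; both statistics
are therefore always reported side by side.

AMOVA partitions squared inter-haplotype distances over a
group/population/individual hierarchy via the classical
sums-of-squared-deviations decomposition. Mismatch counts on the
indel-coded alignment serve directly as squared distances (the
haplotype-data convention; `square = TRUE` squares them instead).
Negative variance components are truncated to zero hierarchically, so
percentages stay in $[0, 100]$ and sum to 100. Permutation p-values
use the standard per-level schemes: individuals among populations
($\Phi_{ST}$), individuals among populations within groups
($\Phi_{SC}$), whole populations among groups ($\Phi_{CT}$). With few
populations and a singleton group the $\Phi_{CT}$ permutation
distribution is coarse — on the packaged 8-population/4-range design
any arrangement isolating the single divergent population recreates a
large $\Phi_{CT}$, so p-values below ~0.1 are structurally
unreachable at that level; this is a property of the design, not of
the estimator.

The statistical parsimony network is a tie-preserving minimum spanning
network: candidate edges in increasing step order, keeping every edge
that joins components still separate when its step level began, never
adding edges beyond the parsimony connection limit. The 95% limit is
computed under a no-multiple-hit approximation — for $j$ mutations on
$m$ sites the probability all hit distinct sites is
$\prod_{i=1}^{j-1}(1 - i/m)$, and the limit is the largest $j$ keeping
this above 0.95 (8 steps at $m = 561$, far above the observed
distances, so the packaged network is limit-insensitive). Multi-step
edges carry their inferred intermediate nodes. Neighbour joining on a
differentiation matrix (typically Jost's $D$) uses `ape::nj()`.

## The simulator: what it emulates, and what it does not

`simulate_melt()` draws a raw melt curve as linear dye drift plus a
single two-state logistic dissociation of amplitude 1000 at the
haplotype's Tm, plus Gaussian noise; amplification curves are logistic
in cycle number, and designated failures give flat traces. A
haplotype's Tm is the empirical amplicon value of the reference
sequence, $T_m = 81.5 + 0.41\,\%GC - 675/L$, plus signed per-SNP
offsets by melt class: transitions 0.5 °C, C/A-G/T transversions
0.25 °C, the GC-neutral C/G and A/T transversions 0.05 °C, and
0.05 °C per indel base pair (deletions melt lower). Signs follow the
GC change of the derived allele. These magnitudes are simulator
parameters motivated by the qualitative class ordering observed in
melt work — transitions shift most, GC-neutral transversions least —
not measured constants, and they are plain configuration
(`snp_class_model()`).

Default noise: fluorescence noise 1 unit (0.1% of melt amplitude,
HRM-grade optics) and per-well Tm jitter 0.005 °C. The rationale is
that an instrument applying a 0.05 °C clustering threshold presupposes
Tm reproducibility well below that threshold; at these defaults the
combined Tm-call scatter is ~0.008 °C, so replicate wells cluster
together while 0.25 °C-separated variants never merge. Duplicate
splits are modelled as carry-over contamination: a sample's second
well amplifies a different haplotype, preferentially one present in
the same population plate group, consistently across loci (the
contaminated extract feeds both PCRs).

The simulator deliberately omits multi-domain melting (amplicons here
are ≤ 561 bp and modelled as one domain), heteroduplex formation (a
chloroplast is effectively haploid), spatial plate gradients beyond
the alignment allowance, and realistic instrument noise spectra.
Passing tests therefore demonstrate that the *pipeline logic* is
correct under the stated melt model — they do not certify performance
on real optics, chemistries or multi-domain amplicons.

## The packaged wild alignment is synthetic

The sequenced wild haplotypes behind the packaged population table are
archived in a public repository and are not shipped. The packaged
alignment (`wild_haplotypes_synthetic.fasta`) is a labelled synthetic
stand-in constructed from the described variation structure: five
haplotypes over 561 bp (217 + 344 across two loci), ~29% GC, five
SNPs (one transition, four class-2 transversions) plus one 7 bp
indel, radiating from the ancestral haplotype A with branch lengths
B = 1, C = 2, D = 2 (SNP + indel) and E = 1 coded steps. Among the
star-consistent allocations of the six difference columns this one
lies closest to the reported among-range AMOVA share; the recovered
percentage (72.0%) still differs from the reported 73.8% because the
true site table is unavailable, and the acceptance test allows the
5-point band appropriate for a reconstructed input. The transversions
are modelled as melt class 2 because the wild screen they emulate
achieved 100% specificity — variants that real melt analysis resolved
cannot have had negligible melt effects.

## Problem sizes and numerical choices

Tests simulate the full 142-accession × 2-locus duplicate screen (568
wells) for the end-to-end and determinism checks, 20 seeds for the
specificity property, 100 random matrices/tables for the brute-force
oracles, and 1,000 replicates for the Mantel null-uniformity check —
sizes chosen to exercise every code path at desk scale. All
randomness flows through explicit seeds; repeated runs are
byte-identical. Degenerate inputs (constant matrices, single
populations, unverified clusters, all-zero rows, inverted baselines)
raise typed errors rather than propagating NaN.
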