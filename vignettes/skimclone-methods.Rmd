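---
title: "Methods: clonal copy-number evolution from skim sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal copy-number evolution from skim sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimclone)
```

## The problem

A transmissible cancer is a single somatic cell lineage spreading between
hosts as an allograft. Sequencing hundreds of tumours at ~1x ("skim")
coverage gives almost no power at single-nucleotide resolution, but read
depth in 100-kb bins resolves copy-number variants (CNVs) of 500 kb and
above. Because every tumour descends from one founder clone, CNVs behave
like phylogenetic characters: they arise once on a branch, are inherited by
descendant tumours, occasionally revert (back mutations), and sometimes
recur independently at the same locus (fragile or selected sites).
`skimclone` implements the full path from bin counts to a cross-cohort CNV
catalogue with this character logic, plus the targeted-panel (MIP)
genotyping used for fine-grained lineage tracing.

## Depth normalisation

Counts are taken in fixed 100-kb bins (trailing partial bins are dropped).
A tumour profile is depth-normalised by its own autosomal median, then
compared bin-by-bin to the median normalised depth of a panel of normals
(PON), on log2 scale:

$$\mathrm{LogR}_j = \log_2\!\frac{t_j/\mathrm{med}_A(t)}{m_j},$$

where $m_j$ is the PON per-bin median. The source phrase for this step is
ambiguous between a global and a per-bin reference; we use per-bin PON
medians because tangent denoising presupposes per-bin reference levels, and
expose `mode = "global"` for the single-median reading. Tangent denoising
subtracts the projection of the centred tumour LogR onto the top-$k$
principal directions of the centred normal LogR matrix; bins are centred
but not variance-standardised, and $k$ defaults to $\min(20, n-1)$ (the
source does not state $k$). The projection is idempotent, so applying it
twice is a no-op — this is tested.

## Purity

Two estimators, averaged when both are available:

* **Region purity.** Over regions known to carry CN1 (LOH) or CN0 (Homdel)
  in every tumour of the lineage, the depth ratio $r$ to the genome-wide
  mean inverts to $\hat\rho = 2(1-r)$ and $\hat\rho = 1-r$ respectively;
  per-region estimates are averaged. The printed formula for this estimator
  is typographically mangled; inverting the read-depth model at CN0/CN1 is
  the only reading consistent with the generative model, and the per-region
  components are reported so any alternative pooling can be audited.
* **Panel purity.** Somatic variants at heterozygous diploid sites have
  expected VAF $\rho/2$, so $\hat\rho = 2\cdot\mathrm{median}(\mathrm{VAF})$
  over variants passing a support threshold. The threshold must scale with
  depth: at 378x and 1% cross-contamination an absent site still draws ~4
  variant reads, so the pipeline uses 10% of the median total reads rather
  than an absolute floor of 3.

Estimates outside $[0,1]$ are clipped and flagged rather than rejected.

## Segmentation

`pcf_segment()` is an exact dynamic program minimising

$$\sum_i (x_i - \mu_{s(i)})^2 + \gamma\,(\text{breakpoints}),$$

subject to a minimum segment length of `kmin` bins; `multipcf_segment()`
minimises the summed objective across a sample group with one shared
breakpoint set (penalty $\gamma\,n_{\text{samples}}$ per breakpoint).
$\gamma = 40$ in units of per-bin variance (estimated by the MAD of first
differences) and `kmin = 5` mirror common practice for this algorithm
family; the source states neither. Optimality is tested against exhaustive
enumeration on all instances up to 15 bins.

Merging then follows three rules: (1) where a single-sample and a
multi-sample segment share a provisional state and reciprocally overlap
more than 95%, the multi-sample breakpoints are retained, elsewhere the
union is kept; (2) adjacent segments merge while both a rank-sum location
test and an Ansari–Bradley dispersion test are non-significant at
$\alpha = 0.05$ (the source does not say whether both or either test must
pass; we require both — the conservative merge — and expose
`rule = "either"`); the iteration is leftmost-pair-first until a pass makes
no merge, since the source does not state an order; (3) non-diploid
segments in different samples with >95% reciprocal overlap and boundaries
within 500 kb are consolidated to the (lower, bin-aligned) median boundary,
making the result independent of sample order, and segments under 500 kb
are absorbed into the neighbour with the closer mean LogR (ties to the
left).

## Copy-number assignment

The read-depth model is
$r_s = \log_2\!\big((2(1-\rho)+\rho\,CN)/\psi\big)$ with exact inverse
$CN = (\psi 2^{r_s} - 2(1-\rho))/\rho$. A Gibbs/Metropolis sampler fits
segment means with states categorical on $0..9$,
$\rho \sim \mathrm{Beta}$ centred at the initial purity (concentration 50),
$\sigma^2$ under a weak inverse-gamma prior, and $\psi \in \{2,4\}$. The
source gives no priors, chain lengths or initialisation; ours is the
minimal hierarchy consistent with the text, with 4 chains x 5000
iterations as the design default (scaled to 2 x 1200–2000 in tests to fit
time budgets; split-$\hat R$ on $\rho$ is monitored throughout and a value
above 1.1 flags, rather than aborts, the fit).

**Ploidy is an input, not an inference.** At $\rho \approx 1$ a tetraploid
profile with doubled states is likelihood-identical to the diploid one, and
once $\sigma$ is small the extra states can even overfit noise. The
original analysis took whole-genome duplication from karyotype information;
we do the same (`psi_fixed`), and the sampling fallback carries a 0.9/0.1
prior favouring $\psi = 2$. Genuine tetraploids are still identified by odd
states at half spacing, which overwhelm the prior; this is tested.

The Poisson cross-check anchors expected counts on the mean per-bin count
$\tilde k$ of provisional-CN2 segments. As printed, $r_n = \tilde k n\rho/2$
is inconsistent at $n=2$ with $\tilde k$'s own definition unless
$\rho \approx 1$; the default `mixture` mode uses the host-dilution form
$r_n = \tilde k\,(2(1-\rho)+n\rho)/2$, with `as_printed` available. Each
segment takes $\arg\max_n \big(k\log r_n - r_n - \log\Gamma(k+1)\big)$.
Disagreements between the two models keep the Bayesian state and are
flagged; a segment whose continuous copy number lies within 0.15 of the
half-integer midpoint between the two candidates is labelled subclonal at
that half-integer (the source does not quantify its subclonality call; 0.15
is our choice, exposed in config). Adjacent same-state segments are merged
afterwards.

## The CNV catalogue

Events are grouped by identical coordinates, direction and amplitude step
(each step away from CN2 is a separate record), then split into
phylogenetically independent occurrences by minimum-change parsimony on the
clone tree with the root constrained to "absent". Among minimum-change
labellings the one with fewest origins is chosen, so an equally
parsimonious single-vs-multiple-origin tie resolves to a single origin
(fewer recurrences — the conservative direction). Occurrences beyond the
first get `R1`, `R2`, ... suffixes; carrier gaps inside an origin's subtree
are emitted as inferred back mutations (`BM`, opposite direction, state
restored to baseline); an observed opposite-direction event nested strictly
inside a parent footprint becomes `PBM` and shares the parent's id; states
beyond one step get `G/LxCNy` suffixes.

Two parsimony subtleties are worth recording. First, an event present in
the cohort ancestor but lost by two or more subtrees is *mis*-read by pure
parsimony as multiple independent gains (two origins cost two changes; one
origin plus two losses costs three). External evidence — karyotype, in the
original setting — is therefore injectable via `ancestral_footprints`,
rooting matching characters at "present" so the losses become the `BM`
records they really are. The emulated M5 marker-chromosome cassette (three
fixed intervals on chr2, chr5 and chrX, gained in the ancestor and lost as
a unit) depends on this. Second, *counting* independent cassette losses
uses irreversible (Camin–Sokal) parsimony on the per-sample loss status: a
lost chromosome cannot revert, and reversible parsimony's single-origin
tie-break would merge separate losses into one origin plus imaginary
regains.

Linkage groups collect events with identical carrier sets and direction
(one mutational event for burden purposes). Burden counts linkage groups,
0.5 for post-duplication groups; genome size is twice the callable haploid
size (2,625,758,988 bp at study scale) plus gain minus loss widths, clonal
records only. Rates come from OLS of burden on date (prediction intervals
included), an ANOVA F-test of the date-by-clade interaction, and a Huber
M-estimator for genome size; year-only dates get a seeded uniform date
within the year. The M5 enrichment test builds a losses-versus-retained-
opportunity 2x2 table (opportunity 1 per diploid, 2 per tetraploid lineage)
and computes a two-sided Fisher exact p by hypergeometric enumeration of
tables at most as probable as the observed one.

## Breakpoint statistics

A breakpoint is a boundary bin of an independent occurrence at 100-kb
resolution. Reuse requires boundaries of two or more occurrences to
coincide after excluding chromosome starts/ends and M5-component events,
and requires at least one pair of occurrences with no shared carrier
(reuse inside a single sample is a segmentation artefact, not a fragile
site). The null model circularises the genome in numeric order with X
wrapping to chromosome 1, resamples each event's start uniformly over bin
starts keeping its length (wrapping events split into arcs carrying the
same occurrence id), and recomputes the statistic over 2,000 replicates;
the empirical p uses the add-one estimator $(1+b)/(n+1)$ and can never be
zero. Whether the original analysis permuted linkage groups or individual
CNVs is unstated; we permute per event, matching the literal method text.
For the built-in overlap statistics the permutation runs vectorised in
circular coordinates — arc intersections equal the summed split-interval
intersections — and bit-for-bit equivalence with the chromosome-mapped
path is tested.

## MIP genotyping

Presence calls follow the three-tier decision tree on the expected variant
reads $E = \text{total} \times \rho \times 0.5$: at $E \ge 10$, present
above the contamination threshold (strict >), absent at $\le 2$ reads, N
between; at $5 \le E < 10$, present or N (absence cannot be called); at
$E < 5$, always N. Matrix filters run in order: variants present in any
normal, variants >50% N, samples >50% N. Probe rebalancing factors are
$\sqrt{\text{overall median}/\text{probe median}}$ with removal of probes
1.5 log10-fold above the overall median, zero-coverage probes, and probes
with >50% off-target reads.

Per-tumour contamination thresholds were reported but not derived in the
source; our stand-in takes a high quantile of variant-read counts at sites
known absent from the sample's lineage, floored at 3 reads. Two practical
notes: the false-present rate scales as $1/(n_{\text{absent}}+1)$, so the
threshold needs hundreds of known-absent sites; and at 378x with 1%
contamination the 0.95 quantile of the contaminant distribution still
leaves a ~4% upper tail, so an error rate below 1% requires a near-max
quantile (0.999 in the tests) — which is what per-tumour empirical
thresholds effectively are.

Allelic genotypes minimise $|\mathrm{VAF}_{\text{expected}} -
\mathrm{VAF}_{\text{observed}}|$ over the half-integer grid
$(T_{\text{total}}-a \mid a)$, with
$\mathrm{VAF} = (H_{Alt}(1-p)+T_{Alt}p)/(H_{Total}(1-p)+T_{Total}p)$,
$H_{Alt}=0$, $H_{Ref}=2$; ties break toward fewer alt copies. The
round-trip (noise-free VAF back to the generating genotype) is exact for
all grids up to total CN 6 and is tested exhaustively. The grid degenerates
at total CN 0 with $p=1$ (no DNA, undefined VAF); callers should not query
such sites.

## The synthetic cohort

`simulate_clone_tree()` builds a random binary tree with monophyletic clade
groups; `scatter_events()` places Poisson-count CNVs per branch with
log-normal lengths truncated at the 500-kb detection limit (the empirical
length distribution is unstated in the source beyond that limit; log-normal
with median 2 Mb is a modelling choice, parameters exposed), optional
breakpoint hotspots, per-branch M5 cassette loss (at most once per lineage)
and whole-genome duplication. `render_bin_counts()` draws Poisson counts
with expectation proportional to $2(1-\rho)+\rho\,CN_j$, rescaled so the
autosomal median matches the target depth, with an optional Gamma per-bin
bias shared across samples (overdispersion enters only through this shared
bias, matching the Poisson coverage assumption of the assignment model).
`render_mip_reads()` draws negative-binomial totals around 378x and
binomial variant reads at $\rho/2$ (present) or the contamination rate
(absent). The default genome is 6 autosomes + X totalling 60 Mb (600 bins)
so the full pipeline runs in seconds.

What the generator does **not** emulate: GC and mappability bias beyond the
shared per-bin factor, reference-assembly fragmentation (which the source
notes may inflate breakpoint hotspots), real CNV length/position
distributions, subclonal mixtures within a biopsy, and read-level
artefacts. A green end-to-end test therefore establishes that the
*inference machinery* is correct under the model's own assumptions — not
that the model captures every property of real skim data.

All stochastic operations take explicit integer seeds and restore the
global RNG state; a pipeline run is a pure function of its configuration,
verified by byte-identical manifests on re-run.

## Known limitations

* No allele-frequency (BAF) segmentation — impossible at 1x coverage.
* The Bayesian model fits segment means, not per-bin likelihoods; very
  short segments lean on the Poisson cross-check.
* Parsimony consolidation is exact on the provided tree; errors in the
  input phylogeny propagate to recurrence counts.
* `purity_from_regions` needs externally supplied region definitions; the
  synthetic pipeline uses the panel route only.
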