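---
title: "Reconstructing burial-group families from low-coverage ancient DNA, radiocarbon and isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing burial-group families from low-coverage ancient DNA, radiocarbon and isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

paleokin reconstructs family relationships within small ancient burial
groups by fusing four independent lines of evidence: autosomal kinship
statistics from very low-coverage genomes, uniparental constraints (mtDNA
lineages and chromosomal sex), Bayesian radiocarbon chronology with a
marine diet correction, and stable-isotope diet and provenance estimates.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology was genuinely open.

## The data regime

Ancient DNA from warm, humid environments is heavily degraded. The regime
this package targets is 0.01–1.2× genome coverage: at most sites at most
one read is observed, so diploid genotypes cannot be called. The standard
response, which the whole kinship stack assumes, is the *pseudohaploid*
call: at each targeted SNP one read is chosen at random and its allele is
taken to represent the individual, giving calls in {0, 2, missing}.
Deamination damage concentrates at read termini; pipelines trim several
bases from read ends before genotyping, so residual damage at genotyped
sites is small. The generator models this as an effective per-call
asymmetric miscall probability (default `damage_rate = 0.003` on top of
`base_error = 0.001`) rather than modelling position-within-read, which the
genotype-level pipeline never sees. These defaults matter: per-call error
inflates the mismatch rate of related pairs relative to the unrelated
baseline, and at a few times these rates the normalised-PMR levels would
drift visibly from their theoretical values.

## Pairwise kinship

**Mismatch rate.** For a pair (i, j) the PMR is the fraction of jointly
non-missing sites with different pseudohaploid alleles. Its expectation is
proportional to 1 − φ·2 where φ is the kinship coefficient... more usefully,
normalised by the mismatch rate b of unrelated individuals from the same
population, the expected levels are 1 (unrelated), 0.9375 (3rd degree),
0.875 (2nd), 0.75 (1st) and 0.5 (identical/twins). Classification uses the
midpoints between those levels (0.953125, 0.90625, 0.8125, 0.625). Two
guards withhold a call: fewer than `min_overlap = 2000` shared SNPs (the
value below which the study's own lowest-coverage individual becomes
unclassifiable), or an estimate within two jackknife SEs of a cutoff. The
SE comes from a leave-one-window-out weighted jackknife over 10-cM map
windows, which (unlike a binomial SE) absorbs the IBD-segment
autocorrelation along the genome.

**Baseline choice.** With only six sampled individuals who are all
relatives, the median-of-all-pairs normalisation used for larger cemeteries
would be biased; the package therefore supports an explicit baseline. In
simulations the baseline is measured on unrelated founder individuals
generated alongside the group; on real data it must be supplied from a
population sample.

**ML k-coefficients.** Per-site binomial genotype likelihoods (alt-read
probability `error`, 0.5, `1 − error` for dosages 0/1/2) are combined with
the population allele frequency into the per-site probabilities of the
observed reads under IBD sharing 0, 1 or 2, and
Σ log(k₀A + k₁B + k₂C) is maximised over the k-simplex by a coarse grid
(step 0.02 by default; 0.05 in the high-throughput paths) followed by
Nelder–Mead refinement on the softmax scale. Ties break toward larger k₀,
the conservative direction. Sites with no reads in either individual are
uninformative and dropped; frequencies are never estimated from the burial
group itself (six relatives cannot support that), they come from the
generator's truth or from the user.

**Sibling versus parent–offspring.** Both relationships are 1st degree
(φ = 1/4) but differ in IBD-state structure: parent–offspring pairs are
IBD1 everywhere, siblings mix IBD0/1/2 ≈ 1:2:1 in segments. Windowed
mismatch counts m_w ~ Binomial(n_w, rate) with state rates b, 0.75b, 0.5b
feed two models: a single-state IBD1 model and a 3-state HMM with
stationary distribution (¼, ½, ¼) and distance-dependent switching
(`switch_per_cm = 0.02`). The reported margin is the absolute
log-likelihood difference; at least 20 usable windows are required.

**Consensus.** Per-pair calls from the available methods are fused by a
confidence-weighted vote; any disagreement among determined calls is
flagged and all calls are reported — conflicts are never silently resolved.

## Runs of homozygosity

Parental relatedness leaves long autozygous segments in the offspring. On
(pseudo-)diploid genotypes the package uses a two-state HMM over windowed
heterozygote counts: the non-autozygous rate is the panel heterozygosity,
the autozygous rate a small residual (`auto_factor = 0.05` of it,
representing genotyping error), with Viterbi segmentation and
forward–backward posteriors. This is a deliberate, documented
simplification of haplotype-copying ROH callers: it requires genotypes of
reasonable quality and is validated here on synthetic diploid data, not on
0.1× pseudohaploid data. The summed length of segments above 20 cM is
compared with the inbreeding expectation F·L (L = 3545 cM by default):
bands at <10, 10–35, 35–110, 110–220 and >220 cM correspond to parents
unrelated, ~6th, ~5th (second cousins), ~4th and ≤3rd degree, with sums
within 2% of a boundary flagged and reported with both classes.

## Pedigree search

The evidence-fusion step is an explicit search over pedigrees with latent
(unsampled) individuals. Every individual chooses a mother and father among
existing nodes, none, or new latent nodes; latent nodes created as parents
subsequently choose their own parents among existing nodes, which expresses
grandparental, avuncular and half-sib paths while keeping the space finite.
Pruning uses three facts: kinship coefficients only grow as edges are
added (monotone bounds per evidence degree); a pair's kinship is final once
neither member has a pending ancestor (exact-degree check); and
parent–child birth gaps must fall in a generational window (default 12–50
years), propagated through the birth intervals by interval arithmetic. The
search core is compiled (Rcpp); candidate pedigrees are deduplicated up to
relabelling of latent nodes, and latent founders with a single child are
stripped (they cannot affect any kinship coefficient). Couples are required
to be unrelated by default (`no_inbreeding = TRUE`): consanguineous unions
are not identifiable from degree estimates and expand the space
combinatorially.

Scoring is an additive log-score: degree agreement weighted by method
confidence (penalty per degree step of disagreement), a **hard veto** when
two labelled individuals on one maternal path carry different mt lineages
(a biological impossibility, not merely unlikely), the log-probability of
each required parent–child birth gap under independent uniforms on the
birth intervals, and the sibling/parent–offspring HMM margins where
available. Ties are reported as ties.

When some individuals have no determined degree to anyone — typical for the
lowest-coverage samples — the space of compatible pedigrees is effectively
unbounded (such individuals attach almost anywhere). `run_pipeline()`
therefore uses a staged strategy: exhaustive enumeration over the
evidence-constrained core, then one-at-a-time attachment of unconstrained
individuals through an explicit move set (child, parent-slot, latent
substitution, avuncular linking, floating), keeping a score-ranked beam
(default 150) between steps. The focal archaeological question — is the
undersequenced adult a sibling or a parent of the main pair — is
additionally answered by scoring the two specific hypotheses directly,
since birth-date intervals are what separates them.

## Chronology

Calibration works on a calendar grid: the posterior of a determination is
proportional to Normal(age; μ(t), √(σ_curve(t)² + σ_lab²)) under a flat
prior, normalised by the trapezoid rule; HPD regions come from density
thresholding. Individuals with marine diet carbon need the marine
calibration curve: the effective curve is the diet-weighted mixture
μ = (1−p)·μ_T + p·(μ_M + ΔR), σ² = (1−p)²σ_T² + p²σ_M², where p is the
marine diet fraction (from the isotope stage, with uncertainty) and ΔR the
local reservoir offset, which is strongly region- and time-dependent under
variable coastal upwelling and is therefore a free parameter with a
deliberately generous Uniform(−600, 100) prior.

The family model binds tissue dates to birth + tissue-formation age,
enforces death = birth + age-at-death (ages sampled within their
osteological ranges), ties the deaths of the co-buried individuals to a
single deposition year within ±5 years (a zero-width event would
over-constrain given age uncertainty), and enforces generational gaps from
the pedigree. Sampling is Metropolis-within-Gibbs over every scalar
parameter plus a joint translation move of the deposition year and all
births, which decorrelates the strongly coupled event-time block; two
chains are run and split-R̂ is reported for the deposition year and ΔR,
with the result flagged (never suppressed) above 1.05. Marine fractions are
sampled per determination under truncated-normal priors, so their
uncertainty propagates into ΔR rather than being folded into σ. Per-date
agreement indices follow the OxCal-style ratio
A = 100·∫L(t)p_model(t)dt / ∫L(t)p_single(t)dt with the conventional 60%
threshold reported as a flag. Internally years are calendar CE (converted
to cal BP only at curve lookups); reported medians and 95% ranges follow
the decadal rounding convention of the field.

The calibration curves shipped with the simulations are synthetic: smooth
wiggly curves with a ~430 ¹⁴C-yr marine offset, deliberately non-monotonic
on short scales like real curves. They are not SHCal20/Marine20; any real
analysis must load the real `.14c` files via `load_calcurve()`.

## Isotope arithmetic

Diet %C4 is linear two-endpoint mixing on the diet scale with C3 = −26‰,
C4 = −12‰ and an enamel–diet spacing of 9.7‰:
%C4 = 100·((δ¹³C_en − 9.7) + 26)/14, clamped to [0, 100]. The published
form of this formula prints a denominator of 16; the endpoint difference
(−12) − (−26) = 14 is the reading that reproduces the published %C4 column
(exactly for the individual with the lowest C4 fraction), and is what the
package implements. Percent marine protein is two-source mixing on δ¹⁵N
between the marine-protein endpoint and a terrestrial composite (half
terrestrial-mammal protein, half a C3/C4 plant blend weighted by the
δ¹³C-derived C4 fraction; the weight is configurable because the exact
composite is under-determined), with endpoint means perturbed by their
stated SDs across Monte-Carlo draws. Estimates are clamped to [0, 100]
rather than erroring, since measurement noise can overshoot endpoints.
Provenance screening is interval-based only: the package deliberately
ships no geological model, the user supplies local ⁸⁷Sr/⁸⁶Sr and Pb ranges
and values on a range boundary are reported as indeterminate.

## The synthetic generator and what passing tests mean

The generator gene-drops a known pedigree over a panel of SNPs with Beta
allele frequencies truncated to [0.01, 0.99] and a uniform genetic map over
22 autosomes totalling 3545 cM, Poisson crossovers without interference,
founder-haplotype labels giving exact IBD truth, Poisson read depth,
symmetric sequencing error plus per-site-direction asymmetric damage, and
uniform pseudohaploid read choice. The default pedigree is a
four-generation family of six sampled and five latent individuals — a
grandfather, three full siblings (one severely undersequenced), a son of
one sibling and a daughter of another, with two mtDNA lineages — matching
the published reconstruction, with coverages named after the study's
0.01–1.2× range and the undersequenced individual tuned to the
few-thousand-SNP overlap regime. Birth years place the joint entombment at
500 CE with the grandfather dying decades earlier; radiocarbon data are
generated with ΔR = −270 and the printed marine diet fractions.

What the generator does *not* emulate: reference bias and mapping
artefacts, contamination, position-within-read damage, linkage between the
frequency panel and a real site-frequency spectrum, X-chromosomal data,
and haplotype sharing with an external reference panel. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the stated observation model — not that any particular real dataset
is free of those additional error modes.

## Problem sizes and numerical choices

The validation suite runs the kinship study at 100k SNPs × 50 replicates
(1.2× coverage, ≈49k pairwise overlap), the ROH study at 60k SNPs × 40
replicates, the chronology recovery at 20 simulated datasets × 2 chains ×
3,000 iterations, and the full pipeline at 50k SNPs — sizes chosen so the
whole suite completes comfortably on one CPU while keeping Monte-Carlo
error well below the tolerances being asserted. Grid steps: 0.02–0.05 on
the k-simplex; 5-yr calendar grid for calibration; 10-cM kinship windows;
1-cM ROH windows. Degenerate inputs (zero overlap, zero reads, sparse
windows, empty intersections) return sentinels or errors as documented
rather than numbers.

## Known limitations

Degrees beyond 3rd are not distinguishable from unrelated at these
coverages and are collapsed. The ROH caller needs diploid-quality
genotypes. The pedigree scorer treats evidence terms as independent. ΔR
and the marine fractions trade off against each other; with few human
dates the ΔR posterior is skewed and its median can sit a few decades from
the generating value even when the 95% interval covers it comfortably. The
staged pipeline search is complete over the constrained core but beam-
limited over unconstrained attachments; the exhaustive enumerator should
be used directly whenever every pair has a determined degree.
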