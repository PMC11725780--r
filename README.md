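# paleokin

Multi-evidence family reconstruction for small ancient burial groups from
low-coverage genomes, radiocarbon dates and stable isotopes.

The package addresses the situation typical of elite tomb groups: a handful
of individuals sequenced at 0.01–1.2× coverage, with pseudohaploid genotype
calls, mtDNA lineage labels, osteological sex and age-at-death estimates,
radiocarbon determinations on tissue and grave goods, and light/heavy
isotope measurements. From these it reconstructs who was related to whom,
how the family tree fits together once unsampled relatives are allowed,
when the individuals were born and died, and what they ate and where they
grew up.

## What is implemented

- **Pairwise kinship from pseudohaploid data.** The pairwise mismatch rate
  PMR(i,j) = #{mismatching shared sites}/#{shared sites} with a
  leave-one-window-out jackknife SE; normalisation by an unrelated
  baseline, so E[nPMR] = 1, 0.9375, 0.875, 0.75, 0.5 for unrelated, 3rd-,
  2nd-, 1st-degree and identical pairs; classification at the midpoint
  cutoffs with a minimum-overlap guard (default 2,000 SNPs).
- **Maximum-likelihood IBD coefficients.** Per-site binomial genotype
  likelihoods feed the likelihood
  L(k) = Σ_sites log[k₀ P(D|IBD0) + k₁ P(D|IBD1) + k₂ P(D|IBD2)] maximised
  over the k-simplex; r = k₁/2 + k₂.
- **Sibling vs parent–offspring.** A 3-state (IBD 0/1/2) HMM over windowed
  mismatch counts, against a parent–offspring model that forbids IBD0;
  decision by log-likelihood margin.
- **Chromosomal sex** from Ry = nY/(nX+nY) (XX if CI < 0.016, XY if
  CI > 0.075) and the X/autosome coverage ratio Rx.
- **Runs of homozygosity** by a two-state genotype HMM on windowed
  heterozygote counts; summed long ROH (>20 cM) mapped to
  parental-relatedness bands around F·L (e.g. ≈55 cM for offspring of
  second cousins at L = 3545 cM).
- **Outgroup-f3 / f4 statistics** with a weighted block jackknife (5-Mb
  blocks), 1/f3 distances and neighbor-joining trees.
- **Pedigree search.** Exhaustive enumeration (C++ core) of pedigrees with
  latent individuals consistent with pairwise degrees, sexes and birth-date
  intervals, plus an additive log-score over the full evidence (degrees,
  mt-lineage consistency with a hard veto on maternal-path mismatches,
  birth-gap probabilities, sibling/parent–offspring margins).
- **Bayesian chronology.** Single-date calibration on a calendar grid and a
  family model with per-individual birth/death events, a shared deposition
  event, diet-weighted terrestrial/marine curve mixing
  μ(t) = (1−p)·μ_T(t) + p·(μ_M(t)+ΔR) with a free local reservoir offset
  ΔR, Metropolis-within-Gibbs sampling and OxCal-style agreement indices.
- **Isotope diet arithmetic.** %C4 = 100·((δ¹³C_en − 9.7) + 26)/14 between
  the C3 (−26‰) and C4 (−12‰) diet endpoints; enamel–collagen spacing;
  Monte-Carlo two-source %marine mixing on δ¹⁵N; Sr/Pb provenance interval
  flags.
- **A synthetic-data generator** (pedigree gene-dropping with Poisson
  crossovers, low-coverage observation with post-trim damage, sex-chromosome
  read counts, isotope records, radiocarbon determinations) providing exact
  ground truth for every stage.

## Worked example

```r
library(paleokin)

# isotope arithmetic on the published table
t1 <- cao_isotopes()
percent_c4(t1$d13c_en[t1$id == "B3s"])      # 35
enamel_collagen_spacing(-6.4, -11.1)        # 4.7

# simulate the fixture burial group and estimate kinship
freqs <- draw_frequencies(50000, seed = 1)
gd    <- gene_drop(cao_pedigree(), freqs, seed = 2)
sim   <- simulate_reads_panel(genotypes(gd), cao_depths(), seed = 3)
panel <- panel_from_calls(sim$calls, freqs, cao_pedigree())
pairwise_mismatch_rate(panel, "B1", "B3")
#> $pmr [1] 0.249  $n_overlap [1] 20914  $pmr_se [1] 0.00415

# or run everything at once
report <- run_pipeline(seed = 1, n_snps = 50000)
print(report)
#> Consensus degrees: B1-B3 1st, B1-B1s 1st, B4-B1 2nd, ...
#> Deposition year: ~500 CE (490-530, 95%)
#> deltaR: -256 +/- 38 14C yr
```

`run_pipeline()` simulates the study design (six sampled individuals across
four generations, coverages 0.05–1.2×), estimates consensus degrees, calls
sex, searches pedigrees (reporting the B2-as-sibling versus B2-as-parent
comparison explicitly), and fits the 13-date chronological model.

A thin command-line wrapper over the same functions is installed as
`exec/paleokin.R` (`simulate`, `kinship`, `sex`, `isotopes`, `pipeline`
subcommands).

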