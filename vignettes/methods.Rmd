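---
title: "Methods: models, estimators and simulators in phagechar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and simulators in phagechar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagechar)
```

`phagechar` implements the standard quantitative assays used when a lytic
bacteriophage is characterized as a therapeutic candidate. Every estimator
is paired with a simulator that generates synthetic assay data with the
same statistical structure as the wet-lab protocol, so that each analysis
function can be validated by parameter recovery: simulate under known
ground truth, estimate, compare. This vignette records the models, the
default parameter values and the reasoning behind both.

## 1. Adsorption kinetics

Free phage attaching to a large excess of bacteria decay exponentially
(Adams' model):

$$P(t) = P_0\, e^{-kBt},$$

where $B$ is the bacterial density (cells/ml), $P_0$ the initial free
titer and $k$ the adsorption rate constant (ml/min).
`fit_adsorption_constant()` supports three estimators:

- **single_point**: $k = \ln(P_0/P(t^*)) / (B\,t^*)$ at one chosen time
  $t^*$ — the classical hand calculation.
- **regression** (default): through-origin least squares of
  $\ln(P(t)/P_0)$ against $t$, using only the pre-plateau window (samples
  before the relative drop between consecutive points falls below 5%, so
  that a residual unadsorbed fraction does not bias the slope).
- **regression with `allow_residual = TRUE`**: fits the two-parameter
  model $P/P_0 = r + (1-r)e^{-kBt}$ by nonlinear least squares
  (`minpack.lm::nlsLM`), returning both $k$ and the residual unadsorbed
  fraction $r$.

The residual fraction matters in practice: many real phages plateau at
5–15% unadsorbed, and a naive log-linear fit over the whole series then
underestimates $k$. A completely flat series returns $k = 0$ with a
warning rather than an error, since "does not adsorb" is a valid assay
outcome.

```{r adsorption}
p <- infection_params(k = 1.2e-9, r = 0.15, B = 1e8, moi = 0.001)
s <- simulate_adsorption(p, times = c(3, 5, 8, 10, 15, 20, 30, 45), noise = FALSE)
fit_adsorption_constant(s, B = 1e8, p0 = p$p0, allow_residual = TRUE)[c("k", "residual_fraction")]
```

## 2. One-step growth

A one-step growth curve samples total PFU/ml on a fixed grid (default
every 3 min to 90 min) after synchronized infection at low MOI.
`estimate_latent_period()` defines the baseline as the mean of the first
two samples and reports the **last sampling time before** the
replicate-mean titer first exceeds `rise_factor` (default 2) times the
baseline. This makes the estimate grid-quantized: for a true latent
period $L$ the estimate lies in $[L - \Delta t, L]$, which matches how
latent periods are read off plotted curves in practice.

`estimate_burst_size()` is the ratio of the plateau titer (mean of the
last three samples, with a warning if they spread by more than 20%) to
the number of infected cells. Infected cells are not observed directly;
`infected_cell_count()` computes them from the initial phage count and
the adsorbed fraction measured in a parallel adsorption assay
(single-hit product rule at low MOI, optional Poisson correction
$C(1 - e^{-m})$ for higher MOI).

```{r onestep}
pr <- phage_presets()$acibel004
os <- simulate_onestep(pr, seed = 1)
onestep_analysis(os, infected_cells = attr(os, "infected_cells"))[c("latent_period", "burst_size")]
```

### Parameter presets

`phage_presets()` ships two worked parameter sets, `acibel004`
(k = 1.2e-9 ml/min, 15% residual unadsorbed, latent 27 min, burst 125)
and `acibel007` (k = 1.7e-9, 5% residual, latent 21 min, burst 145),
both at $B = 10^8$ cells/ml and MOI 0.001. They describe two lytic
*Acinetobacter* phages — one *Myoviridae*-like, one *Podoviridae*-like —
and give the simulators realistic, distinguishable anchor points.

### Noise model and replication

Simulators add **Poisson plating noise only**: an expected titer $\mu$ is
observed as $d \cdot \mathrm{Pois}(\mu/d)$, where the tenfold dilution
$d = 10^{\max(0,\lceil \log_{10}(\mu/300)\rceil)}$ keeps expected plate
counts at or below 300, mirroring real double-agar counting. This makes
the relative error largest at low titers, exactly as on real plates.
Generators default to `n_replicates = 3` (the usual triplicate design);
estimators average replicates at each time point before any thresholding.
All generators are pure functions of `(params, seed)` via an internal
`with_seed()` that restores the caller's RNG state.

## 3. Host range and efficiency of plating

`host_range_matrix()` stores per-strain calls in a three-level ordinal
scale: `propagates` (plaque formation), `adsorbs_only` (adsorption
without productive infection), `resistant`. "Adsorbing" strains are the
union of the first two levels. `eop()` is the titer ratio test/host
strain; EOP values are attached only to `propagates` calls.
`summarize_host_range()` reports counts and percentages (rounded
half-up to one decimal, the convention used in published host-range
tables), optionally filtered by species; `joint_activity()` partitions
strains into both-active / exactly-one / both-resistant — the numbers
that justify a two-phage cocktail.

```{r hostrange}
hr <- read_host_range_csv(system.file("extdata", "synthetic_host_range.csv",
                                      package = "phagechar"))
summarize_host_range(hr, "Acibel004", species_filter = "A. baumannii")
```

## 4. Resistant-mutant frequency

`mutant_frequency()` estimates the frequency of pre-existing resistant
cells as the mean over replicate platings of colonies / cells plated,
with the sample standard deviation ($n-1$) across replicates.
`simulate_resistance()` draws colony counts as
$\mathrm{Pois}(f \cdot \text{cells})$; the estimator is unbiased under
this model and the acceptance tests verify recovery to within two
standard errors over 100 simulated triplicates.

## 5. Appelmans broth assays

`dilution_plan()` lays out a serial-dilution challenge: a phage stock
diluted $10^{-2}$ through $10^{-9}$ into tubes of fixed bacterial
density, giving an MOI ladder (`moi_for_dilution()`). The analysis
functions operate on tidy OD600 tables:

- `lysis_endpoint()`: the most extreme dilution whose replicate-mean OD
  stays below 0.1 at the readout time.
- `stability_call()`: stable lytic activity means OD < 0.1 at 48 h for
  every tube at MOI ≥ 0.01.
- `compare_conditions()`: per-dilution OD difference between a two-phage
  mixture and the better single phage, plus the fraction of dilutions at
  which the mixture is at least as lytic as both singles.

`simulate_appelmans()` generates these tables from a small mechanistic
ODE: bacteria grow logistically ($\mu = 0.9\,/h$, $K = 10^9$ cells/ml),
susceptible cells are killed at rate $a S P$ ($a = 7.2\times10^{-8}$
ml/h) and release `burst` progeny, and each phage has a pre-existing
resistant subpopulation (default frequencies $1.2\times10^{-7}$ and
$3\times10^{-6}$; the mixture only fails on doubly-resistant cells).
OD600 is cells $\times$ 1.25e-9 plus Gaussian read noise (sd 0.01). The
system is stiff when lysis crashes the population, so it is integrated
with `deSolve::lsoda` rather than a fixed-step method. Two modelling
caveats are deliberate: resistant subpopulations are continuous, not
stochastic, so by 48 h *every* condition regrows from resistant cells —
the cocktail advantage (mixture suppressing regrowth better than
singles) is therefore a 24 h readout in this model; and the growth
control carries no dilution series.

## 6. Restriction-fragment fingerprinting (f-RFLP)

`digest()` performs an in silico restriction digest (default HhaI,
`GCGC` cutting after offset 3) using `Biostrings::matchPattern`.
Circular genomes are scanned with a wrap-around window so junction sites
are found, and fragment lengths are taken modulo the genome; linear
genomes keep the two end fragments. Conservation laws (fragments sum to
the genome length; a linear digest with $c$ cuts has $c+1$ fragments)
are enforced by the test suite.

`fingerprint_similarity()` mimics gel-based band matching: bands below
5% of the largest band are dropped (gel detection floor), remaining
bands are greedily matched within ±1 bp (`tolerance_bp`; set it higher
to mimic coarser gel resolution), and similarity is the Dice
coefficient $2M/(n_a + n_b)$. `neighbor_joining()` wraps `ape::nj` on
the resulting distance matrix (distance = 1 − similarity), clamps
negative branch lengths to zero and returns Newick text. The test suite
checks `ape::nj` against an independent closed-form 3-taxon solution and
the four-point condition, so the dependency is trusted but verified.

`simulate_genomes()` plants recognition sites at controlled density in
random backgrounds and can emit near-identical "clones" (a single short
insertion away from any site), giving a known truth for the property
that clones are far more similar to each other than to unrelated
genomes.

```{r frflp}
g <- simulate_genomes(3, length = 20000,
                      clone_edits = list(list(type = "insert", length = 12)),
                      seed = 1)
fps <- lapply(g, digest)
round(fingerprint_distance_matrix(fps), 3)
```

## 7. Genome statistics and codon usage

`genome_stats()` reports length, G+C content (ambiguous `N` bases
excluded from both numerator and denominator) and, given a CDS interval
table, the coding density (union of intervals via `IRanges::reduce`, so
overlapping genes are not double counted). `codon_usage_compare()`
tabulates in-frame codon frequencies over concatenated CDS
(`Biostrings::oligonucleotideFrequency`, step 3), compares them with a
host codon-usage table, and — given a set of phage tRNA anticodons —
reports how many of the corresponding codons (anticodon
reverse-complemented) are used more frequently by the phage than by its
host, the standard argument that phage-encoded tRNAs compensate for
codon-usage mismatch.

## 8. Scale and performance

The intended problem sizes are small: titer series of 10–30 points,
host panels of tens of strains, genomes up to a few hundred kb, distance
matrices over at most dozens of fingerprints. Everything runs in well
under a second except the Appelmans ODE simulation (a few seconds for a
full 3-condition × 8-dilution × 2-timepoint design). No function holds
more than a few MB in memory.

## 9. What the synthetic data does and does not show

The simulators reproduce the *statistical* structure of each assay —
counting noise, replicate design, grid quantization, detection floors —
under simple mechanistic truths, which is exactly what is needed to
validate estimators by parameter recovery. They are not biological
models: no spatial structure, no lysis-from-without, no phenotypic
resistance, deterministic resistant subpopulations, and plating
efficiency fixed at 1. Conclusions about estimator behaviour transfer to
real data only to the extent that these simplifications hold.
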