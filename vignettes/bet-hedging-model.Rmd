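---
title: "The bet-hedging simulation model: structure, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bet-hedging simulation model: structure, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hedgesim` is a forward-time, individual-based simulation of the evolution of
**developmental instability** — the production of randomly variable offspring,
a form of diversified bet-hedging — in a metapopulation arranged along a
linear environmental gradient.

### Genetics and development

Each individual carries two classes of diploid loci (5 of each by default,
so 10 allelic values per class):

* **Deterministic loci** act additively: the genetically determined trait
  value is the sum of the 10 deterministic allelic values,
  $G_j = \sum_k N_{jk}$.
* **Instability loci** are constrained non-negative and also act additively:
  their sum is the standard deviation of a permanent developmental deviate,
  $s_j = \sum_k D_{jk} \ge 0$.

At development — once per life, immediately after birth — the phenotype is
frozen as $T_j = G_j + R_j$ with $R_j \sim \mathcal{N}(0, s_j)$. A fully
canalized genotype ($s_j = 0$) always develops exactly its genetic value.
The sum convention (rather than a mean) lets founder genotypes, whose
deterministic alleles are drawn uniformly from $\{-2,-1,0,1,2\}$, span the
full gradient of optima ($\pm 9.8$ at the defaults, versus a reachable
range of $\pm 20$). We also examined the alternative in which the
instability alleles sum to the *variance* of the deviate; it equilibrates at
visibly different levels and does not reproduce the model's reference
selection-mutation balance, so the standard-deviation convention is the
default and only convention.

Reproduction is sexual with free recombination: at every locus the offspring
receives one uniformly chosen allele from each parent's pair, loci
independent. Each allele of a newborn then mutates independently with
probability 0.1; a mutation adds a $\mathcal{N}(0, 0.1)$ deviate to the
allelic value (an infinite-alleles model). Deterministic alleles are
unbounded; instability alleles that would go negative are set to zero.
Mutation happens before development, so the deviate is drawn from the
post-mutation instability sum.

### Environment

Deme $i$'s baseline optimum is affine in the deme index and centered on
zero: adjacent demes differ by 0.4 trait units, so 50 demes span $-9.8$ to
$+9.8$. Temporal heterogeneity perturbs the optimum once per generation,
before any life-history event:

$$\theta_{it} = O_i + \tau\, x_{it}, \qquad
  x_{it} = \rho\, x_{i,t-1} + \sqrt{1-\rho^2}\, z_{it},
  \quad z_{it} \sim \mathcal{N}(0,1).$$

The latent state $x$ is a stationary AR(1) process with unit marginal
variance, so the marginal standard deviation of the optimum is exactly
$\tau$ for every autocorrelation $\rho \in (-1, 1)$; the state is
initialized with a stationary draw so there is no burn-in transient. In
*synchronized* mode a single process (one latent state, one innovation per
generation) drives every deme, so all optima shift by the same amount; in
independent mode each deme runs its own process. $\tau$ may be specified in
absolute trait units, as a percentage of the gradient range (19.6 units by
default — the scaling used for the spatial-plus-temporal sweeps), or as a
multiple of the selection width.

### Selection

Selection acts on survival. An individual with phenotype $T$ in a deme with
current optimum $\theta$ survives with probability

$$W = \exp\!\left(-\frac{(T-\theta)^2}{2\,\omega^2}\right),$$

a Gaussian function of the mismatch with standard deviation
$\omega = \texttt{width\_multiplier} \times \sigma$. The default is
$\omega = \sigma = 2$ trait units.

The width deserves a note, because the model's verbal description admits two
readings. Descriptive statements about the gradient ("about 2.5 standard
deviations of the width of the selection function end to end", "a 20-deme
displacement cuts survival by about 22%") imply a very broad survival
function — a Gaussian of the mismatch with $\omega = 8\sqrt{2}$, under which
$1 - W(8) = 1 - e^{-1/4} \approx 22\%$. But that width is dynamically
inconsistent with the model's computed results: under it we measure a
selection-mutation balance of about 2.5 (not the reference value of about
0.93), and no amount of temporal noise up to 50% of the gradient can
extinguish even a single small deme (demonstrated in the test suite),
whereas the reference results report 100%-extinction parameter cells. Under $\omega = \sigma = 2$ the simulated
balance is 0.93, the temporal-noise threshold sits at about one width, and
extinction at high noise is real. We therefore default to
$\omega = \sigma$ and keep the broad reading one keystroke away
(`selection_spec(2, width_multiplier = 4*sqrt(2))`); the survival-anchor
checks in the test suite evaluate the broad function explicitly, and all
dynamical results use the default.

### Dispersal

Two movement patterns:

* **Stepping stone.** Each individual draws a $\mathcal{N}(0, s)$
  displacement, truncated toward zero to an integer number of demes;
  movement (a nonzero displacement) therefore has probability
  $P(|\mathcal{N}(0,s)| \ge 1) = 2(1 - \Phi(1/s))$, and the kernel scale $s$
  is calibrated by inverting that relation at the nominal dispersal rate
  (`calibrate_stepping_stone()`). Movement probability and distance rise
  together: at a 74% rate the mean distance among movers is about 2.6 demes
  under exact enumeration of the truncated kernel. Truncation (rather than
  rounding) is used because rounding at 0.5 would put the mean mover
  distance near 1.6 demes at that rate, far below the model's reference
  kernel statistics. Individuals whose target lies beyond the gradient stop
  at the terminal deme (clamping, not reflection).
* **Island.** Each individual moves with the nominal probability; a mover
  picks a destination uniformly among all other demes. An end-deme mover
  travels 25 demes on average; a mid-gradient mover $625/49 \approx 12.8$.

Dispersal is cost-free and conserves the total count.

### Life cycle and regulation

Generations are non-overlapping. Each generation: the environment advances
once; then either *move first* (dispersal, selection, reproduction) or
*select first* (selection, dispersal, reproduction). Reproduction is soft
selection: within each deme that has at least one breeder, pairs are drawn
uniformly with replacement (selfing allowed), each pair leaves one
offspring, until exactly $K$ newborns exist — however many breeders survived
selection. Demes left empty produce nothing that generation but can be
recolonized by later dispersal. A deme that receives immigrants after
selection (*select first*) breeds to full $K$: local density regulation
acts on the post-dispersal breeding pool. Extinction (zero individuals
metapopulation-wide) is absorbing and flags the replicate.

## Parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `n_demes` | 50 | demes on the gradient (1 for temporal-only runs) |
| `carrying_capacity` | 100 | newborns per occupied deme (1000 for single-deme runs) |
| `n_det_loci`, `n_inst_loci` | 5, 5 | diploid loci per class |
| `gradient_steepness` | 0.4 | trait units between adjacent optima |
| `sigma` | 2 | trait units; survival-function width at the default multiplier |
| `width_multiplier` | 1 | survival Gaussian sd = `width_multiplier * sigma` |
| `dispersal_pattern`, `dispersal_rate` | stepping stone, 0 | movement model; the study explored rates 0.05–0.84 |
| `tau_mode`, `tau_value` | absolute, 0 | temporal noise sd (the sweeps scale it as 0–50% of the gradient range) |
| `rho` | 0 | temporal autocorrelation, explored over −0.75…0.75 |
| `synchronized` | FALSE | one shared temporal process for all demes |
| `life_history` | move_first | event order within a generation |
| `generations` | 10,000 | horizon; equilibrium statistics average the final 10% |
| `replicates`, `max_attempts` | 20, 60 | completed runs per cell; attempt cap when runs go extinct |
| `mutation_rate`, `mutation_sd` | 0.1, 0.1 | per-allele probability; mutational deviate sd |

Replicate attempt $a$ of sweep cell $c$ runs under seed
$(\texttt{base\_seed} + 10007\,c + a) \bmod (2^{31}-1)$; a replicate is
bit-for-bit reproducible from its config and seed.

## Summary statistics

* **Mean instability**: the population mean of the individual instability
  sd $s_j$ — the quantity that sits near 0.93 at selection-mutation balance
  under the defaults. (The realized deviates $R_j$ average to zero by
  construction, so the sd is the only population-level reading that yields a
  positive equilibrium.)
* **Mean fitness**: mean survival probability of the cohort entering
  selection, under that generation's optima.
* **Local adaptation**: the OLS slope of deme-mean *genetic* trait values on
  the baseline optima — 1 when every deme mean matches its optimum, 0 when
  demes are undifferentiated, and linear in between. A correlation variant
  is available (`method = "correlation"`); the slope is the default because
  it degrades smoothly as gene flow homogenizes the demes.
* **Replicate aggregation**: cross-replicate mean, sample (n−1) sd, and CV
  (%) of each equilibrium statistic; extinction fraction across attempts.
  Cells with no completed replicate are flagged missing, and means are taken
  over completed replicates only.

## What the generator emulates, and what it does not

All inputs are generated internally: founding genotypes, environments, and
dispersal draws follow the study conditions above. The generator emulates a
linear gradient with Gaussian stabilizing selection, stationary AR(1) noise,
and two idealized dispersal kernels. It does not emulate demographic
stochasticity in fecundity (deme refill is exact), dominance or linkage,
dispersal mortality, nonlinear gradients, or density dependence beyond the
refill rule — so passing tests demonstrate the model's internal logic, not
the behavior of any natural population.

## Numerical and scale choices

* Runs used in the test suite and the acceptance script use horizons of
  1,500–4,000 generations and 2–20 replicate seeds — scales at which the
  asserted equilibria show no remaining trend across the reporting window;
  the full 10,000-generation default remains available and unchanged.
* Equilibrium statistics average the final 10% of the horizon. The
  reference procedure verified equilibrium by absence of trend but stated no
  window; a fixed tail fraction is reproducible and trend-free at these
  horizons.
* Zero-variance Gaussian draws (canalized genotypes, `tau = 0`) are handled
  exactly: the deviate is identically zero, not a degenerate `rnorm` call.
* With dispersal rate 0 the two life histories are statistically equivalent
  (verified by a two-sample test in the suite); they are not bit-identical
  paths because no random draws are spent on the no-op dispersal stage.
* High temporal noise makes single-deme populations genuinely extinction
  prone: a shift of several survival widths can kill all 1,000 individuals
  in one generation. The experiment runner retries extinct attempts up to
  `max_attempts`, averages over completed replicates only, and reports the
  extinction fraction — cells where nothing completes are reported missing
  rather than imputed. Comparisons against such arms (e.g. the
  temporal-only control at noise equal to 37.5% of the gradient) use the
  arms that yield an equilibrium at all.

## Known limitations

* The survival-width question discussed above cannot be settled from the
  model description alone; we pin it by the computed results and expose the
  alternative. All width-dependent prose anchors are reproduced under the
  broad reading, all dynamical results under the default.
* Survivor bias: in high-extinction cells, completed replicates are the
  lucky ones that evolved high instability early; their averages are
  conditional on survival, as in the reference procedure.
* The stepping-stone kernel's printed summary statistics (mover means at
  74% and 84% rates) are approximate prose; exact enumeration of the
  truncated kernel gives 2.6 and 4.1 demes. No single Gaussian
  discretization reproduces every printed kernel statistic simultaneously,
  so they are treated as descriptive, not as targets.
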