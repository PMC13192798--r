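---
title: "Consumer-resource models of community function and global epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-resource models of community function and global epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Community-function landscapes map the composition of a microbial community
(which species, or which resources, are present) to a scalar functional
output F — total biomass, or the accumulated amount of a byproduct such as a
fermentation product. *Global epistasis* is the empirical observation that
the effect of adding one species to a background community, ΔF = F′ − F,
often depends on the background only through its function F, and does so
approximately linearly with a negative slope: low-functioning communities
gain a lot from the newcomer, high-functioning ones gain little or even
lose.

`crmge` implements a family of batch-culture consumer-resource models in
which this pattern arises mechanically from competition for a shared
resource budget, plus the machinery to measure it: exhaustive or subsampled
enumeration of background communities, paired simulations with and without a
focal species (or focal resource), ΔF-vs-F scans, ordinary least squares and
density-weighted correlation fits, and the carbon-share analytic line they
are compared against.

## Model families

All families are closed batch systems integrated to growth arrest; nothing
flows in or out.

**Single species, many carbons** (`single_species_multicarbon`). One strain
grows on m substitutable carbon sources and one essential nitrogen pool
under Liebig's law of the minimum:

$$\dot x = x\,\min\Big(\sum_i Y_{C_i} r_{C_i}\tfrac{C_i}{K_{C_i}+C_i},\;
Y_N r_N \tfrac{N}{K_N+N}\Big),\qquad
\dot C_i = -x\,r_{C_i}\tfrac{C_i}{K_{C_i}+C_i},\qquad
\dot N = -\dot x / Y_N.$$

Function is terminal biomass. Carbon drain is written independently of which
term limits growth, so under nitrogen arrest carbon continues to drain
unconverted. A corollary worth knowing when building experiments: if the
nitrogen *uptake rate* (rather than its budget) is the limiting term while
carbon is still present, carbon is wasted and the clean budget arithmetic
`F = min(x0 + Σ Y_C C_0, x0 + Y_N N_0)` does not apply. The bundled
configurations therefore give nitrogen a fast uptake rate so that only its
budget ever binds — which is the regime the resource-landscape experiments
are about.

**Competitive community** (`competitive`). N strains share one carbon pool
with a common half-saturation constant KM:

$$\dot x_i = \mu_i \tfrac{C}{K_M+C} x_i,\qquad
\dot C = -\sum_i \tfrac{1}{Y_i}\mu_i \tfrac{C}{K_M+C} x_i,\qquad
\dot B = \sum_i \beta_i \tfrac{1}{Y_i}\mu_i \tfrac{C}{K_M+C} x_i.$$

β_i is the byproduct yield *per unit carbon consumed*; function is B(∞). A
variant in which the byproduct flux is instead scaled by the growth yield
(`eq6_literal = TRUE`, flux β_i Y_i ẋ_i) is kept for comparison; it breaks
the identity F = C0·⟨β⟩ that makes the analytic line exact in the symmetric
case, which is why it is not the default.

**Cross-feeding cascade** (`crossfeeding`). Producers consume the primary
carbon C and leak a fraction pp of their consumption into a cross-fed pool
Ccf; consumers grow on Ccf; everyone makes B. With producer consumption rate
$q_p = \mu_p \frac{C}{K_M+C} x_p / ((1-p_p) Y_p)$ (so the biomass yield
applies to retained carbon):

$$\dot C = -\textstyle\sum_p q_p,\qquad
\dot C_{cf} = \textstyle\sum_p p_p q_p
  - \sum_k \tfrac{1}{Y_k}\mu_k \tfrac{C_{cf}}{K_M+C_{cf}} x_k.$$

The stoichiometry of B deserves a paragraph, because it is a genuine design
choice. Two conventions are defensible: β_p counts a producer's *total*
consumed carbon (leaked fraction included), or only the *retained* fraction
(1−pp)·q_p that is routed through growth. The package defaults to the
retained convention, for two reasons. First, uniformity: under it the
byproduct law is the same for every guild, $\dot B = \beta_i \dot x_i /
Y_i$ — byproduct tracks the carbon a strain actually metabolizes into
biomass, and a producer is not credited for carbon it merely passed
downstream (where the consumer is credited for it again). Second, behaviour:
it is the convention under which the guild asymmetry of the leakage sweep
(next section) emerges — producer-focal scans lose linearity as leakage
grows while consumer-focal scans gain it — because the producers'
contribution to the variance of F scales as (1−pp) and the consumers' as pp.
Under the total-carbon convention the producer contribution is
leakage-independent and the asymmetry inverts. The total-carbon variant
remains available as `producer_beta_total = TRUE`.

**Niche partitioning** (`niche_partitioned`): two guilds on two disjoint
carbon pools, one shared B. **Facilitation** (`facilitation`): a present
strain multiplies the β of named target strains
(`facilitation_targets = list(list(id=, multiplier=))`, multiplicative over
facilitators, applied only when both are present).

## Integration to growth arrest

`integrate_to_depletion()` uses `deSolve::lsodar` with derivatives and the
stopping condition compiled in C; the final approach to depletion is stiff
(fast consumers, vanishing resource), which is why a stiff-capable solver is
part of the contract. Integration halts at the root of

> max over species of the per-capita growth rate < `stop_thr` **and**
> total resource-consumption rate < `stop_thr` × C0.

The second clause matters when biomass has plateaued under nitrogen arrest
but carbon still drains. `stop_thr` defaults to 1e-9, chosen so that the
residual carbon at arrest, roughly K·`stop_thr`/μ, is orders of magnitude
below the solver tolerances times the budget for any reasonable (μ, K).
Defaults `rel_tol = 1e-8`, `abs_tol = 1e-10`. Roundoff undershoots below
zero are clipped if smaller than 1e3·`abs_tol`, otherwise they are an error.
A model with nothing able to grow at t = 0 (no species, or no usable
resource) terminates immediately as `growth_arrested`; a run that reaches
`t_max` (default 1e4) without arrest is flagged `max_time` and
`community_function()` refuses it unless overridden.

Two closed-form facts are used by the test suite as independent oracles and
are worth recording. In any single shared pool with a common K, every
strain's biomass is $x_i(t) = x_i(0)e^{\mu_i \tau(t)}$ with the common
$\tau = \int C/(K+C)\,dt$, and total consumption must equal the budget at
depletion — a one-dimensional root find therefore yields the exact terminal
state without integrating. A consequence: terminal states (and hence every
scan statistic) are independent of KM, which only sets the approach speed.
The cascade factorizes the same way because all the cross-fed carbon
(exactly pp·C0 when a producer is present) is eventually consumed whenever
a consumer is present.

## Scans, fits, and the analytic line

`enumerate_backgrounds()` enumerates all 2^k subsets of the non-focal pool
(including the empty set) or draws distinct subsets uniformly under a seed;
the default switches to subsampling above pool size 11. Absent species are
removed from the state vector entirely, so there is no invasion from rare.
`scan_focal_species()` and `scan_focal_carbon()` run the paired simulations
and return the (background, F, F′, ΔF) table.

The analytic line comes from a carbon-share argument: a background S
converts the budget at its average efficiency, F = C0·⟨β⟩_S (⟨β⟩_S is the
*consumption-weighted* mean, which coincides with the arithmetic mean only
under symmetry). An added species j claiming a fraction α_j of the pie
contributes α_j C0 β_j and deprives the background of α_j F, giving

$$\Delta F \approx \alpha_j C_0 \beta_j - \alpha_j F .$$

`estimate_alpha()` measures α_j by simulation as the focal's consumed carbon
over C0; the reference background defaults to the full non-focal pool
(α_j is focal-specific in the approximation, and the full background is the
most conservative single choice; per-background α can be obtained by calling
it per subset). Under exchange symmetry the relation is exact pointwise with
α = 1/(|S|+1) — this is tested, not assumed. One subtlety: when backgrounds
of different sizes are pooled into one regression, the OLS slope is a
variance-weighted mixture of −1/(s+1) over sizes s and is therefore steeper
than −α on the full background even for identical growth rates; with
growth-rate heterogeneity the measured slopes steepen further and the
intercepts rise, which is the bias direction the ensemble experiment
quantifies.

`weighted_correlation()` implements the density-weighted correlation ρ_w as
a weighted Pearson correlation with per-point weights 1/(count of points in
the point's F-bin), over `n_bins = 20` equal-width bins spanning the
observed F range. This is an interpretation, flagged as such: subset
enumeration piles binomially many backgrounds at mid-range F, and inverse
density weighting stops that bulge from dominating. The scheme is
deliberately easy to swap (`n_bins = 1` recovers the unweighted Pearson
correlation); bin-mean variants were evaluated during development and gave
materially identical guild averages. Degenerate clouds (no variance in F or
ΔF) return a flagged `NA`, never a silent 0.

## Random-community ensembles

`ensemble_config()` fixes the sampling law; every downstream result is a
pure function of the config, including its seed (background subsets are also
derived from it, and are shared across the leakage grid so sweeps are paired
in pp). Defaults: growth rates uniform on `mu_center`·(1 ± `mu_spread`)
with spread 0.3 — heterogeneous enough that the invariant-allocation
assumption behind the analytic line visibly breaks, small enough that slow
strains still consume; byproduct yields uniform on [0.05, 0.95] (essentially
the full physical range, with per-guild overrides available); fixed
Y = 0.5, x0 = 1e-3·C0, KM = 0.1·C0, C0 = 10. KM and C0 are scale-setting
only: terminal states do not depend on KM, and all statistics are invariant
to the C0 scale.

`slope_intercept_experiment()` (competitive) emits measured and analytic
slope/intercept per focal and replicate. `leakage_sweep()` (cross-feeding)
computes ρ_w per focal, averages within producer and consumer guilds per
replicate, then reports mean ± sd across replicates, excluding (and
counting) degenerate focals.

```{r}
library(crmge)
cfg <- ensemble_config(n_species = 15, n_producers = 5, n_communities = 10,
                       leakage_grid = c(0.1, 0.4, 0.8),
                       background_mode = "subsample", n_sample = 200,
                       seed = 101)
sw <- leakage_sweep(cfg)
sw$summary
plot_sweep(sw)
```

## What the sweep does and does not reproduce

With the retained-carbon convention the sweep reproduces the qualitative
asymmetry: producer-guild ρ_w rises (toward ≈ −0.6) as leakage grows while
at pp = 0.1 it sits near −0.9, and the consumer guild is the more linear one
at high leakage. Two structural features of batch-to-depletion bookkeeping
cap how far this can go, and they are worth understanding before comparing
against other implementations of this idea:

* every background containing at least one producer converts *all* of C0,
  so the cross-fed total is exactly pp·C0 regardless of how many producers
  are present — there is no gradual saturation of the cross-fed pool with
  producer count;
* a consumer focal's ΔF has amplitude proportional to pp while F retains
  producer-side variance, so consumer-guild ρ_w necessarily tends to 0 as
  pp → 0; and backgrounds with no producers contribute an exactly-(0, 0)
  cluster that the inverse-density weighting emphasizes.

Consequently consumer-guild ρ_w peaks around −0.65 at pp = 0.8 here rather
than −0.9, and is near 0 at low leakage. Reported observations of stronger
consumer-side linearity across all leakage levels would require additional
structure (for example, incomplete primary-carbon depletion, producer
re-uptake of the cross-fed metabolite, or conditioning backgrounds on both
guilds being present), none of which the batch model above contains. The
parameter screen behind this statement (growth-rate spread, inocula,
guild-specific β ranges, alternative ρ_w weightings) is reproduced by the
acceptance checks at study scale.

## What the generator emulates, and what it does not

The synthetic communities emulate phenotype variation of co-cultured strains
competing for one defined substrate in batch: uniform, bounded variation in
maximal growth rate and byproduct yield, equal inocula, shared uptake
affinity. Real communities violate most of this in ways that matter
quantitatively: lag phases, death and maintenance costs, pH and inhibition
feedbacks, many substrates, measurement noise on F, and inocula spanning
orders of magnitude. Passing tests therefore demonstrate the internal
consistency of the resource-constraint mechanism at these scales, not that
any particular real community will show a given slope or ρ_w.

## Problem sizes and numerical tolerances used in the checks

The test suite runs the resource-holdout experiment exhaustively (2^9
backgrounds), the heterogeneity experiment at 14 replicates × 10 species
with 128 subsampled backgrounds per focal, and the leakage sweep at 10
replicates × 15 species (5 producers) with 200 subsampled backgrounds per
focal at pp ∈ {0.1, 0.8} — sizes at which the whole suite completes in a
few minutes on one core while keeping the guild means' replicate standard
errors near 0.01. Identity-style checks (mass balance, budget caps,
symmetry exactness) run at `rel_tol = 1e-10`, `abs_tol = 1e-12` and assert
absolute deviations below 1e-6; statistical checks use the solver defaults.

## Known limitations

Batch-to-depletion only: no chemostat or serial-dilution regimes, no lag or
death terms, no stochastic dynamics, no evolution, no spatial structure.
Single shared KM per model by default (per-species K is accepted but the
closed-form KM-independence then no longer holds exactly for mixed-K pools
sharing a resource). The cross-feeding stoichiometry is one defensible
convention with a switch for its main alternative; conclusions about guild
asymmetries in ρ_w are sensitive to that choice, as discussed above.
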