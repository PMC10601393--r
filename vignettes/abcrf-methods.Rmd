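---
title: "Coalescent ABC with random forests for microsatellites: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent ABC with random forests for microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the defaults and why they were
chosen, and what the simulation-based tests do and do not establish about
real data.

## The inference problem

The package addresses a recurrent phylogeographic design: several
population samples of a long-lived species genotyped at a small panel of
nuclear microsatellites (SSRs), a set of competing hypotheses about how the
sampled lineages diverged and admixed, and two questions — *which history*
and *when*. Likelihoods are intractable for such models, so inference is
simulation-based: approximate Bayesian computation in which random forests
replace the classical rejection step (ABC-RF). The shipped study design
(`scenarios_caucasus()`) has five lineages sampled at 62, 72, 65, 40 and 27
diploid individuals and 9 SSR loci, with eight candidate scenarios; two of
them contain an admixture event that creates the third lineage from the
second and fourth.

## Coalescent model

Backward in time, the sampled gene copies (two per diploid) coalesce within
their population at rate $k(k-1)/2 \cdot 1/(2N_e)$ per generation for $k$
active copies — the continuous-time approximation, appropriate because all
effective sizes in the priors are at least 100. Population structure
changes only at instantaneous events: at a split the derived population's
copies move into the ancestor (a multifurcating split is a single event
with several derived lineages, which keeps event times strictly ordered
while allowing the three-way basal split the design calls for); at an
admixture each copy of the target joins `source1` with probability $r_a$,
else `source2`. Constant sizes, no migration and no bottlenecks: exactly
the class of histories the scenario set spans, and deliberately nothing
more.

Mutation is the generalized stepwise model (GSM). Mutations fall on each
branch as a Poisson process with the per-locus rate $\mu_\ell$; a mutation
changes the repeat count by $\pm s$ with geometric step
$\Pr(s=k) = (1-P_\ell)P_\ell^{k-1}$ and equiprobable sign. $P_\ell = 0$ is
the strict stepwise model — the package treats the SMM as the GSM's
boundary case, since the study protocol names the stepwise model *with* an
estimated geometric parameter $P$. Allele states live in a window of 40
contiguous repeat counts centred on the ancestral state, with reflecting
boundaries; a bounded window is what keeps the Garza–Williamson ratio
informative, and 40 states is the common ABC convention. The per-locus
panel (`default_loci()`) uses an ancestral repeat count of 30 so simulated
alleles stay well inside 3-digit Genepop codes.

## Priors

Scalar parameters are uniform: $N_e \sim U(100,\,30\,000)$ per lineage,
event times $\sim U(10,\,10\,000)$ generations with the ordering
constraints each topology requires (enforced by rejection, which leaves
unconstrained marginals untouched), admixture $r_a \sim U(0.001, 0.999)$,
mean mutation rate $\mu \sim U(10^{-5}, 10^{-3})$ per locus per generation
and mean geometric parameter $P \sim U(0.1, 0.3)$. These ranges span the
posterior medians the design is meant to recover (effective sizes of a few
thousand to ~15,000; times of hundreds to thousands of generations).
Per-locus rates are gamma with shape 2 around the drawn means — a common
ABC convention for mutational heterogeneity — with $P_\ell$ truncated at
0.95 so the step distribution keeps a finite mean. Each draw's rejection
loop is capped at $10^6$ attempts so an unsatisfiable constraint set fails
loudly rather than hanging.

The topologies of scenarios 5–8 are the package's own design choices
(four distinct divergence hierarchies, with scenario 8 rooting all
Caucasian lineages in lineage IV and the European lineage always the
deepest split); the configuration format makes every part of this —
lineages, events, constraints, priors, per-scenario effective-size
rebinding — overridable in plain text.

## Summary statistics

`summarize_dataset()` computes the classic DIYABC microsatellite battery,
averaged over loci: per population NAL, HET (unbiased genic diversity),
VAR (allele-size variance) and MGW (Garza–Williamson $k/(R+1)$); per pair
the pooled NAL2/HET2/VAR2, the Weir–Cockerham $F_{ST}$ (ratio of variance
components summed over loci and alleles), the shared-allele distance DAS
(mean over inter-population individual pairs of one minus the proportion
of shared alleles), $(\delta\mu)^2$, and the two directed mean assignment
log-likelihoods LIK (unseen alleles floored at $1/(2n_Y + k)$ so
log-likelihoods stay finite); per triple the maximum-likelihood admixture
coefficient AML, maximized over the multinomial mixture likelihood summed
across loci by golden-section search (tolerance $10^{-4}$; identical
parents are flagged and reported as 0.5). For five populations this is
exactly $4\cdot5 + 6\cdot10 + 20 + 30 = 130$ features. DAS is defined over
individual pairs, so it is zero only when every individual matches — not
for duplicated populations, whose distinct individuals still differ.

Missing genotypes are deleted locus-wise; per-locus averages weight loci
equally. A population pair with no allelic variation at any locus yields an
undefined $F_{ST}$ ratio; the feature is reported as 0 (no variation
carries no differentiation signal), which keeps the feature matrix finite
for forest training — the relevant edge case is low-$\mu$, low-$N_e$
corners of the prior.

## Forest stages

The reference table (`build_reference_table()`) pairs each scenario label
with a prior draw and its 130 statistics; rows are shuffled with a recorded
permutation and every row has its own deterministic RNG substream, so the
table is reproducible from one integer seed and unchanged rows do not move
when the design grows. Linear discriminant axes of the statistics on the
scenario label ($k-1$ axes for $k$ scenarios, near-constant columns dropped
with a warning) are appended and the projection is stored, so an observed
dataset is projected with exactly the axes the forest saw.

Scenario choice trains a `ranger` classification forest with the DIYABC-RF
defaults: `mtry = floor(sqrt(p))`, unlimited depth, bootstrap resampling;
only the tree count is surfaced (default 2000, the point at which vote
stability was judged sufficient in this literature). The out-of-bag
misclassification rate is the prior error; the posterior probability of the
selected scenario is $1 - \hat E[\text{error} \mid \text{observed}]$ from a
second regression forest fitted to the OOB misclassification indicators —
the published ABC-RF estimator. Vote ties break to the lowest scenario id
and are flagged.

Parameter estimation uses quantile regression forests on the statistics
plus the first five PLS components of the statistics against the target
parameter (computed per parameter, not shared). A held-out test set
(default 1000 rows) supplies the accuracy metrics: global NMAE
($\text{mean}(|\hat\theta - \theta|/\theta)$ with the forest median as
$\hat\theta$), coverage of the 90% interval, and a local NMAE in which test
rows are weighted by how often they share a terminal node with the observed
dataset. Point estimates are the forest mean and weighted median; the 90%
interval is the (q05, q95) pair of weighted quantiles, so
q05 ≤ median ≤ q95 holds by construction.

## Diversity layer

The classical statistics mirror the toolchain this field uses on real
genotype tables. $uH_e$ is Nei's unbiased estimator; allelic richness is
hypergeometric rarefaction at `g` gene copies (default: the data minimum);
F-statistics are Weir–Cockerham variance components with multi-locus
ratios of summed components. The null-allele model is fitted by EM per
population and locus: apparent homozygotes mix true homozygotes with
heterozygotes carrying one null, and blanks are null homozygotes by
default (`blanks = "ignore"` treats them as genotyping failures instead —
the full Bayesian inbreeding machinery with a separate failure rate is out
of scope). Because the EM only approaches a boundary maximum at rate
$r_{k+1} \approx r_k(1-r_k)$, a final likelihood comparison against the
$r = 0$ boundary snaps no-excess data to exactly zero. The ENA-corrected
$F^*_{ST}$ treats the null as a real allelic state — EM-corrected visible
frequencies, blanks restored to the sample as null homozygotes, expected
a/null heterozygotes restored to the visible alleles' heterozygote counts —
and then excludes the null class from the variance-component sums. At zero
null frequency every adjustment vanishes, so $F^*_{ST}$ equals the
uncorrected estimator exactly; under a drifting-but-invisible null allele
the corrected estimator removes most of the upward bias (the test suite
demonstrates both). Bootstrap CIs resample loci ($10^4$ replicates by
default, percentile method at 95%). Group contrasts are tested FSTAT-style
by permuting whole populations across groups,
$p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)$, with the absolute mean
difference for two groups and the variance of group values for more; note
the permutation floor — with two groups of two populations only six
distinct splits exist, so small designs cannot reach small p-values.

## Numerical and reproducibility choices

One master seed governs everything. Derived substreams use a Lehmer-style
map into $[1, 2^{31}-2]$: per reference-table row, per locus within a
dataset (so growing the locus panel never perturbs earlier loci), per
forest. All forests run single-threaded for bitwise reproducibility.
Genepop export uses the 3-digit dialect; titles carry provenance because
the format has no comment syntax. Reference tables on disk are
tab-separated with a `#`-prefixed provenance header (seed, priors hash,
design) that any delimited-text reader can skip.

## Problem sizes in the shipped checks

The packaged test suite and `scripts/acceptance.R` run the full pipeline at
desk scale, chosen so the whole suite completes on one CPU while keeping
every qualitative property testable: 2000 simulations per scenario and
2000-tree forests in the acceptance tests (500 test sets per scenario for
the confusion matrix; 200 for interval coverage), 1000 simulations per
scenario and 1000-tree forests in the acceptance script. The reference
analysis protocol in this literature uses $2\times10^4$ simulations per
scenario for model choice and $10^5$ for parameter estimation; the OOB
error at desk scale is therefore an upper bound on what the full-size table
would give (error falls monotonically with table size in expectation, a
property the suite checks on the separable toy design).

## What the synthetic data do and do not establish

The generator emulates the study design faithfully — sample sizes, locus
count, mutation model, scenario topologies, priors — so tests against it
establish the *internal* correctness of the machinery: the coalescent
matches closed forms (pairwise TMRCA, stepwise-model equilibrium diversity
$1 - 1/\sqrt{1+2\theta}$), the statistics match independent oracles, the
forests recover separable truths and give calibrated intervals under the
prior. They do not establish that any real dataset fits these scenarios:
real SSR data carry genotyping failure, allele-size homoplasy across
non-contiguous motifs, departures from equilibrium within lineages, and
unmodelled gene flow. The scenario-compatibility check (the LDA projection
of observed data against the simulated cloud, `plot_lda_projection()`) is
the package's guard against that gap, exactly as in the source toolchain.

Known limitations: no migration between events, no population-size change,
no sequence-level mutation; admixture with more than two sources must be
composed from pairwise events; the null-allele EM assumes a single null
class per locus. The per-population $F_{IS}$ uses the within-population
Weir–Cockerham components, which for very small samples can fall outside
the $[-1, 1]$ range expected of the parameter — a property of the
estimator, not a bug.
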