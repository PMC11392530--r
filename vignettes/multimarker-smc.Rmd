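---
title: "Multi-marker SMC inference: models, assumptions and design choices"
author: "smcmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-marker SMC inference: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Demographic inference from whole genomes with PSMC'-family hidden Markov
models reads the density of heterozygous sites along a pair of haploid
genomes as a record of local coalescence times (TMRCA). Nucleotide variation
alone limits the resolution of this record in two regimes: in the recent
past (too few mutations accumulate on short branches) and whenever the
recombination rate exceeds the mutation rate (genealogies change faster along
the genome than mutations can register them). Heritable *hyper-mutable*
markers — above all CG methylation in plant genomes, with epimutation rates
around 1e-4 to 1e-3 per site per generation — switch state often enough to
time recent coalescences, at the price of a finite-site, reversible mutation
process whose rates are usually unknown.

`smcmark` implements, in one package:

* closed-form pair emission models for an arbitrary set of heritable marker
  classes (symmetric `nbs`-state chains for nucleotides and generic markers;
  an asymmetric two-state chain for methylation; a coupled region+site chain
  for region-level epimutation);
* a sequential coalescent (SMC') simulator with finite-site multi-marker
  mutation overlay and a methylome layer (single-methylation polymorphisms,
  SMPs, and differentially methylated regions, DMRs);
* the pairwise SMC hidden Markov model over discretized coalescence times,
  fit either by Baum-Welch (generalized EM) or by direct likelihood
  optimization, with a composite likelihood over haplotype pairs;
* rate-transfer estimation of unknown marker rates from a reference marker
  (Watterson-ratio below the 1%-polymorphism threshold, Baum-Welch above
  it);
* the methylation workflow: a binomial test for a region-level epimutation
  effect, a three-state segmentation HMM for the pairwise region status, the
  0-4 / 9-symbol observation codings, and the combined SNP+SMP fit;
* evaluation statistics: demography RMSE on a log-uniform time grid,
  posterior TMRCA decoding, genealogy-span distributions and LD decay.

## Emission models

For a symmetric marker with `nbs` states and rate $\mu$ per site per
generation, the probability that a site is identical between two genomes
whose lineages coalesced $t$ generations ago is

$$P(\mathrm{id}\mid t) = \frac{1}{nbs} + \frac{nbs-1}{nbs}
  \exp\!\Big(-\,2\mu t\,\frac{nbs}{nbs-1}\Big),$$

the Jukes-Cantor-type transition probability evaluated on the two branches
of combined length $2t$. It interpolates between certainty of identity at
$t=0$ and the homoplasy floor $1/nbs$ at large $t$; as a function of $\mu$
the segregating probability saturates below $(nbs-1)/nbs$, which is the
finite-site accuracy limit for very fast markers.

Methylation status is a two-state chain with distinct gain
($\mu_{SM}$, U→M) and loss ($\mu_{SU}$, M→U) rates. The ancestral state at
the pair MRCA is drawn from the chain's stationary distribution
$\pi_M = \mu_{SM}/(\mu_{SM}+\mu_{SU})$ and the two lineages evolve
independently, giving the three observable site-pair symbols: both
unmethylated (code 2), both methylated (3), discordant (4).

With region-level epimutation the observable is the product coding of
region-pair status (UU / UM / MM) and site code (2/3/4), 9 symbols. We
compute this distribution *exactly* from the coupled per-lineage chain on
the four states (region, site): site flips at the site rates, region flips
at the region rates with the side effect of resetting the site to the
region's new status. The ancestral region status is stationary and the
ancestral site state equals it. The 4x4 transition matrix is evaluated by
uniformization with scaling and squaring; the test suite checks the result
against a mechanistic Gillespie simulation of the coupled chains on the
two-branch tree.

## The simulator

`simulate_arg()` generates the sequence of marginal genealogies left to
right under the SMC' approximation: an initial coalescent tree under the
piecewise-constant demography $N(t)$ (pair coalescence rate $1/2N(t)$),
recombination events at rate $r \times$ (total branch length) per bp, each
cutting a uniformly chosen branch point and re-coalescing the detached
lineage into the standing genealogy. Re-coalescence into the remnant of the
cut branch is a silent event — the marginal tree is unchanged — which is
what distinguishes SMC' from plain SMC and matches the transition kernel
used for inference. The simulator is validated against analytic coalescent
expectations (mean pairwise TMRCA $2N$, segregating sites $4N\mu L$ for a
pair, Watterson's theta, tree-count growth in $rL$) rather than against the
inference code.

Mutations are overlaid per marker class under a finite-site model: marker
sites are interleaved deterministically along the genome by their genome
fractions (round-robin with a Bresenham spread, so a 2% marker occupies
every 50th site); ancestral states are stationary draws; mutation events are
Poisson on branches, with repeated hits resampling among the other states.
For hyper-mutable markers, where a site expects many hits per tree, the
per-branch end state is drawn directly from the chain's exact transition
probability — distributionally identical to enumerating the hits, and the
only practical option at $\mu = 10^{-2}$.

The methylome layer annotates all sites inside randomly placed genic regions
(region length 1 kb by default, 150 bp supported) covering a configurable
2-20% of the sequence. Site- and region-level chains run independently;
a region event resets every site of the region. Two simplifications are
deliberate and documented:

* when region rates are nonzero, all sites of a region follow the genealogy
  at the region's midpoint for both chains (a locally tree-constant
  approximation; region lengths are comparable to typical genealogy spans,
  and the approximation is exact in the site-only mode, where every site
  uses its own local tree);
* the ancestral site state equals the ancestral region status, i.e. the
  conditional site distribution tracks the region boundary at the MRCA.

Partial selfing with rate $\sigma$ is handled by the standard rescaling of
the effective recombination rate, $r_\mathrm{eff} = r(1-F)$ with
$F = \sigma/(2-\sigma)$, in both the simulator and the inference model.

Marker classes partition the sites: each position carries exactly one
marker. (In real methylomes a CG site also carries a nucleotide; the pair
coding only ever reports the methylation state at methylable sites, so the
partition is the observable situation anyway.)

## The inference engine

Hidden states are `n_states` coalescence-time intervals holding equal prior
mass under a guess demography (the constant size implied by the reference
marker's Watterson estimate); the representative time of an interval is its
conditional mean. The per-site transition matrix follows the SMC' kernel:
recombination on the pair branches with probability $1-e^{-2rt_k}$, then
re-coalescence under the piecewise-constant demography, integrated
numerically on a fine time grid with the silent (back-coalescence) mass
folded into the diagonal; a quadrature oracle in the tests checks the
off-diagonals to better than 1%.

Observations enter as per-bin symbol counts (default bin width 100 bp): the
hidden state is taken constant within a bin, the bin emission is the product
of per-site emissions (a sum of count-weighted log-probabilities), and the
bin-to-bin transition is the per-site matrix raised to the bin width. The
exact per-site HMM (`bin_w = 1`) is retained and used by the enumeration
oracle test and the binned-vs-exact consistency test. We chose binning
over run-length compression of homogeneous stretches as the default because
a hyper-mutable marker at $\mu_2=10^{-4}$ breaks the sequence into runs of
order 100 bp anyway, which removes the advantage of compression while
binning keeps the forward pass dense and vectorizable.

Missing observations are coded as a symbol that emits probability one in
every hidden state, i.e. they contribute nothing to the likelihood.

The composite likelihood is the product over haplotype pairs (all
$n(n-1)/2$ pairs by default; fits can subsample haplotypes first, and the
direct-likelihood fit defaults to six haploid genomes as a computational
compromise). Two fitters share the parameterization (log-scale tied epoch
sizes on the fixed time grid, log recombination rate, log marker rates):

* **Baum-Welch**: the E-step accumulates expected transition counts,
  initial-state posteriors and expected per-state symbol counts across
  pairs; the M-step maximizes the expected complete-data log-likelihood
  numerically over the free parameters (a partial M-step — any improvement
  of Q preserves the EM monotonicity guarantee, which the tests assert).
  Defaults: at most 30 iterations, relative tolerance 1e-5.
* **Direct likelihood**: box-constrained quasi-Newton optimization of the
  composite log-likelihood (forward passes only). The returned likelihood
  is never below the starting model's.

Unknown marker rates start from the finite-site-adjusted diversity-ratio
estimate and are refined as free emission parameters; starting them orders
of magnitude away makes EM convergence impractically slow, which is worth
knowing when adding new marker classes. Beyond the finite-site saturation
level the likelihood becomes flat (one-sidedly) in a marker's rate — any
sufficiently large rate fits equally well and the nominal maximizer can sit
at infinity. The fitters therefore report the smallest rate within 0.5
log-likelihood units of the maximum: for identified markers this coincides
with the maximum-likelihood estimate, for saturated ones it is the lower
edge of the flat region, which is why very fast markers are systematically
underestimated (the accuracy limit of hyper-mutable markers).

## Rate transfer between markers

Below the 1%-polymorphism threshold (configurable; the threshold the
dispatch rule uses by default) both markers are effectively infinite-site,
and the rate of marker 2 follows from the reference rate by the ratio of
per-site Watterson estimates. Each estimate is first passed through the
finite-site inversion

$$\theta_\mathrm{adj} = -\frac{nbs-1}{nbs}
   \log\!\Big(1 - \theta_W\,\frac{nbs}{nbs-1}\Big),$$

which corrects for the number of possible states; it linearizes to the
identity at low diversity (so equal diversities with equal state counts give
equal rates, and a ten-fold diversity ratio a ten-fold rate ratio) and is
unit-tested against the small-$t$ linearization of the pair emission.
Above the threshold the rate becomes a free emission parameter of the
Baum-Welch fit. Whether a further reversibility adjustment beyond this
inversion is warranted at intermediate saturation is left open in the code
(the estimator is isolated in one function).

The asymmetric (methylation) version splits the symmetric-equivalent rate
$2gl/(g+l)$ by the observed methylated fraction $\hat\pi_M = g/(g+l)$.

## The methylation workflow

**Region-effect test.** Under site-independent epimutation, two successive
annotated sites of one genome share status with probability
$p_0 = \pi_M^2 + \pi_U^2$. The observed count of identical adjacent pairs,
pooled over genomes, is compared to Binomial($n_\mathrm{pairs}$, $p_0$) with
a two-sided exact test at threshold 0.05; a distance-stratified variant
counts only pairs separated by at least a minimum gap. Pooling over genomes
treats genomes as independent, which slightly overstates the effective
sample size for closely related genomes; the calibration test in the
acceptance suite runs the test on simulated site-only methylomes where this
matters least.

**Segmentation HMM.** Hidden states UU / UM / MM for the pairwise region
status; emissions take each genome's site to be methylated with the
*stationary conditional* probability given its region status under the
coupled region+site chain (solving $\pi Q = 0$ of the 4-state chain), the
two genomes independent given their statuses; transitions follow a
geometric region-length prior with switch probability $1-e^{-d/L_r}$ over a
gap of $d$ bp, $L_r$ the configured region length (1 kb / 150 bp). Posterior
decoding yields segments, reported with bp lengths, means and medians. This
deliberately ignores the per-site TMRCA (the segmentation runs before the
SMC) and the shared genealogy of the two genomes; it is the same class of
approximation as standalone DMR callers.

**Codings.** Per-position pair symbols 0 (equal nucleotides), 1 (different),
2/3/4 (methylation pair status), lifted to the 9-symbol region-conditioned
alphabet when a segmentation is supplied; encode/decode is a bijection on
the defined symbols and missing data maps to the uninformative symbol.

**Reductions.** With an empty methylome the SMCm likelihood equals the
SNP-only likelihood exactly. With symmetric site rates ($g=l$) the
methylation emission equals the symmetric two-state emission with the
identical class split evenly between UU and MM, so the SMCm log-likelihood
differs from the generic two-marker fit by exactly
$n_\mathrm{id}\log 2$ — same maximizer, a constant offset; the tests assert
both reductions.

## Evaluation statistics

* `rmse_demography()` evaluates true and estimated step functions at 102
  points uniform in $\log_{10}$ time over the window (default
  $[10^2, 10^6]$ generations) and returns
  $\sqrt{\sum_i (y_i-y_i^*)^2 / 102}$. The evaluation uses 102 points,
  matching the summation bounds of the defining formula even though prose
  descriptions usually say "a hundred"; natural-size scale by default with a
  log-scale option.
* `posterior_tmrca()` rescales the forward-backward posteriors to sum to
  one per position and dots them with the representative times.
* `genealogy_spans()` cuts the sequence where the maximum-a-posteriori
  hidden state changes (robust to posterior noise; an expected-time
  threshold variant is provided).
* `ld_decay()` computes $r^2$ between polymorphic sites of one marker class
  (minor-state count at least 2, since LD is undefined for monomorphic
  sites) in distance bins, with an all-pairs scan capped by site
  subsampling.

## Problem sizes in the tests and the acceptance script

The simulation experiments that motivated the package ran at 10 haplotypes
x 100 Mb with 10 replicates; this package's automated checks reproduce the
patterns at reduced scale, which we consider part of the design: the
acceptance script uses 10 x 10 Mb (3 replicates) for the diversity-ratio
rate transfer, where no HMM is involved and the estimator concentrates
quickly, and 10 haplotypes x 2 Mb scaffolds with 3-5 seeds, 16-18 hidden
states, 100-200 bp bins and Baum-Welch/likelihood fits on a 6-haplotype
subsample for the HMM-based recoveries. At this scale the qualitative
contrasts (single- vs multi-marker, Baum-Welch vs direct likelihood, SMP
gain in recent epochs) reproduce; absolute biases are larger than at full
scale — notably the two-marker Baum-Welch recombination estimate sits near
half the truth where the full-scale experiments report about 0.9 of it —
and the acceptance report should be read with that in mind. The
representative times and discretization stay fixed during fits; sizes are
tied in adjacent-interval pairs by default.

## Known limitations

* Hidden states describe pairs only (no MSMC-style multi-haplotype states);
  the composite likelihood treats pairs as independent.
* Recombination and mutation rates are homogeneous along the genome; real
  applications should split chromosomes into scaffolds with approximately
  constant rates.
* The region-level simulator ties all sites of a region to the midpoint
  genealogy (see above).
* The segmentation HMM conditions each pair's emissions on that pair's own
  segmentation; mislabelled region status propagates into the SMC emission
  matrix, which degrades accuracy when site- and region-level rates are of
  the same order — visible as a loss of accuracy when regions are ignored
  or inferred poorly.
* Cytosine deamination, methylation QTLs, CHG/CHH contexts, tissue
  heterogeneity of methylation calls and gene conversion are out of scope.
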