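# smcmark

Demographic inference from multiple heritable genomic markers with the
pairwise sequentially Markovian coalescent (SMC).

PSMC'-family methods reconstruct past population sizes from the density of
heterozygous nucleotide sites along pairs of haploid genomes. SNPs alone
carry little information about the recent past and about the recombination
rate whenever r exceeds the nucleotide mutation rate. Hyper-mutable heritable
markers — chiefly CG methylation in plant genomes, with epimutation rates of
1e-4 to 1e-3 per site per generation — mutate fast enough to time recent
coalescences. `smcmark` simulates and jointly analyses such multi-marker
genomes: it estimates population size trajectories, the recombination rate,
and unknown marker (epi)mutation rates from SNPs together with single
methylation polymorphisms (SMPs) and differentially methylated regions
(DMRs).

The package is aimed at population geneticists who want to (a) quantify, by
simulation, what a hyper-mutable marker adds to SMC inference under a given
demographic scenario, and (b) run the joint SNP + methylation fit on real
haploid methylome panels (VCF + per-site methylation table + genic BED).

## The models in brief

For a marker with `nbs` possible states and rate mu, the probability that a
site is identical between two genomes coalescing t generations ago is

    P(id | t) = 1/nbs + (nbs-1)/nbs * exp(-2 mu t nbs/(nbs-1)),

the symmetric finite-site (Jukes-Cantor-type) transition on the two branches
of the pair genealogy. Methylation uses a two-state chain with asymmetric
gain/loss rates (muSM, muSU), optionally coupled to a region-level
epimutation process (muRM, muRU over 1 kb or 150 bp regions) that resets all
sites of a region — the 9-symbol region-conditioned emission is computed
exactly from the coupled chain. The hidden Markov model over discretized
pairwise coalescence times uses the SMC' transition kernel under a
piecewise-constant N(t), a composite likelihood over haplotype pairs, and is
fit by Baum-Welch (generalized EM) or direct likelihood optimization.
Unknown rates are transferred from a reference marker by the finite-site
corrected Watterson ratio when under 1% of sites are polymorphic, and by
Baum-Welch otherwise.

## Worked example

Simulate a 10-fold bottleneck with a hyper-mutable second marker and compare
the SNP-only fit with the joint two-marker fit:

```r
library(smcmark)
set.seed(1)

dat <- generate_fixture("bottleneck_fig2A", seed = 1,
                        n_haplotypes = 10, sequence_length = 2e6)
print(dat)
#> <sim_data> 10 haplotypes, 2e+06 bp
#>   marker 'm1': 412 polymorphic / 1.96e+06 sites
#>   marker 'm2': 32604 polymorphic / 40000 sites

diversity_summary(dat)
#>   marker nbs n_sites n_segregating poly_fraction      theta_w
#> 1     m1   4 1960000           412  0.0002102041 7.430415e-05
#> 2     m2   2   40000         32604  0.8151000000 2.881262e-01

f_snp  <- fit_snp_only(dat, mu1 = 1e-8, method = "bw",
                       n_states = 16, max_haplotypes = 6)
f_both <- fit_multimarker(dat, mu1 = 1e-8, mu2 = 1e-4, method = "bw",
                          n_states = 16, max_haplotypes = 6)

rmse_demography(dat$truth$demography, f_snp$demography)
#> [1] 18313.38
rmse_demography(dat$truth$demography, f_both$demography)
#> [1] 5901.907
```

The recent bottleneck leaves only ~400 SNPs on these 2 Mb, so the SNP-only
fit misses the size drop almost entirely, while the hyper-mutable marker
(80% of its sites segregating) recovers it: the RMSE (root mean square error
of N(t) over 102 points log-uniform in [1e2, 1e6] generations) falls to a
third when the second marker enters the likelihood.
`posterior_tmrca()`, `genealogy_spans()` and
`ld_decay()` provide the corresponding per-locus diagnostics, and
`fit_smcm()` runs the methylation-specific workflow (region-effect test, DMR
segmentation, SMP emissions) on simulated or real methylomes.

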