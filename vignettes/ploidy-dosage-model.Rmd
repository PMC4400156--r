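---
title: "The ploidy and allele-dosage model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ploidy and allele-dosage model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidycall)
```

## The problem

When a polyploid genome is assembled from whole-genome shotgun reads,
stretches where several homoeologous (or paralogous) copies are nearly
identical collapse into a single contig. The number of haploid copies such
a contig represents — its ploidy `M` — is then unknown, and it varies from
contig to contig. `ploidycall` estimates `M` per contig from the relative
proportions of alleles at heterozygous positions, and, given `M`, calls
biallelic variants together with their allele dosage. The only assumption
about the sequencing experiment is that reads sample all collapsed copies
uniformly, so a site present in `g` of `M` copies is expected in a fraction
`g / M` of the reads covering it.

## The generative model

At most two alleles are assumed per position. For a contig of length `C`
and a candidate ploidy `m`, the likelihood multiplies over positions `p`
and marginalises, per position, over the latent dosage `g` of the first
allele and, per read, over the latent true allele `T` and the sequencing
error indicator `E`:

* dosage prior: heterozygous mass `P(SNP)` spread uniformly over the
  `m - 1` heterozygous dosages, `P(G = g) = P(SNP) / (m - 1)` for
  `0 < g < m`, and `(1 - P(SNP)) / 2` for each of `g = 0` and `g = m`
  (`genotype_prior()`);
* latent allele: `T ~ Bernoulli(g / m)` over the two candidate alleles
  (`true_allele_prob()`);
* observation: with probability `1 - e` the observed base equals the true
  allele, with probability `e` it is replaced according to a substitution
  multinomial; `e` comes from the error model below.

Because `T` and `E` are the only latent per-read variables, the inner
marginalisation collapses to a two-component mixture
`P(o | g, m) = f P(o | T = a1) + (1 - f) P(o | T = a2)` with `f = g / m`,
so a position's log-likelihood only ever needs to be evaluated on the grid
of distinct dosage fractions `g / m` across the candidate range — 81
fractions for ploidies 1–16. All accumulation is in natural-log space with
log–sum–exp; per-read likelihoods are floored at `1e-300`.

The ploidy maximising log-likelihood plus log ploidy-prior (uniform by
default) is selected; ties break toward the smaller ploidy. Ploidy is
assumed constant along a contig, and contigs are analysed independently,
so results do not depend on processing order.

For `m = 1` the prior above would sum to `1 - P(SNP)` because no
heterozygous states exist; the two homozygous states are renormalised to
`1/2` each so that haploid contigs are not penalised by a constant
`log(1 - P(SNP))` per position.

### Genotype calls

Given the selected `M`, the posterior over `g` at each covered position
follows by Bayes' rule. The variant score is the Phred transform of the
posterior non-variant mass, `-10 log10 P(g = 0 or g = M | data)`; the exact
functional form is this package's choice. Positions whose score exceeds
the threshold (default 40) are emitted as variants. With the default
threshold a variant needs overwhelming evidence, which keeps false
positives near zero at the cost of slightly conservative calls.

## The sequencing-error model

Each aligned base carries four features, all computed from the read itself
in sequencing orientation: its Phred quality `qs`; the neighboring quality
score `nqs` (mean quality of up to five bases on each side, excluding the
base — at read edges the average runs over the neighbors that exist, and a
length-one read falls back to its own quality); whether the base is
preceded in the read by the 2-mer GG (a known Illumina systematic-error
context; the first two bases of a read get 0); and the identity of the
(hypothesised) true nucleotide. The error probability is logistic:

`P(E = 1) = 1 / (1 + exp(alpha + beta log qs + gamma log nqs))`

with separate coefficients per (true nucleotide, GG flag, quality-2
indicator) stratum. Quality 2 is the base-caller's "no confidence" code
and empirically deviates from the Phred line, so `beta` is fixed at zero
in quality-2 strata — the nominal quality carries no information there,
while `nqs` still does. Conditional on an error, a substitution
multinomial indexed by (true nucleotide, GG) distributes the observed base
over the three alternatives. The naive baseline model ignores everything
except `qs` and sets `P(E = 1) = 10^(-qs/10)` with uniform substitutions.

Training compares reads from a monomorphic sample against a trusted
reference, treating every mismatch as a sequencing error. The fit is a
maximum-likelihood logistic regression per stratum (IRLS, convergence
`1e-8` on the penalised log-likelihood, at most 100 iterations) with a
light L2 penalty (`1e-3`) on the slope coefficients and a +-30 cap on
coefficients, both of which only matter in degenerate strata that a small
training set leaves empty or error-free; such strata fall back to the fit
pooled over nucleotides, and empty substitution rows fall back to uniform.
Model comparison uses k-fold cross-validation with mean held-out negative
log-likelihood of the error indicator as the metric.

Bases with `N` or without a quality are dropped from training and
inference. `log(qs)` at `qs = 2` is simply `log 2`; the term is inert in
quality-2 strata anyway.

### Caching and discretisation

Error probabilities are cached per (true nucleotide, GG, `qs`, binned
`nqs`) key; `nqs` is rounded to `nqs_bin` (0.1 by default) so cached and
direct evaluations agree exactly. The streaming simulation kernel uses a
coarser 0.5 bin and additionally quantises the per-read probability pair
to 1/64 of a natural-log unit, sharing cached likelihood rows between
feature combinations that quantise together. The worst-case effect on a
contig log-likelihood is bounded by one quantisation step per base
observation, is common to all candidate ploidies at a position, and in
practice perturbs log-likelihood differences between ploidies by orders of
magnitude less than the differences themselves; a test asserts the bound
and that selections are unchanged. Both knobs can be set to exact
(`nqs_bin` small, `quant = 0`).

## The read simulator

The simulator exists so the whole pipeline can be exercised against known
truth without external data. It emulates:

* a consensus sequence with i.i.d. uniform base composition;
* heterozygous sites placed by a Poisson process with a mean spacing
  (1 kb in the coverage designs, 200 bp in the length designs), dosages
  uniform on `1..M-1`, and the alternative allele assigned to a random
  subset of copies;
* paired 100 bp reads from fragments of Normal(300, 30) bp placed
  uniformly and assigned to haplotype copies uniformly;
* discrete per-base qualities from levels {2, 12, 23, 32, 37} (mirroring
  binned Illumina quality scores), with per-cycle level weights
  interpolated so mean quality decays along the read and the quality-2
  fraction grows;
* errors drawn from the same logistic family the error model fits —
  slopes `beta = 3.0`, `gamma = 0.5` (0.8 in the quality-2 stratum),
  intercepts set so that a quality-23 base with average neighborhood errs
  at about 0.6% and a quality-2 base at about 10% (far below its nominal
  63%, reproducing the miscalibration of the lowest bin), a GG context
  multiplying the error odds by about 1.5, small per-nucleotide intercept
  offsets, and transition-biased substitutions. Overall error rate is
  just under 1%.

Choosing the generating family equal to the fitted family is deliberate:
it makes parameter recovery testable and means the analysis operates near
its modelling assumptions, as it would after training on data from the
same instrument. The simulator does **not** emulate indels, GC bias, PCR
duplicates, chimeric fragments, mapping ambiguity or reference error, so
passing benchmarks here demonstrate the estimator's statistical behaviour
under its stated assumptions, not robustness to alignment artefacts.
Generative error probabilities are evaluated on a 0.1-binned `nqs` grid.

Reads can be materialised as FASTQ/SAM (`simulate_reads()`,
`write_sim_fastq()`, `write_sim_sam()`), or streamed directly into
pileups and likelihoods by a fused kernel (`analyze_simulation()`) that
consumes the identical RNG stream — a test asserts the two paths give the
same likelihoods. Runs are fully reproducible from the design seed.

## Alignment handling

The BAM path keeps primary, mapped, non-duplicate records with mapping
quality strictly above 40 (the uniqueness proxy) and template length
within the fragment range, which defaults to mean +- 4 SD of the first
100,000 proper pairs. Coordinates are 0-based half-open internally and
1-based in VCF. Candidate alleles at a position are the two most frequent
observed nucleotides (ties broken A < C < G < T); the dosage `g` counts
copies of the majority allele. Bases matching neither candidate stay in
the pileup and are explained through the error branch — discarding them
would bias coverage. Where only one allele is observed, the second branch
uses the smallest other nucleotide as a placeholder; no read can match
it, so only its error branch contributes. Overlapping mates are counted
independently, a known double-counting caveat at short fragment sizes.

## Benchmark problem sizes

The bundled benchmarks (tests and `scripts/acceptance.R`) run three
designs chosen to exercise the regimes that matter while staying
desk-sized: the coverage design (100 kb contigs — about 100 SNPs each,
enough informative variants to saturate ploidy-call accuracy at high
ploidy — ploidies 1–16 at 50X per copy, 10 replicates), the long-contig design
(one 200 kb contig per ploidy at 15X/25X/50X/75X per copy, whose per-
condition rates are measured over 200,000 positions), and the length
design (2/20/200 kb at 50X, ploidies 1–8, SNPs every 200 bp, with
100/40/20 replicates for the three lengths — replication is concentrated
on the 10-SNP 2 kb cells, where a single miss moves a cell's accuracy
estimate the most and simulation is cheapest). The analysis prior
`P(SNP)` is set to 1/1000 to match the
simulated SNP density of the coverage designs; for real plant data 1/200
is the recommended default. The analysis-side error model is always
trained on an independent simulated monomorphic sample, never copied from
the generator.

## Known limitations

* Only biallelic SNPs; indels and multi-allelic sites are out of scope.
* Ploidy is constant per contig; within-contig ploidy changes (e.g.
  partial collapse) bias the call toward an intermediate value.
* High ploidies at low coverage are intrinsically hard: neighbouring
  dosage fractions `g/M` approach each other, and estimates degrade
  gracefully (off by one or two) rather than failing loudly.
* Dosage accuracy is lowest for near-balanced ratios, where the Bernoulli
  variance is largest; extreme ratios (e.g. 1 of 15) are the most
  informative for ploidy.
* The error model assumes no real variation in the training sample;
  residual polymorphism inflates the learned error rates slightly.
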