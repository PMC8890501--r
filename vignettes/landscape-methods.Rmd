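---
title: "Methods: magnesium-dependent RNA fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnesium-dependent RNA fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fitscape)
```

## The measurement model

`fitscape` analyzes combinatorial RNA fitness landscapes measured by in
vitro selection across a magnesium titration. The study system is a group I
self-splicing ribozyme whose catalytic activity reports on correct tertiary
folding, and whose folding requires Mg^2+^. Seven nucleotide positions are
fully randomized, giving a library of $4^7 = 16{,}384$ genotypes identified
by their allele string at those positions. The library reacts with a
substrate at each of eight MgCl~2~ concentrations (1--48 mM) in triplicate;
reacted molecules are amplified and sequenced along with the pre-selection
pool.

Relative fitness of genotype $g$ is the enrichment ratio normalized to the
wild type,

$$W(g) \;=\; \frac{p_\text{post}(g)/p_\text{pre}(g)}
                  {p_\text{post}(\text{wt})/p_\text{pre}(\text{wt})},$$

where $p$ are read proportions among all reads matching the library pattern.
Genotypes absent before selection carry no information and are flagged
missing; genotypes present before but absent after selection get fitness 0.
No pseudocounts are added anywhere: a pseudocount would silently inflate the
low-fitness tail, which is exactly the part of the landscape whose
classification drives the ruggedness statistics. Replicates are aggregated
as the arithmetic mean of per-replicate ratios, with the coefficient of
variation computed from the sample ($n-1$) standard deviation.

Read counting matches each merged read against the reference sequence with
wildcards at the variable positions: any read of the wrong length, with a
substitution outside the variable positions, or with an ambiguous base is
rejected and tallied. Matching is case-insensitive and U/T-equivalent, and
streams the FASTQ in chunks so that arbitrarily deep files fit in memory.

## Landscape topography

Every four-genotype "square" $\{g,\,g{+}A,\,g{+}B,\,g{+}AB\}$ (two single
substitutions and their combination) is enumerated once under a canonical
anchoring: the anchor is the lexicographically smallest corner, which forces
its allele to sort below the alternative at both focal positions. For $p$
positions this yields $4^{p-2}\binom{4}{2}^2\binom{p}{2}$ squares --
774,144 for the full library -- and an exhaustive test verifies the
deduplication against brute force on the 2-position toy library.

A square is additive when $W_{AB} + W_0 - W_A - W_B = 0$. Otherwise the
triangle-equality conditions

$$|W_A - W_0 + W_{AB} - W_B| = |W_A - W_0| + |W_{AB} - W_B|$$

(mutation A keeps the sign of its effect in both backgrounds; the strict
`<` analogue for mutation B detects a flip) separate magnitude epistasis
(both signs kept), reciprocal sign epistasis (both flipped) and sign
epistasis (exactly one flipped). Ruggedness is $2 f_{RS} + f_S$. Three
numerical choices deserve note:

* **Equality tolerance.** The conditions compare floating-point values for
  equality. The default `eps = 0` reproduces exact comparison, which is the
  natural choice for measured data (exact ties essentially never occur, and
  any nonzero absolute tolerance preferentially erases the compressed
  low-magnesium landscapes, biasing the trend). For analytically constructed
  landscapes, where additivity holds only up to rounding, tests use
  `eps = 1e-9`.
* **Zero effects.** A mutation with exactly zero effect counts as
  sign-agreeing; this falls out of the conditions and matters only for
  constructed data with exact ties (for example fitness-0 plateaus).
* **Missing corners.** Squares with any missing corner are excluded from
  the fractions and reported in `n_skipped`, so fractions are always over
  classifiable squares.

Classification is invariant to which corner is called the reference; the
test suite checks all three relabelings against an independent sign-pattern
oracle on $10^5$ random squares.

The roughness-to-slope ratio fits the additive model by least squares
(intercept plus one coefficient per non-reference allele per position, 22
coefficients for the full library): roughness $r$ is the RMS residual,
slope $s$ the mean absolute allele coefficient. $r$ and $r/s$ are invariant
to the reference-allele choice; $s$ is not, so the reference (default: the
wild type) is an explicit argument. The cited literature describes the
statistic relative to the most-fit genotype; the definition here is the
standard additive least-squares one, with the reference exposed so either
convention can be reproduced.

## Dose-response fits

Each genotype's fitness-vs-magnesium profile is fit with the Hill model
$W(m) = w_\text{max} m^h / (k^h + m^h)$ -- the conventional
parameterization of a cooperative folding transition with midpoint $k$ (mM)
and slope $h$. Fitting is Levenberg--Marquardt with bounded parameters and
a small multi-start over $h \in \{0.5, 1, 2, 4\}$; $w_\text{max}$ starts at
the observed maximum and $k$ at the interpolated half-maximum crossing.
Profiles that are all zero, constant (the wild type's own profile is
identically 1 and unidentifiable), or that end with $k$ on its bound are
flagged rather than reported as converged. Fits are made to replicate-mean
profiles; genotypes missing at any concentration are not imputed and not
fitted. The interpretable subset keeps converged fits with
$0.15 < w_\text{max} < 3$, $h < 5$ and $k < 16$ mM, with exclusions tallied
by the first failing reason.

Mean fitness per mutational distance $n$ is summarized by
$W(n) = \exp(-\alpha n^\beta)$, fit in the log domain (seeded by the exact
linearization $\log(-\log W) = \log\alpha + \beta\log n$), falling back to
the direct domain with a flag if any mean is non-positive. $\beta = 1$ is
the multiplicative (no directional epistasis) anchor -- verified exactly on
constructed multiplicative landscapes -- and $\beta > 1$ indicates
predominantly negative epistasis. The distance-0 point satisfies the model
identically and is excluded from the residuals.

## Wright-Fisher simulations

Populations evolve on one landscape slice at constant size $N$ (default
1,000, the study condition) with discrete generations: $N$ offspring are
drawn with replacement with probability proportional to parental fitness,
and each offspring independently mutates with probability $\mu$ (default
0.01) to one of its 21 single-step neighbors, chosen uniformly. The
verbal model -- random reproduction proportional to fitness at constant
size -- admits either Wright--Fisher or Moran dynamics; Wright--Fisher was
chosen and is stated here because its generation unit matches the logistic
summaries. Mutation applies at most one substitution per offspring per
generation. Genotypes with missing fitness are assigned fitness 0 (they can
arise but not reproduce) and counted in an audit field. Generation 0 is the
initial monomorphic population; "G50" reads the cross-replicate mean of
population mean fitness at generation 50. One master seed spawns
per-replicate child seeds deterministically.

The starting genotype is chosen deterministically: among genotypes at
maximal Hamming distance from the top-fitness genotype of every
concentration, the one with the lowest mean fitness across concentrations
that still has positive fitness everywhere (a fitness-0 founder population
could never reproduce), ties broken lexicographically. Mean trajectories
are summarized by $f(x) = L/(1 + e^{-k(x - x_0)})$, fit with multi-start
Levenberg--Marquardt; the engine's correctness is pinned by exact checks
(population size, monomorphism without mutation, neutral-drift martingale)
and by matching fixation probabilities on a 10-individual two-genotype
chain against the exact absorbing Markov chain.

## What the synthetic generator emulates

The generator stands in for the archived sequencing data so the pipeline is
testable offline. Each genotype's ground truth is a Hill dose-response:

* per-mutation log-activity effects are $N(-0.5,\,0.8)$ with positive draws
  shrunk by 0.4 -- most mutations are deleterious, and gains in an already
  optimized catalyst are rare and small while losses are unbounded;
* a sparse 10% of mutation pairs carry an extra log-activity interaction
  $N(-0.15,\,0.25)$, making epistasis predominantly negative;
* per-mutation midpoint shifts are $N(1.5,\,2.5)$ mM truncated at 0, so
  mutations destabilize on average and midpoints grow with distance; the
  wild-type midpoint is 2 mM with Hill slope 3, typical of cooperative
  Mg^2+^-dependent tertiary folding;
* 3% of genotypes are dead (no activity at any concentration);
* selection carries a nonspecific background reaction at $10^{-3}$ of the
  saturated wild-type activity. This term matters: below it, genotypes are
  indistinguishable, so the low-magnesium landscape has a wide
  noise-dominated floor. That floor is what makes measured low-magnesium
  landscapes rugged (random sign patterns among near-dead genotypes) and
  slow to adapt on (no usable selection gradient), while high magnesium
  lifts most genotypes above it;
* pre-selection pools are symmetric-Dirichlet uneven (concentration 50),
  because the fitness estimator divides by measured pre-proportions and
  that unevenness must be exercised;
* sequencing is multinomial at $10^7$ reads per condition-replicate, deep
  enough that the low-fitness tail is sampled rather than exactly zero.

Pre counts are multinomial over the pool; post counts are multinomial over
the pool reweighted by Hill-model activity at the given concentration, with
dead genotypes at exactly weight 0. FASTQ output substitutes the alleles
into the reference, writes DNA (U to T) with constant quality, and can spike
a configurable fraction of reads with one off-target mutation to exercise
the exclusion filter.

These choices were fixed from the qualitative structure of the study system
before the acceptance checks were written. What passing tests show is that
the pipeline recovers the structure this generator encodes -- enrichment
ratios, epistasis classes, titration midpoints, adaptation dynamics -- at
realistic depth and noise. What they cannot show is fidelity to effects the
generator omits: RT-PCR amplification bias, sequencing substitution errors,
read-merging artifacts, genotype-specific Hill slopes, and any higher-order
(three-way and up) epistasis in activity.

## Problem sizes in the shipped analyses

The analysis scripts and acceptance checks run one full synthetic
experiment (16,384 genotypes, 8 concentrations, 3 replicates, depth
$10^7$), classify all 774,144 squares per condition-replicate, fit Hill
curves to every genotype whose profile could pass the filters, and run
evolutionary simulations of 10 replicates for 300 generations per
concentration. Parameter-recovery suites use a 1,024-genotype library
(1,000 titrations with identifiable midpoints) at depth $10^5$. These sizes
keep a complete run in the order of a minute while leaving every statistic
over its full-size domain where the statistic concerns the full library.

## Known limitations

* The wild type's own dose-response is unobservable in relative fitness
  (identically 1); its stability parameters exist only in the generator's
  truth. In the laboratory this is resolved with an external gel-based
  activity assay; modeling that assay is out of scope here.
* Ruggedness on measured landscapes conflates true sign epistasis with
  counting noise near the detection floor; the per-replicate values and the
  replicate-mean values are both emitted so the sensitivity is visible.
* `fit_decay` fits per-distance means (an option fits all genotypes); with
  seven distance classes the fit has few residual degrees of freedom and
  $\alpha,\beta$ should be read as summaries, not calibrated parameters.
* The simulator ties mutation to reproduction and excludes recombination
  and within-genotype fitness noise.
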