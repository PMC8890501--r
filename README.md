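# fitscape

Magnesium-dependent RNA fitness landscapes from in vitro selection.

RNA structure and catalysis depend on Mg²⁺, so changing magnesium
concentration reshapes the entire fitness landscape of a catalytic RNA.
`fitscape` is an R package for quantifying that reshaping in combinatorial
ribozyme libraries measured by selection and deep sequencing. It is built
around a 4⁷ = 16,384-member library of a group I self-splicing intron
(seven fully randomized positions) selected for reverse-splicing activity
at eight MgCl₂ concentrations (1, 2, 3, 4, 6, 8, 16, 48 mM) in triplicate,
but every component takes a general library specification.

The pipeline covers:

* **Variant counting** — match merged amplicon reads (FASTQ) against the
  reference with wildcards at the variable positions; reads mutated
  elsewhere are excluded.
* **Fitness estimation** — relative fitness
  `W(g) = [post(g)/pre(g)] / [post(wt)/pre(wt)]` per concentration and
  replicate, replicate means and CVs.
* **Landscape topography** — enumerate all 774,144 mutational squares
  {g, g+A, g+B, g+AB}, classify epistasis as none / magnitude / sign /
  reciprocal sign from the sign conditions on `W_A − W_0`, `W_AB − W_B`
  (and the B analogues), and summarize **ruggedness = 2·f_RS + f_S** plus
  the roughness-to-slope ratio r/s of an additive least-squares fit.
* **Dose–response** — Hill fits `W(m) = wmax·m^h/(k^h + m^h)` per genotype
  with the interpretability filters (0.15 < wmax < 3, h < 5, k < 16 mM),
  midpoint-by-distance summaries, and the directional-epistasis decay
  `W(n) = exp(−α·n^β)` of mean fitness with mutational distance n.
* **Evolutionary simulation** — Wright–Fisher populations (N = 1,000,
  μ = 0.01) on each measured landscape, logistic fits
  `f(x) = L/(1+e^(−k(x−x0)))` to mean trajectories, and the G50 statistic
  (mean fitness at generation 50).
* **Synthetic data** — a generator with a known ground truth (Hill-model
  activities, mostly deleterious effects, destabilizing midpoint shifts,
  sparse negative epistasis, nonspecific selection background, multinomial
  sequencing) so the whole pipeline runs and is tested offline.

## Worked example

The numbered scripts under `analysis/` run the study end to end on
synthetic data (seed 42); each regenerates the experiment deterministically
and writes tables under `results/`. Running
`Rscript analysis/03_landscape_topography.R` prints:

```
ruggedness by mg (replicate means): 0.634 0.402 0.327 0.298 0.266 0.257 0.28 0.274
Spearman rho(ruggedness, mg) = -0.804, p = 2.23e-06 over 24 points
roughness/slope ratio: 4.11 at 1 mM down to 1.82 at 48 mM
```

Ruggedness is the sign-epistasis load of the landscape: at 1 mM most of
the library sits near the detection floor where measured effect signs are
unstable, so almost two thirds of squares show sign or reciprocal-sign
epistasis; by 48 mM the landscape has smoothed and the trend over all 24
condition-replicate points is strongly negative.
`Rscript analysis/05_evolution.R` then shows the evolutionary consequence:

```
 mg    L      k    x0   g50 max_fitness
  1 1.29 0.0326 132.6 0.011        1.45
 48 3.79 0.1006  35.9 3.002        3.91
Spearman rho x0 vs mg: -0.88 (faster adaptation at high mg)
Spearman rho G50 vs mg: 0.98
```

Populations starting seven mutations from every peak need ~133 generations
to reach half their asymptotic fitness at 1 mM but only ~36 at 48 mM, and
the logistic asymptote L reaches 97% of the maximum landscape fitness —
smoother landscapes are climbed faster and fully. The dose–response script
(`analysis/04_dose_response.R`) shows the mechanism at the single-molecule
level: mean Hill midpoints rise from 4.1 mM (single mutants) to 13.2 mM
(distance 7), i.e. mutations destabilize the fold, and the decay exponent β
rises from 0.63 to 1.30 with magnesium while α falls from 1.49 to 0.14.

Individual pieces are ordinary functions:

```r
library(fitscape)
spec <- azoarcus_library_spec()
ex   <- simulate_experiment(spec, generator_params(), seed = 42)
ls   <- fitness_landscape(ex$counts, spec)
ruggedness(ls$mean_matrix[, 1], enumerate_squares(7))
fit_hill(spec$mg_levels, ls$mean_matrix["CAAACGU", ])
```

A YAML-driven end-to-end runner is also available: see `run_pipeline()`,
`validate_config()` and `inst/extdata/example_config.yaml`.

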