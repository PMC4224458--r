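# emdetwin

Expectation-maximization detwinning for serial crystallography.

## The problem

In serial femtosecond crystallography (SFX) every X-ray pulse yields one
still snapshot from a fresh, randomly oriented nanocrystal, and each
recorded Bragg intensity is only a *partial* reflection (a fraction of the
full integrated intensity, set by how the still slices the
mosaic-broadened peak).  When the Bravais lattice has higher symmetry
than the space group — point group 6 crystals such as photosystem I in
P6₃ are the canonical case — auto-indexing cannot distinguish twin-related
settings such as (h,k,l) and (k,h,−l).  Merging thousands of patterns
with modes picked at random then produces data that look physically
twinned: each merged intensity tends to the average of the two twin-mate
intensities, and its correlation with the true intensities saturates near
1/√2 ≈ 0.71.

`emdetwin` resolves this *indexing ambiguity* ("detwinning") for users
merging still-diffraction data: it assigns a consistent reindexing mode
to every pattern by expectation maximization and merges the partial
reflections by Monte Carlo averaging.

## The algorithm

For pattern *i* with partial intensities {I*ᵢ*} and a full-intensity
model {I_full}, define the Pearson correlation over common reflections
*h*:

r*ᵢ*ᵗ = corr( {I*ᵢ*(h)}, {I_full(tᐧh)} ),

where *t* runs over the candidate reindexing operators (identity and the
twin law, for a two-mode ambiguity).  The EM loop starts from a model of
random positive intensities and iterates:

* **E step** — assign every pattern the mode *t* maximizing r*ᵢ*ᵗ against
  the current model;
* **M step** — reindex each pattern by its assigned operator, map indices
  to canonical asymmetric-unit representatives, and average all
  observations of each reflection into a new model;

until assignments stop changing.  The monitored target score is the mean
over patterns of max₍ₜ₎ r*ᵢ*ᵗ.  Pearson correlation is per-pattern
scale-free, so no intensity scaling is needed for assignment.  Because
the two final gauges are equivalent, evaluation labels the mode of a
model that best matches a reference the consistent indexing mode (CIM),
the other the alternative (AIM).

The package also ships a synthetic partial-reflection generator (Wilson
intensities, uniform or resolution-dependent partialities, Poisson shot
noise, random per-pattern modes, full ground truth) and evaluation tools
(consistency fractions, resolution-shell model correlations, multi-run
consistency matrices, dataset-size sweeps, pairwise-vs-model
separability).  See the vignette `vignettes/detwinning-methods.Rmd` for
the model, parameter and design details.

## Worked example

```r
library(emdetwin)

cfg <- sim_config(n_patterns = 2000, seed = 42)   # uniform partiality, Poisson noise
sim <- simulate_dataset(cfg)
st  <- run_em(sim$dataset, config = em_config(seed = 1, cell = cfg$cell))
st
#> <em_state> 4 iterations, converged - final score 0.7806
#>   mode populations: 995 / 1005
round(st$score_history, 3)
#> [1] 0.045 0.632 0.769 0.781

res <- label_and_score(st, sim$dataset, sim$truth$true_model,
                       truth = sim$truth, cell = cfg$cell)
round(unlist(res[c("r_cim", "r_aim", "consistency_truth")]), 4)
#>             r_cim             r_aim consistency_truth
#>            0.9889            0.1014            1.0000
```

Reading the output: the first E step against the random model is
uninformative (score 0.045, a ~50/50 split); by iteration 4 no pattern
changes mode.  The converged merged model correlates 0.989 with the true
full intensities in the consistent gauge and only 0.10 in the alternative
gauge, and every one of the 2,000 patterns is assigned its true indexing
mode.  (The merged means estimate mean-partiality-scaled intensities, so
the CIM correlation is "about 0.99" rather than 1.)

A thin command-line front end wraps the same functions
(`inst/scripts/detwin`, subcommands `simulate`, `detwin`, `evaluate`;
example configuration in `inst/extdata/example_config.yaml`).

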