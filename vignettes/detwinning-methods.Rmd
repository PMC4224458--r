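---
title: "Resolving the serial-crystallography indexing ambiguity by expectation maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving the serial-crystallography indexing ambiguity by expectation maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In serial femtosecond crystallography (SFX), each X-ray pulse produces one
still diffraction snapshot from a fresh, randomly oriented nanocrystal that
is destroyed in the process.  Two features of these data interact badly:

1. **Partiality.** A still exposure samples only a sliver of each
   mosaic-broadened reflection, so every recorded Bragg intensity is a
   *partial* reflection — the full integrated intensity multiplied by an
   unknown per-observation factor in (0, 1].
2. **Indexing ambiguity.** When the Bravais lattice has higher symmetry
   than the space group (e.g. point group 6 crystals such as photosystem I
   in P6~3~), auto-indexing from spot positions alone cannot distinguish
   twin-related settings like (h,k,l) and (k,h,−l).  Merging thousands of
   patterns with modes chosen at random produces a data set that looks
   like one from a physically twinned crystal: each merged intensity tends
   to the average of the two twin-mate intensities, and its correlation
   with the true data saturates at 1/√2 ≈ 0.71.

The remedy implemented here ("detwinning") assigns a *consistent indexing
mode* to every pattern before merging.  It is not a correction for
physical twinning.

## The algorithm

For a pattern *i* with partial intensities {I~i~} and a model of full
intensities {I~full~}, the package uses the Pearson correlation
r~i~^t^ computed over the reflections the two share, where *t* indexes
the candidate reindexing operators (the *ambiguity group*: identity plus,
for the two-mode case, an involutory twin law).  Pearson correlation is
invariant under per-pattern scale, so no scaling of the raw intensities is
required for assignment.

The expectation-maximization loop (`run_em()`):

1. Initialize the model with independent Uniform(0,1) intensities over the
   union of all observed canonical indices under *every* mode (the union
   makes the starting index set invariant under the twin law, so the whole
   loop is exactly gauge-symmetric: relabelling the ground truth merely
   swaps the mode labels).
2. **E step** (`assign_modes()`): compute r~i~^t^ for every pattern and
   mode against the current model; assign each pattern the mode with the
   highest defined correlation.
3. **M step** (`merge_dataset()`): reindex each pattern by its assigned
   operator, map every index to a canonical asymmetric-unit
   representative, and average all observations of each canonical index
   (Monte Carlo merging — the error of each mean falls as the inverse
   square root of its multiplicity).
4. Repeat until no pattern (or fewer than `convergence_fraction` of them)
   changes mode, or `max_iterations` is reached (the state is then flagged
   not converged).

The monitored *target score* is the mean over patterns of the best
per-mode correlation; it rises as merging becomes consistent and is
recorded per iteration without assuming monotonicity.  The loop implements
a coordinate ascent on the summed per-pattern best correlation; the test
suite checks on an enumerable 5-pattern problem that the EM fixed point
coincides with the brute-force maximizer of that objective up to the
global gauge flip.

On the first iteration the model is random, so assignments are
coin flips and the two mode populations split about 50/50; the small
random imbalance seeds a preferred gauge that subsequent iterations
amplify.  Because the two final gauges are equivalent, evaluation labels
the mode of a merged model that best matches a reference as the
*consistent indexing mode* (CIM) and the others as *alternative indexing
modes* (AIM); CIM/AIM labels are interchangeable by a global flip, and all
consistency fractions reported by `label_and_score()` are computed after
gauge alignment (so they are invariant under flipping either reference).
Reference intensities are used only for evaluation; `run_em()` takes no
reference argument.

## Tunable parameters

* `min_common` (default 5): minimum shared reflections for a correlation
  to be defined.  Pearson on fewer points is dominated by noise; patterns
  undefined in every mode are kept in the merge under a seeded random mode
  and re-evaluated each iteration.
* `low_res_cutoff_d` (default 20 Å, applied when a unit cell is
  supplied): reflections with larger d-spacing are excluded from
  correlations.  The few extremely intense low-resolution reflections are
  nearly twin-symmetric in a merged model and compress the contrast
  between modes; excluding them sharpens assignment.
* `convergence_fraction` (default 0.001) and `max_iterations` (default
  20): the stopping rule.  At the scales exercised here convergence
  typically occurs within ten iterations.
* Tie-breaking: equal correlations keep the previous iteration's mode
  (hysteresis, which prevents oscillation), otherwise the lowest mode
  index — deterministic given the seed.
* A single integer seed governs the random starting model and any random
  fallback assignments, making every run exactly reproducible.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the algorithm
exploits, with none of the experimental plumbing:

* **Full intensities** are i.i.d. exponential (Wilson statistics for
  acentric reflections) over the canonical lattice, so twin-related index
  pairs carry independent intensities — the information detwinning relies
  on.  Structure factors are *not* computed from atomic coordinates.
* **Partialities** are either Uniform(0,1), independent of resolution, or
  drawn from Uniform(lo(q), 1] with lo(q) = p_floor + (1 − p_floor)·q/q_max
  — a monotone family reproducing the qualitative trend that the Ewald
  shell is thicker at high scattering angle, so high-resolution partial
  intensities are closer to full.  Note this family has mean partiality
  ≥ 0.5 by construction; severe-partiality regimes with mean below 0.4
  are outside its reach.
* **Shot noise** replaces each partial intensity by a Poisson draw with
  that mean (unbiased, variance = mean).
* **Modes**: each pattern's true indexing mode is drawn from
  `mode_probabilities` (uniform by default) and its reflections are
  recorded under the mode-reindexed Miller indices.

What it does **not** emulate: the curved Ewald-slice geometry of real
patterns (reflection subsets are uniform over the lattice), shot-to-shot
beam fluctuations and crystal-size variation, detector artefacts such as
saturated pixels, background subtraction (simulated intensities are never
negative), and systematic absences.  Passing tests therefore demonstrate
the statistical mechanism of mode recovery, not robustness to every
experimental pathology.

### The default desk-scale lattice

The default cell is hexagonal a = b = 100 Å, c = 58.8 Å — the axial ratio
of photosystem I (the preset `cell_psi()` provides the full-size
281/165.2 Å cell) at roughly a third of the scale — with reflections to
3 Å, giving ~6,700 unique indices under point group 6 with Friedel
pairing.  The scale balances two artefacts:

* A full-size cell yields ~1.5×10⁵ unique reflections, so a few thousand
  patterns of ~100 reflections give per-reflection multiplicities of only
  1–5, far below the Monte Carlo regime in which partiality averages out.
* A very small cell inflates the fraction of *twin-invariant* reflections
  — the planes h = k, h = −k, k = −2h (and images) are fixed classes of
  (h,k,l)→(k,h,−l) modulo the point group — whose twin mates cannot be
  independent.  At quarter scale ~15% of the lattice is invariant and the
  perfectly twinned correlation rises to ~0.76 instead of 1/√2; at the
  chosen scale the invariant fraction is ~10% and the realized twinned
  correlation is 0.71–0.73.

## Numerical and design choices

* Canonical asymmetric-unit representative: the lexicographically
  greatest (h,k,l) over the orbit (point-group rotations, optionally
  Friedel mates).  Arbitrary but total, deterministic and cheap; any fixed
  order would do.
* Miller indices are packed into a single double (offset base-8192
  digits) for exact, vectorized set operations up to |index| < 4096.
* Resolution uses the general triclinic reciprocal-metric tensor; the
  hexagonal closed form 1/d² = 4(h²+hk+k²)/(3a²) + l²/c² serves as an
  independent oracle in the tests (agreement to 1e−9 relative).
* Resolution shells are half-open in d, [d_min, d_max), so adjacent
  shells never double count; the evaluation default is the 3–5 Å shell
  with a full-range option.
* Merged means are plain unweighted averages (no per-pattern scaling, no
  sigma weighting); model entries observed by no pattern under the
  current assignment drop out and are invisible to correlations.
* Negative experimental intensities are retained — Pearson correlation is
  translation-invariant and clipping would bias weak reflections.
* Per-pattern correlations in the EM loop are computed by grouped
  centered sums (one pass of means, one of centered products), which
  matches the direct two-vector formula to 1e−12 and scales to millions of
  observations.
* Undefined correlations (too few common reflections, zero variance) are
  `NA` values, not errors, and propagate as "no information".

## Problem sizes used in the checks

The packaged studies run at: 2,000 patterns for the perfectly twinned
merge (multiplicity ~30); 10,000 patterns for near-perfect recovery under
resolution-dependent partiality; 20 seeded random models on an
800-pattern dataset for the first-iteration 50/50 split; ten random
starts on 2,000–5,000-pattern datasets for multi-run consistency in the
3–5 Å shell; and 250/1,000/4,000 patterns for the N^(−1/2) Monte Carlo
error decay.  A deliberately degenerate set (40 patterns of ~10
reflections over the full lattice) reproduces the failure mode in which
consistency stays near 50%.

## Known limitations

* Only the merging point groups "1" and "6" are built in; other groups
  must be supplied as explicit operator lists.  There is no systematic-
  absence handling and no full space-group machinery.
* The ambiguity group is validated for the two-mode involution case;
  groups with more modes are accepted and composed, but the packaged
  simulations exercise two modes.
* No partiality post-refinement or multi-crystal scaling: merged means
  estimate mean-partiality-scaled full intensities, which is why the
  converged model-truth correlation under the resolution-dependent
  protocol is "about 0.99" rather than 1 — the q-dependent mean
  partiality is a residual systematic on the merged means.
* Orientation recovery for un-indexed patterns (continuous-rotation EM in
  the single-particle style) is out of scope; patterns must arrive
  indexed up to the ambiguity.
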