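# Synthetic partial-reflection generator: Wilson (exponential) full
# intensities, uniform or resolution-dependent partialities, Poisson shot
# noise, and a random twin-related indexing mode per pattern, with the
# complete ground truth recorded.

#' Simulation configuration
#'
#' Defaults describe a desk-scale hexagonal crystal: a reduced
#' photosystem-I-like cell (a = b = 100, c = 58.8 Angstrom, same axial
#' ratio as the PSI preset [cell_psi()]), reflections to 3 Angstrom
#' (~6,700 unique indices under point group 6 with Friedel pairing), about
#' 100 partial reflections per pattern, full intensities with mean 1000
#' photons, and Poisson counting noise.  At these sizes a few thousand
#' patterns give per-reflection multiplicities in the tens to hundreds,
#' the regime in which Monte Carlo merging averages partiality out, while
#' the fraction of twin-invariant reflections (whose twin mates cannot be
#' independent) stays near 10%.
#'
#' @param n_patterns number of patterns to simulate.
#' @param reflections_per_pattern mean reflections per pattern (the count
#'   is Poisson with this mean, truncated below at `min_reflections`).
#' @param cell a [unit_cell()] defining the lattice geometry.
#' @param d_min high-resolution limit of the lattice in Angstrom.
#' @param intensity_scale mean Wilson (exponential) full intensity, in
#'   photons.
#' @param partiality_model `"uniform"` (partialities ~ Uniform(0,1),
#'   independent of resolution) or `"resolution_dependent"` (drawn from
#'   Uniform(lo(q), 1] with lo(q) = p_floor + (1 - p_floor) q/q_max, so the
#'   expected partiality rises towards 1 at the resolution edge, emulating
#'   the thicker Ewald shell at high scattering angle).
#' @param p_floor low-q asymptote of the resolution-dependent model,
#'   in (0, 1].
#' @param noise `"poisson"` (observed intensity is a Poisson draw with the
#'   partial intensity as mean) or `"none"`.
#' @param mode_probabilities probability of each indexing mode (default
#'   uniform over the ambiguity group's modes).
#' @param min_reflections lower truncation of the per-pattern reflection
#'   count (default 5, matching the default `min_common`).
#' @param seed integer seed; identical configurations give byte-identical
#'   datasets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patterns = 1000L, reflections_per_pattern = 100,
                       cell = cell_hexagonal(100, 58.8), d_min = 3,
                       intensity_scale = 1000,
                       partiality_model = c("uniform", "resolution_dependent"),
                       p_floor = 0.1, noise = c("poisson", "none"),
                       mode_probabilities = NULL, min_reflections = 5L,
                       seed = 1L) {
  partiality_model <- match.arg(partiality_model)
  noise <- match.arg(noise)
  stopifnot(n_patterns > 0L, reflections_per_pattern > 0, d_min > 0,
            intensity_scale > 0, p_floor > 0, p_floor <= 1,
            min_reflections >= 1L)
  if (!is.null(mode_probabilities)) {
    stopifnot(all(mode_probabilities >= 0),
              abs(sum(mode_probabilities) - 1) < 1e-8)
  }
  structure(list(n_patterns = as.integer(n_patterns),
                 reflections_per_pattern = reflections_per_pattern,
                 cell = cell, d_min = d_min,
                 intensity_scale = intensity_scale,
                 partiality_model = partiality_model, p_floor = p_floor,
                 noise = noise, mode_probabilities = mode_probabilities,
                 min_reflections = as.integer(min_reflections),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Enumerate the canonical reflection lattice of a cell
#'
#' All symmetry-unique Miller indices (asymmetric-unit representatives
#' under `pg`) with d-spacing >= `d_min`, excluding the origin.
#'
#' @param cell a [unit_cell()].
#' @param d_min high-resolution limit in Angstrom.
#' @param pg a [point_group()].
#' @return n x 3 integer matrix of canonical indices.
#' @export
lattice_indices <- function(cell, d_min, pg = point_group("6")) {
  Gs <- .reciprocal_metric(cell)
  lim <- ceiling(1 / (d_min * sqrt(diag(Gs))))
  grid <- as.matrix(expand.grid(h = -lim[1L]:lim[1L], k = -lim[2L]:lim[2L],
                                l = -lim[3L]:lim[3L]))
  grid <- grid[rowSums(grid != 0) > 0L, , drop = FALSE]
  q2 <- rowSums((grid %*% Gs) * grid)
  grid <- grid[1 / sqrt(q2) >= d_min, , drop = FALSE]
  if (!nrow(grid)) stop("no reflections in the lattice at d_min = ", d_min)
  can <- asu_map(grid, pg)
  unique_keys <- !duplicated(.pack_hkl(can))
  can[unique_keys, , drop = FALSE]
}

#' Wilson (exponential) full intensities over a lattice
#'
#' Acentric reflection intensities follow an exponential distribution;
#' drawing them i.i.d. over canonical indices gives twin-related index
#' pairs independent intensities (except self-paired twin-invariant
#' indices), which is exactly the statistical structure the detwinning
#' statistic exploits.
#'
#' @param hkl canonical Miller indices (n x 3).
#' @param intensity_scale mean intensity.
#' @param seed optional integer seed (current RNG stream when `NULL`).
#' @return a [merged_model()] with `n_obs = 1` per entry.
#' @export
wilson_intensities <- function(hkl, intensity_scale = 1, seed = NULL) {
  m <- as_miller(hkl)
  if (!nrow(m)) stop("empty lattice")
  if (!is.null(seed)) set.seed(seed)
  merged_model(m, rexp(nrow(m), rate = 1 / intensity_scale), rep(1L, nrow(m)))
}

#' Draw partialities for a set of reflections
#'
#' `"uniform"`: Uniform(0,1), independent of resolution.
#' `"resolution_dependent"`: Uniform(lo(q), 1] with
#' lo(q) = p_floor + (1 - p_floor) q/q_max and q = 1/d, q_max = 1/d_min;
#' the expected partiality increases strictly with scattering angle
#' (the Ewald shell is thicker at higher resolution, so high-angle partial
#' intensities are closer to the full reflection).
#'
#' @param hkl Miller indices (matrix).
#' @param cell a [unit_cell()].
#' @param partiality_model `"uniform"` or `"resolution_dependent"`.
#' @param p_floor low-q asymptote in (0, 1].
#' @param d_min resolution limit defining q_max = 1/d_min.
#' @return numeric vector of partialities in (0, 1]; draws come from the
#'   current RNG stream.
#' @export
draw_partiality <- function(hkl, cell, partiality_model = "uniform",
                            p_floor = 0.1, d_min = 3) {
  m <- as_miller(hkl)
  n <- nrow(m)
  if (partiality_model == "uniform") return(runif(n))
  q <- 1 / resolution_d(m, cell)
  lo <- p_floor + (1 - p_floor) * pmin(q * d_min, 1)
  runif(n, min = lo, max = 1)
}

#' Simulate a dataset of partial-reflection patterns with ground truth
#'
#' Draws a Wilson full-intensity model over the cell's canonical lattice;
#' then, for each pattern, samples a reflection subset uniformly without
#' replacement, draws a true indexing mode, multiplies each full intensity
#' by a random partiality, optionally replaces the result by a Poisson
#' draw (shot noise), and records the observation under the mode-reindexed
#' Miller indices -- so the dataset carries the indexing ambiguity that
#' the EM loop must resolve.  Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @return list with `dataset` (a [dataset()]) and `truth`, a list of
#'   class `ground_truth` carrying `true_model` (a [merged_model()]),
#'   `true_modes` (named integer vector, 1-based mode per pattern) and
#'   `true_partialities` (data.table: pattern_id, h, k, l of the true
#'   canonical index, partiality).
#' @export
simulate_dataset <- function(cfg, g = ambiguity_group(), pg = point_group("6")) {
  ok <- validate_group(g)
  if (!isTRUE(ok)) stop("invalid ambiguity group")
  set.seed(cfg$seed)
  lat <- lattice_indices(cfg$cell, cfg$d_min, pg)
  n_lat <- nrow(lat)
  if (cfg$reflections_per_pattern > n_lat)
    stop("reflections_per_pattern (", cfg$reflections_per_pattern,
         ") exceeds the lattice size (", n_lat, ")")
  truth_model <- wilson_intensities(lat, cfg$intensity_scale)
  # wilson_intensities sorts by (h,k,l); work in its order
  lat <- as_miller(truth_model)
  I_true <- truth_model$mean_intensity

  N <- cfg$n_patterns
  Tm <- g$n_modes
  probs <- if (is.null(cfg$mode_probabilities)) rep(1 / Tm, Tm)
           else cfg$mode_probabilities
  counts <- pmin(pmax(rpois(N, cfg$reflections_per_pattern),
                      cfg$min_reflections), n_lat)
  true_modes <- sample.int(Tm, N, replace = TRUE, prob = probs)
  rows <- unlist(lapply(counts, function(n) sample.int(n_lat, n)),
                 use.names = FALSE)
  pat <- rep.int(seq_len(N), counts)

  p_part <- draw_partiality(lat[rows, , drop = FALSE], cfg$cell,
                            cfg$partiality_model, cfg$p_floor, cfg$d_min)
  signal <- p_part * I_true[rows]
  obs_I <- if (cfg$noise == "poisson") as.numeric(rpois(length(signal), signal))
           else signal

  # observed indices are the true canonical indices pushed through the
  # pattern's true mode operator
  hkl_obs <- lat[rows, , drop = FALSE]
  for (t in seq_len(Tm)) {
    sel <- true_modes[pat] == t
    if (any(sel))
      hkl_obs[sel, ] <- apply_operator(g$operators[[t]], hkl_obs[sel, , drop = FALSE])
  }

  ids <- sprintf("sim_%05d", seq_len(N))
  ends <- cumsum(counts)
  starts <- c(1L, head(ends, -1L) + 1L)
  pats <- vector("list", N)
  for (i in seq_len(N)) {
    sl <- starts[i]:ends[i]
    pats[[i]] <- pattern(ids[i], hkl_obs[sl, , drop = FALSE], obs_I[sl],
                         source = "simulated")
  }
  names(true_modes) <- ids
  truth <- structure(list(
    true_model = truth_model,
    true_modes = true_modes,
    true_partialities = data.table(pattern_id = ids[pat],
                                   h = lat[rows, 1L], k = lat[rows, 2L],
                                   l = lat[rows, 3L], partiality = p_part)),
    class = "ground_truth")
  list(dataset = dataset(pats), truth = truth)
}
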