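# Reference-based and reference-free evaluation: CIM/AIM labelling,
# consistency fractions, model-model correlations in resolution shells,
# multi-run consistency, dataset-size sweeps and the pairwise-vs-model
# separability comparison.  Reference intensities are only ever compared
# against results; run_em() takes no reference argument.

#' Promote a single pattern to a merged model
#'
#' Canonicalizes the pattern's indices and installs each mean intensity
#' with `n_obs = 1`.  Used e.g. to compare pairwise (pattern-vs-pattern)
#' and pattern-vs-model correlation on equal footing.
#'
#' @param p a [pattern()].
#' @param pg a [point_group()].
#' @return a [merged_model()].
#' @export
as_merged_model <- function(p, pg = point_group("6")) {
  km <- .pattern_key_means(p, op_identity(), pg)
  merged_model(.unpack_hkl(km$hklkey), km$I, rep(1L, nrow(km)))
}

#' Correlate two merged models under every indexing mode
#'
#' For each operator of the ambiguity group, reindexes `b`, intersects
#' with `a` (entries with observations on both sides, optionally within a
#' resolution shell), and computes the Pearson correlation.  The mode with
#' the highest correlation is labelled the consistent indexing mode (CIM);
#' the alternatives are AIMs, so `r_cim >= r_aim` by construction.
#'
#' @param a,b [merged_model()] objects (non-empty).
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param shell optional `c(d_min, d_max)` resolution shell in Angstrom
#'   (half-open, `d_min <= d < d_max`); requires `cell`.
#' @param cell a [unit_cell()], needed when `shell` is given.
#' @param min_common minimum common reflections for a defined correlation.
#' @return object of class `model_comparison`: list with `r_per_mode`,
#'   `n_common_per_mode`, `cim_mode`, `r_cim`, `r_aim` (highest
#'   alternative-mode correlation, `NA` for a one-mode group), `shell`.
#' @export
model_model_correlation <- function(a, b, g = ambiguity_group(),
                                    pg = point_group("6"), shell = NULL,
                                    cell = NULL, min_common = 5L) {
  if (!nrow(a) || !nrow(b)) stop("models must be non-empty")
  asel <- a$n_obs > 0L
  ahkl <- as_miller(a)[asel, , drop = FALSE]
  akey <- .pack_hkl(ahkl)
  aval <- a$mean_intensity[asel]
  if (!is.null(shell)) {
    if (is.null(cell)) stop("a unit cell is required for shell selection")
    d <- resolution_d(ahkl, cell)
    keep <- d >= shell[1L] & d < shell[2L]
    akey <- akey[keep]; aval <- aval[keep]
  }
  bsel <- b$n_obs > 0L
  bhkl <- as_miller(b)[bsel, , drop = FALSE]
  bval <- b$mean_intensity[bsel]
  Tm <- g$n_modes
  r <- rep(NA_real_, Tm); n <- integer(Tm)
  for (t in seq_len(Tm)) {
    bk <- .pack_hkl(asu_map(apply_operator(g$operators[[t]], bhkl), pg))
    idx <- match(akey, bk)
    ok <- !is.na(idx)
    n[t] <- sum(ok)
    if (n[t] >= min_common) r[t] <- pearson(aval[ok], bval[idx[ok]])
  }
  if (all(is.na(r)))
    stop("fewer than min_common overlapping reflections in every mode")
  cim <- which.max(replace(r, is.na(r), -2))
  structure(list(r_per_mode = r, n_common_per_mode = n, cim_mode = cim,
                 r_cim = r[cim],
                 r_aim = if (Tm > 1L) max(r[-cim], na.rm = TRUE) else NA_real_,
                 shell = if (is.null(shell)) "all" else shell),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> r_cim = %.4f (mode %d), r_aim = %.4f\n",
              x$r_cim, x$cim_mode, x$r_aim))
  invisible(x)
}

# fraction of patterns whose gauge-aligned mode matches reference modes:
# aligns the state's assignments to the frame of `ref_model` through the
# CIM gauge, then compares with `ref_modes` (a named integer vector)
.aligned_consistency <- function(state, ref_model, ref_modes, g, pg,
                                 shell = NULL, cell = NULL, min_common = 5L) {
  mm <- model_model_correlation(state$model, ref_model, g, pg,
                                shell = shell, cell = cell,
                                min_common = min_common)
  modes <- state$assignments$mode
  rel <- vapply(modes, function(m) .compose_mode(g, mm$cim_mode, m), 0L)
  mean(rel == ref_modes[state$assignments$pattern_id])
}

#' Label indexing modes against a reference model and score consistency
#'
#' Determines the global gauge (which mode of the final model agrees with
#' the reference -- the CIM) from the model-model correlation, then
#' reports (a) the fraction of patterns whose EM-assigned mode, aligned
#' through that gauge, matches the per-pattern mode assigned directly from
#' the reference model (the "consistently indexed" fraction), and, when
#' ground truth is available, (b) the fraction matching the true modes
#' (aligned through the model-truth gauge, so the result is invariant
#' under a gauge flip of either reference).
#'
#' @param state an `em_state` from [run_em()].
#' @param ds the [dataset()] the state was computed from (needed to
#'   re-correlate each pattern against the reference).
#' @param reference reference [merged_model()] (e.g. calculated
#'   intensities from a known structure, or a simulation's true model).
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param truth optional `ground_truth` from [simulate_dataset()].
#' @param cell,low_res_cutoff,min_common see [pattern_model_correlation()].
#' @param shell optional resolution shell for the gauge determination.
#' @return list with `gauge_mode`, `r_cim`, `r_aim`,
#'   `consistency_reference`, `consistency_truth` (`NA` without truth) and
#'   `n_patterns`.
#' @export
label_and_score <- function(state, ds, reference, g = ambiguity_group(),
                            pg = point_group("6"), truth = NULL,
                            cell = NULL, low_res_cutoff = 20,
                            min_common = 5L, shell = NULL) {
  if (!nrow(reference)) stop("reference model must be non-empty")
  mm <- model_model_correlation(state$model, reference, g, pg,
                                shell = shell, cell = cell,
                                min_common = min_common)
  modes <- state$assignments$mode
  rel <- vapply(modes, function(m) .compose_mode(g, mm$cim_mode, m), 0L)
  ref_assign <- assign_modes(ds, reference, g, pg, cell = cell,
                             low_res_cutoff = low_res_cutoff,
                             min_common = min_common, seed = 0L)$assignments
  ref_modes <- ref_assign$mode[match(state$assignments$pattern_id,
                                     ref_assign$pattern_id)]
  cons_ref <- mean(rel == ref_modes)
  cons_truth <- if (!is.null(truth)) {
    .aligned_consistency(state, truth$true_model, truth$true_modes, g, pg,
                         shell = shell, cell = cell, min_common = min_common)
  } else NA_real_
  list(gauge_mode = mm$cim_mode, r_cim = mm$r_cim, r_aim = mm$r_aim,
       consistency_reference = cons_ref, consistency_truth = cons_truth,
       n_patterns = length(modes))
}

#' Pairwise consistency matrix of several final models
#'
#' All-pairs [model_model_correlation()] over the final models of
#' independently started runs; the lower triangle holds the same-gauge
#' (CIM) correlations and the upper triangle the alternative-mode (AIM)
#' correlations; the diagonal is 1.
#'
#' @param models list of >= 2 [merged_model()] objects.
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param shell,cell,min_common see [model_model_correlation()].
#' @return list with `matrix` (n x n numeric) and `comparisons` (list of
#'   `model_comparison` keyed "i_j").
#' @export
multi_run_consistency <- function(models, g = ambiguity_group(),
                                  pg = point_group("6"), shell = NULL,
                                  cell = NULL, min_common = 5L) {
  n <- length(models)
  if (n < 2L) stop("need at least two models")
  M <- diag(1, n)
  comparisons <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mc <- model_model_correlation(models[[i]], models[[j]], g, pg,
                                  shell = shell, cell = cell,
                                  min_common = min_common)
    M[j, i] <- mc$r_cim
    M[i, j] <- mc$r_aim
    comparisons[[paste(i, j, sep = "_")]] <- mc
  }
  list(matrix = M, comparisons = comparisons)
}

#' Ground-truth consistency as a function of dataset size
#'
#' For each requested size (and replicate) simulates a fresh dataset from
#' the base configuration, runs the EM loop, and reports the percentage of
#' patterns whose gauge-aligned mode matches the ground truth.  Small
#' datasets with few reflections per pattern are expected to stay near 50%
#' (detwinning fails when Monte Carlo merging cannot approximate the full
#' intensities).
#'
#' @param base a [sim_config()]; `n_patterns` is overridden per size and
#'   the seed is varied deterministically per (size, replicate).
#' @param sizes integer vector of dataset sizes.
#' @param replicates replicates per size (>= 1).
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param em base [em_config()]; its seed is re-derived per run.
#' @return data.frame with columns `size`, `mean_consistency_pct`,
#'   `sd_consistency_pct` (NA for a single replicate).
#' @export
size_sweep <- function(base, sizes, replicates = 1L, g = ambiguity_group(),
                       pg = point_group("6"), em = em_config()) {
  stopifnot(replicates >= 1L)
  rows <- lapply(sizes, function(s) {
    pct <- vapply(seq_len(replicates), function(r) {
      cfg <- base
      cfg$n_patterns <- as.integer(s)
      cfg$seed <- as.integer((base$seed + s + 99991L * r) %% .Machine$integer.max)
      sim <- simulate_dataset(cfg, g, pg)
      ec <- em
      ec$seed <- cfg$seed + 1L
      st <- run_em(sim$dataset, g, pg, ec)
      100 * .aligned_consistency(st, sim$truth$true_model,
                                 sim$truth$true_modes, g, pg)
    }, 0)
    data.frame(size = s, mean_consistency_pct = mean(pct),
               sd_consistency_pct = if (replicates > 1L) sd(pct) else NA_real_)
  })
  do.call(rbind, rows)
}

# standardized mean difference between best-mode and other-mode values
.separation_stat <- function(corr_long) {
  dt <- as.data.table(corr_long)
  per <- dt[!is.na(r), {
    b <- which.max(r)
    list(best = r[b], other = if (.N > 1L) r[-b] else NA_real_)
  }, by = "pattern_id"]
  best <- per[, list(best = best[1L]), by = "pattern_id"]$best
  other <- per$other[!is.na(per$other)]
  if (!length(other) || length(best) < 2L) return(NA_real_)
  (mean(best) - mean(other)) / sqrt((var(best) + var(other)) / 2)
}

#' Compare pairwise and pattern-vs-model mode separability
#'
#' For every pattern computes the per-mode correlation against (i) one
#' reference pattern (the pairwise, partial-vs-partial statistic) and
#' (ii) a merged full-intensity model (the EM statistic), and summarizes
#' each method by a standardized mean difference between the best-mode and
#' other-mode correlations.  A larger separation means the method
#' distinguishes the indexing modes more reliably.
#'
#' @param ds a [dataset()].
#' @param model a [merged_model()] (e.g. a converged EM model).
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param reference_pattern a [pattern()] to play the pairwise reference.
#' @param cell,low_res_cutoff applied to the model method only (and only
#'   when `cell` is non-NULL), mirroring [pattern_model_correlation()].
#' @param min_common minimum common reflections.
#' @return list with `pair` and `model` (long data.tables: pattern_id,
#'   mode, r, n_common) and `separation` (named vector, one standardized
#'   mean difference per method).
#' @export
separability_comparison <- function(ds, model, g = ambiguity_group(),
                                    pg = point_group("6"), reference_pattern,
                                    cell = NULL, low_res_cutoff = 20,
                                    min_common = 5L) {
  ref_model <- as_merged_model(reference_pattern, pg)
  pair <- assign_modes(ds, ref_model, g, pg, cell = NULL,
                       min_common = min_common, seed = 0L)$correlations
  mdl <- assign_modes(ds, model, g, pg, cell = cell,
                      low_res_cutoff = low_res_cutoff,
                      min_common = min_common, seed = 0L)$correlations
  list(pair = pair, model = mdl,
       separation = c(pair = .separation_stat(pair),
                      model = .separation_stat(mdl)))
}
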