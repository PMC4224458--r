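# The detwinning algorithm: Pearson statistics, mode assignment, Monte
# Carlo merging, random initialization, the EM loop and the target score.

#' Pearson correlation with an undefined-value signal
#'
#' Standard product-moment correlation over the supplied entries.  Instead
#' of raising an error, degenerate inputs (fewer than two points, or zero
#' variance in either vector) return `NA_real_`; callers treat `NA` as
#' "no information", which is how undefined pattern/model correlations are
#' propagated throughout the EM loop.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) return(NA_real_)
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# mean intensities per canonical key for a raw pattern (patterns built
# without a point group may still carry orbit duplicates)
.pattern_key_means <- function(p, op, pg) {
  hkl <- as_miller(p$refl)
  img <- asu_map(apply_operator(op, hkl), pg)
  dt <- data.table(hklkey = .pack_hkl(img), I = p$refl$intensity)
  dt[, list(I = mean(I)), by = "hklkey"]
}

#' Pairwise correlation between two patterns
#'
#' Reindexes `q` by `op`, canonicalizes both patterns, intersects their
#' index sets and computes the Pearson correlation over the common
#' reflections (means taken over the common entries only).  This is the
#' pairwise statistic used by clustering-style approaches and serves here
#' as the baseline against which the pattern-vs-model statistic is
#' compared.
#'
#' @param p,q [pattern()] objects.
#' @param op the [reindex_op()] applied to `q`.
#' @param pg a [point_group()].
#' @param min_common minimum shared reflections for a defined correlation.
#' @return list with `r` (`NA_real_` when undefined) and `n_common`.
#' @export
pattern_pair_correlation <- function(p, q, op = op_identity(),
                                     pg = point_group("6"), min_common = 5L) {
  a <- .pattern_key_means(p, op_identity(), pg)
  b <- .pattern_key_means(q, op, pg)
  idx <- match(a$hklkey, b$hklkey)
  ok <- !is.na(idx)
  n <- sum(ok)
  if (n < min_common) return(list(r = NA_real_, n_common = n))
  list(r = pearson(a$I[ok], b$I[idx[ok]]), n_common = n)
}

#' Correlation between a pattern and a merged full-intensity model
#'
#' Reindexes the pattern's indices by `op`, canonicalizes, matches against
#' model entries with at least one observation, and computes the Pearson
#' correlation between the pattern's partial intensities and the model's
#' mean intensities over the matched set.  Reflections at very low
#' resolution (d-spacing above `low_res_cutoff`) are excluded when a unit
#' cell is supplied, since their extreme intensities dominate the
#' correlation and carry no mode information.
#'
#' @param p a [pattern()].
#' @param model a [merged_model()].
#' @param op the [reindex_op()] applied to the pattern.
#' @param pg a [point_group()].
#' @param cell optional [unit_cell()]; required for the low-resolution
#'   exclusion, which is skipped when `cell` is `NULL`.
#' @param low_res_cutoff exclude reflections with d > this many Angstrom.
#' @param min_common minimum matched reflections for a defined correlation.
#' @return list with `r` (`NA_real_` when undefined) and `n_common`.
#' @export
pattern_model_correlation <- function(p, model, op = op_identity(),
                                      pg = point_group("6"), cell = NULL,
                                      low_res_cutoff = 20, min_common = 5L) {
  a <- .pattern_key_means(p, op, pg)
  keep <- model$n_obs > 0L
  if (!is.null(cell))
    keep <- keep & resolution_d(as_miller(model), cell) <= low_res_cutoff
  mk <- .pack_hkl(as_miller(model)[keep, , drop = FALSE])
  mv <- model$mean_intensity[keep]
  idx <- match(a$hklkey, mk)
  ok <- !is.na(idx)
  n <- sum(ok)
  if (n < min_common) return(list(r = NA_real_, n_common = n))
  list(r = pearson(a$I[ok], mv[idx[ok]]), n_common = n)
}

#' Random starting model
#'
#' The first EM iteration correlates every pattern against a model of
#' independent Uniform(0,1) draws (random positive intensities), one per
#' canonical index, each with `n_obs = 1` so the entries are visible to
#' correlations.
#'
#' @param hkl canonical Miller indices (n x 3).
#' @param seed optional integer; when supplied the draw is seeded (and
#'   reproducible), otherwise the current RNG stream is used.
#' @return a [merged_model()].
#' @export
random_model <- function(hkl, seed = NULL) {
  m <- as_miller(hkl)
  if (!nrow(m)) stop("need at least one index")
  if (!is.null(seed)) set.seed(seed)
  merged_model(m, runif(nrow(m)), rep(1L, nrow(m)))
}

#' EM configuration
#'
#' @param max_iterations iteration cap (convergence is typically reached
#'   well within ten iterations).
#' @param min_common minimum shared reflections for a defined correlation.
#' @param low_res_cutoff_d reflections with d-spacing above this (Angstrom)
#'   are excluded from correlations (applied only when `cell` is given).
#' @param cell optional [unit_cell()] enabling the low-resolution cutoff.
#' @param convergence_fraction stop when the fraction of patterns changing
#'   mode falls below this (or when it reaches exactly zero).
#' @param seed integer seed governing the random starting model and any
#'   random assignments of all-undefined patterns.
#' @return list of class `em_config`.
#' @export
em_config <- function(max_iterations = 20L, min_common = 5L,
                      low_res_cutoff_d = 20, cell = NULL,
                      convergence_fraction = 0.001, seed = 1L) {
  stopifnot(max_iterations >= 1L, min_common >= 2L, convergence_fraction >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 min_common = as.integer(min_common),
                 low_res_cutoff_d = low_res_cutoff_d, cell = cell,
                 convergence_fraction = convergence_fraction,
                 seed = as.integer(seed)),
            class = "em_config")
}

# flatten a dataset into one observation table plus per-mode canonical keys
.compile_dataset <- function(ds, g, pg) {
  lst <- lapply(ds$patterns, function(p)
    data.table(h = p$refl$h, k = p$refl$k, l = p$refl$l, I = p$refl$intensity))
  obs <- rbindlist(lst, idcol = "pat")
  hkl <- as_miller(as.matrix(obs[, c("h", "k", "l")]))
  keymat <- matrix(0, nrow(obs), g$n_modes)
  for (t in seq_len(g$n_modes))
    keymat[, t] <- .pack_hkl(asu_map(apply_operator(g$operators[[t]], hkl), pg))
  list(obs = data.table(pat = obs$pat, I = obs$I), keymat = keymat,
       ids = vapply(ds$patterns, `[[`, "", "id"),
       n_patterns = ds$n_patterns, n_modes = g$n_modes)
}

# model entry keys/means that are admissible for correlations
.model_lookup <- function(model, cell, low_res_cutoff) {
  keep <- model$n_obs > 0L
  if (!is.null(cell))
    keep <- keep & resolution_d(as_miller(model), cell) <= low_res_cutoff
  list(keys = .pack_hkl(as_miller(model)[keep, , drop = FALSE]),
       means = model$mean_intensity[keep])
}

# per-pattern, per-mode Pearson correlations via grouped centered sums
.mode_correlations <- function(compiled, lookup, min_common) {
  N <- compiled$n_patterns; Tm <- compiled$n_modes
  rmat <- matrix(NA_real_, N, Tm)
  nmat <- matrix(0L, N, Tm)
  for (t in seq_len(Tm)) {
    y <- lookup$means[match(compiled$keymat[, t], lookup$keys)]
    ok <- !is.na(y)
    if (!any(ok)) next
    dt <- data.table(pat = compiled$obs$pat[ok], x = compiled$obs$I[ok], y = y[ok])
    s <- dt[, {
      mx <- mean(x); my <- mean(y)
      dx <- x - mx; dy <- y - my
      list(n = .N, sxy = sum(dx * dy), sxx = sum(dx * dx), syy = sum(dy * dy))
    }, by = "pat"]
    r <- ifelse(s$n >= min_common & s$sxx > 0 & s$syy > 0,
                s$sxy / sqrt(s$sxx * s$syy), NA_real_)
    rmat[s$pat, t] <- r
    nmat[s$pat, t] <- s$n
  }
  list(rmat = rmat, nmat = nmat)
}

# argmax with hysteresis: equal correlations keep the previous mode when it
# is among the maximizers, otherwise the lowest mode index wins
.pick_modes <- function(rmat, prev = NULL) {
  N <- nrow(rmat)
  rr <- rmat
  rr[is.na(rr)] <- -2        # below any real correlation
  mx <- rr[, 1L]
  if (ncol(rr) > 1L) for (t in 2:ncol(rr)) mx <- pmax(mx, rr[, t])
  mode <- max.col(rr, ties.method = "first")
  if (!is.null(prev)) {
    keep <- !is.na(prev) & rr[cbind(seq_len(N), prev)] == mx
    mode[keep] <- prev[keep]
  }
  undef <- mx == -2
  list(mode = mode, best_r = ifelse(undef, NA_real_, mx), undef = undef)
}

.merge_compiled <- function(compiled, modes) {
  key <- compiled$keymat[cbind(seq_len(nrow(compiled$keymat)),
                               modes[compiled$obs$pat])]
  agg <- data.table(hklkey = key, I = compiled$obs$I)[,
           list(s = sum(I), n = .N), by = "hklkey"]
  merged_model(.unpack_hkl(agg$hklkey), agg$s, agg$n)
}

.correlations_long <- function(compiled, cm) {
  data.table(pattern_id = rep(compiled$ids, times = compiled$n_modes),
             mode = rep(seq_len(compiled$n_modes), each = compiled$n_patterns),
             r = as.vector(cm$rmat), n_common = as.vector(cm$nmat))
}

#' Assign an indexing mode to every pattern
#'
#' Computes, for each pattern, the correlation against the model under
#' every operator of the ambiguity group, and assigns the mode with the
#' highest defined correlation.  Ties keep the previous mode when one is
#' supplied (hysteresis), otherwise the lowest mode index.  Patterns whose
#' correlations are undefined in every mode are assigned a uniformly random
#' mode (from the current RNG stream, or `seed` when given) and flagged.
#'
#' @param ds a [dataset()].
#' @param model a [merged_model()].
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param cell,low_res_cutoff,min_common see [pattern_model_correlation()].
#' @param prev optional integer vector of previous modes (hysteresis).
#' @param seed optional seed for the random fallback assignments.
#' @return list with `correlations` (data.table: pattern_id, mode, r,
#'   n_common) and `assignments` (data.table: pattern_id, mode, best_r,
#'   random).  Modes are 1-based indices into the group's operator list.
#' @export
assign_modes <- function(ds, model, g = ambiguity_group(),
                         pg = point_group("6"), cell = NULL,
                         low_res_cutoff = 20, min_common = 5L,
                         prev = NULL, seed = NULL) {
  ok <- validate_group(g)
  if (!isTRUE(ok)) stop("invalid ambiguity group")
  if (!is.null(seed)) set.seed(seed)
  compiled <- .compile_dataset(ds, g, pg)
  lookup <- .model_lookup(model, cell, low_res_cutoff)
  cm <- .mode_correlations(compiled, lookup, min_common)
  pick <- .pick_modes(cm$rmat, prev)
  if (any(pick$undef))
    pick$mode[pick$undef] <- sample.int(compiled$n_modes, sum(pick$undef),
                                        replace = TRUE)
  list(correlations = .correlations_long(compiled, cm),
       assignments = data.table(pattern_id = compiled$ids, mode = pick$mode,
                                best_r = pick$best_r, random = pick$undef))
}

#' Monte Carlo merge of a dataset under given mode assignments
#'
#' Each pattern's reflections are reindexed by its assigned operator,
#' mapped to canonical asymmetric-unit indices, and accumulated; the full
#' intensity estimate for each canonical index is the unweighted arithmetic
#' mean of all its observations (partiality and other stochastic factors
#' average out as the number of patterns grows).
#'
#' @param ds a [dataset()].
#' @param assignments data.frame with columns `pattern_id` and `mode`
#'   (one row per pattern), as produced by [assign_modes()].
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @return a [merged_model()].
#' @export
merge_dataset <- function(ds, assignments, g = ambiguity_group(),
                          pg = point_group("6")) {
  compiled <- .compile_dataset(ds, g, pg)
  idx <- match(compiled$ids, assignments$pattern_id)
  if (anyNA(idx)) stop("every pattern needs exactly one assignment")
  modes <- as.integer(assignments$mode[idx])
  if (any(modes < 1L | modes > compiled$n_modes)) stop("mode out of range")
  .merge_compiled(compiled, modes)
}

#' Target score of a set of mode correlations
#'
#' The mean over patterns of the highest per-mode correlation with the
#' current model.  It monitors EM progress and reaches its maximum when
#' all patterns are indexed consistently.  Patterns with undefined
#' correlations in every mode are excluded from both numerator and count.
#'
#' @param correlations data.frame with columns `pattern_id`, `mode`, `r`
#'   (as produced by [assign_modes()]).
#' @return the score (a single number).
#' @export
target_score <- function(correlations) {
  dt <- as.data.table(correlations)
  per <- dt[, list(best = if (all(is.na(r))) NA_real_
                          else max(r, na.rm = TRUE)), by = "pattern_id"]
  if (all(is.na(per$best)))
    stop("all patterns have undefined correlations")
  mean(per$best, na.rm = TRUE)
}

#' Run the expectation-maximization detwinning loop
#'
#' Initializes a model with random positive intensities over the union of
#' all observed canonical indices (under every mode, so the index set is
#' invariant under the twin law), then iterates: (E) assign every pattern
#' the mode with the highest correlation against the current model; (M)
#' re-merge the dataset under those assignments.  The loop stops when no
#' pattern changes mode (or fewer than `convergence_fraction` of them do),
#' or at `max_iterations`, in which case the returned state is flagged as
#' not converged.  The per-iteration target score is recorded but no
#' monotonicity is assumed.
#'
#' @param ds a [dataset()].
#' @param g an [ambiguity_group()].
#' @param pg a [point_group()].
#' @param config an [em_config()].
#' @return object of class `em_state`: a list with `iteration`, `model`,
#'   `assignments` (pattern_id, mode, best_r, random), `correlations`
#'   (final E-step, long form), `score_history`, `n_changed_history`,
#'   `mode_populations` (iterations x modes), `converged`, `config`.
#' @export
run_em <- function(ds, g = ambiguity_group(), pg = point_group("6"),
                   config = em_config()) {
  ok <- validate_group(g)
  if (!isTRUE(ok))
    stop("invalid ambiguity group: ", paste(attr(ok, "diagnostics"), collapse = "; "))
  if (!inherits(ds, "dataset") || ds$n_patterns < 1L) stop("empty dataset")
  set.seed(config$seed)
  compiled <- .compile_dataset(ds, g, pg)
  N <- compiled$n_patterns
  Tm <- compiled$n_modes
  keys_union <- sort(unique(as.vector(compiled$keymat)))
  model <- random_model(.unpack_hkl(keys_union))

  prev <- NULL
  score_history <- numeric(0)
  n_changed_history <- integer(0)
  populations <- matrix(0L, 0L, Tm)
  converged <- FALSE
  cm <- NULL
  pick <- NULL
  for (it in seq_len(config$max_iterations)) {
    lookup <- .model_lookup(model, config$cell, config$low_res_cutoff_d)
    cm <- .mode_correlations(compiled, lookup, config$min_common)
    pick <- .pick_modes(cm$rmat, prev)
    if (any(pick$undef))
      pick$mode[pick$undef] <- sample.int(Tm, sum(pick$undef), replace = TRUE)
    n_changed <- if (Tm == 1L) 0L
                 else if (is.null(prev)) N
                 else sum(pick$mode != prev)
    model <- .merge_compiled(compiled, pick$mode)
    score <- if (all(is.na(pick$best_r))) NA_real_
             else mean(pick$best_r, na.rm = TRUE)
    score_history <- c(score_history, score)
    n_changed_history <- c(n_changed_history, n_changed)
    populations <- rbind(populations, tabulate(pick$mode, Tm))
    prev <- pick$mode
    if ((it > 1L || Tm == 1L) &&
        (n_changed == 0L || n_changed / N < config$convergence_fraction)) {
      converged <- TRUE
      break
    }
  }
  structure(list(iteration = length(score_history), model = model,
                 assignments = data.table(pattern_id = compiled$ids,
                                          mode = pick$mode,
                                          best_r = pick$best_r,
                                          random = pick$undef),
                 correlations = .correlations_long(compiled, cm),
                 score_history = score_history,
                 n_changed_history = n_changed_history,
                 mode_populations = populations,
                 converged = converged, config = config),
            class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat("<em_state>", x$iteration, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("- final score %.4f\n", x$score_history[x$iteration]))
  cat("  mode populations:",
      paste(x$mode_populations[x$iteration, ], collapse = " / "), "\n")
  invisible(x)
}
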