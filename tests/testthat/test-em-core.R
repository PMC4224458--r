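test_that("pearson matches the textbook formula and signals degeneracy", {
  expect_equal(pearson(c(2, 4), c(1, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(100); y <- 0.3 * x + rnorm(100)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson(x, y), oracle, tolerance = 1e-12)
  }
  expect_true(is.na(pearson(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(pearson(1, 2)))
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("pattern_pair_correlation intersects common reflections", {
  set.seed(12)
  m <- asu_map(random_indices(40L, 10L), pg6())
  m <- m[!duplicated(emdetwin:::.pack_hkl(m)), , drop = FALSE]
  p <- pattern("a", m, runif(nrow(m), 1, 10))
  self <- pattern_pair_correlation(p, p, op_identity(), pg6())
  expect_equal(self$r, 1)
  expect_equal(self$n_common, nrow(p$refl))
  # disjoint index sets are undefined
  q <- pattern("b", cbind(m[, 1] + 40L, m[, 2], m[, 3]), runif(nrow(m)))
  dis <- pattern_pair_correlation(p, q, op_identity(), pg6())
  expect_true(is.na(dis$r))
  expect_equal(dis$n_common, 0L)
})

test_that("pattern_model_correlation is scale-free and ignores unobserved entries", {
  set.seed(13)
  m <- asu_map(random_indices(80L, 12L), pg6())
  m <- m[!duplicated(emdetwin:::.pack_hkl(m)), , drop = FALSE]
  means <- rexp(nrow(m), 1 / 100)
  model <- merged_model(m, means * 4, rep(4L, nrow(m)))
  p <- pattern("half", m[1:50, , drop = FALSE], 0.5 * means[1:50])
  res <- pattern_model_correlation(p, model, op_identity(), pg6())
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n_common, 50L)
  # entries with n_obs = 0 are invisible
  extra <- merged_model(rbind(m, c(31L, 0L, 0L)),
                        c(means * 4, 1e6), c(rep(4L, nrow(m)), 0L))
  res2 <- pattern_model_correlation(p, extra, op_identity(), pg6())
  expect_equal(res2$r, res$r)
  expect_equal(res2$n_common, res$n_common)
})

test_that("partial intensities correlate with full ones at the closed-form level", {
  # corr(p I, I) = (1/2) / sqrt(5/12) for p ~ U(0,1) independent of I ~ Exp
  set.seed(14)
  n <- 60000L
  hkl <- cbind(seq_len(n), 0L, 1L)   # distinct dummy indices
  I_full <- rexp(n)
  p <- pattern("u", hkl, runif(n) * I_full)
  model <- merged_model(hkl, I_full, rep(1L, n))
  res <- pattern_model_correlation(p, model, op_identity(),
                                   point_group("1", friedel = FALSE))
  expect_equal(res$r, 0.5 / sqrt(5 / 12), tolerance = 0.01)
})

test_that("assign_modes picks the correlation-maximizing mode", {
  set.seed(15)
  g <- hex_group(); pg <- pg6()
  lat <- lattice_indices(cell_hexagonal(40, 24), 3, pg)
  truth <- wilson_intensities(lat, 100)
  m <- as_miller(truth)
  # pattern that equals the model exactly under the twin mode
  obs_hkl <- apply_operator(g$operators[[2]], m[1:60, , drop = FALSE])
  p <- pattern("twinmate", obs_hkl, truth$mean_intensity[1:60])
  ds <- dataset(list(p))
  out <- assign_modes(ds, truth, g, pg)
  expect_equal(out$assignments$mode, 2L)
  expect_equal(out$assignments$best_r, 1, tolerance = 1e-12)
  # a one-mode group assigns everything to mode 1
  g1 <- ambiguity_group(list(op_identity()))
  expect_equal(assign_modes(ds, truth, g1, pg)$assignments$mode, 1L)
})

test_that("fast grouped correlations equal the per-pattern public path", {
  set.seed(16)
  cfg <- sim_config(n_patterns = 25, reflections_per_pattern = 60,
                    cell = cell_hexagonal(40, 24), seed = 99)
  sim <- simulate_dataset(cfg)
  model <- sim$truth$true_model
  out <- assign_modes(sim$dataset, model, hex_group(), pg6(),
                      cell = cfg$cell, low_res_cutoff = 20)
  for (i in c(1L, 7L, 25L)) {
    p <- sim$dataset$patterns[[i]]
    for (t in 1:2) {
      ref <- pattern_model_correlation(p, model, hex_group()$operators[[t]],
                                       pg6(), cell = cfg$cell,
                                       low_res_cutoff = 20)
      row <- out$correlations[out$correlations$pattern_id == p$id &
                              out$correlations$mode == t, ]
      expect_equal(row$r, ref$r, tolerance = 1e-12)
      expect_equal(row$n_common, ref$n_common)
    }
  }
})

test_that("merging averages observations and conserves intensity", {
  g <- hex_group(); pg <- pg6()
  p1 <- pattern("p1", rbind(c(1L, 0L, 0L), c(2L, 1L, 1L)), c(2, 7))
  p2 <- pattern("p2", rbind(c(1L, 0L, 0L)), 4)
  ds <- dataset(list(p1, p2))
  asg <- data.frame(pattern_id = c("p1", "p2"), mode = c(1L, 1L))
  model <- merge_dataset(ds, asg, g, pg)
  key100 <- emdetwin:::.pack_hkl(asu_map(matrix(c(1L, 0L, 0L), 1), pg))
  row <- model[emdetwin:::.pack_hkl(as_miller(model)) == key100, ]
  expect_equal(row$mean_intensity, 3)
  expect_equal(row$n_obs, 2L)
  # conservation: total merged intensity equals total input intensity
  expect_equal(sum(model$sum_intensity), 2 + 7 + 4)
})

test_that("merging is gauge invariant", {
  set.seed(17)
  cfg <- sim_config(n_patterns = 30, reflections_per_pattern = 40,
                    cell = cell_hexagonal(40, 24), seed = 5)
  sim <- simulate_dataset(cfg)
  g <- hex_group(); pg <- pg6()
  asg <- data.frame(pattern_id = names(sim$truth$true_modes),
                    mode = sim$truth$true_modes)
  model <- merge_dataset(sim$dataset, asg, g, pg)
  # reindex every pattern by the twin law and flip every assignment
  flipped <- lapply(sim$dataset$patterns, function(p) {
    pattern(p$id, apply_operator(g$operators[[2]], as_miller(p$refl)),
            p$refl$intensity)
  })
  asg2 <- asg
  asg2$mode <- 3L - asg2$mode
  model2 <- merge_dataset(dataset(flipped), asg2, g, pg)
  expect_identical(as_miller(model2), as_miller(model))
  expect_equal(model2$mean_intensity, model$mean_intensity, tolerance = 1e-12)
  expect_identical(model2$n_obs, model$n_obs)
})

test_that("random models are reproducible, positive, and uncorrelated", {
  idx <- index_block(11L)
  a <- random_model(idx, seed = 101)
  b <- random_model(idx, seed = 101)
  expect_identical(a, b)
  expect_true(all(a$mean_intensity > 0 & a$mean_intensity < 1))
  c2 <- random_model(idx, seed = 202)
  expect_lt(abs(cor(a$mean_intensity, c2$mean_intensity)), 0.05)
  expect_gt(nrow(a), 1e4)
})

test_that("target_score averages the per-pattern best correlations", {
  corr <- data.frame(pattern_id = rep(c("a", "b"), each = 2),
                     mode = rep(1:2, 2), r = c(0.9, 0.3, 0.2, 0.8),
                     n_common = 10L)
  expect_equal(target_score(corr), 0.85)
  # patterns with no defined correlation are excluded from the average
  corr2 <- rbind(corr, data.frame(pattern_id = "c", mode = 1:2, r = NA_real_,
                                  n_common = 0L))
  expect_equal(target_score(corr2), 0.85)
  expect_error(target_score(corr2[corr2$pattern_id == "c", ]), "undefined")
  # independent re-implementation oracle
  set.seed(18)
  big <- data.frame(pattern_id = rep(sprintf("p%03d", 1:50), each = 2),
                    mode = rep(1:2, 50), r = runif(100, -1, 1), n_common = 20L)
  oracle <- mean(vapply(split(big$r, big$pattern_id), max, 0))
  expect_equal(target_score(big), oracle, tolerance = 1e-12)
})

test_that("run_em resolves the ambiguity in the noiseless limit", {
  # partiality identically 1, no noise: every pattern is an exact copy of
  # the truth under its mode
  cfg <- sim_config(n_patterns = 60, reflections_per_pattern = 50,
                    cell = cell_hexagonal(40, 24),
                    partiality_model = "resolution_dependent", p_floor = 1,
                    noise = "none", seed = 23)
  sim <- simulate_dataset(cfg)
  st <- run_em(sim$dataset, config = em_config(seed = 24, cell = cfg$cell))
  expect_true(st$converged)
  expect_lte(st$iteration, 3L)
  ls <- label_and_score(st, sim$dataset, sim$truth$true_model,
                        truth = sim$truth, cell = cfg$cell)
  expect_equal(ls$consistency_truth, 1)
  expect_equal(ls$consistency_reference, 1)
  expect_equal(ls$r_cim, 1, tolerance = 1e-9)
})

test_that("run_em with a single mode converges in one iteration to the plain merge", {
  set.seed(25)
  cfg <- sim_config(n_patterns = 10, reflections_per_pattern = 30,
                    cell = cell_hexagonal(40, 24), seed = 26)
  sim <- simulate_dataset(cfg, ambiguity_group(list(op_identity())))
  g1 <- ambiguity_group(list(op_identity()))
  st <- run_em(sim$dataset, g1, config = em_config(seed = 27, cell = cfg$cell))
  expect_true(st$converged)
  expect_equal(st$iteration, 1L)
  expect_equal(st$n_changed_history, 0L)
  plain <- merge_dataset(sim$dataset,
                         data.frame(pattern_id = st$assignments$pattern_id,
                                    mode = 1L), g1)
  expect_equal(st$model$mean_intensity, plain$mean_intensity)
})

test_that("run_em records one score and population row per iteration", {
  cfg <- sim_config(n_patterns = 80, reflections_per_pattern = 60,
                    cell = cell_hexagonal(40, 24), seed = 31)
  sim <- simulate_dataset(cfg)
  st <- run_em(sim$dataset, config = em_config(seed = 32, cell = cfg$cell))
  expect_length(st$score_history, st$iteration)
  expect_length(st$n_changed_history, st$iteration)
  expect_equal(nrow(st$mode_populations), st$iteration)
  expect_equal(rowSums(st$mode_populations), rep(80, st$iteration))
  expect_equal(st$n_changed_history[st$iteration], 0L)
  # determinism: same config reproduces the run exactly
  st2 <- run_em(sim$dataset, config = em_config(seed = 32, cell = cfg$cell))
  expect_equal(st2$assignments$mode, st$assignments$mode)
  expect_equal(st2$score_history, st$score_history)
})
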