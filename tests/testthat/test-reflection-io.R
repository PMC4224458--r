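test_that("unit cells validate their parameters", {
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, gamma = 181), "angles")
  expect_equal(cell_psi()$a, 281)
  expect_equal(cell_hexagonal(100, 50)$gamma, 120)
})

test_that("resolution_d matches the hexagonal closed form", {
  # axial reflection: d(0,0,l) = c/l
  expect_equal(resolution_d(c(0L, 0L, 1L), cell_hexagonal(90, 100)), 100)
  # 1/d^2 = 4 (h^2 + hk + k^2) / (3 a^2) + l^2 / c^2
  expect_equal(resolution_d(c(1L, 0L, 0L), cell_hexagonal(100, 50)),
               sqrt(3 * 100^2 / 4), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    a <- runif(1, 30, 300); cc <- runif(1, 30, 300)
    cell <- cell_hexagonal(a, cc)
    m <- random_indices(200L, 20L)
    closed <- 1 / sqrt(4 * (m[, 1]^2 + m[, 1] * m[, 2] + m[, 2]^2) / (3 * a^2) +
                       m[, 3]^2 / cc^2)
    expect_equal(resolution_d(m, cell), closed, tolerance = 1e-9)
  }
  # doubling every index halves the d-spacing for any cell
  cell <- unit_cell(50, 60, 70, 80, 95, 100)
  m <- random_indices(50L, 10L)
  expect_equal(resolution_d(2L * m, cell), resolution_d(m, cell) / 2,
               tolerance = 1e-12)
  expect_error(resolution_d(c(0L, 0L, 0L), cell), "resolution")
})

test_that("shell_filter uses a half-open [d_min, d_max) window", {
  cell <- cell_hexagonal(90, 20)
  # d(0,0,4) = 5 exactly, d(0,0,5) = 4
  block <- as_miller(rbind(c(0, 0, 3), c(0, 0, 4), c(0, 0, 5), c(0, 0, 6)))
  kept <- shell_filter(block, cell, 3, 5)
  expect_equal(kept[, "l"], c(5L, 6L))      # d = 4 and d = 10/3
  expect_error(shell_filter(block, cell, 5, 3), "d_min < d_max")
  # brute-force oracle on a dense block
  dense <- index_block(6L)
  d <- resolution_d(dense, cell)
  expect_equal(nrow(shell_filter(dense, cell, 2.5, 6)),
               sum(vapply(seq_len(nrow(dense)), function(i) {
                 di <- resolution_d(dense[i, ], cell)
                 di >= 2.5 && di < 6
               }, TRUE)))
})

test_that("read_reflection_table canonicalizes and averages duplicates", {
  path <- write_tmp(c("# pattern_id: demo", "1 0 0 10.0", "-1 0 0 20.0"))
  p <- read_reflection_table(path, point_group("1", friedel = TRUE))
  expect_s3_class(p, "pattern")
  expect_equal(p$id, "demo")
  expect_equal(nrow(p$refl), 1L)
  expect_equal(p$refl$intensity, 15)
  expect_equal(p$n_merged, 1L)

  path2 <- write_tmp("2 1 3 5.5 0.3")
  p2 <- read_reflection_table(path2, pg6())
  expect_equal(nrow(p2$refl), 1L)
  expect_equal(p2$refl$sigma, 0.3)
  expect_equal(p2$id, sub("\\.txt$", "", basename(path2)))

  bad <- write_tmp("a b c 1.0")
  expect_error(read_reflection_table(bad, pg6()), "line 1")
  empty <- write_tmp("# only a comment")
  expect_error(read_reflection_table(empty, pg6()), "no reflections")
})

test_that("dataset tables round-trip", {
  set.seed(21)
  pats <- lapply(1:3, function(i) {
    m <- asu_map(random_indices(20L, 8L), pg6())
    m <- m[!duplicated(emdetwin:::.pack_hkl(m)), , drop = FALSE]
    pattern(paste0("p", i), m, runif(nrow(m), 1, 100))
  })
  ds <- dataset(pats)
  path <- tempfile()
  write_dataset_table(ds, path)
  ds2 <- read_dataset_table(path, pg6())
  expect_equal(ds2$n_patterns, 3L)
  for (i in 1:3) {
    expect_equal(ds2$patterns[[i]]$id, ds$patterns[[i]]$id)
    a <- ds$patterns[[i]]$refl[order(ds$patterns[[i]]$refl$h,
                                     ds$patterns[[i]]$refl$k,
                                     ds$patterns[[i]]$refl$l), ]
    b <- ds2$patterns[[i]]$refl[order(ds2$patterns[[i]]$refl$h,
                                      ds2$patterns[[i]]$refl$k,
                                      ds2$patterns[[i]]$refl$l), ]
    expect_equal(b$intensity, a$intensity, tolerance = 1e-7)
  }
})

test_that("stream reader handles chunks with and without reflections", {
  stream <- c(
    "CrystFEL stream format 2.3",
    "----- Begin chunk -----",
    "Image filename: img_001.h5",
    "no indexing here",
    "----- End chunk -----",
    "----- Begin chunk -----",
    "Image filename: img_002.h5",
    "--- Begin crystal",
    "Reflections measured after indexing",
    "   h    k    l          I   sigma(I)",
    "   1    2    0     100.5       3.2",
    "   2    0    1      50.0       1.1",
    "  -1    3    2      25.0       0.9",
    "End of reflections",
    "--- End crystal",
    "----- End chunk -----")
  path <- write_tmp(stream)
  ds <- read_stream_subset(path, pg6())
  expect_equal(ds$n_patterns, 1L)
  expect_equal(attr(ds, "n_skipped"), 1L)
  expect_equal(ds$patterns[[1]]$id, "img_002.h5")
  expect_equal(nrow(ds$patterns[[1]]$refl), 3L)
  expect_setequal(ds$patterns[[1]]$refl$intensity, c(100.5, 50, 25))
  expect_error(read_stream_subset(write_tmp("no chunks here"), pg6()),
               "no chunks")
  # unparseable reflection line: chunk skipped with a warning
  broken <- sub("   2    0    1      50.0       1.1", "   2    0    X      50.0",
                stream)
  expect_warning(expect_error(read_stream_subset(write_tmp(broken), pg6()),
                              "no chunks with reflection blocks"),
                 "skipping chunk")
})

test_that("merged models round-trip through write_model/read_model", {
  set.seed(31)
  m <- asu_map(random_indices(50L, 9L), pg6())
  m <- m[!duplicated(emdetwin:::.pack_hkl(m)), , drop = FALSE]
  model <- merged_model(m, runif(nrow(m), 0, 5000), sample(1:20, nrow(m), TRUE))
  expect_equal(model$mean_intensity, model$sum_intensity / model$n_obs)
  path <- tempfile()
  write_model(model, path, comments = "synthetic fixture")
  back <- read_model(path)
  expect_identical(as_miller(back), as_miller(model))
  expect_identical(back$n_obs, model$n_obs)
  expect_equal(back$mean_intensity, model$mean_intensity, tolerance = 1e-7)
  expect_error(write_model(model[0, ], tempfile()), "empty")
})
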