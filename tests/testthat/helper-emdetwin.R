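# shared fixtures: all synthetic, built in code

hex_group <- function() ambiguity_group()
pg6 <- function() point_group("6")

# a small index block, origin excluded
index_block <- function(n = 4L) {
  g <- as.matrix(expand.grid(h = -n:n, k = -n:n, l = -n:n))
  as_miller(g[rowSums(g != 0) > 0L, , drop = FALSE])
}

# random integer indices avoiding the origin
random_indices <- function(n, max_idx = 30L) {
  m <- matrix(sample(seq(-max_idx, max_idx), 3L * n, replace = TRUE), ncol = 3L)
  m[rowSums(m != 0) == 0L, 1L] <- 1L
  as_miller(m)
}

# tiny deterministic pattern
toy_pattern <- function(id, hkl, intensity, ...) pattern(id, hkl, intensity, ...)

# write lines to a tempfile, return path
write_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
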