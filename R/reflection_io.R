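# Data model and text readers/writers for per-pattern partial-reflection
# lists and merged full-intensity models, plus resolution bookkeeping.

#' Unit cell
#'
#' @param a,b,c axis lengths in Angstrom (> 0).
#' @param alpha,beta,gamma angles in degrees, each in (0, 180).
#' @return object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) stop("cell angles must be in (0, 180) degrees")
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' @rdname unit_cell
#' @export
cell_hexagonal <- function(a, c) unit_cell(a, a, c, 90, 90, 120)

#' Photosystem-I-like hexagonal cell preset (a = b = 281, c = 165.2 Angstrom)
#' @rdname unit_cell
#' @export
cell_psi <- function() cell_hexagonal(281, 165.2)

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.2f b=%.2f c=%.2f  alpha=%.1f beta=%.1f gamma=%.1f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# reciprocal metric tensor: 1/d^2 = t(hkl) %*% Gstar %*% hkl
.reciprocal_metric <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  G <- matrix(c(cell$a^2,            cell$a * cell$b * cg, cell$a * cell$c * cb,
                cell$a * cell$b * cg, cell$b^2,            cell$b * cell$c * ca,
                cell$a * cell$c * cb, cell$b * cell$c * ca, cell$c^2), 3L, 3L)
  solve(G)
}

#' Resolution (d-spacing) of reflections
#'
#' Computes the crystallographic d-spacing in Angstrom from the general
#' reciprocal-metric tensor; for a hexagonal cell this reduces to
#' 1/d^2 = 4(h^2 + hk + k^2)/(3 a^2) + l^2/c^2.
#'
#' @param hkl Miller indices (vector or matrix); (0,0,0) is rejected.
#' @param cell a [unit_cell()].
#' @return numeric vector of d-spacings in Angstrom.
#' @export
resolution_d <- function(hkl, cell) {
  m <- as_miller(hkl)
  if (any(rowSums(m != 0L) == 0L)) stop("(0,0,0) has no resolution")
  Gs <- .reciprocal_metric(cell)
  q2 <- rowSums((m %*% Gs) * m)
  1 / sqrt(q2)
}

#' Select reflections within a resolution shell
#'
#' Keeps indices with d_min <= d < d_max (half-open on the high-d edge so
#' adjacent shells never double count).
#'
#' @param hkl Miller indices (matrix).
#' @param cell a [unit_cell()].
#' @param d_min,d_max shell bounds in Angstrom, 0 < d_min < d_max.
#' @return the retained subset of `hkl` (matrix).
#' @export
shell_filter <- function(hkl, cell, d_min, d_max) {
  if (!(d_min > 0 && d_min < d_max)) stop("need 0 < d_min < d_max")
  m <- as_miller(hkl)
  d <- resolution_d(m, cell)
  m[d >= d_min & d < d_max, , drop = FALSE]
}

#' Construct a diffraction pattern
#'
#' A pattern is one snapshot's list of partial reflection intensities.
#' When a point group is supplied the indices are mapped to canonical
#' asymmetric-unit representatives and duplicate observations of one
#' canonical index are averaged (sigma combined as the standard error of
#' the mean); the number of merged duplicates is kept in attribute
#' `n_merged`.
#'
#' @param id pattern identifier (unique within a dataset).
#' @param hkl Miller indices (n x 3).
#' @param intensity numeric vector of intensities (finite; may be slightly
#'   negative for background-subtracted experimental data).
#' @param sigma optional numeric vector of uncertainties (>= 0).
#' @param pg optional [point_group()] used to canonicalize at construction.
#' @param source provenance text (filename, chunk id).
#' @return object of class `pattern` with fields `id`, `refl`
#'   (data.frame h, k, l, intensity, sigma) and `source`.
#' @export
pattern <- function(id, hkl, intensity, sigma = NULL, pg = NULL, source = "") {
  m <- as_miller(hkl)
  if (length(intensity) != nrow(m)) stop("intensity length must match indices")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (!is.null(sigma)) {
    if (length(sigma) != nrow(m)) stop("sigma length must match indices")
    if (any(!is.finite(sigma)) || any(sigma < 0)) stop("sigma must be finite and >= 0")
  }
  n_merged <- 0L
  if (!is.null(pg)) {
    m <- asu_map(m, pg)
    key <- .pack_hkl(m)
    if (anyDuplicated(key)) {
      dt <- data.table(hklkey = key, intensity = intensity,
                       s2 = if (is.null(sigma)) NA_real_ else sigma^2)
      agg <- dt[, list(intensity = mean(intensity),
                       sigma = sqrt(sum(s2)) / .N, n = .N), by = "hklkey"]
      n_merged <- nrow(dt) - nrow(agg)
      m <- .unpack_hkl(agg$hklkey)
      intensity <- agg$intensity
      sigma <- if (is.null(sigma)) NULL else agg$sigma
    }
  }
  refl <- data.frame(h = m[, 1L], k = m[, 2L], l = m[, 3L],
                     intensity = intensity)
  if (!is.null(sigma)) refl$sigma <- sigma
  structure(list(id = as.character(id), refl = refl, source = source,
                 n_merged = n_merged),
            class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat("<pattern>", x$id, "-", nrow(x$refl), "reflections\n")
  invisible(x)
}

#' Construct a dataset of patterns
#'
#' @param patterns list of [pattern()] objects with unique, non-empty ids.
#' @return object of class `dataset` with `patterns` and `n_patterns`.
#' @export
dataset <- function(patterns) {
  if (!length(patterns)) stop("dataset must contain at least one pattern")
  ids <- vapply(patterns, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("pattern ids must be unique")
  if (any(vapply(patterns, function(p) nrow(p$refl), 0L) == 0L))
    stop("patterns admitted to a dataset must be non-empty")
  structure(list(patterns = patterns, n_patterns = length(patterns)),
            class = "dataset")
}

#' @export
print.dataset <- function(x, ...) {
  nr <- vapply(x$patterns, function(p) nrow(p$refl), 0L)
  cat("<dataset>", x$n_patterns, "patterns,",
      sum(nr), "reflections (median", stats::median(nr), "per pattern)\n")
  invisible(x)
}

# parse "h k l I [sigma]" data rows; returns list(hkl, intensity, sigma)
.parse_refl_lines <- function(lines, lineno, path) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt < 4L | nt > 5L)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- sort(unique(c(bad, which(vapply(vals, anyNA, TRUE)))))
  if (length(bad))
    stop(sprintf("%s: malformed reflection line %d: '%s'",
                 path, lineno[bad[1L]], lines[bad[1L]]))
  hkl <- t(vapply(vals, function(v) v[1:3], numeric(3L)))
  if (any(hkl != round(hkl)))
    stop(sprintf("%s: non-integer Miller index at line %d", path,
                 lineno[which(rowSums(hkl != round(hkl)) > 0)[1L]]))
  intensity <- vapply(vals, `[[`, 0, 4L)
  sigma <- if (all(nt == 5L)) vapply(vals, `[[`, 0, 5L) else NULL
  list(hkl = hkl, intensity = intensity, sigma = sigma)
}

#' Read a native reflection table as one pattern
#'
#' The native format is a whitespace-separated text table with rows
#' `h k l I [sigma]`; lines starting with `#` are comments.  A comment of
#' the form `# pattern_id: X` sets the pattern id, otherwise the filename
#' stem is used.  Indices are ASU-canonicalized and duplicate observations
#' (including Friedel mates when the point group identifies them) are
#' averaged.
#'
#' @param path file path.
#' @param pg a [point_group()] for canonicalization.
#' @return a [pattern()].
#' @export
read_reflection_table <- function(path, pg = point_group("6")) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  id_line <- grep("^#\\s*pattern_id:", lines, value = TRUE)
  id <- if (length(id_line)) trimws(sub("^#\\s*pattern_id:", "", id_line[1L]))
        else sub("\\.[^.]*$", "", basename(path))
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop(path, ": no reflections")
  p <- .parse_refl_lines(lines[keep], lineno[keep], path)
  pattern(id, p$hkl, p$intensity, p$sigma, pg = pg, source = path)
}

#' Write a pattern as a native reflection table
#'
#' @param p a [pattern()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_reflection_table <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pattern_id: ", p$id), con)
  r <- p$refl
  if (!is.null(r$sigma))
    writeLines(sprintf("%d %d %d %.8g %.8g", r$h, r$k, r$l, r$intensity, r$sigma), con)
  else
    writeLines(sprintf("%d %d %d %.8g", r$h, r$k, r$l, r$intensity), con)
  invisible(path)
}

#' Read a multi-pattern native table as a dataset
#'
#' Concatenated native tables separated by `# pattern_id:` comment lines.
#'
#' @inheritParams read_reflection_table
#' @return a [dataset()].
#' @export
read_dataset_table <- function(path, pg = point_group("6")) {
  lines <- readLines(path)
  starts <- grep("^#\\s*pattern_id:", lines)
  if (!length(starts)) return(dataset(list(read_reflection_table(path, pg))))
  ends <- c(starts[-1L] - 1L, length(lines))
  pats <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    blk <- starts[i]:ends[i]
    id <- trimws(sub("^#\\s*pattern_id:", "", lines[starts[i]]))
    keep <- blk[!grepl("^\\s*(#|$)", lines[blk])]
    if (!length(keep)) stop(path, ": pattern '", id, "' has no reflections")
    p <- .parse_refl_lines(lines[keep], keep, path)
    pats[[i]] <- pattern(id, p$hkl, p$intensity, p$sigma, pg = pg, source = path)
  }
  dataset(pats)
}

#' Write a dataset as a concatenated native table
#'
#' @param ds a [dataset()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_dataset_table <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in ds$patterns) {
    writeLines(paste0("# pattern_id: ", p$id), con)
    r <- p$refl
    if (!is.null(r$sigma))
      writeLines(sprintf("%d %d %d %.8g %.8g", r$h, r$k, r$l, r$intensity, r$sigma), con)
    else
      writeLines(sprintf("%d %d %d %.8g", r$h, r$k, r$l, r$intensity), con)
  }
  invisible(path)
}

#' Read a tolerant subset of the CrystFEL stream format
#'
#' Chunks are delimited by `----- Begin chunk -----` / `----- End chunk
#' -----`; within a chunk, a reflection block runs from a line containing
#' `Reflections measured after indexing` to one containing
#' `End of reflections`, with whitespace-separated columns whose first four
#' are h, k, l, I (a fifth numeric column is read as sigma).  A column
#' header line beginning `h k l` is skipped.  Chunks without a reflection
#' block (no indexing solution) are skipped and counted; a chunk with an
#' unparseable reflection line is skipped with a warning.  Geometry, cell
#' and peak-list sections are ignored.
#'
#' @param path file path.
#' @param pg a [point_group()] for canonicalization.
#' @return a [dataset()], with the number of skipped chunks in attribute
#'   `n_skipped`.
#' @export
read_stream_subset <- function(path, pg = point_group("6")) {
  lines <- readLines(path)
  begins <- grep("----- Begin chunk -----", lines, fixed = TRUE)
  endsc <- grep("----- End chunk -----", lines, fixed = TRUE)
  if (!length(begins)) stop(path, ": no chunks found")
  pats <- list()
  n_skipped <- 0L
  for (i in seq_along(begins)) {
    lo <- begins[i]
    hi <- endsc[endsc > lo]
    hi <- if (length(hi)) hi[1L] else length(lines)
    blk <- lines[lo:hi]
    rb <- grep("Reflections measured after indexing", blk)
    re <- grep("End of reflections", blk)
    if (!length(rb) || !length(re) || re[1L] <= rb[1L] + 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows <- blk[(rb[1L] + 1L):(re[1L] - 1L)]
    rows <- rows[!grepl("^\\s*h\\s+k\\s+l", rows)]     # column header
    rows <- rows[!grepl("^\\s*$", rows)]
    id_line <- grep("^Image filename:", blk, value = TRUE)
    id <- if (length(id_line)) trimws(sub("^Image filename:", "", id_line[1L]))
          else sprintf("chunk_%04d", i)
    p <- tryCatch({
      toks <- strsplit(trimws(rows), "[ \t]+")
      vals <- suppressWarnings(lapply(toks, function(t) as.numeric(t[1:4])))
      if (any(vapply(vals, anyNA, TRUE))) stop("unparseable reflection line")
      hkl <- t(vapply(vals, function(v) v[1:3], numeric(3L)))
      pattern(id, hkl, vapply(vals, `[[`, 0, 4L), pg = pg, source = path)
    }, error = function(e) {
      warning(path, ": skipping chunk ", i, " (", conditionMessage(e), ")")
      NULL
    })
    if (is.null(p)) n_skipped <- n_skipped + 1L else pats[[length(pats) + 1L]] <- p
  }
  if (!length(pats)) stop(path, ": no chunks with reflection blocks")
  ds <- dataset(pats)
  attr(ds, "n_skipped") <- n_skipped
  ds
}

#' Construct a merged full-intensity model
#'
#' The model is the Monte Carlo accumulator over canonical Miller indices:
#' for each index it stores the running intensity sum, the number of
#' observations, and their mean (the full-intensity estimate).
#'
#' @param hkl canonical Miller indices (n x 3).
#' @param sum_intensity per-index intensity sums.
#' @param n_obs per-index observation counts (>= 0; entries with 0 counts
#'   are invisible to correlations).
#' @return object of class `merged_model`: a data.frame with columns
#'   `h, k, l, sum_intensity, n_obs, mean_intensity`, sorted by (h, k, l).
#' @export
merged_model <- function(hkl, sum_intensity, n_obs) {
  m <- as_miller(hkl)
  if (length(sum_intensity) != nrow(m) || length(n_obs) != nrow(m))
    stop("field lengths must match")
  df <- data.frame(h = m[, 1L], k = m[, 2L], l = m[, 3L],
                   sum_intensity = as.numeric(sum_intensity),
                   n_obs = as.integer(n_obs))
  df$mean_intensity <- ifelse(df$n_obs > 0L, df$sum_intensity / df$n_obs, NA_real_)
  df <- df[order(df$h, df$k, df$l), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("merged_model", "data.frame")
  df
}

# model from known means (e.g. a simulated ground truth), n_obs = 1
.model_from_means <- function(hkl, means) merged_model(hkl, means, rep(1L, nrow(as_miller(hkl))))

#' Write a merged model to a text file
#'
#' Rows are `h k l mean_intensity n_obs`, sorted by (h,k,l); intensities
#' are printed with `%.8g`.  Header comment lines carry free-form metadata.
#'
#' @param model a [merged_model()] (non-empty).
#' @param path output file path.
#' @param comments character vector written as `# ` header lines.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path, comments = character()) {
  if (!nrow(model)) stop("refusing to write an empty model")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# merged intensity model: h k l mean_intensity n_obs",
               if (length(comments)) paste0("# ", comments)), con)
  writeLines(sprintf("%d %d %d %.8g %d", model$h, model$k, model$l,
                     model$mean_intensity, model$n_obs), con)
  invisible(path)
}

#' Read a merged model written by [write_model()]
#'
#' @param path file path.
#' @return a [merged_model()].
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop(path, ": empty model file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  vals <- suppressWarnings(lapply(toks, as.numeric))
  if (any(vapply(vals, anyNA, TRUE)) || any(lengths(vals) != 5L))
    stop(path, ": malformed model row")
  hkl <- t(vapply(vals, function(v) v[1:3], numeric(3L)))
  mean_i <- vapply(vals, `[[`, 0, 4L)
  n_obs <- as.integer(vapply(vals, `[[`, 0, 5L))
  merged_model(hkl, mean_i * n_obs, n_obs)
}
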