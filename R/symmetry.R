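# Reindexing operators act on Miller indices (h,k,l) as column vectors.
# All operators are integer matrices with determinant +/-1 so the
# reciprocal lattice maps onto itself.

#' Coerce to a Miller-index matrix
#'
#' Accepts a length-3 integer vector or an n x 3 matrix/data.frame and
#' returns an n x 3 integer matrix with columns `h`, `k`, `l`.  The origin
#' (0,0,0) is allowed in storage; operations that would be degenerate on it
#' (resolution, ASU mapping) reject it explicitly.
#'
#' @param hkl length-3 vector, n x 3 matrix, or data.frame with columns
#'   h, k, l.
#' @return n x 3 integer matrix.
#' @export
as_miller <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  if (is.null(dim(hkl))) {
    if (length(hkl) != 3L) stop("a single Miller index must have 3 components")
    hkl <- matrix(hkl, nrow = 1L)
  }
  hkl <- as.matrix(hkl)
  if (ncol(hkl) != 3L) stop("Miller indices must have 3 columns (h, k, l)")
  if (anyNA(hkl) || any(!is.finite(hkl)) || any(hkl != round(hkl)))
    stop("Miller indices must be finite integers")
  storage.mode(hkl) <- "integer"
  colnames(hkl) <- c("h", "k", "l")
  rownames(hkl) <- NULL
  hkl
}

#' Create a reindexing (twin-law) operator
#'
#' @param mat 3 x 3 integer matrix acting on (h,k,l) as a column vector;
#'   its determinant must be +1 or -1 (lattice-preserving).
#' @param label short text label.
#' @return object of class `reindex_op`.
#' @examples
#' twin_law_hex()                       # (h,k,l) -> (k,h,-l)
#' apply_operator(twin_law_hex(), c(1, 2, 0))
#' @export
reindex_op <- function(mat, label = "op") {
  mat <- matrix(as.numeric(mat), 3L, 3L)
  if (anyNA(mat) || any(mat != round(mat)))
    stop("operator matrix must be integer")
  d <- round(det(mat))
  if (abs(d) != 1L)
    stop("operator determinant must be +1 or -1 (got ", d, ")")
  storage.mode(mat) <- "integer"
  structure(list(mat = mat, label = label), class = "reindex_op")
}

#' @export
print.reindex_op <- function(x, ...) {
  cat("<reindex_op>", x$label, "\n")
  print(x$mat)
  invisible(x)
}

#' The identity operator
#' @return a `reindex_op`.
#' @export
op_identity <- function() reindex_op(diag(3L), "identity")

#' The hexagonal merohedral twin law (h,k,l) -> (k,h,-l)
#'
#' Standard twin operator for point group 6 (e.g. space group P6_3); in the
#' l = 0 zone it exchanges (h,k,0) and (k,h,0), which is exactly the
#' equivalence an auto-indexer cannot resolve for such crystals.
#' @return a `reindex_op`.
#' @export
twin_law_hex <- function() {
  reindex_op(matrix(c(0, 1, 0,
                      1, 0, 0,
                      0, 0, -1), 3L, 3L, byrow = TRUE), "twin")
}

#' Apply a reindexing operator to Miller indices
#'
#' @param op a `reindex_op`.
#' @param hkl Miller indices (vector or matrix, see [as_miller()]).
#' @return reindexed indices, same shape as the input.
#' @export
apply_operator <- function(op, hkl) {
  was_vec <- is.null(dim(hkl)) && !is.data.frame(hkl)
  m <- as_miller(hkl)
  out <- m %*% t(op$mat)
  storage.mode(out) <- "integer"
  colnames(out) <- c("h", "k", "l")
  if (was_vec) out[1L, ] else out
}

# closure of a set of 3x3 integer matrices under multiplication
.close_group <- function(mats, max_order = 96L) {
  keyof <- function(m) paste(as.integer(m), collapse = ",")
  out <- list(diag(3L))
  names(out) <- keyof(diag(3L))
  queue <- mats
  while (length(queue)) {
    m <- queue[[1L]]; queue <- queue[-1L]
    k <- keyof(m)
    if (!is.null(out[[k]])) next
    out[[k]] <- m
    if (length(out) > max_order) stop("point group does not close (order > ", max_order, ")")
    for (g in out) {
      queue <- c(queue, list(m %*% g), list(g %*% m))
    }
  }
  lapply(unname(out), function(m) { storage.mode(m) <- "integer"; m })
}

#' Merging point group
#'
#' The proper rotations used to map every observation of a Bragg reflection
#' to one canonical asymmetric-unit representative before merging.  Two
#' named groups are built in: `"1"` (identity only) and `"6"` (the six
#' rotations about the c axis in the hexagonal setting, appropriate for
#' P6_3 data).  An explicit list of 3 x 3 integer matrices is also accepted
#' and closed under composition.
#'
#' @param spec `"1"`, `"6"`, or a list of 3 x 3 integer matrices.
#' @param friedel logical; also identify Friedel mates (hkl and -h,-k,-l)
#'   during canonicalization.  Default `TRUE`.
#' @return object of class `point_group` with fields `operators` (list of
#'   matrices, identity first) and `include_friedel`.
#' @export
point_group <- function(spec = "6", friedel = TRUE) {
  if (is.character(spec)) {
    ops <- switch(spec,
      "1" = list(diag(3L)),
      "6" = .close_group(list(matrix(c(0, -1, 0,
                                       1, 1, 0,
                                       0, 0, 1), 3L, 3L, byrow = TRUE))),
      stop("unknown point group name: ", spec)
    )
    name <- spec
  } else {
    ops <- .close_group(spec)
    name <- "custom"
  }
  structure(list(name = name, operators = ops, include_friedel = isTRUE(friedel)),
            class = "point_group")
}

#' @export
print.point_group <- function(x, ...) {
  cat("<point_group>", x$name, "-", length(x$operators), "proper operations,",
      if (x$include_friedel) "Friedel pairs identified" else "no Friedel pairing", "\n")
  invisible(x)
}

#' Ambiguity group of candidate indexing modes
#'
#' The ordered set of reindexing operators among which the EM algorithm
#' chooses one mode per pattern.  The first operator must be the identity;
#' for the two-mode (twin-like) case the second operator must be an
#' involution.  The default is the P6_3-type pair
#' \{identity, (h,k,l) -> (k,h,-l)\}.
#'
#' @param operators list of [reindex_op()] objects, identity first.
#' @return object of class `ambiguity_group` with `operators` and `n_modes`.
#' @export
ambiguity_group <- function(operators = list(op_identity(), twin_law_hex())) {
  if (!length(operators)) stop("at least one operator required")
  if (!all(vapply(operators, inherits, logical(1L), "reindex_op")))
    stop("operators must be reindex_op objects")
  g <- structure(list(operators = operators, n_modes = length(operators)),
                 class = "ambiguity_group")
  ok <- validate_group(g)
  if (!ok) stop("invalid ambiguity group: ",
                paste(attr(ok, "diagnostics"), collapse = "; "))
  g
}

#' @export
print.ambiguity_group <- function(x, ...) {
  cat("<ambiguity_group>", x$n_modes, "indexing modes:",
      paste(vapply(x$operators, `[[`, "", "label"), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an ambiguity group
#'
#' Checks that the first operator is the identity, that every operator is
#' lattice-preserving (determinant +/-1), and that in the two-mode case the
#' non-identity operator is an involution (the twin law applied twice is
#' the identity).
#'
#' @param g an `ambiguity_group` (or a bare list with the same fields).
#' @return `TRUE`, or `FALSE` with a character vector of diagnostics in
#'   attribute `"diagnostics"`.
#' @export
validate_group <- function(g) {
  diags <- character()
  ops <- g$operators
  if (!all(ops[[1L]]$mat == diag(3)))
    diags <- c(diags, "first operator is not the identity")
  for (i in seq_along(ops)) {
    d <- round(det(ops[[i]]$mat))
    if (abs(d) != 1L)
      diags <- c(diags, sprintf("operator %d has determinant %d", i, d))
  }
  if (length(ops) == 2L) {
    sq <- ops[[2L]]$mat %*% ops[[2L]]$mat
    if (!all(sq == diag(3L)))
      diags <- c(diags, "two-mode group: second operator is not an involution")
  }
  if (length(diags)) structure(FALSE, diagnostics = diags) else TRUE
}

# index of op_a %*% op_b within the group's operator list (mode composition)
.compose_mode <- function(g, a, b) {
  m <- g$operators[[a]]$mat %*% g$operators[[b]]$mat
  for (i in seq_len(g$n_modes)) if (all(g$operators[[i]]$mat == m)) return(i)
  stop("ambiguity group is not closed under composition")
}

#' Map Miller indices to canonical asymmetric-unit representatives
#'
#' Every index is replaced by the lexicographically greatest member of its
#' orbit under the point-group rotations (and, if `friedel` is set on the
#' group, the inversion).  The map is idempotent and constant on orbits, so
#' multiple measurements of one Bragg reflection land in one accumulator
#' when merging.
#'
#' @param hkl Miller indices (vector or matrix).
#' @param pg a [point_group()].
#' @return canonical indices, same shape as input.
#' @export
asu_map <- function(hkl, pg) {
  was_vec <- is.null(dim(hkl)) && !is.data.frame(hkl)
  m <- as_miller(hkl)
  if (any(rowSums(m != 0L) == 0L))
    stop("degenerate reflection (0,0,0) has no asymmetric-unit representative")
  ops <- pg$operators
  if (pg$include_friedel) ops <- c(ops, lapply(ops, function(x) -x))
  # dynamic packing offset: orbit images are bounded by the operator row sums
  C <- max(abs(m)) * max(vapply(ops, function(x) max(rowSums(abs(x))), 0)) + 1
  best <- m %*% t(ops[[1L]])
  bestkey <- .pack_hkl(best, C)
  for (op in ops[-1L]) {
    img <- m %*% t(op)
    key <- .pack_hkl(img, C)
    sel <- key > bestkey
    if (any(sel)) {
      best[sel, ] <- img[sel, , drop = FALSE]
      bestkey[sel] <- key[sel]
    }
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  if (was_vec) best[1L, ] else best
}
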