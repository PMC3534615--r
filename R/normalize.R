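# Contact-map normalization: SCN and its alternatives, distance detrending,
# low-signal filtering, correlation maps, binning and the visualization blur.

#' Remove fragments with low interaction signal
#'
#' Masks out rows/columns whose Euclidean norm (over the matrix's scope) is
#' below `threshold`; these are fragments too weakly detected for a
#' normalization that gives every fragment equal weight. A zero row is
#' removed at any positive threshold; `threshold = 0` is the identity.
#'
#' @param cm A `ContactMatrix` (or bare matrix) of raw counts.
#' @param threshold Euclidean-norm cutoff (default 30).
#' @return The filtered matrix; removed count in `attr(, "n_removed")` and
#'   removed fragment ids (when available) in `attr(, "removed_ids")`.
#' @export
filter_low_norm <- function(cm, threshold = 30) {
  v <- .cm_values(cm)
  norms <- sqrt(rowSums(v^2))
  keep <- norms >= threshold
  if (!any(keep)) stop("filter_low_norm: all fragments removed at threshold ",
                       threshold)
  removed_ids <- if (is(cm, "ContactMatrix") && !is.null(cm$index$fragment_id))
    cm$index$fragment_id[!keep] else which(!keep)
  out <- .cm_rewrap(cm, v[keep, keep, drop = FALSE],
                    note = sprintf("filter_low_norm(%g): removed %d", threshold,
                                   sum(!keep)),
                    index = if (is(cm, "ContactMatrix"))
                      cm$index[keep, , drop = FALSE] else NULL)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_ids") <- removed_ids
  out
}

#' Sequential Component Normalization (SCN)
#'
#' Alternately normalizes every column then every row vector to unit
#' Euclidean norm, repeating the sweep until all row and column norms are
#' within `tol` of 1, then symmetrizes the result as `(M + t(M)) / 2`.
#' For the dense positive matrices arising from contact maps, convergence is
#' typically reached in two or three sweeps; it is not guaranteed for
#' arbitrary matrices, so hitting `max_iter` raises a condition of class
#' `scn_non_convergence` carrying the residual deviation.
#'
#' @param cm A `ContactMatrix` or matrix; must have no zero row/column
#'   (apply [filter_low_norm()] first).
#' @param tol Convergence tolerance on `| ||.||_2 - 1 |` (default 1e-3).
#' @param max_iter Maximum number of column+row sweeps.
#' @return `list(matrix, n_iterations, deviation)`; `n_iterations` counts
#'   column+row sweeps actually performed (0 if already normalized).
#' @export
scn <- function(cm, tol = 1e-3, max_iter = 50L) {
  v <- .cm_values(cm)
  zr <- which(rowSums(v^2) == 0)
  zc <- which(colSums(v^2) == 0)
  if (length(zr) || length(zc))
    stop("scn: zero row/column at index ",
         paste(unique(c(zr, zc)), collapse = ", "))
  it <- 0L
  repeat {
    dev <- max(abs(c(sqrt(rowSums(v^2)), sqrt(colSums(v^2))) - 1))
    if (dev < tol) break
    if (it >= max_iter) {
      cond <- structure(class = c("scn_non_convergence", "error", "condition"),
                        list(message = sprintf(
                          "SCN did not converge in %d sweeps (deviation %.3g, tol %.3g)",
                          max_iter, dev, tol), call = sys.call()))
      stop(cond)
    }
    v <- sweep(v, 2L, sqrt(colSums(v^2)), "/")
    v <- sweep(v, 1L, sqrt(rowSums(v^2)), "/")
    it <- it + 1L
  }
  v <- (v + t(v)) / 2
  dev <- max(abs(c(sqrt(rowSums(v^2)), sqrt(colSums(v^2))) - 1))
  list(matrix = .cm_rewrap(cm, v, note = sprintf("scn(tol=%g): %d sweeps", tol, it)),
       n_iterations = it, deviation = dev)
}

#' Norm-product normalization
#'
#' One-shot alternative to SCN: divides each element by the product of the
#' Euclidean norms of its row and column, `c*_ij = c_ij / (||row_i|| *
#' ||col_j||)`. The result is symmetric for symmetric input but its rows are
#' not unit vectors (e.g. an all-ones 2x2 input maps to entries 1/2 with row
#' norm 1/sqrt(2)), which is SCN's raison d'etre.
#'
#' @inheritParams scn
#' @export
norm_product <- function(cm) {
  v <- .cm_values(cm)
  rn <- sqrt(rowSums(v^2)); cn <- sqrt(colSums(v^2))
  if (any(rn == 0) || any(cn == 0)) stop("norm_product: zero row/column norm")
  .cm_rewrap(cm, v / outer(rn, cn), note = "norm_product")
}

#' Marginal-sum normalization
#'
#' Divides each element by the product of its row and column sums,
#' `c*_ij = c_ij / (sum_k c_ik * sum_k c_kj)` — the L1 analogue of
#' [norm_product()], which weights towards fragments with few interactions
#' and yields lower-contrast maps than SCN.
#'
#' @inheritParams scn
#' @export
marginal_sum <- function(cm) {
  v <- .cm_values(cm)
  rs <- rowSums(v); cs <- colSums(v)
  if (any(rs == 0) || any(cs == 0)) stop("marginal_sum: zero row/column sum")
  .cm_rewrap(cm, v / outer(rs, cs), note = "marginal_sum")
}

#' Divide an intra-chromosomal map by its genomic-distance expectation
#'
#' `c_ij <- c_ij / E(D_g(i, j))` where `E` is the fitted expectation from
#' [distance_expectation()]. This removes the polymer distance decay so that
#' distance-independent enrichments stand out; SCN can be applied afterwards.
#'
#' @param cm An intra-scope `ContactMatrix` with a `chrom`/`mid` index.
#' @param expectation A `DistanceExpectation`.
#' @return The normalized `ContactMatrix`.
#' @export
distance_normalize <- function(cm, expectation) {
  stopifnot(is(cm, "ContactMatrix"))
  v <- cm$values
  mid <- cm$index$mid
  same <- outer(cm$index$chrom, cm$index$chrom, "==")
  off <- same & upper.tri(v)
  dg <- abs(outer(mid, mid, "-"))[off]
  e <- expected_contacts(expectation, dg)
  if (any(!is.finite(e)) || any(e <= 0))
    stop("distance_normalize: non-positive fitted expectation (clamping failed)")
  vv <- v
  vv[off] <- v[off] / e
  vv[lower.tri(vv)] <- t(vv)[lower.tri(vv)]
  .cm_rewrap(cm, vv, note = "distance_normalize")
}

#' Pearson correlation map
#'
#' Entry `(i, j)` is the Pearson correlation of rows `i` and `j` of the
#' (normalized) contact matrix; the diagonal is 1 and values lie in
#' `[-1, 1]`. Zero-variance rows produce `NA` entries and a warning.
#'
#' @param cm A `ContactMatrix` (or matrix) with at least 3 retained rows.
#' @export
correlation_map <- function(cm) {
  v <- .cm_values(cm)
  if (nrow(v) < 3L) stop("correlation_map needs >= 3 retained fragments")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) warning(sum(sds == 0),
                             " zero-variance row(s): correlations undefined (NA)")
  cc <- suppressWarnings(stats::cor(t(v)))
  diag(cc)[sds > 0] <- 1
  .cm_rewrap(cm, cc, note = "correlation_map")
}

#' Bin a contact matrix over consecutive fragments
#'
#' Sums counts over non-overlapping runs of `b` consecutive fragments per
#' chromosome (the final partial bin is retained), as used to densify sparse
#' large-genome maps. `b = 1` is the identity. Total mass is conserved.
#'
#' @param cm A `ContactMatrix` with a `chrom` index.
#' @param b Fragments per bin (>= 1).
#' @export
bin_matrix <- function(cm, b) {
  stopifnot(is(cm, "ContactMatrix"), b >= 1)
  b <- as.integer(b)
  chrom <- cm$index$chrom
  grp <- integer(length(chrom))
  offset <- 0L
  for (c0 in unique(chrom)) {
    rows <- which(chrom == c0)
    grp[rows] <- offset + (seq_along(rows) - 1L) %/% b + 1L
    offset <- max(grp[rows])
  }
  g <- factor(grp, levels = unique(grp))
  vb <- rowsum(cm$values, g)
  vb <- t(rowsum(t(vb), g))
  dimnames(vb) <- NULL
  idx <- data.frame(
    bin = seq_len(nlevels(g)),
    chrom = as.vector(tapply(chrom, g, function(x) x[1L])),
    start = as.vector(tapply(cm$index$start, g, min)),
    end = as.vector(tapply(cm$index$end, g, max)),
    mid = as.vector(tapply(cm$index$mid, g, mean)),
    n_frags = as.integer(table(g)),
    stringsAsFactors = FALSE)
  rownames(idx) <- NULL
  .cm_rewrap(cm, vb, note = sprintf("bin_matrix(%d)", b), index = idx)
}

#' Visualization blur
#'
#' Repeated convolution with the uniform 3x3 kernel of value 0.05 (kernel
#' sum 0.45, so intensity is deliberately not preserved) with zero padding at
#' the edges. For display only; never feed blurred matrices to analysis.
#'
#' @param cm Matrix or `ContactMatrix`.
#' @param reps Number of convolution passes (default 10).
#' @export
blur <- function(cm, reps = 10L) {
  v <- .cm_values(cm)
  n <- nrow(v); m <- ncol(v)
  for (r in seq_len(reps)) {
    p <- matrix(0, n + 2L, m + 2L)
    p[2:(n + 1L), 2:(m + 1L)] <- v
    s <- p[1:n, 1:m] + p[1:n, 2:(m + 1L)] + p[1:n, 3:(m + 2L)] +
      p[2:(n + 1L), 1:m] + p[2:(n + 1L), 2:(m + 1L)] + p[2:(n + 1L), 3:(m + 2L)] +
      p[3:(n + 2L), 1:m] + p[3:(n + 2L), 2:(m + 1L)] + p[3:(n + 2L), 3:(m + 2L)]
    v <- 0.05 * s
  }
  .cm_rewrap(cm, v, note = sprintf("blur(%d)", reps))
}
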